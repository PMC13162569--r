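# Independent oracles and fixture builders used across the suite.
# Everything here is deliberately written by a different route than the
# package implementation it checks.

# seeded random binary mask
random_mask <- function(h, w, p = 0.4) matrix(stats::runif(h * w) < p, h, w)

# 8-connected component count by explicit breadth-first flood fill
flood_fill_count <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  seen <- matrix(FALSE, H, W)
  count <- 0L
  for (r0 in seq_len(H)) for (c0 in seq_len(W)) {
    if (!mask[r0, c0] || seen[r0, c0]) next
    count <- count + 1L
    queue <- list(c(r0, c0)); seen[r0, c0] <- TRUE
    while (length(queue)) {
      rc <- queue[[length(queue)]]; queue[[length(queue)]] <- NULL
      for (dr in -1:1) for (dc in -1:1) {
        r <- rc[1] + dr; c <- rc[2] + dc
        if (r >= 1 && r <= H && c >= 1 && c <= W && mask[r, c] && !seen[r, c]) {
          seen[r, c] <- TRUE
          queue[[length(queue) + 1L]] <- c(r, c)
        }
      }
    }
  }
  count
}

# streaming (Welford) mean / sample-variance, plus an explicit sort median
streaming_summary <- function(x) {
  n <- 0; mean <- 0; m2 <- 0
  for (v in x) {
    n <- n + 1
    d <- v - mean
    mean <- mean + d / n
    m2 <- m2 + d * (v - mean)
  }
  s <- sort(x)
  med <- if (n %% 2 == 1) s[(n + 1) / 2] else (s[n / 2] + s[n / 2 + 1]) / 2
  list(mean = mean, median = med, sd = if (n > 1) sqrt(m2 / (n - 1)) else 0)
}

# Brute-force average precision: at every top-k cutoff, redo the greedy
# confidence-ordered matching from scratch, then apply the 101-point
# interpolation definition directly.
brute_force_ap <- function(preds, gts, threshold) {
  n_gt <- length(gts)
  if (n_gt == 0L || !length(preds)) return(0)
  conf <- vapply(preds, function(p) p$confidence, numeric(1))
  preds <- preds[order(-conf)]
  match_topk <- function(k) {
    matched <- logical(n_gt)
    tp <- 0L
    for (i in seq_len(k)) {
      best_j <- 0L; best_iou <- -1
      for (j in seq_len(n_gt)) {
        if (matched[j] || gts[[j]]$image_id != preds[[i]]$image_id) next
        inter <- sum(preds[[i]]$mask & gts[[j]]$mask)
        uni <- sum(preds[[i]]$mask | gts[[j]]$mask)
        v <- if (uni > 0) inter / uni else 0
        if (v >= threshold && v > best_iou) { best_iou <- v; best_j <- j }
      }
      if (best_j > 0L) { matched[best_j] <- TRUE; tp <- tp + 1L }
    }
    tp
  }
  prec <- rec <- numeric(length(preds))
  for (k in seq_along(preds)) {
    tp <- match_topk(k)
    prec[k] <- tp / k
    rec[k] <- tp / n_gt
  }
  total <- 0
  for (r in seq(0, 1, by = 0.01)) {
    best <- 0
    for (k in seq_along(preds)) if (rec[k] >= r && prec[k] > best) best <- prec[k]
    total <- total + best
  }
  total / 101
}

# random toy instances on a small grid: n axis-aligned boxes with confidences
toy_instances <- function(n, h = 24, w = 24, with_conf = TRUE) {
  lapply(seq_len(n), function(i) {
    m <- matrix(FALSE, h, w)
    r0 <- sample.int(h - 6, 1); c0 <- sample.int(w - 6, 1)
    m[r0:(r0 + sample.int(6, 1)), c0:(c0 + sample.int(6, 1))] <- TRUE
    list(image_id = "1", mask = m,
         confidence = if (with_conf) stats::runif(1) else 1)
  })
}

# annotation set with explicit tags/resolutions/patients for filter tests
make_plain_set <- function(n, width = 32, height = 24, tags = NULL,
                           shapes_for = seq_len(n), patient_ids = NULL,
                           class_name = "Cervix") {
  imgs <- lapply(seq_len(n), function(k) {
    m <- empty_mask(height, width); m[5:12, 5:12] <- TRUE
    sh <- if (k %in% shapes_for) {
      list(mask_shape(class_name, rle_encode(m, "cvat-bbox")))
    } else list()
    image_record(as.character(k), sprintf("img_%03d.png", k), width, height,
                 tags = if (is.null(tags)) list() else tags[[k]],
                 shapes = sh,
                 patient_id = if (is.null(patient_ids)) NULL else patient_ids[k])
  })
  annotation_set(default_vocabulary(), imgs, strict = FALSE)
}

dice_of <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))
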