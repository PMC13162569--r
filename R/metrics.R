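# Pixel- and instance-level segmentation evaluation.
#
# Pixel metrics follow the standard formulation with an epsilon of 1e-8
# added to every denominator so empty masks never divide by zero:
#   Dice      = 2*TP / (2*TP + FP + FN + eps)
#   IoU       =   TP / (TP + FP + FN + eps)
#   Precision =   TP / (TP + FP + eps)
#   Recall    =   TP / (TP + FN + eps)
# where TP/FP/FN count pixels.  Instance metrics (mask mAP50-95, F1) use
# greedy confidence-ordered matching and 101-point precision interpolation.

METRIC_EPS <- 1e-8

#' Pixel confusion counts between a prediction and a ground-truth mask
#'
#' @param pred,gt Logical matrices of equal size.
#' @return Object of class `pixel_confusion`: list with integer `tp`
#'   (pixels in both), `fp` (predicted only) and `fn` (ground truth only).
#' @export
pixel_confusion <- function(pred, gt) {
  assert_mask(pred, "pred"); assert_mask(gt, "gt")
  if (!identical(dim(pred), dim(gt))) {
    stop_pkg("frame size mismatch: %dx%d vs %dx%d",
             nrow(pred), ncol(pred), nrow(gt), ncol(gt))
  }
  structure(list(tp = sum(pred & gt), fp = sum(pred & !gt), fn = sum(!pred & gt)),
            class = "pixel_confusion")
}

#' Make a pixel confusion from raw counts
#' @param tp,fp,fn Non-negative pixel counts.
#' @return A `pixel_confusion`.
#' @export
confusion_counts <- function(tp, fp, fn) {
  if (any(c(tp, fp, fn) < 0)) stop_pkg("confusion counts must be non-negative")
  structure(list(tp = tp, fp = fp, fn = fn), class = "pixel_confusion")
}

#' Pixel-level Dice coefficient
#' @param c A [pixel_confusion()].
#' @return `2*tp / (2*tp + fp + fn + 1e-8)`.
#' @export
dice <- function(c) 2 * c$tp / (2 * c$tp + c$fp + c$fn + METRIC_EPS)

#' Pixel-level intersection over union (Jaccard)
#' @inheritParams dice
#' @return `tp / (tp + fp + fn + 1e-8)`.
#' @export
iou <- function(c) c$tp / (c$tp + c$fp + c$fn + METRIC_EPS)

#' Pixel-level precision
#' @inheritParams dice
#' @return `tp / (tp + fp + 1e-8)`.
#' @export
precision <- function(c) c$tp / (c$tp + c$fp + METRIC_EPS)

#' Pixel-level recall (sensitivity)
#' @inheritParams dice
#' @return `tp / (tp + fn + 1e-8)`.
#' @export
recall <- function(c) c$tp / (c$tp + c$fn + METRIC_EPS)

#' Construct an instance prediction
#'
#' @param image_id Image the prediction belongs to.
#' @param class_name Predicted class.
#' @param mask Logical matrix or [polygon_instance()].
#' @param confidence Confidence score in `[0, 1]`.
#' @return Object of class `instance_prediction`.
#' @export
instance_prediction <- function(image_id, class_name, mask, confidence = 1) {
  if (confidence < 0 || confidence > 1) stop_pkg("confidence must be in [0, 1]")
  if (!(is.matrix(mask) && is.logical(mask)) && !inherits(mask, "polygon_instance")) {
    stop_pkg("`mask` must be a logical matrix or polygon_instance")
  }
  structure(list(image_id = as.character(image_id),
                 class_name = as.character(class_name),
                 mask = mask, confidence = confidence),
            class = "instance_prediction")
}

prediction_mask <- function(pred, width_px, height_px) {
  if (inherits(pred$mask, "polygon_instance")) {
    rasterize(pred$mask, width_px, height_px)
  } else {
    pred$mask
  }
}

union_masks <- function(masks, height_px, width_px) {
  out <- empty_mask(height_px, width_px)
  for (m in masks) out <- out | m
  out
}

#' Evaluate one image for one class (pixel level)
#'
#' Class-level masks are formed as the UNION of instances on each side, then
#' pixel metrics are computed; an image with ground truth but no prediction
#' scores zero recall (undetected masks count, they are not skipped).
#'
#' @param preds List of [instance_prediction()]s (any classes/images; only
#'   matching ones are used).
#' @param gt_shapes List of [mask_shape()]s or logical matrices for the
#'   ground truth of this image.
#' @param class_name Class under evaluation.
#' @param image_id Image identifier (used to select predictions and label
#'   the record).
#' @param width_px,height_px Frame size.
#' @return One-row data.frame: `image_id`, `class_name`, `dice`, `iou`,
#'   `precision`, `recall`.
#' @export
evaluate_image <- function(preds, gt_shapes, class_name, image_id,
                           width_px, height_px) {
  gt_masks <- lapply(gt_shapes, function(s) {
    if (inherits(s, "mask_shape")) {
      if (s$class_name != class_name) return(NULL)
      rle_decode(s$payload, width_px, height_px)
    } else {
      assert_mask(s, "gt mask")
    }
  })
  gt_masks <- Filter(Negate(is.null), gt_masks)
  pr_masks <- list()
  for (p in preds) {
    if (p$image_id == as.character(image_id) && p$class_name == class_name) {
      pr_masks[[length(pr_masks) + 1L]] <- prediction_mask(p, width_px, height_px)
    }
  }
  cf <- pixel_confusion(union_masks(pr_masks, height_px, width_px),
                        union_masks(gt_masks, height_px, width_px))
  data.frame(image_id = as.character(image_id), class_name = class_name,
             dice = dice(cf), iou = iou(cf),
             precision = precision(cf), recall = recall(cf),
             stringsAsFactors = FALSE)
}

#' Evaluate an annotation set against predictions, one class at a time
#'
#' Produces one metric record per image that contains the class in its
#' ground truth.  Images whose ground truth lacks the class are excluded
#' from the records by default; false-positive activity on those images is
#' reported as a count (set `include_empty = TRUE` to score them instead).
#'
#' @param preds List of [instance_prediction()]s.
#' @param set Ground-truth [annotation_set()].
#' @param class_name Class under evaluation.
#' @param include_empty Include images without ground truth of the class as
#'   zero/one-scored records (default `FALSE`).
#' @return List with `records` (data.frame of per-image metrics) and
#'   `n_fp_images` (count of GT-empty images with predicted pixels).
#' @export
evaluate_set <- function(preds, set, class_name, include_empty = FALSE) {
  records <- list()
  n_fp_images <- 0L
  for (im in set$images) {
    has_gt <- image_has_class(im, class_name)
    if (!has_gt) {
      pr <- Filter(function(p) p$image_id == im$image_id && p$class_name == class_name,
                   preds)
      fp_active <- length(pr) > 0L &&
        any(vapply(pr, function(p) sum(prediction_mask(p, im$width_px, im$height_px)) > 0L,
                   logical(1)))
      if (fp_active) n_fp_images <- n_fp_images + 1L
      if (!include_empty) next
    }
    records[[length(records) + 1L]] <-
      evaluate_image(preds, im$shapes, class_name, im$image_id,
                     im$width_px, im$height_px)
  }
  list(records = do.call(rbind, records) %||%
         data.frame(image_id = character(0), class_name = character(0),
                    dice = numeric(0), iou = numeric(0),
                    precision = numeric(0), recall = numeric(0)),
       n_fp_images = n_fp_images)
}

#' Summarize per-image metric records for a class
#'
#' Mean, median (midpoint of the two central values for even n) and sample
#' standard deviation (n - 1 denominator; 0 for a single record) of each
#' metric, the "mean (median) +/- SD" convention of segmentation reporting.
#'
#' @param records Data.frame with columns `dice`, `iou`, `precision`,
#'   `recall` (as produced by [evaluate_image()]).
#' @return Data.frame with one row per metric: `metric`, `mean`, `median`,
#'   `sd`, `n_images`.
#' @export
summarize_metrics <- function(records) {
  if (is.null(records) || nrow(records) == 0L) stop_pkg("no metric records to summarize")
  metrics <- c("dice", "iou", "precision", "recall")
  do.call(rbind, lapply(metrics, function(m) {
    x <- records[[m]]
    data.frame(metric = m, mean = mean(x), median = stats::median(x),
               sd = if (length(x) > 1L) stats::sd(x) else 0,
               n_images = length(x), stringsAsFactors = FALSE)
  }))
}

#' Format a class summary in "mean (median) +/- SD" style
#'
#' @param summary Data.frame from [summarize_metrics()].
#' @param digits Decimal places (default 2).
#' @return Named character vector, one formatted entry per metric.
#' @export
format_summary <- function(summary, digits = 2) {
  out <- sprintf(paste0("%.", digits, "f (%.", digits, "f) ± %.", digits, "f"),
                 summary$mean, summary$median, summary$sd)
  stats::setNames(out, summary$metric)
}

# -- instance-level matching --------------------------------------------------

mask_iou_pair <- function(a, b) {
  inter <- sum(a & b)
  uni <- sum(a | b)
  if (uni == 0L) 0 else inter / uni
}

# Greedy confidence-ordered matching at one IoU threshold.
# preds: list with $image_id and decoded matrix $mask, ordered by
# decreasing confidence.  gts: list with $image_id, $mask.
# Returns logical TP flag per prediction (in the given order).
greedy_match <- function(preds, gts, iou_threshold) {
  matched <- logical(length(gts))
  gt_img <- vapply(gts, function(g) g$image_id, character(1))
  tp <- logical(length(preds))
  for (i in seq_along(preds)) {
    cand <- which(gt_img == preds[[i]]$image_id & !matched)
    if (!length(cand)) next
    ious <- vapply(cand, function(j) mask_iou_pair(preds[[i]]$mask, gts[[j]]$mask),
                   numeric(1))
    ok <- ious >= iou_threshold
    if (!any(ok)) next
    j <- cand[ok][which.max(ious[ok])]
    matched[j] <- TRUE
    tp[i] <- TRUE
  }
  tp
}

normalize_instances <- function(x, set = NULL) {
  lapply(x, function(e) {
    if (inherits(e, "instance_prediction")) {
      m <- e$mask
      if (inherits(m, "polygon_instance")) {
        if (is.null(set)) stop_pkg("polygon predictions need the annotation set for frame sizes")
        im <- set$images[[e$image_id]]
        m <- rasterize(m, im$width_px, im$height_px)
      }
      list(image_id = e$image_id, mask = m, confidence = e$confidence %||% 1)
    } else {
      list(image_id = as.character(e$image_id), mask = e$mask,
           confidence = e$confidence %||% 1)
    }
  })
}

#' Mask mean average precision over IoU thresholds 0.50-0.95
#'
#' Predictions are pooled across images, sorted by decreasing confidence and
#' matched greedily one-to-one to the unmatched ground-truth instance of
#' highest mask IoU at each threshold; average precision uses 101-point
#' interpolation (COCO convention), and `map50_95` is the mean of the ten
#' per-threshold APs.  With no ground truth the AP is defined as 0.
#'
#' @param preds List of [instance_prediction()]s (or bare lists with
#'   `image_id`, `mask`, `confidence`).
#' @param gts List of ground-truth instances: [instance_prediction()]s or
#'   bare lists with `image_id` and `mask`.
#' @param set Optional [annotation_set()] for rasterizing polygon masks.
#' @return Object of class `ap_result`: list with `ap` (named vector per
#'   threshold), `map50`, `map50_95`.
#' @export
mask_map <- function(preds, gts, set = NULL) {
  thresholds <- seq(0.50, 0.95, by = 0.05)
  preds <- normalize_instances(preds, set)
  gts <- normalize_instances(gts, set)
  ord <- order(-vapply(preds, function(p) p$confidence, numeric(1)))
  preds <- preds[ord]
  n_gt <- length(gts)
  ap <- vapply(thresholds, function(t) {
    if (n_gt == 0L || !length(preds)) return(0)
    tp <- greedy_match(preds, gts, t)
    cum_tp <- cumsum(tp)
    prec <- cum_tp / seq_along(tp)
    rec <- cum_tp / n_gt
    ap_101(prec, rec)
  }, numeric(1))
  names(ap) <- sprintf("ap%.0f", thresholds * 100)
  structure(list(ap = ap, map50 = ap[["ap50"]], map50_95 = mean(ap)),
            class = "ap_result")
}

# 101-point interpolated AP from a cumulative precision/recall sequence
ap_101 <- function(prec, rec) {
  grid <- seq(0, 1, by = 0.01)
  mean(vapply(grid, function(r) {
    sel <- rec >= r
    if (!any(sel)) 0 else max(prec[sel])
  }, numeric(1)))
}

#' @export
print.ap_result <- function(x, ...) {
  cat(sprintf("<ap_result: mAP50 %.3f, mAP50-95 %.3f>\n", x$map50, x$map50_95))
  invisible(x)
}

#' Instance-level F1 at an IoU threshold
#'
#' Greedy confidence-ordered matching at `iou_threshold`; the F1 score
#' `2PR/(P+R)` is evaluated at every observed confidence cutoff and the
#' maximum is returned (the working point mainstream detector tooling
#' reports).  With no ground truth and no predictions the score is 1 by
#' convention (nothing to detect, nothing hallucinated).
#'
#' @inheritParams mask_map
#' @param iou_threshold Minimum mask IoU for a match (default 0.5).
#' @return F1 in `[0, 1]`.
#' @export
instance_f1 <- function(preds, gts, iou_threshold = 0.5, set = NULL) {
  preds <- normalize_instances(preds, set)
  gts <- normalize_instances(gts, set)
  n_gt <- length(gts)
  if (!length(preds)) return(if (n_gt == 0L) 1 else 0)
  conf <- vapply(preds, function(p) p$confidence, numeric(1))
  ord <- order(-conf)
  preds <- preds[ord]; conf <- conf[ord]
  best <- 0
  for (cut in unique(conf)) {
    sub <- preds[conf >= cut]
    tp <- sum(greedy_match(sub, gts, iou_threshold))
    fp <- length(sub) - tp
    fn <- n_gt - tp
    if (tp == 0L && fp == 0L && fn == 0L) { best <- max(best, 1); next }
    p <- if (tp + fp > 0L) tp / (tp + fp) else 0
    r <- if (n_gt > 0L) tp / n_gt else 1
    f1 <- if (p + r > 0) 2 * p * r / (p + r) else 0
    best <- max(best, f1)
  }
  best
}

#' Composite tuning objective for mask models
#'
#' The weighted combination `0.7 * F1 + 0.3 * mAP50-95` used as the
#' hyperparameter-search objective: it balances working-point segmentation
#' performance (instance F1) against quality across overlap thresholds
#' (mAP50-95).
#'
#' @param f1 Instance-level F1 in `[0, 1]`.
#' @param map50_95 Mask mAP50-95 in `[0, 1]`.
#' @return `0.7 * f1 + 0.3 * map50_95`.
#' @examples
#' composite_objective(1, 0)   # 0.7
#' composite_objective(0.8, 0.5)
#' @export
composite_objective <- function(f1, map50_95) {
  if (f1 < 0 || f1 > 1 || map50_95 < 0 || map50_95 > 1) {
    stop_pkg("composite_objective inputs must lie in [0, 1]")
  }
  0.7 * f1 + 0.3 * map50_95
}
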