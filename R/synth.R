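# Seeded synthetic scenes with the structural properties the pipeline must
# handle: a large elliptical cervix, ring-shaped (donut) epithelium with an
# interior hole, small thin instruments, and multi-component lesions.
# Scenes are flat-shaded geometry, not photorealistic colposcopy: they
# exercise mask topology and metrics, not model perception.

#' Describe one synthetic structure
#'
#' @param kind One of `"ellipse-cervix"`, `"ring-epithelium"`,
#'   `"small-instrument"`, `"multi-blob-lesion"`.
#' @param class_name Mask class for the structure.
#' @param attributes Attribute values for the shape.
#' @param ... Size parameters (all in pixels, 0-based frame coordinates):
#'   `cx`, `cy` center; `rx`, `ry` ellipse radii; `outer_w`, `outer_h`,
#'   `hole_w`, `hole_h` ring rectangle sides; `w`, `h` instrument sides;
#'   `n_blobs`, `blob_size` lesion components.  Missing parameters get
#'   seeded defaults at generation time.
#' @return Object of class `structure_spec`.
#' @export
structure_spec <- function(kind = c("ellipse-cervix", "ring-epithelium",
                                    "small-instrument", "multi-blob-lesion"),
                           class_name, attributes = list(), ...) {
  kind <- match.arg(kind)
  structure(list(kind = kind, class_name = class_name,
                 attributes = attributes, params = list(...)),
            class = "structure_spec")
}

#' Describe a synthetic scene
#'
#' @param seed Integer seed making the scene deterministic.
#' @param width_px,height_px Frame size (default 160 x 120, the aspect of
#'   clinical colposcope frames at desk scale).
#' @param structures List of [structure_spec()]s, drawn in order (later
#'   structures overwrite earlier ones where they overlap).
#' @return Object of class `scene_spec`.
#' @export
scene_spec <- function(seed = 1L, width_px = 160L, height_px = 120L,
                       structures = list()) {
  stopifnot(all(vapply(structures, inherits, logical(1), "structure_spec")))
  structure(list(seed = as.integer(seed), width_px = as.integer(width_px),
                 height_px = as.integer(height_px), structures = structures),
            class = "scene_spec")
}

#' A default scene layout covering the difficult structures
#'
#' One elliptical cervix, one ring-shaped squamous epithelium (donut with a
#' hole standing in for the external os), one thin medical instrument and
#' one multi-component acetowhite lesion.
#'
#' @inheritParams scene_spec
#' @return A [scene_spec()].
#' @export
default_scene_spec <- function(seed = 1L, width_px = 160L, height_px = 120L) {
  s <- min(width_px, height_px)          # structures scale with the frame
  ring <- max(8L, as.integer(round(0.4 * s)))
  scene_spec(seed, width_px, height_px, list(
    structure_spec("ellipse-cervix", "Cervix",
                   cx = width_px * 0.5, cy = height_px * 0.5,
                   rx = width_px * 0.4, ry = height_px * 0.42),
    structure_spec("ring-epithelium", "Squamous epithelium",
                   attributes = list("epithelium type" = "metaplastic"),
                   cx = width_px * 0.5, cy = height_px * 0.5,
                   outer_w = ring, outer_h = ring,
                   hole_w = max(2L, ring %/% 4L), hole_h = max(2L, ring %/% 4L)),
    structure_spec("small-instrument", "Medical instruments",
                   cx = width_px * 0.15, cy = height_px * 0.25,
                   w = max(2L, as.integer(round(0.025 * width_px))),
                   h = as.integer(round(0.3 * height_px))),
    structure_spec("multi-blob-lesion", "Acetowhite epithelium",
                   n_blobs = 3L, blob_size = max(4L, as.integer(round(0.1 * s))))
  ))
}

draw_structure <- function(st, width_px, height_px) {
  p <- st$params
  m <- empty_mask(height_px, width_px)
  cx <- p$cx %||% stats::runif(1, width_px * 0.3, width_px * 0.7)
  cy <- p$cy %||% stats::runif(1, height_px * 0.3, height_px * 0.7)
  if (st$kind == "ellipse-cervix") {
    rx <- p$rx %||% (width_px * 0.35); ry <- p$ry %||% (height_px * 0.35)
    xc <- matrix(rep(seq_len(width_px) - 0.5, each = height_px), height_px)
    yc <- matrix(rep(seq_len(height_px) - 0.5, times = width_px), height_px)
    m <- ((xc - cx) / rx)^2 + ((yc - cy) / ry)^2 <= 1
  } else if (st$kind == "ring-epithelium") {
    ow <- p$outer_w %||% 48L; oh <- p$outer_h %||% 48L
    hw <- p$hole_w %||% max(2L, ow %/% 4L); hh <- p$hole_h %||% max(2L, oh %/% 4L)
    stopifnot(hw >= 1L, hh >= 1L, hw < ow, hh < oh)
    m <- fill_rect(m, cx, cy, ow, oh, TRUE)
    m <- fill_rect(m, cx, cy, hw, hh, FALSE)
  } else if (st$kind == "small-instrument") {
    w <- p$w %||% 3L; h <- p$h %||% 30L
    m <- fill_rect(m, cx, cy, w, h, TRUE)
  } else if (st$kind == "multi-blob-lesion") {
    n <- p$n_blobs %||% 3L; s <- p$blob_size %||% 10L
    for (k in seq_len(n)) {
      bx <- p[[paste0("cx", k)]] %||% stats::runif(1, s, width_px - s)
      by <- p[[paste0("cy", k)]] %||% stats::runif(1, s, height_px - s)
      m <- fill_rect(m, bx, by, s, s, TRUE)
    }
  }
  m
}

# axis-aligned centered rectangle (integer pixel extents, clipped to frame)
fill_rect <- function(mask, cx, cy, w, h, value) {
  H <- nrow(mask); W <- ncol(mask)
  c0 <- max(1L, as.integer(round(cx - w / 2)) + 1L)
  r0 <- max(1L, as.integer(round(cy - h / 2)) + 1L)
  c1 <- min(W, c0 + as.integer(w) - 1L)
  r1 <- min(H, r0 + as.integer(h) - 1L)
  if (c1 >= c0 && r1 >= r0) mask[r0:r1, c0:c1] <- value
  mask
}

#' Generate a synthetic scene with matching ground-truth annotations
#'
#' Deterministic under the spec's seed.  Structures are drawn in order and
#' later structures overwrite earlier ones, so the annotated pixel sets
#' exactly match the visible (top-most) drawing.  Ring structures produce an
#' annular mask whose contours form an outer/hole pair.
#'
#' @param spec A [scene_spec()].
#' @param image_id,file_name Identifiers for the produced image record.
#' @param tags,patient_id Optional metadata passed to the image record.
#' @return List with `image` (numeric matrix in `[0, 1]`, flat-shaded), `set`
#'   (an [annotation_set()] with one image), and `pixel_counts` (named
#'   vector, foreground pixels per structure).
#' @export
generate_scene <- function(spec, image_id = "0", file_name = NULL,
                           tags = list(), patient_id = NULL) {
  stopifnot(inherits(spec, "scene_spec"))
  W <- spec$width_px; H <- spec$height_px
  file_name <- file_name %||% sprintf("scene_%s.png", image_id)
  canvas <- matrix(0L, H, W)   # 0 = background, k = structure k on top
  masks <- with_seed(spec$seed, lapply(spec$structures, draw_structure, W, H))
  for (k in seq_along(masks)) canvas[masks[[k]]] <- k
  shapes <- list()
  counts <- integer(length(masks))
  for (k in seq_along(masks)) {
    vis <- canvas == k
    counts[k] <- sum(vis)
    if (counts[k] == 0L) next
    shapes[[length(shapes) + 1L]] <- mask_shape(
      spec$structures[[k]]$class_name, rle_encode(vis, "cvat-bbox"),
      spec$structures[[k]]$attributes
    )
  }
  names(counts) <- vapply(spec$structures, function(s) s$class_name, character(1))
  im <- image_record(image_id, file_name, W, H, tags = tags, shapes = shapes,
                     patient_id = patient_id)
  set <- annotation_set(default_vocabulary(), list(im), strict = FALSE)
  shade <- if (length(masks)) canvas / length(masks) else canvas
  list(image = shade, set = set, pixel_counts = counts)
}

#' Generate a multi-image synthetic annotation set
#'
#' Convenience wrapper building `n_images` scenes with per-image derived
#' seeds, optional quality tags and patient grouping, merged into one
#' annotation set.
#'
#' @param n_images Number of scenes.
#' @param seed Master seed; image k uses `seed * 1000 + k`.
#' @param width_px,height_px Frame size.
#' @param n_patients If positive, assign images round-robin to this many
#'   patient ids.
#' @return An [annotation_set()].
#' @export
generate_scene_set <- function(n_images, seed = 1L, width_px = 96L, height_px = 72L,
                               n_patients = 0L) {
  images <- lapply(seq_len(n_images), function(k) {
    sp <- default_scene_spec(seed * 1000L + k, width_px, height_px)
    pid <- if (n_patients > 0L) sprintf("P%03d", (k - 1L) %% n_patients + 1L) else NULL
    generate_scene(sp, image_id = as.character(k),
                   file_name = sprintf("scene_%03d.png", k),
                   patient_id = pid)$set$images[[1]]
  })
  annotation_set(default_vocabulary(), images, strict = FALSE)
}

#' Construct a prediction-perturbation specification
#'
#' @param seed Integer seed.
#' @param dilate_px,erode_px Structuring-element radii applied to each
#'   instance (square kernel).
#' @param shift Integer `c(dx, dy)` translation in pixels.
#' @param drop_probability Probability of dropping each instance entirely.
#' @param confidence_base,confidence_jitter Emitted confidence is
#'   `clamp(base + U(-jitter, jitter), 0, 1)`.  The defaults produce
#'   pixel-exact copies at confidence 1.
#' @return Object of class `perturb_spec`.
#' @export
perturb_spec <- function(seed = 1L, dilate_px = 0L, erode_px = 0L,
                         shift = c(0L, 0L), drop_probability = 0,
                         confidence_base = 1, confidence_jitter = 0) {
  if (drop_probability < 0 || drop_probability > 1) {
    stop_pkg("drop_probability must be in [0, 1]")
  }
  structure(list(seed = as.integer(seed), dilate_px = as.integer(dilate_px),
                 erode_px = as.integer(erode_px), shift = as.integer(shift),
                 drop_probability = drop_probability,
                 confidence_base = confidence_base,
                 confidence_jitter = confidence_jitter),
            class = "perturb_spec")
}

#' Derive perturbed predictions from ground truth
#'
#' Each ground-truth instance is independently shifted, dilated, eroded and
#' possibly dropped under the seed, and emitted as an
#' [instance_prediction()] with a jittered confidence.  The default
#' (all-zero) spec returns pixel-exact copies at confidence 1, so
#' self-evaluation scores 1 everywhere.
#'
#' @param gt An [annotation_set()].
#' @param spec A [perturb_spec()].
#' @return List of [instance_prediction()]s.
#' @export
perturb_predictions <- function(gt, spec = perturb_spec()) {
  stopifnot(inherits(gt, "annotation_set"), inherits(spec, "perturb_spec"))
  with_seed(spec$seed, {
    out <- list()
    for (im in gt$images) {
      for (sh in im$shapes) {
        if (spec$drop_probability > 0 && stats::runif(1) < spec$drop_probability) next
        m <- rle_decode(sh$payload, im$width_px, im$height_px)
        if (any(spec$shift != 0L)) m <- shift_mask(m, spec$shift[1], spec$shift[2])
        if (spec$dilate_px > 0L) m <- dilate_mask(m, spec$dilate_px)
        if (spec$erode_px > 0L) m <- erode_mask(m, spec$erode_px)
        conf <- spec$confidence_base +
          if (spec$confidence_jitter > 0)
            stats::runif(1, -spec$confidence_jitter, spec$confidence_jitter) else 0
        out[[length(out) + 1L]] <- instance_prediction(
          im$image_id, sh$class_name, m, min(1, max(0, conf)))
      }
    }
    out
  })
}
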