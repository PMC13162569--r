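# Dataset curation: tag/resolution filtering, per-class general/extended
# variants with background injection, seeded splits and export to YOLO-seg
# label files and COCO JSON.

#' Construct an image filter policy
#'
#' @param rejected_quality_tags Image-quality tag values whose presence
#'   rejects an image (default: unusable and low-quality images).
#' @param allowed_stage_tags Optional set of procedural-stage tag values; if
#'   given, only images carrying one of them survive (some classes only
#'   exist at specific stages, e.g. iodine-negative zones after Lugol's
#'   solution).  Default `NULL` keeps all stages.
#' @param resolution_policy `"keep-two-most-common"` (retain only the two
#'   most frequent width x height pairs), `"keep-all"`, or `"explicit"` with
#'   `resolutions` supplied.
#' @param resolutions For `"explicit"`: list of `c(width, height)` pairs.
#' @param drop_unannotated Drop images without any mask annotation
#'   (default `TRUE`).
#' @return Object of class `filter_policy`.
#' @export
filter_policy <- function(rejected_quality_tags = c("Unusable image", "Low quality image"),
                          allowed_stage_tags = NULL,
                          resolution_policy = c("keep-two-most-common", "keep-all", "explicit"),
                          resolutions = NULL,
                          drop_unannotated = TRUE) {
  resolution_policy <- match.arg(resolution_policy)
  if (resolution_policy == "explicit" && is.null(resolutions)) {
    stop_pkg("explicit resolution policy needs `resolutions`")
  }
  structure(list(rejected_quality_tags = as.character(rejected_quality_tags),
                 allowed_stage_tags = allowed_stage_tags,
                 resolution_policy = resolution_policy,
                 resolutions = resolutions,
                 drop_unannotated = isTRUE(drop_unannotated)),
            class = "filter_policy")
}

#' Filter images by quality tags, stage, resolution and annotation presence
#'
#' Applies, in order: quality-tag rejection, optional stage selection,
#' unannotated-image removal, and the resolution policy.  With
#' `"keep-two-most-common"` the two (width, height) pairs of highest
#' frequency are retained; frequency ties break by larger pixel area, then
#' lexicographically on `"WxH"`.  Survivor order is preserved and surviving
#' records are never mutated.
#'
#' @param set An [annotation_set()].
#' @param policy A [filter_policy()].
#' @return A filtered [annotation_set()] (warns when nothing survives).
#' @export
filter_images <- function(set, policy = filter_policy()) {
  stopifnot(inherits(set, "annotation_set"), inherits(policy, "filter_policy"))
  keep <- vapply(set$images, function(im) {
    q <- image_tag_values(im, "image quality")
    if (length(intersect(q, policy$rejected_quality_tags))) return(FALSE)
    if (!is.null(policy$allowed_stage_tags)) {
      st <- image_tag_values(im, "procedural stage")
      if (!length(intersect(st, policy$allowed_stage_tags))) return(FALSE)
    }
    if (policy$drop_unannotated && length(im$shapes) == 0L) return(FALSE)
    TRUE
  }, logical(1))
  images <- set$images[keep]

  if (policy$resolution_policy == "keep-two-most-common" && length(images)) {
    res <- vapply(images, function(im) sprintf("%dx%d", im$width_px, im$height_px),
                  character(1))
    tab <- table(res)
    areas <- vapply(names(tab), function(s) {
      wh <- as.integer(strsplit(s, "x")[[1]]); wh[1] * wh[2]
    }, numeric(1))
    ord <- order(-as.integer(tab), -areas, names(tab))
    top <- names(tab)[ord][seq_len(min(2L, length(tab)))]
    images <- images[res %in% top]
  } else if (policy$resolution_policy == "explicit" && length(images)) {
    allowed <- vapply(policy$resolutions, function(wh) sprintf("%dx%d", wh[1], wh[2]),
                      character(1))
    res <- vapply(images, function(im) sprintf("%dx%d", im$width_px, im$height_px),
                  character(1))
    images <- images[res %in% allowed]
  }
  if (!length(images)) warn_pkg("filtering removed every image")
  annotation_set(set$vocabulary, unname(images), strict = FALSE)
}

#' Construct a per-class dataset variant specification
#'
#' In the *general* variant the label is the whole class without attribute
#' distinctions; in the *extended* variant the label is the class restricted
#' to one attribute value (e.g. metaplastic squamous epithelium), and
#' "difficult" background images carrying the class with a different
#' attribute value can be injected alongside ordinary backgrounds.
#'
#' @param class_name Target class.
#' @param variant `"general"` or `"extended"`.
#' @param attribute_key,attribute_value Required for the extended variant.
#' @param background_count_general Number of class-free background images to
#'   add.
#' @param background_count_difficult Number of different-attribute background
#'   images to add (extended variant only).
#' @return Object of class `variant_spec`.
#' @export
variant_spec <- function(class_name, variant = c("general", "extended"),
                         attribute_key = NULL, attribute_value = NULL,
                         background_count_general = 0L,
                         background_count_difficult = 0L) {
  variant <- match.arg(variant)
  if (variant == "extended" && (is.null(attribute_key) || is.null(attribute_value))) {
    stop_pkg("the extended variant needs attribute_key and attribute_value")
  }
  if (variant == "general" && background_count_difficult > 0L) {
    stop_pkg("difficult backgrounds exist only in the extended variant")
  }
  structure(list(class_name = class_name, variant = variant,
                 attribute_key = attribute_key, attribute_value = attribute_value,
                 background_count_general = as.integer(background_count_general),
                 background_count_difficult = as.integer(background_count_difficult)),
            class = "variant_spec")
}

#' Build a per-class dataset with seeded background injection
#'
#' Positives are the images containing the target class (general) or the
#' class with the target attribute value (extended).  The requested numbers
#' of general backgrounds (images lacking the class entirely) and, for the
#' extended variant, difficult backgrounds (images carrying the class only
#' with other attribute values) are sampled under `seed`; requests beyond
#' the available pool are capped with a warning.  Non-target shapes are
#' dropped from every image, so backgrounds contribute empty label sets.
#'
#' @param set An [annotation_set()] (normally already filtered).
#' @param spec A [variant_spec()].
#' @param seed Integer seed for background sampling.
#' @return An [annotation_set()] containing positives plus sampled
#'   backgrounds, in stable (positives-then-backgrounds) order.
#' @export
build_class_dataset <- function(set, spec, seed = 0L) {
  stopifnot(inherits(set, "annotation_set"), inherits(spec, "variant_spec"))
  if (!spec$class_name %in% names(set$vocabulary$classes)) {
    stop_pkg("class '%s' is not in the vocabulary", spec$class_name)
  }
  if (spec$variant == "extended") {
    legal <- set$vocabulary$classes[[spec$class_name]]$attributes %||% list()
    if (!spec$attribute_key %in% names(legal) ||
        !spec$attribute_value %in% legal[[spec$attribute_key]]) {
      stop_pkg("attribute %s=%s is not legal for class '%s'",
               spec$attribute_key, spec$attribute_value, spec$class_name)
    }
  }
  target <- if (spec$variant == "general") {
    function(im) image_has_class(im, spec$class_name)
  } else {
    function(im) image_has_class(im, spec$class_name,
                                 spec$attribute_key, spec$attribute_value)
  }
  is_pos <- vapply(set$images, target, logical(1))
  has_class <- vapply(set$images, image_has_class, logical(1),
                      class_name = spec$class_name)
  pool_general <- names(set$images)[!has_class]
  pool_difficult <- if (spec$variant == "extended") {
    names(set$images)[has_class & !is_pos]
  } else character(0)

  take <- function(pool, n, what) {
    if (n > length(pool)) {
      warn_pkg("requested %d %s backgrounds, only %d available", n, what, length(pool))
      n <- length(pool)
    }
    sample_exact(pool, n)
  }
  picked <- with_seed(seed, {
    g <- take(pool_general, spec$background_count_general, "general")
    d <- take(pool_difficult, spec$background_count_difficult, "difficult")
    c(g, d)
  })

  keep_shape <- function(sh) {
    if (sh$class_name != spec$class_name) return(FALSE)
    if (spec$variant == "general") return(TRUE)
    v <- sh$attributes[[spec$attribute_key]]
    !is.null(v) && identical(as.character(v), as.character(spec$attribute_value))
  }
  images <- lapply(set$images[c(names(set$images)[is_pos], picked)], function(im) {
    im$shapes <- Filter(keep_shape, im$shapes)
    im
  })
  annotation_set(set$vocabulary, unname(images), strict = FALSE)
}

#' Seeded train/validation/test split
#'
#' Units (images, or whole patients with `group_key = "patient"`) are
#' shuffled under `seed`; subset sizes are `floor(n * p)` with the remainder
#' distributed train, then validation, then test.  The assignment is a total
#' partition and a patient never spans two subsets.
#'
#' @param set An [annotation_set()].
#' @param proportions Numeric length-3 vector (train, val, test) summing
#'   to 1 (default `c(0.70, 0.20, 0.10)`).
#' @param seed Integer seed.
#' @param group_key `"image"` or `"patient"`; patient grouping requires
#'   every image to carry a `patient_id`.
#' @return Object of class `split_manifest`: list with `assignment` (named
#'   character vector image_id -> "train"/"val"/"test"), `proportions`,
#'   `seed`, `group_key`.
#' @export
split_dataset <- function(set, proportions = c(0.70, 0.20, 0.10), seed = 0L,
                          group_key = c("image", "patient")) {
  stopifnot(inherits(set, "annotation_set"))
  group_key <- match.arg(group_key)
  if (length(proportions) != 3L || any(proportions <= 0) ||
      abs(sum(proportions) - 1) > 1e-9) {
    stop_pkg("proportions must be three positive numbers summing to 1")
  }
  ids <- names(set$images)
  if (group_key == "patient") {
    pats <- vapply(set$images, function(im) im$patient_id %||% NA_character_,
                   character(1))
    if (anyNA(pats)) {
      stop_pkg("patient-level split requested but images lack patient ids: %s",
               paste(ids[is.na(pats)], collapse = ", "))
    }
    units <- unique(pats)
  } else {
    units <- ids
  }
  n <- length(units)
  shuffled <- with_seed(seed, sample_exact(units, n))
  sizes <- floor(n * proportions)
  remainder <- n - sum(sizes)
  if (remainder > 0L) {
    for (k in seq_len(remainder)) sizes[k] <- sizes[k] + 1L  # train, val, test
  }
  subset_of_unit <- rep(c("train", "val", "test"), times = sizes)
  names(subset_of_unit) <- shuffled
  assignment <- if (group_key == "patient") {
    stats::setNames(subset_of_unit[pats], ids)
  } else {
    subset_of_unit[ids]
  }
  structure(list(assignment = assignment, proportions = proportions,
                 seed = as.integer(seed), group_key = group_key),
            class = "split_manifest")
}

#' @export
print.split_manifest <- function(x, ...) {
  tab <- table(factor(x$assignment, levels = c("train", "val", "test")))
  cat(sprintf("<split_manifest (%s-level, seed %d): train %d / val %d / test %d>\n",
              x$group_key, x$seed, tab["train"], tab["val"], tab["test"]))
  invisible(x)
}

#' Export YOLO-seg polygon label files
#'
#' Writes one text label file per image under
#' `<out_dir>/<subset>/labels/<image>.txt`; each line is the 0-based class
#' index followed by the normalized (x, y) vertex sequence of one polygon
#' instance in fixed 6-decimal formatting.  Background images yield empty
#' label files.  A split manifest is written as `<out_dir>/manifest.yaml`.
#'
#' @param set An [annotation_set()] (e.g. from [build_class_dataset()]).
#' @param manifest A [split_manifest()] covering the set's images.
#' @param out_dir Output directory (created if missing).
#' @param class_index_map Named integer vector class name -> 0-based index;
#'   default: alphabetical over the classes present in the set.
#' @param tolerance_px,min_area_px Vectorization parameters (see
#'   [vectorize_mask()]).
#' @return (Invisibly) list with `label_files` (named by image id) and
#'   `manifest_file`.
#' @export
export_yolo_labels <- function(set, manifest, out_dir, class_index_map = NULL,
                               tolerance_px = 0.5, min_area_px = 30) {
  stopifnot(inherits(set, "annotation_set"), inherits(manifest, "split_manifest"))
  present <- sort(unique(unlist(lapply(set$images, function(im)
    vapply(im$shapes, function(s) s$class_name, character(1))))))
  if (is.null(class_index_map)) {
    class_index_map <- stats::setNames(seq_along(present) - 1L, present)
  }
  missing_cls <- setdiff(present, names(class_index_map))
  if (length(missing_cls)) {
    stop_pkg("classes missing from index map: %s", paste(missing_cls, collapse = ", "))
  }
  files <- character(0)
  for (id in names(set$images)) {
    im <- set$images[[id]]
    subset <- unname(manifest$assignment[id])
    if (is.na(subset)) stop_pkg("image %s missing from split manifest", id)
    dir <- file.path(out_dir, subset, "labels")
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    path <- file.path(dir, paste0(tools::file_path_sans_ext(basename(im$file_name)), ".txt"))
    lines <- character(0)
    for (sh in im$shapes) {
      mask <- rle_decode(sh$payload, im$width_px, im$height_px)
      polys <- vectorize_mask(mask, im$width_px, im$height_px,
                              tolerance_px = tolerance_px, min_area_px = min_area_px,
                              class_name = sh$class_name, attributes = sh$attributes)
      for (pg in polys) {
        coords <- as.vector(t(pg$vertices_norm))
        lines <- c(lines, paste(c(class_index_map[[sh$class_name]],
                                  sprintf("%.6f", coords)), collapse = " "))
      }
    }
    writeLines(lines, path)
    files[id] <- path
  }
  manifest_file <- file.path(out_dir, "manifest.yaml")
  yaml::write_yaml(list(seed = manifest$seed,
                        group_key = manifest$group_key,
                        proportions = as.numeric(manifest$proportions),
                        assignment = as.list(manifest$assignment)),
                   manifest_file)
  invisible(list(label_files = files, manifest_file = manifest_file))
}

#' Parse one YOLO-seg label file back into polygon instances
#'
#' Inverse of [export_yolo_labels()] for verification: each line becomes a
#' [polygon_instance()].
#'
#' @param path Label file path.
#' @param class_index_map Named integer vector used at export time.
#' @return List of [polygon_instance()]s (empty for a background image).
#' @export
read_yolo_labels <- function(path, class_index_map) {
  lines <- readLines(path)
  idx_to_class <- stats::setNames(names(class_index_map), as.character(class_index_map))
  lapply(lines[nzchar(lines)], function(ln) {
    f <- as.numeric(strsplit(trimws(ln), "\\s+")[[1]])
    polygon_instance(idx_to_class[[as.character(as.integer(f[1]))]],
                     matrix(f[-1], ncol = 2, byrow = TRUE))
  })
}

#' Export per-subset COCO annotation files
#'
#' Partitions the set by the manifest and writes one COCO JSON per subset
#' (`<out_dir>/<subset>/annotations.json`).  Category ids derive from the
#' full vocabulary, so they are stable across subsets.
#'
#' @inheritParams export_yolo_labels
#' @return (Invisibly) named character vector subset -> file path.
#' @export
export_coco <- function(set, manifest, out_dir) {
  stopifnot(inherits(set, "annotation_set"), inherits(manifest, "split_manifest"))
  out <- character(0)
  for (subset in c("train", "val", "test")) {
    ids <- names(manifest$assignment)[manifest$assignment == subset]
    ids <- intersect(names(set$images), ids)
    sub <- annotation_set(set$vocabulary, unname(set$images[ids]), strict = FALSE)
    dir.create(file.path(out_dir, subset), recursive = TRUE, showWarnings = FALSE)
    path <- file.path(out_dir, subset, "annotations.json")
    writeLines(write_coco(sub), path)
    out[subset] <- path
  }
  invisible(out)
}
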