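# COCO 1.0 JSON dialect: reader, writer and prediction-result reader.
#
# Segmentations are read from polygon lists, uncompressed RLE
# ({"size": [h, w], "counts": [..]}, column-major) or compressed RLE
# (counts as string).  The writer emits uncompressed RLE.  Image tags,
# per-annotation attributes and patient ids travel in extension fields
# ("tags", "attributes", "patient_id") so that write/parse roundtrips
# preserve them.

#' Parse a COCO 1.0 annotation document
#'
#' @param document JSON text or path to a JSON file.
#' @param vocabulary Base vocabulary to extend with the document's
#'   categories.
#' @param strict Passed to [annotation_set()].
#' @return An [annotation_set()] whose decoded instance pixel sets equal the
#'   document's.
#' @export
parse_coco <- function(document, vocabulary = default_vocabulary(), strict = FALSE) {
  doc <- jsonlite::fromJSON(document, simplifyVector = FALSE)
  cat_by_id <- list()
  for (ct in doc$categories %||% list()) {
    cat_by_id[[as.character(ct$id)]] <- ct$name
    if (!ct$name %in% names(vocabulary$classes)) {
      super <- ct$supercategory %||% "findings"
      if (!super %in% MASK_CATEGORIES) super <- "findings"
      vocabulary$classes[[ct$name]] <- list(category = super, attributes = list())
    }
  }
  images <- list()
  dims <- list()
  for (img in doc$images %||% list()) {
    id <- as.character(img$id)
    tags <- lapply(img$tags %||% list(), function(t) tag_record(t$category, t$value))
    images[[id]] <- image_record(
      image_id = id, file_name = img$file_name %||% paste0(id, ".png"),
      width_px = img$width, height_px = img$height, tags = tags,
      patient_id = img$patient_id %||% NULL
    )
    dims[[id]] <- c(img$width, img$height)
  }
  for (ann in doc$annotations %||% list()) {
    iid <- as.character(ann$image_id)
    if (is.null(images[[iid]])) {
      stop_pkg("annotation %s references missing image id %s", ann$id %||% "?", iid)
    }
    cname <- cat_by_id[[as.character(ann$category_id)]]
    if (is.null(cname)) {
      stop_pkg("annotation %s references missing category id %s",
               ann$id %||% "?", ann$category_id)
    }
    w <- dims[[iid]][1]; h <- dims[[iid]][2]
    payload <- coco_segmentation_to_payload(ann$segmentation, w, h)
    attrs <- lapply(ann$attributes %||% list(), as.character)
    sh <- mask_shape(cname, payload, attrs)
    images[[iid]]$shapes <- c(images[[iid]]$shapes, list(sh))
  }
  annotation_set(vocabulary, unname(images), strict = strict)
}

coco_segmentation_to_payload <- function(seg, width_px, height_px) {
  if (!is.null(seg$counts)) {
    if (is.character(seg$counts)) {
      return(rle_payload(seg$counts, "coco-compressed"))
    }
    return(rle_payload(unlist(seg$counts), "coco-uncompressed"))
  }
  # polygon list: each element a flat [x1, y1, x2, y2, ...] ring; rasterize
  mask <- empty_mask(height_px, width_px)
  for (ring in seg) {
    xy <- matrix(unlist(ring), ncol = 2, byrow = TRUE)
    mask <- mask | rasterize_path(xy, width_px, height_px)
  }
  rle_encode(mask, "coco-uncompressed")
}

#' Serialize an annotation set as COCO 1.0 JSON
#'
#' Deterministic: images ordered by image id, categories alphabetically over
#' the whole vocabulary (so category ids are stable across subsets), shapes
#' in stored order.  Repeated calls on the same set yield identical bytes.
#'
#' @param set An [annotation_set()].
#' @param pretty Pretty-print the JSON (default `FALSE`).
#' @return JSON text (single string).
#' @export
write_coco <- function(set, pretty = FALSE) {
  stopifnot(inherits(set, "annotation_set"))
  cat_names <- sort(names(set$vocabulary$classes))
  cat_id_of <- stats::setNames(seq_along(cat_names), cat_names)
  categories <- lapply(seq_along(cat_names), function(i) list(
    id = i, name = cat_names[i],
    supercategory = set$vocabulary$classes[[cat_names[i]]]$category
  ))
  ids <- names(set$images)
  ids <- ids[order(ids)]
  images <- list()
  annotations <- list()
  ann_id <- 0L
  for (id in ids) {
    im <- set$images[[id]]
    rec <- list(id = coerce_id(im$image_id), file_name = im$file_name,
                width = im$width_px, height = im$height_px)
    if (length(im$tags)) {
      rec$tags <- lapply(im$tags, function(t) list(category = t$category, value = t$value))
    }
    if (!is.null(im$patient_id)) rec$patient_id <- im$patient_id
    images[[length(images) + 1L]] <- rec
    for (sh in im$shapes) {
      mask <- rle_decode(sh$payload, im$width_px, im$height_px)
      p <- rle_encode(mask, "coco-uncompressed")
      fg <- which(mask, arr.ind = TRUE)
      bbox <- if (nrow(fg)) {
        c(min(fg[, 2]) - 1L, min(fg[, 1]) - 1L,
          max(fg[, 2]) - min(fg[, 2]) + 1L, max(fg[, 1]) - min(fg[, 1]) + 1L)
      } else c(0L, 0L, 0L, 0L)
      ann_id <- ann_id + 1L
      ann <- list(
        id = ann_id, image_id = coerce_id(im$image_id),
        category_id = unname(cat_id_of[[sh$class_name]]),
        segmentation = list(size = c(im$height_px, im$width_px),
                            counts = as.integer(p$runs)),
        area = sum(mask), bbox = as.integer(bbox), iscrowd = 0L
      )
      if (length(sh$attributes)) ann$attributes <- sh$attributes
      annotations[[length(annotations) + 1L]] <- ann
    }
  }
  jsonlite::toJSON(list(images = images, annotations = annotations,
                        categories = categories),
                   auto_unbox = TRUE, pretty = pretty, digits = NA)
}

coerce_id <- function(id) {
  n <- suppressWarnings(as.integer(id))
  if (!is.na(n) && as.character(n) == id) n else id
}

#' Read instance predictions from COCO-style result JSON
#'
#' Expects an array of records with `image_id`, `category_id` (or
#' `category_name`), `segmentation` and `score`, the standard output layout
#' of detection/segmentation tooling.
#'
#' @param document JSON text or path.
#' @param set The ground-truth [annotation_set()] the predictions refer to
#'   (supplies frame sizes and the category-id mapping used by
#'   [write_coco()]).
#' @return List of [instance_prediction()]s.
#' @export
read_predictions <- function(document, set) {
  stopifnot(inherits(set, "annotation_set"))
  recs <- jsonlite::fromJSON(document, simplifyVector = FALSE)
  cat_names <- sort(names(set$vocabulary$classes))
  out <- list()
  for (r in recs) {
    iid <- as.character(r$image_id)
    im <- set$images[[iid]]
    if (is.null(im)) stop_pkg("prediction references unknown image id %s", iid)
    cname <- r$category_name %||% cat_names[[as.integer(r$category_id)]]
    payload <- coco_segmentation_to_payload(r$segmentation, im$width_px, im$height_px)
    mask <- rle_decode(payload, im$width_px, im$height_px)
    out[[length(out) + 1L]] <- instance_prediction(
      image_id = iid, class_name = cname, mask = mask,
      confidence = r$score %||% 1
    )
  }
  out
}
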