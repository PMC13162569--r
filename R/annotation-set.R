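# Domain containers for annotation data: tag records, mask shapes, image
# records and the annotation set tying them to a vocabulary.

#' Construct a tag record
#'
#' @param category Tag category (`"procedural stage"`, `"clinical assessment"`,
#'   `"image quality"` or `"technical"`).
#' @param value Tag value; legality against a vocabulary is checked when the
#'   record enters an [annotation_set()].
#' @return An object of class `tag_record`.
#' @export
tag_record <- function(category, value) {
  if (!category %in% TAG_CATEGORIES) stop_pkg("unknown tag category '%s'", category)
  structure(list(category = category, value = as.character(value)),
            class = "tag_record")
}

#' Construct a mask shape (one labeled instance annotation)
#'
#' @param class_name Mask class name.
#' @param payload An [rle_payload()] holding the run-length-encoded mask.
#' @param attributes Named list/character vector of attribute values.
#' @return An object of class `mask_shape`.
#' @export
mask_shape <- function(class_name, payload, attributes = list()) {
  if (!inherits(payload, "rle_payload")) stop_pkg("`payload` must be an rle_payload")
  attributes <- as.list(attributes)
  structure(list(class_name = as.character(class_name),
                 attributes = lapply(attributes, as.character),
                 payload = payload),
            class = "mask_shape")
}

#' Construct an image record
#'
#' @param image_id Unique image identifier (coerced to character).
#' @param file_name Image file name.
#' @param width_px,height_px Frame dimensions (>= 1).
#' @param tags List of [tag_record()]s.
#' @param shapes List of [mask_shape()]s.
#' @param patient_id Optional patient identifier enabling patient-level
#'   splitting; `NULL` when unknown.
#' @return An object of class `image_record`.
#' @export
image_record <- function(image_id, file_name, width_px, height_px,
                         tags = list(), shapes = list(), patient_id = NULL) {
  width_px <- as.integer(width_px); height_px <- as.integer(height_px)
  if (is.na(width_px) || is.na(height_px) || width_px < 1L || height_px < 1L) {
    stop_pkg("image '%s': dimensions must be >= 1", image_id)
  }
  stopifnot(all(vapply(tags, inherits, logical(1), "tag_record")),
            all(vapply(shapes, inherits, logical(1), "mask_shape")))
  structure(list(image_id = as.character(image_id),
                 file_name = as.character(file_name),
                 width_px = width_px, height_px = height_px,
                 tags = tags, shapes = shapes,
                 patient_id = if (is.null(patient_id)) NULL else as.character(patient_id)),
            class = "image_record")
}

#' Construct an annotation set
#'
#' Validates that image ids are unique and that every shape's class and
#' attribute values are legal for the vocabulary.
#'
#' @param vocabulary A [label_vocabulary()].
#' @param images List of [image_record()]s.
#' @param strict If `FALSE`, unknown classes or attribute values raise a
#'   warning instead of an error (vocabulary snapshots are not closed
#'   schemas).
#' @return An object of class `annotation_set`.
#' @export
annotation_set <- function(vocabulary = default_vocabulary(), images = list(),
                           strict = TRUE) {
  if (!inherits(vocabulary, "label_vocabulary")) {
    stop_pkg("`vocabulary` must be a label_vocabulary")
  }
  stopifnot(all(vapply(images, inherits, logical(1), "image_record")))
  ids <- vapply(images, function(im) im$image_id, character(1))
  if (anyDuplicated(ids)) {
    stop_pkg("duplicate image ids: %s", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  for (im in images) {
    for (sh in im$shapes) {
      check_class(vocabulary, sh$class_name, sh$attributes, strict = strict)
    }
  }
  names(images) <- ids
  structure(list(vocabulary = vocabulary, images = images), class = "annotation_set")
}

#' @export
print.annotation_set <- function(x, ...) {
  n_shapes <- sum(vapply(x$images, function(im) length(im$shapes), integer(1)))
  cat(sprintf("<annotation_set: %d images, %d shapes, %d vocabulary classes>\n",
              length(x$images), n_shapes, length(x$vocabulary$classes)))
  invisible(x)
}

#' @export
length.annotation_set <- function(x) length(x$images)

#' Per-class shape counts of an annotation set
#'
#' @param set An [annotation_set()].
#' @return Named integer vector (class name -> number of shape instances),
#'   sorted by decreasing count then name.
#' @export
class_counts <- function(set) {
  cls <- unlist(lapply(set$images, function(im)
    vapply(im$shapes, function(s) s$class_name, character(1))))
  if (!length(cls)) return(integer(0))
  tab <- table(cls)
  counts <- as.integer(tab)
  names(counts) <- names(tab)
  counts[order(-counts, names(counts))]
}

# tag values of an image for one category (character vector, possibly empty)
image_tag_values <- function(im, category) {
  vals <- vapply(im$tags, function(t) if (t$category == category) t$value else NA_character_,
                 character(1))
  vals[!is.na(vals)]
}

# does this image contain the class (optionally with a given attribute value)?
image_has_class <- function(im, class_name, attribute_key = NULL, attribute_value = NULL) {
  for (sh in im$shapes) {
    if (sh$class_name != class_name) next
    if (is.null(attribute_key)) return(TRUE)
    v <- sh$attributes[[attribute_key]]
    if (!is.null(v) && identical(as.character(v), as.character(attribute_value))) return(TRUE)
  }
  FALSE
}

# decoded masks of all shapes of a class in one image (list of logical matrices)
decode_class_masks <- function(im, class_name,
                               attribute_key = NULL, attribute_value = NULL) {
  out <- list()
  for (sh in im$shapes) {
    if (sh$class_name != class_name) next
    if (!is.null(attribute_key)) {
      v <- sh$attributes[[attribute_key]]
      if (is.null(v) || !identical(as.character(v), as.character(attribute_value))) next
    }
    out[[length(out) + 1L]] <- rle_decode(sh$payload, im$width_px, im$height_px)
  }
  out
}
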