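# Label vocabulary: the hierarchical class/attribute taxonomy for mask
# annotations plus the categorical tag taxonomy.

MASK_CATEGORIES <- c("physiological-anatomical", "findings", "obstacles-artifacts")
TAG_CATEGORIES <- c("procedural stage", "clinical assessment", "image quality", "technical")

#' Construct a label vocabulary
#'
#' @param classes Named list; one entry per mask class, each a list with
#'   `category` (one of `"physiological-anatomical"`, `"findings"`,
#'   `"obstacles-artifacts"`) and an optional `attributes` named list mapping
#'   attribute names to non-empty character vectors of allowed values.
#' @param tags Named list mapping tag categories (`"procedural stage"`,
#'   `"clinical assessment"`, `"image quality"`, `"technical"`) to their
#'   legal values.
#' @return An object of class `label_vocabulary`.
#' @export
label_vocabulary <- function(classes = list(), tags = list()) {
  if (length(classes)) {
    if (is.null(names(classes)) || anyDuplicated(names(classes))) {
      stop_pkg("class names must be unique and named")
    }
    for (nm in names(classes)) {
      cl <- classes[[nm]]
      if (!cl$category %in% MASK_CATEGORIES) {
        stop_pkg("class '%s': unknown category '%s'", nm, cl$category)
      }
      for (attr in names(cl$attributes %||% list())) {
        vals <- cl$attributes[[attr]]
        if (!length(vals)) stop_pkg("class '%s': attribute '%s' has no allowed values", nm, attr)
        classes[[nm]]$attributes[[attr]] <- as.character(vals)
      }
    }
  }
  if (length(tags)) {
    bad <- setdiff(names(tags), TAG_CATEGORIES)
    if (length(bad)) stop_pkg("unknown tag categories: %s", paste(bad, collapse = ", "))
    tags <- lapply(tags, as.character)
  }
  structure(list(classes = classes, tags = tags), class = "label_vocabulary")
}

#' @export
print.label_vocabulary <- function(x, ...) {
  cat(sprintf("<label_vocabulary: %d mask classes, %d tag categories>\n",
              length(x$classes), length(x$tags)))
  invisible(x)
}

#' Read a vocabulary from a YAML configuration file
#'
#' The file lists mask classes (name, category, optional attribute value
#' sets) and tag categories with their legal values; see the file returned
#' by `system.file("extdata", "vocabulary.yaml", package = "colposeg")` for
#' the schema.
#'
#' @param path Path to the YAML file.
#' @return A [label_vocabulary()].
#' @export
read_vocabulary <- function(path) {
  doc <- yaml::read_yaml(path)
  classes <- list()
  for (entry in doc$masks %||% list()) {
    classes[[entry$name]] <- list(
      category = entry$category,
      attributes = lapply(entry$attributes %||% list(), as.character)
    )
  }
  label_vocabulary(classes = classes, tags = doc$tags %||% list())
}

#' The default colposcopy vocabulary
#'
#' Mask classes covering physiological/anatomical structures, colposcopic
#' findings, and obstacles/artifacts, plus the procedural-stage, clinical
#' assessment, image-quality and technical tag sets used in clinical
#' annotation workflows.
#'
#' @return A [label_vocabulary()].
#' @export
default_vocabulary <- function() {
  read_vocabulary(system.file("extdata", "vocabulary.yaml", package = "colposeg",
                              mustWork = TRUE))
}

#' Tag category legal for a value, or NA
#' @noRd
tag_category_of <- function(vocabulary, value) {
  for (cat in names(vocabulary$tags)) {
    if (value %in% vocabulary$tags[[cat]]) return(cat)
  }
  NA_character_
}

# check a class / attribute assignment against the vocabulary;
# strict = FALSE downgrades unknown classes to a warning
check_class <- function(vocabulary, class_name, attributes = NULL, strict = TRUE) {
  if (!class_name %in% names(vocabulary$classes)) {
    msg <- sprintf("class '%s' is not in the vocabulary", class_name)
    if (strict) stop_pkg("%s", msg) else warn_pkg("%s", msg)
    return(invisible(FALSE))
  }
  legal <- vocabulary$classes[[class_name]]$attributes %||% list()
  for (attr in names(attributes %||% list())) {
    if (!attr %in% names(legal)) {
      msg <- sprintf("class '%s': unknown attribute '%s'", class_name, attr)
      if (strict) stop_pkg("%s", msg) else warn_pkg("%s", msg)
    } else if (!attributes[[attr]] %in% legal[[attr]]) {
      msg <- sprintf("class '%s': value '%s' illegal for attribute '%s'",
                     class_name, attributes[[attr]], attr)
      if (strict) stop_pkg("%s", msg) else warn_pkg("%s", msg)
    }
  }
  invisible(TRUE)
}
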