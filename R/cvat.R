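# CVAT for Images 1.1 XML dialect: reader and writer.
#
# Layout read/written:
#   <annotations>
#     <version>1.1</version>
#     <meta><task><labels><label><name/><attributes>...</label>...</task></meta>
#     <image id="0" name="a.png" width="64" height="48">
#       <tag label="Unusable image" source="manual"/>
#       <mask label="Cervix" rle="0, 12, ..." left="3" top="4"
#             width="10" height="8" source="manual">
#         <attribute name="epithelium type">metaplastic</attribute>
#       </mask>
#     </image>
#   </annotations>
# Mask runs are row-major within the bounding box, first run background.

#' Parse a CVAT for Images 1.1 XML document
#'
#' Reads every image, tag, mask shape and attribute.  Labels declared in the
#' document's meta block are merged into the vocabulary; unknown elements
#' are skipped with a warning.
#'
#' @param document XML text, or a path to an XML file.
#' @param vocabulary Base [label_vocabulary()] to extend (default
#'   [default_vocabulary()]).
#' @param strict If `TRUE`, a mask referencing a class absent from the
#'   vocabulary is an error; otherwise a warning.
#' @return An [annotation_set()].
#' @export
parse_cvat_xml <- function(document, vocabulary = default_vocabulary(),
                           strict = FALSE) {
  doc <- tryCatch(xml2::read_xml(document), error = function(e) {
    stop_pkg("malformed CVAT XML: %s", conditionMessage(e))
  })
  if (xml2::xml_name(doc) != "annotations") {
    stop_pkg("not a CVAT for Images document (root <%s>)", xml2::xml_name(doc))
  }
  # merge label declarations from meta into the vocabulary
  for (lb in xml2::xml_find_all(doc, ".//meta//labels/label")) {
    nm <- xml2::xml_text(xml2::xml_find_first(lb, "./name"))
    if (is.na(nm) || nm %in% names(vocabulary$classes)) next
    attrs <- list()
    for (at in xml2::xml_find_all(lb, "./attributes/attribute")) {
      anm <- xml2::xml_text(xml2::xml_find_first(at, "./name"))
      vals <- xml2::xml_text(xml2::xml_find_first(at, "./values"))
      if (!is.na(anm)) attrs[[anm]] <- strsplit(vals %||% "", "\n")[[1]]
    }
    vocabulary$classes[[nm]] <- list(category = "findings", attributes = attrs)
  }

  images <- list()
  for (img in xml2::xml_find_all(doc, "./image")) {
    w <- as.integer(xml2::xml_attr(img, "width"))
    h <- as.integer(xml2::xml_attr(img, "height"))
    id <- xml2::xml_attr(img, "id")
    tags <- list()
    shapes <- list()
    for (child in xml2::xml_children(img)) {
      nm <- xml2::xml_name(child)
      if (nm == "tag") {
        value <- xml2::xml_attr(child, "label")
        cat_ <- tag_category_of(vocabulary, value)
        if (is.na(cat_)) {
          warn_pkg("image %s: unknown tag '%s' skipped", id, value)
          next
        }
        tags[[length(tags) + 1L]] <- tag_record(cat_, value)
      } else if (nm == "mask") {
        label <- xml2::xml_attr(child, "label")
        if (!label %in% names(vocabulary$classes)) {
          if (strict) stop_pkg("image %s: mask references unknown label '%s'", id, label)
          warn_pkg("image %s: mask references unknown label '%s'", id, label)
        }
        runs <- as.integer(strsplit(xml2::xml_attr(child, "rle"), ",\\s*")[[1]])
        box <- as.integer(c(xml2::xml_attr(child, "left"),
                            xml2::xml_attr(child, "top"),
                            xml2::xml_attr(child, "width"),
                            xml2::xml_attr(child, "height")))
        attrs <- list()
        for (at in xml2::xml_find_all(child, "./attribute")) {
          attrs[[xml2::xml_attr(at, "name")]] <- xml2::xml_text(at)
        }
        shapes[[length(shapes) + 1L]] <-
          mask_shape(label, rle_payload(runs, "cvat-bbox", anchor_box = box), attrs)
      } else if (!nm %in% c("box", "polygon", "polyline", "points")) {
        warn_pkg("image %s: unknown element <%s> skipped", id, nm)
      } else {
        warn_pkg("image %s: unsupported shape <%s> skipped", id, nm)
      }
    }
    patient <- xml2::xml_attr(img, "patient_id")
    images[[length(images) + 1L]] <- image_record(
      image_id = id, file_name = xml2::xml_attr(img, "name"),
      width_px = w, height_px = h, tags = tags, shapes = shapes,
      patient_id = if (is.na(patient)) NULL else patient
    )
  }
  annotation_set(vocabulary, images, strict = strict)
}

#' Serialize an annotation set as CVAT for Images 1.1 XML
#'
#' Deterministic inverse of [parse_cvat_xml()]: images are written in
#' image-id order, shapes in stored order, and RLE payloads are re-encoded
#' into the bounding-box dialect where needed.
#'
#' @param set An [annotation_set()].
#' @return XML text (single string).
#' @export
write_cvat <- function(set) {
  stopifnot(inherits(set, "annotation_set"))
  doc <- xml2::xml_new_root("annotations")
  xml2::xml_add_child(doc, "version", "1.1")
  meta <- xml2::xml_add_child(doc, "meta")
  task <- xml2::xml_add_child(meta, "task")
  labels <- xml2::xml_add_child(task, "labels")
  for (nm in names(set$vocabulary$classes)) {
    lb <- xml2::xml_add_child(labels, "label")
    xml2::xml_add_child(lb, "name", nm)
    attrs <- set$vocabulary$classes[[nm]]$attributes %||% list()
    if (length(attrs)) {
      ats <- xml2::xml_add_child(lb, "attributes")
      for (anm in names(attrs)) {
        at <- xml2::xml_add_child(ats, "attribute")
        xml2::xml_add_child(at, "name", anm)
        xml2::xml_add_child(at, "values", paste(attrs[[anm]], collapse = "\n"))
      }
    }
  }
  ids <- names(set$images)
  for (id in ids[order(ids)]) {
    im <- set$images[[id]]
    img <- xml2::xml_add_child(doc, "image", id = im$image_id, name = im$file_name,
                               width = as.character(im$width_px),
                               height = as.character(im$height_px))
    if (!is.null(im$patient_id)) xml2::xml_attr(img, "patient_id") <- im$patient_id
    for (tg in im$tags) {
      xml2::xml_add_child(img, "tag", label = tg$value, source = "manual")
    }
    for (sh in im$shapes) {
      p <- sh$payload
      if (p$dialect != "cvat-bbox") {
        p <- rle_encode(rle_decode(p, im$width_px, im$height_px), "cvat-bbox")
      }
      mk <- xml2::xml_add_child(img, "mask", label = sh$class_name,
                                source = "manual", occluded = "0", z_order = "0",
                                rle = paste(p$runs, collapse = ", "),
                                left = as.character(p$anchor_box[1]),
                                top = as.character(p$anchor_box[2]),
                                width = as.character(p$anchor_box[3]),
                                height = as.character(p$anchor_box[4]))
      for (anm in names(sh$attributes)) {
        xml2::xml_add_child(mk, "attribute", sh$attributes[[anm]], name = anm)
      }
    }
  }
  as.character(doc)
}
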