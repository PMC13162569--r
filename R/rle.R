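# Run-length codecs for brush masks.
#
# Three dialects are supported, mirroring the two annotation exports the
# toolkit reads plus COCO's compressed form:
#
# * "cvat-bbox":          alternating run lengths, ROW-major within the
#                         shape's anchor bounding box, first run counting
#                         background pixels (possibly 0).
# * "coco-uncompressed":  alternating run lengths over the WHOLE frame,
#                         COLUMN-major, first run background.
# * "coco-compressed":    the COCO LEB128-style string encoding of the
#                         column-major whole-frame runs.

RLE_DIALECTS <- c("cvat-bbox", "coco-uncompressed", "coco-compressed")

#' Construct an RLE payload
#'
#' @param runs Non-negative integer run lengths, alternating
#'   background/foreground and starting with background.  For
#'   `"coco-compressed"` a single character string may be given instead.
#' @param dialect One of `"cvat-bbox"`, `"coco-uncompressed"`,
#'   `"coco-compressed"`.
#' @param anchor_box For `"cvat-bbox"`: integer `c(left, top, width, height)`
#'   in 0-based pixel coordinates.  `NULL` (whole frame) for COCO dialects.
#' @return An object of class `rle_payload`.
#' @export
rle_payload <- function(runs, dialect = "cvat-bbox", anchor_box = NULL) {
  dialect <- match.arg(dialect, RLE_DIALECTS)
  if (is.character(runs)) {
    if (dialect != "coco-compressed") {
      stop_pkg("string counts are only valid for the coco-compressed dialect")
    }
  } else {
    runs <- as.integer(runs)
    if (any(is.na(runs)) || any(runs < 0L)) stop_pkg("runs must be non-negative integers")
  }
  if (dialect == "cvat-bbox") {
    if (is.null(anchor_box)) anchor_box <- c(0L, 0L, 0L, 0L)
    anchor_box <- as.integer(anchor_box)
    if (length(anchor_box) != 4L || any(is.na(anchor_box)) || any(anchor_box < 0L)) {
      stop_pkg("anchor_box must be c(left, top, width, height), all >= 0")
    }
  } else {
    anchor_box <- NULL
  }
  structure(list(runs = runs, anchor_box = anchor_box, dialect = dialect),
            class = "rle_payload")
}

#' @export
print.rle_payload <- function(x, ...) {
  n <- if (is.character(x$runs)) nchar(x$runs) else length(x$runs)
  cat(sprintf("<rle_payload %s, %d %s%s>\n", x$dialect, n,
              if (is.character(x$runs)) "chars" else "runs",
              if (!is.null(x$anchor_box))
                sprintf(", box [%s]", paste(x$anchor_box, collapse = ",")) else ""))
  invisible(x)
}

#' Decode an RLE payload into a binary mask
#'
#' @param payload An [rle_payload()] (a `mask_shape` is also accepted, in
#'   which case its payload is used).
#' @param width_px,height_px Frame dimensions in pixels.
#' @return A logical `height_px` x `width_px` matrix whose foreground pixel
#'   count equals the sum of the foreground runs.
#' @examples
#' p <- rle_payload(c(0L, 4L), "cvat-bbox", anchor_box = c(1L, 1L, 2L, 2L))
#' sum(rle_decode(p, 5L, 5L))
#' @export
rle_decode <- function(payload, width_px, height_px) {
  if (inherits(payload, "mask_shape")) payload <- payload$payload
  if (!inherits(payload, "rle_payload")) stop_pkg("`payload` must be an rle_payload")
  width_px <- as.integer(width_px); height_px <- as.integer(height_px)
  if (width_px < 1L || height_px < 1L) stop_pkg("frame dimensions must be >= 1")

  if (payload$dialect == "cvat-bbox") {
    box <- payload$anchor_box
    bw <- box[3]; bh <- box[4]
    if (bw == 0L || bh == 0L) {
      if (sum(payload$runs) != 0L) stop_pkg("degenerate anchor box with non-empty runs")
      return(empty_mask(height_px, width_px))
    }
    if (box[1] + bw > width_px || box[2] + bh > height_px) {
      stop_pkg("anchor box [%s] exceeds the %dx%d frame",
               paste(box, collapse = ","), width_px, height_px)
    }
    if (sum(payload$runs) != bw * bh) {
      stop_pkg("corrupt payload: run sum %d != anchor-box area %d",
               sum(payload$runs), bw * bh)
    }
    vec <- inverse.rle(list(
      lengths = payload$runs,
      values = rep_len(c(FALSE, TRUE), length(payload$runs))
    ))
    sub <- matrix(vec, nrow = bh, ncol = bw, byrow = TRUE)   # row-major
    mask <- empty_mask(height_px, width_px)
    mask[box[2] + seq_len(bh), box[1] + seq_len(bw)] <- sub
    return(mask)
  }

  runs <- payload$runs
  if (is.character(runs)) runs <- leb128_decode(runs)
  if (sum(runs) != width_px * height_px) {
    stop_pkg("corrupt payload: run sum %d != frame area %d",
             sum(runs), width_px * height_px)
  }
  vec <- inverse.rle(list(lengths = runs,
                          values = rep_len(c(FALSE, TRUE), length(runs))))
  matrix(vec, nrow = height_px, ncol = width_px)              # column-major
}

#' Encode a binary mask as an RLE payload
#'
#' `rle_decode(rle_encode(m, d), ...)` reproduces `m` exactly for every
#' dialect.  With the `"cvat-bbox"` dialect the anchor is the tight bounding
#' box of the foreground; an all-background mask encodes as a documented
#' degenerate payload with an empty anchor box and zero foreground.
#'
#' @param mask Logical matrix.
#' @param dialect Target dialect (see [rle_payload()]).
#' @return An [rle_payload()].
#' @export
rle_encode <- function(mask, dialect = "cvat-bbox") {
  assert_mask(mask)
  dialect <- match.arg(dialect, RLE_DIALECTS)
  if (dialect == "cvat-bbox") {
    fg <- which(mask, arr.ind = TRUE)
    if (nrow(fg) == 0L) {
      return(rle_payload(integer(0), "cvat-bbox", anchor_box = c(0L, 0L, 0L, 0L)))
    }
    r0 <- min(fg[, 1]); r1 <- max(fg[, 1])
    c0 <- min(fg[, 2]); c1 <- max(fg[, 2])
    sub <- mask[r0:r1, c0:c1, drop = FALSE]
    vec <- as.vector(t(sub))                                   # row-major
    r <- rle(vec)
    lens <- r$lengths
    if (r$values[1]) lens <- c(0L, lens)                       # start with bg
    return(rle_payload(as.integer(lens), "cvat-bbox",
                       anchor_box = c(c0 - 1L, r0 - 1L, c1 - c0 + 1L, r1 - r0 + 1L)))
  }
  vec <- as.vector(mask)                                       # column-major
  r <- rle(vec)
  lens <- as.integer(r$lengths)
  if (length(lens) && r$values[1]) lens <- c(0L, lens)
  if (!length(lens)) lens <- integer(0)
  if (dialect == "coco-compressed") {
    return(rle_payload(leb128_encode(lens), "coco-compressed"))
  }
  rle_payload(lens, "coco-uncompressed")
}

# -- COCO compressed counts ---------------------------------------------------
# Variable-length base-32 encoding with sign continuation; counts after the
# second are stored as differences from the count two places earlier.

leb128_encode <- function(counts) {
  counts <- as.integer(counts)
  chars <- integer(0)
  for (i in seq_along(counts)) {
    x <- counts[i]
    if (i > 2L) x <- x - counts[i - 2L]
    repeat {
      c5 <- x %% 32L          # low 5 bits (non-negative)
      x <- x %/% 32L          # arithmetic shift (floor division)
      more <- if (bitwAnd(c5, 0x10L) != 0L) x != -1L else x != 0L
      if (more) c5 <- bitwOr(c5, 0x20L)
      chars <- c(chars, c5 + 48L)
      if (!more) break
    }
  }
  intToUtf8(chars)
}

leb128_decode <- function(s) {
  codes <- utf8ToInt(s) - 48L
  counts <- integer(0)
  i <- 1L
  while (i <= length(codes)) {
    x <- 0L; k <- 0L
    repeat {
      c5 <- codes[i]; i <- i + 1L
      x <- x + bitwShiftL(bitwAnd(c5, 0x1fL), 5L * k)
      k <- k + 1L
      if (bitwAnd(c5, 0x20L) == 0L) {
        if (bitwAnd(c5, 0x10L) != 0L) x <- x - bitwShiftL(1L, 5L * k)
        break
      }
    }
    if (length(counts) >= 2L) x <- x + counts[length(counts) - 1L]
    counts <- c(counts, x)
  }
  counts
}
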