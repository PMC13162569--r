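# Binary masks and connected-component labeling.
#
# A binary mask is a plain logical matrix: rows are image rows (y, top to
# bottom), columns are image columns (x, left to right), so mask[r, c] is the
# pixel whose continuous extent is [c-1, c] x [r-1, r] and whose center sits
# at (c - 0.5, r - 0.5).  Keeping masks as bare matrices makes them
# interoperable with EBImage and with ordinary matrix algebra.

#' Construct a binary mask
#'
#' @param membership A logical (or coercible) matrix; rows index image rows
#'   top-to-bottom, columns index image columns left-to-right.
#' @return A logical matrix.
#' @examples
#' m <- binary_mask(matrix(FALSE, 4, 6))
#' dim(m)
#' @export
binary_mask <- function(membership) {
  if (!is.matrix(membership)) stop_pkg("`membership` must be a matrix")
  storage.mode(membership) <- "logical"
  if (anyNA(membership)) stop_pkg("mask membership must not contain NA")
  membership
}

#' Create an empty (all-background) mask
#'
#' @param height_px,width_px Frame dimensions in pixels (>= 1).
#' @return A logical `height_px` x `width_px` matrix of `FALSE`.
#' @export
empty_mask <- function(height_px, width_px) {
  if (height_px < 1L || width_px < 1L) stop_pkg("mask dimensions must be >= 1")
  matrix(FALSE, nrow = height_px, ncol = width_px)
}

assert_mask <- function(mask, what = "mask") {
  if (!is.matrix(mask) || !is.logical(mask)) {
    stop_pkg("%s must be a logical matrix (see binary_mask())", what)
  }
  invisible(mask)
}

#' Label connected foreground components
#'
#' Foreground connectivity defaults to 8 (diagonal neighbors connect), the
#' convention of mainstream contour extractors; the complementary background
#' is then 4-connected.  Labels are renumbered in raster order of each
#' component's first foreground pixel (top-most, then left-most).
#'
#' @param mask Logical matrix.
#' @param connectivity 4 or 8.
#' @return Integer matrix; 0 is background, components are 1..k.
#' @export
label_components <- function(mask, connectivity = 8L) {
  assert_mask(mask)
  if (!connectivity %in% c(4L, 8L)) stop_pkg("connectivity must be 4 or 8")
  lab <- EBImage::bwlabel(mask * 1L)      # 4-connected labeling
  lab <- matrix(as.integer(round(lab)), nrow(mask), ncol(mask))
  nlab <- max(lab)
  if (connectivity == 8L && nlab > 1L) {
    H <- nrow(lab); W <- ncol(lab)
    # merge labels that touch diagonally (union-find over label ids)
    p <- rbind(
      cbind(as.vector(lab[-H, -W]), as.vector(lab[-1, -1])),
      cbind(as.vector(lab[-H, -1]), as.vector(lab[-1, -W]))
    )
    p <- p[p[, 1] > 0L & p[, 2] > 0L & p[, 1] != p[, 2], , drop = FALSE]
    if (nrow(p)) {
      parent <- seq_len(nlab)
      find <- function(i) {
        while (parent[i] != i) {
          parent[i] <<- parent[parent[i]]
          i <- parent[i]
        }
        i
      }
      for (k in seq_len(nrow(p))) {
        ra <- find(p[k, 1]); rb <- find(p[k, 2])
        if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
      }
      root <- vapply(seq_len(nlab), find, integer(1))
      dense <- match(root, sort(unique(root)))
      lab[lab > 0L] <- dense[lab[lab > 0L]]
    }
  }
  relabel_raster_order(lab)
}

# renumber labels by first foreground pixel in row-major raster order
relabel_raster_order <- function(lab) {
  nlab <- max(lab)
  if (nlab <= 1L) return(lab)
  W <- ncol(lab)
  fg <- which(lab > 0L, arr.ind = TRUE)
  pos <- (fg[, 1] - 1L) * W + (fg[, 2] - 1L)       # row-major position
  first <- tapply(pos, lab[lab > 0L], min)
  ord <- order(first)                               # label id -> rank
  remap <- integer(nlab)
  remap[as.integer(names(first))[ord]] <- seq_len(nlab)
  lab[lab > 0L] <- remap[lab[lab > 0L]]
  lab
}

#' Split a mask into one mask per connected component
#'
#' Components are 8-connected and returned ordered by their top-most then
#' left-most foreground pixel.  The outputs are pairwise disjoint and their
#' union equals the input foreground exactly.
#'
#' @param mask Logical matrix.
#' @return List of logical matrices (empty list for an empty mask).
#' @examples
#' m <- empty_mask(8, 8); m[1:2, 1:2] <- TRUE; m[6:7, 5:6] <- TRUE
#' length(split_components(m))
#' @export
split_components <- function(mask) {
  assert_mask(mask)
  lab <- label_components(mask)
  k <- max(lab)
  if (k == 0L) return(list())
  lapply(seq_len(k), function(i) lab == i)
}

# integer translation with clipping at the frame border
shift_mask <- function(mask, dx = 0L, dy = 0L) {
  assert_mask(mask)
  H <- nrow(mask); W <- ncol(mask)
  out <- empty_mask(H, W)
  src_r <- seq_len(H) - dy
  src_c <- seq_len(W) - dx
  ok_r <- src_r >= 1L & src_r <= H
  ok_c <- src_c >= 1L & src_c <= W
  if (any(ok_r) && any(ok_c)) {
    out[which(ok_r), which(ok_c)] <- mask[src_r[ok_r], src_c[ok_c], drop = FALSE]
  }
  out
}

# morphological dilation/erosion with a (2k+1)-square structuring element
dilate_mask <- function(mask, px) {
  if (px <= 0L) return(mask)
  out <- EBImage::dilate(mask * 1L, EBImage::makeBrush(2L * px + 1L, "box"))
  matrix(as.vector(out) > 0.5, nrow(mask), ncol(mask))
}

erode_mask <- function(mask, px) {
  if (px <= 0L) return(mask)
  out <- EBImage::erode(mask * 1L, EBImage::makeBrush(2L * px + 1L, "box"))
  matrix(as.vector(out) > 0.5, nrow(mask), ncol(mask))
}
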