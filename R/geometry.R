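# Mask-to-polygon geometry: hierarchical contour extraction, simplification,
# minimum-area filtering, donut-shape merging, normalization and a scanline
# rasterizer that inverts the vectorization.
#
# Coordinate convention: a pixel at matrix position [r, c] (1-based) covers
# the continuous square [c-1, c] x [r-1, r]; its center is (c-0.5, r-0.5).
# Contours are traced along pixel EDGES (integer lattice coordinates), so a
# traced contour contains exactly the centers of the pixels it encloses and
# rasterization by center containment is an exact inverse.  Connector
# bridges introduced by donut merging have zero width and cancel under the
# even-odd rule.

#' Construct a contour
#'
#' @param vertices Numeric n x 2 matrix of (x, y) coordinates (closed
#'   implicitly; the first vertex is not repeated).
#' @param role `"outer"` or `"hole"`.
#' @param parent_index For holes, index of the enclosing outer contour in the
#'   containing list; `NA` for outer contours.
#' @return An object of class `contour`.
#' @export
contour <- function(vertices, role = c("outer", "hole"), parent_index = NA_integer_) {
  role <- match.arg(role)
  vertices <- as.matrix(vertices)
  if (ncol(vertices) != 2L || nrow(vertices) < 3L) {
    stop_pkg("a contour needs an n x 2 vertex matrix with n >= 3")
  }
  colnames(vertices) <- c("x", "y")
  if (role == "hole" && is.na(parent_index)) stop_pkg("a hole contour needs a parent_index")
  structure(list(vertices = vertices, role = role,
                 parent_index = as.integer(parent_index)),
            class = "contour")
}

#' @export
print.contour <- function(x, ...) {
  cat(sprintf("<contour %s, %d vertices, area %.1f px>\n",
              x$role, nrow(x$vertices), contour_area(x)))
  invisible(x)
}

#' Enclosed pixel area of a contour
#'
#' Shoelace area; for edge-traced contours this equals the exact number of
#' enclosed pixel cells (holes of an outer contour count as enclosed).
#'
#' @param contour A [contour()] or an n x 2 vertex matrix.
#' @return Non-negative area in pixels.
#' @export
contour_area <- function(contour) {
  abs(signed_area(if (inherits(contour, "contour")) contour$vertices else contour))
}

signed_area <- function(v) {
  n <- nrow(v)
  j <- c(2:n, 1L)
  sum(v[, 1] * v[j, 2] - v[j, 1] * v[, 2]) / 2
}

#' Extract hierarchical contours from a binary mask
#'
#' Boundaries are traced along pixel edges with 8-connected foreground.
#' Every outer contour is followed by links from its holes
#' (`parent_index`); rasterizing each outer region minus its holes
#' reproduces the mask foreground exactly.
#'
#' @param mask Logical matrix.
#' @return List of [contour()]s (empty for an empty mask).  Outer contours
#'   appear in raster order of their components.
#' @examples
#' m <- empty_mask(20, 20); m[3:18, 3:18] <- TRUE; m[8:13, 8:13] <- FALSE
#' cs <- extract_contours(m)
#' vapply(cs, function(ct) ct$role, character(1))
#' @export
extract_contours <- function(mask) {
  assert_mask(mask)
  if (!any(mask)) return(list())
  lab <- label_components(mask)
  loops <- trace_boundaries(mask)
  # classify loops, attach to components, order outers by component id
  comp <- vapply(loops, function(l) lab[l$pixel[1], l$pixel[2]], integer(1))
  pos_area <- vapply(loops, function(l) signed_area(l$vertices), numeric(1))
  outer_idx <- which(pos_area > 0)
  outer_idx <- outer_idx[order(comp[outer_idx])]
  out <- list()
  outer_of_comp <- integer(max(comp))
  for (i in outer_idx) {
    out[[length(out) + 1L]] <- contour(loops[[i]]$vertices, "outer")
    outer_of_comp[comp[i]] <- length(out)
  }
  for (i in which(pos_area < 0)) {
    out[[length(out) + 1L]] <- contour(loops[[i]]$vertices, "hole",
                                       parent_index = outer_of_comp[comp[i]])
  }
  out
}

# Trace all closed crack loops of a mask.  Returns a list of
# list(vertices = n x 2 matrix, pixel = c(r, c) of a generating fg pixel).
trace_boundaries <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  up_bg <- mask & !rbind(FALSE, mask[-H, , drop = FALSE])
  dn_bg <- mask & !rbind(mask[-1, , drop = FALSE], FALSE)
  lf_bg <- mask & !cbind(FALSE, mask[, -W, drop = FALSE])
  rt_bg <- mask & !cbind(mask[, -1, drop = FALSE], FALSE)

  mk <- function(sel, dir) {
    idx <- which(sel, arr.ind = TRUE)
    r <- idx[, 1]; c <- idx[, 2]
    # directed so that foreground stays on the region side of the walk
    switch(dir,
      "0" = data.frame(x0 = c - 1, y0 = r - 1, x1 = c,     y1 = r - 1, d = 0L, r = r, c = c), # top,  +x
      "1" = data.frame(x0 = c,     y0 = r - 1, x1 = c,     y1 = r,     d = 1L, r = r, c = c), # right,+y
      "2" = data.frame(x0 = c,     y0 = r,     x1 = c - 1, y1 = r,     d = 2L, r = r, c = c), # bottom,-x
      "3" = data.frame(x0 = c - 1, y0 = r,     x1 = c - 1, y1 = r - 1, d = 3L, r = r, c = c)  # left, -y
    )
  }
  ed <- rbind(mk(up_bg, "0"), mk(rt_bg, "1"), mk(dn_bg, "2"), mk(lf_bg, "3"))
  n <- nrow(ed)
  vkey <- function(x, y) y * (W + 1) + x + 1
  start_key <- vkey(ed$x0, ed$y0)
  end_key <- vkey(ed$x1, ed$y1)
  out_edges <- split(seq_len(n), start_key)

  used <- logical(n)
  # at a shared-corner vertex prefer the turn that keeps diagonally adjacent
  # foreground pixels in a single loop: d_out = d_in - 90deg, then straight
  pref <- function(d) c((d + 3L) %% 4L, d, (d + 1L) %% 4L)
  loops <- list()
  for (s in seq_len(n)) {
    if (used[s]) next
    path <- integer(0)
    e <- s
    repeat {
      used[e] <- TRUE
      path <- c(path, e)
      cand <- out_edges[[as.character(end_key[e])]]
      cand <- cand[!used[cand]]
      if (!length(cand)) break
      if (length(cand) > 1L) {
        cand <- cand[order(match(ed$d[cand], pref(ed$d[e])))]
      }
      e <- cand[1]
    }
    verts <- cbind(x = ed$x0[path], y = ed$y0[path])
    # drop collinear run-on vertices along straight crack segments
    keep <- collinear_keep(verts)
    loops[[length(loops) + 1L]] <- list(vertices = verts[keep, , drop = FALSE],
                                        pixel = c(ed$r[s], ed$c[s]))
  }
  loops
}

# logical index keeping only direction-change vertices of a closed path
collinear_keep <- function(v) {
  n <- nrow(v)
  prv <- rbind(v[n, ], v[-n, , drop = FALSE])
  nxt <- rbind(v[-1, , drop = FALSE], v[1, ])
  cross <- (v[, 1] - prv[, 1]) * (nxt[, 2] - v[, 2]) -
           (v[, 2] - prv[, 2]) * (nxt[, 1] - v[, 1])
  straight <- cross == 0 &
    ((v[, 1] - prv[, 1]) * (nxt[, 1] - v[, 1]) +
     (v[, 2] - prv[, 2]) * (nxt[, 2] - v[, 2])) > 0
  !straight
}

#' Simplify a contour (Douglas-Peucker)
#'
#' Removes vertices whose perpendicular deviation from the simplified path is
#' at most `tolerance_px`.  Tolerance 0 removes exactly the collinear
#' vertices.
#'
#' @param contour A [contour()].
#' @param tolerance_px Non-negative tolerance in pixels (default 0.5).
#' @return A [contour()] with at most as many vertices.
#' @export
simplify_contour <- function(contour, tolerance_px = 0.5) {
  stopifnot(inherits(contour, "contour"))
  if (tolerance_px < 0) stop_pkg("tolerance_px must be >= 0")
  v <- contour$vertices
  n <- nrow(v)
  if (n <= 3L) return(contour)
  # closed path: anchor at vertex 1 and at the vertex farthest from it
  d1 <- (v[, 1] - v[1, 1])^2 + (v[, 2] - v[1, 2])^2
  a2 <- which.max(d1)
  if (a2 == 1L) return(contour)
  idx1 <- 1:a2
  idx2 <- c(a2:n, 1L)
  half1 <- dp_keep(v[idx1, , drop = FALSE], tolerance_px)
  half2 <- dp_keep(v[idx2, , drop = FALSE], tolerance_px)
  keep <- sort(unique(c(idx1[half1], idx2[half2])))
  out <- v[keep, , drop = FALSE]
  if (nrow(out) < 3L) out <- v[unique(round(seq(1, n, length.out = 3))), , drop = FALSE]
  contour(out, contour$role, contour$parent_index)
}

# iterative Douglas-Peucker on an open polyline; returns kept indices
dp_keep <- function(v, tol) {
  n <- nrow(v)
  keep <- logical(n); keep[c(1L, n)] <- TRUE
  stack <- list(c(1L, n))
  while (length(stack)) {
    seg <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    i <- seg[1]; j <- seg[2]
    if (j - i < 2L) next
    mid <- (i + 1L):(j - 1L)
    d <- point_segment_distance(v[mid, , drop = FALSE], v[i, ], v[j, ])
    k <- mid[which.max(d)]
    if (max(d) > tol + 1e-9) {   # epsilon guards float dust at tolerance 0
      keep[k] <- TRUE
      stack <- c(stack, list(c(i, k)), list(c(k, j)))
    }
  }
  which(keep)
}

point_segment_distance <- function(p, a, b) {
  ab <- b - a
  len2 <- sum(ab^2)
  if (len2 == 0) return(sqrt((p[, 1] - a[1])^2 + (p[, 2] - a[2])^2))
  t <- ((p[, 1] - a[1]) * ab[1] + (p[, 2] - a[2]) * ab[2]) / len2
  t <- pmin(1, pmax(0, t))
  qx <- a[1] + t * ab[1]; qy <- a[2] + t * ab[2]
  sqrt((p[, 1] - qx)^2 + (p[, 2] - qy)^2)
}

#' Discard contours below the minimum pixel area
#'
#' Keeps exactly the contours whose enclosed pixel area is at least
#' `min_area_px` (strictly smaller areas are discarded, so an area equal to
#' the threshold survives).  Holes whose parent outer contour is discarded
#' are discarded with it, and surviving parent links are re-indexed.  The
#' operation is order-preserving and idempotent.
#'
#' @param contours List of [contour()]s.
#' @param min_area_px Minimum retained area (default 30 pixels).
#' @return Filtered list of [contour()]s.
#' @export
filter_small <- function(contours, min_area_px = 30) {
  if (!length(contours)) return(list())
  areas <- vapply(contours, contour_area, numeric(1))
  keep <- areas >= min_area_px
  parent_kept <- function(ct) is.na(ct$parent_index) || keep[ct$parent_index]
  keep <- keep & vapply(contours, parent_kept, logical(1))
  new_index <- cumsum(keep)
  out <- list()
  for (i in which(keep)) {
    ct <- contours[[i]]
    if (ct$role == "hole") ct$parent_index <- new_index[ct$parent_index]
    out[[length(out) + 1L]] <- ct
  }
  out
}

#' Merge an outer contour with its holes into one polygon (donut handling)
#'
#' Annular masks ("donut shapes", e.g. squamous epithelium surrounding the
#' external os) cannot be stored as a single ordinary polygon.  Each hole is
#' spliced into the outer path through a connector bridge of zero width
#' between the closest vertex pair of the current merged path and the hole;
#' under even-odd rasterization the bridge does not fill the hole.  Holes
#' are merged in decreasing area order, traversed with orientation opposite
#' to the outer's; nearest-pair ties break toward the lowest vertex index.
#'
#' @param outer An outer [contour()].
#' @param holes List of hole [contour()]s, each strictly inside `outer`.
#' @return A single [contour()] with role `"outer"`.
#' @export
merge_donut <- function(outer, holes = list()) {
  stopifnot(inherits(outer, "contour"))
  if (outer$role != "outer") stop_pkg("`outer` must have role 'outer'")
  if (!length(holes)) return(outer)
  ov <- outer$vertices
  # outer traversed with positive orientation, holes with the opposite
  if (signed_area(ov) < 0) ov <- ov[rev(seq_len(nrow(ov))), , drop = FALSE]
  hv <- lapply(holes, function(h) {
    stopifnot(inherits(h, "contour"))
    v <- h$vertices
    if (signed_area(v) > 0) v <- v[rev(seq_len(nrow(v))), , drop = FALSE]
    v
  })
  for (v in hv) {
    # interior probe: the cell below-right of the topmost-leftmost vertex is
    # inside any lattice-corner loop; half-integer offsets avoid ray-casting
    # degeneracy on integer coordinates.  Jittered centroid as fallback.
    tl <- v[order(v[, 2], v[, 1])[1], ]
    ctr <- colMeans(v)
    inside <- point_in_path(tl[1] + 0.5, tl[2] + 0.5, ov) ||
      point_in_path(ctr[1] + 1e-4, ctr[2] + 1e-4 * sqrt(2), ov)
    if (!inside) stop_pkg("hole is not inside the outer contour")
  }
  hv <- hv[order(-vapply(hv, function(v) abs(signed_area(v)), numeric(1)))]
  merged <- ov
  for (v in hv) {
    d2 <- base::outer(merged[, 1], v[, 1], "-")^2 +
          base::outer(merged[, 2], v[, 2], "-")^2
    best <- which(d2 == min(d2), arr.ind = TRUE)
    best <- best[order(best[, 1], best[, 2]), , drop = FALSE][1, ]
    i <- best[1]; j <- best[2]
    m <- nrow(v)
    hole_cycle <- v[c(j:m, if (j > 1L) 1:(j - 1L), j), , drop = FALSE]
    merged <- rbind(merged[1:i, , drop = FALSE],
                    hole_cycle,
                    merged[i:nrow(merged), , drop = FALSE])
  }
  contour(merged, "outer")
}

# even-odd point-in-polygon (single closed path, first vertex not repeated)
point_in_path <- function(px, py, v) {
  n <- nrow(v)
  j <- c(2:n, 1L)
  x0 <- v[, 1]; y0 <- v[, 2]; x1 <- v[j, 1]; y1 <- v[j, 2]
  sel <- (pmin(y0, y1) < py) & (pmax(y0, y1) > py)
  if (!any(sel)) return(FALSE)
  xi <- x0[sel] + (py - y0[sel]) * (x1[sel] - x0[sel]) / (y1[sel] - y0[sel])
  sum(xi < px) %% 2 == 1
}

#' Construct a polygon instance (normalized model-ready polygon)
#'
#' @param class_name Mask class the polygon belongs to.
#' @param vertices_norm Numeric n x 2 matrix of (x, y) vertices in `[0, 1]`.
#' @param attributes Named list of attribute values.
#' @return An object of class `polygon_instance`.
#' @export
polygon_instance <- function(class_name, vertices_norm, attributes = list()) {
  vertices_norm <- as.matrix(vertices_norm)
  if (ncol(vertices_norm) != 2L || nrow(vertices_norm) < 3L) {
    stop_pkg("a polygon instance needs an n x 2 vertex matrix with n >= 3")
  }
  if (any(vertices_norm < 0) || any(vertices_norm > 1)) {
    stop_pkg("normalized vertices must lie in [0, 1]")
  }
  colnames(vertices_norm) <- c("x", "y")
  structure(list(class_name = as.character(class_name),
                 attributes = lapply(as.list(attributes), as.character),
                 vertices_norm = vertices_norm),
            class = "polygon_instance")
}

#' Normalize a contour to unit coordinates
#'
#' Divides x by the frame width and y by the frame height and clamps to
#' `[0, 1]`; vertex order is preserved.
#'
#' @param contour A [contour()].
#' @param width_px,height_px Frame dimensions (> 0).
#' @param class_name,attributes Metadata carried onto the polygon.
#' @return A [polygon_instance()].
#' @export
normalize_polygon <- function(contour, width_px, height_px,
                              class_name = "unknown", attributes = list()) {
  stopifnot(inherits(contour, "contour"))
  if (width_px <= 0 || height_px <= 0) stop_pkg("frame dimensions must be positive")
  v <- contour$vertices
  v[, 1] <- pmin(1, pmax(0, v[, 1] / width_px))
  v[, 2] <- pmin(1, pmax(0, v[, 2] / height_px))
  polygon_instance(class_name, v, attributes)
}

#' Rasterize a polygon instance back into a binary mask
#'
#' A pixel is foreground iff its center lies inside the polygon under the
#' even-odd rule, so zero-width connector bridges do not fill holes.  This is
#' the test oracle inverting the vectorization pipeline.
#'
#' @param polygon A [polygon_instance()] (normalized coordinates) or a
#'   [contour()] (pixel coordinates).
#' @param width_px,height_px Frame dimensions.
#' @return A logical matrix.
#' @export
rasterize <- function(polygon, width_px, height_px) {
  if (inherits(polygon, "polygon_instance")) {
    v <- polygon$vertices_norm
    v[, 1] <- v[, 1] * width_px
    v[, 2] <- v[, 2] * height_px
  } else if (inherits(polygon, "contour")) {
    v <- polygon$vertices
  } else {
    stop_pkg("`polygon` must be a polygon_instance or contour")
  }
  rasterize_path(v, width_px, height_px)
}

# even-odd scanline fill of a closed path given in pixel coordinates
rasterize_path <- function(v, width_px, height_px) {
  H <- as.integer(height_px); W <- as.integer(width_px)
  m <- empty_mask(H, W)
  n <- nrow(v)
  j <- c(2:n, 1L)
  x0 <- v[, 1]; y0 <- v[, 2]; x1 <- v[j, 1]; y1 <- v[j, 2]
  ylo <- pmin(y0, y1); yhi <- pmax(y0, y1)
  centers <- seq_len(W) - 0.5
  for (r in seq_len(H)) {
    yc <- r - 0.5
    sel <- ylo < yc & yhi > yc
    if (!any(sel)) next
    xi <- sort(x0[sel] + (yc - y0[sel]) * (x1[sel] - x0[sel]) / (y1[sel] - y0[sel]))
    m[r, findInterval(centers, xi) %% 2L == 1L] <- TRUE
  }
  m
}

#' Vectorize a binary mask into model-ready polygon instances
#'
#' Runs the full pipeline: connected-component splitting, edge-following
#' contour extraction, simplification, minimum-area filtering, donut merging
#' and 0-1 normalization.  Components whose instances survive filtering each
#' yield one simple polygon (holes encoded via connector bridges).
#'
#' @param mask Logical matrix.
#' @param width_px,height_px Frame dimensions (default: mask dimensions).
#' @param tolerance_px Simplification tolerance (default 0.5 px).
#' @param min_area_px Minimum contour area retained (default 30 px).
#' @param class_name,attributes Metadata carried onto the polygons.
#' @param filter_before_merge Apply the area filter before donut merging
#'   (default `TRUE`); set `FALSE` to filter merged polygons instead.
#' @return List of [polygon_instance()]s (one per surviving component).
#' @export
vectorize_mask <- function(mask, width_px = ncol(mask), height_px = nrow(mask),
                           tolerance_px = 0.5, min_area_px = 30,
                           class_name = "unknown", attributes = list(),
                           filter_before_merge = TRUE) {
  assert_mask(mask)
  out <- list()
  for (comp in split_components(mask)) {
    cs <- extract_contours(comp)
    cs <- lapply(cs, simplify_contour, tolerance_px = tolerance_px)
    if (filter_before_merge) cs <- filter_small(cs, min_area_px)
    outers <- which(vapply(cs, function(ct) ct$role == "outer", logical(1)))
    for (oi in outers) {
      holes <- cs[vapply(cs, function(ct)
        ct$role == "hole" && ct$parent_index == oi, logical(1))]
      merged <- merge_donut(cs[[oi]], holes)
      if (!filter_before_merge && contour_area(merged) < min_area_px) next
      out[[length(out) + 1L]] <- normalize_polygon(merged, width_px, height_px,
                                                   class_name, attributes)
    }
  }
  out
}
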