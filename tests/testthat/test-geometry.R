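# Mask-to-polygon geometry: contours, simplification, filtering, donut
# merging, component splitting, normalization, rasterization.

test_that("contour extraction handles empty, solid and annular masks", {
  expect_length(extract_contours(empty_mask(5, 5)), 0)

  solid <- empty_mask(14, 14); solid[3:12, 3:12] <- TRUE
  cs <- extract_contours(solid)
  expect_length(cs, 1)
  expect_equal(cs[[1]]$role, "outer")
  expect_equal(contour_area(cs[[1]]), 100)

  ring <- empty_mask(24, 24); ring[3:22, 3:22] <- TRUE; ring[10:15, 10:15] <- FALSE
  cs <- extract_contours(ring)
  roles <- vapply(cs, function(x) x$role, character(1))
  expect_setequal(roles, c("outer", "hole"))
  hole <- cs[[which(roles == "hole")]]
  expect_equal(hole$parent_index, which(roles == "outer"))
  # rasterization of outer-minus-hole recovers the mask exactly
  rec <- rasterize(cs[[which(roles == "outer")]], 24, 24) &
    !rasterize(hole, 24, 24)
  expect_identical(rec, ring)
})

test_that("simplification respects the deviation tolerance", {
  tri <- contour(rbind(c(0, 0), c(10, 0), c(5, 8)))
  expect_equal(nrow(simplify_contour(tri, 5)$vertices), 3)

  # square boundary with many collinear intermediate vertices
  side <- seq(0, 10, by = 0.1)
  sq <- rbind(cbind(side, 0), cbind(10, side[-1]),
              cbind(rev(side)[-1], 10), cbind(0, rev(side)[-c(1, length(side))]))
  out <- simplify_contour(contour(sq), 0)
  expect_equal(nrow(out$vertices), 4)
  expect_equal(contour_area(out), 100)

  # noisy circle: every removed vertex within tolerance of the kept path
  set.seed(5)
  th <- sort(stats::runif(240, 0, 2 * pi))
  circ <- cbind(20 + (10 + stats::runif(240, -0.2, 0.2)) * cos(th),
                20 + (10 + stats::runif(240, -0.2, 0.2)) * sin(th))
  simp <- simplify_contour(contour(circ), 0.5)$vertices
  # distance from each original vertex to the simplified closed path
  seg_d <- function(p, a, b) {
    ab <- b - a; t <- sum((p - a) * ab) / max(sum(ab^2), 1e-12)
    t <- min(1, max(0, t)); sqrt(sum((a + t * ab - p)^2))
  }
  n <- nrow(simp)
  for (i in seq_len(nrow(circ))) {
    d <- min(vapply(seq_len(n), function(j)
      seg_d(circ[i, ], simp[j, ], simp[(j %% n) + 1, ]), numeric(1)))
    expect_lte(d, 0.5 + 1e-9)
  }
})

test_that("the minimum-area filter keeps area >= 30 and drops orphan holes", {
  expect_identical(filter_small(list()), list())
  mk_square <- function(side) {
    contour(rbind(c(0, 0), c(side, 0), c(side, side), c(0, side)))
  }
  cs <- list(mk_square(5), mk_square(6))      # areas 25 and 36
  out <- filter_small(cs)
  expect_length(out, 1)
  expect_equal(contour_area(out[[1]]), 36)

  # area exactly 30 is retained (only strictly smaller areas are discarded)
  c30 <- contour(rbind(c(0, 0), c(6, 0), c(6, 5), c(0, 5)))
  expect_length(filter_small(list(c30)), 1)

  # a hole whose parent is discarded goes with it; survivors are re-indexed
  small_outer <- mk_square(5)
  its_hole <- contour(rbind(c(1, 1), c(2, 1), c(2, 2), c(1, 2)), "hole", 1)
  big_outer <- mk_square(10)
  big_hole <- contour(rbind(c(2, 2), c(2, 8), c(8, 8), c(8, 2)), "hole", 3)
  out <- filter_small(list(small_outer, its_hole, big_outer, big_hole))
  expect_length(out, 2)
  expect_equal(out[[2]]$parent_index, 1)

  # idempotent and order-preserving
  expect_identical(filter_small(out), out)
})

test_that("donut merging splices holes without filling them", {
  ring <- empty_mask(30, 30); ring[6:25, 6:25] <- TRUE; ring[13:18, 13:18] <- FALSE
  cs <- extract_contours(ring)
  roles <- vapply(cs, function(x) x$role, character(1))
  outer <- cs[[which(roles == "outer")]]
  hole <- cs[[which(roles == "hole")]]

  expect_identical(merge_donut(outer, list()), outer)    # no holes: identity

  merged <- merge_donut(outer, list(hole))
  m <- rasterize(merged, 30, 30)
  expect_equal(sum(m), 400 - 36)
  expect_identical(m, ring)                              # hole pixels stay empty

  # splice audit: vertex count is outer + hole + 2 duplicates
  expect_equal(nrow(merged$vertices), nrow(outer$vertices) + nrow(hole$vertices) + 2)
})

test_that("multiple holes are all spliced and preserved empty", {
  m <- empty_mask(40, 40); m[3:38, 3:38] <- TRUE
  m[8:13, 8:13] <- FALSE; m[25:34, 22:31] <- FALSE
  cs <- extract_contours(m)
  roles <- vapply(cs, function(x) x$role, character(1))
  outer <- cs[[which(roles == "outer")]]
  holes <- cs[roles == "hole"]
  merged <- merge_donut(outer, holes)
  expect_identical(rasterize(merged, 40, 40), m)
  nv <- vapply(holes, function(h) nrow(h$vertices), integer(1))
  expect_equal(nrow(merged$vertices), nrow(outer$vertices) + sum(nv + 2))
})

test_that("a hole outside the outer contour is a topology error", {
  outer <- contour(rbind(c(0, 0), c(10, 0), c(10, 10), c(0, 10)))
  stray <- contour(rbind(c(20, 20), c(24, 20), c(24, 24), c(20, 24)), "hole", 1)
  expect_error(merge_donut(outer, list(stray)), "not inside")
})

test_that("component splitting matches a flood-fill oracle and conserves pixels", {
  expect_length(split_components(empty_mask(6, 6)), 0)

  two <- empty_mask(12, 12); two[2:4, 2:4] <- TRUE; two[8:10, 8:10] <- TRUE
  parts <- split_components(two)
  expect_length(parts, 2)
  expect_identical(parts[[1]] | parts[[2]], two)
  expect_equal(sum(parts[[1]] & parts[[2]]), 0)
  # ordering: top-most then left-most first pixel
  expect_true(parts[[1]][2, 2])

  set.seed(99)
  for (i in 1:10) {
    m <- random_mask(30, 30, p = 0.25)
    parts <- split_components(m)
    expect_equal(length(parts), flood_fill_count(m))
    un <- empty_mask(30, 30)
    for (p in parts) {
      expect_equal(sum(un & p), 0)       # pairwise disjoint
      un <- un | p
    }
    expect_identical(un, m)              # union conserved
  }
})

test_that("diagonally touching pixels form a single 8-connected component", {
  m <- empty_mask(6, 6); m[1, 1] <- TRUE; m[2, 2] <- TRUE; m[3, 3] <- TRUE
  expect_length(split_components(m), 1)
})

test_that("normalization maps the frame to the unit square and roundtrips", {
  ct <- contour(rbind(c(0, 0), c(64, 0), c(64, 48), c(0, 48)))
  pg <- normalize_polygon(ct, 64, 48)
  expect_equal(pg$vertices_norm[1, ], c(x = 0, y = 0))
  expect_equal(pg$vertices_norm[3, ], c(x = 1, y = 1))
  expect_error(normalize_polygon(ct, 0, 48), "positive")

  set.seed(3)
  v <- cbind(stats::runif(17, 0, 64), stats::runif(17, 0, 48))
  pg <- normalize_polygon(contour(v), 64, 48)
  back <- cbind(pg$vertices_norm[, 1] * 64, pg$vertices_norm[, 2] * 48)
  expect_lt(max(abs(back - v) / pmax(abs(v), 1)), 1e-9)
})

test_that("rasterization inverts vectorization", {
  full <- polygon_instance("x", rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)))
  expect_true(all(rasterize(full, 12, 10)))

  degenerate <- polygon_instance("x", rbind(c(0.5, 0.5), c(0.5, 0.5), c(0.5, 0.5)))
  expect_equal(sum(rasterize(degenerate, 12, 10)), 0)

  # vectorize-then-rasterize on scenes with structures >= 100 px
  for (seed in c(2, 8)) {
    sc <- generate_scene(default_scene_spec(seed))
    im <- sc$set$images[[1]]
    for (sh in im$shapes) {
      m <- rle_decode(sh$payload, im$width_px, im$height_px)
      if (sum(m) < 100) next
      polys <- vectorize_mask(m, im$width_px, im$height_px, min_area_px = 0)
      rec <- empty_mask(im$height_px, im$width_px)
      for (pg in polys) rec <- rec | rasterize(pg, im$width_px, im$height_px)
      expect_gte(dice_of(rec, m), 0.99)
    }
  }
})

test_that("the ring fixture survives the full pipeline with its hole intact", {
  ring <- empty_mask(60, 60); ring[11:50, 11:50] <- TRUE; ring[26:35, 26:35] <- FALSE
  polys <- vectorize_mask(ring)
  expect_length(polys, 1)
  rec <- rasterize(polys[[1]], 60, 60)
  expect_equal(sum(rec & !ring), 0)            # zero hole/outside pixels filled
  expect_gte(dice_of(rec, ring), 0.99)
})
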