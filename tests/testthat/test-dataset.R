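# Dataset curation: filtering, per-class variants, seeded splits, exports.

quality_tag <- function(value) list(tag_record("image quality", value))

test_that("quality-tag rejection and unannotated-image removal", {
  tags <- list(quality_tag("Unusable image"), quality_tag("High quality image"))
  set <- make_plain_set(2, tags = tags)
  out <- filter_images(set, filter_policy(resolution_policy = "keep-all"))
  expect_length(out$images, 1)
  expect_equal(out$images[[1]]$image_id, "2")

  # unannotated image dropped by default, kept when disabled
  set2 <- make_plain_set(3, shapes_for = c(1, 3))
  out2 <- filter_images(set2, filter_policy(resolution_policy = "keep-all"))
  expect_setequal(names(out2$images), c("1", "3"))
  out3 <- filter_images(set2, filter_policy(resolution_policy = "keep-all",
                                            drop_unannotated = FALSE))
  expect_length(out3$images, 3)
})

test_that("the two most common resolutions are retained", {
  mk <- function(id, w, h) {
    m <- empty_mask(min(h, 20), min(w, 20)); m[2:8, 2:8] <- TRUE
    p <- rle_encode(m); p2 <- rle_payload(p$runs, "cvat-bbox", p$anchor_box)
    image_record(id, paste0(id, ".png"), w, h,
                 shapes = list(mask_shape("Cervix", p2)))
  }
  imgs <- c(lapply(1:5, function(k) mk(sprintf("a%d", k), 717, 539)),
            lapply(1:3, function(k) mk(sprintf("b%d", k), 1280, 960)),
            list(mk("tiny", 167, 130)))
  set <- annotation_set(default_vocabulary(), imgs)
  out <- filter_images(set, filter_policy())
  expect_length(out$images, 8)
  expect_false("tiny" %in% names(out$images))
})

test_that("resolution frequency ties break by area then lexicographically", {
  mk <- function(id, w, h) {
    m <- empty_mask(20, 20); m[2:8, 2:8] <- TRUE
    image_record(id, paste0(id, ".png"), w, h,
                 shapes = list(mask_shape("Cervix", rle_encode(m))))
  }
  # three resolutions, one image each: 100x100 (area 10000), 200x60 (12000),
  # 120x100 (12000).  Kept: the two largest areas; among equal areas the
  # comparator is deterministic, so repeated runs agree.
  set <- annotation_set(default_vocabulary(),
                        list(mk("p", 100, 100), mk("q", 200, 60), mk("r", 120, 100)))
  out1 <- filter_images(set, filter_policy())
  out2 <- filter_images(set, filter_policy())
  expect_identical(names(out1$images), names(out2$images))
  expect_length(out1$images, 2)
  expect_false("p" %in% names(out1$images))   # smallest area loses the tie-break
})

test_that("filtering everything warns rather than failing silently", {
  set <- make_plain_set(1, tags = list(quality_tag("Unusable image")))
  expect_warning(filter_images(set, filter_policy(resolution_policy = "keep-all")),
                 "every image")
})

test_that("general variant keeps positives only when no backgrounds requested", {
  set <- make_plain_set(6, shapes_for = 1:4)
  set0 <- filter_images(set, filter_policy(resolution_policy = "keep-all",
                                           drop_unannotated = FALSE))
  ds <- build_class_dataset(set0, variant_spec("Cervix"), seed = 1)
  expect_setequal(names(ds$images), as.character(1:4))
  ds2 <- build_class_dataset(set0, variant_spec("Cervix", background_count_general = 2),
                             seed = 1)
  expect_length(ds2$images, 6)
  bg <- setdiff(names(ds2$images), as.character(1:4))
  expect_true(all(vapply(ds2$images[bg], function(im) length(im$shapes) == 0, logical(1))))
})

test_that("extended variant injects difficult backgrounds with the other attribute", {
  m <- empty_mask(24, 32); m[4:12, 4:12] <- TRUE
  mk <- function(id, attr_value) {
    image_record(id, paste0(id, ".png"), 32, 24, shapes = list(
      mask_shape("Squamous epithelium", rle_encode(m),
                 list("epithelium type" = attr_value))))
  }
  imgs <- c(lapply(1:3, function(k) mk(sprintf("met%d", k), "metaplastic")),
            lapply(1:4, function(k) mk(sprintf("orig%d", k), "original")))
  set <- annotation_set(default_vocabulary(), imgs)
  spec <- variant_spec("Squamous epithelium", "extended",
                       "epithelium type", "metaplastic",
                       background_count_difficult = 2)
  ds <- build_class_dataset(set, spec, seed = 9)
  expect_length(ds$images, 5)
  added <- setdiff(names(ds$images), sprintf("met%d", 1:3))
  expect_length(added, 2)
  expect_true(all(grepl("^orig", added)))
  # difficult backgrounds lose their (other-attribute) shapes in label output
  expect_true(all(vapply(ds$images[added], function(im) length(im$shapes) == 0,
                         logical(1))))
  # positives keep only target-attribute shapes
  expect_true(all(vapply(ds$images[sprintf("met%d", 1:3)],
                         function(im) length(im$shapes) == 1, logical(1))))
})

test_that("background sampling is seeded and capped with a warning", {
  set <- make_plain_set(104, shapes_for = 1:4)
  set0 <- filter_images(set, filter_policy(resolution_policy = "keep-all",
                                           drop_unannotated = FALSE))
  spec <- variant_spec("Cervix", background_count_general = 10)
  a <- build_class_dataset(set0, spec, seed = 5)
  b <- build_class_dataset(set0, spec, seed = 5)
  expect_identical(names(a$images), names(b$images))
  c_ <- build_class_dataset(set0, spec, seed = 6)
  expect_false(identical(names(a$images), names(c_$images)))

  expect_warning(
    build_class_dataset(set0, variant_spec("Cervix", background_count_general = 1000),
                        seed = 1),
    "only 100 available")
})

test_that("variant_spec rejects inconsistent requests", {
  expect_error(variant_spec("Cervix", "extended"), "attribute_key")
  expect_error(variant_spec("Cervix", "general", background_count_difficult = 1),
               "extended")
  set <- make_plain_set(2)
  expect_error(build_class_dataset(set, variant_spec("No such class"), 1),
               "not in the vocabulary")
})

test_that("splits follow 70/20/10 with remainder to train, then val, then test", {
  set <- make_plain_set(10)
  man <- split_dataset(set, seed = 1)
  tab <- table(man$assignment)
  expect_equal(unname(tab[c("train", "val", "test")]), c(7L, 2L, 1L),
               ignore_attr = TRUE)

  # a single image lands in train by the remainder rule
  man1 <- split_dataset(make_plain_set(1), seed = 1)
  expect_equal(unname(man1$assignment), "train")

  # n divisible by 10: exact proportions
  man20 <- split_dataset(make_plain_set(20), seed = 3)
  tab20 <- table(man20$assignment)
  expect_equal(unname(tab20[c("train", "val", "test")]), c(14L, 4L, 2L),
               ignore_attr = TRUE)

  # total partition
  expect_setequal(names(man$assignment), names(set$images))
  expect_false(anyNA(man$assignment))
})

test_that("patient-level splits never divide a patient and are reproducible", {
  pats <- rep(c("PA", "PB", "PC"), times = c(5, 3, 2))
  set <- make_plain_set(10, patient_ids = pats)
  man <- split_dataset(set, seed = 7, group_key = "patient")
  by_pat <- tapply(man$assignment, pats, function(x) length(unique(x)))
  expect_true(all(by_pat == 1))
  man2 <- split_dataset(set, seed = 7, group_key = "patient")
  expect_identical(man$assignment, man2$assignment)

  no_pat <- make_plain_set(3)
  expect_error(split_dataset(no_pat, seed = 1, group_key = "patient"),
               "lack patient ids")
})

test_that("split rejects malformed proportions", {
  set <- make_plain_set(5)
  expect_error(split_dataset(set, c(0.5, 0.5), 1), "three positive")
  expect_error(split_dataset(set, c(0.6, 0.3, 0.2), 1), "summing to 1")
})

test_that("YOLO label export writes one line per polygon in 6-decimal format", {
  set <- make_plain_set(5)
  man <- split_dataset(set, seed = 2)
  td <- withr::local_tempdir()
  b <- export_yolo_labels(set, man, td)
  expect_length(b$label_files, 5)
  lines <- readLines(b$label_files[["1"]])
  expect_length(lines, 1)
  fields <- strsplit(lines, " ")[[1]]
  expect_equal(length(fields), 1 + 2 * 4)     # class index + 4 vertices
  expect_equal(fields[1], "0")
  expect_true(all(grepl("^[01]\\.\\d{6}$", fields[-1])))
  expect_true(file.exists(b$manifest_file))
})

test_that("background images get empty label files and lines rasterize back", {
  set <- make_plain_set(6, shapes_for = 1:5)
  set0 <- filter_images(set, filter_policy(resolution_policy = "keep-all",
                                           drop_unannotated = FALSE))
  man <- split_dataset(set0, seed = 4)
  td <- withr::local_tempdir()
  b <- export_yolo_labels(set0, man, td)
  expect_identical(readLines(b$label_files[["6"]]), character(0))

  cim <- setNames(0L, "Cervix")
  im <- set0$images[["2"]]
  polys <- read_yolo_labels(b$label_files[["2"]], cim)
  rec <- Reduce(`|`, lapply(polys, rasterize, width_px = im$width_px,
                            height_px = im$height_px))
  gt <- rle_decode(im$shapes[[1]]$payload, im$width_px, im$height_px)
  expect_gte(dice_of(rec, gt), 0.99)
})

test_that("exports are byte-identical under the same seed", {
  set <- generate_scene_set(6, seed = 12, width_px = 48, height_px = 36)
  run <- function() {
    td <- withr::local_tempdir()
    man <- split_dataset(set, seed = 5)
    export_yolo_labels(set, man, td)
    export_coco(set, man, td)
    files <- sort(list.files(td, recursive = TRUE))
    content <- lapply(files, function(f) readLines(file.path(td, f), warn = FALSE))
    list(files = files, content = content)
  }
  expect_identical(run(), run())
})

test_that("COCO export keeps category ids stable across subsets", {
  set <- generate_scene_set(6, seed = 13, width_px = 48, height_px = 36)
  man <- split_dataset(set, seed = 1)
  td <- withr::local_tempdir()
  paths <- export_coco(set, man, td)
  cats <- lapply(paths, function(p) {
    doc <- jsonlite::fromJSON(p, simplifyVector = FALSE)
    vapply(doc$categories, function(ct) paste(ct$id, ct$name), character(1))
  })
  expect_identical(cats[[1]], cats[[2]])
  expect_identical(cats[[1]], cats[[3]])
})
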