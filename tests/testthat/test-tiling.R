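test_that("tile count closed form matches the stated examples", {
  expect_equal(count_tiles(1024, 1024, 512, 256), 9L)
  expect_equal(count_tiles(512, 512, 512, 256), 1L)
  expect_equal(count_tiles(500, 800, 512, 256), 0L)
  expect_error(count_tiles(100, 100, 32, 0), "stride")
})

test_that("tile count closed form agrees with exhaustive enumeration", {
  # brute-force oracle: enumerate all origins along one axis
  positions_1d <- function(L, T, S) sum(seq(0, max(0, L), by = S) + T <= L)
  for (T in 1:16) {
    for (S in c(1L, 2L, 3L, T %/% 2 + (T %/% 2 == 0), T)) {
      for (L in c(1:20, 31:33, 63:64)) {
        expect_equal(count_tiles(L, 64, T, S),
                     positions_1d(L, T, S) * positions_1d(64, T, S),
                     info = sprintf("L=%d T=%d S=%d", L, T, S))
      }
    }
  }
})

test_that("ROI tiles enumerate the brute-force positions with the ROI label", {
  roi <- data.frame(x = 64L, y = 32L, width = 1024L, height = 1024L,
                    label = "gbm")
  slide <- make_slide("t1", 1280, 1152, rois = roi, diagnosis = "gbm")
  ds <- extract_roi_tiles(slide, tile_size = 512, overlap = 0.5)
  expect_equal(nrow(ds$tiles), 9L)
  expect_true(all(ds$tiles$label == "gbm"))
  expect_true(all(ds$tiles$provenance == "ground_truth"))
  # brute-force origin enumeration
  expect_setequal(unique(ds$tiles$x), 64L + c(0L, 256L, 512L))
  expect_setequal(unique(ds$tiles$y), 32L + c(0L, 256L, 512L))
  # tiles never cross the ROI boundary
  expect_true(all(ds$tiles$x + ds$tiles$size <= roi$x + roi$width))
  expect_true(all(ds$tiles$y + ds$tiles$size <= roi$y + roi$height))
})

test_that("disjoint ROIs contribute independent tile sets", {
  rois <- data.frame(x = c(0L, 640L), y = c(0L, 0L),
                     width = c(512L, 512L), height = c(512L, 512L),
                     label = c("gbm", "normal"))
  slide <- make_slide("t2", 1280, 512, rois = rois, diagnosis = "gbm")
  ds <- extract_roi_tiles(slide, tile_size = 512, overlap = 0.5)
  expect_equal(nrow(ds$tiles), 2L)
  expect_equal(ds$class_counts[["gbm"]], 1L)
  expect_equal(ds$class_counts[["normal"]], 1L)
})

test_that("conflicting overlapping ROIs and out-of-bounds ROIs error", {
  rois <- data.frame(x = c(0L, 0L), y = c(0L, 0L),
                     width = c(512L, 512L), height = c(512L, 512L),
                     label = c("gbm", "necrosis"))
  slide <- make_slide("t3", 512, 512, rois = rois, diagnosis = "gbm")
  expect_error(extract_roi_tiles(slide, 512, 0.5), "overlapping ROIs")
  slide2 <- make_slide("t4", 400, 400,
                       rois = data.frame(x = 0L, y = 0L, width = 512L,
                                         height = 512L, label = "gbm"),
                       diagnosis = "gbm")
  expect_error(extract_roi_tiles(slide2, 512, 0.5), "outside slide bounds")
})

test_that("grid tiles cover the slide and exclude_rois drops intersections", {
  slide <- make_slide("g1", 1024, 1024, diagnosis = "gbm")
  ds <- grid_tiles(slide, 512, 0.5)
  expect_equal(nrow(ds$tiles), 9L)
  expect_true(all(ds$tiles$provenance == "unlabeled"))

  # fully covered by one ROI -> zero tiles under exclusion
  slide$rois <- data.frame(x = 0L, y = 0L, width = 1024L, height = 1024L,
                           label = "gbm")
  expect_equal(nrow(grid_tiles(slide, 512, 0.5,
                               exclude_rois = TRUE)$tiles), 0L)

  # 1536x1024 slide, 512x512 ROI at origin: brute-force intersection oracle
  slide3 <- make_slide("g2", 1536, 1024,
                       rois = data.frame(x = 0L, y = 0L, width = 512L,
                                         height = 512L, label = "gbm"),
                       diagnosis = "gbm")
  all_tiles <- grid_tiles(slide3, 512, 0.5)$tiles
  kept <- grid_tiles(slide3, 512, 0.5, exclude_rois = TRUE)$tiles
  overlaps <- function(x, y) x < 512 && y < 512  # half-open rectangles
  expected_kept <- all_tiles[!mapply(overlaps, all_tiles$x, all_tiles$y), ]
  expect_equal(nrow(all_tiles), 15L)
  expect_equal(nrow(kept), nrow(expected_kept))
  expect_setequal(paste(kept$x, kept$y),
                  paste(expected_kept$x, expected_kept$y))
  expect_equal(nrow(all_tiles) - nrow(kept), 4L)
})

test_that("tissue filter keeps dark tiles, boundary inclusive", {
  white <- array(1, dim = c(64, 64, 3))
  dark <- array(0, dim = c(64, 64, 3))
  # tile with exactly 5% dark pixels
  edge <- array(1, dim = c(64, 64, 3))
  ndark <- ceiling(0.05 * 64 * 64)
  edge[seq_len(ndark)] <- 0; edge[seq_len(ndark) + 64 * 64] <- 0
  edge[seq_len(ndark) + 2 * 64 * 64] <- 0
  canvas <- array(1, dim = c(64, 192, 3))
  canvas[, 65:128, ] <- dark
  canvas[, 129:192, ] <- edge
  slide <- make_slide("tf", 192, 64, diagnosis = "gbm", pixels = canvas)
  ds <- grid_tiles(slide, 64, overlap = 0)
  expect_equal(nrow(ds$tiles), 3L)

  kept <- tissue_filter(ds, min_foreground_fraction = 0.05)
  expect_setequal(kept$tiles$x, c(64L, 128L))  # white tile removed,
                                               # exact-5% tile retained
  # threshold 0 is the identity
  expect_equal(nrow(tissue_filter(ds, 0)$tiles), 3L)
})

test_that("D4 orbit has 8 distinct members, closed under composition", {
  set.seed(11)
  px <- array(runif(8 * 8 * 3), dim = c(8, 8, 3))  # asymmetric pattern
  orbit <- augment_d4(px)
  expect_length(orbit, 8)
  keys <- vapply(orbit, function(a) paste(signif(a, 12), collapse = ","), "")
  expect_equal(length(unique(keys)), 8L)

  # group closure: orbit of any member equals the original orbit as a set
  for (tag in d4_tags()) {
    orbit2 <- augment_d4(orbit[[tag]])
    keys2 <- vapply(orbit2, function(a) paste(signif(a, 12), collapse = ","),
                    "")
    expect_setequal(unname(keys2), unname(keys))
  }

  # constant tile: all 8 views identical
  const <- array(0.5, dim = c(8, 8, 3))
  oc <- augment_d4(const)
  expect_true(all(vapply(oc, function(a) identical(a, const), logical(1))))

  expect_error(augment_d4(array(0, dim = c(4, 8, 3))), "square")
})

test_that("dataset augmentation multiplies ground truth by 8, never test", {
  roi <- data.frame(x = 0L, y = 0L, width = 128L, height = 128L,
                    label = "ac")
  slide <- make_slide("a1", 128, 128, rois = roi, diagnosis = "ac",
                      split = "train")
  ds <- extract_roi_tiles(slide, 64, 0.5)
  aug <- augment_dataset(ds)
  expect_equal(nrow(aug$tiles), 8L * nrow(ds$tiles))
  expect_equal(aug$class_counts[["ac"]], 8L * ds$class_counts[["ac"]])
  expect_setequal(unique(aug$tiles$aug), d4_tags())
  # augmented views load as the D4 transforms of the identity view
  base <- tile_pixels(ds, 1)
  rows1 <- which(aug$tiles$x == ds$tiles$x[1] & aug$tiles$y == ds$tiles$y[1])
  for (r in rows1) {
    expect_equal(tile_pixels(aug, r), d4_apply(base, aug$tiles$aug[r]))
  }

  slide$split <- "test"
  ds_test <- extract_roi_tiles(slide, 64, 0.5)
  expect_error(augment_dataset(ds_test), "test-split")
})

test_that("channel stats equal a brute-force pixel pool and normalization
           round-trips", {
  roi <- data.frame(x = 0L, y = 0L, width = 192L, height = 128L,
                    label = "gbm")
  slide <- make_slide("c1", 192, 128, rois = roi, diagnosis = "gbm",
                      seed = 5)
  ds <- extract_roi_tiles(slide, 64, 0.5)
  st <- compute_channel_stats(ds)

  # brute force: flatten every tile's pixels and recompute
  pool <- lapply(seq_len(nrow(ds$tiles)), function(i) tile_pixels(ds, i))
  for (k in 1:3) {
    v <- unlist(lapply(pool, function(p) as.numeric(p[, , k])))
    expect_equal(st$mean[k], mean(v), tolerance = 1e-12)
    expect_equal(st$std[k], sqrt(mean((v - mean(v))^2)), tolerance = 1e-12)
  }

  # normalizing the set that produced the stats gives mean 0, sd 1
  for (k in 1:3) {
    v <- unlist(lapply(pool, function(p) {
      as.numeric(normalize_pixels(p, st)[, , k])
    }))
    expect_equal(mean(v), 0, tolerance = 1e-6)
    expect_equal(sqrt(mean(v^2)), 1, tolerance = 1e-6)
  }

  # identity stats and algebraic round-trip
  ident <- structure(list(mean = c(0, 0, 0), std = c(1, 1, 1), source = "id"),
                     class = "channel_stats")
  px <- pool[[1]]
  expect_identical(normalize_pixels(px, ident), px)
  expect_equal(denormalize_pixels(normalize_pixels(px, st), st), px,
               tolerance = 1e-6)
  expect_error(normalize_pixels(array(0, c(4, 4, 1)), st), "channel count")

  # constant tiles: epsilon-floored std
  cpx <- array(0, dim = c(32, 32, 3))
  cpx[, , 1] <- 100 / 255; cpx[, , 2] <- 150 / 255; cpx[, , 3] <- 200 / 255
  cslide <- make_slide("c2", 32, 32, diagnosis = "gbm", pixels = cpx,
                       rois = data.frame(x = 0L, y = 0L, width = 32L,
                                         height = 32L, label = "gbm"))
  cds <- extract_roi_tiles(cslide, 32, 0.5)
  cst <- compute_channel_stats(cds)
  expect_equal(cst$mean, c(100, 150, 200) / 255, tolerance = 1e-2)
  expect_true(all(cst$std >= 1e-6))

  expect_error(compute_channel_stats(
    gliotile:::new_tile_dataset(gliotile:::empty_tiles(), scheme5)), "empty")
})

test_that("extraction is deterministic and order-stable", {
  rois <- data.frame(x = c(128L, 0L), y = c(0L, 64L),
                     width = c(128L, 128L), height = c(128L, 128L),
                     label = c("gbm", "normal"))
  slide <- make_slide("o1", 256, 256, rois = rois, diagnosis = "gbm")
  ds1 <- extract_roi_tiles(slide, 64, 0.5)
  ds2 <- extract_roi_tiles(slide, 64, 0.5)
  expect_identical(ds1$tiles, ds2$tiles)
  ord <- order(ds1$tiles$slide_id, ds1$tiles$y, ds1$tiles$x)
  expect_identical(ord, seq_len(nrow(ds1$tiles)))
})

test_that("tile manifests round-trip through TSV", {
  roi <- data.frame(x = 0L, y = 0L, width = 128L, height = 128L,
                    label = "odg")
  slide <- make_slide("m1", 128, 128, rois = roi, diagnosis = "odg")
  ds <- extract_roi_tiles(slide, 64, 0.5)
  path <- tempfile(fileext = ".tsv")
  write_tile_manifest(ds, path)
  back <- read_tile_manifest(path)
  expect_equal(back$tiles$x, ds$tiles$x)
  expect_equal(back$tiles$label, ds$tiles$label)
  expect_equal(back$class_counts, ds$class_counts)
})
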