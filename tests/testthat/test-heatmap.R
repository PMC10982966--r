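test_that("single-tile and two-tile accumulation follow the mean rule", {
  slide <- make_slide("h1", 256, 256, diagnosis = "gbm")
  # one 128-tile at the origin, stride 64
  p <- matrix(c(0.5, 0.2, 0.1, 0.1, 0.1), nrow = 1)
  ds <- gliotile:::new_tile_dataset(data.frame(
    slide_id = "h1", image_path = slide$image_path, x = 0L, y = 0L,
    size = 128L, label = NA_character_, provenance = "unlabeled",
    split = "none", aug = "id", stringsAsFactors = FALSE), scheme5)
  colnames(p) <- paste0("prob_", scheme5$labels)
  preds <- cbind(ds$tiles[, c("slide_id", "x", "y", "size", "split")],
                 as.data.frame(p))
  preds$predicted_label <- "ac"; preds$confidence <- 0.5
  preds <- structure(preds, class = c("prediction_set", "data.frame"),
                     scheme = scheme5)
  grid <- accumulate_tile_scores(preds, slide, stride = 64)
  # the tile covers cells (1:2, 1:2); its vector is constant there
  expect_equal(grid$scores$ac[1, 1], 0.5)
  expect_equal(grid$scores$ac[2, 2], 0.5)
  expect_true(is.na(grid$scores$ac[3, 3]))
  expect_equal(grid$coverage[1, 1], 1L)

  # two overlapping tiles: mean (p+q)/2 on the overlap
  tiles2 <- rbind(ds$tiles, within(ds$tiles, x <- 64L))
  ds2 <- gliotile:::new_tile_dataset(tiles2, scheme5)
  q <- matrix(c(0.1, 0.1, 0.1, 0.2, 0.5), nrow = 1,
              dimnames = list(NULL, paste0("prob_", scheme5$labels)))
  P2 <- rbind(p, q)[order(tiles2$x), , drop = FALSE]
  preds2 <- cbind(ds2$tiles[, c("slide_id", "x", "y", "size", "split")],
                  as.data.frame(P2))
  preds2$predicted_label <- scheme5$labels[max.col(P2)]
  preds2$confidence <- apply(P2, 1, max)
  preds2 <- structure(preds2, class = c("prediction_set", "data.frame"),
                      scheme = scheme5)
  g2 <- accumulate_tile_scores(preds2, slide, stride = 64)
  expect_equal(g2$scores$ac[1, 2], (0.5 + 0.1) / 2)       # overlap column
  expect_equal(g2$scores$necrosis[1, 2], (0.1 + 0.5) / 2)
  expect_equal(g2$scores$ac[1, 1], 0.5)                   # p-only column
  expect_equal(g2$coverage[1, 2], 2L)

  # off-grid coordinates are rejected
  bad <- preds; bad$x <- 13L
  expect_error(accumulate_tile_scores(bad, slide, stride = 64), "off the")
})

test_that("random layouts match a dense per-pixel averaging oracle and stay
           on the simplex", {
  set.seed(37)
  for (rep in 1:5) {
    slide <- make_slide(paste0("ho", rep), 192, 192, diagnosis = "gbm",
                        seed = rep)
    tile <- 64L; stride <- 32L
    ds <- grid_tiles(slide, tile, overlap = 0.5)
    n <- nrow(ds$tiles)
    keep <- sort(sample(n, max(3, n %/% 2)))  # random sub-layout
    ds <- gliotile:::new_tile_dataset(ds$tiles[keep, ], scheme5)
    P <- rdirichlet_rows(nrow(ds$tiles))
    colnames(P) <- paste0("prob_", scheme5$labels)
    preds <- cbind(ds$tiles[, c("slide_id", "x", "y", "size", "split")],
                   as.data.frame(P))
    preds$predicted_label <- scheme5$labels[max.col(P, ties.method = "first")]
    preds$confidence <- apply(P, 1, max)
    preds <- structure(preds, class = c("prediction_set", "data.frame"),
                       scheme = scheme5)
    grid <- accumulate_tile_scores(preds, slide, stride)

    # dense oracle: accumulate per pixel, then read off cell corners
    acc <- array(0, dim = c(192, 192, 5)); cov <- matrix(0, 192, 192)
    for (i in seq_len(nrow(preds))) {
      rs <- (preds$y[i] + 1):(preds$y[i] + tile)
      cs <- (preds$x[i] + 1):(preds$x[i] + tile)
      cov[rs, cs] <- cov[rs, cs] + 1
      for (k in 1:5) acc[rs, cs, k] <- acc[rs, cs, k] + P[i, k]
    }
    for (cy in seq_len(nrow(grid$coverage))) {
      for (cx in seq_len(ncol(grid$coverage))) {
        py <- (cy - 1) * stride + 1; px <- (cx - 1) * stride + 1
        expect_equal(grid$coverage[cy, cx], cov[py, px])
        if (cov[py, px] > 0) {
          for (k in 1:5) {
            expect_equal(grid$scores[[scheme5$labels[k]]][cy, cx],
                         acc[py, px, k] / cov[py, px], tolerance = 1e-12)
          }
        }
      }
    }

    # simplex preservation at every covered cell
    covered <- grid$coverage > 0
    total <- Reduce(`+`, grid$scores)
    expect_equal(unname(total[covered]), rep(1, sum(covered)),
                 tolerance = 1e-6)

    # permuting tile input order leaves the grid unchanged
    perm <- sample(nrow(preds))
    preds_p <- structure(preds[perm, ],
                         class = c("prediction_set", "data.frame"),
                         scheme = scheme5)
    grid_p <- accumulate_tile_scores(preds_p, slide, stride)
    expect_equal(grid_p$scores, grid$scores)
  }
})

test_that("stride equal to tile size reproduces raw tile probabilities", {
  slide <- make_slide("hs", 192, 192, diagnosis = "gbm")
  ds <- grid_tiles(slide, 64, overlap = 0)
  P <- rdirichlet_rows(nrow(ds$tiles))
  colnames(P) <- paste0("prob_", scheme5$labels)
  preds <- cbind(ds$tiles[, c("slide_id", "x", "y", "size", "split")],
                 as.data.frame(P))
  preds$predicted_label <- scheme5$labels[max.col(P, ties.method = "first")]
  preds$confidence <- apply(P, 1, max)
  preds <- structure(preds, class = c("prediction_set", "data.frame"),
                     scheme = scheme5)
  grid <- accumulate_tile_scores(preds, slide, stride = 64)
  for (i in seq_len(nrow(preds))) {
    cy <- preds$y[i] / 64 + 1; cx <- preds$x[i] / 64 + 1
    expect_equal(grid$scores$odg[cy, cx], unname(P[i, 2]),
                 tolerance = 1e-12)
  }
  expect_true(all(grid$coverage == 1))
})

test_that("overlay rendering blends red proportionally to the class score", {
  v <- 128 / 255  # representable exactly in the 8-bit PNG
  slide <- make_slide("hr", 128, 128, diagnosis = "gbm",
                      pixels = array(v, dim = c(128, 128, 3)))
  ds <- grid_tiles(slide, 64, overlap = 0)
  # score 1 for gbm on the left tiles, 0 on the right
  P <- matrix(0, nrow(ds$tiles), 5,
              dimnames = list(NULL, paste0("prob_", scheme5$labels)))
  P[, "prob_gbm"] <- ifelse(ds$tiles$x == 0, 1, 0)
  P[, "prob_normal"] <- 1 - P[, "prob_gbm"]
  preds <- cbind(ds$tiles[, c("slide_id", "x", "y", "size", "split")],
                 as.data.frame(P))
  preds$predicted_label <- ifelse(P[, "prob_gbm"] == 1, "gbm", "normal")
  preds$confidence <- 1
  preds <- structure(preds, class = c("prediction_set", "data.frame"),
                     scheme = scheme5)
  grid <- accumulate_tile_scores(preds, slide, stride = 64)

  ov <- render_overlay(grid, slide$image_path, "gbm", alpha = 0.4,
                       colorbar = FALSE)
  expect_equal(dim(ov), c(128, 128, 3))
  # score-1 region: full blend toward red at alpha
  expect_equal(ov[1, 1, 1], 0.6 * v + 0.4 * 1, tolerance = 1e-6)
  expect_equal(ov[1, 1, 2], 0.6 * v, tolerance = 1e-6)
  # score-0 region: untouched
  expect_equal(ov[1, 128, ], c(v, v, v), tolerance = 1e-6)

  # zero scores everywhere: output equals the input image
  Pz <- P; Pz[, "prob_gbm"] <- 0; Pz[, "prob_normal"] <- 1
  predz <- preds
  predz[, paste0("prob_", scheme5$labels)] <- Pz
  gz <- accumulate_tile_scores(predz, slide, stride = 64)
  ovz <- render_overlay(gz, slide$image_path, "gbm", alpha = 0.4,
                        colorbar = FALSE)
  expect_equal(max(abs(ovz - v)), 0, tolerance = 1e-6)

  # with the color bar the width grows, the height does not
  ovb <- render_overlay(grid, slide$image_path, "gbm", alpha = 0.4)
  expect_equal(dim(ovb)[1], 128)
  expect_gt(dim(ovb)[2], 128)

  expect_error(render_overlay(grid, "no/such/file.png", "gbm"),
               "missing slide image")
  expect_error(render_overlay(grid, slide$image_path, "zz"), "unknown class")
})

test_that("slide summary fractions partition the covered area and flag
           inconclusive tumor calls", {
  slide <- make_slide("hsum", 192, 192, diagnosis = "gbm")
  ds <- grid_tiles(slide, 64, overlap = 0)  # 9 tiles, one cell each
  n <- nrow(ds$tiles)
  P <- matrix(0.02, n, 5, dimnames = list(NULL,
                                          paste0("prob_", scheme5$labels)))
  # all cells argmax gbm
  P[, "prob_gbm"] <- 0.92
  mk <- function(P) {
    preds <- cbind(ds$tiles[, c("slide_id", "x", "y", "size", "split")],
                   as.data.frame(P))
    idx <- max.col(P, ties.method = "first")
    preds$predicted_label <- scheme5$labels[idx]
    preds$confidence <- P[cbind(seq_len(n), idx)]
    structure(preds, class = c("prediction_set", "data.frame"),
              scheme = scheme5)
  }
  g <- accumulate_tile_scores(mk(P), slide, stride = 64)
  s <- slide_summary(g)
  expect_equal(unname(s$fractions["gbm"]), 1)
  expect_equal(s$dominant_tumor, "gbm")
  expect_false(s$inconclusive)
  expect_equal(sum(s$fractions), 1)

  # odg 4/9 vs ac 3/9: lead 1/9 = 0.111 > margin 0.1 -> conclusive;
  # odg 4/9 vs ac 4/9: tie -> inconclusive
  P2 <- matrix(0.02, n, 5, dimnames = dimnames(P))
  P2[1:4, "prob_odg"] <- 0.92
  P2[5:8, "prob_ac"] <- 0.92
  P2[9, "prob_normal"] <- 0.92
  s2 <- slide_summary(accumulate_tile_scores(mk(P2), slide, stride = 64))
  expect_equal(s2$dominant_tumor, "ac")  # equal fractions: tie broken by
                                         # scheme label order (ac first)
  expect_true(s2$inconclusive)
  expect_equal(sum(s2$fractions), 1)

  P3 <- matrix(0.02, n, 5, dimnames = dimnames(P))
  P3[1:5, "prob_odg"] <- 0.92
  P3[6:8, "prob_ac"] <- 0.92
  P3[9, "prob_normal"] <- 0.92
  s3 <- slide_summary(accumulate_tile_scores(mk(P3), slide, stride = 64))
  expect_equal(s3$dominant_tumor, "odg")
  expect_false(s3$inconclusive)  # lead 2/9 > 0.1
})
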