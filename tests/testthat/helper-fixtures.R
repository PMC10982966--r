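# Fixtures are built programmatically: small random slides written as PNG
# into tempdir(), miniature synthetic cohorts, and randomized prediction
# sets for the filter/heatmap property tests.

scheme5 <- class_scheme()

# Write a random-pixel slide PNG and return its slide record.
make_slide <- function(slide_id = "s1", width = 256, height = 256,
                       rois = NULL, diagnosis = "gbm", split = "train",
                       seed = 1, dir = tempdir(), pixels = NULL) {
  path <- file.path(dir, paste0(slide_id, ".png"))
  if (is.null(pixels)) {
    set.seed(seed)
    pixels <- array(runif(height * width * 3), dim = c(height, width, 3))
  }
  png::writePNG(pixels, path)
  if (is.null(rois)) {
    rois <- data.frame(x = integer(), y = integer(), width = integer(),
                       height = integer(), label = character())
  }
  list(slide_id = slide_id, image_path = path, width = width,
       height = height, diagnosis = diagnosis, split = split,
       rois = rois, regions = NULL)
}

# Miniature synthetic cohort: 128-px tiles so texture and training tests
# stay fast. Geometry scales down; densities are per pixel and unchanged.
mini_cohort <- function(n_slides = 6, tiles_per_slide = 6, difficulty = 0,
                        roi_coverage = 1, seed = 1, tile_size = 128,
                        slide_size = c(512, 512)) {
  cfg <- synthetic_config(
    n_slides = n_slides, slide_size = slide_size,
    tiles_per_slide = tiles_per_slide, difficulty = difficulty,
    roi_coverage = roi_coverage, tile_size = tile_size, seed = seed)
  generate_cohort(cfg, out_dir = tempfile("mini_cohort"))
}

# Random prediction set over random tiles with per-slide diagnoses.
# Probabilities are normalized Gamma draws (Dirichlet), occasionally made
# extreme so both sides of the 0.90 gate are exercised.
random_predictions <- function(n, seed = 1, scheme = scheme5) {
  set.seed(seed)
  n_slides <- max(2, n %/% 20)
  diagnoses <- setNames(
    sample(c(scheme$tumor_labels, scheme$normal_label), n_slides,
           replace = TRUE),
    sprintf("rs%03d", seq_len(n_slides)))
  slide_id <- sample(names(diagnoses), n, replace = TRUE)
  P <- matrix(rgamma(n * 5, shape = 0.5), ncol = 5)
  sharp <- runif(n) < 0.4  # sharpen some rows above the gate
  P[sharp, ] <- P[sharp, ] + 20 * diag(5)[sample.int(5, sum(sharp),
                                                     replace = TRUE), ]
  P <- P / rowSums(P)
  colnames(P) <- paste0("prob_", scheme$labels)
  tiles <- data.frame(
    slide_id = slide_id, image_path = "unused.png",
    x = sample(0:31, n, replace = TRUE) * 64L,
    y = sample(0:31, n, replace = TRUE) * 64L,
    size = 128L, label = NA_character_, provenance = "unlabeled",
    split = "train", aug = "id", stringsAsFactors = FALSE)
  ds <- gliotile:::new_tile_dataset(tiles, scheme)
  # align probabilities with the dataset's canonical tile order
  ord <- order(tiles$slide_id, tiles$y, tiles$x, tiles$aug)
  P <- P[ord, , drop = FALSE]
  preds <- cbind(ds$tiles[, c("slide_id", "x", "y", "size", "split")],
                 as.data.frame(P))
  idx <- max.col(P, ties.method = "first")
  preds$predicted_label <- scheme$labels[idx]
  preds$confidence <- P[cbind(seq_len(n), idx)]
  preds <- structure(preds, class = c("prediction_set", "data.frame"),
                     scheme = scheme)
  list(predictions = preds, tiles = ds, diagnoses = diagnoses)
}

# A prediction set on a regular stride grid of one slide, for heatmap tests.
grid_predictions <- function(slide, probs, tile_size, stride,
                             scheme = scheme5) {
  ds <- grid_tiles(slide, tile_size = tile_size,
                   overlap = 1 - stride / tile_size, scheme = scheme)
  stopifnot(nrow(ds$tiles) == nrow(probs))
  colnames(probs) <- paste0("prob_", scheme$labels)
  out <- cbind(ds$tiles[, c("slide_id", "x", "y", "size", "split")],
               as.data.frame(probs))
  idx <- max.col(probs, ties.method = "first")
  out$predicted_label <- scheme$labels[idx]
  out$confidence <- probs[cbind(seq_len(nrow(probs)), idx)]
  structure(out, class = c("prediction_set", "data.frame"), scheme = scheme)
}

# Dirichlet rows that sum to 1, for heatmap fixtures.
rdirichlet_rows <- function(n, k = 5) {
  P <- matrix(rgamma(n * k, shape = 1), ncol = k)
  P / rowSums(P)
}
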