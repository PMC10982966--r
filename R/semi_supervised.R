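#' Pseudo-label policy
#'
#' Controls the second (semi-supervised) training step: a prediction on an
#' unannotated tile becomes a pseudo label only when its confidence (maximum
#' class probability) is at least `confidence_threshold` (inclusive, default
#' 0.90) AND, when `enforce_diagnosis` is on, the predicted class is
#' permitted on the tile's slide given its diagnosis (see
#' [allowed_classes()]). Pseudo tiles are not dihedrally augmented by
#' default: their labels are noisy and augmentation would amplify the noise.
#'
#' @param confidence_threshold Minimum predicted probability in \[0, 1\].
#' @param enforce_diagnosis Apply the diagnosis-consistency filter.
#' @param augment_pseudo Apply the 8-view D4 augmentation to retained
#'   pseudo tiles before retraining.
#' @param min_foreground_fraction Tissue-filter threshold applied to the
#'   unannotated grid before prediction; 0 disables the filter.
#' @return Object of class `pseudo_label_policy`.
#' @export
pseudo_label_policy <- function(confidence_threshold = 0.90,
                                enforce_diagnosis = TRUE,
                                augment_pseudo = FALSE,
                                min_foreground_fraction = 0) {
  stopifnot(confidence_threshold >= 0, confidence_threshold <= 1,
            min_foreground_fraction >= 0, min_foreground_fraction <= 1)
  structure(list(confidence_threshold = confidence_threshold,
                 enforce_diagnosis = isTRUE(enforce_diagnosis),
                 augment_pseudo = isTRUE(augment_pseudo),
                 min_foreground_fraction = min_foreground_fraction),
            class = "pseudo_label_policy")
}

#' Confidence- and diagnosis-gated pseudo-label filter
#'
#' Turns model predictions on unannotated tiles into a pseudo-labeled
#' `tile_dataset`. A prediction is retained iff `confidence >=
#' policy$confidence_threshold` (the comparison is inclusive, so exactly
#' 0.90 passes a 0.90 gate) and, under diagnosis enforcement, the predicted
#' class is in [allowed_classes()] of the slide's diagnosis. Retained tiles
#' carry `label = predicted_label` and provenance `pseudo`.
#'
#' @param predictions A `prediction_set` from [predict_proba()].
#' @param tiles The `tile_dataset` the predictions were computed on (same
#'   row order).
#' @param slide_diagnoses Named character vector mapping `slide_id` to its
#'   diagnosis; every predicted slide must be present.
#' @param policy A [pseudo_label_policy()].
#' @return A list: `dataset` (the retained pseudo `tile_dataset`) and
#'   `audit` (one row per input prediction with `retained` and
#'   `rejection_reason` in `low_confidence`, `impossible_class`, `none`).
#' @export
pseudo_label_filter <- function(predictions, tiles, slide_diagnoses,
                                policy = pseudo_label_policy()) {
  stopifnot(inherits(predictions, "prediction_set"),
            nrow(predictions) == nrow(tiles$tiles))
  scheme <- tiles$scheme
  miss <- setdiff(unique(predictions$slide_id), names(slide_diagnoses))
  if (length(miss)) {
    stop("missing diagnosis for slide(s): ", paste(miss, collapse = ", "))
  }
  conf_ok <- predictions$confidence >= policy$confidence_threshold
  diag_ok <- if (policy$enforce_diagnosis && nrow(predictions)) {
    vapply(seq_len(nrow(predictions)), function(i) {
      predictions$predicted_label[i] %in%
        allowed_classes(slide_diagnoses[[predictions$slide_id[i]]], scheme)
    }, logical(1))
  } else {
    rep(TRUE, nrow(predictions))
  }
  retained <- conf_ok & diag_ok
  reason <- ifelse(retained, "none",
                   ifelse(!conf_ok, "low_confidence", "impossible_class"))

  audit <- data.frame(
    slide_id = predictions$slide_id, x = predictions$x, y = predictions$y,
    predicted_label = predictions$predicted_label,
    confidence = predictions$confidence,
    retained = as.integer(retained), rejection_reason = reason,
    stringsAsFactors = FALSE)

  kept <- tiles$tiles[retained, , drop = FALSE]
  if (nrow(kept)) {
    kept$label <- predictions$predicted_label[retained]
    kept$provenance <- "pseudo"
  }
  list(dataset = new_tile_dataset(kept, scheme), audit = audit)
}

#' Merge ground-truth and pseudo-labeled tiles
#'
#' Concatenates the two datasets for retraining. Tile identities
#' (slide, position, augmentation view) must be disjoint; the merged size is
#' exactly the sum of the two sizes and per-class counts are additive, the
#' bookkeeping by which the training set grows after the pseudo-label step.
#'
#' @param ground_truth,pseudo `tile_dataset` objects sharing a scheme.
#' @return The merged `tile_dataset`.
#' @export
merge_datasets <- function(ground_truth, pseudo) {
  key <- function(t) paste(t$slide_id, t$x, t$y, t$size, t$aug)
  dup <- intersect(key(ground_truth$tiles), key(pseudo$tiles))
  if (length(dup)) {
    stop("tile identity collision between ground-truth and pseudo sets: ",
         paste(utils::head(dup, 5), collapse = "; "),
         if (length(dup) > 5) " ..." else "")
  }
  bind_tile_datasets(ground_truth, pseudo)
}

#' Two-step semi-supervised training
#'
#' The full procedure: (1) train on the pathologist-annotated ground-truth
#' tiles of the training slides (8-view augmented); (2) predict
#' pseudo-labels for the unannotated grid tiles of the *training* slides
#' only, gate them by confidence and slide diagnosis, merge with the ground
#' truth, and retrain a fresh model on the merged set. Both models are
#' evaluated on the untouched test-split ROI tiles (never augmented, never
#' pseudo-labeled).
#'
#' @param cohort A `glioma_cohort` with train/test slide splits.
#' @param spec A [classifier_spec()].
#' @param config A [training_config()]; step 2 uses `config$seed + 1` for a
#'   fresh, seed-controlled initialization.
#' @param policy A [pseudo_label_policy()].
#' @param tile_size,overlap Tiling geometry.
#' @return Object of class `two_step_result`: `fit1`, `fit2`, `metrics1`,
#'   `metrics2` ([metrics_report()] on the test tiles), `pseudo_counts`
#'   (retained pseudo tiles per class), `audit`, `n_ground_truth`,
#'   `n_merged`, `test_predictions` (step-2 `prediction_set`).
#' @export
run_two_step <- function(cohort, spec = classifier_spec(),
                         config = training_config(),
                         policy = pseudo_label_policy(),
                         tile_size = 512, overlap = 0.5) {
  scheme <- cohort$scheme
  train_slides <- Filter(function(s) s$split == "train", cohort$slides)
  test_slides <- Filter(function(s) s$split == "test", cohort$slides)
  if (!length(train_slides) || !length(test_slides)) {
    stop("cohort must contain both train and test slides")
  }

  gt <- do.call(bind_tile_datasets, lapply(train_slides, extract_roi_tiles,
                                           tile_size = tile_size,
                                           overlap = overlap, scheme = scheme))
  gt_aug <- augment_dataset(gt)
  stats <- compute_channel_stats(gt)
  gt_aug <- normalize_tiles(gt_aug, stats)

  fit1 <- fit(gt_aug, spec, config)

  test <- do.call(bind_tile_datasets, lapply(test_slides, extract_roi_tiles,
                                             tile_size = tile_size,
                                             overlap = overlap,
                                             scheme = scheme))
  eval_fit <- function(f) {
    preds <- predict_proba(test, f)
    cm <- confusion_matrix(test$tiles$label, preds$predicted_label, scheme)
    metrics_report(cm)
  }
  metrics1 <- eval_fit(fit1)

  # pseudo-label the unannotated grid of the TRAINING slides only
  grid <- do.call(bind_tile_datasets, lapply(train_slides, grid_tiles,
                                             tile_size = tile_size,
                                             overlap = overlap,
                                             exclude_rois = TRUE,
                                             scheme = scheme))
  if (policy$min_foreground_fraction > 0) {
    grid <- tissue_filter(grid, policy$min_foreground_fraction)
  }
  diagnoses <- stats::setNames(
    vapply(cohort$slides, `[[`, "", "diagnosis"),
    vapply(cohort$slides, `[[`, "", "slide_id"))
  grid_preds <- predict_proba(grid, fit1)
  flt <- pseudo_label_filter(grid_preds, grid, diagnoses, policy)
  pseudo <- flt$dataset
  if (policy$augment_pseudo && nrow(pseudo$tiles)) {
    pseudo <- augment_dataset(pseudo)
  }

  merged <- merge_datasets(gt_aug, pseudo)
  merged <- normalize_tiles(merged, stats)
  config2 <- config
  config2$seed <- config$seed + 1L
  fit2 <- fit(merged, spec, config2)
  metrics2 <- eval_fit(fit2)

  structure(
    list(fit1 = fit1, fit2 = fit2,
         metrics1 = metrics1, metrics2 = metrics2,
         pseudo_counts = pseudo$class_counts, audit = flt$audit,
         n_ground_truth = nrow(gt_aug$tiles), n_merged = nrow(merged$tiles),
         channel_stats = stats,
         test_predictions = predict_proba(test, fit2)),
    class = "two_step_result"
  )
}

#' @export
print.two_step_result <- function(x, ...) {
  cat("<two_step_result>\n",
      "  ground-truth training tiles (augmented): ", x$n_ground_truth, "\n",
      "  merged training tiles after pseudo-labeling: ", x$n_merged, "\n",
      "  step 1 test balanced accuracy: ",
      round(x$metrics1$macro["balanced_accuracy"], 4), "\n",
      "  step 2 test balanced accuracy: ",
      round(x$metrics2$macro["balanced_accuracy"], 4), "\n", sep = "")
  invisible(x)
}

#' Write the pseudo-label audit manifest
#'
#' TSV with one row per predicted grid tile: position, predicted label,
#' confidence, whether it was retained and the rejection reason
#' (`low_confidence`, `impossible_class` or `none`).
#'
#' @param audit The `audit` component of [pseudo_label_filter()] /
#'   [run_two_step()].
#' @param path Output TSV path.
#' @export
write_pseudo_manifest <- function(audit, path) {
  utils::write.table(audit, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
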