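#' Pipeline run configuration
#'
#' Validates and completes a nested configuration list (or YAML file) for
#' [run_pipeline()]. Unknown keys anywhere in the configuration are errors,
#' so a typo in a threshold name cannot silently fall back to a default.
#'
#' Sections and defaults:
#' \describe{
#'   \item{seed}{global seed, propagated to every stochastic stage (default 1)}
#'   \item{out_dir}{run directory (default a fresh temporary directory)}
#'   \item{cohort}{arguments of [synthetic_config()] except `seed`}
#'   \item{tiling}{`tile_size` (512), `overlap` (0.5)}
#'   \item{training}{`backbone` plus arguments of [training_config()] except
#'     `seed`}
#'   \item{pseudo}{`enabled` (TRUE) plus arguments of
#'     [pseudo_label_policy()]}
#'   \item{heatmap}{`enabled` (TRUE), `alpha` (0.4), `classes` ("argmax" or
#'     a label)}
#' }
#'
#' @param config A nested list or the path of a YAML file.
#' @return The completed configuration list, classed `run_config`.
#' @export
run_config <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  defaults <- list(
    seed = 1L,
    out_dir = NULL,
    cohort = list(n_slides = 8, slide_size = c(1536L, 1536L),
                  tiles_per_slide = 10, difficulty = 0, roi_coverage = 1,
                  test_fraction = 0.25, image_format = "png"),
    tiling = list(tile_size = 512L, overlap = 0.5),
    training = list(backbone = "texture_softmax", epochs = 10L,
                    batch_size = 32L, learning_rate = 0.5,
                    validation_fraction = 0.2,
                    class_weight_mode = "inverse_frequency"),
    pseudo = list(enabled = TRUE, confidence_threshold = 0.90,
                  enforce_diagnosis = TRUE, augment_pseudo = FALSE,
                  min_foreground_fraction = 0),
    heatmap = list(enabled = TRUE, alpha = 0.4, classes = "argmax")
  )
  check_keys <- function(given, known, where) {
    bad <- setdiff(names(given), known)
    if (length(bad)) {
      stop("unknown configuration key(s) in ", where, ": ",
           paste(bad, collapse = ", "))
    }
  }
  check_keys(config, names(defaults), "top level")
  out <- defaults
  out$seed <- as.integer(config$seed %||% defaults$seed)
  out$out_dir <- config$out_dir %||% tempfile("gliotile_run")
  extra_cohort <- c("imbalance_targets", "diagnosis_weights")
  for (sec in c("cohort", "tiling", "training", "pseudo", "heatmap")) {
    if (!is.null(config[[sec]])) {
      known <- names(defaults[[sec]])
      if (sec == "cohort") known <- c(known, extra_cohort)
      check_keys(config[[sec]], known, sec)
      out[[sec]] <- utils::modifyList(out[[sec]], config[[sec]])
    }
  }
  structure(out, class = "run_config")
}

#' Run the full pipeline
#'
#' Executes the end-to-end workflow -- synthesize cohort, tile, train,
#' pseudo-label, retrain, evaluate, render heatmaps -- and writes every
#' artifact into the run directory together with a run manifest recording
#' the configuration snapshot, its hash and the seed. Re-running with an
#' identical configuration reproduces the metrics exactly. When the pseudo
#' stage is disabled only the step-1 model and evaluation are produced.
#'
#' @param config A [run_config()], a nested list, or a YAML path.
#' @param scheme A [class_scheme()].
#' @return Invisibly, a list: `dir`, `cohort`, and either a
#'   `two_step_result` (`result`) or the step-1 `fit`/`metrics`.
#' @export
run_pipeline <- function(config = run_config(), scheme = class_scheme()) {
  if (!inherits(config, "run_config")) config <- run_config(config)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_stage <- function(stage, ...) {
    message(sprintf("[%s] %s %s", format(Sys.time(), "%H:%M:%S"),
                    stage, paste0(..., collapse = "")))
  }
  snapshot <- file.path(config$out_dir, "config.yaml")
  yaml::write_yaml(unclass(config), snapshot)

  run <- function(stage, expr) {
    t0 <- proc.time()[["elapsed"]]
    r <- tryCatch(expr, error = function(e) {
      stop("stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    log_stage(stage, sprintf("done in %.1fs", proc.time()[["elapsed"]] - t0))
    r
  }

  cohort <- run("synth", {
    args <- config$cohort
    args$seed <- config$seed
    if (!is.null(args$imbalance_targets)) {
      args$imbalance_targets <- unlist(args$imbalance_targets)
    }
    if (!is.null(args$diagnosis_weights)) {
      args$diagnosis_weights <- unlist(args$diagnosis_weights)
    }
    args$tile_size <- config$tiling$tile_size
    args$overlap <- config$tiling$overlap
    cfg <- do.call(synthetic_config, args)
    generate_cohort(cfg, scheme, file.path(config$out_dir, "cohort"))
  })

  spec <- classifier_spec(backbone = config$training$backbone,
                          n_classes = length(scheme$labels),
                          input_size = config$tiling$tile_size,
                          seed = config$seed)
  tcfg <- training_config(
    epochs = config$training$epochs,
    batch_size = config$training$batch_size,
    learning_rate = config$training$learning_rate,
    validation_fraction = config$training$validation_fraction,
    class_weight_mode = config$training$class_weight_mode,
    seed = config$seed)

  result <- NULL
  if (isTRUE(config$pseudo$enabled)) {
    policy <- pseudo_label_policy(
      confidence_threshold = config$pseudo$confidence_threshold,
      enforce_diagnosis = config$pseudo$enforce_diagnosis,
      augment_pseudo = config$pseudo$augment_pseudo,
      min_foreground_fraction = config$pseudo$min_foreground_fraction)
    result <- run("train+pseudo+retrain", {
      run_two_step(cohort, spec, tcfg, policy,
                   tile_size = config$tiling$tile_size,
                   overlap = config$tiling$overlap)
    })
    run("eval", {
      write_metrics_report(result$metrics1,
                           file.path(config$out_dir, "metrics_step1.json"),
                           file.path(config$out_dir, "confusion_step1.tsv"))
      write_metrics_report(result$metrics2,
                           file.path(config$out_dir, "metrics_step2.json"),
                           file.path(config$out_dir, "confusion_step2.tsv"))
      write_pseudo_manifest(result$audit,
                            file.path(config$out_dir, "pseudo_manifest.tsv"))
      write_channel_stats(result$channel_stats,
                          file.path(config$out_dir, "channel_stats.json"))
    })
  } else {
    step1 <- run("train", {
      train_slides <- Filter(function(s) s$split == "train", cohort$slides)
      gt <- do.call(bind_tile_datasets,
                    lapply(train_slides, extract_roi_tiles,
                           tile_size = config$tiling$tile_size,
                           overlap = config$tiling$overlap, scheme = scheme))
      gt_aug <- augment_dataset(gt)
      write_tile_manifest(gt_aug, file.path(config$out_dir, "tiles_train.tsv"))
      fit(gt_aug, spec, tcfg)
    })
    metrics1 <- run("eval", {
      test_slides <- Filter(function(s) s$split == "test", cohort$slides)
      test <- do.call(bind_tile_datasets,
                      lapply(test_slides, extract_roi_tiles,
                             tile_size = config$tiling$tile_size,
                             overlap = config$tiling$overlap,
                             scheme = scheme))
      preds <- predict_proba(test, step1)
      m <- metrics_report(confusion_matrix(test$tiles$label,
                                           preds$predicted_label, scheme))
      write_metrics_report(m, file.path(config$out_dir, "metrics_step1.json"),
                           file.path(config$out_dir, "confusion_step1.tsv"))
      m
    })
    result <- list(fit1 = step1, metrics1 = metrics1)
  }

  if (isTRUE(config$heatmap$enabled)) {
    run("heatmap", {
      final_fit <- if (inherits(result, "two_step_result")) result$fit2
                   else result$fit1
      stride <- as.integer(round(config$tiling$tile_size *
                                   (1 - config$tiling$overlap)))
      test_slides <- Filter(function(s) s$split == "test", cohort$slides)
      summaries <- lapply(test_slides, function(sl) {
        grid_ds <- grid_tiles(sl, config$tiling$tile_size,
                              config$tiling$overlap, scheme = scheme)
        preds <- predict_proba(grid_ds, final_fit)
        grid <- accumulate_tile_scores(preds, sl, stride)
        summ <- slide_summary(grid, scheme)
        cls <- if (identical(config$heatmap$classes, "argmax")) {
          summ$dominant_tumor
        } else config$heatmap$classes
        ov <- render_overlay(grid, sl$image_path, cls,
                             alpha = config$heatmap$alpha)
        png::writePNG(ov, file.path(config$out_dir,
                                    paste0("heatmap_", sl$slide_id, "_",
                                           cls, ".png")))
        c(list(slide_id = sl$slide_id, diagnosis = sl$diagnosis,
               rendered_class = cls), summ)
      })
      jsonlite::write_json(summaries,
                           file.path(config$out_dir, "slide_summaries.json"),
                           auto_unbox = TRUE, digits = NA)
    })
  }

  manifest <- list(
    seed = config$seed,
    config_file = basename(snapshot),
    config_md5 = unname(tools::md5sum(snapshot)),
    n_slides = length(cohort$slides),
    realized_shares = as.list(cohort$realized_shares),
    stages = c("synth",
               if (isTRUE(config$pseudo$enabled))
                 c("tile", "train", "pseudo", "retrain") else
                 c("tile", "train"),
               "eval",
               if (isTRUE(config$heatmap$enabled)) "heatmap")
  )
  if (inherits(result, "two_step_result")) {
    manifest$n_ground_truth <- result$n_ground_truth
    manifest$n_merged <- result$n_merged
    manifest$pseudo_counts <- as.list(result$pseudo_counts)
  }
  jsonlite::write_json(manifest,
                       file.path(config$out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(dir = config$out_dir, cohort = cohort, result = result))
}
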