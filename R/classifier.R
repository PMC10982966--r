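#' Inverse-frequency class weights
#'
#' Computes the per-class loss weights `w_c = N / (K * n_c)` where `N` is
#' the total tile count, `K` the number of classes present and `n_c` the
#' count of class `c`. The weights have weighted mean 1 over the dataset,
#' so `sum_c n_c * w_c = N` exactly and the loss scale is comparable across
#' imbalance levels. A class listed with count zero is an error: drop it
#' from the scheme explicitly instead.
#'
#' @param class_counts Named integer vector of per-class tile counts.
#' @return Named numeric vector of weights.
#' @examples
#' class_weights(c(a = 10, b = 30))  # 2, 2/3
#' @export
class_weights <- function(class_counts) {
  if (any(class_counts == 0)) {
    stop("zero-count class(es): ",
         paste(names(class_counts)[class_counts == 0], collapse = ", "),
         "; drop them from the scheme explicitly")
  }
  n <- sum(class_counts)
  k <- length(class_counts)
  n / (k * class_counts)
}

#' Class-weighted categorical cross-entropy
#'
#' Loss of one probability vector against its true label:
#' `-w[true] * log(p[true])`, with probabilities clipped to `[1e-12, 1]`.
#' Batch losses are averaged over tiles.
#'
#' @param probs Named probability vector summing to 1.
#' @param true_label The true class label (a name of `probs`).
#' @param weights Named per-class weights, e.g. from [class_weights()];
#'   missing classes default to weight 1.
#' @return The scalar loss.
#' @export
weighted_cross_entropy <- function(probs, true_label, weights = NULL) {
  if (!true_label %in% names(probs)) {
    stop("label not in probability vector: ", true_label)
  }
  p <- probs[[true_label]]
  w <- if (is.null(weights)) 1 else weights[[true_label]] %||% 1
  -w * log(clamp(p, 1e-12, 1))
}

# ---- backbone registry -----------------------------------------------------

backbone_registry <- new.env(parent = emptyenv())

#' Backbone registry
#'
#' A backbone is a feature extractor over normalized tile pixels plus a
#' softmax head (optionally with one hidden tanh layer), trained by seeded
#' minibatch SGD. Two backbones ship with the package:
#' `"texture_softmax"` (linear softmax over per-channel moments and coarse
#' 2x2 block means; the default) and `"texture_mlp"` (the same features
#' through a 16-unit hidden layer). Users can register their own with
#' `register_backbone()`; the featurizer receives a normalized
#' `H x W x 3` array and must return a fixed-length numeric vector.
#'
#' @param name Backbone identifier.
#' @param featurize Function `array -> numeric vector`.
#' @param hidden Hidden-layer width; 0 for a linear softmax head.
#' @export
register_backbone <- function(name, featurize, hidden = 0L) {
  stopifnot(is.character(name), is.function(featurize), hidden >= 0)
  assign(name, list(name = name, featurize = featurize,
                    hidden = as.integer(hidden)),
         envir = backbone_registry)
  invisible(name)
}

#' @rdname register_backbone
#' @export
list_backbones <- function() sort(ls(backbone_registry))

get_backbone <- function(name) {
  if (!exists(name, envir = backbone_registry)) {
    stop("unknown backbone: ", name, "; see list_backbones()")
  }
  get(name, envir = backbone_registry)
}

# Per-channel mean and sd plus 2x2 block per-channel means: 18 features that
# capture overall staining intensity, texture contrast and coarse layout.
texture_features <- function(px) {
  h <- dim(px)[1]; w <- dim(px)[2]
  hs <- max(1L, h %/% 2L); ws <- max(1L, w %/% 2L)
  out <- numeric(18)
  for (k in 1:3) {
    ch <- px[, , k]
    out[k] <- mean(ch)
    out[3 + k] <- stats::sd(ch)
    out[6 + (k - 1) * 4 + 1] <- mean(ch[1:hs, 1:ws])
    out[6 + (k - 1) * 4 + 2] <- mean(ch[1:hs, (ws + 1):w])
    out[6 + (k - 1) * 4 + 3] <- mean(ch[(hs + 1):h, 1:ws])
    out[6 + (k - 1) * 4 + 4] <- mean(ch[(hs + 1):h, (ws + 1):w])
  }
  out
}

.onLoad <- function(libname, pkgname) {
  register_backbone("texture_softmax", texture_features, hidden = 0L)
  register_backbone("texture_mlp", texture_features, hidden = 16L)
}

#' Classifier and training configuration
#'
#' @param backbone Backbone name from the registry.
#' @param n_classes Number of classes (must match the scheme).
#' @param input_size Expected tile side in pixels.
#' @param seed Seed for weight initialization.
#' @return `classifier_spec()`: an object of class `classifier_spec`.
#' @export
classifier_spec <- function(backbone = "texture_softmax", n_classes = 5,
                            input_size = 512, seed = 42L) {
  get_backbone(backbone)  # fail early on unknown names
  structure(list(backbone = backbone, n_classes = as.integer(n_classes),
                 input_size = as.integer(input_size), seed = as.integer(seed)),
            class = "classifier_spec")
}

#' @rdname classifier_spec
#' @param epochs Number of passes over the training fold.
#' @param batch_size Minibatch size.
#' @param learning_rate SGD step size.
#' @param validation_fraction Fraction (0, 0.5\] of training tiles held out
#'   (grouped by slide) for best-epoch selection.
#' @param selection_metric Metric maximized for best-epoch selection.
#' @param class_weight_mode `"inverse_frequency"` or `"none"`.
#' @return `training_config()`: an object of class `training_config`.
#' @export
training_config <- function(epochs = 10, batch_size = 32,
                            learning_rate = 0.5,
                            validation_fraction = 0.2,
                            selection_metric = "balanced_accuracy",
                            class_weight_mode = c("inverse_frequency", "none"),
                            seed = 42L) {
  class_weight_mode <- match.arg(class_weight_mode)
  stopifnot(epochs >= 1, batch_size >= 1, learning_rate > 0,
            validation_fraction > 0, validation_fraction <= 0.5)
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 validation_fraction = validation_fraction,
                 selection_metric = selection_metric,
                 class_weight_mode = class_weight_mode,
                 seed = as.integer(seed)),
            class = "training_config")
}

# Extract the feature matrix for a dataset (grouped by slide for IO
# locality), applying channel normalization then the backbone featurizer.
extract_features <- function(dataset, stats, featurize) {
  n <- nrow(dataset$tiles)
  ord <- order(dataset$tiles$image_path)
  ds <- normalize_tiles(dataset, stats)
  first <- featurize(tile_pixels(ds, ord[1], normalized = TRUE))
  X <- matrix(0, nrow = n, ncol = length(first))
  X[ord[1], ] <- first
  for (i in ord[-1]) {
    X[i, ] <- featurize(tile_pixels(ds, i, normalized = TRUE))
  }
  X
}

softmax <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# Forward pass: list(model) -> probability matrix.
model_forward <- function(model, X) {
  Xs <- sweep(sweep(X, 2, model$center), 2, model$scale, `/`)
  if (model$hidden > 0) {
    H <- tanh(sweep(Xs %*% model$W1, 2, model$b1, `+`))
    softmax(sweep(H %*% model$W2, 2, model$b2, `+`))
  } else {
    softmax(sweep(Xs %*% model$W2, 2, model$b2, `+`))
  }
}

# One SGD update on a minibatch; returns the updated model.
model_update <- function(model, X, Y, w, lr) {
  Xs <- sweep(sweep(X, 2, model$center), 2, model$scale, `/`)
  n <- nrow(Xs)
  if (model$hidden > 0) {
    A <- sweep(Xs %*% model$W1, 2, model$b1, `+`)
    H <- tanh(A)
    P <- softmax(sweep(H %*% model$W2, 2, model$b2, `+`))
    D2 <- (P - Y) * w / n
    D1 <- (D2 %*% t(model$W2)) * (1 - H^2)
    model$W2 <- model$W2 - lr * crossprod(H, D2)
    model$b2 <- model$b2 - lr * colSums(D2)
    model$W1 <- model$W1 - lr * crossprod(Xs, D1)
    model$b1 <- model$b1 - lr * colSums(D1)
  } else {
    P <- softmax(sweep(Xs %*% model$W2, 2, model$b2, `+`))
    D2 <- (P - Y) * w / n
    model$W2 <- model$W2 - lr * crossprod(Xs, D2)
    model$b2 <- model$b2 - lr * colSums(D2)
  }
  model
}

# Grouped-by-slide, class-covering validation split. Returns logical vector
# (TRUE = validation row). Guarantees every class keeps support in the
# training fold; validation gets whole slides until the tile budget is met.
grouped_validation_split <- function(tiles, labels, fraction, seed) {
  per_tile_split <- function() {
    # stratified per-tile fallback for cohorts where no whole slide can be
    # spared without emptying a class in the training fold
    val <- logical(nrow(tiles))
    with_seed(seed, for (cls in unique(labels)) {
      idx <- which(labels == cls)
      k <- max(1L, floor(fraction * length(idx)))
      k <- min(k, length(idx) - 1L)
      if (k > 0) val[sample(idx, k)] <- TRUE
    })
    val
  }
  slides <- unique(tiles$slide_id)
  if (length(slides) < 2) return(per_tile_split())
  budget <- fraction * nrow(tiles)
  val_slides <- character()
  with_seed(seed, {
    cand <- sample(slides)
    taken <- 0
    for (s in cand) {
      if (taken >= budget) break
      rest <- labels[!tiles$slide_id %in% c(val_slides, s)]
      if (!all(unique(labels) %in% rest)) next  # would empty a class in train
      val_slides <- c(val_slides, s)
      taken <- taken + sum(tiles$slide_id == s)
    }
  })
  if (!length(val_slides)) return(per_tile_split())
  tiles$slide_id %in% val_slides
}

#' Train a tile classifier
#'
#' Trains the spec'd backbone on labeled tiles with seeded minibatch SGD and
#' categorical cross-entropy, weighted by inverse class frequency when
#' `config$class_weight_mode = "inverse_frequency"`. A validation fold
#' (whole slides, covering every class in the remaining training fold) is
#' held out; after each epoch the selection metric is evaluated on it and
#' the weights of the best epoch are returned. Channel statistics are
#' computed from the supplied training tiles unless already attached.
#'
#' @param train A labeled `tile_dataset` (every scheme class present).
#' @param spec A [classifier_spec()].
#' @param config A [training_config()].
#' @return Object of class `fit_result`: `model`, `best_epoch` (1-based),
#'   `per_epoch_metrics` (data frame), `channel_stats`, `labels`,
#'   `validation_slides`, `spec`, `config`.
#' @export
fit <- function(train, spec = classifier_spec(), config = training_config()) {
  scheme <- train$scheme
  tiles <- train$tiles
  if (!nrow(tiles)) stop("empty training dataset")
  if (any(is.na(tiles$label))) stop("training dataset contains unlabeled tiles")
  missing <- scheme$labels[!scheme$labels %in% tiles$label]
  if (length(missing)) {
    stop("class(es) absent from the training split: ",
         paste(missing, collapse = ", "))
  }
  if (spec$n_classes != length(scheme$labels)) {
    stop("spec$n_classes does not match the class scheme")
  }
  backbone <- get_backbone(spec$backbone)
  stats <- train$channel_stats %||% compute_channel_stats(train)

  X <- extract_features(train, stats, backbone$featurize)
  y <- factor(tiles$label, levels = scheme$labels)

  val <- grouped_validation_split(tiles, tiles$label,
                                  config$validation_fraction, config$seed)
  Xtr <- X[!val, , drop = FALSE]; ytr <- y[!val]
  Xva <- X[val, , drop = FALSE]; yva <- y[val]

  counts <- table(ytr)
  w_class <- if (config$class_weight_mode == "inverse_frequency") {
    class_weights(stats::setNames(as.numeric(counts), names(counts)))
  } else {
    stats::setNames(rep(1, length(counts)), names(counts))
  }

  k <- length(scheme$labels)
  center <- colMeans(Xtr)
  scale <- pmax(apply(Xtr, 2, stats::sd), 1e-6)
  model <- with_seed(spec$seed, {
    m <- list(hidden = backbone$hidden, center = center, scale = scale,
              backbone = backbone$name, labels = scheme$labels)
    f <- ncol(X)
    if (backbone$hidden > 0) {
      m$W1 <- matrix(stats::rnorm(f * backbone$hidden, 0, 0.1), f)
      m$b1 <- numeric(backbone$hidden)
      m$W2 <- matrix(stats::rnorm(backbone$hidden * k, 0, 0.1),
                     backbone$hidden)
    } else {
      m$W2 <- matrix(stats::rnorm(f * k, 0, 0.01), f)
    }
    m$b2 <- numeric(k)
    m
  })

  Ytr <- diag(k)[as.integer(ytr), , drop = FALSE]
  wtr <- as.numeric(w_class[as.character(ytr)])
  n <- nrow(Xtr)
  history <- data.frame(epoch = integer(), train_loss = numeric(),
                        val_balanced_accuracy = numeric())
  best <- list(metric = -Inf, epoch = NA_integer_, model = model)

  with_seed(config$seed + 1L, {
    for (ep in seq_len(config$epochs)) {
      ord <- sample.int(n)
      for (start in seq(1, n, by = config$batch_size)) {
        idx <- ord[start:min(start + config$batch_size - 1L, n)]
        model <- model_update(model, Xtr[idx, , drop = FALSE],
                               Ytr[idx, , drop = FALSE], wtr[idx],
                               config$learning_rate)
      }
      P <- model_forward(model, Xtr)
      loss <- mean(wtr * -log(clamp(P[cbind(seq_len(n), as.integer(ytr))],
                                    1e-12, 1)))
      Pv <- model_forward(model, Xva)
      pred_v <- scheme$labels[max.col(Pv, ties.method = "first")]
      cm <- confusion_matrix(as.character(yva), pred_v, scheme)
      bacc <- suppressWarnings(balanced_accuracy(cm))
      history[ep, ] <- list(ep, loss, bacc)
      # ties resolved toward the later epoch: among equally validating
      # epochs the most-trained weights are kept
      if (bacc >= best$metric) {
        best <- list(metric = bacc, epoch = ep, model = model)
      }
    }
  })

  structure(
    list(model = best$model, best_epoch = best$epoch,
         per_epoch_metrics = history, channel_stats = stats,
         labels = scheme$labels,
         validation_slides = unique(tiles$slide_id[val]),
         spec = spec, config = config),
    class = "fit_result"
  )
}

#' @export
print.fit_result <- function(x, ...) {
  cat("<fit_result> backbone ", x$model$backbone, ", best epoch ",
      x$best_epoch, " (val balanced accuracy ",
      round(x$per_epoch_metrics$val_balanced_accuracy[x$best_epoch], 4),
      ")\n", sep = "")
  invisible(x)
}

#' Per-tile class probabilities
#'
#' Runs the fitted model over a tile set (normalized with the training
#' channel statistics carried by the fit) and returns one probability
#' vector per tile, in input order. Ties at the argmax are broken by scheme
#' label order, deterministically.
#'
#' @param dataset A `tile_dataset`.
#' @param fit_result A [fit()] result.
#' @return Object of class `prediction_set`: a data frame with the tile
#'   reference columns, one `prob_<label>` column per class,
#'   `predicted_label` and `confidence`.
#' @export
predict_proba <- function(dataset, fit_result) {
  stopifnot(inherits(fit_result, "fit_result"))
  if (!nrow(dataset$tiles)) {
    out <- dataset$tiles[, c("slide_id", "x", "y", "size", "split")]
    out$predicted_label <- character()
    out$confidence <- numeric()
    return(structure(out, class = c("prediction_set", "data.frame"),
                     scheme = dataset$scheme))
  }
  backbone <- get_backbone(fit_result$model$backbone)
  X <- extract_features(dataset, fit_result$channel_stats,
                        backbone$featurize)
  P <- model_forward(fit_result$model, X)
  labels <- fit_result$labels
  colnames(P) <- paste0("prob_", labels)
  out <- cbind(dataset$tiles[, c("slide_id", "x", "y", "size", "split")],
               as.data.frame(P))
  idx <- max.col(P, ties.method = "first")  # first = scheme label order
  out$predicted_label <- labels[idx]
  out$confidence <- P[cbind(seq_len(nrow(P)), idx)]
  structure(out, class = c("prediction_set", "data.frame"),
            scheme = dataset$scheme)
}

# Probability matrix (tiles x classes) from a prediction_set.
prob_matrix <- function(predictions) {
  scheme <- attr(predictions, "scheme")
  as.matrix(predictions[, paste0("prob_", scheme$labels), drop = FALSE])
}
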