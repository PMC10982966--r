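#' Aggregate tile probabilities to a slide-level grid
#'
#' Projects per-tile class probability vectors back onto slide coordinates.
#' The slide is divided into `stride x stride` cells; each covered cell's
#' per-class score is the unweighted mean of the probability vectors of all
#' tiles covering it (so scores stay on the probability simplex), and a
#' coverage grid records how many tiles contributed. Cells covered by no
#' tile are `NA`, never zero-filled. Tile origins must lie on the stride
#' grid.
#'
#' @param predictions A `prediction_set` for a single slide.
#' @param slide The slide record the predictions belong to.
#' @param stride Grid stride in pixels (the inference stride).
#' @return Object of class `heatmap_grid`: list with `slide_id`,
#'   `cell_size`, `scores` (named list of per-class matrices), `coverage`
#'   (integer matrix), `width`, `height`.
#' @export
accumulate_tile_scores <- function(predictions, slide, stride) {
  stopifnot(inherits(predictions, "prediction_set"), stride >= 1)
  scheme <- attr(predictions, "scheme")
  if (length(unique(predictions$slide_id)) > 1) {
    stop("predictions span multiple slides")
  }
  if (nrow(predictions) &&
      !all(predictions$slide_id == slide$slide_id)) {
    stop("predictions do not belong to slide ", slide$slide_id)
  }
  if (any(predictions$x %% stride != 0) || any(predictions$y %% stride != 0)) {
    stop("tile coordinates are off the stride grid")
  }
  ncx <- ceiling(slide$width / stride)
  ncy <- ceiling(slide$height / stride)
  acc <- lapply(scheme$labels, function(l) matrix(0, ncy, ncx))
  names(acc) <- scheme$labels
  coverage <- matrix(0L, ncy, ncx)
  P <- prob_matrix(predictions)
  for (i in seq_len(nrow(predictions))) {
    cx <- (predictions$x[i] %/% stride + 1):
      min(ncx, (predictions$x[i] + predictions$size[i] - 1) %/% stride + 1)
    cy <- (predictions$y[i] %/% stride + 1):
      min(ncy, (predictions$y[i] + predictions$size[i] - 1) %/% stride + 1)
    coverage[cy, cx] <- coverage[cy, cx] + 1L
    for (k in seq_along(scheme$labels)) {
      acc[[k]][cy, cx] <- acc[[k]][cy, cx] + P[i, k]
    }
  }
  scores <- lapply(acc, function(a) {
    out <- a / coverage
    out[coverage == 0] <- NA_real_
    out
  })
  structure(list(slide_id = slide$slide_id, cell_size = stride,
                 scores = scores, coverage = coverage,
                 width = slide$width, height = slide$height,
                 scheme = scheme, aggregation = "mean"),
            class = "heatmap_grid")
}

#' Render a class-probability overlay
#'
#' Alpha-blends a red-intensity heatmap of one class's scores over the
#' slide image; shading at each pixel is proportional to the class score of
#' its grid cell (nearest-neighbor upscaling, so cell boundaries stay
#' visible and no interpolation invents confidence). Uncovered cells are
#' left unshaded. A vertical color bar (score 0 at the bottom to 1 at the
#' top) is appended on the right as a legend.
#'
#' @param grid A [accumulate_tile_scores()] result.
#' @param slide_image The slide pixel array (`H x W x 3`) or a path to it.
#' @param class_label Class to render.
#' @param alpha Blend strength in \[0, 1\].
#' @param colorbar Append the color-bar legend strip.
#' @return Numeric array `H x (W + legend) x 3`.
#' @export
render_overlay <- function(grid, slide_image, class_label, alpha = 0.4,
                           colorbar = TRUE) {
  if (is.character(slide_image)) {
    if (!file.exists(slide_image)) {
      stop("missing slide image: ", slide_image)
    }
    slide_image <- read_slide_image(slide_image)
  }
  s <- grid$scores[[class_label]]
  if (is.null(s)) stop("unknown class: ", class_label)
  h <- dim(slide_image)[1]; w <- dim(slide_image)[2]
  rows <- pmin(nrow(s), (seq_len(h) - 1L) %/% grid$cell_size + 1L)
  cols <- pmin(ncol(s), (seq_len(w) - 1L) %/% grid$cell_size + 1L)
  up <- s[rows, cols, drop = FALSE]
  up[is.na(up)] <- 0  # uncovered cells: unshaded
  out <- slide_image
  red <- c(1, 0, 0)
  for (k in 1:3) {
    out[, , k] <- (1 - alpha * up) * slide_image[, , k] + alpha * up * red[k]
  }
  if (colorbar) {
    bar_w <- max(8L, w %/% 64L)
    ramp <- seq(1, 0, length.out = h)  # score 1 on top
    bar <- array(0, dim = c(h, bar_w, 3))
    for (k in 1:3) {
      bar[, , k] <- matrix((1 - alpha * ramp) + alpha * ramp * red[k],
                           nrow = h, ncol = bar_w)
    }
    gap <- array(1, dim = c(h, 4L, 3))
    out2 <- array(0, dim = c(h, w + 4L + bar_w, 3))
    out2[, 1:w, ] <- out
    out2[, (w + 1):(w + 4), ] <- gap
    out2[, (w + 5):(w + 4 + bar_w), ] <- bar
    out <- out2
  }
  clamp(out)
}

#' Slide-level summary of a heatmap grid
#'
#' Per-class fraction of covered cells where the class attains the argmax
#' (ties broken by scheme label order), plus the dominant tumor call: the
#' tumor class with the largest fraction. When the top two tumor fractions
#' differ by less than `margin` the call is flagged inconclusive --
#' operationalizing the situation where a slide reads ambiguously between
#' two morphologically similar subtypes.
#'
#' @param grid A [accumulate_tile_scores()] result.
#' @param scheme A [class_scheme()]; defaults to the grid's.
#' @param margin Minimum lead of the top tumor fraction over the runner-up.
#' @return List with `fractions` (named, summing to 1), `dominant_tumor`,
#'   `inconclusive` (logical) and `covered_cells`.
#' @export
slide_summary <- function(grid, scheme = grid$scheme, margin = 0.1) {
  covered <- which(grid$coverage > 0)
  if (!length(covered)) stop("heatmap grid has no coverage")
  S <- vapply(scheme$labels, function(l) grid$scores[[l]][covered],
              numeric(length(covered)))
  S <- matrix(S, nrow = length(covered),
              dimnames = list(NULL, scheme$labels))
  winner <- scheme$labels[max.col(S, ties.method = "first")]
  fractions <- vapply(scheme$labels,
                      function(l) mean(winner == l), numeric(1))
  tf <- sort(fractions[scheme$tumor_labels], decreasing = TRUE)
  dominant <- names(tf)[1]
  inconclusive <- length(tf) > 1 && (tf[1] - tf[2]) < margin
  list(fractions = fractions, dominant_tumor = dominant,
       inconclusive = inconclusive, covered_cells = length(covered))
}

#' Serialize a heatmap grid
#'
#' JSON with metadata (slide, cell size, aggregation rule) and the per-class
#' score grids; uncovered cells are `null`.
#'
#' @param grid A `heatmap_grid`.
#' @param path JSON output path.
#' @export
write_heatmap_grid <- function(grid, path) {
  out <- list(slide_id = grid$slide_id, cell_size = grid$cell_size,
              width = grid$width, height = grid$height,
              aggregation = grid$aggregation,
              coverage = grid$coverage, scores = grid$scores)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}
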