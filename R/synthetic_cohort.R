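#' Default per-class texture parameters
#'
#' Each class is rendered as a marked Poisson blob process: nucleus-like
#' disks in a hematoxylin-leaning foreground color scattered over an
#' eosin-leaning background, plus additive Gaussian noise. Classes differ in
#' blob density (nuclei per pixel squared), blob radius, and both colors, so
#' class identity is recoverable from local texture alone -- mirroring how
#' hypercellularity and staining differences separate glioma subtypes,
#' normal brain and necrosis in H&E tiles.
#'
#' The `difficulty` parameter linearly shrinks every numeric parameter toward
#' the cross-class mean: at `difficulty = 0` classes are maximally separated,
#' at `difficulty = 1` all classes share identical parameters and are
#' statistically indistinguishable.
#'
#' @param difficulty Scalar in \[0, 1\] shrinking inter-class separation.
#' @param base Named list of per-class parameter lists to blend; defaults to
#'   the package's built-in palette.
#' @return Named list (one element per class) of lists with fields
#'   `density`, `radius`, `fg`, `bg`, `noise_sd`.
#' @export
texture_params <- function(difficulty = 0, base = NULL) {
  stopifnot(is.numeric(difficulty), length(difficulty) == 1,
            difficulty >= 0, difficulty <= 1)
  if (is.null(base)) {
    base <- list(
      ac       = list(density = 5.0e-4, radius = 7,  fg = c(0.45, 0.30, 0.62),
                      bg = c(0.92, 0.84, 0.90), noise_sd = 0.02),
      odg      = list(density = 8.0e-4, radius = 6,  fg = c(0.30, 0.38, 0.68),
                      bg = c(0.90, 0.88, 0.94), noise_sd = 0.02),
      gbm      = list(density = 1.5e-3, radius = 5,  fg = c(0.28, 0.20, 0.45),
                      bg = c(0.88, 0.80, 0.86), noise_sd = 0.02),
      normal   = list(density = 2.5e-4, radius = 8,  fg = c(0.55, 0.42, 0.68),
                      bg = c(0.94, 0.88, 0.92), noise_sd = 0.02),
      necrosis = list(density = 4.0e-4, radius = 11, fg = c(0.78, 0.52, 0.58),
                      bg = c(0.90, 0.74, 0.76), noise_sd = 0.02)
    )
  }
  for (p in base) {
    stopifnot(p$density > 0, p$radius > 0)
  }
  if (difficulty == 0) return(base)
  fields <- c("density", "radius", "fg", "bg", "noise_sd")
  means <- lapply(fields, function(f) {
    Reduce(`+`, lapply(base, `[[`, f)) / length(base)
  })
  names(means) <- fields
  lapply(base, function(p) {
    for (f in fields) p[[f]] <- (1 - difficulty) * p[[f]] + difficulty * means[[f]]
    p
  })
}

#' Render one class texture patch
#'
#' Draws a rectangle of H&E-like texture for a class: a Poisson number of
#' disks (expected count `density * width * height`) with uniformly random
#' centers, filled with the class foreground color over the class background,
#' plus additive Gaussian noise clipped to \[0, 1\].
#'
#' Uses the current RNG state; seed with [set.seed()] (or pass `seed`) for
#' reproducibility.
#'
#' @param class_label Class to render; must be a name of `params`.
#' @param width,height Patch size in pixels.
#' @param params Per-class parameter list from [texture_params()].
#' @param seed Optional integer seed applied locally.
#' @return Numeric array `height x width x 3` with values in \[0, 1\].
#' @export
render_class_texture <- function(class_label, width, height = width,
                                 params = texture_params(), seed = NULL) {
  p <- params[[class_label]]
  if (is.null(p)) stop("unknown class: ", class_label)
  stopifnot(width >= 1, height >= 1)
  render <- function() {
    img <- array(0, dim = c(height, width, 3))
    for (k in 1:3) img[, , k] <- p$bg[k]
    n <- stats::rpois(1, p$density * width * height)
    if (n > 0) {
      cx <- stats::runif(n, 0, width)
      cy <- stats::runif(n, 0, height)
      r <- p$radius
      for (i in seq_len(n)) {
        rows <- max(1, floor(cy[i] - r)):min(height, ceiling(cy[i] + r))
        cols <- max(1, floor(cx[i] - r)):min(width, ceiling(cx[i] + r))
        mask <- outer((rows - 0.5 - cy[i])^2, (cols - 0.5 - cx[i])^2, `+`) <= r^2
        if (!any(mask)) next
        for (k in 1:3) {
          sub <- img[rows, cols, k]
          sub[mask] <- p$fg[k]
          img[rows, cols, k] <- sub
        }
      }
    }
    if (p$noise_sd > 0) {
      img <- img + stats::rnorm(length(img), 0, p$noise_sd)
      img <- clamp(img)
    }
    img
  }
  if (is.null(seed)) render() else with_seed(seed, render())
}

#' Synthetic cohort configuration
#'
#' Describes a seeded synthetic slide cohort: how many slides, their pixel
#' dimensions, the diagnosis mix, the per-class tile-share targets the region
#' planner aims at, how much of each tissue region is annotated as an ROI,
#' and the texture difficulty.
#'
#' Defaults mimic the shape of a small surgical glioma cohort: a 29-slide
#' diagnosis mix of 8 astrocytoma, 8 oligodendroglioma, 12 glioblastoma and
#' 1 normal control (scaled to `n_slides`), and per-class tile shares with
#' severe imbalance (normal tissue roughly 18 times more frequent than
#' necrosis).
#'
#' @param n_slides Number of slides.
#' @param slide_size Integer `c(width, height)` in pixels.
#' @param tiles_per_slide Average number of planned ground-truth tiles per
#'   slide (at full ROI coverage).
#' @param imbalance_targets Named numeric vector of per-class target tile
#'   shares; must sum to 1 over the scheme's labels.
#' @param diagnosis_weights Named weights for the tumor/control diagnosis mix.
#' @param difficulty Texture difficulty in \[0, 1\]; see [texture_params()].
#' @param roi_coverage Fraction (0, 1\] of each planned tissue region on
#'   *training* slides that is annotated as an ROI; the remainder stays as
#'   unannotated tissue for the semi-supervised step. Test slides are always
#'   fully annotated so evaluation keeps its ground-truth size.
#' @param test_fraction Fraction of slides held out as the test split,
#'   stratified by diagnosis.
#' @param tile_size,overlap Tiling geometry used by the region planner so
#'   planned regions land on the inference stride grid.
#' @param image_format `"png"` (default) or `"tiff"`.
#' @param seed Root seed; each slide derives its own child stream.
#' @return Object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_slides = 20,
                             slide_size = c(2048, 2048),
                             tiles_per_slide = 12,
                             imbalance_targets = c(ac = 30040, odg = 27072,
                                                   gbm = 13064, normal = 56291,
                                                   necrosis = 3112) / 129579,
                             diagnosis_weights = c(ac = 8, odg = 8, gbm = 12,
                                                   normal = 1),
                             difficulty = 0,
                             roi_coverage = 1,
                             test_fraction = 0.25,
                             tile_size = 512,
                             overlap = 0.5,
                             image_format = c("png", "tiff"),
                             seed = 1L) {
  image_format <- match.arg(image_format)
  stopifnot(n_slides >= 2, length(slide_size) == 2,
            all(slide_size >= tile_size),
            abs(sum(imbalance_targets) - 1) < 1e-8,
            all(imbalance_targets >= 0),
            difficulty >= 0, difficulty <= 1,
            roi_coverage > 0, roi_coverage <= 1,
            test_fraction > 0, test_fraction < 1,
            tile_size > 0, overlap >= 0, overlap < 1)
  structure(
    list(n_slides = as.integer(n_slides),
         slide_size = as.integer(slide_size),
         tiles_per_slide = tiles_per_slide,
         imbalance_targets = imbalance_targets,
         diagnosis_weights = diagnosis_weights,
         difficulty = difficulty,
         roi_coverage = roi_coverage,
         test_fraction = test_fraction,
         tile_size = as.integer(tile_size),
         overlap = overlap,
         image_format = image_format,
         seed = as.integer(seed)),
    class = "synthetic_config"
  )
}

# Decompose k tiles into a list of (nx, ny) grid rectangles with
# sum(nx * ny) == k, preferring near-square grids capped at max_grid per
# side so the shelf packer works with moderately sized rectangles.
grid_decompose <- function(k, max_grid = 3L) {
  out <- list()
  while (k > 0) {
    a <- min(max_grid, max(1L, floor(sqrt(k))))
    b <- min(max_grid, k %/% a)
    out[[length(out) + 1L]] <- c(nx = b, ny = a)
    k <- k - a * b
  }
  out
}

# Shelf-pack stride-aligned rectangles (widths/heights in pixels) into a
# slide. Returns x/y offsets or errors when the plan cannot fit.
shelf_pack <- function(widths, heights, slide_w, slide_h, slide_id) {
  ord <- order(heights, decreasing = TRUE)
  x <- y <- integer(length(widths))
  cur_x <- 0L; cur_y <- 0L; shelf_h <- 0L
  for (i in ord) {
    if (cur_x + widths[i] > slide_w) {  # new shelf
      cur_y <- cur_y + shelf_h
      cur_x <- 0L
      shelf_h <- 0L
    }
    if (widths[i] > slide_w || cur_y + heights[i] > slide_h) {
      stop("ROI plan for slide ", slide_id,
           " cannot fit inside the slide; reduce tiles_per_slide or ",
           "enlarge slide_size")
    }
    x[i] <- cur_x
    y[i] <- cur_y
    cur_x <- cur_x + widths[i]
    shelf_h <- max(shelf_h, heights[i])
  }
  list(x = x, y = y)
}

# Plan diagnoses, splits and stride-aligned tissue regions for a cohort.
# Returns a list of per-slide plans. Deterministic given config$seed.
plan_cohort <- function(config, scheme = class_scheme()) {
  n <- config$n_slides
  stride <- max(1L, as.integer(round(config$tile_size * (1 - config$overlap))))

  dw <- config$diagnosis_weights
  assert_labels(names(dw), scheme, "diagnosis")
  # one normal-control slide whenever the mix asks for any, rest apportioned
  tumor_w <- dw[names(dw) %in% scheme$tumor_labels]
  n_normal <- if (scheme$normal_label %in% names(dw) &&
                  dw[[scheme$normal_label]] > 0) 1L else 0L
  tumor_counts <- apportion(tumor_w, n - n_normal)
  diagnoses <- c(rep(names(tumor_w), tumor_counts),
                 rep(scheme$normal_label, n_normal))

  # stratified test split: at least one test slide per tumor diagnosis that
  # has >= 2 slides; the single normal control stays in training
  split <- rep("train", n)
  with_seed(child_seed(config$seed, 0L), {
    for (d in unique(diagnoses)) {
      idx <- which(diagnoses == d)
      if (d == scheme$normal_label || length(idx) < 2) next
      n_test <- max(1L, round(config$test_fraction * length(idx)))
      n_test <- min(n_test, length(idx) - 1L)
      split[sample(idx, n_test)] <- "test"
    }
  })

  # per-split, per-class tile allocation by largest remainder, then spread
  # over eligible slides
  targets <- config$imbalance_targets[scheme$labels]
  targets[is.na(targets)] <- 0
  names(targets) <- scheme$labels
  alloc <- matrix(0L, nrow = n, ncol = length(scheme$labels),
                  dimnames = list(NULL, scheme$labels))
  for (sp in unique(split)) {
    slides_sp <- which(split == sp)
    total_sp <- round(config$tiles_per_slide * length(slides_sp))
    per_class <- apportion(targets, total_sp)
    names(per_class) <- scheme$labels
    for (cls in scheme$labels) {
      k <- per_class[[cls]]
      if (k == 0) next
      eligible <- slides_sp[vapply(slides_sp, function(i) {
        cls %in% allowed_classes(diagnoses[i], scheme)
      }, logical(1))]
      if (!length(eligible)) next  # no slide can carry this class here
      share <- apportion(rep(1, length(eligible)), k)
      alloc[eligible, cls] <- alloc[eligible, cls] + share
    }
  }

  # per slide: decompose class allocations into grid rectangles and pack
  lapply(seq_len(n), function(i) {
    cls_k <- alloc[i, ]
    regions <- do.call(rbind, lapply(scheme$labels, function(cls) {
      if (cls_k[[cls]] == 0) return(NULL)
      do.call(rbind, lapply(grid_decompose(cls_k[[cls]]), function(g) {
        data.frame(label = cls, nx = g[["nx"]], ny = g[["ny"]])
      }))
    }))
    if (is.null(regions)) {
      regions <- data.frame(label = character(), nx = integer(),
                            ny = integer())
    }
    w_px <- config$tile_size + (regions$nx - 1L) * stride
    h_px <- config$tile_size + (regions$ny - 1L) * stride
    pos <- shelf_pack(w_px, h_px, config$slide_size[1], config$slide_size[2],
                      sprintf("slide_%02d", i))
    regions$x <- pos$x
    regions$y <- pos$y
    regions$width <- w_px
    regions$height <- h_px
    # annotated sub-rectangle: roi_coverage fraction of the region's tiles.
    # Annotation scarcity is a training-side condition: test slides are
    # always fully annotated so the evaluation ground truth keeps its size.
    f <- if (split[i] == "train") sqrt(config$roi_coverage) else 1
    regions$roi_nx <- pmax(1L, as.integer(round(regions$nx * f)))
    regions$roi_ny <- pmax(1L, as.integer(round(regions$ny * f)))
    regions$roi_width <- config$tile_size + (regions$roi_nx - 1L) * stride
    regions$roi_height <- config$tile_size + (regions$roi_ny - 1L) * stride
    list(slide_id = sprintf("slide_%02d", i),
         diagnosis = diagnoses[i],
         split = split[i],
         regions = regions)
  })
}

#' Generate a synthetic slide cohort
#'
#' Renders seeded synthetic slides with class-textured tissue regions,
#' writes each slide image to `out_dir`, and returns the cohort with its ROI
#' annotations and train/test split. Every slide is fully covered with
#' tissue: the whole canvas carries normal-tissue texture and planned class
#' regions are painted on top, of which only a `roi_coverage` fraction is
#' annotated -- the rest is unannotated tissue available to the
#' semi-supervised step.
#'
#' By construction every slide satisfies the diagnosis-consistency rule:
#' region and ROI labels are drawn from [allowed_classes()] of the slide's
#' diagnosis. The planner targets `config$imbalance_targets` for the
#' per-class ground-truth tile shares; the realized shares and their
#' deviation from the targets are reported in the returned object.
#'
#' @param config A [synthetic_config()].
#' @param scheme A [class_scheme()].
#' @param out_dir Directory the slide images (and annotation files) are
#'   written to; created if missing.
#' @return Object of class `glioma_cohort`: list with `slides` (one record
#'   per slide: `slide_id`, `image_path`, `width`, `height`, `diagnosis`,
#'   `split`, `rois`, `regions`), `scheme`, `config`, `realized_counts`,
#'   `realized_shares`, `share_deviation`.
#' @examples
#' \donttest{
#' cfg <- synthetic_config(n_slides = 4, tiles_per_slide = 4, seed = 1)
#' cohort <- generate_cohort(cfg, out_dir = tempfile("cohort"))
#' cohort$realized_shares
#' }
#' @export
generate_cohort <- function(config, scheme = class_scheme(),
                            out_dir = tempfile("gliotile_cohort")) {
  stopifnot(inherits(config, "synthetic_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  plans <- plan_cohort(config, scheme)
  params <- texture_params(config$difficulty)
  w <- config$slide_size[1]; h <- config$slide_size[2]

  slides <- lapply(seq_along(plans), function(i) {
    pl <- plans[[i]]
    with_seed(child_seed(config$seed, i), {
      img <- render_class_texture(scheme$normal_label, w, h, params)
      if (nrow(pl$regions)) {
        for (j in seq_len(nrow(pl$regions))) {
          rg <- pl$regions[j, ]
          patch <- render_class_texture(rg$label, rg$width, rg$height, params)
          img[(rg$y + 1):(rg$y + rg$height),
              (rg$x + 1):(rg$x + rg$width), ] <- patch
        }
      }
      ext <- if (config$image_format == "png") ".png" else ".tif"
      path <- file.path(out_dir, paste0(pl$slide_id, ext))
      if (config$image_format == "png") {
        png::writePNG(img, path)
      } else {
        if (!requireNamespace("tiff", quietly = TRUE)) {
          stop("the 'tiff' package is required for image_format = 'tiff'")
        }
        tiff::writeTIFF(img, path)
      }
      rois <- pl$regions[, c("x", "y", "roi_width", "roi_height", "label")]
      names(rois) <- c("x", "y", "width", "height", "label")
      list(slide_id = pl$slide_id, image_path = path, width = w, height = h,
           diagnosis = pl$diagnosis, split = pl$split,
           rois = rois, regions = pl$regions)
    })
  })

  for (sl in slides) validate_slide_record(sl, scheme)

  stride <- max(1L, as.integer(round(config$tile_size * (1 - config$overlap))))
  counts <- stats::setNames(numeric(length(scheme$labels)), scheme$labels)
  for (sl in slides) {
    if (!nrow(sl$rois)) next
    for (j in seq_len(nrow(sl$rois))) {
      r <- sl$rois[j, ]
      counts[[r$label]] <- counts[[r$label]] +
        count_tiles(r$width, r$height, config$tile_size, stride)
    }
  }
  shares <- counts / sum(counts)
  targets <- config$imbalance_targets[scheme$labels]
  dev <- ifelse(targets > 0, abs(shares - targets) / targets, 0)

  cohort <- structure(
    list(slides = slides, scheme = scheme, config = config, dir = out_dir,
         realized_counts = counts, realized_shares = shares,
         share_deviation = dev),
    class = "glioma_cohort"
  )
  write_cohort_annotations(cohort, file.path(out_dir, "annotations.json"))
  write_cohort_manifest(cohort, file.path(out_dir, "manifest.tsv"))
  cohort
}

validate_slide_record <- function(slide, scheme) {
  r <- slide$rois
  if (nrow(r)) {
    assert_labels(r$label, scheme)
    if (any(r$width <= 0) || any(r$height <= 0)) {
      stop("slide ", slide$slide_id, ": ROI with non-positive size")
    }
    if (any(r$x < 0) || any(r$y < 0) ||
        any(r$x + r$width > slide$width) ||
        any(r$y + r$height > slide$height)) {
      stop("slide ", slide$slide_id, ": ROI outside slide bounds")
    }
    allowed <- allowed_classes(slide$diagnosis, scheme)
    bad <- setdiff(unique(r$label), allowed)
    if (length(bad)) {
      stop("slide ", slide$slide_id, " (diagnosis ", slide$diagnosis,
           "): ROI label(s) not permitted: ", paste(bad, collapse = ", "))
    }
  }
  invisible(TRUE)
}

#' @export
print.glioma_cohort <- function(x, ...) {
  splits <- table(vapply(x$slides, `[[`, "", "split"))
  cat("<glioma_cohort> ", length(x$slides), " slides (",
      paste(names(splits), splits, sep = "=", collapse = ", "), ") in ",
      x$dir, "\n", sep = "")
  cat("  realized ground-truth tile shares:\n")
  print(round(x$realized_shares, 4))
  invisible(x)
}

#' Write / read cohort annotations and manifest
#'
#' Annotations are one JSON document per cohort with 0-based pixel
#' coordinates and half-open rectangles `[x, x+width) x [y, y+height)`; the
#' manifest is a TSV with one row per slide.
#'
#' @param cohort A `glioma_cohort`.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_cohort_annotations <- function(cohort, path) {
  doc <- list(slides = lapply(cohort$slides, function(sl) {
    list(slide_id = sl$slide_id, diagnosis = sl$diagnosis, split = sl$split,
         width = sl$width, height = sl$height,
         image_path = basename(sl$image_path),
         rois = sl$rois)
  }))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_cohort_annotations
#' @export
write_cohort_manifest <- function(cohort, path) {
  df <- do.call(rbind, lapply(cohort$slides, function(sl) {
    data.frame(slide_id = sl$slide_id, image_path = sl$image_path,
               diagnosis = sl$diagnosis, width = sl$width,
               height = sl$height, split = sl$split)
  }))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort_annotations
#' @param dir Cohort directory containing `annotations.json` and the slide
#'   images.
#' @param scheme A [class_scheme()].
#' @export
read_cohort <- function(dir, scheme = class_scheme()) {
  doc <- jsonlite::read_json(file.path(dir, "annotations.json"),
                             simplifyVector = TRUE, simplifyDataFrame = TRUE)
  slides <- lapply(seq_len(nrow(doc$slides)), function(i) {
    row <- doc$slides[i, ]
    rois <- row$rois[[1]]
    if (is.null(rois) || !length(rois)) {
      rois <- data.frame(x = integer(), y = integer(), width = integer(),
                         height = integer(), label = character())
    }
    sl <- list(slide_id = row$slide_id,
               image_path = file.path(dir, row$image_path),
               width = row$width, height = row$height,
               diagnosis = row$diagnosis, split = row$split,
               rois = rois, regions = NULL)
    validate_slide_record(sl, scheme)
    sl
  })
  structure(list(slides = slides, scheme = scheme, config = NULL, dir = dir),
            class = "glioma_cohort")
}
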