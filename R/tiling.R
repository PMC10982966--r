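#' Number of tile positions in a rectangle
#'
#' Closed-form count of square tiles of side `tile_size` placed at stride
#' `stride` inside a `roi_width x roi_height` rectangle, partial tiles
#' dropped: `(floor((W - T)/S) + 1) * (floor((H - T)/S) + 1)` when both
#' dimensions are at least `tile_size`, else 0. With 50% overlap the stride
#' is half the tile side.
#'
#' @param roi_width,roi_height Rectangle dimensions in pixels.
#' @param tile_size Tile side in pixels.
#' @param stride Step between tile origins in pixels.
#' @return Integer tile count.
#' @examples
#' count_tiles(1024, 1024, 512, 256)  # 9
#' @export
count_tiles <- function(roi_width, roi_height, tile_size = 512,
                        stride = tile_size %/% 2) {
  if (tile_size <= 0) stop("tile_size must be positive")
  if (stride <= 0) stop("stride must be positive")
  if (roi_width < tile_size || roi_height < tile_size) return(0L)
  nx <- (roi_width - tile_size) %/% stride + 1
  ny <- (roi_height - tile_size) %/% stride + 1
  as.integer(nx * ny)
}

new_tile_dataset <- function(tiles, scheme) {
  tiles <- tiles[order(tiles$slide_id, tiles$y, tiles$x, tiles$aug), ,
                 drop = FALSE]
  rownames(tiles) <- NULL
  counts <- table(factor(tiles$label[tiles$provenance != "unlabeled"],
                         levels = scheme$labels))
  structure(
    list(tiles = tiles, scheme = scheme,
         class_counts = stats::setNames(as.integer(counts), scheme$labels),
         channel_stats = NULL),
    class = "tile_dataset"
  )
}

empty_tiles <- function() {
  data.frame(slide_id = character(), image_path = character(),
             x = integer(), y = integer(), size = integer(),
             label = character(), provenance = character(),
             split = character(), aug = character(),
             stringsAsFactors = FALSE)
}

#' @export
print.tile_dataset <- function(x, ...) {
  cat("<tile_dataset> ", nrow(x$tiles), " tiles\n", sep = "")
  print(x$class_counts)
  invisible(x)
}

tile_positions <- function(origin, extent, tile_size, stride) {
  if (extent < tile_size) return(integer())
  origin + stride * (0:((extent - tile_size) %/% stride))
}

#' Extract labeled tiles from a slide's ROIs
#'
#' Divides each annotated ROI into square, 50%-overlapping (by default)
#' tiles that lie fully inside the ROI; each tile inherits the ROI's class
#' label with provenance `ground_truth` and the slide's split. Partial tiles
#' at ROI edges are dropped, so the per-ROI count equals [count_tiles()].
#' A tile that fits inside two overlapping ROIs of different classes is an
#' annotation conflict and raises an error.
#'
#' @param slide A slide record (element of a `glioma_cohort`'s `slides`).
#' @param tile_size Tile side in pixels (default 512).
#' @param overlap Fractional overlap between neighboring tiles (default 0.5,
#'   i.e. stride = `tile_size / 2`).
#' @param scheme A [class_scheme()].
#' @return A `tile_dataset`.
#' @export
extract_roi_tiles <- function(slide, tile_size = 512, overlap = 0.5,
                              scheme = class_scheme()) {
  stride <- as.integer(round(tile_size * (1 - overlap)))
  if (stride < 1) stop("stride must be >= 1; lower the overlap")
  rois <- slide$rois
  rows <- list()
  if (!is.null(rois) && nrow(rois)) {
    for (j in seq_len(nrow(rois))) {
      r <- rois[j, ]
      if (r$x < 0 || r$y < 0 || r$x + r$width > slide$width ||
          r$y + r$height > slide$height) {
        stop("slide ", slide$slide_id, ", ROI ", j, ": outside slide bounds")
      }
      xs <- tile_positions(r$x, r$width, tile_size, stride)
      ys <- tile_positions(r$y, r$height, tile_size, stride)
      if (!length(xs) || !length(ys)) next
      grid <- expand.grid(x = xs, y = ys)
      rows[[length(rows) + 1L]] <- data.frame(
        slide_id = slide$slide_id, image_path = slide$image_path,
        x = grid$x, y = grid$y, size = as.integer(tile_size),
        label = r$label, provenance = "ground_truth",
        split = slide$split %||% "none", aug = "id",
        stringsAsFactors = FALSE)
    }
  }
  tiles <- if (length(rows)) do.call(rbind, rows) else empty_tiles()
  # annotation-conflict check: same tile rectangle inside ROIs of two classes
  if (nrow(tiles)) {
    key <- paste(tiles$slide_id, tiles$x, tiles$y)
    conflict <- tapply(tiles$label, key, function(l) length(unique(l)) > 1)
    if (any(conflict)) {
      stop("slide ", slide$slide_id, ": tile(s) covered by overlapping ROIs ",
           "of different classes: ",
           paste(names(conflict)[conflict], collapse = "; "))
    }
    tiles <- tiles[!duplicated(key), , drop = FALSE]
  }
  new_tile_dataset(tiles, scheme)
}

rects_intersect <- function(ax, ay, aw, ah, bx, by, bw, bh) {
  ax < bx + bw & bx < ax + aw & ay < by + bh & by < ay + ah
}

#' Unlabeled tile grid over a whole slide
#'
#' Lays a regular stride grid of unlabeled tiles over the full slide (the
#' inference grid used for pseudo-labeling and heatmaps). With
#' `exclude_rois = TRUE` every tile that intersects any annotated ROI is
#' dropped, leaving only tiles outside the annotated regions.
#'
#' @inheritParams extract_roi_tiles
#' @param exclude_rois Drop tiles intersecting any ROI.
#' @return A `tile_dataset` with provenance `unlabeled`.
#' @export
grid_tiles <- function(slide, tile_size = 512, overlap = 0.5,
                       exclude_rois = FALSE, scheme = class_scheme()) {
  stride <- as.integer(round(tile_size * (1 - overlap)))
  if (stride < 1) stop("stride must be >= 1; lower the overlap")
  xs <- tile_positions(0L, slide$width, tile_size, stride)
  ys <- tile_positions(0L, slide$height, tile_size, stride)
  grid <- expand.grid(x = xs, y = ys)
  if (exclude_rois && !is.null(slide$rois) && nrow(slide$rois)) {
    keep <- !vapply(seq_len(nrow(grid)), function(i) {
      any(rects_intersect(grid$x[i], grid$y[i], tile_size, tile_size,
                          slide$rois$x, slide$rois$y,
                          slide$rois$width, slide$rois$height))
    }, logical(1))
    grid <- grid[keep, , drop = FALSE]
  }
  tiles <- if (nrow(grid)) {
    data.frame(slide_id = slide$slide_id, image_path = slide$image_path,
               x = grid$x, y = grid$y, size = as.integer(tile_size),
               label = NA_character_, provenance = "unlabeled",
               split = slide$split %||% "none", aug = "id",
               stringsAsFactors = FALSE)
  } else empty_tiles()
  new_tile_dataset(tiles, scheme)
}

# Cache of decoded slide images, keyed by path; keeps the most recent slide
# only, since tiles are processed grouped by slide.
slide_cache <- new.env(parent = emptyenv())

read_slide_image <- function(path) {
  if (!is.null(slide_cache$path) && identical(slide_cache$path, path)) {
    return(slide_cache$img)
  }
  ext <- tolower(tools::file_ext(path))
  img <- if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE)) {
      stop("the 'tiff' package is required to read TIFF slides")
    }
    tiff::readTIFF(path)
  } else {
    png::readPNG(path)
  }
  if (length(dim(img)) == 2) img <- array(rep(img, 3), dim = c(dim(img), 3))
  if (dim(img)[3] > 3) img <- img[, , 1:3, drop = FALSE]
  slide_cache$path <- path
  slide_cache$img <- img
  img
}

#' Load the pixel array of one tile
#'
#' Crops the tile rectangle from its slide image, applies the tile's
#' dihedral augmentation tag, and (optionally) per-channel normalization
#' when the dataset carries channel statistics.
#'
#' @param dataset A `tile_dataset`.
#' @param i Row index into `dataset$tiles`.
#' @param normalized Apply the dataset's attached [compute_channel_stats()]
#'   statistics, if present.
#' @return Numeric array `size x size x 3`.
#' @export
tile_pixels <- function(dataset, i, normalized = FALSE) {
  t <- dataset$tiles[i, ]
  img <- read_slide_image(t$image_path)
  px <- img[(t$y + 1):(t$y + t$size), (t$x + 1):(t$x + t$size), ,
            drop = FALSE]
  px <- d4_apply(px, t$aug)
  if (normalized) {
    if (is.null(dataset$channel_stats)) {
      stop("dataset has no channel statistics attached; ",
           "call normalize_tiles() first")
    }
    px <- normalize_pixels(px, dataset$channel_stats)
  }
  px
}

#' Dihedral (D4) transforms of a square image
#'
#' `d4_tags()` lists the eight elements of the dihedral group of the square:
#' rotations by 0/90/180/270 degrees, each with and without a horizontal
#' flip. `d4_apply()` applies one transform; `augment_d4()` returns the full
#' 8-element orbit of a pixel array.
#'
#' @param px Numeric array `H x W x C` with `H == W`.
#' @param tag One of `d4_tags()`.
#' @return `d4_apply()`: the transformed array. `augment_d4()`: a named list
#'   of 8 arrays (including the identity view).
#' @examples
#' px <- array(runif(4 * 4 * 3), dim = c(4, 4, 3))
#' length(augment_d4(px))  # 8
#' @export
d4_tags <- function() {
  c("id", "rot90", "rot180", "rot270",
    "flip", "rot90_flip", "rot180_flip", "rot270_flip")
}

#' @rdname d4_tags
#' @export
d4_apply <- function(px, tag) {
  stopifnot(length(dim(px)) == 3)
  rot90 <- function(a) {  # 90 degrees counterclockwise
    aperm(a, c(2, 1, 3))[rev(seq_len(dim(a)[2])), , , drop = FALSE]
  }
  hflip <- function(a) a[, rev(seq_len(dim(a)[2])), , drop = FALSE]
  switch(tag,
         id = px,
         rot90 = rot90(px),
         rot180 = rot90(rot90(px)),
         rot270 = rot90(rot90(rot90(px))),
         flip = hflip(px),
         rot90_flip = rot90(hflip(px)),
         rot180_flip = rot90(rot90(hflip(px))),
         rot270_flip = rot90(rot90(rot90(hflip(px)))),
         stop("unknown D4 tag: ", tag))
}

#' @rdname d4_tags
#' @export
augment_d4 <- function(px) {
  d <- dim(px)
  if (length(d) != 3 || d[1] != d[2]) stop("augment_d4 requires a square tile")
  stats::setNames(lapply(d4_tags(), function(tg) d4_apply(px, tg)), d4_tags())
}

#' Expand a dataset with the 8 dihedral views of each training tile
#'
#' Each ground-truth training tile is replaced by its 8-element D4 orbit
#' (identity included), all carrying the source tile's label; the expansion
#' is recorded in the `aug` column and realized lazily by [tile_pixels()].
#' Test-split tiles are never augmented: passing any raises an error.
#'
#' @param dataset A `tile_dataset` of training tiles.
#' @return The augmented `tile_dataset`, 8x the rows.
#' @export
augment_dataset <- function(dataset) {
  tiles <- dataset$tiles
  if (any(tiles$split == "test")) {
    stop("refusing to augment test-split tiles")
  }
  if (any(tiles$aug != "id")) stop("dataset is already augmented")
  out <- do.call(rbind, lapply(d4_tags(), function(tg) {
    t2 <- tiles
    t2$aug <- tg
    t2
  }))
  new_tile_dataset(out, dataset$scheme)
}

#' Remove background tiles
#'
#' Retains tiles whose fraction of "dark" pixels (mean intensity below
#' `intensity_cutoff`) is at least `min_foreground_fraction`; the comparison
#' is inclusive. A threshold of 0 passes every tile through without reading
#' any image.
#'
#' @param dataset A `tile_dataset`.
#' @param min_foreground_fraction Minimum dark-pixel fraction in \[0, 1\].
#' @param intensity_cutoff Mean-intensity level below which a pixel counts
#'   as tissue foreground.
#' @return The filtered `tile_dataset`.
#' @export
tissue_filter <- function(dataset, min_foreground_fraction = 0.05,
                          intensity_cutoff = 0.8) {
  stopifnot(min_foreground_fraction >= 0, min_foreground_fraction <= 1)
  if (min_foreground_fraction == 0 || !nrow(dataset$tiles)) return(dataset)
  ord <- order(dataset$tiles$image_path)  # group by slide for the cache
  keep <- logical(nrow(dataset$tiles))
  for (i in ord) {
    px <- tile_pixels(dataset, i)
    intensity <- (px[, , 1] + px[, , 2] + px[, , 3]) / 3
    keep[i] <- mean(intensity < intensity_cutoff) >= min_foreground_fraction
  }
  new_tile_dataset(dataset$tiles[keep, , drop = FALSE], dataset$scheme)
}

#' Per-channel normalization statistics
#'
#' Pools all pixels of all tiles in the dataset and returns the per-channel
#' mean and standard deviation (population form), the statistics used to
#' normalize tiles before classification. Standard deviations are floored
#' at `1e-6`. Compute these on the training split only and reuse them for
#' test-time normalization.
#'
#' @param dataset A non-empty `tile_dataset`.
#' @return Object of class `channel_stats`: list with `mean`, `std`
#'   (3-vectors) and `source` (dataset size tag).
#' @export
compute_channel_stats <- function(dataset) {
  n <- nrow(dataset$tiles)
  if (!n) stop("cannot compute channel statistics of an empty tile set")
  s <- s2 <- numeric(3)
  npix <- 0
  for (i in order(dataset$tiles$image_path)) {
    px <- tile_pixels(dataset, i)
    for (k in 1:3) {
      s[k] <- s[k] + sum(px[, , k])
      s2[k] <- s2[k] + sum(px[, , k]^2)
    }
    npix <- npix + prod(dim(px)[1:2])
  }
  m <- s / npix
  v <- pmax(s2 / npix - m^2, 0)
  structure(list(mean = m, std = pmax(sqrt(v), 1e-6),
                 source = sprintf("%d tiles", n)),
            class = "channel_stats")
}

#' Apply / invert per-channel normalization
#'
#' `normalize_pixels()` maps each channel to `(x - mean) / std`;
#' `denormalize_pixels()` is its inverse. `normalize_tiles()` attaches the
#' statistics to a `tile_dataset` so [tile_pixels()] can deliver normalized
#' arrays; the same statistics must be applied to training and test tiles.
#'
#' @param px Numeric array `H x W x 3`.
#' @param stats A `channel_stats`.
#' @return The transformed array, or (for `normalize_tiles`) the dataset
#'   with statistics attached.
#' @export
normalize_pixels <- function(px, stats) {
  if (length(dim(px)) != 3 || dim(px)[3] != length(stats$mean)) {
    stop("channel count mismatch between pixels and statistics")
  }
  for (k in seq_along(stats$mean)) {
    px[, , k] <- (px[, , k] - stats$mean[k]) / stats$std[k]
  }
  px
}

#' @rdname normalize_pixels
#' @export
denormalize_pixels <- function(px, stats) {
  if (length(dim(px)) != 3 || dim(px)[3] != length(stats$mean)) {
    stop("channel count mismatch between pixels and statistics")
  }
  for (k in seq_along(stats$mean)) {
    px[, , k] <- px[, , k] * stats$std[k] + stats$mean[k]
  }
  px
}

#' @rdname normalize_pixels
#' @param dataset A `tile_dataset`.
#' @export
normalize_tiles <- function(dataset, stats) {
  stopifnot(inherits(stats, "channel_stats"))
  dataset$channel_stats <- stats
  dataset
}

#' Write / read a tile manifest
#'
#' TSV with one row per tile: `slide_id`, `image_path`, `x`, `y`, `size`,
#' `label`, `provenance`, `split`, `aug`.
#'
#' @param dataset A `tile_dataset`.
#' @param path Output TSV path.
#' @return The path (write) or a `tile_dataset` (read).
#' @export
write_tile_manifest <- function(dataset, path) {
  utils::write.table(dataset$tiles, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_tile_manifest
#' @param scheme A [class_scheme()].
#' @export
read_tile_manifest <- function(path, scheme = class_scheme()) {
  tiles <- utils::read.delim(path, stringsAsFactors = FALSE)
  tiles$label <- as.character(tiles$label)
  new_tile_dataset(tiles, scheme)
}

#' @rdname compute_channel_stats
#' @param stats A `channel_stats`.
#' @param path JSON file path.
#' @export
write_channel_stats <- function(stats, path) {
  jsonlite::write_json(unclass(stats), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname compute_channel_stats
#' @export
read_channel_stats <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(mean = x$mean, std = x$std, source = x$source),
            class = "channel_stats")
}

# Bind several tile datasets sharing a scheme.
bind_tile_datasets <- function(...) {
  ds <- list(...)
  tiles <- do.call(rbind, lapply(ds, `[[`, "tiles"))
  new_tile_dataset(tiles, ds[[1]]$scheme)
}
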