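# Training-patch sampling from a labelled image half: vertical train/test
# split, tile enumeration, dark-background filtering, and assembly of the
# region tiles plus a seeded random fraction of the remaining tissue tiles.

#' Split an atlas into train and test halves
#'
#' Splits vertically at `floor(W/2)`: the left half (training) gets the first
#' `floor(W/2)` pixel columns, the right half (testing) the rest. No pixel is
#' in both halves.
#'
#' @param atlas An `atlas_labeled_image`.
#' @return List with `left` and `right`, both `atlas_labeled_image`s.
#' @export
split_halves <- function(atlas) {
  W <- ncol(atlas$mask)
  if (W < 2) stop("image too narrow to split", call. = FALSE)
  wl <- W %/% 2L
  take <- function(cols) {
    atlas_labeled_image(
      multiplex_image(atlas$image$data[, cols, , drop = FALSE],
                      atlas$image$channels),
      atlas$mask[, cols, drop = FALSE], atlas$regions)
  }
  list(left = take(seq_len(wl)), right = take((wl + 1L):W))
}

#' Enumerate full tiles of an image at a grid offset
#'
#' Lists the top-left corners (0-based) of all `tile x tile` windows at
#' positions `(offset[1] + tile*a, offset[2] + tile*b)` that fit entirely
#' inside an `H x W` image; partial tiles at the edges are dropped.
#'
#' @param H,W Image height and width in pixels.
#' @param tile Tile side in pixels. Default 48.
#' @param offset Length-2 integer vector (row, col), each in `[0, tile)`.
#' @return A data frame with 0-based columns `row` and `col`.
#' @export
tile_grid <- function(H, W, tile = 48L, offset = c(0L, 0L)) {
  if (any(offset < 0) || any(offset >= tile))
    stop("offset components must lie in [0, tile)", call. = FALSE)
  rows <- seq.int(offset[1], by = tile, length.out = max(0L, (H - offset[1]) %/% tile))
  cols <- seq.int(offset[2], by = tile, length.out = max(0L, (W - offset[2]) %/% tile))
  g <- expand.grid(col = cols, row = rows)
  data.frame(row = as.integer(g$row), col = as.integer(g$col))
}

#' Dark-background filter for a tile
#'
#' A tile is discarded when its mean intensity over all channels and pixels is
#' strictly below the threshold; a mean exactly equal to the threshold keeps
#' the tile.
#'
#' @param tile Numeric array (any shape) of tile intensities.
#' @param threshold Non-negative intensity threshold.
#' @return `TRUE` to keep, `FALSE` to discard.
#' @export
background_filter <- function(tile, threshold) {
  if (threshold < 0) stop("threshold must be non-negative", call. = FALSE)
  mean(tile) >= threshold
}

round_half_up <- function(x) floor(x + 0.5)

extract_tile <- function(data, row0, col0, tile) {
  data[(row0 + 1L):(row0 + tile), (col0 + 1L):(col0 + tile), , drop = FALSE]
}

#' Build the multi-class training patch set
#'
#' Enumerates all aligned `tile x tile` tiles of the (training half) atlas,
#' drops dark-background tiles (mean intensity strictly below `threshold`),
#' includes every remaining tile that overlaps at least `min_region_pixels`
#' labelled region pixels, and adds a seeded uniform random sample (without
#' replacement) of `other_fraction` of the remaining non-background tiles.
#' Each emitted tile carries its per-pixel label map.
#'
#' @param atlas An `atlas_labeled_image` (typically the left half from
#'   [split_halves()]).
#' @param tile Tile side in pixels. Default 48.
#' @param other_fraction Fraction of non-region tiles to sample, in `[0, 1]`.
#'   Default 0.10. The sampled count is `other_fraction * eligible`, rounded
#'   half away from zero.
#' @param threshold Background threshold; default 0.02 of the image maximum.
#' @param min_region_pixels Minimum labelled pixels for a tile to count as
#'   containing a region. Default 1.
#' @param seed Seed for the random sample.
#' @return A list of class `training_set`: `tiles` (array
#'   `tile x tile x channels x n`), `labels` (integer array `tile x tile x n`,
#'   0-based classes), and `records` (data frame with 0-based `row`, `col`,
#'   logical `contains_roi`).
#' @export
build_training_set <- function(atlas, tile = 48L, other_fraction = 0.10,
                               threshold = NULL, min_region_pixels = 1L,
                               seed = 0L) {
  if (other_fraction < 0 || other_fraction > 1)
    stop("other_fraction must lie in [0, 1]", call. = FALSE)
  img <- atlas$image$data
  if (is.null(threshold)) threshold <- 0.02 * max(img)
  grid <- tile_grid(nrow(atlas$mask), ncol(atlas$mask), tile)
  n <- nrow(grid)
  keep <- logical(n); roi <- logical(n)
  for (i in seq_len(n)) {
    tl <- extract_tile(img, grid$row[i], grid$col[i], tile)
    keep[i] <- background_filter(tl, threshold)
    mk <- atlas$mask[(grid$row[i] + 1L):(grid$row[i] + tile),
                     (grid$col[i] + 1L):(grid$col[i] + tile)]
    roi[i] <- sum(mk > 0L) >= min_region_pixels
  }
  take_roi <- which(keep & roi)
  eligible <- which(keep & !roi)
  n_other <- round_half_up(other_fraction * length(eligible))
  set.seed(seed)
  take_other <- if (n_other > 0) sort(sample(eligible, n_other)) else integer(0)
  sel <- c(take_roi, take_other)
  if (length(sel) == 0)
    stop("no training tiles selected; review the background threshold",
         call. = FALSE)
  nch <- dim(img)[3]
  tiles <- array(0, c(tile, tile, nch, length(sel)))
  labels <- array(0L, c(tile, tile, length(sel)))
  for (j in seq_along(sel)) {
    i <- sel[j]
    tiles[, , , j] <- extract_tile(img, grid$row[i], grid$col[i], tile)
    labels[, , j] <- atlas$mask[(grid$row[i] + 1L):(grid$row[i] + tile),
                                (grid$col[i] + 1L):(grid$col[i] + tile)]
  }
  structure(list(tiles = tiles, labels = labels,
                 records = data.frame(row = grid$row[sel], col = grid$col[sel],
                                      contains_roi = roi[sel]),
                 threshold = threshold),
            class = "training_set")
}

#' @export
print.training_set <- function(x, ...) {
  cat(sprintf("training set: %d tiles (%d region, %d sampled other)\n",
              nrow(x$records), sum(x$records$contains_roi),
              sum(!x$records$contains_roi)))
  invisible(x)
}
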