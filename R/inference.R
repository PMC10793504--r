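# Strided sliding-window inference: tiled prediction at a grid of 2D offsets
# and pixel-wise mode voting across the offset maps. With stride factor
# f = tile size this reduces exactly to plain non-overlapping tiling.

#' Build the offset plan for strided inference
#'
#' For an integer `f` dividing the tile size, inference runs over the
#' `n = (tile/f)^2` tilings offset by `(a*f, b*f)` for
#' `a, b in 0..(tile/f)-1`. `f = tile` gives the single offset `(0, 0)`
#' (standard non-overlapping inference); smaller `f` gives more overlapping
#' windows and a smoother vote.
#'
#' @param f Stride factor; must divide `tile`.
#' @param tile Tile side in pixels. Default 48.
#' @return List of class `offset_plan`: `f`, `n`, and a data frame `offsets`
#'   with 0-based columns `row` and `col`.
#' @export
offset_grid <- function(f, tile = 48L) {
  f <- as.integer(f)
  if (f < 1 || tile %% f != 0)
    stop(sprintf("f must be a positive factor of %d", tile), call. = FALSE)
  k <- tile %/% f
  g <- expand.grid(col = seq.int(0L, by = f, length.out = k),
                   row = seq.int(0L, by = f, length.out = k))
  structure(list(f = f, tile = tile, n = k * k,
                 offsets = data.frame(row = g$row, col = g$col)),
            class = "offset_plan")
}

#' Predict a label map over one offset tiling
#'
#' Tiles the image at the given offset, runs the model on every full tile and
#' writes each tile's per-pixel argmax labels back at its location. Pixels not
#' covered by a full tile at this offset are flagged uncovered.
#'
#' @param model A `swinplex_model`.
#' @param image A `multiplex_image` or `H x W x channels` array.
#' @param offset Length-2 integer (row, col) pixel offset, 0-based.
#' @param batch_size Tiles evaluated per forward pass. Default 16.
#' @return List with `map` (integer matrix, 0-based labels, `NA` where
#'   uncovered) and `coverage` (logical matrix).
#' @export
predict_offset_map <- function(model, image, offset = c(0L, 0L),
                               batch_size = 16L) {
  if (inherits(image, "multiplex_image")) image <- image$data
  cfg <- model$config
  ts <- cfg$input_size
  H <- dim(image)[1]; W <- dim(image)[2]
  if (H < ts || W < ts)
    stop("image is smaller than one tile", call. = FALSE)
  grid <- tile_grid(H, W, ts, offset)
  map <- matrix(NA_integer_, H, W)
  coverage <- matrix(FALSE, H, W)
  n <- nrow(grid)
  for (start in seq.int(1L, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, n)
    xb <- array(0, c(ts, ts, cfg$in_channels, length(idx)))
    for (j in seq_along(idx)) {
      i <- idx[j]
      xb[, , , j] <- extract_tile(image, grid$row[i], grid$col[i], ts)
    }
    lg <- fwd_tiles(model, xb)$logits
    lab <- max.col(lg, ties.method = "first") - 1L
    for (j in seq_along(idx)) {
      i <- idx[j]
      rows <- (grid$row[i] + 1L):(grid$row[i] + ts)
      cols <- (grid$col[i] + 1L):(grid$col[i] + ts)
      tile_lab <- matrix(lab[((j - 1L) * ts * ts + 1L):(j * ts * ts)],
                         ts, ts, byrow = TRUE)
      map[rows, cols] <- tile_lab
      coverage[rows, cols] <- TRUE
    }
  }
  list(map = map, coverage = coverage)
}

#' Pixel-wise mode vote over offset label maps
#'
#' For each pixel, returns the most frequent label among the maps that cover
#' it; ties are broken deterministically toward the smallest label index.
#' Every pixel must be covered by at least one map (the `(0, 0)` offset
#' guarantees this on tile-aligned images).
#'
#' @param stack List of per-offset predictions, each a list with `map` and
#'   `coverage` as returned by [predict_offset_map()].
#' @param num_classes Number of label classes (labels `0..num_classes-1`).
#' @return Integer matrix of smoothed labels.
#' @export
mode_smooth <- function(stack, num_classes) {
  H <- nrow(stack[[1]]$map); W <- ncol(stack[[1]]$map)
  counts <- array(0L, c(H, W, num_classes))
  total <- matrix(0L, H, W)
  for (s in stack) {
    cov <- s$coverage
    total <- total + cov
    for (k in seq_len(num_classes)) {
      counts[, , k] <- counts[, , k] + (cov & !is.na(s$map) & s$map == (k - 1L))
    }
  }
  if (any(total == 0L))
    stop("some pixels received no votes", call. = FALSE)
  cm <- matrix(counts, H * W, num_classes)
  matrix(max.col(cm, ties.method = "first") - 1L, H, W)
}

#' Segment an image with mode-smoothed strided inference
#'
#' Runs [predict_offset_map()] at every offset of the [offset_grid()] plan and
#' combines the maps with [mode_smooth()]. Images whose sides are not
#' multiples of the tile size are zero-padded on the right/bottom for
#' inference and cropped afterwards. With `f` equal to the tile size the
#' result is identical to plain non-overlapping tiled inference.
#'
#' @param model A `swinplex_model`.
#' @param image A `multiplex_image` or `H x W x channels` array.
#' @param f Stride factor (a divisor of the tile size). Default 4.
#' @param batch_size Tiles per forward pass.
#' @return Object of class `swinplex_segmentation`: list with the integer
#'   label matrix `labels` (0-based), `f`, and the offset plan.
#' @export
segment_image <- function(model, image, f = 4L, batch_size = 16L) {
  if (inherits(image, "multiplex_image")) image <- image$data
  cfg <- model$config
  ts <- cfg$input_size
  H <- dim(image)[1]; W <- dim(image)[2]
  Hp <- ceiling(H / ts) * ts
  Wp <- ceiling(W / ts) * ts
  if (Hp != H || Wp != W) {
    padded <- array(0, c(Hp, Wp, dim(image)[3]))
    padded[seq_len(H), seq_len(W), ] <- image
    image <- padded
  }
  plan <- offset_grid(f, ts)
  stack <- lapply(seq_len(plan$n), function(i) {
    predict_offset_map(model, image,
                       c(plan$offsets$row[i], plan$offsets$col[i]),
                       batch_size = batch_size)
  })
  labels <- mode_smooth(stack, cfg$num_classes)[seq_len(H), seq_len(W), drop = FALSE]
  structure(list(labels = labels, f = plan$f, plan = plan),
            class = "swinplex_segmentation")
}

#' @export
print.swinplex_segmentation <- function(x, ...) {
  cat(sprintf("segmentation: %d x %d, f=%d (%d offset maps), labels %s\n",
              nrow(x$labels), ncol(x$labels), x$f, x$plan$n,
              paste(range(x$labels), collapse = "..")))
  invisible(x)
}
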