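# File I/O: multi-page TIFF for multi-channel images (channels-first pages),
# 16-bit TIFF / PNG for integer masks, JSON region tables, JSON-lines click
# files, and model checkpoints with an architecture fingerprint guard.

#' Read / write a multi-channel image as multi-page TIFF
#'
#' Images are stored channels-first: one 32-bit page per biomarker channel.
#' Intensities are normalised to `[0, 1]` on write; the normalisation factor
#' and the channel names travel in a JSON sidecar (`<path>.channels.json`)
#' written alongside and applied on read, so intensities round trip on their
#' original scale.
#'
#' @param path TIFF file path.
#' @return `read_multiplex_tiff` returns a `multiplex_image`.
#' @export
read_multiplex_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  H <- nrow(pages[[1]]); W <- ncol(pages[[1]])
  data <- array(0, c(H, W, length(pages)))
  for (i in seq_along(pages)) data[, , i] <- pages[[i]]
  channels <- NULL
  sidecar <- paste0(path, ".channels.json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    if (is.list(meta) && !is.null(meta$channels)) {
      channels <- as.character(meta$channels)
      if (!is.null(meta$scale)) data <- data * meta$scale
    } else {
      channels <- as.character(meta)
    }
  }
  multiplex_image(data, channels)
}

#' @rdname read_multiplex_tiff
#' @param img A `multiplex_image` (or `H x W x channels` array).
#' @export
write_multiplex_tiff <- function(img, path) {
  if (!inherits(img, "multiplex_image")) img <- multiplex_image(img)
  if (min(img$data) < 0)
    stop("negative intensities cannot be written", call. = FALSE)
  scale <- max(img$data, 1)
  pages <- lapply(seq_len(dim(img$data)[3]),
                  function(i) img$data[, , i] / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 32, reduce = FALSE)
  jsonlite::write_json(list(channels = img$channels, scale = scale),
                       paste0(path, ".channels.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read / write an integer label mask
#'
#' Masks are stored as single-channel 16-bit images; TIFF or PNG is chosen by
#' file extension (PNG requires the `png` package).
#'
#' @param path File path ending in `.tif`, `.tiff` or `.png`.
#' @return `read_mask` returns an integer matrix.
#' @export
read_mask <- function(path) {
  v <- if (grepl("\\.png$", path, ignore.case = TRUE)) {
    if (!requireNamespace("png", quietly = TRUE))
      stop("the png package is required for PNG masks", call. = FALSE)
    png::readPNG(path)
  } else {
    tiff::readTIFF(path)
  }
  if (length(dim(v)) == 3) v <- v[, , 1]
  matrix(as.integer(round(v * 65535)), nrow(v), ncol(v))
}

#' @rdname read_mask
#' @param mask Integer matrix (labels in `0..65535`).
#' @export
write_mask <- function(mask, path) {
  v <- mask / 65535
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    if (!requireNamespace("png", quietly = TRUE))
      stop("the png package is required for PNG masks", call. = FALSE)
    png::writePNG(v, path)
  } else {
    tiff::writeTIFF(v, path, bits.per.sample = 16)
  }
  invisible(path)
}

#' Read / write a region-name table as JSON
#'
#' @param path JSON file path mapping region ids to names.
#' @return `read_region_table` returns a named character vector (names are
#'   region ids).
#' @export
read_region_table <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  out <- as.character(x)
  names(out) <- names(x)
  out
}

#' @rdname read_region_table
#' @param regions Named character vector of region names.
#' @export
write_region_table <- function(regions, path) {
  jsonlite::write_json(as.list(regions), path, auto_unbox = TRUE)
  invisible(path)
}

#' Read / write click annotations as JSON lines
#'
#' One JSON object per line, e.g.
#' `{"region":"mt","row":1104,"col":432,"label":"region","round":1}`.
#' Coordinates are 0-based top-left corners of 48 x 48 patches.
#'
#' @param path JSONL file path.
#' @param region_id Region to extract; default: the file's single region.
#' @return `read_clicks` returns a `click_set`.
#' @export
read_clicks <- function(path, region_id = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  rows <- lapply(lines, function(l) jsonlite::fromJSON(l))
  df <- do.call(rbind, lapply(rows, function(r) {
    data.frame(region = r$region, row = as.integer(r$row),
               col = as.integer(r$col), label = r$label,
               round = if (is.null(r$round)) 1L else as.integer(r$round))
  }))
  if (is.null(region_id)) {
    ids <- unique(df$region)
    if (length(ids) != 1)
      stop("file contains several regions; pass region_id", call. = FALSE)
    region_id <- ids
  }
  df <- df[df$region == region_id, ]
  click_set(region_id, df[, c("row", "col", "label", "round")])
}

#' @rdname read_clicks
#' @param clicks A `click_set`.
#' @export
write_clicks <- function(clicks, path) {
  ent <- clicks$entries
  lines <- vapply(seq_len(nrow(ent)), function(i) {
    jsonlite::toJSON(list(region = clicks$region_id, row = ent$row[i],
                          col = ent$col[i], label = ent$label[i],
                          round = ent$round[i]), auto_unbox = TRUE)
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Save / load a model checkpoint
#'
#' Checkpoints bundle the named parameter set with the model configuration
#' and its fingerprint. `load_checkpoint` refuses a checkpoint whose stored
#' fingerprint does not match its own configuration (corruption), or whose
#' configuration does not match `expected_config` when one is given.
#'
#' @param model A `swinplex_model`.
#' @param path Checkpoint file path.
#' @return `load_checkpoint` returns a `swinplex_model`.
#' @export
save_checkpoint <- function(model, path) {
  cfg <- unclass(model$config)
  saveRDS(list(config = cfg, fingerprint = model$fingerprint,
               params = model$params), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @param expected_config Optional `swinplex_config` the checkpoint must match.
#' @export
load_checkpoint <- function(path, expected_config = NULL) {
  raw <- readRDS(path)
  cfg <- do.call(model_config,
                 raw$config[setdiff(names(raw$config), "embed_dim")])
  if (!identical(config_fingerprint(cfg), raw$fingerprint))
    stop("checkpoint config hash mismatch", call. = FALSE)
  if (!is.null(expected_config) &&
      !identical(config_fingerprint(expected_config), raw$fingerprint))
    stop("checkpoint does not match the expected config (hash mismatch)",
         call. = FALSE)
  model <- list(config = cfg, params = raw$params,
                fingerprint = raw$fingerprint)
  class(model) <- "swinplex_model"
  model
}
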