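#' Model configuration for the multi-channel Swin-UNet
#'
#' Builds and validates the hyperparameter set of the segmentation network.
#' The network consumes square multi-channel tiles (`input_size` pixels per
#' side), embeds non-overlapping `patch_size` x `patch_size` pixel patches with
#' a depthwise (per-biomarker-channel) convolution, and processes the token
#' grid through a reduced-depth encoder-decoder of paired window / shifted
#' window attention blocks with two skip connections.
#'
#' The latent width is `embed_dim = in_channels * filters_per_channel`; each
#' downsampling stage doubles it. `stage_depths`, `heads_per_stage` and
#' `mlp_ratio` describe the encoder stages followed by the bottleneck (the
#' decoder mirrors the encoder), so with the default three entries the model
#' has two encoder stages, a bottleneck, and two decoder stages.
#'
#' @param input_size Tile side in pixels. Default 48.
#' @param patch_size Embedding patch side in pixels. Default 4.
#' @param in_channels Number of biomarker channels. Default 8.
#' @param filters_per_channel Depthwise filters learned per channel. Default 12.
#' @param window_size Attention window side, in tokens. Default 6. At scales
#'   where the token grid is not larger than the window, the window is clamped
#'   to the grid and the shift is disabled, as usual for shifted-window models.
#' @param shift_size Cyclic shift, in tokens, used by the second block of each
#'   pair. Default `window_size %/% 2`.
#' @param stage_depths Integer vector of attention-block counts per scale
#'   (encoder stages then bottleneck). Blocks come in window/shifted pairs, so
#'   entries must be even. Default `c(2, 2, 2)`.
#' @param heads_per_stage Attention heads per scale. Default `c(4, 4, 8)`.
#' @param mlp_ratio Feed-forward expansion ratio per scale. Default `c(4, 2, 2)`.
#' @param num_classes Output classes (regions + background). Default 11.
#' @param use_relative_position_bias Learn a relative position bias table per
#'   attention block. Default TRUE.
#' @param qkv_bias Add bias terms to the query/key/value projections. Default TRUE.
#' @param embed_pointwise Add a pointwise (cross-channel mixing) projection
#'   after the depthwise embedding. Default FALSE: the embedding treats each
#'   biomarker channel separately.
#' @param channel_names Optional character vector of biomarker names, length
#'   `in_channels`.
#'
#' @return An object of class `swinplex_config` (a validated named list).
#' @seealso [reference_config()], [build_model()]
#' @export
model_config <- function(input_size = 48,
                         patch_size = 4,
                         in_channels = 8,
                         filters_per_channel = 12,
                         window_size = 6,
                         shift_size = window_size %/% 2,
                         stage_depths = c(2, 2, 2),
                         heads_per_stage = c(4, 4, 8),
                         mlp_ratio = c(4, 2, 2),
                         num_classes = 11,
                         use_relative_position_bias = TRUE,
                         qkv_bias = TRUE,
                         embed_pointwise = FALSE,
                         channel_names = NULL) {
  cfg <- list(
    input_size = as.integer(input_size),
    patch_size = as.integer(patch_size),
    in_channels = as.integer(in_channels),
    filters_per_channel = as.integer(filters_per_channel),
    embed_dim = as.integer(in_channels * filters_per_channel),
    window_size = as.integer(window_size),
    shift_size = as.integer(shift_size),
    stage_depths = as.integer(stage_depths),
    heads_per_stage = as.integer(heads_per_stage),
    mlp_ratio = as.numeric(mlp_ratio),
    num_classes = as.integer(num_classes),
    use_relative_position_bias = isTRUE(use_relative_position_bias),
    qkv_bias = isTRUE(qkv_bias),
    embed_pointwise = isTRUE(embed_pointwise),
    channel_names = channel_names
  )
  class(cfg) <- "swinplex_config"
  validate_config(cfg)
  cfg
}

#' Validate a model configuration
#'
#' Checks every structural invariant the architecture relies on and stops with
#' a message naming the violated invariant.
#'
#' @param cfg A `swinplex_config`.
#' @return `cfg`, invisibly, if valid.
#' @export
validate_config <- function(cfg) {
  fail <- function(msg) stop("invalid model config: ", msg, call. = FALSE)
  if (cfg$input_size %% cfg$patch_size != 0)
    fail("input_size must be divisible by patch_size")
  if (cfg$embed_dim != cfg$in_channels * cfg$filters_per_channel)
    fail("embed_dim must equal in_channels * filters_per_channel")
  if (cfg$shift_size >= cfg$window_size || cfg$shift_size < 0)
    fail("shift_size must satisfy 0 <= shift_size < window_size")
  n_stage <- length(cfg$stage_depths)
  if (n_stage < 1) fail("at least one stage is required")
  if (length(cfg$heads_per_stage) != n_stage ||
      length(cfg$mlp_ratio) != n_stage)
    fail("stage_depths, heads_per_stage and mlp_ratio must have equal length")
  if (any(cfg$stage_depths %% 2 != 0))
    fail("stage_depths entries must be even (attention blocks come in pairs)")
  grid <- cfg$input_size %/% cfg$patch_size
  for (s in seq_len(n_stage)) {
    d <- cfg$embed_dim * 2^(s - 1)
    if (d %% cfg$heads_per_stage[s] != 0)
      fail(sprintf("heads_per_stage[%d] must divide the stage width %d", s, d))
    w_eff <- min(cfg$window_size, grid)
    if (grid %% w_eff != 0)
      fail(sprintf("token grid side %d at stage %d is not divisible by window %d",
                   grid, s, w_eff))
    if (s < n_stage) {
      if (grid %% 2 != 0)
        fail(sprintf("token grid side %d at stage %d is odd; cannot merge", grid, s))
      grid <- grid %/% 2
    }
  }
  if (cfg$num_classes < 2) fail("num_classes must be at least 2")
  if (!is.null(cfg$channel_names) &&
      length(cfg$channel_names) != cfg$in_channels)
    fail("channel_names must have length in_channels")
  invisible(cfg)
}

#' The frozen reference configuration
#'
#' The calibrated configuration of the compact multi-channel Swin-UNet:
#' 48 x 48 input, 4 x 4 depthwise patch embedding with 12 filters per channel
#' (latent width 96 at 8 channels), window size 6, two encoder stages plus a
#' bottleneck (one merging stage fewer than the standard model, hence two skip
#' connections), per-stage heads (4, 4, 8) and feed-forward ratios (4, 2, 2),
#' and an 11-class per-pixel head. This configuration carries exactly
#' 4,990,032 trainable parameters.
#'
#' The values are shipped in `inst/extdata/reference_config.yaml` and read
#' from there, so the file is the single source of truth.
#'
#' @param num_classes Optionally override the output-class count (e.g. 2 for a
#'   binary model); every other field stays frozen.
#' @return A `swinplex_config`.
#' @export
reference_config <- function(num_classes = NULL) {
  path <- system.file("extdata", "reference_config.yaml", package = "swinplex")
  cfg <- read_config(path)
  if (!is.null(num_classes)) {
    cfg$num_classes <- as.integer(num_classes)
    validate_config(cfg)
  }
  cfg
}

#' Read / write a model configuration as YAML
#'
#' @param path File path.
#' @return `read_config` returns a validated `swinplex_config`;
#'   `write_config` returns `path` invisibly.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(model_config, raw[setdiff(names(raw), "embed_dim")])
}

#' @rdname read_config
#' @param cfg A `swinplex_config`.
#' @export
write_config <- function(cfg, path) {
  validate_config(cfg)
  out <- unclass(cfg)
  out$channel_names <- if (is.null(out$channel_names)) NULL else as.list(out$channel_names)
  yaml::write_yaml(out, path)
  invisible(path)
}

#' @export
print.swinplex_config <- function(x, ...) {
  grid <- x$input_size %/% x$patch_size
  cat(sprintf("multi-channel Swin-UNet config: %dx%dx%d tiles -> %dx%d tokens, C=%d\n",
              x$input_size, x$input_size, x$in_channels, grid, grid, x$embed_dim))
  cat(sprintf("  stages: depths [%s], heads [%s], mlp ratios [%s], window %d (shift %d)\n",
              paste(x$stage_depths, collapse = ","),
              paste(x$heads_per_stage, collapse = ","),
              paste(x$mlp_ratio, collapse = ","),
              x$window_size, x$shift_size))
  cat(sprintf("  classes: %d\n", x$num_classes))
  invisible(x)
}

# Deterministic fingerprint of a config (FNV-1a over its canonical YAML),
# used to refuse loading checkpoints built for a different architecture.
config_fingerprint <- function(cfg) {
  s <- yaml::as.yaml(unclass(cfg)[order(names(unclass(cfg)))])
  bytes <- utf8ToInt(s)
  h <- 2166136261
  for (b in bytes) {
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), as.integer(b %% 256))
    # 32-bit modular multiply by the FNV prime 16777619, done in two halves
    # to stay inside double precision
    lo <- (h %% 65536) * 16777619
    hi <- ((h %/% 65536) * 16777619) %% 65536
    h <- (lo + hi * 65536) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

# Per-stage geometry: token grid side, width, effective window and shift.
stage_geometry <- function(cfg) {
  n_stage <- length(cfg$stage_depths)
  grid <- cfg$input_size %/% cfg$patch_size
  out <- vector("list", n_stage)
  for (s in seq_len(n_stage)) {
    dim_s <- cfg$embed_dim * 2^(s - 1)
    w_eff <- min(cfg$window_size, grid)
    shift_eff <- if (grid <= w_eff) 0L else cfg$shift_size
    out[[s]] <- list(grid = grid, dim = dim_s, window = w_eff,
                     shift = as.integer(shift_eff),
                     heads = cfg$heads_per_stage[s],
                     mlp_ratio = cfg$mlp_ratio[s],
                     depth = cfg$stage_depths[s])
    if (s < n_stage) grid <- grid %/% 2
  }
  out
}
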