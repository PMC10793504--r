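# Forward pass of the network, plus the exported single-grid operations.

# Pixel gather map for the patch embedding: row t = token (row-major), column
# k = within-patch position (row-major); entries are linear indices into an
# input_size x input_size matrix.
embed_gather_index <- function(input_size, ps) {
  memo(sprintf("embgi_%d_%d", input_size, ps), function() {
    G <- input_size %/% ps
    I0 <- matrix(0L, G * G, ps * ps)
    for (pr in 1:G) for (pc in 1:G) {
      t <- (pr - 1L) * G + pc
      for (i in 1:ps) for (j in 1:ps) {
        h <- (pr - 1L) * ps + i
        w <- (pc - 1L) * ps + j
        I0[t, (i - 1L) * ps + j] <- h + (w - 1L) * input_size
      }
    }
    I0
  })
}

embed_fwd <- function(x, p, cfg, B, want_cache) {
  ps <- cfg$patch_size
  G <- cfg$input_size %/% ps
  I0 <- embed_gather_index(cfg$input_size, ps)
  n_tok <- G * G
  N <- B * n_tok
  fpc <- cfg$filters_per_channel
  E <- matrix(0, N, cfg$embed_dim)
  Mc <- vector("list", cfg$in_channels)
  for (ch in seq_len(cfg$in_channels)) {
    M <- matrix(0, N, ps * ps)
    for (b in seq_len(B)) {
      v <- x[, , ch, b]
      M[((b - 1L) * n_tok + 1L):(b * n_tok), ] <-
        matrix(v[as.vector(I0)], n_tok, ps * ps)
    }
    Mc[[ch]] <- M
    E[, ((ch - 1L) * fpc + 1L):(ch * fpc)] <- M %*% p$w[, , ch]
  }
  E <- E + rep(p$b, each = N)
  pre_point <- NULL
  if (cfg$embed_pointwise) {
    pre_point <- E
    E <- linear_fwd(E, p$point$w, p$point$b)
  }
  ln <- layernorm_fwd(E, p$norm$g, p$norm$b)
  if (!want_cache) return(list(out = ln$out))
  list(out = ln$out, cache = list(Mc = Mc, pre_point = pre_point, ln = ln))
}

merge_fwd <- function(X, p, B, G, want_cache) {
  idx <- merge_indices(B, G)
  Xcat <- cbind(X[idx$tl, , drop = FALSE], X[idx$bl, , drop = FALSE],
                X[idx$tr, , drop = FALSE], X[idx$br, , drop = FALSE])
  ln <- layernorm_fwd(Xcat, p$norm$g, p$norm$b)
  out <- ln$out %*% p$w
  if (!want_cache) return(list(out = out))
  list(out = out, cache = list(ln = ln, B = B, G = G, d = ncol(X)))
}

expand_fwd <- function(X, p, B, G, want_cache) {
  Y <- X %*% p$w
  d_out <- ncol(Y) %/% 4L
  idxs <- expand_indices(B, G, 2L)
  X2 <- matrix(0, 4L * nrow(X), d_out)
  for (s in 1:4) {
    X2[idxs[[s]], ] <- Y[, ((s - 1L) * d_out + 1L):(s * d_out), drop = FALSE]
  }
  if (!want_cache) return(list(out = X2))
  list(out = X2, cache = list(X = X, B = B, G = G, d_out = d_out))
}

final_expand_fwd <- function(X, p, B, G, ps, want_cache) {
  Y <- X %*% p$w
  C <- ncol(Y) %/% (ps * ps)
  idxs <- expand_indices(B, G, ps)
  X2 <- matrix(0, ps * ps * nrow(X), C)
  for (s in seq_len(ps * ps)) {
    X2[idxs[[s]], ] <- Y[, ((s - 1L) * C + 1L):(s * C), drop = FALSE]
  }
  ln <- layernorm_fwd(X2, p$norm$g, p$norm$b)
  if (!want_cache) return(list(out = ln$out))
  list(out = ln$out, cache = list(X = X, ln = ln, B = B, G = G, C = C))
}

# Full forward over a batch of tiles. `x` is (input_size, input_size,
# in_channels, B) (a single tile may omit the batch axis). Returns the logit
# matrix (B * input_size^2) x num_classes, rows tile-major then row-major over
# pixels, plus caches when `want_cache`.
fwd_tiles <- function(model, x, want_cache = FALSE) {
  cfg <- model$config
  if (length(dim(x)) == 3) dim(x) <- c(dim(x), 1L)
  dx <- dim(x)
  if (dx[1] != cfg$input_size || dx[2] != cfg$input_size ||
      dx[3] != cfg$in_channels)
    stop(sprintf("tile shape %dx%dx%d does not match config %dx%dx%d",
                 dx[1], dx[2], dx[3], cfg$input_size, cfg$input_size,
                 cfg$in_channels), call. = FALSE)
  B <- dx[4]
  p <- model$params
  geom <- stage_geometry(cfg)
  S <- length(geom)
  cache <- if (want_cache) list(B = B) else NULL
  emb <- embed_fwd(x, p$embed, cfg, B, want_cache)
  if (want_cache) cache$embed <- emb$cache
  X <- emb$out
  skips <- vector("list", max(S - 1, 0))
  if (S > 1) {
    if (want_cache) cache$enc <- vector("list", S - 1)
    for (s in seq_len(S - 1)) {
      g <- geom[[s]]
      blk_caches <- vector("list", g$depth)
      for (k in seq_len(g$depth)) {
        shift <- if (k %% 2 == 0) g$shift else 0L
        r <- swin_block_fwd(X, p$enc[[s]]$blocks[[k]], B, g$grid, g$window,
                            shift, g$heads, want_cache)
        X <- r$out
        if (want_cache) blk_caches[[k]] <- r$cache
      }
      skips[[s]] <- X
      mg <- merge_fwd(X, p$mrg[[s]], B, g$grid, want_cache)
      X <- mg$out
      if (want_cache) cache$enc[[s]] <- list(blocks = blk_caches, merge = mg$cache)
    }
  }
  gS <- geom[[S]]
  bot_caches <- vector("list", gS$depth)
  for (k in seq_len(gS$depth)) {
    shift <- if (k %% 2 == 0) gS$shift else 0L
    r <- swin_block_fwd(X, p$bot$blocks[[k]], B, gS$grid, gS$window,
                        shift, gS$heads, want_cache)
    X <- r$out
    if (want_cache) bot_caches[[k]] <- r$cache
  }
  if (want_cache) cache$bot <- bot_caches
  if (S > 1) {
    if (want_cache) cache$dec <- vector("list", S - 1)
    for (s in rev(seq_len(S - 1))) {
      g <- geom[[s]]
      ex <- expand_fwd(X, p$dec[[s]]$expand, B, g$grid %/% 2L, want_cache)
      Xcat <- cbind(ex$out, skips[[s]])
      Xf <- linear_fwd(Xcat, p$dec[[s]]$fuse$w, p$dec[[s]]$fuse$b)
      blk_caches <- vector("list", g$depth)
      X <- Xf
      for (k in seq_len(g$depth)) {
        shift <- if (k %% 2 == 0) g$shift else 0L
        r <- swin_block_fwd(X, p$dec[[s]]$blocks[[k]], B, g$grid, g$window,
                            shift, g$heads, want_cache)
        X <- r$out
        if (want_cache) blk_caches[[k]] <- r$cache
      }
      if (want_cache)
        cache$dec[[s]] <- list(expand = ex$cache, Xcat = Xcat, blocks = blk_caches)
    }
  }
  fe <- final_expand_fwd(X, p$final, B, geom[[1]]$grid, cfg$patch_size, want_cache)
  if (want_cache) cache$final <- fe$cache
  logits <- fe$out %*% p$head$w
  if (want_cache) cache$head_in <- fe$out
  list(logits = logits, cache = cache)
}

#' Forward segmentation pass on one tile
#'
#' Runs the network on a single multi-channel tile and returns per-pixel class
#' logits. The computation is deterministic given the parameters and input.
#'
#' @param model A `swinplex_model`.
#' @param tile Numeric array `input_size x input_size x in_channels`.
#' @return Numeric array `num_classes x input_size x input_size` of logits.
#' @export
forward_segment <- function(model, tile) {
  cfg <- model$config
  lg <- fwd_tiles(model, tile)$logits
  aperm(array(t(lg), c(cfg$num_classes, cfg$input_size, cfg$input_size)),
        c(1, 3, 2))
}

#' Embed a multi-channel tile with the separable patch embedding
#'
#' Applies the depthwise (per-biomarker-channel) 4x4 stride-4 convolution:
#' each input channel is filtered by its own `filters_per_channel` kernels
#' with no cross-channel mixing, and the outputs are concatenated channel-wise
#' to depth `embed_dim`. The embedding LayerNorm (and the optional pointwise
#' mixing projection) is applied as in the full model.
#'
#' @param tile Numeric array `input_size x input_size x in_channels`.
#' @param params The embedding parameter list (`model$params$embed`).
#' @param config The model's `swinplex_config`.
#' @return A token grid array `G x G x embed_dim` with `G = input_size /
#'   patch_size`.
#' @export
separable_patch_embed <- function(tile, params, config) {
  if (length(dim(tile)) != 3 ||
      dim(tile)[1] != config$input_size || dim(tile)[2] != config$input_size ||
      dim(tile)[3] != config$in_channels)
    stop(sprintf("tile must be %d x %d x %d", config$input_size,
                 config$input_size, config$in_channels), call. = FALSE)
  dim(tile) <- c(dim(tile), 1L)
  G <- config$input_size %/% config$patch_size
  mat_to_tokens(embed_fwd(tile, params, config, 1L, FALSE)$out, G, G)
}

#' Merge 2x2 token neighbourhoods (downsampling)
#'
#' Concatenates each 2x2 token neighbourhood to depth `4d`, normalises, and
#' linearly projects down to `2d`, halving both grid sides.
#'
#' @param tokens Numeric array `H x W x d` with even `H` and `W`.
#' @param params Merge parameters: `norm` (LayerNorm over `4d`) and the
#'   `4d x 2d` projection `w`.
#' @return Array `(H/2) x (W/2) x 2d`.
#' @export
patch_merge <- function(tokens, params) {
  d <- dim(tokens)
  if (d[1] %% 2 != 0 || d[2] %% 2 != 0)
    stop("token grid sides must be even to merge", call. = FALSE)
  if (d[1] != d[2]) stop("token grid must be square", call. = FALSE)
  X <- tokens_to_mat(tokens)
  out <- merge_fwd(X, params, 1L, d[1], FALSE)$out
  mat_to_tokens(out, d[1] %/% 2L, d[2] %/% 2L)
}

#' Expand tokens to double resolution (upsampling)
#'
#' Linearly projects each depth-`d` token to `2d`, then rearranges the result
#' into a 2x2 group of depth-`d/2` tokens, doubling both grid sides and
#' halving the depth — the inverse shape transform of [patch_merge()].
#'
#' @param tokens Numeric array `H x W x d`; `d` must be divisible by 2.
#' @param params Expansion parameters: the `d x 2d` projection `w`.
#' @return Array `2H x 2W x (d/2)`.
#' @export
patch_expand <- function(tokens, params) {
  d <- dim(tokens)
  if (d[3] %% 2 != 0)
    stop("token depth must be divisible by 2 to expand", call. = FALSE)
  if (d[1] != d[2]) stop("token grid must be square", call. = FALSE)
  X <- tokens_to_mat(tokens)
  out <- expand_fwd(X, params, 1L, d[1], FALSE)$out
  mat_to_tokens(out, 2L * d[1], 2L * d[2])
}
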