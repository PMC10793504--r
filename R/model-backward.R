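# Manual reverse-mode pass mirroring fwd_tiles. Returns a gradient tree with
# the same shape as model$params.

embed_bwd <- function(dE, p, cfg, cache) {
  gr <- list()
  ln <- layernorm_bwd(dE, cache$ln, p$norm$g)
  gr$norm <- list(g = ln$dg, b = ln$db)
  d <- ln$dX
  if (cfg$embed_pointwise) {
    pw <- linear_bwd(d, cache$pre_point, p$point$w, TRUE)
    gr$point <- list(w = pw$dW, b = pw$db)
    d <- pw$dX
  }
  gr$b <- colSums(d)
  fpc <- cfg$filters_per_channel
  gr$w <- array(0, dim(p$w))
  for (ch in seq_len(cfg$in_channels)) {
    cols <- ((ch - 1L) * fpc + 1L):(ch * fpc)
    gr$w[, , ch] <- crossprod(cache$Mc[[ch]], d[, cols, drop = FALSE])
  }
  gr
}

merge_bwd <- function(dY, p, cache) {
  d <- cache$d
  idx <- merge_indices(cache$B, cache$G)
  dLN <- tcrossprod(dY, p$w)
  gr <- list(w = crossprod(cache$ln$out, dY))
  ln <- layernorm_bwd(dLN, cache$ln, p$norm$g)
  gr$norm <- list(g = ln$dg, b = ln$db)
  dXcat <- ln$dX
  dX <- matrix(0, 4L * nrow(dY), d)
  dX[idx$tl, ] <- dXcat[, 1:d, drop = FALSE]
  dX[idx$bl, ] <- dXcat[, (d + 1):(2 * d), drop = FALSE]
  dX[idx$tr, ] <- dXcat[, (2 * d + 1):(3 * d), drop = FALSE]
  dX[idx$br, ] <- dXcat[, (3 * d + 1):(4 * d), drop = FALSE]
  list(dX = dX, grads = gr)
}

expand_bwd <- function(dX2, p, cache) {
  d_out <- cache$d_out
  idxs <- expand_indices(cache$B, cache$G, 2L)
  dY <- matrix(0, nrow(cache$X), 4L * d_out)
  for (s in 1:4) {
    dY[, ((s - 1L) * d_out + 1L):(s * d_out)] <- dX2[idxs[[s]], , drop = FALSE]
  }
  list(dX = tcrossprod(dY, p$w), grads = list(w = crossprod(cache$X, dY)))
}

final_expand_bwd <- function(dOut, p, cache, ps) {
  gr <- list()
  ln <- layernorm_bwd(dOut, cache$ln, p$norm$g)
  gr$norm <- list(g = ln$dg, b = ln$db)
  C <- cache$C
  idxs <- expand_indices(cache$B, cache$G, ps)
  dY <- matrix(0, nrow(cache$X), ps * ps * C)
  for (s in seq_len(ps * ps)) {
    dY[, ((s - 1L) * C + 1L):(s * C)] <- ln$dX[idxs[[s]], , drop = FALSE]
  }
  gr$w <- crossprod(cache$X, dY)
  list(dX = tcrossprod(dY, p$w), grads = gr)
}

bwd_tiles <- function(model, cache, dlogits) {
  cfg <- model$config
  p <- model$params
  geom <- stage_geometry(cfg)
  S <- length(geom)
  B <- cache$B
  grads <- list()
  grads$head <- list(w = crossprod(cache$head_in, dlogits))
  dX <- tcrossprod(dlogits, p$head$w)
  fe <- final_expand_bwd(dX, p$final, cache$final, cfg$patch_size)
  grads$final <- fe$grads
  dX <- fe$dX
  if (S > 1) {
    grads$dec <- vector("list", S - 1)
    for (s in seq_len(S - 1)) {      # decoder ran S-1 .. 1; backprop 1 .. S-1
      g <- geom[[s]]
      dgr <- list(blocks = vector("list", g$depth))
      for (k in rev(seq_len(g$depth))) {
        r <- swin_block_bwd(dX, p$dec[[s]]$blocks[[k]], cache$dec[[s]]$blocks[[k]])
        dgr$blocks[[k]] <- r$grads
        dX <- r$dX
      }
      fl <- linear_bwd(dX, cache$dec[[s]]$Xcat, p$dec[[s]]$fuse$w, TRUE)
      dgr$fuse <- list(w = fl$dW, b = fl$db)
      d_half <- g$dim
      dEx <- fl$dX[, 1:d_half, drop = FALSE]
      dSkip <- fl$dX[, (d_half + 1):(2 * d_half), drop = FALSE]
      ex <- expand_bwd(dEx, p$dec[[s]]$expand, cache$dec[[s]]$expand)
      dgr$expand <- ex$grads
      grads$dec[[s]] <- dgr
      cache$dec[[s]]$dSkip <- dSkip   # consumed by the encoder sweep
      dX <- ex$dX                     # flows into decoder stage s+1 / bottleneck
    }
  }
  gS <- geom[[S]]
  grads$bot <- list(blocks = vector("list", gS$depth))
  for (k in rev(seq_len(gS$depth))) {
    r <- swin_block_bwd(dX, p$bot$blocks[[k]], cache$bot[[k]])
    grads$bot$blocks[[k]] <- r$grads
    dX <- r$dX
  }
  if (S > 1) {
    grads$enc <- vector("list", S - 1)
    grads$mrg <- vector("list", S - 1)
    for (s in rev(seq_len(S - 1))) {
      g <- geom[[s]]
      mg <- merge_bwd(dX, p$mrg[[s]], cache$enc[[s]]$merge)
      grads$mrg[[s]] <- mg$grads
      dX <- mg$dX + cache$dec[[s]]$dSkip
      egr <- list(blocks = vector("list", g$depth))
      for (k in rev(seq_len(g$depth))) {
        r <- swin_block_bwd(dX, p$enc[[s]]$blocks[[k]], cache$enc[[s]]$blocks[[k]])
        egr$blocks[[k]] <- r$grads
        dX <- r$dX
      }
      grads$enc[[s]] <- egr
    }
  }
  grads$embed <- embed_bwd(dX, p$embed, cfg, cache$embed)
  grads
}
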