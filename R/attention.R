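# Window-based multi-head self-attention: the shifted-window masks, the
# internal (matrix-form) Swin block forward/backward used by the model, and
# the user-facing token-grid operations.

# Attention mask for shifted windows on a G x G grid: token pairs that are
# only adjacent because of the toroidal wrap get a -1e9 pre-softmax offset.
# Returns NULL when no mask is needed, else an m x m x n_windows array in
# row-major window order.
shifted_window_masks <- function(G, w, s) {
  if (s == 0 || G <= w) return(NULL)
  memo(sprintf("mask_%d_%d_%d", G, w, s), function() {
    axis_id <- function(p) ifelse(p <= G - w, 0L, ifelse(p <= G - s, 1L, 2L))
    ids <- outer(axis_id(1:G), axis_id(1:G), function(a, b) 3L * a + b)
    idv <- as.vector(t(ids))                       # row-major position order
    perm <- window_partition_perm(1L, G, w)
    m <- w * w
    nw <- (G %/% w)^2
    grouped <- matrix(idv[perm], m, nw)
    out <- array(0, c(m, m, nw))
    for (k in seq_len(nw)) {
      g <- grouped[, k]
      out[, , k] <- ifelse(outer(g, g, "!=") , -1e9, 0)
    }
    out
  })
}

# Core of one attention block: windowed multi-head self-attention over a token
# matrix already ordered by (tile, window, position). Returns the attended
# matrix plus softmax maps for the backward pass.
window_attention_fwd <- function(Q, K, V, h, m, masks, rpb, nw_per_tile) {
  N <- nrow(Q); d <- ncol(Q)
  NW <- N %/% m
  dh <- d %/% h
  scale <- 1 / sqrt(dh)
  bias_h <- NULL
  if (!is.null(rpb)) {
    rpi <- as.vector(relative_position_index(as.integer(sqrt(m))))
    bias_h <- lapply(seq_len(h), function(hh) matrix(rpb[rpi, hh], m, m))
  }
  P_arr <- array(0, c(m, m, h, NW))
  O <- matrix(0, N, d)
  for (g in seq_len(NW)) {
    rows <- ((g - 1L) * m + 1L):(g * m)
    maskg <- if (!is.null(masks)) masks[, , ((g - 1L) %% nw_per_tile) + 1L] else NULL
    for (hh in seq_len(h)) {
      cols <- ((hh - 1L) * dh + 1L):(hh * dh)
      S <- tcrossprod(Q[rows, cols, drop = FALSE], K[rows, cols, drop = FALSE]) * scale
      if (!is.null(bias_h)) S <- S + bias_h[[hh]]
      if (!is.null(maskg)) S <- S + maskg
      P <- softmax_rows(S)
      P_arr[, , hh, g] <- P
      O[rows, cols] <- P %*% V[rows, cols, drop = FALSE]
    }
  }
  list(out = O, P = P_arr, scale = scale)
}

window_attention_bwd <- function(dO, Q, K, V, att, h, m, use_rpb) {
  N <- nrow(Q); d <- ncol(Q)
  NW <- N %/% m
  dh <- d %/% h
  scale <- att$scale
  dQ <- matrix(0, N, d); dK <- matrix(0, N, d); dV <- matrix(0, N, d)
  dS_sum <- if (use_rpb) array(0, c(m, m, h)) else NULL
  for (g in seq_len(NW)) {
    rows <- ((g - 1L) * m + 1L):(g * m)
    for (hh in seq_len(h)) {
      cols <- ((hh - 1L) * dh + 1L):(hh * dh)
      P <- att$P[, , hh, g]
      dOg <- dO[rows, cols, drop = FALSE]
      Vg <- V[rows, cols, drop = FALSE]
      dP <- tcrossprod(dOg, Vg)
      dV[rows, cols] <- crossprod(P, dOg)
      dS <- P * (dP - rowSums(dP * P))
      if (use_rpb) dS_sum[, , hh] <- dS_sum[, , hh] + dS
      dQ[rows, cols] <- (dS %*% K[rows, cols, drop = FALSE]) * scale
      dK[rows, cols] <- crossprod(dS, Q[rows, cols, drop = FALSE]) * scale
    }
  }
  dRPB <- NULL
  if (use_rpb) {
    w <- as.integer(sqrt(m))
    rpi <- as.vector(relative_position_index(w))
    Tn <- (2L * w - 1L)^2
    dRPB <- matrix(0, Tn, h)
    for (hh in seq_len(h)) {
      acc <- rowsum(as.vector(dS_sum[, , hh]), rpi)
      dRPB[as.integer(rownames(acc)), hh] <- acc
    }
  }
  list(dQ = dQ, dK = dK, dV = dV, dRPB = dRPB)
}

# One full Swin block (pre-norm): X + WMSA(LN(X)) then + MLP(LN(.)).
# `shift` > 0 selects the shifted-window variant with wrap masking.
swin_block_fwd <- function(X, p, B, G, w, shift, h, want_cache = FALSE) {
  N <- nrow(X)
  m <- w * w
  nw <- (G %/% w)^2
  ln1 <- layernorm_fwd(X, p$norm1$g, p$norm1$b)
  xn <- ln1$out
  if (shift > 0) xn <- xn[cyclic_shift_perm(B, G, shift), , drop = FALSE]
  perm <- window_partition_perm(B, G, w)
  xp <- xn[perm, , drop = FALSE]
  Q <- linear_fwd(xp, p$q$w, p$q$b)
  K <- linear_fwd(xp, p$k$w, p$k$b)
  V <- linear_fwd(xp, p$v$w, p$v$b)
  masks <- shifted_window_masks(G, w, shift)
  att <- window_attention_fwd(Q, K, V, h, m, masks, p$rpb, nw)
  A <- linear_fwd(att$out, p$proj$w, p$proj$b)
  A <- A[inverse_perm(perm, sprintf("part_%d_%d_%d", B, G, w)), , drop = FALSE]
  if (shift > 0)
    A <- A[cyclic_shift_perm(B, G, (G - shift) %% G), , drop = FALSE]
  X2 <- X + A
  ln2 <- layernorm_fwd(X2, p$norm2$g, p$norm2$b)
  H1 <- linear_fwd(ln2$out, p$fc1$w, p$fc1$b)
  G1 <- gelu_fwd(H1)
  out <- X2 + linear_fwd(G1, p$fc2$w, p$fc2$b)
  if (!want_cache) return(list(out = out))
  list(out = out,
       cache = list(X = X, ln1 = ln1, xp = xp, Q = Q, K = K, V = V,
                    att = att, O = att$out, X2 = X2, ln2 = ln2,
                    H1 = H1, G1 = G1, B = B, G = G, w = w, shift = shift, h = h))
}

swin_block_bwd <- function(dOut, p, cache) {
  B <- cache$B; G <- cache$G; w <- cache$w; shift <- cache$shift; h <- cache$h
  m <- w * w
  gr <- list()
  # MLP branch
  l2 <- linear_bwd(dOut, cache$G1, p$fc2$w, TRUE)
  gr$fc2 <- list(w = l2$dW, b = l2$db)
  dH1 <- gelu_bwd(l2$dX, cache$H1)
  l1 <- linear_bwd(dH1, cache$ln2$out, p$fc1$w, TRUE)
  gr$fc1 <- list(w = l1$dW, b = l1$db)
  n2 <- layernorm_bwd(l1$dX, cache$ln2, p$norm2$g)
  gr$norm2 <- list(g = n2$dg, b = n2$db)
  dX2 <- dOut + n2$dX
  # attention branch (undo residual, shift, partition)
  dA <- dX2
  if (shift > 0)
    dA <- dA[cyclic_shift_perm(B, G, shift), , drop = FALSE]
  dA <- dA[window_partition_perm(B, G, w), , drop = FALSE]
  pl <- linear_bwd(dA, cache$O, p$proj$w, TRUE)
  gr$proj <- list(w = pl$dW, b = pl$db)
  ab <- window_attention_bwd(pl$dX, cache$Q, cache$K, cache$V, cache$att,
                             h, m, !is.null(p$rpb))
  if (!is.null(p$rpb)) gr$rpb <- ab$dRPB
  has_qkv_b <- !is.null(p$q$b)
  ql <- linear_bwd(ab$dQ, cache$xp, p$q$w, has_qkv_b)
  kl <- linear_bwd(ab$dK, cache$xp, p$k$w, has_qkv_b)
  vl <- linear_bwd(ab$dV, cache$xp, p$v$w, has_qkv_b)
  gr$q <- list(w = ql$dW, b = ql$db)
  gr$k <- list(w = kl$dW, b = kl$db)
  gr$v <- list(w = vl$dW, b = vl$db)
  dxn <- ql$dX + kl$dX + vl$dX
  perm <- window_partition_perm(B, G, w)
  dxn <- dxn[inverse_perm(perm, sprintf("part_%d_%d_%d", B, G, w)), , drop = FALSE]
  if (shift > 0)
    dxn <- dxn[cyclic_shift_perm(B, G, (G - shift) %% G), , drop = FALSE]
  n1 <- layernorm_bwd(dxn, cache$ln1, p$norm1$g)
  gr$norm1 <- list(g = n1$dg, b = n1$db)
  list(dX = dX2 + n1$dX, grads = gr)
}

# --- user-facing token-grid operations -------------------------------------

tokens_to_mat <- function(arr) {
  d <- dim(arr)
  matrix(aperm(arr, c(2, 1, 3)), d[1] * d[2], d[3])
}

mat_to_tokens <- function(mat, H, W) {
  aperm(array(mat, c(W, H, ncol(mat))), c(2, 1, 3))
}

#' Partition a token grid into non-overlapping windows
#'
#' Splits an `H x W x d` token grid into `w x w` windows (row-major order).
#' Every token appears in exactly one window; [window_reverse()] inverts the
#' operation exactly.
#'
#' @param tokens Numeric array `H x W x d`.
#' @param w Window side, in tokens; must divide both grid sides.
#' @return A list of `w x w x d` arrays.
#' @export
window_partition <- function(tokens, w) {
  d <- dim(tokens)
  if (length(d) != 3) stop("tokens must be an H x W x d array", call. = FALSE)
  if (d[1] %% w != 0 || d[2] %% w != 0)
    stop("grid sides must be divisible by the window size", call. = FALSE)
  out <- list()
  for (wi in seq_len(d[1] %/% w)) {
    for (wj in seq_len(d[2] %/% w)) {
      out[[length(out) + 1L]] <-
        tokens[((wi - 1) * w + 1):(wi * w), ((wj - 1) * w + 1):(wj * w), , drop = FALSE]
    }
  }
  out
}

#' @rdname window_partition
#' @param blocks A list of `w x w x d` window arrays as produced by
#'   [window_partition()].
#' @param H,W Token grid sides to reassemble to.
#' @export
window_reverse <- function(blocks, H, W) {
  w <- dim(blocks[[1]])[1]
  d <- dim(blocks[[1]])[3]
  out <- array(0, c(H, W, d))
  k <- 1L
  for (wi in seq_len(H %/% w)) {
    for (wj in seq_len(W %/% w)) {
      out[((wi - 1) * w + 1):(wi * w), ((wj - 1) * w + 1):(wj * w), ] <- blocks[[k]]
      k <- k + 1L
    }
  }
  out
}

#' Cyclically shift a token grid
#'
#' Rolls the grid toward the upper-left by `shift` tokens on both axes
#' (toroidal wrap), as used by the second block of each attention pair.
#' `inverse_cyclic_shift()` undoes the roll.
#'
#' @param tokens Numeric array `H x W x d`.
#' @param shift Non-negative integer shift; 0 is the identity.
#' @return The shifted array.
#' @export
cyclic_shift <- function(tokens, shift) {
  d <- dim(tokens)
  if (shift == 0) return(tokens)
  ri <- ((seq_len(d[1]) + shift - 1L) %% d[1]) + 1L
  ci <- ((seq_len(d[2]) + shift - 1L) %% d[2]) + 1L
  tokens[ri, ci, , drop = FALSE]
}

#' @rdname cyclic_shift
#' @export
inverse_cyclic_shift <- function(tokens, shift) {
  d <- dim(tokens)
  cyclic_shift(tokens, (d[1] - (shift %% d[1])) %% d[1])
}

#' Multi-head self-attention over a token sequence
#'
#' Dense (unwindowed) multi-head self-attention: the sequence is projected to
#' queries, keys and values, split channel-wise into `heads` sub-spaces, and
#' each head's scaled dot-product scores (softmax rows summing to 1) weight the
#' values. Head outputs are concatenated and passed through the output
#' projection. Scores are scaled by `1/sqrt(C/heads)`.
#'
#' @param tokens Numeric matrix `n x C` (one row per token).
#' @param params List with elements `q`, `k`, `v`, `proj`, each a list with
#'   weight matrix `w` (`C x C`) and optional bias `b`.
#' @param heads Number of attention heads; must divide `C`.
#' @param bias Optional pre-softmax additive bias: an `n x n` matrix shared by
#'   all heads, or an `n x n x heads` array (e.g. a relative position bias).
#' @return The attended `n x C` matrix.
#' @export
multi_head_self_attention <- function(tokens, params, heads, bias = NULL) {
  n <- nrow(tokens); C <- ncol(tokens)
  if (C %% heads != 0)
    stop("heads must divide the channel depth C", call. = FALSE)
  dh <- C %/% heads
  Q <- linear_fwd(tokens, params$q$w, params$q$b)
  K <- linear_fwd(tokens, params$k$w, params$k$b)
  V <- linear_fwd(tokens, params$v$w, params$v$b)
  O <- matrix(0, n, C)
  for (hh in seq_len(heads)) {
    cols <- ((hh - 1L) * dh + 1L):(hh * dh)
    S <- tcrossprod(Q[, cols, drop = FALSE], K[, cols, drop = FALSE]) / sqrt(dh)
    if (!is.null(bias)) {
      S <- S + (if (length(dim(bias)) == 3) bias[, , hh] else bias)
    }
    O[, cols] <- softmax_rows(S) %*% V[, cols, drop = FALSE]
  }
  linear_fwd(O, params$proj$w, params$proj$b)
}

#' Apply one window / shifted-window attention block pair
#'
#' The first block runs windowed attention on the plain partition; the second
#' repeats the computation on a cyclically shifted partition with wrap
#' masking, bridging the seams of the first. Output shape equals input shape.
#'
#' @param tokens Numeric array `G x G x d` (square token grid).
#' @param params List with elements `blk1` and `blk2`, each holding the block
#'   parameters (`norm1`, `q`, `k`, `v`, `proj`, optional `rpb`, `norm2`,
#'   `fc1`, `fc2`).
#' @param window_size Window side in tokens; clamped to the grid side.
#' @param shift_size Cyclic shift used by the second block; forced to 0 when a
#'   single window covers the grid.
#' @param heads Number of attention heads.
#' @return The transformed `G x G x d` array.
#' @export
swin_block_pair <- function(tokens, params, window_size, shift_size, heads) {
  d <- dim(tokens)
  if (d[1] != d[2]) stop("token grid must be square", call. = FALSE)
  G <- d[1]
  w <- min(window_size, G)
  if (G %% w != 0)
    stop("grid side must be divisible by the window size", call. = FALSE)
  s <- if (G <= w) 0L else as.integer(shift_size)
  X <- tokens_to_mat(tokens)
  X <- swin_block_fwd(X, params$blk1, 1L, G, w, 0L, heads)$out
  X <- swin_block_fwd(X, params$blk2, 1L, G, w, s, heads)$out
  mat_to_tokens(X, G, G)
}
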