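# Numerical primitives for the transformer: dense layers, layer
# normalisation, GELU, row softmax, parameter initialisation, and the memoised
# token-index permutations that implement window partitioning, cyclic shifts
# and patch merging/expansion as pure row reorderings.
#
# Token tensors are stored as (B*G*G) x d matrices; row order is tile-major,
# then row-major over the G x G token grid.

.idx_cache <- new.env(parent = emptyenv())

memo <- function(key, make) {
  if (!is.null(.idx_cache[[key]])) return(.idx_cache[[key]])
  val <- make()
  assign(key, val, envir = .idx_cache)
  val
}

# Row index of token (r, c) of tile b on a G-grid.
token_row <- function(b, r, c, G) (b - 1L) * G * G + (r - 1L) * G + c

# Permutation grouping rows by (tile, window, within-window position),
# windows and positions both row-major. X[perm, ] puts each window's w*w
# tokens contiguous.
window_partition_perm <- function(B, G, w) {
  memo(sprintf("part_%d_%d_%d", B, G, w), function() {
    nwin <- G %/% w
    g <- expand.grid(j = 1:w, i = 1:w, wj = 1:nwin, wi = 1:nwin, b = 1:B)
    token_row(g$b, (g$wi - 1L) * w + g$i, (g$wj - 1L) * w + g$j, G)
  })
}

inverse_perm <- function(p, key) {
  memo(paste0("inv_", key), function() {
    inv <- integer(length(p))
    inv[p] <- seq_along(p)
    inv
  })
}

# Toroidal shift toward the upper-left by s tokens: row i of the result is
# taken from perm[i] of the input.
cyclic_shift_perm <- function(B, G, s) {
  memo(sprintf("shift_%d_%d_%d", B, G, s), function() {
    g <- expand.grid(c = 1:G, r = 1:G, b = 1:B)
    token_row(g$b, ((g$r + s - 1L) %% G) + 1L, ((g$c + s - 1L) %% G) + 1L, G)
  })
}

# 2x2 neighbourhood gather for patch merging: four row-index vectors (top-left,
# bottom-left, top-right, bottom-right), each ordered by output token.
merge_indices <- function(B, G) {
  memo(sprintf("merge_%d_%d", B, G), function() {
    G2 <- G %/% 2L
    g <- expand.grid(c2 = 1:G2, r2 = 1:G2, b = 1:B)
    list(tl = token_row(g$b, 2L * g$r2 - 1L, 2L * g$c2 - 1L, G),
         bl = token_row(g$b, 2L * g$r2,      2L * g$c2 - 1L, G),
         tr = token_row(g$b, 2L * g$r2 - 1L, 2L * g$c2,      G),
         br = token_row(g$b, 2L * g$r2,      2L * g$c2,      G))
  })
}

# Patch expansion scatter: sub-block s (row-major over a p x p block) of input
# token (r, c) lands at output row expand_indices(...)[[s]].
expand_indices <- function(B, G, p) {
  memo(sprintf("expand_%d_%d_%d", B, G, p), function() {
    Gp <- G * p
    g <- expand.grid(c = 1:G, r = 1:G, b = 1:B)
    out <- vector("list", p * p)
    for (a in 0:(p - 1)) for (bb in 0:(p - 1)) {
      out[[a * p + bb + 1L]] <-
        token_row(g$b, p * (g$r - 1L) + a + 1L, p * (g$c - 1L) + bb + 1L, Gp)
    }
    out
  })
}

# Relative-position index for a w x w window: m x m matrix of 1-based indices
# into a (2w-1)^2 bias table.
relative_position_index <- function(w) {
  memo(sprintf("rpi_%d", w), function() {
    pos <- expand.grid(j = 1:w, i = 1:w)   # row-major token order
    di <- outer(pos$i, pos$i, "-")
    dj <- outer(pos$j, pos$j, "-")
    (di + w - 1L) * (2L * w - 1L) + (dj + w - 1L) + 1L
  })
}

# --- dense / norm / activation layers (forward + backward) -----------------

linear_fwd <- function(X, W, b = NULL) {
  Y <- X %*% W
  if (!is.null(b)) Y <- Y + rep(b, each = nrow(X))
  Y
}

linear_bwd <- function(dY, X, W, has_bias) {
  list(dX = tcrossprod(dY, W),
       dW = crossprod(X, dY),
       db = if (has_bias) colSums(dY) else NULL)
}

layernorm_fwd <- function(X, g, b, eps = 1e-5) {
  mu <- rowMeans(X)
  xc <- X - mu
  inv <- 1 / sqrt(rowMeans(xc * xc) + eps)
  xhat <- xc * inv
  list(out = xhat * rep(g, each = nrow(X)) + rep(b, each = nrow(X)),
       xhat = xhat, inv = inv)
}

layernorm_bwd <- function(dY, cache, g) {
  xhat <- cache$xhat
  dxhat <- dY * rep(g, each = nrow(dY))
  dX <- cache$inv * (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat))
  list(dX = dX, dg = colSums(dY * xhat), db = colSums(dY))
}

# GELU in the usual tanh approximation.
.gelu_c <- sqrt(2 / pi)

gelu_fwd <- function(X) {
  0.5 * X * (1 + tanh(.gelu_c * (X + 0.044715 * X^3)))
}

gelu_bwd <- function(dY, X) {
  t <- tanh(.gelu_c * (X + 0.044715 * X^3))
  dY * (0.5 * (1 + t) + 0.5 * X * (1 - t^2) * .gelu_c * (1 + 3 * 0.044715 * X^2))
}

row_max <- function(S) S[cbind(seq_len(nrow(S)), max.col(S, ties.method = "first"))]

softmax_rows <- function(S) {
  E <- exp(S - row_max(S))
  E / rowSums(E)
}

# --- parameter initialisation ----------------------------------------------

init_dense <- function(d_in, d_out, sd = 0.02) {
  matrix(stats::rnorm(d_in * d_out, sd = sd), d_in, d_out)
}

# Mean cross-entropy over rows of a logit matrix; labels are 1-based.
cross_entropy_fwd <- function(logits, labels) {
  m <- row_max(logits)
  lse <- m + log(rowSums(exp(logits - m)))
  picked <- logits[cbind(seq_len(nrow(logits)), labels)]
  mean(lse - picked)
}

cross_entropy_bwd <- function(logits, labels) {
  P <- softmax_rows(logits)
  P[cbind(seq_len(nrow(logits)), labels)] <-
    P[cbind(seq_len(nrow(logits)), labels)] - 1
  P / nrow(logits)
}
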