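test_that("separable patch embedding is local and channel-separable", {
  cfg <- tiny_config()
  m <- build_model(cfg, seed = 1)
  zero <- array(0, c(48, 48, 2))
  t0 <- separable_patch_embed(zero, m$params$embed, cfg)
  expect_equal(dim(t0), c(12, 12, cfg$embed_dim))
  # all tokens of a constant input are identical
  flat <- matrix(t0, 144, cfg$embed_dim)
  expect_true(all(abs(sweep(flat, 2, flat[1, ])) < 1e-12))
  # a single-pixel impulse only changes the token of its 4x4 patch
  imp <- zero
  imp[1, 1, 1] <- 5
  t1 <- separable_patch_embed(imp, m$params$embed, cfg)
  diff <- apply(abs(t1 - t0), c(1, 2), max)
  expect_gt(diff[1, 1], 0)
  expect_equal(max(diff[-1, ]), 0)
  expect_equal(max(diff[1, -1]), 0)
  # wrong shape errors
  expect_error(separable_patch_embed(array(0, c(48, 48, 3)), m$params$embed, cfg),
               "must be")
})

test_that("reference-width embedding produces a 12x12 grid of depth 96", {
  cfg <- reference_config()
  m <- build_model(cfg, seed = 1)
  tile <- array(stats::runif(48 * 48 * 8), c(48, 48, 8))
  tk <- separable_patch_embed(tile, m$params$embed, cfg)
  expect_equal(dim(tk), c(12, 12, 96))
  expect_true(all(is.finite(tk)))
})

test_that("window partition covers every token once and reverses exactly", {
  set.seed(2)
  g <- array(rnorm(12 * 12 * 5), c(12, 12, 5))
  blocks <- window_partition(g, 6)
  expect_length(blocks, 4)
  expect_equal(window_reverse(blocks, 12, 12), g)
  g1 <- array(rnorm(6 * 6 * 3), c(6, 6, 3))
  b1 <- window_partition(g1, 6)
  expect_length(b1, 1)
  expect_equal(b1[[1]], g1)
  expect_error(window_partition(g, 5), "divisible")
})

test_that("cyclic shift rolls toroidally and inverts exactly", {
  set.seed(3)
  g <- array(rnorm(12 * 12 * 4), c(12, 12, 4))
  expect_identical(cyclic_shift(g, 0), g)
  expect_equal(inverse_cyclic_shift(cyclic_shift(g, 3), 3), g)
  s <- cyclic_shift(g, 3)
  # token (0,0) relocates to (H-3, W-3) in 0-based coordinates
  expect_equal(s[12 - 2, 12 - 2, ], g[1, 1, ])
  expect_equal(s[1, 1, ], g[4, 4, ])
})

test_that("multi-head self-attention matches the brute-force oracle", {
  set.seed(4)
  for (case in list(list(n = 4, C = 8, h = 2), list(n = 9, C = 12, h = 3),
                    list(n = 16, C = 8, h = 4))) {
    tokens <- matrix(rnorm(case$n * case$C), case$n, case$C)
    params <- random_attention_params(case$C, seed = case$n)
    got <- multi_head_self_attention(tokens, params, case$h)
    want <- oracle_mhsa(tokens, params, case$h)
    expect_equal(got, want, tolerance = 1e-10)
  }
})

test_that("single-token attention reduces to projected value", {
  C <- 8
  params <- random_attention_params(C, seed = 5)
  x <- matrix(rnorm(C), 1, C)
  got <- multi_head_self_attention(x, params, 2)
  v <- x %*% params$v$w + rep(params$v$b, each = 1)
  want <- v %*% params$proj$w + rep(params$proj$b, each = 1)
  expect_equal(got, want, tolerance = 1e-12)
})

test_that("attention without position bias is permutation-equivariant", {
  set.seed(6)
  n <- 7; C <- 8
  tokens <- matrix(rnorm(n * C), n, C)
  params <- random_attention_params(C, seed = 6)
  perm <- sample(n)
  out <- multi_head_self_attention(tokens, params, 2)
  out_p <- multi_head_self_attention(tokens[perm, ], params, 2)
  expect_equal(out_p, out[perm, ], tolerance = 1e-10)
})

test_that("attention rows are convex weights: constant values pass through", {
  # if every value vector is the same constant row, any softmax weighting that
  # sums to 1 must return exactly that row before the output projection
  C <- 8
  params <- random_attention_params(C, seed = 7)
  params$v$w[] <- 0
  cv <- rnorm(C)
  params$v$b <- cv
  tokens <- matrix(rnorm(5 * C), 5, C)
  got <- multi_head_self_attention(tokens, params, 4)
  want <- matrix(cv, 5, C, byrow = TRUE) %*% params$proj$w +
    rep(params$proj$b, each = 5)
  expect_equal(got, want, tolerance = 1e-9)
})

test_that("swin block pairs preserve shape and reduce to identity when zeroed", {
  cfg <- tiny_config()
  m <- build_model(cfg, seed = 2)
  pair <- list(blk1 = m$params$enc[[1]]$blocks[[1]],
               blk2 = m$params$enc[[1]]$blocks[[2]])
  set.seed(8)
  g <- array(rnorm(12 * 12 * cfg$embed_dim), c(12, 12, cfg$embed_dim))
  out <- swin_block_pair(g, pair, cfg$window_size, cfg$shift_size, 2)
  expect_equal(dim(out), dim(g))
  expect_false(isTRUE(all.equal(out, g)))
  zeroed <- lapply(pair, function(p) {
    p$proj$w[] <- 0; p$proj$b[] <- 0
    p$fc2$w[] <- 0; p$fc2$b[] <- 0
    p
  })
  out0 <- swin_block_pair(g, zeroed, cfg$window_size, cfg$shift_size, 2)
  expect_equal(out0, g, tolerance = 1e-12)
})

test_that("windowed attention with one window equals dense attention", {
  # grid side equal to the window size: block-1 attention must match the
  # brute-force dense oracle applied to the normalised tokens
  C <- 8; G <- 4
  blk <- list(norm1 = list(g = rep(1, C), b = rep(0, C)),
              norm2 = list(g = rep(1, C), b = rep(0, C)))
  ap <- random_attention_params(C, seed = 9)
  blk$q <- ap$q; blk$k <- ap$k; blk$v <- ap$v; blk$proj <- ap$proj
  blk$fc1 <- list(w = matrix(rnorm(C * 2 * C, sd = 0.1), C, 2 * C), b = rnorm(2 * C))
  blk$fc2 <- list(w = matrix(rnorm(2 * C * C, sd = 0.1), 2 * C, C), b = rnorm(C))
  set.seed(10)
  g <- array(rnorm(G * G * C), c(G, G, C))
  got <- swinplex:::swin_block_fwd(swinplex:::tokens_to_mat(g), blk,
                                   1L, G, G, 0L, 2L)$out
  X <- swinplex:::tokens_to_mat(g)
  ln <- swinplex:::layernorm_fwd(X, blk$norm1$g, blk$norm1$b)
  att <- oracle_mhsa(ln$out, ap, 2)
  X2 <- X + att
  ln2 <- swinplex:::layernorm_fwd(X2, blk$norm2$g, blk$norm2$b)
  want <- X2 + swinplex:::gelu_fwd(ln2$out %*% blk$fc1$w +
                                     rep(blk$fc1$b, each = G * G)) %*%
    blk$fc2$w + rep(blk$fc2$b, each = G * G)
  expect_equal(got, want, tolerance = 1e-9)
})

test_that("patch merging halves the grid and doubles the depth", {
  cfg <- tiny_config()
  m <- build_model(cfg, seed = 3)
  d <- cfg$embed_dim
  set.seed(11)
  g <- array(rnorm(12 * 12 * d), c(12, 12, d))
  out <- patch_merge(g, m$params$mrg[[1]])
  expect_equal(dim(out), c(6, 6, 2 * d))
  # constant grid stays constant
  gc <- array(rep(rnorm(d), each = 144), c(12, 12, d))
  oc <- patch_merge(gc, m$params$mrg[[1]])
  flat <- matrix(oc, 36, 2 * d)
  expect_true(all(abs(sweep(flat, 2, flat[1, ])) < 1e-10))
  expect_error(patch_merge(array(0, c(5, 5, d)),
                           m$params$mrg[[1]]), "even")
})

test_that("a selection projection reproduces hand-computed merging", {
  d <- 2L
  g <- array(seq_len(2 * 2 * d), c(2, 2, d))
  p <- list(norm = list(g = rep(1, 4 * d), b = rep(0, 4 * d)),
            w = rbind(diag(2 * d), matrix(0, 2 * d, 2 * d)))
  out <- patch_merge(g, p)
  # hand computation: concat order (top-left, bottom-left, top-right,
  # bottom-right), LayerNorm over the 4d vector, then take the first 2d coords
  v <- c(g[1, 1, ], g[2, 1, ], g[1, 2, ], g[2, 2, ])
  vn <- (v - mean(v)) / sqrt(mean((v - mean(v))^2) + 1e-5)
  expect_equal(as.vector(out[1, 1, ]), vn[1:(2 * d)], tolerance = 1e-12)
})

test_that("patch expansion inverts merge shapes and maps zero to zero", {
  cfg <- tiny_config()
  m <- build_model(cfg, seed = 4)
  d <- 2 * cfg$embed_dim
  set.seed(12)
  g <- array(rnorm(6 * 6 * d), c(6, 6, d))
  out <- patch_expand(g, m$params$dec[[1]]$expand)
  expect_equal(dim(out), c(12, 12, d %/% 2))
  merged <- patch_merge(array(rnorm(12 * 12 * cfg$embed_dim),
                              c(12, 12, cfg$embed_dim)), m$params$mrg[[1]])
  back <- patch_expand(merged, m$params$dec[[1]]$expand)
  expect_equal(dim(back), c(12, 12, cfg$embed_dim))
  zero <- patch_expand(array(0, c(6, 6, d)), m$params$dec[[1]]$expand)
  expect_equal(max(abs(zero)), 0)
})

test_that("parameter count is config-determined, seed-invariant and monotone", {
  cfg <- tiny_config()
  c1 <- count_trainable_parameters(build_model(cfg, seed = 1))
  c2 <- count_trainable_parameters(build_model(cfg, seed = 99))
  expect_identical(c1, c2)
  wider <- tiny_config()
  wider <- model_config(in_channels = 2, filters_per_channel = 8,
                        heads_per_stage = c(2, 2, 4), mlp_ratio = c(2, 2, 2),
                        num_classes = 3)
  expect_gt(count_trainable_parameters(build_model(wider, seed = 1)), c1)
})

test_that("class-head swap changes the count by exactly the head size", {
  cfg11 <- reference_config()
  cfg2 <- reference_config(num_classes = 2)
  m11 <- build_model(cfg11, seed = 1)
  m2 <- build_model(cfg2, seed = 1)
  # unbiased linear head: difference is embed_dim * (11 - 2)
  expect_identical(count_trainable_parameters(m11) - count_trainable_parameters(m2),
                   cfg11$embed_dim * (11L - 2L))
  s11 <- lapply(swinplex:::tree_leaves(m11$params), dim)
  s2 <- lapply(swinplex:::tree_leaves(m2$params), dim)
  nm <- setdiff(names(s11), "params.head.w")
  expect_identical(s11[nm], s2[nm])
})

test_that("a minimal single-stage config matches analytic parameter accounting", {
  cfg <- model_config(in_channels = 1, filters_per_channel = 4,
                      stage_depths = 2L, heads_per_stage = 2L,
                      mlp_ratio = 2, num_classes = 3,
                      use_relative_position_bias = FALSE, qkv_bias = FALSE)
  m <- build_model(cfg, seed = 1)
  C <- 4
  blk <- 3 * C^2 + (C^2 + C) + 4 * C + (C * 2 * C + 2 * C) + (2 * C * C + C)
  want <- (16 * 4 + C) + 2 * C +          # depthwise embed + norm
    2 * blk +                             # one stage of two blocks
    (16 * C^2) + 2 * C +                  # final expansion + norm
    C * 3                                 # class head
  expect_identical(count_trainable_parameters(m), as.integer(want))
})

test_that("forward segmentation is deterministic, finite and skip-dependent", {
  cfg <- tiny_config()
  m <- build_model(cfg, seed = 5)
  set.seed(13)
  tile <- array(runif(48 * 48 * 2), c(48, 48, 2))
  l1 <- forward_segment(m, tile)
  l2 <- forward_segment(m, tile)
  expect_identical(l1, l2)
  expect_equal(dim(l1), c(3, 48, 48))
  expect_true(all(is.finite(l1)))
  z <- forward_segment(m, array(0, c(48, 48, 2)))
  expect_true(all(is.finite(z)))
  # ablating a skip connection (zeroing its fusion columns) changes the logits
  for (s in 1:2) {
    ma <- m
    d <- cfg$embed_dim * 2^(s - 1)
    ma$params$dec[[s]]$fuse$w[(d + 1):(2 * d), ] <- 0
    expect_false(isTRUE(all.equal(forward_segment(ma, tile), l1)))
  }
  # argmax yields labels in 0..num_classes-1
  lab <- apply(l1, c(2, 3), which.max) - 1L
  expect_true(all(lab %in% 0:2))
  expect_error(forward_segment(m, array(0, c(48, 48, 5))), "does not match")
})

test_that("analytic gradients agree with central finite differences", {
  cfg <- tiny_config()
  m <- build_model(cfg, seed = 6)
  set.seed(14)
  x <- array(runif(48 * 48 * 2), c(48, 48, 2, 1))
  y <- sample(1:3, 48 * 48, replace = TRUE)
  fw <- swinplex:::fwd_tiles(m, x, want_cache = TRUE)
  grads <- swinplex:::bwd_tiles(m, fw$cache,
                                swinplex:::cross_entropy_bwd(fw$logits, y))
  gl <- swinplex:::tree_leaves(grads)
  leaves <- swinplex:::tree_leaves(m$params)
  loss_at <- function(model) {
    swinplex:::cross_entropy_fwd(swinplex:::fwd_tiles(model, x)$logits, y)
  }
  perturb <- function(model, path, i, delta) {
    rec <- function(tree, pp) {
      if (length(pp) == 1) {
        tree[[pp[[1]]]][i] <- tree[[pp[[1]]]][i] + delta
      } else {
        tree[[pp[[1]]]] <- rec(tree[[pp[[1]]]], pp[-1])
      }
      tree
    }
    model$params <- rec(model$params, path)
    model
  }
  set.seed(15)
  eps <- 1e-5
  for (nm in sample(names(leaves), 12)) {
    path <- strsplit(sub("^params\\.", "", nm), ".", fixed = TRUE)[[1]]
    path <- lapply(path, function(p) if (grepl("^[0-9]+$", p)) as.integer(p) else p)
    i <- sample(length(leaves[[nm]]), 1)
    g_num <- (loss_at(perturb(m, path, i, eps)) -
                loss_at(perturb(m, path, i, -eps))) / (2 * eps)
    g_ana <- gl[[nm]][i]
    expect_lt(abs(g_num - g_ana), 1e-6 + 1e-3 * (abs(g_num) + abs(g_ana)))
  }
})
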