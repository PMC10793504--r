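# Shared fixtures and independent oracles, all built in code.

# A small but structurally complete configuration (three scales, both window
# partitions exercised at the first scale).
tiny_config <- function(num_classes = 3L) {
  model_config(in_channels = 2L, filters_per_channel = 4L,
               heads_per_stage = c(2L, 2L, 4L), mlp_ratio = c(2, 2, 2),
               num_classes = num_classes)
}

random_attention_params <- function(C, qkv_bias = TRUE, seed = 1) {
  set.seed(seed)
  lin <- function() list(w = matrix(rnorm(C * C, sd = 0.2), C, C),
                         b = if (qkv_bias) rnorm(C, sd = 0.1) else NULL)
  list(q = lin(), k = lin(), v = lin(),
       proj = list(w = matrix(rnorm(C * C, sd = 0.2), C, C),
                   b = rnorm(C, sd = 0.1)))
}

# Brute-force multi-head self-attention written as explicit elementwise
# loops: the independent oracle for the scaled dot-product formula.
oracle_mhsa <- function(tokens, params, heads, bias = NULL) {
  n <- nrow(tokens); C <- ncol(tokens)
  dh <- C %/% heads
  project <- function(p) {
    out <- matrix(0, n, C)
    for (a in 1:n) for (j in 1:C) {
      s <- if (is.null(p$b)) 0 else p$b[j]
      for (k in 1:C) s <- s + tokens[a, k] * p$w[k, j]
      out[a, j] <- s
    }
    out
  }
  Q <- project(params$q); K <- project(params$k); V <- project(params$v)
  O <- matrix(0, n, C)
  for (h in 1:heads) {
    cols <- ((h - 1) * dh + 1):(h * dh)
    S <- matrix(0, n, n)
    for (a in 1:n) for (b in 1:n) {
      s <- 0
      for (k in cols) s <- s + Q[a, k] * K[b, k]
      S[a, b] <- s / sqrt(dh)
      if (!is.null(bias))
        S[a, b] <- S[a, b] + (if (length(dim(bias)) == 3) bias[a, b, h] else bias[a, b])
    }
    for (a in 1:n) {
      e <- exp(S[a, ] - max(S[a, ]))
      p <- e / sum(e)
      for (j in cols) O[a, j] <- sum(p * V[, j])
    }
  }
  out <- matrix(0, n, C)
  for (a in 1:n) for (j in 1:C) {
    s <- params$proj$b[j]
    for (k in 1:C) s <- s + O[a, k] * params$proj$w[k, j]
    out[a, j] <- s
  }
  out
}

# Exhaustive-scan oracle for training-tile selection: enumerates every aligned
# tile and applies the inclusion rules directly.
oracle_tile_selection <- function(atlas, tile = 48L, threshold,
                                  min_region_pixels = 1L) {
  H <- nrow(atlas$mask); W <- ncol(atlas$mask)
  roi <- data.frame(row = integer(0), col = integer(0))
  eligible <- data.frame(row = integer(0), col = integer(0))
  for (r0 in seq.int(0L, H - tile, by = tile)) {
    for (c0 in seq.int(0L, W - tile, by = tile)) {
      px <- atlas$image$data[(r0 + 1):(r0 + tile), (c0 + 1):(c0 + tile), , drop = FALSE]
      if (mean(px) < threshold) next
      mk <- atlas$mask[(r0 + 1):(r0 + tile), (c0 + 1):(c0 + tile)]
      if (sum(mk > 0) >= min_region_pixels) {
        roi <- rbind(roi, data.frame(row = r0, col = c0))
      } else {
        eligible <- rbind(eligible, data.frame(row = r0, col = c0))
      }
    }
  }
  list(roi = roi, eligible = eligible)
}

# A tiny labelled atlas with one bright rectangular region, for sampling and
# metric tests.
rectangle_atlas <- function(H = 144L, W = 192L, region = c(50L, 50L, 60L, 60L),
                            nch = 2L, seed = 7) {
  set.seed(seed)
  img <- array(runif(H * W * nch, 0.1, 0.3), c(H, W, nch))
  mask <- matrix(0L, H, W)
  rows <- region[1]:(region[1] + region[3] - 1L)
  cols <- region[2]:(region[2] + region[4] - 1L)
  mask[rows, cols] <- 1L
  img[rows, cols, ] <- img[rows, cols, ] + 0.4
  atlas_labeled_image(multiplex_image(img), mask, c("1" = "rect"))
}

# Table of published per-region IoU values used by the aggregation checks
# (multi-class baseline and second fine-tuning round; NA marks DNP).
published_region_ious <- function() {
  regions <- c("cc", "MHb", "Rt", "mt", "Stg", "MGP", "VMH", "opt", "fi", "sm")
  list(
    multiclass = stats::setNames(
      c(0.59, 0.97, 0.94, 0.25, NA, 0.66, 0.72, 0.79, 0.58, 0.69), regions),
    finetune2 = stats::setNames(
      c(0.70, 0.95, 0.96, 0.91, 0.68, 0.82, 0.78, 0.89, 0.77, 0.64), regions))
}
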