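# Model construction and parameter accounting. Parameters live in a nested
# list tree whose numeric leaves are the trainable arrays; optimizer and
# gradient code walk the same tree shape.

tree_map <- function(f, tree) {
  if (is.numeric(tree)) return(f(tree))
  if (is.list(tree)) return(lapply(tree, tree_map, f = f))
  tree
}

tree_map2 <- function(f, t1, t2) {
  if (is.numeric(t1)) return(f(t1, t2))
  if (is.list(t1)) {
    out <- t1
    for (nm in names(t1)) out[[nm]] <- tree_map2(f, t1[[nm]], t2[[nm]])
    return(out)
  }
  t1
}

tree_leaves <- function(tree) {
  out <- list()
  walk <- function(x, path) {
    if (is.numeric(x)) {
      out[[path]] <<- x
    } else if (is.list(x)) {
      nms <- names(x)
      if (is.null(nms)) nms <- as.character(seq_along(x))
      for (i in seq_along(x)) {
        if (!is.null(x[[i]])) walk(x[[i]], paste0(path, ".", nms[i]))
      }
    }
  }
  walk(tree, "params")
  out
}

init_block_params <- function(d, heads, w_eff, ratio, cfg) {
  hid <- as.integer(round(ratio * d))
  p <- list(
    norm1 = list(g = rep(1, d), b = rep(0, d)),
    q = list(w = init_dense(d, d), b = if (cfg$qkv_bias) rep(0, d) else NULL),
    k = list(w = init_dense(d, d), b = if (cfg$qkv_bias) rep(0, d) else NULL),
    v = list(w = init_dense(d, d), b = if (cfg$qkv_bias) rep(0, d) else NULL),
    proj = list(w = init_dense(d, d), b = rep(0, d)),
    norm2 = list(g = rep(1, d), b = rep(0, d)),
    fc1 = list(w = init_dense(d, hid), b = rep(0, hid)),
    fc2 = list(w = init_dense(hid, d), b = rep(0, d))
  )
  if (cfg$use_relative_position_bias)
    p$rpb <- matrix(stats::rnorm((2 * w_eff - 1)^2 * heads, sd = 0.02),
                    (2 * w_eff - 1)^2, heads)
  p
}

init_stage_params <- function(geom_s, cfg) {
  list(blocks = lapply(seq_len(geom_s$depth), function(k)
    init_block_params(geom_s$dim, geom_s$heads, geom_s$window,
                      geom_s$mlp_ratio, cfg)))
}

#' Build a multi-channel Swin-UNet segmentation model
#'
#' Instantiates the network described by a [model_config()]: depthwise patch
#' embedding, encoder stages interleaved with patch merging, a bottleneck
#' stage, a mirrored decoder with patch expansion and skip fusion (two skip
#' connections with the default three-scale layout), a final expansion back to
#' pixel resolution and a per-pixel linear class head. All weights are drawn
#' from a seeded normal initialisation (sd 0.02); normalisation gains start at
#' 1 and biases at 0.
#'
#' @param config A `swinplex_config`.
#' @param seed Integer seed for the parameter initialisation.
#' @return An object of class `swinplex_model`: a list with elements `config`,
#'   `params` (the trainable parameter tree) and `fingerprint` (a hash of the
#'   architecture used to guard checkpoint loading).
#' @examples
#' cfg <- model_config(in_channels = 1, filters_per_channel = 8,
#'                     heads_per_stage = c(2, 2, 4), num_classes = 3)
#' m <- build_model(cfg, seed = 1)
#' count_trainable_parameters(m)
#' @export
build_model <- function(config, seed = 0L) {
  validate_config(config)
  cfg <- config
  set.seed(seed)
  geom <- stage_geometry(cfg)
  S <- length(geom)
  ps <- cfg$patch_size
  C <- cfg$embed_dim
  params <- list()
  params$embed <- list(
    w = array(stats::rnorm(ps^2 * cfg$filters_per_channel * cfg$in_channels,
                           sd = 0.02),
              c(ps^2, cfg$filters_per_channel, cfg$in_channels)),
    b = rep(0, C))
  if (cfg$embed_pointwise)
    params$embed$point <- list(w = init_dense(C, C), b = rep(0, C))
  params$embed$norm <- list(g = rep(1, C), b = rep(0, C))
  if (S > 1) {
    params$enc <- lapply(seq_len(S - 1), function(s) init_stage_params(geom[[s]], cfg))
    params$mrg <- lapply(seq_len(S - 1), function(s) {
      d <- geom[[s]]$dim
      list(norm = list(g = rep(1, 4 * d), b = rep(0, 4 * d)),
           w = init_dense(4 * d, 2 * d))
    })
  }
  params$bot <- init_stage_params(geom[[S]], cfg)
  if (S > 1) {
    params$dec <- lapply(seq_len(S - 1), function(s) {
      d <- geom[[s]]$dim
      stage <- init_stage_params(geom[[s]], cfg)
      list(expand = list(w = init_dense(2 * d, 4 * d)),
           fuse = list(w = init_dense(2 * d, d), b = rep(0, d)),
           blocks = stage$blocks)
    })
  }
  params$final <- list(w = init_dense(C, ps^2 * C),
                       norm = list(g = rep(1, C), b = rep(0, C)))
  params$head <- list(w = init_dense(C, cfg$num_classes))
  model <- list(config = cfg, params = params,
                fingerprint = config_fingerprint(cfg))
  class(model) <- "swinplex_model"
  model
}

#' Count the trainable parameters of a model
#'
#' Sums the sizes of every trainable parameter array. The count is a pure
#' function of the configuration: it does not depend on the seed or on any
#' input. The frozen [reference_config()] yields exactly 4,990,032.
#'
#' @param model A `swinplex_model`.
#' @return Integer parameter count.
#' @export
count_trainable_parameters <- function(model) {
  sum(vapply(tree_leaves(model$params), length, integer(1)))
}

#' @export
print.swinplex_model <- function(x, ...) {
  print(x$config)
  cat(sprintf("  trainable parameters: %s\n",
              format(count_trainable_parameters(x), big.mark = ",")))
  invisible(x)
}
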