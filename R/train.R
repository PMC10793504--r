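# Optimisation: per-pixel cross-entropy, AdamW, multi-class pre-training,
# binary seeding and the incremental click-driven fine-tuning rounds.

#' Training configuration
#'
#' @param epochs Number of passes over the training set. Default 100.
#' @param lr Learning rate. Defaults follow the workflow convention of 1e-4
#'   for multi-class pre-training and a lower rate for fine-tuning.
#' @param batch_size Tiles per optimisation step. Default 32.
#' @param weight_decay Decoupled weight decay applied to weight matrices (not
#'   biases or normalisation parameters). Default 0.01.
#' @param seed Seed controlling batch shuffling.
#' @param optimizer Optimiser name; `"adamw"` is implemented.
#' @param loss Loss name; `"cross_entropy"` is implemented.
#' @return A list of class `train_config`.
#' @export
train_config <- function(epochs = 100L, lr = 1e-4, batch_size = 32L,
                         weight_decay = 0.01, seed = 0L,
                         optimizer = "adamw", loss = "cross_entropy") {
  if (epochs < 0) stop("epochs must be non-negative", call. = FALSE)
  optimizer <- match.arg(optimizer, "adamw")
  loss <- match.arg(loss, "cross_entropy")
  structure(list(epochs = as.integer(epochs), lr = lr,
                 batch_size = as.integer(batch_size),
                 weight_decay = weight_decay, seed = as.integer(seed),
                 optimizer = optimizer, loss = loss),
            class = "train_config")
}

adamw_init <- function(params) {
  zeros <- tree_map(function(x) x * 0, params)
  list(m = zeros, v = zeros, t = 0L)
}

# One AdamW step over the parameter tree. Weight decay is applied only to
# leaves named "w" (projection/kernel matrices).
adamw_step <- function(params, grads, state, lr, weight_decay = 0.01,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  walk <- function(p, g, m, v, decay) {
    if (is.numeric(p)) {
      m <- beta1 * m + (1 - beta1) * g
      v <- beta2 * v + (1 - beta2) * g * g
      p <- p - lr * ((m / bc1) / (sqrt(v / bc2) + eps) + decay * p)
      return(list(p = p, m = m, v = v))
    }
    for (nm in names(p)) {
      if (is.null(p[[nm]])) next
      r <- walk(p[[nm]], g[[nm]], m[[nm]], v[[nm]],
                if (nm == "w") weight_decay else 0)
      p[[nm]] <- r$p; m[[nm]] <- r$m; v[[nm]] <- r$v
    }
    list(p = p, m = m, v = v)
  }
  r <- walk(params, grads, state$m, state$v, 0)
  list(params = r$p, state = list(m = r$m, v = r$v, t = state$t))
}

# Shared minibatch loop over (tiles, labels). Labels are 0-based per-pixel
# class maps. Returns the trained model and the mean loss per epoch.
train_loop <- function(model, tiles, labels, cfg) {
  n <- dim(tiles)[4]
  state <- adamw_init(model$params)
  history <- numeric(cfg$epochs)
  if (cfg$epochs == 0L) return(list(model = model, history = history))
  set.seed(cfg$seed)
  ts <- model$config$input_size
  for (ep in seq_len(cfg$epochs)) {
    ord <- sample.int(n)
    losses <- c()
    for (start in seq.int(1L, n, by = cfg$batch_size)) {
      idx <- ord[start:min(start + cfg$batch_size - 1L, n)]
      xb <- tiles[, , , idx, drop = FALSE]
      # labels to 1-based vector in (tile, row-major pixel) order
      yb <- integer(length(idx) * ts * ts)
      for (j in seq_along(idx)) {
        yb[((j - 1L) * ts * ts + 1L):(j * ts * ts)] <-
          as.integer(t(labels[, , idx[j]])) + 1L
      }
      fw <- fwd_tiles(model, xb, want_cache = TRUE)
      losses <- c(losses, cross_entropy_fwd(fw$logits, yb))
      grads <- bwd_tiles(model, fw$cache, cross_entropy_bwd(fw$logits, yb))
      st <- adamw_step(model$params, grads, state, cfg$lr, cfg$weight_decay)
      model$params <- st$params
      state <- st$state
    }
    history[ep] <- mean(losses)
  }
  list(model = model, history = history)
}

#' Pre-train the multi-class segmentation model
#'
#' Trains the network on the global multi-class task with per-pixel
#' cross-entropy and AdamW. The run is deterministic given the configuration
#' seed.
#'
#' @param model A `swinplex_model` with `num_classes = K + 1` for K regions.
#' @param training_set A `training_set` from [build_training_set()].
#' @param cfg A [train_config()].
#' @return List with `model` (trained) and `history` (mean loss per epoch,
#'   length `epochs`).
#' @export
pretrain_multiclass <- function(model, training_set, cfg = train_config()) {
  if (dim(training_set$tiles)[4] < 1)
    stop("training set is empty", call. = FALSE)
  present <- sort(unique(as.vector(training_set$labels)))
  absent <- setdiff(seq_len(model$config$num_classes) - 1L, present)
  if (length(absent))
    warning("classes absent from all label tiles (possible DNP): ",
            paste(absent, collapse = ", "), call. = FALSE)
  train_loop(model, training_set$tiles, training_set$labels, cfg)
}

#' Seed a binary model from a trained multi-class model
#'
#' Copies every non-head parameter exactly and re-initialises the output head
#' with 2 classes (region of interest vs background). With
#' `head_init = "copy"`, the head columns for the background and the selected
#' region are copied from the multi-class head instead of randomly drawn.
#'
#' @param model A trained multi-class `swinplex_model`.
#' @param seed Seed for the fresh head initialisation.
#' @param head_init `"random"` (default) or `"copy"`.
#' @param region_id Region id whose head column to copy when
#'   `head_init = "copy"`.
#' @return A `swinplex_model` with `num_classes = 2`.
#' @export
init_binary_from_multiclass <- function(model, seed = 0L,
                                        head_init = c("random", "copy"),
                                        region_id = NULL) {
  head_init <- match.arg(head_init)
  cfg <- model$config
  bcfg <- cfg
  bcfg$num_classes <- 2L
  validate_config(bcfg)
  bin <- model
  bin$config <- bcfg
  bin$fingerprint <- config_fingerprint(bcfg)
  if (head_init == "copy") {
    if (is.null(region_id)) stop("region_id required for head_init='copy'",
                                 call. = FALSE)
    bin$params$head$w <- model$params$head$w[, c(1L, region_id + 1L),
                                             drop = FALSE]
  } else {
    set.seed(seed)
    bin$params$head$w <- init_dense(cfg$embed_dim, 2L)
  }
  bin
}

click_tiles <- function(clicks, image, ts, nch) {
  ent <- clicks$entries
  H <- dim(image)[1]; W <- dim(image)[2]
  bad <- ent$row < 0 | ent$col < 0 | ent$row + ts > H | ent$col + ts > W
  if (any(bad))
    stop("click patches fall outside the image", call. = FALSE)
  n <- nrow(ent)
  tiles <- array(0, c(ts, ts, nch, n))
  labels <- array(0L, c(ts, ts, n))
  for (i in seq_len(n)) {
    tiles[, , , i] <- extract_tile(image, ent$row[i], ent$col[i], ts)
    labels[, , i] <- if (ent$label[i] == "region") 1L else 0L
  }
  list(tiles = tiles, labels = labels)
}

#' Fine-tune a binary model on expert click patches
#'
#' Each click labels a whole `input_size`-square patch as region of interest
#' or background; training targets are the corresponding uniform per-pixel
#' label maps. The epoch budget is capped (default 400).
#'
#' @param model A binary (`num_classes = 2`) `swinplex_model`.
#' @param clicks A `click_set`.
#' @param image The image the clicks refer to (`multiplex_image` or array).
#' @param cfg A [train_config()]; a lower learning rate than pre-training is
#'   conventional.
#' @param max_epochs Hard cap on `cfg$epochs`. Default 400.
#' @return List with `model` and `history`.
#' @export
finetune_binary <- function(model, clicks, image,
                            cfg = train_config(epochs = 100L, lr = 1e-5),
                            max_epochs = 400L) {
  if (!inherits(clicks, "click_set") || nrow(clicks$entries) == 0)
    stop("click set is empty", call. = FALSE)
  if (model$config$num_classes != 2L)
    stop("model must be binary (num_classes = 2)", call. = FALSE)
  if (cfg$epochs > max_epochs)
    stop(sprintf("fine-tuning epoch budget exceeded: %d > %d",
                 cfg$epochs, max_epochs), call. = FALSE)
  if (length(unique(clicks$entries$label)) < 2)
    warning("all clicks carry the same label", call. = FALSE)
  if (inherits(image, "multiplex_image")) image <- image$data
  ct <- click_tiles(clicks, image, model$config$input_size,
                    model$config$in_channels)
  train_loop(model, ct$tiles, ct$labels, cfg)
}

#' Create a click set
#'
#' A click set collects expert patch annotations for one region: 0-based
#' top-left corners of `48 x 48` patches, each labelled wholly `"region"` or
#' `"background"`, with the fine-tuning round that introduced them.
#'
#' @param region_id Region id (or name) the clicks belong to.
#' @param entries Data frame with columns `row`, `col`, `label`
#'   (`"region"`/`"background"`) and optionally `round` (default 1).
#' @return An object of class `click_set`.
#' @export
click_set <- function(region_id, entries) {
  if (is.null(entries$round)) entries$round <- rep(1L, nrow(entries))
  entries <- entries[, c("row", "col", "label", "round")]
  if (!all(entries$label %in% c("region", "background")))
    stop("click labels must be 'region' or 'background'", call. = FALSE)
  if (anyDuplicated(entries[, c("row", "col")]))
    stop("duplicate click locations", call. = FALSE)
  structure(list(region_id = region_id, entries = entries,
                 removed = entries[0, ]), class = "click_set")
}

#' @export
print.click_set <- function(x, ...) {
  cat(sprintf("click set for region %s: %d patches (%d region, %d background), rounds %s\n",
              x$region_id, nrow(x$entries), sum(x$entries$label == "region"),
              sum(x$entries$label == "background"),
              paste(sort(unique(x$entries$round)), collapse = ",")))
  invisible(x)
}

#' Run one incremental fine-tuning round
#'
#' Applies the expert's edits to the click set — the effective set becomes
#' `(previous union additions) minus removals` — and resumes training from
#' the passed model's current parameters (the model is not re-seeded).
#' Provenance is kept: added entries carry the new round index and removed
#' entries are archived on the click set.
#'
#' @param model The binary model from the previous round.
#' @param clicks The cumulative `click_set`.
#' @param additions Data frame of new entries (`row`, `col`, `label`), or NULL.
#' @param removals Data frame of existing entry locations (`row`, `col`) to
#'   drop, or NULL. Removing a non-existent entry is an error.
#' @param image The image the clicks refer to.
#' @param cfg A [train_config()] for this round.
#' @param max_epochs Epoch cap passed to [finetune_binary()].
#' @return List with `model`, `clicks` (updated) and `history`.
#' @export
incremental_round <- function(model, clicks, additions = NULL, removals = NULL,
                              image, cfg = train_config(epochs = 100L, lr = 1e-5),
                              max_epochs = 400L) {
  ent <- clicks$entries
  round_idx <- if (nrow(ent)) max(ent$round) + 1L else 1L
  if (!is.null(additions) && nrow(additions)) {
    additions$round <- round_idx
    ent <- rbind(ent, additions[, c("row", "col", "label", "round")])
  }
  removed <- clicks$removed
  if (!is.null(removals) && nrow(removals)) {
    for (i in seq_len(nrow(removals))) {
      hit <- which(ent$row == removals$row[i] & ent$col == removals$col[i])
      if (!length(hit))
        stop(sprintf("removal of non-existent click at (%d, %d)",
                     removals$row[i], removals$col[i]), call. = FALSE)
      removed <- rbind(removed, ent[hit[1], ])
      ent <- ent[-hit[1], , drop = FALSE]
    }
  }
  if (anyDuplicated(ent[, c("row", "col")]))
    stop("duplicate click locations after edits", call. = FALSE)
  clicks$entries <- ent
  clicks$removed <- removed
  ft <- finetune_binary(model, clicks, image, cfg, max_epochs)
  list(model = ft$model, clicks = clicks, history = ft$history)
}
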