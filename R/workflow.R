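# End-to-end human-in-the-loop workflow on the synthetic phantom: multi-class
# pre-training on the left half, per-region binary seeding + click fine-tuning,
# strided inference on the held-out right half, and IoU comparison.

#' Reduced-width model configuration for phantom experiments
#'
#' Same architecture as the reference model but with 2 depthwise filters per
#' channel (latent width 16) and proportionally fewer heads, sized for CPU
#' training on the 480 x 480 phantom.
#'
#' @param num_classes Output classes. Default 4 (3 phantom regions +
#'   background).
#' @param in_channels Biomarker channels. Default 8.
#' @return A `swinplex_config`.
#' @export
phantom_model_config <- function(num_classes = 4L, in_channels = 8L) {
  model_config(in_channels = in_channels, filters_per_channel = 2L,
               heads_per_stage = c(2L, 2L, 4L), mlp_ratio = c(4, 2, 2),
               num_classes = num_classes)
}

#' Run the full incremental-learning workflow on a synthetic phantom
#'
#' Generates a mirrored phantom, pre-trains a multi-class model on tiles from
#' the left half, evaluates it on the right half with strided mode-smoothed
#' inference, then for every region seeds a binary model from the multi-class
#' weights, fine-tunes it on a small synthetic click set drawn from the test
#' half, and compares per-region IoU of the binarized multi-class prediction
#' against the fine-tuned binary prediction.
#'
#' @param seed Master seed; every random stage derives from it.
#' @param phantom_cfg A [phantom_config()]; its own seed is replaced by a
#'   value derived from `seed`.
#' @param model_cfg Model configuration; default [phantom_model_config()].
#' @param pretrain_cfg [train_config()] for multi-class pre-training.
#' @param finetune_cfg [train_config()] for each binary fine-tune.
#' @param n_pos,n_neg Click counts per region.
#' @param f Stride factor for inference smoothing.
#' @return A list of class `phantom_workflow`: `report` (per-region data frame
#'   with multi-class and binary IoU), `improved` (count of regions with
#'   strictly higher binary IoU), `multiclass` (trained model), `binary`
#'   (list of fine-tuned models), `pretrain_history`, and the `atlas`.
#' @export
phantom_workflow <- function(seed = 1L,
                             phantom_cfg = phantom_config(),
                             model_cfg = phantom_model_config(),
                             pretrain_cfg = train_config(epochs = 80L,
                                                         lr = 1e-3,
                                                         batch_size = 16L,
                                                         seed = seed + 1L),
                             finetune_cfg = train_config(epochs = 100L,
                                                         lr = 3e-4,
                                                         batch_size = 16L,
                                                         seed = seed + 2L),
                             n_pos = 8L, n_neg = 8L, f = 48L) {
  phantom_cfg$seed <- seed
  atlas <- generate_phantom(phantom_cfg)
  halves <- split_halves(atlas)
  K <- length(atlas$regions)
  stopifnot(model_cfg$num_classes == K + 1L)

  ts <- build_training_set(halves$left, seed = seed + 3L)
  model <- build_model(model_cfg, seed = seed + 4L)
  pt <- pretrain_multiclass(model, ts, pretrain_cfg)

  seg_mc <- segment_image(pt$model, halves$right$image, f = f)
  mc_iou <- numeric(K); mc_dnp <- logical(K)
  for (k in seq_len(K)) {
    r <- iou(binarize_for_region(seg_mc$labels, k),
             binarize_for_region(halves$right$mask, k))
    mc_iou[k] <- r$iou; mc_dnp[k] <- r$dnp
  }

  bin_models <- vector("list", K)
  bin_iou <- numeric(K); bin_dnp <- logical(K)
  for (k in seq_len(K)) {
    clicks <- generate_clickset(halves$right$mask, k, n_pos, n_neg,
                                seed = seed + 10L + k)
    bcfg <- finetune_cfg
    bcfg$seed <- finetune_cfg$seed + k
    bin <- init_binary_from_multiclass(pt$model, seed = seed + 20L + k)
    ft <- finetune_binary(bin, clicks, halves$right$image, bcfg)
    bin_models[[k]] <- ft$model
    seg_b <- segment_image(ft$model, halves$right$image, f = f)
    r <- iou(seg_b$labels == 1L, binarize_for_region(halves$right$mask, k))
    bin_iou[k] <- r$iou; bin_dnp[k] <- r$dnp
  }

  report <- data.frame(region = unname(atlas$regions),
                       multiclass_iou = mc_iou, multiclass_dnp = mc_dnp,
                       binary_iou = bin_iou, binary_dnp = bin_dnp)
  out <- list(report = report,
              improved = improvement_count(mc_iou, bin_iou),
              multiclass = pt$model, binary = bin_models,
              pretrain_history = pt$history, atlas = atlas, seed = seed)
  class(out) <- "phantom_workflow"
  out
}

#' @export
print.phantom_workflow <- function(x, ...) {
  cat("phantom incremental-learning workflow\n")
  r <- x$report
  for (i in seq_len(nrow(r))) {
    cat(sprintf("  %-10s multi-class IoU %s -> binary IoU %s\n", r$region[i],
                if (r$multiclass_dnp[i]) "DNP" else sprintf("%.2f", r$multiclass_iou[i]),
                if (r$binary_dnp[i]) "DNP" else sprintf("%.2f", r$binary_iou[i])))
  }
  cat(sprintf("  improved regions: %d of %d\n", x$improved, nrow(r)))
  invisible(x)
}
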