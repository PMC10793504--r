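make_overfit_set <- function(n = 6, seed = 30) {
  # tiles with class-dependent intensity so a small model can overfit fast
  set.seed(seed)
  tiles <- array(0, c(48, 48, 2, n))
  labels <- array(0L, c(48, 48, n))
  for (i in seq_len(n)) {
    cls <- (i - 1L) %% 2L
    tiles[, , , i] <- runif(48 * 48 * 2, 0.1, 0.2) + 0.4 * cls
    labels[, , i] <- cls + 1L
  }
  structure(list(tiles = tiles, labels = labels,
                 records = data.frame(row = 0, col = 0, contains_roi = TRUE)),
            class = "training_set")
}

test_that("zero-epoch training leaves parameters untouched", {
  cfg <- tiny_config()
  m <- build_model(cfg, seed = 1)
  ts <- make_overfit_set()
  r <- suppressWarnings(pretrain_multiclass(m, ts, train_config(epochs = 0, seed = 1)))
  expect_identical(r$model$params, m$params)
  expect_length(r$history, 0)
})

test_that("training reduces the loss on a small overfit set", {
  cfg <- tiny_config()
  m <- build_model(cfg, seed = 2)
  ts <- make_overfit_set()
  r <- suppressWarnings(
    pretrain_multiclass(m, ts, train_config(epochs = 12, lr = 1e-3,
                                            batch_size = 6, seed = 2)))
  expect_length(r$history, 12)
  expect_lt(r$history[12], r$history[1])
})

test_that("pretraining warns when a class never appears in the labels", {
  cfg <- tiny_config()  # 3 classes, but the overfit set only has 0 and 1
  m <- build_model(cfg, seed = 3)
  ts <- make_overfit_set()
  ts$labels[ts$labels == 2L] <- 1L
  expect_warning(pretrain_multiclass(m, ts, train_config(epochs = 0)),
                 "absent")
})

test_that("binary seeding copies all non-head parameters exactly", {
  cfg <- tiny_config()
  m <- build_model(cfg, seed = 4)
  bin <- init_binary_from_multiclass(m, seed = 9)
  expect_identical(bin$config$num_classes, 2L)
  expect_equal(dim(bin$params$head$w), c(cfg$embed_dim, 2L))
  a <- swinplex:::tree_leaves(m$params)
  b <- swinplex:::tree_leaves(bin$params)
  nm <- setdiff(names(a), "params.head.w")
  expect_identical(a[nm], b[nm])
  # idempotent in non-head parameters
  bin2 <- init_binary_from_multiclass(bin, seed = 10)
  expect_identical(swinplex:::tree_leaves(bin2$params)[nm], b[nm])
  # forward yields 2 x 48 x 48 logits
  lg <- forward_segment(bin, array(0.5, c(48, 48, 2)))
  expect_equal(dim(lg), c(2, 48, 48))
  # the copy variant takes the region's multi-class head column
  binc <- init_binary_from_multiclass(m, head_init = "copy", region_id = 2)
  expect_identical(binc$params$head$w[, 2], m$params$head$w[, 3])
  expect_error(init_binary_from_multiclass(m, head_init = "copy"), "region_id")
})

test_that("fine-tuning validates clicks and enforces the epoch budget", {
  cfg <- tiny_config()
  m <- build_model(cfg, seed = 5)
  bin <- init_binary_from_multiclass(m, seed = 5)
  img <- array(runif(96 * 96 * 2), c(96, 96, 2))
  cl <- click_set("r", data.frame(row = c(0, 48), col = c(0, 48),
                                  label = c("region", "background")))
  expect_error(finetune_binary(bin, click_set("r", data.frame(
    row = integer(0), col = integer(0), label = character(0))), img), "empty")
  expect_error(finetune_binary(bin, cl, img,
                               train_config(epochs = 401)), "budget")
  expect_error(finetune_binary(m, cl, img), "binary")
  one <- click_set("r", data.frame(row = 0, col = 0, label = "region"))
  expect_warning(finetune_binary(bin, one, img, train_config(epochs = 0)),
                 "same label")
  out_of_bounds <- click_set("r", data.frame(row = c(90, 0), col = c(0, 0),
                                             label = c("region", "background")))
  expect_error(finetune_binary(bin, out_of_bounds, img,
                               train_config(epochs = 1)), "outside")
  # zero epochs returns the seeded initialisation unchanged
  r <- finetune_binary(bin, cl, img, train_config(epochs = 0))
  expect_identical(r$model$params, bin$params)
})

test_that("region-only clicks push predictions toward the region class", {
  cfg <- tiny_config()
  m <- build_model(cfg, seed = 6)
  bin <- init_binary_from_multiclass(m, seed = 6)
  set.seed(31)
  img <- array(runif(96 * 96 * 2, 0.2, 0.6), c(96, 96, 2))
  cl <- suppressWarnings(click_set("r", data.frame(
    row = c(0, 0, 48), col = c(0, 48, 0), label = "region")))
  region_fraction <- function(model) {
    fr <- 0
    for (i in seq_len(nrow(cl$entries))) {
      tile <- img[(cl$entries$row[i] + 1):(cl$entries$row[i] + 48),
                  (cl$entries$col[i] + 1):(cl$entries$col[i] + 48), ]
      lab <- apply(forward_segment(model, tile), c(2, 3), which.max) - 1L
      fr <- fr + mean(lab == 1L)
    }
    fr / nrow(cl$entries)
  }
  before <- region_fraction(bin)
  r <- suppressWarnings(
    finetune_binary(bin, cl, img, train_config(epochs = 8, lr = 1e-3,
                                               batch_size = 4, seed = 3)))
  expect_gt(region_fraction(r$model), before)
})

test_that("incremental rounds apply set algebra and keep provenance", {
  cfg <- tiny_config()
  m <- build_model(cfg, seed = 7)
  bin <- init_binary_from_multiclass(m, seed = 7)
  img <- array(runif(96 * 96 * 2), c(96, 96, 2))
  cl <- click_set("r", data.frame(row = c(0, 48), col = c(0, 0),
                                  label = c("region", "background")))
  cfg0 <- train_config(epochs = 0)
  # empty edits leave the set unchanged
  r0 <- incremental_round(bin, cl, NULL, NULL, img, cfg0)
  expect_identical(r0$clicks$entries, cl$entries)
  # add then remove the same patch restores the set
  add <- data.frame(row = 0, col = 48, label = "region")
  r1 <- incremental_round(bin, cl, add, NULL, img, cfg0)
  expect_equal(nrow(r1$clicks$entries), 3)
  expect_equal(max(r1$clicks$entries$round), 2)
  r2 <- incremental_round(r1$model, r1$clicks, NULL,
                          data.frame(row = 0, col = 48), img, cfg0)
  expect_equal(r2$clicks$entries[, c("row", "col", "label")],
               cl$entries[, c("row", "col", "label")], ignore_attr = TRUE)
  expect_equal(nrow(r2$clicks$removed), 1)
  # removing a non-existent entry errors
  expect_error(incremental_round(bin, cl, NULL,
                                 data.frame(row = 7, col = 7), img, cfg0),
               "non-existent")
})

test_that("the pretrain -> seed -> finetune pipeline repeats bitwise", {
  cfg <- tiny_config()
  run <- function() {
    m <- build_model(cfg, seed = 8)
    ts <- make_overfit_set()
    pt <- suppressWarnings(
      pretrain_multiclass(m, ts, train_config(epochs = 3, lr = 1e-3,
                                              batch_size = 4, seed = 11)))
    bin <- init_binary_from_multiclass(pt$model, seed = 12)
    img <- array(0.3, c(96, 96, 2))
    cl <- click_set("r", data.frame(row = c(0, 48), col = c(0, 0),
                                    label = c("region", "background")))
    ft <- finetune_binary(bin, cl, img, train_config(epochs = 3, lr = 1e-4,
                                                     batch_size = 2, seed = 13))
    ft$model$params
  }
  expect_identical(run(), run())
})
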