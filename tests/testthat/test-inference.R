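test_that("offset plans enumerate (48/f)^2 distinct offsets", {
  p48 <- offset_grid(48)
  expect_equal(p48$n, 1)
  expect_equal(p48$offsets, data.frame(row = 0L, col = 0L))
  p24 <- offset_grid(24)
  expect_equal(p24$n, 4)
  expect_setequal(paste(p24$offsets$row, p24$offsets$col),
                  c("0 0", "0 24", "24 0", "24 24"))
  p4 <- offset_grid(4)
  expect_equal(p4$n, 144)
  expect_equal(nrow(unique(p4$offsets)), 144)
  expect_error(offset_grid(5), "factor")
  expect_error(offset_grid(0), "factor")
})

test_that("offset maps cover exactly the full tiles at each offset", {
  cfg <- tiny_config()
  m <- build_model(cfg, seed = 1)
  set.seed(21)
  img <- array(runif(96 * 96 * 2), c(96, 96, 2))
  full <- predict_offset_map(m, img, c(0, 0))
  expect_true(all(full$coverage))
  expect_true(all(full$map %in% 0:2))
  off <- predict_offset_map(m, img, c(24, 24))
  expect_equal(sum(off$coverage), 48 * 48)
  expect_true(all(off$coverage[25:72, 25:72]))
  expect_true(all(is.na(off$map[!off$coverage])))
  expect_error(predict_offset_map(m, array(0, c(32, 32, 2))), "smaller")
})

test_that("mode voting takes the majority and breaks ties downward", {
  mk <- function(v) list(map = matrix(v, 1, 1), coverage = matrix(TRUE, 1, 1))
  expect_equal(mode_smooth(list(mk(2), mk(2), mk(2)), 3)[1, 1], 2)
  expect_equal(mode_smooth(list(mk(0), mk(0), mk(1)), 3)[1, 1], 0)
  # exhaustive 2-vote enumeration: the tie goes to the smaller label
  for (a in 0:2) for (b in 0:2) {
    got <- mode_smooth(list(mk(a), mk(b)), 3)[1, 1]
    expect_equal(got, min(a, b))
  }
  # uncovered pixel errors
  bad <- list(list(map = matrix(NA_integer_, 1, 1),
                   coverage = matrix(FALSE, 1, 1)))
  expect_error(mode_smooth(bad, 3), "no votes")
})

test_that("vote order does not affect the smoothed map", {
  set.seed(22)
  maps <- lapply(1:5, function(i) {
    list(map = matrix(sample(0:3, 36, replace = TRUE), 6, 6),
         coverage = matrix(TRUE, 6, 6))
  })
  a <- mode_smooth(maps, 4)
  b <- mode_smooth(rev(maps), 4)
  expect_identical(a, b)
})

test_that("the smoothed label is always one of the cast votes", {
  set.seed(23)
  maps <- lapply(1:3, function(i) {
    cov <- matrix(runif(36) < 0.8, 6, 6)
    cov[1, ] <- TRUE   # guarantee full coverage via the first map
    mp <- matrix(sample(0:3, 36, replace = TRUE), 6, 6)
    mp[!cov] <- NA_integer_
    list(map = mp, coverage = cov)
  })
  maps[[1]]$coverage[] <- TRUE
  maps[[1]]$map <- matrix(sample(0:3, 36, replace = TRUE), 6, 6)
  sm <- mode_smooth(maps, 4)
  for (i in 1:6) for (j in 1:6) {
    votes <- unlist(lapply(maps, function(s) {
      if (s$coverage[i, j]) s$map[i, j] else NULL
    }))
    expect_true(sm[i, j] %in% votes)
  }
})

test_that("f=48 segmentation equals naive non-overlapping tiling bitwise", {
  cfg <- tiny_config()
  m <- build_model(cfg, seed = 2)
  set.seed(24)
  img <- array(runif(96 * 144 * 2), c(96, 144, 2))
  seg <- segment_image(m, img, f = 48)
  naive <- matrix(NA_integer_, 96, 144)
  for (r0 in c(0, 48)) for (c0 in c(0, 48, 96)) {
    lg <- forward_segment(m, img[(r0 + 1):(r0 + 48), (c0 + 1):(c0 + 48), ])
    naive[(r0 + 1):(r0 + 48), (c0 + 1):(c0 + 48)] <-
      apply(lg, c(2, 3), which.max) - 1L
  }
  expect_identical(seg$labels, naive)
})

test_that("a constant-output model yields a constant map for any f", {
  cfg <- tiny_config(num_classes = 5L)
  m <- build_model(cfg, seed = 3)
  m$params$final$norm$g[] <- 0
  m$params$final$norm$b[] <- 1
  m$params$head$w[] <- 0
  m$params$head$w[, 4] <- 1   # class index 3 wins everywhere
  set.seed(25)
  img <- array(runif(96 * 96 * 2), c(96, 96, 2))
  for (f in c(48, 24)) {
    seg <- segment_image(m, img, f = f)
    expect_true(all(seg$labels == 3L))
  }
})

test_that("pixels where all offset maps agree are unchanged by smoothing", {
  cfg <- tiny_config()
  m <- build_model(cfg, seed = 4)
  set.seed(26)
  img <- array(runif(96 * 96 * 2), c(96, 96, 2))
  seg48 <- segment_image(m, img, f = 48)
  seg24 <- segment_image(m, img, f = 24)
  plan <- offset_grid(24)
  stack <- lapply(seq_len(plan$n), function(i) {
    predict_offset_map(m, img, c(plan$offsets$row[i], plan$offsets$col[i]))
  })
  agree <- Reduce(`&`, lapply(stack, function(s) {
    s$coverage & !is.na(s$map) & s$map == stack[[1]]$map
  }))
  expect_true(all(seg24$labels[agree] == seg48$labels[agree]))
})

test_that("finer strides never reduce per-pixel vote counts", {
  count_votes <- function(f, H = 96, W = 96) {
    plan <- offset_grid(f)
    total <- matrix(0L, H, W)
    for (i in seq_len(plan$n)) {
      g <- tile_grid(H, W, 48, c(plan$offsets$row[i], plan$offsets$col[i]))
      cov <- matrix(FALSE, H, W)
      for (j in seq_len(nrow(g))) {
        cov[(g$row[j] + 1):(g$row[j] + 48), (g$col[j] + 1):(g$col[j] + 48)] <- TRUE
      }
      total <- total + cov
    }
    total
  }
  v48 <- count_votes(48)
  v24 <- count_votes(24)
  v12 <- count_votes(12)
  expect_true(all(v24 >= v48))
  expect_true(all(v12 >= v24))
})

test_that("images not divisible by the tile are padded then cropped", {
  cfg <- tiny_config()
  m <- build_model(cfg, seed = 5)
  set.seed(27)
  img <- array(runif(60 * 70 * 2), c(60, 70, 2))
  seg <- segment_image(m, img, f = 48)
  expect_equal(dim(seg$labels), c(60, 70))
  expect_true(all(seg$labels %in% 0:2))
})
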