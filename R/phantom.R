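# Synthetic multiplex tissue phantom: a dark canvas holding a bright
# elliptical "tissue" area (part of the background class) in which smooth
# random-blob regions with distinct per-channel intensity/texture signatures
# are embedded. Mirror symmetry emulates the roughly symmetric brain section
# behind the train-on-left / test-on-right protocol.

#' Default phantom regions: one per visibility class
#'
#' Three regions emulating the visibility taxonomy of anatomical regions:
#' class 1 (`plain`) has strong mean contrast in several channels; class 2
#' (`textured`) has weak mean contrast but a dense cell-speckle texture;
#' class 3 (`cryptic`) matches the surrounding tissue in mean intensity on
#' every channel and differs only in higher-order texture statistics
#' (zero-mean speckle).
#'
#' @param channels Number of biomarker channels.
#' @return A list of region descriptors.
#' @export
default_phantom_regions <- function(channels = 8L) {
  sig <- function(vals) {
    s <- numeric(channels)
    s[seq_along(vals)] <- vals
    s
  }
  rotate <- function(s, k) c(s[-seq_len(k)], s[seq_len(k)])
  list(
    list(name = "plain", visibility = 1L, target_area = 6500,
         center = c(110, 125), complexity = 0.22,
         signature = sig(c(0.45, 0.40, 0.35, 0.10)),
         speckle = list(density = 0.02, gain = 0.25, size = 2L,
                        channels = seq_len(min(3L, channels)),
                        zero_mean = FALSE)),
    list(name = "textured", visibility = 2L, target_area = 6000,
         center = c(240, 118), complexity = 0.25,
         signature = rotate(sig(c(0.10, 0.08, 0.06)), 3L),
         speckle = list(density = 0.10, gain = 0.50, size = 2L,
                        channels = seq.int(min(4L, channels), channels),
                        zero_mean = FALSE)),
    list(name = "cryptic", visibility = 3L, target_area = 5500,
         center = c(370, 125), complexity = 0.22,
         signature = numeric(channels),
         speckle = list(density = 0.12, gain = 0.45, size = 2L,
                        channels = seq_len(channels), zero_mean = TRUE))
  )
}

#' Phantom configuration
#'
#' @param height,width Canvas size in pixels; multiples of 48. Default 480.
#' @param channels Biomarker channels. Default 8.
#' @param regions Region descriptor list; see [default_phantom_regions()].
#'   Centers are given in left-half coordinates.
#' @param background_level Intensity of the dark margin outside the tissue;
#'   kept below the default sampling threshold. Default 0.005.
#' @param tissue_level Mean intensity of the unlabelled tissue. Default 0.15.
#' @param noise_sd Additive Gaussian noise level. Default 0.01.
#' @param contrast_margin Minimum inside-vs-outside mean contrast guaranteed
#'   for visibility-class-1 regions. Default 0.2.
#' @param mirror Mirror the left half onto the right so both halves contain
#'   every region. Default TRUE.
#' @param seed Seed making the phantom fully deterministic.
#' @return A list of class `phantom_config`.
#' @export
phantom_config <- function(height = 480L, width = 480L, channels = 8L,
                           regions = default_phantom_regions(channels),
                           background_level = 0.005, tissue_level = 0.15,
                           noise_sd = 0.01, contrast_margin = 0.2,
                           mirror = TRUE, seed = 0L) {
  if (height %% 48 != 0 || width %% 48 != 0)
    stop("height and width must be multiples of 48", call. = FALSE)
  structure(list(height = as.integer(height), width = as.integer(width),
                 channels = as.integer(channels), regions = regions,
                 background_level = background_level,
                 tissue_level = tissue_level, noise_sd = noise_sd,
                 contrast_margin = contrast_margin, mirror = isTRUE(mirror),
                 seed = as.integer(seed)),
            class = "phantom_config")
}

# Rasterize a smooth random blob: a disc whose boundary radius is modulated
# by a few random angular harmonics.
rasterize_blob <- function(H, W, center, area, complexity) {
  r0 <- sqrt(area / pi)
  amp <- stats::rnorm(3, sd = complexity / sqrt(1:3))
  phase <- stats::runif(3, 0, 2 * pi)
  rr <- outer(seq_len(H) - center[1], rep(1, W))
  cc <- outer(rep(1, H), seq_len(W) - center[2])
  dist <- sqrt(rr^2 + cc^2)
  theta <- atan2(rr, cc)
  rmod <- r0 * (1 + amp[1] * cos(2 * theta + phase[1]) +
                    amp[2] * cos(3 * theta + phase[2]) +
                    amp[3] * cos(4 * theta + phase[3]))
  dist <= rmod
}

# Cell-like speckle: small square dots scattered uniformly inside a support
# mask. Returns an H x W texture field; zero-mean speckle alternates dot sign.
speckle_field <- function(support, density, gain, size) {
  H <- nrow(support); W <- ncol(support)
  idx <- which(support)
  n_dots <- round_half_up(density * length(idx) / (size * size))
  out <- matrix(0, H, W)
  if (n_dots < 1) return(out)
  centers <- sample(idx, min(n_dots, length(idx)))
  sign <- rep_len(c(1, -1), length(centers))
  rr <- ((centers - 1L) %% H) + 1L
  cc <- ((centers - 1L) %/% H) + 1L
  for (k in seq_along(centers)) {
    r <- rr[k]:min(rr[k] + size - 1L, H)
    c <- cc[k]:min(cc[k] + size - 1L, W)
    out[r, c] <- out[r, c] + gain * sign[k]
  }
  out
}

#' Generate a synthetic multiplex tissue phantom
#'
#' Builds a deterministic (seeded) labelled multi-channel image: a dark
#' margin, a bright elliptical tissue area, and the configured regions
#' rasterized as smooth random blobs, each contributing its per-channel mean
#' signature and cell-speckle texture, plus additive Gaussian noise. With
#' `mirror = TRUE` the right half is the mirrored left half (with independent
#' noise and texture), so each half contains every region.
#'
#' @param cfg A [phantom_config()].
#' @return An `atlas_labeled_image`; the generating config is attached as
#'   attribute `phantom_config`.
#' @export
generate_phantom <- function(cfg = phantom_config()) {
  set.seed(cfg$seed)
  H <- cfg$height; W <- cfg$width
  Wh <- W %/% 2L
  nch <- cfg$channels
  K <- length(cfg$regions)

  # label mask on the left half; earlier regions take priority
  mask_left <- matrix(0L, H, Wh)
  for (k in seq_len(K)) {
    reg <- cfg$regions[[k]]
    rmax <- sqrt(reg$target_area / pi) * (1 + 3 * reg$complexity)
    if (reg$center[1] - rmax < 1 || reg$center[1] + rmax > H ||
        reg$center[2] - rmax < 1 || reg$center[2] + rmax > Wh)
      stop(sprintf("region '%s' overflows the canvas half", reg$name),
           call. = FALSE)
    blob <- rasterize_blob(H, Wh, reg$center, reg$target_area, reg$complexity)
    mask_left[blob & mask_left == 0L] <- k
  }
  mask <- if (cfg$mirror) {
    cbind(mask_left, mask_left[, Wh:1])
  } else {
    cbind(mask_left, matrix(0L, H, W - Wh))
  }

  # tissue ellipse on the full canvas (mirror-symmetric by construction)
  rr <- outer(seq_len(H) - (H + 1) / 2, rep(1, W))
  cc <- outer(rep(1, H), seq_len(W) - (W + 1) / 2)
  tissue <- (rr / (0.46 * H))^2 + (cc / (0.46 * W))^2 <= 1
  tissue <- tissue | mask > 0L

  img <- array(0, c(H, W, nch))
  tissue_tex <- speckle_field(tissue, 0.02, 0.25, 2L)
  for (ch in seq_len(nch)) {
    plane <- matrix(cfg$background_level, H, W)
    plane[tissue] <- cfg$tissue_level
    plane <- plane + tissue_tex * (0.5 + 0.1 * ch / nch)
    for (k in seq_len(K)) {
      reg <- cfg$regions[[k]]
      inside <- mask == k
      plane[inside] <- plane[inside] + reg$signature[ch]
      if (ch %in% reg$speckle$channels) {
        tex <- speckle_field(inside, reg$speckle$density,
                             reg$speckle$gain, reg$speckle$size)
        if (reg$speckle$zero_mean) tex <- tex - mean(tex[inside])
        plane[inside] <- plane[inside] + tex[inside]
      }
    }
    plane <- plane + matrix(stats::rnorm(H * W, sd = cfg$noise_sd), H, W)
    img[, , ch] <- pmax(plane, 0)
  }

  regions <- vapply(cfg$regions, function(r) r$name, character(1))
  names(regions) <- as.character(seq_len(K))
  out <- atlas_labeled_image(
    multiplex_image(img, paste0("marker", seq_len(nch))), mask, regions)
  attr(out, "phantom_config") <- cfg
  out
}

# Summed-area table lookup of tile sums of a 0/1 matrix for every 0-based
# top-left position; returns an (H-tile+1) x (W-tile+1) matrix.
window_sums <- function(ind, tile) {
  H <- nrow(ind); W <- ncol(ind)
  S <- matrix(0, H + 1L, W + 1L)
  S[-1, -1] <- apply(apply(ind, 2, cumsum), 1, cumsum) |> t()
  i <- seq_len(H - tile + 1L)
  j <- seq_len(W - tile + 1L)
  S[i + tile, j + tile, drop = FALSE] - S[i + tile, j, drop = FALSE] -
    S[i, j + tile, drop = FALSE] + S[i, j, drop = FALSE]
}

#' Generate a synthetic expert click set for one region
#'
#' Samples `n_pos` patches whose `tile x tile` extent is at least
#' `inside_min` (default 90%) inside the region and `n_neg` patches fully
#' outside it. Negative patches are drawn from the candidates nearest the
#' region (its surroundings), as an expert correcting a region's segmentation
#' would. Sampling is seeded and deterministic. Exceeding the conventional
#' 30-patch budget triggers a warning.
#'
#' @param mask Integer label mask.
#' @param region_id Region id to annotate.
#' @param n_pos,n_neg Number of region / background patches.
#' @param seed Sampling seed.
#' @param tile Patch side in pixels. Default 48.
#' @param inside_min Minimum inside fraction for positive patches. Default 0.9.
#' @return A `click_set` with 0-based patch corners.
#' @export
generate_clickset <- function(mask, region_id, n_pos, n_neg, seed = 0L,
                              tile = 48L, inside_min = 0.9) {
  ind <- mask == region_id
  if (!any(ind)) stop("region not present in mask", call. = FALSE)
  if (n_pos + n_neg > 30)
    warning("click budget exceeds the conventional 30-patch maximum",
            call. = FALSE)
  ws <- window_sums(ind, tile)
  pos_cand <- which(ws >= inside_min * tile * tile)
  neg_cand <- which(ws == 0)
  if (length(pos_cand) < n_pos)
    stop("not enough fully-inside positions for positive clicks", call. = FALSE)
  if (length(neg_cand) < n_neg)
    stop("not enough fully-outside positions for negative clicks", call. = FALSE)
  nr <- nrow(ws)
  cand_rc <- function(idx) {
    data.frame(row = ((idx - 1L) %% nr), col = ((idx - 1L) %/% nr))
  }
  set.seed(seed)
  pos <- cand_rc(sample(pos_cand, n_pos))
  ctr <- c(mean(which(ind, arr.ind = TRUE)[, 1]),
           mean(which(ind, arr.ind = TRUE)[, 2]))
  neg_rc <- cand_rc(neg_cand)
  d2 <- (neg_rc$row + tile / 2 - ctr[1])^2 + (neg_rc$col + tile / 2 - ctr[2])^2
  pool <- order(d2)[seq_len(min(length(neg_cand), max(5L * n_neg, 50L)))]
  neg <- neg_rc[sample(pool, n_neg), ]
  entries <- rbind(
    data.frame(row = pos$row, col = pos$col, label = "region"),
    data.frame(row = neg$row, col = neg$col, label = "background"))
  entries$round <- 1L
  entries <- entries[!duplicated(entries[, c("row", "col")]), ]
  click_set(region_id, entries)
}
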