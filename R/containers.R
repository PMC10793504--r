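# Lightweight S3 containers for multiplex imagery and labelled atlases.
# Images are stored H x W x channels; masks are integer H x W matrices with
# 0 = background and 1..K = regions. All pixel coordinates in records and
# click files are 0-based, row-major, with half-open 48x48 tile extents.

#' Construct a multiplex image
#'
#' @param data Numeric array `H x W x channels` of intensities. A plain matrix
#'   is treated as a single channel.
#' @param channels Optional character vector of biomarker channel names.
#' @return An object of class `multiplex_image`.
#' @export
multiplex_image <- function(data, channels = NULL) {
  if (is.matrix(data)) dim(data) <- c(dim(data), 1L)
  if (length(dim(data)) != 3)
    stop("data must be an H x W x channels array", call. = FALSE)
  if (is.null(channels)) channels <- paste0("ch", seq_len(dim(data)[3]))
  if (length(channels) != dim(data)[3])
    stop("channels must name every channel", call. = FALSE)
  structure(list(data = data, channels = channels), class = "multiplex_image")
}

#' @export
print.multiplex_image <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("multiplex image: %d x %d pixels, %d channels (%s)\n",
              d[1], d[2], d[3], paste(x$channels, collapse = ", ")))
  invisible(x)
}

#' Construct a labelled atlas image
#'
#' Pairs a [multiplex_image()] with an integer region-label mask and a region
#' name table.
#'
#' @param image A `multiplex_image` (or a raw `H x W x channels` array).
#' @param mask Integer matrix `H x W`; 0 is background, `1..K` are regions.
#' @param regions Named character vector mapping region ids (as names, e.g.
#'   `"1"`) to region names, or an unnamed vector for ids `1..K`.
#' @return An object of class `atlas_labeled_image`.
#' @export
atlas_labeled_image <- function(image, mask, regions) {
  if (!inherits(image, "multiplex_image")) image <- multiplex_image(image)
  if (!is.matrix(mask)) stop("mask must be a matrix", call. = FALSE)
  if (!all(dim(mask) == dim(image$data)[1:2]))
    stop("image and mask must share height and width", call. = FALSE)
  mask <- matrix(as.integer(mask), nrow(mask), ncol(mask))
  if (is.null(names(regions))) names(regions) <- as.character(seq_along(regions))
  labs <- sort(unique(as.vector(mask)))
  bad <- setdiff(labs, c(0L, as.integer(names(regions))))
  if (length(bad))
    stop("mask contains labels not in the region table: ",
         paste(bad, collapse = ", "), call. = FALSE)
  structure(list(image = image, mask = mask, regions = regions),
            class = "atlas_labeled_image")
}

#' @export
print.atlas_labeled_image <- function(x, ...) {
  print(x$image)
  cat(sprintf("  regions (%d): %s\n", length(x$regions),
              paste(x$regions, collapse = ", ")))
  invisible(x)
}
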