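# Intersection-over-union evaluation: per-region IoU with did-not-predict
# (DNP) handling, multi-class -> binary comparison convention, and table-style
# aggregation.

#' Intersection over union of two binary masks
#'
#' `IoU = |A intersect B| / |A union B|` where A is the model segmentation and
#' B the ground truth. When the prediction is empty the region is flagged DNP
#' ("did not predict"); its IoU is 0 and is counted as 0 in means.
#'
#' @param pred,truth Binary (logical or 0/1) masks of equal shape.
#' @return List with `iou` (in `[0, 1]`) and `dnp` (logical).
#' @export
iou <- function(pred, truth) {
  if (!all(dim(pred) == dim(truth)))
    stop("pred and truth must have the same shape", call. = FALSE)
  pred <- pred > 0; truth <- truth > 0
  if (!any(truth))
    stop("ground-truth mask is empty; IoU is undefined", call. = FALSE)
  inter <- sum(pred & truth)
  list(iou = inter / sum(pred | truth), dnp = !any(pred))
}

#' Binarize a multi-class label map for one region
#'
#' Pixels equal to `region_id` become foreground; every other class, including
#' other regions, is treated as a common background class. This is the
#' convention used to compare a multi-class segmentation with per-region
#' binary models.
#'
#' @param map Integer label map.
#' @param region_id Region label to isolate.
#' @return Logical mask of the same shape.
#' @export
binarize_for_region <- function(map, region_id) {
  map == region_id
}

#' Aggregate per-region IoU values into a report
#'
#' Computes the arithmetic mean IoU over exactly the listed regions, counting
#' DNP regions as 0. Values are kept at full precision internally; rounding to
#' two decimals happens only when printing.
#'
#' @param values Named numeric vector of per-region IoU values. `NA` entries
#'   are interpreted as DNP.
#' @param dnp Optional logical vector flagging DNP regions (default: the `NA`
#'   pattern of `values`).
#' @return An object of class `region_iou_report` with elements `iou` (DNP
#'   replaced by 0), `dnp` and `mean_iou`.
#' @export
region_report <- function(values, dnp = NULL) {
  if (length(values) < 1) stop("at least one region is required", call. = FALSE)
  if (is.null(dnp)) dnp <- is.na(values)
  vals <- ifelse(dnp, 0, values)
  names(vals) <- names(values)
  structure(list(iou = vals, dnp = dnp, mean_iou = mean(vals)),
            class = "region_iou_report")
}

#' @export
print.region_iou_report <- function(x, ...) {
  cat("per-region IoU:\n")
  nm <- names(x$iou)
  if (is.null(nm)) nm <- as.character(seq_along(x$iou))
  for (i in seq_along(x$iou)) {
    cat(sprintf("  %-6s %s\n", nm[i],
                if (x$dnp[i]) "DNP" else sprintf("%.2f", x$iou[i])))
  }
  cat(sprintf("mean IoU (DNP as 0): %.2f\n", x$mean_iou))
  invisible(x)
}

#' Count regions improved by fine-tuning
#'
#' Number of regions whose fine-tuned IoU is strictly greater than the
#' baseline IoU, with DNP entries counted as 0 on both sides.
#'
#' @param baseline,finetuned Named numeric vectors of per-region IoU over the
#'   same region set; `NA` means DNP.
#' @return Integer count.
#' @export
improvement_count <- function(baseline, finetuned) {
  if (length(baseline) != length(finetuned))
    stop("region sets must match", call. = FALSE)
  if (!is.null(names(baseline)) && !is.null(names(finetuned)) &&
      !identical(names(baseline), names(finetuned)))
    stop("region sets must match", call. = FALSE)
  b <- ifelse(is.na(baseline), 0, baseline)
  f <- ifelse(is.na(finetuned), 0, finetuned)
  sum(f > b)
}
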