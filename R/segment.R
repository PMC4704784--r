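#' Nuclear mask from DAPI and gamma-tubulin thresholds
#'
#' Nuclear voxels are those inside the ROI where DAPI is at or above
#' `t_dapi` and gamma-tubulin background (absent from the nucleus) is below
#' `t_tub_low`. Pure global thresholding, no morphological cleanup.
#'
#' @param stack a [volume_stack()] with `dapi` and `gamma_tubulin` channels.
#' @param roi_mask 3-D logical ROI mask.
#' @param t_dapi DAPI threshold (nuclear iff dapi >= t_dapi).
#' @param t_tub_low gamma-tubulin background threshold (nuclear iff
#'   tub < t_tub_low).
#' @return 3-D logical array.
#' @export
nuclear_mask <- function(stack, roi_mask, t_dapi, t_tub_low) {
  check_mask(roi_mask, "roi_mask")
  if (!any(roi_mask))
    stopf("roi_mask is empty", class = "bbenrich_empty_input")
  dapi <- get_channel(stack, "dapi")
  tub <- get_channel(stack, "gamma_tubulin")
  roi_mask & (dapi >= t_dapi) & (tub < t_tub_low)
}

#' Cytoplasmic mask: ROI minus nuclei
#'
#' @param roi_mask 3-D logical ROI mask.
#' @param nuclear 3-D logical nuclear mask; must be a subset of `roi_mask`.
#' @return 3-D logical array, the set difference.
#' @export
cytoplasm_mask <- function(roi_mask, nuclear) {
  check_mask(roi_mask, "roi_mask"); check_mask(nuclear, "nuclear")
  if (any(nuclear & !roi_mask))
    stopf("nuclear mask is not a subset of the ROI mask",
          class = "bbenrich_invariant_error")
  roi_mask & !nuclear
}

#' Nuclear / cytoplasm partition of an ROI
#'
#' Convenience wrapper returning the disjoint nuclear and cytoplasmic masks
#' whose union is the ROI.
#'
#' @inheritParams nuclear_mask
#' @return a `region_masks` list with elements `nuclear`, `cytoplasm`,
#'   `roi`.
#' @export
region_masks <- function(stack, roi_mask, t_dapi, t_tub_low) {
  nuc <- nuclear_mask(stack, roi_mask, t_dapi, t_tub_low)
  structure(list(nuclear = nuc,
                 cytoplasm = cytoplasm_mask(roi_mask, nuc),
                 roi = roi_mask),
            class = "region_masks")
}

#' Automatic threshold by between-class variance
#'
#' Convenience default for the otherwise user-specified thresholds: the
#' classic between-class-variance maximizer on the intensity histogram.
#' Returns the midpoint between the two levels that straddle the optimal
#' split, so that `x >= threshold` selects the bright class; when several
#' splits tie, their midpoints are averaged (which keeps the result
#' symmetric under intensity mirroring).
#'
#' @param values numeric intensities (e.g. a channel restricted to a mask).
#' @param method currently `"otsu"`.
#' @return a single threshold intensity.
#' @export
auto_threshold <- function(values, method = c("otsu")) {
  method <- match.arg(method)
  values <- values[is.finite(values)]
  lv <- sort(unique(values))
  if (length(lv) < 2L)
    stopf("cannot threshold constant-intensity input",
          class = "bbenrich_degenerate_input")
  cnt <- tabulate(match(values, lv))
  n <- length(values)
  csum <- cumsum(cnt)
  cmean <- cumsum(cnt * lv)
  total <- cmean[length(lv)]
  k <- seq_len(length(lv) - 1L)        # split after level k
  w0 <- csum[k] / n
  w1 <- 1 - w0
  mu0 <- cmean[k] / csum[k]
  mu1 <- (total - cmean[k]) / (n - csum[k])
  sb <- w0 * w1 * (mu0 - mu1)^2
  best <- which(sb >= max(sb) - 1e-12 * max(sb))
  mean((lv[best] + lv[best + 1L]) / 2)
}
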