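#' PSF size in pixels
#'
#' `(0.8 * lambda_ex / NA) / pixel_size`, the block side used by the
#' scramble test. For typical confocal acquisition (488-561 nm excitation,
#' NA 1.3, ~120-160 nm pixels) this is about 2.5-3 pixels.
#'
#' @param lambda_ex excitation wavelength in nm.
#' @param numerical_aperture objective NA.
#' @param pixel_size_nm pixel pitch in nm.
#' @return PSF size in pixels (not rounded).
#' @export
#' @examples
#' psf_pixels(488, 1.3, 120)
psf_pixels <- function(lambda_ex, numerical_aperture, pixel_size_nm) {
  if (any(c(lambda_ex, numerical_aperture, pixel_size_nm) <= 0) ||
      any(!is.finite(c(lambda_ex, numerical_aperture, pixel_size_nm))))
    stopf("all PSF inputs must be positive finite numbers",
          class = "bbenrich_validation_error")
  (0.8 * lambda_ex / numerical_aperture) / pixel_size_nm
}

#' Pearson correlation of two channels within a mask
#'
#' Standard product-moment correlation over the masked voxels. A constant
#' channel makes the correlation undefined: `NA` is returned with a
#' warning.
#'
#' @param ch1,ch2 intensity arrays of identical shape.
#' @param mask logical array selecting the voxels to correlate.
#' @return correlation in `[-1, 1]`, or `NA` if undefined.
#' @export
coloc_pearson <- function(ch1, ch2, mask) {
  v1 <- ch1[mask]; v2 <- ch2[mask]
  if (length(v1) < 2L)
    stopf("need at least 2 voxels in the mask",
          class = "bbenrich_degenerate_input")
  if (stats::sd(v1) == 0 || stats::sd(v2) == 0) {
    warning("constant channel within mask: Pearson undefined", call. = FALSE)
    return(NA_real_)
  }
  stats::cor(v1, v2)
}

## per-slice tiling of the mask into complete b x b blocks (linear indices
## into the 3-D array); edge-partial and outside-mask blocks are excluded
scramble_blocks <- function(mask, block) {
  dims <- dim(mask)
  blocks <- list()
  for (z in seq_len(dims[1])) {
    sl <- mask[z, , ]
    if (!any(sl)) next
    ys <- range(which(rowSums(sl) > 0))
    xs <- range(which(colSums(sl) > 0))
    for (by in seq(ys[1], ys[2] - block + 1L, by = block))
      for (bx in seq(xs[1], xs[2] - block + 1L, by = block)) {
        yy <- by:(by + block - 1L); xx <- bx:(bx + block - 1L)
        if (!all(sl[yy, xx])) next
        g <- expand.grid(y = yy, x = xx)
        blocks[[length(blocks) + 1L]] <-
          (g$x - 1L) * dims[1] * dims[2] + (g$y - 1L) * dims[1] + z
      }
  }
  blocks
}

#' Block-scramble significance of a colocalization
#'
#' Emulates the randomization used by interactive colocalization plug-ins:
#' each z-slice's masked region is tiled into square blocks of side
#' `round(block_pixels)` (minimum 1, typically the PSF size); the blocks of
#' `ch2` are permuted uniformly at random within each slice; the Pearson
#' correlation is recomputed; and the returned value is the fraction of
#' iterations whose scrambled correlation lies strictly below the observed
#' one. Under this convention a clearly genuine colocalization gives 1.0
#' ("the probability of obtaining the observed R from a random image"
#' saturates).
#'
#' @inheritParams coloc_pearson
#' @param block_pixels block side in pixels (rounded; >= 1).
#' @param n_iterations number of scrambles (default 100).
#' @param seed integer seed; the scramble stream is isolated from the
#'   session RNG.
#' @return fraction in `[0, 1]`.
#' @export
scramble_p <- function(ch1, ch2, mask, block_pixels, n_iterations = 100L,
                       seed = 1L) {
  if (n_iterations < 1L) stopf("n_iterations must be >= 1")
  block <- max(1L, as.integer(round(block_pixels)))
  obs <- coloc_pearson(ch1, ch2, mask)
  if (is.na(obs)) stopf("observed correlation undefined",
                        class = "bbenrich_degenerate_input")
  blocks <- scramble_blocks(mask, block)
  if (length(blocks) < 2L)
    stopf("fewer than 2 complete blocks of side %d within the mask", block,
          class = "bbenrich_degenerate_input")
  # slice id per block, to permute within slices only
  dims <- dim(mask)
  zof <- vapply(blocks, function(b) ((b[1] - 1L) %% dims[1]) + 1L, integer(1))
  idxmat <- matrix(unlist(blocks), nrow = block * block)
  vals <- matrix(ch2[idxmat], nrow = block * block)
  v1 <- ch1[mask]
  scram <- ch2
  withr::with_seed(seed, {
    r <- numeric(n_iterations)
    for (it in seq_len(n_iterations)) {
      perm <- seq_along(blocks)
      for (z in unique(zof)) {
        sel <- which(zof == z)
        if (length(sel) > 1L) perm[sel] <- sel[sample.int(length(sel))]
      }
      scram[idxmat] <- vals[, perm]
      r[it] <- stats::cor(v1, scram[mask])
    }
  })
  mean(r < obs)
}

#' Manders overlap coefficients
#'
#' Thresholded Manders coefficients: `m1` is the fraction of total
#' above-threshold `ch1` signal found at voxels where `ch2` exceeds its
#' threshold; `m2` symmetrically. Both lie in `[0, 1]`; a zero denominator
#' (no above-threshold signal) gives `NA` with a warning.
#'
#' @inheritParams coloc_pearson
#' @param t1,t2 intensity thresholds for `ch1` and `ch2`.
#' @return named numeric `c(m1 =, m2 =)`.
#' @export
manders <- function(ch1, ch2, mask, t1 = 0, t2 = 0) {
  v1 <- ch1[mask]; v2 <- ch2[mask]
  a1 <- v1 > t1; a2 <- v2 > t2
  den1 <- sum(v1[a1]); den2 <- sum(v2[a2])
  m1 <- if (den1 > 0) sum(v1[a1 & a2]) / den1 else NA_real_
  m2 <- if (den2 > 0) sum(v2[a1 & a2]) / den2 else NA_real_
  if (anyNA(c(m1, m2)))
    warning("no above-threshold signal: Manders undefined", call. = FALSE)
  c(m1 = m1, m2 = m2)
}

#' Full colocalization analysis of a channel pair
#'
#' Pearson correlation, PSF-block scramble significance and Manders
#' coefficients in one call.
#'
#' @inheritParams scramble_p
#' @param t1,t2 Manders thresholds (defaults 0).
#' @param lambda_ex,numerical_aperture,pixel_size_nm optional acquisition
#'   parameters; when given, `block_pixels` is derived via [psf_pixels()].
#' @param block_pixels block side in pixels (ignored if acquisition
#'   parameters are supplied).
#' @return a `coloc_result` list: `pearson_r`, `p_scramble`, `manders_m1`,
#'   `manders_m2`, `psf_pixels` (block side used), `n_iterations`.
#' @export
colocalize <- function(ch1, ch2, mask, block_pixels = NULL,
                       lambda_ex = NULL, numerical_aperture = NULL,
                       pixel_size_nm = NULL,
                       t1 = 0, t2 = 0, n_iterations = 100L, seed = 1L) {
  if (!is.null(lambda_ex))
    block_pixels <- psf_pixels(lambda_ex, numerical_aperture, pixel_size_nm)
  if (is.null(block_pixels))
    stopf("supply block_pixels or acquisition parameters",
          class = "bbenrich_config_error")
  r <- coloc_pearson(ch1, ch2, mask)
  p <- scramble_p(ch1, ch2, mask, block_pixels, n_iterations, seed)
  m <- manders(ch1, ch2, mask, t1, t2)
  structure(list(pearson_r = r, p_scramble = p,
                 manders_m1 = unname(m["m1"]), manders_m2 = unname(m["m2"]),
                 psf_pixels = max(1L, as.integer(round(block_pixels))),
                 n_iterations = as.integer(n_iterations)),
            class = "coloc_result")
}

#' @export
print.coloc_result <- function(x, ...) {
  cat(sprintf("coloc_result: R = %.3f, p(scramble) = %.2f, M1 = %.3f, M2 = %.3f (block %d px, %d iterations)\n",
              x$pearson_r, x$p_scramble, x$manders_m1, x$manders_m2,
              x$psf_pixels, x$n_iterations))
  invisible(x)
}
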