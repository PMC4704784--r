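`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ..., class = NULL) {
  msg <- sprintf(fmt, ...)
  if (is.null(class)) stop(msg, call. = FALSE)
  stop(structure(class = c(class, "error", "condition"),
                 list(message = msg, call = NULL)))
}

#' Physical coordinates of voxel centers
#'
#' Voxels are addressed 0-based as (z, y, x); the physical position of the
#' center of voxel index k along an axis with spacing d is `k * d` (in um).
#' `voxel_coords` returns the physical (z, y, x) coordinates, in um, for a
#' matrix of 1-based array indices.
#'
#' @param ind integer matrix of 1-based (z, y, x) array indices, one row per
#'   voxel.
#' @param voxel_size numeric length-3 spacing (dz, dy, dx) in um.
#' @return numeric matrix with columns z, y, x in um.
#' @keywords internal
voxel_coords <- function(ind, voxel_size) {
  out <- sweep(ind - 1, 2, voxel_size, `*`)
  colnames(out) <- c("z", "y", "x")
  out
}

## squared physical distance from each voxel (rows of `ind`, 1-based) to a
## single physical point (z, y, x) in um
dist2_to_point <- function(ind, point, voxel_size) {
  dz <- (ind[, 1] - 1) * voxel_size[1] - point[1]
  dy <- (ind[, 2] - 1) * voxel_size[2] - point[2]
  dx <- (ind[, 3] - 1) * voxel_size[3] - point[3]
  dz * dz + dy * dy + dx * dx
}

check_mask <- function(mask, name = "mask") {
  if (!is.logical(mask) || length(dim(mask)) != 3L)
    stopf("%s must be a 3-D logical array", name)
  invisible(mask)
}

check_voxel_size <- function(voxel_size) {
  if (!is.numeric(voxel_size) || length(voxel_size) != 3L ||
      any(!is.finite(voxel_size)) || any(voxel_size <= 0))
    stopf("voxel_size must be 3 positive values (dz, dy, dx) in um")
  as.numeric(voxel_size)
}

#' Significance stars for p-values
#'
#' Star coding used throughout: `****` p < 0.0001, `**` p < 0.01,
#' `*` p < 0.05, `ns` otherwise.
#'
#' @param p numeric p-value(s).
#' @return character vector of star codes.
#' @export
#' @examples
#' significance_stars(c(0.2, 0.03, 0.002, 1e-6))
significance_stars <- function(p) {
  ifelse(p < 1e-4, "****", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "ns")))
}

## full-precision numeric formatting for result tables (round-trips doubles)
format_full <- function(x) {
  out <- ifelse(is.na(x), "", sprintf("%.17g", x))
  out
}
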