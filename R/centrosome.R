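neighbor_offsets <- function(connectivity = 26L) {
  offs <- as.matrix(expand.grid(dz = -1:1, dy = -1:1, dx = -1:1))
  offs <- offs[rowSums(offs != 0) > 0, , drop = FALSE]
  ord <- rowSums(abs(offs))
  switch(as.character(connectivity),
         "6" = offs[ord == 1, , drop = FALSE],
         "18" = offs[ord <= 2, , drop = FALSE],
         "26" = offs,
         stopf("connectivity must be 6, 18 or 26"))
}

#' Label 3-D connected components
#'
#' Vectorized min-label propagation over the foreground voxels: every
#' foreground voxel starts with its own label and repeatedly adopts the
#' smallest label in its neighborhood until a fixed point. Components are
#' renumbered 1..k in order of their first voxel (ascending linear index).
#'
#' @param mask 3-D logical array.
#' @param connectivity 6 (faces), 18 (faces + edges) or 26 (full), applied
#'   in voxel space (anisotropy does not change adjacency).
#' @return integer array of component labels, 0 for background.
#' @export
label_components <- function(mask, connectivity = 26L) {
  check_mask(mask)
  dims <- dim(mask)
  out <- array(0L, dims)
  idx <- which(mask)
  if (length(idx) == 0L) return(out)
  coord <- arrayInd(idx, dims)
  pos <- integer(prod(dims))
  pos[idx] <- seq_along(idx)
  lab <- seq_along(idx)
  offs <- neighbor_offsets(connectivity)
  repeat {
    changed <- FALSE
    for (r in seq_len(nrow(offs))) {
      nz <- coord[, 1] + offs[r, 1]
      ny <- coord[, 2] + offs[r, 2]
      nx <- coord[, 3] + offs[r, 3]
      ok <- nz >= 1L & nz <= dims[1] & ny >= 1L & ny <= dims[2] &
        nx >= 1L & nx <= dims[3]
      if (!any(ok)) next
      nlin <- (nx[ok] - 1L) * dims[1] * dims[2] + (ny[ok] - 1L) * dims[1] +
        nz[ok]
      j <- pos[nlin]
      has <- j > 0L
      if (!any(has)) next
      i <- which(ok)[has]
      newlab <- pmin(lab[i], lab[j[has]])
      if (any(newlab < lab[i])) {
        lab[i] <- newlab
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  first <- !duplicated(lab)
  relab <- integer(length(idx))
  relab[lab[first]] <- seq_len(sum(first))
  out[idx] <- relab[lab]
  out
}

#' Center point of a voxel component via the Euclidean distance transform
#'
#' Computes the anisotropic Euclidean distance transform of the component's
#' binary mask (distance from each component voxel center to the nearest
#' background voxel center, in um; everything outside the component is
#' background) and returns the centroid of the voxels attaining the maximal
#' distance, converted to physical um. Exact: distances are evaluated
#' against all background voxels in the component's bounding box padded by
#' one voxel, which always contains a nearest background voxel.
#'
#' @param voxel_set integer matrix of 1-based `(z, y, x)` voxel indices.
#' @param voxel_size `(dz, dy, dx)` in um.
#' @return numeric `(z, y, x)` center in um.
#' @export
centrosome_center <- function(voxel_set, voxel_size) {
  voxel_size <- check_voxel_size(voxel_size)
  if (!is.matrix(voxel_set) || ncol(voxel_set) != 3L || nrow(voxel_set) == 0L)
    stopf("voxel_set must be a non-empty (z, y, x) index matrix")
  if (nrow(voxel_set) == 1L)
    return(stats::setNames(as.numeric((voxel_set[1, ] - 1) * voxel_size),
                           c("z", "y", "x")))
  lo <- apply(voxel_set, 2, min) - 1L
  hi <- apply(voxel_set, 2, max) + 1L
  dl <- hi - lo + 1L
  local <- sweep(voxel_set, 2, lo - 1L)  # 1-based within padded box
  box <- array(FALSE, dl)
  box[local] <- TRUE
  bg <- which(!box)
  bgc <- arrayInd(bg, dl)
  fgp <- sweep(local - 1, 2, voxel_size, `*`)
  bgp <- sweep(bgc - 1, 2, voxel_size, `*`)
  nf <- nrow(fgp)
  dt2 <- rep(Inf, nf)
  chunk <- max(1L, floor(2e6 / nf))
  for (s in seq(1L, nrow(bgp), by = chunk)) {
    e <- min(s + chunk - 1L, nrow(bgp))
    d2 <- outer(fgp[, 1], bgp[s:e, 1], `-`)^2 +
      outer(fgp[, 2], bgp[s:e, 2], `-`)^2 +
      outer(fgp[, 3], bgp[s:e, 3], `-`)^2
    dt2 <- pmin(dt2, d2[cbind(seq_len(nf), max.col(-d2, "first"))])
  }
  dt <- sqrt(dt2)
  sel <- dt >= max(dt) - 1e-9
  ctr_local <- colMeans(local[sel, , drop = FALSE])
  # local 1-based -> global 1-based is (+ lo - 1); physical is (idx - 1) * d
  stats::setNames(as.numeric((ctr_local + lo - 2) * voxel_size),
                  c("z", "y", "x"))
}

#' Detect centrosomes in the gamma-tubulin channel
#'
#' A centrosome is a 3-D connected component of at least `min_voxels`
#' voxels, within the ROI, whose gamma-tubulin intensity is at or above
#' `t_tub_min`. Each component gets a physical center point from the
#' distance-transform rule of [centrosome_center()]. Components touching
#' the ROI border (or the stack edge) are kept but flagged.
#'
#' @param tub 3-D gamma-tubulin intensity array.
#' @param roi_mask 3-D logical ROI mask.
#' @param t_tub_min minimum centrosome intensity; should exceed the
#'   cytoplasmic background threshold used for nuclear exclusion.
#' @param min_voxels minimum component size (default 8, the "at least eight
#'   connected pixels" rule).
#' @param connectivity 6, 18 or 26 (default 26).
#' @param voxel_size `(dz, dy, dx)` in um.
#' @return list of `centrosome` objects sorted by descending size (ties by
#'   ascending `(z, y, x)` of the first voxel), each with elements
#'   `voxel_set` (1-based index matrix), `center` (um), `size_voxels`,
#'   `peak_intensity`, `border_touching`. An empty list when nothing
#'   qualifies.
#' @export
detect_centrosomes <- function(tub, roi_mask, t_tub_min, min_voxels = 8L,
                               connectivity = 26L, voxel_size) {
  check_mask(roi_mask, "roi_mask")
  if (min_voxels < 1L) stopf("min_voxels must be >= 1")
  voxel_size <- check_voxel_size(voxel_size)
  fg <- roi_mask & (tub >= t_tub_min)
  labs <- label_components(fg, connectivity)
  k <- max(labs)
  if (k == 0L) return(list())
  dims <- dim(fg)
  offs6 <- neighbor_offsets(6L)
  comps <- list()
  for (ci in seq_len(k)) {
    vox <- arrayInd(which(labs == ci), dims)
    if (nrow(vox) < min_voxels) next
    # border: any 6-neighbor outside the array or outside the ROI
    border <- FALSE
    for (r in seq_len(nrow(offs6))) {
      off <- offs6[r, ]
      nz <- vox[, 1] + off[1]; ny <- vox[, 2] + off[2]; nx <- vox[, 3] + off[3]
      out_arr <- nz < 1L | nz > dims[1] | ny < 1L | ny > dims[2] |
        nx < 1L | nx > dims[3]
      if (any(out_arr)) { border <- TRUE; break }
      if (any(!roi_mask[cbind(nz, ny, nx)])) { border <- TRUE; break }
    }
    ordv <- order(vox[, 1], vox[, 2], vox[, 3])
    vox <- vox[ordv, , drop = FALSE]
    comps[[length(comps) + 1L]] <- structure(
      list(voxel_set = vox,
           center = centrosome_center(vox, voxel_size),
           size_voxels = nrow(vox),
           peak_intensity = max(tub[labs == ci]),
           border_touching = border),
      class = "centrosome")
  }
  if (length(comps) == 0L) return(list())
  sz <- vapply(comps, `[[`, integer(1), "size_voxels")
  fz <- t(vapply(comps, function(cc) cc$voxel_set[1, ], integer(3)))
  comps[order(-sz, fz[, 1], fz[, 2], fz[, 3])]
}

#' @export
print.centrosome <- function(x, ...) {
  cat(sprintf("centrosome: %d voxels, peak %g, center (z,y,x) um = %s%s\n",
              x$size_voxels, x$peak_intensity,
              paste(sprintf("%.3f", x$center), collapse = ", "),
              if (x$border_touching) " [border]" else ""))
  invisible(x)
}
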