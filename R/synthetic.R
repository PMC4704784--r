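#' Specification of a synthetic ovary stack
#'
#' Defines the geometry, intensities and noise of a generated multi-channel
#' stack. Defaults emulate the imaged material: mid-zygotene nest cells of
#' ~12 um diameter, cleft-stage oocytes of 17-25 um (default 20), a z-step
#' of 0.53 um, 12-bit intensities, a compact perinuclear gamma-tubulin
#' punctum, DAPI-bright nuclei (spherical, or cleft-indented for the
#' oocyte), and an experimental channel whose intensity is uniform or
#' enriched by a known factor around the centrosome. The enrichment field
#' is flat within `enrichment_radius` of the centrosome and falls off as a
#' Gaussian shoulder of scale `enrichment_sigma` beyond it, emulating a
#' precursor aggregate that fills the cleft (or hugs the centrosome in
#' nests) rather than a point source.
#'
#' @param mode `"oocyte_cleft"`, `"uniform_control"`, `"nest"` or
#'   `"dispersed_control"`. The controls render the experimental channel
#'   spatially uniform (enrichment factor 1), the dispersed control being
#'   the nocodazole-like nest null.
#' @param n_cells number of cells (nest modes; default 8).
#' @param cell_diameter cell diameter in um (default 20 for cleft modes,
#'   12 for nest modes).
#' @param nucleus_fraction nucleus radius as a fraction of the cell radius
#'   (default 0.5).
#' @param cleft_depth depth of the spherical-cap nuclear indentation in um
#'   (default 3 for cleft modes, 0 = spherical nucleus for nest modes).
#' @param enrichment_factor ratio of near-centrosome to far cytoplasmic
#'   experimental intensity (>= 0; 1 = uniform).
#' @param enrichment_radius,enrichment_sigma flat-core radius and shoulder
#'   scale of the enrichment field, um (cleft defaults 4.5 / 0.8; nest
#'   defaults 1.1 / 0.3).
#' @param base_intensity cytoplasmic experimental signal (counts).
#' @param exp_offset experimental background present everywhere in the
#'   tissue, including nuclei (counts); this is what the nuclear-mean
#'   subtraction removes.
#' @param dapi_nuclear,dapi_background,tub_background,tub_nuclear,punctum_intensity
#'   channel levels in counts.
#' @param punctum_radius centrosome punctum radius in um (default 0.7,
#'   comfortably above the 8-voxel detection rule at the default grid).
#' @param missing_punctum integer indices of cells rendered without a
#'   centrosome (and without an enrichment field); nest modes only.
#' @param packing_jitter random displacement of nest cell centers, as a
#'   fraction of the diameter (default 0.05, which always packs; larger
#'   values can make packing fail after bounded attempts).
#' @param noise list `(poisson = TRUE/FALSE, gaussian_sd = counts)`.
#' @param voxel_size `(dz, dy, dx)` um; default `(0.53, 0.2, 0.2)`.
#' @param bit_depth intensity bit depth (default 12; values are clipped).
#' @param margin empty border around the cells, um.
#' @param seed default RNG seed for the generators.
#' @return a `synthetic_spec` list.
#' @export
synthetic_spec <- function(mode = c("oocyte_cleft", "uniform_control",
                                    "nest", "dispersed_control"),
                           n_cells = NULL, cell_diameter = NULL,
                           nucleus_fraction = 0.5, cleft_depth = NULL,
                           enrichment_factor = NULL,
                           enrichment_radius = NULL, enrichment_sigma = NULL,
                           base_intensity = 600, exp_offset = 100,
                           dapi_nuclear = 2500, dapi_background = 100,
                           tub_background = 150, tub_nuclear = 20,
                           punctum_intensity = 3000, punctum_radius = 0.7,
                           missing_punctum = integer(0),
                           packing_jitter = 0.05,
                           noise = list(poisson = TRUE, gaussian_sd = 10),
                           voxel_size = c(0.53, 0.2, 0.2), bit_depth = 12L,
                           margin = 2, seed = 1L) {
  mode <- match.arg(mode)
  nestlike <- mode %in% c("nest", "dispersed_control")
  n_cells <- n_cells %||% if (nestlike) 8L else 1L
  cell_diameter <- cell_diameter %||% if (nestlike) 12 else 20
  cleft_depth <- cleft_depth %||% if (nestlike) 0 else 3
  enrichment_factor <- enrichment_factor %||%
    switch(mode, oocyte_cleft = 2, nest = 1.6, 1)
  if (mode %in% c("uniform_control", "dispersed_control"))
    enrichment_factor <- 1
  enrichment_radius <- enrichment_radius %||% if (nestlike) 1.1 else 4.5
  enrichment_sigma <- enrichment_sigma %||% if (nestlike) 0.3 else 0.8
  if (enrichment_factor < 0) stopf("enrichment_factor must be >= 0")
  if (cell_diameter <= 0) stopf("cell_diameter must be > 0")
  if (!nestlike && n_cells != 1L)
    stopf("oocyte modes render a single cell")
  structure(list(mode = mode, n_cells = as.integer(n_cells),
                 cell_diameter = cell_diameter,
                 nucleus_fraction = nucleus_fraction,
                 cleft_depth = cleft_depth,
                 enrichment_factor = enrichment_factor,
                 enrichment_radius = enrichment_radius,
                 enrichment_sigma = enrichment_sigma,
                 base_intensity = base_intensity, exp_offset = exp_offset,
                 dapi_nuclear = dapi_nuclear,
                 dapi_background = dapi_background,
                 tub_background = tub_background, tub_nuclear = tub_nuclear,
                 punctum_intensity = punctum_intensity,
                 punctum_radius = punctum_radius,
                 missing_punctum = as.integer(missing_punctum),
                 packing_jitter = packing_jitter,
                 noise = noise, voxel_size = check_voxel_size(voxel_size),
                 bit_depth = as.integer(bit_depth), margin = margin,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Default analysis configuration for synthetic stacks
#'
#' Thresholds matched to the default [synthetic_spec()] intensity levels:
#' DAPI 1200 (between the nuclear 2500 and background 100 levels),
#' gamma-tubulin background 80 (between nuclear ~20 and cytoplasmic ~150),
#' centrosome minimum 1500 (between the ~150 background and the 3000
#' punctum).
#'
#' @param mode `"cleft"` or `"nest"`.
#' @param ... overrides passed to [analysis_config()].
#' @return an [analysis_config()].
#' @export
synthetic_default_config <- function(mode, ...) {
  args <- list(...)
  defaults <- list(mode = mode, t_dapi = 1200, t_tub_low = 80,
                   t_tub_min = 1500)
  do.call(analysis_config, utils::modifyList(defaults, args))
}

## squared physical distance of every voxel center to a point (z,y,x) um
dist2_field <- function(dims, voxel_size, point) {
  zc <- ((0:(dims[1] - 1)) * voxel_size[1] - point[1])^2
  yc <- ((0:(dims[2] - 1)) * voxel_size[2] - point[2])^2
  xc <- ((0:(dims[3] - 1)) * voxel_size[3] - point[3])^2
  array(rep(zc, times = dims[2] * dims[3]) +
          rep(rep(yc, each = dims[1]), times = dims[3]) +
          rep(xc, each = dims[1] * dims[2]),
        dims)
}

## flat-core enrichment profile: 1 inside r_core, Gaussian shoulder beyond
enrichment_profile <- function(d, r_core, sigma) {
  excess <- pmax(d - r_core, 0)
  exp(-excess^2 / (2 * sigma^2))
}

random_unit_vector <- function() {
  v <- stats::rnorm(3)
  v / sqrt(sum(v^2))
}

## 24-gon outline of a circle, drawn half a pixel inside the radius so the
## rasterized ROI stays within the cell (a conservative hand-drawn outline)
circle_polygon <- function(center_yx_um, radius_um, voxel_size, n = 24L) {
  r_px <- (radius_um / voxel_size[3] - 0.5) / cos(pi / n)
  if (r_px <= 0.5) return(NULL)
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  list(x = center_yx_um[2] / voxel_size[3] + r_px * cos(th),
       y = center_yx_um[1] / voxel_size[2] + r_px * sin(th))
}

apply_noise_and_quantize <- function(clean, noise, bit_depth) {
  x <- as.numeric(clean)
  if (isTRUE(noise$poisson)) x <- stats::rpois(length(x), x)
  sdg <- noise$gaussian_sd %||% 0
  if (sdg > 0) x <- x + stats::rnorm(length(x), 0, sdg)
  array(pmin(pmax(round(x), 0), 2^bit_depth - 1), dim(clean))
}

## shared renderer: cells described by centers/direction vectors, channels
## painted over `region` (the cytoplasmic continuum), nuclei on top
render_cells <- function(spec, dims, centers, dirs, with_punctum) {
  vs <- spec$voxel_size
  R <- spec$cell_diameter / 2
  Rn <- R * spec$nucleus_fraction
  n <- nrow(centers)
  nucleus <- array(FALSE, dims)
  punctum <- array(FALSE, dims)
  cent_pos <- matrix(NA_real_, n, 3)
  dmin2 <- NULL  # squared distance to nearest active centrosome
  for (i in seq_len(n)) {
    nc <- centers[i, ]
    d2n <- dist2_field(dims, vs, nc)
    nuc_i <- d2n <= Rn^2
    if (spec$cleft_depth > 0) {
      indent_c <- nc + dirs[i, ] * (2 * Rn - spec$cleft_depth)
      nuc_i <- nuc_i & (dist2_field(dims, vs, indent_c) > Rn^2)
    }
    nucleus <- nucleus | nuc_i
    if (with_punctum[i]) {
      cp <- nc + dirs[i, ] * (Rn - spec$cleft_depth + 1.0)
      cent_pos[i, ] <- cp
      d2c <- dist2_field(dims, vs, cp)
      punctum <- punctum | (d2c <= spec$punctum_radius^2)
      dmin2 <- if (is.null(dmin2)) d2c else pmin(dmin2, d2c)
    }
  }
  list(nucleus = nucleus, punctum = punctum, cent_pos = cent_pos,
       dmin2 = dmin2, Rn = Rn)
}

compose_channels <- function(spec, dims, region, geo) {
  cyto <- region & !geo$nucleus
  dapi <- array(spec$dapi_background, dims)
  dapi[geo$nucleus] <- spec$dapi_nuclear
  tub <- array(spec$tub_background, dims)
  tub[geo$nucleus] <- spec$tub_nuclear
  tub[geo$punctum & cyto] <- spec$punctum_intensity
  expch <- array(spec$exp_offset, dims)
  sig <- array(0, dims)
  if (!is.null(geo$dmin2) && spec$enrichment_factor != 1) {
    g <- enrichment_profile(sqrt(geo$dmin2), spec$enrichment_radius,
                            spec$enrichment_sigma)
    sig <- spec$base_intensity * (1 + (spec$enrichment_factor - 1) * g)
  } else {
    sig <- array(spec$base_intensity, dims)
  }
  expch[cyto] <- spec$exp_offset + sig[cyto]
  list(dapi = dapi, gamma_tubulin = tub, experimental = expch, cyto = cyto)
}

finish_stack <- function(spec, chans) {
  channels <- list(
    experimental = apply_noise_and_quantize(chans$experimental, spec$noise,
                                            spec$bit_depth),
    gamma_tubulin = apply_noise_and_quantize(chans$gamma_tubulin, spec$noise,
                                             spec$bit_depth),
    dapi = apply_noise_and_quantize(chans$dapi, spec$noise, spec$bit_depth))
  volume_stack(channels, spec$voxel_size, spec$bit_depth)
}

#' Generate a synthetic cleft-stage oocyte
#'
#' Renders one spherical oocyte: a DAPI-bright nucleus carrying a
#' spherical-cap indentation (the nuclear cleft) of depth `cleft_depth`, a
#' compact gamma-tubulin punctum at the cleft mouth, and an experimental
#' channel enriched by `enrichment_factor` around the punctum. Poisson then
#' Gaussian noise, 12-bit clipping. The ROI polygon outlines the cell on
#' every slice. All randomness (cleft orientation, noise) comes from one
#' seeded stream, so output is bit-reproducible.
#'
#' @param spec a [synthetic_spec()] with an oocyte mode.
#' @param seed RNG seed (default `spec$seed`).
#' @return list with `stack` ([volume_stack()]), `rois` ([roi_set()]) and
#'   `truth` (nucleus mask, cell/centrosome geometry in um, the generative
#'   enrichment factor, and the pre-noise experimental channel).
#' @export
generate_oocyte <- function(spec, seed = spec$seed) {
  if (!spec$mode %in% c("oocyte_cleft", "uniform_control"))
    stopf("spec$mode must be oocyte_cleft or uniform_control")
  vs <- spec$voxel_size
  extent <- spec$cell_diameter + 2 * spec$margin
  dims <- as.integer(ceiling(extent / vs)) + 1L
  center <- (dims - 1) * vs / 2
  R <- spec$cell_diameter / 2
  if (any(spec$cell_diameter > (dims - 1) * vs))
    stopf("cell larger than the requested grid", class = "bbenrich_sizing_error")
  withr::with_seed(seed, {
    dir <- random_unit_vector()
    geo <- render_cells(spec, dims, matrix(center, 1), matrix(dir, 1), TRUE)
    cellmask <- dist2_field(dims, vs, center) <= R^2
    polys <- list()
    for (z in seq_len(dims[1])) {
      h2 <- R^2 - ((z - 1) * vs[1] - center[1])^2
      if (h2 <= 0) next
      p <- circle_polygon(center[2:3], sqrt(h2), vs)
      if (!is.null(p)) polys[[length(polys) + 1L]] <-
          list(z = z - 1L, x = p$x, y = p$y)
    }
    unit <- roi_unit("oocyte_1", "oocyte", polys)
    region <- rasterize_unit(unit, dims) & cellmask
    chans <- compose_channels(spec, dims, region, geo)
    stack <- finish_stack(spec, chans)
  })
  list(stack = stack,
       rois = roi_set(list(unit)),
       truth = list(mode = spec$mode,
                    cell_center = center, cell_radius = R,
                    nucleus_mask = geo$nucleus,
                    cleft_direction = dir,
                    centrosome_center = geo$cent_pos[1, ],
                    enrichment_factor = spec$enrichment_factor,
                    clean_experimental = chans$experimental,
                    cytoplasm_mask = chans$cyto))
}

#' Generate a synthetic zygotene nest
#'
#' Packs `n_cells` touching cells of stage diameter (centers jittered on a
#' cubic grid, pairwise distance at least one diameter), each with a
#' spherical nucleus and one perinuclear centrosome punctum, inside a
#' single nest ROI. The cytoplasmic intensity continuum fills the whole ROI
#' (cells in a nest are tightly adjacent with nothing between them), and
#' each active centrosome contributes its own enrichment field. The
#' dispersed control renders the experimental channel uniformly, emulating
#' the nocodazole-induced radial expansion.
#'
#' @param spec a [synthetic_spec()] with a nest mode.
#' @param seed RNG seed (default `spec$seed`).
#' @return as [generate_oocyte()]; `truth$centrosome_centers` is an
#'   `n_cells x 3` matrix in um (NA rows for cells in `missing_punctum`).
#' @export
generate_nest <- function(spec, seed = spec$seed) {
  if (!spec$mode %in% c("nest", "dispersed_control"))
    stopf("spec$mode must be nest or dispersed_control")
  if (spec$n_cells < 2L) stopf("nest needs n_cells >= 2")
  vs <- spec$voxel_size
  D <- spec$cell_diameter
  side <- ceiling(spec$n_cells^(1 / 3))
  spacing <- 1.12 * D
  withr::with_seed(seed, {
    centers <- NULL
    for (attempt in 1:50) {
      grid <- as.matrix(expand.grid(z = 0:(side - 1), y = 0:(side - 1),
                                    x = 0:(side - 1)))[seq_len(spec$n_cells), ,
                                                       drop = FALSE]
      cand <- grid * spacing +
        matrix(stats::runif(3 * spec$n_cells, -spec$packing_jitter * D,
                            spec$packing_jitter * D), ncol = 3)
      if (spec$n_cells == 1L || min(stats::dist(cand)) >= D) {
        centers <- cand
        break
      }
    }
    if (is.null(centers))
      stopf("failed to pack %d non-overlapping cells; retry with a new seed",
            spec$n_cells, class = "bbenrich_packing_error")
    centers <- sweep(centers, 2, apply(centers, 2, min) -
                       (D / 2 + spec$margin))
    extent <- apply(centers, 2, max) + D / 2 + spec$margin
    dims <- as.integer(ceiling(extent / vs)) + 1L
    dirs <- t(vapply(seq_len(spec$n_cells),
                     function(i) random_unit_vector(), numeric(3)))
    with_punctum <- !(seq_len(spec$n_cells) %in% spec$missing_punctum)
    geo <- render_cells(spec, dims, centers, dirs, with_punctum)
    # nest ROI: per-slice circle enclosing every cell's cross-section
    cxy <- colMeans(centers)[2:3]
    polys <- list()
    for (z in seq_len(dims[1])) {
      zp <- (z - 1) * vs[1]
      rmax <- 0
      for (i in seq_len(spec$n_cells)) {
        h2 <- (D / 2)^2 - (zp - centers[i, 1])^2
        if (h2 <= 0) next
        rmax <- max(rmax, sqrt(sum((centers[i, 2:3] - cxy)^2)) + sqrt(h2))
      }
      if (rmax <= 0) next
      p <- circle_polygon(cxy, rmax + 0.5 * vs[3], vs, n = 36L)
      if (!is.null(p)) polys[[length(polys) + 1L]] <-
          list(z = z - 1L, x = p$x, y = p$y)
    }
    unit <- roi_unit("nest_1", "nest", polys)
    region <- rasterize_unit(unit, dims)
    chans <- compose_channels(spec, dims, region, geo)
    stack <- finish_stack(spec, chans)
  })
  list(stack = stack,
       rois = roi_set(list(unit)),
       truth = list(mode = spec$mode,
                    cell_centers = centers, cell_radius = D / 2,
                    nucleus_mask = geo$nucleus,
                    centrosome_centers = geo$cent_pos,
                    enrichment_factor = spec$enrichment_factor,
                    clean_experimental = chans$experimental,
                    cytoplasm_mask = chans$cyto))
}

#' Generate a punctate channel pair with known overlap
#'
#' Renders two spot channels on a thin stack sharing a known fraction of
#' spot positions: the colocalization test bed. Non-shared spots of the
#' second channel are kept away from every first-channel spot so that
#' `overlap_fraction = 0` is genuinely disjoint.
#'
#' @param overlap_fraction fraction of shared spot positions in `[0, 1]`.
#' @param n_puncta spots per channel (default 40).
#' @param dims stack dimensions (default `c(1, 96, 96)`).
#' @param amplitude,offset spot peak and background (counts).
#' @param spot_sigma_px spot Gaussian width in pixels.
#' @param noise as in [synthetic_spec()].
#' @param bit_depth intensity bit depth (default 12).
#' @param seed RNG seed.
#' @return list `ch1`, `ch2` (3-D arrays), `mask` (all TRUE), `truth`
#'   (positions and the generative overlap fraction).
#' @export
generate_coloc_pair <- function(overlap_fraction, n_puncta = 40L,
                                dims = c(1L, 96L, 96L), amplitude = 1500,
                                offset = 50, spot_sigma_px = 1.5,
                                noise = list(poisson = TRUE, gaussian_sd = 5),
                                bit_depth = 12L, seed = 1L) {
  if (overlap_fraction < 0 || overlap_fraction > 1)
    stopf("overlap_fraction must be in [0, 1]")
  pad <- ceiling(4 * spot_sigma_px) + 2
  render <- function(pos) {
    a <- array(0, dims)
    for (k in seq_len(nrow(pos))) {
      yy <- outer((seq_len(dims[2]) - pos[k, 1])^2,
                  (seq_len(dims[3]) - pos[k, 2])^2, `+`)
      a[pos[k, 3], , ] <- a[pos[k, 3], , ] +
        amplitude * exp(-yy / (2 * spot_sigma_px^2))
    }
    a + offset
  }
  withr::with_seed(seed, {
    rpos <- function(n) cbind(stats::runif(n, pad, dims[2] - pad),
                              stats::runif(n, pad, dims[3] - pad),
                              sample.int(dims[1], n, replace = TRUE))
    p1 <- rpos(n_puncta)
    n_shared <- round(overlap_fraction * n_puncta)
    fresh <- matrix(numeric(0), 0, 3)
    guard <- 0L
    while (nrow(fresh) < n_puncta - n_shared && guard < 200L) {
      cand <- rpos(n_puncta)
      d <- sqrt(outer(cand[, 1], p1[, 1], `-`)^2 +
                  outer(cand[, 2], p1[, 2], `-`)^2)
      keep <- apply(d, 1, min) > 6 * spot_sigma_px
      fresh <- rbind(fresh, cand[keep, , drop = FALSE])
      guard <- guard + 1L
    }
    fresh <- fresh[seq_len(n_puncta - n_shared), , drop = FALSE]
    p2 <- rbind(p1[seq_len(n_shared), , drop = FALSE], fresh)
    ch1 <- apply_noise_and_quantize(render(p1), noise, bit_depth)
    ch2 <- apply_noise_and_quantize(render(p2), noise, bit_depth)
  })
  list(ch1 = ch1, ch2 = ch2, mask = array(TRUE, dims),
       truth = list(overlap_fraction = overlap_fraction,
                    positions_ch1 = p1, positions_ch2 = p2))
}
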