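#' Analysis configuration for cleft / nest enrichment runs
#'
#' Bundles the thresholds, radii and options of one analysis run. Radii
#' default per mode to the published procedure: cleft analysis draws a
#' 4.8 um sphere (centrosome-adjacent, the in-cleft cytoplasm) and a 6.0 um
#' sphere (everything outside is centrosome-nonadjacent); nest analysis
#' uses 1.2 / 2.4 um around every centrosome. The annular shell between the
#' radii belongs to neither region.
#'
#' @param mode `"cleft"` or `"nest"`.
#' @param t_dapi DAPI threshold defining nuclei.
#' @param t_tub_low gamma-tubulin background threshold (nuclei lie below it).
#' @param t_tub_min minimum gamma-tubulin intensity of a centrosome voxel;
#'   must exceed `t_tub_low`.
#' @param min_centrosome_voxels minimum connected-component size (default 8).
#' @param r_adjacent,r_nonadjacent sphere radii in um; defaults by mode
#'   (cleft 4.8 / 6.0, nest 1.2 / 2.4).
#' @param connectivity component connectivity, 6/18/26 (default 26).
#' @param threshold_method `"manual"` (thresholds as given, the published
#'   procedure) or `"automatic"` (between-class variance via
#'   [auto_threshold()] where a threshold is `NA`).
#' @param rng_seed integer seed recorded in run manifests.
#' @return an `analysis_config` list.
#' @export
analysis_config <- function(mode = c("cleft", "nest"),
                            t_dapi = NA_real_, t_tub_low = NA_real_,
                            t_tub_min = NA_real_,
                            min_centrosome_voxels = 8L,
                            r_adjacent = NULL, r_nonadjacent = NULL,
                            connectivity = 26L,
                            threshold_method = c("manual", "automatic"),
                            rng_seed = 1L) {
  mode <- match.arg(mode)
  threshold_method <- match.arg(threshold_method)
  r_adjacent <- r_adjacent %||% if (mode == "cleft") 4.8 else 1.2
  r_nonadjacent <- r_nonadjacent %||% if (mode == "cleft") 6.0 else 2.4
  if (r_adjacent >= r_nonadjacent)
    stopf("r_adjacent (%g) must be smaller than r_nonadjacent (%g)",
          r_adjacent, r_nonadjacent)
  if (min_centrosome_voxels < 1L) stopf("min_centrosome_voxels must be >= 1")
  if (is.finite(t_tub_min) && is.finite(t_tub_low) && t_tub_min <= t_tub_low)
    stopf("t_tub_min must exceed t_tub_low")
  structure(list(mode = mode, t_dapi = t_dapi, t_tub_low = t_tub_low,
                 t_tub_min = t_tub_min,
                 min_centrosome_voxels = as.integer(min_centrosome_voxels),
                 r_adjacent = r_adjacent, r_nonadjacent = r_nonadjacent,
                 connectivity = as.integer(connectivity),
                 threshold_method = threshold_method,
                 rng_seed = as.integer(rng_seed)),
            class = "analysis_config")
}

#' Partition cytoplasm into centrosome-adjacent / shell / nonadjacent
#'
#' For every cytoplasmic voxel the physical distance `d` to the nearest
#' centrosome center decides its region: adjacent iff `d <= r_adjacent`,
#' nonadjacent iff `d > r_nonadjacent`, shell otherwise. The shell is
#' reported but excluded from the enrichment ratio.
#'
#' @param cytoplasm 3-D logical cytoplasm mask.
#' @param centers numeric matrix of centrosome centers, one `(z, y, x)` um
#'   row per centrosome.
#' @param r_adjacent,r_nonadjacent radii in um, `r_adjacent < r_nonadjacent`.
#' @param voxel_size `(dz, dy, dx)` in um.
#' @return a `region_partition` list: logical masks `adjacent`, `shell`,
#'   `nonadjacent`; `centers_used`; the radii.
#' @export
partition_cytoplasm <- function(cytoplasm, centers, r_adjacent, r_nonadjacent,
                                voxel_size) {
  check_mask(cytoplasm, "cytoplasm")
  voxel_size <- check_voxel_size(voxel_size)
  if (is.null(dim(centers))) centers <- matrix(centers, nrow = 1)
  if (nrow(centers) == 0L)
    stopf("no centrosome centers supplied", class = "bbenrich_no_centrosome")
  if (r_adjacent >= r_nonadjacent)
    stopf("r_adjacent must be smaller than r_nonadjacent")
  dims <- dim(cytoplasm)
  idx <- which(cytoplasm)
  ind <- arrayInd(idx, dims)
  d2min <- rep(Inf, length(idx))
  for (r in seq_len(nrow(centers)))
    d2min <- pmin(d2min, dist2_to_point(ind, centers[r, ], voxel_size))
  d <- sqrt(d2min)
  adjacent <- shell <- nonadjacent <- array(FALSE, dims)
  adjacent[idx[d <= r_adjacent]] <- TRUE
  nonadjacent[idx[d > r_nonadjacent]] <- TRUE
  shell[idx[d > r_adjacent & d <= r_nonadjacent]] <- TRUE
  structure(list(adjacent = adjacent, shell = shell,
                 nonadjacent = nonadjacent, centers_used = centers,
                 r_adjacent = r_adjacent, r_nonadjacent = r_nonadjacent),
            class = "region_partition")
}

#' Raw regional means of the experimental stain
#'
#' Arithmetic mean of the raw experimental intensities over the nuclear,
#' centrosome-adjacent and centrosome-nonadjacent masks. Empty regions give
#' `NA` with a QC flag.
#'
#' @param experimental 3-D intensity array of the experimental stain.
#' @param masks a [region_masks()] object.
#' @param partition a [partition_cytoplasm()] result.
#' @return list with `mean_nuclear`, `mean_adjacent`, `mean_nonadjacent`,
#'   voxel counts, and `qc_flags`.
#' @export
regional_means <- function(experimental, masks, partition) {
  qc <- character(0)
  m <- function(mask, what) {
    if (!any(mask)) {
      qc <<- c(qc, paste0("empty_region_", what))
      return(NA_real_)
    }
    mean(experimental[mask])
  }
  list(mean_nuclear = m(masks$nuclear, "nuclear"),
       mean_adjacent = m(partition$adjacent, "adjacent"),
       mean_nonadjacent = m(partition$nonadjacent, "nonadjacent"),
       n_nuclear = sum(masks$nuclear),
       n_adjacent = sum(partition$adjacent),
       n_shell = sum(partition$shell),
       n_nonadjacent = sum(partition$nonadjacent),
       qc_flags = qc)
}

#' Background-normalized fold enrichment
#'
#' The nuclear mean is the between-stack background reference: normalized
#' intensities are `mean_X - mean_nuclear`, and the fold enrichment is
#' `(mean_adjacent - mean_nuclear) / (mean_nonadjacent - mean_nuclear)`.
#' The fold is undefined (NA, QC-flagged, never an error) when the
#' denominator is not positive. Negative normalized values are retained and
#' flagged.
#'
#' @param mean_adjacent,mean_nonadjacent,mean_nuclear raw regional means.
#' @return list with `norm_adjacent`, `norm_nonadjacent`, `fold`
#'   (`NA` if undefined) and `qc_flags`.
#' @export
fold_enrichment <- function(mean_adjacent, mean_nonadjacent, mean_nuclear) {
  qc <- character(0)
  if (anyNA(c(mean_adjacent, mean_nonadjacent, mean_nuclear)))
    return(list(norm_adjacent = NA_real_, norm_nonadjacent = NA_real_,
                fold = NA_real_, qc_flags = "undefined_fold"))
  na <- mean_adjacent - mean_nuclear
  nn <- mean_nonadjacent - mean_nuclear
  if (na < 0 || nn < 0) qc <- c(qc, "negative_norm")
  fold <- if (nn > 0) na / nn else NA_real_
  if (!is.finite(fold)) {
    fold <- NA_real_
    qc <- c(qc, "undefined_fold")
  }
  list(norm_adjacent = na, norm_nonadjacent = nn, fold = fold, qc_flags = qc)
}

resolve_thresholds <- function(stack, roi_mask, config) {
  t_dapi <- config$t_dapi; t_tub_low <- config$t_tub_low
  t_tub_min <- config$t_tub_min
  if (config$threshold_method == "automatic") {
    dapi <- get_channel(stack, "dapi")[roi_mask]
    tub <- get_channel(stack, "gamma_tubulin")[roi_mask]
    if (!is.finite(t_dapi)) t_dapi <- auto_threshold(dapi)
    if (!is.finite(t_tub_low)) t_tub_low <- auto_threshold(tub)
    if (!is.finite(t_tub_min))
      t_tub_min <- auto_threshold(tub[tub >= t_tub_low])
  }
  if (!all(is.finite(c(t_dapi, t_tub_low, t_tub_min))))
    stopf("manual threshold_method requires t_dapi, t_tub_low, t_tub_min",
          class = "bbenrich_config_error")
  list(t_dapi = t_dapi, t_tub_low = t_tub_low, t_tub_min = t_tub_min)
}

skipped_result <- function(unit, mode, qc) {
  structure(list(unit_id = unit$name, mode = mode, skipped = TRUE,
                 n_centrosomes = 0L,
                 mean_nuclear = NA_real_, mean_adjacent = NA_real_,
                 mean_nonadjacent = NA_real_, norm_adjacent = NA_real_,
                 norm_nonadjacent = NA_real_, fold = NA_real_,
                 n_nuclear = NA_integer_, n_adjacent = NA_integer_,
                 n_shell = NA_integer_, n_nonadjacent = NA_integer_,
                 qc_flags = qc),
            class = "enrichment_result")
}

analyze_unit <- function(stack, unit, config) {
  roi_mask <- rasterize_unit(unit, dim(stack))
  if (!any(roi_mask)) return(skipped_result(unit, config$mode, "empty_roi"))
  th <- resolve_thresholds(stack, roi_mask, config)
  masks <- region_masks(stack, roi_mask, th$t_dapi, th$t_tub_low)
  cents <- detect_centrosomes(get_channel(stack, "gamma_tubulin"), roi_mask,
                              th$t_tub_min, config$min_centrosome_voxels,
                              config$connectivity, stack$voxel_size)
  qc <- character(0)
  if (length(cents) == 0L)
    return(skipped_result(unit, config$mode, "no_centrosome"))
  if (config$mode == "cleft") {
    if (length(cents) > 1L) {
      qc <- c(qc, "multiple_centrosomes")
      warning(sprintf("unit '%s': %d centrosomes detected, using the largest",
                      unit$name, length(cents)), call. = FALSE)
    }
    used <- cents[1]
  } else {
    used <- cents
  }
  if (any(vapply(used, `[[`, logical(1), "border_touching")))
    qc <- c(qc, "border_touching")
  centers <- t(vapply(used, `[[`, numeric(3), "center"))
  part <- partition_cytoplasm(masks$cytoplasm, centers, config$r_adjacent,
                              config$r_nonadjacent, stack$voxel_size)
  rm_ <- regional_means(get_channel(stack, "experimental"), masks, part)
  fe <- fold_enrichment(rm_$mean_adjacent, rm_$mean_nonadjacent,
                        rm_$mean_nuclear)
  structure(list(unit_id = unit$name, mode = config$mode, skipped = FALSE,
                 n_centrosomes = length(cents),
                 mean_nuclear = rm_$mean_nuclear,
                 mean_adjacent = rm_$mean_adjacent,
                 mean_nonadjacent = rm_$mean_nonadjacent,
                 norm_adjacent = fe$norm_adjacent,
                 norm_nonadjacent = fe$norm_nonadjacent,
                 fold = fe$fold,
                 n_nuclear = rm_$n_nuclear, n_adjacent = rm_$n_adjacent,
                 n_shell = rm_$n_shell, n_nonadjacent = rm_$n_nonadjacent,
                 qc_flags = unique(c(qc, rm_$qc_flags, fe$qc_flags))),
            class = "enrichment_result")
}

#' Cleft analysis of a single oocyte
#'
#' Runs segmentation, centrosome detection, sphere partition (4.8 / 6.0 um
#' defaults) and background-normalized fold enrichment for one oocyte ROI.
#' Exactly one centrosome seeds the spheres: when several qualify the
#' largest is used and the unit is flagged `multiple_centrosomes`. Units
#' without a detectable centrosome are skipped with QC flag
#' `no_centrosome`.
#'
#' @param stack a [volume_stack()] with `experimental`, `gamma_tubulin` and
#'   `dapi` channels.
#' @param unit an oocyte [roi_unit()].
#' @param config an [analysis_config()] with `mode = "cleft"`.
#' @return an `enrichment_result`.
#' @export
analyze_cleft <- function(stack, unit, config) {
  if (config$mode != "cleft") stopf("config$mode must be 'cleft'")
  if (unit$kind != "oocyte")
    warning(sprintf("unit '%s' has kind '%s' but mode is cleft", unit$name,
                    unit$kind), call. = FALSE)
  analyze_unit(stack, unit, config)
}

#' Zygotene nest analysis (bulk)
#'
#' As [analyze_cleft()], but every detected centrosome seeds a sphere
#' (1.2 / 2.4 um defaults) and the cytoplasm of the whole nest is measured
#' in bulk, without separating individual cells: one result per nest ROI.
#'
#' @inheritParams analyze_cleft
#' @param unit a nest [roi_unit()].
#' @param config an [analysis_config()] with `mode = "nest"`.
#' @return an `enrichment_result`.
#' @export
analyze_nest <- function(stack, unit, config) {
  if (config$mode != "nest") stopf("config$mode must be 'nest'")
  if (unit$kind != "nest")
    warning(sprintf("unit '%s' has kind '%s' but mode is nest", unit$name,
                    unit$kind), call. = FALSE)
  analyze_unit(stack, unit, config)
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("enrichment_result '%s' [%s]%s\n", x$unit_id, x$mode,
              if (isTRUE(x$skipped)) " (skipped)" else ""))
  if (!isTRUE(x$skipped))
    cat(sprintf("  centrosomes: %d | means nuc/adj/nonadj: %.2f / %.2f / %.2f | fold: %s\n",
                x$n_centrosomes, x$mean_nuclear, x$mean_adjacent,
                x$mean_nonadjacent,
                if (is.na(x$fold)) "undefined" else sprintf("%.3f", x$fold)))
  if (length(x$qc_flags))
    cat("  qc:", paste(x$qc_flags, collapse = ", "), "\n")
  invisible(x)
}

#' @export
as.data.frame.enrichment_result <- function(x, ...) {
  data.frame(unit_id = x$unit_id, mode = x$mode,
             n_centrosomes = x$n_centrosomes,
             n_nuclear = x$n_nuclear, n_adjacent = x$n_adjacent,
             n_shell = x$n_shell, n_nonadjacent = x$n_nonadjacent,
             mean_nuclear = x$mean_nuclear, mean_adjacent = x$mean_adjacent,
             mean_nonadjacent = x$mean_nonadjacent,
             norm_adjacent = x$norm_adjacent,
             norm_nonadjacent = x$norm_nonadjacent,
             fold = x$fold,
             qc_flags = paste(x$qc_flags, collapse = ";"),
             stringsAsFactors = FALSE)
}

#' Group-level average fold enrichment
#'
#' Mean of the per-unit folds over units with a defined fold (units with an
#' undefined fold are dropped, matching per-unit scatter plots with
#' mean +/- SEM).
#'
#' @param results list of `enrichment_result` objects or a results
#'   data.frame with a `fold` column.
#' @return list with `mean_fold`, `sem`, `n_used`, `n_dropped`.
#' @export
average_fold <- function(results) {
  folds <- if (is.data.frame(results)) results$fold
  else vapply(results, `[[`, numeric(1), "fold")
  ok <- is.finite(folds)
  list(mean_fold = mean(folds[ok]),
       sem = stats::sd(folds[ok]) / sqrt(sum(ok)),
       n_used = sum(ok), n_dropped = sum(!ok))
}
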