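#' Write / read per-unit result tables
#'
#' CSV with a fixed, documented column order: `unit_id, mode,
#' n_centrosomes, n_nuclear, n_adjacent, n_shell, n_nonadjacent,
#' mean_nuclear, mean_adjacent, mean_nonadjacent, norm_adjacent,
#' norm_nonadjacent, fold, qc_flags`. Numerics are written with 17
#' significant digits so a read round-trips doubles exactly; an undefined
#' fold is written as an empty field (its QC flag carries the reason).
#'
#' @param results list of `enrichment_result` objects or a data.frame as
#'   produced by `as.data.frame()` on them.
#' @param path output CSV path.
#' @return `path` invisibly; `read_result_table` returns a data.frame.
#' @export
write_result_table <- function(results, path) {
  df <- if (is.data.frame(results)) results
  else do.call(rbind, lapply(results, as.data.frame))
  if (is.null(df) || nrow(df) == 0L) stopf("results must be non-empty")
  cols <- c("unit_id", "mode", "n_centrosomes", "n_nuclear", "n_adjacent",
            "n_shell", "n_nonadjacent", "mean_nuclear", "mean_adjacent",
            "mean_nonadjacent", "norm_adjacent", "norm_nonadjacent",
            "fold", "qc_flags")
  df <- df[, cols]
  out <- df
  num <- vapply(df, is.numeric, logical(1))
  out[num] <- lapply(df[num], format_full)
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE, na = "")
  invisible(path)
}

#' @rdname write_result_table
#' @export
read_result_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  intcols <- c("n_centrosomes", "n_nuclear", "n_adjacent", "n_shell",
               "n_nonadjacent")
  numcols <- c("mean_nuclear", "mean_adjacent", "mean_nonadjacent",
               "norm_adjacent", "norm_nonadjacent", "fold")
  for (cc in intcols) df[[cc]] <- as.integer(df[[cc]])
  for (cc in numcols) df[[cc]] <- as.numeric(ifelse(df[[cc]] == "", NA,
                                                    df[[cc]]))
  df
}

#' Run a full cleft / nest analysis from a configuration file
#'
#' Executes load -> ROI rasterization -> segmentation -> centrosome
#' detection -> sphere partition -> regional means -> fold for every ROI
#' unit, and writes `results.csv` plus a reproducibility manifest
#' `manifest.json` (full configuration, package version, seed) to the
#' output directory. Unit-level failures are flagged in the table, never
#' fatal. Reruns with identical configuration and inputs are byte-identical.
#'
#' @param config path to a JSON run configuration, or an equivalent list.
#'   Fields: `mode`; `stack` (TIFF path); optional `channel_roles`,
#'   `voxel_size`, `bit_depth` (else sidecar metadata); `rois` (JSON
#'   dialect `.json`, ImageJ `.zip`/directory); thresholds `t_dapi`,
#'   `t_tub_low`, `t_tub_min`; optional `r_adjacent`, `r_nonadjacent`,
#'   `min_centrosome_voxels`, `connectivity`, `threshold_method`, `seed`;
#'   `out_dir`.
#' @param out_dir overrides `config$out_dir`.
#' @return invisibly, the list of `enrichment_result` objects.
#' @export
run_analysis <- function(config, out_dir = NULL) {
  cfg <- if (is.character(config))
    jsonlite::read_json(config, simplifyVector = TRUE) else config
  out_dir <- out_dir %||% cfg$out_dir
  if (is.null(cfg$mode) || is.null(cfg$stack) || is.null(cfg$rois) ||
      is.null(out_dir))
    stopf("config needs mode, stack, rois and out_dir",
          class = "bbenrich_config_error")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stack <- load_stack(cfg$stack, cfg$channel_roles, cfg$voxel_size,
                      cfg$bit_depth)
  rois <- if (grepl("\\.json$", cfg$rois, ignore.case = TRUE))
    read_roi_json(cfg$rois)
  else read_imagej_rois(cfg$rois,
                        kind = if (cfg$mode == "nest") "nest" else "oocyte")
  acfg <- analysis_config(mode = cfg$mode,
                          t_dapi = cfg$t_dapi %||% NA_real_,
                          t_tub_low = cfg$t_tub_low %||% NA_real_,
                          t_tub_min = cfg$t_tub_min %||% NA_real_,
                          min_centrosome_voxels =
                            cfg$min_centrosome_voxels %||% 8L,
                          r_adjacent = cfg$r_adjacent,
                          r_nonadjacent = cfg$r_nonadjacent,
                          connectivity = cfg$connectivity %||% 26L,
                          threshold_method =
                            cfg$threshold_method %||% "manual",
                          rng_seed = cfg$seed %||% 1L)
  analyze <- if (acfg$mode == "cleft") analyze_cleft else analyze_nest
  results <- lapply(rois$units, function(u) {
    tryCatch(analyze(stack, u, acfg),
             error = function(e)
               skipped_result(u, acfg$mode,
                              paste0("error:", conditionMessage(e))))
  })
  write_result_table(results, file.path(out_dir, "results.csv"))
  manifest <- list(package = "bbenrich",
                   version = as.character(utils::packageVersion("bbenrich")),
                   config = unclass(acfg),
                   inputs = list(stack = cfg$stack, rois = cfg$rois),
                   n_units = length(results),
                   n_skipped = sum(vapply(results, function(r)
                     isTRUE(r$skipped), logical(1))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(results)
}

#' Two-group comparison by unpaired t test
#'
#' Two-tailed unpaired Student's t test (equal variances by default; Welch
#' with `var_equal = FALSE`) with the star coding `*` < 0.05, `**` < 0.01,
#' `****` < 0.0001, `ns` otherwise.
#'
#' @param values_a,values_b numeric vectors, each with at least two finite
#'   values.
#' @param var_equal pool variances (default TRUE).
#' @return a `group_comparison` list: per-group mean, SEM (SD/sqrt(n)) and
#'   n, `t_statistic`, `p_value`, `stars`, `method`.
#' @export
compare_groups <- function(values_a, values_b, var_equal = TRUE) {
  a <- values_a[is.finite(values_a)]
  b <- values_b[is.finite(values_b)]
  if (length(a) < 2L || length(b) < 2L)
    stopf("each group needs at least 2 finite values",
          class = "bbenrich_validation_error")
  tt <- stats::t.test(a, b, var.equal = var_equal)
  structure(list(mean_a = mean(a), mean_b = mean(b),
                 sem_a = stats::sd(a) / sqrt(length(a)),
                 sem_b = stats::sd(b) / sqrt(length(b)),
                 n_a = length(a), n_b = length(b),
                 t_statistic = unname(tt$statistic),
                 p_value = tt$p.value,
                 stars = significance_stars(tt$p.value),
                 method = if (var_equal) "student" else "welch"),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("group A: %.4g +/- %.4g (SEM), n = %d\n", x$mean_a, x$sem_a,
              x$n_a))
  cat(sprintf("group B: %.4g +/- %.4g (SEM), n = %d\n", x$mean_b, x$sem_b,
              x$n_b))
  cat(sprintf("two-tailed unpaired t (%s): t = %.4g, p = %.4g %s\n",
              x$method, x$t_statistic, x$p_value, x$stars))
  invisible(x)
}

#' Frequency table of scored categories per group
#'
#' Counts and percentages of per-unit category labels (e.g. normal /
#' affected scoring of nest phenotypes) per group, with a per-replicate
#' breakdown retained when a replicate column is present. Percentages per
#' group sum to 100.
#'
#' @param annotations data.frame with columns `group`, `category` and
#'   optionally `replicate`.
#' @param categories declared label set; any label outside it is an error.
#' @return a `frequency_table` data.frame (`group`, `category`, `count`,
#'   `percent`) with the per-replicate breakdown in
#'   `attr(, "by_replicate")`.
#' @export
tabulate_frequencies <- function(annotations,
                                 categories = sort(unique(annotations$category))) {
  if (!all(c("group", "category") %in% names(annotations)))
    stopf("annotations needs 'group' and 'category' columns")
  if (nrow(annotations) == 0L)
    stopf("annotations is empty", class = "bbenrich_validation_error")
  bad <- setdiff(unique(annotations$category), categories)
  if (length(bad))
    stopf("unknown category label(s): %s", paste(bad, collapse = ", "),
          class = "bbenrich_validation_error")
  groups <- unique(annotations$group)
  if (any(vapply(groups, function(g)
    sum(annotations$group == g) == 0L, logical(1))))
    stopf("empty group", class = "bbenrich_validation_error")
  tab <- table(factor(annotations$group, levels = groups),
               factor(annotations$category, levels = categories))
  df <- as.data.frame(tab, stringsAsFactors = FALSE)
  names(df) <- c("group", "category", "count")
  totals <- tapply(df$count, df$group, sum)
  df$percent <- 100 * df$count / as.numeric(totals[df$group])
  df <- df[order(match(df$group, groups), match(df$category, categories)), ]
  rownames(df) <- NULL
  if ("replicate" %in% names(annotations)) {
    rep_tab <- as.data.frame(table(
      group = annotations$group, replicate = annotations$replicate,
      category = factor(annotations$category, levels = categories)),
      stringsAsFactors = FALSE)
    names(rep_tab)[4] <- "count"
    attr(df, "by_replicate") <- rep_tab
  }
  class(df) <- c("frequency_table", "data.frame")
  df
}
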