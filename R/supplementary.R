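#' Recompute group summaries from a per-unit supplementary table
#'
#' Published figures report group means, SEMs and average fold enrichments
#' computed from per-unit values that live in a supplementary workbook
#' (one spreadsheet per figure panel). This reads such a sheet (XLSX via
#' readxl, or a CSV export), maps its columns through an explicit mapping
#' stanza, and recomputes the summaries; when the mapping carries the
#' printed values they are placed side by side with the recomputed ones.
#' Nothing about the sheet layout is guessed: a column missing from the
#' mapping or the sheet is an error.
#'
#' @param path `.xlsx` workbook or `.csv` file of per-unit values.
#' @param mapping list with `value_col` (per-unit measurement, e.g. the
#'   per-oocyte fold enrichment), `group_col` (or NULL to treat the sheet
#'   as one group named "all"), optional `sheet` (name or index, XLSX
#'   only), optional `reported` (named numeric: group -> printed value).
#' @return data.frame with `group`, `n`, `mean`, `sem` and, when provided,
#'   `reported` and `delta` (recomputed minus printed).
#' @export
recompute_supplementary <- function(path, mapping) {
  if (is.null(mapping$value_col))
    stopf("mapping$value_col is required (no layout guessing)",
          class = "bbenrich_mapping_error")
  ext <- tolower(tools::file_ext(path))
  df <- switch(ext,
               xlsx = as.data.frame(readxl::read_excel(
                 path, sheet = mapping$sheet %||% 1)),
               csv = utils::read.csv(path, stringsAsFactors = FALSE),
               stopf("unsupported sheet format '.%s'", ext,
                     class = "bbenrich_mapping_error"))
  need <- c(mapping$value_col, mapping$group_col)
  miss <- setdiff(need, names(df))
  if (length(miss))
    stopf("mapped column(s) not in sheet: %s", paste(miss, collapse = ", "),
          class = "bbenrich_mapping_error")
  vals <- suppressWarnings(as.numeric(df[[mapping$value_col]]))
  grp <- if (is.null(mapping$group_col)) rep("all", nrow(df))
  else as.character(df[[mapping$group_col]])
  keep <- is.finite(vals)
  vals <- vals[keep]; grp <- grp[keep]
  if (length(vals) == 0L)
    stopf("no finite values in column '%s'", mapping$value_col,
          class = "bbenrich_mapping_error")
  groups <- unique(grp)
  out <- data.frame(
    group = groups,
    n = vapply(groups, function(g) sum(grp == g), integer(1)),
    mean = vapply(groups, function(g) mean(vals[grp == g]), numeric(1)),
    sem = vapply(groups, function(g)
      stats::sd(vals[grp == g]) / sqrt(sum(grp == g)), numeric(1)),
    stringsAsFactors = FALSE)
  if (!is.null(mapping$reported)) {
    out$reported <- as.numeric(mapping$reported[out$group])
    out$delta <- out$mean - out$reported
  }
  rownames(out) <- NULL
  out
}
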