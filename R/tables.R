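# Report tables ----------------------------------------------------------

METRIC_ROWS <- c("n_nodes", "density", "diameter", "path_length",
                 "assortativity", "clustering", "reciprocity",
                 "degree_score", "closeness_score", "betweenness_score")

fmt_cell <- function(v) {
  v <- v[!is.na(v)]
  if (!length(v)) return("")
  s <- if (length(v) > 1L) sd(v) else 0
  sprintf("%.3f(%.3f)", mean(v), s)
}

#' Summary table of mean (SD) per measure, year and care band
#'
#' One row per structural measure, one column per year-by-band cell,
#' formatted `"mean(SD)"` with three decimals (sample SD, n - 1
#' denominator; a singleton's SD is reported as 0.000). Undefined
#' (`NA`) values are excluded per cell.
#'
#' @param records Metric-record `data.frame` from [compute_metrics()].
#' @param path Optional CSV output path.
#' @return The summary `data.frame` (invisibly when `path` is given).
#' @export
write_summary_table <- function(records, path = NULL) {
  if (is.null(records) || nrow(records) == 0L) {
    stop("no metric records to summarise", call. = FALSE)
  }
  records$care_band[is.na(records$care_band)] <- "ALL"
  cells <- unique(records[, c("year", "care_band")])
  cells <- cells[order(cells$year, cells$care_band), ]
  tab <- data.frame(metric = METRIC_ROWS, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(cells))) {
    sub <- records[records$year == cells$year[i] &
                     records$care_band == cells$care_band[i], ]
    tab[[sprintf("%d_%s", cells$year[i], cells$care_band[i])]] <-
      vapply(METRIC_ROWS, function(m) fmt_cell(sub[[m]]), character(1))
  }
  if (!is.null(path)) {
    utils::write.csv(tab, path, row.names = FALSE)
    return(invisible(tab))
  }
  tab
}

#' Demographic table of retained networks
#'
#' Per year and care band: number of analyzable networks, female and
#' male patient counts with percentages, and patient age mean (SD).
#' Bands with no retained network in a year appear as zero rows rather
#' than being omitted.
#'
#' @param groups Group metadata table (see [read_groups()]).
#' @param retained List of retained `patient_network` objects.
#' @param path Optional CSV output path.
#' @return The demographic `data.frame` (invisibly when `path` given).
#' @export
demographic_table <- function(groups, retained, path = NULL) {
  if (!length(retained)) stop("no retained networks", call. = FALSE)
  g <- data.table::as.data.table(groups)
  if (!"care_band" %in% names(g)) g[, care_band := care_band(care_level)]
  keys <- data.frame(group_id = vapply(retained, function(n) n$group_id, character(1)),
                     year = vapply(retained, function(n) n$year, integer(1)),
                     stringsAsFactors = FALSE)
  gk <- merge(keys, as.data.frame(g), by = c("group_id", "year"))
  years <- sort(unique(gk$year)); bands <- c("LIGHT", "HEAVY")
  rows <- list()
  for (yr in years) for (bd in bands) {
    sub <- gk[gk$year == yr & gk$care_band == bd, ]
    nf <- sum(sub$patient_sex == "F"); nm <- sum(sub$patient_sex == "M")
    n <- nrow(sub)
    rows[[length(rows) + 1L]] <- data.frame(
      year = yr, care_band = bd, n_networks = n,
      female = nf, female_pct = if (n) sprintf("%.1f%%", 100 * nf / n) else "",
      male = nm, male_pct = if (n) sprintf("%.1f%%", 100 * nm / n) else "",
      age = if (n) sprintf("%.1f(%.1f)", mean(sub$patient_age),
                           if (n > 1L) sd(sub$patient_age) else 0) else "",
      stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  if (!is.null(path)) {
    utils::write.csv(tab, path, row.names = FALSE)
    return(invisible(tab))
  }
  tab
}

#' Run all year-to-year comparisons and tidy the results
#'
#' Applies [compare_years()] to every measure for the requested strata
#' and stacks the pairwise rows into one tidy table.
#'
#' @param records Metric-record `data.frame`.
#' @param strata Character vector among `"ALL"`, `"LIGHT"`, `"HEAVY"`.
#' @param alpha Familywise significance level.
#' @param metrics Measure columns to test (default: all ten).
#' @param path Optional CSV output path.
#' @return Tidy `data.frame`: metric, stratum, pair, t, p, n, verdict.
#' @export
comparison_table <- function(records, strata = c("ALL", "LIGHT", "HEAVY"),
                             alpha = 0.05, metrics = METRIC_ROWS,
                             path = NULL) {
  rows <- list()
  for (st in strata) for (m in metrics) {
    res <- withCallingHandlers(
      compare_years(records, m, st, alpha),
      warning = function(w) invokeRestart("muffleWarning"))
    if (!is.null(res)) rows[[length(rows) + 1L]] <- res
  }
  if (!length(rows)) return(NULL)
  tab <- do.call(rbind, rows)
  if (!is.null(path)) {
    utils::write.csv(tab, path, row.names = FALSE)
    return(invisible(tab))
  }
  tab
}
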