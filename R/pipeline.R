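# End-to-end pipeline ----------------------------------------------------

#' Run the full log-to-comparison pipeline
#'
#' Orchestrates: read and validate the logs, build one network per
#' active (group, year), apply the analyzable-network filter, compute
#' all structural measures, and write summary, demographic and
#' Steel-Dwass comparison tables plus a JSON run log. Stage counts are
#' reconciled (`groups seen = built + excluded`,
#' `built = retained + filtered out`) and the run aborts if they do not.
#'
#' @param events Event table or path to an event file.
#' @param groups Group metadata table or CSV path.
#' @param roster Roster table or CSV path.
#' @param out_dir Output directory.
#' @param min_nodes Analyzable-network node threshold (default 10).
#' @param cfg A [metric_config()].
#' @param alpha Familywise significance level for comparisons.
#' @param dump_networks If `TRUE`, write every retained network as node
#'   and edge lists under `out_dir/networks/`.
#' @param force Proceed despite validation issues (they are still
#'   written to the run log).
#' @return Invisibly, a list with the tables, the retained networks and
#'   the run-log list; files are written under `out_dir`.
#' @export
run_pipeline <- function(events, groups, roster, out_dir,
                         min_nodes = 10L, cfg = metric_config(),
                         alpha = 0.05, dump_networks = FALSE,
                         force = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.character(events)) events <- read_events(events)
  if (is.character(groups)) groups <- read_groups(groups)
  if (is.character(roster)) roster <- read_roster(roster)
  validation <- attr(events, "validation")
  n_dangling <- if (is.null(validation)) 0L else nrow(validation)
  if (n_dangling > 0L && !force) {
    stop("[validate] ", n_dangling,
         " dangling VIEW_MARK(s); rerun with force = TRUE to proceed",
         call. = FALSE)
  }

  nets <- build_cohort(events, groups, roster)
  build_report <- attr(nets, "report")
  retained <- filter_networks(nets, min_nodes = min_nodes)
  n_excluded <- attr(retained, "excluded")

  # conservation checks
  stopifnot(build_report$group_years_active ==
              build_report$networks_built + build_report$missing_metadata,
            build_report$networks_built == length(retained) + n_excluded)

  records <- compute_metrics(retained, cfg)
  summary_tab <- write_summary_table(records, file.path(out_dir, "summary.csv"))
  demo_tab <- demographic_table(groups, retained,
                                file.path(out_dir, "demographics.csv"))
  strata <- c("ALL", "LIGHT", "HEAVY")
  comp_tab <- comparison_table(records, strata, alpha,
                               path = file.path(out_dir, "comparisons.csv"))
  utils::write.csv(records, file.path(out_dir, "metrics.csv"), row.names = FALSE)

  if (dump_networks) {
    ndir <- file.path(out_dir, "networks")
    dir.create(ndir, showWarnings = FALSE)
    for (net in retained) {
      write_network(net, file.path(ndir, sprintf("%s_%d", net$group_id, net$year)))
    }
  }

  retained_by_cell <- table(
    year = vapply(retained, function(n) n$year, integer(1)),
    band = vapply(retained, function(n) n$care_band, character(1)))
  run_log <- list(
    group_years_active = build_report$group_years_active,
    networks_built = build_report$networks_built,
    missing_metadata = build_report$missing_metadata,
    filtered_out = n_excluded,
    retained = length(retained),
    retained_per_cell = as.data.frame(retained_by_cell),
    dangling_view_marks = n_dangling,
    min_nodes = min_nodes,
    alpha = alpha,
    metric_config = unclass(cfg))
  jsonlite::write_json(run_log, file.path(out_dir, "run_log.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(records = records, summary = summary_tab,
                 demographics = demo_tab, comparisons = comp_tab,
                 networks = retained, run_log = run_log))
}
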