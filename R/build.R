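# Network construction from log events ----------------------------------

#' Build one patient network from a group's log events
#'
#' Nodes are the professionals registered in the group (isolated nodes
#' included); patients themselves are never nodes. A directed link
#' (u, v) is created when, within `year`, v marked "viewed" on a message
#' posted by u. Links are unweighted and deduplicated; self-view marks
#' (viewer equal to poster) generate no link. Year attribution of a link
#' follows the POST's date. A viewer observed in the logs but absent
#' from the roster is retained as a node with role `"other"` and
#' reported, rather than dropped: discarding observed communication
#' would bias density downward.
#'
#' @param events Event table of a single group (see [read_events()]).
#' @param roster Character vector of registered professional ids, or a
#'   data.frame with columns `actor_id` and optionally `role`.
#' @param year Calendar year to bin on.
#' @param group_id Group identifier; defaults to the one in `events`.
#' @param care_band `"LIGHT"`, `"HEAVY"` or `NA`.
#' @param patient_id Optional patient account id to exclude from nodes.
#' @return A `patient_network`; attribute `"report"` lists counts of
#'   out-of-year events and off-roster viewers.
#' @export
build_network <- function(events, roster, year, group_id = NULL,
                          care_band = NA_character_, patient_id = NULL) {
  ev <- data.table::as.data.table(events)
  if (is.null(group_id)) {
    gid <- unique(ev$group_id)
    if (length(gid) != 1L) stop("events span several groups; pass group_id", call. = FALSE)
    group_id <- gid
  }
  if (is.data.frame(roster)) {
    roles <- setNames(normalize_role(roster$role %||% rep("other", nrow(roster))),
                      as.character(roster$actor_id))
    roster <- as.character(roster$actor_id)
  } else {
    roster <- as.character(roster)
    roles <- setNames(rep("other", length(roster)), roster)
  }
  if (length(roster) == 0L) stop("roster is empty", call. = FALSE)
  if (!is.null(patient_id)) {
    roles <- roles[!names(roles) %in% patient_id]
    roster <- setdiff(roster, patient_id)
    ev <- ev[!(actor_id %in% patient_id)]
  }

  posts <- ev[kind == "POST"]
  views <- ev[kind == "VIEW_MARK"]
  # link year follows the POST's date
  post_year <- setNames(as.integer(format(posts$date, "%Y")), posts$message_id)
  post_actor <- setNames(posts$actor_id, posts$message_id)
  views[, post_year := post_year[message_id]]
  views[, post_actor := post_actor[message_id]]
  dangling <- views[is.na(post_actor)]
  in_year <- views[!is.na(post_actor) & post_year == year & actor_id != post_actor]
  out_of_year <- nrow(views[!is.na(post_actor) & post_year != year])

  edges <- NULL
  if (nrow(in_year)) {
    edges <- unique(cbind(from = in_year$post_actor, to = in_year$actor_id))
  }
  observed <- unique(c(if (!is.null(edges)) c(edges)))
  off_roster <- setdiff(observed, roster)
  if (length(off_roster)) {
    roles[off_roster] <- "other"
  }
  nodes <- union(roster, off_roster)
  net <- patient_network(group_id, year, care_band, nodes, edges,
                         roles = roles[nodes])
  attr(net, "report") <- list(out_of_year_views = out_of_year,
                              dangling_views = nrow(dangling),
                              off_roster_viewers = off_roster)
  net
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Keep analyzable networks
#'
#' Very small networks are uninformative for structural analysis; only
#' those with at least `min_nodes` nodes are retained (inclusive
#' threshold, default 10). Order is preserved.
#'
#' @param nets List of `patient_network` objects.
#' @param min_nodes Inclusive node-count threshold (default 10).
#' @return The retained sublist; attribute `"excluded"` gives the count
#'   filtered out.
#' @export
filter_networks <- function(nets, min_nodes = 10L) {
  if (min_nodes < 2L) stop("min_nodes must be >= 2", call. = FALSE)
  keep <- vapply(nets, n_nodes, integer(1)) >= min_nodes
  out <- nets[keep]
  attr(out, "excluded") <- sum(!keep)
  out
}

#' Build the full cohort of per-group, per-year networks
#'
#' Repeated cross-sectional construction: one network per (group, year)
#' pair that has at least one POST in that year; a group active in
#' several years yields an independent network per year.
#'
#' @param events Event table for the whole cohort.
#' @param groups Group metadata (see [read_groups()]); one row per
#'   (group, year). Groups with events but no metadata row for an active
#'   year are reported and excluded.
#' @param roster Roster table with columns `group_id, actor_id, role`.
#' @param years Integer vector of years to build (default: all years
#'   present in `groups`).
#' @return List of `patient_network`; attribute `"report"` records the
#'   number of group-years seen, built, and excluded for missing
#'   metadata.
#' @export
build_cohort <- function(events, groups, roster, years = NULL) {
  ev <- data.table::as.data.table(events)
  g <- data.table::as.data.table(groups)
  if (!"care_band" %in% names(g)) g[, care_band := care_band(care_level)]
  r <- data.table::as.data.table(roster)
  if (is.null(years)) years <- sort(unique(g$year))
  if (!length(years)) stop("years is empty", call. = FALSE)

  posts <- ev[kind == "POST"]
  posts[, year := as.integer(format(date, "%Y"))]
  active <- unique(posts[year %in% years, .(group_id, year)])

  meta_key <- paste(g$group_id, g$year)
  no_meta <- active[!paste(group_id, year) %in% meta_key]
  active <- active[paste(group_id, year) %in% meta_key]
  data.table::setorder(active, year, group_id)

  ev_by_group <- split(ev, by = "group_id")
  roster_by_group <- split(r, by = "group_id")
  nets <- vector("list", nrow(active))
  for (i in seq_len(nrow(active))) {
    gid <- active$group_id[i]; yr <- active$year[i]
    band <- g[group_id == gid & year == yr, care_band][1L]
    ros <- roster_by_group[[gid]]
    if (is.null(ros)) ros <- data.frame(actor_id = character(0), role = character(0))
    if (nrow(ros) == 0L) { # no registered roster: fall back to event actors
      ros <- data.frame(actor_id = unique(ev_by_group[[gid]]$actor_id),
                        role = "other")
    }
    nets[[i]] <- build_network(ev_by_group[[gid]], ros, yr,
                               group_id = gid, care_band = band)
  }
  attr(nets, "report") <- list(
    group_years_active = nrow(active) + nrow(no_meta),
    networks_built = nrow(active),
    missing_metadata = nrow(no_meta),
    missing_metadata_groups = unique(no_meta$group_id))
  nets
}
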