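# Log-event and metadata IO ---------------------------------------------

EVENT_COLUMNS <- c("kind", "message_id", "group_id", "actor_id", "date")

#' Read a message-log event table
#'
#' Events are message POSTs and per-viewer VIEW_MARKs. The canonical
#' dialect is CSV with header `kind,message_id,group_id,actor_id,date`;
#' JSON Lines with the same keys is accepted as an alternate dialect
#' (one object per line). Dates are parsed ISO-8601; only the calendar
#' year is ever used for binning.
#'
#' Validation never drops rows silently: VIEW_MARKs whose `message_id`
#' matches no POST anywhere in the file are returned in the attached
#' validation report (attribute `"validation"`), not removed.
#'
#' @param path Path to a `.csv` or `.jsonl` event file.
#' @return A `data.table` of events in file order with columns
#'   `kind` (`"POST"`/`"VIEW_MARK"`), `message_id`, `group_id`,
#'   `actor_id`, `date` (`Date`); attribute `"validation"` holds a
#'   `data.table` of dangling VIEW_MARKs (zero rows when clean).
#' @export
read_events <- function(path) {
  if (!file.exists(path)) stop("event file not found: ", path, call. = FALSE)
  if (grepl("\\.jsonl$", path, ignore.case = TRUE)) {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    ev <- if (length(lines)) {
      data.table::rbindlist(lapply(lines, jsonlite::fromJSON), fill = TRUE)
    } else {
      data.table::as.data.table(
        setNames(rep(list(character(0)), 5L), EVENT_COLUMNS))
    }
  } else {
    ev <- data.table::fread(path, colClasses = "character")
  }
  missing <- setdiff(EVENT_COLUMNS, names(ev))
  if (length(missing)) {
    stop("event file lacks required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  ev <- ev[, EVENT_COLUMNS, with = FALSE]
  ev[, kind := toupper(kind)]
  bad_kind <- !ev$kind %in% c("POST", "VIEW_MARK")
  if (any(bad_kind)) {
    stop("unknown event kind(s): ",
         paste(unique(ev$kind[bad_kind]), collapse = ", "), call. = FALSE)
  }
  ev[, date := as.Date(date)]
  if (anyNA(ev$date)) stop("unparseable date(s) in event file", call. = FALSE)
  dangling <- ev[kind == "VIEW_MARK" & !message_id %in% ev[kind == "POST", message_id]]
  data.table::setattr(ev, "validation", data.table::copy(dangling))
  ev[]
}

#' Write an event table
#'
#' @param events Event `data.table`/`data.frame` (see [read_events()]).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path) {
  ev <- data.table::as.data.table(events)[, EVENT_COLUMNS, with = FALSE]
  data.table::fwrite(ev, path)
  invisible(path)
}

#' Read a patient-group metadata table
#'
#' Expects columns `group_id, year, care_level, patient_sex, patient_age`.
#'
#' @param path CSV path.
#' @return `data.table` with a derived `care_band` column.
#' @export
read_groups <- function(path) {
  g <- data.table::fread(path)
  need <- c("group_id", "year", "care_level", "patient_sex", "patient_age")
  missing <- setdiff(need, names(g))
  if (length(missing)) {
    stop("group file lacks required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  g[, group_id := as.character(group_id)]
  g[, year := as.integer(year)]
  g[, care_level := as.integer(care_level)]
  if (any(!g$care_level %in% 1:5)) stop("care_level outside 1..5", call. = FALSE)
  g[, patient_sex := toupper(as.character(patient_sex))]
  if (any(!g$patient_sex %in% c("F", "M"))) stop("patient_sex must be F or M", call. = FALSE)
  g[, care_band := care_band(care_level)]
  g[]
}

#' Read a professional roster table
#'
#' Expects columns `group_id, actor_id, role`; roles outside the closed
#' vocabulary ([role_levels()]) are mapped to `"other"`.
#'
#' @param path CSV path.
#' @return `data.table` with columns `group_id, actor_id, role`.
#' @export
read_roster <- function(path) {
  r <- data.table::fread(path, colClasses = "character")
  missing <- setdiff(c("group_id", "actor_id", "role"), names(r))
  if (length(missing)) {
    stop("roster file lacks required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  r[, role := normalize_role(role)]
  r[, c("group_id", "actor_id", "role"), with = FALSE]
}

# Network persistence ----------------------------------------------------

#' Write a patient network to disk
#'
#' Persists a network as a node list plus a two-column directed edge
#' list (`<stem>.nodes.csv`, `<stem>.edges.csv`), so that isolated
#' nodes survive the round trip. [read_network()] restores the object
#' exactly.
#'
#' @param net A `patient_network`.
#' @param stem Path stem; the two CSV files are written next to it.
#' @return Character vector of the two paths, invisibly.
#' @export
write_network <- function(net, stem) {
  stopifnot(inherits(net, "patient_network"))
  nodes <- data.frame(actor_id = net$nodes,
                      role = if (is.null(net$roles)) NA_character_
                             else unname(net$roles[net$nodes]))
  meta <- sprintf("# group_id=%s year=%d care_band=%s",
                  net$group_id, net$year, net$care_band)
  npath <- paste0(stem, ".nodes.csv")
  epath <- paste0(stem, ".edges.csv")
  writeLines(c(meta, "actor_id,role",
               paste(nodes$actor_id, ifelse(is.na(nodes$role), "", nodes$role),
                     sep = ",")), npath)
  edges <- as.data.frame(net$edges, stringsAsFactors = FALSE)
  writeLines(c(meta, "from,to",
               if (nrow(edges)) paste(edges$from, edges$to, sep = ",")), epath)
  invisible(c(npath, epath))
}

#' Read a patient network written by [write_network()]
#'
#' @param stem Path stem used at write time.
#' @return A `patient_network`.
#' @export
read_network <- function(stem) {
  npath <- paste0(stem, ".nodes.csv")
  epath <- paste0(stem, ".edges.csv")
  if (!file.exists(npath)) stop("node list not found: ", npath, call. = FALSE)
  meta <- readLines(npath, n = 1L)
  m <- regmatches(meta, regexec("group_id=(\\S+) year=(\\d+) care_band=(\\S+)", meta))[[1L]]
  if (length(m) != 4L) stop("malformed network header: ", meta, call. = FALSE)
  nodes <- utils::read.csv(npath, skip = 1L, colClasses = "character")
  edges <- utils::read.csv(epath, skip = 1L, colClasses = "character")
  roles <- NULL
  if (any(nzchar(nodes$role))) roles <- setNames(nodes$role, nodes$actor_id)
  patient_network(group_id = m[2L], year = as.integer(m[3L]),
                  care_band = m[4L], nodes = nodes$actor_id,
                  edges = if (nrow(edges)) as.matrix(edges) else NULL,
                  roles = roles)
}
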