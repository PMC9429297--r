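# Domain vocabulary -----------------------------------------------------

#' Professional role vocabulary
#'
#' The closed set of healthcare-professional roles recognised by the
#' package. Any role string outside this set is mapped to `"other"`.
#'
#' @return Character vector of role names.
#' @export
role_levels <- function() {
  c("physician", "clinic nurse", "home care nurse", "pharmacist",
    "physical therapist", "occupational therapist", "care manager",
    "medical social worker", "home care worker", "care worker", "other")
}

#' Normalise role strings to the closed vocabulary
#'
#' @param role Character vector of role names.
#' @return Character vector with unknown roles replaced by `"other"`.
#' @export
normalize_role <- function(role) {
  role <- tolower(trimws(as.character(role)))
  role[!role %in% role_levels() | is.na(role)] <- "other"
  role
}

#' Care band from long-term-care level
#'
#' Care levels 1-3 form the LIGHT band (lighter care requirement),
#' levels 4-5 the HEAVY band (heavier care requirement).
#'
#' @param care_level Integer vector with values in 1..5.
#' @return Character vector, `"LIGHT"` or `"HEAVY"`.
#' @export
care_band <- function(care_level) {
  care_level <- as.integer(care_level)
  if (any(!care_level %in% 1:5)) {
    stop("care_level must be in 1..5", call. = FALSE)
  }
  ifelse(care_level <= 3L, "LIGHT", "HEAVY")
}

# Patient network --------------------------------------------------------

#' Construct a patient network
#'
#' An unweighted directed graph over the professionals of one patient
#' group in one calendar year. A directed link (u, v) records that v
#' marked "viewed" on at least one message posted by u within the year.
#' Isolated nodes (registered professionals with no links) are kept: they
#' belong to the network but are neither input nor output.
#'
#' @param group_id Group (patient) identifier.
#' @param year Calendar year of the network.
#' @param care_band `"LIGHT"`, `"HEAVY"` or `NA`.
#' @param nodes Character vector of professional identifiers (unique).
#' @param edges Two-column character matrix of directed links (from, to);
#'   zero rows allowed. Self-loops and duplicates are rejected.
#' @param roles Optional named character vector mapping node id to role.
#' @return Object of class `patient_network`.
#' @export
patient_network <- function(group_id, year, care_band = NA_character_,
                            nodes, edges = NULL, roles = NULL) {
  nodes <- as.character(nodes)
  if (length(nodes) < 1L) stop("a patient network needs at least one node", call. = FALSE)
  if (anyDuplicated(nodes)) stop("duplicate node identifiers", call. = FALSE)
  if (is.null(edges) || NROW(edges) == 0L) {
    edges <- matrix(character(0), ncol = 2L,
                    dimnames = list(NULL, c("from", "to")))
  } else {
    edges <- as.matrix(edges)
    storage.mode(edges) <- "character"
    colnames(edges) <- c("from", "to")
    if (any(edges[, 1L] == edges[, 2L])) stop("self-loops are not permitted", call. = FALSE)
    if (!all(edges %in% nodes)) stop("edge endpoint not among nodes", call. = FALSE)
    edges <- unique(edges)
  }
  structure(
    list(group_id = as.character(group_id), year = as.integer(year),
         care_band = as.character(care_band), nodes = nodes, edges = edges,
         roles = roles),
    class = "patient_network"
  )
}

#' @export
print.patient_network <- function(x, ...) {
  cat(sprintf("<patient_network> group %s, year %d [%s]\n",
              x$group_id, x$year, x$care_band))
  cat(sprintf("  %d nodes, %d directed links, %d isolated\n",
              length(x$nodes), nrow(x$edges),
              sum(!x$nodes %in% c(x$edges))))
  invisible(x)
}

#' Number of nodes of a patient network
#' @param net A `patient_network`.
#' @return Integer node count.
#' @export
n_nodes <- function(net) length(net$nodes)

# directed adjacency as logical matrix, nodes in roster order
adjacency_matrix <- function(net) {
  n <- length(net$nodes)
  A <- matrix(FALSE, n, n, dimnames = list(net$nodes, net$nodes))
  if (nrow(net$edges) > 0L) A[net$edges] <- TRUE
  A
}

# condition helper: measures that are undefined on a given network signal
# this class; compute_all() turns it into an NA field instead of aborting
undefined_measure <- function(msg) {
  stop(structure(class = c("carenets_undefined_measure", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}
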