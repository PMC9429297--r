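# Structural network measures -------------------------------------------
#
# All measures are implemented from first principles on a logical
# adjacency matrix; no graph library is used. Distance-based measures
# operate by default on the undirected projection restricted to its
# largest connected component (finite values on graphs with isolated
# nodes), while density, degree and reciprocity always see the full
# directed graph.

#' Measure configuration
#'
#' Collects the conventions that the underlying study left open. Each
#' knob is explicit so a run log can record exactly which interpretation
#' produced a table.
#'
#' @param path_mode `"include_self"` (default): mean path length
#'   averages over all ordered pairs including node-with-itself pairs at
#'   distance 0; `"exclude_self"` is the conventional alternative.
#' @param projection `"undirected"` (default) or `"directed"` treatment
#'   for the distance-based measures (diameter, path length, closeness,
#'   betweenness).
#' @param centrality_aggregation `"centralization"` (default): Freeman
#'   centralization, the standard star-normalised single-number summary
#'   of a centrality vector; `"mean"`: mean of the normalised node
#'   centralities.
#' @param unreachable_policy `"largest_component"` (default): distance
#'   measures are computed on the largest connected component of the
#'   projection; `"reachable_pairs"`: averages run over all reachable
#'   ordered pairs of the whole graph.
#' @return Object of class `metric_config`.
#' @export
metric_config <- function(path_mode = c("include_self", "exclude_self"),
                          projection = c("undirected", "directed"),
                          centrality_aggregation = c("centralization", "mean"),
                          unreachable_policy = c("largest_component", "reachable_pairs")) {
  structure(list(path_mode = match.arg(path_mode),
                 projection = match.arg(projection),
                 centrality_aggregation = match.arg(centrality_aggregation),
                 unreachable_policy = match.arg(unreachable_policy)),
            class = "metric_config")
}

# --- internal graph machinery ------------------------------------------

as_adj <- function(net) {
  if (inherits(net, "patient_network")) return(adjacency_matrix(net))
  A <- as.matrix(net)
  storage.mode(A) <- "logical"
  diag(A) <- FALSE
  A
}

projection_matrix <- function(A, cfg) {
  if (cfg$projection == "undirected") A | t(A) else A
}

# BFS shortest-path distances from `src` on adjacency list `nbr`
bfs_dist <- function(nbr, n, src) {
  d <- rep.int(NA_integer_, n)
  d[src] <- 0L
  frontier <- src
  while (length(frontier)) {
    nxt <- unique(unlist(nbr[frontier], use.names = FALSE))
    nxt <- nxt[is.na(d[nxt])]
    if (!length(nxt)) break
    d[nxt] <- d[frontier[1L]] + 1L
    frontier <- nxt
  }
  d
}

# all-pairs shortest-path matrix via per-source BFS (unweighted)
dist_matrix <- function(M) {
  n <- nrow(M)
  nbr <- lapply(seq_len(n), function(i) which(M[i, ]))
  D <- matrix(NA_integer_, n, n)
  for (s in seq_len(n)) D[s, ] <- bfs_dist(nbr, n, s)
  D
}

# connected components of an undirected logical matrix
components_of <- function(U) {
  n <- nrow(U)
  comp <- rep.int(0L, n)
  k <- 0L
  nbr <- lapply(seq_len(n), function(i) which(U[i, ]))
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    k <- k + 1L
    frontier <- s
    comp[s] <- k
    while (length(frontier)) {
      nxt <- unique(unlist(nbr[frontier], use.names = FALSE))
      nxt <- nxt[comp[nxt] == 0L]
      comp[nxt] <- k
      frontier <- nxt
    }
  }
  comp
}

# index set of the largest component of the undirected projection of A
# (ties broken by lowest node index, for determinism)
largest_component <- function(A) {
  U <- A | t(A)
  comp <- components_of(U)
  sizes <- tabulate(comp)
  which(comp == which.max(sizes))
}

# admitted submatrix for distance-based measures under the policy
admitted <- function(A, cfg) {
  M <- projection_matrix(A, cfg)
  if (cfg$unreachable_policy == "largest_component") {
    idx <- largest_component(A)
    M[idx, idx, drop = FALSE]
  } else M
}

# --- measures ----------------------------------------------------------

#' Network density
#'
#' Observed directed links divided by the maximum possible n(n-1).
#'
#' @param net A `patient_network` or adjacency matrix.
#' @return Fraction in \[0, 1\].
#' @export
net_density <- function(net) {
  A <- as_adj(net)
  n <- nrow(A)
  if (n < 2L) undefined_measure("density needs at least 2 nodes")
  sum(A) / (n * (n - 1))
}

#' Network diameter
#'
#' Longest shortest-path length (in hops) over reachable ordered pairs
#' of the admitted projection (by default, the largest connected
#' component of the undirected projection).
#'
#' @param net A `patient_network` or adjacency matrix.
#' @param cfg A [metric_config()].
#' @return Integer hop count, at least 1 for any network with a link.
#' @export
net_diameter <- function(net, cfg = metric_config()) {
  A <- as_adj(net)
  if (!any(A)) undefined_measure("diameter needs at least one link")
  D <- dist_matrix(admitted(A, cfg))
  max(D, na.rm = TRUE)
}

#' Mean path length
#'
#' Average shortest-path distance over ordered node pairs of the
#' admitted projection. Under the default `"include_self"` mode the
#' average runs over all m^2 ordered pairs of the admitted node set,
#' self-pairs contributing distance 0; `"exclude_self"` uses the
#' conventional m(m-1) off-diagonal pairs.
#'
#' @inheritParams net_diameter
#' @return Mean hop count.
#' @export
net_path_length <- function(net, cfg = metric_config()) {
  A <- as_adj(net)
  if (!any(A)) undefined_measure("path length needs at least one link")
  D <- dist_matrix(admitted(A, cfg))
  m <- nrow(D)
  if (cfg$path_mode == "exclude_self") diag(D) <- NA_integer_
  tot <- sum(D, na.rm = TRUE)
  npairs <- if (cfg$unreachable_policy == "reachable_pairs") {
    sum(!is.na(D))
  } else if (cfg$path_mode == "include_self") m^2 else m * (m - 1)
  tot / npairs
}

#' Average clustering coefficient
#'
#' Mean local clustering coefficient on the undirected projection;
#' nodes of degree below 2 contribute 0.
#'
#' @param net A `patient_network` or adjacency matrix.
#' @return Fraction in \[0, 1\].
#' @export
net_clustering <- function(net) {
  A <- as_adj(net)
  n <- nrow(A)
  if (n < 3L) undefined_measure("clustering needs at least 3 nodes")
  U <- (A | t(A)) * 1
  deg <- rowSums(U)
  tri <- diag(U %*% U %*% U) / 2   # closed triangles through each node
  local <- ifelse(deg >= 2, tri / (deg * (deg - 1) / 2), 0)
  mean(local)
}

#' Degree assortativity
#'
#' Pearson correlation of endpoint total degrees over the links of the
#' undirected projection (each undirected link contributes both
#' orientations, the standard convention). Undefined — returned as
#' `NA` — when the endpoint degrees have zero variance, e.g. on regular
#' graphs.
#'
#' @param net A `patient_network` or adjacency matrix.
#' @return Correlation in \[-1, 1\], or `NA` when undefined.
#' @export
net_assortativity <- function(net) {
  A <- as_adj(net)
  U <- A | t(A)
  if (!any(U)) undefined_measure("assortativity needs at least one link")
  deg <- rowSums(U)
  idx <- which(U, arr.ind = TRUE)  # both orientations of each link
  x <- deg[idx[, 1L]]; y <- deg[idx[, 2L]]
  if (sd(x) == 0 || sd(y) == 0) return(NA_real_)
  cor(x, y)
}

#' Reciprocity
#'
#' Fraction of directed links whose reverse link also exists.
#'
#' @param net A `patient_network` or adjacency matrix.
#' @return Fraction in \[0, 1\].
#' @export
net_reciprocity <- function(net) {
  A <- as_adj(net)
  if (!any(A)) undefined_measure("reciprocity needs at least one link")
  sum(A & t(A)) / sum(A)
}

# Freeman centralization of a node-centrality vector, given the
# theoretical maximum of sum(c_max - c_i) for that order; clamped to
# [0, 1] against floating-point overshoot at the extremes
freeman <- function(ci, denom) min(max(sum(max(ci) - ci) / denom, 0), 1)

#' Degree centrality score
#'
#' Node degree centrality on the undirected projection, summarised per
#' network. Under the default Freeman centralization the score is
#' sum(c_max - c_i) / ((n-1)(n-2)), which is 1 for a star and 0 for any
#' regular graph; under `"mean"` it is the mean of degree/(n-1).
#'
#' @inheritParams net_diameter
#' @return Fraction in \[0, 1\].
#' @export
net_degree_score <- function(net, cfg = metric_config()) {
  A <- as_adj(net)
  n <- nrow(A)
  if (n < 3L) undefined_measure("degree score needs at least 3 nodes")
  deg <- rowSums(A | t(A))
  if (cfg$centrality_aggregation == "mean") return(mean(deg / (n - 1)))
  freeman(deg, (n - 1) * (n - 2))
}

#' Closeness centrality score
#'
#' Normalised closeness c_i = (m-1)/sum_j d(i,j) on the admitted
#' component (size m), Freeman-centralized with the star maximum
#' (m-1)(m-2)/(2m-3), or the mean of c_i under `"mean"`.
#'
#' @inheritParams net_diameter
#' @return Fraction in \[0, 1\].
#' @export
net_closeness_score <- function(net, cfg = metric_config()) {
  A <- as_adj(net)
  if (nrow(A) < 3L) undefined_measure("closeness score needs at least 3 nodes")
  D <- dist_matrix(admitted(A, cfg))
  m <- nrow(D)
  if (m < 3L) undefined_measure("admitted component has fewer than 3 nodes")
  if (anyNA(D)) undefined_measure("admitted node set is not connected")
  ci <- (m - 1) / rowSums(D)
  if (cfg$centrality_aggregation == "mean") return(mean(ci))
  freeman(ci, (m - 1) * (m - 2) / (2 * m - 3))
}

# Brandes' accumulation algorithm for unweighted betweenness on a
# logical adjacency matrix (directed or undirected as given)
brandes_betweenness <- function(M) {
  n <- nrow(M)
  nbr <- lapply(seq_len(n), function(i) which(M[i, ]))
  bc <- numeric(n)
  for (s in seq_len(n)) {
    sigma <- numeric(n); sigma[s] <- 1
    d <- rep.int(-1L, n); d[s] <- 0L
    preds <- vector("list", n)
    order_seen <- integer(0)
    queue <- s
    while (length(queue)) {
      v <- queue[1L]; queue <- queue[-1L]
      order_seen <- c(order_seen, v)
      for (w in nbr[[v]]) {
        if (d[w] < 0L) { d[w] <- d[v] + 1L; queue <- c(queue, w) }
        if (d[w] == d[v] + 1L) {
          sigma[w] <- sigma[w] + sigma[v]
          preds[[w]] <- c(preds[[w]], v)
        }
      }
    }
    delta <- numeric(n)
    for (w in rev(order_seen)) {
      for (v in preds[[w]]) {
        delta[v] <- delta[v] + sigma[v] / sigma[w] * (1 + delta[w])
      }
      if (w != s) bc[w] <- bc[w] + delta[w]
    }
  }
  if (isTRUE(all(M == t(M)))) bc / 2 else bc
}

#' Betweenness centrality score
#'
#' Node betweenness (Brandes shortest-path counting) on the admitted
#' projection, normalised by (m-1)(m-2)/2, then Freeman-centralized
#' (divide sum(b_max - b_i) by m-1, the star maximum), or the mean of
#' the normalised values under `"mean"`.
#'
#' @inheritParams net_diameter
#' @return Fraction in \[0, 1\].
#' @export
net_betweenness_score <- function(net, cfg = metric_config()) {
  A <- as_adj(net)
  if (nrow(A) < 3L) undefined_measure("betweenness score needs at least 3 nodes")
  M <- admitted(A, cfg)
  m <- nrow(M)
  if (m < 3L) undefined_measure("admitted component has fewer than 3 nodes")
  b <- brandes_betweenness(M) / ((m - 1) * (m - 2) / 2)
  if (cfg$centrality_aggregation == "mean") return(mean(b))
  freeman(b, m - 1)
}

#' Compute all structural measures of one network
#'
#' Evaluates the full measure set and returns a one-row data frame (a
#' metric record). A measure that is undefined on the given network
#' (for example assortativity on a regular graph, or any link-based
#' measure on a linkless network) is reported as `NA` rather than
#' aborting, so cohort runs never stop on a degenerate network.
#'
#' @param net A `patient_network`.
#' @param cfg A [metric_config()].
#' @return One-row `data.frame` with columns `group_id, year, care_band,
#'   n_nodes, density, diameter, path_length, assortativity, clustering,
#'   reciprocity, degree_score, closeness_score, betweenness_score`.
#' @export
compute_all <- function(net, cfg = metric_config()) {
  safe <- function(expr) {
    tryCatch(expr, carenets_undefined_measure = function(e) NA_real_)
  }
  data.frame(
    group_id = if (inherits(net, "patient_network")) net$group_id else NA_character_,
    year = if (inherits(net, "patient_network")) net$year else NA_integer_,
    care_band = if (inherits(net, "patient_network")) net$care_band else NA_character_,
    n_nodes = nrow(as_adj(net)),
    density = safe(net_density(net)),
    diameter = safe(net_diameter(net, cfg)),
    path_length = safe(net_path_length(net, cfg)),
    assortativity = safe(net_assortativity(net)),
    clustering = safe(net_clustering(net)),
    reciprocity = safe(net_reciprocity(net)),
    degree_score = safe(net_degree_score(net, cfg)),
    closeness_score = safe(net_closeness_score(net, cfg)),
    betweenness_score = safe(net_betweenness_score(net, cfg)),
    stringsAsFactors = FALSE
  )
}

#' Compute metric records for a list of networks
#'
#' @param nets List of `patient_network` objects.
#' @param cfg A [metric_config()].
#' @return `data.frame`, one metric record per network.
#' @export
compute_metrics <- function(nets, cfg = metric_config()) {
  do.call(rbind, lapply(nets, compute_all, cfg = cfg))
}
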