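# Independent brute-force twins of every structural measure.
# Deliberately naive (Floyd-Warshall, triple enumeration, explicit
# pair counting): slow, transparent, and sharing no code with the
# package's BFS/Brandes implementations.

rand_digraph <- function(n, p) {
  A <- matrix(runif(n * n) < p, n, n)
  diag(A) <- FALSE
  A
}

adj_to_net <- function(A, group_id = "g", year = 2018L, band = "LIGHT") {
  n <- nrow(A)
  nodes <- sprintf("v%02d", seq_len(n))
  idx <- which(A, arr.ind = TRUE)
  edges <- if (nrow(idx)) cbind(from = nodes[idx[, 1]], to = nodes[idx[, 2]]) else NULL
  patient_network(group_id, year, band, nodes, edges)
}

undirect <- function(A) A | t(A)

floyd_warshall <- function(M) {
  n <- nrow(M)
  D <- matrix(Inf, n, n)
  D[M] <- 1
  diag(D) <- 0
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n)) {
    if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  }
  D
}

# node indices of the largest undirected component, via FW reachability
oracle_largest_comp <- function(A) {
  D <- floyd_warshall(undirect(A))
  reach <- is.finite(D)
  sizes <- rowSums(reach)
  members <- which(reach[which.max(sizes), ])
  members
}

oracle_density <- function(A) {
  n <- nrow(A)
  cnt <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) if (i != j && A[i, j]) cnt <- cnt + 1
  cnt / (n * (n - 1))
}

oracle_diameter <- function(A) {
  idx <- oracle_largest_comp(A)
  D <- floyd_warshall(undirect(A)[idx, idx, drop = FALSE])
  max(D[is.finite(D)])
}

oracle_path_length <- function(A, include_self = TRUE) {
  idx <- oracle_largest_comp(A)
  D <- floyd_warshall(undirect(A)[idx, idx, drop = FALSE])
  m <- length(idx)
  if (!include_self) diag(D) <- NA
  sum(D, na.rm = TRUE) / (if (include_self) m^2 else m * (m - 1))
}

oracle_clustering <- function(A) {
  U <- undirect(A)
  n <- nrow(U)
  local <- numeric(n)
  for (v in seq_len(n)) {
    nb <- which(U[v, ])
    if (length(nb) < 2) next
    closed <- 0
    pairs <- 0
    for (a in nb) for (b in nb) if (a < b) {
      pairs <- pairs + 1
      if (U[a, b]) closed <- closed + 1
    }
    local[v] <- closed / pairs
  }
  mean(local)
}

oracle_assortativity <- function(A) {
  U <- undirect(A)
  deg <- rowSums(U)
  xs <- c(); ys <- c()
  n <- nrow(U)
  for (i in seq_len(n)) for (j in seq_len(n)) if (U[i, j]) {
    xs <- c(xs, deg[i]); ys <- c(ys, deg[j])
  }
  if (sd(xs) == 0 || sd(ys) == 0) return(NA_real_)
  cor(xs, ys)
}

oracle_reciprocity <- function(A) {
  n <- nrow(A)
  links <- 0; mutual <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) if (i != j && A[i, j]) {
    links <- links + 1
    if (A[j, i]) mutual <- mutual + 1
  }
  mutual / links
}

oracle_degree_score <- function(A, mode = "centralization") {
  deg <- rowSums(undirect(A))
  n <- nrow(A)
  if (mode == "mean") return(mean(deg / (n - 1)))
  sum(max(deg) - deg) / ((n - 1) * (n - 2))
}

oracle_closeness_score <- function(A, mode = "centralization") {
  idx <- oracle_largest_comp(A)
  D <- floyd_warshall(undirect(A)[idx, idx, drop = FALSE])
  m <- length(idx)
  if (m < 3) return(NA_real_)
  ci <- (m - 1) / rowSums(D)
  if (mode == "mean") return(mean(ci))
  sum(max(ci) - ci) / ((m - 1) * (m - 2) / (2 * m - 3))
}

# shortest-path counts by distance-layer recursion on FW distances;
# betweenness by explicit (s, v, t) pair counting
oracle_path_counts <- function(D, U) {
  m <- nrow(U)
  sigma <- matrix(0, m, m)
  for (s in seq_len(m)) {
    sigma[s, s] <- 1
    ord <- order(D[s, ])
    for (t in ord) {
      if (t == s || !is.finite(D[s, t])) next
      preds <- which(U[, t] & D[s, ] == D[s, t] - 1)
      sigma[s, t] <- sum(sigma[s, preds])
    }
  }
  sigma
}

oracle_betweenness_score <- function(A, mode = "centralization") {
  idx <- oracle_largest_comp(A)
  U <- undirect(A)[idx, idx, drop = FALSE]
  m <- length(idx)
  if (m < 3) return(NA_real_)
  D <- floyd_warshall(U)
  sigma <- oracle_path_counts(D, U)
  b <- numeric(m)
  for (v in seq_len(m)) {
    for (s in seq_len(m)) for (t in seq_len(m)) {
      if (s == t || s == v || t == v) next
      if (!is.finite(D[s, t])) next
      if (D[s, v] + D[v, t] == D[s, t]) {
        b[v] <- b[v] + sigma[s, v] * sigma[v, t] / sigma[s, t]
      }
    }
  }
  b <- b / 2                       # each unordered pair counted twice
  b <- b / ((m - 1) * (m - 2) / 2)
  if (mode == "mean") return(mean(b))
  sum(max(b) - b) / (m - 1)
}
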