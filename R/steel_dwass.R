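# Steel-Dwass all-pairs nonparametric comparison ------------------------

#' Survival function of the studentized range (df = infinity)
#'
#' Tail probability P(Q_k >= q) of the range of k independent standard
#' normal variates, the large-sample Steel-Dwass reference distribution.
#' Computed by adaptive quadrature of
#' 1 - k * integral phi(z) (Phi(z) - Phi(z - q))^(k-1) dz
#' to absolute error below 1e-8. For k = 2 this reduces analytically to
#' 2 Phi(-q / sqrt(2)).
#'
#' @param q Nonnegative quantile(s).
#' @param k Number of groups, at least 2.
#' @return Tail probability in \[0, 1\], vectorised over `q`.
#' @export
studentized_range_sf <- function(q, k) {
  if (k < 2) stop("k must be >= 2", call. = FALSE)
  vapply(q, function(qi) {
    if (qi < 0) stop("q must be nonnegative", call. = FALSE)
    if (qi == 0) return(1)
    cdf <- k * integrate(function(z) dnorm(z) * (pnorm(z) - pnorm(z - qi))^(k - 1),
                         -Inf, Inf, rel.tol = 1e-11, abs.tol = 1e-12)$value
    min(max(1 - cdf, 0), 1)
  }, numeric(1))
}

#' Standardized pairwise rank-sum statistic with tie correction
#'
#' Mid-ranks the pooled two-sample data and returns
#' z = (W - E) / sqrt(V), where W is the rank sum of `x`,
#' E = n_x (N + 1) / 2, and V is the tie-corrected variance
#' (n_x n_y / (N (N - 1))) (sum r_i^2 - N (N + 1)^2 / 4) with
#' N = n_x + n_y. When every pooled observation is tied, V = 0 and the
#' result carries `degenerate = TRUE` with no statistic.
#'
#' @param x,y Numeric samples, each of size at least 2.
#' @return List with `z`, `W`, `E`, `V`, `n_x`, `n_y`, `degenerate`.
#' @export
pair_statistic <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  n_x <- length(x); n_y <- length(y)
  if (n_x < 2L || n_y < 2L) stop("each sample needs at least 2 observations", call. = FALSE)
  N <- n_x + n_y
  r <- rank(c(x, y))             # mid-ranks
  W <- sum(r[seq_len(n_x)])
  E <- n_x * (N + 1) / 2
  V <- n_x * n_y / (N * (N - 1)) * (sum(r^2) - N * (N + 1)^2 / 4)
  if (V <= 0) {
    return(list(z = NA_real_, W = W, E = E, V = V,
                n_x = n_x, n_y = n_y, degenerate = TRUE))
  }
  list(z = (W - E) / sqrt(V), W = W, E = E, V = V,
       n_x = n_x, n_y = n_y, degenerate = FALSE)
}

#' Steel-Dwass all-pairs comparison
#'
#' For each of the k(k-1)/2 group pairs, the tie-corrected standardized
#' rank-sum statistic z is computed on that pair alone, the test
#' statistic t = |z| * sqrt(2) is referred to the studentized range
#' distribution with k groups (df = infinity), and the familywise
#' adjusted p-value is P(Q_k >= t). Two-sided throughout.
#'
#' @param samples Named list of k >= 2 numeric vectors (each length >= 2).
#' @param alpha Familywise significance level (default 0.05).
#' @return `data.frame` with one row per pair: `group_a, group_b, n_a,
#'   n_b, z, statistic_t, p_value, significant, degenerate`.
#' @export
steel_dwass_all_pairs <- function(samples, alpha = 0.05) {
  k <- length(samples)
  if (k < 2L) stop("need at least 2 groups", call. = FALSE)
  labs <- names(samples)
  if (is.null(labs)) labs <- as.character(seq_len(k))
  pairs <- utils::combn(k, 2L)
  rows <- lapply(seq_len(ncol(pairs)), function(j) {
    a <- pairs[1L, j]; b <- pairs[2L, j]
    st <- pair_statistic(samples[[a]], samples[[b]])
    t_stat <- if (st$degenerate) NA_real_ else abs(st$z) * sqrt(2)
    p <- if (st$degenerate) NA_real_ else studentized_range_sf(t_stat, k)
    data.frame(group_a = labs[a], group_b = labs[b],
               n_a = st$n_x, n_b = st$n_y,
               z = if (st$degenerate) NA_real_ else st$z,
               statistic_t = t_stat, p_value = p,
               significant = !st$degenerate && p < alpha,
               degenerate = st$degenerate,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "k") <- k
  attr(out, "alpha") <- alpha
  out
}

#' Permutation oracle for the Steel-Dwass p-value
#'
#' Estimates each pair's familywise p-value as the proportion of group
#' label shuffles in which the maximum pairwise statistic
#' max_pairs |z*| sqrt(2) reaches the pair's observed t. This is the
#' resampling analogue of referring t to the studentized range and is
#' used to validate the analytic p-values on small samples.
#'
#' @param samples Named list of k >= 2 numeric vectors.
#' @param n_perm Number of shuffles (default 20000).
#' @return `data.frame` as [steel_dwass_all_pairs()] plus `p_perm` and
#'   `p_perm_se` (binomial Monte-Carlo standard error).
#' @export
steel_dwass_permutation <- function(samples, n_perm = 20000L) {
  obs <- steel_dwass_all_pairs(samples)
  k <- length(samples)
  sizes <- lengths(samples)
  pooled <- unlist(samples, use.names = FALSE)
  grp <- rep(seq_len(k), sizes)
  pairs <- utils::combn(k, 2L)
  max_t <- numeric(n_perm)
  for (i in seq_len(n_perm)) {
    g <- sample(grp)
    ts <- vapply(seq_len(ncol(pairs)), function(j) {
      st <- pair_statistic(pooled[g == pairs[1L, j]], pooled[g == pairs[2L, j]])
      if (st$degenerate) 0 else abs(st$z) * sqrt(2)
    }, numeric(1))
    max_t[i] <- max(ts)
  }
  obs$p_perm <- vapply(obs$statistic_t, function(t0) {
    if (is.na(t0)) return(NA_real_)
    (1 + sum(max_t >= t0 - 1e-12)) / (1 + n_perm)
  }, numeric(1))
  obs$p_perm_se <- sqrt(obs$p_perm * (1 - obs$p_perm) / n_perm)
  obs
}

#' Year-to-year Steel-Dwass comparisons of one measure
#'
#' Extracts the per-network values of `metric_name` from a metric-record
#' table, restricted to one care-band stratum (`"LIGHT"`, `"HEAVY"` or
#' `"ALL"`), groups them by year, drops undefined (`NA`) values with a
#' count, excludes years left with fewer than 2 defined values (with a
#' warning) and runs the all-pairs comparison across years.
#'
#' @param records Metric-record `data.frame` from [compute_metrics()].
#' @param metric_name One of the measure column names.
#' @param stratum `"ALL"`, `"LIGHT"` or `"HEAVY"`.
#' @param alpha Familywise significance level.
#' @return `data.frame` of pairwise results with `metric` and `stratum`
#'   columns prepended; attribute `"dropped_undefined"` counts removed
#'   `NA` values. `NULL` (with a warning) when fewer than 2 usable years
#'   remain.
#' @export
compare_years <- function(records, metric_name, stratum = "ALL", alpha = 0.05) {
  stopifnot(metric_name %in% names(records))
  stratum <- match.arg(stratum, c("ALL", "LIGHT", "HEAVY"))
  rec <- if (stratum == "ALL") records else records[records$care_band == stratum, ]
  vals <- split(rec[[metric_name]], rec$year)
  n_undef <- sum(vapply(vals, function(v) sum(is.na(v)), numeric(1)))
  vals <- lapply(vals, function(v) v[!is.na(v)])
  small <- lengths(vals) < 2L
  if (any(small)) {
    warning(sprintf("excluding year(s) with <2 defined values of %s: %s",
                    metric_name, paste(names(vals)[small], collapse = ", ")),
            call. = FALSE)
    vals <- vals[!small]
  }
  if (length(vals) < 2L) {
    warning("fewer than 2 usable years; comparison skipped", call. = FALSE)
    return(NULL)
  }
  out <- steel_dwass_all_pairs(vals, alpha = alpha)
  out <- cbind(metric = metric_name, stratum = stratum, out,
               stringsAsFactors = FALSE)
  attr(out, "dropped_undefined") <- n_undef
  out
}
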