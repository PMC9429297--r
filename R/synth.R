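# Synthetic message-log cohorts -----------------------------------------
#
# Stand-in for unavailable raw SNS logs. The generator emits explicit
# POST / VIEW_MARK events (one post per professional; view-marks realise
# links), so the full log-to-network pipeline is exercised, not just the
# measures. Link realisation per unordered pair {u, v}:
#   forward  u->v  ~ Bernoulli(p)
#   reverse  v->u | forward     ~ Bernoulli(m + (1 - m) p)
#   reverse  v->u | no forward  ~ Bernoulli(p (1 - m))
# which keeps the marginal link probability at p while the conditional
# reciprocation probability -- the closed-form expected reciprocity --
# is m + (1 - m) p. Pairs touching a hub use p' = min(1, p * hub_boost):
# hubs connect to everyone, inducing the negative degree assortativity
# and the degree centralization seen in coordinator-led care networks.

#' Cohort generator configuration
#'
#' Defaults emulate a three-year repeated cross-sectional wave of
#' home-care patient groups: network sizes near 20 (SD 8) professionals,
#' link probability 0.4 (density), mutuality 0.4 (reciprocity), two
#' high-activity coordinator hubs, the published role mix of a Japanese
#' multidisciplinary home-care workforce, patient ages 83.1 (SD 10.6)
#' and about two thirds female, with the heavy care band (levels 4-5)
#' slightly larger than the light band.
#'
#' @param years Calendar years of the waves.
#' @param groups_per_year Patient groups generated per year.
#' @param size_mean,size_sd Normal node-count distribution, rounded and
#'   truncated at >= 3.
#' @param care_level_probs Probability 5-vector over care levels 1..5.
#' @param role_probs Named probability vector over [role_levels()].
#' @param p_view Marginal link probability per ordered pair.
#' @param mutuality Probability a link is reciprocated beyond chance.
#' @param n_hubs,hub_boost Number of coordinator hubs per group and the
#'   multiplier applied to link probabilities of pairs touching a hub.
#' @param patient_age_mean,patient_age_sd Patient age distribution.
#' @param female_prob Probability a patient is female.
#' @param seed Integer seed; the whole cohort is a deterministic
#'   function of the configuration.
#' @return Object of class `cohort_config`.
#' @export
cohort_config <- function(years = 2018:2020,
                          groups_per_year = 100L,
                          size_mean = 20, size_sd = 8,
                          care_level_probs = c(0.155, 0.155, 0.15, 0.27, 0.27),
                          role_probs = default_role_probs(),
                          p_view = 0.4, mutuality = 0.4,
                          n_hubs = 2L, hub_boost = 4,
                          patient_age_mean = 83.1, patient_age_sd = 10.6,
                          female_prob = 0.67,
                          seed = 20180101L) {
  stopifnot(length(care_level_probs) == 5L, all(care_level_probs >= 0),
            p_view >= 0, p_view <= 1, mutuality >= 0, mutuality <= 1,
            female_prob >= 0, female_prob <= 1, size_mean > 0,
            n_hubs >= 0, hub_boost >= 1, length(years) >= 1L)
  care_level_probs <- care_level_probs / sum(care_level_probs)
  role_probs <- role_probs[role_levels()]
  role_probs[is.na(role_probs)] <- 0
  names(role_probs) <- role_levels()
  role_probs <- role_probs / sum(role_probs)
  structure(list(years = as.integer(years),
                 groups_per_year = as.integer(groups_per_year),
                 size_mean = size_mean, size_sd = size_sd,
                 care_level_probs = care_level_probs,
                 role_probs = role_probs,
                 p_view = p_view, mutuality = mutuality,
                 n_hubs = as.integer(n_hubs), hub_boost = hub_boost,
                 patient_age_mean = patient_age_mean,
                 patient_age_sd = patient_age_sd,
                 female_prob = female_prob, seed = as.integer(seed)),
            class = "cohort_config")
}

#' Default professional role mix
#'
#' Proportions of the eleven-role vocabulary in a multidisciplinary
#' home-care workforce, dominated by home-care nurses, care managers,
#' clinic nurses and care workers.
#'
#' @return Named probability vector over [role_levels()].
#' @export
default_role_probs <- function() {
  counts <- c("physician" = 17, "clinic nurse" = 190, "home care nurse" = 264,
              "pharmacist" = 31, "physical therapist" = 38,
              "occupational therapist" = 36, "care manager" = 224,
              "medical social worker" = 7, "home care worker" = 31,
              "care worker" = 115, "other" = 159)
  counts / sum(counts)
}

#' Paper-scale preset configuration
#'
#' A cohort sized so that the 2018-wave count of analyzable networks
#' (node filter at 10) lands near 241 across both care bands, matching
#' the scale of the study population the defaults emulate.
#'
#' @param seed Integer seed.
#' @return A [cohort_config()].
#' @export
paper_preset <- function(seed = 20180101L) {
  cohort_config(years = 2018:2020, groups_per_year = 263L, seed = seed)
}

# truncated-normal node count, >= 3, by inverse-CDF sampling
draw_sizes <- function(n, mean, sd) {
  lo <- pnorm(2.5, mean, sd)  # round(x) >= 3  <=>  x >= 2.5
  as.integer(round(qnorm(lo + runif(n) * (1 - lo), mean, sd)))
}

#' Generate one synthetic patient group
#'
#' Draws a professional roster of the given size with roles from the
#' configured mix, designates the first `n_hubs` members as coordinator
#' hubs, and emits one POST per professional plus the VIEW_MARK events
#' that realise the pairwise link model described in [cohort_config()].
#' All events are dated within `year`.
#'
#' @param group_id Group identifier.
#' @param year Calendar year.
#' @param size Number of professionals (>= 3).
#' @param cfg A [cohort_config()].
#' @return List with `roster` (data.frame `group_id, actor_id, role`)
#'   and `events` (data.table in [read_events()] layout). Uses the
#'   current RNG state; seed control happens in [generate_cohort()].
#' @export
generate_group <- function(group_id, year, size, cfg = cohort_config()) {
  if (size < 3L) stop("group size must be >= 3", call. = FALSE)
  ids <- sprintf("%s_a%02d", group_id, seq_len(size))
  roles <- sample(names(cfg$role_probs), size, replace = TRUE,
                  prob = cfg$role_probs)
  hubs <- seq_len(min(cfg$n_hubs, size))

  # unordered pairs and their link probability
  pr <- utils::combn(size, 2L)
  touches_hub <- (pr[1L, ] %in% hubs) | (pr[2L, ] %in% hubs)
  p <- ifelse(touches_hub, pmin(1, cfg$p_view * cfg$hub_boost), cfg$p_view)
  m <- cfg$mutuality
  fwd <- runif(ncol(pr)) < p
  p_rev <- ifelse(fwd, m + (1 - m) * p, p * (1 - m))
  rev <- runif(ncol(pr)) < p_rev

  from <- c(pr[1L, fwd], pr[2L, rev])
  to <- c(pr[2L, fwd], pr[1L, rev])

  # one POST per professional, dated uniformly within the year
  msg_ids <- sprintf("%s_m%03d", group_id, seq_len(size))
  post_dates <- as.Date(sprintf("%d-01-01", year)) +
    sample.int(365L, size, replace = TRUE) - 1L
  posts <- data.table::data.table(kind = "POST", message_id = msg_ids,
                                  group_id = group_id, actor_id = ids,
                                  date = post_dates)
  views <- if (length(from)) {
    data.table::data.table(kind = "VIEW_MARK",
                           message_id = msg_ids[from],
                           group_id = group_id,
                           actor_id = ids[to],
                           date = post_dates[from])
  } else posts[0L]
  list(roster = data.frame(group_id = group_id, actor_id = ids, role = roles,
                           stringsAsFactors = FALSE),
       events = rbind(posts, views))
}

#' Generate a synthetic repeated cross-sectional cohort
#'
#' Deterministic given `cfg$seed`: draws group sizes, care levels,
#' patient demographics and all message-log events for every
#' (group, year) cell. Each year is an independent wave of new groups,
#' as in a repeated cross-sectional design.
#'
#' @param cfg A [cohort_config()].
#' @return List with `groups` (patient metadata), `roster`
#'   (professional table) and `events` (log-event table), all directly
#'   consumable by [build_cohort()].
#' @export
generate_cohort <- function(cfg = cohort_config()) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(cfg$seed)

  groups_list <- list(); roster_list <- list(); events_list <- list()
  i <- 0L
  for (yr in cfg$years) {
    n_g <- cfg$groups_per_year
    sizes <- draw_sizes(n_g, cfg$size_mean, cfg$size_sd)
    levels_ <- sample(1:5, n_g, replace = TRUE, prob = cfg$care_level_probs)
    sexes <- ifelse(runif(n_g) < cfg$female_prob, "F", "M")
    ages <- round(rnorm(n_g, cfg$patient_age_mean, cfg$patient_age_sd), 1)
    for (j in seq_len(n_g)) {
      i <- i + 1L
      gid <- sprintf("g%d_%04d", yr, j)
      gg <- generate_group(gid, yr, sizes[j], cfg)
      groups_list[[i]] <- data.frame(group_id = gid, year = yr,
                                     care_level = levels_[j],
                                     patient_sex = sexes[j],
                                     patient_age = ages[j],
                                     stringsAsFactors = FALSE)
      roster_list[[i]] <- gg$roster
      events_list[[i]] <- gg$events
    }
  }
  groups <- data.table::rbindlist(groups_list)
  groups[, care_band := care_band(care_level)]
  list(groups = groups[],
       roster = data.table::rbindlist(roster_list),
       events = data.table::rbindlist(events_list))
}

#' Expected reciprocity of the generator's link model
#'
#' Closed form for the conditional reciprocation probability of the
#' pairwise model: m + (1 - m) p, the large-sample expectation of the
#' derived networks' reciprocity when no hubs are present.
#'
#' @param p_view Marginal link probability.
#' @param mutuality Mutuality parameter m.
#' @return Expected reciprocity in \[0, 1\].
#' @export
expected_reciprocity <- function(p_view, mutuality) {
  mutuality + (1 - mutuality) * p_view
}

#' Write a synthetic cohort to disk
#'
#' @param cohort Result of [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of the three CSV paths, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(events = file.path(dir, "events.csv"),
             groups = file.path(dir, "groups.csv"),
             roster = file.path(dir, "roster.csv"))
  write_events(cohort$events, paths[["events"]])
  data.table::fwrite(cohort$groups, paths[["groups"]])
  data.table::fwrite(cohort$roster, paths[["roster"]])
  invisible(paths)
}
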