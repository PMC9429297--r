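---
title: "Annual structural analysis of care-team information-sharing networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Annual structural analysis of care-team information-sharing networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(carenets)
```

## The problem

Multidisciplinary home-care teams increasingly coordinate through
SNS-style message boards: each patient has a group where registered
professionals (physicians, nurses, care managers, care workers, ...)
post messages and mark others' messages as "viewed". The communication
structure of such a group in a calendar year can be summarised as an
unweighted directed graph: professionals are nodes, and a directed link
$(u, v)$ exists when $v$ marked "viewed" on at least one message posted
by $u$ that year. Because each yearly wave samples whichever patient
groups were active, the design is repeated cross-sectional: year-to-year
samples need not share patients, and differences across years are tested
with a rank-based all-pairs procedure rather than paired methods.

`carenets` implements this analysis end to end: log ingestion and
validation, per-group-per-year network construction, an
analyzable-network filter, ten structural measures, Steel–Dwass
all-pairs year comparisons per care-level stratum, report tables, and a
seeded synthetic log generator standing in for raw data that cannot be
redistributed.

## Network construction

Nodes are the professionals *registered* in the group, not merely the
active ones: a registered professional who neither posted nor viewed is
an isolated node, deliberately retained because it contributes to the
denominator of density and degree centralization. The patient's own
account, if present in the logs, is never a node. Self-view marks
generate no link. A viewer observed in the logs but missing from the
roster is kept as a node with role `"other"` and reported — dropping
observed communication would bias density downward. A link's year is the
year of the *post* it responds to.

Networks with fewer than 10 nodes are excluded from analysis
(`filter_networks`, inclusive threshold, configurable): structural
measures on very small graphs are dominated by integer effects.

## The ten measures and their conventions

For a directed graph $G=(V,E)$, $n=|V|$:

* **Density** $|E| / (n(n-1))$, directed.
* **Reciprocity** — fraction of directed links whose reverse also exists.
* **Degree assortativity** — Pearson correlation of endpoint total
  degrees over the links of the undirected projection (both orientations
  of each link, the standard convention). Undefined on regular graphs
  (zero degree variance); reported as `NA`, never coerced.
* **Clustering** — mean local clustering coefficient of the undirected
  projection; degree-<2 nodes contribute 0.
* **Diameter / mean path length** — longest and mean shortest-path
  length. By default these are computed on the **largest connected
  component of the undirected projection** (`unreachable_policy`),
  because observed care networks are generically not strongly connected
  (isolated nodes exist) yet finite diameters must be reported. Mean
  path length by default averages over all $m^2$ ordered pairs of the
  component *including self-pairs at distance zero* (`path_mode`), an
  unusual but deliberate convention of the emulated analysis; the
  conventional $m(m-1)$ mode is one switch away.
* **Degree, closeness, betweenness scores** — per-network single-number
  summaries of the node centralities. The default is **Freeman
  centralization**: $\sum_i (c_{\max} - c_i)$ divided by its maximum
  over graphs of the same order (attained by the star), giving 1 for a
  star and 0 for any regular graph. The alternative
  (`centrality_aggregation = "mean"`) is the mean normalised centrality;
  both are first-class because a published per-network centrality value
  in $(0,1)$ can be either, and the two interpretations bracket it.
  Closeness uses $c_i = (m-1)/\sum_j d(i,j)$ on the admitted component;
  betweenness uses Brandes' algorithm normalised by $(m-1)(m-2)/2$.

Every convention above sits behind an explicit `metric_config()` knob,
and the pipeline's JSON run log records the configuration used, so any
table is reproducible down to its interpretation choices.

Degenerate inputs: each measure has a stated precondition (density
$n \ge 2$; clustering and the centrality scores $n \ge 3$; link-based
measures at least one link). Violations raise a typed condition,
`carenets_undefined_measure`, which `compute_all()` converts to an `NA`
field — a cohort run never aborts on a degenerate network, and
comparison sample sizes count only defined values.

## The Steel–Dwass procedure

For $k$ yearly samples, each of the $k(k-1)/2$ pairs is mid-ranked in
isolation; the rank sum $W$ of the first sample is standardized with the
tie-corrected variance
$V = \frac{n_x n_y}{N(N-1)}\left(\sum r_i^2 - \frac{N(N+1)^2}{4}\right)$
to $z = (W - E)/\sqrt V$, and $t = |z|\sqrt 2$ is referred to the
studentized range distribution $Q_k$ with infinite degrees of freedom:
$p = P(Q_k \ge t)$. This controls the familywise error across all pairs.
The survival function is computed from scratch by adaptive quadrature of
$1 - k\int \phi(z)\,[\Phi(z) - \Phi(z-q)]^{k-1}\,dz$ (absolute error
below $10^{-8}$); the tests cross-check it against `stats::ptukey` and
the analytic $k=2$ identity $2\Phi(-q/\sqrt2)$. All-tied pairs are
flagged degenerate, not forced to $p = 1$. The test is two-sided;
$\alpha$ defaults to 0.05.

**Small-sample caveat.** This is the *large-sample* formulation. At
group sizes around 5–6 the exact permutation distribution of the max
pairwise statistic is a coarse lattice, and the continuous
studentized-range approximation can differ from it by up to ~0.05 in
absolute $p$ (worst near $p \to 1$, where the permutation tail
saturates). The package ships a permutation oracle
(`steel_dwass_permutation`) that quantifies this; the corresponding
acceptance check is intentionally left failing as documentation of the
limitation, while the null-calibration check (familywise type-I within
[0.03, 0.07] at $n = 30$) passes. At the cohort sizes this package
targets (tens of networks per year) the analytic $p$ is well calibrated.

## What the synthetic generator emulates — and what it does not

The generator stands in for message logs that cannot be redistributed.
It is a *stated world*, fixed before testing, not a tuning dial:

* **Scale and mix** — three yearly waves; node counts $\sim N(20, 8^2)$
  rounded and truncated at 3; care levels with the heavy band (4–5)
  slightly more prevalent than the light band; patient age
  $\sim N(83.1, 10.6^2)$, about two thirds female; professional roles
  drawn from a published workforce mix dominated by home-care nurses,
  care managers, clinic nurses and care workers.
* **Link model** — per unordered pair $\{u,v\}$: a forward link with
  probability $p$ (`p_view = 0.4`); the reverse link with probability
  $m + (1-m)p$ given the forward link and $p(1-m)$ otherwise
  (`mutuality = 0.4`). This keeps the marginal link probability at
  exactly $p$ (so mean derived density recovers 0.40) while the expected
  reciprocity has the closed form $m + (1-m)p = 0.64$
  (`expected_reciprocity()`).
* **Hubs** — `n_hubs = 2` coordinator nodes whose pairs get
  $p' = \min(1, p \cdot \texttt{hub\_boost})$. Hubs connect to everyone,
  which produces the negative degree assortativity and the degree
  centralization characteristic of coordinator-led care networks. With
  the default boost of 4 those pairs saturate, so hub cohorts run denser
  (~0.52) and more reciprocal than the no-hub target values; recovery
  checks for density/reciprocity therefore use `n_hubs = 0`.
* **Mechanics** — links are realised through explicit POST/VIEW_MARK
  events (one post per professional; view-marks create links), so the
  generator exercises the log-to-network pipeline end to end, and every
  generated VIEW_MARK references a generated POST by construction.

Not modelled: message text, within-year timing dynamics, professional
turnover, cross-group professional identity, and the large mass of
near-silent tiny groups in the real system — the `paper_preset()` is
sized to the *analyzable* wave (~241 networks in 2018 at
`groups_per_year = 263`), not the raw group census. A green generator
test therefore establishes that the pipeline recovers configured
structural targets from logs, not that the generator reproduces any real
system's printed values — which is also why the real tables' numbers are
never asserted anywhere in this package.

## Numerical choices

* Quadrature: `stats::integrate` over $(-\infty, \infty)$ with
  `rel.tol = 1e-11`; results clamped to $[0,1]$.
* Centralization ratios clamped to $[0,1]$ against floating-point
  overshoot at the exact extremes (star, complete).
* Largest-component ties broken by lowest node index, deterministically.
* Sample SD ($n-1$) in report tables; a singleton's SD prints as 0.000.
* Seeds: `generate_cohort` derives everything from `cohort_config$seed`
  and restores the caller's RNG state on exit.

## Limitations

* The analytic Steel–Dwass $p$ is asymptotic; below ~10 networks per
  year prefer the permutation oracle.
* Centralities are computed on the undirected projection by design;
  directed-mode distance measures are available but not the directed
  in/out assortativity flavours.
* No weighted, temporal or multilayer variants; no eigenvector-family
  centralities.
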