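Package: carenets
Title: Social Network Analysis of Care-Team Message Logs
Version: 0.1.0
Authors@R: person("carenets", "maintainers", email = "carenets@example.org",
    role = c("aut", "cre"))
Description: Builds per-patient, per-year directed post/view networks of
    healthcare professionals from message-board logs, computes structural
    network measures (density, diameter, path length, clustering,
    assortativity, reciprocity, and Freeman centralization of degree,
    closeness and betweenness centrality), and tests year-to-year
    differences per care-level stratum with the Steel-Dwass all-pairs
    nonparametric procedure on a from-scratch studentized-range
    distribution. Includes a seeded synthetic log-cohort generator for
    repeated cross-sectional study designs and an end-to-end pipeline with
    summary and comparison tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
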