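test_that("analytic graph cases give the known closed-form values", {
  # star: maximal hierarchy for all three centralization scores
  for (n in c(4, 5, 11, 30)) {
    A <- adj_star(n)
    expect_equal(net_degree_score(A), 1)
    expect_equal(net_closeness_score(A), 1)
    expect_equal(net_betweenness_score(A), 1)
  }
  expect_equal(net_assortativity(adj_star(4)), -1)
  expect_equal(net_diameter(adj_star(5)), 2)
  expect_equal(net_clustering(adj_star(5)), 0)

  # complete graph: perfectly even, dense, fully clustered
  for (n in c(3, 10, 30)) {
    A <- adj_complete(n)
    expect_equal(net_degree_score(A), 0)
    expect_equal(net_closeness_score(A), 0)
    expect_equal(net_betweenness_score(A), 0)
  }
  expect_equal(net_density(adj_complete(4)), 1)
  expect_equal(net_clustering(adj_complete(4)), 1)
  expect_equal(net_reciprocity(adj_complete(4)), 1)

  # path on 4 nodes
  P <- adj_path(4)
  expect_equal(net_diameter(P), 3)
  expect_equal(net_degree_score(P), 1 / 3)
  expect_equal(net_betweenness_score(P), 4 / 9)
  expect_equal(net_closeness_score(P), 0.5 / 1.2)

  # density by formula
  set.seed(31)
  A5 <- matrix(FALSE, 5, 5)
  A5[sample(which(row(A5) != col(A5)), 8)] <- TRUE
  expect_equal(net_density(A5), 8 / 20)
})

test_that("path length honors the self-pair convention", {
  tri <- adj_cycle(3)
  expect_equal(net_path_length(tri), 6 / 9)
  expect_equal(net_path_length(tri, metric_config(path_mode = "exclude_self")), 1)
  expect_equal(net_path_length(adj_star(4)), 18 / 16)
})

test_that("reciprocity counts mutual directed links", {
  A <- matrix(FALSE, 3, 3)
  A[1, 2] <- A[2, 1] <- A[1, 3] <- TRUE
  expect_equal(net_reciprocity(A), 2 / 3)
  # any DAG has zero reciprocity
  expect_equal(net_reciprocity(adj_path(6)), 0)
})

test_that("assortativity is undefined on regular graphs, defined elsewhere", {
  expect_true(is.na(net_assortativity(adj_cycle(5))))
  expect_true(is.na(net_assortativity(adj_complete(6))))
  expect_equal(net_assortativity(adj_star(7)), -1)
})

test_that("undefined-measure preconditions raise the dedicated condition", {
  one <- matrix(FALSE, 1, 1)
  expect_error(net_density(one), class = "carenets_undefined_measure")
  iso3 <- matrix(FALSE, 3, 3)
  expect_error(net_diameter(iso3), class = "carenets_undefined_measure")
  expect_error(net_path_length(iso3), class = "carenets_undefined_measure")
  expect_error(net_reciprocity(iso3), class = "carenets_undefined_measure")
  expect_error(net_clustering(matrix(FALSE, 2, 2)),
               class = "carenets_undefined_measure")
  expect_error(net_degree_score(matrix(FALSE, 2, 2)),
               class = "carenets_undefined_measure")
})

test_that("every measure matches its brute-force oracle on random digraphs", {
  set.seed(2024)
  for (i in 1:60) {
    n <- sample(3:12, 1)
    A <- rand_digraph(n, runif(1, 0.1, 0.9))
    if (!any(A)) next
    expect_equal(net_density(A), oracle_density(A), tolerance = 1e-12)
    expect_equal(net_diameter(A), oracle_diameter(A), tolerance = 1e-12)
    expect_equal(net_path_length(A), oracle_path_length(A), tolerance = 1e-12)
    expect_equal(net_clustering(A), oracle_clustering(A), tolerance = 1e-12)
    expect_equal(net_assortativity(A), oracle_assortativity(A), tolerance = 1e-12)
    expect_equal(net_reciprocity(A), oracle_reciprocity(A), tolerance = 1e-12)
    expect_equal(net_degree_score(A), oracle_degree_score(A), tolerance = 1e-12)
    cs <- tryCatch(net_closeness_score(A), carenets_undefined_measure = function(e) NA_real_)
    expect_equal(cs, oracle_closeness_score(A), tolerance = 1e-12)
    bs <- tryCatch(net_betweenness_score(A), carenets_undefined_measure = function(e) NA_real_)
    expect_equal(bs, oracle_betweenness_score(A), tolerance = 1e-12)
    # mean-aggregation mode against its own oracle
    cfgm <- metric_config(centrality_aggregation = "mean")
    expect_equal(net_degree_score(A, cfgm), oracle_degree_score(A, "mean"),
                 tolerance = 1e-12)
    bm <- tryCatch(net_betweenness_score(A, cfgm),
                   carenets_undefined_measure = function(e) NA_real_)
    expect_equal(bm, oracle_betweenness_score(A, "mean"), tolerance = 1e-12)
  }
})

test_that("measures are invariant under node relabelling", {
  set.seed(88)
  for (i in 1:10) {
    n <- sample(4:10, 1)
    A <- rand_digraph(n, 0.4)
    if (!any(A)) next
    perm <- sample(n)
    B <- A[perm, perm]
    for (f in list(net_density, net_diameter, net_path_length, net_clustering,
                   net_reciprocity, net_degree_score)) {
      expect_equal(f(A), f(B), tolerance = 1e-12)
    }
    expect_equal(net_assortativity(A), net_assortativity(B), tolerance = 1e-12)
  }
})

test_that("directed and undirected projections agree on symmetric digraphs", {
  set.seed(12)
  cfg_dir <- metric_config(projection = "directed")
  for (i in 1:8) {
    n <- sample(4:10, 1)
    U <- rand_digraph(n, 0.35)
    A <- U | t(U)                      # fully symmetric digraph
    if (!any(A)) next
    expect_equal(net_diameter(A), net_diameter(A, cfg_dir))
    expect_equal(net_path_length(A), net_path_length(A, cfg_dir), tolerance = 1e-12)
  }
})

test_that("all [0,1]-scaled outputs respect their bounds", {
  set.seed(321)
  for (i in 1:40) {
    A <- rand_digraph(sample(3:12, 1), runif(1, 0.1, 0.9))
    if (!any(A)) next
    rec <- compute_all(adj_to_net(A))
    for (m in c("density", "clustering", "reciprocity", "degree_score",
                "closeness_score", "betweenness_score")) {
      v <- rec[[m]]
      if (!is.na(v)) expect_true(v >= 0 && v <= 1, label = m)
    }
    if (!is.na(rec$assortativity)) {
      expect_true(abs(rec$assortativity) <= 1 + 1e-12)
    }
    if (!is.na(rec$diameter)) expect_gte(rec$diameter, 1)
  }
})

test_that("compute_all flags undefined measures instead of aborting", {
  # complete digraph: centralizations 0, assortativity undefined
  rec <- compute_all(adj_to_net(adj_complete(10)))
  expect_equal(rec$density, 1)
  expect_equal(rec$reciprocity, 1)
  expect_equal(rec$clustering, 1)
  expect_equal(rec$degree_score, 0)
  expect_equal(rec$closeness_score, 0)
  expect_equal(rec$betweenness_score, 0)
  expect_true(is.na(rec$assortativity))

  # star digraph, center posts and all view
  rec2 <- compute_all(adj_to_net(adj_star(11)))
  expect_equal(rec2$degree_score, 1)
  expect_equal(rec2$closeness_score, 1)
  expect_equal(rec2$betweenness_score, 1)

  # linkless network: link-based measures all flagged, run does not abort
  rec3 <- compute_all(adj_to_net(matrix(FALSE, 4, 4)))
  expect_equal(rec3$n_nodes, 4L)
  expect_true(is.na(rec3$diameter))
  expect_true(is.na(rec3$reciprocity))
  expect_equal(rec3$density, 0)
})
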