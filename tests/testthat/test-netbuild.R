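roster_abc <- data.frame(actor_id = c("A", "B", "C"),
                         role = c("physician", "home care nurse", "care manager"))

test_that("a view-mark on u's message creates link (u, v)", {
  ev <- post_with_views("m1", "g1", "A", c("B", "C"))
  net <- build_network(ev, roster_abc, 2018)
  expect_setequal(apply(net$edges, 1, paste, collapse = ">"), c("A>B", "A>C"))
  expect_setequal(net$nodes, c("A", "B", "C"))
})

test_that("posts without view-marks give isolated nodes only", {
  ev <- rbind(event_row("POST", "m1", "g1", "A", "2018-02-01"),
              event_row("POST", "m2", "g1", "B", "2018-03-01"))
  net <- build_network(ev, roster_abc, 2018)
  expect_equal(length(net$nodes), 3L)
  expect_equal(nrow(net$edges), 0L)
})

test_that("links are deduplicated and unweighted", {
  ev <- rbind(post_with_views("m1", "g1", "A", "B"),
              post_with_views("m2", "g1", "B", "A"),
              post_with_views("m3", "g1", "B", "A"))
  net <- build_network(ev, roster_abc, 2018)
  expect_setequal(apply(net$edges, 1, paste, collapse = ">"), c("A>B", "B>A"))
})

test_that("replicating events k times yields the identical network", {
  ev <- rbind(post_with_views("m1", "g1", "A", c("B", "C")),
              post_with_views("m2", "g1", "B", "A"))
  base <- build_network(ev, roster_abc, 2018)
  for (k in 2:4) {
    evk <- ev[rep(seq_len(nrow(ev)), k), ]
    netk <- build_network(evk, roster_abc, 2018)
    expect_equal(sort(apply(netk$edges, 1, paste, collapse = ">")),
                 sort(apply(base$edges, 1, paste, collapse = ">")))
    expect_setequal(netk$nodes, base$nodes)
  }
})

test_that("adding view-marks never removes links or nodes", {
  set.seed(77)
  ev <- post_with_views("m1", "g1", "A", "B")
  net_prev <- build_network(ev, roster_abc, 2018)
  extra <- list(c("m1", "C"), c("m2", "A"), c("m2", "C"))
  ev <- rbind(ev, event_row("POST", "m2", "g1", "B", "2018-05-01"))
  for (e in extra) {
    ev <- rbind(ev, event_row("VIEW_MARK", e[1], "g1", e[2], "2018-06-01"))
    net <- build_network(ev, roster_abc, 2018)
    prev_edges <- apply(net_prev$edges, 1, paste, collapse = ">")
    cur_edges <- apply(net$edges, 1, paste, collapse = ">")
    expect_true(all(prev_edges %in% cur_edges))
    expect_true(all(net_prev$nodes %in% net$nodes))
    net_prev <- net
  }
})

test_that("self-views, out-of-year views and patient accounts are excluded", {
  ev <- rbind(post_with_views("m1", "g1", "A", "A"),            # self-view
              post_with_views("m2", "g1", "A", "B", "2017-12-31"), # wrong year
              post_with_views("m3", "g1", "A", "C"))
  net <- build_network(ev, roster_abc, 2018)
  expect_equal(apply(net$edges, 1, paste, collapse = ">"), "A>C")
  expect_equal(attr(net, "report")$out_of_year_views, 1L)

  # the patient's own account is never a node
  ev2 <- rbind(post_with_views("m1", "g1", "A", c("B", "patient1")))
  net2 <- build_network(ev2, roster_abc, 2018, patient_id = "patient1")
  expect_false("patient1" %in% net2$nodes)
  expect_equal(apply(net2$edges, 1, paste, collapse = ">"), "A>B")
})

test_that("off-roster viewers are kept as nodes with role other and reported", {
  ev <- post_with_views("m1", "g1", "A", c("B", "Z"))
  net <- build_network(ev, roster_abc, 2018)
  expect_true("Z" %in% net$nodes)
  expect_equal(unname(net$roles[["Z"]]), "other")
  expect_equal(attr(net, "report")$off_roster_viewers, "Z")
})

test_that("no self-loops and link count bounded by n(n-1) on random event logs", {
  set.seed(99)
  for (i in 1:25) {
    n <- sample(3:8, 1)
    actors <- sprintf("a%d", seq_len(n))
    ev <- do.call(rbind, lapply(seq_len(10), function(m) {
      post_with_views(sprintf("m%d", m), "g1", sample(actors, 1),
                      sample(actors, sample(0:n, 1), replace = TRUE))
    }))
    net <- build_network(ev, actors, 2018)
    expect_true(all(net$edges[, 1] != net$edges[, 2]))
    expect_lte(nrow(net$edges), length(net$nodes) * (length(net$nodes) - 1))
  }
})

test_that("filter_networks applies the inclusive node threshold", {
  nets <- lapply(c(5, 9, 10, 15), sized_net)
  kept <- filter_networks(nets, min_nodes = 10)
  expect_equal(length(kept), 2L)
  expect_equal(attr(kept, "excluded"), 2L)
  expect_equal(vapply(kept, n_nodes, integer(1)), c(10L, 15L))

  expect_equal(length(filter_networks(list())), 0L)
  expect_error(filter_networks(nets, min_nodes = 1), ">= 2")

  # brute-force census over random sizes
  set.seed(5)
  sizes <- sample(3:25, 100, replace = TRUE)
  nets2 <- lapply(seq_along(sizes), function(i) sized_net(sizes[i], sprintf("q%d", i)))
  expect_equal(length(filter_networks(nets2, 10)), sum(sizes >= 10))
})

test_that("build_cohort yields one network per active group-year", {
  groups <- data.frame(group_id = rep(c("g1", "g2", "g3"), each = 2),
                       year = rep(2018:2019, 3), care_level = 2,
                       patient_sex = "F", patient_age = 84)
  roster <- data.frame(group_id = rep(c("g1", "g2", "g3"), each = 3),
                       actor_id = paste0(rep(c("g1", "g2", "g3"), each = 3), "_", 1:3),
                       role = "other")
  mk <- function(g, yr) post_with_views(sprintf("%s_%d", g, yr), g,
                                        paste0(g, "_1"), paste0(g, "_2"),
                                        sprintf("%d-06-01", yr))
  # g3 silent in 2019
  ev <- rbind(mk("g1", 2018), mk("g1", 2019), mk("g2", 2018), mk("g2", 2019),
              mk("g3", 2018))
  nets <- build_cohort(ev, groups, roster)
  expect_equal(length(nets), 5L)
  expect_equal(sum(vapply(nets, function(n) n$group_id == "g1", logical(1))), 2L)

  # group with events but no metadata row: reported, excluded
  ev2 <- rbind(ev, mk("g9", 2018))
  nets2 <- build_cohort(ev2, groups, roster)
  expect_equal(length(nets2), 5L)
  rep2 <- attr(nets2, "report")
  expect_equal(rep2$missing_metadata, 1L)
  expect_equal(rep2$missing_metadata_groups, "g9")
  expect_equal(rep2$group_years_active, rep2$networks_built + rep2$missing_metadata)
})
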