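test_that("degenerate snapshots: all-synchronized and all-below threshold", {
  g <- complete_graph(6)
  snap <- find_clusters(rep(1, 6), g, threshold = 0.5)
  expect_length(snap$clusters, 1)
  expect_equal(snap$clusters[[1]]$members, 1:6)
  expect_length(snap$unclustered, 0)
  expect_lte(length(snap$clusters[[1]]$central), 5)

  # triangle with phases 2*pi/3 apart: r = 0.5 < 0.6 everywhere
  snap2 <- find_clusters(c(0, 2 * pi / 3, 4 * pi / 3), complete_graph(3),
                         threshold = 0.6)
  expect_length(snap2$clusters, 0)
  expect_equal(snap2$unclustered, 1:3)
  expect_error(find_clusters(rep(1, 6), g, threshold = 0),
               class = "tesync_parameter_error")
})

test_that("a sub-threshold node blocks expansion along a path", {
  # 6-node path, phases chosen so r is 1,1,1,0,0,1: the supra block
  # {1,2,3} forms one cluster and the far leaf 6 is cut off by 4-5
  g <- path_graph(6)
  theta <- c(0, 0, 0, 0, pi, pi)
  r <- local_order(theta, g)
  expect_equal(r, c(1, 1, 1, 0, 0, 1))
  snap <- find_clusters(theta, g, threshold = 0.5)
  sets <- member_sets(snap)
  expect_true(same_partition(sets, list(c(1L, 2L, 3L), 6L)))
  expect_true(same_partition(sets, components_oracle(theta, g, 0.5)))
})

test_that("cluster member sets equal supra-threshold connected components", {
  set.seed(99)
  for (rep in 1:100) {
    n <- sample(5:12, 1)
    g <- random_small_graph(n, p = runif(1, 0.2, 0.6))
    theta <- runif(n, 0, 2 * pi)
    thr <- runif(1, 0.3, 0.8)
    snap <- find_clusters(theta, g, thr)
    expect_true(same_partition(member_sets(snap),
                               components_oracle(theta, g, thr)))
    # partition property: clusters disjoint, union + unclustered = all
    all_members <- unlist(member_sets(snap))
    expect_false(anyDuplicated(all_members) > 0)
    expect_setequal(c(all_members, snap$unclustered), seq_len(n))
  }
})

test_that("raising the threshold never enlarges a cluster", {
  set.seed(7)
  for (rep in 1:20) {
    g <- random_small_graph(10, 0.4)
    theta <- runif(10, 0, 2 * pi)
    lo <- find_clusters(theta, g, 0.4)
    hi <- find_clusters(theta, g, 0.6)
    for (cl in member_sets(hi)) {
      containing <- Filter(function(x) all(cl %in% x), member_sets(lo))
      expect_gte(length(containing), 1)
    }
  }
})

test_that("identities persist through time and main-cluster time accrues", {
  # two-epoch window on a path: 1-2-3 synchronized throughout, node 4
  # joining for the second half (via its neighbourhood coherence)
  g <- path_graph(6)
  epoch1 <- c(0, 0, 0, 0, pi, pi)    # r = 1 1 1 0 0 1
  epoch2 <- c(0, 0, 0, 0, 0, 0)      # r = 1 everywhere
  panel <- rbind(matrix(epoch1, 5, 6, byrow = TRUE),
                 matrix(epoch2, 6, 6, byrow = TRUE))
  w <- window_from_panel(panel, g, stride = 1)
  lin <- track_clusters(w, g, threshold = 0.5, eval_stride = 1)
  expect_length(lin$snapshots, 11)
  # the main cluster keeps one persistent id across the epoch change
  expect_length(unique(lin$main_cluster$cluster), 1)
  # membership instants (initial instant carries no time): nodes 1-3
  # all 10 instants, node 4 the 6 second-epoch instants
  expect_equal(lin$time_in_main[1:4], c(10, 10, 10, 6))
  expect_equal(max(lin$time_in_main), 10)

  # static fully synchronized window: everyone spends the full window
  w2 <- window_from_panel(matrix(0, 11, 6), g, stride = 1)
  lin2 <- track_clusters(w2, g, 0.5, eval_stride = 1)
  expect_equal(lin2$time_in_main, rep(10, 6))

  # static incoherent window: no main-cluster time at all
  g3 <- complete_graph(3)
  w3 <- window_from_panel(matrix(rep(c(0, 2 * pi / 3, 4 * pi / 3),
                                     each = 11), 11, 3), g3, stride = 1)
  lin3 <- track_clusters(w3, g3, 0.6, eval_stride = 1)
  expect_equal(lin3$time_in_main, rep(0, 3))
})

test_that("residence statistics use median and population variance", {
  mk <- function(x) structure(list(time_in_main = x),
                              class = "cluster_lineage")
  st <- time_in_main_stats(list(mk(c(10, 0)), mk(c(30, 0))))
  expect_equal(st$median_time, c(20, 0))
  expect_equal(st$var_time, c(100, 0))   # population convention
  st1 <- time_in_main_stats(list(mk(c(7, 3))))
  expect_equal(st1$median_time, c(7, 3))
  expect_equal(st1$var_time, c(0, 0))
})

test_that("driver selection applies all three thresholds", {
  g <- fixture_graph()
  st <- tibble::tibble(node = 1:60,
                       median_time = rep(5, 60),
                       var_time = rep(100, 60))
  # nobody qualifies with defaults on this small fixture
  expect_identical(nrow(driver_nodes(st, g)), 0L)
  od <- out_degree(g)
  hi <- which(od > 10)[1:3]
  st$median_time[hi] <- c(45, 40, 50)
  st$var_time[hi] <- 10
  got <- driver_nodes(st, g, min_out_degree = 10, min_median = 35,
                      max_variance = 49)
  expect_setequal(got$node, hi)
  # sorted by median descending
  expect_equal(got$median_time, sort(got$median_time, decreasing = TRUE))
  # high out-degree alone is not enough
  lone <- which.max(od)
  expect_false(lone %in%
    driver_nodes(st, g, min_out_degree = 10, min_median = 60,
                 max_variance = 49)$node)
})
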