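test_that("small-world generator respects the lattice limit and conserves edges", {
  # p = 0: pure ring lattice, every node has degree exactly k
  g0 <- make_small_world(10, 4, 0, seed = 1)
  expect_equal(in_degree(g0), rep(4L, 10))
  expect_false(g0$directed)
  expect_true(all(g0$weights %in% c(0, 1)))
  # full rewiring still conserves the edge count n*k/2
  for (s in 1:5) {
    g1 <- make_small_world(20, 4, 1, seed = s)
    expect_identical(n_edges(g1), 40L)
    expect_true(all(diag(g1$weights) == 0))
  }
  expect_error(make_small_world(10, 11, 0.1), class = "tesync_parameter_error")
  expect_error(make_small_world(10, 3, 0.1), class = "tesync_parameter_error")
  expect_error(make_small_world(10, 4, 1.5), class = "tesync_parameter_error")
})

test_that("scale-free generator matches the growth convention", {
  # n = m + 1 attaches every new node to all existing ones: complete K5
  g <- make_scale_free(5, 4, seed = 1)
  expect_equal(g$weights, complete_graph(5)$weights)
  # growth from a single node: sum_i min(m, i-1) edges
  g2 <- make_scale_free(100, 5, seed = 2)
  expect_identical(n_edges(g2), 5L * 95L + 10L)
  expect_error(make_scale_free(5, 5), class = "tesync_parameter_error")
})

test_that("random graph generator hits the G(n, p) contract", {
  # mean_degree = n - 1 forces the complete graph, whose L_p is exactly 1
  g <- make_random(10, 9, seed = 1)
  expect_equal(g$weights, complete_graph(10)$weights)
  expect_equal(graph_metrics(g)$avg_path_length, 1)
  # dense-regime closed form: L ~ 2 - p when nearly all pairs are at
  # distance <= 2
  gm <- graph_metrics(make_random(426, 45, seed = 3))
  expect_equal(gm$avg_path_length, 2 - 45 / 425, tolerance = 0.02)
})

test_that("metrics recover textbook values on degenerate graphs", {
  expect_equal(graph_metrics(complete_graph(8))$avg_path_length, 1)
  # a path is a tree: no triangles, clustering exactly 0
  expect_equal(graph_metrics(path_graph(10))$clustering_coeff, 0)
  # ring lattice: strongly clustered, long paths -> omega < 0
  expect_lt(graph_metrics(make_small_world(100, 10, 0, seed = 1),
                          reference = "sampled")$small_world_omega, 0)
  # random graph: omega close to 1
  expect_gt(graph_metrics(make_random(200, 10, seed = 1),
                          reference = "sampled")$small_world_omega, 0.5)
  expect_error(graph_metrics(empty_graph(1)), class = "tesync_parameter_error")
})

test_that("scale-free degree distribution has a heavy-tail log-log slope", {
  gam <- mean(vapply(1:3, function(s)
    graph_metrics(make_scale_free(400, 20, seed = s))$powerlaw_exponent,
    numeric(1)))
  expect_lt(abs(gam - (-2)), 0.6)
})

test_that("connectome loading rescales, binarizes and cleans self-loops", {
  el <- tempfile(fileext = ".csv")
  writeLines(c("source target weight", "a b 2", "b c 4", "c a 5.0"), el)
  g <- load_connectome(el, "edge_list")
  expect_equal(max(g$weights), 1)           # rescaled by the maximum
  expect_equal(sort(unique(as.vector(g$weights))), c(0, 0.4, 0.8, 1))
  expect_true(g$directed && g$weighted)

  # binarize: exactly the positive entries become 1
  el2 <- tempfile(fileext = ".txt")
  writeLines(c("1 2 2", "2 3 4"), el2)
  gb <- load_connectome(el2, "edge_list", binarize = TRUE)
  expect_equal(sum(gb$weights), 2)
  expect_true(all(gb$weights %in% c(0, 1)))

  # dense matrix with a self-loop: diagonal zeroed with a warning
  dm <- tempfile(fileext = ".csv")
  m <- matrix(c(0.5, 1, 0, 0, 0, 2, 0, 0, 0), 3, 3)
  write.table(m, dm, sep = ",", row.names = FALSE, col.names = FALSE)
  expect_warning(gd <- load_connectome(dm, "dense_matrix"), "self-loops")
  expect_equal(diag(gd$weights), rep(0, 3))
  expect_equal(max(gd$weights), 1)

  # negative weights are a format error
  dm2 <- tempfile(fileext = ".csv")
  write.table(matrix(c(0, -1, 1, 0), 2, 2), dm2, sep = ",",
              row.names = FALSE, col.names = FALSE)
  expect_error(load_connectome(dm2, "dense_matrix"),
               class = "tesync_format_error")

  # symmetrize takes the elementwise max
  gs <- load_connectome(el, "edge_list", symmetrize = TRUE)
  expect_false(gs$directed)
  expect_equal(gs$weights, t(gs$weights))
})

test_that("edge-list writer round-trips through the loader", {
  g <- make_synthetic_connectome(n_regions = 20, n_modules = 2, seed = 3)
  f <- tempfile(fileext = ".csv")
  write_edge_list(g, f)
  g2 <- load_connectome(f, "edge_list")
  # loader interns labels in file order; compare via label matching
  perm <- match(g$node_labels, g2$node_labels)
  expect_equal(g2$weights[perm, perm], g$weights, tolerance = 1e-12)
})

test_that("synthetic connectome keeps its structural contracts", {
  for (s in 1:3) {
    g <- make_synthetic_connectome(seed = s)
    expect_equal(max(g$weights), 1)
    expect_gte(min(g$weights), 0)
    expect_equal(diag(g$weights), rep(0, 60))
    expect_identical(length(unique(g$modules)), 6L)
  }
  # inter_density = 0 isolates the modules: at least n_modules weak
  # components per hemisphere
  g0 <- make_synthetic_connectome(n_regions = 40, n_modules = 2,
                                  intra_density = 0.6, inter_density = 0,
                                  seed = 1)
  comp <- igraph::components(as_igraph(g0, skeleton = TRUE))
  expect_gte(comp$no, 4)
  expect_error(make_synthetic_connectome(n_regions = 21),
               class = "tesync_parameter_error")
  expect_error(make_synthetic_connectome(intra_density = 0.1,
                                         inter_density = 0.2),
               class = "tesync_parameter_error")
})

test_that("planted modules are recovered by community detection", {
  for (s in 1:10) {
    g <- make_synthetic_connectome(seed = s)
    part <- detect_communities(g, seed = s)
    ari <- tesync:::adjusted_rand(part$community, g$modules)
    expect_gte(ari, 0.9)
  }
})
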