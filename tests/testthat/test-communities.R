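test_that("two disconnected cliques are split exactly in two", {
  w <- matrix(0, 8, 8)
  w[1:4, 1:4] <- 1
  w[5:8, 5:8] <- 1
  diag(w) <- 0
  g <- sync_network(w, directed = FALSE, weighted = FALSE)
  part <- detect_communities(g, seed = 1)
  expect_identical(attr(part, "n_communities"), 2L)
  expect_length(unique(part$community[1:4]), 1)
  expect_length(unique(part$community[5:8]), 1)
  expect_false(part$community[1] == part$community[5])
})

test_that("reported modularity equals a direct evaluation of the formula", {
  g <- make_small_world(10, 4, 0, seed = 1)  # ring lattice
  part <- detect_communities(g, seed = 2)
  # direct Q = (1/2m) sum_ij (A_ij - k_i k_j / 2m) delta(c_i, c_j)
  A <- g$weights
  k <- rowSums(A)
  m2 <- sum(A)
  delta <- outer(part$community, part$community, "==")
  Q_direct <- sum((A - outer(k, k) / m2) * delta) / m2
  expect_equal(attr(part, "Q"), Q_direct, tolerance = 1e-12)
})

test_that("community detection is reproducible given a seed", {
  g <- fixture_graph()
  p1 <- detect_communities(g, seed = 5)
  p2 <- detect_communities(g, seed = 5)
  expect_identical(p1$community, p2$community)
  f <- tempfile(fileext = ".csv")
  write_partition(p1, f)
  expect_equal(read_partition(f)$community, p1$community)
})

test_that("intramodular synchrony matches hand-computed phasor moduli", {
  g <- complete_graph(6)
  part <- partition_from_labels(c("a", "a", "a", "b", "b", "b"))
  # community a fully aligned; community b at 0, pi/2, pi
  panel <- matrix(c(1, 1, 1, 0, pi / 2, pi), nrow = 1)
  w <- window_from_panel(panel, g)
  ims <- intramodular_synchrony(list(w), part)
  expect_equal(ims$ims_mean[ims$community == 1], 1)
  expect_equal(ims$ims_mean[ims$community == 2], 1 / 3)  # |1 + i - 1| / 3
  # antiphase pair: zero
  part2 <- partition_from_labels(c("a", "a", "b", "b", "b", "b"))
  panel2 <- matrix(c(0, pi, 0, 0, 0, 0), nrow = 1)
  ims2 <- intramodular_synchrony(list(window_from_panel(panel2, g)), part2)
  expect_equal(ims2$ims_mean[ims2$community == 1], 0)
  # empty community is an error
  bad <- partition_from_labels(c("a", "a", "a", "a", "a", "a"))
  bad$community[1] <- 3L
  expect_error(intramodular_synchrony(list(w), bad[-1, ]),
               class = "tesync_parameter_error")
})

test_that("intermodular synchrony follows the closed-form phasor identity", {
  g <- complete_graph(6)
  part <- partition_from_labels(c("a", "a", "a", "b", "b", "b"))
  # both communities aligned at the same phase: 1
  w1 <- window_from_panel(matrix(rep(0.4, 6), 1), g)
  expect_equal(intermodular_synchrony(list(w1), part)$ims_mean, 1)
  # internally aligned but in antiphase: |0.5 (1 + e^{i pi})| = 0
  w2 <- window_from_panel(matrix(c(0, 0, 0, pi, pi, pi), 1), g)
  expect_equal(intermodular_synchrony(list(w2), part)$ims_mean, 0)
  # P1 = 1, P2 = i: |0.5 (1 + i)| = sqrt(2)/2
  w3 <- window_from_panel(matrix(c(0, 0, 0, rep(pi / 2, 3)), 1), g)
  expect_equal(intermodular_synchrony(list(w3), part)$ims_mean,
               sqrt(2) / 2)
})

test_that("literal double sum and phasor shortcut agree to machine precision", {
  set.seed(11)
  for (rep in 1:20) {
    theta <- runif(9, 0, 2 * pi)
    idx1 <- 1:4
    idx2 <- 5:9
    literal <- tesync:::ims_pair_literal(theta, idx1, idx2)
    shortcut <- Mod(0.5 * (mean(exp(1i * theta[idx1])) +
                           mean(exp(1i * theta[idx2]))))
    expect_equal(literal, shortcut, tolerance = 1e-12)
    # symmetry of the literal form
    expect_equal(literal, tesync:::ims_pair_literal(theta, idx2, idx1),
                 tolerance = 1e-12)
  }
})

test_that("self-pairing reduces intermodular to intramodular synchrony", {
  g <- complete_graph(6)
  part <- partition_from_labels(c("a", "a", "a", "b", "b", "b"))
  set.seed(3)
  w <- window_from_panel(matrix(runif(18, 0, 2 * pi), 3), g)
  intra <- intramodular_synchrony(list(w), part)
  inter <- intermodular_synchrony(list(w), part, include_self = TRUE)
  for (cc in 1:2) {
    expect_equal(inter$ims_mean[inter$c1 == cc & inter$c2 == cc],
                 intra$ims_mean[intra$community == cc], tolerance = 1e-12)
  }
})

test_that("trial averaging pools windows pointwise", {
  g <- complete_graph(4)
  part <- partition_from_labels(c("a", "a", "a", "a"))
  w1 <- window_from_panel(matrix(rep(0, 4), 1), g)           # IMS 1
  w2 <- window_from_panel(matrix(c(0, pi, 0, pi), 1), g)     # IMS 0
  ims <- intramodular_synchrony(list(w1, w2), part)
  expect_equal(ims$ims_mean, 0.5)
  expect_equal(ims$n_trials, 2L)
})
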