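test_that("order parameters match hand-computed phasor sums", {
  g <- graph_from_edges(4, rbind(c(2, 1), c(3, 1), c(4, 1)))  # star on 1
  # all neighbours in phase
  expect_equal(local_order(c(0, 1, 1, 1), g)[1], 1)
  # two equal neighbours in antiphase cancel
  g2 <- graph_from_edges(3, rbind(c(2, 1), c(3, 1)))
  expect_equal(local_order(c(0.7, 0, pi), g2)[1], 0)
  # three unit neighbours at 0, pi/2, pi: |1 + i - 1| / 3 = 1/3
  expect_equal(local_order(c(0, 0, pi / 2, pi), g)[1], 1 / 3)

  expect_equal(global_order(rep(1.3, 5)), 1)
  expect_equal(global_order(c(0, 2 * pi / 3, 4 * pi / 3)), 0)
  expect_equal(global_order(c(0, pi / 2)), sqrt(2) / 2)
})

test_that("isolated nodes get zero local synchrony and free rotation", {
  g <- empty_graph(3)
  p <- model_params(lambda_o = 0.5)
  s <- init_state(g, p, 1)
  expect_equal(local_order(s$theta, g), rep(0, 3))
  d <- derivatives(s, g, p)
  expect_equal(d$dtheta, s$omega)
  expect_equal(d$dlam, rep(0, 3))  # lambda = lambda_o, r = 0: fixed point
})

test_that("derivatives match a nested-loop evaluation of the equations", {
  set.seed(42)
  for (rep in 1:20) {
    n <- sample(3:6, 1)
    g <- if (rep %% 2) random_small_graph(n) else random_weighted_graph(n)
    p <- if (rep %% 3 == 0) model_params(fixed_lambda = runif(1, 0, 2))
         else model_params(lambda_o = runif(1, 0, 0.5))
    s <- init_state(g, p, rep)
    if (is.null(p$fixed_lambda))
      s$lam <- runif(n, 0, p$lambda_o)  # exercise off-bath resources
    got <- derivatives(s, g, p)
    want <- derivatives_oracle(s, g, p)
    expect_equal(got$dtheta, want$dtheta, tolerance = 1e-12)
    expect_equal(got$dlam, want$dlam, tolerance = 1e-12)
  }
})

test_that("two-node fixed-resource example evaluates by hand", {
  g <- graph_from_edges(2, rbind(c(1, 2)))
  p <- model_params(fixed_lambda = 1)
  s <- structure(list(theta = c(0, pi / 2), omega = c(0.3, -0.2),
                      lam = c(1, 1)), class = "oscillator_state")
  d <- derivatives(s, g, p)
  # node 1 sees its single neighbour at pi/2: r = 1, coupling sin(pi/2)
  expect_equal(d$dtheta[1], 0.3 + 1)
  expect_equal(d$dtheta[2], -0.2 - 1)
})

test_that("initial states are seeded, uniform and mode-consistent", {
  g <- empty_graph(2000)
  p <- model_params(lambda_o = 0.3)
  s1 <- init_state(g, p, 7)
  s2 <- init_state(g, p, 7)
  expect_identical(s1, s2)
  expect_true(all(s1$theta >= 0 & s1$theta < 2 * pi))
  # CLT bound on the natural-frequency mean: 3 SE of Uniform(-1, 1)
  se <- (2 / sqrt(12)) / sqrt(2000)
  expect_lt(abs(mean(s1$omega)), 3 * se)
  expect_equal(s1$lam, rep(0.3, 2000))
  pf <- model_params(fixed_lambda = 0.1)
  expect_equal(init_state(g, pf, 1)$lam, rep(0.1, 2000))
})

test_that("simulation is deterministic and respects the resource bound", {
  g <- make_small_world(60, 8, 0.2, seed = 2)
  p <- model_params(lambda_o = 0.4)
  t1 <- simulate_dynamics(g, p, 100, seed = 5, record_per_node = TRUE)
  t2 <- simulate_dynamics(g, p, 100, seed = 5, record_per_node = TRUE)
  expect_identical(t1$R, t2$R)
  expect_identical(attr(t1, "theta"), attr(t2, "theta"))
  expect_true(all(t1$R >= 0 & t1$R <= 1))
  r <- attr(t1, "r")
  expect_true(all(r >= 0 & r <= 1))
  # lambda_i(0) = lambda_o implies lambda_i(t) <= lambda_o for all t
  expect_true(all(attr(t1, "lambda") <= p$lambda_o + 1e-12))
})

test_that("quiescent resources relax exponentially toward the bath", {
  g <- empty_graph(4)
  p <- model_params(lambda_o = 0.2, alpha = 0.01, dt = 0.05)
  s <- init_state(g, p, 1)
  s$lam <- rep(0.05, 4)  # start below the bath
  tr <- simulate_dynamics(g, p, 5, state = s, record_stride = 0.05,
                          record_per_node = TRUE)
  lam <- attr(tr, "lambda")[, 1]
  k <- seq_along(lam) - 1
  # exact Euler solution of dlam = alpha (lambda_o - lam)
  euler <- 0.2 + (0.05 - 0.2) * (1 - p$alpha * p$dt)^k
  expect_equal(lam, euler, tolerance = 1e-12)
  # and within O(dt) of the continuous exponential over 100 steps
  exact <- 0.2 + (0.05 - 0.2) * exp(-p$alpha * k * p$dt)
  expect_lt(max(abs(lam - exact)), 1e-4)
  # started exactly at the bath with no coupling: pinned there
  s2 <- init_state(g, p, 1)
  tr2 <- simulate_dynamics(g, p, 5, state = s2, record_per_node = TRUE)
  expect_true(all(attr(tr2, "lambda") == 0.2))
})

test_that("zero fixed resource keeps the network at the incoherent level", {
  g <- make_small_world(400, 40, 0.232, seed = 1)
  p <- model_params(fixed_lambda = 0)
  tr <- simulate_dynamics(g, p, 100, seed = 3)
  # incoherent phasor scaling: time-averaged R of order 1/sqrt(N)
  expect_lt(mean(tr$R), 3 / sqrt(400))
})

test_that("trajectory table round-trips through CSV", {
  g <- make_small_world(30, 6, 0.2, seed = 1)
  tr <- simulate_dynamics(g, model_params(lambda_o = 0.2), 20, seed = 1)
  f <- tempfile(fileext = ".csv")
  write_trajectory(tr, f)
  tr2 <- read_trajectory(f)
  expect_equal(tr2$R, tr$R, tolerance = 1e-15)
  expect_equal(tr2$mean_lambda, tr$mean_lambda, tolerance = 1e-15)
})

test_that("parameter validation rejects inconsistent modes", {
  expect_error(model_params(lambda_o = 0.1, fixed_lambda = 0.1),
               class = "tesync_parameter_error")
  expect_error(model_params(), class = "tesync_parameter_error")
  expect_error(model_params(lambda_o = 0.1, dt = 0),
               class = "tesync_parameter_error")
  expect_error(model_params(lambda_o = 0.1, alpha = -1),
               class = "tesync_parameter_error")
})
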