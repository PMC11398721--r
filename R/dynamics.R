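#' Model parameters for the adaptive-coupling resource-constrained model
#'
#' The dynamics couple each oscillator's phase to its neighbours with a
#' gain set jointly by its local synchrony \eqn{r_i} and its
#' excitability resource \eqn{\lambda_i}:
#' \deqn{\dot\theta_i = \omega_i + \lambda_i r_i \sum_j W_{ij}
#'   \sin(\theta_j - \theta_i)}
#' \deqn{\dot\lambda_i = \alpha (\lambda_o - \lambda_i) - \beta r_i}
#' Exactly one of the two resource modes is active: the
#' resource-constrained mode (give `lambda_o`; \eqn{\lambda_i} evolves)
#' or the fixed-resource mode (give `fixed_lambda`; \eqn{\lambda_i
#' \equiv \Lambda}, the resource equation is dropped).
#'
#' @param alpha resource recovery rate per unit time (> 0).
#' @param beta maximal consumption rate per unit time (> 0); actual
#'   consumption is `beta * r_i`.
#' @param lambda_o resource-bath capacity (>= 0), resource mode.
#' @param fixed_lambda fixed resource level, fixed mode.
#' @param dt Euler step size in time units.
#' @param omega_range interval of the uniform natural-frequency
#'   distribution.
#' @return a `model_params` object.
#' @export
model_params <- function(alpha = 0.01, beta = 0.002, lambda_o = NULL,
                         fixed_lambda = NULL, dt = 0.05,
                         omega_range = c(-1, 1)) {
  p <- structure(list(alpha = alpha, beta = beta, lambda_o = lambda_o,
                      fixed_lambda = fixed_lambda, dt = dt,
                      omega_range = omega_range),
                 class = "model_params")
  errs <- validate_params(p)
  if (length(errs)) abort(paste(errs, collapse = "; "),
                          class = "tesync_parameter_error")
  p
}

validate_params <- function(p) {
  errs <- character()
  if (!is.numeric(p$alpha) || p$alpha <= 0) errs <- c(errs, "alpha must be > 0")
  if (!is.numeric(p$beta) || p$beta <= 0) errs <- c(errs, "beta must be > 0")
  if (!is.numeric(p$dt) || p$dt <= 0) errs <- c(errs, "dt must be > 0")
  fixed <- !is.null(p$fixed_lambda)
  reso <- !is.null(p$lambda_o)
  if (fixed == reso)
    errs <- c(errs, "exactly one of lambda_o / fixed_lambda must be given")
  if (reso && p$lambda_o < 0) errs <- c(errs, "lambda_o must be >= 0")
  if (length(p$omega_range) != 2 || diff(p$omega_range) < 0)
    errs <- c(errs, "omega_range must be an increasing interval")
  errs
}

is_fixed_mode <- function(p) !is.null(p$fixed_lambda)

#' @export
print.model_params <- function(x, ...) {
  mode <- if (is_fixed_mode(x))
    sprintf("fixed-resource (Lambda = %g)", x$fixed_lambda)
  else sprintf("resource-constrained (lambda_o = %g)", x$lambda_o)
  cat(sprintf("<model_params> %s; alpha = %g, beta = %g, dt = %g\n",
              mode, x$alpha, x$beta, x$dt))
  invisible(x)
}

#' Draw an initial oscillator state
#'
#' Phases uniform in `[0, 2*pi)`, natural frequencies uniform over
#' `p$omega_range`, resources initialised at the bath capacity
#' `lambda_o` (resource mode) or pinned at `fixed_lambda` (fixed mode).
#'
#' @param g a [sync_network()].
#' @param p a [model_params()].
#' @param seed integer seed; the draw is reproducible.
#' @return an `oscillator_state`: list with numeric vectors `theta`,
#'   `omega`, `lam`.
#' @export
init_state <- function(g, p, seed = 1L) {
  n <- n_nodes(g)
  with_seed(seed, {
    theta <- runif(n, 0, 2 * pi)
    omega <- runif(n, p$omega_range[1], p$omega_range[2])
    lam <- rep(if (is_fixed_mode(p)) p$fixed_lambda else p$lambda_o, n)
    structure(list(theta = theta, omega = omega, lam = lam),
              class = "oscillator_state")
  })
}

#' Local synchrony of each node
#'
#' \eqn{r_i = |\sum_j W_{ij} e^{i\theta_j}| / s_i} with \eqn{s_i =
#' \sum_j W_{ij}} the in-strength (in-degree on binary graphs).
#' Isolated nodes (no in-edges) get `r_i = 0`.
#'
#' @param theta numeric vector of phases.
#' @param g a [sync_network()].
#' @return numeric vector in `[0, 1]`.
#' @export
local_order <- function(theta, g) {
  stopifnot(length(theta) == n_nodes(g))
  s <- in_strength(g)
  Cc <- as.vector(g$weights %*% cos(theta))
  Ss <- as.vector(g$weights %*% sin(theta))
  r <- numeric(length(theta))
  pos <- s > 0
  r[pos] <- sqrt(Cc[pos]^2 + Ss[pos]^2) / s[pos]
  pmin(r, 1)
}

#' Global order parameter
#'
#' Modulus of the population-mean phasor: 0 for complete incoherence,
#' 1 for full phase locking.
#'
#' @param theta numeric vector of phases (length >= 1).
#' @return scalar in `[0, 1]`.
#' @export
global_order <- function(theta) {
  stopifnot(length(theta) >= 1)
  min(1, Mod(mean(exp(1i * theta))))
}

#' Instantaneous derivatives of the model
#'
#' Reference implementation of the phase and resource derivatives,
#' exactly the quantities the integrator steps with.  In fixed mode the
#' resource derivative is zero.
#'
#' @param state an [init_state()] result (or compatible list).
#' @param g a [sync_network()].
#' @param p a [model_params()].
#' @return list with numeric vectors `dtheta` and `dlam`.
#' @export
derivatives <- function(state, g, p) {
  r <- local_order(state$theta, g)
  cs <- cos(state$theta); sn <- sin(state$theta)
  Cc <- as.vector(g$weights %*% cs)
  Ss <- as.vector(g$weights %*% sn)
  coupling <- cs * Ss - sn * Cc  # sum_j W_ij sin(theta_j - theta_i)
  lam_eff <- if (is_fixed_mode(p)) rep(p$fixed_lambda, n_nodes(g))
             else state$lam
  dtheta <- state$omega + lam_eff * r * coupling
  dlam <- if (is_fixed_mode(p)) numeric(n_nodes(g))
          else p$alpha * (p$lambda_o - state$lam) - p$beta * r
  list(dtheta = dtheta, dlam = dlam)
}

# flatten the weight matrix to parallel edge arrays for the C++ core
edge_arrays <- function(g) {
  idx <- which(g$weights > 0, arr.ind = TRUE)
  list(src = as.integer(idx[, 2] - 1L), tgt = as.integer(idx[, 1] - 1L),
       w = g$weights[idx], instrength = in_strength(g))
}

#' Simulate the network dynamics
#'
#' Explicit Euler integration with step `p$dt`; phases are wrapped to
#' `[0, 2*pi)` and both updates use the same pre-step state.  The
#' global order `R` and mean resource level are recorded every
#' `record_stride` time units (including the initial state at `t = 0`);
#' with `record_per_node = TRUE` the per-node phase, local synchrony
#' and resource snapshots are kept as matrices (time x node).
#'
#' Provide either `seed` (an initial state is drawn) or `state` (warm
#' start, used by the adiabatic sweeps).
#'
#' @param g a [sync_network()].
#' @param p a [model_params()].
#' @param duration simulated time in time units.
#' @param seed integer seed for the initial state.
#' @param state optional `oscillator_state` warm start.
#' @param record_stride recording interval, a multiple of `p$dt`.
#' @param record_per_node keep per-node snapshots.
#' @return a `sync_trajectory`: tibble with columns `t`, `R`,
#'   `mean_lambda`, plus attributes `theta`, `r`, `lambda` (matrices,
#'   when recorded), `final_state`, `params`, and a graph fingerprint.
#' @export
simulate_dynamics <- function(g, p, duration, seed = NULL, state = NULL,
                              record_stride = 10 * p$dt,
                              record_per_node = FALSE) {
  if (duration <= 0)
    abort("duration must be > 0.", class = "tesync_parameter_error")
  stride_steps <- record_stride / p$dt
  if (abs(stride_steps - round(stride_steps)) > 1e-8)
    abort("record_stride must be a multiple of dt.",
          class = "tesync_parameter_error")
  stride_steps <- max(1L, as.integer(round(stride_steps)))
  if (is.null(state)) {
    if (is.null(seed))
      abort("provide `seed` or a warm-start `state`.",
            class = "tesync_parameter_error")
    state <- init_state(g, p, seed)
  }
  n_steps <- as.integer(round(duration / p$dt))
  ea <- edge_arrays(g)
  res <- .sim_core(ea$src, ea$tgt, ea$w, ea$instrength, n_nodes(g),
                   state$theta, state$omega, state$lam,
                   p$alpha, p$beta,
                   if (is_fixed_mode(p)) 0 else p$lambda_o,
                   is_fixed_mode(p),
                   if (is_fixed_mode(p)) p$fixed_lambda else 0,
                   p$dt, n_steps, stride_steps, record_per_node)
  out <- tibble(t = res$t, R = res$R, mean_lambda = res$mean_lambda)
  final <- structure(list(theta = res$theta_end, omega = state$omega,
                          lam = if (is_fixed_mode(p)) state$lam
                                else res$lambda_end),
                     class = "oscillator_state")
  structure(out,
            class = c("sync_trajectory", class(out)),
            theta = if (record_per_node) res$theta else NULL,
            r = if (record_per_node) res$r else NULL,
            lambda = if (record_per_node) res$lambda else NULL,
            final_state = final,
            params = p,
            graph_nodes = n_nodes(g),
            graph_edges = n_edges(g),
            record_stride = stride_steps * p$dt,
            seed = seed)
}

#' @export
print.sync_trajectory <- function(x, ...) {
  cat(sprintf(
    "<sync_trajectory> %d samples over %g time units (stride %g)%s\n",
    nrow(x), max(x$t), attr(x, "record_stride"),
    if (!is.null(attr(x, "theta"))) ", per-node snapshots kept" else ""))
  NextMethod()
}

#' Trajectory CSV round-trip
#'
#' Writes the `(t, R, mean_lambda)` table; [read_trajectory()] restores
#' it (without per-node snapshots) exactly.
#'
#' @param traj a `sync_trajectory`.
#' @param path output CSV path.
#' @return `path` (write) / a tibble (read), invisibly for write.
#' @export
write_trajectory <- function(traj, path) {
  df <- as.data.frame(traj[, c("t", "R", "mean_lambda")])
  write.csv(format(df, digits = 17, scientific = TRUE, trim = TRUE),
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  df <- read.csv(path)
  structure(as_tibble(df), class = c("sync_trajectory", class(as_tibble(df))))
}
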