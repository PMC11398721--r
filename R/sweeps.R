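#' Adiabatic sweep over the fixed resource level
#'
#' Quasi-statically steps the fixed resource \eqn{\Lambda} across a
#' grid, carrying the oscillator state from one dwell to the next (the
#' warm start is what makes the sweep adiabatic), and records the
#' stationary global order of each dwell as the mean of `R` over its
#' last 25%.
#'
#' @param g a [sync_network()].
#' @param p a [model_params()] in fixed-resource mode (`fixed_lambda`
#'   sets the starting level; it is overridden by the grid).
#' @param lambda_start,lambda_end sweep limits.
#' @param delta positive step size of the grid.
#' @param dwell time units simulated at each grid value.
#' @param direction `"forward"` (increasing) or `"backward"`.
#' @param seed integer seed for the initial state.
#' @param state optional warm-start `oscillator_state`.
#' @param tail_frac fraction of the dwell averaged for the stationary
#'   value.
#' @return tibble with columns `Lambda`, `R_stat` and attribute
#'   `final_state`.
#' @export
adiabatic_sweep <- function(g, p, lambda_start, lambda_end, delta = 0.003,
                            dwell = 50, direction = c("forward", "backward"),
                            seed = 1L, state = NULL, tail_frac = 0.25) {
  direction <- match.arg(direction)
  if (!is_fixed_mode(p))
    abort("adiabatic_sweep requires fixed-resource mode parameters.",
          class = "tesync_mode_error")
  if (delta <= 0)
    abort("delta must be > 0.", class = "tesync_parameter_error")
  grid <- seq(min(lambda_start, lambda_end), max(lambda_start, lambda_end),
              by = delta)
  if (direction == "backward") grid <- rev(grid)
  if (is.null(state)) state <- init_state(g, p, seed)
  ea <- edge_arrays(g)
  dwell_steps <- as.integer(round(dwell / p$dt))
  res <- .adiabatic_core(ea$src, ea$tgt, ea$w, ea$instrength, n_nodes(g),
                         state$theta, state$omega, grid,
                         p$dt, dwell_steps, tail_frac)
  out <- tibble(Lambda = grid, R_stat = res$R_stat)
  attr(out, "final_state") <- structure(
    list(theta = res$theta_end, omega = state$omega, lam = state$lam),
    class = "oscillator_state")
  out
}

#' Detect the tipping point of a sweep branch
#'
#' The critical resource level is located at the largest single-step
#' jump in stationary `R` along the branch, provided the jump exceeds
#' `jump_threshold`; returns `NA` when no step qualifies.  The returned
#' `Lambda` is the grid value at which the new state is first attained.
#'
#' @param branch tibble with columns `Lambda`, `R_stat` in sweep order.
#' @param jump_threshold minimal `|dR|` that counts as a transition.
#' @return scalar `Lambda` or `NA`.
#' @export
detect_tipping <- function(branch, jump_threshold = 0.2) {
  if (nrow(branch) < 2) return(NA_real_)
  jumps <- abs(diff(branch$R_stat))
  if (max(jumps) <= jump_threshold) return(NA_real_)
  branch$Lambda[which.max(jumps) + 1]
}

#' Forward/backward hysteresis experiment
#'
#' Runs an adiabatic forward sweep from `lambda_min` to `lambda_max`
#' and a backward sweep that continues from the forward end state, then
#' locates both tipping points.  With hysteresis the backward critical
#' level lies below the forward one.
#'
#' @inheritParams adiabatic_sweep
#' @param lambda_min,lambda_max sweep limits.
#' @param jump_threshold passed to [detect_tipping()].
#' @return a `hysteresis_curve`: list with tibbles `forward`,
#'   `backward` and scalars `tipping_forward`, `tipping_backward`.
#' @export
hysteresis_sweep <- function(g, p, lambda_min = 0, lambda_max = 0.12,
                             delta = 0.003, dwell = 50, seed = 1L,
                             jump_threshold = 0.2) {
  fw <- adiabatic_sweep(g, p, lambda_min, lambda_max, delta, dwell,
                        "forward", seed)
  bw <- adiabatic_sweep(g, p, lambda_min, lambda_max, delta, dwell,
                        "backward", state = attr(fw, "final_state"))
  structure(
    list(forward = fw, backward = bw,
         tipping_forward = detect_tipping(fw, jump_threshold),
         tipping_backward = detect_tipping(bw, jump_threshold)),
    class = "hysteresis_curve")
}

#' @export
print.hysteresis_curve <- function(x, ...) {
  cat(sprintf(
    "<hysteresis_curve> %d grid points; tipping fw = %s, bw = %s\n",
    nrow(x$forward), format(x$tipping_forward), format(x$tipping_backward)))
  invisible(x)
}

#' Bifurcation diagram over the resource-bath capacity
#'
#' For each `lambda_o` on the grid the resource-constrained model is
#' simulated for `dwell` time units from a fresh initial state
#' (resources start full, at `lambda_o`); after discarding the first
#' `burn_in` fraction, the dwell is classified from the range of the
#' recorded global order:
#' * `incoherent` if `max(R) < R_high`,
#' * `synchronized` if `min(R) > R_low`,
#' * `bistable` if both `R < R_low` and `R > R_high` are visited.
#' The synchronized-time fraction `sync_fraction` is the fraction of
#' recorded samples with `R > R_high`.  The bistable-region boundaries
#' are the first and last grid values classified bistable.
#'
#' @param g a [sync_network()].
#' @param p a [model_params()] in resource-constrained mode
#'   (`lambda_o` is overridden by the grid).
#' @param lambda_o_grid increasing grid of bath capacities.
#' @param dwell time units per grid value.
#' @param R_low,R_high classification thresholds, `0 < R_low < R_high < 1`.
#' @param seed integer; grid value `k` uses seed `seed + k - 1`.
#' @param burn_in fraction of the dwell discarded before
#'   classification.
#' @param record_stride recording interval in time units.
#' @return a `bifurcation_diagram`: tibble with columns `lambda_o`,
#'   `R_min`, `R_max`, `state_class`, `sync_fraction`, plus attributes
#'   `left_boundary` and `right_boundary`.
#' @export
bifurcation_sweep <- function(g, p, lambda_o_grid = seq(0.01, 0.3, 0.01),
                              dwell = 500, R_low = 0.2, R_high = 0.5,
                              seed = 1L, burn_in = 0.2,
                              record_stride = 4 * p$dt) {
  if (is_fixed_mode(p))
    abort("bifurcation_sweep requires resource-constrained parameters.",
          class = "tesync_mode_error")
  if (!(R_low > 0 && R_low < R_high && R_high < 1))
    abort("need 0 < R_low < R_high < 1.", class = "tesync_parameter_error")
  rows <- purrr::map_dfr(seq_along(lambda_o_grid), function(k) {
    lo <- lambda_o_grid[k]
    pk <- p
    pk$lambda_o <- lo
    traj <- simulate_dynamics(g, pk, dwell, seed = seed + k - 1L,
                              record_stride = record_stride)
    Rv <- traj$R[traj$t >= burn_in * dwell]
    cls <- if (max(Rv) < R_high) "incoherent"
           else if (min(Rv) > R_low) "synchronized"
           else "bistable"
    tibble(lambda_o = lo, R_min = min(Rv), R_max = max(Rv),
           state_class = cls, sync_fraction = mean(Rv > R_high))
  })
  bist <- which(rows$state_class == "bistable")
  structure(rows,
            class = c("bifurcation_diagram", class(rows)),
            left_boundary = if (length(bist)) rows$lambda_o[min(bist)] else NA_real_,
            right_boundary = if (length(bist)) rows$lambda_o[max(bist)] else NA_real_,
            R_low = R_low, R_high = R_high, dwell = dwell, seed = seed)
}

#' @export
print.bifurcation_diagram <- function(x, ...) {
  cat(sprintf(
    "<bifurcation_diagram> %d grid points; bistable region [%s, %s]\n",
    nrow(x), format(attr(x, "left_boundary")),
    format(attr(x, "right_boundary"))))
  NextMethod()
}

#' State-space trace of a trajectory
#'
#' Time-ordered pairs of mean resource level and global order.
#' Restricting to `node_subset` (indices or labels; requires per-node
#' recording) replaces the mean-resource coordinate by the mean over
#' the subset only, as used to contrast actively participating nodes
#' with the whole network.
#'
#' @param traj a `sync_trajectory`.
#' @param node_subset optional node indices (or labels if the
#'   trajectory's graph labels were node names).
#' @param g network (only needed to resolve label subsets).
#' @return tibble with columns `t`, `mean_lambda`, `R`.
#' @export
state_space_trace <- function(traj, node_subset = NULL, g = NULL) {
  if (is.null(node_subset))
    return(tibble(t = traj$t, mean_lambda = traj$mean_lambda, R = traj$R))
  if (length(node_subset) == 0)
    abort("node_subset must be non-empty.", class = "tesync_parameter_error")
  lam <- attr(traj, "lambda")
  if (is.null(lam))
    abort("per-node resources not recorded; rerun with record_per_node = TRUE.",
          class = "tesync_parameter_error")
  if (is.character(node_subset)) {
    if (is.null(g)) abort("pass `g` to resolve node labels.")
    node_subset <- match(node_subset, g$node_labels)
  }
  tibble(t = traj$t,
         mean_lambda = rowMeans(lam[, node_subset, drop = FALSE]),
         R = traj$R)
}

#' Probability of transient synchronization within the bistable region
#'
#' Trapezoidal area under the synchronized-time-fraction curve between
#' the bistable-region boundaries, normalised by the rectangle
#' `(right - left) x 1`; 1 means the network is synchronized
#' throughout the region, 0 never.
#'
#' @param diagram a [bifurcation_sweep()] result.
#' @return scalar in `[0, 1]`, or `NA` (with a message) if the diagram
#'   has no bistable region.
#' @export
tes_probability <- function(diagram) {
  left <- attr(diagram, "left_boundary")
  right <- attr(diagram, "right_boundary")
  if (!is.finite(left) || !is.finite(right) || right <= left) {
    inform("no bistable region in diagram; tes_probability undefined.")
    return(NA_real_)
  }
  sel <- diagram$lambda_o >= left & diagram$lambda_o <= right
  x <- diagram$lambda_o[sel]
  y <- diagram$sync_fraction[sel]
  area <- sum(diff(x) * (head(y, -1) + y[-1]) / 2)
  area / (right - left)
}

#' Recovery-to-consumption ratio sweep
#'
#' Repeats the bifurcation sweep for a list of consumption rates
#' `beta` at fixed recovery rate `alpha` and summarises, per `beta`,
#' the bistable-region boundaries and the tES probability against the
#' ratio `alpha / beta`.  When no grid is supplied a per-`beta` default
#' is built spanning `0.01` to `0.12 + 1.3 * beta / alpha`, since the
#' bistable window shifts upward roughly with the consumption-to-
#' recovery ratio.
#'
#' @param g a [sync_network()].
#' @param alpha fixed recovery rate.
#' @param beta_list consumption rates to scan.
#' @param lambda_o_grid one grid for all `beta`, a list of grids (one
#'   per `beta`), or `NULL` for the adaptive default.
#' @param dwell time units per grid value.
#' @param seed integer seed.
#' @param grid_points number of grid values in the default grids.
#' @param ... further arguments to [bifurcation_sweep()].
#' @return tibble with one row per `beta`: `beta`, `ratio`,
#'   `left_boundary`, `right_boundary`, `width`, `tes_probability`.
#' @export
ratio_sweep <- function(g, alpha = 0.01,
                        beta_list = c(0.01, 0.005, 0.002, 0.001,
                                      0.0005, 0.00025, 0.0002),
                        lambda_o_grid = NULL, dwell = 500, seed = 1L,
                        grid_points = 30, ...) {
  if (alpha <= 0 || any(beta_list <= 0))
    abort("rates must be > 0.", class = "tesync_parameter_error")
  grids <- if (is.null(lambda_o_grid)) {
    lapply(beta_list, function(b)
      round(seq(0.01, 0.12 + 1.3 * b / alpha, length.out = grid_points), 4))
  } else if (is.list(lambda_o_grid)) lambda_o_grid
  else rep(list(lambda_o_grid), length(beta_list))
  purrr::map_dfr(seq_along(beta_list), function(i) {
    p <- model_params(alpha = alpha, beta = beta_list[i], lambda_o = 0.1)
    d <- bifurcation_sweep(g, p, grids[[i]], dwell = dwell, seed = seed, ...)
    tibble(beta = beta_list[i], ratio = alpha / beta_list[i],
           left_boundary = attr(d, "left_boundary"),
           right_boundary = attr(d, "right_boundary"),
           width = attr(d, "right_boundary") - attr(d, "left_boundary"),
           tes_probability = suppressMessages(tes_probability(d)))
  })
}
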