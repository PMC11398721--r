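#' Locate onset indices of abrupt synchronization transitions
#'
#' A transition event is an upward crossing of `sync_threshold` by the
#' recorded global order; its onset index is the latest preceding
#' sample at which `R` had dropped below `desync_threshold` (the point
#' of near-complete desynchronization immediately before the abrupt
#' rise).  Crossings within `refractory` time units of the previous
#' accepted event are skipped, as are crossings with no preceding
#' desynchronized sample.
#'
#' @param traj a `sync_trajectory` recorded at a stride of at most
#'   ~0.2 time units.
#' @param desync_threshold `R` level counting as near-complete
#'   desynchronization.
#' @param sync_threshold `R` level whose upward crossing marks a
#'   transition.
#' @param refractory dead time after an accepted event, in time units.
#' @return numeric vector of onset times (possibly empty).
#' @export
find_onset_indices <- function(traj, desync_threshold = 0.1,
                               sync_threshold = 0.5, refractory = 100) {
  R <- traj$R
  t <- traj$t
  up <- which(R[-1] > sync_threshold & R[-length(R)] <= sync_threshold) + 1
  onsets <- numeric(0)
  last_event <- -Inf
  for (k in up) {
    if (t[k] - last_event < refractory) next
    below <- which(R[seq_len(k - 1)] < desync_threshold)
    if (length(below) == 0) next
    onsets <- c(onsets, t[max(below)])
    last_event <- t[k]
  }
  onsets
}

#' Extract fixed-length transient windows from repeated runs
#'
#' Runs the resource-constrained model `n_runs` times with distinct
#' seeds and per-node recording, detects onset indices on each run's
#' global-order trace, and cuts a window of `window` time units of
#' per-node phases and local synchrony starting at each onset.  Windows
#' that would cross the end of a run are dropped, so all windows share
#' the same shape (`window / stride + 1` samples).
#'
#' @param g a [sync_network()].
#' @param p a [model_params()] in resource-constrained mode.
#' @param n_runs number of independent runs.
#' @param run_duration time units per run (must exceed `window`).
#' @param window window length in time units.
#' @param seeds integer vector of per-run seeds (default
#'   `seed + 0:(n_runs-1)`).
#' @param seed base seed used when `seeds` is not given.
#' @param stride recording stride in time units.
#' @param ... thresholds passed to [find_onset_indices()].
#' @return a `transient_set`: list of `transient_window` objects, each
#'   with `onset_time`, `times` (relative to onset), `theta_panel`,
#'   `r_panel` (time x node), `run`, `seed`.
#' @export
extract_transients <- function(g, p, n_runs = 4, run_duration = 2000,
                               window = 50, seeds = NULL, seed = 1L,
                               stride = 0.2, ...) {
  if (is_fixed_mode(p))
    abort("extract_transients requires resource-constrained parameters.",
          class = "tesync_mode_error")
  if (window > run_duration)
    abort("window longer than run_duration.",
          class = "tesync_parameter_error")
  if (is.null(seeds)) seeds <- seed + seq_len(n_runs) - 1L
  n_win <- as.integer(round(window / stride))
  windows <- list()
  for (run in seq_len(n_runs)) {
    traj <- simulate_dynamics(g, p, run_duration, seed = seeds[run],
                              record_stride = stride,
                              record_per_node = TRUE)
    onsets <- find_onset_indices(traj, ...)
    theta <- attr(traj, "theta")
    r <- attr(traj, "r")
    for (ot in onsets) {
      k0 <- which.min(abs(traj$t - ot))
      k1 <- k0 + n_win
      if (k1 > nrow(traj)) next  # window would cross the run boundary
      idx <- k0:k1
      windows[[length(windows) + 1]] <- structure(
        list(onset_time = ot,
             times = traj$t[idx] - traj$t[k0],
             theta_panel = theta[idx, , drop = FALSE],
             r_panel = r[idx, , drop = FALSE],
             R = traj$R[idx],
             run = run, seed = seeds[run]),
        class = "transient_window")
    }
  }
  structure(windows, class = "transient_set")
}

#' @export
print.transient_set <- function(x, ...) {
  cat(sprintf("<transient_set> %d windows%s\n", length(x),
              if (length(x)) sprintf(" of %g time units (%d nodes)",
                                     max(x[[1]]$times),
                                     ncol(x[[1]]$theta_panel)) else ""))
  invisible(x)
}

#' @export
print.transient_window <- function(x, ...) {
  cat(sprintf("<transient_window> onset t = %g, %d samples x %d nodes\n",
              x$onset_time, nrow(x$theta_panel), ncol(x$theta_panel)))
  invisible(x)
}

#' Actively participating nodes of a transient window
#'
#' Nodes whose local synchrony, averaged over the final `tail_frac`
#' fraction of the window (the partially synchronized plateau),
#' exceeds `r_threshold`.
#'
#' @param window a `transient_window`.
#' @param r_threshold participation threshold on local synchrony.
#' @param tail_frac plateau fraction of the window used for averaging.
#' @return integer vector of node indices.
#' @export
active_nodes <- function(window, r_threshold = 0.7, tail_frac = 0.2) {
  nt <- nrow(window$r_panel)
  tail_idx <- seq.int(max(1L, nt - ceiling(tail_frac * nt) + 1L), nt)
  which(colMeans(window$r_panel[tail_idx, , drop = FALSE]) > r_threshold)
}
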