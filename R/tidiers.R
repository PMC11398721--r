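# broom-style tidiers for the package's result objects.

#' Tidy a trajectory
#'
#' @param x a `sync_trajectory`.
#' @param per_node if `TRUE` and per-node snapshots were recorded,
#'   return the long per-node table (`t`, `node`, `theta`, `r`,
#'   `lambda`) instead of the summary series.
#' @param ... unused.
#' @return a tibble.
#' @exportS3Method
tidy.sync_trajectory <- function(x, per_node = FALSE, ...) {
  if (!per_node)
    return(tibble(t = x$t, R = x$R, mean_lambda = x$mean_lambda))
  th <- attr(x, "theta")
  if (is.null(th))
    abort("no per-node snapshots recorded.", class = "tesync_parameter_error")
  n <- ncol(th)
  tibble(t = rep(x$t, times = n),
         node = rep(seq_len(n), each = nrow(th)),
         theta = as.vector(th),
         r = as.vector(attr(x, "r")),
         lambda = as.vector(attr(x, "lambda")))
}

#' @rdname tidy.sync_trajectory
#' @param sync_threshold `R` level above which a sample counts as
#'   synchronized in the `frac_sync` summary.
#' @exportS3Method
glance.sync_trajectory <- function(x, sync_threshold = 0.5, ...) {
  tibble(duration = max(x$t), n_samples = nrow(x),
         R_mean = mean(x$R), R_min = min(x$R), R_max = max(x$R),
         frac_sync = mean(x$R > sync_threshold),
         mean_lambda_end = x$mean_lambda[nrow(x)])
}

#' Tidy a hysteresis curve
#'
#' @param x a `hysteresis_curve`.
#' @param ... unused.
#' @return long tibble with columns `Lambda`, `R_stat`, `direction`.
#' @exportS3Method
tidy.hysteresis_curve <- function(x, ...) {
  dplyr::bind_rows(
    mutate(x$forward, direction = "forward"),
    mutate(x$backward, direction = "backward"))
}

#' @rdname tidy.hysteresis_curve
#' @exportS3Method
glance.hysteresis_curve <- function(x, ...) {
  tibble(tipping_forward = x$tipping_forward,
         tipping_backward = x$tipping_backward,
         hysteresis_width = x$tipping_forward - x$tipping_backward,
         n_grid = nrow(x$forward))
}

#' Tidy a bifurcation diagram
#'
#' @param x a `bifurcation_diagram`.
#' @param ... unused.
#' @return the per-`lambda_o` tibble (already tidy).
#' @exportS3Method
tidy.bifurcation_diagram <- function(x, ...) as_tibble(x)

#' @rdname tidy.bifurcation_diagram
#' @exportS3Method
glance.bifurcation_diagram <- function(x, ...) {
  tibble(left_boundary = attr(x, "left_boundary"),
         right_boundary = attr(x, "right_boundary"),
         width = attr(x, "right_boundary") - attr(x, "left_boundary"),
         tes_probability = suppressMessages(tes_probability(x)),
         n_grid = nrow(x))
}

#' Tidy a community partition
#'
#' @param x a `community_partition`.
#' @param ... unused.
#' @return tibble `node`, `label`, `community`.
#' @exportS3Method
tidy.community_partition <- function(x, ...) as_tibble(x)

#' @rdname tidy.community_partition
#' @exportS3Method
glance.community_partition <- function(x, ...) {
  tibble(n_communities = attr(x, "n_communities"), Q = attr(x, "Q"),
         resolution = attr(x, "resolution"))
}

#' Tidy a cluster lineage
#'
#' @param x a `cluster_lineage`.
#' @param ... unused.
#' @return long membership tibble (`time`, `cluster`, `node`).
#' @exportS3Method
tidy.cluster_lineage <- function(x, ...) x$membership

#' @rdname tidy.cluster_lineage
#' @exportS3Method
glance.cluster_lineage <- function(x, ...) {
  tibble(n_snapshots = length(x$snapshots),
         n_cluster_ids = length(unique(x$membership$cluster)),
         main_peak_size = max(x$main_cluster$size),
         threshold = x$threshold)
}
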