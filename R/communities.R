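#' Structure-based community detection
#'
#' Louvain partition of the network.  Directed weighted graphs are
#' symmetrized with the max rule, `w = max(w_ij, w_ji)`, and standard
#' (undirected, weighted) modularity Louvain is run on the result;
#' the reported modularity `Q` is evaluated on that symmetrized graph.
#'
#' @param g a [sync_network()].
#' @param resolution Louvain resolution parameter.
#' @param seed integer seed (Louvain is randomised).
#' @return a `community_partition`: tibble with columns `node`,
#'   `label`, `community`, plus attributes `Q`, `n_communities`,
#'   `resolution`.
#' @export
detect_communities <- function(g, resolution = 1, seed = 1L) {
  W <- pmax(g$weights, t(g$weights))
  ig <- igraph::graph_from_adjacency_matrix(
    W, mode = "undirected", weighted = if (g$weighted) TRUE else NULL)
  cl <- with_seed(seed, igraph::cluster_louvain(
    ig, weights = if (g$weighted) igraph::E(ig)$weight else NULL,
    resolution = resolution))
  memb <- igraph::membership(cl)
  Q <- igraph::modularity(ig, memb,
                          weights = if (g$weighted) igraph::E(ig)$weight
                                    else NULL)
  out <- tibble(node = seq_along(memb), label = g$node_labels,
                community = as.integer(memb))
  structure(out, class = c("community_partition", class(out)),
            Q = Q, n_communities = length(unique(memb)),
            resolution = resolution, seed = seed)
}

#' @export
print.community_partition <- function(x, ...) {
  cat(sprintf("<community_partition> %d communities, Q = %.3f\n",
              attr(x, "n_communities"), attr(x, "Q")))
  NextMethod()
}

#' Partition CSV round-trip
#' @param part a `community_partition` (or compatible tibble).
#' @param path CSV path.
#' @return `path` / tibble.
#' @export
write_partition <- function(part, path) {
  write.csv(as.data.frame(part[, c("label", "community")]), path,
            row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_partition
#' @export
read_partition <- function(path) {
  df <- read.csv(path)
  tibble(node = seq_len(nrow(df)), label = as.character(df$label),
         community = as.integer(df$community))
}

# community sizes and index lists, with validation
community_index <- function(part, n) {
  if (nrow(part) != n)
    abort("partition does not cover all nodes.",
          class = "tesync_parameter_error")
  split(part$node, part$community)
}

# mean phasor of each community at every time of a phase panel:
# returns complex matrix (time x community)
community_phasors <- function(theta_panel, comm_idx) {
  ph <- exp(1i * theta_panel)
  do.call(cbind, lapply(comm_idx, function(ix)
    rowMeans(ph[, ix, drop = FALSE])))
}

#' Intramodular synchrony across transients
#'
#' For each community `c` with members `N_c`, the intramodular
#' synchrony at a time point is the modulus of the mean phasor of its
#' members, \eqn{IMS_c = |\frac{1}{N_c}\sum_{i \in c} e^{i\theta_i}|}.
#' Values are computed per transient window on the window's time grid
#' (relative to onset) and then averaged across windows.
#'
#' @param windows a `transient_set` (or list of `transient_window`).
#' @param part a [detect_communities()] partition covering all nodes.
#' @return tibble with columns `time`, `community`, `ims_mean`,
#'   `ims_sd`, `n_trials`.
#' @export
intramodular_synchrony <- function(windows, part) {
  stopifnot(length(windows) >= 1)
  n <- ncol(windows[[1]]$theta_panel)
  comm_idx <- community_index(part, n)
  if (any(lengths(comm_idx) == 0))
    abort("empty community.", class = "tesync_parameter_error")
  times <- windows[[1]]$times
  nt <- length(times)
  per_win <- lapply(windows, function(w)
    matrix(Mod(community_phasors(w$theta_panel, comm_idx)),
           nt, length(comm_idx)))
  arr <- array(unlist(per_win),
               dim = c(nt, length(comm_idx), length(windows)))
  tibble(
    time = rep(times, times = length(comm_idx)),
    community = rep(as.integer(names(comm_idx)), each = length(times)),
    ims_mean = as.vector(apply(arr, c(1, 2), mean)),
    ims_sd = as.vector(apply(arr, c(1, 2), stats::sd)),
    n_trials = length(windows))
}

# literal double-sum intermodular synchrony at one time point
# (reference oracle for the phasor identity)
ims_pair_literal <- function(theta, idx1, idx2) {
  ph <- exp(1i * theta)
  s <- 0
  for (i in idx1) for (j in idx2) s <- s + 0.5 * (ph[i] + ph[j])
  Mod(s) / (length(idx1) * length(idx2))
}

#' Intermodular synchrony across transients
#'
#' For communities `c1`, `c2` the intermodular synchrony is
#' \deqn{IMS_{c_1 c_2} = \frac{1}{N_{c_1} N_{c_2}}
#'   \left|\sum_{i \in c_1}\sum_{j \in c_2}
#'   0.5 (e^{i\theta_i} + e^{i\theta_j})\right|
#'   = \left|0.5 (P_{c_1} + P_{c_2})\right|,}
#' where \eqn{P_c} is the mean phasor of community `c`; the closed-form
#' identity is used for computation.  The measure is symmetric in the
#' pair and reduces to the intramodular synchrony when `c1 == c2`.
#' Values are averaged across windows.
#'
#' @inheritParams intramodular_synchrony
#' @param include_self include the diagonal pairs `(c, c)`.
#' @return tibble with columns `time`, `c1`, `c2`, `ims_mean`,
#'   `ims_sd`, `n_trials` (unordered pairs, `c1 <= c2` when
#'   `include_self`, `c1 < c2` otherwise).
#' @export
intermodular_synchrony <- function(windows, part, include_self = FALSE) {
  stopifnot(length(windows) >= 1)
  n <- ncol(windows[[1]]$theta_panel)
  comm_idx <- community_index(part, n)
  ids <- as.integer(names(comm_idx))
  pairs <- which(upper.tri(diag(length(ids)), diag = include_self),
                 arr.ind = TRUE)
  times <- windows[[1]]$times
  nt <- length(times)
  per_win <- lapply(windows, function(w) {
    P <- community_phasors(w$theta_panel, comm_idx)
    vals <- vapply(seq_len(nrow(pairs)), function(k)
      Mod(0.5 * (P[, pairs[k, 1]] + P[, pairs[k, 2]])),
      numeric(nt))
    matrix(vals, nt, nrow(pairs))
  })
  arr <- array(unlist(per_win), dim = c(nt, nrow(pairs), length(windows)))
  tibble(
    time = rep(times, times = nrow(pairs)),
    c1 = rep(ids[pairs[, 1]], each = length(times)),
    c2 = rep(ids[pairs[, 2]], each = length(times)),
    ims_mean = as.vector(apply(arr, c(1, 2), mean)),
    ims_sd = as.vector(apply(arr, c(1, 2), stats::sd)),
    n_trials = length(windows))
}
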