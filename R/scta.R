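#' Synchronization clusters at one instant (SCTA step)
#'
#' Builds the synchronization clusters of a phase snapshot by
#' threshold-gated breadth-first expansion on the undirected skeleton
#' of the network.  A node may belong to a cluster only if its local
#' synchrony `r` (evaluated on the full network at the given phases)
#' reaches `threshold`; expansion proceeds only through nodes that have
#' joined, so a sub-threshold node blocks the path.
#'
#' Three steps:
#' 1. *Expansion around central nodes* - clusters carried over from the
#'    previous instant are processed in descending previous size (ties:
#'    ascending id); each seeds an expansion from its central nodes
#'    (ordered by descending current `r`); the first cluster to reach a
#'    node keeps it.
#' 2. *Expansion for unassigned nodes* - remaining supra-threshold
#'    nodes seed fresh clusters in descending-`r` order.
#' 3. *Update central node list* - the up-to-5 members with highest `r`
#'    become the cluster's central nodes.
#'
#' Identity: a step-1 cluster inherits the id of the previous cluster
#' that seeded it; when a previous cluster's central nodes are split
#' over several current clusters, the id follows the central node of
#' highest current `r` (first claim wins); step-2 clusters get fresh
#' ids.
#'
#' @param theta numeric phase vector.
#' @param g a [sync_network()].
#' @param threshold local-synchrony membership threshold in `(0, 1)`.
#' @param prev optional previous `cluster_snapshot` whose clusters seed
#'   step 1.
#' @param time time stamp stored on the snapshot.
#' @param next_id smallest id available for new clusters (bookkeeping
#'   carried by [track_clusters()]).
#' @param nbrs optional precomputed skeleton adjacency list (caching
#'   used by [track_clusters()]).
#' @return a `cluster_snapshot`: list with `time`, `clusters` (list of
#'   `list(id, members, central)`), `unclustered`, `r`, `next_id`.
#' @export
find_clusters <- function(theta, g, threshold = 0.5, prev = NULL,
                          time = 0, next_id = NULL, nbrs = NULL) {
  if (threshold <= 0 || threshold >= 1)
    abort("threshold must be in (0, 1).", class = "tesync_parameter_error")
  n <- n_nodes(g)
  r <- local_order(theta, g)
  if (is.null(nbrs)) nbrs <- skeleton_neighbors(g)
  supra <- r >= threshold
  assigned <- integer(n)  # 0 = unassigned; else tentative cluster index
  tentative <- list()

  expand <- function(seeds) {
    seeds <- seeds[supra[seeds] & assigned[seeds] == 0]
    if (length(seeds) == 0) return(integer(0))
    members <- integer(0)
    queue <- seeds
    ti <- length(tentative) + 1L
    while (length(queue)) {
      v <- queue[1]
      queue <- queue[-1]
      if (assigned[v] != 0) next
      assigned[v] <<- ti
      members <- c(members, v)
      nb <- nbrs[[v]]
      queue <- c(queue, nb[supra[nb] & assigned[nb] == 0])
    }
    members
  }

  # --- step 1: carried-over clusters, descending previous size
  inherited <- list()  # tentative index -> candidate (prev id, central r)
  if (!is.null(prev) && length(prev$clusters)) {
    sizes <- vapply(prev$clusters, function(cl) length(cl$members), 0L)
    ids <- vapply(prev$clusters, function(cl) cl$id, 0L)
    ord <- order(-sizes, ids)
    for (ci in ord) {
      cl <- prev$clusters[[ci]]
      seeds <- cl$central[order(-r[cl$central])]
      members <- expand(seeds)
      if (length(members))
        tentative[[length(tentative) + 1L]] <- list(members = members)
    }
    # id inheritance: highest-r assigned central node claims the id
    for (ci in ord) {
      cl <- prev$clusters[[ci]]
      cen <- cl$central[assigned[cl$central] != 0]
      if (length(cen) == 0) next
      best <- cen[which.max(r[cen])]
      ti <- assigned[best]
      if (is.null(tentative[[ti]]$id)) tentative[[ti]]$id <- cl$id
    }
  }

  # --- step 2: fresh clusters from remaining supra-threshold nodes
  rest <- which(supra & assigned == 0)
  for (v in rest[order(-r[rest])]) {
    if (assigned[v] != 0) next
    members <- expand(v)
    if (length(members))
      tentative[[length(tentative) + 1L]] <- list(members = members)
  }

  # --- step 3: ids and central nodes
  if (is.null(next_id))
    next_id <- if (!is.null(prev)) prev$next_id else 1L
  clusters <- lapply(tentative, function(cl) {
    if (is.null(cl$id)) {
      cl$id <- next_id
      next_id <<- next_id + 1L
    }
    m <- cl$members
    cl$central <- m[order(-r[m], m)][seq_len(min(5L, length(m)))]
    cl$members <- sort(m)
    cl
  })
  clusters <- clusters[order(vapply(clusters, function(cl) cl$id, 0L))]
  structure(list(time = time, clusters = clusters,
                 unclustered = which(!supra), r = r, next_id = next_id),
            class = "cluster_snapshot")
}

#' @export
print.cluster_snapshot <- function(x, ...) {
  sizes <- vapply(x$clusters, function(cl) length(cl$members), 0L)
  cat(sprintf("<cluster_snapshot> t = %g: %d clusters (sizes %s), %d unclustered\n",
              x$time, length(sizes), paste(sizes, collapse = ","),
              length(x$unclustered)))
  invisible(x)
}

#' Track synchronization clusters through a transient window
#'
#' Applies [find_clusters()] at every `eval_stride` within the window,
#' passing each snapshot's central nodes forward so cluster identities
#' persist.  The main synchronization cluster at each instant is the
#' largest (ties: smallest id).  Per-node residence time in the main
#' cluster accumulates `eval_stride` per membership instant (the
#' initial instant carries no time), so the total is bounded by the
#' window duration.
#'
#' @param window a `transient_window` (from [extract_transients()]).
#' @param g a [sync_network()].
#' @param threshold local-synchrony membership threshold.
#' @param eval_stride evaluation interval, a multiple of the window's
#'   recording stride.
#' @return a `cluster_lineage`: list with `snapshots`, tibble
#'   `membership` (`time`, `cluster`, `node`), `main_cluster` (tibble
#'   `time`, `cluster`, `size`), and numeric `time_in_main` per node.
#' @export
track_clusters <- function(window, g, threshold = 0.5, eval_stride = 0.2) {
  times <- window$times
  stride <- times[2] - times[1]
  every <- eval_stride / stride
  if (abs(every - round(every)) > 1e-8)
    abort("eval_stride must be a multiple of the window stride.",
          class = "tesync_parameter_error")
  idx <- seq(1, length(times), by = max(1L, as.integer(round(every))))
  n <- n_nodes(g)
  snap <- NULL
  snapshots <- vector("list", length(idx))
  time_in_main <- numeric(n)
  main_rows <- vector("list", length(idx))
  memb_rows <- vector("list", length(idx))
  nbrs <- skeleton_neighbors(g)
  for (k in seq_along(idx)) {
    snap <- find_clusters(window$theta_panel[idx[k], ], g, threshold,
                          prev = snap, time = times[idx[k]], nbrs = nbrs)
    snapshots[[k]] <- snap
    if (length(snap$clusters)) {
      sizes <- vapply(snap$clusters, function(cl) length(cl$members), 0L)
      ids <- vapply(snap$clusters, function(cl) cl$id, 0L)
      main <- which(sizes == max(sizes))
      main <- main[which.min(ids[main])]
      main_rows[[k]] <- tibble(time = snap$time, cluster = ids[main],
                               size = sizes[main])
      if (k > 1)
        time_in_main[snap$clusters[[main]]$members] <-
          time_in_main[snap$clusters[[main]]$members] + eval_stride
      memb_rows[[k]] <- tibble(
        time = snap$time,
        cluster = rep(ids, sizes),
        node = unlist(lapply(snap$clusters, function(cl) cl$members)))
    } else {
      main_rows[[k]] <- tibble(time = snap$time, cluster = NA_integer_,
                               size = 0L)
    }
  }
  structure(list(snapshots = snapshots,
                 membership = dplyr::bind_rows(memb_rows),
                 main_cluster = dplyr::bind_rows(main_rows),
                 time_in_main = time_in_main,
                 threshold = threshold, eval_stride = eval_stride),
            class = "cluster_lineage")
}

#' @export
print.cluster_lineage <- function(x, ...) {
  cat(sprintf(
    "<cluster_lineage> %d snapshots, main-cluster peak size %d\n",
    length(x$snapshots), max(x$main_cluster$size)))
  invisible(x)
}

#' Per-node residence statistics in the main cluster
#'
#' Median and variance (population convention, divide by n) of the
#' time each node spent in the main synchronization cluster across a
#' set of transients.
#'
#' @param lineages list of [track_clusters()] results.
#' @return tibble with columns `node`, `median_time`, `var_time`.
#' @export
time_in_main_stats <- function(lineages) {
  stopifnot(length(lineages) >= 1)
  tm <- do.call(rbind, lapply(lineages, `[[`, "time_in_main"))
  pop_var <- function(x) mean((x - mean(x))^2)
  tibble(node = seq_len(ncol(tm)),
         median_time = apply(tm, 2, median),
         var_time = apply(tm, 2, pop_var))
}

#' Driver-node identification
#'
#' Nodes combining high out-degree with consistently long residence in
#' the main synchronization cluster: out-degree above `min_out_degree`,
#' median residence time above `min_median` and variance below
#' `max_variance`, sorted by median descending.
#'
#' @param stats a [time_in_main_stats()] tibble.
#' @param g a [sync_network()] sharing the node set.
#' @param min_out_degree,min_median,max_variance selection thresholds.
#' @return tibble of selected nodes with `label`, `out_degree`,
#'   `median_time`, `var_time`.
#' @export
driver_nodes <- function(stats, g, min_out_degree = 30, min_median = 35,
                         max_variance = 49) {
  stopifnot(nrow(stats) == n_nodes(g))
  out <- stats %>%
    mutate(out_degree = out_degree(g)[.data$node],
           label = g$node_labels[.data$node]) %>%
    filter(.data$out_degree > min_out_degree,
           .data$median_time > min_median,
           .data$var_time < max_variance) %>%
    arrange(dplyr::desc(.data$median_time))
  out[, c("node", "label", "out_degree", "median_time", "var_time")]
}
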