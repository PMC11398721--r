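# Small graphs and panels built in code for the tests.

# binary undirected graph from an edge list matrix (rows: from, to)
graph_from_edges <- function(n, edges) {
  w <- matrix(0, n, n)
  for (k in seq_len(nrow(edges))) {
    w[edges[k, 2], edges[k, 1]] <- 1
    w[edges[k, 1], edges[k, 2]] <- 1
  }
  sync_network(w, directed = FALSE, weighted = FALSE)
}

path_graph <- function(n) {
  graph_from_edges(n, cbind(seq_len(n - 1), seq_len(n - 1) + 1))
}

complete_graph <- function(n) {
  w <- matrix(1, n, n) - diag(n)
  sync_network(w, directed = FALSE, weighted = FALSE)
}

# graph with no edges (isolated oscillators)
empty_graph <- function(n) {
  sync_network(matrix(0, n, n), directed = FALSE, weighted = FALSE)
}

# random connected binary undirected graph on n nodes (for oracles)
random_small_graph <- function(n, p = 0.4) {
  repeat {
    w <- matrix(0, n, n)
    up <- upper.tri(w)
    w[up] <- runif(sum(up)) < p
    w <- w + t(w)
    g <- sync_network(w, directed = FALSE, weighted = FALSE)
    if (igraph::is_connected(as_igraph(g, skeleton = TRUE))) return(g)
  }
}

# random weighted directed graph (for the derivatives oracle)
random_weighted_graph <- function(n, p = 0.5) {
  w <- matrix(runif(n * n), n, n) * (matrix(runif(n * n), n, n) < p)
  diag(w) <- 0
  sync_network(w / max(max(w), 1), directed = TRUE, weighted = TRUE)
}

# hand-rolled transient_window from a phase panel (time x node)
window_from_panel <- function(theta_panel, g, stride = 1) {
  nt <- nrow(theta_panel)
  r_panel <- t(apply(theta_panel, 1, local_order, g = g))
  structure(list(onset_time = 0,
                 times = (seq_len(nt) - 1) * stride,
                 theta_panel = theta_panel,
                 r_panel = r_panel,
                 R = apply(theta_panel, 1, global_order),
                 run = 1L, seed = 0L),
            class = "transient_window")
}

# partition tibble from a label vector
partition_from_labels <- function(labels) {
  tibble::tibble(node = seq_along(labels),
                 label = paste0("n", seq_along(labels)),
                 community = as.integer(factor(labels)))
}

# the study fixture shared by several test files
fixture_graph <- function(seed = 1) make_synthetic_connectome(seed = seed)

fixture_params <- function() model_params(lambda_o = 0.72)

# slow nested-loop evaluation of the model equations (oracle)
derivatives_oracle <- function(state, g, p) {
  n <- n_nodes(g)
  W <- g$weights
  r <- numeric(n)
  for (i in seq_len(n)) {
    s <- sum(W[i, ])
    if (s > 0) {
      acc <- 0 + 0i
      for (j in seq_len(n)) acc <- acc + W[i, j] * exp(1i * state$theta[j])
      r[i] <- Mod(acc) / s
    }
  }
  lam <- if (is.null(p$fixed_lambda)) state$lam else rep(p$fixed_lambda, n)
  dtheta <- numeric(n)
  for (i in seq_len(n)) {
    acc <- 0
    for (j in seq_len(n))
      acc <- acc + W[i, j] * sin(state$theta[j] - state$theta[i])
    dtheta[i] <- state$omega[i] + lam[i] * min(r[i], 1) * acc
  }
  dlam <- if (is.null(p$fixed_lambda))
    p$alpha * (p$lambda_o - state$lam) - p$beta * pmin(r, 1)
  else numeric(n)
  list(dtheta = dtheta, dlam = dlam)
}

# connected components of the supra-threshold induced subgraph (oracle
# for the cluster finder): list of sorted member vectors
components_oracle <- function(theta, g, threshold) {
  r <- local_order(theta, g)
  keep <- which(r >= threshold)
  if (length(keep) == 0) return(list())
  ig <- as_igraph(g, skeleton = TRUE)
  sub <- igraph::induced_subgraph(ig, keep)
  memb <- igraph::components(sub)$membership
  unname(lapply(split(keep[seq_along(memb)], memb), sort))
}

member_sets <- function(snapshot) {
  unname(lapply(snapshot$clusters, function(cl) sort(cl$members)))
}

# set-of-sets equality ignoring order
same_partition <- function(a, b) {
  key <- function(x) paste(x, collapse = ",")
  setequal(vapply(a, key, ""), vapply(b, key, ""))
}
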