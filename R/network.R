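#' Oscillator network substrate
#'
#' A `sync_network` holds the adjacency structure on which the
#' phase/resource dynamics run.  Weights are stored as a dense matrix
#' `W` with the *incoming-edge* convention: `W[i, j]` is the weight of
#' the directed edge from source `j` to target `i`, so row `i` collects
#' everything that drives node `i`.  Undirected graphs are stored
#' symmetrically.
#'
#' Invariants enforced by the constructor: no self-loops (zero
#' diagonal), weighted entries within `[0, 1]`, symmetry when
#' undirected, and unique node labels.
#'
#' @param weights n x n non-negative numeric matrix, `weights[i, j]` =
#'   weight of edge j -> i.
#' @param directed logical; if `FALSE` the matrix must be symmetric.
#' @param weighted logical; if `FALSE` entries must be 0/1.
#' @param node_labels character vector of unique node names; defaults
#'   to `"n1" ... "nN"`.
#' @param regions optional character vector mapping each node to a
#'   region label (e.g. major brain divisions).
#' @param modules optional character/integer vector of planted module
#'   labels (set by [make_synthetic_connectome()]), used to score
#'   community recovery.
#'
#' @return An object of class `sync_network`.
#' @seealso [make_small_world()], [make_scale_free()], [make_random()],
#'   [make_synthetic_connectome()], [load_connectome()], [graph_metrics()]
#' @export
sync_network <- function(weights, directed, weighted,
                         node_labels = NULL, regions = NULL,
                         modules = NULL) {
  if (!is.matrix(weights) || nrow(weights) != ncol(weights))
    abort("`weights` must be a square matrix.", class = "tesync_format_error")
  n <- nrow(weights)
  if (n < 1) abort("empty graph", class = "tesync_format_error")
  if (any(weights < 0))
    abort("negative edge weights are not allowed.",
          class = "tesync_format_error")
  if (any(diag(weights) != 0)) {
    warn("non-zero diagonal entries found; self-loops removed.")
    diag(weights) <- 0
  }
  if (!directed && !isTRUE(all.equal(weights, t(weights))))
    abort("undirected network requires a symmetric weight matrix.",
          class = "tesync_format_error")
  if (weighted) {
    if (max(weights) > 1)
      abort("weighted networks must have weights in [0, 1]; rescale first.",
            class = "tesync_format_error")
  } else if (!all(weights %in% c(0, 1))) {
    abort("unweighted networks must have 0/1 weights.",
          class = "tesync_format_error")
  }
  if (is.null(node_labels)) node_labels <- paste0("n", seq_len(n))
  if (length(node_labels) != n || anyDuplicated(node_labels))
    abort("node labels must be unique and match the number of nodes.",
          class = "tesync_format_error")
  structure(
    list(weights = weights, directed = directed, weighted = weighted,
         node_labels = as.character(node_labels),
         regions = regions, modules = modules),
    class = "sync_network")
}

#' @export
print.sync_network <- function(x, ...) {
  cat(sprintf("<sync_network> %d nodes, %d edges (%s, %s)\n",
              n_nodes(x), n_edges(x),
              if (x$directed) "directed" else "undirected",
              if (x$weighted) "weighted" else "binary"))
  if (!is.null(x$modules))
    cat("  planted modules:", paste(unique(x$modules), collapse = ", "), "\n")
  invisible(x)
}

#' Number of nodes / edges of a network
#' @param g a [sync_network()].
#' @return integer scalar.
#' @export
n_nodes <- function(g) nrow(g$weights)

#' @rdname n_nodes
#' @export
n_edges <- function(g) {
  ne <- sum(g$weights > 0)
  as.integer(if (g$directed) ne else ne / 2)
}

#' Per-node in-strength, in-degree and out-degree
#'
#' In-strength is the row sum of the weight matrix (total incoming
#' weight); it equals the in-degree on binary graphs and is the
#' normaliser of the local synchrony.
#'
#' @param g a [sync_network()].
#' @return numeric (or integer) vector of length `n_nodes(g)`.
#' @export
in_strength <- function(g) rowSums(g$weights)

#' @rdname in_strength
#' @export
in_degree <- function(g) as.integer(rowSums(g$weights > 0))

#' @rdname in_strength
#' @export
out_degree <- function(g) as.integer(colSums(g$weights > 0))

#' Convert a network to an igraph object
#'
#' @param g a [sync_network()].
#' @param skeleton if `TRUE`, return the binarized undirected skeleton
#'   (used for path-based metrics and cluster traversal).
#' @return an [igraph::graph] object.
#' @export
as_igraph <- function(g, skeleton = FALSE) {
  w <- g$weights
  if (skeleton) {
    w <- (w > 0) + 0
    w <- pmax(w, t(w))
    ig <- igraph::graph_from_adjacency_matrix(w, mode = "undirected")
  } else {
    # igraph reads A[i,j] as i -> j; transpose our target-row convention
    ig <- igraph::graph_from_adjacency_matrix(
      t(w), mode = if (g$directed) "directed" else "undirected",
      weighted = if (g$weighted) TRUE else NULL)
  }
  igraph::set_vertex_attr(ig, "name", value = g$node_labels)
}

# adjacency list of the undirected skeleton (internal; SCTA traversal)
skeleton_neighbors <- function(g) {
  w <- g$weights > 0
  w <- w | t(w)
  apply(w, 1, which, simplify = FALSE)
}

from_igraph <- function(ig, directed, weighted, labels = NULL, ...) {
  a <- as.matrix(igraph::as_adjacency_matrix(ig, sparse = TRUE))
  a <- t(a)  # igraph row = source; we store row = target
  if (!weighted) a <- (a > 0) + 0
  dimnames(a) <- NULL
  sync_network(a, directed = directed, weighted = weighted,
               node_labels = labels, ...)
}

# Regenerate with incremented seed until connected (up to 20 attempts).
ensure_connected <- function(make, seed, what) {
  for (k in 0:19) {
    g <- make(seed + k)
    ig <- as_igraph(g, skeleton = TRUE)
    if (igraph::is_connected(ig)) {
      if (k > 0)
        inform(sprintf("%s: disconnected for seeds %s; used seed %d.",
                       what, paste(seed + 0:(k - 1), collapse = ", "),
                       seed + k))
      return(g)
    }
  }
  abort(sprintf("%s: no connected graph in 20 attempts from seed %d.",
                what, seed))
}

#' Watts-Strogatz small-world network
#'
#' Classic single-endpoint rewiring: start from a ring lattice in which
#' every node connects to its `mean_degree` nearest neighbours
#' (`mean_degree/2` on each side); each lattice edge is then rewired
#' with probability `rewire_p` by moving its far endpoint to a uniform
#' random node, avoiding self-loops and duplicate edges.  Rewiring
#' conserves the edge count `n * mean_degree / 2`.  Disconnected
#' outcomes are regenerated with an incremented seed (logged).
#'
#' @param n number of nodes.
#' @param mean_degree even integer lattice degree (>= 2, < n).
#' @param rewire_p rewiring probability in `[0, 1]`.
#' @param seed integer seed.
#' @return a binary undirected [sync_network()].
#' @export
make_small_world <- function(n, mean_degree, rewire_p, seed = 1L) {
  if (n <= mean_degree || mean_degree < 2 || mean_degree %% 2 != 0)
    abort("need n > mean_degree >= 2 with mean_degree even.",
          class = "tesync_parameter_error")
  if (rewire_p < 0 || rewire_p > 1)
    abort("rewire_p must be in [0, 1].", class = "tesync_parameter_error")
  half <- mean_degree / 2
  make <- function(s) with_seed(s, {
    adj <- matrix(FALSE, n, n)
    for (j in seq_len(half)) {
      i <- 0:(n - 1)
      tgt <- (i + j) %% n
      adj[cbind(i + 1, tgt + 1)] <- TRUE
      adj[cbind(tgt + 1, i + 1)] <- TRUE
    }
    if (rewire_p > 0) {
      for (j in seq_len(half)) {
        for (i in 0:(n - 1)) {
          if (runif(1) < rewire_p) {
            old <- (i + j) %% n
            cand <- which(!adj[i + 1, ] & seq_len(n) != (i + 1))
            if (length(cand) > 0) {
              new <- if (length(cand) == 1) cand else sample(cand, 1)
              adj[i + 1, old + 1] <- adj[old + 1, i + 1] <- FALSE
              adj[i + 1, new] <- adj[new, i + 1] <- TRUE
            }
          }
        }
      }
    }
    sync_network(adj + 0, directed = FALSE, weighted = FALSE)
  })
  ensure_connected(make, seed, "make_small_world")
}

#' Barabasi-Albert scale-free network
#'
#' Preferential-attachment growth starting from a single node; each new
#' node attaches to `min(m, existing nodes)` distinct targets with
#' probability proportional to their degree, so the final edge count is
#' `m * (n - m) + m * (m - 1) / 2` and `(n = m + 1)` yields the
#' complete graph.
#'
#' @param n number of nodes (> m).
#' @param m attachment parameter (>= 1).
#' @param seed integer seed.
#' @return a binary undirected [sync_network()].
#' @export
make_scale_free <- function(n, m, seed = 1L) {
  if (n <= m || m < 1)
    abort("need n > m >= 1.", class = "tesync_parameter_error")
  make <- function(s) with_seed(s, {
    ig <- igraph::sample_pa(n, m = m, directed = FALSE)
    from_igraph(ig, directed = FALSE, weighted = FALSE)
  })
  ensure_connected(make, seed, "make_scale_free")
}

#' Erdos-Renyi random network
#'
#' `G(n, p)` with `p = mean_degree / (n - 1)`.
#'
#' @param n number of nodes.
#' @param mean_degree target expected degree, in `(0, n - 1)`.
#' @param seed integer seed.
#' @return a binary undirected [sync_network()].
#' @export
make_random <- function(n, mean_degree, seed = 1L) {
  if (mean_degree <= 0 || mean_degree >= n)
    abort("need 0 < mean_degree < n - 1.", class = "tesync_parameter_error")
  p <- mean_degree / (n - 1)
  make <- function(s) with_seed(s, {
    ig <- igraph::sample_gnp(n, p)
    from_igraph(ig, directed = FALSE, weighted = FALSE)
  })
  ensure_connected(make, seed, "make_random")
}

#' Synthetic brain-like connectome
#'
#' Generates a weighted, directed, modular, bilaterally mirrored
#' network that emulates the gross architecture of a mesoscale
#' connectome: two hemispheres of `n_regions / 2` nodes, each divided
#' into `n_modules` modules; directed edges appear within a module with
#' probability `intra_density` and between any other pair of nodes
#' (including across hemispheres) with probability `inter_density`;
#' the right hemisphere is an exact mirror copy of the left.  Edge
#' weights are drawn from a Pareto distribution with shape
#' `weight_shape` (heavier tail for smaller values) and rescaled so the
#' maximum is 1.
#'
#' Modules are wired with a coupling hierarchy: weights in module `m`
#' are scaled by `module_strengths[m]`, emulating strongly coupled
#' cortical-like modules down to a weakly coupled hindbrain-like module
#' that stays out of the synchronization cluster.  Planted module
#' labels (`L1`, ..., `R1`, ...) are recorded for community-recovery
#' checks.
#'
#' @param n_regions even total node count.
#' @param n_modules modules per hemisphere.
#' @param intra_density,inter_density edge probabilities with
#'   `intra_density > inter_density`, both in `[0, 1]`.
#' @param weight_shape positive Pareto shape for edge weights.
#' @param module_strengths numeric vector of length `n_modules` of
#'   relative coupling strengths; default a linear gradient from 1 to
#'   0.5.
#' @param seed integer seed.
#' @return a weighted directed [sync_network()] with planted `modules`
#'   and mirrored `regions` (`"L"`/`"R"`).
#' @export
make_synthetic_connectome <- function(n_regions = 60, n_modules = 3,
                                      intra_density = 0.5,
                                      inter_density = 0.05,
                                      weight_shape = 6,
                                      module_strengths = NULL,
                                      seed = 1L) {
  if (n_regions %% 2 != 0)
    abort("n_regions must be even (two mirrored hemispheres).",
          class = "tesync_parameter_error")
  for (d in c(intra_density, inter_density))
    if (d < 0 || d > 1)
      abort("densities must lie in [0, 1].", class = "tesync_parameter_error")
  if (intra_density <= inter_density)
    abort("need intra_density > inter_density.",
          class = "tesync_parameter_error")
  if (weight_shape <= 0)
    abort("weight_shape must be positive.", class = "tesync_parameter_error")
  if (is.null(module_strengths))
    module_strengths <- seq(1, 0.5, length.out = n_modules)
  if (length(module_strengths) != n_modules)
    abort("module_strengths must have one entry per module.",
          class = "tesync_parameter_error")

  nh <- n_regions / 2
  module_h <- rep(seq_len(n_modules), length.out = nh)[order(rep(
    seq_len(n_modules), length.out = nh))]  # contiguous blocks
  with_seed(seed, {
    same <- outer(module_h, module_h, "==")
    diag(same) <- NA  # no self-loops
    p_h <- ifelse(same, intra_density, inter_density)
    draw <- function(p) {
      a <- matrix(runif(nh * nh) < p, nh, nh)
      a[is.na(a)] <- FALSE
      a
    }
    adj_h <- draw(p_h)                       # within left hemisphere
    adj_x <- matrix(runif(nh * nh) < inter_density, nh, nh)  # L -> R
    adj_x2 <- matrix(runif(nh * nh) < inter_density, nh, nh) # R -> L

    pareto <- function(k) (1 - runif(k))^(-1 / weight_shape)
    weigh <- function(a, scale_row) {
      w <- matrix(0, nh, nh)
      w[a] <- pareto(sum(a))
      w * scale_row
    }
    scale_vec <- module_strengths[module_h]
    w_h <- weigh(adj_h, scale_vec)          # row = target
    w_x <- weigh(adj_x, scale_vec)
    w_x2 <- weigh(adj_x2, scale_vec)

    W <- rbind(cbind(w_h, w_x2),            # left targets
               cbind(w_x, w_h))             # right targets mirror left
    if (max(W) > 0) W <- W / max(W)
    modules <- c(paste0("L", module_h), paste0("R", module_h))
    labels <- c(paste0("L", module_h, "_", seq_len(nh)),
                paste0("R", module_h, "_", seq_len(nh)))
    sync_network(W, directed = TRUE, weighted = TRUE,
                 node_labels = labels,
                 regions = rep(c("L", "R"), each = nh),
                 modules = modules)
  })
}

#' Load a connectome from disk
#'
#' Reads a weighted directed network from either an edge list (`source
#' target weight` per line, whitespace- or comma-separated, optional
#' header, node ids interned from labels) or a dense CSV matrix whose
#' row index is the *target* node.  Weights are rescaled to `[0, 1]` by
#' dividing by the maximum.  `binarize` maps positive weights to 1;
#' `symmetrize` takes `max(w_ij, w_ji)` and returns an undirected
#' network; combining both yields the binary-undirected variant.
#'
#' @param path file path.
#' @param fmt `"edge_list"` or `"dense_matrix"`.
#' @param binarize,symmetrize logical transforms applied after loading.
#' @return a [sync_network()].
#' @export
load_connectome <- function(path, fmt = c("edge_list", "dense_matrix"),
                            binarize = FALSE, symmetrize = FALSE) {
  fmt <- match.arg(fmt)
  if (!file.exists(path))
    abort(sprintf("file not found: %s", path), class = "tesync_format_error")
  if (fmt == "edge_list") {
    raw <- readLines(path, warn = FALSE)
    raw <- raw[nzchar(trimws(raw))]
    fields <- strsplit(trimws(raw), "[,[:space:]]+")
    first <- suppressWarnings(as.numeric(fields[[1]][3]))
    if (is.na(first) && length(fields) > 1) fields <- fields[-1]  # header
    src <- vapply(fields, `[`, "", 1)
    tgt <- vapply(fields, `[`, "", 2)
    w <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 3)))
    if (anyNA(w)) w[is.na(w)] <- 1
    labels <- unique(c(src, tgt))
    n <- length(labels)
    W <- matrix(0, n, n)
    W[cbind(match(tgt, labels), match(src, labels))] <- w
  } else {
    W <- as.matrix(read.csv(path, header = FALSE))
    if (nrow(W) != ncol(W))
      abort("dense matrix must be square.", class = "tesync_format_error")
    storage.mode(W) <- "double"
    labels <- paste0("n", seq_len(nrow(W)))
  }
  if (any(is.na(W)))
    abort("non-numeric entries in connectome.", class = "tesync_format_error")
  if (any(W < 0))
    abort("negative weights are not allowed.", class = "tesync_format_error")
  if (any(diag(W) != 0)) {
    warn("self-loops found in connectome; diagonal zeroed.")
    diag(W) <- 0
  }
  if (max(W) > 0) W <- W / max(W)
  directed <- TRUE
  if (symmetrize) {
    W <- pmax(W, t(W))
    directed <- FALSE
  }
  weighted <- TRUE
  if (binarize) {
    W <- (W > 0) + 0
    weighted <- FALSE
  }
  sync_network(W, directed = directed, weighted = weighted,
               node_labels = labels)
}

#' Write a network to a CSV edge list
#'
#' One line per edge, `source,target,weight`, using node labels.
#' Round-trips through [load_connectome()] up to weight rescaling.
#'
#' @param g a [sync_network()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(g, path) {
  idx <- which(g$weights > 0, arr.ind = TRUE)
  if (!g$directed) idx <- idx[idx[, 1] < idx[, 2], , drop = FALSE]
  df <- data.frame(source = g$node_labels[idx[, 2]],
                   target = g$node_labels[idx[, 1]],
                   weight = g$weights[idx])
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
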