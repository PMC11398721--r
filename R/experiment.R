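#' Experiment configuration
#'
#' Bundles a graph source, model parameters, sweep grids, transient
#' and SCTA settings, and a master seed into a single validated,
#' JSON-serializable object.  Every random draw in [run_experiment()]
#' derives from the master seed (child seeds are `seed + stage
#' offset`), so re-running a config reproduces identical outputs.
#'
#' @param graph list describing the graph source: either
#'   `list(family = "sw"|"sf"|"er"|"synthetic", ...params)` or
#'   `list(path = "...", fmt = "edge_list"|"dense_matrix", ...)`.
#' @param params list of [model_params()] arguments.
#' @param lambda_grid fixed-resource grid for the hysteresis stage
#'   (`list(min, max, delta, dwell)`).
#' @param lambda_o_grid resource-bath grid for the bifurcation stage
#'   (`list(min, max, delta, dwell, R_low, R_high)`).
#' @param beta_list consumption rates for the ratio stage (optional).
#' @param transients list of transient-extraction settings (`n_runs`,
#'   `run_duration`, `window`, `stride`, thresholds; optional).
#' @param scta list of SCTA settings (`threshold`, `stride`; optional).
#' @param seed master seed.
#' @return an `experiment_config` object.
#' @export
experiment_config <- function(graph, params = list(),
                              lambda_grid = NULL, lambda_o_grid = NULL,
                              beta_list = NULL, transients = NULL,
                              scta = NULL, seed = 1L) {
  cfg <- structure(list(graph = graph, params = params,
                        lambda_grid = lambda_grid,
                        lambda_o_grid = lambda_o_grid,
                        beta_list = beta_list, transients = transients,
                        scta = scta, seed = as.integer(seed)),
                   class = "experiment_config")
  errs <- validate_config(cfg)
  if (length(errs))
    abort(paste0("invalid config:\n", paste("-", errs, collapse = "\n")),
          class = "tesync_parameter_error")
  cfg
}

#' Validate an experiment configuration
#'
#' Checks all parameter and grid invariants, collecting every problem
#' rather than stopping at the first.
#'
#' @param cfg an `experiment_config` (or plain list with the same
#'   fields).
#' @return character vector of error messages (empty when valid).
#' @export
validate_config <- function(cfg) {
  errs <- character()
  gs <- cfg$graph
  if (is.null(gs$family) && is.null(gs$path))
    errs <- c(errs, "graph source needs a `family` or a `path`")
  if (!is.null(gs$family) &&
      !gs$family %in% c("sw", "sf", "er", "synthetic"))
    errs <- c(errs, "unknown graph family")
  pl <- cfg$params
  if (!is.null(pl$fixed_lambda) && !is.null(pl$lambda_o))
    errs <- c(errs, "fixed_lambda and lambda_o modes conflict")
  base <- utils::modifyList(
    list(alpha = 0.01, beta = 0.002, dt = 0.05, omega_range = c(-1, 1)),
    pl[setdiff(names(pl), c("lambda_o", "fixed_lambda"))])
  probe <- structure(c(base, list(lambda_o = 0.1, fixed_lambda = NULL)),
                     class = "model_params")
  errs <- c(errs, validate_params(probe))
  for (grid_name in c("lambda_grid", "lambda_o_grid")) {
    gr <- cfg[[grid_name]]
    if (!is.null(gr)) {
      if (is.null(gr$min) || is.null(gr$max) || is.null(gr$delta))
        errs <- c(errs, sprintf("%s needs min, max, delta", grid_name))
      else if (gr$delta <= 0 || gr$max < gr$min)
        errs <- c(errs, sprintf("%s must be increasing", grid_name))
    }
  }
  if (!is.null(cfg$beta_list) && length(cfg$beta_list) == 0)
    errs <- c(errs, "beta_list is empty")
  if (!is.null(cfg$beta_list) && any(cfg$beta_list <= 0))
    errs <- c(errs, "beta_list entries must be > 0")
  if (!is.null(cfg$transients) && !is.null(cfg$transients$window) &&
      !is.null(cfg$transients$run_duration) &&
      cfg$transients$window > cfg$transients$run_duration)
    errs <- c(errs, "transient window longer than run_duration")
  errs
}

#' Named preset configurations
#'
#' * `"swn-tes"` - the small-world study: WS(400, 40, 0.232),
#'   `alpha = 0.01`, `beta = 0.002`; hysteresis grid 0 to 0.12 step
#'   0.003 (dwell 50), bifurcation grid 0.01 to 0.3 step 0.01
#'   (dwell 500).
#' * `"swn-ratio"` - the recovery-to-consumption sweep on the same
#'   network, `beta` from 0.01 down to 0.0002.
#' * `"synthetic-tes"` - the built-in brain-like fixture in its
#'   bistable regime, with transient extraction and SCTA settings.
#' * `"mbn"` - template for a user-supplied mesoscale connectome
#'   (weighted directed; set `graph$path` before running): bifurcation
#'   around `lambda_o = 2.87`, dwell 2000, grid step 0.02,
#'   `R_high = 0.45`.
#'
#' @param name preset name.
#' @param seed master seed.
#' @return an `experiment_config`.
#' @export
preset_config <- function(name = c("swn-tes", "swn-ratio",
                                   "synthetic-tes", "mbn"),
                          seed = 1L) {
  name <- match.arg(name)
  switch(name,
    "swn-tes" = experiment_config(
      graph = list(family = "sw", n = 400, mean_degree = 40,
                   rewire_p = 0.232),
      params = list(alpha = 0.01, beta = 0.002),
      lambda_grid = list(min = 0, max = 0.12, delta = 0.003, dwell = 50),
      lambda_o_grid = list(min = 0.01, max = 0.3, delta = 0.01,
                           dwell = 500, R_low = 0.2, R_high = 0.5),
      seed = seed),
    "swn-ratio" = experiment_config(
      graph = list(family = "sw", n = 400, mean_degree = 40,
                   rewire_p = 0.232),
      params = list(alpha = 0.01),
      beta_list = c(0.01, 0.005, 0.002, 0.001, 0.0005, 0.00025, 0.0002),
      seed = seed),
    "synthetic-tes" = experiment_config(
      graph = list(family = "synthetic", n_regions = 60, n_modules = 3,
                   intra_density = 0.5, inter_density = 0.05),
      params = list(alpha = 0.01, beta = 0.002, lambda_o = 0.72),
      lambda_o_grid = list(min = 0.1, max = 1.6, delta = 0.1, dwell = 500,
                           R_low = 0.2, R_high = 0.45),
      transients = list(n_runs = 4, run_duration = 2000, window = 50,
                        stride = 0.2, desync_threshold = 0.15,
                        sync_threshold = 0.5),
      scta = list(threshold = 0.5, stride = 0.2),
      seed = seed),
    "mbn" = experiment_config(
      graph = list(path = NA_character_, fmt = "edge_list"),
      params = list(alpha = 0.01, beta = 0.002, lambda_o = 2.87),
      lambda_grid = list(min = 2.4, max = 2.9, delta = 0.02, dwell = 2000),
      lambda_o_grid = list(min = 2.4, max = 3.2, delta = 0.02,
                           dwell = 2000, R_low = 0.2, R_high = 0.45),
      transients = list(n_runs = 4, run_duration = 20000, window = 50,
                        stride = 0.2, desync_threshold = 0.1,
                        sync_threshold = 0.5),
      scta = list(threshold = 0.5, stride = 0.2),
      seed = seed))
}

config_graph <- function(cfg) {
  gs <- cfg$graph
  if (!is.null(gs$path)) {
    if (is.na(gs$path) || !file.exists(gs$path))
      abort(paste0("this configuration requires an external connectome ",
                   "file; set graph$path to its location."),
            class = "tesync_parameter_error")
    return(load_connectome(gs$path, gs$fmt %||% "edge_list",
                           binarize = isTRUE(gs$binarize),
                           symmetrize = isTRUE(gs$symmetrize)))
  }
  switch(gs$family,
    sw = make_small_world(gs$n, gs$mean_degree, gs$rewire_p, cfg$seed),
    sf = make_scale_free(gs$n, gs$m, cfg$seed),
    er = make_random(gs$n, gs$mean_degree, cfg$seed),
    synthetic = make_synthetic_connectome(
      n_regions = gs$n_regions %||% 60, n_modules = gs$n_modules %||% 3,
      intra_density = gs$intra_density %||% 0.5,
      inter_density = gs$inter_density %||% 0.05,
      weight_shape = gs$weight_shape %||% 2, seed = cfg$seed))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

config_params <- function(cfg, mode = c("resource", "fixed"),
                          value = NULL) {
  mode <- match.arg(mode)
  pl <- cfg$params
  base <- list(alpha = pl$alpha %||% 0.01, beta = pl$beta %||% 0.002,
               dt = pl$dt %||% 0.05,
               omega_range = pl$omega_range %||% c(-1, 1))
  if (mode == "fixed")
    do.call(model_params, c(base, list(fixed_lambda = value %||% 0)))
  else
    do.call(model_params, c(base, list(lambda_o = value %||%
                                         (pl$lambda_o %||% 0.1))))
}

#' Config JSON round-trip
#'
#' @param cfg an `experiment_config`.
#' @param path JSON file path.
#' @return `path` / the restored `experiment_config`.
#' @export
write_config <- function(cfg, path) {
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw$seed <- as.integer(raw$seed)
  do.call(experiment_config, raw)
}

#' Run a configured experiment end to end
#'
#' Executes the requested stages against the configured network and
#' writes tabular results plus a JSON manifest to `out_dir`.  Stages
#' (any subset of `"hysteresis"`, `"bifurcation"`, `"transients"`,
#' `"communities"`, `"scta"`, `"ratio"`) default to every stage the
#' config provides settings for.  Re-running the same config writes
#' identical numeric output.
#'
#' @param cfg an `experiment_config`.
#' @param out_dir output directory (created if missing).
#' @param stages character vector of stages to run.
#' @return named list of written file paths, invisibly.
#' @export
run_experiment <- function(cfg, out_dir, stages = NULL) {
  errs <- validate_config(cfg)
  if (length(errs))
    abort(paste0("invalid config:\n", paste("-", errs, collapse = "\n")),
          class = "tesync_parameter_error")
  avail <- c(
    if (!is.null(cfg$lambda_grid)) "hysteresis",
    if (!is.null(cfg$lambda_o_grid)) "bifurcation",
    if (!is.null(cfg$transients)) "transients",
    if (!is.null(cfg$transients)) "communities",
    if (!is.null(cfg$transients) && !is.null(cfg$scta)) "scta",
    if (!is.null(cfg$beta_list)) "ratio")
  stages <- if (is.null(stages)) avail else match.arg(stages, avail,
                                                      several.ok = TRUE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  g <- config_graph(cfg)
  files <- list()
  summaries <- list(seed = cfg$seed)
  t0 <- Sys.time()

  if ("hysteresis" %in% stages) {
    gr <- cfg$lambda_grid
    p <- config_params(cfg, "fixed", gr$min)
    hc <- hysteresis_sweep(g, p, gr$min, gr$max, gr$delta,
                           gr$dwell %||% 50, seed = cfg$seed + 1L)
    files$hysteresis <- file.path(out_dir, "hysteresis.csv")
    write.csv(as.data.frame(tidy(hc)), files$hysteresis,
              row.names = FALSE, quote = FALSE)
    summaries$tipping_forward <- hc$tipping_forward
    summaries$tipping_backward <- hc$tipping_backward
  }
  if ("bifurcation" %in% stages) {
    gr <- cfg$lambda_o_grid
    p <- config_params(cfg, "resource")
    bd <- bifurcation_sweep(g, p, seq(gr$min, gr$max, gr$delta),
                            dwell = gr$dwell %||% 500,
                            R_low = gr$R_low %||% 0.2,
                            R_high = gr$R_high %||% 0.5,
                            seed = cfg$seed + 100L)
    files$bifurcation <- file.path(out_dir, "bifurcation.csv")
    write.csv(as.data.frame(bd), files$bifurcation,
              row.names = FALSE, quote = FALSE)
    summaries$left_boundary <- attr(bd, "left_boundary")
    summaries$right_boundary <- attr(bd, "right_boundary")
    summaries$tes_probability <- suppressMessages(tes_probability(bd))
  }
  windows <- NULL
  if ("transients" %in% stages || "scta" %in% stages ||
      "communities" %in% stages) {
    tr <- cfg$transients
    p <- config_params(cfg, "resource")
    windows <- extract_transients(
      g, p, n_runs = tr$n_runs %||% 4,
      run_duration = tr$run_duration %||% 2000,
      window = tr$window %||% 50, seed = cfg$seed + 200L,
      stride = tr$stride %||% 0.2,
      desync_threshold = tr$desync_threshold %||% 0.1,
      sync_threshold = tr$sync_threshold %||% 0.5)
    files$transients <- file.path(out_dir, "transients.csv")
    write.csv(data.frame(
      window = seq_along(windows),
      run = vapply(windows, `[[`, 0, "run"),
      seed = vapply(windows, `[[`, 0, "seed"),
      onset_time = vapply(windows, `[[`, 0, "onset_time")),
      files$transients, row.names = FALSE, quote = FALSE)
    summaries$n_transients <- length(windows)
  }
  if ("communities" %in% stages && length(windows)) {
    part <- detect_communities(g, seed = cfg$seed + 300L)
    files$partition <- file.path(out_dir, "partition.csv")
    write_partition(part, files$partition)
    ims <- intramodular_synchrony(windows, part)
    files$intramodular <- file.path(out_dir, "intramodular.csv")
    write.csv(as.data.frame(ims), files$intramodular,
              row.names = FALSE, quote = FALSE)
    ims2 <- intermodular_synchrony(windows, part)
    files$intermodular <- file.path(out_dir, "intermodular.csv")
    write.csv(as.data.frame(ims2), files$intermodular,
              row.names = FALSE, quote = FALSE)
    summaries$modularity_Q <- attr(part, "Q")
    summaries$n_communities <- attr(part, "n_communities")
  }
  if ("scta" %in% stages && length(windows)) {
    sc <- cfg$scta
    lineages <- lapply(windows, track_clusters, g = g,
                       threshold = sc$threshold %||% 0.5,
                       eval_stride = sc$stride %||% 0.2)
    st <- time_in_main_stats(lineages)
    st$out_degree <- out_degree(g)
    st$label <- g$node_labels
    files$scta_stats <- file.path(out_dir, "scta_stats.csv")
    write.csv(as.data.frame(st), files$scta_stats,
              row.names = FALSE, quote = FALSE)
  }
  if ("ratio" %in% stages) {
    rs <- ratio_sweep(g, alpha = cfg$params$alpha %||% 0.01,
                      beta_list = cfg$beta_list, seed = cfg$seed + 400L)
    files$ratio <- file.path(out_dir, "ratio_sweep.csv")
    write.csv(as.data.frame(rs), files$ratio, row.names = FALSE,
              quote = FALSE)
  }

  manifest <- list(
    config = unclass(cfg), stages = stages,
    files = lapply(files, basename),
    n_nodes = n_nodes(g), n_edges = n_edges(g),
    summaries = summaries,
    r_version = as.character(getRversion()),
    package_version = as.character(utils::packageVersion("tesync")),
    wall_time_s = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  files$manifest <- manifest_path
  invisible(files)
}
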