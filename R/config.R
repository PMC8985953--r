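config_keys <- c("variant", "params", "engine", "experiment", "options",
                 "seed", "out_dir", "provenance")
engines <- c("ode", "ssa", "cme", "reduced")
experiments <- c("simulate", "equilibria", "bifurcation", "chart",
                 "hysteresis", "stationary", "first_passage", "reactivation",
                 "events", "robustness", "scaling")

#' Load and validate a scenario configuration
#'
#' Reads a YAML or JSON scenario file describing a circuit variant, its
#' dimensionless parameters, the engine and the experiment to run, and fills
#' defaults (order-one factors \code{b = beta = 1}, count margin
#' \code{options$margin = 6}). Stochastic engines require a seed.
#'
#' @param path path to a YAML or JSON file, or a named list already in
#'   memory.
#' @return Object of class \code{"scenario_config"}.
#' @export
load_config <- function(path) {
  cfg <- if (is.list(path)) path
  else if (grepl("\\.json$", path)) jsonlite::fromJSON(path,
                                                       simplifyVector = TRUE)
  else yaml::read_yaml(path)
  unknown <- setdiff(names(cfg), config_keys)
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  cfg$variant <- cfg$variant %||% "full"
  if (!cfg$variant %in% c("full", "histone_only", "autoregulated",
                          "mutual_repression"))
    stop("config field 'variant': unknown variant '", cfg$variant, "'")
  cfg$engine <- cfg$engine %||% "ode"
  if (!cfg$engine %in% engines)
    stop("config field 'engine': must be one of ",
         paste(engines, collapse = ", "))
  cfg$experiment <- cfg$experiment %||% "simulate"
  if (!cfg$experiment %in% experiments)
    stop("config field 'experiment': must be one of ",
         paste(experiments, collapse = ", "))
  bad <- setdiff(names(cfg$params),
                 names(formals(chromatin_params)))
  if (length(bad))
    stop("config field 'params': unknown parameters ",
         paste(bad, collapse = ", "))
  params <- do.call(chromatin_params, as.list(cfg$params))
  cfg$params <- unclass(params)
  cfg$options <- cfg$options %||% list()
  cfg$options$margin <- cfg$options$margin %||% 6L
  if (cfg$engine == "ssa" && is.null(cfg$seed))
    stop("config field 'seed': required for the ssa engine")
  cfg$seed <- cfg$seed %||% 1L
  structure(cfg, class = "scenario_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Save a resolved configuration
#'
#' @param config a \code{"scenario_config"} object.
#' @param path output YAML path.
#' @return \code{path}, invisibly.
#' @export
save_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path, precision = 17L)
  invisible(path)
}

config_network <- function(config) {
  params <- do.call(chromatin_params, config$params)
  switch(config$variant,
         full = build_network(params, "full"),
         histone_only = build_network(params, "histone_only"),
         autoregulated = make_autoregulated(
           params, uA_tilde = config$options$uA_tilde %||% 1),
         mutual_repression = make_mutual_repression(
           params, uA_tilde = config$options$uA_tilde %||% 1,
           uR_tilde = config$options$uR_tilde %||% 1))
}

#' Run a scenario
#'
#' Dispatches a validated configuration to the requested engine and
#' experiment, writes CSV/JSON outputs plus the resolved configuration and a
#' small run log to \code{out_dir}, and returns the result object.
#'
#' @param config a \code{"scenario_config"} (or path, passed through
#'   \code{\link{load_config}}).
#' @param out_dir output directory (overrides the config's); \code{NULL}
#'   skips writing files.
#' @return The experiment's result object, invisibly when written to disk.
#' @export
run_scenario <- function(config, out_dir = config$out_dir %||% NULL) {
  if (!inherits(config, "scenario_config")) config <- load_config(config)
  params <- do.call(chromatin_params, config$params)
  net <- config_network(config)
  opt <- config$options
  set.seed(config$seed)
  result <- switch(
    config$experiment,
    simulate = {
      init <- opt$init %||% chromatin_state(net, "repressed")
      if (config$engine == "ode")
        simulate_ode(net, unlist(init) / net$Dtot,
                     tau_max = opt$tau_max %||% 100)
      else ssa_run(net, unlist(init), tau_max = opt$tau_max %||% 100,
                   seed = config$seed,
                   sample_times = seq(0, opt$tau_max %||% 100,
                                      length.out = opt$n_out %||% 101))
    },
    equilibria = find_equilibria(net, seed = config$seed),
    bifurcation = bifurcation_scan(params, opt$scan_param,
                                   unlist(opt$grid),
                                   variant = config$variant,
                                   seed = config$seed),
    chart = stability_chart(params, opt$xname, unlist(opt$xgrid),
                            opt$yname, unlist(opt$ygrid),
                            variant = config$variant, seed = config$seed),
    hysteresis = hysteresis_sweep(params, opt$input,
                                  unlist(opt$values),
                                  variant = config$variant),
    stationary = {
      if (config$engine == "cme") {
        g <- build_generator(net)
        exact_stationary(g$Q, g$states, net)
      } else stationary_histogram(net, horizon = opt$horizon %||% 500,
                                  reps = opt$reps %||% 50,
                                  seed = config$seed)
    },
    first_passage = {
      start <- unlist(opt$start %||% chromatin_state(net, "repressed"))
      target <- opt$target %||%
        list(species = "DA", op = ">=", value = net$Dtot - opt$margin)
      first_passage_sample(net, start, target, reps = opt$reps %||% 200,
                           max_time = opt$max_time %||% 1e5,
                           seed = config$seed)
    },
    reactivation = reactivation_experiment(params, uA = opt$uA %||% 1,
                                           reps = opt$reps %||% 100,
                                           margin = opt$margin,
                                           seed = config$seed),
    events = apply_events(net, unlist(opt$init), opt$tau_max %||% 100,
                          opt$events, engine = config$engine,
                          seed = config$seed),
    robustness = robustness_scan(params, unlist(opt$uR_grid),
                                 unlist(opt$px_grid)),
    scaling = mfpt_scaling_check(params,
                                 eps_grid = unlist(opt$eps_grid) %||%
                                   exp(seq(log(1e-4), log(1e-3),
                                           length.out = 6)),
                                 variant = config$variant))
  if (is.null(out_dir)) return(result)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  save_config(config, file.path(out_dir, "resolved-config.yaml"))
  write_result(result, config, out_dir)
  log <- list(timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
              seed = config$seed,
              config_hash = config_fingerprint(config),
              r_version = R.version.string,
              package_version = as.character(utils::packageVersion("chromem")))
  jsonlite::write_json(log, file.path(out_dir, "run-log.json"),
                       auto_unbox = TRUE)
  invisible(result)
}

# config fingerprint without external dependencies
config_fingerprint <- function(x) {
  s <- paste(deparse(unclass(x)), collapse = "")
  sprintf("%08x", sum(utf8ToInt(s) * seq_along(utf8ToInt(s))) %% .Machine$integer.max)
}

write_result <- function(result, config, out_dir) {
  csv <- function(df, name) utils::write.csv(
    df, file.path(out_dir, paste0(name, ".csv")), row.names = FALSE)
  if (inherits(result, "ode_trajectory") || inherits(result, "io_characteristic"))
    csv(as.data.frame(result), "result")
  else if (inherits(result, "ssa_run")) {
    if (!is.null(result$snapshots)) csv(result$snapshots, "trajectory")
    jsonlite::write_json(list(final_state = as.list(result$state),
                              time = result$time, stopped = result$stopped),
                         file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE)
  } else if (inherits(result, "stationary_distribution")) {
    csv(result$full, "distribution-full")
    csv(result$macro, "distribution-macro")
  } else if (inherits(result, "first_passage")) {
    csv(data.frame(time = result$times, censored = result$censored),
        "first-passage-samples")
    jsonlite::write_json(list(mean = result$mean, se = result$se,
                              n_censored = result$n_censored),
                         file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE)
  } else if (inherits(result, "equilibrium_set")) {
    df <- do.call(rbind, lapply(seq_along(result$equilibria), function(i) {
      e <- result$equilibria[[i]]
      data.frame(id = i, stability = e$stability,
                 leading_eig = e$leading_eig, t(e$state))
    }))
    if (!is.null(df)) csv(df, "equilibria")
    jsonlite::write_json(list(classification = result$classification),
                         file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE)
  } else if (is.data.frame(result)) csv(result, "result")
  else if (is.list(result)) {
    for (nm in names(result))
      if (is.data.frame(result[[nm]])) csv(result[[nm]], nm)
    flat <- Filter(function(v) is.atomic(v) && length(v) <= 10, result)
    if (length(flat))
      jsonlite::write_json(flat, file.path(out_dir, "summary.json"),
                           auto_unbox = TRUE)
  }
  invisible(NULL)
}

#' Built-in scenario presets
#'
#' Named configurations for the characteristic regimes of the circuit:
#' deterministic bistability and its loss at large basal erasure, input
#' hysteresis, bimodal stationary distributions, memory-loss first-passage
#' experiments, reactivation, autoregulation robustness, and the
#' mutual-repression pattern census. Values not fixed by a regime are chosen
#' as documented defaults and marked \code{assumed} in the provenance note.
#'
#' @return \code{list_scenarios}: character vector of preset names.
#' @export
list_scenarios <- function() names(scenario_presets())

#' @param name preset name from \code{\link{list_scenarios}}.
#' @rdname list_scenarios
#' @return \code{scenario_config}: the corresponding
#'   \code{"scenario_config"}.
#' @export
scenario_config <- function(name) {
  presets <- scenario_presets()
  if (!name %in% names(presets))
    stop("unknown scenario '", name, "'; see list_scenarios()")
  load_config(presets[[name]])
}

scenario_presets <- function() list(
  bistable_equilibria = list(
    variant = "full", engine = "ode", experiment = "equilibria",
    params = list(eps = 0.1),
    provenance = "no external inputs, basal drives 0.1 (caption-derived); eps assumed small"),
  eps_bifurcation = list(
    variant = "full", engine = "ode", experiment = "bifurcation",
    params = list(),
    options = list(scan_param = "eps",
                   grid = exp(seq(log(0.02), log(2), length.out = 15))),
    provenance = "scan of basal erasure rate; inputs caption-derived"),
  activation_hysteresis = list(
    variant = "full", engine = "ode", experiment = "hysteresis",
    params = list(eps = 0.1, mu_prime = 0.8),
    options = list(input = "uA", values = seq(0, 4, by = 0.25)),
    provenance = "uA sweep from repressed state; eps assumed small"),
  stationary_low_eps = list(
    variant = "full", engine = "ssa", experiment = "stationary", seed = 1L,
    params = list(eps = 0.1, alpha = 0.2, alpha_bar = 0.2,
                  alpha_prime = 0.2, Dtot = 20),
    options = list(horizon = 2000, reps = 40),
    provenance = "bimodal regime; catalysis ratios 0.2 caption-derived, Dtot reduced (assumed)"),
  memory_loss = list(
    variant = "full", engine = "ssa", experiment = "first_passage", seed = 1L,
    params = list(eps = 0.36, alpha = 0.2, alpha_bar = 0.2,
                  alpha_prime = 0.2, Dtot = 20),
    options = list(reps = 200),
    provenance = "repressed-to-active hitting times; eps caption-derived"),
  reactivation = list(
    variant = "full", engine = "ssa", experiment = "reactivation", seed = 1L,
    params = list(eps = 0.24, mu_prime = 0.1, alpha = 0.2, alpha_bar = 0.2,
                  alpha_prime = 0.2, Dtot = 20),
    options = list(uA = 3.2, reps = 50),
    provenance = "uA = 3.2, mu_prime = 0.1 caption-derived; Dtot reduced (assumed)"),
  autoregulation_robustness = list(
    variant = "autoregulated", engine = "ode", experiment = "robustness",
    params = list(eps = 0.1, mu_prime = 0.7),
    options = list(uR_grid = seq(0, 2, by = 0.2), px_grid = c(0, 0.5, 1, 2)),
    provenance = "eps = 0.1, mu_prime = 0.7 caption-derived; px grid assumed"),
  mutual_repression_census = list(
    variant = "mutual_repression", engine = "ssa", experiment = "stationary",
    seed = 1L,
    params = list(eps = 0.2, mu_prime = 0.6, alpha = 0.2, alpha_bar = 0.2,
                  alpha_prime = 0.2, px = 10, Dtot = 20),
    options = list(horizon = 1500, reps = 40),
    provenance = "mu_prime = 0.6 caption-derived; p large regime; Dtot reduced (assumed)")
)
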