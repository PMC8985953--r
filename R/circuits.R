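#' Positively autoregulated chromatin circuit
#'
#' Couples gene expression to the chromatin modification circuit: the gene
#' product X is produced from active nucleosomes and recruits writers of the
#' activating modification back to its own gene, so the de novo activating
#' drive becomes \code{u0A + uA_tilde * X} (with \code{X = nX/Dtot}; a
#' saturating Hill coupling is available). Protein reactions are
#' \code{DA -> DA + X} at rate \code{px * gamma_x * nA} and first-order decay
#' of X at rate \code{gamma_x}.
#'
#' With \code{qss = TRUE} the protein is eliminated at quasi-steady state
#' (\code{X = px * DA}), which turns the feedback into an additional
#' auto-catalysis reaction with coefficient \code{uA_tilde * px}; the result
#' is a pure chromatin network amenable to exact Markov analysis.
#'
#' @param params chromatin parameters; \code{params$px} and
#'   \code{params$gamma_x} set the protein production/decay ratio and decay
#'   rate unless overridden.
#' @param uA_tilde coupling gain from protein fraction to the activating
#'   drive.
#' @param px,gamma_x protein production/decay ratio and normalized decay rate
#'   (defaults taken from \code{params}).
#' @param coupling \code{"linear"} (default) or \code{"hill"}.
#' @param hill_K,hill_h threshold and coefficient for Hill coupling.
#' @param qss eliminate the protein by quasi-steady state.
#' @return A \code{"chromatin_network"} with variant \code{"autoregulated"}
#'   (or \code{"autoregulated_qss"}).
#' @examples
#' circ <- make_autoregulated(chromatin_params(eps = 0.1), px = 1)
#' circ
#' @export
make_autoregulated <- function(params, uA_tilde = 1, px = params$px,
                               gamma_x = params$gamma_x,
                               coupling = c("linear", "hill"),
                               hill_K = NULL, hill_h = NULL, qss = FALSE) {
  coupling <- match.arg(coupling)
  stopifnot(uA_tilde >= 0, px >= 0, gamma_x >= 0)
  hill <- NULL
  if (coupling == "hill") {
    if (is.null(hill_K) || is.null(hill_h))
      stop("hill coupling requires hill_K and hill_h")
    hill <- list(K = hill_K, h = hill_h)
  }
  params <- set_param(params, "px", px)
  net <- build_network(params, "full")
  if (qss) {
    if (coupling == "hill")
      stop("quasi-steady-state reduction is implemented for linear coupling")
    if (px > 0) {
      net$reactions <- c(net$reactions, list(
        reaction("PA-qss", "D", "DA", uA_tilde * px, catalysts = "DA",
                 class = "coupling")))
    }
    net$variant <- "autoregulated_qss"
    net$builder <- function(p) make_autoregulated(
      p, uA_tilde = uA_tilde, px = p$px, gamma_x = p$gamma_x, qss = TRUE)
    return(net)
  }
  net$species <- c(net$species, "X")
  net$reactions <- c(net$reactions, list(
    reaction("PA", "D", "DA", uA_tilde, catalysts = "X",
             class = "coupling", hill = hill),
    reaction("P1", NA_character_, "X", px * gamma_x, rate_species = "DA",
             class = "protein"),
    reaction("P2", "X", NA_character_, gamma_x, rate_species = "X",
             class = "protein")))
  net$variant <- "autoregulated"
  net$builder <- function(p) make_autoregulated(
    p, uA_tilde = uA_tilde, px = p$px, gamma_x = p$gamma_x,
    coupling = coupling, hill_K = hill_K, hill_h = hill_h)
  net
}

suffix_reactions <- function(reactions, suffix) {
  lapply(reactions, function(r) {
    r$label <- paste0(r$label, suffix)
    if (!is.na(r$from)) r$from <- paste0(r$from, suffix)
    if (!is.na(r$to)) r$to <- paste0(r$to, suffix)
    if (!is.na(r$rate_species)) r$rate_species <- paste0(r$rate_species, suffix)
    r$catalysts <- if (length(r$catalysts)) paste0(r$catalysts, suffix)
    else character(0)
    r
  })
}

#' Two mutually repressing, positively autoregulated genes
#'
#' Builds the composition of two autoregulated chromatin circuits in which
#' the product of each gene recruits writers of repressive modifications
#' (both CpG methylation and H3K9 methylation, equally) to the other gene.
#' Gene-X species carry the suffix \code{.X}, gene-Z species \code{.Z};
#' protein species are \code{X} and \code{Z}.
#'
#' @param params_x,params_z per-gene chromatin parameters (gene Z defaults to
#'   gene X's).
#' @param uA_tilde self-activation coupling gain.
#' @param uR_tilde cross-repression coupling gain (applied to both repressive
#'   drives of the other gene).
#' @param px,pz protein production/decay ratios.
#' @param gamma_x,gamma_z normalized protein decay rates.
#' @return A \code{"chromatin_network"} with variant
#'   \code{"mutual_repression"} and two conserved nucleosome groups.
#' @export
make_mutual_repression <- function(params_x, params_z = params_x,
                                   uA_tilde = 1, uR_tilde = 1,
                                   px = params_x$px, pz = params_z$px,
                                   gamma_x = params_x$gamma_x,
                                   gamma_z = params_z$gamma_x) {
  if (params_x$Dtot != params_z$Dtot)
    stop("both genes must share Dtot")
  stopifnot(uA_tilde >= 0, uR_tilde >= 0, px >= 0, pz >= 0)
  gene <- function(params, suffix, protein, other, p, gamma) {
    net <- build_network(params, "full")
    rx <- suffix_reactions(net$reactions, suffix)
    rx <- c(rx, list(
      reaction(paste0("PA", suffix), paste0("D", suffix),
               paste0("DA", suffix), uA_tilde, catalysts = protein,
               class = "coupling"),
      reaction(paste0("R2", suffix), paste0("D", suffix),
               paste0("D2R", suffix), uR_tilde, catalysts = other,
               class = "coupling"),
      reaction(paste0("R2b", suffix), paste0("D1R", suffix),
               paste0("D12R", suffix), uR_tilde, catalysts = other,
               class = "coupling"),
      reaction(paste0("R1", suffix), paste0("D", suffix),
               paste0("D1R", suffix), uR_tilde, catalysts = other,
               class = "coupling"),
      reaction(paste0("R1b", suffix), paste0("D2R", suffix),
               paste0("D12R", suffix), uR_tilde, catalysts = other,
               class = "coupling"),
      reaction(paste0("P1", suffix), NA_character_, protein, p * gamma,
               rate_species = paste0("DA", suffix), class = "protein"),
      reaction(paste0("P2", suffix), protein, NA_character_, gamma,
               rate_species = protein, class = "protein")))
    list(species = paste0(net$species, suffix), reactions = rx)
  }
  px_set <- set_param(params_x, "px", px)
  gx <- gene(px_set, ".X", "X", "Z", px, gamma_x)
  gz <- gene(set_param(params_z, "px", pz), ".Z", "Z", "X", pz, gamma_z)
  structure(list(species = c(gx$species, gz$species, "X", "Z"),
                 reactions = c(gx$reactions, gz$reactions),
                 variant = "mutual_repression", params = px_set,
                 params_z = set_param(params_z, "px", pz),
                 Dtot = params_x$Dtot,
                 conserved = list(gx$species, gz$species),
                 builder = function(p) make_mutual_repression(
                   p, p, uA_tilde = uA_tilde, uR_tilde = uR_tilde,
                   px = p$px, pz = p$px,
                   gamma_x = p$gamma_x, gamma_z = p$gamma_x)),
            class = "chromatin_network")
}

validate_events <- function(network, events, tau_max) {
  times <- vapply(events, `[[`, numeric(1), "time")
  if (is.unsorted(times)) stop("event times must be sorted")
  if (any(times < 0) || any(times > tau_max))
    stop("event times must lie within the simulated horizon")
  for (e in events) {
    if (!e$action %in% c("reset_protein_to_zero", "set_input",
                         "overexpress_protein"))
      stop("unknown event action: ", e$action)
    if (e$action != "set_input" && !all(e$target %in% network$species))
      stop("event targets missing species: ",
           paste(e$target, collapse = ", "))
  }
  events
}

apply_action <- function(network, state, event) {
  switch(event$action,
         reset_protein_to_zero = {
           state[event$target] <- 0L
           list(network = network, state = state)
         },
         overexpress_protein = {
           state[event$target] <- state[event$target] +
             as.integer(round(event$magnitude))
           list(network = network, state = state)
         },
         set_input = {
           if (is.null(network$builder))
             network$builder <- function(p) build_network(p, network$variant)
           p <- set_param(network$params, event$target, event$magnitude)
           list(network = network$builder(p), state = state)
         })
}

#' Simulate with timed perturbation events
#'
#' Runs a simulation in segments separated by perturbation events. Supported
#' actions: \code{reset_protein_to_zero} (TF removal, as in repeated
#' disruption of a regulatory link), \code{overexpress_protein} (add
#' \code{magnitude} copies of the target), and \code{set_input} (change an
#' input parameter and rebuild the network). The SSA resumes with fresh
#' propensities after each event; the ODE engine restarts integration from
#' the modified state.
#'
#' @param network a network object.
#' @param init initial copy numbers (SSA) or fractions (ODE).
#' @param tau_max horizon.
#' @param events list of events, each \code{list(time, action, target,
#'   magnitude)}, sorted by time.
#' @param engine \code{"ssa"} or \code{"ode"}.
#' @param seed integer seed (SSA).
#' @param n_out snapshot count per segment.
#' @return Data frame of sampled trajectories (tau plus one column per
#'   species), with an attribute \code{"events"} logging the applied actions.
#' @export
apply_events <- function(network, init, tau_max, events,
                         engine = c("ssa", "ode"), seed = NULL, n_out = 100) {
  engine <- match.arg(engine)
  events <- validate_events(network, events, tau_max)
  if (!is.null(seed)) set.seed(seed)
  bounds <- c(0, vapply(events, `[[`, numeric(1), "time"), tau_max)
  segs <- list()
  state <- init
  log <- list()
  for (k in seq_len(length(bounds) - 1L)) {
    t0 <- bounds[k]; t1 <- bounds[k + 1L]
    if (t1 > t0) {
      if (engine == "ssa") {
        times <- seq(0, t1 - t0, length.out = n_out)
        run <- ssa_run(network, state, tau_max = t1 - t0,
                       sample_times = times)
        snap <- run$snapshots
        snap$tau <- snap$tau + t0
        segs[[length(segs) + 1L]] <- snap
        state <- run$state
      } else {
        tr <- simulate_ode(network, state, tau_max = t1 - t0, n_out = n_out)
        tr$tau <- tr$tau + t0
        segs[[length(segs) + 1L]] <- as.data.frame(tr)
        state <- unlist(tr[nrow(tr), network$species])
      }
    }
    if (k <= length(events)) {
      upd <- apply_action(network, state, events[[k]])
      network <- upd$network
      state <- upd$state
      log[[length(log) + 1L]] <- events[[k]]
    }
  }
  out <- do.call(rbind, segs)
  attr(out, "events") <- log
  out
}

#' Robustness of the active state to repressive inputs under autoregulation
#'
#' For each autoregulation strength \code{px}, sweeps the repressive input
#' \code{uR} upward from the active initial condition
#' \code{(DA, X) = (1, px)} with quasi-static continuation and records the
#' steady-state active fraction. The persistence threshold \code{uR*(px)}
#' (largest swept \code{uR} at which the gene remains active) increases with
#' \code{px}.
#'
#' @param params baseline chromatin parameters.
#' @param uR_grid increasing repressive-input values.
#' @param px_grid autoregulation strengths.
#' @param uA_tilde coupling gain.
#' @param gamma_x normalized protein decay.
#' @return List with \code{map} (data frame: px, uR, DA) and
#'   \code{thresholds} (data frame: px, uR_star; \code{uR_star} is -Inf when
#'   the active state is lost at the first sweep point).
#' @export
robustness_scan <- function(params, uR_grid, px_grid, uA_tilde = 1,
                            gamma_x = 1) {
  rows <- list()
  thresholds <- numeric(length(px_grid))
  for (i in seq_along(px_grid)) {
    px <- px_grid[i]
    network_fn <- function(p) make_autoregulated(
      p, uA_tilde = uA_tilde, px = px, gamma_x = gamma_x)
    net0 <- network_fn(params)
    x <- setNames(numeric(length(net0$species)), net0$species)
    x["DA"] <- 1
    x["X"] <- px
    DAs <- numeric(length(uR_grid))
    for (k in seq_along(uR_grid)) {
      net <- network_fn(set_param(params, "uR", uR_grid[k]))
      x <- relax_to_steady(net, x)
      DAs[k] <- x[["DA"]]
      rows[[length(rows) + 1L]] <- data.frame(px = px, uR = uR_grid[k],
                                              DA = DAs[k])
    }
    active <- DAs > 0.5
    thresholds[i] <- if (any(active)) max(uR_grid[active]) else -Inf
  }
  list(map = do.call(rbind, rows),
       thresholds = data.frame(px = px_grid, uR_star = thresholds))
}

#' Expression-pattern census for the mutual-repression motif
#'
#' Runs independent SSA replicates of a mutual-repression network and
#' classifies sampled states into the four qualitative expression patterns:
#' \code{x_on_z_off}, \code{z_on_x_off}, \code{both_on}, \code{both_off}.
#' A gene counts as "on" when its activating-mark count is at least
#' \code{Dtot - margin} and as "off" when at most \code{margin}; states in
#' neither band are \code{intermediate}.
#'
#' @param network a \code{\link{make_mutual_repression}} network.
#' @param init named copy numbers, or a list cycled over replicates
#'   (default: all nucleosomes unmodified, proteins 0).
#' @param horizon run length in normalized time.
#' @param burn_in fraction of the horizon discarded.
#' @param reps replicates.
#' @param samples_per_rep snapshots kept per replicate.
#' @param margin count tolerance for calling a gene on/off.
#' @param seed integer seed.
#' @return Data frame \code{pattern}, \code{prob}.
#' @export
pattern_census <- function(network, init = NULL, horizon = 500,
                           burn_in = 0.5, reps = 50, samples_per_rep = 20,
                           margin = 2L, seed = 1L) {
  if (!all(c("DA.X", "DA.Z") %in% network$species))
    stop("pattern_census requires a mutual-repression network")
  set.seed(seed)
  if (is.null(init)) init <- chromatin_state(network, "unmodified")
  if (!is.list(init)) init <- list(init)
  times <- seq(burn_in * horizon, horizon, length.out = samples_per_rep)
  Dtot <- network$Dtot
  lab <- character(0)
  for (r in seq_len(reps)) {
    run <- ssa_run(network, init[[((r - 1L) %% length(init)) + 1L]],
                   tau_max = horizon, sample_times = times)
    lab <- c(lab, classify_pattern(run$snapshots$DA.X, run$snapshots$DA.Z,
                                   Dtot, margin))
  }
  tab <- table(factor(lab, levels = c("x_on_z_off", "z_on_x_off", "both_on",
                                      "both_off", "intermediate")))
  data.frame(pattern = names(tab), prob = as.numeric(tab) / sum(tab))
}

classify_pattern <- function(nAx, nAz, Dtot, margin) {
  xs <- ifelse(nAx >= Dtot - margin, "on",
               ifelse(nAx <= margin, "off", "mid"))
  zs <- ifelse(nAz >= Dtot - margin, "on",
               ifelse(nAz <= margin, "off", "mid"))
  out <- rep("intermediate", length(xs))
  out[xs == "on" & zs == "off"] <- "x_on_z_off"
  out[xs == "off" & zs == "on"] <- "z_on_x_off"
  out[xs == "on" & zs == "on"] <- "both_on"
  out[xs == "off" & zs == "off"] <- "both_off"
  out
}

#' Pattern survival under repeated protein resets
#'
#' Starts the mutual-repression network in the gene-X-on pattern, zeroes both
#' proteins at regular intervals (repeated disruption of the TF links), and
#' reports the fraction of replicates still in the initial pattern at the
#' horizon.
#'
#' @param network a \code{\link{make_mutual_repression}} network.
#' @param horizon total run length.
#' @param reset_every interval between protein resets.
#' @param reps replicates.
#' @param margin count tolerance for calling a gene on/off.
#' @param seed integer seed.
#' @return List: \code{survival} (fraction in \code{x_on_z_off} at the end)
#'   and \code{final_patterns}.
#' @export
pattern_survival <- function(network, horizon = 200, reset_every = 20,
                             reps = 50, margin = 2L, seed = 1L) {
  if (!all(c("DA.X", "DA.Z") %in% network$species))
    stop("pattern_survival requires a mutual-repression network")
  Dtot <- network$Dtot
  prot <- intersect(c("X", "Z"), network$species)
  init <- setNames(integer(length(network$species)), network$species)
  init["DA.X"] <- Dtot
  init["D12R.Z"] <- Dtot
  init["X"] <- max(1L, as.integer(round(network$params$px)))
  events <- lapply(seq(reset_every, horizon - 1e-9, by = reset_every),
                   function(tm) list(time = tm, action = "reset_protein_to_zero",
                                     target = prot))
  finals <- character(reps)
  for (r in seq_len(reps)) {
    tr <- apply_events(network, init, horizon, events, engine = "ssa",
                       seed = seed + r, n_out = 2)
    finals[r] <- classify_pattern(tr$DA.X[nrow(tr)], tr$DA.Z[nrow(tr)],
                                  Dtot, margin)
  }
  list(survival = mean(finals == "x_on_z_off"), final_patterns = finals)
}
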