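ssa_args <- function(network) {
  sp <- network$species
  list(
    stoich = stoich_matrix(network),
    coeff = vapply(network$reactions, `[[`, numeric(1), "coefficient"),
    rate_sp = vapply(network$reactions, function(r)
      if (is.na(r$rate_species)) -1L else match(r$rate_species, sp) - 1L,
      integer(1)),
    cat_idx = lapply(network$reactions, function(r)
      as.integer(match(r$catalysts, sp) - 1L)),
    hill_K = vapply(network$reactions, function(r)
      if (is.null(r$hill)) 0 else r$hill$K, numeric(1)),
    hill_h = vapply(network$reactions, function(r)
      if (is.null(r$hill)) 0 else r$hill$h, numeric(1))
  )
}

resolve_stop <- function(network, stop) {
  if (is.null(stop))
    return(list(w = numeric(length(network$species)), thresh = 0, dir = 0L))
  w <- setNames(numeric(length(network$species)), network$species)
  if (!is.null(stop$weights)) w[names(stop$weights)] <- stop$weights
  else w[stop$species] <- 1
  dir <- switch(stop$op, ">=" = 1L, "<=" = -1L,
                stop("stop$op must be '>=' or '<='"))
  list(w = unname(w), thresh = stop$value, dir = dir)
}

resolve_init <- function(network, init) {
  n <- setNames(integer(length(network$species)), network$species)
  n[names(init)] <- as.integer(round(init))
  if (any(n < 0)) stop("negative initial copy numbers")
  for (g in network$conserved)
    if (sum(n[g]) != network$Dtot)
      stop("initial nucleosome counts must sum to Dtot in group: ",
           paste(g, collapse = ","))
  n
}

#' Run one stochastic (Gillespie) realization
#'
#' Exact direct-method simulation of the continuous-time Markov chain defined
#' by the network's propensities, in normalized time. Reproducible: the run is
#' driven by R's RNG, so \code{set.seed}/\code{seed} fixes the event sequence.
#'
#' @param network a network object.
#' @param init named integer copy numbers (each conserved nucleosome group
#'   must sum to \code{Dtot}); see \code{\link{chromatin_state}}.
#' @param tau_max maximum normalized time.
#' @param stop optional stop condition: a list with \code{species} (summed
#'   with weight 1) or \code{weights} (named), \code{op} (\code{">="} or
#'   \code{"<="}) and \code{value}. The run ends the first time the weighted
#'   count satisfies the condition.
#' @param seed optional integer seed.
#' @param sample_times optional times at which to record state snapshots.
#' @param log_events record the full event log (time, reaction label).
#' @param max_events safety cap on the number of reaction events.
#' @return Object of class \code{"ssa_run"}: final \code{state}, final
#'   \code{time}, \code{stopped} flag, optional \code{snapshots} data frame
#'   and \code{events} data frame.
#' @examples
#' net <- build_network(chromatin_params(eps = 0.3, Dtot = 20))
#' run <- ssa_run(net, chromatin_state(net, "repressed"), tau_max = 10,
#'                seed = 1)
#' run$state
#' @export
ssa_run <- function(network, init, tau_max, stop = NULL, seed = NULL,
                    sample_times = numeric(0), log_events = FALSE,
                    max_events = 5e8) {
  if (!is.null(seed)) set.seed(seed)
  n0 <- resolve_init(network, init)
  a <- ssa_args(network)
  s <- resolve_stop(network, stop)
  res <- ssa_core(unname(n0), a$stoich, a$coeff, a$rate_sp, a$cat_idx,
                  a$hill_K, a$hill_h,
                  network$Dtot, tau_max, s$w, s$thresh, s$dir,
                  as.numeric(sample_times), log_events, max_events)
  out <- list(state = setNames(res$state, network$species),
              time = res$time, stopped = res$stopped,
              n_events = res$n_events, seed = seed)
  if (length(sample_times)) {
    snap <- as.data.frame(res$snapshots)
    names(snap) <- network$species
    out$snapshots <- cbind(tau = as.numeric(sample_times), snap)
  }
  if (log_events)
    out$events <- data.frame(
      tau = res$event_times,
      reaction = vapply(network$reactions, `[[`, "", "label")[res$event_reactions])
  class(out) <- "ssa_run"
  out
}

#' @export
print.ssa_run <- function(x, ...) {
  cat("SSA run:", x$n_events, "events, final time", format(x$time), "\n")
  cat("final state:",
      paste(sprintf("%s=%d", names(x$state), x$state), collapse = " "), "\n")
  if (x$stopped) cat("(stop condition reached)\n")
  invisible(x)
}

#' @param object a \code{\link{build_network}} network.
#' @param nsim number of replicate realizations.
#' @param seed optional integer seed.
#' @param init initial copy numbers (default: fully repressed).
#' @param tau_max horizon in normalized time.
#' @param sample_times snapshot times (default 101 equally spaced points).
#' @param ... unused.
#' @return A list of \code{\link{ssa_run}} objects of length \code{nsim}.
#' @rdname ssa_run
#' @exportS3Method stats::simulate
simulate.chromatin_network <- function(object, nsim = 1, seed = NULL,
                                       init = NULL, tau_max = 100,
                                       sample_times = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(init)) init <- chromatin_state(object, "repressed")
  if (is.null(sample_times)) sample_times <- seq(0, tau_max, length.out = 101)
  lapply(seq_len(nsim), function(i)
    ssa_run(object, init, tau_max, sample_times = sample_times))
}

macro_counts <- function(network, states) {
  sp <- network$species
  if (!"DA" %in% sp) return(NULL)  # composed networks have per-gene copies
  nA <- states[, match("DA", sp), drop = TRUE]
  rsp <- intersect(c("D1R", "D2R", "D12R"), sp)
  nR <- rowSums(states[, match(rsp, sp), drop = FALSE])
  cbind(nA = nA, nR = nR)
}

#' Empirical stationary distribution from pooled SSA runs
#'
#' Runs independent replicates from an ensemble of initial states, discards a
#' burn-in fraction of each run, and pools state snapshots into a normalized
#' histogram over the full state and over the macro-coordinates
#' \code{(nA, nR)} (active and total repressive counts).
#'
#' @param network a network object.
#' @param init named copy numbers, or a list of such vectors cycled over
#'   replicates (default: half the replicates start active, half repressed).
#' @param horizon run length in normalized time.
#' @param burn_in fraction of the horizon discarded (default 0.2).
#' @param reps number of independent replicates.
#' @param samples_per_rep snapshots retained per replicate after burn-in.
#' @param seed integer seed.
#' @return Object of class \code{"stationary_distribution"}: list with
#'   \code{full} (data frame of species counts and \code{prob}),
#'   \code{macro} (data frame \code{nA}, \code{nR}, \code{prob}), and
#'   protocol metadata.
#' @export
stationary_histogram <- function(network, init = NULL, horizon = 500,
                                 burn_in = 0.2, reps = 50,
                                 samples_per_rep = 100, seed = 1L) {
  set.seed(seed)
  if (is.null(init))
    init <- list(chromatin_state(network, "active"),
                 chromatin_state(network, "repressed"))
  if (!is.list(init)) init <- list(init)
  times <- seq(burn_in * horizon, horizon, length.out = samples_per_rep)
  pool <- vector("list", reps)
  for (r in seq_len(reps)) {
    run <- ssa_run(network, init[[((r - 1L) %% length(init)) + 1L]],
                   tau_max = horizon, sample_times = times)
    pool[[r]] <- as.matrix(run$snapshots[, network$species])
  }
  states <- do.call(rbind, pool)
  key <- apply(states, 1L, paste, collapse = ",")
  tab <- table(key)
  uniq <- do.call(rbind, lapply(strsplit(names(tab), ","), as.integer))
  colnames(uniq) <- network$species
  full <- data.frame(uniq, prob = as.numeric(tab) / sum(tab))
  mc <- macro_counts(network, states)
  macro <- NULL
  if (!is.null(mc)) {
    mk <- paste(mc[, 1L], mc[, 2L])
    mt <- table(mk)
    muniq <- do.call(rbind, lapply(strsplit(names(mt), " "), as.integer))
    macro <- data.frame(nA = muniq[, 1L], nR = muniq[, 2L],
                        prob = as.numeric(mt) / sum(mt))
    m <- 6L
    act <- sum(macro$prob[macro$nA >= network$Dtot - m])
    rep_mass <- sum(macro$prob[macro$nR >= network$Dtot - m])
    if (act == 0 || rep_mass == 0)
      warning("one macro-state was never visited; runs may not be mixing")
  }
  structure(list(full = full, macro = macro,
                 provenance = list(method = "ssa", horizon = horizon,
                                   burn_in = burn_in, reps = reps,
                                   samples_per_rep = samples_per_rep,
                                   seed = seed)),
            class = "stationary_distribution")
}

#' @export
print.stationary_distribution <- function(x, ...) {
  cat("Stationary distribution (", x$provenance$method, "),",
      nrow(x$full), "support states\n")
  if (!is.null(x$macro)) {
    top <- x$macro[order(-x$macro$prob), ][seq_len(min(5L, nrow(x$macro))), ]
    cat("top (nA, nR) mass:\n")
    print(top, row.names = FALSE)
  }
  invisible(x)
}

#' @export
plot.stationary_distribution <- function(x, ...) {
  graphics::plot(x$macro$nA, x$macro$nR, cex = 6 * sqrt(x$macro$prob),
                 pch = 16, col = grDevices::adjustcolor("steelblue", 0.6),
                 xlab = "nA", ylab = "nR", ...)
  invisible(x)
}

#' Total-variation distance between two distributions over states
#'
#' @param p,q \code{"stationary_distribution"} objects (or data frames with a
#'   \code{prob} column and matching state columns).
#' @param on \code{"full"} or \code{"macro"}.
#' @return Total-variation distance in [0, 1].
#' @export
tv_distance <- function(p, q, on = c("full", "macro")) {
  on <- match.arg(on)
  get <- function(z) if (inherits(z, "stationary_distribution")) z[[on]] else z
  dp <- get(p); dq <- get(q)
  cols <- setdiff(intersect(names(dp), names(dq)), "prob")
  kp <- do.call(paste, dp[cols]); kq <- do.call(paste, dq[cols])
  keys <- union(kp, kq)
  vp <- setNames(numeric(length(keys)), keys); vp[kp] <- dp$prob
  vq <- setNames(numeric(length(keys)), keys); vq[kq] <- dq$prob
  sum(abs(vp - vq)) / 2
}

#' Sample first-passage ("time to memory loss") times
#'
#' Replicated SSA runs from a common start state, each stopped when the
#' target condition first holds. The mean hitting time over uncensored
#' replicates estimates the time to memory loss of the starting chromatin
#' state; replicates that reach \code{max_time} first are reported censored
#' and excluded from the mean.
#'
#' @param network a network object.
#' @param start named initial copy numbers.
#' @param target stop condition (as in \code{\link{ssa_run}}).
#' @param reps number of replicates.
#' @param max_time censoring horizon.
#' @param seed integer seed.
#' @return Object of class \code{"first_passage"}: \code{times},
#'   \code{censored}, \code{mean}, \code{se}, \code{n_censored}.
#' @export
first_passage_sample <- function(network, start, target, reps = 200,
                                 max_time = 1e5, seed = 1L) {
  set.seed(seed)
  times <- numeric(reps)
  censored <- logical(reps)
  for (r in seq_len(reps)) {
    run <- ssa_run(network, start, tau_max = max_time, stop = target)
    times[r] <- run$time
    censored[r] <- !run$stopped
  }
  ok <- times[!censored]
  structure(list(times = times, censored = censored,
                 mean = if (length(ok)) mean(ok) else NA_real_,
                 se = if (length(ok) > 1L) stats::sd(ok) / sqrt(length(ok))
                 else NA_real_,
                 n_censored = sum(censored), start = start, target = target),
            class = "first_passage")
}

#' @export
print.first_passage <- function(x, ...) {
  cat("First-passage samples: n =", length(x$times),
      "(", x$n_censored, "censored )\n")
  cat(sprintf("mean = %.4g  SE = %.3g\n", x$mean, x$se))
  invisible(x)
}

#' Gene reactivation experiment
#'
#' Applies an activating input \code{uA} to a gene starting in the repressed
#' chromatin state and records, per replicate, the latency until the active
#' count first reaches \code{Dtot - margin}. Trajectories show switch-like
#' transitions with highly variable latency when \code{eps} and
#' \code{mu_prime} are both small.
#'
#' @param params a \code{\link{chromatin_params}} object (its \code{uA} is
#'   overridden).
#' @param uA activating input strength (positive).
#' @param reps number of replicates.
#' @param margin count margin defining reactivation (default 6:
#'   \code{nA >= Dtot - margin}).
#' @param max_time censoring horizon.
#' @param seed integer seed.
#' @param n_traj number of replicates for which a sampled trajectory of
#'   \code{nA} is returned.
#' @param variant network variant.
#' @return List with \code{latency} (a \code{"first_passage"} object),
#'   \code{cv} (coefficient of variation of uncensored latencies) and
#'   \code{trajectories} (data frame: tau, nA, replicate).
#' @export
reactivation_experiment <- function(params, uA, reps = 100, margin = 6L,
                                    max_time = 1e4, seed = 1L, n_traj = 0L,
                                    variant = "full") {
  stopifnot(uA > 0)
  net <- build_network(set_param(params, "uA", uA), variant)
  start <- chromatin_state(net, "repressed")
  nA0 <- as.integer(round(0.1 * net$Dtot))
  start[["DA"]] <- nA0
  start[[if (variant == "histone_only") "D2R" else "D12R"]] <- net$Dtot - nA0
  target <- list(species = "DA", op = ">=", value = net$Dtot - margin)
  fp <- first_passage_sample(net, start, target, reps = reps,
                             max_time = max_time, seed = seed)
  ok <- fp$times[!fp$censored]
  trajectories <- NULL
  if (n_traj > 0L) {
    set.seed(seed + 1L)
    tl <- lapply(seq_len(n_traj), function(i) {
      run <- ssa_run(net, start, tau_max = max_time, stop = target,
                     sample_times = seq(0, max_time, length.out = 400))
      keep <- run$snapshots$tau <= run$time
      data.frame(tau = run$snapshots$tau[keep],
                 nA = run$snapshots$DA[keep], replicate = i)
    })
    trajectories <- do.call(rbind, tl)
  }
  list(latency = fp,
       cv = if (length(ok) > 1L) stats::sd(ok) / mean(ok) else NA_real_,
       trajectories = trajectories)
}
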