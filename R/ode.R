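#' Mean-field right-hand side of the chromatin circuit
#'
#' Hand-written non-dimensional ODEs for the fractions of nucleosomes carrying
#' each modification, with \code{D = 1 - DA - D1R - D2R - D12R}. Writing to
#' the repressive states is driven by the total drives plus auto/cross
#' catalysis (H3K9me read by \code{K9 = D2R + D12R}, CpGme by
#' \code{ME = D1R + D12R}); erasure has basal terms scaled by \code{eps} and
#' terms recruited by the opposing marks scaled by \code{eps_prime}.
#'
#' @param state named numeric vector with components \code{DA}, \code{D1R},
#'   \code{D2R}, \code{D12R} (fractions in [0, 1]).
#' @param params a \code{\link{chromatin_params}} object.
#' @return Named numeric vector of time derivatives for \code{D}, \code{DA},
#'   \code{D1R}, \code{D2R}, \code{D12R} (summing to zero).
#' @export
mean_field_rhs <- function(state, params) {
  p <- params
  u <- total_inputs(p)
  DA <- state[["DA"]]; D1R <- state[["D1R"]]
  D2R <- state[["D2R"]]; D12R <- state[["D12R"]]
  D <- 1 - DA - D1R - D2R - D12R
  K9 <- D2R + D12R
  ME <- D1R + D12R
  dDA <- (u$uA_bar + DA) * D - p$eps * DA - p$eps_prime * (K9 + ME) * DA
  dD1R <- (u$u1R_bar + p$alpha_prime * K9) * D -
    (u$u2R_bar + p$alpha * K9 + p$alpha_bar * ME) * D1R -
    p$beta * p$eps * p$mu_prime * D1R -
    p$mu_prime * p$eps_prime * DA * D1R +
    p$b * p$eps * p$mu * D12R + p$mu * p$eps_prime * DA * D12R
  dD2R <- (u$u2R_bar + p$alpha * K9 + p$alpha_bar * ME) * D -
    (u$u1R_bar + p$alpha_prime * K9) * D2R -
    p$b * p$eps * p$mu * D2R - p$mu * p$eps_prime * DA * D2R +
    p$beta * p$eps * p$mu_prime * D12R +
    p$mu_prime * p$eps_prime * DA * D12R
  dD12R <- (u$u1R_bar + p$alpha_prime * K9) * D2R +
    (u$u2R_bar + p$alpha * K9 + p$alpha_bar * ME) * D1R -
    (p$b * p$eps * p$mu + p$beta * p$eps * p$mu_prime) * D12R -
    (p$mu + p$mu_prime) * p$eps_prime * DA * D12R
  c(D = -(dDA + dD1R + dD2R + dD12R),
    DA = dDA, D1R = dD1R, D2R = dD2R, D12R = dD12R)
}

#' Gene-expression right-hand side
#'
#' Protein dynamics in normalized time: production proportional to the active
#' nucleosome fraction and first-order decay,
#' \code{dX/dtau = alpha_x_bar * DA - gamma_x_bar * X}. At steady state
#' \code{X = px * DA} with \code{px = alpha_x_bar/gamma_x_bar}.
#'
#' @param state named numeric vector with components \code{DA} and \code{X}.
#' @param alpha_x_bar,gamma_x_bar normalized production and decay rates.
#' @return \code{dX/dtau}.
#' @export
gene_expression_rhs <- function(state, alpha_x_bar, gamma_x_bar) {
  stopifnot(alpha_x_bar >= 0, gamma_x_bar >= 0)
  alpha_x_bar * state[["DA"]] - gamma_x_bar * state[["X"]]
}

#' Mean-field right-hand side generated from a reaction network
#'
#' Mass-action mean field of any network built by this package, on nucleosome
#' fractions (and protein counts per nucleosome). Agrees with
#' \code{\link{mean_field_rhs}} on the core circuit.
#'
#' @param network a \code{\link{build_network}} (or composed) network.
#' @param state named numeric vector of fractions over all network species.
#' @return Named numeric vector of derivatives over all species.
#' @export
network_rhs <- function(network, state) {
  x <- as.numeric(state)[match(network$species, names(state))]
  names(x) <- network$species
  S <- stoich_matrix(network)
  rates <- vapply(network$reactions, function(r) {
    a <- r$coefficient
    if (!is.na(r$rate_species)) a <- a * x[[r$rate_species]]
    if (length(r$catalysts)) a <- a * catalyst_factor(r, sum(x[r$catalysts]))
    a
  }, numeric(1))
  drop(S %*% rates)
}

# free coordinates: drop the first species of every conserved group; species
# outside all groups (proteins) are free and unbounded above
free_coords <- function(network) {
  dropped <- vapply(network$conserved, `[[`, "", 1L)
  setdiff(network$species, dropped)
}

full_state <- function(network, free) {
  x <- setNames(numeric(length(network$species)), network$species)
  x[names(free)] <- free
  for (g in network$conserved) x[g[1L]] <- 1 - sum(x[g[-1L]])
  x
}

reduced_rhs <- function(network, free) {
  network_rhs(network, full_state(network, free))[names(free)]
}

#' Integrate the deterministic model
#'
#' Integrates the mean-field ODEs with a stiff-capable solver
#' (\code{deSolve::lsoda}) on the free coordinates, reconstructing the
#' conserved unmodified fraction so that the total is exactly preserved.
#'
#' @param network a network object.
#' @param init named initial fractions (any subset of species; missing ones
#'   are 0 and the unmodified fraction takes the remainder).
#' @param tau_max final normalized time.
#' @param n_out number of output points.
#' @param rtol,atol solver tolerances.
#' @return An object of class \code{"ode_trajectory"}: a data frame with a
#'   \code{tau} column and one column per species.
#' @examples
#' net <- build_network(chromatin_params(eps = 0.1))
#' tr <- simulate_ode(net, c(D12R = 1), tau_max = 50)
#' tail(tr, 1)
#' @export
simulate_ode <- function(network, init, tau_max = 100, n_out = 201,
                         rtol = 1e-8, atol = 1e-10) {
  x0 <- setNames(numeric(length(network$species)), network$species)
  x0[names(init)] <- init
  fc <- free_coords(network)
  y0 <- x0[fc]
  deriv <- function(t, y, parms) list(reduced_rhs(network, y))
  times <- seq(0, tau_max, length.out = n_out)
  sol <- deSolve::lsoda(y0, times, deriv, rtol = rtol, atol = atol)
  if (attr(sol, "istate")[1L] < 0)
    stop("ODE integration failed: ", paste(attr(sol, "istate"), collapse = " "))
  out <- as.data.frame(sol)
  names(out)[1L] <- "tau"
  for (g in network$conserved)
    out[[g[1L]]] <- 1 - rowSums(out[, g[-1L], drop = FALSE])
  out <- out[, c("tau", network$species)]
  class(out) <- c("ode_trajectory", "data.frame")
  attr(out, "network") <- network
  out
}

#' @export
plot.ode_trajectory <- function(x, species = setdiff(names(x), "tau"), ...) {
  graphics::matplot(x$tau, as.matrix(x[, species, drop = FALSE]), type = "l",
                    lty = 1, xlab = "normalized time", ylab = "fraction", ...)
  graphics::legend("topright", legend = species, lty = 1,
                   col = seq_along(species), bty = "n")
  invisible(x)
}

newton_polish <- function(network, free, tol = 1e-12, max_iter = 60) {
  y <- free
  for (i in seq_len(max_iter)) {
    f <- reduced_rhs(network, y)
    if (max(abs(f)) < tol) return(list(free = y, converged = TRUE))
    J <- num_jacobian(network, y)
    step <- tryCatch(solve(J, -f), error = function(e) NULL)
    if (is.null(step)) return(list(free = y, converged = FALSE))
    lambda <- 1
    repeat {
      y_new <- y + lambda * step
      f_new <- tryCatch(reduced_rhs(network, y_new), error = function(e) NULL)
      if (!is.null(f_new) && all(is.finite(f_new)) &&
          (max(abs(f_new)) < max(abs(f)) || lambda < 1e-4)) break
      lambda <- lambda / 2
    }
    y <- y + lambda * step
  }
  list(free = y, converged = max(abs(reduced_rhs(network, y))) < 1e-9)
}

num_jacobian <- function(network, free, h = 1e-7) {
  n <- length(free)
  J <- matrix(0, n, n)
  f0 <- reduced_rhs(network, free)
  for (j in seq_len(n)) {
    y <- free
    hj <- h * max(1, abs(y[j]))
    y[j] <- y[j] + hj
    J[, j] <- (reduced_rhs(network, y) - f0) / hj
  }
  J
}

in_simplex <- function(network, x, tol = 1e-7) {
  if (any(x < -tol)) return(FALSE)
  for (g in network$conserved)
    if (abs(sum(x[g]) - 1) > 1e-6) return(FALSE)
  TRUE
}

classify_equilibria <- function(eq) {
  stable <- Filter(function(e) e$stability == "stable", eq)
  n <- length(stable)
  if (n == 0L) return("none")
  if (n >= 2L) return(c("bistable", "tristable", "quadristable",
                        "multistable")[min(n - 1L, 4L)])
  s <- stable[[1L]]$state
  if (!"DA" %in% names(s)) return("monostable_other")
  DA <- s[["DA"]]
  DR <- sum(s[grep("^D(1R|2R|12R)$", names(s))])
  if (DA > 0.5 && DA > DR) "monostable_active"
  else if (DR > 0.5 && DR > DA) "monostable_repressed"
  else "monostable_other"
}

#' Locate the equilibria of the deterministic model
#'
#' Multistart root finding on the mean-field ODEs: random Dirichlet starts on
#' the nucleosome-fraction simplex (plus its vertices), Newton iteration with
#' line search, deduplication, and stability classification via the
#' eigenvalues of the finite-difference Jacobian on the free coordinates.
#'
#' @param network a network object.
#' @param n_starts number of random starting points (default 200).
#' @param tol residual tolerance for accepting a root.
#' @param merge_tol pairwise max-abs distance below which roots are merged.
#' @param eig_tol stability threshold on the leading eigenvalue real part;
#'   equilibria with \code{|Re(lambda)| <= eig_tol} are flagged marginal.
#' @param seed RNG seed for the starting points.
#' @return Object of class \code{"equilibrium_set"}: list with
#'   \code{equilibria} (each: \code{state}, \code{stability},
#'   \code{leading_eig}) and \code{classification}.
#' @examples
#' eq <- find_equilibria(build_network(chromatin_params(eps = 0.05)))
#' eq$classification
#' @export
find_equilibria <- function(network, n_starts = 200, tol = 1e-9,
                            merge_tol = 1e-6, eig_tol = 1e-8, seed = 1L) {
  fc <- free_coords(network)
  proteins <- setdiff(network$species, unlist(network$conserved))
  starts <- list()
  rng <- local({ set.seed(seed); function(n) stats::rexp(n) })
  for (i in seq_len(n_starts)) {
    x <- setNames(numeric(length(network$species)), network$species)
    for (g in network$conserved) {
      w <- rng(length(g))
      x[g] <- w / sum(w)
    }
    if (length(proteins))
      x[proteins] <- network$params$px * x[["DA"]]
    starts[[length(starts) + 1L]] <- x[fc]
  }
  for (sp in unlist(network$conserved)) {   # simplex vertices
    x <- setNames(numeric(length(network$species)), network$species)
    x[sp] <- 1
    if (length(proteins)) x[proteins] <- network$params$px * x[["DA"]]
    starts[[length(starts) + 1L]] <- x[fc]
  }
  roots <- list()
  for (s in starts) {
    res <- newton_polish(network, s)
    if (!res$converged) next
    x <- full_state(network, res$free)
    if (!in_simplex(network, x)) next
    if (max(abs(network_rhs(network, x))) > tol) next
    x <- pmax(x, 0)
    dup <- any(vapply(roots, function(r) max(abs(r - x)) < merge_tol,
                      logical(1)))
    if (!dup) roots[[length(roots) + 1L]] <- x
  }
  if (!length(roots))
    warning("no equilibria found from any start")
  eq <- lapply(roots, function(x) {
    J <- num_jacobian(network, x[fc])
    lead <- max(Re(eigen(J, only.values = TRUE)$values))
    stability <- if (lead < -eig_tol) "stable"
    else if (lead > eig_tol) "unstable" else "marginal"
    list(state = x, stability = stability, leading_eig = lead)
  })
  structure(list(equilibria = eq, classification = classify_equilibria(eq)),
            class = "equilibrium_set")
}

#' @export
print.equilibrium_set <- function(x, ...) {
  cat("Equilibrium set:", x$classification, "(",
      length(x$equilibria), "equilibria )\n")
  for (e in x$equilibria) {
    cat(sprintf("  [%s, Re(lambda)=% .3e] ", e$stability, e$leading_eig))
    cat(paste(sprintf("%s=%.4f", names(e$state), e$state), collapse = " "),
        "\n")
  }
  invisible(x)
}

set_param <- function(params, name, value) {
  p <- unclass(params)
  if (name == "uR") { p$u1R <- value; p$u2R <- value }
  else p[[name]] <- value
  do.call(chromatin_params, p)
}

#' Scan equilibria along one parameter
#'
#' Runs \code{\link{find_equilibria}} on a monotone grid of one parameter and
#' locates saddle-node bifurcations by bisection between grid points where the
#' number of stable equilibria changes.
#'
#' @param params baseline \code{\link{chromatin_params}}.
#' @param scan_param one of \code{"eps"}, \code{"mu"}, \code{"mu_prime"},
#'   \code{"eps_prime"}, \code{"px"}, \code{"uA"}, \code{"uR"}.
#' @param grid monotone numeric grid of parameter values.
#' @param variant network variant.
#' @param network_fn optional function(params) building the network (used for
#'   composed circuits); defaults to \code{build_network}.
#' @param n_starts,seed passed to \code{find_equilibria}.
#' @param refine_rel relative width for saddle-node bisection.
#' @return List with \code{table} (data frame: value, classification,
#'   n_stable) , \code{equilibria} (per grid point) and \code{saddle_nodes}
#'   (refined parameter values where the stable count changes).
#' @export
bifurcation_scan <- function(params, scan_param, grid, variant = "full",
                             network_fn = NULL, n_starts = 80, seed = 1L,
                             refine_rel = 1e-3) {
  if (is.unsorted(grid) && is.unsorted(rev(grid)))
    stop("grid must be monotone")
  if (is.null(network_fn))
    network_fn <- function(p) build_network(p, variant)
  eq_at <- function(v) find_equilibria(
    network_fn(set_param(params, scan_param, v)),
    n_starts = n_starts, seed = seed)
  sets <- lapply(grid, eq_at)
  n_stable <- vapply(sets, function(s)
    sum(vapply(s$equilibria, function(e) e$stability == "stable", logical(1))),
    integer(1))
  tab <- data.frame(value = grid,
                    classification = vapply(sets, `[[`, "", "classification"),
                    n_stable = n_stable)
  sn <- numeric(0)
  for (i in seq_len(length(grid) - 1L)) {
    if (n_stable[i] == n_stable[i + 1L]) next
    lo <- grid[i]; hi <- grid[i + 1L]
    n_lo <- n_stable[i]
    while ((hi - lo) > refine_rel * max(abs(hi), abs(lo), 1e-12)) {
      mid <- (lo + hi) / 2
      s <- eq_at(mid)
      nm <- sum(vapply(s$equilibria, function(e) e$stability == "stable",
                       logical(1)))
      if (nm == n_lo) lo <- mid else hi <- mid
    }
    sn <- c(sn, (lo + hi) / 2)
  }
  list(table = tab, equilibria = sets, saddle_nodes = sn)
}

#' Stability chart over a two-parameter grid
#'
#' Classifies the equilibrium structure on a grid over two parameters
#' (typically \code{eps} against \code{mu} or \code{mu_prime}).
#'
#' @param params baseline parameters.
#' @param xname,yname parameter names (as in \code{\link{bifurcation_scan}}).
#' @param xgrid,ygrid numeric grids.
#' @param variant network variant.
#' @param n_starts,seed passed to \code{find_equilibria}.
#' @return Data frame in long format: columns \code{xname}, \code{yname},
#'   \code{classification}.
#' @export
stability_chart <- function(params, xname, xgrid, yname, ygrid,
                            variant = "full", n_starts = 60, seed = 1L) {
  out <- expand.grid(x = xgrid, y = ygrid)
  cls <- character(nrow(out))
  for (i in seq_len(nrow(out))) {
    p <- set_param(set_param(params, xname, out$x[i]), yname, out$y[i])
    cls[i] <- tryCatch(
      find_equilibria(build_network(p, variant), n_starts = n_starts,
                      seed = seed)$classification,
      error = function(e) "unknown")
  }
  names(out) <- c(xname, yname)
  out$classification <- cls
  out
}

relax_to_steady <- function(network, x0, tol = 1e-10, tau_chunk = 1000,
                            max_chunks = 50) {
  x <- x0
  for (i in seq_len(max_chunks)) {
    tr <- simulate_ode(network, x, tau_max = tau_chunk, n_out = 2)
    x <- unlist(tr[nrow(tr), network$species])
    res <- newton_polish(network, x[free_coords(network)], tol = tol)
    xN <- full_state(network, res$free)
    if (res$converged && in_simplex(network, xN) &&
        max(abs(network_rhs(network, xN))) < tol)
      return(pmax(xN, 0))
  }
  stop("relaxation to steady state did not converge")
}

#' Quasi-static input sweep (hysteresis)
#'
#' Sweeps one input up through \code{values} and back down, at each point
#' relaxing the ODEs to steady state starting from the previous converged
#' state (continuation). Differing up and down branches indicate hysteresis;
#' retention of the switched state at zero input indicates irreversibility
#' (epigenetic memory of the stimulus).
#'
#' @param params baseline parameters (input components are overridden).
#' @param input \code{"uA"} (activating) or \code{"uR"} (sets
#'   \code{u1R = u2R = uR}).
#' @param values increasing input values, typically starting at 0.
#' @param init named initial fractions for the first sweep point (default:
#'   repressed for \code{uA} sweeps, active for \code{uR} sweeps).
#' @param variant network variant.
#' @param network_fn optional function(params) building the network.
#' @return Object of class \code{"io_characteristic"}: data frame with
#'   columns \code{input}, \code{direction} (up/down), \code{DA}, \code{DR}
#'   and all species fractions.
#' @export
hysteresis_sweep <- function(params, input = c("uA", "uR"), values,
                             init = NULL, variant = "full",
                             network_fn = NULL) {
  input <- match.arg(input)
  if (is.null(network_fn))
    network_fn <- function(p) build_network(p, variant)
  net0 <- network_fn(params)
  if (is.null(init))
    init <- chromatin_state(net0, if (input == "uA") "repressed" else "active")
  x <- setNames(numeric(length(net0$species)), net0$species)
  x[names(init)] <- init / ifelse(max(init) > 1, net0$Dtot, 1)
  rows <- list()
  sweep_one <- function(vals, direction, x) {
    for (v in vals) {
      net <- network_fn(set_param(params, input, v))
      x <- relax_to_steady(net, x)
      DR <- sum(x[intersect(c("D1R", "D2R", "D12R"), net$species)])
      rows[[length(rows) + 1L]] <<-
        c(list(input = v, direction = direction,
               DA = unname(x[["DA"]]), DR = unname(DR)),
          as.list(x[setdiff(names(x), "DA")]))
    }
    x
  }
  x <- sweep_one(values, "up", x)
  sweep_one(rev(values), "down", x)
  out <- do.call(rbind, lapply(rows, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
  out$input <- as.numeric(out$input)
  for (cl in setdiff(names(out), "direction")) out[[cl]] <- as.numeric(out[[cl]])
  class(out) <- c("io_characteristic", "data.frame")
  out
}
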