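compositions <- function(n, k) {
  # all k-part compositions of n, one per row
  if (k == 1L) return(matrix(n, ncol = 1L))
  out <- vector("list", n + 1L)
  for (i in 0:n) {
    rest <- compositions(n - i, k - 1L)
    out[[i + 1L]] <- cbind(i, rest)
  }
  m <- do.call(rbind, out)
  dimnames(m) <- NULL
  m
}

#' Enumerate the finite state space of a chromatin network
#'
#' All assignments of \code{Dtot} nucleosomes to the network's chromatin
#' species (protein species are not enumerated; use quasi-steady-state
#' reduction for coupled circuits).
#'
#' @param network a network object with a single conserved nucleosome group.
#' @return Integer matrix, one state per row, columns named by species.
#' @export
state_space <- function(network) {
  if (length(network$conserved) != 1L ||
      !setequal(unlist(network$conserved), network$species))
    stop("exact analysis requires a pure chromatin network; ",
         "apply protein quasi-steady state first")
  m <- compositions(network$Dtot, length(network$species))
  colnames(m) <- network$species
  m
}

state_keys <- function(states) apply(states, 1L, paste, collapse = ",")

reaction_propensity_matrix <- function(network, states) {
  # propensity of each reaction (columns) at each state (rows)
  sp <- colnames(states)
  m <- sapply(network$reactions, function(r) {
    a <- rep(r$coefficient, nrow(states))
    if (!is.na(r$rate_species)) a <- a * states[, r$rate_species]
    if (length(r$catalysts)) {
      frac <- rowSums(states[, r$catalysts, drop = FALSE]) / network$Dtot
      a <- a * catalyst_factor(r, frac)
    }
    a
  })
  matrix(m, nrow = nrow(states))
}

#' Build the sparse CME generator of a network
#'
#' Infinitesimal generator Q of the continuous-time Markov chain on the
#' enumerated state space: off-diagonal entry (s, s') is the summed propensity
#' of reactions taking s to s'; rows sum to zero.
#'
#' @param network a network object.
#' @param states optional state matrix from \code{\link{state_space}}.
#' @return A list with \code{Q} (sparse \code{dgCMatrix}) and \code{states}.
#' @export
build_generator <- function(network, states = NULL) {
  if (is.null(states)) states <- state_space(network)
  keys <- state_keys(states)
  index <- setNames(seq_along(keys), keys)
  S <- stoich_matrix(network)
  A <- reaction_propensity_matrix(network, states)
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  for (j in seq_along(network$reactions)) {
    a <- A[, j]
    hit <- which(a > 0)
    if (!length(hit)) next
    tgt <- sweep(states[hit, , drop = FALSE], 2L, -S[, j])
    ti <- unname(index[state_keys(tgt)])
    if (anyNA(ti)) stop("reaction ", network$reactions[[j]]$label,
                        " leaves the state space")
    ii <- c(ii, hit); jj <- c(jj, ti); xx <- c(xx, a[hit])
  }
  n <- nrow(states)
  Q <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n))
  Matrix::diag(Q) <- Matrix::diag(Q) - Matrix::rowSums(Q)
  list(Q = Q, states = states)
}

reachable_from <- function(Q, start) {
  pattern <- Q != 0
  v <- logical(nrow(Q))
  v[start] <- TRUE
  repeat {
    nv <- v | (as.logical(Matrix::t(pattern) %*% v) )
    if (identical(nv, v)) return(v)
    v <- nv
  }
}

#' Exact stationary distribution of a generator
#'
#' Solves \code{pi Q = 0}, \code{sum(pi) = 1} by sparse LU on the transposed
#' generator with one balance equation replaced by the normalization. Warns
#' if the chain is not irreducible or the residual exceeds 1e-10.
#'
#' @param Q sparse generator matrix (rows sum to 0).
#' @param states optional state matrix used to attach macro-coordinates.
#' @param network optional network for macro-coordinates (nA, nR).
#' @return If \code{states} is supplied, a \code{"stationary_distribution"}
#'   object (as in \code{\link{stationary_histogram}}); otherwise the bare
#'   probability vector.
#' @export
exact_stationary <- function(Q, states = NULL, network = NULL) {
  n <- nrow(Q)
  fwd <- reachable_from(Q, 1L)
  bwd <- reachable_from(Matrix::t(Q), 1L)
  if (!all(fwd & bwd))
    warning("chain is not irreducible; stationary solution may be one of ",
            "several per-class distributions")
  A <- Matrix::t(Q)
  A[n, ] <- 1
  b <- c(rep(0, n - 1L), 1)
  pi <- tryCatch(as.numeric(Matrix::solve(A, b)), error = function(e) NULL)
  if (is.null(pi)) {
    ev <- eigen(t(as.matrix(Q)))
    k <- which.min(abs(ev$values))
    pi <- Re(ev$vectors[, k])
    pi <- pi / sum(pi)
  }
  pi[pi < 0 & pi > -1e-12] <- 0
  if (any(pi < 0)) warning("negative stationary masses beyond tolerance")
  pi <- pmax(pi, 0)
  pi <- pi / sum(pi)
  res <- max(abs(as.numeric(pi %*% Q)))
  if (res > 1e-10)
    warning(sprintf("stationary residual %.2e exceeds 1e-10", res))
  if (is.null(states)) return(pi)
  full <- data.frame(states, prob = pi)
  mc <- macro_counts(network, states)
  macro <- stats::aggregate(list(prob = pi),
                            by = list(nA = mc[, "nA"], nR = mc[, "nR"]), sum)
  structure(list(full = full, macro = macro,
                 provenance = list(method = "cme", residual = res)),
            class = "stationary_distribution")
}

#' Exact mean first-passage times
#'
#' Expected hitting time of a target state set from every state, by solving
#' the restricted linear system \code{Q[T, T] h = -1} with \code{h = 0} on
#' the target. States from which the target is unreachable get \code{Inf}.
#' The solve uses subtraction-free (GTH-style) Gaussian elimination: in the
#' metastable regime the restricted generator's condition number exceeds the
#' reach of double-precision LU, while elimination on the M-matrix
#' \code{-Q[T, T]} with the diagonal rebuilt from row sums never cancels and
#' stays entrywise accurate.
#'
#' @param Q sparse generator.
#' @param target integer indices (or logical vector) of the target states.
#' @return Numeric vector of expected hitting times, one per state.
#' @export
exact_mfpt <- function(Q, target) {
  n <- nrow(Q)
  tgt <- logical(n)
  tgt[target] <- TRUE
  if (!any(tgt)) stop("target set is empty")
  can_reach <- reachable_from(Matrix::t(Q), which(tgt))
  h <- rep(Inf, n)
  h[tgt] <- 0
  Tset <- which(!tgt & can_reach)
  m <- length(Tset)
  if (m) {
    # R[i, j] (i != j): rate i -> j within T; texit: rate mass leaving T
    R <- as.matrix(Q[Tset, Tset, drop = FALSE])
    diag(R) <- 0
    texit <- pmax(as.numeric(-Matrix::diag(Q[Tset, Tset, drop = FALSE])) -
                    rowSums(R), 0)
    b <- rep(1, m)
    if (m > 1) {
      for (k in 1:(m - 1)) {
        idx <- (k + 1):m
        piv <- sum(R[k, idx]) + texit[k]
        w <- R[idx, k] / piv
        R[idx, idx] <- R[idx, idx] + w %o% R[k, idx]
        # the i -> k -> i excursion is absorbed into the recomputed pivot,
        # never stored as a self-loop
        R[cbind(idx, idx)] <- 0
        texit[idx] <- texit[idx] + w * texit[k]
        b[idx] <- b[idx] + w * b[k]
      }
    }
    sol <- numeric(m)
    for (k in m:1) {
      idx <- if (k < m) (k + 1):m else integer(0)
      piv <- sum(R[k, idx]) + texit[k]
      sol[k] <- (b[k] + sum(R[k, idx] * sol[idx])) / piv
    }
    h[Tset] <- sol
  }
  h
}

#' Reduce the chromatin chain to a one-dimensional birth-death chain
#'
#' In the time-scale-separation regime (both basal and recruited erasure slow
#' relative to catalysis), the doubly repressed count \code{x = n12R} is the
#' slow coordinate. For each \code{x}, the x-preserving subnetwork is solved
#' exactly for its conditional stationary distribution, and the up/down rates
#' \code{lambda(x)}, \code{gamma(x)} are the conditional expectations of the
#' x-changing propensities (stochastic averaging).
#'
#' @param network a full-variant network.
#' @param warn_regime warn when \code{eps} or \code{eps_prime} exceed 0.5
#'   (outside the reduction's stated regime).
#' @return Object of class \code{"reduced_chain"}: \code{x}, \code{lambda},
#'   \code{gamma}, \code{provenance}.
#' @export
reduce_to_1d <- function(network, warn_regime = TRUE) {
  if (!"D12R" %in% network$species)
    stop("reduction requires the full circuit (slow coordinate n12R)")
  p <- network$params
  if (warn_regime && (p$eps > 0.5 || p$eps_prime > 0.5))
    warning("eps and eps_prime should be small for the reduction to hold")
  Dtot <- network$Dtot
  S <- stoich_matrix(network)
  dx <- S["D12R", ]
  fast <- which(dx == 0L)
  up <- which(dx == 1L)
  down <- which(dx == -1L)
  others <- setdiff(network$species, "D12R")
  lambda <- gamma <- numeric(Dtot + 1L)
  for (x in 0:Dtot) {
    slice <- compositions(Dtot - x, length(others))
    colnames(slice) <- others
    slice <- cbind(slice, D12R = x)[, network$species, drop = FALSE]
    A <- reaction_propensity_matrix(network, slice)
    if (nrow(slice) == 1L) {
      cond <- 1
    } else {
      sub <- network
      sub$reactions <- network$reactions[fast]
      keys <- state_keys(slice)
      index <- setNames(seq_along(keys), keys)
      ii <- integer(0); jj <- integer(0); xx <- numeric(0)
      for (j in fast) {
        a <- A[, j]
        hit <- which(a > 0)
        if (!length(hit)) next
        tgt <- sweep(slice[hit, , drop = FALSE], 2L, -S[, j])
        ti <- unname(index[state_keys(tgt)])
        ii <- c(ii, hit); jj <- c(jj, ti); xx <- c(xx, a[hit])
      }
      Qf <- Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                                 dims = c(nrow(slice), nrow(slice)))
      Matrix::diag(Qf) <- Matrix::diag(Qf) - Matrix::rowSums(Qf)
      cond <- suppressWarnings(exact_stationary(Qf))
    }
    lambda[x + 1L] <- sum(cond * rowSums(A[, up, drop = FALSE]))
    gamma[x + 1L] <- sum(cond * rowSums(A[, down, drop = FALSE]))
  }
  structure(list(x = 0:Dtot, lambda = lambda, gamma = gamma,
                 provenance = "numeric-averaging", Dtot = Dtot),
            class = "reduced_chain")
}

#' @export
print.reduced_chain <- function(x, ...) {
  cat("Reduced birth-death chain on x = n12R (0..", x$Dtot, "), ",
      x$provenance, "\n", sep = "")
  print(data.frame(x = x$x, lambda = x$lambda, gamma = x$gamma),
        row.names = FALSE)
  invisible(x)
}

#' Stationary distribution of a birth-death chain
#'
#' Product-form solution evaluated in log space.
#'
#' @param chain a \code{"reduced_chain"} object.
#' @return Numeric probability vector over \code{x = 0..Dtot}.
#' @export
bd_stationary <- function(chain) {
  n <- length(chain$x)
  logw <- numeric(n)
  for (i in 2:n) {
    if (chain$lambda[i - 1L] <= 0) { logw[i:n] <- -Inf; break }
    if (chain$gamma[i] <= 0) stop("gamma(x) = 0 for x > 0: chain not ergodic")
    logw[i] <- logw[i - 1L] + log(chain$lambda[i - 1L]) - log(chain$gamma[i])
  }
  w <- exp(logw - max(logw[is.finite(logw)]))
  w / sum(w)
}

#' Mean first-passage time on a birth-death chain
#'
#' @param chain a \code{"reduced_chain"} object.
#' @param from starting value of x.
#' @param to target value of x.
#' @return Expected hitting time of \code{to} from \code{from}.
#' @export
bd_mfpt <- function(chain, from, to) {
  n <- length(chain$x)
  Q <- matrix(0, n, n)
  for (i in seq_len(n)) {
    if (i < n) Q[i, i + 1L] <- chain$lambda[i]
    if (i > 1L) Q[i, i - 1L] <- chain$gamma[i]
  }
  diag(Q) <- -rowSums(Q)
  h <- exact_mfpt(Matrix::Matrix(Q, sparse = TRUE), to + 1L)
  h[from + 1L]
}

log_or_inf <- function(x) if (x <= 0) -Inf else log(x)

#' Closed-form small-eps stationary law of the reduced chain
#'
#' Evaluates the analytic limit of the stationary distribution for
#' \code{eps << 1}: all mass sits on the fully active (x = 0) and fully
#' repressed (x = Dtot) states, with odds \code{P = P1 * P2} computed in log
#' space. The per-level coefficients are supplied as a pluggable callable
#' (default 1); the limit and all monotonicity consequences are independent
#' of their values. With \code{px > 0} the positively autoregulated form is
#' used, in which the activating drive gains the term \code{uA_tilde * px}.
#'
#' @param params a \code{\link{chromatin_params}} object.
#' @param Kbar function(i) giving the level-i coefficient (default 1 for all
#'   i, including i = Dtot).
#' @param px autoregulation strength (protein production/decay ratio);
#'   0 gives the open-loop circuit.
#' @param uA_tilde coupling gain from protein to the activating drive (used
#'   when \code{px > 0}).
#' @return List with \code{pi0} (active mass), \code{piD} (repressed mass),
#'   \code{P} and \code{logP}.
#' @export
limit_stationary <- function(params, Kbar = function(i) 1, px = 0,
                             uA_tilde = 1) {
  p <- params
  u <- total_inputs(p)
  Dtot <- p$Dtot
  acat <- p$alpha + p$alpha_bar + p$alpha_prime
  mm <- p$mu * p$mu_prime
  if (px > 0) {
    utot <- p$u0A + u$u12R_bar
    logP1 <- log(utot + acat) - log(utot + uA_tilde * px + 1)
    drive0 <- p$u0A
    gain <- uA_tilde * px + 1
  } else {
    logP1 <- log(u$uA_bar + u$u12R_bar + acat) - log(u$uA_bar + u$u12R_bar + 1)
    drive0 <- u$uA_bar
    gain <- 1
  }
  logP2 <- 0
  for (i in seq_len(Dtot - 1L)) {
    f <- Dtot - i
    num <- 2 * (u$u12R_bar + acat * i / Dtot)
    den <- mm * p$eps_prime * (f / Dtot) * Kbar(i) *
      (if (px > 0) p$u0A + gain * f / Dtot else u$uA_bar + f / Dtot)
    logP2 <- logP2 + log_or_inf(num) - log_or_inf(den)
  }
  num_last <- u$u12R_bar
  den_last <- mm * p$b * p$beta * p$eps * Kbar(Dtot) * drive0
  logP <- logP1 + logP2 + log_or_inf(num_last) - log_or_inf(den_last)
  piD <- if (logP == Inf) 1 else if (logP == -Inf) 0 else 1 / (1 + exp(-logP))
  list(pi0 = 1 - piD, piD = piD, P = exp(logP), logP = logP)
}

#' Scaling of the times to memory loss with the basal erasure rate
#'
#' Computes exact mean first-passage times between the fully repressed and
#' fully active states over a grid of \code{eps} and fits log-log slopes.
#' For the full circuit the repressed-to-active time scales like
#' \code{1/eps^2} (slope -2) while the active-to-repressed time scales like
#' \code{1/eps} (slope -1); the histone-only circuit has slope -1 for both.
#'
#' @param params baseline parameters (use a small \code{Dtot} so the exact
#'   solve is cheap).
#' @param eps_grid grid of \code{eps} values. The asymptotic exponents hold
#'   deep in the time-scale-separated regime \code{eps << eps_prime << 1};
#'   at moderate \code{eps} the apparent slope of the full circuit is steeper
#'   because the escape path still relies on several basal-erasure steps.
#' @param variant network variant.
#' @return List with \code{slope_repressed}, \code{slope_active} and the
#'   per-eps table of MFPTs.
#' @export
mfpt_scaling_check <- function(params, eps_grid = exp(seq(log(1e-4), log(1e-3),
                                                          length.out = 6)),
                               variant = "full") {
  tauR <- tauA <- numeric(length(eps_grid))
  for (k in seq_along(eps_grid)) {
    net <- build_network(set_param(params, "eps", eps_grid[k]), variant)
    g <- build_generator(net)
    keys <- state_keys(g$states)
    active <- which(keys == state_keys(t(chromatin_state(net, "active"))))
    repressed <- which(keys == state_keys(t(chromatin_state(net, "repressed"))))
    tauR[k] <- exact_mfpt(g$Q, active)[repressed]
    tauA[k] <- exact_mfpt(g$Q, repressed)[active]
  }
  if (any(diff(tauR) > 0) || any(diff(tauA) > 0))
    warning("MFPT not monotone over the eps grid; check the regime")
  fit <- function(tau) unname(stats::coef(
    stats::lm(log(tau) ~ log(eps_grid)))[2L])
  list(slope_repressed = fit(tauR), slope_active = fit(tauA),
       table = data.frame(eps = eps_grid, tau_repressed = tauR,
                          tau_active = tauA))
}
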