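#' Dimensionless parameters of the chromatin modification circuit
#'
#' Construct the non-dimensional parameterization used throughout the package.
#' All rates are expressed relative to the auto-catalysis rate of the
#' activating modification, so that one unit of normalized time corresponds to
#' the characteristic time of auto/cross-catalysis.
#'
#' @param alpha auto-catalysis rate of repressive histone methylation (H3K9me)
#'   relative to that of the activating mark.
#' @param alpha_bar cross-catalysis rate: CpG methylation recruiting H3K9
#'   writers, relative to activating auto-catalysis.
#' @param alpha_prime cross-catalysis rate: H3K9me recruiting CpG-methylation
#'   writers, relative to activating auto-catalysis.
#' @param eps basal (dilution plus non-specific) erasure rate of all
#'   modifications relative to auto/cross-catalysis. Small \code{eps} is the
#'   time-scale-separation regime in which bistability and long memory arise.
#' @param eps_prime recruited-erasure rate relative to auto/cross-catalysis.
#' @param mu ratio of (basal and recruited) erasure rates of repressive histone
#'   modifications to those of activating modifications.
#' @param mu_prime ratio of (basal and recruited) erasure rates of DNA
#'   methylation to those of activating histone modifications.
#' @param b,beta order-one scale factors relating the basal erasure rates of
#'   the repressive histone mark and of DNA methylation to \code{eps*mu} and
#'   \code{eps*mu_prime} respectively.
#' @param u0A,u10R,u20R basal (input-independent) de novo writing strengths for
#'   the activating mark, CpG methylation, and H3K9me.
#' @param uA,u1R,u2R external (TF-driven) de novo writing inputs.
#' @param px protein production/decay ratio \code{alpha_x/gamma_x} for coupled
#'   gene-expression circuits (0 for the open-loop chromatin circuit).
#' @param gamma_x normalized protein decay rate (sets how fast protein
#'   dynamics are relative to chromatin dynamics).
#' @param Dtot total number of modifiable nucleosomes in the gene (integer,
#'   at least 2).
#'
#' @return An object of class \code{"chromatin_params"}: a validated named
#'   list with derived accessors available through \code{\link{total_inputs}}.
#' @examples
#' p <- chromatin_params(eps = 0.1)
#' p
#' total_inputs(p)
#' @export
chromatin_params <- function(alpha = 1, alpha_bar = 1, alpha_prime = 1,
                             eps = 1, eps_prime = 1, mu = 1, mu_prime = 1,
                             b = 1, beta = 1,
                             u0A = 0.1, u10R = 0.1, u20R = 0.1,
                             uA = 0, u1R = 0, u2R = 0,
                             px = 0, gamma_x = 1, Dtot = 50L) {
  p <- list(alpha = alpha, alpha_bar = alpha_bar, alpha_prime = alpha_prime,
            eps = eps, eps_prime = eps_prime, mu = mu, mu_prime = mu_prime,
            b = b, beta = beta,
            u0A = u0A, u10R = u10R, u20R = u20R,
            uA = uA, u1R = u1R, u2R = u2R,
            px = px, gamma_x = gamma_x, Dtot = as.integer(Dtot))
  validate_params(p)
  class(p) <- "chromatin_params"
  p
}

validate_params <- function(p) {
  num <- setdiff(names(p), "Dtot")
  for (f in num) {
    v <- p[[f]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0)
      stop("parameter '", f, "' must be a single non-negative number")
  }
  if (p$Dtot < 2L) stop("Dtot must be an integer >= 2")
  invisible(p)
}

#' @export
print.chromatin_params <- function(x, ...) {
  cat("Dimensionless chromatin circuit parameters (Dtot =", x$Dtot, ")\n")
  cat(sprintf("  catalysis   alpha = %g  alpha_bar = %g  alpha_prime = %g\n",
              x$alpha, x$alpha_bar, x$alpha_prime))
  cat(sprintf("  erasure     eps = %g  eps_prime = %g  mu = %g  mu_prime = %g  b = %g  beta = %g\n",
              x$eps, x$eps_prime, x$mu, x$mu_prime, x$b, x$beta))
  cat(sprintf("  inputs      u0A = %g  u10R = %g  u20R = %g | uA = %g  u1R = %g  u2R = %g\n",
              x$u0A, x$u10R, x$u20R, x$uA, x$u1R, x$u2R))
  if (x$px > 0)
    cat(sprintf("  protein     px = %g  gamma_x = %g\n", x$px, x$gamma_x))
  invisible(x)
}

#' Total (basal plus external) writing drives
#'
#' @param p a \code{\link{chromatin_params}} object.
#' @return Named list with \code{uA_bar}, \code{u1R_bar}, \code{u2R_bar} and
#'   the lumped repressive drive \code{u12R_bar}.
#' @export
total_inputs <- function(p) {
  list(uA_bar = p$u0A + p$uA,
       u1R_bar = p$u10R + p$u1R,
       u2R_bar = p$u20R + p$u2R,
       u12R_bar = p$u10R + p$u1R + p$u20R + p$u2R)
}

#' Dimensional rate constants of the chromatin modification circuit
#'
#' Bundle the dimensional reaction-rate constants. Catalytic constants are
#' per concentration per time; writing and erasure constants are per time.
#'
#' @param kW0A,kW01,kW02 basal de novo writing rate constants (activating
#'   mark, CpGme, H3K9me).
#' @param kWA,kW1,kW2 TF-driven de novo writing rate constants.
#' @param kMA,kM,kM_bar,kM_prime catalysis rate constants: activating
#'   auto-catalysis (the normalization, must be positive), repressive
#'   auto-catalysis, and the two cross-catalysis constants.
#' @param kEA_bar,kER_bar basal active-erasure constants for activating and
#'   repressive histone marks.
#' @param kEA,kER recruited-erasure constants for activating and repressive
#'   histone marks.
#' @param delta dilution rate constant (DNA replication).
#' @param delta_prime effective passive DNA-demethylation constant.
#' @param kT_prime effective TET-mediated basal DNA-demethylation constant.
#' @param kT_star recruited DNA-demethylation constant.
#' @param alpha_x,gamma_x protein production (per active nucleosome) and decay.
#' @param Omega reaction volume.
#' @param Dtot nucleosome count (integer, at least 2).
#' @return An object of class \code{"rate_constants"}.
#' @seealso \code{\link{nondimensionalize}}, \code{\link{dimensionalize}}
#' @export
rate_constants <- function(kW0A = 0, kW01 = 0, kW02 = 0,
                           kWA = 0, kW1 = 0, kW2 = 0,
                           kMA = 1, kM = 1, kM_bar = 1, kM_prime = 1,
                           kEA_bar = 0, kER_bar = 0,
                           kEA = 1, kER = 1,
                           delta = 0, delta_prime = 0, kT_prime = 0,
                           kT_star = 1,
                           alpha_x = 0, gamma_x = 1,
                           Omega = 1, Dtot = 50L) {
  r <- list(kW0A = kW0A, kW01 = kW01, kW02 = kW02,
            kWA = kWA, kW1 = kW1, kW2 = kW2,
            kMA = kMA, kM = kM, kM_bar = kM_bar, kM_prime = kM_prime,
            kEA_bar = kEA_bar, kER_bar = kER_bar,
            kEA = kEA, kER = kER,
            delta = delta, delta_prime = delta_prime, kT_prime = kT_prime,
            kT_star = kT_star,
            alpha_x = alpha_x, gamma_x = gamma_x,
            Omega = Omega, Dtot = as.integer(Dtot))
  for (f in setdiff(names(r), "Dtot")) {
    v <- r[[f]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0)
      stop("rate constant '", f, "' must be a single non-negative number")
  }
  if (r$kMA <= 0) stop("kMA must be positive (it sets the time normalization)")
  if (r$Omega <= 0) stop("Omega must be positive")
  if (r$Dtot < 2L) stop("Dtot must be an integer >= 2")
  class(r) <- "rate_constants"
  r
}

#' Map dimensional rate constants to dimensionless parameters
#'
#' Normalizes all rates by the activating auto-catalysis scale
#' \code{kMA * Dtot/Omega}: \code{eps = (delta + kEA_bar)/(kMA*Dtot/Omega)},
#' \code{eps_prime = kEA/kMA}, \code{mu = kER/kEA},
#' \code{mu_prime = kT_star/kEA}, catalysis ratios \code{alpha = kM/kMA} etc.,
#' and writing inputs \code{u = kW/(kMA*Dtot/Omega)}. The order-one factors
#' are \code{b = (delta + kER_bar)/((delta + kEA_bar)*mu)} and
#' \code{beta = (delta_prime + kT_prime)/((delta + kEA_bar)*mu_prime)} (taken
#' as 1 when the corresponding erasure scale vanishes).
#'
#' @param rates a \code{\link{rate_constants}} object.
#' @return A \code{\link{chromatin_params}} object.
#' @export
nondimensionalize <- function(rates) {
  stopifnot(inherits(rates, "rate_constants"))
  if (rates$kEA == 0 && (rates$kER > 0 || rates$kT_star > 0))
    stop("kEA = 0 with positive kER or kT_star leaves mu/mu_prime undefined")
  conc <- rates$Dtot / rates$Omega       # nucleosome concentration
  scale <- rates$kMA * conc              # catalysis time scale
  mu <- if (rates$kEA > 0) rates$kER / rates$kEA else 1
  mu_prime <- if (rates$kEA > 0) rates$kT_star / rates$kEA else 1
  basal_A <- rates$delta + rates$kEA_bar
  eps <- basal_A / scale
  b <- if (basal_A > 0 && mu > 0)
    (rates$delta + rates$kER_bar) / (basal_A * mu) else 1
  beta <- if (basal_A > 0 && mu_prime > 0)
    (rates$delta_prime + rates$kT_prime) / (basal_A * mu_prime) else 1
  chromatin_params(
    alpha = rates$kM / rates$kMA,
    alpha_bar = rates$kM_bar / rates$kMA,
    alpha_prime = rates$kM_prime / rates$kMA,
    eps = eps, eps_prime = rates$kEA / rates$kMA,
    mu = mu, mu_prime = mu_prime, b = b, beta = beta,
    u0A = rates$kW0A / scale, u10R = rates$kW01 / scale,
    u20R = rates$kW02 / scale,
    uA = rates$kWA / scale, u1R = rates$kW1 / scale, u2R = rates$kW2 / scale,
    px = if (rates$gamma_x > 0) rates$alpha_x / rates$gamma_x else 0,
    gamma_x = rates$gamma_x / scale,
    Dtot = rates$Dtot)
}

#' Map dimensionless parameters back to dimensional rate constants
#'
#' Inverse of \code{\link{nondimensionalize}} given the normalization scale.
#' By convention all basal erasure is attributed to the enzymatic constants
#' (\code{delta = 0}) unless a dilution fraction is supplied; only the sums
#' \code{delta + kEA_bar} etc. are dynamically meaningful.
#'
#' @param params a \code{\link{chromatin_params}} object.
#' @param kMA activating auto-catalysis rate constant (positive).
#' @param Omega reaction volume (positive).
#' @param dilution_fraction fraction of the basal activating-mark erasure
#'   attributed to dilution (\code{delta}); default 0.
#' @return A \code{\link{rate_constants}} object for which
#'   \code{nondimensionalize} recovers \code{params}.
#' @export
dimensionalize <- function(params, kMA = 1, Omega = 1,
                           dilution_fraction = 0) {
  stopifnot(inherits(params, "chromatin_params"),
            kMA > 0, Omega > 0,
            dilution_fraction >= 0, dilution_fraction <= 1)
  conc <- params$Dtot / Omega
  scale <- kMA * conc
  basal_A <- params$eps * scale
  delta <- dilution_fraction * basal_A
  kEA <- params$eps_prime * kMA
  gx <- params$gamma_x * scale
  rate_constants(
    kW0A = params$u0A * scale, kW01 = params$u10R * scale,
    kW02 = params$u20R * scale,
    kWA = params$uA * scale, kW1 = params$u1R * scale,
    kW2 = params$u2R * scale,
    kMA = kMA, kM = params$alpha * kMA, kM_bar = params$alpha_bar * kMA,
    kM_prime = params$alpha_prime * kMA,
    kEA_bar = basal_A - delta,
    kER_bar = max(params$b * params$mu * basal_A - delta, 0),
    kEA = kEA, kER = params$mu * kEA,
    delta = delta,
    delta_prime = 0,
    kT_prime = params$beta * params$mu_prime * basal_A,
    kT_star = params$mu_prime * kEA,
    alpha_x = params$px * gx, gamma_x = gx,
    Omega = Omega, Dtot = params$Dtot)
}
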