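#' @useDynLib chromem, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# A reaction converts `from` into `to` (either may be NA for pure production
# or degradation) at propensity
#   coefficient * n[rate_species] * sum(n[catalysts]) / Dtot
# in normalized time; the catalyst factor is dropped for de novo/basal
# reactions and the count factor for reactions with no rate species. This
# scaling makes the mean field of the stochastic model coincide with the
# non-dimensional ODEs on nucleosome fractions.
reaction <- function(label, from, to, coefficient, catalysts = character(),
                     rate_species = from, class = "chromatin", hill = NULL) {
  if (!is.null(hill) && (is.null(hill$K) || is.null(hill$h)))
    stop("hill coupling requires a threshold K and coefficient h")
  list(label = label, from = from, to = to,
       coefficient = coefficient, catalysts = catalysts,
       rate_species = rate_species, class = class, hill = hill)
}

# catalyst activation factor: linear read-out of the catalyst fraction, or a
# saturating Hill function of it for TF-coupling laws
catalyst_factor <- function(r, frac) {
  if (is.null(r$hill)) frac
  else frac^r$hill$h / (r$hill$K^r$hill$h + frac^r$hill$h)
}

#' Build the chromatin modification reaction network
#'
#' Assembles the species and reactions of the gene's inner chromatin
#' modification circuit. Species are the unmodified nucleosome \code{D}, the
#' activating-mark nucleosome \code{DA} (H3K4me3/ac), \code{D1R} (CpG
#' methylation only), \code{D2R} (H3K9me3 only) and \code{D12R} (both
#' repressive modifications). Reaction classes are de novo establishment,
#' auto-catalysis, cross-catalysis between the repressive modifications,
#' basal erasure, and recruited erasure. The \code{histone_only} variant drops
#' DNA methylation and keeps only \code{D}, \code{DA} and \code{D2R} with
#' their de novo, auto-catalysis and erasure reactions.
#'
#' Catalyst sets: the activating mark is read by \code{DA}; H3K9me by
#' \code{D2R} and \code{D12R}; CpGme by \code{D1R} and \code{D12R}. A doubly
#' modified nucleosome appears in both repressive catalyst sets, so it
#' recruits erasers of the activating mark through both of its modifications.
#'
#' @param params a \code{\link{chromatin_params}} object.
#' @param variant \code{"full"} (histone plus DNA methylation) or
#'   \code{"histone_only"}.
#' @return An object of class \code{"chromatin_network"} with fields
#'   \code{species}, \code{reactions}, \code{variant}, \code{params},
#'   \code{Dtot} and (for composed circuits) \code{conserved}, a list of
#'   species groups each summing to \code{Dtot}.
#' @examples
#' net <- build_network(chromatin_params(eps = 0.1))
#' net
#' @export
build_network <- function(params, variant = c("full", "histone_only")) {
  stopifnot(inherits(params, "chromatin_params"))
  variant <- match.arg(variant)
  u <- total_inputs(params)
  p <- params
  if (variant == "full") {
    species <- c("D", "DA", "D1R", "D2R", "D12R")
    A <- "DA"; K9 <- c("D2R", "D12R"); ME <- c("D1R", "D12R")
    rx <- list(
      # de novo establishment
      reaction("0+1", "D", "DA", u$uA_bar, class = "de_novo"),
      reaction("2", "D", "D2R", u$u2R_bar, class = "de_novo"),
      reaction("3", "D1R", "D12R", u$u2R_bar, class = "de_novo"),
      reaction("10", "D", "D1R", u$u1R_bar, class = "de_novo"),
      reaction("11", "D2R", "D12R", u$u1R_bar, class = "de_novo"),
      # auto-catalysis
      reaction("4", "D", "DA", 1, catalysts = A, class = "auto_catalysis"),
      reaction("5a", "D", "D2R", p$alpha, catalysts = K9, class = "auto_catalysis"),
      reaction("5b", "D1R", "D12R", p$alpha, catalysts = K9, class = "auto_catalysis"),
      # cross-catalysis
      reaction("15a", "D", "D2R", p$alpha_bar, catalysts = ME, class = "cross_catalysis"),
      reaction("15b", "D1R", "D12R", p$alpha_bar, catalysts = ME, class = "cross_catalysis"),
      reaction("16a", "D", "D1R", p$alpha_prime, catalysts = K9, class = "cross_catalysis"),
      reaction("16b", "D2R", "D12R", p$alpha_prime, catalysts = K9, class = "cross_catalysis"),
      # basal erasure
      reaction("6", "DA", "D", p$eps, class = "basal_erasure"),
      reaction("7a", "D2R", "D", p$b * p$eps * p$mu, class = "basal_erasure"),
      reaction("7b", "D12R", "D1R", p$b * p$eps * p$mu, class = "basal_erasure"),
      reaction("12a", "D1R", "D", p$beta * p$eps * p$mu_prime, class = "basal_erasure"),
      reaction("12b", "D12R", "D2R", p$beta * p$eps * p$mu_prime, class = "basal_erasure"),
      # recruited erasure
      reaction("8a", "D2R", "D", p$mu * p$eps_prime, catalysts = A, class = "recruited_erasure"),
      reaction("8b", "D12R", "D1R", p$mu * p$eps_prime, catalysts = A, class = "recruited_erasure"),
      reaction("9", "DA", "D", p$eps_prime, catalysts = K9, class = "recruited_erasure"),
      reaction("13", "DA", "D", p$eps_prime, catalysts = ME, class = "recruited_erasure"),
      reaction("14a", "D1R", "D", p$mu_prime * p$eps_prime, catalysts = A, class = "recruited_erasure"),
      reaction("14b", "D12R", "D2R", p$mu_prime * p$eps_prime, catalysts = A, class = "recruited_erasure")
    )
  } else {
    species <- c("D", "DA", "D2R")
    A <- "DA"; K9 <- "D2R"
    rx <- list(
      reaction("0+1", "D", "DA", u$uA_bar, class = "de_novo"),
      reaction("2", "D", "D2R", u$u2R_bar, class = "de_novo"),
      reaction("4", "D", "DA", 1, catalysts = A, class = "auto_catalysis"),
      reaction("5", "D", "D2R", p$alpha, catalysts = K9, class = "auto_catalysis"),
      reaction("6", "DA", "D", p$eps, class = "basal_erasure"),
      reaction("7", "D2R", "D", p$b * p$eps * p$mu, class = "basal_erasure"),
      reaction("8", "D2R", "D", p$mu * p$eps_prime, catalysts = A, class = "recruited_erasure"),
      reaction("9", "DA", "D", p$eps_prime, catalysts = K9, class = "recruited_erasure")
    )
  }
  structure(list(species = species, reactions = rx, variant = variant,
                 params = params, Dtot = params$Dtot,
                 conserved = list(species)),
            class = "chromatin_network")
}

#' @export
print.chromatin_network <- function(x, ...) {
  cat("Chromatin modification network (variant:", x$variant,
      ", Dtot =", x$Dtot, ")\n")
  cat(length(x$species), "species:", paste(x$species, collapse = ", "), "\n")
  cat(length(x$reactions), "reactions\n")
  invisible(x)
}

#' Stoichiometry matrix of a network
#'
#' @param network a \code{\link{build_network}} object.
#' @return Integer matrix, species by reactions; column j is the state change
#'   of reaction j.
#' @export
stoich_matrix <- function(network) {
  ns <- length(network$species)
  nr <- length(network$reactions)
  S <- matrix(0L, ns, nr,
              dimnames = list(network$species,
                              vapply(network$reactions, `[[`, "", "label")))
  for (j in seq_len(nr)) {
    r <- network$reactions[[j]]
    if (!is.na(r$from)) S[r$from, j] <- S[r$from, j] - 1L
    if (!is.na(r$to)) S[r$to, j] <- S[r$to, j] + 1L
  }
  S
}

#' Reaction propensities at a state
#'
#' Evaluates the propensity of every reaction at integer copy numbers
#' \code{state} under the normalized-time convention (catalyzed reactions are
#' scaled by \code{1/Dtot}).
#'
#' @param network a \code{\link{build_network}} object.
#' @param state named (or network-ordered) non-negative integer vector of
#'   copy numbers.
#' @return Numeric vector of propensities, one per reaction.
#' @export
propensities <- function(network, state) {
  n <- as.numeric(state)
  if (!is.null(names(state))) n <- n[match(network$species, names(state))]
  if (length(n) != length(network$species) || anyNA(n))
    stop("state must provide a count for every species")
  if (any(n < 0)) stop("negative copy numbers")
  vapply(network$reactions, function(r) {
    a <- r$coefficient
    if (!is.na(r$rate_species)) a <- a * n[match(r$rate_species, network$species)]
    if (length(r$catalysts)) {
      frac <- sum(n[match(r$catalysts, network$species)]) / network$Dtot
      a <- a * catalyst_factor(r, frac)
    }
    a
  }, numeric(1))
}

#' Default initial states
#'
#' Convenience constructors for the fully active, fully repressed and
#' unmodified chromatin states as named count vectors.
#'
#' @param network a \code{\link{build_network}} object.
#' @param which one of \code{"active"}, \code{"repressed"},
#'   \code{"unmodified"}.
#' @return Named integer vector over the network species.
#' @export
chromatin_state <- function(network,
                            which = c("active", "repressed", "unmodified")) {
  which <- match.arg(which)
  n <- setNames(integer(length(network$species)), network$species)
  target <- switch(which,
                   active = "DA",
                   repressed = if (network$variant == "histone_only") "D2R" else "D12R",
                   unmodified = "D")
  # composed networks carry one conserved gene copy per suffix (e.g. DA.X)
  for (group in network$conserved) {
    hit <- group[sub("\\..*$", "", group) == target]
    if (length(hit) != 1L)
      stop("no species matching '", target, "' in conserved group")
    n[hit] <- network$Dtot
  }
  n
}

#' Serialize a network to JSON
#'
#' @param network a \code{\link{build_network}} object.
#' @param path optional file path; if missing the JSON string is returned.
#' @return The JSON string, invisibly when written to a file.
#' @export
network_to_json <- function(network, path = NULL) {
  obj <- list(
    species = network$species,
    variant = network$variant,
    Dtot = network$Dtot,
    conserved = network$conserved,
    params = unclass(network$params),
    reactions = lapply(network$reactions, function(r)
      list(label = r$label, substrate = r$from, product = r$to,
           catalysts = as.list(r$catalysts), coefficient = r$coefficient,
           rate_species = r$rate_species, class = r$class, hill = r$hill))
  )
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, null = "null")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' Deserialize a network from JSON
#'
#' @param json a JSON string or file path produced by
#'   \code{\link{network_to_json}}.
#' @return A \code{"chromatin_network"} object.
#' @export
network_from_json <- function(json) {
  obj <- jsonlite::fromJSON(json, simplifyVector = FALSE)
  params <- do.call(chromatin_params, obj$params)
  rx <- lapply(obj$reactions, function(r)
    reaction(r$label,
             if (is.null(r$substrate)) NA_character_ else r$substrate,
             if (is.null(r$product)) NA_character_ else r$product,
             r$coefficient,
             catalysts = as.character(unlist(r$catalysts)),
             rate_species = if (is.null(r$rate_species)) NA_character_ else r$rate_species,
             class = r$class, hill = r$hill))
  conserved <- if (is.null(obj$conserved))
    list(as.character(unlist(obj$species)))
  else lapply(obj$conserved, function(g) as.character(unlist(g)))
  structure(list(species = as.character(unlist(obj$species)), reactions = rx,
                 variant = obj$variant, params = params, Dtot = obj$Dtot,
                 conserved = conserved),
            class = "chromatin_network")
}
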