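test_that("autoregulated network couples protein to activation", {
  p <- small_params(eps = 0.1)
  ar <- make_autoregulated(p, uA_tilde = 1, px = 2)
  expect_true("X" %in% ar$species)
  labels <- vapply(ar$reactions, `[[`, character(1), "label")
  expect_true(all(c("PA", "P1", "P2") %in% labels))
  # protein production propensity is px * gamma_x * nDA
  n <- setNames(integer(6), ar$species); n["DA"] <- 4
  a <- propensities(ar, n)
  expect_equal(unname(a[labels == "P1"]), 2 * 1 * 4)
  # protein decay is gamma_x * nX
  n["X"] <- 3
  expect_equal(unname(propensities(ar, n)[labels == "P2"]), 3)
  # coupling reaction: uA_tilde * nD * nX / Dtot
  n["D"] <- 4; n["DA"] <- 0
  expect_equal(unname(propensities(ar, n)[labels == "PA"]), 1 * 4 * 3 / 8)
})

test_that("QSS autoregulation matches the mean protein level coupling", {
  p <- small_params(eps = 0.1)
  arq <- make_autoregulated(p, uA_tilde = 0.7, px = 3, qss = TRUE)
  expect_false("X" %in% arq$species)
  labels <- vapply(arq$reactions, `[[`, character(1), "label")
  expect_true("PA-qss" %in% labels)
  n <- c(D = 4, DA = 2, D1R = 0, D2R = 0, D12R = 2)
  a <- propensities(arq, n)
  # X_qss = px * nDA, coupling rate = uA_tilde * px * nD * nDA/Dtot
  expect_equal(unname(a[labels == "PA-qss"]), 0.7 * 3 * 4 * 2 / 8)
})

test_that("mutual repression wires cross-repression through proteins", {
  p <- small_params(eps = 0.2, px = 5)
  mr <- make_mutual_repression(p)
  expect_setequal(intersect(c("X", "Z"), mr$species), c("X", "Z"))
  expect_equal(length(mr$conserved), 2L)
  labels <- vapply(mr$reactions, `[[`, character(1), "label")
  # gene X gains repressive writing catalyzed by protein Z and vice versa
  rx <- Filter(function(r) startsWith(r$label, "R") &&
                 endsWith(r$from, ".X"), mr$reactions)
  expect_true(all(vapply(rx, function(r) identical(r$catalysts, "Z"),
                         logical(1))))
})

test_that("perturbation events are validated and applied", {
  p <- small_params(eps = 0.1)
  ar <- make_autoregulated(p, px = 2)
  init <- chromatin_state(ar, "active"); init["X"] <- 2
  expect_error(apply_events(ar, init, 10,
                            list(list(time = 20, action = "reset_protein_to_zero",
                                      target = "X"))), "horizon")
  expect_error(apply_events(ar, init, 10,
                            list(list(time = 5, action = "explode",
                                      target = "X"))), "unknown")
  expect_error(apply_events(ar, init, 10,
                            list(list(time = 5, action = "reset_protein_to_zero",
                                      target = "Y"))), "missing")
  # with px = 0 the protein cannot be re-synthesized, so the reset and the
  # overexpression leave unambiguous signatures in the trajectory
  ar0 <- make_autoregulated(p, px = 0)
  init0 <- chromatin_state(ar0, "active"); init0["X"] <- 10
  ev <- list(list(time = 3, action = "reset_protein_to_zero", target = "X"),
             list(time = 6, action = "overexpress_protein", target = "X",
                  magnitude = 25))
  tr <- apply_events(ar0, init0, 9, ev, engine = "ssa", seed = 2, n_out = 200)
  expect_true(all(c("tau", "X") %in% names(tr)))
  # the sample at exactly tau = 3 is the pre-reset value, so look just past it
  expect_equal(max(tr$X[tr$tau > 3.1 & tr$tau < 6]), 0)
  expect_gte(max(tr$X[tr$tau >= 6]), 20)
})

test_that("robustness threshold increases with autoregulation strength", {
  p <- small_params(eps = 0.1, mu_prime = 0.7)
  rob <- robustness_scan(p, uR_grid = seq(0, 1.5, by = 0.25),
                         px_grid = c(0, 5, 10))
  th <- rob$thresholds$uR_star
  expect_true(all(diff(th) > 0))
})

test_that("pattern census distinguishes low- and high-autoregulation regimes", {
  mk <- function(px, eps) make_mutual_repression(
    paper_ratios(eps = eps, mu_prime = 0.6, px = px))
  low <- pattern_census(mk(0.1, 0.2), horizon = 300, reps = 30, seed = 1)
  expect_gt(low$prob[low$pattern == "both_off"], 0.5)
  high <- pattern_census(mk(10, 0.1), horizon = 300, reps = 30, seed = 1)
  excl <- sum(high$prob[high$pattern %in% c("x_on_z_off", "z_on_x_off")])
  expect_gt(excl, 0.8)
  expect_lt(high$prob[high$pattern == "both_off"], 0.1)
})
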