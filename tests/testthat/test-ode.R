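test_that("hand-written mean-field RHS matches the generic network RHS", {
  p <- small_params(eps = 0.17, eps_prime = 0.4, mu = 0.8, mu_prime = 0.6,
                    alpha = 0.3, alpha_bar = 0.7, alpha_prime = 1.2,
                    b = 1.1, beta = 0.9, uA = 0.4, u1R = 0.2, u2R = 0.6)
  net <- build_network(p)
  set.seed(42)
  for (i in 1:5) {
    x <- as.numeric(stats::runif(5))
    x <- x / sum(x)
    names(x) <- c("D", "DA", "D1R", "D2R", "D12R")
    r1 <- mean_field_rhs(x, p)
    r2 <- network_rhs(net, x)
    expect_equal(r1, r2[names(r1)], tolerance = 1e-12)
    expect_equal(sum(r1), 0, tolerance = 1e-12)
  }
})

test_that("ODE trajectories conserve the nucleosome fraction sum", {
  net <- build_network(small_params(eps = 0.1))
  tr <- simulate_ode(net, c(D = 0.2, DA = 0.5, D1R = 0.1, D2R = 0.1,
                            D12R = 0.1), tau_max = 1e4, n_out = 51)
  sums <- rowSums(tr[, c("D", "DA", "D1R", "D2R", "D12R")])
  expect_lt(max(abs(sums - 1)), 1e-8)
})

test_that("equilibrium finder classifies bistable and monostable regimes", {
  bi <- find_equilibria(build_network(small_params(eps = 0.05)),
                        n_starts = 60, seed = 1)
  expect_equal(bi$classification, "bistable")
  stab <- vapply(bi$equilibria, `[[`, character(1), "stability")
  expect_equal(sum(stab == "stable"), 2L)
  expect_equal(sum(stab == "unstable"), 1L)
  # residuals at every reported equilibrium are tiny
  for (e in bi$equilibria)
    expect_lt(max(abs(network_rhs(build_network(small_params(eps = 0.05)),
                                  e$state))), 1e-8)
  mono <- find_equilibria(build_network(small_params(eps = 5)),
                          n_starts = 60, seed = 1)
  expect_match(mono$classification, "monostable")
})

test_that("bifurcation scan finds loss of bistability as eps grows", {
  sc <- bifurcation_scan(small_params(), "eps",
                         c(0.05, 0.1, 0.5, 2, 5), seed = 1)
  cls <- sc$table$classification
  expect_equal(cls[1], "bistable")
  expect_match(cls[length(cls)], "monostable")
  # the loss of bistability is bracketed by a refined saddle-node location
  expect_gte(length(sc$saddle_nodes), 1L)
  expect_true(all(sc$saddle_nodes > 0.05 & sc$saddle_nodes < 5))
})

test_that("hysteresis sweep shows switching, memory and asymmetry", {
  p <- small_params(eps = 0.1)
  hs <- hysteresis_sweep(p, "uA", c(0, 2, 6, 12, 20))
  up <- hs[hs$direction == "up", ]
  dn <- hs[hs$direction == "down", ]
  expect_lt(up$DA[1], 0.1)             # starts repressed
  expect_gt(up$DA[nrow(up)], 0.9)      # switches at high input
  expect_gt(dn$DA[nrow(dn)], 0.5)      # retains active state at u = 0
  hr <- hysteresis_sweep(p, "uR", c(0, 2, 6, 12, 20))
  upr <- hr[hr$direction == "up", ]
  crit_uA <- up$input[which(up$DA > 0.5)[1]]
  crit_uR <- upr$input[which(upr$DR > 0.5)[1]]
  expect_lt(crit_uR, crit_uA)          # easier to silence than to activate
})

test_that("stability chart labels both regimes on a small grid", {
  ch <- stability_chart(small_params(), "eps", c(0.05, 2),
                        "mu_prime", c(0.05, 1), seed = 1)
  expect_true(is.data.frame(ch))
  expect_setequal(names(ch)[1:2], c("eps", "mu_prime"))
  expect_true("bistable" %in% ch$classification)
  expect_true(any(grepl("monostable", ch$classification)))
})
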