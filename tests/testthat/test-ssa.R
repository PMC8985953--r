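test_that("identical seeds give identical event logs", {
  net <- build_network(small_params(eps = 0.3))
  init <- chromatin_state(net, "repressed")
  r1 <- ssa_run(net, init, tau_max = 30, seed = 11, log_events = TRUE)
  r2 <- ssa_run(net, init, tau_max = 30, seed = 11, log_events = TRUE)
  expect_gt(nrow(r1$events), 0)
  expect_identical(r1$events, r2$events)
  expect_identical(r1$state, r2$state)
  r3 <- ssa_run(net, init, tau_max = 30, seed = 12, log_events = TRUE)
  expect_false(identical(r1$events$tau, r3$events$tau))
})

test_that("SSA conserves nucleosome number along the whole trajectory", {
  net <- build_network(small_params(eps = 0.5))
  run <- ssa_run(net, chromatin_state(net, "unmodified"), tau_max = 50,
                 seed = 3, sample_times = seq(0, 50, by = 1))
  sums <- rowSums(run$snapshots[, net$species])
  expect_true(all(sums == 8))
})

test_that("stop conditions halt at the crossing time", {
  net <- build_network(small_params(eps = 0.3, uA = 5))
  run <- ssa_run(net, chromatin_state(net, "repressed"), tau_max = 1e4,
                 stop = list(species = "DA", op = ">=", value = 6), seed = 4)
  expect_true(run$stopped)
  expect_gte(run$state[["DA"]], 6)
  expect_lt(run$time, 1e4)
  # already-satisfied condition stops at time zero
  run0 <- ssa_run(net, chromatin_state(net, "active"), tau_max = 10,
                  stop = list(species = "DA", op = ">=", value = 6), seed = 4)
  expect_true(run0$stopped)
  expect_equal(run0$time, 0)
})

test_that("single-reaction birth process matches its exact mean", {
  # D -> DA at rate u per substrate molecule; the count of remaining D at
  # time t is binomial(Dtot, exp(-u t))
  p <- small_params(eps = 0, eps_prime = 0, u0A = 0.5, u10R = 0, u20R = 0,
                    alpha = 0, alpha_bar = 0, alpha_prime = 0, mu = 0,
                    mu_prime = 0)
  net <- build_network(p)
  # remove the A auto-catalysis to keep only the pure birth reaction
  net$reactions <- Filter(function(r) r$label == "0+1", net$reactions)
  finals <- vapply(1:400, function(s)
    ssa_run(net, chromatin_state(net, "unmodified"), tau_max = 2,
            seed = s)$state[["D"]], numeric(1))
  expect_equal(mean(finals), 8 * exp(-0.5 * 2), tolerance = 0.08)
})

test_that("stationary histogram is bimodal in the memory regime", {
  net <- build_network(paper_ratios(eps = 0.1))
  sh <- stationary_histogram(net, horizon = 300, reps = 60,
                             samples_per_rep = 30, seed = 5)
  act <- sum(sh$macro$prob[sh$macro$nA >= 6])
  rep_mass <- sum(sh$macro$prob[sh$macro$nR >= 6])
  mid <- 1 - act - rep_mass
  expect_gt(act, 0.05)
  expect_gt(rep_mass, 0.3)
  expect_lt(mid, 0.2)
})

test_that("first-passage sampling reports censoring honestly", {
  net <- build_network(small_params(eps = 1e-3))
  fp <- first_passage_sample(net, chromatin_state(net, "repressed"),
                             list(species = "DA", op = ">=", value = 8),
                             reps = 5, max_time = 5, seed = 6)
  expect_equal(fp$n_censored, 5L)
  expect_true(is.na(fp$mean) || is.nan(fp$mean))
})

test_that("reactivation latency falls with stronger activating input", {
  p <- paper_ratios(eps = 0.24, mu_prime = 0.5)
  r_lo <- reactivation_experiment(p, uA = 2, reps = 40, seed = 7)
  r_hi <- reactivation_experiment(p, uA = 8, reps = 40, seed = 7)
  expect_equal(r_lo$latency$n_censored, 0L)
  expect_equal(r_hi$latency$n_censored, 0L)
  expect_lt(r_hi$latency$mean, r_lo$latency$mean)
})
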