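test_that("chromatin_params validates and stores fields", {
  p <- chromatin_params(eps = 0.1, Dtot = 10L)
  expect_s3_class(p, "chromatin_params")
  expect_equal(p$eps, 0.1)
  expect_equal(p$Dtot, 10L)
  expect_equal(p$b, 1)
  expect_equal(p$beta, 1)
  expect_error(chromatin_params(eps = -1), "eps")
  expect_error(chromatin_params(Dtot = 0L), "Dtot")
  expect_error(chromatin_params(mu = -0.5), "mu")
})

test_that("total_inputs sums basal and external drives", {
  p <- chromatin_params(u0A = 0.1, uA = 0.4, u10R = 0.1, u20R = 0.2,
                        u1R = 0.3, u2R = 0.5)
  u <- total_inputs(p)
  expect_equal(u$uA_bar, 0.5)
  expect_equal(u$u1R_bar, 0.4)
  expect_equal(u$u2R_bar, 0.7)
  expect_equal(u$u12R_bar, 1.1)
})

test_that("nondimensionalize and dimensionalize are mutually consistent", {
  r <- rate_constants(kM = 2, kM_bar = 1.5, kM_prime = 0.8, kMA = 4,
                      kEA = 2, kER = 1, kT_star = 0.6, kEA_bar = 0.02,
                      kER_bar = 0.03, kT_prime = 0.05,
                      delta = 0.02, kWA = 0.4, kW1 = 0.2, kW2 = 0.3,
                      kW0A = 0.1, kW01 = 0.1, kW02 = 0.1,
                      Dtot = 20L, Omega = 1)
  p <- nondimensionalize(r)
  expect_equal(p$alpha, 0.5)
  expect_equal(p$eps, (0.02 + 0.02) / (4 * 20))
  expect_equal(p$eps_prime, 0.5)
  expect_equal(p$mu, 0.5)
  expect_equal(p$mu_prime, 0.3)
  expect_equal(p$uA, 0.4 / 80)
  r2 <- dimensionalize(p, kMA = 4, Omega = 1)
  p2 <- nondimensionalize(r2)
  for (nm in c("alpha", "alpha_bar", "alpha_prime", "eps", "eps_prime",
               "mu", "mu_prime", "u0A", "uA", "u1R", "u2R"))
    expect_equal(p2[[nm]], p[[nm]], tolerance = 1e-12)
})

test_that("print method runs", {
  expect_output(print(chromatin_params()), "eps")
})
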