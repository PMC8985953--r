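test_that("state space enumerates the full simplex", {
  net <- build_network(small_params())
  ss <- state_space(net)
  expect_equal(nrow(ss), choose(8 + 4, 4))   # compositions of 8 into 5 parts
  expect_true(all(rowSums(ss) == 8))
  h <- build_network(small_params(), "histone_only")
  expect_equal(nrow(state_space(h)), choose(8 + 2, 2))
})

test_that("generator rows sum to zero and off-diagonals are propensities", {
  net <- build_network(small_params(eps = 0.3))
  g <- build_generator(net)
  expect_lt(max(abs(Matrix::rowSums(g$Q))), 1e-12)
  # pick a state and check one transition rate against the propensity
  i <- state_index(g$states, "D12R", 8)
  a <- propensities(net, setNames(as.integer(g$states[i, ]), colnames(g$states)))
  expect_equal(-Matrix::diag(g$Q)[i], sum(a), tolerance = 1e-12)
})

test_that("hand-enumerated two-nucleosome histone generator is reproduced", {
  # histone-only, Dtot = 2: states (D, DA, D2R) with D+DA+D2R = 2.
  p <- chromatin_params(Dtot = 2L, eps = 0.2, eps_prime = 0.4, mu = 0.5,
                        alpha = 0.3, u0A = 0.1, u20R = 0.3, u10R = 0,
                        uA = 0, u2R = 0)
  net <- build_network(p, "histone_only")
  g <- build_generator(net)
  key <- apply(g$states, 1, paste, collapse = ",")
  idx <- function(d, da, d2r) which(key == paste(d, da, d2r, sep = ","))
  rate <- function(from, to) g$Q[from, to]
  # from (2,0,0): de novo activation 0.1*2; de novo repression 0.3*2
  expect_equal(rate(idx(2, 0, 0), idx(1, 1, 0)), 0.2)
  expect_equal(rate(idx(2, 0, 0), idx(1, 0, 1)), 0.6)
  # from (1,1,0): activation of remaining D = de novo + autocat 1*(1)*(1/2)
  expect_equal(rate(idx(1, 1, 0), idx(0, 2, 0)), 0.1 + 0.5)
  # basal erasure of the single DA
  expect_equal(rate(idx(1, 1, 0), idx(2, 0, 0)), 0.2)
  # from (0, 1, 1): recruited erasure of DA by K9 (eps' * 1 * 1/2) has no
  # basal partner subtracted; total DA -> D rate is eps + eps'*frac
  expect_equal(rate(idx(0, 1, 1), idx(1, 0, 1)), 0.2 + 0.4 * 0.5)
  # recruited erasure of D2R by A: mu * eps' * 1 * 1/2, plus basal b*eps*mu
  expect_equal(rate(idx(0, 1, 1), idx(1, 1, 0)), 0.5 * 0.4 * 0.5 + 0.2 * 0.5)
})

test_that("exact stationary distribution solves pi Q = 0 and matches eigen", {
  net <- build_network(small_params(eps = 0.4))
  g <- build_generator(net)
  pi1 <- exact_stationary(g$Q)
  expect_equal(sum(pi1), 1, tolerance = 1e-12)
  expect_lt(max(abs(as.numeric(pi1 %*% g$Q))), 1e-10)
})

test_that("exact MFPT matches closed forms on small chains", {
  # two-state chain: MFPT = 1/rate
  Q <- Matrix::sparseMatrix(i = c(1, 1), j = c(1, 2), x = c(-0.25, 0.25),
                            dims = c(2, 2))
  expect_equal(exact_mfpt(Q, 2)[1], 4)
  expect_equal(exact_mfpt(Q, 2)[2], 0)
  # three-state birth-death chain, closed-form hitting time of state 3
  lam <- c(0.7, 1.3); mu_ <- 0.4
  Q3 <- Matrix::sparseMatrix(
    i = c(1, 1, 2, 2, 2),
    j = c(1, 2, 1, 2, 3),
    x = c(-lam[1], lam[1], mu_, -(mu_ + lam[2]), lam[2]), dims = c(3, 3))
  h <- exact_mfpt(Q3, 3)
  # h1 = 1/l1 + h2; h2 = (1 + mu h1)/(mu + l2)
  h2 <- (1 + mu_ / lam[1]) / lam[2]
  expect_equal(h[2], h2, tolerance = 1e-12)
  expect_equal(h[1], 1 / lam[1] + h2, tolerance = 1e-12)
  # unreachable targets give Inf
  Q2 <- Matrix::sparseMatrix(i = 2, j = 1, x = 1e-9, dims = c(2, 2))
  Q2[2, 2] <- -1e-9
  expect_equal(exact_mfpt(Q2, 1)[2], 1e9)
  Qd <- Matrix::sparseMatrix(i = 1, j = 1, x = 0, dims = c(2, 2))
  expect_true(is.infinite(exact_mfpt(Qd, 2)[1]))
})

test_that("MFPT agrees with the ill-conditioned deep-metastable regime", {
  # the solve must stay accurate when rates span 9+ orders of magnitude
  net <- build_network(small_params(eps = 1e-4, eps_prime = 0.1))
  g <- build_generator(net)
  i_rep <- state_index(g$states, "D12R", 8)
  i_act <- state_index(g$states, "DA", 8)
  h <- exact_mfpt(g$Q, i_act)
  expect_true(all(h[-i_act] > 0))
  expect_true(is.finite(h[i_rep]))
  # renewal consistency: MFPT from the neighbor one basal step away is
  # within the repressed-state MFPT (no negative or wild entries)
  expect_lt(h[i_rep], 1e25)
  expect_gt(h[i_rep], 1e10)
})

test_that("1-D reduction reproduces exact stationary odds at small eps", {
  p <- paper_ratios(eps = 0.01, eps_prime = 0.1)
  net <- build_network(p)
  rc <- reduce_to_1d(net, warn_regime = FALSE)
  expect_s3_class(rc, "reduced_chain")
  expect_equal(length(rc$lambda), 9)
  expect_true(all(rc$gamma[-1] > 0))
  pi_red <- bd_stationary(rc)
  expect_equal(sum(pi_red), 1, tolerance = 1e-12)
  # exact CME marginal over x = n12R
  g <- build_generator(net)
  pi_ex <- exact_stationary(g$Q)
  x <- g$states[, "D12R"]
  marg <- vapply(0:8, function(k) sum(pi_ex[x == k]), numeric(1))
  # the reduction should capture the dominant repressed mass
  expect_equal(pi_red[9], marg[9], tolerance = 0.1)
  expect_equal(which.max(pi_red), which.max(marg))
})

test_that("closed-form limit masses follow the published monotonicities", {
  p0 <- small_params(eps = 1e-6, u0A = 0.1, u10R = 0.1, u20R = 0.1)
  lim <- limit_stationary(p0)
  expect_equal(lim$pi0 + lim$piD, 1, tolerance = 1e-12)
  expect_gt(lim$piD, 0.99)
  # activating input raises the active mass; repressive input lowers it
  up_uA <- limit_stationary(small_params(eps = 0.05, uA = 2))
  base <- limit_stationary(small_params(eps = 0.05))
  up_uR <- limit_stationary(small_params(eps = 0.05, u1R = 2, u2R = 2))
  expect_gt(up_uA$pi0, base$pi0)
  expect_lt(up_uR$pi0, base$pi0)
  # autoregulation raises the active mass
  expect_gt(limit_stationary(small_params(eps = 0.05), px = 2)$pi0,
            base$pi0)
})

test_that("reduced-chain MFPTs reproduce the qualitative memory structure", {
  # The 1-D chain is an asymptotic device: it captures the divergence of both
  # memory times as eps -> 0 and the repressed/active asymmetry, but its
  # conditional averaging mixes the within-slice modes, so no quantitative
  # agreement with the exact MFPT is asserted here.
  taus <- vapply(c(2e-2, 5e-3, 1e-3), function(eps) {
    rc <- reduce_to_1d(build_network(paper_ratios(eps = eps,
                                                  eps_prime = 0.1)),
                       warn_regime = FALSE)
    c(bd_mfpt(rc, 8, 0), bd_mfpt(rc, 0, 8))
  }, numeric(2))
  # the repressed-escape time diverges as eps decreases
  expect_true(all(diff(taus[1, ]) > 0))
  expect_gt(taus[1, 3] / taus[1, 1], 1e3)
  # repressed escape is slower than active escape (structural asymmetry)
  expect_true(all(taus[1, ] > taus[2, ]))
})
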