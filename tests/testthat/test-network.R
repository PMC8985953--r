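test_that("full network has the expected species and reaction classes", {
  net <- build_network(small_params())
  expect_s3_class(net, "chromatin_network")
  expect_setequal(net$species, c("D", "DA", "D1R", "D2R", "D12R"))
  classes <- vapply(net$reactions, `[[`, character(1), "class")
  expect_true(all(c("de_novo", "auto_catalysis", "cross_catalysis",
                    "basal_erasure", "recruited_erasure") %in% classes))
  # every reaction conserves total nucleosome number
  S <- stoich_matrix(net)
  expect_equal(unname(colSums(S)), rep(0, ncol(S)))
})

test_that("histone-only variant drops DNA methylation species", {
  net <- build_network(small_params(), variant = "histone_only")
  expect_setequal(net$species, c("D", "DA", "D2R"))
  touched <- unique(unlist(lapply(net$reactions, function(r)
    c(r$from, r$to, r$catalysts))))
  expect_false(any(c("D1R", "D12R") %in% touched))
})

test_that("propensities follow the normalized mass-action convention", {
  p <- small_params(eps = 0.25, u0A = 0.3, u10R = 0, u20R = 0,
                    alpha = 0.5, alpha_bar = 0, alpha_prime = 0)
  net <- build_network(p)
  n <- c(D = 4, DA = 2, D1R = 0, D2R = 2, D12R = 0)
  a <- propensities(net, n)
  labels <- vapply(net$reactions, `[[`, character(1), "label")
  # de novo activation: coeff * substrate count
  expect_equal(unname(a[labels == "0+1"]), 0.3 * 4)
  # activating auto-catalysis: 1 * substrate * catalyst fraction
  expect_equal(unname(a[labels == "4"]), 1 * 4 * 2 / 8)
  # repressive auto-catalysis catalyzed by K9 marks (D2R + D12R)
  expect_equal(unname(a[labels == "5a"]), 0.5 * 4 * 2 / 8)
  # basal erasure of DA: eps * count
  expect_equal(unname(a[labels == "6"]), 0.25 * 2)
})

test_that("chromatin_state builds extreme states for all variants", {
  net <- build_network(small_params())
  expect_equal(chromatin_state(net, "active")[["DA"]], 8)
  expect_equal(chromatin_state(net, "repressed")[["D12R"]], 8)
  h <- build_network(small_params(), "histone_only")
  expect_equal(chromatin_state(h, "repressed")[["D2R"]], 8)
  mr <- make_mutual_repression(small_params(px = 1))
  s <- chromatin_state(mr, "unmodified")
  expect_equal(unname(s[c("D.X", "D.Z")]), c(8, 8))
  expect_equal(sum(s), 16)
})

test_that("network JSON round-trip preserves dynamics", {
  net <- build_network(small_params(eps = 0.3))
  js <- network_to_json(net)
  net2 <- network_from_json(js)
  n <- c(D = 1, DA = 3, D1R = 1, D2R = 1, D12R = 2)
  expect_equal(propensities(net2, n), propensities(net, n))
  expect_equal(net2$species, net$species)
})
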