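# the shared coarse steady map is tabulated once per session (helper)

test_that("steady-rate map is sigmoidal and monotone in the product", {
  map <- test_steady_map()
  # silent limit: vanishing affinity leaves only spontaneous activity
  expect_lt(map$rate[1], 10)
  # monotone up to simulation noise: envelope deviation below 3 spikes/s
  expect_true(all(cummax(map$rate) - map$rate < 3))
  # spiking starts only after the product crosses a threshold
  expect_lt(max(map$rate[map$product < 1e-3]), 5)
  expect_gt(max(map$rate), 150)
})

test_that("affinity inversion is order-preserving and self-consistent", {
  map <- test_steady_map()
  r <- seq(40, 150, by = 10)
  a <- vapply(r, estimate_affinity, numeric(1), amplitude = 20, map = map)
  expect_true(all(diff(a) > 0))   # higher rate, higher affinity
  expect_error(estimate_affinity(1e4, 20, map), "outside")
  # round trip: simulate at a known affinity, re-estimate from its own rate
  a0 <- 3e-3
  w <- wave_constant(20, t_end = 5)
  tr <- osn_simulate(w, rate_pair(a0 * 10, 10), n_neurons = 10, seed = 7)
  steady <- sum(tr$time >= 4) / 10
  a_hat <- estimate_affinity(steady, 20, map)
  expect_within_factor(a_hat, a0, 2)  # the session map is deliberately coarse
})

test_that("dissociation inversion recovers a known rate pair", {
  map <- test_steady_map()
  a0 <- 3e-3; d0 <- 5
  w <- wave_step(20, t_end = 3)
  tr <- osn_simulate(w, rate_pair(a0 * d0, d0), n_neurons = 10, seed = 8)
  st <- psth_stats(compute_psth(tr), onset = 0.5)
  pm <- suppressWarnings(peak_rate_map(
    a0, 20, d_grid = 10^seq(-0.5, 1.5, length.out = 9),
    n_neurons = 10, seed = 9))
  d_hat <- suppressWarnings(
    estimate_dissociation(st$peak, a0, 20, map = pm))
  expect_within_factor(d_hat, d0, 1.6)
})

test_that("binding rate is the product of affinity and dissociation", {
  expect_equal(binding_from(4.264e-3, 3.788), 1.615e-2, tolerance = 1e-3)
  expect_equal(binding_from(0.42, 1), 0.42)
  # printed acetone rates round-trip through the affinity definition
  aff <- 2.17e-2 / 2.94
  expect_equal(binding_from(aff, 2.94), 2.17e-2)
})

test_that("affinity-matrix estimation recovers synthetic ground truth", {
  map <- test_steady_map()
  fx <- synth_count_matrix(n_receptors = 6, n_odorants = 10,
                           amplitude = 100, map = map, seed = 3)
  est <- estimate_affinity_matrix(fx$counts, amplitude = 100, map = map)
  expect_equal(nrow(est), 60)
  ok <- !est$flagged
  expect_gt(sum(ok), 40)
  expect_gt(cor(log10(est$affinity[ok]), log10(fx$truth$affinity[ok]),
                method = "spearman"), 0.99)
  # zero-count entries clamp to the floor affinity and are flagged
  zc <- fx$counts
  zc$count[1] <- 0
  est0 <- estimate_affinity_matrix(zc, amplitude = 100, map = map)
  expect_true(est0$flagged[1])
  # floor: no unflagged estimate sits below the silent-entry affinity
  expect_lte(est0$affinity[1], min(est0$affinity[!est0$flagged]))
})

test_that("matrix input as a labelled matrix keeps its labels", {
  map <- test_steady_map()
  m <- matrix(c(50, 80, 20, 120), 2, 2,
              dimnames = list(c("Or59b", "Or7a"), c("acetone", "butanone")))
  est <- estimate_affinity_matrix(m, amplitude = 100, map = map)
  expect_setequal(unique(est$receptor), c("Or59b", "Or7a"))
  expect_equal(nrow(est), 4)
})
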