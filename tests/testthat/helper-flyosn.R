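# shared fixtures for the test suite; everything is generated in code

acetone_rates <- function() rate_pair(2.17e-2, 2.94)

# coarse steady map shared by the estimation tests (cached per session)
.test_cache <- new.env(parent = emptyenv())

test_steady_map <- function() {
  if (is.null(.test_cache$map)) {
    .test_cache$map <- suppressWarnings(steady_rate_map(
      amplitude = 1, affinity_grid = 10^seq(-4, 1, by = 1 / 6),
      n_neurons = 10, seed = 101
    ))
  }
  .test_cache$map
}

# sample value nearest to time x (avoids exact float matching on grids)
u_at <- function(w, x) w$u[which.min(abs(w$t - x))]

expect_within_factor <- function(value, target, factor) {
  expect_gt(value, target / factor)
  expect_lt(value, target * factor)
}
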