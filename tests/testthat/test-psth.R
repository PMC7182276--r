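fake_trains <- function(times_by_neuron, duration) {
  structure(
    tibble::tibble(
      neuron = rep(seq_along(times_by_neuron),
                   lengths(times_by_neuron)),
      time = unlist(times_by_neuron)
    ),
    n_trains = length(times_by_neuron), duration = duration
  )
}

test_that("sliding-window rates match hand-computed values", {
  # no spikes
  empty <- fake_trains(rep(list(numeric(0)), 5), duration = 1)
  expect_true(all(compute_psth(empty)$rate == 0))
  # 25 trains, one spike each inside one 20 ms window -> 50 spikes/s
  tr <- fake_trains(rep(list(0.205), 25), duration = 1)
  p <- compute_psth(tr)
  expect_equal(max(p$rate), 25 / (0.020 * 25))
  expect_error(compute_psth(fake_trains(list(), 1)), "one spike train")
})

test_that("Poisson trains recover their rate", {
  set.seed(8)
  dur <- 5; n <- 20; lambda <- 100
  trains <- fake_trains(
    lapply(seq_len(n), function(i) sort(runif(rpois(1, lambda * dur), 0, dur))),
    duration = dur)
  p <- compute_psth(trains)
  se <- sqrt(lambda / (dur * n))
  expect_lt(abs(mean(p$rate) - lambda), 3 * se)
})

test_that("non-overlapping bins conserve the total spike count", {
  set.seed(9)
  trains <- fake_trains(lapply(1:4, function(i) sort(runif(50, 0, 2))),
                        duration = 2)
  p <- compute_psth(trains, bin = 0.02, shift = 0.02)
  total <- sum(p$rate * 0.02 * 4)
  expect_equal(total, 200)
})

test_that("histogram mean squared error follows its definition", {
  tr <- fake_trains(list(c(0.1, 0.5), 0.7), duration = 1)
  a <- compute_psth(tr)
  expect_equal(psth_mse(a, a), 0)
  b <- a; b$rate <- b$rate + 3
  expect_equal(psth_mse(a, b), 9)
  # printed 3-bin toy: (10,20,30) vs (12,18,33) -> 17/3
  toy <- function(r) structure(tibble::tibble(t = 1:3, rate = r),
                               class = class(a), bin = 0.02, shift = 0.01,
                               n_trains = 1, duration = 3)
  expect_equal(psth_mse(toy(c(10, 20, 30)), toy(c(12, 18, 33))), 17 / 3)
  bad <- compute_psth(tr, bin = 0.05)
  expect_error(psth_mse(a, bad), "binning")
})

test_that("summary rates pick out spontaneous, peak and steady levels", {
  tr <- fake_trains(rep(list(numeric(0)), 2), duration = 5)
  p <- compute_psth(tr)
  s <- psth_stats(p, onset = 0.5, steady_window = c(4, 5))
  expect_equal(unlist(s), c(spontaneous = 0, peak = 0, steady = 0))
  # constant-rate train: steady == peak == rate
  reg <- fake_trains(list(seq(0.005, 4.995, by = 0.01)), duration = 5)
  pr <- compute_psth(reg)
  sr <- psth_stats(pr, onset = 0.5, steady_window = c(4, 5))
  expect_equal(sr$steady, 100, tolerance = 0.02)
  # away from the truncated edge windows the rate is flat at 100
  interior <- pr$rate[pr$t > 0.05 & pr$t < 4.95]
  expect_equal(max(interior), 100, tolerance = 0.02)
  expect_error(psth_stats(pr, steady_window = c(5.5, 6.5)), "beyond")
})
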