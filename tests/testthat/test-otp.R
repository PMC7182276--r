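test_that("default transduction parameters carry the fitted values", {
  p <- otp_params()
  expect_equal(p$alpha1, 45)
  expect_equal(p$gamma, 0.2105)
  expect_equal(p$alpha2, 146.1)
  expect_equal(p$beta2, 117.2)
  expect_equal(p$kappa, 8841)
  expect_equal(p$c, 0.06546)
  expect_equal(p$Imax, 62.13)
  expect_equal(p$feedback_power, 2 / 3)
  expect_error(otp_params(alpha2 = -1), "rate")
  expect_error(otp_params(nonsense = 1), "unknown")
  expect_error(rate_pair(1, 0), "dissociation")
})

test_that("peri-receptor filter has unit DC gain and is causal", {
  w <- wave_constant(100, t_end = 2)
  f <- otp_filter(w)
  expect_equal(f$u_filt[nrow(f)], 100, tolerance = 1e-6)
  z <- otp_filter(wave_constant(0, t_end = 1))
  expect_true(all(z$u_filt == 0))
  s <- otp_filter(wave_step(50))
  expect_true(all(s$u_filt[s$t < 0.5] == 0))           # causal
  rise <- s$u_filt[s$t >= 0.5 & s$t <= 0.56]
  expect_true(all(diff(rise) >= -1e-12))               # monotone onset
  expect_lt(max(s$u_filt), 50 * 1.05)                  # mild ringing only
})

test_that("concentration profile mixes concentration and gradient", {
  w <- wave_constant(80, t_end = 2)
  v <- otp_profile(w)
  expect_equal(v$v[nrow(v)], 80, tolerance = 1e-5)
  # gamma = 0 ablation reduces to the filtered concentration
  s <- wave_step(50)
  expect_equal(otp_profile(s, otp_params(gamma = 0))$v,
               pmax(otp_filter(s)$u_filt, 0), tolerance = 1e-12)
  # upward staircase jump overshoots the new tread
  st <- wave_staircase(data.frame(amplitude = c(0, 40, 60),
                                  duration = c(1, 2, 2)))
  pv <- otp_profile(st)
  expect_gt(max(pv$v[pv$t > 3 & pv$t < 3.5]), 60)
  expect_lt(abs(pv$v[which.min(abs(pv$t - 4.9))] - 60), 1)
})

test_that("cascade integration respects fixed points and the Hill form", {
  w0 <- wave_constant(0, t_end = 1)
  tr <- otp_integrate(w0, acetone_rates())
  expect_true(all(tr$x1 == 0 & tr$x2 == 0 & tr$x3 == 0 & tr$I == 0))
  # b = 0: bound fraction decays regardless of stimulus
  tr2 <- otp_integrate(wave_constant(100, t_end = 4), rate_pair(0, 2),
                       init = c(0.8, 0, 0))
  expect_lt(tail(tr2$x1, 1), 1e-3)
  expect_true(all(diff(tr2$x1) <= 1e-12))
  # transduction current is the Hill function of x2 (half activation at c)
  p <- otp_params()
  tr3 <- otp_integrate(wave_constant(100, t_end = 2), acetone_rates(), p)
  expect_equal(tr3$I, tr3$x2 / (tr3$x2 + p$c) * p$Imax, tolerance = 1e-12)
})

test_that("bound-receptor equilibrium matches the closed form", {
  # printed rates: b = 2.17e-2 (ppm s)^-1, d = 2.94 s^-1, v = 100 ppm
  ss <- otp_steady_state(100, acetone_rates())
  expect_equal(ss$x1, 2.17 / (2.17 + 2.94), tolerance = 1e-12)
  expect_equal(ss$x1, 0.4247, tolerance = 1e-4)
  expect_equal(otp_steady_state(0, acetone_rates())$I, 0)
  # long-horizon integration converges to the steady state
  tr <- otp_integrate(wave_constant(100, t_end = 10), acetone_rates())
  expect_equal(tail(tr$x1, 1), ss$x1, tolerance = 1e-6)
  expect_equal(tail(tr$x2, 1), ss$x2, tolerance = 1e-6)
})

test_that("equilibrium oracle agrees with integration over random draws", {
  set.seed(42)
  for (i in 1:20) {
    b <- 10^runif(1, -3, -0.5)
    d <- 10^runif(1, 0, 1)
    v <- 10^runif(1, 1, 2.5)
    rates <- rate_pair(b, d)
    ss <- otp_steady_state(v, rates)
    tr <- otp_integrate(wave_constant(v, t_end = 12), rates)
    expect_equal(tail(tr$x1, 1), ss$x1, tolerance = 1e-4)
    expect_equal(tail(tr$x2, 1), ss$x2, tolerance = 1e-4)
    expect_equal(tail(tr$I, 1), ss$I, tolerance = 1e-4)
  }
})

test_that("steady-state current is nondecreasing in affinity x amplitude", {
  prod_grid <- 10^seq(-3, 2, by = 0.25)
  I <- vapply(prod_grid, function(pr)
    otp_steady_state(pr / 1e-2, rate_pair(1e-2 * 5, 5))$I, numeric(1))
  expect_true(all(diff(I) >= -1e-12))
})

test_that("state bounds hold across randomized stimuli and parameters", {
  set.seed(99)
  for (i in 1:30) {
    w <- switch(sample(3, 1),
      wave_step(runif(1, 1, 200), dt = 5e-4),
      wave_staircase(data.frame(amplitude = runif(3, 0, 150),
                                duration = c(1, 1, 1)), dt = 5e-4),
      wave_white_noise(mean = runif(1, 20, 80), sd = runif(1, 5, 30),
                       t_end = 3, dt = 5e-4, seed = i))
    rates <- rate_pair(10^runif(1, -3, 0), 10^runif(1, -0.5, 1.5))
    tr <- suppressWarnings(otp_integrate(w, rates))
    expect_true(all(tr$x1 >= 0 & tr$x1 <= 1))
    expect_true(all(tr$x2 >= 0 & tr$x2 <= 1))
    expect_true(all(tr$x3 >= 0))
    expect_true(all(tr$I >= 0 & tr$I <= otp_params()$Imax))
    expect_true(all(tr$v >= 0))
  }
})

test_that("trajectories are invariant under (k b, u / k) rescaling", {
  wn <- wave_white_noise(mean = 0.6, sd = 0.2, bandwidth = 20,
                        t_end = 2, seed = 5)
  # the paper's instance: one waveform scaled by 100 with b, by 10 with 10 b
  w100 <- as_odor_waveform(wn$t, wn$u * 100)
  w10 <- as_odor_waveform(wn$t, wn$u * 10)
  t1 <- otp_integrate(w100, rate_pair(2.17e-2, 2.94))
  t2 <- otp_integrate(w10, rate_pair(2.17e-1, 2.94))
  expect_lt(max(abs(t1$I - t2$I)), 1e-10)
  expect_lt(max(abs(t1$x1 - t2$x1)), 1e-10)
})
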