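test_that("pulse families evaluate to their closed forms", {
  # step: plateau on [0.5, 2.5]
  s <- wave_step(100)
  expect_equal(u_at(s, 1.0), 100)
  expect_equal(u_at(s, 0.4), 0)
  expect_true(all(wave_step(0)$u == 0))

  # ramp: rise slope c/1.8, fast fall
  r <- wave_ramp(100)
  expect_equal(u_at(r, 1.0), 100 * 0.5 / 1.8, tolerance = 1e-6)
  expect_equal(max(r$u), 100, tolerance = 1e-3)  # limit of the rise at 2.3-
  expect_equal(u_at(r, 0.49), 0)

  # parabola: quadratic rise, (0.95/1.9)^2 at t = 1.45
  p <- wave_parabola(100)
  expect_equal(u_at(p, 1.45), 25, tolerance = 1e-6)
  expect_equal(max(p$u), 100, tolerance = 2e-3)  # limit of the rise at 2.4-
  expect_equal(u_at(p, 0.5), 0)
})

test_that("pulse families reject invalid arguments", {
  expect_error(wave_step(100, dt = 0), "dt")
  expect_error(wave_step(100, t_end = 2), "t_end")
  expect_error(wave_ramp(-1), "amplitude")
})

test_that("amplitude sweep attains max(u) = c for all three families", {
  for (c_amp in seq(1, 101, by = 5)) {
    expect_equal(max(wave_step(c_amp, dt = 1e-3)$u), c_amp)
    expect_equal(max(wave_ramp(c_amp, dt = 1e-3)$u), c_amp, tolerance = 1e-2)
    expect_equal(max(wave_parabola(c_amp, dt = 1e-3)$u), c_amp,
                 tolerance = 2e-2)
  }
})

test_that("staircase holds treads and rejects negative dwell times", {
  w <- wave_staircase(data.frame(amplitude = c(0, 20, 40),
                                 duration = c(1, 2, 2)))
  expect_equal(u_at(w, 2.0), 20)
  expect_true(all(wave_staircase(data.frame(amplitude = 0,
                                            duration = 1))$u == 0))
  expect_error(wave_staircase(data.frame(amplitude = 1, duration = -1)),
               "dwell")
  # the default staircase visits the 80 and 100 ppm treads
  def <- wave_staircase()
  expect_true(all(c(80, 100) %in% unique(def$u)))
})

test_that("triangular set has the documented count and geometry", {
  tris <- wave_triangles()
  expect_length(tris, 110)
  one <- wave_triangle(10, 2)
  expect_equal(max(one$u), 10, tolerance = 1e-2)
  expect_equal(one$t[which.max(one$u)], 0.5 + 1, tolerance = 2e-3)
  slopes <- unique(round(one$du[one$du != 0], 9))
  expect_setequal(slopes, c(10, -10))  # +-peak/(dur/2)
  expect_error(wave_triangles(peaks = numeric(0)), "empty")
})

test_that("white noise is reproducible, band-limited around its mean", {
  w0 <- wave_white_noise(mean = 50, sd = 0, t_end = 3)
  expect_true(all(w0$u == 50))
  wa <- wave_white_noise(seed = 7)
  wb <- wave_white_noise(seed = 7)
  expect_identical(wa$u, wb$u)
  # sample mean within 3 s.e. (effective n ~ 2 * bandwidth * t_end)
  w <- wave_white_noise(mean = 50, sd = 15, bandwidth = 30, t_end = 10,
                        seed = 3)
  se <- 15 / sqrt(2 * 30 * 10)
  expect_lt(abs(mean(w$u) - 50), 3 * se)
})

test_that("gradients match analytic slopes and integrate back to u", {
  r <- wave_ramp(100)
  g <- wave_gradient(r)
  expect_equal(unique(g$du[r$t > 0.6 & r$t < 2.2]), 100 / 1.8,
               tolerance = 1e-10)
  s <- wave_step(100)
  expect_equal(unique(wave_gradient(s)$du[s$t > 0.6 & s$t < 2.4]), 0)
  cw <- wave_constant(5, t_end = 3)
  expect_true(all(wave_gradient(cw)$du == 0))
  # finite-difference gradient integrates to u(T) - u(0)
  for (w in list(wave_ramp(50), wave_parabola(50),
                 wave_white_noise(seed = 2, t_end = 3))) {
    du <- wave_gradient(w, "finite")$du
    dt <- attr(w, "dt")
    integral <- sum(du[-length(du)] + du[-1]) / 2 * dt
    expect_equal(integral, w$u[nrow(w)] - w$u[1], tolerance = 1e-6 +
                   2 * dt * max(abs(du)))
  }
  expect_error(as_odor_waveform(0, 1), "two samples")
})

test_that("waveform CSV round-trips", {
  w <- wave_ramp(30, dt = 1e-3)
  f <- withr::local_tempfile(fileext = ".csv")
  write_waveform(w, f)
  w2 <- read_waveform(f)
  expect_equal(w2$u, w$u, tolerance = 1e-8)
})
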