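#' Odorant concentration waveforms
#'
#' An `odor_waveform` is a tibble with columns `t` (seconds, uniform grid),
#' `u` (odorant concentration, ppm) and `du` (concentration gradient,
#' ppm/s). For the piecewise-polynomial families (`step`, `ramp`,
#' `parabola`, `staircase`, `triangle`) `du` holds the analytic slope, with
#' jump discontinuities represented as one-sample rectangular pulses whose
#' area equals the jump (the distributional derivative sampled on the
#' grid); for stochastic or custom waveforms it holds central finite
#' differences. The sampling step, family tag and family parameters are
#' stored as attributes.
#'
#' @param t,u,du Time grid (s), concentration (ppm) and gradient (ppm/s).
#' @param family Family tag.
#' @param params Named list of family parameters.
#' @return A tibble of class `odor_waveform`.
#' @keywords internal
new_odor_waveform <- function(t, u, du, family, params = list()) {
  if (length(t) < 2L) abort("a waveform needs at least two samples")
  dt <- diff(t)
  if (any(dt <= 0) || max(abs(dt - dt[1])) > 1e-12 * max(dt[1], 1))
    abort("time grid must be strictly increasing with constant step")
  if (!all(is.finite(u))) abort("concentration samples must be finite")
  out <- tibble::tibble(t = t, u = u, du = du)
  structure(out,
    class = c("odor_waveform", class(out)),
    dt = dt[1], family = family, params = params
  )
}

wave_grid <- function(t_end, dt) {
  if (!is.numeric(dt) || dt <= 0) abort("`dt` must be positive")
  seq(0, t_end, by = dt)
}

#' @export
print.odor_waveform <- function(x, ...) {
  cat(sprintf("<odor_waveform: %s, dt = %g s, %d samples, max u = %.3g ppm>\n",
              attr(x, "family"), attr(x, "dt"), nrow(x), max(x$u)))
  NextMethod()
}

#' Step, ramp and parabola odorant waveforms
#'
#' The three deterministic pulse families used for I/O characterisation of
#' the transduction cascade. All three are supported on `[0.5, 2.5]` s:
#' * step: `u = c` on `[0.5, 2.5]`;
#' * ramp: linear rise `c*(t - 0.5)/1.8` on `[0.5, 2.3)`, fast linear fall
#'   `c*(1 - 5*(t - 2.3))` on `[2.3, 2.5)`;
#' * parabola: quadratic rise `c*((t - 0.5)/1.9)^2` on `[0.5, 2.4)`,
#'   quadratic fall `c*(1 - 10*(t - 2.4))^2` on `[2.4, 2.5)`.
#'
#' @param amplitude Plateau/peak concentration `c`, ppm (>= 0).
#' @param t_end Trace duration, s (>= 3 so the response tail is visible).
#' @param dt Sampling step, s. The default (1e-4) resolves the fastest
#'   transduction rates.
#' @return An [new_odor_waveform()] tibble.
#' @examples
#' w <- wave_step(100)
#' w$u[w$t == 1] # 100
#' @export
wave_step <- function(amplitude, t_end = 3, dt = 1e-4) {
  check_pulse_args(amplitude, t_end, dt)
  t <- wave_grid(t_end, dt)
  u <- ifelse(t >= 0.5 & t <= 2.5, amplitude, 0)
  du <- numeric(length(t))
  du[delta_index(t, 0.5)] <- amplitude / dt
  du[delta_index(t, 2.5 + dt / 2)] <- -amplitude / dt
  new_odor_waveform(t, u, du, "step", list(amplitude = amplitude))
}

#' @rdname wave_step
#' @export
wave_ramp <- function(amplitude, t_end = 3, dt = 1e-4) {
  check_pulse_args(amplitude, t_end, dt)
  t <- wave_grid(t_end, dt)
  u <- rep(0, length(t)); du <- rep(0, length(t))
  rise <- t >= 0.5 & t < 2.3
  fall <- t >= 2.3 & t < 2.5
  u[rise] <- amplitude * (t[rise] - 0.5) / 1.8
  du[rise] <- amplitude / 1.8
  u[fall] <- amplitude * (1 - 5 * (t[fall] - 2.3))
  du[fall] <- -5 * amplitude
  new_odor_waveform(t, u, du, "ramp", list(amplitude = amplitude))
}

#' @rdname wave_step
#' @export
wave_parabola <- function(amplitude, t_end = 3, dt = 1e-4) {
  check_pulse_args(amplitude, t_end, dt)
  t <- wave_grid(t_end, dt)
  u <- rep(0, length(t)); du <- rep(0, length(t))
  rise <- t >= 0.5 & t < 2.4
  fall <- t >= 2.4 & t < 2.5
  u[rise] <- amplitude * ((t[rise] - 0.5) / 1.9)^2
  du[rise] <- 2 * amplitude * (t[rise] - 0.5) / 1.9^2
  u[fall] <- amplitude * (1 - 10 * (t[fall] - 2.4))^2
  du[fall] <- -20 * amplitude * (1 - 10 * (t[fall] - 2.4))
  new_odor_waveform(t, u, du, "parabola", list(amplitude = amplitude))
}

check_pulse_args <- function(amplitude, t_end, dt) {
  if (!is.numeric(amplitude) || amplitude < 0) abort("`amplitude` must be >= 0")
  if (!is.numeric(dt) || dt <= 0) abort("`dt` must be positive")
  if (!is.numeric(t_end) || t_end < 3) abort("`t_end` must be >= 3 s")
  invisible(NULL)
}

delta_index <- function(t, at) which(t >= at)[1]

#' Constant odorant waveform
#'
#' A constant concentration held for the whole trace, used for
#' steady-state characterisation (the settled rate is conventionally
#' measured on the 4-5 s window of a 5-s constant stimulus).
#'
#' @param amplitude Concentration, ppm (>= 0).
#' @param t_end Duration, s.
#' @param dt Sampling step, s.
#' @return An [new_odor_waveform()] tibble.
#' @export
wave_constant <- function(amplitude, t_end = 5, dt = 1e-4) {
  if (amplitude < 0) abort("`amplitude` must be >= 0")
  t <- wave_grid(t_end, dt)
  new_odor_waveform(t, rep(amplitude, length(t)), rep(0, length(t)),
                    "constant", list(amplitude = amplitude))
}

#' Piecewise-constant (staircase) odorant waveform
#'
#' @param levels A data frame (or tibble) with columns `amplitude` (ppm)
#'   and `duration` (s), one row per tread, in order. The default is a
#'   2-s-per-tread staircase rising 0, 20, ..., 100 ppm and returning to 0,
#'   so the 80 -> 100 ppm jump falls at 10 s.
#' @param dt Sampling step, s.
#' @return An [new_odor_waveform()] tibble; jumps contribute one-sample
#'   gradient pulses of area equal to the jump.
#' @export
wave_staircase <- function(levels = staircase_default_levels(), dt = 1e-4) {
  levels <- tibble::as_tibble(levels)
  if (nrow(levels) == 0) abort("`levels` must be non-empty")
  if (any(levels$duration < 0)) abort("dwell times must be >= 0")
  if (any(levels$amplitude < 0)) abort("amplitudes must be >= 0")
  t_end <- sum(levels$duration)
  t <- wave_grid(t_end, dt)
  edges <- cumsum(levels$duration)
  idx <- findInterval(t, c(0, edges[-length(edges)]), rightmost.closed = FALSE)
  u <- levels$amplitude[pmin(idx, nrow(levels))]
  du <- numeric(length(t))
  amp <- levels$amplitude
  for (j in seq_along(edges)[-length(edges)]) {
    jump <- amp[j + 1] - amp[j]
    if (jump != 0) du[delta_index(t, edges[j])] <- jump / dt
  }
  new_odor_waveform(t, u, du, "staircase", list(levels = levels))
}

#' @rdname wave_staircase
#' @export
staircase_default_levels <- function() {
  tibble::tibble(
    amplitude = c(0, 20, 40, 60, 80, 100, 0),
    duration  = c(2, 2, 2, 2, 2, 2, 2)
  )
}

#' Triangular odorant waveform set
#'
#' Symmetric rise/fall triangles over a peak-by-duration grid; the default
#' grid of 10 peaks by 11 durations yields the 110-waveform set used to map
#' the concentration/concentration-gradient encoding plane. Only the count
#' of that set is documented, so the grid itself is a package default.
#'
#' @param peaks Peak concentrations, ppm.
#' @param durations Triangle base durations, s.
#' @param dt Sampling step, s.
#' @param t_start Onset time, s.
#' @param tail Zero padding after the triangle, s.
#' @return A list of [new_odor_waveform()] tibbles, one per (peak,
#'   duration) combination (columns of the grid vary fastest in duration).
#' @export
wave_triangles <- function(peaks = seq(10, 100, by = 10),
                           durations = seq(0.3, 2.3, by = 0.2),
                           dt = 1e-3, t_start = 0.5, tail = 0.5) {
  if (length(peaks) == 0 || length(durations) == 0) abort("empty grid")
  if (any(peaks <= 0) || any(durations <= 0))
    abort("peaks and durations must be positive")
  grid <- tidyr::expand_grid(peak = peaks, duration = durations)
  purrr::pmap(grid, function(peak, duration) {
    wave_triangle(peak, duration, dt = dt, t_start = t_start, tail = tail)
  })
}

#' @rdname wave_triangles
#' @param peak,duration Single triangle peak (ppm) and base duration (s).
#' @export
wave_triangle <- function(peak, duration, dt = 1e-3, t_start = 0.5,
                          tail = 0.5) {
  t <- wave_grid(t_start + duration + tail, dt)
  mid <- t_start + duration / 2
  u <- rep(0, length(t)); du <- rep(0, length(t))
  rise <- t >= t_start & t < mid
  fall <- t >= mid & t < t_start + duration
  slope <- 2 * peak / duration
  u[rise] <- slope * (t[rise] - t_start)
  du[rise] <- slope
  u[fall] <- peak - slope * (t[fall] - mid)
  du[fall] <- -slope
  new_odor_waveform(t, u, du, "triangle",
                    list(peak = peak, duration = duration))
}

#' Band-limited Gaussian white-noise odorant waveform
#'
#' Gaussian samples drawn at the Nyquist spacing of the requested bandwidth
#' and spline-interpolated onto the fine grid, rescaled to the requested
#' mean and standard deviation, then clipped at zero to keep concentrations
#' physical. The recorded waveform this family stands in for is not
#' published, so the statistics are free parameters.
#'
#' @param mean,sd Target mean and standard deviation, ppm (before
#'   clipping).
#' @param bandwidth Approximate bandwidth, Hz.
#' @param t_end Duration, s.
#' @param dt Sampling step, s.
#' @param seed Integer seed; the same seed reproduces the waveform exactly.
#' @return An [new_odor_waveform()] tibble (`du` from central finite
#'   differences).
#' @export
wave_white_noise <- function(mean = 50, sd = 15, bandwidth = 30,
                             t_end = 10, dt = 1e-4, seed = 1L) {
  if (sd < 0) abort("`sd` must be >= 0")
  if (bandwidth <= 0) abort("`bandwidth` must be positive")
  t <- wave_grid(t_end, dt)
  if (sd == 0) {
    u <- rep(mean, length(t))
  } else {
    step <- 1 / (2 * bandwidth)
    tc <- seq(-2 * step, t_end + 2 * step, by = step)
    z <- withr_seed(seed, rnorm(length(tc)))
    u <- spline(tc, z, xout = t)$y
    u <- mean + (u - base::mean(u)) / stats::sd(u) * sd
    u <- pmax(u, 0)
  }
  du <- finite_diff(u, dt)
  new_odor_waveform(t, u, du, "white_noise",
                    list(mean = mean, sd = sd, bandwidth = bandwidth,
                         seed = seed))
}

# evaluate expr under a local RNG state seeded with `seed`
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

finite_diff <- function(u, dt) {
  n <- length(u)
  if (n < 2) abort("gradient needs at least two samples")
  du <- numeric(n)
  du[1] <- (u[2] - u[1]) / dt
  du[n] <- (u[n] - u[n - 1]) / dt
  if (n > 2) du[2:(n - 1)] <- (u[3:n] - u[1:(n - 2)]) / (2 * dt)
  du
}

#' Concentration gradient of a waveform
#'
#' @param w An `odor_waveform`.
#' @param method `"stored"` uses the gradient column built with the
#'   waveform (analytic slopes for the polynomial families, including
#'   one-sample pulses of area equal to any jump); `"finite"` recomputes
#'   central finite differences from `u` (one-sided at the ends).
#' @return A tibble with columns `t` and `du` (ppm/s).
#' @export
wave_gradient <- function(w, method = c("stored", "finite")) {
  method <- match.arg(method)
  stopifnot(inherits(w, "odor_waveform"))
  du <- switch(method,
    stored = w$du,
    finite = finite_diff(w$u, attr(w, "dt"))
  )
  tibble::tibble(t = w$t, du = du)
}

#' Build a waveform from arbitrary samples
#'
#' @param t,u Time grid (s) and concentration samples (ppm).
#' @param family Family tag (default `"custom"`).
#' @return An [new_odor_waveform()] tibble with finite-difference gradient.
#' @export
as_odor_waveform <- function(t, u, family = "custom") {
  dt <- t[2] - t[1]
  new_odor_waveform(t, u, finite_diff(u, dt), family)
}

#' Read and write waveform CSV files
#'
#' The on-disk format is a two-column CSV `time_s, u_ppm`.
#'
#' @param w An `odor_waveform`.
#' @param path File path.
#' @return `read_waveform()` returns an `odor_waveform`;
#'   `write_waveform()` returns `path` invisibly.
#' @export
write_waveform <- function(w, path) {
  utils::write.csv(
    data.frame(time_s = w$t, u_ppm = w$u),
    path, row.names = FALSE
  )
  invisible(path)
}

#' @rdname write_waveform
#' @export
read_waveform <- function(path) {
  d <- utils::read.csv(path)
  as_odor_waveform(d$time_s, d$u_ppm)
}
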