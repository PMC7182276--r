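#' Transduction-model parameters
#'
#' The eleven parameters shared by all odorant-receptor pairs, plus the
#' calcium-feedback exponent. Defaults are the fitted values for the
#' acetone/Or59b cascade:
#'
#' * `alpha1` (s^-1): cutoff frequency of the peri-receptor low-pass filter;
#' * `beta1` (unitless): damping, i.e. the slope of the filter transition;
#' * `gamma` (s): weight of the filtered concentration gradient;
#' * `alpha2`, `beta2` (s^-1): co-receptor channel activation/deactivation;
#' * `alpha3`, `beta3` (s^-1): calcium channel increase/decrease rates;
#' * `kappa` (s^-1): calcium-feedback strength;
#' * `c` (unitless): half-activation of the transduction current;
#' * `p` (unitless): Hill coefficient of the transduction current;
#' * `Imax` (pA): maximal transduction current;
#' * `feedback_power`: exponent applied to both gating variables in the
#'   calcium-feedback product (2/3 by default).
#'
#' @param ... Named overrides of the defaults.
#' @return A named list of class `otp_params`.
#' @export
otp_params <- function(...) {
  p <- list(
    alpha1 = 4.500e1, beta1 = 8.000e-1, gamma = 2.105e-1,
    alpha2 = 1.461e2, beta2 = 1.172e2,
    alpha3 = 2.539e0, beta3 = 9.096e-1,
    kappa = 8.841e3, c = 6.546e-2, p = 1, Imax = 6.213e1,
    feedback_power = 2 / 3
  )
  dots <- list(...)
  bad <- setdiff(names(dots), names(p))
  if (length(bad)) abort(paste0("unknown parameter(s): ",
                                paste(bad, collapse = ", ")))
  p[names(dots)] <- dots
  rates <- c("alpha1", "alpha2", "beta2", "alpha3", "beta3", "kappa")
  if (any(unlist(p[rates]) <= 0)) abort("all rate parameters must be > 0")
  if (p$c <= 0 || p$Imax <= 0) abort("`c` and `Imax` must be > 0")
  if (p$p < 1) abort("Hill coefficient `p` must be >= 1")
  structure(p, class = "otp_params")
}

#' Odorant-receptor binding and dissociation rates
#'
#' @param b Binding rate, (ppm s)^-1 (>= 0).
#' @param d Dissociation rate, s^-1 (> 0).
#' @return A list of class `rate_pair` with elements `b`, `d` and the
#'   derived `affinity = b/d` (ppm^-1).
#' @examples
#' rate_pair(2.17e-2, 2.94) # acetone / Or59b
#' @export
rate_pair <- function(b, d) {
  if (b < 0) abort("binding rate `b` must be >= 0")
  if (d <= 0) abort("dissociation rate `d` must be > 0")
  structure(list(b = b, d = d, affinity = b / d), class = "rate_pair")
}

#' @export
print.rate_pair <- function(x, ...) {
  cat(sprintf("<rate_pair: b = %.4g (ppm s)^-1, d = %.4g s^-1, affinity = %.4g ppm^-1>\n",
              x$b, x$d, x$affinity))
  invisible(x)
}

# filter w (= u + gamma*du) through the unit-DC-gain second-order low-pass
# y'' + 2*beta1*alpha1*y' + alpha1^2*y = alpha1^2*w, returning max(y, 0) if
# rectify. Reuses the compiled cascade integrator with inert kinetics.
second_order_lowpass <- function(w, dt, alpha1, beta1) {
  pars <- list(alpha1 = alpha1, beta1 = beta1, alpha2 = 1, beta2 = 1,
               alpha3 = 1, beta3 = 1, kappa = 0, c = 1, p = 1, Imax = 1)
  out <- cpp_otp_integrate(w, dt, pars, 0, 1, 1, c(0, 0, 0))
  out[, 1]
}

#' Peri-receptor filter response
#'
#' Applies the peri-receptor low-pass filter (a causal second-order system
#' with unit DC gain, natural frequency `alpha1` and damping `beta1`) to
#' the concentration waveform alone, without the gradient term.
#'
#' @param w An `odor_waveform`.
#' @param params An [otp_params()] list.
#' @return A tibble with columns `t` and `u_filt` (ppm).
#' @export
otp_filter <- function(w, params = otp_params()) {
  stopifnot(inherits(w, "odor_waveform"))
  tibble::tibble(
    t = w$t,
    u_filt = second_order_lowpass(w$u, attr(w, "dt"),
                                  params$alpha1, params$beta1)
  )
}

#' Odorant concentration profile
#'
#' The rectified weighted sum of the filtered concentration and the
#' filtered concentration gradient,
#' `v = max(0, h*u + gamma * h*(du/dt))`. With `gamma = 0` the gradient
#' channel is ablated and `v` is the filtered concentration alone.
#'
#' @inheritParams otp_filter
#' @param gradient Passed to [wave_gradient()].
#' @return A tibble with columns `t` and `v` (ppm).
#' @export
otp_profile <- function(w, params = otp_params(),
                        gradient = c("stored", "finite")) {
  stopifnot(inherits(w, "odor_waveform"))
  du <- wave_gradient(w, match.arg(gradient))$du
  y <- second_order_lowpass(w$u + params$gamma * du, attr(w, "dt"),
                            params$alpha1, params$beta1)
  tibble::tibble(t = w$t, v = pmax(y, 0))
}

#' Integrate the odorant transduction cascade
#'
#' Fixed-step fourth-order Runge-Kutta integration of the transduction
#' states driven by the concentration profile of `w`: the bound-receptor
#' ratio `x1`, the co-receptor channel gating variable `x2` and the
#' calcium gating variable `x3`, with the Hill-type transduction current
#' `I = x2^p / (x2^p + c^p) * Imax`. Fractional powers in the calcium
#' feedback are evaluated on the non-negative clamp of the state, and
#' every step is projected back onto the invariant set (`x1, x2` in
#' `[0, 1]`, `x3 >= 0`); pre-projection excursions beyond 1e-4 raise a
#' warning suggesting a smaller step.
#'
#' @param w An `odor_waveform`.
#' @param rates A [rate_pair()].
#' @param params An [otp_params()] list.
#' @param init Initial `(x1, x2, x3)`; the default all-zero state is the
#'   resting fixed point in the absence of odorant.
#' @param gradient Passed to [wave_gradient()].
#' @return A tibble of class `otp_trajectory` with columns `t`, `v`, `x1`,
#'   `x2`, `x3`, `I`.
#' @export
otp_integrate <- function(w, rates, params = otp_params(),
                          init = c(0, 0, 0),
                          gradient = c("stored", "finite")) {
  stopifnot(inherits(w, "odor_waveform"), inherits(rates, "rate_pair"))
  du <- wave_gradient(w, match.arg(gradient))$du
  win <- w$u + params$gamma * du
  m <- cpp_otp_integrate(win, attr(w, "dt"), unclass(params),
                         rates$b, rates$d, params$feedback_power, init)
  if (attr(m, "excursion") > 1e-4)
    warn(sprintf(
      "state excursion %.2g beyond [0, 1] before projection; consider a smaller dt",
      attr(m, "excursion")))
  out <- tibble::tibble(t = w$t, v = m[, 1], x1 = m[, 2], x2 = m[, 3],
                        x3 = m[, 4], I = m[, 5])
  structure(out, class = c("otp_trajectory", class(out)),
            dt = attr(w, "dt"), rates = rates, params = params)
}

#' Steady state of the transduction cascade
#'
#' Closed-form/rootfinding solution of the transduction equilibrium under
#' a constant concentration profile `v`:
#' `x1* = b v / (b v + d)`, `x3* = (alpha3/beta3) x2*`, and `x2*` the root
#' in `[0, 1]` of
#' `alpha2 x1* (1 - x2) - beta2 x2 - kappa x2^q ((alpha3/beta3) x2)^q = 0`
#' (`q` the feedback exponent), with the transduction current from the
#' Hill nonlinearity. Serves as an independent oracle for the long-time
#' limit of [otp_integrate()].
#'
#' @param v Constant concentration profile, ppm (>= 0).
#' @param rates A [rate_pair()].
#' @param params An [otp_params()] list.
#' @return A one-row tibble with columns `x1`, `x2`, `x3`, `I`.
#' @export
otp_steady_state <- function(v, rates, params = otp_params()) {
  stopifnot(inherits(rates, "rate_pair"))
  if (v < 0) abort("`v` must be >= 0")
  if (v == 0 || rates$b == 0)
    return(tibble::tibble(x1 = 0, x2 = 0, x3 = 0, I = 0))
  x1 <- rates$b * v / (rates$b * v + rates$d)
  q <- params$feedback_power
  r3 <- params$alpha3 / params$beta3
  f <- function(x2) {
    params$alpha2 * x1 * (1 - x2) - params$beta2 * x2 -
      params$kappa * x2^q * (r3 * x2)^q
  }
  root <- uniroot(f, c(0, 1), tol = 1e-14)
  if (abs(f(root$root)) > 1e-6)
    abort("steady-state root finding did not converge")
  x2 <- root$root
  I <- x2^params$p / (x2^params$p + params$c^params$p) * params$Imax
  tibble::tibble(x1 = x1, x2 = x2, x3 = r3 * x2, I = I)
}

#' Write a transduction trajectory to CSV
#'
#' Columns `t, v, x1, x2, x3, I`.
#'
#' @param traj An `otp_trajectory`.
#' @param path File path.
#' @export
write_trajectory <- function(traj, path) {
  utils::write.csv(as.data.frame(traj), path, row.names = FALSE)
  invisible(path)
}
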