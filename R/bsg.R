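#' Biophysical spike generator parameters
#'
#' Connor-Stevens point neuron (type I excitability: continuous f-I curve
#' from zero, sustaining rates beyond 300 spikes/s). Conductance densities
#' and reversal potentials are the canonical Connor-Stevens set; two
#' calibration constants couple the neuron to the transduction cascade:
#'
#' * `current_gain` ((uA/cm2)/pA): maps the transduction current onto
#'   membrane current density; calibrated so the f-I curve spans 0 to
#'   > 300 spikes/s over the admissible transduction-current range
#'   (0-62.13 pA);
#' * `sigma` (uA/cm2 sqrt(ms)): amplitude of the Brownian current term,
#'   calibrated for a spontaneous rate in the low single digits.
#'
#' @param ... Named overrides: `C` (uF/cm2), `gNa`, `gK`, `gA`, `gL`
#'   (mS/cm2), `ENa`, `EK`, `EA`, `EL` (mV), `sigma`, `current_gain`,
#'   `dt` (s, Euler-Maruyama step), `v0` (mV, initial potential).
#' @return A named list of class `bsg_params`.
#' @export
bsg_params <- function(...) {
  p <- list(
    C = 1, gNa = 120, ENa = 55, gK = 20, EK = -72,
    gA = 47.7, EA = -75, gL = 0.3, EL = -17,
    sigma = 1.3, current_gain = 3.0,
    dt = 1e-5, v0 = -68
  )
  dots <- list(...)
  bad <- setdiff(names(dots), names(p))
  if (length(bad)) abort(paste0("unknown parameter(s): ",
                                paste(bad, collapse = ", ")))
  p[names(dots)] <- dots
  if (any(unlist(p[c("gNa", "gK", "gA", "gL")]) < 0))
    abort("conductances must be >= 0")
  if (p$sigma < 0) abort("`sigma` must be >= 0")
  if (p$dt <= 0) abort("`dt` must be positive")
  structure(p, class = "bsg_params")
}

new_spike_train <- function(times, duration, neuron = 1L, seed = NA_integer_) {
  structure(
    tibble::tibble(time = times),
    class = c("spike_train", class(tibble::tibble())),
    duration = duration, neuron = neuron, seed = seed
  )
}

#' Simulate the spike generator for a given current trace
#'
#' Euler-Maruyama integration of the Connor-Stevens equations (exponential
#' Euler on the gating variables) driven by the transduction current plus
#' the Brownian term. Spikes are upward crossings of 0 mV with a 2 ms
#' lockout.
#'
#' @param current Either an `otp_trajectory` (its `I` column is used) or a
#'   tibble/data frame with columns `t` (s) and `I` (pA) on a uniform grid.
#' @param params A [bsg_params()] list.
#' @param seed Integer seed for the Brownian term (ignored when
#'   `sigma = 0`).
#' @param return_v Also return the membrane-potential trace (decimated to
#'   ~ 0.1 ms)?
#' @return A `spike_train` tibble (column `time`, s) with the trace
#'   duration as an attribute; with `return_v`, the trace is attached as
#'   attribute `v` (tibble `t`, `v_mV`).
#' @export
bsg_simulate <- function(current, params = bsg_params(), seed = 1L,
                         return_v = FALSE) {
  stopifnot(all(c("t", "I") %in% names(current)))
  if (!all(is.finite(current$I))) abort("current trace must be finite")
  dt_in <- current$t[2] - current$t[1]
  res <- withr_seed(seed, cpp_bsg_simulate(
    current$I, dt_in, params$dt, unclass(params),
    params$sigma, params$current_gain, params$v0,
    return_v, max(1L, as.integer(round(1e-4 / params$dt)))
  ))
  duration <- max(current$t) - min(current$t)
  out <- new_spike_train(res$spikes, duration, seed = seed)
  if (return_v) {
    attr(out, "v") <- tibble::tibble(
      t = seq_along(res$v) * res$v_dt - res$v_dt, v_mV = res$v)
  }
  out
}

#' Frequency-current curve of the spike generator
#'
#' Deterministic (`sigma = 0`) firing rate for each constant current on
#' the grid, measured after discarding an initial transient.
#'
#' @param params A [bsg_params()] list.
#' @param I_grid Sorted constant transduction currents, pA.
#' @param t_sim,t_skip Simulation length and discarded transient, s.
#' @return A tibble with columns `I` (pA) and `rate` (spikes/s).
#' @export
bsg_fi <- function(params = bsg_params(), I_grid = seq(0, 62.13, by = 2),
                   t_sim = 1.2, t_skip = 0.2) {
  if (is.unsorted(I_grid)) abort("`I_grid` must be sorted")
  p0 <- params; p0$sigma <- 0
  rate <- vapply(I_grid, function(I) {
    tr <- bsg_simulate(
      tibble::tibble(t = c(0, t_sim), I = c(I, I)), p0, seed = 0L)
    sum(tr$time >= t_skip) / (t_sim - t_skip)
  }, numeric(1))
  tibble::tibble(I = I_grid, rate = rate)
}

#' Simulate a group of olfactory sensory neurons
#'
#' One shared transduction trajectory (binding and dissociation rates are
#' common to all neurons expressing a receptor) drives `n_neurons`
#' Connor-Stevens generators with independent Brownian sample paths. The
#' per-neuron seed is `seed + neuron_index` (a documented splitting rule,
#' so a group simulation is reproducible from the master seed alone).
#'
#' @param w An `odor_waveform`.
#' @param rates A [rate_pair()].
#' @param params An [otp_params()] list.
#' @param bsg A [bsg_params()] list.
#' @param n_neurons Neurons in the group (default 25).
#' @param seed Master seed.
#' @return A tibble of class `spike_trains` with columns `neuron` and
#'   `time`, carrying `n_trains` and `duration` attributes (neurons that
#'   never fire still count towards `n_trains`).
#' @export
osn_simulate <- function(w, rates, params = otp_params(),
                         bsg = bsg_params(), n_neurons = 25, seed = 1L) {
  if (n_neurons < 1) abort("`n_neurons` must be >= 1")
  traj <- otp_integrate(w, rates, params)
  osn_spikes_from_current(traj, bsg, n_neurons, seed)
}

# shared helper: replicate noisy spike generators over one current trace
osn_spikes_from_current <- function(traj, bsg, n_neurons, seed) {
  trains <- purrr::map(seq_len(n_neurons), function(i) {
    st <- bsg_simulate(traj, bsg, seed = seed + i)
    tibble::tibble(neuron = i, time = st$time)
  })
  out <- dplyr::bind_rows(trains)
  structure(out, class = c("spike_trains", class(tibble::tibble())),
            n_trains = n_neurons, duration = max(traj$t) - min(traj$t))
}

#' Write spike trains to CSV
#'
#' Columns `neuron_id, spike_time_s`.
#'
#' @param trains A `spike_trains` tibble.
#' @param path File path.
#' @export
write_spike_trains <- function(trains, path) {
  utils::write.csv(
    data.frame(neuron_id = trains$neuron, spike_time_s = trains$time),
    path, row.names = FALSE
  )
  invisible(path)
}
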