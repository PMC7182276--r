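#' Tabulate the steady-state rate map
#'
#' Simulates the full transduction/spike-generator cascade with 5-s
#' constant stimuli over a grid of affinities and records the settled
#' spike rate (4-5 s window). In steady state the rate depends on
#' affinity and amplitude only through their product (the steady
#' bound-receptor ratio is `a*v / (a*v + 1)`), so one map serves any
#' amplitude: the table is keyed by `product = affinity * amplitude`.
#'
#' The full characterisation sweep spans affinities 1e-2 to 1e1 ppm^-1 at
#' 0.01 log steps; the default grid here covers the same span (extended
#' down to 1e-4 for low-affinity receptor-odorant tables) at 12 points per
#' decade, which the monotone-interpolation inverse resolves to well under
#' the noise floor of the simulated rates.
#'
#' @param amplitude Constant stimulus amplitude, ppm.
#' @param affinity_grid Sorted affinity grid, ppm^-1.
#' @param params,bsg Cascade parameters.
#' @param n_neurons Spike generators averaged per grid point.
#' @param seed Master seed.
#' @param t_end,window Stimulus length and settled-rate window, s.
#' @param d_ref Dissociation rate used during tabulation, s^-1 (the
#'   settled rate is insensitive to it; it only sets approach speed).
#' @return A tibble of class `rate_map` with columns `affinity`,
#'   `product` and `rate`, plus the tabulation settings as attributes.
#' @export
steady_rate_map <- function(amplitude = 1,
                            affinity_grid = 10^seq(-4, 1, by = 1 / 12),
                            params = otp_params(), bsg = bsg_params(),
                            n_neurons = 25, seed = 1L,
                            t_end = 5, window = c(4, 5), d_ref = 10) {
  if (amplitude <= 0) abort("`amplitude` must be positive")
  if (is.unsorted(affinity_grid)) abort("`affinity_grid` must be sorted")
  t <- seq(0, t_end, by = 1e-4)
  w <- new_odor_waveform(t, rep(amplitude, length(t)),
                         rep(0, length(t)), "constant",
                         list(amplitude = amplitude))
  rate <- vapply(seq_along(affinity_grid), function(i) {
    a <- affinity_grid[i]
    trains <- osn_simulate(w, rate_pair(a * d_ref, d_ref), params, bsg,
                           n_neurons = n_neurons, seed = seed + 1000L * i)
    sum(trains$time >= window[1] & trains$time <= window[2]) /
      (diff(window) * n_neurons)
  }, numeric(1))
  structure(
    tibble::tibble(affinity = affinity_grid,
                   product = affinity_grid * amplitude, rate = rate),
    class = c("rate_map", class(tibble::tibble())),
    amplitude = amplitude, n_neurons = n_neurons, seed = seed,
    window = window, params = params, bsg = bsg
  )
}

# monotone (cummax) envelope interpolation: rate -> log10(x)
invert_monotone <- function(rate_tab, x, query, what) {
  env <- cummax(rate_tab)
  if (any(env != rate_tab))
    warn(paste0("non-monotone ", what,
                " map segment; using the monotone envelope"))
  lo <- env[1]; hi <- env[length(env)]
  if (query < lo || query > hi)
    abort(sprintf(
      "rate %.4g spikes/s outside the tabulated %s map range [%.4g, %.4g]",
      query, what, lo, hi))
  # keep the last point of each flat run so interpolation brackets the
  # rising segment tightly from below
  keep <- !duplicated(env, fromLast = TRUE)
  10^approx(env[keep], log10(x[keep]), xout = query, ties = "ordered")$y
}

#' Estimate affinity from a settled spike rate
#'
#' Inverts the tabulated steady-state map by monotone interpolation: the
#' observed rate is mapped to the affinity-amplitude product, and the
#' product divided by the stimulus amplitude gives the affinity.
#'
#' @param steady_rate Settled spike rate, spikes/s.
#' @param amplitude Constant stimulus amplitude, ppm.
#' @param map A [steady_rate_map()].
#' @return Affinity, ppm^-1.
#' @export
estimate_affinity <- function(steady_rate, amplitude, map) {
  stopifnot(inherits(map, "rate_map"))
  if (amplitude <= 0) abort("`amplitude` must be positive")
  invert_monotone(map$rate, map$product, steady_rate, "steady-rate") /
    amplitude
}

#' Tabulate the peak-rate map for a fixed affinity
#'
#' For each dissociation rate on the grid the cascade is simulated with a
#' step stimulus (binding rate `affinity * d`) and the peak of the
#' response histogram is recorded; faster dissociation tracks the
#' transient concentration-profile overshoot more closely and yields a
#' higher peak.
#'
#' @param affinity Fixed affinity, ppm^-1.
#' @param amplitude Step amplitude, ppm.
#' @param d_grid Sorted dissociation-rate grid, s^-1.
#' @param params,bsg Cascade parameters.
#' @param n_neurons Spike generators averaged per grid point.
#' @param seed Master seed.
#' @param onset Stimulus onset of the step family, s.
#' @return A tibble of class `peak_map` with columns `d` and `peak`.
#' @export
peak_rate_map <- function(affinity, amplitude,
                          d_grid = 10^seq(-1, 2, length.out = 16),
                          params = otp_params(), bsg = bsg_params(),
                          n_neurons = 25, seed = 1L, onset = 0.5) {
  if (is.unsorted(d_grid)) abort("`d_grid` must be sorted")
  w <- wave_step(amplitude, t_end = 3)
  peak <- vapply(seq_along(d_grid), function(i) {
    d <- d_grid[i]
    trains <- osn_simulate(w, rate_pair(affinity * d, d), params, bsg,
                           n_neurons = n_neurons, seed = seed + 1000L * i)
    psth_stats(compute_psth(trains), onset = onset)$peak
  }, numeric(1))
  structure(
    tibble::tibble(d = d_grid, peak = peak),
    class = c("peak_map", class(tibble::tibble())),
    affinity = affinity, amplitude = amplitude, n_neurons = n_neurons,
    seed = seed
  )
}

#' Estimate the dissociation rate from a peak spike rate
#'
#' Given the affinity estimated from the settled rate, tabulates (or
#' reuses) the peak-rate map over a dissociation grid and inverts it by
#' monotone interpolation.
#'
#' @param peak_rate Peak spike rate of the step response, spikes/s.
#' @param affinity Affinity, ppm^-1 (typically from
#'   [estimate_affinity()]).
#' @param amplitude Step amplitude, ppm.
#' @param map Optional precomputed [peak_rate_map()]; built on the fly
#'   otherwise.
#' @param ... Passed to [peak_rate_map()] when `map` is `NULL`.
#' @return Dissociation rate, s^-1.
#' @export
estimate_dissociation <- function(peak_rate, affinity, amplitude,
                                  map = NULL, ...) {
  if (is.null(map)) map <- peak_rate_map(affinity, amplitude, ...)
  stopifnot(inherits(map, "peak_map"))
  invert_monotone(map$peak, map$d, peak_rate, "peak-rate")
}

#' Binding rate from affinity and dissociation rate
#'
#' @param affinity Affinity, ppm^-1.
#' @param d Dissociation rate, s^-1.
#' @return Binding rate `affinity * d`, (ppm s)^-1.
#' @export
binding_from <- function(affinity, d) affinity * d

#' Run the full rate-pair estimation procedure
#'
#' The inverse-mapping procedure for one odorant-receptor pair: estimate
#' the affinity from the settled rate, then the dissociation rate from the
#' peak rate given that affinity, then the binding rate as their product.
#'
#' @param steady_rate,peak_rate Settled and peak spike rates of a step
#'   response, spikes/s.
#' @param amplitude Step amplitude, ppm.
#' @param steady_map A [steady_rate_map()].
#' @param ... Passed to [peak_rate_map()].
#' @return A one-row tibble with `affinity`, `d` and `b`.
#' @export
estimate_rate_pair <- function(steady_rate, peak_rate, amplitude,
                               steady_map, ...) {
  a <- estimate_affinity(steady_rate, amplitude, steady_map)
  d <- estimate_dissociation(peak_rate, a, amplitude, ...)
  tibble::tibble(affinity = a, d = d, b = binding_from(a, d))
}

#' Estimate a receptor-by-odorant affinity matrix
#'
#' Applies [estimate_affinity()] entrywise to a spike-count table (counts
#' are read as settled spike rates at the stated constant amplitude),
#' using one shared steady-rate map. Entries at or below the map's floor
#' rate are assigned the floor affinity (the largest affinity still
#' consistent with a silent response at this amplitude) and flagged;
#' entries above the map ceiling are assigned the ceiling affinity and
#' flagged.
#'
#' @param counts A numeric matrix (rows = receptors, columns = odorants,
#'   dimnames used as labels) or a long tibble with columns `receptor`,
#'   `odorant`, `count`.
#' @param amplitude Constant stimulus amplitude of the recordings, ppm.
#' @param map A [steady_rate_map()].
#' @return A tibble with columns `receptor`, `odorant`, `count`,
#'   `affinity` (ppm^-1) and `flagged` (out-of-range entries clamped to
#'   the map edge).
#' @export
estimate_affinity_matrix <- function(counts, amplitude = 100, map) {
  stopifnot(inherits(map, "rate_map"))
  if (is.matrix(counts)) {
    rn <- rownames(counts) %||% paste0("receptor_", seq_len(nrow(counts)))
    cn <- colnames(counts) %||% paste0("odorant_", seq_len(ncol(counts)))
    counts <- tibble::tibble(
      receptor = rep(rn, times = ncol(counts)),
      odorant = rep(cn, each = nrow(counts)),
      count = as.vector(counts)
    )
  }
  stopifnot(all(c("receptor", "odorant", "count") %in% names(counts)))
  if (any(counts$count < 0)) abort("spike counts must be >= 0")

  env <- cummax(map$rate)
  lo <- env[1]; hi <- env[length(env)]
  dplyr::mutate(
    tibble::as_tibble(counts),
    flagged = .data$count <= lo | .data$count >= hi,
    affinity = purrr::map_dbl(.data$count, function(r) {
      rc <- min(max(r, lo), hi)
      invert_monotone(map$rate, map$product, rc, "steady-rate") / amplitude
    })
  )
}
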