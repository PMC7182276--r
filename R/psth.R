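#' Peristimulus time histogram
#'
#' Sliding-window rate estimate from an ensemble of spike trains: windows
#' of width `bin` advance by `shift` (overlapping when `shift < bin`);
#' the rate in a window is the total spike count across trains divided by
#' the effective window length times the number of trains. Windows are
#' truncated at the edges of the trace and the truncated length is used in
#' the denominator.
#'
#' @param trains A `spike_trains` tibble (from [osn_simulate()]), a
#'   `spike_train`, or a plain data frame with columns `neuron` and `time`
#'   (then `n_trains`/`duration` must be supplied).
#' @param bin Window width, s (default 20 ms).
#' @param shift Window shift, s (default 10 ms).
#' @param n_trains,duration Overrides for inputs that do not carry them as
#'   attributes.
#' @return A tibble of class `psth` with columns `t` (window centre, s)
#'   and `rate` (spikes/s), with `bin`, `shift`, `n_trains` and `duration`
#'   attributes.
#' @export
compute_psth <- function(trains, bin = 0.020, shift = 0.010,
                         n_trains = NULL, duration = NULL) {
  if (inherits(trains, "spike_train"))
    trains <- structure(
      tibble::tibble(neuron = 1L, time = trains$time),
      n_trains = 1L, duration = attr(trains, "duration"))
  n_trains <- n_trains %||% attr(trains, "n_trains")
  duration <- duration %||% attr(trains, "duration")
  if (is.null(n_trains) || is.null(duration))
    abort("`n_trains` and `duration` must be available")
  if (n_trains < 1) abort("need at least one spike train")
  if (bin <= 0 || shift <= 0) abort("`bin` and `shift` must be positive")

  centers <- seq(shift / 2, duration, by = shift)
  lo <- pmax(centers - bin / 2, 0)
  hi <- pmin(centers + bin / 2, duration)
  st <- sort(trains$time)
  # count spikes in [lo, hi): findInterval on half-open windows
  counts <- findInterval(hi - 1e-12, st) - findInterval(lo - 1e-12, st)
  rate <- counts / ((hi - lo) * n_trains)
  structure(
    tibble::tibble(t = centers, rate = rate),
    class = c("psth", class(tibble::tibble())),
    bin = bin, shift = shift, n_trains = n_trains, duration = duration
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Mean squared error between two rate histograms
#'
#' @param a,b `psth` objects with identical binning.
#' @return Mean of squared per-bin rate differences, (spikes/s)^2.
#' @export
psth_mse <- function(a, b) {
  stopifnot(inherits(a, "psth"), inherits(b, "psth"))
  if (!isTRUE(all.equal(attr(a, "bin"), attr(b, "bin"))) ||
      !isTRUE(all.equal(attr(a, "shift"), attr(b, "shift"))))
    abort("binning mismatch between the two histograms")
  n <- min(nrow(a), nrow(b))
  if (nrow(a) != nrow(b) &&
      abs(nrow(a) - nrow(b)) * attr(a, "shift") > attr(a, "bin"))
    abort("histogram lengths differ by more than one bin")
  mean((a$rate[seq_len(n)] - b$rate[seq_len(n)])^2)
}

#' Summary rates of a response histogram
#'
#' @param p A `psth`.
#' @param onset Stimulus onset, s.
#' @param steady_window Window over which the settled rate is averaged;
#'   defaults to the final second of the trace (for the 5-s constant
#'   stimuli used in steady-state characterisation this is the 4-5 s
#'   window).
#' @param peak_skip Dead time after onset ignored by the peak search
#'   (10 ms, to avoid the one-sample gradient pulse of analytic-gradient
#'   step stimuli).
#' @return A one-row tibble with `spontaneous`, `peak` and `steady`
#'   rates, spikes/s.
#' @export
psth_stats <- function(p, onset = 0.5, steady_window = NULL,
                       peak_skip = 0.010) {
  stopifnot(inherits(p, "psth"))
  dur <- attr(p, "duration")
  steady_window <- steady_window %||% c(max(dur - 1, onset), dur)
  if (steady_window[2] > dur + attr(p, "bin"))
    abort("steady window extends beyond the trace")
  pre <- p$rate[p$t < onset]
  post <- p$rate[p$t >= onset + peak_skip]
  steady <- p$rate[p$t >= steady_window[1] & p$t <= steady_window[2]]
  tibble::tibble(
    spontaneous = if (length(pre)) mean(pre) else 0,
    peak = if (length(post)) max(post) else 0,
    steady = if (length(steady)) mean(steady) else 0
  )
}

#' Write a rate histogram to CSV
#'
#' Columns `t_center_s, rate_hz`.
#'
#' @param p A `psth`.
#' @param path File path.
#' @export
write_psth <- function(p, path) {
  utils::write.csv(data.frame(t_center_s = p$t, rate_hz = p$rate),
                   path, row.names = FALSE)
  invisible(path)
}
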