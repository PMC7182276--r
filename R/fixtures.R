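#' Synthetic receptor-by-odorant spike-count matrix
#'
#' Draws ground-truth affinities log-uniformly inside the dynamic range of
#' the supplied steady-rate map, forward-maps them to settled spike rates
#' at the stated amplitude (interpolating the tabulated map, which was
#' itself built by full cascade simulation), converts the rates to counts
#' over an observation window, and optionally perturbs them with Poisson
#' noise. Both truth and observation are returned, so estimator recovery
#' can be scored directly. Everything is reproducible from the seed; the
#' default shape (24 receptors by 110 odorants) emulates the published
#' consensus spike-count tables for Drosophila receptors. All output is
#' synthetic.
#'
#' @param n_receptors,n_odorants Matrix shape (default 24 x 110).
#' @param amplitude Constant stimulus amplitude, ppm.
#' @param map A [steady_rate_map()] used as the forward model.
#' @param affinity_range Log-uniform bounds for the true affinities,
#'   ppm^-1; defaults to the interior of the map's invertible range at
#'   this amplitude.
#' @param noise `"none"` for exact rates, `"poisson"` for Poisson counts
#'   on `rate * window`.
#' @param window Observation window for the Poisson model, s.
#' @param seed Seed.
#' @return A list with `truth` (tibble `receptor`, `odorant`, `affinity`)
#'   and `counts` (tibble `receptor`, `odorant`, `count`, in spikes/s
#'   units for `noise = "none"`).
#' @export
synth_count_matrix <- function(n_receptors = 24, n_odorants = 110,
                               amplitude = 100, map,
                               affinity_range = NULL,
                               noise = c("none", "poisson"),
                               window = 1, seed = 1L) {
  stopifnot(inherits(map, "rate_map"))
  noise <- match.arg(noise)
  if (is.null(affinity_range)) {
    # interior of the sigmoid's dynamic range: products whose settled
    # rate sits clear of both the spontaneous floor and the ceiling
    env <- cummax(map$rate)
    active <- map$product[env > env[1] + 2 & env < env[length(env)] - 2]
    if (length(active) < 2)
      abort("map has no usable dynamic range; supply `affinity_range`")
    affinity_range <- range(active) / amplitude
  }
  withr_seed(seed, {
    n <- n_receptors * n_odorants
    a <- 10^runif(n, log10(affinity_range[1]), log10(affinity_range[2]))
    truth <- tibble::tibble(
      receptor = rep(sprintf("R%02d", seq_len(n_receptors)),
                     times = n_odorants),
      odorant = rep(sprintf("O%03d", seq_len(n_odorants)),
                    each = n_receptors),
      affinity = a
    )
    rate <- approx(log10(map$product), map$rate,
                   xout = log10(a * amplitude), rule = 2)$y
    count <- switch(noise,
      none = rate,
      poisson = stats::rpois(n, rate * window) / window
    )
    list(truth = truth,
         counts = tibble::tibble(receptor = truth$receptor,
                                 odorant = truth$odorant,
                                 count = count))
  })
}

#' Synthetic fitting targets from known parameters
#'
#' Simulates noiseless response histograms under known transduction
#' parameters for a transient-set stimulus (band-limited white noise) and
#' a steady-set stimulus (a pulse), and packages them as a
#' [fit_problem()] whose ground truth is known. With zero noise the loss
#' at the true parameters is numerically zero, so optimiser recovery can
#' be scored against the truth.
#'
#' @param true_params An [otp_params()] list used to generate the
#'   targets.
#' @param rates A [rate_pair()].
#' @param stimuli Optional list of `odor_waveform`s; by default one
#'   white-noise and one step stimulus.
#' @param set Partition labels parallel to `stimuli`.
#' @param lambda Loss weight (default 40).
#' @param free Free-parameter names for the resulting problem.
#' @param bsg Spike-generator parameters; the default is noiseless with a
#'   0.02 ms step (targets and candidate simulations share the step, so
#'   the loss at the true parameters is exactly zero).
#' @param n_neurons Neurons per simulated target.
#' @param seed Seed.
#' @return A [fit_problem()] with attribute `true_params`.
#' @export
synth_fit_targets <- function(true_params = otp_params(),
                              rates = rate_pair(2.17e-2, 2.94),
                              stimuli = NULL, set = NULL, lambda = 40,
                              free = c("alpha2", "beta2", "kappa"),
                              bsg = bsg_params(sigma = 0, dt = 2e-5),
                              n_neurons = 1, seed = 1L) {
  if (is.null(stimuli)) {
    stimuli <- list(
      wave_white_noise(mean = 60, sd = 25, bandwidth = 15, t_end = 2,
                       seed = seed),
      wave_step(100, t_end = 3)
    )
    set <- c("transient", "steady")
  }
  if (is.null(set) || length(set) != length(stimuli))
    abort("`set` must be given alongside `stimuli`")
  targets <- purrr::map(seq_along(stimuli), function(i) {
    trains <- osn_simulate(stimuli[[i]], rates, true_params, bsg,
                           n_neurons = n_neurons, seed = seed)
    compute_psth(trains)
  })
  pr <- fit_problem(stimuli, targets, set, rates,
                    base = true_params, free = free, lambda = lambda,
                    bsg = bsg, n_neurons = n_neurons, seed = seed)
  attr(pr, "true_params") <- true_params
  pr
}
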