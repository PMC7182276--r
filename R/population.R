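#' Default antennal affinity grid
#'
#' The 50-value arithmetic affinity grid used for the antenna/maxillary
#' palp population: 2e-4 to 1e-2 ppm^-1 in steps of 2e-4.
#'
#' @return A numeric vector of length 50.
#' @export
affinity_grid_default <- function() seq(2e-4, 1e-2, by = 2e-4)

#' Specify an OSN population
#'
#' One group per receptor type; every group shares the transduction and
#' spike-generator parameters and the dissociation rate, and differs only
#' in affinity (hence binding rate). The default population is the
#' 50-group antenna/maxillary palp unit with 25 neurons per group (1250
#' neurons in total) and dissociation rate 1e2 s^-1.
#'
#' @param affinities Per-group affinities, ppm^-1.
#' @param dissociation Shared dissociation rate, s^-1.
#' @param n_per_group Neurons per group.
#' @param labels Group labels.
#' @param params,bsg Shared cascade parameters.
#' @param seed Master seed.
#' @return A list of class `population_spec`.
#' @export
population_spec <- function(affinities = affinity_grid_default(),
                            dissociation = 1e2, n_per_group = 25,
                            labels = NULL,
                            params = otp_params(), bsg = bsg_params(),
                            seed = 1L) {
  if (length(affinities) < 1) abort("need at least one group")
  if (any(affinities < 0)) abort("affinities must be >= 0")
  if (n_per_group < 1) abort("`n_per_group` must be >= 1")
  labels <- labels %||% sprintf("group_%02d", seq_along(affinities))
  structure(
    list(affinities = affinities, labels = labels,
         dissociation = dissociation, n_per_group = n_per_group,
         params = params, bsg = bsg, seed = seed),
    class = "population_spec"
  )
}

#' @export
print.population_spec <- function(x, ...) {
  cat(sprintf("<population_spec: %d groups x %d neurons = %d OSNs, d = %g s^-1>\n",
              length(x$affinities), x$n_per_group,
              length(x$affinities) * x$n_per_group, x$dissociation))
  invisible(x)
}

#' Simulate an OSN population
#'
#' For each group one transduction trajectory is integrated (binding and
#' dissociation rates are shared within a group) and drives the group's
#' independent noisy spike generators; the group response is summarised
#' as a sliding-window histogram. Groups with identical affinity reuse
#' one transduction solve (for a fixed dissociation rate and waveform the
#' trajectory depends on the binding rate only).
#'
#' @param spec A [population_spec()].
#' @param w An `odor_waveform` applied to every group.
#' @param bin,shift Histogram windows, s.
#' @return A tibble of class `population_psth` with columns `group`,
#'   `affinity`, `t`, `rate`, and attributes `n_osn`, `bin`, `shift`.
#' @export
population_simulate <- function(spec, w, bin = 0.020, shift = 0.010) {
  stopifnot(inherits(spec, "population_spec"),
            inherits(w, "odor_waveform"))
  traj_cache <- new.env(parent = emptyenv())
  res <- purrr::map(seq_along(spec$affinities), function(g) {
    a <- spec$affinities[g]
    key <- sprintf("%.15g", a)
    traj <- if (!is.null(traj_cache[[key]])) traj_cache[[key]] else {
      tr <- otp_integrate(
        w, rate_pair(a * spec$dissociation, spec$dissociation),
        spec$params)
      traj_cache[[key]] <- tr
      tr
    }
    trains <- osn_spikes_from_current(traj, spec$bsg, spec$n_per_group,
                                      spec$seed + 100L * g)
    p <- compute_psth(trains, bin = bin, shift = shift)
    tibble::tibble(group = spec$labels[g], affinity = a,
                   t = p$t, rate = p$rate)
  })
  out <- dplyr::bind_rows(res)
  structure(out, class = c("population_psth", class(tibble::tibble())),
            n_osn = length(spec$affinities) * spec$n_per_group,
            bin = bin, shift = shift, duration = max(w$t))
}

#' Time-resolved spike-rate matrix for a receptor-by-odorant table
#'
#' Simulates one OSN group per (receptor, odorant) affinity entry under a
#' shared waveform and a shared dissociation rate, and assembles the
#' per-group histograms into a time-indexed rate matrix (one frame per
#' histogram shift, 10 ms by default). Identical affinity entries reuse
#' one transduction solve and, with the same per-entry seed policy
#' disabled (`share_seeds = TRUE`), identical rows produce identical
#' rows in every frame.
#'
#' @param affinities A tibble with columns `receptor`, `odorant`,
#'   `affinity` (e.g. from [estimate_affinity_matrix()]) or a numeric
#'   matrix with dimnames.
#' @param dissociation Shared dissociation rate, s^-1 (default 132, the
#'   working assumption for receptor-by-odorant tables, which constrain
#'   only the affinity).
#' @param w An `odor_waveform`.
#' @param n_neurons Neurons per entry.
#' @param params,bsg Shared cascade parameters.
#' @param seed Master seed.
#' @param share_seeds Reuse the same spike-generator seeds for entries
#'   with equal affinity (makes equal entries exactly equal).
#' @param bin,shift Histogram windows, s.
#' @return A tibble of class `rate_movie` with columns `t`, `receptor`,
#'   `odorant`, `rate`.
#' @export
rate_matrix_movie <- function(affinities, dissociation = 132, w,
                              n_neurons = 25,
                              params = otp_params(), bsg = bsg_params(),
                              seed = 1L, share_seeds = TRUE,
                              bin = 0.020, shift = 0.010) {
  if (is.matrix(affinities)) {
    rn <- rownames(affinities) %||% paste0("receptor_", seq_len(nrow(affinities)))
    cn <- colnames(affinities) %||% paste0("odorant_", seq_len(ncol(affinities)))
    affinities <- tibble::tibble(
      receptor = rep(rn, times = ncol(affinities)),
      odorant = rep(cn, each = nrow(affinities)),
      affinity = as.vector(affinities)
    )
  }
  stopifnot(all(c("receptor", "odorant", "affinity") %in% names(affinities)))
  if (any(affinities$affinity < 0)) abort("affinities must be >= 0")

  psth_cache <- new.env(parent = emptyenv())
  res <- purrr::map(seq_len(nrow(affinities)), function(i) {
    a <- affinities$affinity[i]
    key <- sprintf("%.15g", a)
    ent_seed <- if (share_seeds) seed else seed + 100L * i
    cache_key <- paste(key, ent_seed)
    p <- if (!is.null(psth_cache[[cache_key]])) psth_cache[[cache_key]] else {
      traj <- otp_integrate(w, rate_pair(a * dissociation, dissociation),
                            params)
      trains <- osn_spikes_from_current(traj, bsg, n_neurons, ent_seed)
      pp <- compute_psth(trains, bin = bin, shift = shift)
      psth_cache[[cache_key]] <- pp
      pp
    }
    tibble::tibble(receptor = affinities$receptor[i],
                   odorant = affinities$odorant[i],
                   t = p$t, rate = p$rate)
  })
  out <- dplyr::bind_rows(res)
  structure(out, class = c("rate_movie", class(tibble::tibble())),
            bin = bin, shift = shift)
}

#' Extract one frame of a rate movie as a matrix
#'
#' @param movie A `rate_movie`.
#' @param time Frame time, s (snapped to the nearest histogram centre).
#' @return A receptors-by-odorants numeric matrix.
#' @export
movie_frame <- function(movie, time) {
  stopifnot(inherits(movie, "rate_movie"))
  tq <- movie$t[which.min(abs(movie$t - time))]
  fr <- dplyr::filter(movie, abs(.data$t - tq) < 1e-9)
  wide <- tidyr::pivot_wider(fr[, c("receptor", "odorant", "rate")],
                             names_from = "odorant",
                             values_from = "rate")
  m <- as.matrix(wide[, -1, drop = FALSE])
  rownames(m) <- wide$receptor
  m
}
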