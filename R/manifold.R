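#' Collect concentration/gradient/rate samples
#'
#' Applies each waveform to a group of cascades, histograms the spikes,
#' and pairs every histogram bin with the stimulus concentration and
#' concentration gradient at the bin centre. The pooled triples sample
#' the neuron's two-dimensional encoding of concentration and
#' concentration gradient.
#'
#' @param waveforms A list of `odor_waveform`s (e.g. [wave_triangles()]).
#' @param rates A [rate_pair()] shared by all cascades.
#' @param params,bsg Cascade parameters.
#' @param n_neurons Neurons per waveform.
#' @param seed Master seed.
#' @param bin,shift Histogram windows, s.
#' @return A tibble of class `encoding_samples` with columns `wave`, `t`,
#'   `u` (ppm), `dudt` (ppm/s) and `rate` (spikes/s).
#' @export
manifold_samples <- function(waveforms, rates, params = otp_params(),
                             bsg = bsg_params(), n_neurons = 25,
                             seed = 1L, bin = 0.020, shift = 0.010) {
  if (length(waveforms) == 0) abort("`waveforms` must be non-empty")
  res <- purrr::map(seq_along(waveforms), function(i) {
    w <- waveforms[[i]]
    trains <- osn_simulate(w, rates, params, bsg, n_neurons = n_neurons,
                           seed = seed + 1000L * i)
    p <- compute_psth(trains, bin = bin, shift = shift)
    tibble::tibble(
      wave = i, t = p$t,
      u = approx(w$t, w$u, xout = p$t, rule = 2)$y,
      dudt = approx(w$t, w$du, xout = p$t, rule = 2)$y,
      rate = p$rate
    )
  })
  out <- dplyr::bind_rows(res)
  structure(out, class = c("encoding_samples", class(tibble::tibble())))
}

# tensor-product polynomial design over scaled (u, dudt)
manifold_design <- function(u, dudt, degree, scale_u, scale_du) {
  su <- u / scale_u
  sd_ <- dudt / scale_du
  cols <- list()
  for (i in 0:degree) for (j in 0:degree) {
    if (i + j == 0 || i + j > degree) next
    cols[[paste0("u", i, "g", j)]] <- su^i * sd_^j
  }
  do.call(cbind, cols)
}

#' Fit the 2D encoding manifold by ridge regression
#'
#' Penalised least squares of the firing rate on a tensor-product
#' polynomial basis over (concentration, concentration gradient), with
#' the ridge penalty chosen by generalised cross-validation over a grid.
#' The intercept is unpenalised (so in the infinite-penalty limit the
#' surface collapses to the sample mean), and the two coordinates are
#' scaled by their observed spread before the basis is built.
#'
#' @param samples An `encoding_samples` tibble (or any data frame with
#'   columns `u`, `dudt`, `rate`).
#' @param degree Total polynomial degree of the tensor basis.
#' @param lambdas Ridge-penalty grid for generalised cross-validation.
#' @return An object of class `osn_manifold` with the fitted
#'   coefficients, the penalty chosen by GCV and the GCV table;
#'   supports [predict()], [tidy()], [glance()] and [autoplot()].
#' @export
manifold_fit <- function(samples, degree = 4,
                         lambdas = 10^seq(-8, 4, by = 0.5)) {
  stopifnot(all(c("u", "dudt", "rate") %in% names(samples)))
  if (nrow(samples) < 10) abort("need at least 10 samples")
  y <- samples$rate
  scale_u <- max(abs(samples$u), 1e-12)
  scale_du <- max(abs(samples$dudt), 1e-12)
  X <- manifold_design(samples$u, samples$dudt, degree, scale_u, scale_du)
  xm <- colMeans(X)
  Xc <- sweep(X, 2, xm)
  ym <- mean(y)
  yc <- y - ym
  sv <- svd(Xc)
  if (min(sv$d) < 1e-12 * max(sv$d) && max(lambdas) <= 0)
    abort("singular design; increase the ridge penalty")
  uty <- crossprod(sv$u, yc)
  n <- length(y)
  gcv <- vapply(lambdas, function(l) {
    shrink <- sv$d^2 / (sv$d^2 + l)
    fit <- sv$u %*% (shrink * uty)
    edf <- sum(shrink) + 1
    mean((yc - fit)^2) / (1 - edf / n)^2
  }, numeric(1))
  l <- lambdas[which.min(gcv)]
  beta <- sv$v %*% ((sv$d / (sv$d^2 + l)) * uty)
  beta <- drop(beta)
  names(beta) <- colnames(X)
  structure(
    list(beta = beta, intercept = ym, center = xm,
         degree = degree, scale_u = scale_u, scale_du = scale_du,
         lambda = l, gcv = tibble::tibble(lambda = lambdas, gcv = gcv),
         n = n, u_range = range(samples$u), dudt_range = range(samples$dudt),
         r_squared = 1 - mean((yc - sv$u %*% ((sv$d^2 / (sv$d^2 + l)) * uty))^2) / mean(yc^2)),
    class = "osn_manifold"
  )
}

#' @export
print.osn_manifold <- function(x, ...) {
  cat(sprintf("<osn_manifold: degree %d tensor basis, lambda = %g (GCV), R2 = %.3f, n = %d>\n",
              x$degree, x$lambda, x$r_squared, x$n))
  invisible(x)
}

#' Predict firing rate on the encoding plane
#'
#' @param object An `osn_manifold`.
#' @param newdata Data frame with columns `u` and `dudt`.
#' @param ... Unused.
#' @return Predicted rate, spikes/s.
#' @export
predict.osn_manifold <- function(object, newdata, ...) {
  X <- manifold_design(newdata$u, newdata$dudt, object$degree,
                       object$scale_u, object$scale_du)
  drop(sweep(X, 2, object$center) %*% object$beta) + object$intercept
}

#' Evaluate the fitted manifold on a regular grid
#'
#' @param fit An `osn_manifold`.
#' @param u_range,dudt_range Ranges of the two coordinates.
#' @param n Grid points per axis.
#' @return A tibble with columns `u`, `dudt` and `rate` suitable for
#'   contour plotting or CSV export.
#' @export
manifold_grid <- function(fit, u_range, dudt_range, n = 60) {
  g <- tidyr::expand_grid(
    u = seq(u_range[1], u_range[2], length.out = n),
    dudt = seq(dudt_range[1], dudt_range[2], length.out = n)
  )
  g$rate <- predict(fit, g)
  g
}

#' @export
tidy.osn_manifold <- function(x, ...) {
  tibble::tibble(term = c("(Intercept)", names(x$beta)),
                 estimate = c(x$intercept, unname(x$beta)))
}

#' @export
glance.osn_manifold <- function(x, ...) {
  tibble::tibble(lambda = x$lambda, r.squared = x$r_squared,
                 df = length(x$beta) + 1, nobs = x$n)
}
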