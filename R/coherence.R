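#' Partial-coherence model
#'
#' Separable Gaussian model of the source's spatial coherence at the detector
#' plane, parameterized by the horizontal and vertical coherence lengths. The
#' model generates the intensity point spread function ([ipsf()]), its
#' transfer function ([iotf()]), the sample transfer function
#' ([stf_window()]) and the Tikhonov regularization window
#' ([regularization_window()]).
#'
#' @param x_coh,y_coh Horizontal and vertical spatial coherence lengths in
#'   metres (both `> 0`).
#' @return An object of class `coherence_model`.
#' @examples
#' coherence_model(3.47e-6, 4.31e-6)
#' @export
coherence_model <- function(x_coh, y_coh = x_coh) {
  stopifnot(is.numeric(x_coh), x_coh > 0, is.numeric(y_coh), y_coh > 0)
  structure(list(x_coh = x_coh, y_coh = y_coh), class = "coherence_model")
}

#' @export
print.coherence_model <- function(x, ...) {
  cat(sprintf("<coherence_model> x_coh %.4g m, y_coh %.4g m\n",
              x$x_coh, x$y_coh))
  invisible(x)
}

#' Second-order speckle autocorrelation profile
#'
#' Computes the normalized intensity autocorrelation
#' \eqn{g^{(2)}(\Delta) = \langle I(s) I(s+\Delta)\rangle / \langle I\rangle^2}
#' one-dimensionally along the chosen axis, averaged over the orthogonal
#' axis. For fully developed speckle the Siegert relation
#' \eqn{g^{(2)} = 1 + |g^{(1)}|^2} ties this profile to the field coherence.
#'
#' The estimator works in the Fourier domain on the mean-removed image
#' (periodic lags), then restores the \eqn{\langle I\rangle^2} baseline. Lags
#' are truncated to a quarter of the axis length to keep periodic wrap-around
#' out of the fitted peak.
#'
#' @param values Real non-negative `ny x nx` intensity matrix.
#' @param axis `"horizontal"` (lags along x) or `"vertical"` (lags along y).
#' @param max_lag_frac Fraction of the axis length to keep as lags
#'   (default 1/4).
#' @return Numeric vector `g2[1..L]`, where `g2[k]` is the value at lag
#'   `k - 1` pixels; `g2[1]` is \eqn{g^{(2)}(0) \ge 1}.
#' @export
g2_autocorrelation <- function(values,
                               axis = c("horizontal", "vertical"),
                               max_lag_frac = 0.25) {
  axis <- match.arg(axis)
  stopifnot(is.matrix(values), all(is.finite(values)))
  if (axis == "vertical") values <- t(values)
  n <- ncol(values)
  if (n < 64) stop("need >= 64 pixels along the chosen axis")
  mu <- mean(values)
  if (mu <= 0) stop("mean intensity must be positive")
  # Row-wise periodic autocovariance via the Wiener-Khinchin theorem,
  # averaged over rows, using the global mean as the stationarity baseline:
  # Cov(lag) = mean_s d(s) d(s + lag), then g2 = 1 + Cov / mu^2.
  d <- values - mu
  sp <- stats::mvfft(t(d))                 # FFT of each along-axis profile
  ac <- Re(stats::mvfft(sp * Conj(sp), inverse = TRUE)) / n     # sums over s
  cov_prof <- rowMeans(ac) / n             # average profiles, sum -> mean
  n_lag <- max(2L, floor(n * max_lag_frac))
  1 + cov_prof[seq_len(n_lag)] / mu^2
}

#' Fit a Gaussian coherence length to a g2 profile
#'
#' Least-squares fit of the Siegert-relation Gaussian model
#' \eqn{g^{(2)}(\Delta) = 1 + c \exp(-\pi \Delta^2 / \ell^2)} to a measured
#' autocorrelation profile. The contrast amplitude `c` is free: detector
#' binning and partial coherence push \eqn{g^{(2)}(0)} below the ideal value
#' of 2, but leave the width — which carries the coherence length — intact.
#'
#' @param g2_profile Numeric vector from [g2_autocorrelation()] (lag 0 first).
#' @param lag_pitch Physical spacing of consecutive lags in metres.
#' @return List with `length` (the fitted \eqn{\ell} in metres), `contrast`
#'   (fitted `c`) and the `fit` object from [minpack.lm::nlsLM()].
#' @export
fit_coherence_length <- function(g2_profile, lag_pitch) {
  stopifnot(is.numeric(g2_profile), length(g2_profile) >= 4, lag_pitch > 0)
  lag <- (seq_along(g2_profile) - 1) * lag_pitch
  y <- g2_profile
  contrast0 <- y[1] - 1
  if (!is.finite(contrast0) || contrast0 <= 0)
    stop("no correlation contrast at zero lag; cannot fit a coherence length")
  # moment-based width start: first lag where the excess drops below half
  half <- which(y - 1 < contrast0 / 2)
  ell0 <- if (length(half)) max(lag[half[1]], lag_pitch) else lag[length(lag)] / 2
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ 1 + c0 * exp(-pi * lag^2 / ell^2),
      start = list(c0 = contrast0, ell = ell0),
      lower = c(0, lag_pitch / 100),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) stop("coherence-length fit failed: ",
                             conditionMessage(e), call. = FALSE)
  )
  est <- stats::coef(fit)
  list(length = unname(est["ell"]), contrast = unname(est["c0"]), fit = fit)
}

#' Calibrate coherence lengths from a reference speckle
#'
#' Runs [g2_autocorrelation()] plus [fit_coherence_length()] along both axes
#' of a flat-field-corrected reference speckle image and returns the implied
#' [coherence_model()].
#'
#' @param values Reference speckle intensity matrix (mean near 1).
#' @param geometry An [imaging_geometry()].
#' @return List with `model` (a [coherence_model()]), and per-axis fits
#'   `horizontal`, `vertical`.
#' @export
calibrate_coherence <- function(values, geometry) {
  h <- fit_coherence_length(g2_autocorrelation(values, "horizontal"),
                            geometry$pitch)
  v <- fit_coherence_length(g2_autocorrelation(values, "vertical"),
                            geometry$pitch)
  list(model = coherence_model(h$length, v$length), horizontal = h,
       vertical = v)
}

#' Intensity point spread function
#'
#' Gaussian intensity blur kernel imprinted by the partially coherent source:
#' \deqn{IPSF(x, y) = \frac{2}{x_{coh} y_{coh}}
#'   \exp\!\left[-2\pi\left(\frac{x^2}{x_{coh}^2} +
#'   \frac{y^2}{y_{coh}^2}\right)\right]}
#' sampled on the geometry's grid in unshifted (DC at `[1,1]`) order, so its
#' FFT aligns with [iotf()]. The continuous kernel integrates to 1; the
#' discrete sum times `pitch^2` is 1 up to truncation error.
#'
#' @param model A [coherence_model()].
#' @param geometry An [imaging_geometry()].
#' @return Real `ny x nx` matrix.
#' @export
ipsf <- function(model, geometry) {
  if (model$x_coh < 2 * geometry$pitch || model$y_coh < 2 * geometry$pitch)
    warning("coherence length below 2 pixels: IPSF is under-resolved",
            call. = FALSE)
  g <- space_grids(geometry)
  2 / (model$x_coh * model$y_coh) *
    exp(-2 * pi * (g$x^2 / model$x_coh^2 + g$y^2 / model$y_coh^2))
}

#' Intensity optical transfer function
#'
#' Fourier transform of the [ipsf()]:
#' \deqn{IOTF(u, v) = \exp\!\left[-\frac{\pi}{2}\left(u^2 x_{coh}^2 +
#'   v^2 y_{coh}^2\right)\right]}
#' evaluated on the geometry's frequency grid (unshifted order). Values lie
#' in (0, 1] with `IOTF(0, 0) = 1`.
#'
#' @inheritParams ipsf
#' @return Real `ny x nx` matrix.
#' @export
iotf <- function(model, geometry) {
  fr <- frequency_grids(geometry)
  exp(-pi / 2 * (fr$u^2 * model$x_coh^2 + fr$v^2 * model$y_coh^2))
}

#' Measured and reconstructed spatial mode counts
#'
#' The number of measured spatial modes is the space-bandwidth product of the
#' intensity image, \eqn{M = (FOV_x / x_{coh}) (FOV_y / y_{coh})} (a factor
#' 1/2 for intensity-vs-field bandwidth cancels the two \eqn{\sqrt2}
#' effective-bandwidth factors). The reconstructed mode count is
#' \eqn{N = M / \gamma} for oversampling ratio \eqn{\gamma}.
#'
#' @inheritParams ipsf
#' @param gamma Oversampling ratio \eqn{\gamma = M/N > 0}.
#' @return List with real-valued `M`, `N` and `gamma`.
#' @export
count_modes <- function(model, geometry, gamma = 1) {
  stopifnot(gamma > 0)
  fov_x <- geometry$nx * geometry$pitch
  fov_y <- geometry$ny * geometry$pitch
  M <- (fov_x / model$x_coh) * (fov_y / model$y_coh)
  list(M = M, N = M / gamma, gamma = gamma)
}

#' Sample transfer function
#'
#' Gaussian soft bound on the retrievable sample bandwidth implied by the
#' oversampling ratio:
#' \deqn{STF(u, v) = \exp\!\left[-\pi\gamma\left(u^2 x_{coh}^2 +
#'   v^2 y_{coh}^2\right)\right]}
#' with `STF(0, 0) = 1` and monotone decay; doubling \eqn{\gamma} squares the
#' window.
#'
#' @inheritParams count_modes
#' @return Real `ny x nx` matrix on the unshifted frequency grid.
#' @export
stf_window <- function(model, geometry, gamma = 1) {
  stopifnot(gamma > 0)
  fr <- frequency_grids(geometry)
  exp(-pi * gamma * (fr$u^2 * model$x_coh^2 + fr$v^2 * model$y_coh^2))
}

#' Tikhonov regularization window
#'
#' Complement of the sample transfer function,
#' \eqn{\Gamma^2(u,v) = 1 - STF(u,v)}: zero at DC, approaching 1 beyond the
#' retrievable band. Weights the solver's Tikhonov penalty so that only
#' spectral content outside the transferred band is damped.
#'
#' @inheritParams count_modes
#' @return Real `ny x nx` matrix in `[0, 1)`.
#' @export
regularization_window <- function(model, geometry, gamma = 1) {
  1 - stf_window(model, geometry, gamma)
}

#' Expected spatial resolution from the coherence lengths
#'
#' Closed-form resolution estimate at the STF = 0.1 retrievability boundary:
#' \deqn{res = \frac{\sqrt{\pi}}{2\ln 10}\, \ell_{coh} \approx 0.385\,
#'   \ell_{coh}} per axis (natural logarithm), plus the root-mean-square of
#' the two axes.
#'
#' @param model A [coherence_model()].
#' @return List with `horizontal`, `vertical`, `rms` (metres) and the
#'   dimensionless `prefactor`.
#' @examples
#' r <- expected_resolution(coherence_model(3.47e-6, 4.31e-6))
#' round(c(r$horizontal, r$vertical, r$rms) * 1e6, 2)   # 1.34 1.66 1.51 um
#' @export
expected_resolution <- function(model) {
  pref <- sqrt(pi) / (2 * log(10))
  h <- pref * model$x_coh
  v <- pref * model$y_coh
  list(horizontal = h, vertical = v, rms = sqrt((h^2 + v^2) / 2),
       prefactor = pref)
}

#' Write a plain-text coherence calibration report
#'
#' @param calibration Result of [calibrate_coherence()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_calibration_report <- function(calibration, path) {
  res <- expected_resolution(calibration$model)
  lines <- c(
    sprintf("x_coh_m: %.8g", calibration$model$x_coh),
    sprintf("y_coh_m: %.8g", calibration$model$y_coh),
    sprintf("contrast_horizontal: %.6g", calibration$horizontal$contrast),
    sprintf("contrast_vertical: %.6g", calibration$vertical$contrast),
    sprintf("expected_resolution_horizontal_m: %.8g", res$horizontal),
    sprintf("expected_resolution_vertical_m: %.8g", res$vertical),
    sprintf("expected_resolution_rms_m: %.8g", res$rms)
  )
  writeLines(lines, path)
  invisible(path)
}
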