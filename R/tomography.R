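#' Dark-frame subtraction and flat-field correction
#'
#' `(raw - dark) / (flat - dark)`, with non-positive denominators replaced by
#' the median denominator so a handful of dead pixels cannot poison a frame.
#'
#' @param raw,dark,flat Real matrices of equal shape.
#' @return List with the corrected matrix `values` and `replaced`, the count
#'   of substituted denominator pixels.
#' @export
preprocess_frame <- function(raw, dark, flat) {
  stopifnot(is.matrix(raw), all(dim(raw) == dim(dark)),
            all(dim(raw) == dim(flat)))
  den <- flat - dark
  if (all(den == 0)) stop("flat field equals dark frame everywhere")
  bad <- den <= 0
  if (mean(bad) > 0.01)
    stop(sprintf("flat - dark is non-positive on %.1f%% of pixels",
                 100 * mean(bad)))
  if (any(bad)) den[bad] <- stats::median(den[!bad])
  list(values = (raw - dark) / den, replaced = sum(bad))
}

#' Assemble a projection series
#'
#' @param angles Strictly increasing rotation angles in degrees (0-180).
#' @param phase_maps List of complex `ny x nx` phase maps, one per angle.
#' @param geometry An [imaging_geometry()].
#' @return An object of class `projection_series`.
#' @export
projection_series <- function(angles, phase_maps, geometry) {
  stopifnot(length(angles) == length(phase_maps), length(angles) >= 2,
            all(diff(angles) > 0))
  for (p in phase_maps) check_field(p, geometry, "phase map")
  if (max(angles) - min(angles) < 90)
    warning("angular range below 90 degrees: expect severe limited-angle artifacts",
            call. = FALSE)
  structure(list(angles = angles, phase_maps = phase_maps,
                 geometry = geometry),
            class = "projection_series")
}

# Discrete Ram-Lak (ramp) filter frequency response of length n, built from
# the standard band-limited spatial kernel h(0) = 1/4, h(odd k) = -1/(pi k)^2
# (zero at even lags), as in textbook FBP implementations.  Returns the real
# nonnegative response in unshifted DFT order.
ramlak_response <- function(n) {
  k <- fft_freq(n) * n          # integer lags 0, 1, ..., -1
  h <- numeric(n)
  h[k == 0] <- 0.25
  odd <- (k %% 2) != 0
  h[odd] <- -1 / (pi * k[odd])^2
  2 * Re(stats::fft(h))         # factor 2: kernel defined for sampling 1/2
}

# Filtered back projection of one sinogram (n_angles x n_det) onto an
# n_det x n_det slice with linear interpolation.  Detector sampling and
# voxel pitch are treated as 1 (unit-spacing convention); physical scaling
# is applied afterwards by to_refractive_index().
fbp_slice <- function(sinogram, angles_deg) {
  n_ang <- nrow(sinogram)
  n_det <- ncol(sinogram)
  npad <- 2^ceiling(log2(2 * n_det))
  filt <- ramlak_response(npad)
  centre <- floor(n_det / 2) + 1
  xs <- seq_len(n_det) - centre
  xg <- matrix(xs, n_det, n_det, byrow = TRUE)
  yg <- matrix(xs, n_det, n_det)           # row = y, same centring as x
  out <- matrix(0, n_det, n_det)
  th <- angles_deg * pi / 180
  for (a in seq_len(n_ang)) {
    row <- numeric(npad)
    row[seq_len(n_det)] <- sinogram[a, ]
    frow <- Re(stats::fft(stats::fft(row) * filt, inverse = TRUE)) / npad
    frow <- frow[seq_len(n_det)]
    # detector coordinate of each voxel for this view
    s <- xg * cos(th[a]) + yg * sin(th[a]) + centre
    i0 <- floor(s)
    w <- s - i0
    ok <- i0 >= 1 & i0 < n_det
    acc <- matrix(0, n_det, n_det)
    acc[ok] <- (1 - w[ok]) * frow[i0[ok]] + w[ok] * frow[i0[ok] + 1L]
    out <- out + acc
  }
  out * pi / (2 * n_ang)
}

#' Slice-wise filtered back projection of a projection series
#'
#' Reconstructs a 3D volume channel from the per-angle retrieved phase maps
#' by standard parallel-beam FBP with the Ram-Lak filter, applied
#' independently at each vertical (row) position. The rotation axis is
#' assumed vertical through the grid centre column; `axis_offset` shifts it
#' by a (possibly fractional) number of pixels.
#'
#' Channel signs follow n = 1 - delta + i*beta: the physical exit phase for
#' `delta > 0` is negative, so the phase sinogram is `-Im(psi)` (making the
#' reconstructed delta positive) and the attenuation sinogram is `-Re(psi)`
#' (making beta positive).
#'
#' @param series A [projection_series()].
#' @param channel `"phase"` (reconstructs delta) or `"attenuation"`
#'   (reconstructs beta).
#' @param axis_offset Rotation-axis offset in pixels (default 0).
#' @return 3D array of shape `(ny, nx, nx)` in unit-spacing FBP values;
#'   convert with [to_refractive_index()].
#' @export
reconstruct_fbp <- function(series, channel = c("phase", "attenuation"),
                            axis_offset = 0) {
  channel <- match.arg(channel)
  stopifnot(inherits(series, "projection_series"))
  geom <- series$geometry
  n_ang <- length(series$angles)
  vol <- array(0, dim = c(geom$ny, geom$nx, geom$nx))
  maps <- lapply(series$phase_maps, function(p)
    if (channel == "phase") -Im(p) else -Re(p))
  for (iy in seq_len(geom$ny)) {
    sino <- t(vapply(maps, function(m) m[iy, ], numeric(geom$nx)))
    if (axis_offset != 0) {
      xs <- seq_len(geom$nx)
      sino <- t(apply(sino, 1, function(r)
        stats::approx(xs, r, xs + axis_offset, rule = 2)$y))
    }
    vol[iy, , ] <- fbp_slice(sino, series$angles)
  }
  vol
}

#' Convert unit-spacing FBP values to refractive-index units
#'
#' Retrieved phase projections are line integrals of \eqn{(2\pi/\lambda)
#' \delta} in metres; FBP with unit detector spacing therefore returns
#' \eqn{(2\pi/\lambda) \delta p} per voxel. Multiplying by the constant
#' \eqn{\lambda / p / (2\pi)} yields dimensionless \eqn{\delta} (or
#' \eqn{\beta} for the attenuation channel).
#'
#' @param volume 3D array from [reconstruct_fbp()].
#' @param geometry The [imaging_geometry()] (uses `wavelength` and `pitch`).
#' @return 3D array in refractive-index units.
#' @export
to_refractive_index <- function(volume, geometry) {
  volume * geometry$wavelength / geometry$pitch / (2 * pi)
}

#' Flatten residual low-frequency background of a tomogram
#'
#' Per-slice least-squares fit of a 2D quadratic
#' `a + b x + c y + d x^2 + e x y + f y^2` over the background voxels,
#' subtracted from the whole slice. Removes the slow background curvature
#' that the reduced low-frequency phase sensitivity leaves behind.
#'
#' @param volume 3D array `(ny, nx, nx)` (slices indexed by the first
#'   dimension).
#' @param mask Logical array of the same shape marking background voxels, or
#'   `NULL` for the default mask (voxels outside a centred cylinder of 90%
#'   of the slice width).
#' @return Flattened 3D array.
#' @export
flatten_background <- function(volume, mask = NULL) {
  d <- dim(volume)
  stopifnot(length(d) == 3)
  n <- d[2]
  if (is.null(mask)) {
    centre <- floor(n / 2) + 1
    xs <- seq_len(n) - centre
    rr <- sqrt(outer(xs^2, xs^2, "+"))
    slice_mask <- rr > 0.45 * n
    mask <- array(rep(slice_mask, each = d[1]), dim = d)
  }
  stopifnot(all(dim(mask) == d))
  xs <- seq_len(n)
  xg <- matrix(xs, n, n)
  yg <- matrix(xs, n, n, byrow = TRUE)
  X <- cbind(1, as.vector(xg), as.vector(yg), as.vector(xg)^2,
             as.vector(xg) * as.vector(yg), as.vector(yg)^2)
  out <- volume
  for (iy in seq_len(d[1])) {
    sl <- volume[iy, , ]
    mk <- as.vector(mask[iy, , ])
    if (sum(mk) < max(6, 0.01 * n * n))
      stop(sprintf("background mask covers too few voxels in slice %d", iy))
    fit <- tryCatch(stats::lm.fit(X[mk, , drop = FALSE], as.vector(sl)[mk]),
                    error = function(e) stop("degenerate background mask: ",
                                             conditionMessage(e)))
    if (any(is.na(fit$coefficients)))
      stop("degenerate background mask: quadratic fit is rank-deficient")
    out[iy, , ] <- sl - matrix(X %*% fit$coefficients, n, n)
  }
  out
}

#' Minimum projection count by the Crowther criterion
#'
#' Number of equally spaced projections over 0-180 degrees needed to
#' reconstruct an object of the given diameter at the given resolution:
#' \eqn{\mathrm{round}(\pi D / (2 d))}.
#'
#' @param diameter Object diameter in metres.
#' @param resolution Target resolution in metres.
#' @return Integer projection count.
#' @examples
#' crowther_min_angles(1e-3, 1.5e-6)  # 1047
#' @export
crowther_min_angles <- function(diameter, resolution) {
  stopifnot(diameter > 0, resolution > 0)
  as.integer(round(pi * diameter / (2 * resolution)))
}
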