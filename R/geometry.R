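#' Imaging geometry
#'
#' Bundles the fixed constants of a parallel-beam speckle imaging setup: grid
#' size, detector sampling period, X-ray wavelength and the two free-space
#' propagation distances (sample to diffuser, `L1`, and diffuser to detector,
#' `L2`).
#'
#' Conventions used throughout the package: matrix rows index `y` (vertical),
#' columns index `x` (horizontal); spatial frequencies `u` (along x) and `v`
#' (along y) are in physical cycles per metre in unshifted DFT order, so the
#' `[1, 1]` element of any Fourier-domain array is DC.
#'
#' @param nx,ny Number of pixels along x (columns) and y (rows).
#' @param pitch Sampling period in metres (e.g. `650e-9` for a 650 nm
#'   effective detector pixel).
#' @param wavelength X-ray wavelength in metres (e.g. `0.124e-9` at 10 keV).
#' @param L1 Sample-to-diffuser distance in metres.
#' @param L2 Diffuser-to-detector distance in metres.
#' @return An object of class `imaging_geometry`.
#' @examples
#' geom <- imaging_geometry(nx = 128, ny = 128, pitch = 650e-9,
#'                          wavelength = 0.124e-9, L1 = 3e-3, L2 = 20e-3)
#' geom
#' @export
imaging_geometry <- function(nx, ny, pitch, wavelength, L1 = 0, L2 = 0) {
  stopifnot(
    length(nx) == 1L, length(ny) == 1L, nx >= 2, ny >= 2,
    nx == round(nx), ny == round(ny),
    is.numeric(pitch), pitch > 0,
    is.numeric(wavelength), wavelength > 0,
    is.numeric(L1), L1 >= 0, is.numeric(L2), L2 >= 0
  )
  structure(
    list(nx = as.integer(nx), ny = as.integer(ny), pitch = pitch,
         wavelength = wavelength, L1 = L1, L2 = L2),
    class = "imaging_geometry"
  )
}

#' @export
print.imaging_geometry <- function(x, ...) {
  cat(sprintf("<imaging_geometry> %d x %d px, pitch %.4g m\n", x$nx, x$ny, x$pitch))
  cat(sprintf("  wavelength %.4g m, L1 %.4g m, L2 %.4g m\n",
              x$wavelength, x$L1, x$L2))
  cat(sprintf("  FOV %.4g m x %.4g m\n", x$nx * x$pitch, x$ny * x$pitch))
  invisible(x)
}

# DFT sample frequencies for n points at sampling period `pitch`,
# in unshifted order: 0, 1, ..., floor((n-1)/2), -ceiling((n-1)/2), ..., -1,
# each divided by n*pitch.  Matches the standard fftfreq convention.
fft_freq <- function(n, pitch = 1) {
  k <- c(0:floor((n - 1) / 2), -(ceiling((n - 1) / 2):1))
  k / (n * pitch)
}

#' Spatial-frequency grids for a geometry
#'
#' Returns the 2D arrays of horizontal (`u`) and vertical (`v`) spatial
#' frequencies, in cycles per metre, laid out in unshifted DFT order so they
#' multiply `fft()` output elementwise without any shifting.
#'
#' @param geometry An [imaging_geometry()].
#' @param per_pixel If `TRUE`, frequencies are returned in cycles per pixel
#'   (i.e. the pitch is treated as 1); used by the solver's preconditioner.
#' @return A list with `ny x nx` matrices `u` and `v`; element `[1, 1]` of
#'   each is 0 (DC).
#' @export
frequency_grids <- function(geometry, per_pixel = FALSE) {
  stopifnot(inherits(geometry, "imaging_geometry"))
  p <- if (per_pixel) 1 else geometry$pitch
  fu <- fft_freq(geometry$nx, p)
  fv <- fft_freq(geometry$ny, p)
  list(
    u = matrix(fu, nrow = geometry$ny, ncol = geometry$nx, byrow = TRUE),
    v = matrix(fv, nrow = geometry$ny, ncol = geometry$nx)
  )
}

# Real-space coordinate grids (metres) in the same unshifted ordering as the
# frequency grids, so a kernel built on them Fourier-transforms without
# fftshift bookkeeping: x_j in {0, pitch, ..., -pitch} wrapping at n/2.
space_grids <- function(geometry) {
  xs <- fft_freq(geometry$nx) * geometry$nx * geometry$pitch
  ys <- fft_freq(geometry$ny) * geometry$ny * geometry$pitch
  list(
    x = matrix(xs, nrow = geometry$ny, ncol = geometry$nx, byrow = TRUE),
    y = matrix(ys, nrow = geometry$ny, ncol = geometry$nx)
  )
}

# Centred real-space coordinates (metres): origin at the grid centre pixel
# (floor(n/2)+1).  Used for phantoms and back projection.
centred_grids <- function(geometry) {
  xs <- (seq_len(geometry$nx) - (floor(geometry$nx / 2) + 1)) * geometry$pitch
  ys <- (seq_len(geometry$ny) - (floor(geometry$ny / 2) + 1)) * geometry$pitch
  list(
    x = matrix(xs, nrow = geometry$ny, ncol = geometry$nx, byrow = TRUE),
    y = matrix(ys, nrow = geometry$ny, ncol = geometry$nx)
  )
}

# 2D FFT helpers: fft2/ifft2 form an exact inverse pair; ifft2 carries the
# 1/(nx*ny) factor.
fft2 <- function(m) stats::fft(m)
ifft2 <- function(m) stats::fft(m, inverse = TRUE) / length(m)

check_field <- function(values, geometry, what = "field") {
  if (!is.matrix(values) ||
      nrow(values) != geometry$ny || ncol(values) != geometry$nx) {
    stop(sprintf("%s must be a %d x %d matrix matching the geometry",
                 what, geometry$ny, geometry$nx))
  }
  if (!all(is.finite(Re(values))) || !all(is.finite(Im(values)))) {
    stop(sprintf("%s contains non-finite values", what))
  }
  invisible(values)
}
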