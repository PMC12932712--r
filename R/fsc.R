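#' Fourier shell correlation between two volumes
#'
#' Shell-wise normalized cross-correlation of the 3D Fourier transforms of
#' two independently reconstructed volumes:
#' \deqn{FSC(\kappa) = \frac{\mathrm{Re}\langle \tilde g_1^* \tilde g_2
#'   \rangle_{\|k\|=\kappa}}{\sqrt{\langle|\tilde g_1|^2\rangle
#'   \langle|\tilde g_2|^2\rangle}}}
#' Shells are one Fourier voxel wide on the unshifted DFT radius; the real
#' part of the cross term is used, as is standard practice.
#'
#' @param vol1,vol2 Real 3D arrays of identical (isotropic) shape.
#' @param voxel_pitch Voxel size in metres (sets the physical frequency
#'   axis).
#' @param shell_width Shell width in Fourier voxels (default 1).
#' @return An object of class `fsc_curve`: a data.frame with columns
#'   `radius` (cycles/metre, shell centre), `fsc`, and `n_voxels`, plus the
#'   voxel pitch as an attribute. The DC shell is excluded.
#' @export
fsc_curve <- function(vol1, vol2, voxel_pitch, shell_width = 1) {
  stopifnot(length(dim(vol1)) == 3, all(dim(vol1) == dim(vol2)),
            voxel_pitch > 0, shell_width >= 1)
  d <- dim(vol1)
  f1 <- stats::fft(vol1)
  f2 <- stats::fft(vol2)
  # radial index grid in Fourier voxels (unshifted), normalized per axis so
  # shells are spherical for cubic volumes and sensible for ny != nx
  ax <- lapply(d, function(n) fft_freq(n) * max(d))
  kk <- sqrt(outer(outer(ax[[1]]^2, ax[[2]]^2, "+"), ax[[3]]^2, "+"))
  n_shell <- floor(max(d) / 2 / shell_width)
  shell <- pmin(floor(kk / shell_width) + 1L, n_shell + 1L)
  cross <- as.vector(Re(Conj(f1) * f2))
  p1 <- as.vector(Mod(f1)^2)
  p2 <- as.vector(Mod(f2)^2)
  idx <- as.vector(shell)
  num <- tapply(cross, idx, sum)
  d1 <- tapply(p1, idx, sum)
  d2 <- tapply(p2, idx, sum)
  cnt <- tapply(rep(1, length(idx)), idx, sum)
  keep <- as.integer(names(num))
  keep <- keep[keep >= 2 & keep <= n_shell]   # drop DC shell and remainder
  sel <- as.character(keep)
  fsc <- num[sel] / sqrt(d1[sel] * d2[sel])
  # shell centre radius in cycles/metre: shell i covers [(i-1), i)*width
  # Fourier voxels; one Fourier voxel = 1/(max(d)*pitch) cycles/metre
  radius <- ((keep - 0.5) * shell_width) / (max(d) * voxel_pitch)
  structure(
    data.frame(radius = radius, fsc = as.numeric(fsc),
               n_voxels = as.numeric(cnt[sel])),
    class = c("fsc_curve", "data.frame"),
    voxel_pitch = voxel_pitch,
    nyquist = 1 / (2 * voxel_pitch)
  )
}

#' Resolution from an FSC curve at a threshold
#'
#' Locates the first crossing of the curve below the threshold by linear
#' interpolation between adjacent shells and returns `1 / kappa_cross` in
#' metres. If the curve never drops below the threshold, the Nyquist-limited
#' resolution `2 * voxel_pitch` is returned with `crossed = FALSE`.
#'
#' @param curve An [fsc_curve()].
#' @param threshold Criterion value (default 1/4; see [derive_threshold()]).
#' @return List with `resolution` (metres), `frequency` (cycles/metre) and
#'   logical `crossed`.
#' @export
resolution_at_threshold <- function(curve, threshold = 0.25) {
  stopifnot(inherits(curve, "fsc_curve"), nrow(curve) > 0)
  below <- which(curve$fsc < threshold)
  if (!length(below)) {
    return(list(resolution = 2 * attr(curve, "voxel_pitch"),
                frequency = attr(curve, "nyquist"), crossed = FALSE))
  }
  i <- below[1]
  if (i == 1) {
    k_cross <- curve$radius[1]
  } else {
    f0 <- curve$fsc[i - 1]; f1 <- curve$fsc[i]
    r0 <- curve$radius[i - 1]; r1 <- curve$radius[i]
    k_cross <- r0 + (f0 - threshold) / (f0 - f1) * (r1 - r0)
  }
  list(resolution = 1 / k_cross, frequency = k_cross, crossed = TRUE)
}

#' FSC threshold from a required signal-correlation floor
#'
#' If a shell is deemed reliable when the normalized correlation between the
#' data and the ideal signal is at least `c`, then, writing the correlation
#' as \eqn{\sqrt{S/(S+N)}} and the FSC of two independent measurements as
#' \eqn{S/(S+N)}, the corresponding FSC threshold is \eqn{c^2}. A floor of
#' 1/2 yields the 1/4 criterion used for single-measurement reconstructions.
#'
#' @param correlation_floor Required signal correlation in (0, 1).
#' @return FSC threshold (dimensionless).
#' @examples
#' derive_threshold(0.5)   # 0.25
#' @export
derive_threshold <- function(correlation_floor) {
  stopifnot(correlation_floor > 0, correlation_floor < 1)
  correlation_floor^2
}

#' @export
print.fsc_curve <- function(x, ...) {
  cat(sprintf("<fsc_curve> %d shells up to %.4g cycles/m\n",
              nrow(x), max(x$radius)))
  res <- resolution_at_threshold(x, 0.25)
  cat(sprintf("  resolution at 1/4 criterion: %.4g m (%s)\n",
              res$resolution,
              if (res$crossed) "crossed" else "not crossed; Nyquist bound"))
  invisible(x)
}

#' @export
plot.fsc_curve <- function(x, threshold = 0.25, ...) {
  plot(x$radius, x$fsc, type = "l", xlab = "spatial frequency (cycles/m)",
       ylab = "FSC", ylim = c(min(0, min(x$fsc)), 1), ...)
  graphics::abline(h = threshold, lty = 3)
  res <- resolution_at_threshold(x, threshold)
  if (res$crossed) graphics::abline(v = res$frequency, lty = 2, col = 2)
  invisible(x)
}

#' Write an FSC curve to CSV
#'
#' @param curve An [fsc_curve()].
#' @param path Output CSV path (columns: radius, fsc, voxels_per_shell).
#' @return `path`, invisibly.
#' @export
write_fsc_csv <- function(curve, path) {
  df <- data.frame(radius = curve$radius, fsc = curve$fsc,
                   voxels_per_shell = curve$n_voxels)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
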