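# Angular-spectrum kernel H(u, v) = exp(i 2 pi (d / lambda) sqrt(1 - (lambda
# u)^2 - (lambda v)^2)) on the geometry's frequency grid.  Evanescent
# components ((lambda u)^2 + (lambda v)^2 > 1) are hard-zeroed: at the
# millimetre-to-centimetre distances used here they are numerically zero
# anyway, and the hard zero keeps the adjoint exact.
asm_kernel <- function(geometry, distance, conjugate = FALSE) {
  fr <- frequency_grids(geometry)
  lam <- geometry$wavelength
  s2 <- 1 - (lam * fr$u)^2 - (lam * fr$v)^2
  prop <- s2 >= 0
  H <- matrix(0 + 0i, geometry$ny, geometry$nx)
  phase <- 2 * pi * (distance / lam) * sqrt(pmax(s2[prop], 0))
  H[prop] <- exp((if (conjugate) -1i else 1i) * phase)
  H
}

# Warn when the kernel phase changes by more than pi between adjacent
# frequency samples at the band edge: the sampled chirp is then aliased and
# wrap-around artifacts appear.  The bound below is |dphi/du| * du at
# u = 1/(2 pitch).
check_asm_sampling <- function(geometry, distance) {
  lam <- geometry$wavelength
  for (ax in list(c(geometry$nx, "x"), c(geometry$ny, "y"))) {
    n <- as.numeric(ax[[1]])
    u_edge <- 1 / (2 * geometry$pitch)
    du <- 1 / (n * geometry$pitch)
    s2 <- 1 - (lam * u_edge)^2
    if (s2 <= 0) next  # band edge already evanescent; no chirp to alias
    dphi <- 2 * pi * distance * lam * u_edge * du / sqrt(s2)
    if (dphi > pi) {
      pad <- ceiling(n * dphi / pi)
      warning(sprintf(
        paste0("angular-spectrum kernel is aliased along %s at distance ",
               "%.3g m (phase step %.2f rad > pi at the band edge); ",
               "consider padding the grid to >= %d samples"),
        ax[[2]], distance, dphi, pad), call. = FALSE)
      return(invisible(FALSE))
    }
  }
  invisible(TRUE)
}

#' Free-space propagation by the angular-spectrum method
#'
#' Propagates a monochromatic scalar field over a distance `d` by multiplying
#' its spatial-frequency spectrum with the exact propagation kernel
#' \eqn{H(u,v) = \exp[i 2\pi (d/\lambda)\sqrt{1-(\lambda u)^2-(\lambda v)^2}]}.
#' Evanescent frequencies are set to zero. `propagate(x, geom, 0)` is the
#' identity up to floating-point error, and for negative `d` the field is
#' propagated backwards.
#'
#' @param values Complex (or real) `ny x nx` matrix of field amplitudes.
#' @param geometry An [imaging_geometry()] supplying pitch and wavelength.
#' @param distance Propagation distance in metres (may be negative).
#' @return Complex matrix of the same shape.
#' @examples
#' geom <- imaging_geometry(64, 64, 650e-9, 0.124e-9)
#' pw <- matrix(1 + 0i, 64, 64)
#' out <- propagate(pw, geom, 1e-3)          # plane wave: global phase only
#' Mod(out[1, 1])
#' @seealso [propagate_adjoint()]
#' @export
propagate <- function(values, geometry, distance) {
  check_field(values, geometry)
  if (distance == 0) return(values + 0i)
  check_asm_sampling(geometry, distance)
  H <- asm_kernel(geometry, distance)
  ifft2(fft2(values) * H)
}

#' Adjoint of free-space propagation
#'
#' Applies the conjugate-transposed angular-spectrum kernel, i.e. the exact
#' adjoint of [propagate()] with respect to the unweighted inner product
#' \eqn{\langle a, b\rangle = \sum \bar a\, b}. Because the propagating band
#' of the kernel is unimodular, the adjoint coincides with propagation by
#' `-distance` followed by the same evanescent clipping.
#'
#' @inheritParams propagate
#' @return Complex matrix of the same shape.
#' @export
propagate_adjoint <- function(values, geometry, distance) {
  check_field(values, geometry)
  if (distance == 0) return(values + 0i)
  check_asm_sampling(geometry, distance)
  H <- asm_kernel(geometry, distance, conjugate = TRUE)
  ifft2(fft2(values) * H)
}
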