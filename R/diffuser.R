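#' Wiener deconvolution of an intensity image
#'
#' Removes a known blur in the Fourier domain with the regularized inverse
#' filter \eqn{OTF / (OTF^2 + nsr)}. With `nsr = 0` this reduces to plain
#' inverse filtering wherever the OTF is nonzero.
#'
#' @param values Real `ny x nx` intensity matrix.
#' @param otf Real transfer-function matrix of the same shape, in unshifted
#'   DFT order (DC at `[1, 1]`), with `otf[1, 1] > 0`.
#' @param nsr Scalar noise-to-signal power ratio (`>= 0`).
#' @return Deconvolved real matrix of the same shape.
#' @export
wiener_deconvolve <- function(values, otf, nsr = 1e-2) {
  stopifnot(is.matrix(values), all(dim(values) == dim(otf)),
            is.numeric(nsr), nsr >= 0, otf[1, 1] > 0)
  filt <- otf / (otf^2 + nsr)
  filt[otf == 0 & nsr == 0] <- 0
  Re(ifft2(fft2(values) * filt))
}

#' Estimate the diffuser transmission function from a reference speckle
#'
#' Reconstructs the complex diffuser-plane transmission `t` that the forward
#' model needs, from the (sample-free) reference speckle alone: the source
#' blur is removed by Wiener deconvolution with the calibrated IOTF, giving
#' an estimate of the coherent speckle intensity at the detector; its square
#' root with the phase fixed to zero is then numerically back-propagated over
#' `-L2` to the diffuser plane. The zero-phase convention leaves the true
#' diffuser phase unknown, but sample retrieval is insensitive to this
#' ambiguity for weakly scattering samples in a near-field setup.
#'
#' @param reference Flat-field-corrected reference speckle (mean near 1).
#' @param model A [coherence_model()] calibrated from the same reference.
#' @param geometry An [imaging_geometry()] (uses `L2`).
#' @param nsr Wiener noise-to-signal ratio (default `1e-2`).
#' @return List with `values` (complex transmission at the diffuser plane),
#'   and `clipped` (count of negative deconvolved pixels clipped to zero).
#' @export
estimate_transmission <- function(reference, model, geometry, nsr = 1e-2) {
  check_field(reference, geometry, "reference")
  dec <- wiener_deconvolve(reference, iotf(model, geometry), nsr)
  clipped <- sum(dec < 0)
  amp <- sqrt(pmax(dec, 0))
  tr <- propagate(amp + 0i, geometry, -geometry$L2)
  list(values = tr, clipped = clipped)
}
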