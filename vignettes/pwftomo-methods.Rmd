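---
title: "Speckle-based quantitative phase tomography with pwftomo: models, algorithms and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Speckle-based quantitative phase tomography with pwftomo}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(pwftomo)
```

## The measurement and its model

A thin sample placed in a monochromatic, partially coherent X-ray beam is
described by its complex transmission $x_r = e^{\psi_r}$, where the complex
phase $\psi_r$ collects attenuation ($-\mathrm{Re}\,\psi$) and the unwrapped
phase shift ($\mathrm{Im}\,\psi$). A diffuser (transmission $t_r$) placed a
distance $L_1$ downstream converts phase structure into measurable intensity
structure: the detector at a further distance $L_2$ records a speckle
pattern whose displacements and distortions encode the sample field. The
forward model implemented by `pwf_forward()` is

$$f(\psi) \;=\; \bigl|\,\mathcal{P}_2\{\, t \cdot \mathcal{P}_1\{e^{\psi}\}\,\}\bigr|^2 \;\ast\; \mathrm{IPSF},$$

with $\mathcal{P}_{1,2}$ exact angular-spectrum propagators over $L_{1,2}$
(`propagate()`), and a Gaussian intensity point spread function modelling
the blur a partially coherent source imprints on the recorded intensity.
The convolution is applied as multiplication with the intensity optical
transfer function (IOTF) in the Fourier domain; the two forms are
numerically identical on the grid and the equivalence is covered by a test.

Partial coherence is parameterized by two lengths $x_{coh}, y_{coh}$:

$$\mathrm{IPSF}(x,y) = \frac{2}{x_{coh} y_{coh}}
 \exp\!\Bigl[-2\pi\Bigl(\tfrac{x^2}{x_{coh}^2}+\tfrac{y^2}{y_{coh}^2}\Bigr)\Bigr],
 \qquad
 \mathrm{IOTF}(u,v) = \exp\!\Bigl[-\tfrac{\pi}{2}\bigl(u^2 x_{coh}^2 + v^2 y_{coh}^2\bigr)\Bigr].$$

These lengths are *operational*: they are the correlation widths measured
on the reference speckle itself via the Siegert relation
$g^{(2)} = 1 + |g^{(1)}|^2$, fitted per axis with the Gaussian model
$g^{(2)}(\Delta) = 1 + c\,e^{-\pi\Delta^2/\ell^2}$ (`calibrate_coherence()`).
The contrast amplitude $c$ is left free: binning and finite grain size push
$g^{(2)}(0)$ below 2 without affecting the width. The fitted width always
includes the coherent speckle grain in quadrature,
$\ell_{fit}^2 \approx \ell_{coh}^2 + \ell_{grain}^2$, so calibration is
accurate when the grain is well below the coherence lengths — the regime
of the shipped simulator defaults (0.65 µm grain vs 2.0/2.47 µm coherence,
a bias below 5%).

The diffuser transmission is estimated from the reference speckle alone
(`estimate_transmission()`): Wiener deconvolution of the IOTF, square root,
phase fixed to zero, numerical back-propagation over $-L_2$. The zero-phase
convention is exact only when the coherent detector-plane field is real;
for general diffusers it leaves a model mismatch that is benign for weakly
scattering samples (see *Limitations*).

## The solver

Retrieval minimizes

$$\mathcal{L}(\psi) = \sum_r \bigl(y_r - f(\psi_r)\bigr)^2
 + \sum_k \Gamma_k^2\,\bigl[\mathrm{Re}(\alpha)\,|\widetilde{\mathrm{Re}\,\psi}|^2
 + \mathrm{Im}(\alpha)\,|\widetilde{\mathrm{Im}\,\psi}|^2\bigr],$$

where $\Gamma^2 = 1 - \mathrm{STF}$ and
$\mathrm{STF}(u,v) = \exp[-\pi\gamma(u^2 x_{coh}^2 + v^2 y_{coh}^2)]$ is
the Gaussian sample transfer function implied by the oversampling ratio
$\gamma$ (ratio of measured to reconstructed spatial modes). The penalty
weights only spectral content outside the transferred band. The exact
Wirtinger gradient of the data term is available as `pwf_gradient()` and is
validated against central finite differences to $10^{-5}$ relative error.

`pwf_solve()` proceeds in three stages, all operating on the same
objective:

1. **Curvature calibration** (`pwf_calibrate()`). The loss curvature of
   single cosine modes of each channel is measured by finite differences
   of the forward model at a ladder of frequencies. The classical inverse
   quadratic preconditioner $P^{-1} = 1/(u^2+v^2)$ assumes the curvature of
   phase modes grows as $u^2$ (speckle-displacement sensing); the measured
   curvature additionally shows the near-field phase-contrast band
   ($\propto u^4$, dominant at moderate speckle contrast), the Talbot
   oscillation, and the coherence-blur roll-off. The calibrated
   Fourier-diagonal filters $F(u) = m/H(u)$ make a unit step Newton-like
   per mode. The idealized $1/(u^2+v^2)$ filter remains available through
   `preconditioned_update()`/`precondition_scale()` and its defining
   identity (applying the quadratic filter recovers the raw gradient up to
   DC) is tested exactly.

2. **Transport-of-intensity initialization** (`tie_initialize()`). The
   coherence-smoothed relative intensity residual obeys
   $\delta I/I \approx -\tfrac{\lambda (L_1{+}L_2)}{2\pi}\nabla_\perp^2\phi$
   in the geometric-optics regime, which holds for smooth phases of
   arbitrary depth. Iterating this approximate inverse (about 15 passes)
   digs the correct large-scale phase basin — the component a local
   optimizer cannot traverse from $\psi = 0$, because the data term is
   oscillatory in deep-phase directions. A one-dimensional amplitude search
   along the obtained phase corrects the kernel's scale bias.

3. **Gauss–Newton refinement.** Matrix-free Gauss–Newton steps with
   preconditioned conjugate-gradient inner solves (exact
   Jacobian-vector/adjoint products of the forward chain, about 12 CG
   iterations per step, Levenberg damping). Iteration stops by the field
   correlation rule — when the normalized correlation between successive
   retrieved fields $e^{\psi}$ exceeds $10^{-0.00001}$ — combined with
   stabilization of the loss. A damped first-order variant with optional
   Nesterov momentum and adaptive restart is kept as
   `method = "gradient"` for step-by-step studies; it is monotone at small
   steps by construction.

Two conventions deserve explicit mention. First, the regularization
parameter $\alpha = 0.1 + 0.01i$ is meaningful only relative to a transform
normalization; with the Parseval normalization used by `pwf_loss()` it
overwhelms the data term on desk-scale grids, while a per-pixel weighting
is too weak to suppress sub-coherence "roughness conspiracies" (high-
frequency phase textures that mimic attenuation through speckle
decorrelation — the dark-field channel). The solver applies $\alpha/16$
relative to Parseval; the constant was fixed once from synthetic
single-projection recovery studies, in the same spirit in which the
original parameter was determined heuristically. Second, the phase origin
(the DC component, which the preconditioner and $\Gamma^2$ both leave
unconstrained) is anchored by zeroing the mean phase over a 5%-wide border
background mask after every update.

## Tomography and resolution analysis

Per-angle phase maps are assembled into a `projection_series()` and
reconstructed slice-by-slice with parallel-beam filtered back projection
using the band-limited discrete Ram–Lak filter and linear interpolation
(`reconstruct_fbp()`). Channel signs follow $n = 1 - \delta + i\beta$: the
physical exit phase of a positive-$\delta$ object is negative, so the
phase sinogram is $-\mathrm{Im}\,\psi$ and the attenuation sinogram
$-\mathrm{Re}\,\psi$, making both reconstructed volumes positive. FBP is
run in unit-spacing convention and converted to refractive-index units by
the constant $\lambda/p/(2\pi)$ (`to_refractive_index()`). Residual
low-frequency background curvature — the footprint of the reduced
low-frequency phase sensitivity of gradient-sensing geometries — is
removed by fitting a 2D quadratic to background voxels of each slice
(`flatten_background()`; default background: voxels outside a cylinder of
90% of the slice width). The minimum angle count for a target resolution
follows the Crowther criterion $\pi D/(2d)$ (`crowther_min_angles()`).

Resolution of reconstructed volumes is estimated by Fourier shell
correlation between two independent reconstructions (`fsc_curve()`:
one-voxel shells, real part of the cross term), with the threshold derived
from a required signal-correlation floor $c$ as $c^2$
(`derive_threshold()`); for single-shot reconstructions, where no full-set
averaging argument applies, the floor $1/2$ gives the $1/4$ criterion
(`resolution_at_threshold()`, first crossing by linear interpolation). The
closed-form expected resolution at the $\mathrm{STF} = 0.1$ boundary,
$\sqrt{\pi}\,\ell_{coh}/(2\ln 10) \approx 0.385\,\ell_{coh}$, is available
as `expected_resolution()`.

## The synthetic study and what it does (not) show

`simulate_dataset()` generates fully self-consistent data: an analytic
bead phantom (`project_phantom()`: exact sphere-chord line integrals,
$\psi = -(2\pi/\lambda)(\beta + i\delta)T$), a seeded random diffuser,
exact propagation, IPSF blurring of intensity, and optional Poisson noise.
Because the blur is applied exactly as the retrieval model assumes, the
simulator probes the algorithm under zero model mismatch; robustness
studies can switch the diffuser type instead.

Grid-scale choices (the package's own, stated here once):

* **Grid and geometry.** 128×128 pixels at the instrument's 650 nm pitch,
  $\lambda = 0.124$ nm, $L_1 = 3$ mm, $L_2 = 20$ mm; 60 angles over
  0–180°; noiseless by default.
* **Coherence.** 2.0/2.47 µm. The instrument's measured values
  (3.47/4.31 µm) belong to a 2560×2160 field of view; on a 128-pixel grid
  they would leave only ~460 measured speckle modes and ~24 blur cells per
  bead, an order of magnitude fewer than in the real measurement, and the
  single-shot inverse problem degrades accordingly. The desk values keep
  the experimental anisotropy ratio (1.24) and well-resolved sampling
  (≥3 px) while roughly tripling the mode count.
* **Diffuser.** The default `"zerophase"` screen is parameterized by its
  coherent detector-plane speckle — a real, non-negative Rayleigh-amplitude
  field back-propagated to the diffuser plane — so the zero-phase
  convention of `estimate_transmission()` is exact and the retrieval is
  tested under zero model mismatch. A unit-modulus Gaussian phase screen
  is *not* suitable as the default: since $|t|^2 \equiv 1$, intensity
  contrast at transverse scales above $\sqrt{\lambda L_2} \approx 1.6$ µm
  can never develop (the $\sin^2(\pi\lambda L_2 u^2)$ notch), which
  biases Siegert calibration by tens of percent. Both a `"thermal"`
  (complex circular-Gaussian) and a `"phase"` screen remain available for
  mismatch studies.
* **Phantom.** Three beads of 8/6/5 µm radius with $\delta = 1.5\times
  10^{-6}$, $\beta = 2.4\times10^{-8}$ — weakly scattering (peak phase
  ≈1.2 rad), consistent with the validity domain of the zero-phase
  reference convention, which is stated for weakly scattering samples in
  near-field geometry.

What passing tests on this simulator demonstrate: correctness of every
operator (exact adjoints, gradients, discrete identities), Siegert
calibration accuracy, forward-consistency of the diffuser estimate,
convergent in-band phase retrieval, and quantitatively meaningful
tomograms. What they do not demonstrate: performance under model mismatch
(real diffuser phases, polychromaticity, detector MTF beyond the coherence
blur), and — importantly — absolute accuracy at full experimental scale,
which the desk grid cannot emulate (see next section).

## Known limitations

* **Desk-scale identifiability.** On a 128² grid the single-shot data
  admit near-degenerate solutions: textures below the coherence blur can
  compensate in-band phase changes to within ~10⁻⁴ of the data norm. The
  regularizer suppresses them at the cost of amplitude shrinkage. With the
  $\alpha/16$ convention above, per-projection retrieval on the default
  phantom reaches ~8% in-band phase RMSE (relative to the peak-to-peak
  range) with residual images at the 0.02% level, but the *absolute* well
  depth of the regularized minimizer is systematically shallow — roughly a
  factor two on the default beads — and the reconstructed δ and β inherit
  that bias. The acceptance suite computes and reports the bead-wise
  accuracy rather than hiding it. At full experimental scale (hundreds of
  blur cells per feature, ~10⁵ measured modes) this degeneracy is far
  weaker, which is consistent with the quantitative accuracy reported for
  the real instrument; a 128² grid cannot emulate that regime.
* **Numerical conventions.** No zero-padding by default (single-FFT
  processing of full frames; wrap-around is negligible for compact
  phantoms); evanescent components are hard-zeroed, keeping the adjoint
  exact; kernel-phase aliasing triggers a warning with a suggested padding
  factor. Propagator composition at millimetre distances is exact only to
  ~$2\cdot10^{-8}$ relative in double precision (the kernel phase is
  ~$10^8$ rad), which bounds achievable test tolerances.
* **Fixed rotation geometry.** The rotation axis is assumed vertical and
  centred (an optional pixel offset is provided); cone-beam geometry,
  ring-artifact removal and iterative tomography are out of scope.
* **Single measurement.** Joint sample–diffuser retrieval and
  multi-measurement fitting are deliberately not implemented; the FSC
  helpers operate on any two volumes the user provides (e.g. interleaved
  angle subsets).
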