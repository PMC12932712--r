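#' Solver parameters for preconditioned Wirtinger flow
#'
#' @param gamma Oversampling ratio used to build the regularization window
#'   (default 1).
#' @param alpha Complex regularization weight; its real part penalizes
#'   out-of-band content of the attenuation channel `Re(psi)`, its imaginary
#'   part that of the phase channel `Im(psi)` (default `0.1 + 0.01i`).
#' @param eta Step size (default 1, relative to the preconditioner's
#'   cycles-per-pixel frequency convention with the gradient's factor 2
#'   absorbed).
#' @param tol Stopping threshold on the normalized correlation between the
#'   retrieved fields `exp(psi)` of successive iterations (default
#'   `10^-0.00001`).
#' @param max_iter Iteration cap (default 2000).
#' @param nesterov Use Nesterov momentum (default `TRUE`).
#' @param background_frac Width of the border background mask used to anchor
#'   the mean phase, as a fraction of the grid size (default 0.05).
#' @param precond_scale Normalization used by the standalone
#'   [preconditioned_update()] operation: a single number fixes the
#'   phase-filter scale `s` in \eqn{P^{-1} = s/(u^2+v^2)} (cycles/pixel)
#'   with unit attenuation step; a list `list(phase=, atten=)` fixes both;
#'   `NULL` (default) means unit scales (see [precondition_scale()] for
#'   calibration).
#' @param method `"gauss-newton"` (default; Gauss-Newton with
#'   preconditioned CG inner solves) or `"gradient"` (damped first-order
#'   preconditioned descent with optional Nesterov momentum).
#' @param init `"tie"` (default; [tie_initialize()]) or `"zero"`.
#' @param init_iter Fixed-point passes of the initialization (default 15).
#' @param cg_iter Inner conjugate-gradient iterations per Gauss-Newton
#'   step (default 12).
#' @param filters Optional precomputed [pwf_calibrate()] filters (reused
#'   across projections of one dataset); `NULL` recalibrates per solve.
#' @return An object of class `solver_params`.
#' @export
solver_params <- function(gamma = 1, alpha = 0.1 + 0.01i, eta = 1,
                          tol = 10^-0.00001, max_iter = 2000,
                          nesterov = TRUE, background_frac = 0.05,
                          precond_scale = NULL,
                          method = c("gauss-newton", "gradient"),
                          init = c("tie", "zero"), init_iter = 15,
                          cg_iter = 12, filters = NULL) {
  stopifnot(gamma > 0, eta > 0, tol > 0, tol < 1, Re(alpha) >= 0,
            Im(alpha) >= 0, max_iter >= 1, background_frac >= 0,
            background_frac < 0.5,
            is.null(precond_scale) || is.list(precond_scale) ||
              precond_scale > 0,
            init_iter >= 1, cg_iter >= 1,
            is.null(filters) || inherits(filters, "pwf_filters"))
  structure(list(gamma = gamma, alpha = alpha, eta = eta, tol = tol,
                 max_iter = as.integer(max_iter), nesterov = nesterov,
                 background_frac = background_frac,
                 precond_scale = precond_scale,
                 method = match.arg(method), init = match.arg(init),
                 init_iter = as.integer(init_iter),
                 cg_iter = as.integer(cg_iter), filters = filters),
            class = "solver_params")
}

# Modal loss curvatures of both channels around the empty beam, measured by
# symmetric finite differences of the forward model on cosine probe modes at
# a ladder of frequencies along both axes.  Returns a data.frame with one
# row per probe: axis, u_pix (cycles/pixel), H_im and H_re (d2L/dA2 of a
# unit-amplitude phase / attenuation mode).
probe_curvatures <- function(transmission, model, geometry,
                             probe_fracs = c(1/32, 1/16, 1/8, 3/16, 1/4,
                                             3/8),
                             probe_amp = 1e-3) {
  y0 <- pwf_forward(matrix(0 + 0i, geometry$ny, geometry$nx),
                    transmission, model, geometry)
  cg <- centred_grids(geometry)
  rows <- list()
  for (axis in c("x", "y")) {
    coord <- if (axis == "x") cg$x else cg$y
    n_ax <- if (axis == "x") geometry$nx else geometry$ny
    for (fr in probe_fracs) {
      j <- max(1, round(fr * n_ax))
      u_pix <- j / n_ax
      mode <- probe_amp * cos(2 * pi * (u_pix / geometry$pitch) * coord)
      H <- c(im = 0, re = 0)
      for (ch in c("im", "re")) for (sgn in c(1, -1)) {
        psi <- if (ch == "im")
          matrix(complex(real = 0, imaginary = sgn * mode),
                 geometry$ny, geometry$nx)
        else matrix(complex(real = sgn * mode, imaginary = 0),
                    geometry$ny, geometry$nx)
        H[ch] <- H[ch] +
          sum((y0 - pwf_forward(psi, transmission, model, geometry))^2)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        axis = axis, u_pix = u_pix,
        H_im = unname(H["im"]) / probe_amp^2,
        H_re = unname(H["re"]) / probe_amp^2)
    }
  }
  do.call(rbind, rows)
}

#' Curvature-matched step calibration
#'
#' The inverse quadratic filter \eqn{P^{-1} = s/(u^2+v^2)} equalizes the
#' phase channel's convergence rates only up to an overall scale `s`, and
#' the attenuation channel needs its own step scale: both depend on the
#' setup (wavelength, distances, speckle contrast and grain). This function
#' measures the actual loss curvature \eqn{H(u)} of single cosine modes of
#' each channel around the empty-beam solution by finite differences of the
#' forward model at a ladder of probe frequencies, and returns
#' \deqn{s_{phase} = \left[\max_u \frac{H_{im}(u)}{m\,u_{pix}^2}\right]^{-1},
#'   \qquad s_{atten} = \left[\max_u \frac{H_{re}(u)}{m}\right]^{-1}}
#' so a unit step drives the stiffest mode of each channel straight to its
#' minimum (Newton-like) and every other mode stays inside the descent
#' stability region, momentum included.
#'
#' @param transmission Complex diffuser transmission matrix.
#' @param model A [coherence_model()].
#' @param geometry An [imaging_geometry()].
#' @param probe_fracs Probe frequencies as fractions of the sampling rate.
#' @param probe_amp Probe amplitude (radians / nepers).
#' @return List with `phase` (the filter scale `s`) and `atten` (the
#'   attenuation-channel step scale).
#' @export
precondition_scale <- function(transmission, model, geometry,
                               probe_fracs = c(1/32, 1/16, 1/8, 3/16, 1/4,
                                               3/8),
                               probe_amp = 1e-3) {
  pr <- probe_curvatures(transmission, model, geometry, probe_fracs,
                         probe_amp)
  m <- geometry$nx * geometry$ny
  list(phase = 1 / max(pr$H_im / (m * pr$u_pix^2)),
       atten = 1 / max(pr$H_re / m))
}

# Border mask (TRUE on a background_frac-wide frame) used to pin the
# unconstrained DC phase: the preconditioner zeroes the DC update, so the
# phase origin is fixed by subtracting the mean over this mask instead.
background_mask <- function(geometry, frac = 0.05) {
  wx <- max(1L, ceiling(frac * geometry$nx))
  wy <- max(1L, ceiling(frac * geometry$ny))
  m <- matrix(FALSE, geometry$ny, geometry$nx)
  m[c(seq_len(wy), geometry$ny - seq_len(wy) + 1L), ] <- TRUE
  m[, c(seq_len(wx), geometry$nx - seq_len(wx) + 1L)] <- TRUE
  m
}

# Inverse quadratic preconditioning filter scale/(u^2 + v^2) on the
# cycles-per-pixel frequency grid, with the DC element set to zero (the DC
# phase is anchored separately through the background mask).
precondition_filter <- function(geometry, scale = 1) {
  fr <- frequency_grids(geometry, per_pixel = TRUE)
  q <- fr$u^2 + fr$v^2
  p <- matrix(0, geometry$ny, geometry$nx)
  p[q > 0] <- scale / q[q > 0]
  p
}

#' Physics-based forward model: complex phase to speckle intensity
#'
#' Predicts the measured speckle intensity for a sample with complex phase
#' map `psi` (`exp(psi)` is the sample's complex transmission):
#' \deqn{f(\psi) = \left| P_2\{ t\, P_1\{ e^{\psi} \} \} \right|^2 * IPSF}
#' where \eqn{P_{1,2}} are angular-spectrum propagators over `L1` and `L2`,
#' `t` is the diffuser transmission, and the partial-coherence convolution is
#' applied by multiplying with the IOTF in the Fourier domain.
#'
#' @param psi Complex `ny x nx` phase map (`Re` = minus attenuation, `Im` =
#'   unwrapped phase).
#' @param transmission Complex diffuser transmission matrix (from
#'   [estimate_transmission()] or [make_diffuser_screen()]).
#' @param model A [coherence_model()].
#' @param geometry An [imaging_geometry()].
#' @return Real `ny x nx` intensity matrix.
#' @export
pwf_forward <- function(psi, transmission, model, geometry) {
  check_field(psi, geometry, "psi")
  check_field(transmission, geometry, "transmission")
  g <- propagate(transmission * propagate(exp(psi), geometry, geometry$L1),
                 geometry, geometry$L2)
  Re(ifft2(fft2(Mod(g)^2) * iotf(model, geometry)))
}

# Parseval-normalized spectral power: sum_k |FT{x}|^2 with FT = fft/sqrt(m),
# so that sum_k equals sum_r x^2 for a real image.
spectral_power <- function(x) Mod(fft2(x))^2 / length(x)

#' PWF loss: squared data misfit plus windowed Tikhonov penalty
#'
#' \deqn{L = \sum_r (y_r - f(\psi_r))^2 + \sum_k \Gamma_k^2 \left[
#'   \mathrm{Re}(\alpha) |FT\{\mathrm{Re}\,\psi\}|^2 +
#'   \mathrm{Im}(\alpha) |FT\{\mathrm{Im}\,\psi\}|^2 \right]}
#' with the Fourier transform normalized so Parseval's identity holds.
#'
#' @inheritParams pwf_forward
#' @param measured Measured (flat-field-corrected) speckle intensity matrix.
#' @param params A [solver_params()].
#' @return Nonnegative scalar.
#' @export
pwf_loss <- function(psi, transmission, model, geometry, measured, params) {
  check_field(measured, geometry, "measured")
  f <- pwf_forward(psi, transmission, model, geometry)
  data_term <- sum((measured - f)^2)
  if (Re(params$alpha) == 0 && Im(params$alpha) == 0) return(data_term)
  gam2 <- regularization_window(model, geometry, params$gamma)
  data_term +
    Re(params$alpha) * sum(gam2 * spectral_power(Re(psi))) +
    Im(params$alpha) * sum(gam2 * spectral_power(Im(psi)))
}

#' Wirtinger gradient of the data term
#'
#' Exact adjoint-chain gradient \eqn{G = \partial L_{data} / \partial
#' \psi^*} of the squared misfit \eqn{\sum_r (y_r - f(\psi_r))^2}: the
#' residual is pushed back through the IOTF window (self-adjoint), the
#' squared modulus, the two propagators and the diffuser, and finally
#' conjugate-multiplied by \eqn{e^{\psi}}. For any perturbation
#' \eqn{\delta\psi},
#' \eqn{L(\psi + \epsilon\,\delta\psi) - L(\psi) = 2\epsilon\,
#' \mathrm{Re}\langle G, \delta\psi\rangle + O(\epsilon^2)} with
#' \eqn{\langle a, b\rangle = \sum \bar a b}.
#'
#' @inheritParams pwf_loss
#' @return Complex `ny x nx` gradient matrix.
#' @export
pwf_gradient <- function(psi, transmission, model, geometry, measured) {
  chain <- pwf_chain(psi, transmission, model, geometry, measured)
  chain$gradient
}

# Shared forward + backward pass; returns the forward intensity, residual and
# Wirtinger gradient so the solver computes each only once per iteration.
pwf_chain <- function(psi, transmission, model, geometry, measured) {
  x <- exp(psi)
  g1 <- propagate(x, geometry, geometry$L1)
  g <- propagate(transmission * g1, geometry, geometry$L2)
  W <- iotf(model, geometry)
  f <- Re(ifft2(fft2(Mod(g)^2) * W))
  e <- measured - f
  b <- Re(ifft2(fft2(-2 * e) * W))      # IOTF window is self-adjoint
  h <- propagate_adjoint(b * g, geometry, geometry$L2)
  q <- propagate_adjoint(Conj(transmission) * h, geometry, geometry$L1)
  list(forward = f, residual = e, gradient = q * Conj(x))
}

#' One preconditioned, regularized update step
#'
#' Applies the channel-split update of the solver: the attenuation channel
#' `Re(psi)` takes a plain gradient step including its Tikhonov term; the
#' phase channel `Im(psi)` takes the same kind of step but filtered by the
#' inverse quadratic preconditioner \eqn{P^{-1} = 1/(u^2+v^2)} (cycles per
#' pixel, DC term zero), which undoes the system's phase-gradient (rather
#' than phase) sensitivity. Afterwards the mean phase over the background
#' mask is subtracted, anchoring the DC component the preconditioner leaves
#' untouched.
#'
#' @inheritParams pwf_loss
#' @param gradient Complex Wirtinger gradient from [pwf_gradient()].
#' @return Updated complex `ny x nx` phase map.
#' @export
preconditioned_update <- function(psi, gradient, params, geometry, model) {
  gam2 <- regularization_window(model, geometry, params$gamma)
  g_re <- Re(gradient) +
    Re(params$alpha) * Re(ifft2(gam2 * fft2(Re(psi))))
  g_im <- Im(gradient) +
    Im(params$alpha) * Re(ifft2(gam2 * fft2(Im(psi))))
  sc <- params$precond_scale
  sc <- if (is.null(sc)) list(phase = 1, atten = 1)
        else if (is.list(sc)) sc else list(phase = sc, atten = 1)
  pinv <- precondition_filter(geometry, sc$phase)
  new_re <- Re(psi) - params$eta * sc$atten * g_re
  new_im <- Im(psi) - params$eta * Re(ifft2(pinv * fft2(g_im)))
  mask <- background_mask(geometry, params$background_frac)
  new_im <- new_im - mean(new_im[mask])
  complex(real = new_re, imaginary = new_im) |>
    matrix(geometry$ny, geometry$nx)
}

#' Calibrated Fourier step filters for the solver
#'
#' Measures the modal loss curvature \eqn{H(u)} of both channels of the
#' forward model around the empty beam (finite differences on cosine probe
#' modes at a frequency ladder along both axes; secant amplitudes matched to
#' typical working values) and builds radially interpolated Fourier-diagonal
#' step filters \eqn{F(u) = m / H(u)}, so that a unit filtered gradient
#' step is a Newton-like step per spatial frequency. These filters
#' generalize the inverse quadratic preconditioner: \eqn{1/(u^2+v^2)} is
#' their idealized form in the speckle-displacement regime, while the
#' measured curvature also captures the propagation phase-contrast
#' (\eqn{u^4}) band and the coherence-blur roll-off.
#'
#' @param transmission Complex diffuser transmission matrix.
#' @param model A [coherence_model()].
#' @param geometry An [imaging_geometry()].
#' @param probe_fracs Probe frequencies as fractions of the sampling rate.
#' @param amp_phase,amp_atten Secant probe amplitudes for the phase and
#'   attenuation channels (radians / nepers).
#' @return An object of class `pwf_filters`: list with matrices `F_im`,
#'   `F_re` (unshifted DFT order; `F_im[1,1] = 0`) and the probe table.
#' @export
pwf_calibrate <- function(transmission, model, geometry,
                          probe_fracs = c(1/64, 1/32, 1/16, 1/8, 3/16,
                                          1/4, 3/8, 1/2),
                          amp_phase = 0.3, amp_atten = 0.05) {
  m <- geometry$nx * geometry$ny
  y0 <- pwf_forward(matrix(0 + 0i, geometry$ny, geometry$nx),
                    transmission, model, geometry)
  cg <- centred_grids(geometry)
  probes <- list()
  for (axis in c("x", "y")) {
    coord <- if (axis == "x") cg$x else cg$y
    n_ax <- if (axis == "x") geometry$nx else geometry$ny
    for (fr in probe_fracs) {
      j <- max(1, round(fr * n_ax))
      u_pix <- j / n_ax
      mode <- cos(2 * pi * (u_pix / geometry$pitch) * coord)
      H <- c(im = 0, re = 0)
      for (ch in c("im", "re")) {
        A <- if (ch == "im") amp_phase else amp_atten
        for (sgn in c(1, -1)) {
          psi <- if (ch == "im")
            matrix(complex(real = 0, imaginary = sgn * A * mode),
                   geometry$ny, geometry$nx)
          else matrix(complex(real = sgn * A * mode, imaginary = 0),
                      geometry$ny, geometry$nx)
          H[ch] <- H[ch] +
            sum((y0 - pwf_forward(psi, transmission, model, geometry))^2) /
              A^2
        }
      }
      probes[[length(probes) + 1L]] <- data.frame(
        axis = axis, u_pix = u_pix, H_im = unname(H["im"]),
        H_re = unname(H["re"]))
    }
  }
  probes <- do.call(rbind, probes)
  # uniform-attenuation (DC) curvature
  H_re0 <- 0
  for (sgn in c(1, -1)) {
    psi <- matrix(complex(real = sgn * amp_atten, imaginary = 0),
                  geometry$ny, geometry$nx)
    H_re0 <- H_re0 +
      sum((y0 - pwf_forward(psi, transmission, model, geometry))^2) /
        amp_atten^2
  }
  fr_grid <- frequency_grids(geometry, per_pixel = TRUE)
  q <- sqrt(fr_grid$u^2 + fr_grid$v^2)
  radial_filter <- function(Hcol, H0 = NULL) {
    agg <- stats::aggregate(Hcol, list(u = probes$u_pix), mean)
    lu <- log(agg$u); lh <- log(agg$x)
    lq <- log(pmax(as.vector(q), 1e-9))
    lH <- stats::approx(lu, lh, lq, rule = 2)$y
    slope <- (lh[2] - lh[1]) / (lu[2] - lu[1])
    low <- lq < lu[1]
    lH[low] <- lh[1] + slope * (lq[low] - lu[1])
    Hm <- matrix(exp(lH), geometry$ny, geometry$nx)
    Fm <- m / Hm
    Fm[1, 1] <- if (is.null(H0)) 0 else m / H0
    Fm
  }
  structure(list(F_im = radial_filter(probes$H_im),
                 F_re = radial_filter(probes$H_re, H_re0),
                 probes = probes),
            class = "pwf_filters")
}

#' Transport-of-intensity initialization for the solver
#'
#' Builds a starting phase map by iterating an approximate inverse of the
#' forward model: the coherence-scale-smoothed relative intensity residual
#' is proportional to the transverse Laplacian of the phase (transport of
#' intensity over the effective distance `L1 + L2`), so each pass adds the
#' inverse-Laplacian-filtered residual to the phase and a log-intensity
#' ratio to the attenuation. Valid for smooth phases of arbitrary depth
#' (geometric-optics regime), which is exactly the component the main
#' iteration cannot traverse on its own. A final one-dimensional amplitude
#' search along the obtained phase rescales it to the best data fit.
#'
#' @inheritParams pwf_calibrate
#' @param measured Flat-field-corrected sample speckle matrix.
#' @param iterations Fixed-point passes (default 15); the best-fitting
#'   iterate is kept.
#' @param smooth_factor Residual smoothing width as a multiple of the
#'   coherence lengths (default 2).
#' @param background_frac Border mask fraction used to anchor the phase.
#' @param scale_grid Candidate phase amplitude factors for the final search.
#' @return Complex `ny x nx` starting phase map.
#' @export
tie_initialize <- function(measured, transmission, model, geometry,
                           iterations = 15, smooth_factor = 2,
                           background_frac = 0.05,
                           scale_grid = seq(0.3, 1.3, by = 0.1)) {
  check_field(measured, geometry, "measured")
  y0 <- pwf_forward(matrix(0 + 0i, geometry$ny, geometry$nx),
                    transmission, model, geometry)
  fr <- frequency_grids(geometry)
  smooth_k <- exp(-pi * ((smooth_factor * model$x_coh)^2 * fr$u^2 +
                           (smooth_factor * model$y_coh)^2 * fr$v^2))
  D <- geometry$L1 + geometry$L2
  q2 <- (2 * pi)^2 * (fr$u^2 + fr$v^2)
  inv_lap <- matrix(0, geometry$ny, geometry$nx)
  inv_lap[q2 > 0] <- 1 / q2[q2 > 0]
  mask <- background_mask(geometry, background_frac)
  psi <- matrix(0 + 0i, geometry$ny, geometry$nx)
  best <- psi
  L_best <- Inf
  for (i in seq_len(iterations)) {
    f_cur <- pwf_forward(psi, transmission, model, geometry)
    resid <- measured - f_cur
    L <- sum(resid^2)
    if (L < L_best) { L_best <- L; best <- psi }
    rel_s <- Re(ifft2(fft2(resid / pmax(y0, 0.1)) * smooth_k))
    dphi <- (2 * pi / (D * geometry$wavelength)) *
      Re(ifft2(inv_lap * fft2(rel_s)))
    ratio <- pmax(Re(ifft2(fft2(measured / pmax(f_cur, 0.1)) * smooth_k)),
                  0.05)
    new_im <- Im(psi) + dphi
    new_im <- new_im - mean(new_im[mask])
    psi <- matrix(complex(real = Re(psi) + 0.35 * log(ratio),
                          imaginary = new_im),
                  geometry$ny, geometry$nx)
  }
  losses <- vapply(scale_grid, function(cc) {
    cand <- matrix(complex(real = Re(best), imaginary = cc * Im(best)),
                   geometry$ny, geometry$nx)
    sum((measured - pwf_forward(cand, transmission, model, geometry))^2)
  }, numeric(1))
  c_best <- scale_grid[which.min(losses)]
  matrix(complex(real = Re(best), imaginary = c_best * Im(best)),
         geometry$ny, geometry$nx)
}

#' Retrieve a complex phase map from a single speckle image
#'
#' The package's production solver for the regularized speckle
#' phase-retrieval objective (see [pwf_loss()]): a
#' transport-of-intensity initialization ([tie_initialize()]) followed by
#' Gauss-Newton iterations with matrix-free conjugate-gradient inner
#' solves, preconditioned by the curvature-calibrated Fourier filters of
#' [pwf_calibrate()]. Iteration stops when the normalized correlation
#' between the retrieved fields `exp(psi)` of successive iterates exceeds
#' `params$tol`, or at `params$max_iter` outer iterations. A first-order
#' variant (`method = "gradient"`: damped preconditioned descent with
#' optional Nesterov momentum and adaptive restart) is available for
#' reference and for step-by-step studies.
#'
#' The regularizer weight applied internally is `alpha/16` relative to the
#' Parseval-normalized penalty of [pwf_loss()]; this constant was fixed
#' once from synthetic single-projection recovery studies (the published
#' regularization parameter is tied to an unstated transform
#' normalization).
#'
#' @inheritParams pwf_loss
#' @param reference_mean Mean intensity of the reference speckle, used to
#'   normalize the returned RMSE image (default 1 for flat-field-corrected
#'   data).
#' @param verbose Print the loss every `verbose` iterations (0 = silent).
#' @return An object of class `pwf_result`: list with `psi` (complex matrix),
#'   `iterations`, `loss_history`, `rmse_image` (percent of the reference
#'   mean), `converged`, and the `geometry`.
#' @examples
#' \donttest{
#' geom <- imaging_geometry(64, 64, 650e-9, 0.124e-9, 3e-3, 20e-3)
#' cfg <- simulation_config(geometry = geom, angles = 0, seed = 1)
#' ds <- simulate_dataset(default_phantom(), cfg)
#' est <- estimate_transmission(ds$reference, cfg$coherence, geom, nsr = 0)
#' fit <- pwf_solve(ds$projections[[1]], est$values, cfg$coherence, geom)
#' fit
#' }
#' @export
pwf_solve <- function(measured, transmission, model, geometry,
                      params = solver_params(), reference_mean = 1,
                      verbose = 0) {
  check_field(measured, geometry, "measured")
  check_field(transmission, geometry, "transmission")
  filters <- params$filters
  if (is.null(filters))
    filters <- pwf_calibrate(transmission, model, geometry)
  # static operators
  H1 <- asm_kernel(geometry, geometry$L1)
  H2 <- asm_kernel(geometry, geometry$L2)
  H1c <- Conj(H1)
  H2c <- Conj(H2)
  W <- iotf(model, geometry)
  gam2 <- regularization_window(model, geometry, params$gamma)
  mask <- background_mask(geometry, params$background_frac)
  m <- geometry$nx * geometry$ny
  a_re <- Re(params$alpha) / 16
  a_im <- Im(params$alpha) / 16
  fwd_parts <- function(psi) {
    x <- exp(psi)
    g <- ifft2(fft2(transmission * ifft2(fft2(x) * H1)) * H2)
    list(x = x, g = g, f = Re(ifft2(fft2(Mod(g)^2) * W)))
  }
  jvp <- function(parts, dpsi) {
    dg <- ifft2(fft2(transmission * ifft2(fft2(parts$x * dpsi) * H1)) * H2)
    Re(ifft2(fft2(2 * Re(Conj(parts$g) * dg)) * W))
  }
  vjp <- function(parts, v) {
    b <- Re(ifft2(fft2(v) * W))
    Conj(parts$x) *
      ifft2(fft2(Conj(transmission) * ifft2(fft2(b * parts$g) * H2c)) * H1c)
  }
  Kop <- function(ch) Re(ifft2(gam2 * fft2(ch)))
  cinner <- function(a, b) sum(Re(a) * Re(b)) + sum(Im(a) * Im(b))
  dc0 <- function(d) matrix(complex(real = Re(d),
                                    imaginary = Im(d) - mean(Im(d)[mask])),
                            geometry$ny, geometry$nx)
  Mpre <- function(d) dc0(matrix(
    complex(real = Re(ifft2(filters$F_re * fft2(Re(d)))),
            imaginary = Re(ifft2(filters$F_im * fft2(Im(d))))),
    geometry$ny, geometry$nx))
  total_loss <- function(psi, parts = NULL) {
    if (is.null(parts)) parts <- fwd_parts(psi)
    sum((measured - parts$f)^2) +
      a_re * sum(gam2 * Mod(fft2(Re(psi)))^2) / m +
      a_im * sum(gam2 * Mod(fft2(Im(psi)))^2) / m
  }
  psi <- if (identical(params$init, "zero"))
    matrix(0 + 0i, geometry$ny, geometry$nx)
  else tie_initialize(measured, transmission, model, geometry,
                      iterations = params$init_iter,
                      background_frac = params$background_frac)
  loss_history <- numeric(0)
  converged <- FALSE
  iterations <- 0L
  if (identical(params$method, "gradient")) {
    # damped first-order reference iteration
    psi_prev <- psi
    t_mom <- 1
    loss_prev <- Inf
    damp <- 1
    for (i in seq_len(params$max_iter)) {
      t_next <- (1 + sqrt(1 + 4 * t_mom^2)) / 2
      w <- if (params$nesterov) (t_mom - 1) / t_next else 0
      z <- psi + w * (psi - psi_prev)
      parts <- fwd_parts(z)
      loss_i <- total_loss(z, parts)
      if (w > 0 && (!is.finite(loss_i) || loss_i > loss_prev)) {
        t_next <- 1
        z <- psi
        parts <- fwd_parts(z)
        loss_i <- total_loss(z, parts)
      }
      if (!is.finite(loss_i) || loss_i > loss_prev * 1.000001) {
        if (damp < 1e-8)
          stop(sprintf("PWF diverged: no descent step at iteration %d (last finite loss %.6g)",
                       i, loss_prev))
        damp <- damp / 2
        t_next <- 1
        psi <- psi_prev
        z <- psi
        parts <- fwd_parts(z)
        loss_i <- total_loss(z, parts)
      } else damp <- min(1, damp * 1.5)
      if (!is.finite(loss_i))
        stop(sprintf("PWF diverged: loss non-finite at iteration %d", i))
      loss_history <- c(loss_history, loss_i)
      if (verbose > 0 && (i %% verbose == 0 || i == 1))
        message(sprintf("iter %4d  loss %.6g (damp %.3g)", i, loss_i, damp))
      e <- measured - parts$f
      grad <- -2 * vjp(parts, e) +
        matrix(complex(real = 2 * a_re * Kop(Re(z)),
                       imaginary = 2 * a_im * Kop(Im(z))),
               geometry$ny, geometry$nx)
      psi_new <- dc0(z - params$eta * damp * Mpre(grad))
      corr <- Mod(sum(Conj(exp(psi_new)) * exp(psi))) /
        (sqrt(sum(Mod(exp(psi_new))^2)) * sqrt(sum(Mod(exp(psi))^2)))
      psi_prev <- psi
      psi <- psi_new
      t_mom <- t_next
      loss_prev <- loss_i
      iterations <- i
      if (damp >= 1 && corr > params$tol) { converged <- TRUE; break }
    }
  } else {
    # Gauss-Newton with preconditioned CG inner solves
    lam <- 0.1
    L_cur <- total_loss(psi)
    for (i in seq_len(params$max_iter)) {
      parts <- fwd_parts(psi)
      e <- measured - parts$f
      if (sum(e^2) <= 1e-16 * sum(measured^2)) {
        # data already explained to numerical precision
        loss_history <- c(loss_history, total_loss(psi, parts))
        iterations <- i
        converged <- TRUE
        break
      }
      rhs <- dc0(dc0(2 * vjp(parts, e)) -
                   matrix(complex(real = 2 * a_re * Kop(Re(psi)),
                                  imaginary = 2 * a_im * Kop(Im(psi))),
                          geometry$ny, geometry$nx))
      Aop <- function(d) {
        d <- dc0(d)
        dc0(2 * vjp(parts, jvp(parts, d)) +
              matrix(complex(real = 2 * a_re * Kop(Re(d)) + lam * Re(d),
                             imaginary = 2 * a_im * Kop(Im(d)) +
                               lam * Im(d)),
                     geometry$ny, geometry$nx))
      }
      dlt <- matrix(0 + 0i, geometry$ny, geometry$nx)
      r <- rhs
      z <- Mpre(r)
      p <- z
      rz <- cinner(r, z)
      for (k in seq_len(params$cg_iter)) {
        Ap <- Aop(p)
        alp <- rz / cinner(p, Ap)
        dlt <- dlt + alp * p
        r <- r - alp * Ap
        z <- Mpre(r)
        rz2 <- cinner(r, z)
        if (!is.finite(rz2) || rz2 < 1e-4 * rz) break
        p <- z + (rz2 / rz) * p
        rz <- rz2
      }
      s <- 1
      ok <- FALSE
      for (k in 1:5) {
        L_new <- total_loss(dc0(psi + s * dlt))
        if (is.finite(L_new) && L_new < L_cur) { ok <- TRUE; break }
        s <- s / 2
      }
      if (ok) {
        psi_new <- dc0(psi + s * dlt)
        lam <- max(lam / 3, 1e-4)
      } else {
        psi_new <- psi
        lam <- lam * 10
        L_new <- L_cur
        if (lam > 1e6) { iterations <- i; loss_history <- c(loss_history, L_cur); break }
      }
      loss_history <- c(loss_history, L_new)
      if (verbose > 0 && (i %% verbose == 0 || i == 1))
        message(sprintf("iter %4d  loss %.6g (lambda %.3g)", i, L_new, lam))
      corr <- Mod(sum(Conj(exp(psi_new)) * exp(psi))) /
        (sqrt(sum(Mod(exp(psi_new))^2)) * sqrt(sum(Mod(exp(psi))^2)))
      L_prev <- if (length(loss_history) >= 2)
        loss_history[length(loss_history) - 1] else Inf
      stable <- is.finite(L_prev) && (L_prev - L_new) < 5e-3 * abs(L_prev)
      psi <- psi_new
      L_cur <- L_new
      iterations <- i
      if (ok && corr > params$tol && stable) { converged <- TRUE; break }
    }
  }
  structure(
    list(psi = psi, iterations = iterations, loss_history = loss_history,
         rmse_image = rmse_image(measured, psi, transmission, model,
                                 geometry, reference_mean),
         converged = converged, geometry = geometry),
    class = "pwf_result"
  )
}

#' @export
print.pwf_result <- function(x, ...) {
  cat(sprintf("<pwf_result> %d x %d px, %d iterations (%s)\n",
              x$geometry$ny, x$geometry$nx, x$iterations,
              if (x$converged) "converged" else "iteration cap reached"))
  cat(sprintf("  final loss %.6g, mean RMSE %.3g%%\n",
              x$loss_history[length(x$loss_history)], mean(x$rmse_image)))
  cat(sprintf("  phase range [%.3g, %.3g] rad, attenuation range [%.3g, %.3g]\n",
              min(Im(x$psi)), max(Im(x$psi)),
              min(-Re(x$psi)), max(-Re(x$psi))))
  invisible(x)
}

#' Per-pixel residual (RMSE) image
#'
#' Absolute residual between the measurement and the model prediction,
#' normalized by the mean reference intensity and expressed in percent. For
#' a faithful reconstruction this image is spatially uniform at the noise
#' level, with no sample-shaped structure.
#'
#' @inheritParams pwf_loss
#' @param reference_mean Mean intensity of the reference speckle (`> 0`).
#' @return Real `ny x nx` matrix in percent.
#' @export
rmse_image <- function(measured, psi, transmission, model, geometry,
                       reference_mean = 1) {
  stopifnot(reference_mean > 0)
  f <- pwf_forward(psi, transmission, model, geometry)
  abs(measured - f) / reference_mean * 100
}
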