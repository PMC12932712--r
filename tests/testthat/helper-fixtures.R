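# Shared fixtures, built once per test run and memoised in this environment.
# Geometry mirrors the reference setup (10 keV, 650 nm pitch, L1 = 3 mm,
# L2 = 20 mm) at desk-scale grid sizes.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

test_geometry <- function(n = 64) {
  imaging_geometry(n, n, 650e-9, 0.124e-9, 3e-3, 20e-3)
}

test_model <- function() coherence_model(3.47e-6, 4.31e-6)

# coherence used by the simulator fixtures (desk-scaled defaults)
fixture_model <- function() simulation_config()$coherence

# single-angle 128^2 noiseless dataset with ground truth
fixture_single <- function() {
  memo("single", {
    cfg <- simulation_config(geometry = test_geometry(128), angles = 0,
                             seed = 3)
    simulate_dataset(default_phantom(), cfg)
  })
}

# estimated diffuser transmission for fixture_single
fixture_transmission <- function() {
  memo("transmission", {
    ds <- fixture_single()
    estimate_transmission(ds$reference, fixture_model(), ds$geometry,
                          nsr = 0)
  })
}

# solver step filters for the fixture, computed once
fixture_filters <- function() {
  memo("filters", {
    ds <- fixture_single()
    pwf_calibrate(fixture_transmission()$values, fixture_model(),
                  ds$geometry)
  })
}

# random complex field matrices
random_field <- function(n, sd = 1) {
  matrix(complex(real = stats::rnorm(n * n, sd = sd),
                 imaginary = stats::rnorm(n * n, sd = sd)), n, n)
}

# random plausible phase map: negative real part, phase of order a radian
random_psi <- function(n, atten_sd = 0.05, phase_sd = 0.5) {
  matrix(complex(real = -abs(stats::rnorm(n * n, sd = atten_sd)),
                 imaginary = stats::rnorm(n * n, sd = phase_sd)), n, n)
}

# analytic parallel-beam sinogram of a centred disc of radius R (in pixels):
# chord length 2*sqrt(R^2 - s^2) for detector coordinate s
disc_sinogram <- function(n_det, angles_deg, radius_px,
                          centre = c(0, 0)) {
  ctr <- floor(n_det / 2) + 1
  s_axis <- seq_len(n_det) - ctr
  t(vapply(angles_deg * pi / 180, function(th) {
    sc <- centre[1] * cos(th) + centre[2] * sin(th)
    d2 <- radius_px^2 - (s_axis - sc)^2
    2 * sqrt(pmax(d2, 0))
  }, numeric(n_det)))
}
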