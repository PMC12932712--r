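test_that("phantom projections are analytic sphere chords", {
  geom <- test_geometry(64)
  k <- 2 * pi / geom$wavelength
  R <- 8e-6
  ph <- bead_phantom(cbind(0, 0, 0), R, delta = 5.4e-6, beta = 2.4e-8)
  psi <- project_phantom(ph, 0, geom)
  ctr <- floor(64 / 2) + 1
  # central ray: chord 2R
  expect_equal(Im(psi[ctr, ctr]), -k * 5.4e-6 * 2 * R, tolerance = 1e-12)
  expect_equal(Re(psi[ctr, ctr]), -k * 2.4e-8 * 2 * R, tolerance = 1e-12)
  # ray missing the sphere
  expect_identical(psi[1, 1], 0 + 0i)
  # total phase scales with the analytic chord at every pixel
  g <- pwftomo:::centred_grids(geom)
  rho2 <- g$x^2 + g$y^2
  chord <- ifelse(rho2 < R^2, 2 * sqrt(pmax(R^2 - rho2, 0)), 0)
  expect_equal(Im(psi), -k * 5.4e-6 * chord, tolerance = 1e-12)
})

test_that("a 50 um-radius bead reaches the optically thick regime", {
  geom <- imaging_geometry(256, 256, 650e-9, 0.124e-9)
  ph <- bead_phantom(cbind(0, 0, 0), 50e-6, delta = 1.3e-5, beta = 0)
  psi <- project_phantom(ph, 0, geom)
  peak <- max(abs(Im(psi)))
  expect_equal(peak, (2 * pi / 0.124e-9) * 1.3e-5 * 100e-6,
               tolerance = 1e-6)
  expect_gt(peak, 20 * pi)   # tens of pi, as for strongly phase-shifting samples
})

test_that("projection rotates about the vertical axis", {
  geom <- test_geometry(64)
  ph <- bead_phantom(cbind(10e-6, 2e-6, 0), 4e-6, 1e-6, 0)
  p0 <- project_phantom(ph, 0, geom)
  p90 <- project_phantom(ph, 90, geom)
  ctr <- floor(64 / 2) + 1
  px <- round(10e-6 / geom$pitch)
  py <- round(2e-6 / geom$pitch)
  expect_lt(Im(p0[ctr + py, ctr + px]), 0)      # bead at +x for angle 0
  expect_equal(Im(p0[ctr + py, ctr]), 0)
  expect_lt(Im(p90[ctr + py, ctr]), 0)          # rotated onto the axis at 90
})

test_that("cylinder component adds a y-invariant chord", {
  geom <- test_geometry(64)
  cyl <- list(x = 0, z = 0, radius = 5e-6, delta = 2e-6, beta = 0)
  ph <- bead_phantom(cbind(0, 0, 0), 1e-9, 0, 0, cylinder = cyl)
  psi <- project_phantom(ph, 37, geom)
  ctr <- floor(64 / 2) + 1
  k <- 2 * pi / geom$wavelength
  expect_equal(Im(psi[10, ctr]), -k * 2e-6 * 2 * 5e-6, tolerance = 1e-6)
  expect_equal(Im(psi[10, ]), Im(psi[50, ]), tolerance = 1e-9)
})

test_that("diffuser screens are deterministic given the seed", {
  cfg <- simulation_config(geometry = test_geometry(64), seed = 42)
  s1 <- make_diffuser_screen(cfg)
  s2 <- make_diffuser_screen(cfg)
  expect_identical(s1, s2)
  cfg2 <- simulation_config(geometry = test_geometry(64), seed = 43)
  expect_gt(max(Mod(make_diffuser_screen(cfg2) - s1)), 0.1)
  # thermal screens are normalized to unit mean intensity
  expect_equal(mean(Mod(s1)^2), 1, tolerance = 1e-12)
})

test_that("phase-type screen honours its zero-depth and grain contracts", {
  cfg0 <- simulation_config(geometry = test_geometry(64),
                            diffuser_type = "phase",
                            diffuser_grain = 2e-6, diffuser_phase_sd = 0)
  expect_equal(make_diffuser_screen(cfg0), matrix(1 + 0i, 64, 64))
  cfg <- simulation_config(geometry = imaging_geometry(512, 512, 650e-9,
                                                       0.124e-9),
                           diffuser_type = "phase",
                           diffuser_grain = 2.6e-6, diffuser_phase_sd = 1.5,
                           seed = 7)
  scr <- make_diffuser_screen(cfg)
  expect_equal(Mod(scr), matrix(1, 512, 512), tolerance = 1e-12)
  phi <- Arg(scr)
  expect_equal(stats::sd(phi), 1.5, tolerance = 0.15)
  # autocorrelation length of the phase within 10% of the request:
  # fit the measured covariance to exp(-pi d^2 / l^2)
  cov_prof <- (g2_autocorrelation(phi - min(phi) + 10, "horizontal") - 1)
  cov_prof <- cov_prof / cov_prof[1]
  lags <- (seq_along(cov_prof) - 1) * 650e-9
  fit <- stats::nls(cov_prof ~ exp(-pi * lags^2 / l^2),
                    start = list(l = 2e-6))
  expect_equal(unname(stats::coef(fit)["l"]), 2.6e-6, tolerance = 0.1)
})

test_that("simulated datasets are deterministic and self-consistent", {
  cfg <- simulation_config(geometry = test_geometry(64), angles = c(0, 90),
                           seed = 5, photon_count = 1e4)
  ph <- default_phantom()
  d1 <- simulate_dataset(ph, cfg)
  d2 <- simulate_dataset(ph, cfg)
  expect_identical(d1$reference, d2$reference)
  expect_identical(d1$projections, d2$projections)
  expect_equal(mean(d1$reference), 1, tolerance = 0.05)
  # empty phantom at infinite photons: projections equal the reference
  cfg0 <- simulation_config(geometry = test_geometry(64), angles = 0,
                            seed = 5)
  empty <- bead_phantom(cbind(0, 0, 0), 1e-9, 0, 0)
  d0 <- simulate_dataset(empty, cfg0)
  expect_equal(d0$projections[[1]], d0$reference, tolerance = 1e-12)
})

test_that("speckle contrast falls as the coherence blur widens", {
  contrasts <- sapply(c(1.5e-6, 3e-6, 6e-6), function(cl) {
    cfg <- simulation_config(geometry = test_geometry(128),
                             coherence = coherence_model(cl, cl),
                             angles = 0, seed = 8)
    ds <- simulate_dataset(bead_phantom(cbind(0, 0, 0), 1e-9, 0, 0), cfg)
    stats::sd(ds$reference) / mean(ds$reference)
  })
  expect_true(all(diff(contrasts) < 0))
})

test_that("coherent reference speckle has exponential intensity statistics", {
  cfg <- simulation_config(geometry = imaging_geometry(1024, 1024, 650e-9,
                                                       0.124e-9, 3e-3,
                                                       20e-3),
                           seed = 9)
  scr <- make_diffuser_screen(cfg)
  I <- Mod(propagate(scr, cfg$geometry, cfg$geometry$L2))^2
  ks <- suppressWarnings(stats::ks.test(as.vector(I) / mean(I), "pexp"))
  expect_lt(unname(ks$statistic), 0.02)
  expect_equal(g2_autocorrelation(I, "horizontal")[1], 2, tolerance = 0.05)
})

test_that("Poisson noise level follows the photon budget", {
  cfg <- simulation_config(geometry = test_geometry(128), angles = 0,
                           seed = 11, photon_count = 1e4,
                           coherence = coherence_model(30e-6, 30e-6))
  ds <- simulate_dataset(bead_phantom(cbind(0, 0, 0), 1e-9, 0, 0), cfg)
  # heavy blur removes speckle contrast, leaving shot noise ~ 1/sqrt(N)
  expect_equal(stats::sd(ds$reference), 1e-2, tolerance = 0.25)
})
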