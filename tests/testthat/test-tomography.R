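test_that("preprocessing implements (raw - dark)/(flat - dark)", {
  set.seed(12)
  flat <- matrix(stats::runif(64 * 64, 0.5, 1.5), 64, 64)
  dark <- matrix(stats::runif(64 * 64, 0, 0.05), 64, 64)
  expect_equal(preprocess_frame(flat, dark * 0, flat)$values,
               matrix(1, 64, 64))
  expect_equal(preprocess_frame(dark, dark, flat)$values,
               matrix(0, 64, 64))
  I_true <- matrix(stats::runif(64 * 64, 0.2, 2), 64, 64)
  raw <- (flat - dark) * I_true + dark
  got <- preprocess_frame(raw, dark, flat)
  expect_equal(got$values, I_true, tolerance = 1e-12)
  expect_equal(got$replaced, 0)
  # dead pixels are patched with the median denominator and counted
  flat2 <- flat; flat2[5, 5] <- dark[5, 5]
  got2 <- preprocess_frame(raw, dark, flat2)
  expect_equal(got2$replaced, 1)
  expect_error(preprocess_frame(raw, dark, dark), "everywhere")
})

test_that("FBP reconstructs a centred disc from its analytic sinogram", {
  n <- 128
  angles <- seq(0, 179.5, length.out = 180)
  sino <- disc_sinogram(n, angles, radius_px = 30)
  rec <- pwftomo:::fbp_slice(sino, angles)
  ctr <- floor(n / 2) + 1
  xs <- seq_len(n) - ctr
  rr <- sqrt(outer(xs^2, xs^2, "+"))
  interior <- rr < 0.8 * 30
  expect_lt(max(abs(rec[interior] - 1)), 0.05)
  exterior <- rr > 1.3 * 30 & rr < 0.45 * n
  expect_lt(max(abs(rec[exterior])), 0.05)
  # an off-centre disc lands at its centre
  sino2 <- disc_sinogram(n, angles, radius_px = 12, centre = c(20, -10))
  rec2 <- pwftomo:::fbp_slice(sino2, angles)
  expect_gt(rec2[ctr - 10, ctr + 20], 0.9)  # row = z, column = x
  expect_lt(abs(rec2[ctr, ctr]), 0.05)
})

test_that("FBP is linear and maps zero to zero", {
  n <- 64
  angles <- seq(0, 177, by = 3)
  s1 <- disc_sinogram(n, angles, 10)
  s2 <- disc_sinogram(n, angles, 18, centre = c(-8, 4))
  r12 <- pwftomo:::fbp_slice(s1 + s2, angles)
  r1 <- pwftomo:::fbp_slice(s1, angles)
  r2 <- pwftomo:::fbp_slice(s2, angles)
  expect_lt(max(abs(r12 - r1 - r2)), 1e-10)
  expect_equal(pwftomo:::fbp_slice(s1 * 0, angles), matrix(0, n, n))
})

test_that("projection series validates its inputs and angle coverage", {
  geom <- test_geometry(16)
  maps <- replicate(2, matrix(0 + 0i, 16, 16), simplify = FALSE)
  expect_error(projection_series(c(10, 5), maps, geom))
  expect_warning(projection_series(c(0, 45), maps, geom), "limited-angle")
  # the experimental series: 0 to 180 inclusive at 0.225 degrees = 801 maps
  angles <- seq(0, 180, by = 0.225)
  expect_length(angles, 801)
  maps801 <- rep(maps[1], 801)
  ps <- projection_series(angles, maps801, geom)
  expect_length(ps$angles, 801)
})

test_that("reconstruct_fbp applies the n = 1 - delta + i beta sign convention", {
  geom <- imaging_geometry(32, 32, 650e-9, 0.124e-9, 3e-3, 20e-3)
  ph <- bead_phantom(cbind(0, 0, 0), 6e-6, delta = 5e-6, beta = 5e-8)
  angles <- seq(0, 174, by = 6)
  maps <- lapply(angles, function(a) project_phantom(ph, a, geom))
  series <- projection_series(angles, maps, geom)
  vol_d <- to_refractive_index(reconstruct_fbp(series, "phase"), geom)
  vol_b <- to_refractive_index(reconstruct_fbp(series, "attenuation"), geom)
  ctr <- floor(32 / 2) + 1
  expect_gt(vol_d[ctr, ctr, ctr], 0)       # positive delta
  expect_gt(vol_b[ctr, ctr, ctr], 0)       # positive beta
  expect_equal(vol_d[ctr, ctr, ctr], 5e-6, tolerance = 0.05)
  expect_equal(vol_b[ctr, ctr, ctr], 5e-8, tolerance = 0.05)
})

test_that("refractive-index conversion is the constant lambda/p/(2 pi)", {
  geom <- imaging_geometry(8, 8, 650e-9, 0.124e-9)
  vol <- array(1, dim = c(2, 2, 2))
  expect_equal(to_refractive_index(vol, geom)[1, 1, 1], 3.036e-5,
               tolerance = 1e-3)
  expect_equal(to_refractive_index(vol * 0, geom),
               array(0, dim = c(2, 2, 2)))
})

test_that("background flattening removes exactly quadratic surfaces", {
  set.seed(13)
  n <- 32
  vol <- array(0, dim = c(4, n, n))
  xs <- seq_len(n)
  quad <- outer(xs, xs, function(x, y) 1 + 0.1 * x - 0.05 * y +
                  0.002 * x^2 - 0.001 * x * y + 0.003 * y^2)
  for (i in 1:4) vol[i, , ] <- quad * i
  flat <- flatten_background(vol)
  expect_lt(max(abs(flat)), 1e-8)
  # untouched zero-background volume stays put
  vol2 <- array(0, dim = c(4, n, n))
  vol2[2, 10, 12] <- 1    # inside the cylinder support, not in the mask
  flat2 <- flatten_background(vol2)
  expect_lt(max(abs(flat2 - vol2)), 1e-10)
  # masked mean is zero after flattening (least-squares property)
  vol3 <- vol + array(stats::rnorm(4 * n * n), dim = c(4, n, n))
  mask <- array(TRUE, dim = dim(vol3))
  flat3 <- flatten_background(vol3, mask)
  for (i in 1:4) expect_lt(abs(mean(flat3[i, , ])), 1e-10)
})

test_that("Crowther criterion reproduces the printed projection counts", {
  expect_equal(crowther_min_angles(1e-3, 1.5e-6), 1047L)
  expect_equal(crowther_min_angles(1e-3, 3.0e-6), 524L)
  expect_equal(crowther_min_angles(2 * 1.1e-6 / pi, 1.1e-6), 1L)
})
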