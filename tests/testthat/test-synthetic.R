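test_that("noiseless wedge-free phantom profile equals the closed-form generative profile", {
  spec <- phantom_spec(psd_d1 = 15, psd_lambda = 18, noise_sigma = 0)
  ph <- make_synapse_phantom(spec)
  prof <- phantom_raw_profile(spec)
  truth <- ph$truth$profile_fn(prof$d)
  expect_lt(max(abs(prof$v - truth), na.rm = TRUE), 1e-9)
  # flat region (100-200 nm) identically the background constant
  flat <- prof$v[prof$d >= 100 & prof$d <= 200]
  expect_true(all(abs(flat - spec$background) < 1e-12))
  # analytic PSD crest sits exactly at d1* (membrane terms vanish out there)
  dd <- seq(6, 60, by = 0.01)
  vals <- ph$truth$profile_fn(dd)
  expect_equal(dd[which.max(vals)], 15, tolerance = 0.02)
})

test_that("phantom generation is seed-deterministic", {
  spec <- phantom_spec(noise_sigma = 2, seed = 11)
  a <- make_synapse_phantom(spec)
  b <- make_synapse_phantom(spec)
  expect_identical(a$tomogram$data, b$tomogram$data)
  v1 <- make_vesicle_field(n = 12, noise_sigma = 0.5,
                           box_nm = c(200, 200, 120), seed = 4)
  v2 <- make_vesicle_field(n = 12, noise_sigma = 0.5,
                           box_nm = c(200, 200, 120), seed = 4)
  expect_identical(v1$tomogram$data, v2$tomogram$data)
  expect_identical(v1$truth$diameter, v2$truth$diameter)
  lp1 <- make_landmark_pairs(affine2d(diag(2), c(1, 2)), 8, 1, seed = 5)
  lp2 <- make_landmark_pairs(affine2d(diag(2), c(1, 2)), 8, 1, seed = 5)
  expect_identical(lp1$target, lp2$target)
})

test_that("volume too small for the junction raises a sizing error", {
  spec <- phantom_spec(volume_shape = c(40, 16, 8))
  expect_error(make_synapse_phantom(spec), "too small")
})

test_that("missing wedge preserves the volume mean and removes beam-axis frequencies", {
  set.seed(2)
  t0 <- tomogram(array(rnorm(32^3, mean = 5), c(32, 32, 32)), 1)
  tw <- apply_missing_wedge(t0, 60)
  expect_equal(mean(tw$data), mean(t0$data), tolerance = 1e-10)
  # a pure kz oscillation (inside the wedge) is wiped out
  z <- array(rep(cos(2 * pi * 4 * (0:31) / 32), each = 32 * 32), c(32, 32, 32))
  zw <- apply_missing_wedge(tomogram(z, 1), 60)
  expect_lt(max(abs(zw$data)), 1e-8)
  # a pure kx oscillation (fully sampled) is untouched
  x <- array(cos(2 * pi * 4 * (0:31) / 32), c(32, 32, 32))
  xw <- apply_missing_wedge(tomogram(x, 1), 60)
  expect_equal(xw$data, x, tolerance = 1e-8)
})

test_that("vesicle field renders shells at the right radius with clean interiors", {
  vf <- make_vesicle_field(n = 1, diameter_range = c(40, 40),
                           ellipsoidal_fraction = 0, noise_sigma = 0,
                           box_nm = c(100, 100, 100), seed = 3)
  tr <- vf$truth
  expect_equal(tr$s1, tr$s3)            # sphere
  d <- dim(vf$tomogram)
  ax <- list((seq_len(d[1]) - 1) * 2 - tr$x,
             (seq_len(d[2]) - 1) * 2 - tr$y,
             (seq_len(d[3]) - 1) * 2 - tr$z)
  r <- sqrt(outer(outer(ax[[1]]^2, ax[[2]]^2, "+"), ax[[3]]^2, "+"))
  on_shell <- abs(r - 20) <= 2
  interior <- r < 14
  expect_true(all(vf$tomogram$data[on_shell] == 1))
  expect_true(all(vf$tomogram$data[interior] == 0))
})

test_that("ellipsoidal_fraction 0 yields only spheres; impossible packing errors out", {
  vf <- make_vesicle_field(n = 20, ellipsoidal_fraction = 0, noise_sigma = 0,
                           box_nm = c(300, 300, 160), seed = 6)
  expect_true(all(vf$truth$shape == "sphere"))
  expect_true(all(abs(vf$truth$s1 - vf$truth$s3) < 1e-12))
  expect_error(
    make_vesicle_field(n = 40, box_nm = c(80, 80, 80), seed = 1,
                       max_tries = 50),
    "non-overlapping")
})

test_that("landmark generator applies the transform exactly and validates n", {
  tr <- affine2d(diag(2), c(10, -4))
  lp <- make_landmark_pairs(tr, 6, noise_sigma_px = 0, seed = 2)
  expect_equal(lp$target - lp$source,
               matrix(rep(c(10, -4), each = 6), ncol = 2),
               tolerance = 1e-12)
  id <- affine2d(diag(2), c(0, 0))
  lp0 <- make_landmark_pairs(id, 5, 0, seed = 8)
  expect_identical(lp0$source, lp0$target)
  expect_error(make_landmark_pairs(id, 2, 0, seed = 1), "at least 3")
})

test_that("ellipsoid point clouds lie on the surface with residuals at the noise scale", {
  p <- make_ellipsoid_points(c(20, 20, 20), n = 40, noise_sigma = 0, seed = 4)
  expect_lt(max(abs(sqrt(rowSums(p^2)) - 20)), 1e-9)
  p2 <- make_ellipsoid_points(c(15, 25, 25), n = 18, noise_sigma = 0, seed = 5)
  impl <- rowSums(sweep(p2^2, 2, c(15, 25, 25)^2, "/"))
  expect_lt(max(abs(impl - 1)), 1e-9)
  # Monte-Carlo: mean radial residual of a noisy sphere ~ noise scale
  res <- vapply(1:100, function(s) {
    q <- make_ellipsoid_points(c(20, 20, 20), n = 18, noise_sigma = 1,
                               seed = s)
    mean(abs(sqrt(rowSums(q^2)) - 20))
  }, numeric(1))
  expect_gt(mean(res), 0.5)
  expect_lt(mean(res), 1.2)
  expect_error(make_ellipsoid_points(c(10, 10, 10), n = 5), "at least 9")
})
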