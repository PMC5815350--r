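test_that("project_slab averages exactly the slices a brute-force loop averages", {
  set.seed(3)
  vol <- array(rnorm(20 * 15 * 12), c(20, 15, 12))
  tomo <- tomogram(vol, voxel_size = 1)
  img <- project_slab(tomo, z_center = 5.5, thickness = 4)
  # brute force: slices whose centres fall within the slab
  zc <- 5.5 / 1 + 1
  zs <- ceiling(zc - 2):floor(zc + 2)
  ref <- apply(vol[, , zs], c(1, 2), mean)
  expect_equal(unclass(img)[, ], ref, ignore_attr = TRUE, tolerance = 1e-12)
  # constant volume -> constant image; 1-voxel slab -> the slice itself
  cv <- tomogram(array(7, c(8, 8, 8)), 1)
  expect_true(all(project_slab(cv, 4, 3) == 7))
  one <- project_slab(tomo, z_center = 6, thickness = 1)
  expect_equal(unclass(one)[, ], vol[, , 7], ignore_attr = TRUE)
  expect_error(project_slab(tomo, z_center = 1, thickness = 10), "exceeds")
})

test_that("extract_profile on a separable image reproduces the generating 1D function", {
  px <- 0.5
  nx <- 120; ny <- 40
  xs <- (seq_len(nx) - 1) * px
  f <- function(x) 2 * exp(-(x - 25)^2 / 8) + 0.3 * sin(x / 5)
  img <- matrix(rep(f(xs), ny), nx, ny)
  attr(img, "pixel_size") <- px
  x0 <- 30   # trace on the pixel grid
  tr <- membrane_trace(cbind(c(x0, x0), c(0, (ny - 1) * px)), "right")
  prof <- extract_profile(img, tr, d_min = -20, d_max = 25, step = px)
  expect_equal(prof$v, f(x0 + prof$d), tolerance = 1e-9)
  # all-zero image -> all-zero profile
  z <- matrix(0, nx, ny); attr(z, "pixel_size") <- px
  pz <- extract_profile(z, tr, d_min = -10, d_max = 10)
  expect_true(all(pz$v == 0, na.rm = TRUE))
})

test_that("extract_profile on a circular-arc trace recovers the radial function", {
  px <- 0.5
  n <- 160
  ax <- (seq_len(n) - 1) * px
  ctr <- c(40, 40)
  r <- sqrt(outer((ax - ctr[1])^2, (ax - ctr[2])^2, "+"))
  img <- r   # radial ramp: mean over an annulus equals its central radius
  attr(img, "pixel_size") <- px
  R0 <- 20
  th <- seq(0, 2 * pi * 0.97, length.out = 200)
  arc <- cbind(ctr[1] + R0 * cos(th), ctr[2] + R0 * sin(th))
  tr <- membrane_trace(arc, "right")   # outside of a CCW arc is its right
  prof <- extract_profile(img, tr, d_min = -10, d_max = 15, step = px)
  sel <- abs(prof$d) <= 10
  expect_lt(max(abs(prof$v[sel] - (R0 + prof$d[sel])), na.rm = TRUE), 0.1)
})

test_that("normalization is idempotent, affine-invariant, and flags degenerate input", {
  d <- seq(-40, 200, by = 1)
  set.seed(8)
  v <- exp(-(d - 15) / 18) * (d >= 15) + rnorm(length(d), 0, 0.1)
  p <- density_profile(d, v)
  n1 <- normalize_profile(p)
  inw <- n1$d >= 100 & n1$d <= 200
  expect_equal(mean(n1$v[inw]), 0, tolerance = 1e-9)
  expect_equal(sd(n1$v[inw]), 1, tolerance = 1e-9)
  n2 <- normalize_profile(n1)
  expect_equal(n1$v, n2$v, tolerance = 1e-9)
  n3 <- normalize_profile(density_profile(d, 3 * v + 5))
  expect_equal(n1$v, n3$v, tolerance = 1e-9)
  flat <- density_profile(d, rep(2, length(d)))
  expect_error(normalize_profile(flat), "zero variance")
  short <- density_profile(seq(-10, 50, 1), rnorm(61))
  expect_error(normalize_profile(short), "fewer than 10")
})

test_that("fit_peaks recovers synthetic junction peaks within 0.2 nm", {
  d <- seq(-40, 200, by = 0.5)
  g <- function(mu, s, a) a * exp(-(d - mu)^2 / (2 * s^2))
  v <- g(-26, 2, 5) + g(-13, 2, 2) + g(0, 2, 5) + g(15, 3, 3)
  pk <- fit_peaks(density_profile(d, v))
  expect_equal(pk$presynaptic, -26, tolerance = 0.2)
  expect_equal(pk$intercleft, -13, tolerance = 0.2)
  expect_equal(pk$psd, 15, tolerance = 0.2)
  expect_true(pk$psd_present)
  expect_equal(cleft_width(pk), 26, tolerance = 0.2)
  # cleft width depends only on the membrane separation, not on the PSD
  pk2 <- fit_peaks(density_profile(d, g(-22, 2, 5) + g(0, 2, 5) +
                                     g(15, 3, 3)))
  expect_equal(cleft_width(pk2), 22, tolerance = 0.2)
})

test_that("a membrane-only profile yields a structured no-PSD result", {
  d <- seq(-40, 200, by = 0.5)
  v <- 5 * exp(-d^2 / 8)
  pk <- fit_peaks(density_profile(d, v))
  expect_false(pk$psd_present)
  expect_true(is.na(pk$psd))
  expect_equal(pk$postsynaptic, 0)
  expect_error(cleft_width(pk), "presynaptic")
})

test_that("exponential decay fit is exact on exact samples and defines d2 = d1 + lambda", {
  d <- seq(-40, 200, by = 1)
  v <- ifelse(d >= 5, 2 * exp(-(d - 5) / 10), 0)
  dec <- fit_psd_decay(density_profile(d, v), d1 = 5)
  expect_equal(dec$A, 2, tolerance = 1e-6)
  expect_equal(dec$lambda, 10, tolerance = 1e-6)
  expect_equal(dec$B, 0, tolerance = 1e-6)
  expect_equal(dec$d2, 15, tolerance = 1e-5)
  # population-mean arithmetic: d1 = 14.7 with lambda = 18.0 gives d2 = 32.7
  v2 <- ifelse(d >= 14.7, 1.5 * exp(-(d - 14.7) / 18), 0)
  dec2 <- fit_psd_decay(density_profile(d, v2), d1 = 14.7)
  expect_equal(dec2$d2, 32.7, tolerance = 1e-4)
})

test_that("lambda is recovered within 10% on average from noisy realizations", {
  d <- seq(-40, 200, by = 0.755)
  lam <- vapply(1:20, function(s) {
    set.seed(s)
    v <- ifelse(d >= 15, 2 * exp(-(d - 15) / 18), 0) +
      rnorm(length(d), 0, 0.1)
    fit_psd_decay(density_profile(d, v), d1 = 15)$lambda
  }, numeric(1))
  expect_lt(abs(mean(lam) - 18) / 18, 0.10)
})

test_that("profile averaging is the pointwise mean with sensible edge cases", {
  d <- seq(-40, 200, by = 1)
  set.seed(5)
  p1 <- density_profile(d, rnorm(length(d)))
  expect_equal(average_profiles(list(p1, p1))$v, p1$v, tolerance = 1e-12)
  # mirrored pair about zero averages to an even function
  dd <- seq(-50, 50, by = 1)
  v <- rnorm(length(dd))
  pa <- density_profile(dd, v)
  pb <- density_profile(dd, rev(v))
  avg <- average_profiles(list(pa, pb))
  expect_equal(avg$v, rev(avg$v), tolerance = 1e-12)
  expect_error(average_profiles(list()), "no profiles")
  # sup-distance to truth shrinks roughly like 1/sqrt(N)
  truth <- exp(-abs(dd) / 10)
  sup_err <- function(n, seed) {
    set.seed(seed)
    ps <- lapply(seq_len(n), function(i)
      density_profile(dd, truth + rnorm(length(dd), 0, 0.5)))
    max(abs(average_profiles(ps)$v - truth))
  }
  e4 <- mean(vapply(1:8, function(s) sup_err(4, s), numeric(1)))
  e64 <- mean(vapply(1:8, function(s) sup_err(64, s + 100), numeric(1)))
  expect_lt(e64, e4 / 2)
})

test_that("phantom metrics recover generative d1, cleft width and lambda", {
  spec <- phantom_spec(psd_d1 = 15, psd_lambda = 18, cleft_width = 24,
                       noise_sigma = 0)
  prof <- phantom_raw_profile(spec)
  pk <- fit_peaks(prof)
  expect_equal(pk$psd, 15, tolerance = spec$voxel_size)
  expect_equal(cleft_width(pk), 24, tolerance = spec$voxel_size / 2)
  dec <- fit_psd_decay(pk$profile, pk$psd)
  expect_lt(abs(dec$d2 - 33) / 33, 0.1)
})
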