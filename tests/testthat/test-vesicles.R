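test_that("default template bank has 46 normalized, symmetric shells", {
  bank <- build_template_bank(voxel_size = 2)
  expect_length(bank$templates, 46)
  expect_equal(bank$diameters, 25:70)
  for (t in bank$templates[c(1, 23, 46)]) {
    expect_lt(abs(mean(t)), 1e-12)
    expect_equal(sum(t^2), 1, tolerance = 1e-9)
    # rotational symmetry under 90-degree axis permutations
    expect_equal(t, aperm(t, c(2, 1, 3)), tolerance = 1e-9)
    expect_equal(t, aperm(t, c(3, 2, 1)), tolerance = 1e-9)
  }
  expect_error(build_template_bank(d_min = 70, d_max = 25), "d_min")
  expect_error(build_template_bank(voxel_size = 2, box_vox = 10), "too small")
})

test_that("a single noiseless sphere is detected at the right place and diameter", {
  vf <- make_vesicle_field(n = 1, diameter_range = c(40, 40),
                           ellipsoidal_fraction = 0, noise_sigma = 0,
                           box_nm = c(100, 100, 100), seed = 3)
  bank <- build_template_bank(voxel_size = 2)
  det <- match_templates(vf$tomogram, bank)
  expect_equal(nrow(det), 1)
  expect_lt(abs(det$diameter - vf$truth$diameter), 1.5)
  expect_lt(sqrt((det$x - vf$truth$x)^2 + (det$y - vf$truth$y)^2 +
                   (det$z - vf$truth$z)^2), 2 * vf$tomogram$voxel_size)
})

test_that("template diameter estimates are within 1 nm across the bank range", {
  bank <- build_template_bank(voxel_size = 2)
  errs <- vapply(c(28, 40, 55, 66), function(dia) {
    vf <- make_vesicle_field(n = 1, diameter_range = c(dia, dia),
                             ellipsoidal_fraction = 0, noise_sigma = 0,
                             box_nm = c(130, 130, 130), seed = dia)
    det <- match_templates(vf$tomogram, bank)
    abs(det$diameter[1] - vf$truth$diameter)
  }, numeric(1))
  expect_true(all(errs <= 1.5))
})

test_that("pure-noise volumes produce no detections at the default threshold", {
  fps <- vapply(1:5, function(s) {
    set.seed(s)
    nv <- tomogram(array(rnorm(70 * 70 * 50), c(70, 70, 50)), 2)
    bank <- build_template_bank(voxel_size = 2)
    nrow(match_templates(nv, bank))
  }, numeric(1))
  expect_true(all(fps == 0))
})

test_that("equatorial point extraction respects the donut mask and error paths", {
  vf <- make_vesicle_field(n = 1, diameter_range = c(40, 40),
                           ellipsoidal_fraction = 0, noise_sigma = 0,
                           box_nm = c(100, 100, 100), seed = 3)
  ctr <- c(vf$truth$x, vf$truth$y, vf$truth$z)
  pts <- extract_equatorial_points(vf$tomogram, ctr, radius = 20)
  r <- sqrt((pts[, 1] - ctr[1])^2 + (pts[, 2] - ctr[2])^2)
  expect_true(all(r >= 15 - 1e-9 & r <= 25 + 1e-9))
  # radial spread stays within shell half-thickness + one voxel
  expect_lt(max(abs(r - 20)), 2.5 + 2)
  # strict ">" on a uniform slice selects nothing
  flat <- tomogram(array(1, c(40, 40, 40)), 2)
  expect_error(extract_equatorial_points(flat, c(40, 40, 40), radius = 20),
               "above the annulus mean")
})

test_that("ellipse fits are exact on noiseless points and rigid-motion equivariant", {
  th <- seq(0, 2 * pi, length.out = 41)[-41]
  circ <- cbind(20 * cos(th), 20 * sin(th))
  fc <- fit_ellipse_2d(circ)
  expect_equal(fc$major, 20, tolerance = 1e-6)
  expect_equal(fc$minor, 20, tolerance = 1e-6)
  expect_equal(fc$ratio, 1, tolerance = 1e-9)
  ell <- cbind(25 * cos(th), 18 * sin(th)) %*% t(rot_2d(pi / 6))
  ell <- sweep(ell, 2, c(40, -12), "+")
  fe <- fit_ellipse_2d(ell)
  expect_equal(fe$major, 25, tolerance = 1e-6)
  expect_equal(fe$minor, 18, tolerance = 1e-6)
  expect_equal(fe$center, c(40, -12), tolerance = 1e-6)
  expect_equal(fe$angle, pi / 6, tolerance = 1e-6)
  # equivariance: rotating the points rotates the fit, axes unchanged
  rot <- ell %*% t(rot_2d(0.8))
  fr <- fit_ellipse_2d(rot)
  expect_equal(fr$major, fe$major, tolerance = 1e-6)
  expect_equal(fr$minor, fe$minor, tolerance = 1e-6)
  expect_error(fit_ellipse_2d(cbind(1:10, 2 * (1:10))), "ellipse|degenerate")
})

test_that("ellipsoid fits are exact on noiseless points and robust to 1 nm noise", {
  p <- make_ellipsoid_points(c(20, 20, 20), n = 18, seed = 2)
  f <- fit_ellipsoid_3d(p)
  expect_equal(f$semi_axes, c(20, 20, 20), tolerance = 1e-6)
  R <- rot_z(0.7)
  p2 <- make_ellipsoid_points(c(15, 25, 26), orientation = R, n = 18,
                              center = c(5, -3, 8), seed = 4)
  f2 <- fit_ellipsoid_3d(p2)
  expect_equal(f2$semi_axes, c(15, 25, 26), tolerance = 1e-6)
  expect_equal(f2$center, c(5, -3, 8), tolerance = 1e-6)
  # Monte-Carlo: median axis error at 1 nm point noise stays under 1 nm
  errs <- vapply(1:100, function(s) {
    q <- make_ellipsoid_points(c(15, 25, 26), n = 36, noise_sigma = 1,
                               seed = s)
    ft <- try(fit_ellipsoid_3d(q), silent = TRUE)
    if (inherits(ft, "try-error")) return(NA_real_)
    max(abs(ft$semi_axes - c(15, 25, 26)))
  }, numeric(1))
  expect_lt(median(errs, na.rm = TRUE), 1)
  expect_error(fit_ellipsoid_3d(matrix(rnorm(15), 5, 3)), "at least 9")
})

test_that("ellipticity and spheroid classification follow the threshold rules", {
  expect_identical(classify_ellipticity(1.07), "spherical")
  expect_identical(classify_ellipticity(1.50), "ellipsoidal")
  expect_identical(classify_ellipticity(1.14), "spherical")  # strict >
  expect_identical(classify_ellipticity(1.1400001), "ellipsoidal")
  expect_identical(classify_shape_3d(c(20, 35, 36)), "discus")
  expect_identical(classify_shape_3d(c(15, 16, 30)), "olive")
  expect_identical(classify_shape_3d(c(20, 20, 20)), "sphere")
  expect_identical(classify_shape_3d(c(10, 15, 25)), "other")
  # scale invariance
  for (k in c(0.3, 2, 7)) {
    expect_identical(classify_shape_3d(k * c(20, 35, 36)), "discus")
    expect_identical(classify_shape_3d(k * c(15, 16, 30)), "olive")
  }
})

test_that("missing wedge does not bias fitted vesicle shape beyond 5%", {
  # noiseless shell, wedge-filtered; points picked as the strongest voxels
  # near the membrane on many directions, then fitted in 3D
  vf <- make_vesicle_field(n = 1, diameter_range = c(40, 40),
                           ellipsoidal_fraction = 0, noise_sigma = 0,
                           box_nm = c(100, 100, 100), seed = 3)
  tw <- apply_missing_wedge(vf$tomogram, 60)
  ctr <- c(vf$truth$x, vf$truth$y, vf$truth$z)
  # emulate manual picking: along directions where the membrane is
  # actually visible (its normal within the tilt-sampled belt; the z-caps
  # of a vesicle are invisible under a missing wedge and are never
  # picked), locate the membrane as the density centroid along the ray
  trilin <- function(vol, p) {
    i <- p / tw$voxel_size + 1
    i0 <- floor(i); f <- i - i0
    acc <- 0
    for (dx in 0:1) for (dy in 0:1) for (dz in 0:1)
      acc <- acc + vol[i0[1] + dx, i0[2] + dy, i0[3] + dz] *
        (if (dx) f[1] else 1 - f[1]) * (if (dy) f[2] else 1 - f[2]) *
        (if (dz) f[3] else 1 - f[3])
    acc
  }
  set.seed(3)
  u <- matrix(rnorm(3 * 200), 200, 3)
  u <- u / sqrt(rowSums(u^2))
  u <- u[abs(u[, 3]) < 0.6, ][1:60, ]
  rads <- seq(14, 26, by = 0.25)
  pick_r <- apply(u, 1, function(dir) {
    vals <- vapply(rads, function(r) trilin(tw$data, ctr + r * dir),
                   numeric(1))
    w <- pmax(vals - 0.5 * max(vals), 0)
    sum(w * rads) / sum(w)
  })
  fit <- fit_ellipsoid_3d(u * pick_r)
  expect_true(all(abs(fit$semi_axes - 20) / 20 < 0.05))
})

test_that("per-synapse population statistics aggregate fractions and diameters", {
  fits <- data.frame(
    synapse = rep(c("a", "b"), c(10, 8)),
    major = c(rep(10.5, 8), 13, 13, rep(10.2, 8)),
    minor = c(rep(10, 8), 10, 10, rep(10, 8)),
    group = rep(c("exc", "inh"), c(10, 8)))
  ps <- population_stats(fits)
  expect_equal(ps$per_synapse$ellipsoidal_fraction[
    ps$per_synapse$synapse == "a"], 0.2)
  expect_equal(ps$per_synapse$ellipsoidal_fraction[
    ps$per_synapse$synapse == "b"], 0)
  expect_equal(ps$per_vesicle$diameter[1], 20.5)
  expect_s3_class(ps$ks, "ks2")
  # all-spherical input: zero fractions and KS D = 0 against itself
  sph <- data.frame(synapse = rep(c("a", "b"), each = 5),
                    major = 10, minor = 10,
                    group = rep(c("exc", "inh"), each = 5))
  ps2 <- population_stats(sph)
  expect_true(all(ps2$per_synapse$ellipsoidal_fraction == 0))
  expect_equal(ps2$ks$D, 0)
})
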