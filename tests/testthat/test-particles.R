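test_that("rectangular particles on a membrane are measured within a pixel", {
  pf <- make_particle_field(n = 5, noise_sigma = 0, seed = 2)
  for (i in 1:5) {
    m <- measure_particle(pf$image,
                          c(pf$truth$base_x[i], pf$truth$base_y[i]),
                          pixel_size = pf$pixel_size)
    expect_lt(abs(m$length - pf$truth$length[i]), pf$pixel_size + 0.2)
    expect_lt(abs(m$width - pf$truth$width[i]), 2 * pf$pixel_size)
  }
})

test_that("phantom particle fields are recovered with sub-pixel median error", {
  errs <- unlist(lapply(1:3, function(s) {
    pf <- make_particle_field(n = 6, noise_sigma = 0.2, seed = s)
    vapply(1:6, function(i) {
      m <- measure_particle(pf$image,
                            c(pf$truth$base_x[i], pf$truth$base_y[i]),
                            pixel_size = pf$pixel_size)
      abs(m$length - pf$truth$length[i])
    }, numeric(1))
  }))
  expect_lt(median(errs), 0.435)   # one pixel at the fine sampling
})

test_that("a Gaussian blob at level 0.5 measures its FWHM", {
  px <- 0.5; sig <- 3
  xs <- seq(0, 40, by = px)
  img <- outer(exp(-(xs - 20)^2 / (2 * sig^2)),
               exp(-(xs - 12)^2 / (2 * sig^2)))
  attr(img, "pixel_size") <- px
  m <- measure_particle(img, c(20, 6), level = 0.5,
                        background_annulus = c(25, 35), search_length = 35)
  fwhm <- 2 * sqrt(2 * log(2)) * sig
  expect_lt(abs(m$width - fwhm), 2 * px)
})

test_that("measurement is equivariant under image rotation", {
  pf <- make_particle_field(n = 3, noise_sigma = 0, seed = 4)
  m0 <- measure_particle(pf$image,
                         c(pf$truth$base_x[2], pf$truth$base_y[2]),
                         pixel_size = pf$pixel_size)
  # rotate the image 90 degrees: x' = y, y' = nx - x
  rot <- t(pf$image)[, rev(seq_len(nrow(pf$image)))]
  attr(rot, "pixel_size") <- pf$pixel_size
  w_nm <- (nrow(pf$image) - 1) * pf$pixel_size
  base_rot <- c(pf$truth$base_y[2], w_nm - pf$truth$base_x[2])
  m90 <- measure_particle(rot, base_rot, normal = c(1, 0),
                          pixel_size = pf$pixel_size)
  expect_lt(abs(m0$length - m90$length), pf$pixel_size)
  expect_lt(abs(m0$width - m90$width), pf$pixel_size)
})

test_that("empty particles raise the documented error", {
  flat <- matrix(1, 60, 60)
  attr(flat, "pixel_size") <- 0.5
  expect_error(measure_particle(flat, c(15, 5)), "no density above")
})

test_that("size-gate classification labels reference-like and outlier particles", {
  ref <- data.frame(name = c("AMPAR", "NMDAR"),
                    length = c(12.0, 10.5), width = c(10.5, 10.3),
                    sd_length = c(0.2, 0.2), sd_width = c(2.4, 1.4))
  meas <- data.frame(length = c(12.0, 30), width = c(10.5, 2))
  out <- classify_by_size(meas, ref)
  expect_identical(out$size_class, c("receptor_like", "nonreceptor"))
  expect_identical(out$nearest_reference[1], "AMPAR")
  # simulated clouds at characteristic receptor/nonreceptor centroids
  set.seed(6)
  rec <- data.frame(length = rnorm(80, 12.1, 1.4), width = rnorm(80, 8.6, 1.4))
  non <- data.frame(length = rnorm(80, 20, 4), width = rnorm(80, 3.5, 1))
  both <- classify_by_size(rbind(rec, non),
                           data.frame(length = 12.1, width = 8.6,
                                      sd_length = 1.4, sd_width = 1.4))
  truth <- rep(c("receptor_like", "nonreceptor"), each = 80)
  expect_gt(mean(both$size_class == truth), 0.85)
  expect_true(is.numeric(attr(both, "gate_fraction")))
})

test_that("alignment removes rotation and averaging is idempotent", {
  pf <- make_particle_field(n = 3, noise_sigma = 0, seed = 7)
  m <- measure_particle(pf$image,
                        c(pf$truth$base_x[1], pf$truth$base_y[1]),
                        pixel_size = pf$pixel_size)
  one <- align_and_average(pf$image, m, pixel_size = pf$pixel_size)
  two <- align_and_average(pf$image, list(m, m), pixel_size = pf$pixel_size)
  expect_equal(one$average, two$average, tolerance = 1e-12)
  expect_equal(two$n, 2)
  # averaging noisy copies of one particle shrinks background noise
  # roughly as 1/sqrt(N): the clean field is fixed, noise is per copy
  pfs <- make_particle_field(n = 1, noise_sigma = 0, seed = 11)
  ms <- measure_particle(pfs$image,
                         c(pfs$truth$base_x[1], pfs$truth$base_y[1]),
                         pixel_size = pfs$pixel_size)
  set.seed(9)
  noise_sd <- function(n_copies) {
    imgs <- lapply(seq_len(n_copies), function(i) {
      img <- pfs$image + matrix(rnorm(length(pfs$image), 0, 0.5),
                                nrow(pfs$image))
      attr(img, "pixel_size") <- pfs$pixel_size
      align_and_average(img, ms, pixel_size = pfs$pixel_size)$average
    })
    avg <- Reduce("+", imgs) / n_copies
    stats::sd(avg[, ncol(avg) - (0:5)], na.rm = TRUE)  # far-field rows
  }
  expect_lt(noise_sd(16), noise_sd(1) / 2)
})
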