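# Phantom generators: synthetic junction slabs, vesicle fields, landmark
# sets and picked point clouds with known ground truth, so that profile
# extraction, template matching, shape fitting and registration can all be
# validated without real tomograms.

# Run code under a fixed seed without disturbing the caller's RNG stream.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}

# Gaussian bump, unit amplitude
gauss1 <- function(d, mu, sigma) exp(-(d - mu)^2 / (2 * sigma^2))

#' Phantom specification for a synaptic junction
#'
#' Collects the generative parameters of [make_synapse_phantom()]. The
#' junction is modelled as two parallel bilayer membranes (each a pair of
#' Gaussian leaflet ridges) separated by `cleft_width`, an intercleft band
#' between them, and a PSD density on the postsynaptic side whose noiseless
#' cross-sectional profile is a peak at `psd_d1` with an exponential tail of
#' length constant `psd_lambda`. Distances are signed: 0 at the centre of
#' the postsynaptic membrane, positive into the postsynaptic side.
#'
#' The PSD term at signed distance d is
#' `peak_amp * g(d; d1, sigma) + tail_amp * t(d)` where `g` is a unit
#' Gaussian and the tail `t` equals `exp(-(d - d1)/lambda)` (shifted to
#' reach exactly zero at the start of the flat window, 100 nm, so the flat
#' region stays at background) for `d >= d1`, and falls off as `g` for
#' `d < d1`. Its maximum is therefore exactly at `d1`. The default
#' `peak_amp = 0` makes the crest of the PSD the start of the exponential
#' itself, which is how the junction's quantitative model reads the
#' profile; a separate Gaussian crest (`peak_amp > 0`) is supported for
#' sensitivity analysis, but as its amplitude grows the decay from the
#' peak departs from a single exponential and the tail fit degrades.
#'
#' @param volume_shape voxel triple (x, y, z).
#' @param voxel_size nm per voxel (default 0.755, a typical CCD pixel size
#'   at tomography magnification).
#' @param cleft_width nm between membrane centres (default 26, the scale
#'   observed at central synapses).
#' @param membrane_amp leaflet ridge amplitude (density units).
#' @param leaflet_sep nm between the two leaflet ridges of one bilayer
#'   (default 3.5).
#' @param leaflet_sigma nm, leaflet ridge width (default 1).
#' @param band_amp,band_offset intercleft band amplitude and signed offset
#'   (nm, default mid-cleft).
#' @param psd_d1 nm, PSD peak position (ground truth d1*).
#' @param psd_peak_amp PSD peak amplitude.
#' @param psd_peak_sigma nm, PSD peak width.
#' @param psd_lambda nm, exponential tail length constant (ground truth).
#' @param psd_tail_amp tail amplitude at the peak (ground truth A*).
#' @param background constant background density.
#' @param membrane_x nm, physical x-coordinate of the postsynaptic membrane
#'   centre plane; default 80 voxels from the volume edge, aligning the
#'   membrane with the voxel grid.
#' @param noise_sigma additive white Gaussian noise SD (density units).
#' @param wedge_halfangle degrees, or `NULL` for no missing wedge.
#' @param seed integer; fully determines the output.
#' @return list of class `"phantom_spec"`.
#' @export
phantom_spec <- function(volume_shape = c(360, 48, 16),
                         voxel_size = 0.755,
                         cleft_width = 26,
                         membrane_amp = 5,
                         leaflet_sep = 3.5,
                         leaflet_sigma = 1,
                         band_amp = 2,
                         band_offset = NULL,
                         psd_d1 = 15,
                         psd_peak_amp = 0,
                         psd_peak_sigma = 2,
                         psd_lambda = 18,
                         psd_tail_amp = 2,
                         background = 0,
                         membrane_x = NULL,
                         noise_sigma = 0,
                         wedge_halfangle = NULL,
                         seed = 1L) {
  if (voxel_size <= 0) stop("voxel_size must be > 0")
  if (cleft_width <= 0) stop("cleft_width must be > 0")
  if (psd_lambda <= 0) stop("psd_lambda must be > 0")
  if (is.null(band_offset)) band_offset <- -cleft_width / 2
  if (is.null(membrane_x)) membrane_x <- 80 * voxel_size
  spec <- as.list(environment())
  class(spec) <- "phantom_spec"
  spec
}

# Closed-form noiseless junction profile of a phantom_spec at signed
# distance d (nm). flat_start fixes where the shifted tail reaches zero.
phantom_profile <- function(spec, d, flat_start = 100) {
  leaf <- spec$leaflet_sep / 2
  memb <- function(center) {
    gauss1(d, center - leaf, spec$leaflet_sigma) +
      gauss1(d, center + leaf, spec$leaflet_sigma)
  }
  tail_shape <- ifelse(
    d >= spec$psd_d1,
    pmax(0, exp(-(d - spec$psd_d1) / spec$psd_lambda) -
           exp(-(flat_start - spec$psd_d1) / spec$psd_lambda)),
    (1 - exp(-(flat_start - spec$psd_d1) / spec$psd_lambda)) *
      gauss1(d, spec$psd_d1, spec$psd_peak_sigma))
  spec$background +
    spec$membrane_amp * memb(0) +
    spec$membrane_amp * memb(-spec$cleft_width) +
    spec$band_amp * gauss1(d, spec$band_offset, 2) +
    spec$psd_peak_amp * gauss1(d, spec$psd_d1, spec$psd_peak_sigma) +
    spec$psd_tail_amp * tail_shape
}

#' Generate a synaptic-junction phantom tomogram
#'
#' Renders the junction model of a [phantom_spec()] into a volume: the
#' density varies only along x (the membrane normal), membranes lie in
#' y-z planes, noise is added voxelwise and, optionally, a hard binary
#' missing-wedge filter is applied in Fourier space.
#'
#' @param spec a [phantom_spec()].
#' @return list with `tomogram` (a [tomogram()]) and `truth` (all
#'   generative parameters plus `profile_fn`, the closed-form noiseless
#'   profile as a function of signed distance in nm).
#' @export
make_synapse_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  dims <- spec$volume_shape
  x_nm <- (seq_len(dims[1]) - 1) * spec$voxel_size
  d <- x_nm - spec$membrane_x
  if (min(d) > -(spec$cleft_width + 10) || max(d) < 60)
    stop("volume too small to contain the junction at the requested ",
         "membrane offset")
  prof <- phantom_profile(spec, d)
  vol <- array(prof, dim = dims)   # x varies fastest: profile replicated
  vol <- with_seed(spec$seed, {
    if (spec$noise_sigma > 0)
      vol + array(stats::rnorm(prod(dims), 0, spec$noise_sigma), dim = dims)
    else vol
  })
  tomo <- tomogram(vol, spec$voxel_size)
  if (!is.null(spec$wedge_halfangle))
    tomo <- apply_missing_wedge(tomo, spec$wedge_halfangle)
  truth <- list(
    d1 = spec$psd_d1, lambda = spec$psd_lambda, d2 = spec$psd_d1 +
      spec$psd_lambda, A = spec$psd_tail_amp, cleft_width = spec$cleft_width,
    membrane_x = spec$membrane_x, background = spec$background,
    spec = spec,
    profile_fn = function(dd) phantom_profile(spec, dd))
  list(tomogram = tomo, truth = truth)
}

#' Apply a missing-wedge filter
#'
#' Zeroes the Fourier components not sampled by a tilt series of range
#' `+/- halfangle` about the y (tilt) axis with the beam along z: a
#' direction (kx, kz) is unobserved when it lies within
#' `90 - halfangle` degrees of the kz axis. The zero-frequency component
#' is always kept, so the volume mean is preserved.
#'
#' @param tomo a [tomogram()].
#' @param halfangle tilt half-range in degrees (default 60).
#' @return filtered [tomogram()].
#' @export
apply_missing_wedge <- function(tomo, halfangle = 60) {
  stopifnot(inherits(tomo, "tomogram"))
  d <- dim(tomo$data)
  kx <- fft_freqs(d[1]); kz <- fft_freqs(d[3])
  # wedge in the kx-kz plane, independent of ky
  KX <- matrix(abs(kx), d[1], d[3])
  KZ <- matrix(abs(kz), d[1], d[3], byrow = TRUE)
  keep <- KZ <= KX * tan(halfangle * pi / 180)
  keep[1, 1] <- TRUE   # DC
  keep3 <- aperm(array(keep, dim = c(d[1], d[3], d[2])), c(1, 3, 2))
  ft <- stats::fft(tomo$data) * keep3
  out <- Re(stats::fft(ft, inverse = TRUE)) / prod(d)
  tomogram(out, tomo$voxel_size, tomo$origin)
}

# cycles-per-grid frequency index for an FFT axis of length n
fft_freqs <- function(n) {
  k <- c(0:(floor(n / 2)), -((ceiling(n / 2) - 1):1))
  if (n == 1) k <- 0
  k[seq_len(n)]
}

# Render an ellipsoidal shell into vol (modified in place semantics via
# return). center nm, semi_axes nm (length 3), R rotation matrix mapping
# body coords to lab coords, thickness nm, hard-edged shell of given
# amplitude added to the existing densities.
render_shell <- function(vol, voxel_size, center, semi_axes, R = diag(3),
                         thickness = 5, amplitude = 1) {
  d <- dim(vol)
  rmax <- max(semi_axes) + thickness
  lo <- pmax(1, floor(center / voxel_size + 1 - rmax / voxel_size))
  hi <- pmin(d, ceiling(center / voxel_size + 1 + rmax / voxel_size))
  if (any(lo > hi)) return(vol)
  xs <- (lo[1]:hi[1] - 1) * voxel_size - center[1]
  ys <- (lo[2]:hi[2] - 1) * voxel_size - center[2]
  zs <- (lo[3]:hi[3] - 1) * voxel_size - center[3]
  g <- expand.grid(x = xs, y = ys, z = zs)
  body <- t(R) %*% rbind(g$x, g$y, g$z)   # lab -> body frame
  m <- sqrt((body[1, ] / semi_axes[1])^2 + (body[2, ] / semi_axes[2])^2 +
              (body[3, ] / semi_axes[3])^2)
  # |m - 1| scaled by the local radius approximates distance to the surface
  rad <- sqrt(g$x^2 + g$y^2 + g$z^2) / pmax(m, 1e-12)
  inside <- abs((m - 1) * rad) <= thickness / 2
  sub <- vol[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]]
  sub[inside] <- sub[inside] + amplitude
  vol[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- sub
  vol
}

# uniform random rotation matrix (from QR of Gaussian matrix, det +1)
random_rotation <- function() {
  q <- qr.Q(qr(matrix(stats::rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

#' Generate a field of synaptic-vesicle shells
#'
#' Places `n` non-overlapping vesicles — 5 nm-thick shells of elevated
#' density, mimicking the membrane of neurotransmitter vesicles — in a box
#' and returns the ground-truth list. A fraction of the vesicles are
#' ellipsoidal (oblate "discus" or prolate "olive" spheroids); the rest are
#' spheres.
#'
#' @param n number of vesicles (>= 1).
#' @param diameter_range nm, range of the reference (spherical-equivalent)
#'   diameter; default 25-60, the physiological size range.
#' @param ellipsoidal_fraction proportion in `[0, 1]` of ellipsoidal
#'   vesicles (axis ratio drawn in 1.2-1.6).
#' @param noise_sigma additive Gaussian noise SD (shell amplitude is 1, so
#'   `noise_sigma = 1` gives SNR 1).
#' @param voxel_size nm (default 2: template matching does not need the
#'   full reconstruction sampling).
#' @param box_nm physical box size, length-3 nm vector.
#' @param shell_thickness nm (default 5).
#' @param seed integer.
#' @param max_tries placement retries per vesicle before giving up.
#' @return list with `tomogram` and `truth`, a data frame with one row per
#'   vesicle: center (nm), sorted semi-axes `s1 <= s2 <= s3` (nm),
#'   `diameter` (reference diameter, nm), `shape` (sphere/discus/olive).
#' @export
make_vesicle_field <- function(n, diameter_range = c(25, 60),
                               ellipsoidal_fraction = 0.15,
                               noise_sigma = 0, voxel_size = 2,
                               box_nm = c(400, 400, 200),
                               shell_thickness = 5, seed = 1L,
                               max_tries = 2000L) {
  stopifnot(n >= 1)
  dims <- round(box_nm / voxel_size)
  with_seed(seed, {
    centers <- matrix(NA_real_, 0, 3)
    radii <- numeric(0)
    truth <- vector("list", n)
    for (i in seq_len(n)) {
      is_ell <- stats::runif(1) < ellipsoidal_fraction
      dia <- stats::runif(1, diameter_range[1],
                          min(diameter_range[2], if (is_ell) 50 else Inf))
      s <- rep(dia / 2, 3)
      shape <- "sphere"
      if (is_ell) {
        ratio <- stats::runif(1, 1.2, 1.6)
        if (stats::runif(1) < 0.7) { s[1] <- s[1] / ratio; shape <- "discus" }
        else { s[3] <- s[3] * ratio; shape <- "olive" }
      }
      R <- if (is_ell) random_rotation() else diag(3)
      rmax <- max(s) + shell_thickness / 2
      placed <- FALSE
      for (try in seq_len(max_tries)) {
        c_nm <- stats::runif(3, rmax + 2, box_nm - rmax - 2)
        if (nrow(centers) == 0 ||
            all(sqrt(colSums((t(centers) - c_nm)^2)) >
                radii + rmax + 2)) {
          placed <- TRUE
          break
        }
      }
      if (!placed)
        stop("could not place ", n, " non-overlapping vesicles in the box; ",
             "increase box_nm or reduce n")
      centers <- rbind(centers, c_nm)
      radii <- c(radii, rmax)
      truth[[i]] <- data.frame(
        id = i, x = c_nm[1], y = c_nm[2], z = c_nm[3],
        s1 = sort(s)[1], s2 = sort(s)[2], s3 = sort(s)[3],
        diameter = dia, shape = shape)
      truth[[i]]$R <- list(R)
      truth[[i]]$semi_axes_raw <- list(s)
    }
    truth <- do.call(rbind, truth)
    vol <- array(0, dim = dims)
    for (i in seq_len(n)) {
      vol <- render_shell(vol, voxel_size,
                          center = c(truth$x[i], truth$y[i], truth$z[i]),
                          semi_axes = truth$semi_axes_raw[[i]],
                          R = truth$R[[i]],
                          thickness = shell_thickness, amplitude = 1)
    }
    if (noise_sigma > 0)
      vol <- vol + array(stats::rnorm(prod(dims), 0, noise_sigma), dim = dims)
    list(tomogram = tomogram(vol, voxel_size), truth = truth)
  })
}

#' Generate paired landmark sets under a known transform
#'
#' Test bed for [estimate_transform()]: source points are drawn uniformly
#' in a square field, targets are the transformed sources plus isotropic
#' Gaussian pixel noise.
#'
#' @param true_transform an [affine2d()].
#' @param n_points >= 3.
#' @param noise_sigma_px Gaussian noise SD added to targets (pixels).
#' @param seed integer.
#' @param extent_px field size (source points in `[0, extent_px]^2`).
#' @return list with `source` and `target`, n x 2 matrices.
#' @export
make_landmark_pairs <- function(true_transform, n_points,
                                noise_sigma_px = 0, seed = 1L,
                                extent_px = 1000) {
  if (n_points < 3) stop("need at least 3 landmark points")
  with_seed(seed, {
    src <- cbind(stats::runif(n_points, 0, extent_px),
                 stats::runif(n_points, 0, extent_px))
    tgt <- map_points(true_transform, src)
    if (noise_sigma_px > 0)
      tgt <- tgt + matrix(stats::rnorm(2 * n_points, 0, noise_sigma_px),
                          ncol = 2)
    list(source = src, target = tgt)
  })
}

#' Generate picked points on an ellipsoid surface
#'
#' Emulates manual picking of membrane points on a vesicle in 3D: uniform
#' directions mapped onto the ellipsoid surface, plus isotropic noise.
#'
#' @param semi_axes length-3 nm vector.
#' @param orientation 3x3 rotation matrix (body -> lab).
#' @param n number of points (>= 9, the quadric minimum; 18 by default,
#'   matching picking practice).
#' @param noise_sigma nm.
#' @param center length-3 nm vector.
#' @param seed integer.
#' @return n x 3 matrix of nm coordinates.
#' @export
make_ellipsoid_points <- function(semi_axes, orientation = diag(3), n = 18,
                                  noise_sigma = 0, center = c(0, 0, 0),
                                  seed = 1L) {
  if (n < 9) stop("need at least 9 points to constrain a quadric")
  with_seed(seed, {
    u <- matrix(stats::rnorm(3 * n), n, 3)
    u <- u / sqrt(rowSums(u^2))
    p <- t(orientation %*% (t(u) * semi_axes))
    p <- sweep(p, 2, center, "+")
    if (noise_sigma > 0)
      p <- p + matrix(stats::rnorm(3 * n, 0, noise_sigma), n, 3)
    p
  })
}

#' Generate a 2D field of membrane-attached particles
#'
#' Renders a flat membrane (horizontal Gaussian ridge pair) with
#' rectangular particles of known length and width standing on its upper
#' edge, as a test bed for particle morphometry on z-averaged projections.
#'
#' @param n particles.
#' @param length_range,width_range nm.
#' @param pixel_size nm (default 0.435, a typical direct-detector pixel
#'   size at high magnification).
#' @param image_nm c(width, height) of the field in nm.
#' @param membrane_y nm, y-coordinate of the membrane centre line.
#' @param amplitude particle density amplitude.
#' @param noise_sigma Gaussian noise SD.
#' @param seed integer.
#' @return list with `image` (matrix, x by y), `pixel_size`, and `truth`
#'   data frame (base point nm, length nm, width nm); particles extend in
#'   +y from the membrane outer edge.
#' @export
make_particle_field <- function(n, length_range = c(8, 14),
                                width_range = c(5, 10),
                                pixel_size = 0.435,
                                image_nm = c(300, 80), membrane_y = 20,
                                amplitude = 2, noise_sigma = 0, seed = 1L) {
  dims <- round(image_nm / pixel_size)
  with_seed(seed, {
    xs <- (seq_len(dims[1]) - 1) * pixel_size
    ys <- (seq_len(dims[2]) - 1) * pixel_size
    img <- outer(rep(1, dims[1]),
                 gauss1(ys, membrane_y - 1.75, 1) +
                   gauss1(ys, membrane_y + 1.75, 1)) * amplitude * 1.5
    # particle bases spaced to avoid overlap
    slots <- seq(15, image_nm[1] - 15, length.out = n)
    len <- stats::runif(n, length_range[1], length_range[2])
    wid <- pmin(stats::runif(n, width_range[1], width_range[2]), len)
    memb_edge <- membrane_y + 2.5   # outer leaflet edge
    for (i in seq_len(n)) {
      in_x <- abs(xs - slots[i]) <= wid[i] / 2
      in_y <- ys >= memb_edge & ys <= memb_edge + len[i]
      img[in_x, in_y] <- img[in_x, in_y] + amplitude
    }
    if (noise_sigma > 0)
      img <- img + matrix(stats::rnorm(prod(dims), 0, noise_sigma),
                          dims[1], dims[2])
    list(image = img, pixel_size = pixel_size,
         truth = data.frame(id = seq_len(n), base_x = slots,
                            base_y = memb_edge, length = len, width = wid))
  })
}
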