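# Cross-sectional density profiling of the synaptic junction: slab
# projection, parallel-offset averaging along a traced postsynaptic
# membrane, flat-region normalization, Gaussian peak fitting and the
# exponential PSD-tail fit that defines d2 = d1 + lambda.

#' Density profile container
#'
#' Cross-sectional mean density versus signed distance from the
#' postsynaptic membrane: 0 at the membrane centre, positive into the
#' postsynaptic side.
#'
#' @param d strictly increasing, uniformly spaced distances (nm).
#' @param v density values (raw or normalized).
#' @param normalization `NULL`, or a list with `flat_mean`, `flat_sd`,
#'   `flat_window` recorded by [normalize_profile()].
#' @param n_px optional per-sample pixel counts from [extract_profile()].
#' @return object of class `"density_profile"`.
#' @export
density_profile <- function(d, v, normalization = NULL, n_px = NULL) {
  stopifnot(length(d) == length(v), length(d) >= 2)
  steps <- diff(d)
  if (any(steps <= 0)) stop("distances must be strictly increasing")
  if (diff(range(steps)) > 1e-6 * mean(steps))
    stop("distances must be uniformly spaced")
  structure(list(d = as.numeric(d), v = as.numeric(v),
                 step = mean(steps), normalization = normalization,
                 n_px = n_px),
            class = "density_profile")
}

#' @export
print.density_profile <- function(x, ...) {
  cat(sprintf("density_profile: %d samples, d in [%.1f, %.1f] nm, step %.3g nm%s\n",
              length(x$d), min(x$d), max(x$d), x$step,
              if (is.null(x$normalization)) " (raw)" else " (normalized)"))
  invisible(x)
}

#' @export
as.data.frame.density_profile <- function(x, ...) {
  data.frame(d_nm = x$d, v = x$v)
}

#' Project a slab of a tomogram along z
#'
#' Averages the z-slices of a `thickness`-nm slab centred at `z_center`
#' into a 2D image, emulating virtual-slice averaging of a subvolume that
#' contains the structure of interest. The default 10 nm matches junction
#' profiling practice; particle work uses thinner or thicker slabs.
#'
#' @param tomo a [tomogram()].
#' @param z_center nm (physical z of the slab centre).
#' @param thickness nm.
#' @return matrix (x by y) of mean densities, with attributes `pixel_size`
#'   (nm) and `n_slices`.
#' @export
project_slab <- function(tomo, z_center, thickness = 10) {
  stopifnot(inherits(tomo, "tomogram"))
  d <- dim(tomo$data)
  zc <- (z_center - tomo$origin[3]) / tomo$voxel_size + 1
  half <- thickness / tomo$voxel_size / 2
  z0 <- ceiling(zc - half - 1e-9); z1 <- floor(zc + half + 1e-9)
  z0 <- max(z0, ceiling(zc - half)); # guard rounding
  if (z0 < 1 || z1 > d[3])
    stop("slab [", z0, ", ", z1, "] exceeds volume z-extent 1..", d[3])
  if (z1 < z0) { z0 <- round(zc); z1 <- z0 }   # sub-voxel slab: one slice
  n <- z1 - z0 + 1
  img <- apply(tomo$data[, , z0:z1, drop = FALSE], c(1, 2), mean)
  attr(img, "pixel_size") <- tomo$voxel_size
  attr(img, "n_slices") <- n
  img
}

#' Membrane trace
#'
#' An ordered polyline (nm) drawn along the postsynaptic membrane in the
#' slab-projection plane, plus a flag giving which side of the trace is
#' postsynaptic.
#'
#' @param xy n x 2 matrix of nm coordinates (>= 2 vertices).
#' @param postsynaptic_side "left" or "right" of the walking direction
#'   (left = the side that the 90 degree counter-clockwise normal points
#'   to, in image coordinates with x right and y up).
#' @return object of class `"membrane_trace"`.
#' @export
membrane_trace <- function(xy, postsynaptic_side = c("left", "right")) {
  xy <- as.matrix(xy)
  stopifnot(ncol(xy) == 2, nrow(xy) >= 2)
  postsynaptic_side <- match.arg(postsynaptic_side)
  structure(list(xy = xy, postsynaptic_side = postsynaptic_side),
            class = "membrane_trace")
}

# Signed distance of points (n x 2, nm) to a polyline: unsigned distance to
# nearest segment; sign from the cross product with the segment direction
# (positive on the left of the walking direction).
signed_distance_to_polyline <- function(pts, poly) {
  n <- nrow(pts)
  best_d2 <- rep(Inf, n)
  best_sign <- rep(1, n)
  for (i in seq_len(nrow(poly) - 1)) {
    a <- poly[i, ]; b <- poly[i + 1, ]
    ab <- b - a
    len2 <- sum(ab^2)
    if (len2 == 0) next
    t_par <- ((pts[, 1] - a[1]) * ab[1] + (pts[, 2] - a[2]) * ab[2]) / len2
    t_cl <- pmin(1, pmax(0, t_par))
    qx <- a[1] + t_cl * ab[1]; qy <- a[2] + t_cl * ab[2]
    d2 <- (pts[, 1] - qx)^2 + (pts[, 2] - qy)^2
    cross <- ab[1] * (pts[, 2] - a[2]) - ab[2] * (pts[, 1] - a[1])
    upd <- d2 < best_d2
    best_d2[upd] <- d2[upd]
    best_sign[upd] <- sign(cross[upd] + (cross[upd] == 0))
  }
  sqrt(best_d2) * best_sign
}

#' Extract a cross-sectional density profile along a membrane trace
#'
#' For each signed distance bin, averages the image over all pixels whose
#' signed distance to the trace falls in `[d - step/2, d + step/2)`. For a
#' straight trace this equals averaging along virtual lines parallel to the
#' trace; the signed-distance construction extends the same definition to
#' curved traces. Distances are positive on the postsynaptic side.
#'
#' @param image 2D matrix (x by y) with attribute `pixel_size` (nm), e.g.
#'   from [project_slab()]; or pass `pixel_size` explicitly.
#' @param trace a [membrane_trace()].
#' @param d_min,d_max profile range (nm); the default -40..200 covers the
#'   presynaptic membrane through the flat cytoplasmic background.
#' @param step bin width (nm); default one pixel.
#' @param pixel_size nm, overrides the image attribute.
#' @return a raw [density_profile()]; bins whose offset curve leaves the
#'   image (no pixels) carry `NA` values, with per-bin counts in `n_px`.
#' @export
extract_profile <- function(image, trace, d_min = -40, d_max = 200,
                            step = NULL, pixel_size = NULL) {
  stopifnot(inherits(trace, "membrane_trace"))
  if (is.null(pixel_size)) pixel_size <- attr(image, "pixel_size")
  if (is.null(pixel_size)) stop("pixel_size not given and not an attribute")
  if (is.null(step)) step <- pixel_size
  dims <- dim(image)
  px <- (seq_len(dims[1]) - 1) * pixel_size
  py <- (seq_len(dims[2]) - 1) * pixel_size
  pts <- cbind(rep(px, times = dims[2]), rep(py, each = dims[1]))
  sd_ <- signed_distance_to_polyline(pts, trace$xy)
  if (trace$postsynaptic_side == "right") sd_ <- -sd_
  centers <- seq(d_min, d_max, by = step)
  idx <- floor((sd_ - (d_min - step / 2)) / step) + 1
  ok <- idx >= 1 & idx <= length(centers)
  sums <- tapply(as.vector(image)[ok], idx[ok], sum)
  cnts <- tapply(rep(1, sum(ok)), idx[ok], sum)
  v <- rep(NA_real_, length(centers))
  n_px <- rep(0L, length(centers))
  ii <- as.integer(names(sums))
  v[ii] <- sums / cnts
  n_px[ii] <- as.integer(cnts)
  density_profile(centers, v, n_px = n_px)
}

#' Normalize a profile against its flat region
#'
#' Subtracts the mean and divides by the SD of the "flat" cytoplasmic
#' window (default 100-200 nm from the postsynaptic membrane), compensating
#' for variable imaging conditions. The result has flat-window mean 0 and
#' SD 1; the operation is affine in value, so profile shape is preserved
#' and re-normalizing is a no-op.
#'
#' @param profile a [density_profile()].
#' @param flat_window length-2 nm range.
#' @return normalized [density_profile()] with the flat statistics recorded.
#' @export
normalize_profile <- function(profile, flat_window = c(100, 200)) {
  stopifnot(inherits(profile, "density_profile"))
  inw <- profile$d >= flat_window[1] & profile$d <= flat_window[2] &
    !is.na(profile$v)
  if (sum(inw) < 10)
    stop("flat window [", flat_window[1], ", ", flat_window[2],
         "] nm contains fewer than 10 profile samples")
  m <- mean(profile$v[inw])
  s <- stats::sd(profile$v[inw])
  if (!is.finite(s) || s <= 0)
    stop("flat window has zero variance; cannot normalize")
  density_profile(profile$d, (profile$v - m) / s,
                  normalization = list(flat_mean = m, flat_sd = s,
                                       flat_window = flat_window),
                  n_px = profile$n_px)
}

# Gaussian-plus-linear-baseline fit around a local maximum at index i0,
# window +/- half_window nm. The linear term absorbs the slope of any
# asymmetric background under the peak (e.g. the exponential PSD tail),
# which would otherwise bias the fitted centre. Returns the fitted centre
# (nm), or the discrete peak position on failure.
fit_local_gaussian <- function(d, v, i0, half_window = 5) {
  sel <- which(abs(d - d[i0]) <= half_window & !is.na(v))
  if (length(sel) < 6) return(list(mu = d[i0], ok = FALSE))
  dd <- d[sel]; vv <- v[sel]
  base <- min(vv)
  d0 <- d[i0]
  fit <- try(suppressWarnings(minpack.lm::nlsLM(
    vv ~ b + slope * (dd - d0) + a * exp(-(dd - mu)^2 / (2 * s^2)),
    start = list(b = base, slope = 0, a = v[i0] - base, mu = d0,
                 s = half_window / 2),
    lower = c(-Inf, -Inf, 0, d0 - half_window, 1e-3),
    upper = c(Inf, Inf, Inf, d0 + half_window, 4 * half_window),
    control = minpack.lm::nls.lm.control(maxiter = 300))), silent = TRUE)
  if (inherits(fit, "try-error"))
    return(list(mu = d[i0], ok = FALSE))
  cf <- stats::coef(fit)
  list(mu = unname(cf["mu"]), sigma = unname(cf["s"]),
       amp = unname(cf["a"]), ok = TRUE,
       resid = sqrt(mean(stats::resid(fit)^2)))
}

# Gaussian smoothing of a 1D signal (sigma in samples), NA-aware
# normalized convolution; sigma <= 0 returns the input unchanged.
smooth_gauss_1d <- function(v, sigma) {
  if (sigma <= 0) return(v)
  half <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-half):half)^2 / (2 * sigma^2))
  ok <- as.numeric(!is.na(v))
  v0 <- ifelse(is.na(v), 0, v)
  num <- stats::filter(v0, k, sides = 2)
  den <- stats::filter(ok, k, sides = 2)
  out <- as.numeric(num / den)
  out[is.nan(out)] <- NA
  # filter() leaves NA margins; fall back to the raw values there
  edge <- is.na(out) & !is.na(v)
  out[edge] <- v[edge]
  out
}

# Sub-sample peak refinement: stationary point of a least-squares
# parabola over +/- half_window nm around the discrete maximum at i0,
# clamped to the window. Unlike a Gaussian fit, this estimates the local
# crest without assuming peak symmetry. The default window (+/- 1.6 nm,
# about two profile samples at tomographic sampling) keeps enough points
# for a stable quadratic while staying narrow enough that the slowly
# decaying exponential side of the PSD crest cannot drag the vertex
# toward the tail.
refine_peak_quadratic <- function(d, v, i0, half_window = 1.6) {
  sel <- which(abs(d - d[i0]) <= half_window & !is.na(v))
  if (length(sel) < 4) return(d[i0])
  dd <- d[sel] - d[i0]; vv <- v[sel]
  cf <- stats::coef(stats::lm(vv ~ dd + I(dd^2)))
  if (!is.finite(cf[3]) || cf[3] >= 0) return(d[i0])
  mu <- d[i0] - cf[2] / (2 * cf[3])
  max(min(mu, d[i0] + half_window), d[i0] - half_window)
}

# indices of strict local maxima of v (NA-safe)
local_maxima <- function(v) {
  n <- length(v)
  if (n < 3) return(integer(0))
  out <- integer(0)
  for (i in 2:(n - 1)) {
    if (is.na(v[i])) next
    l <- v[i - 1]; r <- v[i + 1]
    if (!is.na(l) && !is.na(r) && v[i] >= l && v[i] > r && v[i] > l)
      out <- c(out, i)
    else if (!is.na(l) && !is.na(r) && v[i] > l && v[i] >= r)
      out <- c(out, i)
  }
  out
}

#' Locate the junction peaks in a density profile
#'
#' Detects local maxima and assigns the presynaptic membrane, intercleft
#' band, postsynaptic membrane, and PSD peaks; each assigned position is
#' then refined by a local Gaussian fit. Distances are finally re-centred
#' so that the postsynaptic membrane sits exactly at 0.
#'
#' A synapse without a detectable PSD (no local maximum above threshold
#' beyond the membrane) yields `psd_present = FALSE` rather than an error,
#' mirroring the existence of synapses with no visible PSD.
#'
#' @param profile a [density_profile()], normally normalized.
#' @param fit_half_window nm, Gaussian-fit window half-width around each
#'   detected maximum (default 5).
#' @param threshold_sd detection threshold in flat-window SD units
#'   (default 1.5).
#' @param membrane_halfwidth nm; PSD candidates must lie beyond this
#'   (default 5).
#' @param psd_max_d nm; PSD candidates must lie within this (default 60).
#' @param smooth_sigma nm; Gaussian pre-smoothing applied for peak
#'   detection and for the membrane/band peak fits (default 1.5). When the
#'   two leaflets of a bilayer are resolved as sub-peaks, this merges them
#'   so the fitted membrane position is the bilayer centre. The PSD peak
#'   is refined on the unsmoothed profile, since smoothing an asymmetric
#'   peak shifts its crest.
#' @return list of class `"psd_peaks"` with elements `presynaptic`,
#'   `intercleft`, `postsynaptic`, `psd` (nm, re-centred; `NA` when
#'   absent), `psd_present`, `shift` (the re-centring offset), and
#'   `profile` (the re-centred profile).
#' @export
fit_peaks <- function(profile, fit_half_window = 5, threshold_sd = 1.5,
                      membrane_halfwidth = 5, psd_max_d = 60,
                      smooth_sigma = 1.5) {
  stopifnot(inherits(profile, "density_profile"))
  d <- profile$d; v <- profile$v
  vs <- smooth_gauss_1d(v, smooth_sigma / profile$step)
  flat_sd <- if (!is.null(profile$normalization)) 1 else {
    inw <- d >= 100 & d <= 200 & !is.na(v)
    if (sum(inw) >= 10) stats::sd(v[inw]) else stats::sd(v, na.rm = TRUE)
  }
  flat_mean <- if (!is.null(profile$normalization)) 0 else {
    inw <- d >= 100 & d <= 200 & !is.na(v)
    if (sum(inw) >= 10) mean(v[inw]) else stats::median(v, na.rm = TRUE)
  }
  thr <- flat_mean + threshold_sd * max(flat_sd, 1e-9 * diff(range(v, na.rm = TRUE)))
  cand <- local_maxima(vs)
  cand <- cand[vs[cand] > thr]
  if (length(cand) == 0) stop("no peaks found above threshold")
  # postsynaptic membrane: the strongest candidate near d = 0
  near0 <- cand[abs(d[cand]) <= 8]
  if (length(near0) == 0)
    stop("no postsynaptic membrane peak found within 8 nm of d = 0; ",
         "is the trace on the membrane?")
  i_post <- near0[which.max(vs[near0])]
  post_fit <- fit_local_gaussian(d, vs, i_post, fit_half_window)
  post_mu <- post_fit$mu
  # presynaptic membrane: strongest candidate well before the membrane
  pre_cand <- cand[d[cand] < post_mu - 12]
  pre_fit <- NULL
  if (length(pre_cand) > 0) {
    i_pre <- pre_cand[which.max(vs[pre_cand])]
    pre_fit <- fit_local_gaussian(d, vs, i_pre, fit_half_window)
  }
  # intercleft band: strongest candidate strictly between the membranes
  band_fit <- NULL
  if (!is.null(pre_fit)) {
    band_cand <- cand[d[cand] > pre_fit$mu + 4 & d[cand] < post_mu - 4]
    if (length(band_cand) > 0) {
      i_band <- band_cand[which.max(vs[band_cand])]
      band_fit <- fit_local_gaussian(d, vs, i_band, fit_half_window)
    }
  }
  # PSD peak: first candidate beyond the membrane half-width, refined on
  # the unsmoothed profile by a local quadratic around the crest — robust
  # for the asymmetric PSD peak (sharp rise from the gap, slow exponential
  # fall), where a symmetric Gaussian fit slides down the rise edge
  psd_fit <- NULL
  psd_cand <- cand[d[cand] > post_mu + membrane_halfwidth &
                     d[cand] <= post_mu + psd_max_d]
  if (length(psd_cand) > 0) {
    i_psd <- psd_cand[1]
    psd_fit <- list(mu = refine_peak_quadratic(d, v, i_psd), ok = TRUE)
  }
  shift <- post_mu
  recentred <- density_profile(d - shift, v,
                               normalization = profile$normalization,
                               n_px = profile$n_px)
  structure(list(
    presynaptic = if (is.null(pre_fit)) NA_real_ else pre_fit$mu - shift,
    intercleft = if (is.null(band_fit)) NA_real_ else band_fit$mu - shift,
    postsynaptic = 0,
    psd = if (is.null(psd_fit)) NA_real_ else psd_fit$mu - shift,
    psd_present = !is.null(psd_fit),
    shift = shift,
    profile = recentred), class = "psd_peaks")
}

#' Synaptic cleft width from fitted peaks
#'
#' Distance from the centre of the postsynaptic membrane to the centre of
#' the presynaptic membrane.
#'
#' @param peaks a `"psd_peaks"` result from [fit_peaks()].
#' @return nm.
#' @export
cleft_width <- function(peaks) {
  stopifnot(inherits(peaks, "psd_peaks"))
  if (is.na(peaks$presynaptic))
    stop("presynaptic membrane peak missing; cleft width undefined")
  abs(peaks$presynaptic - peaks$postsynaptic)
}

#' Fit the exponential PSD tail
#'
#' From the PSD peak toward the cytoplasmic background, fits
#' `v = A * exp(-d / lambda) + B` where `d` is the distance from the PSD
#' peak, by nonlinear least squares. The PSD thickness measure is
#' `d2 = d1 + lambda`.
#'
#' @param profile a [density_profile()] whose distances are re-centred on
#'   the postsynaptic membrane (e.g. `fit_peaks(p)$profile`).
#' @param d1 nm, PSD peak position (from [fit_peaks()]).
#' @param fit_max nm, far end of the fit range measured from the membrane
#'   (default 100, the start of the flat window).
#' @return list of class `"psd_decay"`: `A`, `lambda`, `B`, `d1`,
#'   `d2 = d1 + lambda`, `rmse`.
#' @export
fit_psd_decay <- function(profile, d1, fit_max = 100) {
  stopifnot(inherits(profile, "density_profile"))
  sel <- profile$d >= d1 & profile$d <= fit_max & !is.na(profile$v)
  if (sum(sel) < 10)
    stop("fewer than 10 samples between the PSD peak and the flat region")
  dd <- profile$d[sel] - d1
  vv <- profile$v[sel]
  B0 <- mean(vv[dd >= 0.8 * max(dd)])
  A0 <- max(vv[1] - B0, 1e-6)
  # initial lambda: distance at which v first drops to B + A/e
  drop_i <- which(vv <= B0 + A0 / exp(1))
  L0 <- if (length(drop_i) > 0) max(dd[drop_i[1]], 1) else max(dd) / 3
  fit <- try(suppressWarnings(minpack.lm::nlsLM(
    vv ~ A * exp(-dd / lambda) + B,
    start = list(A = A0, lambda = L0, B = B0),
    lower = c(0, 1e-3, -Inf), upper = c(Inf, 100, Inf),
    control = minpack.lm::nls.lm.control(maxiter = 500))), silent = TRUE)
  if (inherits(fit, "try-error"))
    stop("exponential fit did not converge (start A=", signif(A0, 3),
         ", lambda=", signif(L0, 3), ", B=", signif(B0, 3), ")")
  cf <- stats::coef(fit)
  structure(list(A = unname(cf["A"]), lambda = unname(cf["lambda"]),
                 B = unname(cf["B"]), d1 = d1,
                 d2 = d1 + unname(cf["lambda"]),
                 rmse = sqrt(mean(stats::resid(fit)^2))),
            class = "psd_decay")
}

#' Average several density profiles
#'
#' Pointwise mean over profiles sharing a distance grid; profiles on other
#' grids are first linearly resampled onto the grid of the first. Missing
#' values are dropped pointwise and per-point counts reported.
#'
#' @param profiles list of [density_profile()] objects (non-empty).
#' @return a [density_profile()] with `n_px` holding the per-point count
#'   of contributing profiles.
#' @export
average_profiles <- function(profiles) {
  if (length(profiles) == 0) stop("no profiles to average")
  stopifnot(all(vapply(profiles, inherits, TRUE, "density_profile")))
  grid <- profiles[[1]]$d
  vals <- vapply(profiles, function(p) {
    if (length(p$d) == length(grid) && max(abs(p$d - grid)) < 1e-9) p$v
    else stats::approx(p$d, p$v, xout = grid, rule = 1)$y
  }, numeric(length(grid)))
  vals <- matrix(vals, nrow = length(grid))
  density_profile(grid, rowMeans(vals, na.rm = TRUE),
                  n_px = rowSums(!is.na(vals)))
}

#' Full junction metrics for one synapse
#'
#' Convenience wrapper: normalize, locate peaks, measure cleft width and
#' fit the PSD tail, returning the per-synapse metric set.
#'
#' @param profile raw [density_profile()].
#' @param flat_window nm, passed to [normalize_profile()].
#' @param ... passed to [fit_peaks()].
#' @return list of class `"psd_metrics"`: `d1`, `lambda`, `A`, `B`, `d2`,
#'   `cleft_width`, `peaks`, `decay`, `psd_present`, `profile`
#'   (normalized, re-centred).
#' @export
psd_metrics <- function(profile, flat_window = c(100, 200), ...) {
  norm <- normalize_profile(profile, flat_window)
  peaks <- fit_peaks(norm, ...)
  cw <- if (is.na(peaks$presynaptic)) NA_real_ else cleft_width(peaks)
  if (peaks$psd_present) {
    decay <- fit_psd_decay(peaks$profile, peaks$psd)
    out <- list(d1 = peaks$psd, lambda = decay$lambda, A = decay$A,
                B = decay$B, d2 = decay$d2, cleft_width = cw,
                peaks = peaks, decay = decay, psd_present = TRUE,
                profile = peaks$profile)
  } else {
    out <- list(d1 = NA_real_, lambda = NA_real_, A = NA_real_,
                B = NA_real_, d2 = NA_real_, cleft_width = cw,
                peaks = peaks, decay = NULL, psd_present = FALSE,
                profile = peaks$profile)
  }
  class(out) <- "psd_metrics"
  out
}
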