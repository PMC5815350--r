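# Morphometry of membrane-attached particles (putative receptors) on
# z-averaged projections: a reproducible length/width operator replacing
# by-eye calipers, a size-gate classification against reference receptor
# dimensions, and membrane-end-aligned particle averaging.

# bilinear interpolation; x, y in continuous 1-based pixel coordinates;
# outside the image -> NA
bilinear_sample <- function(image, x, y) {
  d <- dim(image)
  x0 <- floor(x); y0 <- floor(y)
  fx <- x - x0; fy <- y - y0
  ok <- x0 >= 1 & y0 >= 1 & x0 + 1 <= d[1] & y0 + 1 <= d[2]
  out <- rep(NA_real_, length(x))
  if (!any(ok)) return(out)
  i00 <- cbind(x0[ok], y0[ok]); i10 <- cbind(x0[ok] + 1, y0[ok])
  i01 <- cbind(x0[ok], y0[ok] + 1); i11 <- cbind(x0[ok] + 1, y0[ok] + 1)
  out[ok] <- image[i00] * (1 - fx[ok]) * (1 - fy[ok]) +
    image[i10] * fx[ok] * (1 - fy[ok]) +
    image[i01] * (1 - fx[ok]) * fy[ok] +
    image[i11] * fx[ok] * fy[ok]
  out
}

# sample a chip in a rotated frame: origin_nm at (u, t) = (0, 0), u along
# `axis` (unit vector), t along the perpendicular; returns matrix [t, u]
sample_chip <- function(image, pixel_size, origin_nm, axis,
                        u_range, t_range, step = pixel_size) {
  us <- seq(u_range[1], u_range[2], by = step)
  ts <- seq(t_range[1], t_range[2], by = step)
  perp <- c(-axis[2], axis[1])
  g <- expand.grid(t = ts, u = us)
  px <- (origin_nm[1] + g$u * axis[1] + g$t * perp[1]) / pixel_size + 1
  py <- (origin_nm[2] + g$u * axis[2] + g$t * perp[2]) / pixel_size + 1
  chip <- matrix(bilinear_sample(image, px, py), nrow = length(ts))
  attr(chip, "u") <- us; attr(chip, "t") <- ts
  chip
}

# 4-connected component of mask containing any seed cell (matrix indices)
connected_component <- function(mask, seeds) {
  d <- dim(mask)
  lab <- matrix(FALSE, d[1], d[2])
  queue <- seeds[mask[seeds], , drop = FALSE]
  if (nrow(queue) == 0) return(lab)
  lab[queue] <- TRUE
  head <- 1
  qi <- queue[, 1]; qj <- queue[, 2]
  while (head <= length(qi)) {
    i <- qi[head]; j <- qj[head]; head <- head + 1
    for (nb in list(c(i - 1, j), c(i + 1, j), c(i, j - 1), c(i, j + 1))) {
      if (nb[1] >= 1 && nb[1] <= d[1] && nb[2] >= 1 && nb[2] <= d[2] &&
          mask[nb[1], nb[2]] && !lab[nb[1], nb[2]]) {
        lab[nb[1], nb[2]] <- TRUE
        qi <- c(qi, nb[1]); qj <- c(qj, nb[2])
      }
    }
  }
  lab
}

#' Measure a membrane-attached particle
#'
#' Reproducible operator for particle length and width on a 2D projection:
#' the image is resampled in a frame attached to the membrane (u along the
#' outward membrane normal from the base point, t tangential); background
#' is the mean over a far annulus `u in background_annulus`; pixels above
#' `background + level * (peak - background)` are thresholded; the
#' 4-connected component touching the base is kept; its principal axis
#' (intensity-weighted second moments, seeded by the membrane normal)
#' defines the particle axis. Length is the extent of the component along
#' that axis, width the perpendicular extent at the same level.
#'
#' @param image matrix (x by y) with attribute `pixel_size`, or pass
#'   `pixel_size`.
#' @param base_point length-2 nm coordinates of the membrane attachment
#'   (outer membrane edge).
#' @param normal length-2 outward membrane normal (default `c(0, 1)`).
#' @param search_length nm along the normal (default 30).
#' @param search_halfwidth nm to each side (default 12).
#' @param background_annulus nm range of u used as background (default
#'   `c(22, 30)`).
#' @param level fraction of (peak - background) defining the contour
#'   (default 0.5, i.e. full width at half maximum for a Gaussian blob).
#' @param membrane_clearance nm; rows closer than this to the membrane
#'   edge are excluded from the component so the laterally continuous
#'   membrane density cannot bridge neighbouring particles (default 2).
#' @param pixel_size nm.
#' @return list of class `"particle_measure"`: `length`, `width` (nm),
#'   `axis` (unit vector in image coordinates), `peak`, `background`,
#'   `threshold`, `n_px`.
#' @export
measure_particle <- function(image, base_point, normal = c(0, 1),
                             search_length = 30, search_halfwidth = 12,
                             background_annulus = c(22, 30), level = 0.5,
                             membrane_clearance = 2, pixel_size = NULL) {
  if (is.null(pixel_size)) pixel_size <- attr(image, "pixel_size")
  if (is.null(pixel_size)) stop("pixel_size not given and not an attribute")
  normal <- normal / sqrt(sum(normal^2))
  chip <- sample_chip(image, pixel_size, base_point, normal,
                      u_range = c(0, search_length),
                      t_range = c(-search_halfwidth, search_halfwidth))
  us <- attr(chip, "u"); ts <- attr(chip, "t")
  bgsel <- us >= background_annulus[1] & us <= background_annulus[2]
  bg <- mean(chip[, bgsel], na.rm = TRUE)
  # particle peak: clear of the membrane rows, near the base axis
  peak_zone <- outer(abs(ts) <= 4,
                     us >= membrane_clearance & us < background_annulus[1])
  peak_zone <- peak_zone & !is.na(chip)
  if (!any(peak_zone)) stop("search region is empty")
  peak <- max(chip[peak_zone])
  if (!is.finite(peak) || peak <= bg)
    stop("no density above background at this base point")
  thr <- bg + level * (peak - bg)
  mask <- !is.na(chip) & chip >= thr
  mask[, us < membrane_clearance] <- FALSE
  seed <- which(chip == peak & peak_zone, arr.ind = TRUE)[1, , drop = FALSE]
  comp <- connected_component(mask, seed)
  if (!any(comp))
    stop("no above-level pixels connected to the base point")
  idx <- which(comp, arr.ind = TRUE)
  tt <- ts[idx[, 1]]; uu <- us[idx[, 2]]
  w <- pmax(chip[comp] - bg, 0)
  # principal axis in (t, u), seeded by the membrane normal (u direction)
  mt <- sum(w * tt) / sum(w); mu_ <- sum(w * uu) / sum(w)
  ctt <- sum(w * (tt - mt)^2); cuu <- sum(w * (uu - mu_)^2)
  ctu <- sum(w * (tt - mt) * (uu - mu_))
  C <- matrix(c(ctt, ctu, ctu, cuu), 2, 2) / sum(w)
  ev <- eigen(C, symmetric = TRUE)
  # axis seeded by the membrane normal: only a clearly elongated
  # component (moment ratio > 2) overrides the normal with its own
  # principal direction; squat or near-square particles are measured
  # along the normal, as a human caliper would
  ax <- if (ev$values[2] > 0 && ev$values[1] / ev$values[2] > 2)
    ev$vectors[, 1] else c(0, 1)
  if (ax[2] < 0) ax <- -ax                  # point away from membrane
  # length: from the membrane outer edge (u = 0 on the base axis) to the
  # farthest connected pixel along the particle axis
  proj_l <- tt * ax[1] + uu * ax[2]
  proj_w <- tt * ax[2] - uu * ax[1]
  len <- max(proj_l) + pixel_size / 2
  wid <- diff(range(proj_w)) + pixel_size
  perp <- c(-normal[2], normal[1])
  axis_img <- ax[1] * perp + ax[2] * normal
  structure(list(length = len, width = wid, axis = axis_img,
                 peak = peak, background = bg, threshold = thr,
                 n_px = nrow(idx), base_point = base_point,
                 level = level),
            class = "particle_measure")
}

#' Size-gate classification of particles against reference receptors
#'
#' Labels a particle receptor-like when its (length, width) lies within an
#' elliptical gate of `k` SDs around any reference centroid. The receptor
#' and non-receptor populations on real membranes overlap, so these labels
#' are advisory; an optional manual label column is preserved alongside.
#'
#' @param measurements data frame with `length` and `width` (nm).
#' @param reference data frame with `name`, `length`, `width` and
#'   optionally `sd_length`, `sd_width` (nm; default 1.5 where absent —
#'   crystal-structure projection SDs understate biological variability).
#' @param k gate half-width in SDs (default 2).
#' @return `measurements` with added `size_class`
#'   ("receptor_like"/"nonreceptor") and `nearest_reference`; attribute
#'   `"gate_fraction"` gives the fraction of particles inside any gate.
#' @export
classify_by_size <- function(measurements, reference, k = 2) {
  stopifnot(all(c("length", "width") %in% names(measurements)),
            all(c("length", "width") %in% names(reference)))
  if (is.null(reference$sd_length)) reference$sd_length <- 1.5
  if (is.null(reference$sd_width)) reference$sd_width <- 1.5
  reference$sd_length[is.na(reference$sd_length)] <- 1.5
  reference$sd_width[is.na(reference$sd_width)] <- 1.5
  nm_ <- if (!is.null(reference$name)) reference$name
         else seq_len(nrow(reference))
  dmat <- sapply(seq_len(nrow(reference)), function(i) {
    sqrt(((measurements$length - reference$length[i]) /
            (k * pmax(reference$sd_length[i], 1e-6)))^2 +
         ((measurements$width - reference$width[i]) /
            (k * pmax(reference$sd_width[i], 1e-6)))^2)
  })
  dmat <- matrix(dmat, nrow = nrow(measurements))
  best <- apply(dmat, 1, which.min)
  inside <- apply(dmat, 1, min) <= 1
  measurements$size_class <- ifelse(inside, "receptor_like", "nonreceptor")
  measurements$nearest_reference <- nm_[best]
  attr(measurements, "gate_fraction") <- mean(inside)
  measurements
}

#' Align particle chips on their membrane end and average
#'
#' Each particle is resampled into a common frame — membrane attachment
#' point at the origin, long axis vertical (+u) — and the chips are
#' averaged pixelwise, ignoring samples that fall outside the source
#' image. This is the projection-averaging used to compare putative
#' receptors with reference structures.
#'
#' @param image source 2D projection (matrix, x by y).
#' @param measurements list of `"particle_measure"` results (or a single
#'   one).
#' @param chip_nm c(halfwidth, length): chip spans t in
#'   `[-halfwidth, halfwidth]`, u in `[-5, length]` nm (5 nm of membrane
#'   kept below the attachment point).
#' @param pixel_size nm.
#' @return list of class `"particle_average"`: `average` (matrix [t, u]),
#'   `count` (contributing chips per pixel), `n`, `u`, `t` (nm axes).
#' @export
align_and_average <- function(image, measurements, chip_nm = c(10, 25),
                              pixel_size = NULL) {
  if (inherits(measurements, "particle_measure"))
    measurements <- list(measurements)
  if (length(measurements) == 0) stop("no measurements to average")
  if (is.null(pixel_size)) pixel_size <- attr(image, "pixel_size")
  if (is.null(pixel_size)) stop("pixel_size not given and not an attribute")
  chips <- lapply(measurements, function(m) {
    sample_chip(image, pixel_size, m$base_point, m$axis,
                u_range = c(-5, chip_nm[2]),
                t_range = c(-chip_nm[1], chip_nm[1]))
  })
  arr <- simplify2array(chips)
  if (length(dim(arr)) == 2) arr <- array(arr, dim = c(dim(arr), 1))
  avg <- apply(arr, c(1, 2), mean, na.rm = TRUE)
  cnt <- apply(arr, c(1, 2), function(v) sum(!is.na(v)))
  avg[cnt == 0] <- NA
  structure(list(average = avg, count = cnt, n = length(chips),
                 t = attr(chips[[1]], "t"), u = attr(chips[[1]], "u")),
            class = "particle_average")
}
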