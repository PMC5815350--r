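# Reference receptor dimensions from atomic models: simulate a density
# map from atom positions, low-pass to the tomographic resolution, project
# at even angular spacing about the longest principal axis, and measure
# length/width per projection. Used to gate particle measurements against
# what a receptor extracellular domain should look like at that
# resolution.

#' Resolve an atomic model into nm coordinates
#'
#' Accepts a bio3d `pdb` object, a path to a PDB/mmCIF file, or a plain
#' n x 3 coordinate matrix (already in nm). Optionally restricts to chains
#' and/or a residue range — in practice the receptor's extracellular
#' domain, since the transmembrane region is buried in the membrane and
#' invisible in projections of membrane-attached particles.
#'
#' @param model pdb object, file path, or n x 3 matrix (nm).
#' @param chains optional character vector of chain IDs.
#' @param resno_range optional length-2 residue number range.
#' @return n x 3 matrix of atom coordinates in nm.
#' @export
model_atoms <- function(model, chains = NULL, resno_range = NULL) {
  if (is.matrix(model)) {
    if (ncol(model) != 3) stop("coordinate matrix must be n x 3")
    return(model)
  }
  if (is.character(model)) {
    if (!file.exists(model)) stop("model file not found: ", model)
    model <- bio3d::read.pdb(model)
  }
  if (!inherits(model, "pdb")) stop("cannot interpret model input")
  sel <- rep(TRUE, nrow(model$atom))
  if (!is.null(chains)) sel <- sel & model$atom$chain %in% chains
  if (!is.null(resno_range))
    sel <- sel & model$atom$resno >= resno_range[1] &
      model$atom$resno <= resno_range[2]
  if (!any(sel)) stop("atom selection is empty")
  as.matrix(model$atom[sel, c("x", "y", "z")]) / 10   # Angstrom -> nm
}

#' Simulate a density map from an atomic model
#'
#' Splats each atom onto the grid (trilinear, unit mass per atom) and
#' Gaussian low-pass filters to the target resolution, so each atom
#' becomes a Gaussian whose width is set by the resolution. The integrated
#' density equals the atom count exactly (the filter preserves the DC
#' component).
#'
#' @param model anything [model_atoms()] accepts.
#' @param resolution nm (default 2.7, i.e. 27 Angstrom).
#' @param pixel_size nm (default `resolution / 3`).
#' @param margin nm of padding around the model (default `2 * resolution`).
#' @param chains,resno_range forwarded to [model_atoms()].
#' @return a [tomogram()].
#' @export
model_to_density <- function(model, resolution = 2.7, pixel_size = NULL,
                             margin = NULL, chains = NULL,
                             resno_range = NULL) {
  xyz <- model_atoms(model, chains, resno_range)
  if (is.null(pixel_size)) pixel_size <- resolution / 3
  if (is.null(margin)) margin <- 2 * resolution
  lo <- apply(xyz, 2, min) - margin
  hi <- apply(xyz, 2, max) + margin
  dims <- pmax(ceiling((hi - lo) / pixel_size) + 1, 8)
  vol <- array(0, dim = dims)
  p <- sweep(xyz, 2, lo) / pixel_size + 1   # continuous 1-based index
  p0 <- floor(p); f <- p - p0
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    w <- (if (dx) f[, 1] else 1 - f[, 1]) *
         (if (dy) f[, 2] else 1 - f[, 2]) *
         (if (dz) f[, 3] else 1 - f[, 3])
    ii <- cbind(p0[, 1] + dx, p0[, 2] + dy, p0[, 3] + dz)
    keep <- w > 0
    if (any(keep)) {
      # accumulate with possible repeated indices
      lin <- (ii[keep, 3] - 1) * dims[1] * dims[2] +
        (ii[keep, 2] - 1) * dims[1] + ii[keep, 1]
      acc <- tapply(w[keep], lin, sum)
      vol[as.integer(names(acc))] <- vol[as.integer(names(acc))] + acc
    }
  }
  vol <- lowpass_gauss(vol, pixel_size, resolution)
  tomogram(vol, pixel_size, origin = lo)
}

# intensity-weighted principal axes of a volume; columns of $vectors are
# axes sorted by decreasing spread
density_principal_axes <- function(tomo) {
  d <- dim(tomo$data)
  w <- pmax(tomo$data, 0)
  xs <- (seq_len(d[1]) - 1) * tomo$voxel_size
  ys <- (seq_len(d[2]) - 1) * tomo$voxel_size
  zs <- (seq_len(d[3]) - 1) * tomo$voxel_size
  W <- sum(w)
  mx <- sum(apply(w, 1, sum) * xs) / W
  my <- sum(apply(w, 2, sum) * ys) / W
  mz <- sum(apply(w, 3, sum) * zs) / W
  g <- expand.grid(x = xs - mx, y = ys - my, z = zs - mz)
  wv <- as.vector(w)
  C <- crossprod(sqrt(wv) * as.matrix(g)) / W
  ev <- eigen(C, symmetric = TRUE)
  list(center = c(mx, my, mz), vectors = ev$vectors, values = ev$values)
}

#' Project a density map about its longest principal axis
#'
#' Viewing directions are spaced evenly over 180 degrees, all
#' perpendicular to the longest intensity-weighted principal axis of the
#' density, so the full length of the molecule is visible in every
#' projection while the apparent width varies with angle. The default
#' 9-degree spacing yields 20 projections. Each voxel's mass is pushed
#' (bilinear scatter) into the projection plane, so every projection's sum
#' equals the volume's total density exactly.
#'
#' @param tomo a [tomogram()].
#' @param spacing degrees (0 < spacing <= 180).
#' @return list of class `"projection_set"`: `projections` (list of
#'   matrices; columns span the long axis, i.e. the long axis is the
#'   second image dimension), `angles` (degrees), `pixel_size`,
#'   `long_axis` (lab-frame unit vector).
#' @export
project_density <- function(tomo, spacing = 9) {
  stopifnot(inherits(tomo, "tomogram"))
  if (spacing <= 0 || spacing > 180) stop("spacing must be in (0, 180]")
  angles <- (seq_len(ceiling(180 / spacing)) - 1) * spacing
  pa <- density_principal_axes(tomo)
  long <- pa$vectors[, 1]
  # orthonormal frame (e1, e2, long)
  seed <- if (abs(long[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- seed - sum(seed * long) * long
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(long[2] * e1[3] - long[3] * e1[2],
          long[3] * e1[1] - long[1] * e1[3],
          long[1] * e1[2] - long[2] * e1[1])
  d <- dim(tomo$data)
  xs <- (seq_len(d[1]) - 1) * tomo$voxel_size - pa$center[1]
  ys <- (seq_len(d[2]) - 1) * tomo$voxel_size - pa$center[2]
  zs <- (seq_len(d[3]) - 1) * tomo$voxel_size - pa$center[3]
  g <- as.matrix(expand.grid(x = xs, y = ys, z = zs))
  wv <- as.vector(tomo$data)
  u_long <- g %*% long                      # coordinate along long axis
  u1 <- g %*% e1; u2 <- g %*% e2
  rmax <- max(sqrt(u1^2 + u2^2))
  lmax <- max(abs(u_long))
  px <- tomo$voxel_size
  nw <- 2 * ceiling(rmax / px) + 3
  nl <- 2 * ceiling(lmax / px) + 3
  projections <- lapply(angles, function(a) {
    th <- a * pi / 180
    # viewing direction cos(th) e1 + sin(th) e2; image width axis is the
    # in-plane perpendicular
    tcoord <- -sin(th) * u1 + cos(th) * u2
    img <- matrix(0, nw, nl)
    ci <- tcoord / px + (nw + 1) / 2
    cj <- u_long / px + (nl + 1) / 2
    i0 <- floor(ci); j0 <- floor(cj)
    fi <- ci - i0; fj <- cj - j0
    for (di in 0:1) for (dj in 0:1) {
      wgt <- wv * (if (di) fi else 1 - fi) * (if (dj) fj else 1 - fj)
      lin <- (j0 + dj - 1) * nw + (i0 + di)
      acc <- tapply(wgt, lin, sum)
      img[as.integer(names(acc))] <- img[as.integer(names(acc))] + acc
    }
    attr(img, "pixel_size") <- px
    img
  })
  structure(list(projections = projections, angles = angles,
                 pixel_size = px, long_axis = long),
            class = "projection_set")
}

#' Measure length and width of a projection
#'
#' Thresholds the projection at `level` of its maximum and measures the
#' extent of the above-level region along the intensity-weighted principal
#' axis (length) and perpendicular to it (width). The default level of
#' 0.1 captures the molecular envelope including its low-density halo; the
#' same operator at 0.5 gives FWHM-style dimensions. Length >= width by
#' convention.
#'
#' @param projection matrix with attribute `pixel_size`, from
#'   [project_density()].
#' @param level fraction of the maximum (default 0.1).
#' @param pixel_size nm, overrides the attribute.
#' @return c(length, width) in nm.
#' @export
measure_projection <- function(projection, level = 0.1, pixel_size = NULL) {
  if (is.null(pixel_size)) pixel_size <- attr(projection, "pixel_size")
  if (is.null(pixel_size)) stop("pixel_size not given and not an attribute")
  mx <- max(projection)
  if (mx <= 0) stop("projection has no positive density")
  mask <- projection >= level * mx
  if (!any(mask)) stop("no pixels above the measurement level")
  idx <- which(mask, arr.ind = TRUE)
  w <- projection[mask]
  xy <- (idx - 1) * pixel_size
  mu <- colSums(xy * w) / sum(w)
  q <- sweep(xy, 2, mu)
  C <- crossprod(sqrt(w) * q) / sum(w)
  ev <- eigen(C, symmetric = TRUE)
  proj1 <- q %*% ev$vectors[, 1]
  proj2 <- q %*% ev$vectors[, 2]
  len <- diff(range(proj1)) + pixel_size
  wid <- diff(range(proj2)) + pixel_size
  c(length = max(len, wid), width = min(len, wid))
}

#' Reference dimensions of a receptor model
#'
#' Full pipeline: atomic model to simulated density at the target
#' resolution, evenly spaced projections about the longest axis, and
#' per-projection length/width measurement, summarized as mean +/- SD.
#'
#' @param model anything [model_atoms()] accepts.
#' @param resolution nm (default 2.7).
#' @param spacing degrees (default 9, giving 20 projections).
#' @param level measurement level (default 0.1).
#' @param chains,resno_range atom selection.
#' @param pixel_size nm; default `resolution / 3`.
#' @return list of class `"ref_dimensions"`: `per_projection` (data frame
#'   angle/length/width), `length_mean`, `length_sd`, `width_mean`,
#'   `width_sd`, `n_projections`, and the configuration used.
#' @export
reference_dimensions <- function(model, resolution = 2.7, spacing = 9,
                                 level = 0.1, chains = NULL,
                                 resno_range = NULL, pixel_size = NULL) {
  vol <- model_to_density(model, resolution = resolution,
                          pixel_size = pixel_size,
                          chains = chains, resno_range = resno_range)
  ps <- project_density(vol, spacing = spacing)
  dims <- t(vapply(ps$projections, measure_projection, numeric(2),
                   level = level))
  per <- data.frame(angle = ps$angles, length = dims[, 1],
                    width = dims[, 2])
  structure(list(per_projection = per,
                 length_mean = mean(per$length),
                 length_sd = stats::sd(per$length),
                 width_mean = mean(per$width),
                 width_sd = stats::sd(per$width),
                 n_projections = nrow(per),
                 resolution = resolution, spacing = spacing,
                 level = level),
            class = "ref_dimensions")
}

#' @export
print.ref_dimensions <- function(x, ...) {
  cat(sprintf(
    "reference dimensions (%d projections, %g nm resolution, level %.2f):\n",
    x$n_projections, x$resolution, x$level))
  cat(sprintf("  length %.2f +/- %.2f nm, width %.2f +/- %.2f nm\n",
              x$length_mean, x$length_sd, x$width_mean, x$width_sd))
  invisible(x)
}

#' Generate a synthetic ellipsoidal pseudo-model
#'
#' Random pseudo-atoms filling an ellipsoid of known semi-axes: a stand-in
#' atomic model with known ground-truth extents for validating the
#' density-projection-measurement pipeline when no crystal structure is at
#' hand. Not a real molecule.
#'
#' @param semi_axes length-3 nm.
#' @param n_atoms number of pseudo-atoms.
#' @param seed integer.
#' @return n x 3 matrix of nm coordinates (usable as `model`).
#' @export
make_pseudo_model <- function(semi_axes = c(3, 3, 6), n_atoms = 2000,
                              seed = 1L) {
  with_seed(seed, {
    out <- matrix(NA_real_, 0, 3)
    while (nrow(out) < n_atoms) {
      cand <- matrix(stats::runif(3 * n_atoms, -1, 1), ncol = 3)
      keep <- rowSums(cand^2) <= 1
      out <- rbind(out, cand[keep, , drop = FALSE])
    }
    sweep(out[seq_len(n_atoms), ], 2, semi_axes, "*")
  })
}
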