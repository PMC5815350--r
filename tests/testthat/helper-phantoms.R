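# Shared fixtures: all synthetic inputs are generated in code.

# straight membrane trace along y at the phantom's membrane plane, with
# the postsynaptic side toward +x
phantom_trace <- function(spec) {
  ylen <- (spec$volume_shape[2] - 1) * spec$voxel_size
  membrane_trace(cbind(c(spec$membrane_x, spec$membrane_x), c(0, ylen)),
                 postsynaptic_side = "right")
}

# full phantom -> slab -> profile -> metrics pipeline for one spec
phantom_metrics <- function(spec, normalize = TRUE) {
  ph <- make_synapse_phantom(spec)
  zc <- (dim(ph$tomogram)[3] / 2) * spec$voxel_size
  img <- project_slab(ph$tomogram, z_center = zc, thickness = 10)
  prof <- extract_profile(img, phantom_trace(spec))
  psd_metrics(prof)
}

# raw noiseless profile of a phantom on a pixel-aligned grid
phantom_raw_profile <- function(spec) {
  ph <- make_synapse_phantom(spec)
  zc <- (dim(ph$tomogram)[3] / 2) * spec$voxel_size
  img <- project_slab(ph$tomogram, z_center = zc, thickness = 10)
  vx <- spec$voxel_size
  extract_profile(img, phantom_trace(spec),
                  d_min = -vx * round(40 / vx), d_max = vx * round(200 / vx))
}

# rotation matrix about z by theta (radians), for 3D point sets
rot_z <- function(theta) {
  matrix(c(cos(theta), sin(theta), 0,
           -sin(theta), cos(theta), 0,
           0, 0, 1), 3, 3)
}

rot_2d <- function(theta) {
  matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
}

# brute-force permutation-enumeration oracle for the two-sample KS test:
# exact P(D >= observed) over all label assignments
ks_enumeration_oracle <- function(x, y) {
  n <- length(x); m <- length(y)
  pooled <- c(x, y)
  grid <- sort(unique(pooled))
  ks_d <- function(a, b) {
    max(abs(stats::ecdf(a)(grid) - stats::ecdf(b)(grid)))
  }
  d_obs <- ks_d(x, y)
  combs <- utils::combn(n + m, n)
  ds <- apply(combs, 2, function(ix) ks_d(pooled[ix], pooled[-ix]))
  mean(ds >= d_obs - 1e-12)
}
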