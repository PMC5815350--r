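#' Tomogram container
#'
#' A light wrapper around a numeric 3D array holding a density volume with
#' its voxel size in nanometres. The axis convention follows tomographic
#' reconstruction practice: the first array dimension is x, the second y
#' (the tilt axis), the third z (the electron-beam axis). Densities are
#' stored "protein-positive": a larger value means more mass. Raw cryo-EM
#' volumes use the opposite contrast; see `invert` in [read_mrc()].
#'
#' @param data numeric 3D array (x, y, z).
#' @param voxel_size voxel edge length in nm (isotropic), > 0.
#' @param origin physical coordinate (nm) of the centre of voxel
#'   `[1, 1, 1]`; defaults to `c(0, 0, 0)`.
#' @return An object of class `"tomogram"`.
#' @export
tomogram <- function(data, voxel_size, origin = c(0, 0, 0)) {
  stopifnot(is.array(data), length(dim(data)) == 3L)
  if (!is.numeric(voxel_size) || length(voxel_size) != 1L || voxel_size <= 0)
    stop("voxel_size must be a single positive number (nm)")
  structure(
    list(data = data, voxel_size = voxel_size, origin = as.numeric(origin)),
    class = "tomogram"
  )
}

#' @export
print.tomogram <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "tomogram: %d x %d x %d voxels @ %.4g nm/voxel (%.3g x %.3g x %.3g nm)\n",
    d[1], d[2], d[3], x$voxel_size,
    d[1] * x$voxel_size, d[2] * x$voxel_size, d[3] * x$voxel_size))
  cat(sprintf("  density range [%.4g, %.4g], mean %.4g\n",
              min(x$data), max(x$data), mean(x$data)))
  invisible(x)
}

#' @export
dim.tomogram <- function(x) dim(x$data)

# voxel index (1-based) of a physical coordinate in nm, unclamped
voxel_index <- function(tomo, coord_nm) {
  (coord_nm - tomo$origin) / tomo$voxel_size + 1
}

# physical nm coordinate of a 1-based voxel index
voxel_coord <- function(tomo, index) {
  (index - 1) * tomo$voxel_size + tomo$origin
}
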