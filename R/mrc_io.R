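#' Read an MRC2014 volume
#'
#' Minimal reader for the MRC2014 format as written by tomographic
#' reconstruction software: the 1024-byte header is parsed for dimensions,
#' mode, pixel size and the extended-header length; the data block is read
#' as a 3D array. Modes 0 (int8), 1 (int16), 2 (float32) and 6 (uint16)
#' are supported, which covers cryo-ET practice.
#'
#' @param path file path.
#' @param invert logical; if `TRUE` the density sign is flipped so that
#'   protein is positive. Raw cryo-EM reconstructions conventionally store
#'   protein as low (dark) values; all analysis in this package assumes
#'   protein-positive contrast.
#' @return A [tomogram()]. Voxel size (nm) is taken from the cell dimensions
#'   divided by the grid size (MRC stores Angstrom; converted to nm). A
#'   zero cell falls back to 1 nm with a warning.
#' @export
read_mrc <- function(path, invert = FALSE) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr_int <- readBin(con, "integer", n = 10L, size = 4L, endian = "little")
  nx <- hdr_int[1]; ny <- hdr_int[2]; nz <- hdr_int[3]; mode <- hdr_int[4]
  # words 11-13: cell dimensions in Angstrom
  seek(con, 40L)
  cella <- readBin(con, "numeric", n = 3L, size = 4L, endian = "little")
  seek(con, 92L)
  nsymbt <- readBin(con, "integer", n = 1L, size = 4L, endian = "little")
  seek(con, 1024L + nsymbt)
  n <- as.double(nx) * ny * nz
  vals <- switch(as.character(mode),
    "0" = readBin(con, "integer", n = n, size = 1L, signed = TRUE,
                  endian = "little"),
    "1" = readBin(con, "integer", n = n, size = 2L, signed = TRUE,
                  endian = "little"),
    "2" = readBin(con, "numeric", n = n, size = 4L, endian = "little"),
    "6" = readBin(con, "integer", n = n, size = 2L, signed = FALSE,
                  endian = "little"),
    stop("unsupported MRC mode: ", mode))
  if (length(vals) != n) stop("truncated MRC data block in ", path)
  if (cella[1] > 0) {
    voxel_nm <- cella[1] / nx / 10   # Angstrom -> nm
  } else {
    warning("MRC cell dimension is zero; assuming 1 nm voxels")
    voxel_nm <- 1
  }
  v <- array(as.double(vals), dim = c(nx, ny, nz))
  if (invert) v <- -v
  tomogram(v, voxel_size = voxel_nm)
}

#' Write a tomogram as MRC2014 (mode 2, float32)
#'
#' @param tomo a [tomogram()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_mrc <- function(tomo, path) {
  stopifnot(inherits(tomo, "tomogram"))
  d <- dim(tomo$data)
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4L, endian = "little")
  wf <- function(x) writeBin(as.double(x), con, size = 4L, endian = "little")
  wi(d)                      # nx ny nz
  wi(2L)                     # mode 2 = float32
  wi(c(0L, 0L, 0L))          # nxstart
  wi(d)                      # mx my mz
  wf(d * tomo$voxel_size * 10)  # cell (Angstrom)
  wf(c(90, 90, 90))          # cell angles
  wi(c(1L, 2L, 3L))          # axis mapping
  wf(c(min(tomo$data), max(tomo$data), mean(tomo$data)))
  wi(c(0L, 0L))              # ispg, nsymbt
  writeBin(raw(100L), con)   # extra
  wf(c(0, 0, 0))             # origin
  writeChar("MAP ", con, nchars = 4L, eos = NULL)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # little-endian stamp
  wf(stats::sd(as.vector(tomo$data)))
  wi(0L)                     # nlabl
  writeBin(raw(800L), con)   # labels
  wf(as.vector(tomo$data))
  invisible(path)
}
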