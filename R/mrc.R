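# MRC2014 volume/stack I/O (mode 2, 32-bit float, little-endian).
# x is the fastest axis (mapc/mapr/maps = 1/2/3), matching the package's
# array layout where the first index is x.

#' Write a volume or image stack as an MRC2014 file
#'
#' @param vol A [density_volume()], or a 3D array (then `voxel_size` is
#'   required), or a 2D image.
#' @param path Output path.
#' @param voxel_size Voxel size in Angstrom when `vol` is a bare array.
#' @return `path`, invisibly.
#' @export
write_mrc <- function(vol, path, voxel_size = NULL) {
  if (inherits(vol, "density_volume")) {
    data <- vol$data; vs <- vol$voxel_size
  } else {
    data <- vol; vs <- voxel_size
    if (is.null(vs)) stop("voxel_size required for a bare array")
  }
  if (length(dim(data)) == 2) data <- array(data, c(dim(data), 1))
  dm <- dim(data)
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wi(dm)                       # nx ny nz
  wi(2)                        # mode 2 = float32
  wi(c(0, 0, 0))               # nxstart nystart nzstart
  wi(dm)                       # mx my mz
  wf(dm * vs)                  # cella
  wf(c(90, 90, 90))            # cellb
  wi(c(1, 2, 3))               # mapc mapr maps
  wf(c(min(data), max(data), mean(data)))  # dmin dmax dmean
  wi(1)                        # ispg
  wi(0)                        # nsymbt
  writeBin(raw(100), con)      # extra (words 25-49)
  wf(c(0, 0, 0))               # origin
  writeChar("MAP ", con, nchars = 4, eos = NULL)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # little-endian stamp
  wf(stats::sd(data))          # rms
  wi(0)                        # nlabl
  writeBin(raw(800), con)      # labels
  writeBin(as.numeric(data), con, size = 4, endian = "little")
  invisible(path)
}

#' Read an MRC2014 file
#'
#' Supports mode 2 (float32) and mode 1 (int16). Voxel size is recovered from
#' the cell dimensions. A truncated or corrupt file raises an error rather
#' than returning a partial volume.
#'
#' @param path Path to an MRC file.
#' @return A [density_volume()].
#' @export
read_mrc <- function(path) {
  sz <- file.info(path)$size
  if (is.na(sz) || sz < 1024) stop("not an MRC file (shorter than the 1024-byte header): ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  ri <- function(n) readBin(con, "integer", n, size = 4, endian = "little")
  rf <- function(n) readBin(con, "numeric", n, size = 4, endian = "little")
  dm <- ri(3)
  mode <- ri(1)
  ri(3)                        # nxstart..
  mx <- ri(3)
  cella <- rf(3)
  rf(3); ri(3); rf(3)          # cellb, map axes, dmin/dmax/dmean
  ri(2)                        # ispg, nsymbt
  seek(con, 208)
  map_id <- readBin(con, "raw", 4)
  if (!identical(map_id[1:3], charToRaw("MAP")))
    stop("corrupt MRC header: missing MAP stamp at byte offset 208 in ", path)
  if (any(dm <= 0)) stop("corrupt MRC header: non-positive dimensions")
  if (!mode %in% c(1, 2)) stop("unsupported MRC mode ", mode, " (only 1 and 2)")
  bytes_per <- if (mode == 2) 4 else 2
  need <- 1024 + prod(dm) * bytes_per
  if (sz < need)
    stop(sprintf("truncated MRC file %s: %d bytes, need %d", path, sz, need))
  seek(con, 1024)
  data <- if (mode == 2) {
    readBin(con, "numeric", prod(dm), size = 4, endian = "little")
  } else {
    as.numeric(readBin(con, "integer", prod(dm), size = 2, endian = "little"))
  }
  vs <- if (mx[1] > 0) cella[1] / mx[1] else 1
  density_volume(array(data, dm), voxel_size = vs)
}
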