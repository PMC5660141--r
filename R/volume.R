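#' 3D density volume
#'
#' A voxel grid with a physical voxel size in Angstrom and a centre-origin
#' convention: the physical point (0,0,0) sits at the grid centre voxel
#' `(dim + 1) / 2` (fractional for even dimensions), with z along the
#' myofibril axis and the Z-disk central plane at z = 0.
#'
#' @param data 3D numeric array.
#' @param voxel_size Voxel edge in Angstrom (> 0).
#' @return An object of class `density_volume`.
#' @export
density_volume <- function(data, voxel_size) {
  if (voxel_size <= 0) stop("voxel_size must be positive")
  if (length(dim(data)) != 3) stop("data must be a 3D array")
  structure(list(data = data, voxel_size = voxel_size), class = "density_volume")
}

#' @export
print.density_volume <- function(x, ...) {
  dm <- dim(x$data)
  cat(sprintf("density_volume: %d x %d x %d voxels, %.3f A/voxel (%.1f x %.1f x %.1f nm)\n",
              dm[1], dm[2], dm[3], x$voxel_size,
              dm[1] * x$voxel_size / 10, dm[2] * x$voxel_size / 10, dm[3] * x$voxel_size / 10))
  cat(sprintf("  mean %.4g, sd %.4g, range [%.4g, %.4g]\n",
              mean(x$data), stats::sd(x$data), min(x$data), max(x$data)))
  invisible(x)
}

vol_center <- function(vol) (dim(vol$data) + 1) / 2

# Physical (Angstrom, centre-origin) -> fractional voxel coordinates (1-based)
phys_to_voxel <- function(vol, pts) {
  sweep(pts / vol$voxel_size, 2, vol_center(vol), `+`)
}

#' Synthesize a density volume from a point model
#'
#' Each atom (or pseudo-atom) contributes an isotropic Gaussian whose width
#' is tied to the requested resolution as `sigma = resolution / (2 * pi *
#' sqrt(2))`, the low-pass-equivalent width, so the map is band-limited to the
#' stated resolution. Atoms are deposited by trilinear (cloud-in-cell)
#' splatting and the Gaussian is applied in Fourier space, which makes the
#' operation exactly linear in the model and mass-conserving: the integrated
#' density is proportional to the (weighted) atom count.
#'
#' @param model An `atomic_model` (coordinates in Angstrom) or a
#'   `zdisk_lattice_model` (converted via [zdisk_atoms()]).
#' @param voxel_size Voxel edge in Angstrom; must satisfy
#'   `voxel_size <= resolution / 2` (sampling).
#' @param resolution Target resolution in Angstrom.
#' @param dim Output grid dimensions (length 3). Default 64^3.
#' @param center Physical centre of the grid in Angstrom (length 3).
#' @param weights Optional per-atom weights.
#' @return A [density_volume()].
#' @export
synthesize_density <- function(model, voxel_size, resolution, dim = c(64, 64, 64),
                               center = c(0, 0, 0), weights = NULL) {
  if (voxel_size > resolution / 2)
    stop("voxel_size must be <= resolution/2 to sample the requested resolution")
  if (inherits(model, "zdisk_lattice_model")) {
    need_nm <- (max(dim[1:2]) * voxel_size / 2 + max(abs(center[1:2]))) / 10 + 6
    model <- zdisk_atoms(model, xy_range = need_nm)
  }
  pts <- coords_matrix(model)
  w <- weights %||% model$weight %||% rep(1, nrow(pts))
  g <- array(0, dim)
  vol <- density_volume(g, voxel_size)
  vx <- phys_to_voxel(vol, sweep(pts, 2, center))
  vol$data <- splat_cic(dim, vx, w)
  sigma <- resolution / (2 * pi * sqrt(2))
  vol$data <- gaussian_kernel_filter(vol$data, sigma / voxel_size)
  vol
}

# Cloud-in-cell deposition of weighted points (fractional 1-based voxel coords).
splat_cic <- function(dm, vx, w) {
  out <- numeric(prod(dm))
  x0 <- floor(vx[, 1]); y0 <- floor(vx[, 2]); z0 <- floor(vx[, 3])
  fx <- vx[, 1] - x0; fy <- vx[, 2] - y0; fz <- vx[, 3] - z0
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    i <- x0 + dx; j <- y0 + dy; k <- z0 + dz
    ww <- w * (if (dx) fx else 1 - fx) * (if (dy) fy else 1 - fy) * (if (dz) fz else 1 - fz)
    ok <- i >= 1 & j >= 1 & k >= 1 & i <= dm[1] & j <= dm[2] & k <= dm[3] & ww > 0
    if (!any(ok)) next
    idx <- i[ok] + (j[ok] - 1) * dm[1] + (k[ok] - 1) * dm[1] * dm[2]
    s <- rowsum(ww[ok], idx)
    ii <- as.integer(rownames(s))
    out[ii] <- out[ii] + s[, 1]
  }
  array(out, dm)
}

# Isotropic real-space-sigma Gaussian filter (sigma in voxels), via FFT.
gaussian_kernel_filter <- function(x, sigma_vox) {
  if (sigma_vox <= 0) return(x)
  q2 <- freq_sq_grid(dim(x))
  h <- exp(-2 * pi^2 * sigma_vox^2 * q2)
  Re(fft(fft(x) * h, inverse = TRUE)) / prod(dim(x))
}

#' Resample a volume under a rigid rotation about its centre
#'
#' Output voxel x takes the value of the input at `R^-1 (x - c) + c` (plus an
#' optional shift in voxels), by trilinear interpolation.
#'
#' @param vol A `density_volume`.
#' @param R 3x3 rotation matrix (the map applied to the object).
#' @param shift Translation applied to the object, in voxels.
#' @return A `density_volume` on the same grid.
#' @export
rotate_volume <- function(vol, R, shift = c(0, 0, 0)) {
  dm <- dim(vol$data)
  ctr <- vol_center(vol)
  g <- as.matrix(expand.grid(x = seq_len(dm[1]), y = seq_len(dm[2]), z = seq_len(dm[3])))
  rel <- sweep(g, 2, ctr)
  rel <- sweep(rel, 2, shift)
  src <- rel %*% R          # (R^-1 %*% rel)^T = rel %*% R for orthonormal R
  src <- sweep(src, 2, ctr, `+`)
  out <- vol
  out$data <- array(trilinear(vol$data, src), dm)
  out
}
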