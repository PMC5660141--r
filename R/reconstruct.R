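# Block-average binning of a 2D image by an integer factor.
bin_image <- function(img, f) {
  if (f == 1) return(img)
  dm <- dim(img) %/% f * f
  img <- img[seq_len(dm[1]), seq_len(dm[2])]
  out <- matrix(0, dm[1] / f, dm[2] / f)
  for (i in 0:(f - 1)) for (j in 0:(f - 1))
    out <- out + img[seq(1 + i, dm[1], by = f), seq(1 + j, dm[2], by = f)]
  out / f^2
}

# r-weighting (ramp) filter perpendicular to the tilt axis, with a Hann
# rolloff at Nyquist.
ramp_filter_image <- function(img, tilt_azimuth) {
  dm <- dim(img)
  fx <- fft_freq(dm[1]); fy <- fft_freq(dm[2])
  u <- c(cos(tilt_azimuth * pi / 180), sin(tilt_azimuth * pi / 180))
  # frequency component perpendicular to the tilt axis
  qperp <- outer(fx * (-u[2]), fy * u[1], `+`)
  qabs <- sqrt(outer(fx^2, fy^2, `+`))
  w <- abs(qperp) * 0.5 * (1 + cos(pi * pmin(qabs / 0.5, 1)))
  Re(fft(fft(img) * w, inverse = TRUE)) / prod(dm)
}

#' Weighted back-projection reconstruction
#'
#' r-weighted (ramp-filtered, Hann rolloff at Nyquist) back-projection of an
#' aligned single-axis tilt series. Images may be binned by an integer
#' factor first; the output voxel size is `pixel_size * binning`.
#'
#' @param series A [tilt_series()] (aligned; per-image distortions are
#'   inverted using the recorded geometry).
#' @param geometries Optional list of corrected [tilt_geometry()] (default:
#'   the series' own).
#' @param out_size Output dimensions (length 3); default: binned in-plane
#'   dimensions with z equal to the smaller in-plane extent.
#' @param binning Integer binning factor (>= 1).
#' @param include Optional logical/integer subset of images to use.
#' @return A [density_volume()].
#' @export
weighted_back_projection <- function(series, geometries = NULL, out_size = NULL,
                                     binning = 1, include = NULL) {
  if (binning < 1 || binning != round(binning)) stop("binning must be a positive integer")
  geometries <- geometries %||% series$geometries
  n <- dim(series$images)[3]
  if (n == 0) stop("empty tilt series")
  idx <- seq_len(n)
  if (!is.null(include)) idx <- idx[include]
  if (length(idx) == 0) stop("empty tilt series after selection")
  vs <- series$pixel_size * binning
  dmi <- dim(bin_image(series$images[, , 1], binning))
  out_size <- out_size %||% c(dmi, min(dmi))
  acc <- array(0, out_size)
  ctr <- (out_size + 1) / 2
  g2 <- as.matrix(expand.grid(x = seq_len(out_size[1]), y = seq_len(out_size[2]),
                              z = seq_len(out_size[3])))
  rel <- sweep(g2, 2, ctr)
  for (i in idx) {
    geo <- geometries[[i]]
    img <- series$images[, , i]
    # undo the recorded image-frame transform (shift/rotation/distortion)
    A <- geo$distortion %*% rot_axis("z", geo$in_plane_rotation)[1:2, 1:2]
    if (max(abs(A - diag(2))) > 1e-12 || any(geo$shift != 0)) {
      cimg <- (dim(img) + 1) / 2
      gg <- as.matrix(expand.grid(x = seq_len(dim(img)[1]), y = seq_len(dim(img)[2])))
      src <- sweep(gg, 2, cimg + geo$shift) %*% t(solve(A))
      src <- sweep(src, 2, cimg, `+`)
      img <- matrix(bilinear(img, src), dim(img)[1], dim(img)[2])
    }
    img <- bin_image(img, binning)
    img <- ramp_filter_image(img, geo$tilt_azimuth)
    u <- c(cos(geo$tilt_azimuth * pi / 180), sin(geo$tilt_azimuth * pi / 180), 0)
    R <- rot_about(u, geo$tilt_angle)
    lab <- rel %*% t(R)                        # specimen -> lab
    pts <- cbind(lab[, 1] + (dmi[1] + 1) / 2, lab[, 2] + (dmi[2] + 1) / 2)
    acc <- acc + array(bilinear(img, pts), out_size)
  }
  acc <- acc * pi / (2 * length(idx))
  density_volume(acc, vs)
}

#' Reciprocal-space coverage of a tilt geometry set
#'
#' Builds the binary mask of central slices (each thickened by one voxel)
#' contributed by the given tilt geometries, optionally replicated under a
#' list of rotation operators (as applied to the object by symmetry
#' expansion). The missing region inside the Nyquist sphere is classified as
#' a wedge (reaching the equatorial plane), a cone (confined about the kz
#' axis), or absent (`full`).
#'
#' @param geometries List of [tilt_geometry()].
#' @param dim Mask dimensions (default 33^3; odd is natural for a centred
#'   mask).
#' @param rotations Optional list of 3x3 rotation matrices (e.g. from a
#'   [symmetry_group()]) replicating the coverage.
#' @return An object of class `fourier_coverage`: centred logical `mask`,
#'   `kind` ("wedge", "cone" or "full"), `tilt_range`, and the covered
#'   fraction of the Nyquist sphere.
#' @export
fourier_coverage <- function(geometries, dim = c(33, 33, 33), rotations = NULL) {
  rotations <- rotations %||% list(diag(3))
  ctr <- (dim + 1) / 2
  kx <- seq_len(dim[1]) - ctr[1]
  ky <- seq_len(dim[2]) - ctr[2]
  kz <- seq_len(dim[3]) - ctr[3]
  g <- as.matrix(expand.grid(kx = kx, ky = ky, kz = kz))
  mask <- rep(FALSE, nrow(g))
  for (Rg in rotations) for (geo in geometries) {
    u <- c(cos(geo$tilt_azimuth * pi / 180), sin(geo$tilt_azimuth * pi / 180), 0)
    R <- rot_about(u, geo$tilt_angle)
    nrm <- Rg %*% R %*% c(0, 0, 1)             # beam direction for this copy
    mask <- mask | abs(g %*% nrm) <= 1
  }
  rad <- sqrt(rowSums(g^2))
  nyq <- min(dim) / 2 - 1
  inside <- rad <= nyq & rad > 0
  missing <- inside & !mask
  kind <- if (!any(missing)) "full" else {
    polar <- acos(pmin(1, abs(g[missing, 3]) / rad[missing])) * 180 / pi
    if (max(polar) < 60) "cone" else "wedge"
  }
  ang <- vapply(geometries, `[[`, numeric(1), "tilt_angle")
  structure(list(mask = array(mask, dim), kind = kind,
                 tilt_range = range(ang),
                 covered_fraction = sum(mask & inside) / sum(inside)),
            class = "fourier_coverage")
}

#' @export
print.fourier_coverage <- function(x, ...) {
  cat(sprintf("fourier_coverage: kind = %s, tilt range [%.1f, %.1f] deg, %.1f%% of sphere\n",
              x$kind, x$tilt_range[1], x$tilt_range[2], 100 * x$covered_fraction))
  invisible(x)
}
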