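#' Per-image tilt geometry
#'
#' @param tilt_angle Tilt angle in degrees (|angle| < 90).
#' @param tilt_azimuth Direction of the tilt axis in the image plane, degrees
#'   from +x (default 0: tilt axis along x).
#' @param in_plane_rotation In-plane rotation in degrees.
#' @param shift 2D shift in pixels.
#' @param distortion 2x2 distortion matrix (near-identity for valid
#'   alignments).
#' @return An object of class `tilt_geometry`.
#' @export
tilt_geometry <- function(tilt_angle, tilt_azimuth = 0, in_plane_rotation = 0,
                          shift = c(0, 0), distortion = diag(2)) {
  if (abs(tilt_angle) >= 90) stop("|tilt_angle| must be < 90")
  structure(list(tilt_angle = tilt_angle, tilt_azimuth = tilt_azimuth,
                 in_plane_rotation = in_plane_rotation, shift = shift,
                 distortion = distortion), class = "tilt_geometry")
}

#' Single-axis tilt series
#'
#' Images are stored in angle order (one 2D slice per image); the
#' acquisition (exposure) order, which governs cumulative dose, is kept as a
#' permutation alongside.
#'
#' @param images 3D array `[nx, ny, n]`, angle order.
#' @param geometries List of [tilt_geometry()], one per image.
#' @param pixel_size Pixel size in Angstrom.
#' @param dose_per_image Electron dose per image in e/A^2.
#' @param exposure_order Integer vector: `exposure_order[i]` is the exposure
#'   rank (1 = first acquired) of storage slot i.
#' @return An object of class `tilt_series`.
#' @export
tilt_series <- function(images, geometries, pixel_size, dose_per_image = 0.7,
                        exposure_order = seq_along(geometries)) {
  if (dim(images)[3] != length(geometries))
    stop("number of images and geometries differ")
  if (pixel_size <= 0) stop("pixel_size must be positive")
  structure(list(images = images, geometries = geometries,
                 pixel_size = pixel_size, dose_per_image = dose_per_image,
                 exposure_order = exposure_order), class = "tilt_series")
}

#' @export
print.tilt_series <- function(x, ...) {
  ang <- vapply(x$geometries, `[[`, numeric(1), "tilt_angle")
  cat(sprintf("tilt_series: %d images %d x %d, %.2f A/px, %.1f to %.1f deg, %.2f e/A^2 per image\n",
              length(ang), dim(x$images)[1], dim(x$images)[2], x$pixel_size,
              min(ang), max(ang), x$dose_per_image))
  invisible(x)
}

#' Saxton-scheme tilt angles
#'
#' Starting at 0 degrees, successive increments shrink with the cosine of
#' the current angle (`d_theta = step0 * cos(theta)`), equalising the
#' information per image as the specimen foreshortens; both branches are
#' generated independently from 0. The exposure order runs through the
#' positive branch first (starting at 0) and then the negative branch, so
#' cumulative dose is lowest at low positive tilts.
#'
#' @param step0 Initial step in degrees (> 0).
#' @param max_pos,max_neg Positive and negative tilt limits in degrees
#'   (given as positive numbers, each in (0, 90)).
#' @param cosine If `FALSE`, uniform stepping (an arithmetic sequence) is
#'   used instead of the cosine rule.
#' @return Data frame with `angle` (sorted ascending), `exposure` (rank in
#'   acquisition order) and `branch`.
#' @export
saxton_angles <- function(step0 = 2, max_pos = 70, max_neg = 70, cosine = TRUE) {
  if (step0 <= 0) stop("step0 must be positive")
  if (max_pos <= 0 || max_pos >= 90 || max_neg <= 0 || max_neg >= 90)
    stop("tilt limits must lie in (0, 90)")
  branch <- function(limit) {
    th <- 0; out <- 0
    repeat {
      d <- if (cosine) step0 * cos(th * pi / 180) else step0
      th <- th + d
      if (th > limit + 1e-9) break
      out <- c(out, th)
    }
    out
  }
  pos <- branch(max_pos)
  neg <- -branch(max_neg)[-1]
  ang <- c(pos, neg)
  expo <- seq_along(ang)
  ord <- order(ang)
  data.frame(angle = ang[ord], exposure = expo[ord],
             branch = ifelse(ang[ord] >= 0, "pos", "neg"))
}

#' Parallel-beam projection of a volume
#'
#' Line integral along the beam (lab z) after tilting the specimen by
#' `tilt_angle` about an in-plane axis at `tilt_azimuth`, with trilinear
#' interpolation. The integration step is one voxel, aligned with the voxel
#' planes, so at zero tilt the projection is exactly the z sum of the volume
#' (flux conservation). The geometry's distortion, in-plane rotation and
#' shift are applied to the resulting image.
#'
#' @param volume A `density_volume`.
#' @param geometry A [tilt_geometry()].
#' @return 2D image array of the volume's in-plane dimensions.
#' @export
project <- function(volume, geometry) {
  vol <- volume$data
  dm <- dim(vol)
  ctr <- (dm + 1) / 2
  u <- c(cos(geometry$tilt_azimuth * pi / 180),
         sin(geometry$tilt_azimuth * pi / 180), 0)
  R <- rot_about(u, geometry$tilt_angle)    # applied to the specimen
  pad <- ceiling((sqrt(sum(dm^2)) - dm[3]) / 2)
  ts <- seq(1 - pad, dm[3] + pad)
  g2 <- as.matrix(expand.grid(x = seq_len(dm[1]), y = seq_len(dm[2])))
  img <- numeric(nrow(g2))
  relx <- g2[, 1] - ctr[1]; rely <- g2[, 2] - ctr[2]
  for (t in ts) {
    lab <- cbind(relx, rely, t - ctr[3])
    src <- lab %*% R                         # R^T %*% lab, as rows
    src <- sweep(src, 2, ctr, `+`)
    img <- img + trilinear(vol, src)
  }
  img <- matrix(img, dm[1], dm[2])
  A <- geometry$distortion %*% rot_axis("z", geometry$in_plane_rotation)[1:2, 1:2]
  if (max(abs(A - diag(2))) > 1e-12 || any(geometry$shift != 0)) {
    # output(x) = clean(A (x - c) + c + shift): warp by the recorded transform
    img <- affine_resample2(img, A, geometry$shift)
  }
  img
}

#' Simulate a tilt series from a phantom volume
#'
#' @param volume A `density_volume`.
#' @param angles Data frame from [saxton_angles()] (or a numeric vector of
#'   angles, exposure order = given order).
#' @param tilt_azimuth Tilt-axis azimuth in degrees.
#' @param dose_per_image Dose per image in e/A^2.
#' @return A [tilt_series()] of clean (noise-free, undamaged) projections.
#' @export
simulate_tilt_series <- function(volume, angles = saxton_angles(),
                                 tilt_azimuth = 0, dose_per_image = 0.7) {
  if (is.numeric(angles)) angles <- data.frame(angle = angles,
                                               exposure = seq_along(angles))
  geoms <- lapply(angles$angle, tilt_geometry, tilt_azimuth = tilt_azimuth)
  imgs <- array(0, c(dim(volume$data)[1:2], nrow(angles)))
  for (i in seq_len(nrow(angles))) imgs[, , i] <- project(volume, geoms[[i]])
  tilt_series(imgs, geoms, volume$voxel_size, dose_per_image,
              exposure_order = angles$exposure)
}

#' Apply cumulative radiation damage and noise to a tilt series
#'
#' Image k in exposure order is attenuated with a B factor proportional to
#' the dose accumulated before it (`B_k = damage_rate * (k-1) * dose`,
#' attenuation `exp(-B q^2 / 4)` with q in 1/Angstrom), then corrupted with
#' signal-independent Gaussian noise. The noise level is set either directly
#' (`noise_sd`) or through a target signal-to-noise ratio defined as the
#' clean stack's variance over the noise variance.
#'
#' @param series A [tilt_series()].
#' @param dose Dose per image in e/A^2 (default: the series' value).
#' @param damage_rate B-factor accumulation rate in A^2 per (e/A^2).
#' @param snr Target SNR (ignored if `noise_sd` given); `Inf` for no noise.
#' @param noise_sd Gaussian noise standard deviation in image units.
#' @return The damaged [tilt_series()].
#' @export
apply_dose_and_damage <- function(series, dose = series$dose_per_image,
                                  damage_rate = 60, snr = 0.3,
                                  noise_sd = NULL) {
  if (dose <= 0) stop("dose must be positive")
  dm <- dim(series$images)[1:2]
  q2 <- freq_sq_grid(dm) / series$pixel_size^2    # (1/A)^2
  if (is.null(noise_sd)) {
    noise_sd <- if (is.infinite(snr)) 0 else stats::sd(series$images) / sqrt(snr)
  }
  out <- series
  for (i in seq_len(dim(series$images)[3])) {
    k <- series$exposure_order[i]                 # 1 = first acquired
    B <- damage_rate * (k - 1) * dose
    img <- series$images[, , i]
    if (B > 0) {
      h <- exp(-B * q2 / 4)
      img <- Re(fft(fft(img) * h, inverse = TRUE)) / prod(dm)
    }
    if (noise_sd > 0) img <- img + stats::rnorm(length(img), 0, noise_sd)
    out$images[, , i] <- img
  }
  out
}
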