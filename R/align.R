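# Global normalised cross-correlation over translations, via FFT.
# Returns the best shift (image moved by `shift` matches the reference) with
# parabolic sub-pixel refinement, and the correlation peak value.
ncc_shift <- function(image, reference) {
  dm <- dim(image)
  a <- image - mean(image); b <- reference - mean(reference)
  sa <- sqrt(sum(a^2)); sb <- sqrt(sum(b^2))
  if (sa == 0 || sb == 0) stop("flat (zero-variance) input")
  cc <- Re(fft(fft(a) * Conj(fft(b)), inverse = TRUE)) / prod(dm) / (sa * sb)
  w <- which(cc == max(cc), arr.ind = TRUE)[1, ]
  # lag: cc[i,j] corresponds to image shifted by -(i-1) matching reference?
  # cross-corr c(d) = sum_x a(x+d) b(x); peak d* => a(x+d*) ~ b(x),
  # i.e. reference(x) = image(x + d*): shift convention below.
  lag <- unname(w - 1)
  lag <- ifelse(lag > dm / 2, lag - dm, lag)
  # parabolic refinement per axis
  sub <- numeric(2)
  for (ax in 1:2) {
    im <- w[ax] - 1; ip <- w[ax] + 1
    im <- ((im - 1) %% dm[ax]) + 1; ip <- ((ip - 1) %% dm[ax]) + 1
    cm <- if (ax == 1) cc[im, w[2]] else cc[w[1], im]
    cp <- if (ax == 1) cc[ip, w[2]] else cc[w[1], ip]
    c0 <- cc[w[1], w[2]]
    den <- cm - 2 * c0 + cp
    sub[ax] <- if (den < 0) 0.5 * (cm - cp) / den else 0
  }
  list(shift = lag + sub, cc = max(cc))
}

#' Area matching of an image against a reference
#'
#' Finds the 2x2 distortion matrix and shift that best map the raw image
#' onto the reference, in the sense `reference(x) ~ image(D (x - c) + c +
#' shift)` with c the image centre. Translation is found by FFT normalised
#' cross-correlation with parabolic sub-pixel refinement; the distortion is
#' optimised over (scale_x, scale_y, skew, rotation) by Nelder-Mead from a
#' small coarse grid, each candidate scored by its best translation NCC.
#'
#' @param image,reference 2D arrays of identical dimensions.
#' @param search List of bounds: `scale` (c(lo, hi)), `skew`, `rot_deg`;
#'   set `distortion = FALSE` to fit translation only.
#' @return List with `distortion` (2x2), `shift` (length 2, pixels) and
#'   `cc_peak`.
#' @export
area_match <- function(image, reference,
                       search = list(scale = c(0.8, 1.2), skew = 0.1,
                                     rot_deg = 5, distortion = TRUE)) {
  if (!all(dim(image) == dim(reference))) stop("image and reference dimensions differ")
  if (stats::sd(image) == 0 || stats::sd(reference) == 0)
    stop("flat (zero-variance) input")
  if (isFALSE(search$distortion)) {
    s <- ncc_shift(image, reference)
    return(list(distortion = diag(2), shift = s$shift, cc_peak = s$cc))
  }
  score <- function(p) {
    A <- matrix(c(p[1], p[3] + p[4], p[3] - p[4], p[2]), 2, 2)
    warped <- affine_resample2(image, A)
    if (stats::sd(warped) == 0) return(1)
    -ncc_shift(warped, reference)$cc
  }
  lo <- c(search$scale[1], search$scale[1], -search$skew, -search$skew)
  hi <- c(search$scale[2], search$scale[2], search$skew, search$skew)
  # coarse grid on the two scales, identity skew/rotation
  grid <- expand.grid(sx = seq(lo[1], hi[1], length.out = 5),
                      sy = seq(lo[2], hi[2], length.out = 5))
  best <- c(1, 1, 0, 0); bestv <- score(best)
  for (r in seq_len(nrow(grid))) {
    p <- c(grid$sx[r], grid$sy[r], 0, 0)
    v <- score(p)
    if (v < bestv) { bestv <- v; best <- p }
  }
  opt <- stats::optim(best, score, method = "Nelder-Mead",
                      control = list(maxit = 200, reltol = 1e-6))
  p <- pmin(pmax(opt$par, lo), hi)
  A <- matrix(c(p[1], p[3] + p[4], p[3] - p[4], p[2]), 2, 2)
  s <- ncc_shift(affine_resample2(image, A), reference)
  list(distortion = A, shift = s$shift, cc_peak = s$cc)
}

# In-plane foreshortening transform of a thin specimen tilted by theta about
# an in-plane axis at azimuth phi (both degrees): compression by cos(theta)
# perpendicular to the axis.
foreshortening <- function(theta, phi) {
  Rp <- rot_axis("z", phi)[1:2, 1:2]
  Rp %*% diag(c(1, cos(theta * pi / 180))) %*% t(Rp)
}

#' Marker-free alignment of a tilt series
#'
#' Re-implements correlation alignment against reprojections: images are
#' merged outward from the 0-degree image (alternating branches); each new
#' image is aligned, by [area_match()], to the reprojection of the weighted
#' back-projection of the previously merged images. Low-tilt images are
#' never re-aligned against references derived from high-tilt images, which
#' prevents propagation of alignment errors from the damaged high-dose end
#' of the series into the low-tilt images. Images whose correlation peak
#' falls below the threshold are flagged and not merged.
#'
#' @param series A [tilt_series()].
#' @param cc_threshold Correlation peak below which an image is flagged
#'   (default 0.1).
#' @param fit_distortion Also search the 2x2 distortion (default FALSE:
#'   translation only, which is the dominant term for simulated series).
#' @param recon_z z extent (voxels) of the intermediate reconstruction.
#' @param ramp_reference Ramp-filter the intermediate back-projection used
#'   for references (default TRUE).
#' @param n_passes Number of outward merge passes (>= 1). Later passes redo
#'   the same low-to-high-tilt sweep with the previous pass's corrections in
#'   place, sharpening the intermediate references; each image is still only
#'   ever aligned against lower-tilt data.
#' @return List with `records` (data frame: image, angle, exposure, cc_peak,
#'   shift, residual, retained flag) and `geometries` (corrected list).
#' @export
align_tilt_series <- function(series, cc_threshold = 0.1,
                              fit_distortion = FALSE, recon_z = NULL,
                              n_passes = 2, ramp_reference = TRUE) {
  n <- dim(series$images)[3]
  if (n < 3) stop("need at least 3 images")
  ang <- vapply(series$geometries, `[[`, numeric(1), "tilt_angle")
  dmi <- dim(series$images)[1:2]
  recon_z <- recon_z %||% min(dmi)
  out_size <- c(dmi, recon_z)
  # merge order: 0 degrees outward, alternating branches
  ord <- order(abs(ang), sign(ang))
  geoms <- series$geometries
  records <- data.frame(image = seq_len(n), angle = ang,
                        exposure = series$exposure_order,
                        cc_peak = NA_real_, shift_x = NA_real_, shift_y = NA_real_,
                        residual = NA_real_, retained = FALSE)
  acc <- array(0, out_size)                    # running back-projection
  ctr <- (out_size + 1) / 2
  g3 <- as.matrix(expand.grid(x = seq_len(out_size[1]), y = seq_len(out_size[2]),
                              z = seq_len(out_size[3])))
  rel <- sweep(g3, 2, ctr)
  contribution <- function(i, geo) {
    img <- series$images[, , i]
    A <- geo$distortion %*% rot_axis("z", geo$in_plane_rotation)[1:2, 1:2]
    if (max(abs(A - diag(2))) > 1e-12) {
      cimg <- (dmi + 1) / 2
      gg <- as.matrix(expand.grid(x = seq_len(dmi[1]), y = seq_len(dmi[2])))
      src <- sweep(sweep(gg, 2, cimg + geo$shift) %*% t(solve(A)), 2, cimg, `+`)
      img <- matrix(bilinear(img, src), dmi[1], dmi[2])
    } else if (any(geo$shift != 0)) {
      img <- fourier_shift2(img, -geo$shift)  # clean(x) = raw(x - shift)
    }
    if (ramp_reference) img <- ramp_filter_image(img, geo$tilt_azimuth)
    u <- c(cos(geo$tilt_azimuth * pi / 180), sin(geo$tilt_azimuth * pi / 180), 0)
    R <- rot_about(u, geo$tilt_angle)
    lab <- rel %*% t(R)
    pts <- cbind(lab[, 1] + ctr[1], lab[, 2] + ctr[2])
    array(bilinear(img, pts), out_size)
  }
  first <- ord[1]
  records$cc_peak[first] <- 1
  records$shift_x[first] <- 0; records$shift_y[first] <- 0
  records$residual[first] <- 0
  records$retained[first] <- TRUE
  for (pass in seq_len(n_passes)) {
    acc[] <- 0
    acc <- acc + contribution(first, geoms[[first]])
    n_merged <- 1
    for (i in ord[-1]) {
      # from the second pass on, the reference also contains this image's own
      # previous-pass contribution (never any higher-tilt image), which
      # removes most of the partial-wedge reprojection bias
      ref_acc <- acc; ref_n <- n_merged
      if (pass > 1 && records$retained[i]) {
        ref_acc <- ref_acc + contribution(i, geoms[[i]])
        ref_n <- ref_n + 1
      }
      ref <- project(density_volume(ref_acc / ref_n, series$pixel_size),
                     tilt_geometry(ang[i], geoms[[i]]$tilt_azimuth))
      am <- area_match(series$images[, , i], ref,
                       search = list(scale = c(0.9, 1.1), skew = 0.05, rot_deg = 3,
                                     distortion = fit_distortion))
      records$cc_peak[i] <- am$cc_peak
      records$shift_x[i] <- am$shift[1]
      records$shift_y[i] <- am$shift[2]
      records$residual[i] <- norm(am$distortion - diag(2), "F") / norm(diag(2), "F")
      if (is.finite(am$cc_peak) && am$cc_peak >= cc_threshold) {
        records$retained[i] <- TRUE
        # convert the observed raw->reference transform into the stored
        # forward-warp convention raw(x) = clean(D_f (x-c) + c + s_f)
        D_f <- solve(am$distortion)
        s_f <- as.vector(-D_f %*% am$shift)
        geoms[[i]] <- tilt_geometry(ang[i], geoms[[i]]$tilt_azimuth,
                                    in_plane_rotation = geoms[[i]]$in_plane_rotation,
                                    shift = s_f, distortion = D_f)
        acc <- acc + contribution(i, geoms[[i]])
        n_merged <- n_merged + 1
      } else {
        records$retained[i] <- FALSE
      }
    }
  }
  list(records = records, geometries = geoms)
}

#' Least-squares refinement of the global tilt geometry
#'
#' Fits a global tilt-axis azimuth correction and a per-series tilt-angle
#' offset by minimising the discrepancy between observed per-image
#' distortion matrices and the foreshortening predicted by cos(tilt) about
#' the axis: the predicted distortion of image i is
#' `F(theta_i + d_theta, phi0 + d_phi) %*% solve(F(theta_i, phi0))`.
#' Per-image residuals are reported as a fraction of the ideal
#' (identity-normalised Frobenius norm).
#'
#' @param records Data frame with `angle` and the observed distortions as a
#'   list column `distortion`, or a list of [area_match()] results plus
#'   `angles`.
#' @param distortions List of observed 2x2 matrices (one per record row) if
#'   not carried as a list column.
#' @param nominal_azimuth Nominal tilt-axis azimuth (deg).
#' @return List with `azimuth_correction` and `tilt_offset` (deg),
#'   `azimuth`, and per-image `residuals`.
#' @export
refine_geometry <- function(records, distortions = records$distortion,
                            nominal_azimuth = 0) {
  ang <- records$angle
  if (length(ang) < 5) stop("need at least 5 usable records")
  if (is.null(distortions)) stop("observed distortion matrices required")
  pred <- function(p, th) {
    foreshortening(th + p[2], nominal_azimuth + p[1]) %*%
      solve(foreshortening(th, nominal_azimuth))
  }
  obj <- function(p) {
    sum(vapply(seq_along(ang), function(i)
      norm(distortions[[i]] - pred(p, ang[i]), "F")^2, numeric(1)))
  }
  # degenerate design: an azimuth is unidentifiable from untilted images only
  if (all(abs(ang) < 1e-6)) stop("rank-deficient fit: tilt azimuth is not ",
                                 "identifiable from untilted images")
  opt <- stats::optim(c(0, 0), obj, method = "Nelder-Mead",
                      control = list(maxit = 500, reltol = 1e-10))
  p <- opt$par
  res <- vapply(seq_along(ang), function(i) {
    pr <- pred(p, ang[i])
    norm(distortions[[i]] - pr, "F") / norm(pr, "F")
  }, numeric(1))
  list(azimuth_correction = p[1], tilt_offset = p[2],
       azimuth = nominal_azimuth + p[1], residuals = res)
}

#' Truncate a damaged tilt series
#'
#' Retains the maximal exposure-order prefix whose correlation peaks stay at
#' or above the threshold: acquisition stops being useful at the first
#' sub-threshold image, and any later recovery is discarded (cumulative
#' damage makes those images untrustworthy).
#'
#' @param records Data frame with `cc_peak` and `exposure` columns (and
#'   `image` storage indices), as produced by [align_tilt_series()].
#' @param threshold Correlation threshold (default 0.1).
#' @return Integer vector of retained storage indices (`image` values),
#'   in exposure order.
#' @export
truncate_damaged <- function(records, threshold = 0.1) {
  if (nrow(records) == 0) stop("no records")
  ord <- order(records$exposure)
  cc <- records$cc_peak[ord]
  bad <- which(!(is.finite(cc) & cc >= threshold))
  keep <- if (length(bad) == 0) ord else ord[seq_len(bad[1] - 1)]
  records$image[keep]
}
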