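#' Fourier shell correlation between two maps
#'
#' Shell-wise normalised cross-correlation of the (optionally soft-masked)
#' Fourier transforms of two co-registered maps. The resolution is the
#' reciprocal of the first frequency at which the curve falls below the
#' cutoff, linearly interpolated between shells; if the curve never crosses,
#' the resolution is reported as Nyquist-limited (2 x voxel size).
#'
#' @param map1,map2 `density_volume`s on identical grids.
#' @param mask Optional real-space mask (array in `[0,1]`, same grid);
#'   soft-edged masks should be used (see [soft_spherical_mask()]).
#' @param shell_width Shell width in reciprocal voxels (default 1).
#' @param cutoff Threshold defining the resolution (default 0.143, the
#'   half-map standard).
#' @return An object of class `fsc_curve`: data frame of shell centre
#'   frequencies (1/Angstrom) and correlations, with `resolution` (Angstrom)
#'   and `crossed` attributes.
#' @export
fsc <- function(map1, map2, mask = NULL, shell_width = 1, cutoff = 0.143) {
  if (!identical(dim(map1$data), dim(map2$data)))
    stop("maps must share grid dimensions")
  if (abs(map1$voxel_size - map2$voxel_size) > 1e-9)
    stop("maps must share voxel size")
  a <- map1$data; b <- map2$data
  if (!is.null(mask)) { a <- a * mask; b <- b * mask }
  dm <- dim(a)
  fa <- fft(a); fb <- fft(b)
  q <- sqrt(freq_sq_grid(dm))              # cycles/voxel
  nshell <- floor(min(dm) / 2 / shell_width)
  shell <- floor(q * min(dm) / shell_width) + 1
  sel <- as.vector(shell <= nshell)                  # drop corners beyond Nyquist
  shl <- as.vector(shell)[sel]
  num <- Re(fa * Conj(fb)); pa <- Mod(fa)^2; pb <- Mod(fb)^2
  s_num <- rowsum(as.vector(num)[sel], shl)
  s_pa <- rowsum(as.vector(pa)[sel], shl)
  s_pb <- rowsum(as.vector(pb)[sel], shl)
  k <- seq_len(nshell)
  corr <- s_num[k, 1] / sqrt(s_pa[k, 1] * s_pb[k, 1])
  corr[!is.finite(corr)] <- 0
  freq <- (k - 0.5) * shell_width / (min(dm) * map1$voxel_size)  # 1/A
  below <- which(corr < cutoff)
  below <- below[below > 1]
  if (length(below) == 0) {
    res <- 2 * map1$voxel_size
    crossed <- FALSE
  } else {
    i <- below[1]
    f0 <- freq[i - 1]; f1 <- freq[i]
    c0 <- corr[i - 1]; c1 <- corr[i]
    fc <- f0 + (c0 - cutoff) / (c0 - c1) * (f1 - f0)
    res <- 1 / fc
    crossed <- TRUE
  }
  structure(data.frame(freq = freq, corr = corr),
            class = c("fsc_curve", "data.frame"),
            resolution = res, crossed = crossed, cutoff = cutoff)
}

#' @export
print.fsc_curve <- function(x, ...) {
  cat(sprintf("fsc_curve: %d shells, cutoff %.3f, resolution %.1f A%s\n",
              nrow(x), attr(x, "cutoff"), attr(x, "resolution"),
              if (attr(x, "crossed")) "" else " (Nyquist-limited, no crossing)"))
  invisible(x)
}

#' Soft-edged spherical mask
#'
#' @param dm Grid dimensions.
#' @param radius Mask radius in voxels.
#' @param edge Cosine edge width in voxels (default 5).
#' @return Array in `[0, 1]`.
#' @export
soft_spherical_mask <- function(dm, radius, edge = 5) {
  ctr <- (dm + 1) / 2
  x <- (seq_len(dm[1]) - ctr[1])^2
  y <- (seq_len(dm[2]) - ctr[2])^2
  z <- (seq_len(dm[3]) - ctr[3])^2
  r <- sqrt(outer(outer(x, y, `+`), z, `+`))
  m <- 0.5 * (1 + cos(pi * pmin(pmax((r - radius) / edge, 0), 1)))
  m[r <= radius] <- 1
  m
}

#' Map-versus-model resolution
#'
#' FSC between an experimental average and a reference map synthesised from
#' an atomic model, with a 0.5 cutoff (the half-map 0.143 criterion applies
#' only to independent halves).
#'
#' @param map Experimental `density_volume`.
#' @param reference_model_map Reference `density_volume` (e.g. from
#'   [synthesize_density()]).
#' @param mask Optional mask array; must not be all-zero.
#' @param cutoff FSC threshold (default 0.5).
#' @return Resolution in Angstrom, with the `fsc_curve` as attribute.
#' @export
model_map_resolution <- function(map, reference_model_map, mask = NULL, cutoff = 0.5) {
  if (!is.null(mask) && sum(mask) == 0) stop("empty mask")
  fc <- fsc(map, reference_model_map, mask = mask, cutoff = cutoff)
  res <- attr(fc, "resolution")
  attr(res, "fsc") <- fc
  res
}

# Fit an equilateral triangle to the low-density solvent channel of a
# transverse section. The channel boundary is traced by ray casting from the
# lattice point: along each azimuth, the boundary radius is the first point
# at which the density reaches a fixed fraction of the wall density (98th
# percentile within the disc); rays that never reach the wall stop at the
# disc edge (the channel's corner lobes). The corner azimuth is the phase of
# the third circular harmonic of this boundary profile -- the
# maximum-likelihood phase of a threefold shape, far more robust on sparse
# maps than a pixel-classification segmentation -- and the inradius is the
# least-squares scale of the triangle's polar form d / cos(phi mod 120 - 60).
fit_channel_triangle <- function(section, center_xy, disc_radius_vox,
                                 wall_fraction = 0.25, angle_step = 1,
                                 radial_step = 0.25) {
  dm <- dim(section)
  xs <- seq_len(dm[1]) - center_xy[1]
  ys <- seq_len(dm[2]) - center_xy[2]
  rr <- sqrt(outer(xs^2, ys^2, `+`))
  disc <- rr <= disc_radius_vox
  tau <- wall_fraction * stats::quantile(section[disc], 0.98, names = FALSE)
  if (!is.finite(tau) || tau <= 0)
    stop("no channel found: section has no significant wall density")
  ang <- seq(0, 360 - angle_step, by = angle_step)
  rs <- seq(1, disc_radius_vox, by = radial_step)
  prof <- vapply(ang, function(a) {
    pts <- cbind(center_xy[1] + rs * cos(a * pi / 180),
                 center_xy[2] + rs * sin(a * pi / 180))
    v <- bilinear(section, pts)
    hit <- which(v >= tau)
    if (length(hit)) rs[hit[1]] else disc_radius_vox
  }, numeric(1))
  if (all(prof >= disc_radius_vox - radial_step))
    stop("no channel found: no wall within the segmentation disc")
  w <- prof - mean(prof)
  z3 <- sum(w * exp(3i * ang * pi / 180))
  psi <- (Arg(z3) * 180 / pi / 3) %% 120
  ci <- 1 / cos((((ang - psi) %% 120) - 60) * pi / 180)
  d <- sum(prof * ci) / sum(ci^2)
  side_cv <- Mod(z3) / sum(abs(w))   # threefold modulation strength
  list(orientation = psi, inradius = d, modulation = side_cv,
       threshold = tau, profile = data.frame(angle = ang, radius = prof))
}

#' Rotation of the solvent-channel triangle across the disk
#'
#' In each of two transverse sections the large triangular solvent channel at
#' the lattice point is segmented (Otsu threshold on the density within a
#' disc of radius `0.45 * cell_edge` around the lattice point) and an
#' equilateral triangle is fitted to its boundary by a grid search over the
#' corner azimuth. The result is the orientation difference (high minus low
#' section), unwrapped to (-60, 60] to resolve the threefold ambiguity.
#'
#' @param map A `density_volume` centred on a lattice point (x, y) and the
#'   disk central plane (z).
#' @param section_lo,section_hi Signed section indices (voxels from the
#'   central plane), e.g. -50 and +50.
#' @param cell_edge_a Unit-cell edge in nm (sets the segmentation disc).
#' @return Rotation in degrees in (-60, 60], with per-section fits as the
#'   `fits` attribute.
#' @export
channel_rotation <- function(map, section_lo = -50, section_hi = 50,
                             cell_edge_a = 52) {
  dm <- dim(map$data)
  ctr <- (dm + 1) / 2
  disc_vox <- 0.45 * cell_edge_a * 10 / map$voxel_size
  if (dm[3] %% 2 == 0)
    stop("channel_rotation needs an odd z dimension so that signed sections ",
         "sit symmetrically about the central plane")
  get_fit <- function(s) {
    k <- ctr[3] + s
    if (k < 1 || k > dm[3]) stop("section ", s, " outside the map")
    fit_channel_triangle(map$data[, , k], ctr[1:2], disc_vox)
  }
  flo <- get_fit(section_lo)
  fhi <- get_fit(section_hi)
  rot <- wrap_angle(fhi$orientation - flo$orientation, period = 120)
  attr(rot, "fits") <- list(lo = flo, hi = fhi)
  rot
}

#' Axial thickness and antiparallel overlap of the disk
#'
#' Thickness is the axial extent over which the in-plane-integrated density
#' (within a centred in-plane window, lightly smoothed along z) stays above
#' `threshold_fraction` of its maximum, with linear interpolation at the two
#' outermost crossings. The overlap is the axial extent over which both
#' polarity groups' filament density co-occurs; it requires per-group maps
#' (from the phantom's labelled components) and is `NA` otherwise.
#'
#' @param map A `density_volume` centred on the disk plane.
#' @param threshold_fraction Fraction of the profile maximum (default 0.5).
#' @param group_maps Optional list of two `density_volume`s holding the two
#'   polarity groups' filament density.
#' @param window_fraction In-plane window half-width as a fraction of the
#'   grid (default 0.4, avoiding edge fall-off).
#' @return List with `thickness_nm`, `overlap_nm` and the axial profile.
#' @export
measure_axial_extent <- function(map, threshold_fraction = 0.5,
                                 group_maps = NULL, window_fraction = 0.4) {
  prof_of <- function(vol) {
    dm <- dim(vol$data)
    ctr <- (dm + 1) / 2
    ix <- seq(max(1, round(ctr[1] - window_fraction * dm[1])),
              min(dm[1], round(ctr[1] + window_fraction * dm[1])))
    iy <- seq(max(1, round(ctr[2] - window_fraction * dm[2])),
              min(dm[2], round(ctr[2] + window_fraction * dm[2])))
    p <- apply(vol$data[ix, iy, , drop = FALSE], 3, sum)
    ps <- stats::filter(p, rep(1 / 3, 3), sides = 2)
    ps[1] <- p[1]; ps[length(p)] <- p[length(p)]
    ps
  }
  extent_nm <- function(p, vs) {
    thr <- threshold_fraction * max(p)
    above <- which(p >= thr)
    if (length(above) == 0) return(0)
    i0 <- above[1]; i1 <- above[length(above)]
    # linear interpolation at the two outermost crossings
    lo <- if (i0 > 1) i0 - (p[i0] - thr) / (p[i0] - p[i0 - 1]) else i0
    hi <- if (i1 < length(p)) i1 + (p[i1] - thr) / (p[i1] - p[i1 + 1]) else i1
    (hi - lo) * vs / 10
  }
  prof <- prof_of(map)
  thickness <- extent_nm(prof, map$voxel_size)
  overlap <- NA_real_
  if (!is.null(group_maps)) {
    pa <- prof_of(group_maps[[1]]); pb <- prof_of(group_maps[[2]])
    ka <- pa >= threshold_fraction * max(pa)
    kb <- pb >= threshold_fraction * max(pb)
    both <- which(ka & kb)
    if (length(both) > 0)
      overlap <- (both[length(both)] - both[1]) * map$voxel_size / 10
  }
  list(thickness_nm = thickness, overlap_nm = overlap, profile = as.numeric(prof))
}

#' Half-set resolution protocol
#'
#' Gold-standard half-map resolution: the kept picks are split into two
#' random halves by parent pick, prior to any symmetry expansion; each half
#' is processed independently through the averaging pipeline (extraction,
#' alignment by classification, its own symmetry expansion, averaging); the
#' two half-maps are then compared by masked FSC at the 0.143 cutoff.
#'
#' @param tomogram A `density_volume`.
#' @param picks Pick table ([pick_lattice_points()]); kept rows are used.
#' @param group A [symmetry_group()] for the expansion (or `NULL` to skip).
#' @param seed Integer seed controlling the random split (reproducible:
#'   identical seeds give identical halves).
#' @param box_size Box edge in voxels.
#' @param k,max_iter Classification parameters passed on.
#' @param mask_radius_frac Soft FSC mask radius as a fraction of the box.
#' @return Resolution in Angstrom, with attributes `fsc` (the curve),
#'   `halves` (the parent split) and `maps`.
#' @export
half_set_protocol <- function(tomogram, picks, group = NULL, seed = 1,
                              box_size = 32, k = 2, max_iter = 3,
                              mask_radius_frac = 0.35) {
  if (!is.null(picks$status)) picks <- picks[picks$status == "kept", ]
  n <- nrow(picks)
  if (n < 8) stop("too few picks: need at least 4 per half")
  set.seed(seed)
  perm <- sample.int(n)
  h1 <- sort(perm[seq_len(floor(n / 2))])
  h2 <- sort(perm[(floor(n / 2) + 1):n])
  one_half <- function(rows) {
    s <- extract_subvolumes(tomogram, picks[rows, ], box_size)
    s <- align_by_classification(s, k = min(k, length(s)), max_iter = max_iter)
    if (!is.null(group)) s <- symmetry_expand(s, group, global_ref = FALSE)
    average_subvolumes(s)
  }
  m1 <- one_half(h1)
  m2 <- one_half(h2)
  mask <- soft_spherical_mask(dim(m1$data), mask_radius_frac * box_size, edge = 5)
  fc <- fsc(m1, m2, mask = mask, cutoff = 0.143)
  res <- attr(fc, "resolution")
  attr(res, "fsc") <- fc
  attr(res, "halves") <- list(half1 = h1, half2 = h2)
  attr(res, "maps") <- list(m1, m2)
  res
}

#' Low-pass filter a map and contour it
#'
#' @param map A `density_volume`.
#' @param resolution Target resolution in Angstrom (> 2 x voxel size).
#' @param contour_level Contour threshold in map standard deviations above
#'   the mean (default 1.15).
#' @return List with the filtered `density_volume`, the binary surface mask,
#'   and the enclosed volume in nm^3.
#' @export
filter_and_contour <- function(map, resolution, contour_level = 1.15) {
  if (resolution <= 2 * map$voxel_size)
    stop("resolution must exceed twice the voxel size")
  filt <- map
  filt$data <- gaussian_lowpass(map$data, resolution, map$voxel_size)
  thr <- mean(filt$data) + contour_level * stats::sd(filt$data)
  mask <- filt$data >= thr
  list(map = filt, mask = mask,
       enclosed_volume_nm3 = sum(mask) * (map$voxel_size / 10)^3,
       threshold = thr)
}
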