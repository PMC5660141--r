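#' Fit a 2D reciprocal lattice to a power spectrum
#'
#' Detects significant peaks in a 2D power spectrum (as produced by
#' `Mod(fft(image))^2`, unshifted), chooses the two shortest non-collinear
#' peak vectors as a provisional basis, indexes all peaks, and refines the
#' basis by least squares. Peak positions are refined to sub-bin precision by
#' a 3x3 centre of mass.
#'
#' @param power_spectrum 2D array, unshifted (DC at `[1, 1]`).
#' @param pixel_size Pixel size of the originating image in Angstrom.
#' @param min_spacing_nm,max_spacing_nm Real-space spacing range (nm) within
#'   which lattice reflections are searched (default 20-150 nm).
#' @param n_peaks Maximum number of peaks used for the fit.
#' @return An object of class `reciprocal_lattice`: reciprocal basis
#'   `a_star`, `b_star` (1/nm), real-space basis in image pixels, the fitted
#'   real-space cell edge (nm) and cell angle (deg), and the peak table.
#' @export
fit_reciprocal_lattice <- function(power_spectrum, pixel_size,
                                   min_spacing_nm = 20, max_spacing_nm = 150,
                                   n_peaks = 40) {
  dm <- dim(power_spectrum)
  ps <- fftshift2(power_spectrum)
  ctr <- floor(dm / 2) + 1
  # frequency of one bin, in 1/nm, along each axis
  dq <- 1 / (dm * pixel_size / 10)
  fx <- (seq_len(dm[1]) - ctr[1]) * dq[1]
  fy <- (seq_len(dm[2]) - ctr[2]) * dq[2]
  qq <- sqrt(outer(fx^2, fy^2, `+`))
  band <- qq >= 1 / max_spacing_nm & qq <= 1 / min_spacing_nm
  if (!any(band)) stop("no lattice: search band empty at this image size")
  bg <- stats::median(ps[band])
  sp <- stats::mad(ps[band])
  if (sp == 0) stop("no lattice: featureless power spectrum")
  thr <- bg + 8 * sp
  # local maxima in 3x3 neighbourhoods
  is_max <- ps >= thr & band
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0 && dj == 0) next
    sh <- ps * 0
    si <- max(1, 1 + di):min(dm[1], dm[1] + di)
    ti <- max(1, 1 - di):min(dm[1], dm[1] - di)
    sj <- max(1, 1 + dj):min(dm[2], dm[2] + dj)
    tj <- max(1, 1 - dj):min(dm[2], dm[2] - dj)
    sh[ti, tj] <- ps[si, sj]
    is_max <- is_max & (ps >= sh)
  }
  pk <- which(is_max, arr.ind = TRUE)
  if (nrow(pk) < 2) stop("no lattice: fewer than two significant peaks")
  v <- ps[is_max]
  ord <- order(v, decreasing = TRUE)[seq_len(min(n_peaks, length(v)))]
  pk <- pk[ord, , drop = FALSE]
  # sub-bin centre of mass refinement and conversion to 1/nm
  pos <- t(vapply(seq_len(nrow(pk)), function(i) {
    ii <- pk[i, 1] + (-1:1); jj <- pk[i, 2] + (-1:1)
    ii <- ii[ii >= 1 & ii <= dm[1]]; jj <- jj[jj >= 1 & jj <= dm[2]]
    w <- ps[ii, jj, drop = FALSE] - bg
    w[w < 0] <- 0
    c(sum(outer(ii, rep(1, length(jj))) * w) / sum(w),
      sum(outer(rep(1, length(ii)), jj) * w) / sum(w))
  }, numeric(2)))
  qvec <- cbind((pos[, 1] - ctr[1]) * dq[1], (pos[, 2] - ctr[2]) * dq[2])
  # basis: two shortest non-collinear vectors (one per Friedel pair)
  lens <- sqrt(rowSums(qvec^2))
  ordl <- order(lens)
  a_star <- qvec[ordl[1], ]
  b_star <- NULL
  for (i in ordl[-1]) {
    cr <- a_star[1] * qvec[i, 2] - a_star[2] * qvec[i, 1]
    if (abs(cr) > 0.2 * lens[ordl[1]] * lens[i]) { b_star <- qvec[i, ]; break }
  }
  if (is.null(b_star)) stop("no lattice: all peaks collinear")
  B <- cbind(a_star, b_star)
  # index and refine by least squares (two rounds)
  for (round in 1:2) {
    hk <- t(round(solve(B, t(qvec))))
    pred <- hk %*% t(B)
    res <- sqrt(rowSums((qvec - pred)^2))
    good <- res < 0.25 * min(sqrt(colSums(B^2))) & rowSums(abs(hk)) > 0
    if (sum(good) < 2) break
    B <- t(stats::lm.fit(hk[good, , drop = FALSE], qvec[good, , drop = FALSE])$coefficients)
  }
  # real-space basis (nm): A = (B*)^-T, columns a and b
  A <- t(solve(B))
  # Gauss reduction to the shortest primitive basis (the peak list may have
  # yielded e.g. a fundamental plus a (1,1) vector, a valid but non-reduced
  # cell)
  repeat {
    if (sum(A[, 1]^2) > sum(A[, 2]^2)) A <- A[, 2:1]
    m <- round(sum(A[, 1] * A[, 2]) / sum(A[, 1]^2))
    if (m == 0) break
    A[, 2] <- A[, 2] - m * A[, 1]
  }
  B <- t(solve(A))
  cell_a <- sqrt(sum(A[, 1]^2))
  cell_b <- sqrt(sum(A[, 2]^2))
  gam <- acos(sum(A[, 1] * A[, 2]) / (cell_a * cell_b)) * 180 / pi
  if (gam < 90) {           # canonical obtuse setting (hexagonal: 120 deg)
    A[, 2] <- -A[, 2]
    B <- t(solve(A))
    gam <- 180 - gam
  }
  a_star <- B[, 1]; b_star <- B[, 2]
  structure(list(
    a_star = a_star, b_star = b_star,
    real_a_nm = A[, 1], real_b_nm = A[, 2],
    real_a_px = A[, 1] * 10 / pixel_size, real_b_px = A[, 2] * 10 / pixel_size,
    cell_edge_nm = cell_a, cell_edge_b_nm = cell_b, gamma = gam,
    pixel_size = pixel_size, orders_a = 3L, orders_b = 5L,
    n_peaks = nrow(qvec)
  ), class = "reciprocal_lattice")
}

#' @export
print.reciprocal_lattice <- function(x, ...) {
  cat(sprintf(paste0("reciprocal_lattice: |a| = %.2f nm, |b| = %.2f nm, ",
                     "gamma = %.1f deg (%d peaks; orders %d in a*, %d in b*)\n"),
              x$cell_edge_nm, x$cell_edge_b_nm, x$gamma, x$n_peaks,
              x$orders_a, x$orders_b))
  invisible(x)
}

#' Reciprocal-lattice Fourier filter
#'
#' Zeroes the Fourier transform outside small discs centred on the
#' reciprocal-lattice nodes h a* + k b* with `|h| <= orders_a`,
#' `|k| <= orders_b` (the origin is always passed). For a 3D array the
#' filter is applied to every z section. Output is real-valued; the mask is
#' Friedel-symmetric by construction of the node set.
#'
#' @param map 2D or 3D numeric array.
#' @param lattice A `reciprocal_lattice`.
#' @param orders_a,orders_b Included orders (defaults from the lattice
#'   object: 3 in a*, 5 in b*).
#' @param disc_radius Radius of each passed disc in reciprocal pixels
#'   (default 1.5).
#' @return Filtered array of the same shape.
#' @export
lattice_filter <- function(map, lattice, orders_a = lattice$orders_a,
                           orders_b = lattice$orders_b, disc_radius = 1.5) {
  dm2 <- dim(map)[1:2]
  # node positions in reciprocal pixels relative to DC
  astar_px <- lattice$a_star * (dm2 * lattice$pixel_size / 10)
  bstar_px <- lattice$b_star * (dm2 * lattice$pixel_size / 10)
  if (orders_a == 0 && orders_b == 0) {
    # DC only: the filtered image is the image mean
    out <- map
    if (length(dim(map)) == 2) { out[] <- mean(map); return(out) }
    for (k in seq_len(dim(map)[3])) out[, , k] <- mean(map[, , k])
    return(out)
  }
  hk <- expand.grid(h = -orders_a:orders_a, k = -orders_b:orders_b)
  nodes <- cbind(hk$h * astar_px[1] + hk$k * bstar_px[1],
                 hk$h * astar_px[2] + hk$k * bstar_px[2])
  ix <- fft_freq(dm2[1]) * dm2[1]
  iy <- fft_freq(dm2[2]) * dm2[2]
  mask <- matrix(FALSE, dm2[1], dm2[2])
  for (n in seq_len(nrow(nodes))) {
    d2 <- outer((ix - nodes[n, 1])^2, (iy - nodes[n, 2])^2, `+`)
    mask <- mask | (d2 <= disc_radius^2)
  }
  filt2 <- function(img) Re(fft(fft(img) * mask, inverse = TRUE)) / prod(dm2)
  if (length(dim(map)) == 2) return(filt2(map))
  out <- map
  for (k in seq_len(dim(map)[3])) out[, , k] <- filt2(map[, , k])
  out
}

#' Normalised cross-correlation map of a tomogram against a reference
#'
#' FFT-based normalised cross-correlation at every translation: the
#' reference (mean-subtracted) is correlated with the tomogram, and each
#' value is normalised by the local standard deviation of the tomogram under
#' the reference's footprint, so values lie in [-1, 1]. The map is indexed
#' by the position of the reference centre.
#'
#' @param tomogram A `density_volume` (or 3D array).
#' @param reference A smaller 3D array (typically a subvolume masked from
#'   within the tomogram).
#' @return 3D correlation array of the tomogram's dimensions.
#' @export
cc_map <- function(tomogram, reference) {
  vol <- if (inherits(tomogram, "density_volume")) tomogram$data else tomogram
  ref <- if (inherits(reference, "density_volume")) reference$data else reference
  dmv <- dim(vol); dmr <- dim(ref)
  if (any(dmr > dmv)) stop("reference must be smaller than the tomogram")
  if (stats::sd(ref) == 0) stop("zero-variance reference")
  n <- prod(dmr)
  refc <- ref - mean(ref)
  # embed reference and a box kernel, both centred at the origin voxel
  emb <- function(x) {
    e <- array(0, dmv)
    e[seq_len(dmr[1]), seq_len(dmr[2]), seq_len(dmr[3])] <- x
    # circularly shift so the reference centre sits at index (1,1,1)
    sh <- floor(dmr / 2)
    idx <- lapply(1:3, function(a) ((seq_len(dmv[a]) - 1 + sh[a]) %% dmv[a]) + 1)
    e[idx[[1]], idx[[2]], idx[[3]]]
  }
  fr <- Conj(fft(emb(refc)))
  fb <- Conj(fft(emb(array(1, dmr))))
  fv <- fft(vol)
  fv2 <- fft(vol^2)
  num <- Re(fft(fv * fr, inverse = TRUE)) / prod(dmv)
  s1 <- Re(fft(fv * fb, inverse = TRUE)) / prod(dmv)
  s2 <- Re(fft(fv2 * fb, inverse = TRUE)) / prod(dmv)
  denom_loc <- s2 - s1^2 / n
  denom_loc[denom_loc < 0] <- 0
  den <- sqrt(denom_loc * sum(refc^2))
  out <- num / den
  out[!is.finite(out)] <- 0
  pmax(pmin(out, 1), -1)
}

#' Pick subvolume positions on the predicted lattice grid
#'
#' For each predicted lattice node (h, k) inside the map, the correlation
#' peak within a local search radius (one third of the lattice spacing, ties
#' broken toward the predicted node) is taken as the pick position. Nodes
#' outside the disc mask are labelled `outside_disc`; picks closer than
#' `edge_margin` voxels to the tomogram boundary are labelled `near_edge`;
#' both are excluded from the kept set.
#'
#' @param ccmap 3D correlation array (from [cc_map()]).
#' @param lattice A `reciprocal_lattice` (supplies the real-space basis in
#'   pixels).
#' @param disc_mask Optional 2D logical array marking the specimen disc.
#' @param edge_margin Margin in voxels (default half a typical box, 16).
#' @param origin_xy In-plane voxel position of the (0,0) node (default: grid
#'   centre).
#' @param z_index z voxel at which picks are centred (default: central
#'   section; the peak is searched within +-2 voxels of it).
#' @return Data frame of picks: x, y, z (voxels), h, k, cc, status,
#'   euler_in_plane (deg, from [initial_euler()]).
#' @export
pick_lattice_points <- function(ccmap, lattice, disc_mask = NULL,
                                edge_margin = 16, origin_xy = NULL,
                                z_index = NULL) {
  dm <- dim(ccmap)
  ctr <- (dm + 1) / 2
  origin_xy <- origin_xy %||% ctr[1:2]
  z_index <- z_index %||% round(ctr[3])
  av <- lattice$real_a_px; bv <- lattice$real_b_px
  spacing <- min(sqrt(sum(av^2)), sqrt(sum(bv^2)))
  rad <- spacing / 3
  nmax <- ceiling(max(dm[1:2]) / spacing) + 1
  euler0 <- initial_euler(lattice)
  rows <- list()
  for (h in -nmax:nmax) for (k in -nmax:nmax) {
    p <- origin_xy + h * av + k * bv
    if (p[1] < 1 || p[1] > dm[1] || p[2] < 1 || p[2] > dm[2]) next
    status <- "kept"
    if (!is.null(disc_mask) && !disc_mask[round(p[1]), round(p[2])])
      status <- "outside_disc"
    # local peak search
    i0 <- max(1, floor(p[1] - rad)):min(dm[1], ceiling(p[1] + rad))
    j0 <- max(1, floor(p[2] - rad)):min(dm[2], ceiling(p[2] + rad))
    k0 <- max(1, z_index - 2):min(dm[3], z_index + 2)
    sub <- ccmap[i0, j0, k0, drop = FALSE]
    # distance penalty breaks ties toward the predicted node
    dx <- outer(i0 - p[1], rep(1, length(j0)))
    dy <- outer(rep(1, length(i0)), j0 - p[2])
    ok <- sqrt(dx^2 + dy^2) <= rad
    pen <- array(rep(sqrt(dx^2 + dy^2) * 1e-6, length(k0)), dim(sub))
    score <- sub - pen
    score[array(rep(!ok, length(k0)), dim(sub))] <- -Inf
    w <- which(score == max(score), arr.ind = TRUE)[1, ]
    pos <- c(i0[w[1]], j0[w[2]], k0[w[3]])
    ccv <- sub[w[1], w[2], w[3]]
    if (status == "kept" &&
        (pos[1] <= edge_margin || pos[2] <= edge_margin ||
         pos[1] > dm[1] - edge_margin || pos[2] > dm[2] - edge_margin))
      status <- "near_edge"
    rows[[length(rows) + 1]] <- data.frame(
      x = pos[1], y = pos[2], z = pos[3], h = h, k = k, cc = ccv,
      status = status, euler_in_plane = euler0)
  }
  picks <- do.call(rbind, rows)
  picks[order(picks$h, picks$k), ]
}

#' Initial in-plane Euler angle from the lattice orientation
#'
#' The signed angle from the tomogram x axis to the real-space a axis, in
#' degrees; assigned as the initial in-plane Euler angle of every pick.
#' Invariant to uniform scaling of the lattice.
#'
#' @param lattice A `reciprocal_lattice`.
#' @return Angle in degrees in (-180, 180].
#' @export
initial_euler <- function(lattice) {
  angle2d(lattice$real_a_px)
}
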