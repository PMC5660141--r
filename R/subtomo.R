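#' Subvolume set
#'
#' Boxed subvolumes with their alignment state. Each subvolume carries an
#' intrinsic Z-X-Z Euler triple (degrees) and a shift (voxels); the aligned
#' copy of subvolume i is `rotate_volume(box_i, R(euler_i), shift_i)`, and
#' the set average is the mean of aligned copies. `parent_id` tracks the
#' originating lattice pick and `sym_op_index` the symmetry-expansion
#' provenance (0 = unexpanded), so half-set splitting can be performed on
#' parents, prior to expansion.
#'
#' @param boxes 4D array `[b, b, b, n]` of cubic boxes.
#' @param meta Data frame with columns parent_id, x, y, z, phi, theta, psi,
#'   sx, sy, sz, sym_op_index.
#' @param voxel_size Voxel size in Angstrom.
#' @return An object of class `subvolume_set`.
#' @export
subvolume_set <- function(boxes, meta, voxel_size) {
  if (dim(boxes)[4] != nrow(meta)) stop("boxes and meta disagree")
  if (length(unique(dim(boxes)[1:3])) != 1) stop("boxes must be cubic")
  structure(list(boxes = boxes, meta = meta, voxel_size = voxel_size),
            class = "subvolume_set")
}

#' @export
length.subvolume_set <- function(x) dim(x$boxes)[4]

#' @export
print.subvolume_set <- function(x, ...) {
  cat(sprintf("subvolume_set: %d boxes of %d^3 voxels (%.2f A), %d parents, %s\n",
              length(x), dim(x$boxes)[1], x$voxel_size,
              length(unique(x$meta$parent_id)),
              if (all(x$meta$sym_op_index == 0)) "unexpanded" else "symmetry-expanded"))
  invisible(x)
}

#' Extract subvolumes at kept lattice picks
#'
#' @param tomogram A `density_volume`.
#' @param picks Data frame from [pick_lattice_points()] (rows with
#'   `status == "kept"` are used; a plain x/y/z data frame also works).
#' @param box_size Cubic box edge in voxels.
#' @return A [subvolume_set()]; picks whose box would exceed the tomogram
#'   bounds are dropped with a message.
#' @export
extract_subvolumes <- function(tomogram, picks, box_size = 32) {
  if (!is.null(picks$status)) picks <- picks[picks$status == "kept", ]
  dm <- dim(tomogram$data)
  h <- box_size %/% 2
  lo <- function(p) round(p) - h
  ok <- lo(picks$x) >= 1 & lo(picks$x) + box_size - 1 <= dm[1] &
        lo(picks$y) >= 1 & lo(picks$y) + box_size - 1 <= dm[2] &
        lo(picks$z) >= 1 & lo(picks$z) + box_size - 1 <= dm[3]
  if (any(!ok)) message(sum(!ok), " pick(s) dropped: box exceeds tomogram bounds")
  picks <- picks[ok, , drop = FALSE]
  n <- nrow(picks)
  if (n == 0) stop("no picks left after bounds filtering")
  boxes <- array(0, c(box_size, box_size, box_size, n))
  for (i in seq_len(n)) {
    ix <- lo(picks$x[i]) + 0:(box_size - 1)
    iy <- lo(picks$y[i]) + 0:(box_size - 1)
    iz <- lo(picks$z[i]) + 0:(box_size - 1)
    boxes[, , , i] <- tomogram$data[ix, iy, iz]
  }
  meta <- data.frame(
    parent_id = seq_len(n), x = picks$x, y = picks$y, z = picks$z,
    phi = picks$euler_in_plane %||% 0, theta = 0, psi = 0,
    sx = 0, sy = 0, sz = 0, sym_op_index = 0L)
  subvolume_set(boxes, meta, tomogram$voxel_size)
}

# Aligned copy of subvolume i (rotated into the reference frame).
aligned_copy <- function(set, i) {
  m <- set$meta[i, ]
  R <- euler_to_matrix(c(m$phi, m$theta, m$psi))
  rotate_volume(density_volume(set$boxes[, , , i], set$voxel_size), R,
                shift = c(m$sx, m$sy, m$sz))$data
}

#' Average of a subvolume set
#'
#' Mean of the aligned copies (each box rotated/shifted into the reference
#' frame by its current transform).
#'
#' @param set A [subvolume_set()].
#' @return A [density_volume()].
#' @export
average_subvolumes <- function(set) {
  acc <- array(0, dim(set$boxes)[1:3])
  for (i in seq_len(length(set))) acc <- acc + aligned_copy(set, i)
  density_volume(acc / length(set), set$voxel_size)
}

# Band-pass plus soft spherical mask feature extraction for classification.
feature_vector <- function(vol3, voxel_size, band = c(300, 30), mask,
                           coverage_mask = NULL) {
  dm <- dim(vol3)
  q <- sqrt(freq_sq_grid(dm)) / voxel_size        # 1/A
  bp <- q >= 1 / band[1] & q <= 1 / band[2]
  if (!is.null(coverage_mask)) bp <- bp & coverage_mask
  f <- fft(vol3) * bp
  as.vector(Re(fft(f, inverse = TRUE)) / prod(dm) * mask)
}

# Best translation (within +-range voxels) and in-plane rotation (within
# +-ang_range deg) mapping `vol` onto `ref`, by correlation.
match_to_reference <- function(vol, ref, voxel_size, range = 3,
                               ang_range = 8, ang_step = 2) {
  best <- list(cc = -Inf, dphi = 0, dt = c(0, 0, 0))
  angles <- if (ang_range > 0) seq(-ang_range, ang_range, by = ang_step) else 0
  dm <- dim(vol)
  for (da in angles) {
    v <- if (da == 0) vol else
      rotate_volume(density_volume(vol, voxel_size), rot_axis("z", da))$data
    a <- v - mean(v); b <- ref - mean(ref)
    cc <- Re(fft(fft(a) * Conj(fft(b)), inverse = TRUE)) / prod(dm)
    cc <- cc / (sqrt(sum(a^2)) * sqrt(sum(b^2)))
    # restrict to small shifts
    sh <- as.matrix(expand.grid(dx = -range:range, dy = -range:range, dz = -range:range))
    idx <- cbind(((sh[, 1]) %% dm[1]) + 1, ((sh[, 2]) %% dm[2]) + 1, ((sh[, 3]) %% dm[3]) + 1)
    vals <- cc[idx]
    j <- which.max(vals)
    if (vals[j] > best$cc) best <- list(cc = vals[j], dphi = da, dt = -as.numeric(sh[j, ]))
  }
  best
}

#' Alignment by classification
#'
#' Iterates the classification-alignment scheme: (1) features are extracted
#' from band-passed, soft-masked aligned copies (optionally restricted to
#' the measured Fourier region to avoid wedge-driven clustering); (2)
#' principal components retaining 90% of the variance; (3) hierarchical
#' ascendant classification (Ward criterion) cut at k classes; (4) class
#' averages; (5) each class average is aligned to the global average over
#' residual translations and a small in-plane angle range about the
#' lattice-derived Euler angle; (6) members inherit their class's transform.
#' Iteration stops when the mean shift change drops below `tol` voxels or
#' after `max_iter` rounds.
#'
#' @param set A [subvolume_set()].
#' @param k Number of classes.
#' @param band Band-pass limits in Angstrom (low-resolution, high-resolution).
#' @param mask_radius_frac Soft mask radius as a fraction of the box.
#' @param coverage Optional [fourier_coverage()] whose mask restricts the
#'   feature band to measured frequencies.
#' @param shift_range,ang_range,ang_step Residual search space (voxels, deg).
#' @param tol Convergence tolerance on the mean shift change (voxels).
#' @param max_iter Maximum iterations.
#' @return The aligned [subvolume_set()] with a `class` column and a
#'   `history` attribute (per-iteration mean shift change).
#' @export
align_by_classification <- function(set, k = 4, band = c(300, 30),
                                    mask_radius_frac = 0.4, coverage = NULL,
                                    shift_range = 3, ang_range = 8,
                                    ang_step = 2, tol = 0.25, max_iter = 10) {
  n <- length(set)
  if (n < 2) stop("need at least 2 subvolumes")
  if (k > n) stop("k exceeds the set size")
  b <- dim(set$boxes)[1]
  mask <- soft_spherical_mask(rep(b, 3), mask_radius_frac * b, edge = 3)
  cov_mask <- NULL
  if (!is.null(coverage)) {
    # centred coverage mask -> FFT layout
    cm <- coverage$mask
    sh <- floor(dim(cm) / 2)
    idx <- lapply(1:3, function(a) ((seq_len(dim(cm)[a]) - 1 + sh[a]) %% dim(cm)[a]) + 1)
    cov_mask <- cm[idx[[1]], idx[[2]], idx[[3]]]
  }
  history <- numeric(0)
  for (iter in seq_len(max_iter)) {
    aligned <- lapply(seq_len(n), function(i) aligned_copy(set, i))
    glob <- Reduce(`+`, aligned) / n
    feats <- t(vapply(aligned, feature_vector, numeric(b^3),
                      voxel_size = set$voxel_size, band = band, mask = mask,
                      coverage_mask = cov_mask))
    keep <- which(apply(feats, 2, stats::sd) > 0)
    if (length(keep) < 2) {               # identical subvolumes: one class
      set$meta$class <- 1L
      history <- c(history, 0)
      break
    }
    pc <- stats::prcomp(feats[, keep, drop = FALSE], center = TRUE)
    nv <- which(cumsum(pc$sdev^2) / sum(pc$sdev^2) >= 0.9)[1]
    scores <- pc$x[, seq_len(max(nv, 1)), drop = FALSE]
    hc <- stats::hclust(stats::dist(scores), method = "ward.D2")
    cls <- stats::cutree(hc, k = k)
    set$meta$class <- cls
    dshift <- 0
    for (cl in unique(cls)) {
      idx <- which(cls == cl)
      cavg <- Reduce(`+`, aligned[idx]) / length(idx)
      m <- match_to_reference(cavg, glob, set$voxel_size, range = shift_range,
                              ang_range = ang_range, ang_step = ang_step)
      if (m$dphi != 0 || any(m$dt != 0)) {
        dR <- rot_axis("z", m$dphi)
        for (i in idx) {
          Rold <- euler_to_matrix(as.numeric(set$meta[i, c("phi", "theta", "psi")]))
          eul <- matrix_to_euler(dR %*% Rold)
          sold <- as.numeric(set$meta[i, c("sx", "sy", "sz")])
          snew <- as.vector(dR %*% sold) + m$dt
          set$meta[i, c("phi", "theta", "psi")] <- eul
          set$meta[i, c("sx", "sy", "sz")] <- snew
        }
      }
      dshift <- dshift + length(idx) * sqrt(sum(m$dt^2))
    }
    history <- c(history, dshift / n)
    if (dshift / n < tol) break
  }
  attr(set, "history") <- history
  set
}

#' Sixfold crystallographic symmetry expansion
#'
#' Replicates every subvolume once per group operator: copy (i, g) carries
#' the orientation `R_g %*% R_i` (and correspondingly rotated shift), so all
#' symmetry-related views of the lattice motif enter the average. Each
#' expanded copy is locally refined (translation only) against the global
#' reference. `parent_id` is preserved; `sym_op_index` records provenance.
#'
#' @param set A [subvolume_set()] (aligned).
#' @param group A [symmetry_group()].
#' @param global_ref Optional reference `density_volume` for the local
#'   refinement (default: the set's own average); `FALSE` disables
#'   refinement.
#' @param shift_range Refinement translation range in voxels.
#' @return The expanded [subvolume_set()] (size = group order x input size).
#' @export
symmetry_expand <- function(set, group, global_ref = NULL, shift_range = 2) {
  n <- length(set)
  g <- length(group$operators)
  refine <- !isFALSE(global_ref)
  if (refine) {
    ref <- if (is.null(global_ref)) average_subvolumes(set)$data else global_ref$data
  }
  b <- dim(set$boxes)[1]
  boxes <- array(0, c(b, b, b, n * g))
  metas <- vector("list", g)
  for (j in seq_len(g)) {
    Rg <- group$operators[[j]]$R
    meta_j <- set$meta
    for (i in seq_len(n)) {
      Rold <- euler_to_matrix(as.numeric(set$meta[i, c("phi", "theta", "psi")]))
      eul <- matrix_to_euler(Rg %*% Rold)
      sold <- as.numeric(set$meta[i, c("sx", "sy", "sz")])
      snew <- as.vector(Rg %*% sold)
      meta_j[i, c("phi", "theta", "psi")] <- eul
      meta_j[i, c("sx", "sy", "sz")] <- snew
    }
    meta_j$sym_op_index <- j - 1L
    boxes[, , , (j - 1) * n + seq_len(n)] <- set$boxes
    metas[[j]] <- meta_j
  }
  out <- subvolume_set(boxes, do.call(rbind, metas), set$voxel_size)
  if (refine) {
    for (i in seq_len(length(out))) {
      ac <- aligned_copy(out, i)
      m <- match_to_reference(ac, ref, out$voxel_size, range = shift_range,
                              ang_range = 0)
      out$meta[i, c("sx", "sy", "sz")] <-
        as.numeric(out$meta[i, c("sx", "sy", "sz")]) + m$dt
    }
  }
  out
}

#' Symmetrize a density map over a point group
#'
#' Mean of the map over all group operators; the result is invariant under
#' every operator up to interpolation error.
#'
#' @param avg A `density_volume`.
#' @param group A [symmetry_group()].
#' @return The symmetrized `density_volume`.
#' @export
symmetrize_average <- function(avg, group) {
  acc <- avg$data * 0
  for (op in group$operators) acc <- acc + rotate_volume(avg, op$R)$data
  avg$data <- acc / length(group$operators)
  avg
}

#' Recompute the global average from the first half of the tilt series
#'
#' Missing-cone compensation: the tomogram is rebuilt from the retained
#' (less-damaged) first half of the exposure order; subvolumes are
#' re-extracted at the expanded set's positions and averaged with the
#' expanded alignment parameters. Because the expanded orientations contain
#' the in-plane threefold, the average's Fourier coverage is a missing cone
#' rather than a missing wedge.
#'
#' @param series A [tilt_series()].
#' @param expanded An expanded [subvolume_set()] (supplies positions and
#'   orientations; positions are looked up by `parent_id` from `picks`).
#' @param geometries Corrected geometries for the reconstruction.
#' @param group The [symmetry_group()] used for the expansion (for the
#'   coverage report).
#' @param n_keep Number of images retained (default: first half of the
#'   exposure order).
#' @param out_size,binning Passed to [weighted_back_projection()].
#' @return List with `average` (a `density_volume`), `coverage` (a
#'   [fourier_coverage()], kind `cone` for a symmetry-expanded set) and the
#'   rebuilt `tomogram`.
#' @export
recompute_half_series_average <- function(series, expanded, geometries = NULL,
                                          group = NULL, n_keep = NULL,
                                          out_size = NULL, binning = 1) {
  n <- dim(series$images)[3]
  n_keep <- n_keep %||% ceiling(n / 2)
  keep <- which(series$exposure_order <= n_keep)
  tomo <- weighted_back_projection(series, geometries = geometries,
                                   out_size = out_size, binning = binning,
                                   include = keep)
  b <- dim(expanded$boxes)[1]
  m <- expanded$meta
  h <- b %/% 2
  dm <- dim(tomo$data)
  inb <- round(m$x) - h >= 1 & round(m$x) - h + b - 1 <= dm[1] &
         round(m$y) - h >= 1 & round(m$y) - h + b - 1 <= dm[2] &
         round(m$z) - h >= 1 & round(m$z) - h + b - 1 <= dm[3]
  m <- m[inb, , drop = FALSE]
  if (nrow(m) == 0) stop("no expanded subvolume fits the rebuilt tomogram")
  re_ext <- extract_subvolumes(tomo, m[, c("x", "y", "z")], b)
  # carry over the expanded alignment parameters
  re_ext$meta[, c("phi", "theta", "psi", "sx", "sy", "sz")] <-
    m[, c("phi", "theta", "psi", "sx", "sy", "sz")]
  re_ext$meta$parent_id <- m$parent_id
  re_ext$meta$sym_op_index <- m$sym_op_index
  avg <- average_subvolumes(re_ext)
  rots <- NULL
  if (!is.null(group)) rots <- lapply(group$operators, `[[`, "R")
  cov <- fourier_coverage(lapply(keep, function(i) series$geometries[[i]]),
                          dim = rep(min(33, b), 3), rotations = rots)
  list(average = avg, coverage = cov, tomogram = tomo, n_images = length(keep))
}
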