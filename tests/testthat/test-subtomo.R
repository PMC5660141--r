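make_picks <- function(pos, euler = 0) {
  data.frame(x = pos[, 1], y = pos[, 2], z = pos[, 3],
             h = 0, k = 0, cc = 1, status = "kept", euler_in_plane = euler)
}

test_that("extraction yields one box per interior pick, deterministically", {
  tomo <- phantom_tomogram()
  picks <- make_picks(rbind(c(65, 65, 25), c(40, 52, 25), c(90, 78, 25)))
  s1 <- extract_subvolumes(tomo, picks, box_size = 12)
  expect_equal(length(s1), 3L)
  s2 <- extract_subvolumes(tomo, picks, box_size = 12)
  expect_identical(s1$boxes, s2$boxes)
  # out-of-bounds picks are dropped with a message
  picks2 <- rbind(picks, make_picks(matrix(c(3, 65, 25), 1)))
  expect_message(s3 <- extract_subvolumes(tomo, picks2, 12), "dropped")
  expect_equal(length(s3), 3L)
})

test_that("a set of identical subvolumes collapses to identity transforms", {
  tomo <- phantom_tomogram()
  picks <- make_picks(matrix(rep(c(65, 65, 25), 4), ncol = 3, byrow = TRUE))
  s <- extract_subvolumes(tomo, picks, 12)
  out <- align_by_classification(s, k = 2, max_iter = 3)
  expect_true(all(abs(out$meta[, c("sx", "sy", "sz")]) < 1e-9))
  expect_true(all(abs(out$meta$phi) < 1e-9))
})

test_that("planted subvolume jitter is recovered within one voxel RMS", {
  set.seed(31)
  b <- 20
  motif <- zdisktomo:::gaussian_kernel_filter(array(stats::rnorm(b^3), rep(b, 3)), 2) *
    soft_spherical_mask(rep(b, 3), 6, 3)
  n <- 12
  jit <- cbind(sample(-2:2, n, TRUE), sample(-2:2, n, TRUE), sample(-2:2, n, TRUE))
  boxes <- array(0, c(b, b, b, n))
  for (i in 1:n)
    boxes[, , , i] <- rotate_volume(density_volume(motif, 7.6), diag(3),
                                    shift = -jit[i, ])$data +
      stats::rnorm(b^3, 0, stats::sd(motif) * 0.3)
  meta <- data.frame(parent_id = 1:n, x = 0, y = 0, z = 0, phi = 0, theta = 0,
                     psi = 0, sx = 0, sy = 0, sz = 0, sym_op_index = 0L)
  s <- subvolume_set(boxes, meta, 7.6)
  out <- align_by_classification(s, k = 4, max_iter = 8, ang_range = 0, tol = 0.05)
  rec <- as.matrix(out$meta[, c("sx", "sy", "sz")])
  # recovery up to a common offset (the reference frame is self-defined)
  resid <- sweep(rec, 2, colMeans(rec)) - sweep(jit, 2, colMeans(jit))
  expect_lt(sqrt(mean(resid^2)), 1)
})

test_that("two planted motif variants separate at k = 2", {
  set.seed(7)
  b <- 12
  motifA <- zdisktomo:::gaussian_kernel_filter(array(stats::rnorm(b^3), rep(b, 3)), 1.5)
  motifB <- motifA
  motifB[4:9, 4:9, 4:9] <- motifB[4:9, 4:9, 4:9] + 1.5   # filament present
  truth <- rep(1:2, each = 8)
  noise_sd <- stats::sd(motifA) / sqrt(0.5)   # SNR 0.5
  boxes <- array(0, c(b, b, b, 16))
  for (i in 1:16) {
    m <- if (truth[i] == 1) motifA else motifB
    boxes[, , , i] <- m + stats::rnorm(b^3, 0, noise_sd)
  }
  meta <- data.frame(parent_id = 1:16, x = 0, y = 0, z = 0,
                     phi = 0, theta = 0, psi = 0, sx = 0, sy = 0, sz = 0,
                     sym_op_index = 0L)
  s <- subvolume_set(boxes, meta, 7.6)
  out <- align_by_classification(s, k = 2, max_iter = 1, ang_range = 0,
                                 shift_range = 0)
  cls <- out$meta$class
  purity <- max(mean(cls[truth == 1] == cls[truth == 1][1]) *
                  mean(cls[truth == 2] == cls[truth == 2][1]), 0)
  agree <- max(sum((cls == 1) == (truth == 1)), sum((cls == 2) == (truth == 1))) / 16
  expect_gte(agree, 0.9)
})

test_that("symmetry expansion is sixfold and preserves provenance", {
  tomo <- phantom_tomogram()
  picks <- make_picks(rbind(c(65, 65, 25), c(40, 52, 25)))
  s <- extract_subvolumes(tomo, picks, 12)
  grp <- p321_operators()
  ex <- symmetry_expand(s, grp, global_ref = FALSE)
  expect_equal(length(ex), 6L * length(s))
  expect_setequal(unique(ex$meta$sym_op_index), 0:5)
  expect_setequal(unique(ex$meta$parent_id), s$meta$parent_id)
  # identity-only group leaves the set unchanged
  id_grp <- symmetry_group(list(list(R = diag(3), t = c(0, 0, 0))), "identity")
  ex1 <- symmetry_expand(s, id_grp, global_ref = FALSE)
  expect_equal(length(ex1), length(s))
  expect_equal(ex1$meta$phi, s$meta$phi)
})

test_that("expanding an already-symmetric motif barely changes the average", {
  vs <- smooth_symmetric_motif()
  boxes <- array(vs$data, c(33, 33, 33, 2))
  meta <- data.frame(parent_id = 1:2, x = 0, y = 0, z = 0, phi = 0,
                     theta = 0, psi = 0, sx = 0, sy = 0, sz = 0,
                     sym_op_index = 0L)
  s <- subvolume_set(boxes, meta, 7.6)
  ex <- symmetry_expand(s, p321_operators(), global_ref = FALSE)
  avg0 <- average_subvolumes(s)
  avg6 <- average_subvolumes(ex)
  msk <- soft_spherical_mask(c(33, 33, 33), 12, 1) > 0.5
  rel <- sqrt(mean((avg6$data[msk] - avg0$data[msk])^2)) /
    sqrt(mean(avg0$data[msk]^2))
  expect_lt(rel, 0.05)
})

test_that("the average is invariant to subvolume order", {
  tomo <- phantom_tomogram()
  picks <- make_picks(rbind(c(65, 65, 25), c(40, 52, 25), c(90, 78, 25)))
  s <- extract_subvolumes(tomo, picks, 12)
  set.seed(42)
  perm <- sample(1:3)
  s2 <- subvolume_set(s$boxes[, , , perm, drop = FALSE], s$meta[perm, ], s$voxel_size)
  a1 <- average_subvolumes(s)
  a2 <- average_subvolumes(s2)
  expect_equal(a2$data, a1$data, tolerance = 1e-12)
})

test_that("symmetrization makes a map invariant under every operator", {
  grp <- p321_operators()
  vs <- symmetrize_average(smooth_symmetric_motif(), grp)
  msk <- soft_spherical_mask(c(33, 33, 33), 10, 1) > 0.5
  for (op in grp$operators[-1]) {
    rot <- rotate_volume(vs, op$R)
    expect_gt(stats::cor(vs$data[msk], rot$data[msk]), 0.999)
  }
  # an already-invariant map is unchanged within interpolation error
  vss <- symmetrize_average(vs, grp)
  expect_gt(stats::cor(vs$data[msk], vss$data[msk]), 0.999)
})

test_that("corresponding +-s sections of the symmetrized average are twofold images", {
  vs <- channel_map()
  ctr <- c(37, 37, 65)
  s1 <- vs$data[, , ctr[3] + 50]
  s2 <- vs$data[, , ctr[3] - 50]
  # in-plane twofold about the x axis through the lattice point: y -> -y
  s2_flipped <- s2[, rev(seq_len(dim(s2)[2]))]
  msk <- sqrt(outer((1:73 - 37)^2, (1:73 - 37)^2, `+`)) <= 30
  expect_gt(stats::cor(s1[msk], s2_flipped[msk]), 0.98)
})

test_that("half-tilt recomputation yields a cone, identity group a wedge", {
  v <- blob_volume(32, seed = 4)
  ang <- seq(-66, 66, by = 6)
  adf <- data.frame(angle = ang, exposure = rank(2 * abs(ang) - (ang > 0)))
  ts <- simulate_tilt_series(v, adf)
  picks <- make_picks(matrix(c(16, 16, 16), 1))
  tomo0 <- weighted_back_projection(ts)
  s <- extract_subvolumes(tomo0, picks, 12)
  grp <- p321_operators()
  ex <- symmetry_expand(s, grp, global_ref = FALSE)
  out <- recompute_half_series_average(ts, ex, group = grp,
                                       out_size = dim(tomo0$data))
  expect_equal(out$coverage$kind, "cone")
  id_grp <- symmetry_group(list(list(R = diag(3), t = c(0, 0, 0))), "id")
  ex1 <- symmetry_expand(s, id_grp, global_ref = FALSE)
  out1 <- recompute_half_series_average(ts, ex1, group = id_grp,
                                        out_size = dim(tomo0$data))
  expect_equal(out1$coverage$kind, "wedge")
  # noise-free: within the measured Fourier region the half-series average
  # matches the ground-truth motif (coverage-filtered on the full grid;
  # residual deviation reflects back-projection weighting and interpolation)
  keepang <- ang[adf$exposure <= ceiling(length(ang) / 2)]
  cov32 <- fourier_coverage(lapply(keepang, tilt_geometry), dim = rep(32, 3))
  sh <- floor(rep(32, 3) / 2)
  idx <- lapply(1:3, function(a) ((seq_len(32) - 1 + sh[a]) %% 32) + 1)
  cmask <- cov32$mask[idx[[1]], idx[[2]], idx[[3]]]
  vf <- v
  vf$data <- Re(fft(fft(v$data) * cmask, inverse = TRUE)) / 32^3
  truth_box <- extract_subvolumes(vf, picks, 12)$boxes[, , , 1]
  msk <- soft_spherical_mask(c(12, 12, 12), 5, 1) > 0.5
  expect_gt(stats::cor(out1$average$data[msk], truth_box[msk]), 0.85)
})

test_that("half-set splitting happens on parents, never on expanded copies", {
  tomo <- phantom_tomogram()
  set.seed(8)
  pos <- cbind(sample(20:110, 10), sample(20:110, 10), 25)
  picks <- make_picks(pos)
  res <- half_set_protocol(tomo, picks, group = p321_operators(), seed = 3,
                           box_size = 12, k = 2, max_iter = 1)
  halves <- attr(res, "halves")
  expect_length(intersect(halves$half1, halves$half2), 0)
  expect_setequal(c(halves$half1, halves$half2), 1:10)
  res2 <- half_set_protocol(tomo, picks, group = p321_operators(), seed = 3,
                            box_size = 12, k = 2, max_iter = 1)
  expect_identical(attr(res2, "halves"), halves)
})
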