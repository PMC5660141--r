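test_that("FSC of a map with itself is unity and Nyquist-limited", {
  v <- blob_volume(32, seed = 4)
  fc <- fsc(v, v)
  expect_true(all(fc$corr > 0.999))
  expect_false(attr(fc, "crossed"))
  expect_equal(attr(fc, "resolution"), 2 * v$voxel_size)
  w <- v; w$voxel_size <- 5
  expect_error(fsc(v, w), "voxel")
  u <- density_volume(array(0, c(16, 16, 16)), 7.6)
  expect_error(fsc(v, u), "dimensions")
})

test_that("band-limited noise places the FSC crossing at the known frequency", {
  # constructed oracle: map2 = map1 + strong noise only above frequency f0
  set.seed(10)
  n <- 48
  base <- zdisktomo:::gaussian_kernel_filter(array(stats::rnorm(n^3), rep(n, 3)), 1)
  noise <- array(stats::rnorm(n^3), rep(n, 3))
  q <- sqrt(zdisktomo:::freq_sq_grid(rep(n, 3)))   # cycles/voxel
  f0 <- 0.25
  hi <- q >= f0
  noise_hi <- Re(fft(fft(noise) * hi, inverse = TRUE)) / n^3
  m1 <- density_volume(base, 7.6)
  m2 <- density_volume(base + 12 * stats::sd(base) * noise_hi /
                         stats::sd(noise_hi), 7.6)
  fc <- fsc(m1, m2)
  res <- attr(fc, "resolution")
  f_cross <- 1 / res                      # 1/A
  f0_A <- f0 / 7.6
  shell <- 1 / (n * 7.6)
  expect_lt(abs(f_cross - f0_A), 1.5 * shell)
})

test_that("independent pure-noise maps correlate to zero beyond the first shells", {
  set.seed(11)
  n <- 48
  m1 <- density_volume(array(stats::rnorm(n^3), rep(n, 3)), 7.6)
  m2 <- density_volume(array(stats::rnorm(n^3), rep(n, 3)), 7.6)
  fc <- fsc(m1, m2)
  expect_lt(abs(mean(fc$corr[4:nrow(fc)])), 0.05)
})

test_that("map-versus-model FSC finds a constructed 60 A cutoff", {
  m <- default_model()
  ref <- synthesize_density(m, voxel_size = 7.6, resolution = 30,
                            dim = c(49, 49, 49))
  filt <- ref
  filt$data <- zdisktomo:::gaussian_lowpass(ref$data, 60, 7.6)
  res <- model_map_resolution(filt, ref, cutoff = 0.5)
  # the Gaussian response crosses 0.5 at exp(-2 (60 q)^2) = 0.5 -> 1/q = 102 A;
  # check the crossing against that closed form rather than the nominal 60
  expect_equal(as.numeric(res), 60 * sqrt(2 / log(2)), tolerance = 10)
  expect_error(model_map_resolution(ref, ref, mask = array(0, c(49, 49, 49))),
               "mask")
  same <- model_map_resolution(ref, ref)
  expect_equal(as.numeric(same), 2 * 7.6)
})

test_that("channel rotation tracks the per-trimer rotation and is antisymmetric", {
  vs <- channel_map()
  rot <- channel_rotation(vs, -50, 50)
  expect_equal(as.numeric(rot), 22, tolerance = 2)
  # zero obliquity: no rotation
  m0 <- build_zdisk_lattice(trimer_rotation = 0)
  v0 <- symmetrize_average(synthesize_density(m0, 7.6, 60, c(73, 73, 129)),
                           m0$symmetry)
  expect_equal(abs(as.numeric(channel_rotation(v0, -50, 50))), 0, tolerance = 1)
  # odd function of section separation about the central plane
  r30 <- as.numeric(channel_rotation(vs, -30, 0)) 
  r30b <- as.numeric(channel_rotation(vs, 0, 30))
  expect_equal(r30, r30b, tolerance = 2)
})

test_that("intermediate trimer rotations scale the channel rotation linearly", {
  m5 <- build_zdisk_lattice(trimer_rotation = 5.5)
  v5 <- symmetrize_average(synthesize_density(m5, 7.6, 60, c(73, 73, 129)),
                           m5$symmetry)
  expect_equal(as.numeric(channel_rotation(v5, -50, 50)), 11, tolerance = 2)
})

test_that("thickness and overlap recover the study geometry", {
  m <- default_model()
  at <- zdisk_atoms(m, xy_range = 26)
  v <- synthesize_density(at, 7.6, 30, c(97, 97, 181))
  sub <- function(df, sel) { x <- df[sel, ]; class(x) <- class(df); x }
  ga <- synthesize_density(sub(at, at$group == "A" & at$component == "filament"),
                           7.6, 30, c(97, 97, 181))
  gb <- synthesize_density(sub(at, at$group == "B" & at$component == "filament"),
                           7.6, 30, c(97, 97, 181))
  mx <- measure_axial_extent(v, 0.5, group_maps = list(ga, gb),
                             window_fraction = 0.5)
  expect_equal(mx$thickness_nm, 120, tolerance = 8)
  expect_equal(mx$overlap_nm, 80, tolerance = 8)
})

test_that("a uniform 100 nm slab measures 100 nm within one voxel", {
  dm <- c(33, 33, 161)
  v <- density_volume(array(0, dm), 7.6)
  nz <- round(1000 / 7.6)              # 100 nm in voxels
  z0 <- (dm[3] - nz) / 2
  v$data[, , (z0 + 1):(z0 + nz)] <- 1
  mx <- measure_axial_extent(v, 0.5, window_fraction = 0.5)
  expect_equal(mx$thickness_nm, 100, tolerance = 0.76)
})

test_that("contouring behaves as a level set", {
  vs <- channel_map()
  fc <- filter_and_contour(vs, 80, contour_level = 1.15)
  expect_gt(fc$enclosed_volume_nm3, 0)
  vols <- vapply(c(0.5, 1.15, 2, 4), function(lv)
    filter_and_contour(vs, 80, lv)$enclosed_volume_nm3, numeric(1))
  expect_true(all(diff(vols) <= 0))
  inf_mask <- filter_and_contour(vs, 80, 1e9)
  expect_equal(sum(inf_mask$mask), 0)
  expect_error(filter_and_contour(vs, 10, 1), "resolution")
})

test_that("half-set resolution improves with more subvolumes", {
  tomo0 <- phantom_tomogram()
  set.seed(5)
  noisy <- tomo0
  noisy$data <- noisy$data + stats::rnorm(length(noisy$data),
                                          0, stats::sd(noisy$data) / sqrt(0.6))
  grid8 <- cbind(rep(seq(25, 105, length.out = 4), 2),
                 rep(c(45, 85), each = 4), 25)
  grid32 <- as.matrix(expand.grid(x = seq(20, 110, length.out = 6),
                                  y = seq(20, 110, length.out = 6), z = 25))[1:32, ]
  mk <- function(pos) data.frame(x = pos[, 1], y = pos[, 2], z = pos[, 3],
                                 h = 0, k = 0, cc = 1, status = "kept",
                                 euler_in_plane = 0)
  r8 <- as.numeric(half_set_protocol(noisy, mk(grid8), group = NULL, seed = 2,
                                     box_size = 12, max_iter = 1))
  r32 <- as.numeric(half_set_protocol(noisy, mk(grid32), group = NULL, seed = 2,
                                      box_size = 12, max_iter = 1))
  expect_lte(r32, r8 + 1e-9)
  # never finer than the sampling band limit
  expect_gte(r32, 2 * noisy$voxel_size - 1e-9)
})
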