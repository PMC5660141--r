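test_that("Saxton stepping starts at step0 and shrinks with cos(theta)", {
  sa <- saxton_angles(2, 70, 70)
  pos <- sa$angle[sa$angle >= 0]
  expect_equal(pos[1:3], c(0, 2, 2 + 2 * cos(2 * pi / 180)), tolerance = 1e-9)
  expect_true(all(diff(pos) > 0))
  neg <- rev(sa$angle[sa$angle < 0])
  expect_true(all(diff(neg) < 0))
})

test_that("the study's acquisition bounds give close to 96 images", {
  sa <- saxton_angles(2, 69.87, 67.66)
  expect_gte(nrow(sa), 91)
  expect_lte(nrow(sa), 101)
  expect_equal(sa$exposure[which(sa$angle == 0)], 1L)
})

test_that("disabling the cosine rule yields an arithmetic sequence", {
  sa <- saxton_angles(5, 30, 30, cosine = FALSE)
  expect_equal(sa$angle, seq(-30, 30, by = 5))
})

test_that("zero-tilt projection is the z sum and conserves flux", {
  v <- blob_volume()
  p0 <- project(v, tilt_geometry(0))
  expect_equal(p0, apply(v$data, 1:2, sum), tolerance = 1e-12)
  p30 <- project(v, tilt_geometry(30))
  expect_equal(sum(p30), sum(v$data), tolerance = 0.01 * abs(sum(v$data)) + 1e-6)
})

test_that("projection is linear to machine precision", {
  v <- blob_volume()
  w <- density_volume(v$data^2, v$voxel_size)
  g <- tilt_geometry(25, tilt_azimuth = 40)
  lhs <- project(density_volume(2 * v$data - 3 * w$data, 7.6), g)
  rhs <- 2 * project(v, g) - 3 * project(w, g)
  expect_equal(lhs, rhs, tolerance = 1e-10)
})

test_that("a tilted sphere's footprint is foreshortened by cos(tilt)", {
  dm <- c(64, 64, 64)
  ctr <- (dm + 1) / 2
  r2 <- outer(outer((1:64 - ctr[1])^2, (1:64 - ctr[2])^2, `+`), (1:64 - ctr[3])^2, `+`)
  v <- density_volume(array(as.numeric(r2 <= 10^2), dm), 7.6)
  p <- project(v, tilt_geometry(60, tilt_azimuth = 0))   # axis along x
  supp <- p > 0.05 * max(p)
  wx <- diff(range(which(apply(supp, 1, any))))
  wy <- diff(range(which(apply(supp, 2, any))))
  # a sphere stays round: footprint width constant along the axis,
  # and the shadow is the volume integral so only weak foreshortening shows;
  # use a flat disc instead for the classic cos(theta) shrinkage
  disc <- array(0, dm)
  disc[abs(outer((1:64 - ctr[1]), rep(1, 64))) <= 20 &
       abs(outer(rep(1, 64), (1:64 - ctr[2]))) <= 20] <- 1
  vd <- density_volume(array(disc[, , 1], dm) * 0, 7.6)
  vd$data[, , 32:33] <- array(as.numeric(
    abs(outer((1:64 - ctr[1]), rep(1, 64))) <= 20 &
    abs(outer(rep(1, 64), (1:64 - ctr[2]))) <= 20), c(64, 64, 2))
  pd <- project(vd, tilt_geometry(60, tilt_azimuth = 0))
  sd_ <- pd > 0.5 * max(pd)
  wxd <- diff(range(which(apply(sd_, 1, any))))
  wyd <- diff(range(which(apply(sd_, 2, any))))
  expect_equal(wyd / wxd, cos(60 * pi / 180), tolerance = 0.1)
  expect_gt(wx, 0); expect_gt(wy, 0)
})

test_that("the projection obeys the Fourier-slice theorem (analytic oracle)", {
  # independent oracle: three Gaussian blobs with closed-form projection and FT
  n <- 32; vs <- 7.6; sigma <- 12
  set.seed(2)
  centers <- matrix(stats::runif(9, -40, 40), 3, 3)
  ctr <- (n + 1) / 2
  g <- as.matrix(expand.grid(x = 1:n, y = 1:n, z = 1:n))
  phys <- sweep(g, 2, rep(ctr, 3)) * vs
  rho <- 0
  for (i in 1:3)
    rho <- rho + exp(-rowSums(sweep(phys, 2, centers[i, ])^2) / (2 * sigma^2))
  v <- density_volume(array(rho, rep(n, 3)), vs)
  fr <- zdisktomo:::fft_freq(n)
  ph2 <- exp(2i * pi * (outer(fr * (ctr - 1), rep(1, n)) +
                        outer(rep(1, n), fr * (ctr - 1))))
  g2 <- as.matrix(expand.grid(x = 1:n, y = 1:n))
  xy <- sweep(g2, 2, rep(ctr, 2)) * vs
  for (theta in c(35, 60)) {
    p <- project(v, tilt_geometry(theta))
    R <- rot_about(c(1, 0, 0), theta)
    # real space: analytic projection of the rotated blobs
    pa <- 0
    for (i in 1:3) {
      cc <- as.vector(R %*% centers[i, ])
      pa <- pa + exp(-rowSums(sweep(xy, 2, cc[1:2])^2) / (2 * sigma^2)) *
        sqrt(2 * pi) * sigma / vs
    }
    expect_gt(stats::cor(as.vector(p), pa), 0.999)
    # Fourier space: the projection FT equals the central slice of the
    # volume FT at the tilted orientation (analytic 3D FT of the blobs)
    P <- fft(p) * ph2
    ks <- -6:6
    got <- expected <- complex(length(ks)^2)
    i <- 0
    for (kx in ks) for (ky in ks) {
      i <- i + 1
      q <- as.vector(t(R) %*% c(kx, ky, 0)) / (n * vs)
      val <- 0 + 0i
      for (a in 1:3)
        val <- val + exp(-2 * pi^2 * sigma^2 * sum(q^2)) *
          exp(-2i * pi * sum(q * centers[a, ]))
      got[i] <- val * (2 * pi * sigma^2)^(3 / 2) / vs^3
      expected[i] <- P[(kx %% n) + 1, (ky %% n) + 1]
    }
    expect_gt(stats::cor(Re(got), Re(expected)), 0.999)
    expect_gt(stats::cor(Im(got), Im(expected)), 0.999)
  }
})

test_that("dose and damage leave the series unchanged when disabled", {
  v <- blob_volume()
  ts <- simulate_tilt_series(v, c(-20, 0, 20))
  out <- apply_dose_and_damage(ts, damage_rate = 0, snr = Inf)
  expect_equal(out$images, ts$images, tolerance = 1e-12)
})

test_that("cumulative damage degrades images monotonically with exposure", {
  v <- blob_volume()
  ang <- seq(-40, 40, by = 10)
  ts <- simulate_tilt_series(v, ang)
  dmg <- apply_dose_and_damage(ts, damage_rate = 400, snr = Inf)
  cc <- vapply(seq_along(ang), function(i)
    safe_cor_pub(dmg$images[, , i], ts$images[, , i]), numeric(1))
  ord <- order(ts$exposure_order)
  expect_true(all(diff(cc[ord]) <= 1e-9))
})
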