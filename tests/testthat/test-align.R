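test_that("area matching recovers identity, shifts, and scalings", {
  img <- blob_volume(48, seed = 3, slab = TRUE)$data[, , 24]
  ident <- area_match(img, img, search = list(distortion = FALSE))
  expect_equal(ident$shift, c(0, 0), tolerance = 1e-9)
  expect_equal(ident$cc_peak, 1, tolerance = 1e-9)

  ref <- zdisktomo:::affine_resample2(img, diag(2), shift = c(3, -2))
  sh <- area_match(img, ref, search = list(distortion = FALSE))
  expect_equal(sh$shift, c(3, -2), tolerance = 0.1)

  ref2 <- zdisktomo:::affine_resample2(img, diag(c(0.95, 1)))
  d <- area_match(img, ref2)
  expect_equal(d$distortion, diag(c(0.95, 1)), tolerance = 0.01,
               ignore_attr = TRUE)
})

test_that("flat input is rejected", {
  flat <- matrix(1, 16, 16)
  expect_error(area_match(flat, flat), "zero-variance")
})

test_that("an unshifted noise-free series aligns to identity geometry", {
  ts <- memo_series_clean()
  al <- align_tilt_series(ts, n_passes = 2)
  sh <- t(vapply(al$geometries, function(g) g$shift, numeric(2)))
  expect_lt(max(abs(sh[abs(al$records$angle) <= 45, ])), 0.5)
  expect_true(all(vapply(al$geometries, function(g)
    max(abs(g$distortion - diag(2))), numeric(1)) < 1e-9))
})

test_that("known shifts are recovered within half a pixel", {
  ts <- memo_series_clean()
  n <- dim(ts$images)[3]
  set.seed(12)
  true_s <- matrix(round(stats::runif(2 * n, -4, 4)), ncol = 2)
  true_s[which(abs(al_angles(ts)) < 1e-9), ] <- 0
  for (i in seq_len(n))
    ts$images[, , i] <- zdisktomo:::affine_resample2(ts$images[, , i], diag(2),
                                                     true_s[i, ])
  al <- align_tilt_series(ts, n_passes = 2)
  rec <- t(vapply(al$geometries, function(g) g$shift, numeric(2)))
  err <- sqrt(rowSums((rec - true_s)^2))
  interior <- abs(al_angles(ts)) <= 45
  expect_lt(max(err[interior]), 0.5)
  expect_lt(sqrt(mean(err^2)), 0.5)
})

test_that("damaged series flag a suffix of the exposure order", {
  v <- blob_volume(40, seed = 11, slab = TRUE)
  # Saxton-style exposure order: dose accumulates from 0 degrees outward,
  # so heavily damaged images are the late, high-tilt exposures
  sa <- saxton_angles(10, 50, 50, cosine = FALSE)
  ts <- simulate_tilt_series(v, sa)
  set.seed(9)
  dmg <- apply_dose_and_damage(ts, damage_rate = 60000, snr = 4)
  al <- align_tilt_series(dmg, cc_threshold = 0.3, n_passes = 1)
  rec <- al$records[order(al$records$exposure), ]
  flagged <- !rec$retained
  expect_true(any(flagged))
  # flagged images form a suffix of the exposure order
  first_bad <- which(flagged)[1]
  expect_true(all(flagged[first_bad:length(flagged)]))
  kept <- truncate_damaged(al$records, 0.3)
  expect_lt(length(kept), nrow(rec))
})

test_that("truncation keeps the maximal good exposure prefix", {
  rec <- data.frame(image = 1:5, exposure = 1:5,
                    cc_peak = c(.9, .8, .7, .2, .8))
  expect_equal(truncate_damaged(rec, 0.5), 1:3)
  rec2 <- data.frame(image = 1:4, exposure = 1:4, cc_peak = rep(.9, 4))
  expect_equal(truncate_damaged(rec2, 0.5), 1:4)
  expect_error(truncate_damaged(rec[0, ], 0.5), "no records")
})

test_that("geometry refinement recovers a mis-set tilt azimuth", {
  set.seed(5)
  ang <- seq(-60, 60, by = 10)
  D <- lapply(ang, function(th)
    zdisktomo:::foreshortening(th, 3) %*%
      solve(zdisktomo:::foreshortening(th, 0)) +
      matrix(stats::rnorm(4, 0, 0.003), 2, 2))
  rg <- refine_geometry(data.frame(angle = ang), distortions = D)
  expect_equal(rg$azimuth_correction, 3, tolerance = 0.3)
})

test_that("exactly-predicted distortions give zero residuals", {
  ang <- seq(-40, 40, by = 10)
  D <- lapply(ang, function(th) diag(2))
  rg <- refine_geometry(data.frame(angle = ang), distortions = D)
  expect_true(all(rg$residuals < 1e-6))
})

test_that("a degenerate all-zero-tilt design is rejected by name", {
  D <- lapply(1:6, function(i) diag(2))
  expect_error(refine_geometry(data.frame(angle = rep(0, 6)),
                               distortions = D), "azimuth")
})

test_that("refinement is invariant to a global in-plane rotation", {
  ang <- seq(-50, 50, by = 10)
  make <- function(phi0) lapply(ang, function(th)
    zdisktomo:::foreshortening(th, phi0 + 2) %*%
      solve(zdisktomo:::foreshortening(th, phi0)))
  r0 <- refine_geometry(data.frame(angle = ang), distortions = make(0),
                        nominal_azimuth = 0)
  r25 <- refine_geometry(data.frame(angle = ang), distortions = make(25),
                         nominal_azimuth = 25)
  expect_equal(r0$azimuth_correction, r25$azimuth_correction, tolerance = 0.05)
})

test_that("shift recovery error decreases with SNR", {
  v <- blob_volume(32, seed = 21, slab = TRUE)
  ang <- seq(-40, 40, by = 10)
  clean <- simulate_tilt_series(v, ang)
  n <- length(ang)
  mean_err <- function(snr) {
    errs <- numeric(5)
    for (s in 1:5) {
      set.seed(100 + s)
      true_s <- matrix(round(stats::runif(2 * n, -3, 3)), ncol = 2)
      true_s[which(ang == 0), ] <- 0
      ts <- clean
      for (i in seq_len(n))
        ts$images[, , i] <- zdisktomo:::affine_resample2(ts$images[, , i],
                                                         diag(2), true_s[i, ])
      ts <- apply_dose_and_damage(ts, damage_rate = 0, snr = snr)
      al <- align_tilt_series(ts, n_passes = 1)
      rec <- t(vapply(al$geometries, function(g) g$shift, numeric(2)))
      errs[s] <- sqrt(mean((rec - true_s)^2))
    }
    mean(errs)
  }
  e <- vapply(c(0.2, 1, 5), mean_err, numeric(1))
  expect_true(all(diff(e) < 0))
})
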