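# Internal numerical helpers: FFT frequency grids, interpolation, filters.

# FFT sample frequencies for n points at unit spacing (cycles/sample),
# matching the layout of stats::fft output.
fft_freq <- function(n) {
  k <- c(0:(floor((n - 1) / 2)), -(ceiling((n - 1) / 2):1))
  k / n
}

# |q|^2 grid (cycles/sample units) for a 2D or 3D array of dims `dm`.
freq_sq_grid <- function(dm) {
  fs <- lapply(dm, fft_freq)
  if (length(dm) == 2) {
    outer(fs[[1]]^2, fs[[2]]^2, `+`)
  } else {
    q2 <- array(0, dm)
    q2 <- q2 + array(fs[[1]]^2, dm)
    q2 <- q2 + array(rep(fs[[2]]^2, each = dm[1]), dm)
    q2 + array(rep(fs[[3]]^2, each = dm[1] * dm[2]), dm)
  }
}

fftshift2 <- function(x) {
  dm <- dim(x)
  i <- c((floor(dm[1] / 2) + 1):dm[1], 1:floor(dm[1] / 2))
  j <- c((floor(dm[2] / 2) + 1):dm[2], 1:floor(dm[2] / 2))
  x[i, j, drop = FALSE]
}

# Gaussian low-pass in Fourier space. `cutoff` is a resolution in the same
# length units as `spacing` (per sample); attenuation reaches exp(-2) at the
# cutoff frequency 1/cutoff.
gaussian_lowpass <- function(x, cutoff, spacing) {
  dm <- dim(x)
  q2 <- freq_sq_grid(dm) / spacing^2        # (1/length)^2
  h <- exp(-2 * q2 * cutoff^2)
  Re(fft(fft(x) * h, inverse = TRUE)) / prod(dm)
}

# Trilinear interpolation of 3D array `vol` at fractional 1-based coordinates
# given as an n x 3 matrix. Points outside return `fill`.
trilinear <- function(vol, pts, fill = 0) {
  dm <- dim(vol)
  x <- pts[, 1]; y <- pts[, 2]; z <- pts[, 3]
  x0 <- floor(x); y0 <- floor(y); z0 <- floor(z)
  fx <- x - x0; fy <- y - y0; fz <- z - z0
  ok <- x0 >= 1 & y0 >= 1 & z0 >= 1 & x0 <= dm[1] - 1 & y0 <= dm[2] - 1 & z0 <= dm[3] - 1
  out <- rep(fill, nrow(pts))
  if (!any(ok)) return(out)
  x0 <- x0[ok]; y0 <- y0[ok]; z0 <- z0[ok]
  fx <- fx[ok]; fy <- fy[ok]; fz <- fz[ok]
  idx <- function(i, j, k) i + (j - 1) * dm[1] + (k - 1) * dm[1] * dm[2]
  v000 <- vol[idx(x0, y0, z0)];     v100 <- vol[idx(x0 + 1, y0, z0)]
  v010 <- vol[idx(x0, y0 + 1, z0)]; v110 <- vol[idx(x0 + 1, y0 + 1, z0)]
  v001 <- vol[idx(x0, y0, z0 + 1)]; v101 <- vol[idx(x0 + 1, y0, z0 + 1)]
  v011 <- vol[idx(x0, y0 + 1, z0 + 1)]; v111 <- vol[idx(x0 + 1, y0 + 1, z0 + 1)]
  out[ok] <-
    v000 * (1 - fx) * (1 - fy) * (1 - fz) + v100 * fx * (1 - fy) * (1 - fz) +
    v010 * (1 - fx) * fy * (1 - fz) + v110 * fx * fy * (1 - fz) +
    v001 * (1 - fx) * (1 - fy) * fz + v101 * fx * (1 - fy) * fz +
    v011 * (1 - fx) * fy * fz + v111 * fx * fy * fz
  out
}

# Bilinear interpolation of 2D array at fractional 1-based coords (n x 2).
bilinear <- function(img, pts, fill = 0) {
  dm <- dim(img)
  x <- pts[, 1]; y <- pts[, 2]
  x0 <- floor(x); y0 <- floor(y)
  fx <- x - x0; fy <- y - y0
  ok <- x0 >= 1 & y0 >= 1 & x0 <= dm[1] - 1 & y0 <= dm[2] - 1
  out <- rep(fill, nrow(pts))
  if (!any(ok)) return(out)
  x0 <- x0[ok]; y0 <- y0[ok]; fx <- fx[ok]; fy <- fy[ok]
  idx <- function(i, j) i + (j - 1) * dm[1]
  out[ok] <-
    img[idx(x0, y0)] * (1 - fx) * (1 - fy) + img[idx(x0 + 1, y0)] * fx * (1 - fy) +
    img[idx(x0, y0 + 1)] * (1 - fx) * fy + img[idx(x0 + 1, y0 + 1)] * fx * fy
  out
}

# Resample 2D image under an affine map: output(x) = image(A %*% (x - c) + c + shift),
# with A a 2x2 matrix and c the image centre (1-based). Used for area matching.
affine_resample2 <- function(img, A, shift = c(0, 0)) {
  dm <- dim(img)
  ctr <- (dm + 1) / 2
  g <- as.matrix(expand.grid(x = seq_len(dm[1]), y = seq_len(dm[2])))
  rel <- sweep(g, 2, ctr)
  src <- rel %*% t(A)
  src <- sweep(src, 2, ctr + shift, `+`)
  matrix(bilinear(img, src), dm[1], dm[2])
}

# Pearson correlation of two arrays, guarding zero variance.
safe_cor <- function(a, b) {
  sa <- stats::sd(a); sb <- stats::sd(b)
  if (sa == 0 || sb == 0) return(0)
  stats::cor(as.vector(a), as.vector(b))
}

# Otsu threshold of a numeric vector (256-bin histogram).
otsu_threshold <- function(x, nbins = 256) {
  r <- range(x, finite = TRUE)
  if (diff(r) == 0) return(r[1])
  br <- seq(r[1], r[2], length.out = nbins + 1)
  h <- tabulate(findInterval(x, br, rightmost.closed = TRUE), nbins)
  p <- h / sum(h)
  mids <- (br[-1] + br[-(nbins + 1)]) / 2
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[nbins]
  sigma_b <- (mu_t * w0 - mu)^2 / (w0 * (1 - w0))
  sigma_b[!is.finite(sigma_b)] <- 0
  mids[which.max(sigma_b)]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Exact (Fourier) shift of a 2D image: output(x) = img(x + s).
fourier_shift2 <- function(img, s) {
  dm <- dim(img)
  px <- exp(2i * pi * fft_freq(dm[1]) * s[1])
  py <- exp(2i * pi * fft_freq(dm[2]) * s[2])
  ph <- outer(px, py)
  Re(fft(fft(img) * ph, inverse = TRUE)) / prod(dm)
}
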