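# Shared fixtures, built once per test run and cached.

.fix <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (is.null(.fix[[name]])) .fix[[name]] <- force(expr)
  .fix[[name]]
}

pseudo_monomer <- function() {
  memo("monomer", read_pdb(system.file("extdata", "pseudo_monomer.pdb",
                                       package = "zdisktomo")))
}

default_model <- function() memo("model", build_zdisk_lattice())

# symmetrized default-phantom map around a lattice point, 7.6 A voxels
channel_map <- function() {
  memo("channel_map", {
    m <- default_model()
    v <- synthesize_density(m, voxel_size = 7.6, resolution = 60,
                            dim = c(73, 73, 129))
    symmetrize_average(v, m$symmetry)
  })
}

# smooth confined random blob volume for projection/alignment tests
blob_volume <- function(n = 40, seed = 11, slab = FALSE) {
  key <- paste0("blob", n, seed, slab)
  memo(key, {
    set.seed(seed)
    raw <- zdisktomo:::gaussian_kernel_filter(array(stats::rnorm(n^3), rep(n, 3)), 1.8)
    if (slab) raw <- sweep(raw, 3, exp(-0.5 * ((1:n - (n + 1) / 2) / 4)^2), `*`)
    density_volume(raw * soft_spherical_mask(rep(n, 3), n / 3, 5), 7.6)
  })
}

# noise-free tomogram of the phantom with ground-truth lattice positions:
# synthesized directly on a grid where lattice points sit on exact nodes
phantom_tomogram <- function() {
  memo("phantom_tomo", {
    m <- default_model()
    synthesize_density(m, voxel_size = 15.2, resolution = 36,
                       dim = c(129, 129, 49))
  })
}

small_pipeline_config <- function(seed = 1, dir = tempfile("zdrun")) {
  cfg <- zd_config(seed = seed, output_dir = dir)
  cfg$simulator$dim <- c(65, 65, 33)
  cfg$simulator$step0 <- 10
  cfg$simulator$max_pos <- 50
  cfg$simulator$max_neg <- 50
  cfg$reconstruction$out_z <- 25
  cfg$averaging$box_size <- 12
  cfg
}

safe_cor_pub <- function(a, b) stats::cor(as.vector(a), as.vector(b))

al_angles <- function(ts) vapply(ts$geometries, `[[`, numeric(1), "tilt_angle")

memo_series_clean <- function() {
  memo("series_clean", {
    v <- blob_volume(48, seed = 11, slab = TRUE)
    simulate_tilt_series(v, seq(-50, 50, by = 5))
  })
}

fftshift3 <- function(x) {
  dm <- dim(x)
  idx <- lapply(1:3, function(a)
    c((floor(dm[a] / 2) + 1):dm[a], 1:floor(dm[a] / 2)))
  x[idx[[1]], idx[[2]], idx[[3]]]
}

# smooth, exactly p321-symmetric Gaussian motif (interpolation-friendly)
smooth_symmetric_motif <- function() {
  memo("sym_motif", {
    grp <- p321_operators()
    base <- rbind(c(40, 15, 25), c(-20, 35, -40))       # Angstrom
    pts <- do.call(rbind, lapply(grp$operators, apply_op, pts = base))
    mod <- atomic_model(pts[, 1], pts[, 2], pts[, 3])
    synthesize_density(mod, voxel_size = 7.6, resolution = 120,
                       dim = c(33, 33, 33))
  })
}
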