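#' Default pipeline configuration
#'
#' Parameter blocks for every stage of the phantom experiment, with the
#' study's geometry as defaults (52 nm hexagonal cell, 120 nm thickness,
#' 80 nm overlap, 11 degree per-trimer rotation; Saxton acquisition with
#' 0.7 e/A^2 per image). The `simulator` block works at a coarsened voxel
#' so the end-to-end run stays desk-scale; the validation measurements are
#' made at the analysis voxel size of 7.6 A.
#'
#' @param seed Master seed; every stochastic stage derives its own seed from
#'   it deterministically.
#' @param output_dir Output directory for artifacts.
#' @return A nested list of class `zd_config`.
#' @export
zd_config <- function(seed = 1, output_dir = file.path(tempdir(), "zdisk_run")) {
  structure(list(
    seed = as.integer(seed),
    output_dir = output_dir,
    phantom = list(cell_edge_a = 52, thickness = 120, overlap = 80,
                   trimer_rotation = 11, n_cells = 3),
    simulator = list(voxel_size = 15.2, resolution = 36,
                     dim = c(129, 129, 65),
                     step0 = 4, max_pos = 60, max_neg = 60,
                     dose = 0.7, damage_rate = 60, snr = 0.3,
                     tilt_azimuth = 0),
    alignment = list(cc_threshold = 0.1, n_passes = 2),
    reconstruction = list(binning = 1, out_z = 49),
    lattice = list(orders_a = 3, orders_b = 5),
    averaging = list(box_size = 20, k = 2, max_iter = 3),
    validation = list(voxel_size = 7.6, resolution = 60,
                      sections = c(-50, 50), contour = 1.15)
  ), class = "zd_config")
}

stage_seed <- function(config, stage) {
  offs <- match(stage, c("simulate", "align", "reconstruct", "pick",
                         "average", "validate"))
  (config$seed %% 1000000L) * 1000L + offs
}

need_artifact <- function(path, stage) {
  if (!file.exists(path))
    stop("missing artifact '", basename(path), "': run stage '", stage,
         "' first", call. = FALSE)
  path
}

write_summary <- function(dir, stage, x) {
  jsonlite::write_json(x, file.path(dir, paste0(stage, "_summary.json")),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE)
}

#' Run pipeline stages
#'
#' Stage-per-subcommand driver for the phantom experiment: `simulate`
#' (phantom + tilt series), `align` (marker-free alignment), `reconstruct`
#' (weighted back-projection with damage truncation), `pick` (lattice fit
#' and subvolume picking), `average` (classification alignment, sixfold
#' expansion, half-series missing-cone average, symmetrization), `validate`
#' (half-set FSC plus structural measurements), or `full` (all of them).
#' Each stage writes its artifacts (MRC volumes, CSV tables, JSON summary)
#' into `config$output_dir` and errors with the name of the missing upstream
#' stage if run out of order. The master seed is logged and every stochastic
#' stage derives its own sub-seed from it, so two runs with the same
#' configuration are bit-identical.
#'
#' @param stage One of "simulate", "align", "reconstruct", "pick",
#'   "average", "validate", "full".
#' @param config A [zd_config()].
#' @return Invisibly, the stage summary list.
#' @export
zd_run <- function(stage = c("full", "simulate", "align", "reconstruct",
                             "pick", "average", "validate"),
                   config = zd_config()) {
  stage <- match.arg(stage)
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  yaml::write_yaml(unclass(config), file.path(config$output_dir, "config.yaml"))
  if (stage == "full") {
    for (s in c("simulate", "align", "reconstruct", "pick", "average",
                "validate"))
      zd_run(s, config)
    return(invisible(jsonlite::read_json(
      file.path(config$output_dir, "validate_summary.json"))))
  }
  out <- switch(stage,
                simulate = stage_simulate(config),
                align = stage_align(config),
                reconstruct = stage_reconstruct(config),
                pick = stage_pick(config),
                average = stage_average(config),
                validate = stage_validate(config))
  write_summary(config$output_dir, stage, out)
  invisible(out)
}

stage_simulate <- function(config) {
  set.seed(stage_seed(config, "simulate"))
  ph <- config$phantom; sm <- config$simulator
  model <- build_zdisk_lattice(cell_edge_a = ph$cell_edge_a,
                               thickness = ph$thickness, overlap = ph$overlap,
                               trimer_rotation = ph$trimer_rotation,
                               n_cells = ph$n_cells)
  vol <- synthesize_density(model, voxel_size = sm$voxel_size,
                            resolution = sm$resolution, dim = sm$dim)
  ang <- saxton_angles(sm$step0, sm$max_pos, sm$max_neg)
  ts <- simulate_tilt_series(vol, ang, tilt_azimuth = sm$tilt_azimuth,
                             dose_per_image = sm$dose)
  ts <- apply_dose_and_damage(ts, damage_rate = sm$damage_rate, snr = sm$snr)
  d <- config$output_dir
  write_mrc(vol, file.path(d, "phantom.mrc"))
  write_mrc(ts$images, file.path(d, "tilt_series.mrc"), voxel_size = sm$voxel_size)
  utils::write.csv(cbind(ang, dose = sm$dose),
                   file.path(d, "tilt_metadata.csv"), row.names = FALSE)
  saveRDS(list(model = model, series = ts), file.path(d, "simulate.rds"))
  list(seed = config$seed, n_images = nrow(ang),
       obliquity_deg = model$obliquity,
       tilt_range = range(ang$angle), voxel_size = sm$voxel_size)
}

stage_align <- function(config) {
  d <- config$output_dir
  sim <- readRDS(need_artifact(file.path(d, "simulate.rds"), "simulate"))
  al <- align_tilt_series(sim$series, cc_threshold = config$alignment$cc_threshold,
                          n_passes = config$alignment$n_passes)
  retained <- truncate_damaged(al$records, config$alignment$cc_threshold)
  utils::write.csv(al$records, file.path(d, "alignment_report.csv"),
                   row.names = FALSE)
  saveRDS(list(alignment = al, retained = retained),
          file.path(d, "align.rds"))
  list(n_images = nrow(al$records), n_retained = length(retained),
       cc_range = range(al$records$cc_peak, na.rm = TRUE))
}

stage_reconstruct <- function(config) {
  d <- config$output_dir
  sim <- readRDS(need_artifact(file.path(d, "simulate.rds"), "simulate"))
  al <- readRDS(need_artifact(file.path(d, "align.rds"), "align"))
  bin <- config$reconstruction$binning
  dmi <- dim(sim$series$images)[1:2] %/% bin
  out_size <- c(dmi, config$reconstruction$out_z)
  tomo <- weighted_back_projection(sim$series, geometries = al$alignment$geometries,
                                   out_size = out_size, binning = bin,
                                   include = al$retained)
  write_mrc(tomo, file.path(d, "tomogram.mrc"))
  saveRDS(tomo, file.path(d, "reconstruct.rds"))
  list(dim = dim(tomo$data), voxel_size = tomo$voxel_size,
       n_images_used = length(al$retained))
}

stage_pick <- function(config) {
  d <- config$output_dir
  tomo <- readRDS(need_artifact(file.path(d, "reconstruct.rds"), "reconstruct"))
  ctrz <- round((dim(tomo$data)[3] + 1) / 2)
  # average the power spectra of a few central sections; bound the spacing
  # search around the expected intermyofilament scale
  dm2 <- dim(tomo$data)[1:2]
  npad <- 4 * 2^ceiling(log2(max(dm2)))       # zero-pad: finer reciprocal bins
  han <- outer(0.5 * (1 - cos(2 * pi * (seq_len(dm2[1]) - 1) / (dm2[1] - 1))),
               0.5 * (1 - cos(2 * pi * (seq_len(dm2[2]) - 1) / (dm2[2] - 1))))
  ps <- 0
  for (kz in (ctrz - 2):(ctrz + 2)) {
    pad <- matrix(0, npad, npad)
    pad[seq_len(dm2[1]), seq_len(dm2[2])] <- tomo$data[, , kz] * han
    ps <- ps + Mod(stats::fft(pad))^2
  }
  lat <- fit_reciprocal_lattice(ps, tomo$voxel_size,
                                min_spacing_nm = 25,
                                max_spacing_nm = 1.2 * config$phantom$cell_edge_a)
  lat$orders_a <- config$lattice$orders_a
  lat$orders_b <- config$lattice$orders_b
  b <- config$averaging$box_size
  ctr <- round((dim(tomo$data) + 1) / 2)
  ref <- tomo$data[ctr[1] - b / 2 + seq_len(b) - 1,
                   ctr[2] - b / 2 + seq_len(b) - 1,
                   ctr[3] - b / 2 + seq_len(b) - 1]
  ccm <- cc_map(tomo, ref)
  picks <- pick_lattice_points(ccm, lat, edge_margin = b / 2)
  utils::write.csv(picks, file.path(d, "picks.csv"), row.names = FALSE)
  saveRDS(list(lattice = lat, picks = picks), file.path(d, "pick.rds"))
  list(cell_edge_nm = lat$cell_edge_nm, gamma = lat$gamma,
       n_kept = sum(picks$status == "kept"),
       n_total = nrow(picks), euler_in_plane = initial_euler(lat))
}

stage_average <- function(config) {
  d <- config$output_dir
  sim <- readRDS(need_artifact(file.path(d, "simulate.rds"), "simulate"))
  al <- readRDS(need_artifact(file.path(d, "align.rds"), "align"))
  tomo <- readRDS(need_artifact(file.path(d, "reconstruct.rds"), "reconstruct"))
  pk <- readRDS(need_artifact(file.path(d, "pick.rds"), "pick"))
  av <- config$averaging
  set.seed(stage_seed(config, "average"))
  grp <- p321_operators(config$phantom$cell_edge_a)
  subs <- extract_subvolumes(tomo, pk$picks, av$box_size)
  subs <- align_by_classification(subs, k = min(av$k, length(subs)),
                                  max_iter = av$max_iter)
  expanded <- symmetry_expand(subs, grp)
  half <- recompute_half_series_average(
    sim$series, expanded, geometries = al$alignment$geometries, group = grp,
    out_size = dim(tomo$data), binning = config$reconstruction$binning)
  symm <- symmetrize_average(half$average, grp)
  utils::write.csv(expanded$meta, file.path(d, "subvolumes.csv"),
                   row.names = FALSE)
  write_mrc(average_subvolumes(subs), file.path(d, "average_raw.mrc"))
  write_mrc(half$average, file.path(d, "average_halfseries.mrc"))
  write_mrc(symm, file.path(d, "average_symmetrized.mrc"))
  saveRDS(list(subs = subs, expanded = expanded, half = half, symm = symm),
          file.path(d, "average.rds"))
  list(n_subvolumes = length(subs), n_expanded = length(expanded),
       expansion_factor = length(expanded) / length(subs),
       coverage_kind = half$coverage$kind)
}

stage_validate <- function(config) {
  d <- config$output_dir
  tomo <- readRDS(need_artifact(file.path(d, "reconstruct.rds"), "reconstruct"))
  pk <- readRDS(need_artifact(file.path(d, "pick.rds"), "pick"))
  avg <- readRDS(need_artifact(file.path(d, "average.rds"), "average"))
  va <- config$validation
  grp <- p321_operators(config$phantom$cell_edge_a)
  hs <- tryCatch(half_set_protocol(
    tomo, pk$picks, group = grp, seed = stage_seed(config, "validate"),
    box_size = config$averaging$box_size, k = config$averaging$k,
    max_iter = 1), error = function(e) NULL)
  res <- if (is.null(hs)) NA_real_ else as.numeric(hs)
  # structural measurements on the phantom at the analysis voxel size
  model <- readRDS(file.path(d, "simulate.rds"))$model
  chan_vol <- synthesize_density(model, voxel_size = va$voxel_size,
                                 resolution = va$resolution,
                                 dim = c(73, 73, 129))
  chan_sym <- symmetrize_average(chan_vol, grp)
  rot <- channel_rotation(chan_sym, va$sections[1], va$sections[2],
                          cell_edge_a = config$phantom$cell_edge_a)
  at <- zdisk_atoms(model, xy_range = 26)
  thick_vol <- synthesize_density(at, voxel_size = va$voxel_size,
                                  resolution = 30, dim = c(97, 97, 181))
  pick_sub <- function(df, sel) { x <- df[sel, ]; class(x) <- class(df); x }
  ga <- synthesize_density(pick_sub(at, at$group == "A" & at$component == "filament"),
                           va$voxel_size, 30, c(97, 97, 181))
  gb <- synthesize_density(pick_sub(at, at$group == "B" & at$component == "filament"),
                           va$voxel_size, 30, c(97, 97, 181))
  ext <- measure_axial_extent(thick_vol, 0.5, group_maps = list(ga, gb),
                              window_fraction = 0.5)
  fc <- filter_and_contour(chan_sym, va$resolution + 1e-9, va$contour)
  out <- list(half_map_resolution_A = res,
              channel_rotation_deg = as.numeric(rot),
              thickness_nm = ext$thickness_nm,
              overlap_nm = ext$overlap_nm,
              cell_edge_nm = pk$lattice$cell_edge_nm,
              coverage_kind = avg$half$coverage$kind,
              contour_enclosed_nm3 = fc$enclosed_volume_nm3)
  fc_curve <- if (is.null(hs)) NULL else attr(hs, "fsc")
  utils::write.csv(
    data.frame(freq = fc_curve$freq %||% numeric(0),
               corr = fc_curve$corr %||% numeric(0)),
    file.path(d, "fsc.csv"), row.names = FALSE)
  out
}
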