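# Parametric Z-disk phantom: a hexagonal two-sided p321 lattice (cell edge
# 52 nm) of oblique antiparallel F-actin trimers centred on the two trigonal
# positions, with alpha-actinin-like cross-link rods and trigonal-channel
# plug density toward the disk faces. All geometry is in nm; emitted atom
# models are in Angstrom.

# In-plane geometry of the asymmetric-unit filament at height z (nm).
# Returns the 2D position of the filament axis. The filament is a straight
# line: anchor (at z = 0) plus an in-plane velocity v per unit z.
asym_filament_geom <- function(cell_edge_a, trimer_radius, anchor_azimuth,
                               velocity_azimuth, obliquity) {
  t_site <- c(0, cell_edge_a / sqrt(3))              # trigonal position (1/3, 2/3)
  a0 <- (-90 + anchor_azimuth) * pi / 180            # from the site toward the lattice point
  rhat <- c(cos(a0), sin(a0))
  that <- c(-rhat[2], rhat[1])
  p0 <- t_site + trimer_radius * rhat
  chi <- velocity_azimuth * pi / 180
  v <- tan(obliquity * pi / 180) * (-cos(chi) * rhat + sin(chi) * that)
  list(site = t_site, anchor = p0, v = v, rhat = rhat, that = that)
}

# Rotation of the asymmetric filament's azimuth about the lattice point,
# from z = 0 to z (deg). This is the trimer profile rotation "referred to
# the large channel": the angular displacement of the channel-bounding
# filament as seen from the channel centre.
referred_rotation <- function(z, cell_edge_a, trimer_radius, anchor_azimuth,
                              velocity_azimuth, obliquity) {
  g <- asym_filament_geom(cell_edge_a, trimer_radius, anchor_azimuth,
                          velocity_azimuth, obliquity)
  p <- g$anchor + g$v * z
  wrap_angle(angle2d(p) - angle2d(g$anchor))
}

#' Calibrate the filament obliquity from the per-trimer profile rotation
#'
#' The obliquity (tilt of the filament axis from the myofibril axis) is not a
#' directly observed quantity; what is observed is the rotation of the trimer
#' profile through the disk. This routine inverts the phantom geometry: it
#' finds the obliquity for which the filament azimuth about the lattice
#' point rotates by `trimer_rotation` degrees between the central plane and
#' the edge of the antiparallel overlap region (z = overlap/2).
#'
#' @param trimer_rotation Target per-trimer profile rotation in degrees.
#' @param cell_edge_a Unit-cell edge (nm).
#' @param overlap Antiparallel filament overlap (nm).
#' @param trimer_radius Filament distance from the trimer axis (nm).
#' @param anchor_azimuth Azimuthal offset of the filament anchor from the
#'   site-to-lattice-point direction (deg); breaks the accidental sixfold of
#'   the channel wall so the channel profile is genuinely triangular.
#' @param velocity_azimuth Direction of the filament's in-plane drift,
#'   measured from the inward radial direction toward the tangential (deg).
#' @return Obliquity in degrees.
#' @export
calibrate_obliquity <- function(trimer_rotation, cell_edge_a = 52, overlap = 80,
                                trimer_radius = 12, anchor_azimuth = 25,
                                velocity_azimuth = -50) {
  if (trimer_rotation == 0) return(0)
  f <- function(alpha) {
    referred_rotation(overlap / 2, cell_edge_a, trimer_radius, anchor_azimuth,
                      velocity_azimuth, alpha) - trimer_rotation
  }
  stats::uniroot(f, c(1e-4, 45), tol = 1e-8)$root
}

#' Build the parametric Z-disk lattice model
#'
#' Places two antiparallel groups of three oblique filaments on the trigonal
#' positions of each hexagonal unit cell, related exactly by the six p321
#' site-symmetry operators: the whole model is generated by expanding a
#' single asymmetric-unit filament (plus its cross-link rods and trigonal
#' plug column) under the group, so the symmetry holds by construction. One
#' group's filaments converge toward +z (their convergence point, where the
#' extrapolated axes meet the trimer axis, lies above the disk face at the
#' thick-filament position of the neighbouring A-band lattice), the other
#' toward -z.
#'
#' @param cell_edge_a Hexagonal unit-cell edge (nm).
#' @param thickness Full disk thickness (nm).
#' @param overlap Axial extent of the antiparallel overlap (nm);
#'   `0 < overlap <= thickness`.
#' @param obliquity Filament axis tilt from z in degrees, or `NULL` to
#'   calibrate it from `trimer_rotation` via [calibrate_obliquity()].
#' @param n_cells Number of unit-cell rings kept around the origin when
#'   realising atoms (the disc radius is `n_cells * cell_edge_a`).
#' @param trimer_rotation Per-trimer profile rotation (deg) used when
#'   `obliquity` is `NULL`.
#' @param trimer_radius,anchor_azimuth,velocity_azimuth Trimer geometry, see
#'   [calibrate_obliquity()].
#' @return An object of class `zdisk_lattice_model`.
#' @export
build_zdisk_lattice <- function(cell_edge_a = 52, thickness = 120, overlap = 80,
                                obliquity = NULL, n_cells = 3,
                                trimer_rotation = 11, trimer_radius = 12,
                                anchor_azimuth = 25, velocity_azimuth = -50) {
  if (cell_edge_a <= 0) stop("cell_edge_a must be positive")
  if (overlap <= 0 || overlap > thickness) stop("need 0 < overlap <= thickness")
  if (is.null(obliquity)) {
    obliquity <- calibrate_obliquity(trimer_rotation, cell_edge_a, overlap,
                                     trimer_radius, anchor_azimuth, velocity_azimuth)
  }
  geom <- asym_filament_geom(cell_edge_a, trimer_radius, anchor_azimuth,
                             velocity_azimuth, obliquity)
  # no filament crossing inside a trimer: the extrapolated convergence point
  # (radius about the trimer axis -> 0) must lie beyond the disk face
  radial_rate <- -sum(geom$v * geom$rhat)            # nm inward per nm of z
  if (radial_rate > 0 && trimer_radius / radial_rate <= thickness / 2)
    stop("obliquity too steep: filaments cross inside the trimer within the disk")
  sym <- p321_operators(cell_edge_a)
  model <- structure(list(
    cell_edge_a = cell_edge_a, gamma = 120, thickness = thickness,
    overlap = overlap, obliquity = obliquity, trimer_rotation = trimer_rotation,
    trimer_radius = trimer_radius, anchor_azimuth = anchor_azimuth,
    velocity_azimuth = velocity_azimuth, n_cells = n_cells,
    symmetry = sym, helix = helical_params(),
    crosslink = list(seam_spacing = 1, seam_halfwidth = 1.2, weight = 2.6),
    plug = list(z_start = 23, atom_spacing = 2, weight = 32)
  ), class = "zdisk_lattice_model")
  model$filaments <- zdisk_filaments(model)
  model
}

#' @export
print.zdisk_lattice_model <- function(x, ...) {
  cat(sprintf(paste0(
    "zdisk_lattice_model: p321, cell edge %.1f nm, thickness %.0f nm, ",
    "overlap %.0f nm\n  obliquity %.3f deg (trimer rotation %.1f deg), ",
    "6 filaments/cell in two antiparallel trimers\n"),
    x$cell_edge_a, x$thickness, x$overlap, x$obliquity, x$trimer_rotation))
  invisible(x)
}

# Hexagonal lattice translation vectors (nm) within a radius.
lattice_translations <- function(cell_edge_a, radius) {
  a1 <- cell_edge_a * c(1, 0)
  a2 <- cell_edge_a * c(-1 / 2, sqrt(3) / 2)
  nmax <- ceiling(radius / cell_edge_a) + 1
  g <- expand.grid(i = -nmax:nmax, j = -nmax:nmax)
  t(apply(g, 1, function(ij) ij[1] * a1 + ij[2] * a2))
}

#' Filament instances of one unit cell
#'
#' Expands the asymmetric-unit filament under the six p321 operators and
#' reduces anchors into the home cell, giving the six filaments per unit
#' cell: two antiparallel groups of three centred on the trigonal positions.
#'
#' @param model A `zdisk_lattice_model`.
#' @return A data frame with anchor (nm, at z = 0), in-plane velocity
#'   (nm per nm of z), axial span, polarity and group columns.
#' @export
zdisk_filaments <- function(model) {
  g <- asym_filament_geom(model$cell_edge_a, model$trimer_radius,
                          model$anchor_azimuth, model$velocity_azimuth,
                          model$obliquity)
  half <- model$thickness / 2
  zmin <- -model$overlap / 2; zmax <- half     # asymmetric unit: plus toward +z
  rows <- lapply(seq_along(model$symmetry$operators), function(i) {
    op <- model$symmetry$operators[[i]]
    flips <- op$R[3, 3] < 0
    # image of the line p(z) = (anchor + v z, z) under the operator,
    # re-parametrised by global z
    A2 <- op$R[1:2, 1:2]
    anc <- as.vector(A2 %*% g$anchor)
    vel <- as.vector(A2 %*% g$v) * (if (flips) -1 else 1)
    data.frame(op = i, anchor_x = anc[1], anchor_y = anc[2],
               vx = vel[1], vy = vel[2],
               zmin = if (flips) -zmax else zmin,
               zmax = if (flips) -zmin else zmax,
               polarity = if (flips) "plus-toward-negative-z" else "plus-toward-positive-z",
               group = if (flips) "B" else "A")
  })
  fil <- do.call(rbind, rows)
  # reduce anchors into the home cell for readability (site A or B)
  fil
}

# Atoms (nm coordinates) of the asymmetric unit: one helical filament, its
# cross-link rods and the trigonal plug column. Returned as a list of
# position matrix, weights and labels.
asym_unit_atoms_nm <- function(model) {
  g <- asym_filament_geom(model$cell_edge_a, model$trimer_radius,
                          model$anchor_azimuth, model$velocity_azimuth,
                          model$obliquity)
  zmin <- -model$overlap / 2; zmax <- model$thickness / 2
  # Filaments are rendered as smooth rods (an axial line plus a static
  # three-point cross-section ring of radius 2.2 nm): at the 30-60 A
  # resolutions this phantom serves, helical substructure is invisible and
  # would only inject a z-dependent nuisance into section profiles.
  zs <- seq(zmin, zmax, by = 1)
  ctr <- cbind(g$anchor[1] + g$v[1] * zs, g$anchor[2] + g$v[2] * zs, zs)
  ring_az <- c(0, 120, 240) * pi / 180
  pos <- ctr
  for (az in ring_az)
    pos <- rbind(pos, sweep(ctr, 2, 2.2 * c(cos(az), sin(az), 0), `+`))
  w <- c(rep(2, length(zs)), rep(1, 3 * length(zs)))
  lab <- rep("filament", nrow(pos))
  # cross-link seam: continuous connecting density (alpha-actinin plus
  # unassigned linkers) between this filament and its nearest antiparallel
  # neighbour, running the full length of the overlap region midway across
  # the gap; modelled as a thin ribbon of pseudo-atoms
  cl <- model$crosslink
  fil <- model$filaments
  trans <- lattice_translations(model$cell_edge_a, 2.5 * model$cell_edge_a)
  best <- NULL; bestd <- Inf
  for (r in seq_len(nrow(fil))) {
    if (fil$group[r] != "B") next
    base <- c(fil$anchor_x[r], fil$anchor_y[r])
    for (tt in seq_len(nrow(trans))) {
      anc <- base + trans[tt, ]
      d <- sqrt(sum((anc - g$anchor)^2))
      if (d > 1e-6 && d < bestd) {
        bestd <- d
        best <- list(anchor = anc, v = c(fil$vx[r], fil$vy[r]))
      }
    }
  }
  zseam <- seq(-model$overlap / 2, model$overlap / 2, by = cl$seam_spacing)
  p_self <- cbind(g$anchor[1] + g$v[1] * zseam, g$anchor[2] + g$v[2] * zseam)
  p_part <- cbind(best$anchor[1] + best$v[1] * zseam, best$anchor[2] + best$v[2] * zseam)
  mid <- (p_self + p_part) / 2
  gapdir <- (p_part - p_self) / sqrt(rowSums((p_part - p_self)^2))
  seam <- rbind(cbind(mid + cl$seam_halfwidth * gapdir, zseam),
                cbind(mid - cl$seam_halfwidth * gapdir, zseam))
  pos <- rbind(pos, seam)
  w <- c(w, rep(cl$weight, nrow(seam)))
  lab <- c(lab, rep("crosslink", nrow(seam)))
  # trigonal plug column: density filling the small channel toward the face
  pg <- model$plug
  zp <- seq(pg$z_start, model$thickness / 2, by = pg$atom_spacing)
  plug <- cbind(g$site[1], g$site[2], zp)
  pos <- rbind(pos, plug)
  w <- c(w, rep(pg$weight, length(zp)))
  lab <- c(lab, rep("plug", length(zp)))
  list(pos = pos, w = w, lab = lab)
}

#' Realise the Z-disk lattice model as a pseudo-atom cloud
#'
#' Generates atoms for every copy of the asymmetric unit whose anchor lies
#' within `xy_range` nm of the origin, expanded under the six p321 operators.
#' Because the operators are applied to the complete translated set (with a
#' rotation-invariant radius cut), the returned cloud is exactly
#' p321-symmetric.
#'
#' @param model A `zdisk_lattice_model`.
#' @param xy_range Disc radius (nm) of the realised phantom; defaults to
#'   `n_cells * cell_edge_a`.
#' @param include_crosslinks Include cross-link rods and plug columns.
#' @return An `atomic_model` (Angstrom) with `weight`, `component`, `group`
#'   and `filament_op` columns.
#' @export
zdisk_atoms <- function(model, xy_range = NULL, include_crosslinks = TRUE) {
  xy_range <- xy_range %||% (model$n_cells * model$cell_edge_a)
  au <- asym_unit_atoms_nm(model)
  if (!include_crosslinks) {
    keep <- au$lab == "filament"
    au$pos <- au$pos[keep, , drop = FALSE]; au$w <- au$w[keep]; au$lab <- au$lab[keep]
  }
  g <- asym_filament_geom(model$cell_edge_a, model$trimer_radius,
                          model$anchor_azimuth, model$velocity_azimuth,
                          model$obliquity)
  trans <- lattice_translations(model$cell_edge_a, xy_range + model$cell_edge_a)
  anchors <- sweep(trans, 2, g$anchor, `+`)
  keep_t <- sqrt(rowSums(anchors^2)) <= xy_range
  trans <- trans[keep_t, , drop = FALSE]
  n_au <- nrow(au$pos)
  n_t <- nrow(trans)
  # translate the asymmetric unit to every kept cell
  pos_t <- au$pos[rep(seq_len(n_au), n_t), ]
  pos_t[, 1] <- pos_t[, 1] + rep(trans[, 1], each = n_au)
  pos_t[, 2] <- pos_t[, 2] + rep(trans[, 2], each = n_au)
  w_t <- rep(au$w, n_t)
  lab_t <- rep(au$lab, n_t)
  # expand under the group
  out <- vector("list", length(model$symmetry$operators))
  for (i in seq_along(model$symmetry$operators)) {
    op <- model$symmetry$operators[[i]]
    out[[i]] <- data.frame(
      pos_t %*% t(op$R), weight = w_t, component = lab_t,
      group = if (op$R[3, 3] > 0) "A" else "B", filament_op = i)
  }
  out <- do.call(rbind, out)
  names(out)[1:3] <- c("x", "y", "z")
  out$x <- out$x * 10; out$y <- out$y * 10; out$z <- out$z * 10  # nm -> A
  out$element <- "C"
  class(out) <- c("atomic_model", "data.frame")
  out
}
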