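#' Atomic (or pseudo-atomic) model
#'
#' A light container for point models: a data frame with coordinates in
#' Angstrom (`x`, `y`, `z`), an `element` label, and optional annotation
#' columns (`subunit`, `component`, `group`). Real atomic models read from PDB
#' files and synthetic pseudo-atom models are represented identically, so the
#' density synthesis and model-building code never needs a real structure.
#'
#' @param x,y,z Coordinates in Angstrom.
#' @param element Element or pseudo-atom labels (recycled).
#' @param ... Further annotation columns (recycled).
#' @return An object of class `atomic_model` (a data frame).
#' @export
atomic_model <- function(x, y, z, element = "C", ...) {
  df <- data.frame(x = x, y = y, z = z, element = element, ...)
  class(df) <- c("atomic_model", "data.frame")
  df
}

#' @export
print.atomic_model <- function(x, ...) {
  cat(sprintf("atomic_model: %d atoms", nrow(x)))
  if (!is.null(x$subunit)) cat(sprintf(", %d subunits", length(unique(x$subunit))))
  if (!is.null(x$component)) cat(sprintf(", components: %s",
                                         paste(unique(x$component), collapse = ", ")))
  cat("\n")
  invisible(x)
}

coords_matrix <- function(model) as.matrix(model[, c("x", "y", "z")])

#' Read an atomic model from a PDB file
#'
#' Thin wrapper over [bio3d::read.pdb()] returning the package's
#' `atomic_model` container (coordinates in Angstrom, element symbols and
#' chain identifiers preserved).
#'
#' @param path Path to a PDB file.
#' @return An `atomic_model`.
#' @export
read_pdb <- function(path) {
  pdb <- bio3d::read.pdb(path)
  at <- pdb$atom
  if (nrow(at) == 0) stop("no ATOM records in ", path)
  elem <- at$elesy
  if (all(is.na(elem) | elem == "")) elem <- substr(trimws(at$elety), 1, 1)
  atomic_model(at$x, at$y, at$z, element = elem, chain = at$chain)
}

#' Write an atomic model to a PDB file
#'
#' @param model An `atomic_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(model, path) {
  n <- nrow(model)
  bio3d::write.pdb(
    file = path,
    xyz = as.vector(t(coords_matrix(model))),
    resno = if (!is.null(model$subunit)) model$subunit else rep(1L, n),
    chain = if (!is.null(model$chain)) model$chain else rep("A", n),
    elety = rep("CA", n),
    resid = rep("GLY", n)
  )
  invisible(path)
}

#' Helical symmetry parameters
#'
#' Describes an N/T helix: `subunits_per_repeat` subunits completing
#' `turns_per_repeat` full turns, with a per-subunit axial rise. The
#' per-subunit twist is `turns_per_repeat * 360 / subunits_per_repeat`
#' degrees, negated for a left-handed genetic helix. The F-actin default is
#' the 28/13 helix with a 27.5 Angstrom rise, so that the same-strand axial
#' spacing (every second subunit) is 55 Angstrom.
#'
#' @param subunits_per_repeat Integer > 0.
#' @param turns_per_repeat Integer > 0.
#' @param rise_per_subunit Axial rise per subunit in Angstrom.
#' @param handedness `"left"` or `"right"`.
#' @return An object of class `helical_params`.
#' @export
helical_params <- function(subunits_per_repeat = 28L, turns_per_repeat = 13L,
                           rise_per_subunit = 27.5,
                           handedness = c("left", "right")) {
  handedness <- match.arg(handedness)
  if (subunits_per_repeat < 1) stop("subunits_per_repeat must be positive")
  if (turns_per_repeat < 1) stop("turns_per_repeat must be positive")
  twist <- turns_per_repeat * 360 / subunits_per_repeat
  structure(list(
    subunits_per_repeat = as.integer(subunits_per_repeat),
    turns_per_repeat = as.integer(turns_per_repeat),
    rise_per_subunit = rise_per_subunit,
    handedness = handedness,
    twist_per_subunit = if (handedness == "left") -twist else twist
  ), class = "helical_params")
}

#' @export
print.helical_params <- function(x, ...) {
  cat(sprintf("%d/%d helix, rise %.2f A, twist %+.3f deg/subunit (%s-handed)\n",
              x$subunits_per_repeat, x$turns_per_repeat, x$rise_per_subunit,
              x$twist_per_subunit, x$handedness))
  invisible(x)
}

#' Build a helical filament model from a monomer
#'
#' Generates `n_subunits` copies of `monomer`, copy k (k = 0, ..., n-1)
#' rotated by k times the per-subunit twist about the +z helix axis and
#' translated by k times the rise along it. With the default 28/13 actin
#' parameters, 28 subunits complete exactly 13 turns (cumulative twist = 0
#' mod 360) and span one full helical repeat.
#'
#' @param monomer An `atomic_model` of the monomer (any pseudo-monomer works).
#' @param params A [helical_params()] object.
#' @param n_subunits Number of subunits (>= 1).
#' @return An `atomic_model` with a `subunit` column (1-based).
#' @export
build_factin_model <- function(monomer, params = helical_params(), n_subunits = 28L) {
  if (n_subunits < 1) stop("n_subunits must be >= 1")
  if (nrow(monomer) == 0) stop("monomer model is empty")
  xy <- coords_matrix(monomer)
  pieces <- lapply(seq_len(n_subunits) - 1L, function(k) {
    R <- rot_axis("z", k * params$twist_per_subunit)
    p <- xy %*% t(R)
    p[, 3] <- p[, 3] + k * params$rise_per_subunit
    data.frame(x = p[, 1], y = p[, 2], z = p[, 3],
               element = monomer$element, subunit = k + 1L)
  })
  out <- do.call(rbind, pieces)
  class(out) <- c("atomic_model", "data.frame")
  out
}
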