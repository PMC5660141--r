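#' Symmetry group of rigid point operations
#'
#' A list of rigid transforms (3x3 proper rotation `R` plus translation `t`)
#' closed under composition. For the Z-disk the relevant group is the site
#' symmetry 32 of the two-sided plane group p321 at a lattice point: identity,
#' in-plane threefold rotations about z, and three twofold rotations about
#' in-plane axes parallel to the unit-cell edge directions, which invert z.
#'
#' @param operators List of `list(R = <3x3>, t = <length-3>)`.
#' @param group_name Text label.
#' @return An object of class `symmetry_group`.
#' @export
symmetry_group <- function(operators, group_name = "") {
  for (op in operators) {
    if (abs(det(op$R) - 1) > 1e-8) stop("operator rotation must have determinant +1")
  }
  structure(list(operators = operators, group_name = group_name),
            class = "symmetry_group")
}

#' @export
length.symmetry_group <- function(x) length(x$operators)

#' @export
print.symmetry_group <- function(x, ...) {
  cat(sprintf("symmetry_group '%s': order %d\n", x$group_name, length(x$operators)))
  invisible(x)
}

#' Point-group operators of p321 at a lattice point
#'
#' Returns the six site-symmetry operations of the two-sided plane group p321
#' about a lattice point at the origin: identity, rotations by 120 and 240
#' degrees about z, and three 180-degree rotations about in-plane axes
#' parallel to the three unit-cell edge directions (at 0, 60 and 120 degrees
#' from +x, with the a axis along +x). The in-plane twofolds invert z and so
#' relate the two faces of the disk.
#'
#' @param cell_edge_a Unit-cell edge in nm (recorded; the point operators are
#'   independent of scale).
#' @return A [symmetry_group()] of order 6.
#' @export
p321_operators <- function(cell_edge_a = 52) {
  if (cell_edge_a <= 0) stop("cell_edge_a must be positive")
  ops <- c(
    lapply(c(0, 120, 240), function(a) list(R = rot_axis("z", a), t = c(0, 0, 0))),
    lapply(c(0, 60, 120), function(a) {
      u <- c(cos(a * pi / 180), sin(a * pi / 180), 0)
      list(R = rot_about(u, 180), t = c(0, 0, 0))
    })
  )
  g <- symmetry_group(ops, "p321 site symmetry 32")
  g$cell_edge_a <- cell_edge_a
  g
}

#' Compose two rigid operators
#' @param a,b Operators as `list(R, t)`; returns a then b applied after a
#'   (i.e. x -> b(a(x))).
#' @return Composed operator.
#' @export
compose_ops <- function(b, a) {
  list(R = b$R %*% a$R, t = as.vector(b$R %*% a$t) + b$t)
}

#' Apply a rigid operator to points
#' @param op Operator `list(R, t)`.
#' @param pts n x 3 matrix.
#' @return Transformed n x 3 matrix.
#' @export
apply_op <- function(op, pts) {
  sweep(pts %*% t(op$R), 2, op$t, `+`)
}

op_equal <- function(a, b, tol = 1e-8) {
  max(abs(a$R - b$R)) < tol && max(abs(a$t - b$t)) < tol
}

#' Verify group closure
#'
#' Checks that the operator set contains the identity, is closed under
#' composition, and contains no duplicates.
#'
#' @param group A [symmetry_group()].
#' @return `TRUE` (or an error describing the failure).
#' @export
verify_group_closure <- function(group) {
  ops <- group$operators
  id <- list(R = diag(3), t = c(0, 0, 0))
  if (!any(vapply(ops, op_equal, logical(1), b = id))) stop("group lacks identity")
  n <- length(ops)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i < j && op_equal(ops[[i]], ops[[j]])) stop("duplicate operators ", i, ",", j)
    comp <- compose_ops(ops[[i]], ops[[j]])
    if (!any(vapply(ops, op_equal, logical(1), b = comp)))
      stop("composition ", i, " o ", j, " falls outside the group")
  }
  TRUE
}
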