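#' Rotation-translation operators
#'
#' A proper rigid-body operator `y = R x + t` with `R` orthonormal and
#' `det(R) = +1` (checked to 1e-8).
#'
#' @param rotation 3 x 3 rotation matrix
#' @param translation length-3 translation, Angstrom
#' @return an object of class `rt_op`
#' @export
rt_op <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  stopifnot(all(dim(rotation) == c(3, 3)), length(translation) == 3)
  check_rotation(rotation)
  structure(list(R = rotation, t = as.numeric(translation)), class = "rt_op")
}

check_rotation <- function(R, tol = 1e-8) {
  if (max(abs(crossprod(R) - diag(3))) > tol || abs(det(R) - 1) > tol)
    stop("rotation must be proper orthonormal (det +1) within 1e-8")
  invisible(TRUE)
}

#' @export
print.rt_op <- function(x, ...) {
  ang <- rotation_angle(x$R)
  cat(sprintf("<rt_op> rotation %.3f deg, translation (%.3f, %.3f, %.3f)\n",
              ang, x$t[1], x$t[2], x$t[3]))
  invisible(x)
}

#' Identity operator
#' @export
rt_identity <- function() rt_op()

#' Apply an operator to coordinates
#' @param op an [rt_op()]
#' @param coords n x 3 matrix (or length-3 vector)
#' @return transformed coordinates, same shape
#' @export
apply_rt <- function(op, coords) {
  stopifnot(inherits(op, "rt_op"))
  vec <- is.null(dim(coords))
  if (vec) coords <- matrix(coords, 1, 3)
  out <- coords %*% t(op$R) + matrix(op$t, nrow(coords), 3, byrow = TRUE)
  if (vec) drop(out) else out
}

#' Apply an operator to a model's coordinates
#' @param op an [rt_op()]
#' @param model an [atomic_model()]
#' @export
apply_rt_model <- function(op, model) {
  model_coords(model) <- apply_rt(op, model_coords(model))
  model
}

#' Compose two operators: `(a %rt% b)(x) = a(b(x))`
#' @param a,b [rt_op()] objects
#' @export
rt_compose <- function(a, b) {
  rt_op(a$R %*% b$R, as.numeric(a$R %*% b$t) + a$t)
}

#' Invert an operator
#' @param op an [rt_op()]
#' @export
rt_invert <- function(op) rt_op(t(op$R), -as.numeric(t(op$R) %*% op$t))

#' Net rotation angle of a rotation matrix, degrees
#' @param R 3 x 3 rotation matrix
#' @export
rotation_angle <- function(R) {
  acos(max(-1, min(1, (sum(diag(R)) - 1) / 2))) * 180 / pi
}

rot_x <- function(a) { a <- a * pi / 180
  matrix(c(1, 0, 0, 0, cos(a), sin(a), 0, -sin(a), cos(a)), 3, 3) }
rot_y <- function(a) { a <- a * pi / 180
  matrix(c(cos(a), 0, -sin(a), 0, 1, 0, sin(a), 0, cos(a)), 3, 3) }
rot_z <- function(a) { a <- a * pi / 180
  matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3) }

#' Rotation matrix about an arbitrary axis
#' @param axis rotation axis (any length, normalized internally)
#' @param angle_deg rotation angle, degrees
#' @return 3 x 3 rotation matrix
#' @export
axis_rotation <- function(axis, angle_deg) {
  u <- axis / sqrt(sum(axis^2))
  a <- angle_deg * pi / 180
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(a) * K + (1 - cos(a)) * (K %*% K)
}

#' Build an operator from named angle conventions
#'
#' `euler`: intrinsic z-y-z Euler angles `(alpha, beta, gamma)` in degrees,
#' `R = Rz(alpha) Ry(beta) Rz(gamma)`.  `polar`: spherical axis angles
#' `(omega, phi)` (polar angle from +z and azimuth) plus spin `kappa` about
#' that axis.  These are the conventions common in crystallographic
#' molecular replacement; both are documented choices.
#'
#' @param convention `"euler"` or `"polar"`
#' @param angles length-3 angle triple, degrees
#' @param translation length-3 translation, Angstrom
#' @export
angles_to_rt <- function(convention = c("euler", "polar"), angles,
                         translation = c(0, 0, 0)) {
  convention <- match.arg(convention)
  stopifnot(length(angles) == 3, all(is.finite(angles)))
  R <- if (convention == "euler") {
    rot_z(angles[1]) %*% rot_y(angles[2]) %*% rot_z(angles[3])
  } else {
    om <- angles[1] * pi / 180; ph <- angles[2] * pi / 180
    axis <- c(sin(om) * cos(ph), sin(om) * sin(ph), cos(om))
    axis_rotation(axis, angles[3])
  }
  rt_op(R, translation)
}

#' Recover z-y-z Euler angles (degrees) from an operator
#' @param op an [rt_op()]
#' @return list with `angles` (alpha, beta, gamma) and `translation`
#' @export
rt_to_angles <- function(op) {
  R <- op$R
  beta <- acos(max(-1, min(1, R[3, 3])))
  if (sin(beta) > 1e-10) {
    alpha <- atan2(R[2, 3], R[1, 3])
    gamma <- atan2(R[3, 2], -R[3, 1])
  } else {
    alpha <- atan2(R[2, 1], R[1, 1])
    gamma <- 0
  }
  list(angles = c(alpha, beta, gamma) * 180 / pi, translation = op$t)
}

#' Point-group symmetry as a list of operators
#'
#' The group must contain the identity; closure under composition is checked
#' for small groups within tolerance.
#'
#' @param operators list of [rt_op()] (identity included)
#' @param check verify closure (default `TRUE` for groups of up to 24 ops)
#' @export
symmetry_group <- function(operators, check = TRUE) {
  stopifnot(length(operators) >= 1, all(vapply(operators, inherits, TRUE, "rt_op")))
  has_id <- any(vapply(operators, function(o)
    max(abs(o$R - diag(3))) < 1e-6 && max(abs(o$t)) < 1e-6, TRUE))
  if (!has_id) stop("symmetry group must contain the identity")
  g <- structure(list(operators = operators), class = "symmetry_group")
  if (check && length(operators) <= 24) check_group_closure(g)
  g
}

check_group_closure <- function(group, tol = 1e-6) {
  ops <- group$operators
  for (a in ops) for (b in ops) {
    ab <- rt_compose(a, b)
    ok <- any(vapply(ops, function(o)
      max(abs(o$R - ab$R)) < tol && max(abs(o$t - ab$t)) < tol, TRUE))
    if (!ok) stop("symmetry group not closed under composition")
  }
  invisible(TRUE)
}

#' Cyclic point group about an axis
#' @param n fold (>= 1)
#' @param axis rotation axis (default z)
#' @param center point on the axis
#' @export
cyclic_group <- function(n, axis = c(0, 0, 1), center = c(0, 0, 0)) {
  ops <- lapply(seq_len(n) - 1L, function(k) {
    R <- axis_rotation(axis, 360 * k / n)
    rt_op(R, as.numeric(center - R %*% center))
  })
  symmetry_group(ops)
}

#' Symmetry-related atoms within contact distance of a model
#'
#' Expands the model through every non-identity operator and keeps the
#' images that have at least one atom within `contact_cutoff` of the input
#' model, i.e. the mates that can make nonbonded interactions.
#'
#' @param model an [atomic_model()]
#' @param group a [symmetry_group()]
#' @param contact_cutoff Angstrom
#' @return data.frame of image atoms with an `op` column (operator index),
#'   or zero rows when no mate is in contact
#' @export
expand_symmetry <- function(model, group, contact_cutoff = 4) {
  if (!inherits(group, "symmetry_group") || !length(group$operators))
    stop("empty or invalid symmetry group")
  x0 <- model_coords(model)
  out <- list()
  for (k in seq_along(group$operators)) {
    op <- group$operators[[k]]
    if (max(abs(op$R - diag(3))) < 1e-9 && max(abs(op$t)) < 1e-9) next
    xi <- apply_rt(op, x0)
    dmin2 <- min_cross_dist2(xi, x0)
    if (dmin2 <= contact_cutoff^2) {
      a <- model$atoms
      a$x <- xi[, 1]; a$y <- xi[, 2]; a$z <- xi[, 3]
      a$op <- k
      out[[length(out) + 1]] <- a
    }
  }
  if (!length(out)) {
    a <- model$atoms[0, , drop = FALSE]; a$op <- integer()
    return(a)
  }
  do.call(rbind, out)
}

min_cross_dist2 <- function(a, b) {
  # smallest squared distance between two point sets (small-n quadratic scan)
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * a %*% t(b)
  min(d2)
}

#' Least-squares superposition of two models
#'
#' Kabsch superposition of paired atoms; the returned operator maps
#' `model_b` onto `model_a`.  Pairing defaults to identical
#' (chain, seqid, ins, atom) identifiers.
#'
#' @param model_a,model_b [atomic_model()] objects
#' @param pairing optional 2-column matrix of atom-row indices (a, b)
#' @return list with `op` (an [rt_op()]) and `rmsd` after transformation
#' @export
superpose <- function(model_a, model_b, pairing = NULL) {
  if (is.null(pairing)) {
    ka <- with(model_a$atoms, paste(chain, seqid, ins, atom))
    kb <- with(model_b$atoms, paste(chain, seqid, ins, atom))
    ib <- match(ka, kb)
    pairing <- cbind(which(!is.na(ib)), ib[!is.na(ib)])
  }
  if (nrow(pairing) < 3) stop("need at least 3 paired atoms")
  xa <- model_coords(model_a)[pairing[, 1], , drop = FALSE]
  xb <- model_coords(model_b)[pairing[, 2], , drop = FALSE]
  ca <- colMeans(xa); cb <- colMeans(xb)
  A <- sweep(xa, 2, ca); B <- sweep(xb, 2, cb)
  sv <- svd(t(B) %*% A)
  if (sv$d[2] < 1e-8 * max(sv$d[1], 1e-30)) stop("paired atoms are collinear")
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  t <- ca - as.numeric(R %*% cb)
  op <- rt_op(R, t)
  rmsd <- sqrt(mean(rowSums((apply_rt(op, xb) - xa)^2)))
  list(op = op, rmsd = rmsd)
}
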