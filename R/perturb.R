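#' Randomly displace a model's atoms
#'
#' Adds i.i.d. Gaussian displacements scaled so that the expected coordinate
#' RMSD equals `rms`; used to remove model bias before half-map
#' cross-validation refinement.
#'
#' @param model an [atomic_model()]
#' @param rms expected displacement RMSD, Angstrom (>= 0)
#' @param seed integer RNG seed
#' @export
shake_model <- function(model, rms, seed = 1) {
  stopifnot(rms >= 0)
  if (rms == 0) return(model)
  n <- n_atoms(model)
  d <- with_seed(seed, matrix(rnorm(3 * n, 0, rms / sqrt(3)), n, 3))
  model_coords(model) <- model_coords(model) + d
  model
}

#' Bend a model rigidly about a hinge residue
#'
#' Residues after the hinge are rotated about `axis` through the hinge
#' residue's CA (or first atom), creating controlled conformational change
#' for morphing experiments.
#'
#' @param model an [atomic_model()]
#' @param hinge_residue residue ordinal (see [residue_table()])
#' @param axis rotation axis
#' @param angle degrees
#' @export
bend_model <- function(model, hinge_residue, axis = c(0, 0, 1), angle = 10) {
  nr <- n_residues(model)
  if (hinge_residue <= 1 || hinge_residue >= nr)
    stop("hinge must be an interior residue (got ", hinge_residue,
         " of ", nr, ")")
  a <- model$atoms
  hinge_rows <- which(a$res_index == hinge_residue)
  ca <- hinge_rows[match("CA", a$atom[hinge_rows])]
  if (is.na(ca)) ca <- hinge_rows[1]
  pivot <- as.numeric(a[ca, c("x", "y", "z")])
  R <- axis_rotation(axis, angle)
  sel <- a$res_index > hinge_residue
  x <- model_coords(model)
  x[sel, ] <- sweep(sweep(x[sel, , drop = FALSE], 2, pivot) %*% t(R), 2, -pivot)
  model_coords(model) <- x
  model
}
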