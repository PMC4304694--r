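#' Atomic model container
#'
#' An atomic model is stored as a flat atom table (one row per atom) plus the
#' chain/residue hierarchy implied by its `chain`, `seqid` and `ins` columns,
#' in file order.  This mirrors how `bio3d` represents structures and keeps
#' every whole-model operation a vectorized data-frame/matrix operation.
#'
#' @param atoms data.frame with columns `chain` (character), `seqid`
#'   (integer), `ins` (character, `""` when absent), `resname`, `atom`,
#'   `element`, `x`, `y`, `z` (Angstrom), `occ` (in `[0,1]`) and `b`
#'   (Angstrom^2, non-negative).  A `kind` column (protein / rna / dna /
#'   other) is derived from `resname` when missing.
#' @return An object of class `atomic_model`.
#' @export
atomic_model <- function(atoms) {
  need <- c("chain", "seqid", "ins", "resname", "atom", "element",
            "x", "y", "z", "occ", "b")
  miss <- setdiff(need, names(atoms))
  if (length(miss)) stop("atoms table lacks columns: ", paste(miss, collapse = ", "))
  atoms$seqid <- as.integer(atoms$seqid)
  atoms$ins <- as.character(atoms$ins)
  atoms$ins[is.na(atoms$ins)] <- ""
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z)))
    stop("non-finite atom coordinates")
  if (any(atoms$occ < 0 | atoms$occ > 1 | !is.finite(atoms$occ)))
    stop("occupancies must lie in [0, 1]")
  if (any(atoms$b < 0 | !is.finite(atoms$b)))
    stop("B factors must be finite and non-negative")
  if (is.null(atoms$kind)) atoms$kind <- residue_kind(atoms$resname)
  key <- paste(atoms$chain, atoms$seqid, atoms$ins, sep = "|")
  atoms$res_index <- match(key, unique(key))
  # atom names unique within each residue
  if (anyDuplicated(paste(key, atoms$atom)))
    stop("duplicate atom name within a residue")
  rownames(atoms) <- NULL
  structure(list(atoms = atoms), class = "atomic_model")
}

#' @export
print.atomic_model <- function(x, ...) {
  a <- x$atoms
  cat(sprintf("<atomic_model> %d atoms, %d residues, %d chain(s): %s\n",
              nrow(a), max(a$res_index, 0), length(unique(a$chain)),
              paste(unique(a$chain), collapse = " ")))
  invisible(x)
}

.aa3 <- c("ALA","ARG","ASN","ASP","CYS","GLN","GLU","GLY","HIS","ILE","LEU",
          "LYS","MET","MSE","PHE","PRO","SER","THR","TRP","TYR","VAL")
.rna1 <- c("A","C","G","U","I")
.dna2 <- c("DA","DC","DG","DT","DI")

residue_kind <- function(resname) {
  out <- rep("other", length(resname))
  out[resname %in% .aa3] <- "protein"
  out[resname %in% .rna1] <- "rna"
  out[resname %in% .dna2] <- "dna"
  out
}

#' Number of atoms / residues in a model
#' @param model an `atomic_model`
#' @export
n_atoms <- function(model) nrow(model$atoms)

#' @rdname n_atoms
#' @export
n_residues <- function(model) if (nrow(model$atoms)) max(model$atoms$res_index) else 0L

#' Coordinates of a model as an n x 3 matrix
#' @param model an `atomic_model`
#' @export
model_coords <- function(model) {
  cbind(x = model$atoms$x, y = model$atoms$y, z = model$atoms$z)
}

#' Replace the coordinates of a model
#' @param model an `atomic_model`
#' @param value n x 3 coordinate matrix
#' @export
`model_coords<-` <- function(model, value) {
  stopifnot(nrow(value) == nrow(model$atoms), ncol(value) == 3)
  model$atoms$x <- value[, 1]
  model$atoms$y <- value[, 2]
  model$atoms$z <- value[, 3]
  model
}

#' Residue-level summary table of a model
#'
#' One row per residue, in model order, with the atom-row range of each.
#' @param model an `atomic_model`
#' @export
residue_table <- function(model) {
  a <- model$atoms
  first <- !duplicated(a$res_index)
  data.frame(res_index = a$res_index[first], chain = a$chain[first],
             seqid = a$seqid[first], ins = a$ins[first],
             resname = a$resname[first], kind = a$kind[first],
             stringsAsFactors = FALSE)
}

#' Subset a model by atom rows or residue indices
#' @param model an `atomic_model`
#' @param atom_rows integer/logical selection of atom rows
#' @param res_index residue ordinals to keep (alternative to `atom_rows`)
#' @export
model_subset <- function(model, atom_rows = NULL, res_index = NULL) {
  if (is.null(atom_rows)) {
    if (is.null(res_index)) stop("give atom_rows or res_index")
    atom_rows <- model$atoms$res_index %in% res_index
  }
  atomic_model(model$atoms[atom_rows, , drop = FALSE])
}

#' Concatenate models (chains must not collide on residue identity)
#' @param ... `atomic_model` objects
#' @export
model_rbind <- function(...) {
  tabs <- lapply(list(...), function(m) m$atoms[setdiff(names(m$atoms), "res_index")])
  atomic_model(do.call(rbind, tabs))
}

#' Centroid of a model's atoms
#' @param model an `atomic_model`
#' @export
model_centroid <- function(model) colMeans(model_coords(model))

#' Coordinate RMSD between two models with identical atom ordering
#' @param a,b `atomic_model` objects with equal atom counts
#' @export
rmsd_models <- function(a, b) {
  xa <- model_coords(a); xb <- model_coords(b)
  stopifnot(nrow(xa) == nrow(xb))
  sqrt(mean(rowSums((xa - xb)^2)))
}

#' Translate a model so its centroid sits at a target point
#' @param model an `atomic_model`
#' @param at target centroid (default origin)
#' @export
center_model <- function(model, at = c(0, 0, 0)) {
  shift <- at - model_centroid(model)
  model_coords(model) <- sweep(model_coords(model), 2, -shift)
  model
}

#' Atomic numbers for model elements
#'
#' Looks elements up in the shipped scattering table; unknown elements are
#' assigned the carbon weight with a warning so scoring can proceed.
#' @param model an `atomic_model`
#' @export
atomic_numbers <- function(model) {
  tab <- scattering_table("electron")
  z <- tab$z[match(toupper(model$atoms$element), tab$element)]
  if (anyNA(z)) {
    warning("unknown element(s): ",
            paste(unique(model$atoms$element[is.na(z)]), collapse = ", "),
            "; using carbon weight")
    z[is.na(z)] <- tab$z[tab$element == "C"]
  }
  z
}
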