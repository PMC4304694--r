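#' Restraint-set container
#'
#' Collects typed restraints generated by the various generators:
#' `distance` (one row per restrained atom pair; the `targets` list-column
#' holds one or more `(d, sigma, label)` alternatives, with multi-target
#' rows grouped by `alt_group`), `torsion` (four atom references with
#' angle targets) and `plane` (parallel-plane restraints, a list).
#'
#' @param distance distance-restraint data.frame (see details)
#' @param torsion torsion-restraint data.frame
#' @param plane list of parallel-plane restraints
#' @param provenance free-text provenance tag
#' @export
restraint_set <- function(distance = NULL, torsion = NULL, plane = NULL,
                          provenance = "") {
  if (is.null(distance)) distance <- empty_distance_restraints()
  if (!nrow(distance)) distance <- empty_distance_restraints()
  dup <- duplicated(paste(distance$kind, distance$chain_a, distance$seqid_a,
                          distance$ins_a, distance$atom_a, distance$chain_b,
                          distance$seqid_b, distance$ins_b, distance$atom_b))
  if (any(dup)) stop("duplicate atom pair within a restraint kind")
  for (tg in distance$targets) {
    stopifnot(is.data.frame(tg), nrow(tg) >= 1,
              all(tg$d > 0), all(tg$sigma > 0))
  }
  multi <- vapply(distance$targets, nrow, 1L) > 1
  if (any(multi & distance$kind != "basepair"))
    stop("multi-target restraints are only allowed for kind 'basepair'")
  structure(list(distance = distance, torsion = torsion, plane = plane,
                 provenance = provenance, active = NULL),
            class = "restraint_set")
}

empty_distance_restraints <- function() {
  data.frame(kind = character(), chain_a = character(), seqid_a = integer(),
             ins_a = character(), atom_a = character(), chain_b = character(),
             seqid_b = integer(), ins_b = character(), atom_b = character(),
             alt_group = integer(),
             targets = I(list()), stringsAsFactors = FALSE)
}

#' @export
print.restraint_set <- function(x, ...) {
  cat(sprintf("<restraint_set> %d distance, %d torsion, %d plane restraint(s)%s\n",
              nrow(x$distance),
              if (is.null(x$torsion)) 0L else nrow(x$torsion),
              length(x$plane),
              if (nzchar(x$provenance)) paste0(" [", x$provenance, "]") else ""))
  if (nrow(x$distance))
    print(table(x$distance$kind))
  invisible(x)
}

#' Combine restraint sets
#' @param ... `restraint_set` objects
#' @export
restraints_rbind <- function(...) {
  sets <- list(...)
  dist <- do.call(rbind, lapply(sets, `[[`, "distance"))
  # renumber alt groups to stay unique
  off <- 0L
  at <- 0L
  for (i in seq_along(sets)) {
    n <- nrow(sets[[i]]$distance)
    if (n) {
      idx <- seq.int(at + 1, at + n)
      g <- dist$alt_group[idx]
      if (any(!is.na(g))) dist$alt_group[idx] <- g + off
      off <- off + max(c(0L, g), na.rm = TRUE)
      at <- at + n
    }
  }
  tor <- do.call(rbind, lapply(sets, `[[`, "torsion"))
  pl <- do.call(c, lapply(sets, `[[`, "plane"))
  restraint_set(dist, tor, pl,
                provenance = paste(unique(vapply(sets, `[[`, "", "provenance")),
                                   collapse = "; "))
}

# Resolve restraint atom references to atom-row indices of a model.
restraint_atom_rows <- function(model, distance) {
  key <- with(model$atoms, paste(chain, seqid, ins, atom))
  ia <- match(paste(distance$chain_a, distance$seqid_a, distance$ins_a,
                    distance$atom_a), key)
  ib <- match(paste(distance$chain_b, distance$seqid_b, distance$ins_b,
                    distance$atom_b), key)
  if (anyNA(ia) || anyNA(ib)) {
    bad <- which(is.na(ia) | is.na(ib))[1]
    stop("restraint ", bad, " references a missing atom (",
         distance$chain_a[bad], " ", distance$seqid_a[bad], " ",
         distance$atom_a[bad], " / ", distance$chain_b[bad], " ",
         distance$seqid_b[bad], " ", distance$atom_b[bad], ")")
  }
  cbind(ia, ib)
}

# Default restrained atom subsets: protein main chain + CB; nucleic-acid
# backbone + glycosidic N.  Keeps the pair count near-linear in size while
# spanning the medium-range distances external restraints are meant to hold.
restrainable_atoms <- function(model, all_atoms = FALSE) {
  a <- model$atoms
  if (all_atoms) return(seq_len(nrow(a)))
  prot <- a$kind == "protein" & a$atom %in% c("N", "CA", "C", "O", "CB")
  nuc <- a$kind %in% c("rna", "dna") &
    a$atom %in% c("P", "O5'", "C5'", "C4'", "C3'", "O3'", "C1'", "N1", "N9")
  nuc_gly <- a$kind %in% c("rna", "dna") & a$atom %in% c("N1", "N9")
  # keep only the true glycosidic N per base type
  gly_ok <- (a$atom == "N9" & base_letter(a$resname) %in% c("A", "G")) |
    (a$atom == "N1" & base_letter(a$resname) %in% c("C", "U", "T"))
  which(prot | (nuc & (!nuc_gly | gly_ok)))
}

#' Generate reference (external) distance restraints
#'
#' For every pair of corresponded atoms whose distance in the reference
#' structure is below `d_max` and whose residue separation is at least
#' `min_seq_sep` (cross-chain pairs always qualify), emits a distance
#' restraint whose target is the reference distance.  The 4.2 Angstrom
#' default threshold keeps restraints local enough to tolerate global
#' conformational differences between target and reference.  By default
#' only main-chain + CB (protein) and backbone + glycosidic N (nucleic)
#' atoms are restrained.
#'
#' @param target the [atomic_model()] being refined
#' @param reference the reference [atomic_model()]
#' @param correspondence optional 2-column matrix of residue ordinals
#'   (target, reference); defaults to matching (chain, seqid, ins)
#' @param d_max distance threshold, Angstrom (default 4.2)
#' @param min_seq_sep minimum residue separation within a chain (default 2)
#' @param sigma restraint sigma, Angstrom (default 0.1)
#' @param all_atoms restrain every atom pair instead of the default subset
#' @param kind restraint kind label
#' @return a [restraint_set()]
#' @export
generate_reference_restraints <- function(target, reference,
                                          correspondence = NULL,
                                          d_max = 4.2, min_seq_sep = 2,
                                          sigma = 0.1, all_atoms = FALSE,
                                          kind = "reference") {
  rt_t <- residue_table(target)
  rt_r <- residue_table(reference)
  if (is.null(correspondence)) {
    kt <- paste(rt_t$chain, rt_t$seqid, rt_t$ins)
    kr <- paste(rt_r$chain, rt_r$seqid, rt_r$ins)
    m <- match(kt, kr)
    correspondence <- cbind(which(!is.na(m)), m[!is.na(m)])
  }
  if (!nrow(correspondence)) stop("empty residue correspondence")
  res_map <- rep(NA_integer_, nrow(rt_t))
  res_map[correspondence[, 1]] <- correspondence[, 2]
  sel_t <- restrainable_atoms(target, all_atoms)
  at <- target$atoms[sel_t, , drop = FALSE]
  ref_res <- res_map[at$res_index]
  keep <- !is.na(ref_res)
  at <- at[keep, , drop = FALSE]; ref_res <- ref_res[keep]
  if (!nrow(at)) stop("no restrainable corresponded atoms")
  # locate the corresponding reference atoms by residue ordinal + atom name
  ar <- reference$atoms
  ref_key <- paste(ar$res_index, ar$atom)
  ridx <- match(paste(ref_res, at$atom), ref_key)
  keep <- !is.na(ridx)
  at <- at[keep, , drop = FALSE]; ridx <- ridx[keep]
  xr <- model_coords(reference)[ridx, , drop = FALSE]
  n <- nrow(at)
  if (n < 2) stop("fewer than two corresponded atoms")
  d2 <- outer(rowSums(xr^2), rowSums(xr^2), "+") - 2 * xr %*% t(xr)
  d2[d2 < 0] <- 0
  same_chain <- outer(at$chain, at$chain, "==")
  sep <- abs(outer(at$res_index, at$res_index, "-"))
  ok <- upper.tri(d2) & d2 < d_max^2 & (!same_chain | sep >= min_seq_sep)
  idx <- which(ok, arr.ind = TRUE)
  if (!nrow(idx)) return(restraint_set(provenance = kind))
  d <- sqrt(d2[ok])
  dist <- data.frame(kind = kind,
                     chain_a = at$chain[idx[, 1]], seqid_a = at$seqid[idx[, 1]],
                     ins_a = at$ins[idx[, 1]], atom_a = at$atom[idx[, 1]],
                     chain_b = at$chain[idx[, 2]], seqid_b = at$seqid[idx[, 2]],
                     ins_b = at$ins[idx[, 2]], atom_b = at$atom[idx[, 2]],
                     alt_group = NA_integer_, stringsAsFactors = FALSE)
  dist$targets <- I(lapply(seq_along(d), function(i)
    data.frame(d = d[i], sigma = sigma, label = kind)))
  restraint_set(dist, provenance = kind)
}

#' Generate jelly-body restraints from the model's own geometry
#'
#' Reference restraints with the model acting as its own reference: the
#' current interatomic distances become the targets, so at generation time
#' the restraint energy is exactly zero and the set acts as a stiffness
#' regularizer during refinement.
#'
#' @inheritParams generate_reference_restraints
#' @param model the [atomic_model()]
#' @param sigma default 0.02 (stiff)
#' @export
generate_jelly_restraints <- function(model, d_max = 4.2, min_seq_sep = 2,
                                      sigma = 0.02, all_atoms = FALSE) {
  generate_reference_restraints(model, model, d_max = d_max,
                                min_seq_sep = min_seq_sep, sigma = sigma,
                                all_atoms = all_atoms, kind = "jelly")
}

#' Generate generic helical hydrogen-bond restraints
#'
#' Emits O(i)-N(i+4) restraints targeting 2.9 Angstrom wherever the current
#' O-N distance is below `detect_max`, i.e. wherever the chain is at least
#' loosely helical.
#'
#' @param model an [atomic_model()]
#' @param detect_max detection threshold on the current O-N distance (3.5 A)
#' @param target restrained distance (2.9 A)
#' @param sigma restraint sigma (0.2 A)
#' @export
generate_hbond_restraints <- function(model, detect_max = 3.5, target = 2.9,
                                      sigma = 0.2) {
  a <- model$atoms
  rt <- residue_table(model)
  rows <- list()
  for (i in seq_len(nrow(rt))) {
    j <- i + 4
    if (j > nrow(rt) || rt$chain[j] != rt$chain[i]) next
    if (rt$kind[i] != "protein" || rt$kind[j] != "protein") next
    oi <- which(a$res_index == i & a$atom == "O")
    nj <- which(a$res_index == j & a$atom == "N")
    if (!length(oi) || !length(nj)) next
    d <- sqrt(sum((model_coords(model)[oi, ] - model_coords(model)[nj, ])^2))
    if (d >= detect_max) next
    rows[[length(rows) + 1]] <-
      data.frame(kind = "hbond", chain_a = a$chain[oi], seqid_a = a$seqid[oi],
                 ins_a = a$ins[oi], atom_a = "O", chain_b = a$chain[nj],
                 seqid_b = a$seqid[nj], ins_b = a$ins[nj], atom_b = "N",
                 alt_group = NA_integer_, stringsAsFactors = FALSE)
  }
  if (!length(rows)) return(restraint_set(provenance = "hbond"))
  dist <- do.call(rbind, rows)
  dist$targets <- I(replicate(nrow(dist),
                              data.frame(d = target, sigma = sigma,
                                         label = "hbond"), simplify = FALSE))
  restraint_set(dist, provenance = "hbond")
}

#' Generate helical-fragment restraints
#'
#' Slides a window along each protein chain, superposes an ideal helix
#' fragment onto the window's backbone and, when the backbone RMSD is below
#' `rmsd_max` (a tolerant criterion that does not require strict helical
#' dihedrals), emits the ideal fragment's internal backbone distances below
#' `d_max` as targets.  Unlike hydrogen-bond restraints these cover all
#' sufficiently close backbone atom pairs of the fragment.
#'
#' @param model an [atomic_model()]
#' @param window fragment length in residues (default 9)
#' @param rmsd_max acceptance RMSD, Angstrom (default 1.5)
#' @param d_max distance threshold on ideal distances (default 4.2)
#' @param sigma restraint sigma (default 0.1)
#' @export
generate_helix_fragment_restraints <- function(model, window = 9,
                                               rmsd_max = 1.5, d_max = 4.2,
                                               sigma = 0.1) {
  rt <- residue_table(model)
  ideal <- build_ideal_helix(window)
  bb <- c("N", "CA", "C", "O", "CB")
  rows <- list()
  seen <- character()
  for (start in seq_len(max(0, nrow(rt) - window + 1))) {
    idx <- start:(start + window - 1)
    if (length(unique(rt$chain[idx])) != 1) next
    if (!all(rt$kind[idx] == "protein")) next
    frag <- model_subset(model, res_index = idx)
    # pair backbone atoms by position-in-window + name
    fa <- frag$atoms; ia <- ideal$atoms
    fkey <- paste(match(fa$res_index, unique(fa$res_index)), fa$atom)
    ikey <- paste(ia$res_index, ia$atom)
    m <- match(fkey[fa$atom %in% bb], ikey)
    rows_f <- which(fa$atom %in% bb)
    ok <- !is.na(m)
    if (sum(ok) < 9) next
    pair <- cbind(rows_f[ok], m[ok])
    sp <- tryCatch(superpose(frag, ideal, pairing = pair),
                   error = function(e) NULL)
    if (is.null(sp) || sp$rmsd >= rmsd_max) next
    xi <- model_coords(ideal)
    for (p in seq_len(nrow(pair))) for (q in seq_len(nrow(pair))) {
      if (q <= p) next
      ra <- pair[p, 1]; rb <- pair[q, 1]
      if (fa$res_index[ra] == fa$res_index[rb]) next
      dij <- sqrt(sum((xi[pair[p, 2], ] - xi[pair[q, 2], ])^2))
      if (dij >= d_max) next
      key <- paste(fa$chain[ra], fa$seqid[ra], fa$atom[ra],
                   fa$chain[rb], fa$seqid[rb], fa$atom[rb])
      if (key %in% seen) next
      seen <- c(seen, key)
      rows[[length(rows) + 1]] <-
        data.frame(kind = "helix_fragment", chain_a = fa$chain[ra],
                   seqid_a = fa$seqid[ra], ins_a = fa$ins[ra],
                   atom_a = fa$atom[ra], chain_b = fa$chain[rb],
                   seqid_b = fa$seqid[rb], ins_b = fa$ins[rb],
                   atom_b = fa$atom[rb], alt_group = NA_integer_,
                   d = dij, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(restraint_set(provenance = "helix_fragment"))
  dist <- do.call(rbind, rows)
  tg <- lapply(dist$d, function(d)
    data.frame(d = d, sigma = sigma, label = "helix_fragment"))
  dist$d <- NULL
  dist$targets <- I(tg)
  restraint_set(dist, provenance = "helix_fragment")
}
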