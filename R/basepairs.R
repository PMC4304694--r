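# Base-pair detection and multi-target restraint generation for nucleic
# acids: canonical Watson-Crick pairs plus the two alternative G:U
# geometries (wobble and reverse wobble).

# Chirality / planarity guard: normalized signed volume of the tetrahedron
# (N_gly_a, C1'_a, N_gly_b, C1'_b).  For any in-plane (cis-like) pairing of
# bases the glycosidic attachments are nearly coplanar, so the volume is
# close to zero; a large magnitude marks a pyramidal arrangement that no
# base-pair class can produce and the candidate is rejected.
pair_chirality_volume <- function(na_, c1a, nb, c1b) {
  u <- c1a - na_; v <- nb - na_; w <- c1b - na_
  det(rbind(u, v, w)) /
    (sqrt(sum(u^2)) * sqrt(sum(v^2)) * sqrt(sum(w^2)))
}

#' Detect base pairs in a model
#'
#' Candidate pairs are bases with at least one N/O-N/O contact between
#' 2.4 and 3.5 Angstrom.  A candidate is accepted for a class (WC A:U or
#' A:T, WC G:C, G:U wobble, G:U reverse wobble) when every hydrogen-bond
#' distance of that class pattern lies within `tol` of its reference
#' value, the acute angle between the two base planes is below
#' `max_plane_angle`, and the glycosidic chirality sign matches the class.
#' Each residue joins at most one pair; conflicts are resolved in favour of
#' the smallest total distance deviation.
#'
#' @param model an [atomic_model()]
#' @param tol hydrogen-bond distance tolerance, Angstrom (default 0.5)
#' @param max_plane_angle inter-plane angle limit, degrees (default 35)
#' @param check_chirality toggle the chirality criterion
#' @return data.frame with one row per pair: residue ordinals and
#'   identifiers, `class`, `deviation`, plus a `hbonds` list-column of the
#'   matched atom pairs and distances
#' @export
detect_base_pairs <- function(model, tol = 0.5, max_plane_angle = 35,
                              check_chirality = TRUE) {
  a <- model$atoms
  rt <- residue_table(model)
  nuc <- which(rt$kind %in% c("rna", "dna"))
  if (length(nuc) < 2) return(empty_base_pairs())
  x <- model_coords(model)
  # candidate residue pairs by N/O base-atom contacts
  base_rows <- lapply(nuc, function(i) {
    letter <- base_letter(rt$resname[i])
    nm <- base_atom_names(letter)
    which(a$res_index == i & a$atom %in% nm &
            a$element %in% c("N", "O"))
  })
  names(base_rows) <- as.character(nuc)
  cand <- list()
  for (ii in seq_along(nuc)) for (jj in seq_along(nuc)) {
    if (jj <= ii) next
    ra <- base_rows[[ii]]; rb <- base_rows[[jj]]
    if (!length(ra) || !length(rb)) next
    d2 <- outer(rowSums(x[ra, , drop = FALSE]^2),
                rowSums(x[rb, , drop = FALSE]^2), "+") -
      2 * x[ra, , drop = FALSE] %*% t(x[rb, , drop = FALSE])
    if (any(d2 >= 2.4^2 & d2 <= 3.5^2))
      cand[[length(cand) + 1]] <- c(nuc[ii], nuc[jj])
  }
  if (!length(cand)) return(empty_base_pairs())
  pats <- base_pair_patterns()
  hits <- list()
  for (cp in cand) {
    for (ord in list(cp, rev(cp))) {
      la <- base_letter(rt$resname[ord[1]]); lb <- base_letter(rt$resname[ord[2]])
      la_u <- sub("T", "U", la); lb_u <- sub("T", "U", lb)
      for (cls in names(pats)) {
        p <- pats[[cls]]
        if (la_u != p$first || lb_u != p$second) next
        rows_a <- which(a$res_index == ord[1]); rows_b <- which(a$res_index == ord[2])
        ia <- rows_a[match(p$bonds$a, a$atom[rows_a])]
        ib <- rows_b[match(p$bonds$b, a$atom[rows_b])]
        if (anyNA(ia) || anyNA(ib)) next
        dd <- sqrt(rowSums((x[ia, , drop = FALSE] - x[ib, , drop = FALSE])^2))
        if (any(abs(dd - p$bonds$d) > tol)) next
        # plane angle
        pa <- ls_plane(x[rows_a[a$atom[rows_a] %in% base_atom_names(la)], ,
                         drop = FALSE])
        pb <- ls_plane(x[rows_b[a$atom[rows_b] %in% base_atom_names(lb)], ,
                         drop = FALSE])
        if (acute_angle(pa$normal, pb$normal) >= max_plane_angle) next
        if (check_chirality) {
          na_i <- rows_a[match(glycosidic_n(la), a$atom[rows_a])]
          c1a <- rows_a[match("C1'", a$atom[rows_a])]
          nb_i <- rows_b[match(glycosidic_n(lb), a$atom[rows_b])]
          c1b <- rows_b[match("C1'", a$atom[rows_b])]
          if (!anyNA(c(na_i, c1a, nb_i, c1b))) {
            vnorm <- pair_chirality_volume(x[na_i, ], x[c1a, ],
                                           x[nb_i, ], x[c1b, ])
            if (abs(vnorm) > 0.3) next
          }
        }
        hits[[length(hits) + 1]] <-
          list(res_a = ord[1], res_b = ord[2], class = cls,
               deviation = sum(abs(dd - p$bonds$d)),
               hbonds = data.frame(atom_a = p$bonds$a, atom_b = p$bonds$b,
                                   d = dd, target = p$bonds$d))
      }
    }
  }
  if (!length(hits)) return(empty_base_pairs())
  # greedy assignment: best (smallest deviation) first, one pair per residue
  devs <- vapply(hits, `[[`, 0, "deviation")
  used <- integer()
  keep <- list()
  for (k in order(devs)) {
    h <- hits[[k]]
    if (h$res_a %in% used || h$res_b %in% used) next
    used <- c(used, h$res_a, h$res_b)
    keep[[length(keep) + 1]] <- h
  }
  out <- do.call(rbind, lapply(keep, function(h) {
    data.frame(res_a = h$res_a, res_b = h$res_b,
               chain_a = rt$chain[h$res_a], seqid_a = rt$seqid[h$res_a],
               resname_a = rt$resname[h$res_a],
               chain_b = rt$chain[h$res_b], seqid_b = rt$seqid[h$res_b],
               resname_b = rt$resname[h$res_b],
               class = h$class, deviation = h$deviation,
               stringsAsFactors = FALSE)
  }))
  out$hbonds <- I(lapply(keep, `[[`, "hbonds"))
  out[order(out$res_a), , drop = FALSE]
}

empty_base_pairs <- function() {
  out <- data.frame(res_a = integer(), res_b = integer(), chain_a = character(),
                    seqid_a = integer(), resname_a = character(),
                    chain_b = character(), seqid_b = integer(),
                    resname_b = character(), class = character(),
                    deviation = numeric(), stringsAsFactors = FALSE)
  out$hbonds <- I(list())
  out
}

# All pattern atom pairs of the two G:U alternatives, with each
# configuration's distances measured on the idealized pair geometry.
gu_alternative_targets <- function() {
  if (is.null(.cf_env$gu_targets)) {
    atoms <- data.frame(a = c("O6", "N1", "N1"), b = c("N3", "O2", "O4"),
                        stringsAsFactors = FALSE)
    out <- list()
    for (cls in c("GU_wobble", "GU_reverse_wobble")) {
      pr <- build_base_pair("G", "U", cls)
      xg <- model_coords(pr$first); xu <- model_coords(pr$second)
      ag <- pr$first$atoms$atom; au <- pr$second$atoms$atom
      out[[cls]] <- vapply(seq_len(nrow(atoms)), function(i)
        sqrt(sum((xg[ag == atoms$a[i], ] - xu[au == atoms$b[i], ])^2)), 0)
    }
    .cf_env$gu_targets <- list(atoms = atoms, d = out)
  }
  .cf_env$gu_targets
}

#' Generate distance restraints from detected base pairs
#'
#' Watson-Crick pairs yield one single-target restraint per hydrogen bond.
#' G:U pairs are genuinely ambiguous between the wobble and reverse-wobble
#' geometries, so their restraints carry both alternatives as a jointly
#' selected multi-target group: each pattern atom pair holds the distance
#' it takes in either configuration, and refinement picks the best-agreeing
#' alternative each cycle (see [select_multi_targets()]).
#'
#' @param pairs output of [detect_base_pairs()]
#' @param sigma restraint sigma, Angstrom (default 0.15)
#' @return a [restraint_set()]
#' @export
generate_base_pair_restraints <- function(pairs, sigma = 0.15) {
  if (!nrow(pairs)) return(restraint_set(provenance = "basepair"))
  rows <- list()
  grp <- 0L
  for (i in seq_len(nrow(pairs))) {
    p <- pairs[i, ]
    if (p$class %in% c("GU_wobble", "GU_reverse_wobble")) {
      grp <- grp + 1L
      gu <- gu_alternative_targets()
      # orient so that residue a is the G
      g_first <- base_letter(p$resname_a) == "G"
      for (k in seq_len(nrow(gu$atoms))) {
        tg <- data.frame(d = c(gu$d$GU_wobble[k], gu$d$GU_reverse_wobble[k]),
                         sigma = sigma,
                         label = c("GU_wobble", "GU_reverse_wobble"))
        rows[[length(rows) + 1]] <- list(
          df = data.frame(kind = "basepair",
                          chain_a = if (g_first) p$chain_a else p$chain_b,
                          seqid_a = if (g_first) p$seqid_a else p$seqid_b,
                          ins_a = "", atom_a = gu$atoms$a[k],
                          chain_b = if (g_first) p$chain_b else p$chain_a,
                          seqid_b = if (g_first) p$seqid_b else p$seqid_a,
                          ins_b = "", atom_b = gu$atoms$b[k],
                          alt_group = grp, stringsAsFactors = FALSE),
          tg = tg)
      }
    } else {
      hb <- p$hbonds[[1]]
      for (k in seq_len(nrow(hb))) {
        rows[[length(rows) + 1]] <- list(
          df = data.frame(kind = "basepair", chain_a = p$chain_a,
                          seqid_a = p$seqid_a, ins_a = "",
                          atom_a = hb$atom_a[k], chain_b = p$chain_b,
                          seqid_b = p$seqid_b, ins_b = "",
                          atom_b = hb$atom_b[k], alt_group = NA_integer_,
                          stringsAsFactors = FALSE),
          tg = data.frame(d = hb$target[k], sigma = sigma, label = p$class))
      }
    }
  }
  dist <- do.call(rbind, lapply(rows, `[[`, "df"))
  dist$targets <- I(lapply(rows, `[[`, "tg"))
  restraint_set(dist, provenance = "basepair")
}
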