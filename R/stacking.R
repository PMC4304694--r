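# Parallel-plane (stacking) restraints between predefined planar groups.

# Predefined planar atom sets per residue type: nucleic-acid bases and the
# planar protein side chains.
planar_groups <- function(resname) {
  letter <- base_letter(resname)
  if (resname %in% c(.rna1, .dna2) && letter %in% c("A", "G", "C", "U", "T"))
    return(list(base = base_atom_names(letter)))
  switch(resname,
         PHE = , TYR = list(ring = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")),
         TRP = list(ring = c("CG", "CD1", "CD2", "NE1", "CE2", "CE3",
                             "CZ2", "CZ3", "CH2")),
         HIS = list(ring = c("CG", "ND1", "CD2", "CE1", "NE2")),
         ARG = list(guanidinium = c("CZ", "NE", "NH1", "NH2")),
         list())
}

#' Detect stacked planar groups
#'
#' Planes are orthogonal least-squares fits through each predefined planar
#' atom set (bases; Phe/Tyr/Trp/His rings; Arg guanidinium).  Two groups
#' are accepted as stacked when the acute angle between their normals is
#' below `max_normal_angle`, the angle between each normal and the
#' centroid-to-centroid vector is below `max_centroid_angle` (this is what
#' separates stacking from mere coplanarity), and the centroid distance
#' lies within `dist_range`.
#'
#' @param model an [atomic_model()]
#' @param max_normal_angle degrees (default 30)
#' @param max_centroid_angle degrees (default 30)
#' @param dist_range centroid distance bounds, Angstrom (default 2.5-4.5)
#' @param sigma restraint sigma on the inter-normal angle, degrees
#' @return list of parallel-plane restraints (atom row sets, residue info,
#'   measured geometry, target angle 0)
#' @export
detect_stacking <- function(model, max_normal_angle = 30,
                            max_centroid_angle = 30,
                            dist_range = c(2.5, 4.5), sigma = 10) {
  a <- model$atoms
  rt <- residue_table(model)
  x <- model_coords(model)
  groups <- list()
  for (i in seq_len(nrow(rt))) {
    for (gnm in names(planar_groups(rt$resname[i]))) {
      nm <- planar_groups(rt$resname[i])[[gnm]]
      rows <- which(a$res_index == i & a$atom %in% nm)
      if (length(rows) < 3) {
        warning("planar group ", gnm, " of residue ", i,
                " has fewer than 3 atoms; skipped")
        next
      }
      pl <- ls_plane(x[rows, , drop = FALSE])
      groups[[length(groups) + 1]] <-
        list(res = i, name = gnm, rows = rows, center = pl$center,
             normal = pl$normal)
    }
  }
  out <- list()
  if (length(groups) < 2) return(out)
  for (i in seq_along(groups)) for (j in seq_along(groups)) {
    if (j <= i) next
    gi <- groups[[i]]; gj <- groups[[j]]
    if (gi$res == gj$res) next
    dv <- gj$center - gi$center
    dc <- sqrt(sum(dv^2))
    if (dc < dist_range[1] || dc > dist_range[2]) next
    ang_n <- acute_angle(gi$normal, gj$normal)
    if (ang_n >= max_normal_angle) next
    if (acute_angle(gi$normal, dv) >= max_centroid_angle) next
    if (acute_angle(gj$normal, dv) >= max_centroid_angle) next
    out[[length(out) + 1]] <-
      list(res_a = gi$res, group_a = gi$name, rows_a = gi$rows,
           res_b = gj$res, group_b = gj$name, rows_b = gj$rows,
           normal_angle = ang_n, centroid_dist = dc,
           target_angle = 0, sigma = sigma, dist_bounds = dist_range)
  }
  out
}
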