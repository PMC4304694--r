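# Energy terms for restrained refinement: covalent bonds/angles derived
# from the idealized monomer table, robust (Geman-McClure) distance
# restraints with per-cycle multi-target selection, torsion and
# parallel-plane terms, and real/reciprocal-space density terms.

# Covalent connectivity of a model: bonded atom-row pairs with ideal
# distances, and bonded triples with ideal angles.  Intra-residue bonds and
# targets come from the idealized monomer coordinates (atoms closer than
# 1.75 A there are bonded); inter-residue links are the peptide C-N and
# phosphodiester O3'-P bonds.  Residue types without ideal geometry are
# skipped with a warning.
model_connectivity <- function(model) {
  a <- model$atoms
  rt <- residue_table(model)
  mono <- monomer_table()
  bonds <- list(); angles <- list()
  add_bond <- function(i, j, d0) bonds[[length(bonds) + 1]] <<- c(i, j, d0)
  for (ri in seq_len(nrow(rt))) {
    rows <- which(a$res_index == ri)
    m <- mono[mono$residue == rt$resname[ri], , drop = FALSE]
    if (!nrow(m)) {
      warning("no ideal geometry for residue ", rt$resname[ri], "; skipped")
      next
    }
    mi <- match(a$atom[rows], m$atom)
    pres <- which(!is.na(mi))
    if (length(pres) < 2) next
    xm <- as.matrix(m[, c("x", "y", "z")])
    for (p in seq_along(pres)) for (q in seq_along(pres)) {
      if (q <= p) next
      d0 <- sqrt(sum((xm[mi[pres[p]], ] - xm[mi[pres[q]], ])^2))
      if (d0 < 1.75) add_bond(rows[pres[p]], rows[pres[q]], d0)
    }
  }
  # inter-residue links along each chain
  for (ri in seq_len(nrow(rt) - 1)) {
    rj <- ri + 1
    if (rt$chain[ri] != rt$chain[rj]) next
    rows_i <- which(a$res_index == ri); rows_j <- which(a$res_index == rj)
    if (rt$kind[ri] == "protein" && rt$kind[rj] == "protein") {
      ci <- rows_i[match("C", a$atom[rows_i])]
      nj <- rows_j[match("N", a$atom[rows_j])]
      if (!anyNA(c(ci, nj))) add_bond(ci, nj, 1.329)
    }
    if (rt$kind[ri] %in% c("rna", "dna") && rt$kind[rj] %in% c("rna", "dna")) {
      oi <- rows_i[match("O3'", a$atom[rows_i])]
      pj <- rows_j[match("P", a$atom[rows_j])]
      if (!anyNA(c(oi, pj))) add_bond(oi, pj, 1.607)
    }
  }
  if (length(bonds)) {
    bm <- do.call(rbind, bonds)
    bond_df <- data.frame(i = as.integer(bm[, 1]), j = as.integer(bm[, 2]),
                          d0 = bm[, 3])
  } else bond_df <- data.frame(i = integer(), j = integer(), d0 = numeric())
  # angles: for each atom, every pair of its bonded neighbours; target from
  # the current *ideal* geometry via the law of cosines on ideal distances
  # where both flank distances are intra-residue, else standard defaults
  nb <- vector("list", nrow(a))
  for (k in seq_len(nrow(bond_df))) {
    nb[[bond_df$i[k]]] <- c(nb[[bond_df$i[k]]], bond_df$j[k])
    nb[[bond_df$j[k]]] <- c(nb[[bond_df$j[k]]], bond_df$i[k])
  }
  x <- model_coords(model)
  ideal_pos <- function(row) {
    m <- mono[mono$residue == a$resname[row] & mono$atom == a$atom[row], ,
              drop = FALSE]
    if (nrow(m)) as.numeric(m[1, c("x", "y", "z")]) else NULL
  }
  for (ctr in seq_len(nrow(a))) {
    ns <- nb[[ctr]]
    if (length(ns) < 2) next
    for (p in seq_along(ns)) for (q in seq_along(ns)) {
      if (q <= p) next
      i <- ns[p]; j <- ns[q]
      same_res <- a$res_index[i] == a$res_index[ctr] &&
        a$res_index[j] == a$res_index[ctr]
      ang0 <- if (same_res) {
        pi_ <- ideal_pos(i); pc <- ideal_pos(ctr); pj <- ideal_pos(j)
        if (is.null(pi_) || is.null(pc) || is.null(pj)) next
        acos(max(-1, min(1, sum(unit(pi_ - pc) * unit(pj - pc))))) * 180 / pi
      } else if (a$kind[ctr] == "protein") {
        # peptide-link angles
        if (a$atom[ctr] == "C") 116.2 else if (a$atom[ctr] == "N") 121.7
        else 111.0
      } else 115.0
      angles[[length(angles) + 1]] <- c(i, ctr, j, ang0)
    }
  }
  if (length(angles)) {
    am <- do.call(rbind, angles)
    angle_df <- data.frame(i = as.integer(am[, 1]), ctr = as.integer(am[, 2]),
                           j = as.integer(am[, 3]), a0 = am[, 4])
  } else angle_df <- data.frame(i = integer(), ctr = integer(), j = integer(),
                                a0 = numeric())
  list(bonds = bond_df, angles = angle_df, neighbours = nb)
}

# 1-2 and 1-3 exclusion pairs for the nonbonded term.
connectivity_exclusions <- function(conn, n) {
  keys <- c(paste(conn$bonds$i, conn$bonds$j), paste(conn$bonds$j, conn$bonds$i),
            paste(conn$angles$i, conn$angles$j), paste(conn$angles$j, conn$angles$i))
  unique(keys)
}

#' Select the active alternative of multi-target restraints
#'
#' For every multi-target group (a base pair's bonds are selected jointly)
#' the alternative with the least total squared deviation from the current
#' model geometry becomes the cycle's active target; single-target
#' restraints are untouched.  Returns the per-restraint active-target index.
#'
#' @param model an [atomic_model()]
#' @param restraints a [restraint_set()]
#' @return integer vector (one entry per distance restraint) with an
#'   attribute `labels` naming the selected alternative per group
#' @export
select_multi_targets <- function(model, restraints) {
  d <- restraints$distance
  active <- rep(1L, nrow(d))
  if (!nrow(d)) return(active)
  rows <- restraint_atom_rows(model, d)
  x <- model_coords(model)
  cur <- sqrt(rowSums((x[rows[, 1], , drop = FALSE] -
                         x[rows[, 2], , drop = FALSE])^2))
  labels <- list()
  for (g in unique(d$alt_group[!is.na(d$alt_group)])) {
    idx <- which(d$alt_group == g)
    nalt <- nrow(d$targets[[idx[1]]])
    dev <- vapply(seq_len(nalt), function(k)
      sum(vapply(idx, function(i) (cur[i] - d$targets[[i]]$d[k])^2, 0)), 0)
    k <- which.min(dev)
    active[idx] <- k
    labels[[as.character(g)]] <- d$targets[[idx[1]]]$label[k]
  }
  structure(active, labels = labels)
}

#' Geometry (prior-knowledge) energy and gradient
#'
#' Sum of (i) harmonic covalent bond and angle terms derived from the
#' idealized monomer geometry, (ii) Geman-McClure weighted distance
#' restraints `gm((d - d0)/sigma, c)`, (iii) harmonic torsion restraints
#' and (iv) parallel-plane terms `sin^2(theta)/sin^2(sigma)` on the
#' inter-normal angle.  All gradients are analytic.
#'
#' @param model an [atomic_model()]
#' @param restraints a [restraint_set()] (or `NULL` for covalent terms only)
#' @param gm_scale Geman-McClure scale `c` on the sigma-standardized
#'   residual (default 5)
#' @param include_covalent include the covalent bond/angle terms
#' @param active optional precomputed [select_multi_targets()] result
#' @param conn optional precomputed connectivity
#' @param sigma_bond,sigma_angle covalent sigmas (A, degrees)
#' @return list with `value`, `grad` (n x 3), and `components`
#' @export
geometry_energy <- function(model, restraints = NULL, gm_scale = 5,
                            include_covalent = TRUE, active = NULL,
                            conn = NULL, sigma_bond = 0.02,
                            sigma_angle = 3) {
  x <- model_coords(model)
  n <- nrow(x)
  grad <- matrix(0, n, 3)
  comp <- c(covalent = 0, restraint = 0, torsion = 0, plane = 0)
  if (include_covalent) {
    if (is.null(conn)) conn <- model_connectivity(model)
    b <- conn$bonds
    if (nrow(b)) {
      dv <- x[b$i, , drop = FALSE] - x[b$j, , drop = FALSE]
      dd <- sqrt(rowSums(dv^2))
      u <- (dd - b$d0) / sigma_bond
      comp["covalent"] <- comp["covalent"] + sum(u^2)
      coef <- 2 * u / (sigma_bond * pmax(dd, 1e-9))
      g <- dv * coef
      for (k in 1:3) {
        grad[, k] <- grad[, k] + tapply_add(g[, k], b$i, n) -
          tapply_add(g[, k], b$j, n)
      }
    }
    ang <- conn$angles
    if (nrow(ang)) {
      for (k in seq_len(nrow(ang))) {
        ae <- angle_energy_grad(x[ang$i[k], ], x[ang$ctr[k], ], x[ang$j[k], ],
                                ang$a0[k], sigma_angle)
        comp["covalent"] <- comp["covalent"] + ae$value
        grad[ang$i[k], ] <- grad[ang$i[k], ] + ae$gi
        grad[ang$ctr[k], ] <- grad[ang$ctr[k], ] + ae$gc
        grad[ang$j[k], ] <- grad[ang$j[k], ] + ae$gj
      }
    }
  }
  if (!is.null(restraints) && nrow(restraints$distance)) {
    d <- restraints$distance
    if (is.null(active)) active <- select_multi_targets(model, restraints)
    rows <- restraint_atom_rows(model, d)
    dv <- x[rows[, 1], , drop = FALSE] - x[rows[, 2], , drop = FALSE]
    dd <- sqrt(rowSums(dv^2))
    d0 <- vapply(seq_len(nrow(d)), function(i) d$targets[[i]]$d[active[i]], 0)
    sg <- vapply(seq_len(nrow(d)), function(i) d$targets[[i]]$sigma[active[i]], 0)
    u <- (dd - d0) / sg
    gm <- geman_mcclure(u, gm_scale)
    comp["restraint"] <- sum(gm$value)
    coef <- gm$deriv / (sg * pmax(dd, 1e-9))
    g <- dv * coef
    for (k in 1:3) {
      grad[, k] <- grad[, k] + tapply_add(g[, k], rows[, 1], n) -
        tapply_add(g[, k], rows[, 2], n)
    }
  }
  if (!is.null(restraints) && !is.null(restraints$torsion) &&
      nrow(restraints$torsion)) {
    tr <- restraints$torsion
    rows <- cbind(
      restraint_atom_rows(model, data.frame(
        chain_a = tr$chain_1, seqid_a = tr$seqid_1, ins_a = tr$ins_1,
        atom_a = tr$atom_1, chain_b = tr$chain_2, seqid_b = tr$seqid_2,
        ins_b = tr$ins_2, atom_b = tr$atom_2)),
      restraint_atom_rows(model, data.frame(
        chain_a = tr$chain_3, seqid_a = tr$seqid_3, ins_a = tr$ins_3,
        atom_a = tr$atom_3, chain_b = tr$chain_4, seqid_b = tr$seqid_4,
        ins_b = tr$ins_4, atom_b = tr$atom_4)))
    for (k in seq_len(nrow(tr))) {
      te <- torsion_energy_grad(x[rows[k, 1], ], x[rows[k, 2], ],
                                x[rows[k, 3], ], x[rows[k, 4], ],
                                tr$angle[k], tr$sigma[k])
      comp["torsion"] <- comp["torsion"] + te$value
      for (m in 1:4)
        grad[rows[k, m], ] <- grad[rows[k, m], ] + te$g[[m]]
    }
  }
  if (!is.null(restraints) && length(restraints$plane)) {
    for (p in restraints$plane) {
      pe <- plane_energy_grad(x, p$rows_a, p$rows_b, p$sigma)
      comp["plane"] <- comp["plane"] + pe$value
      grad <- grad + pe$grad
    }
  }
  list(value = sum(comp), grad = grad, components = comp)
}

tapply_add <- function(v, idx, n) {
  out <- numeric(n)
  t <- tapply(v, idx, sum)
  out[as.integer(names(t))] <- t
  out
}

# Harmonic angle term ((theta - a0)/sigma)^2 with analytic gradient.
angle_energy_grad <- function(pi_, pc, pj, a0, sigma) {
  u <- pi_ - pc; v <- pj - pc
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  cth <- max(-1 + 1e-12, min(1 - 1e-12, sum(u * v) / (nu * nv)))
  th <- acos(cth)
  res <- (th * 180 / pi - a0) / sigma
  dEdth <- 2 * res * (180 / pi) / sigma
  sth <- sqrt(1 - cth^2)
  dth_du <- -(v / (nu * nv) - cth * u / nu^2) / sth
  dth_dv <- -(u / (nu * nv) - cth * v / nv^2) / sth
  list(value = res^2, gi = dEdth * dth_du, gj = dEdth * dth_dv,
       gc = -dEdth * (dth_du + dth_dv))
}

# Harmonic torsion term on the wrapped angular difference, degrees.
torsion_energy_grad <- function(p1, p2, p3, p4, a0, sigma) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- pracma_cross(b1, b2); n2 <- pracma_cross(b2, b3)
  nb2 <- sqrt(sum(b2^2))
  m1 <- pracma_cross(n1, b2 / nb2)
  phi <- atan2(sum(m1 * n2), sum(n1 * n2))
  diff <- (phi * 180 / pi - a0 + 180) %% 360 - 180
  res <- diff / sigma
  # sign matches the atan2 convention used for phi above
  dEdphi <- -2 * res * (180 / pi) / sigma
  # standard analytic dihedral derivatives
  g1 <- -nb2 / sum(n1^2) * n1
  g4 <- nb2 / sum(n2^2) * n2
  s12 <- sum(b1 * b2) / nb2^2
  s32 <- sum(b3 * b2) / nb2^2
  g2 <- -(1 + s12) * g1 + s32 * g4
  g3 <- s12 * g1 - (1 + s32) * g4
  list(value = res^2,
       g = list(dEdphi * g1, dEdphi * g2, dEdphi * g3, dEdphi * g4))
}

# Parallel-plane term: E = sin^2(theta) / sin^2(sigma) where theta is the
# angle between the least-squares plane normals.  The normal of a plane is
# the smallest-eigenvalue eigenvector of the centred covariance; its
# derivative w.r.t. the member atoms follows the eigenvector perturbation
# formula dn = sum_{k != min} v_k v_k^T / (l_min - l_k) dM n.
plane_energy_grad <- function(x, rows_a, rows_b, sigma_deg) {
  pa <- plane_eig(x[rows_a, , drop = FALSE])
  pb <- plane_eig(x[rows_b, , drop = FALSE])
  cth <- sum(pa$normal * pb$normal)
  s2 <- sin(sigma_deg * pi / 180)^2
  value <- (1 - cth^2) / s2
  dE_dcth <- -2 * cth / s2
  grad <- matrix(0, nrow(x), 3)
  grad[rows_a, ] <- grad[rows_a, ] +
    dE_dcth * plane_normal_grad_dot(pa, pb$normal)
  grad[rows_b, ] <- grad[rows_b, ] +
    dE_dcth * plane_normal_grad_dot(pb, pa$normal)
  list(value = value, grad = grad)
}

plane_eig <- function(xs) {
  ctr <- colMeans(xs)
  xc <- sweep(xs, 2, ctr)
  M <- crossprod(xc)
  e <- eigen(M, symmetric = TRUE)
  list(xc = xc, vals = e$values, vecs = e$vectors,
       normal = e$vectors[, 3], m = nrow(xs))
}

# d(n . w)/d(atom positions) for the plane's member atoms.
plane_normal_grad_dot <- function(pl, w) {
  n <- pl$normal
  P <- matrix(0, 3, 3)
  for (k in 1:2) {
    vk <- pl$vecs[, k]
    P <- P + (vk %*% t(vk)) / (pl$vals[3] - pl$vals[k])
  }
  Pw <- P %*% w
  out <- matrix(0, pl$m, 3)
  for (j in seq_len(pl$m)) {
    dj <- pl$xc[j, ]
    # dM for atom j along axis alpha: E_a d_j^T + d_j E_a^T
    for (al in 1:3) {
      dMn <- dj * n[al]
      dMn[al] <- dMn[al] + sum(dj * n)
      out[j, al] <- sum(Pw * dMn)
    }
  }
  out
}
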