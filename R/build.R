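#' Build an ideal poly-alanine alpha-helix
#'
#' Backbone constructed from standard bond lengths and angles with uniform
#' dihedrals (default phi = -57, psi = -47 degrees), giving a rise of about
#' 1.5 A per residue and consecutive CA-CA distances of 3.8 A.
#'
#' @param n_res number of residues (>= 1)
#' @param phi,psi backbone dihedrals, degrees
#' @param chain chain identifier
#' @param b B factor for every atom
#' @return an [atomic_model()] with atoms N, CA, C, O, CB per residue
#' @export
build_ideal_helix <- function(n_res, phi = -57, psi = -47, chain = "A", b = 20) {
  stopifnot(n_res >= 1)
  bl <- c(n_ca = 1.458, ca_c = 1.525, c_n = 1.329, c_o = 1.231, ca_cb = 1.521)
  an <- c(n_ca_c = 111.2, ca_c_n = 116.2, c_n_ca = 121.7, ca_c_o = 120.8,
          n_ca_cb = 110.4)
  N <- list(); CA <- list(); C <- list(); O <- list(); CB <- list()
  N[[1]] <- c(0, 0, 0)
  CA[[1]] <- c(bl["n_ca"], 0, 0)
  ang <- an["n_ca_c"] * pi / 180
  C[[1]] <- CA[[1]] + bl["ca_c"] * c(-cos(ang), sin(ang), 0)
  for (i in seq_len(n_res)) {
    if (i < n_res) {
      N[[i + 1]] <- place_atom(N[[i]], CA[[i]], C[[i]], bl["c_n"], an["ca_c_n"], psi)
      CA[[i + 1]] <- place_atom(CA[[i]], C[[i]], N[[i + 1]], bl["n_ca"], an["c_n_ca"], 180)
      C[[i + 1]] <- place_atom(C[[i]], N[[i + 1]], CA[[i + 1]], bl["ca_c"], an["n_ca_c"], phi)
      O[[i]] <- place_atom(N[[i]], CA[[i]], C[[i]], bl["c_o"], an["ca_c_o"], psi + 180)
    } else {
      O[[i]] <- place_atom(N[[i]], CA[[i]], C[[i]], bl["c_o"], an["ca_c_o"], psi + 180)
    }
    CB[[i]] <- place_atom(C[[i]], N[[i]], CA[[i]], bl["ca_cb"], an["n_ca_cb"], 122.6)
  }
  rows <- list()
  for (i in seq_len(n_res)) {
    xyz <- rbind(N[[i]], CA[[i]], C[[i]], O[[i]], CB[[i]])
    rows[[i]] <- data.frame(chain = chain, seqid = i, ins = "", resname = "ALA",
                            atom = c("N", "CA", "C", "O", "CB"),
                            element = c("N", "C", "C", "O", "C"),
                            x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                            occ = 1, b = b, stringsAsFactors = FALSE)
  }
  atomic_model(do.call(rbind, rows))
}

#' Principal axis of a model's CA (or P) trace
#' @param model an [atomic_model()]
#' @return unit vector along the dominant direction of the trace
#' @export
helix_axis <- function(model) {
  x <- model_coords(model)[model$atoms$atom %in% c("CA", "P"), , drop = FALSE]
  if (nrow(x) < 3) x <- model_coords(model)
  sv <- svd(sweep(x, 2, colMeans(x)))
  ax <- sv$v[, 1]
  # orient along increasing residue order
  if (sum((x[nrow(x), ] - x[1, ]) * ax) < 0) ax <- -ax
  ax
}

# Hydrogen-bond patterns of the supported base-pair classes.  Target
# distances (A) are documented defaults in the 2.8-2.95 A range validated
# against the ideal-duplex generator; first residue listed is the pattern
# anchor.  `c1c1` is the target C1'-C1' span used when only two bonds leave
# an in-plane degree of freedom.
base_pair_patterns <- function() {
  list(
    WC_AU = list(first = "A", second = "U",
                 bonds = data.frame(a = c("N1", "N6"), b = c("N3", "O4"),
                                    d = c(2.82, 2.95)), c1c1 = 10.4),
    WC_GC = list(first = "G", second = "C",
                 bonds = data.frame(a = c("O6", "N1", "N2"),
                                    b = c("N4", "N3", "O2"),
                                    d = c(2.91, 2.95, 2.86)), c1c1 = 10.4),
    GU_wobble = list(first = "G", second = "U",
                     bonds = data.frame(a = c("O6", "N1"), b = c("N3", "O2"),
                                        d = c(2.83, 2.78)), c1c1 = 10.4),
    GU_reverse_wobble = list(first = "G", second = "U",
                             bonds = data.frame(a = c("O6", "N1"),
                                                b = c("N3", "O4"),
                                                d = c(2.83, 2.79)), c1c1 = 10.4)
  )
}

# Build an idealized base pair: returns the two monomers (full nucleotides)
# in the pair frame, partner flipped anti-parallel and placed by least-
# squares fit of the pattern's hydrogen-bond distances.
build_base_pair <- function(res1, res2, class,
                            kind = c("RNA", "DNA")) {
  kind <- match.arg(kind)
  key <- paste(res1, res2, class, kind)
  if (!is.null(.cf_env$pairs[[key]])) return(.cf_env$pairs[[key]])
  pat <- base_pair_patterns()[[class]]
  if (is.null(pat)) stop("unknown base-pair class ", class)
  m1 <- monomer_in_base_frame(res1)
  m2 <- monomer_in_base_frame(res2)
  # flip partner so the pair is anti-parallel (faces opposed)
  x2 <- model_coords(m2) %*% t(rot_x(180))
  l1 <- base_letter(res1); l2 <- base_letter(res2)
  stopifnot(l1 == pat$first, sub("T", "U", l2) == pat$second)
  bname <- pat$bonds
  i1 <- match(bname$a, m1$atoms$atom)
  i2 <- match(bname$b, m2$atoms$atom)
  if (anyNA(i1) || anyNA(i2)) stop("pattern atoms missing from monomers")
  c1a <- match("C1'", m1$atoms$atom); c1b <- match("C1'", m2$atoms$atom)
  p1 <- model_coords(m1)
  objective <- function(par) {
    R <- rot_z(par[1] * 180 / pi)
    q <- x2 %*% t(R)
    q[, 1] <- q[, 1] + par[2]; q[, 2] <- q[, 2] + par[3]
    dd <- sqrt(rowSums((p1[i1, , drop = FALSE] - q[i2, , drop = FALSE])^2))
    e <- sum((dd - bname$d)^2)
    dc <- sqrt(sum((p1[c1a, ] - q[c1b, ])^2))
    e + 0.25 * (dc - pat$c1c1)^2
  }
  best <- NULL
  for (g0 in seq(0, 330, by = 30) * pi / 180)
    for (tx in c(7, 9, 11)) for (ty in c(-3, 0, 3)) {
      r <- optim(c(g0, tx, ty), objective, method = "Nelder-Mead",
                 control = list(maxit = 500, reltol = 1e-12))
      if (is.null(best) || r$value < best$value) best <- r
    }
  best <- optim(best$par, objective, method = "Nelder-Mead",
                control = list(maxit = 2000, reltol = 1e-14))
  R <- rot_z(best$par[1] * 180 / pi)
  x2p <- x2 %*% t(R)
  x2p[, 1] <- x2p[, 1] + best$par[2]; x2p[, 2] <- x2p[, 2] + best$par[3]
  # pair frame: origin midway between the base-ring centroids with the
  # centroid-to-centroid direction along x, so the eventual helix axis
  # threads the stacked base cores
  ctr1 <- colMeans(p1[m1$atoms$atom %in% base_atom_names(l1), , drop = FALSE])
  ctr2 <- colMeans(x2p[m2$atoms$atom %in% base_atom_names(l2), , drop = FALSE])
  mid <- (ctr1 + ctr2) / 2
  xd <- ctr2 - ctr1
  gamma <- atan2(xd[2], xd[1]) * 180 / pi
  Rc <- rot_z(-gamma)
  model_coords(m1) <- sweep(p1, 2, mid) %*% t(Rc)
  model_coords(m2) <- sweep(x2p, 2, mid) %*% t(Rc)
  out <- list(first = m1, second = m2, fit = best$value)
  if (is.null(.cf_env$pairs)) .cf_env$pairs <- list()
  .cf_env$pairs[[key]] <- out
  out
}

wc_complement <- function(letter, kind) {
  comp <- c(A = "U", U = "A", G = "C", C = "G", T = "A")
  out <- comp[[letter]]
  if (kind == "DNA" && out == "U") out <- "T"
  if (kind == "DNA" && letter == "A") out <- "T"
  out
}

#' Build an idealized Watson-Crick duplex
#'
#' Generates a double helix from the given sequence with canonical WC base
#' pairing, by placing idealized base pairs under helical symmetry
#' (per-form rise and twist about the z axis).  The complementary strand is
#' the reverse complement, numbered 5' to 3' in its own chain.  Helical
#' parameters are implementation defaults: A-form rise 2.81 A / twist 32.7
#' degrees, B-form rise 3.38 A / twist 36.0 degrees, with the helix axis
#' through the C1'-C1' midpoints.
#'
#' @param sequence character string over A, C, G, U (RNA) or A, C, G, T (DNA)
#' @param form `"A"` or `"B"`
#' @param kind `"RNA"` or `"DNA"`
#' @return an [atomic_model()] with chains A and B
#' @export
build_ideal_duplex <- function(sequence, form = c("A", "B"),
                               kind = c("RNA", "DNA")) {
  form <- match.arg(form); kind <- match.arg(kind)
  letters1 <- strsplit(toupper(sequence), "")[[1]]
  valid <- if (kind == "RNA") c("A", "C", "G", "U") else c("A", "C", "G", "T")
  if (!length(letters1) || !all(letters1 %in% valid))
    stop("invalid sequence letter(s): ",
         paste(setdiff(letters1, valid), collapse = ", "))
  rise <- if (form == "A") 2.81 else 3.38
  twist <- if (form == "A") 32.7 else 36.0
  n <- length(letters1)
  resname <- function(l) if (kind == "DNA") paste0("D", l) else l
  rows_a <- list(); rows_b <- list()
  for (i in seq_len(n)) {
    l1 <- letters1[i]
    l2 <- wc_complement(l1, kind)
    cls <- if (paste0(sub("T", "U", l1), sub("T", "U", l2)) %in% c("AU", "UA"))
      "WC_AU" else "WC_GC"
    pat <- base_pair_patterns()[[cls]]
    swap <- sub("T", "U", l1) != pat$first
    pair <- if (swap)
      build_base_pair(resname(l2), resname(l1), cls, kind)
    else
      build_base_pair(resname(l1), resname(l2), cls, kind)
    mfirst <- if (swap) pair$second else pair$first
    msecond <- if (swap) pair$first else pair$second
    if (swap) {
      # keep the strand-A base on a fixed side of the helix axis
      Rflip <- rot_z(180)
      model_coords(mfirst) <- model_coords(mfirst) %*% t(Rflip)
      model_coords(msecond) <- model_coords(msecond) %*% t(Rflip)
    }
    Rh <- rot_z((i - 1) * twist)
    shift <- c(0, 0, (i - 1) * rise)
    place <- function(m) {
      x <- model_coords(m) %*% t(Rh)
      sweep(x, 2, -shift)
    }
    a1 <- mfirst$atoms; x1 <- place(mfirst)
    a1$x <- x1[, 1]; a1$y <- x1[, 2]; a1$z <- x1[, 3]
    a1$chain <- "A"; a1$seqid <- i
    rows_a[[i]] <- a1
    a2 <- msecond$atoms; x2 <- place(msecond)
    a2$x <- x2[, 1]; a2$y <- x2[, 2]; a2$z <- x2[, 3]
    a2$chain <- "B"; a2$seqid <- n - i + 1L   # strand B runs antiparallel
    rows_b[[n - i + 1L]] <- a2
  }
  atoms <- do.call(rbind, c(rows_a, rows_b))
  atoms$res_index <- NULL
  atomic_model(atoms)
}
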