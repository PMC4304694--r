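# Idealized monomer geometry (non-hydrogen atoms of ALA, the four RNA and
# four DNA nucleotides, and water), shipped as a plain-text table of ideal
# Chemical Component Dictionary coordinates.  Used by the duplex builder,
# base-pair fixtures and the covalent-geometry tables of the refiner.

monomer_table <- function() {
  if (is.null(.cf_env$monomers)) {
    path <- system.file("extdata", "monomer_geometry.csv", package = "cryofit",
                        mustWork = TRUE)
    .cf_env$monomers <- read.csv(path, stringsAsFactors = FALSE)
  }
  .cf_env$monomers
}

#' Idealized monomer as an atomic model
#'
#' @param resname one of ALA, A, C, G, U, DA, DC, DG, DT, HOH
#' @param chain,seqid identifiers for the returned residue
#' @param b B factor assigned to every atom
#' @export
ideal_monomer <- function(resname, chain = "A", seqid = 1L, b = 20) {
  tab <- monomer_table()
  m <- tab[tab$residue == resname, , drop = FALSE]
  if (!nrow(m)) stop("no ideal geometry for residue '", resname, "'")
  atomic_model(data.frame(chain = chain, seqid = as.integer(seqid), ins = "",
                          resname = resname, atom = m$atom, element = m$element,
                          x = m$x, y = m$y, z = m$z, occ = 1, b = b,
                          stringsAsFactors = FALSE))
}

# Base (ring + exocyclic) atom names per nucleotide letter.
base_atom_names <- function(letter) {
  switch(letter,
    A = c("N9", "C8", "N7", "C5", "C6", "N6", "N1", "C2", "N3", "C4"),
    G = c("N9", "C8", "N7", "C5", "C6", "O6", "N1", "C2", "N2", "N3", "C4"),
    C = c("N1", "C2", "O2", "N3", "C4", "N4", "C5", "C6"),
    U = c("N1", "C2", "O2", "N3", "C4", "O4", "C5", "C6"),
    T = c("N1", "C2", "O2", "N3", "C4", "O4", "C5", "C7", "C6"),
    stop("unknown base letter ", letter))
}

glycosidic_n <- function(letter) if (letter %in% c("A", "G")) "N9" else "N1"

base_letter <- function(resname) sub("^D", "", resname)

# Transform an ideal monomer into its base frame: glycosidic N at the
# origin, base plane = z = 0, C1'->N direction along +x.
monomer_in_base_frame <- function(resname) {
  m <- ideal_monomer(resname)
  letter <- base_letter(resname)
  ring <- base_atom_names(letter)
  a <- m$atoms
  bx <- model_coords(m)[a$atom %in% ring, , drop = FALSE]
  pl <- ls_plane(bx)
  ngly <- model_coords(m)[a$atom == glycosidic_n(letter), ]
  c1p <- model_coords(m)[a$atom == "C1'", ]
  ez <- pl$normal
  # orient the normal consistently across residue types using the ring
  # numbering direction, so "flipping" a partner base is well defined
  ref <- if (letter %in% c("A", "G"))
    pracma_cross(model_coords(m)[a$atom == "C4", ] - ngly,
                 model_coords(m)[a$atom == "C8", ] - ngly)
  else
    pracma_cross(model_coords(m)[a$atom == "C2", ] - ngly,
                 model_coords(m)[a$atom == "C6", ] - ngly)
  if (sum(ez * ref) < 0) ez <- -ez
  xdir <- ngly - c1p
  xdir <- unit(xdir - sum(xdir * ez) * ez)
  ey <- pracma_cross(ez, xdir)
  Rf <- rbind(xdir, ey, ez)           # world -> frame
  model_coords(m) <- sweep(model_coords(m), 2, ngly) %*% t(Rf)
  m
}
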