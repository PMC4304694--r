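#' Read a PDB file into an atomic model
#'
#' Parses fixed-column `ATOM`/`HETATM` records.  Alternate locations are
#' collapsed to the highest-occupancy conformer (first on ties), and
#' hydrogens are dropped by default since maps in the 3-7 Angstrom regime
#' carry no hydrogen signal.  The element is taken from columns 77-78 with a
#' fallback derived from the atom name.
#'
#' @param path PDB file path
#' @param keep_hydrogens keep H/D atoms (default `FALSE`)
#' @return an [atomic_model()]
#' @export
read_pdb <- function(path, keep_hydrogens = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  sel <- which(rec %in% c("ATOM  ", "HETATM"))
  if (!length(sel))
    return(atomic_model(empty_atoms()))
  ln <- lines[sel]
  if (any(nchar(ln) < 54)) {
    bad <- sel[which(nchar(ln) < 54)[1]]
    stop("truncated ATOM/HETATM record at line ", bad)
  }
  num <- function(s, what, lns) {
    v <- suppressWarnings(as.numeric(s))
    if (anyNA(v))
      stop("unparseable ", what, " at line ", lns[which(is.na(v))[1]])
    v
  }
  name <- trimws(substr(ln, 13, 16))
  altloc <- substr(ln, 17, 17)
  resname <- trimws(substr(ln, 18, 20))
  chain <- substr(ln, 22, 22)
  seqid <- as.integer(num(substr(ln, 23, 26), "residue number", sel))
  ins <- trimws(substr(ln, 27, 27))
  x <- num(substr(ln, 31, 38), "x coordinate", sel)
  y <- num(substr(ln, 39, 46), "y coordinate", sel)
  z <- num(substr(ln, 47, 54), "z coordinate", sel)
  occ_s <- trimws(substr(ln, 55, 60))
  occ <- ifelse(occ_s == "", 1, suppressWarnings(as.numeric(occ_s)))
  if (anyNA(occ)) stop("unparseable occupancy at line ", sel[which(is.na(occ))[1]])
  b_s <- trimws(substr(ln, 61, 66))
  b <- ifelse(b_s == "", 0, suppressWarnings(as.numeric(b_s)))
  if (anyNA(b)) stop("unparseable B factor at line ", sel[which(is.na(b))[1]])
  element <- trimws(substr(ln, 77, 78))
  element[element == ""] <- element_from_name(name[element == ""])
  atoms <- data.frame(chain = chain, seqid = seqid, ins = ins,
                      resname = resname, atom = name, element = element,
                      x = x, y = y, z = z, occ = occ, b = b,
                      stringsAsFactors = FALSE)
  # altloc handling: highest occupancy wins, first on ties (stable order)
  if (any(altloc != " " & altloc != "")) {
    key <- paste(chain, seqid, ins, name)
    ord <- order(factor(key, levels = unique(key)), -occ)
    atoms <- atoms[ord, , drop = FALSE]
    atoms <- atoms[!duplicated(paste(atoms$chain, atoms$seqid, atoms$ins, atoms$atom)), , drop = FALSE]
  }
  if (!keep_hydrogens)
    atoms <- atoms[!(toupper(atoms$element) %in% c("H", "D")), , drop = FALSE]
  atomic_model(atoms)
}

empty_atoms <- function() {
  data.frame(chain = character(), seqid = integer(), ins = character(),
             resname = character(), atom = character(), element = character(),
             x = numeric(), y = numeric(), z = numeric(),
             occ = numeric(), b = numeric(), stringsAsFactors = FALSE)
}

element_from_name <- function(name) {
  if (!length(name)) return(character())
  up <- toupper(gsub("[0-9']", "", name))
  two <- c("FE", "NI", "ZN", "MG", "MN", "CL", "BR", "NA", "SE")
  out <- substr(up, 1, 1)
  out[up %in% two] <- up[up %in% two]
  out
}

#' Write an atomic model as a fixed-column PDB file
#'
#' Coordinates are written to three decimals; a round trip through
#' [read_pdb()] reproduces them to that precision.
#'
#' @param model an [atomic_model()]
#' @param path output path
#' @export
write_pdb <- function(model, path) {
  a <- model$atoms
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("REMARK   generated by cryofit", con)
  if (nrow(a)) {
    if (any(abs(c(a$x, a$y, a$z)) >= 10000))
      stop("coordinates exceed PDB field width")
    name4 <- ifelse(nchar(a$atom) >= 4 | nchar(a$element) == 2,
                    sprintf("%-4s", a$atom), sprintf(" %-3s", a$atom))
    rec <- ifelse(a$kind == "other", "HETATM", "ATOM  ")
    lines <- sprintf("%s%5d %s %-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                     rec, seq_len(nrow(a)) %% 100000L, name4, a$resname,
                     a$chain, a$seqid, ifelse(a$ins == "", " ", a$ins),
                     a$x, a$y, a$z, a$occ, a$b, toupper(a$element))
    # TER between chains
    chain_end <- c(a$chain[-1] != a$chain[-nrow(a)], TRUE)
    out <- character()
    for (i in seq_along(lines)) {
      out <- c(out, lines[i])
      if (chain_end[i]) out <- c(out, "TER")
    }
    writeLines(out, con)
  }
  writeLines("END", con)
  invisible(NULL)
}
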