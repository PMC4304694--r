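# External-restraint text I/O in the REFMAC "exte" dialect, plus JSON.

#' Write distance restraints as REFMAC-style external restraint text
#'
#' One line per target, e.g.
#' `exte dist first chain A resi 10 atom CA second chain B resi 22 atom CA
#' value 3.800 sigma 0.100 type 1`; alternative targets of a multi-target
#' group are adjacent lines sharing an `alt group <id>` tag.
#'
#' @param restraints a [restraint_set()]
#' @param path output path
#' @export
write_restraints <- function(restraints, path) {
  d <- restraints$distance
  lines <- character()
  for (i in seq_len(nrow(d))) {
    tg <- d$targets[[i]]
    for (k in seq_len(nrow(tg))) {
      ln <- sprintf(
        "exte dist first chain %s resi %d atom %s second chain %s resi %d atom %s value %.3f sigma %.3f type 1",
        d$chain_a[i], d$seqid_a[i], d$atom_a[i],
        d$chain_b[i], d$seqid_b[i], d$atom_b[i], tg$d[k], tg$sigma[k])
      if (!is.na(d$alt_group[i]))
        ln <- paste0(ln, sprintf(" alt group %d", d$alt_group[i]))
      lines <- c(lines, ln)
    }
  }
  writeLines(lines, path)
  invisible(NULL)
}

#' Read REFMAC-style external restraint text
#'
#' Parses the dialect written by [write_restraints()].  Adjacent lines for
#' the same atom pair sharing an `alt group` tag are merged back into one
#' multi-target restraint.
#'
#' @param path input path
#' @param kind kind label assigned to the restraints
#' @return a [restraint_set()]
#' @export
read_restraints <- function(path, kind = "reference") {
  lines <- grep("^exte dist", readLines(path, warn = FALSE), value = TRUE)
  if (!length(lines)) return(restraint_set(provenance = kind))
  pat <- paste0("^exte dist first chain (\\S+) resi (-?\\d+) atom (\\S+) ",
                "second chain (\\S+) resi (-?\\d+) atom (\\S+) ",
                "value ([0-9.eE+-]+) sigma ([0-9.eE+-]+) type 1",
                "( alt group (\\d+))?\\s*$")
  m <- regmatches(lines, regexec(pat, lines))
  bad <- which(vapply(m, length, 0L) == 0)
  if (length(bad))
    stop("unparseable restraint line ", bad[1], ": ", lines[bad[1]])
  fld <- function(i) vapply(m, `[`, "", i + 1)
  df <- data.frame(
    chain_a = fld(1), seqid_a = as.integer(fld(2)), atom_a = fld(3),
    chain_b = fld(4), seqid_b = as.integer(fld(5)), atom_b = fld(6),
    d = as.numeric(fld(7)), sigma = as.numeric(fld(8)),
    alt_group = suppressWarnings(as.integer(fld(10))),
    stringsAsFactors = FALSE)
  key <- paste(df$chain_a, df$seqid_a, df$atom_a, df$chain_b, df$seqid_b,
               df$atom_b)
  first <- !duplicated(key)
  out <- df[first, c("chain_a", "seqid_a", "atom_a", "chain_b", "seqid_b",
                     "atom_b", "alt_group")]
  out$kind <- ifelse(is.na(out$alt_group), kind, "basepair")
  out$ins_a <- ""; out$ins_b <- ""
  out$targets <- I(lapply(key[first], function(k) {
    sel <- df[key == k, ]
    data.frame(d = sel$d, sigma = sel$sigma,
               label = paste0("alt", seq_len(nrow(sel))))
  }))
  out <- out[, c("kind", "chain_a", "seqid_a", "ins_a", "atom_a", "chain_b",
                 "seqid_b", "ins_b", "atom_b", "alt_group", "targets")]
  restraint_set(out, provenance = paste0("read:", path))
}

#' Serialize a restraint set to JSON
#' @param restraints a [restraint_set()]
#' @param path output path (NULL returns the JSON string)
#' @export
restraints_to_json <- function(restraints, path = NULL) {
  d <- restraints$distance
  obj <- list(
    provenance = restraints$provenance,
    distance = lapply(seq_len(nrow(d)), function(i) {
      list(kind = d$kind[i],
           first = list(chain = d$chain_a[i], seqid = d$seqid_a[i],
                        ins = d$ins_a[i], atom = d$atom_a[i]),
           second = list(chain = d$chain_b[i], seqid = d$seqid_b[i],
                         ins = d$ins_b[i], atom = d$atom_b[i]),
           alt_group = if (is.na(d$alt_group[i])) NULL else d$alt_group[i],
           targets = d$targets[[i]])
    }),
    plane = lapply(restraints$plane, function(p)
      p[c("res_a", "group_a", "res_b", "group_b", "target_angle", "sigma")])
  )
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, null = "null")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(NULL)
}
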