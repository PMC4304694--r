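#' Atomic scattering-factor tables
#'
#' Five-Gaussian parameterizations of atomic scattering factors,
#' `f(s) = sum a_i exp(-b_i s^2 / 4)` with `s = 1/d` in inverse Angstrom.
#' The electron table is the five-Gaussian parameterization of electron
#' scattering factors from International Tables for Crystallography Vol. C
#' (ch. 4.3); the X-ray table is the Cromer-Mann parameterization with its
#' constant term represented as a fifth Gaussian with `b = 0` so both tables
#' share one shape.  Shipped elements: H, C, N, O, P, S, Mg, Fe, Ni, Zn.
#'
#' @param source `"electron"` (default, appropriate for cryo-EM Coulomb
#'   potential maps) or `"xray"`
#' @return data.frame with `element`, `z` and columns `a1..a5`, `b1..b5`
#' @export
scattering_table <- function(source = c("electron", "xray")) {
  source <- match.arg(source)
  key <- paste0("scat_", source)
  if (is.null(.cf_env[[key]])) {
    path <- system.file("extdata", "scattering_factors.csv", package = "cryofit",
                        mustWork = TRUE)
    tab <- read.csv(path, stringsAsFactors = FALSE)
    tab$element <- toupper(tab$element)
    .cf_env[[key]] <- tab[tab$source == source, , drop = FALSE]
  }
  .cf_env[[key]]
}

#' Evaluate an atomic scattering factor
#'
#' @param table a [scattering_table()]
#' @param element element symbol (case-insensitive)
#' @param s spatial frequency `1/d`, inverse Angstrom (vectorized)
#' @return `f(s)`
#' @export
form_factor <- function(table, element, s) {
  row <- table[table$element == toupper(element), , drop = FALSE]
  if (!nrow(row))
    stop("unknown element '", element, "'; supported: ",
         paste(table$element, collapse = ", "))
  a <- as.numeric(row[1, paste0("a", 1:5)])
  b <- as.numeric(row[1, paste0("b", 1:5)])
  out <- numeric(length(s))
  for (i in 1:5) out <- out + a[i] * exp(-b[i] * s^2 / 4)
  out
}

# Per-atom real-space Gaussian mixture parameters for rasterization.
# f(s) = sum a_i exp(-(b_i + B) s^2/4)  <->
# rho(r) = sum a_i (4 pi / (b_i + B))^(3/2) exp(-4 pi^2 r^2 / (b_i + B))
# b is floored at b_min to keep every term resolvable on the grid.
atom_gaussians <- function(model, table, b_add = 0, b_min = 5) {
  el <- toupper(model$atoms$element)
  uel <- unique(el)
  rows <- lapply(uel, function(e) {
    r <- table[table$element == e, , drop = FALSE]
    if (!nrow(r)) {
      warning("element '", e, "' not in scattering table; using C")
      r <- table[table$element == "C", , drop = FALSE]
    }
    r[1, ]
  })
  names(rows) <- uel
  na <- nrow(model$atoms)
  amp <- matrix(0, na, 5); wexp <- matrix(0, na, 5)
  for (e in uel) {
    idx <- which(el == e)
    a <- as.numeric(rows[[e]][paste0("a", 1:5)])
    b <- as.numeric(rows[[e]][paste0("b", 1:5)])
    for (g in 1:5) {
      beff <- pmax(b[g] + model$atoms$b[idx] + b_add, b_min)
      amp[idx, g] <- model$atoms$occ[idx] * a[g] * (4 * pi / beff)^1.5
      wexp[idx, g] <- 4 * pi^2 / beff
    }
  }
  # cutoff where the widest Gaussian falls to 1e-4 of its peak
  rcut <- sqrt(log(1e4) / apply(wexp, 1, min))
  list(amp = amp, wexp = wexp, rcut = pmin(pmax(rcut, 2), 8))
}
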