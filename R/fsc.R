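#' Fourier shell correlation between two maps
#'
#' Per resolution shell (equal width in `s = 1/d`),
#' `FSC = Re(sum F_a conj(F_b)) / sqrt(sum |F_a|^2 sum |F_b|^2)`.  Friedel
#' mates are counted once, so the shell coefficient counts `n_coeffs` are
#' the numbers of independent structure factors.
#'
#' @param a,b [density_map()]s on identical grids
#' @param n_shells number of shells; default `min(dims)/2` capped at 50,
#'   thin enough that weights are about constant within a shell
#' @return an `fsc_curve` data.frame: `shell`, `s_min`, `s_max`, `s_mid`,
#'   `d_max`, `d_min`, `fsc`, `n_coeffs`
#' @export
fsc_between_maps <- function(a, b, n_shells = NULL) {
  if (!same_grid(a, b)) stop("grid mismatch between maps")
  fsc_between_sf(fft(a$values), fft(b$values), dim(a$values), a$voxel, n_shells)
}

fsc_between_sf <- function(Fa, Fb, dims, voxel, n_shells = NULL) {
  sh <- shell_assignment(dims, voxel, n_shells)
  half <- friedel_half_mask(dims)
  use <- half & !is.na(sh$shell)
  shl <- sh$shell[use]
  fa <- Fa[use]; fb <- Fb[use]
  num <- tapply(Re(fa * Conj(fb)), shl, sum)
  da <- tapply(Mod(fa)^2, shl, sum)
  db <- tapply(Mod(fb)^2, shl, sum)
  nn <- tapply(rep(1, length(shl)), shl, sum)
  idx <- as.integer(names(num))
  den <- sqrt(da * db)
  keep <- den > 0 & nn >= 1
  if (any(!keep)) warning(sum(!keep), " empty/zero shell(s) dropped")
  idx <- idx[keep]
  curve <- data.frame(shell = idx,
                      s_min = (idx - 1) * sh$width,
                      s_max = idx * sh$width,
                      s_mid = (idx - 0.5) * sh$width,
                      fsc = as.numeric(num[keep] / den[keep]),
                      n_coeffs = as.integer(nn[keep]))
  curve$d_max <- ifelse(curve$s_min > 0, 1 / curve$s_min, Inf)
  curve$d_min <- 1 / curve$s_max
  curve <- curve[order(curve$shell), ]
  rownames(curve) <- NULL
  class(curve) <- c("fsc_curve", "data.frame")
  curve
}

#' Fourier shell correlation between a model and a map
#'
#' The model side uses complex structure factors from
#' [calc_structure_factors()] on the map's own grid, so phase information
#' enters the comparison (unlike amplitude-only R factors).
#'
#' @param model an [atomic_model()] inside the map box
#' @param map a [density_map()]
#' @param d_min resolution cutoff for the model transform (default Nyquist)
#' @param table a [scattering_table()]
#' @param n_shells number of shells
#' @export
fsc_model_map <- function(model, map, d_min = NULL,
                          table = scattering_table("electron"),
                          n_shells = NULL) {
  sf <- calc_structure_factors(model, map, d_min = d_min, table = table)
  curve <- if (is.null(d_min))
    fsc_between_sf(Conj(sf$F), fft(map$values), sf$dims, sf$voxel, n_shells)
  else
    # shells beyond the model cutoff are empty by construction
    suppressWarnings(fsc_between_sf(Conj(sf$F), fft(map$values), sf$dims,
                                    sf$voxel, n_shells))
  if (!is.null(d_min)) curve <- curve[curve$s_min < 1 / d_min + 1e-12, ]
  class(curve) <- c("fsc_curve", "data.frame")
  curve
}

#' Coefficient-weighted average FSC
#'
#' `FSC_average = sum(N_i FSC_i) / sum(N_i)` over shells, where `N_i` is
#' the number of independent structure factors in shell i.  Because any
#' per-shell-constant reweighting of the coefficients cancels inside each
#' shell's correlation, this single-number metric is approximately
#' independent of sharpening/weighting provided the shells are thin.
#'
#' @param curve an `fsc_curve`
#' @export
fsc_average <- function(curve) {
  if (!nrow(curve)) stop("empty FSC curve")
  sum(curve$n_coeffs * curve$fsc) / sum(curve$n_coeffs)
}

#' Weighted R factor on structure-factor amplitudes
#'
#' `R_w = sum w |F_o - F_c| / sum w |F_o|` over matching coefficients
#' (amplitudes only, so phase errors are invisible to it).  Unlike
#' [fsc_average()], this statistic changes under resolution-dependent
#' reweighting such as sharpening.
#'
#' @param f_obs,f_calc amplitude vectors (or `sf_grid`s, flattened)
#' @param w non-negative weights (default 1)
#' @export
weighted_r_factor <- function(f_obs, f_calc, w = 1) {
  if (inherits(f_obs, "sf_grid")) f_obs <- Mod(f_obs$F)
  if (inherits(f_calc, "sf_grid")) f_calc <- Mod(f_calc$F)
  stopifnot(length(f_obs) == length(f_calc))
  w <- rep(w, length.out = length(f_obs))
  if (any(w < 0) || !all(is.finite(w))) stop("weights must be finite and >= 0")
  den <- sum(w * abs(f_obs))
  if (den == 0) stop("sum of weighted observed amplitudes is zero")
  sum(w * abs(abs(f_obs) - abs(f_calc))) / den
}

#' Resolution at an FSC threshold
#'
#' Finds the first downward crossing of the threshold walking from coarse
#' to fine shells and interpolates linearly in `s` between shell midpoints.
#' The 0.143 default is the half-map criterion for the resolution limit of
#' a reconstruction.  If the curve never crosses, the finest shell edge is
#' returned with attribute `crossed = FALSE`.
#'
#' @param curve an `fsc_curve`
#' @param threshold FSC threshold (default 0.143)
#' @return resolution d in Angstrom with attribute `crossed`
#' @export
resolution_at_threshold <- function(curve, threshold = 0.143) {
  stopifnot(nrow(curve) >= 1)
  f <- curve$fsc; s <- curve$s_mid
  if (f[1] < threshold)
    return(structure(1 / s[1], crossed = TRUE))
  for (i in seq_len(nrow(curve))[-1]) {
    if (f[i - 1] >= threshold && f[i] < threshold) {
      sc <- s[i - 1] + (threshold - f[i - 1]) * (s[i] - s[i - 1]) / (f[i] - f[i - 1])
      return(structure(1 / sc, crossed = TRUE))
    }
  }
  structure(curve$d_min[nrow(curve)], crossed = FALSE)
}

#' Write an FSC curve as two-column text (1/d, FSC)
#' @param curve an `fsc_curve`
#' @param path output path
#' @export
write_fsc_curve <- function(curve, path) {
  write.table(data.frame(s = curve$s_mid, fsc = curve$fsc), path,
              row.names = FALSE, col.names = c("inv_d", "fsc"), quote = FALSE)
  invisible(NULL)
}
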