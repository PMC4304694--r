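# Reciprocal-space helpers shared by sharpening, scaling, structure-factor
# calculation and FSC.  Spatial frequency uses s = 1/d (A^-1) throughout,
# so a temperature factor B multiplies coefficients by exp(-B s^2 / 4).

# Signed integer frequencies along one axis of length n (FFT ordering).
signed_freq_index <- function(n) {
  k <- 0:(n - 1)
  k[k > n / 2] <- k[k > n / 2] - n
  k
}

# Array of |s| (A^-1) for a grid, plus per-axis signed index lists.
map_s_array <- function(dims, voxel) {
  sx <- signed_freq_index(dims[1]) / (dims[1] * voxel[1])
  sy <- signed_freq_index(dims[2]) / (dims[2] * voxel[2])
  sz <- signed_freq_index(dims[3]) / (dims[3] * voxel[3])
  sqrt(outer(outer(sx^2, sy^2, "+"), sz^2, "+"))
}

# Logical mask selecting one member of each Friedel pair (plus the origin).
friedel_half_mask <- function(dims) {
  hx <- signed_freq_index(dims[1])
  hy <- signed_freq_index(dims[2])
  hz <- signed_freq_index(dims[3])
  mz <- array(rep(hz, each = dims[1] * dims[2]), dims)
  my <- array(rep(rep(hy, each = dims[1]), dims[3]), dims)
  mx <- array(rep(hx, dims[2] * dims[3]), dims)
  (mz > 0) | (mz == 0 & my > 0) | (mz == 0 & my == 0 & mx >= 0)
}

inv_fft_real <- function(F) {
  Re(fft(F, inverse = TRUE)) / length(F)
}

#' Structure-factor grid of a density map
#'
#' Complex Fourier coefficients of the map under the crystallographic sign
#' convention `F(h) = sum rho(x) exp(+2 pi i h.x)` scaled by the voxel
#' volume; coefficients beyond `d_min` are zeroed when a cutoff is given.
#'
#' @param map a [density_map()]
#' @param d_min optional resolution cutoff, Angstrom
#' @return object of class `sf_grid`: complex array `F`, `dims`, `voxel`,
#'   `origin`, `d_min`
#' @export
map_structure_factors <- function(map, d_min = NULL) {
  F <- Conj(fft(map$values)) * prod(map$voxel)
  dims <- dim(map$values)
  if (!is.null(d_min)) {
    s <- map_s_array(dims, map$voxel)
    F[s > 1 / d_min] <- 0
  }
  structure(list(F = F, dims = dims, voxel = map$voxel, origin = map$origin,
                 d_min = d_min), class = "sf_grid")
}

sf_to_map <- function(sf, label = "") {
  # inverse of F = Conj(fft(rho)) * Vvox
  vals <- Re(fft(Conj(sf$F) / prod(sf$voxel), inverse = TRUE))
  vals <- array(vals / length(sf$F), sf$dims)
  density_map(vals, sf$voxel, sf$origin, label)
}

#' Sharpen or blur a map with a temperature factor
#'
#' Multiplies every Fourier coefficient by `exp(-B s^2 / 4)` with `s = 1/d`.
#' Negative `B` sharpens (boosts high resolution), positive `B` blurs.  The
#' zero-frequency term is unchanged.
#'
#' @param map a [density_map()]
#' @param B temperature factor, Angstrom^2
#' @export
sharpen_map <- function(map, B) {
  if (!is.finite(B)) stop("B must be finite")
  Fm <- fft(map$values)
  s <- map_s_array(dim(map$values), map$voxel)
  out <- map
  out$values <- array(inv_fft_real(Fm * exp(-B * s^2 / 4)), dim(map$values))
  out
}

#' Low-pass filter a map at a resolution cutoff
#' @param map a [density_map()]
#' @param d resolution, Angstrom; coefficients with `s > 1/d` are zeroed
#' @export
lowpass_map <- function(map, d) {
  Fm <- fft(map$values)
  s <- map_s_array(dim(map$values), map$voxel)
  Fm[s > 1 / d] <- 0
  out <- map
  out$values <- array(inv_fft_real(Fm), dim(map$values))
  out
}

# Shell assignment for a grid: integer shell per coefficient (NA beyond the
# finest usable limit), with shell edges equal width in s.
shell_assignment <- function(dims, voxel, n_shells = NULL) {
  if (is.null(n_shells)) n_shells <- max(2L, min(50L, floor(min(dims) / 2)))
  s <- map_s_array(dims, voxel)
  s_max <- 1 / (2 * max(voxel))    # Nyquist of the coarsest axis
  width <- s_max / n_shells
  shell <- floor(s / width) + 1L
  shell[s > s_max + 1e-12] <- NA_integer_
  shell[shell > n_shells] <- n_shells  # coefficients exactly at the edge
  list(shell = shell, n_shells = as.integer(n_shells), width = width, s = s)
}

#' Scale a map's shell amplitudes to a reference
#'
#' Applies a per-resolution-shell multiplicative factor so that the output
#' map's shell-averaged Fourier amplitude matches the reference: either a
#' reference map on the same grid or a radial amplitude curve (data.frame
#' with columns `s` and `amplitude`).  This places maps with different
#' sharpening histories on a common scale.
#'
#' @param map a [density_map()]
#' @param reference a [density_map()] or a data.frame `(s, amplitude)`
#' @param n_shells number of resolution shells (default from grid size)
#' @param max_scale cap for the per-shell factor (warned when hit)
#' @param method `"shell"` applies one constant factor per shell so shell
#'   means match the reference exactly; `"smooth"` interpolates the
#'   log-scale in `s` (cubic spline through the shell estimates), which
#'   tracks smooth amplitude falloffs such as temperature factors more
#'   faithfully within shells
#' @export
scale_to_reference <- function(map, reference, n_shells = NULL,
                               max_scale = 1e3,
                               method = c("shell", "smooth")) {
  method <- match.arg(method)
  dims <- dim(map$values)
  sh <- shell_assignment(dims, map$voxel, n_shells)
  Fm <- fft(map$values)
  amp <- Mod(Fm)
  shell_mean <- function(v) {
    out <- rep(NA_real_, sh$n_shells)
    t <- tapply(v, sh$shell, mean)
    out[as.integer(names(t))] <- t
    out
  }
  map_amp <- shell_mean(amp)
  if (inherits(reference, "density_map")) {
    if (!same_grid(map, reference)) stop("grid mismatch with reference map")
    ref_amp <- shell_mean(Mod(fft(reference$values)))
  } else {
    stopifnot(is.data.frame(reference), all(c("s", "amplitude") %in% names(reference)))
    mids <- (seq_len(sh$n_shells) - 0.5) * sh$width
    ref_amp <- approx(reference$s, reference$amplitude, xout = mids, rule = 2)$y
  }
  scale <- ref_amp / map_amp
  bad <- !is.na(scale) & (!is.finite(scale) | scale > max_scale)
  zero_ref <- !is.na(map_amp) & map_amp > 0 & !is.na(ref_amp) & ref_amp == 0
  if (any(bad | zero_ref)) {
    warning("per-shell scale capped in ", sum(bad | zero_ref), " shell(s)")
    scale[bad] <- max_scale
  }
  scale[zero_ref] <- 0
  scale[is.na(scale)] <- 1
  fac <- array(1, dims)
  ok <- !is.na(sh$shell)
  if (method == "shell" || any(scale <= 0)) {
    fac[ok] <- scale[sh$shell[ok]]
  } else {
    mids <- (seq_len(sh$n_shells) - 0.5) * sh$width
    sp <- stats::spline(mids, log(scale), xout = pmin(sh$s[ok], max(mids)),
                        method = "natural")
    fac[ok] <- exp(sp$y)
  }
  out <- map
  out$values <- array(inv_fft_real(Fm * fac), dims)
  out
}

#' Radial amplitude profile of a map
#' @param map a [density_map()]
#' @param n_shells number of shells
#' @return data.frame with `s` (shell midpoint, 1/A) and `amplitude`
#' @export
radial_amplitude <- function(map, n_shells = NULL) {
  sh <- shell_assignment(dim(map$values), map$voxel, n_shells)
  amp <- Mod(fft(map$values))
  t <- tapply(amp, sh$shell, mean)
  idx <- as.integer(names(t))
  data.frame(s = (idx - 0.5) * sh$width, amplitude = as.numeric(t))
}
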