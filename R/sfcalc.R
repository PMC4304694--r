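#' Structure factors of an atomic model on a map grid
#'
#' Computes `F(h) = sum_a occ_a f_a(s) exp(-B_a s^2/4) exp(2 pi i s.x_a)`
#' by rasterizing the model's real-space Gaussian density onto the grid and
#' applying an FFT; coefficients beyond `d_min` are zeroed.  Atom B factors
#' are taken from the model (`b_add` is added on top, e.g. to emulate an
#' overall temperature factor).
#'
#' @param model an [atomic_model()] lying inside the box
#' @param geometry list with `dims` (grid size), `voxel` and `origin`, or a
#'   [density_map()] to borrow geometry from
#' @param d_min resolution cutoff, Angstrom (must respect the Nyquist limit
#'   `2 * voxel`); `NULL` keeps every coefficient
#' @param table a [scattering_table()] (default electron)
#' @param b_add extra overall B, Angstrom^2
#' @return an `sf_grid` (see [map_structure_factors()])
#' @export
calc_structure_factors <- function(model, geometry, d_min = NULL,
                                   table = scattering_table("electron"),
                                   b_add = 0) {
  g <- as_geometry(geometry)
  if (!is.null(d_min) && d_min < 2 * max(g$voxel) - 1e-9)
    stop("d_min ", d_min, " is finer than the Nyquist limit ", 2 * max(g$voxel))
  x <- model_coords(model)
  lo <- g$origin; hi <- g$origin + (g$dims - 1) * g$voxel
  if (any(sweep(x, 2, lo) < 0) || any(sweep(x, 2, hi) > 0))
    stop("model extends outside the box")
  rho <- model_density(model, g, table, b_add)
  F <- Conj(fft(rho$values)) * prod(g$voxel)
  if (!is.null(d_min)) {
    s <- map_s_array(g$dims, g$voxel)
    F[s > 1 / d_min] <- 0
  }
  structure(list(F = F, dims = g$dims, voxel = g$voxel, origin = g$origin,
                 d_min = d_min), class = "sf_grid")
}

as_geometry <- function(geometry) {
  if (inherits(geometry, "density_map"))
    return(list(dims = dim(geometry$values), voxel = geometry$voxel,
                origin = geometry$origin))
  stopifnot(all(c("dims", "voxel", "origin") %in% names(geometry)))
  list(dims = as.integer(geometry$dims),
       voxel = rep(as.numeric(geometry$voxel), length.out = 3),
       origin = as.numeric(geometry$origin))
}

#' Rasterize a model's scattering density onto a grid
#'
#' @inheritParams calc_structure_factors
#' @return a [density_map()]
#' @export
model_density <- function(model, geometry,
                          table = scattering_table("electron"), b_add = 0) {
  g <- as_geometry(geometry)
  p <- atom_gaussians(model, table, b_add)
  vals <- cpp_atom_density(g$dims, g$origin, g$voxel, model_coords(model),
                           p$amp, p$wexp, p$rcut)
  density_map(array(vals, g$dims), g$voxel, g$origin, label = "model density")
}

#' Simulate a band-limited reconstruction of a model
#'
#' Computes the model's structure factors on the requested grid, truncates
#' them at the stated resolution, inverts, and adds independent white
#' Gaussian voxel noise.  This emulates the signal content of a single-
#' particle reconstruction at a given nominal resolution; see the package
#' vignette for what it deliberately does not emulate (CTF, alignment error,
#' colored noise).
#'
#' @param model an [atomic_model()]
#' @param box box edge lengths, Angstrom (length 1 or 3)
#' @param voxel voxel size, Angstrom
#' @param resolution band limit, Angstrom (>= `2 * voxel`)
#' @param noise_sigma standard deviation of the added voxel noise, density
#'   units; `noise_rel` instead gives it as a fraction of the noiseless
#'   signal's robust sd
#' @param seed integer RNG seed (ignored when no noise is added)
#' @param noise_rel optional relative noise level (overrides `noise_sigma`)
#' @param table a [scattering_table()]
#' @return a [density_map()] with origin at 0
#' @export
simulate_map <- function(model, box, voxel = 1, resolution = 4,
                         noise_sigma = 0, seed = 1, noise_rel = NULL,
                         table = scattering_table("electron")) {
  box <- rep(box, length.out = 3)
  dims <- as.integer(round(box / voxel))
  g <- list(dims = dims, voxel = rep(voxel, 3), origin = c(0, 0, 0))
  sf <- calc_structure_factors(model, g, d_min = resolution, table = table)
  map <- sf_to_map(sf, label = sprintf("simulated %.2f A", resolution))
  if (!is.null(noise_rel)) {
    st <- robust_map_stats(map)
    noise_sigma <- noise_rel * st$sd
  }
  if (noise_sigma > 0) {
    noise <- with_seed(seed, rnorm(length(map$values), 0, noise_sigma))
    map$values <- map$values + array(noise, dims)
  }
  map
}

#' Simulate an independent-noise half-map pair
#'
#' The two maps share the identical band-limited signal and differ only in
#' their noise realizations, mirroring the two reconstructions computed
#' from disjoint halves of a particle stack.
#'
#' @inheritParams simulate_map
#' @param seed_pair two distinct integer seeds
#' @return list of two [density_map()]s
#' @export
simulate_half_maps <- function(model, box, voxel = 1, resolution = 4,
                               noise_sigma = 0, seed_pair = c(1, 2),
                               noise_rel = NULL,
                               table = scattering_table("electron")) {
  stopifnot(length(seed_pair) == 2)
  if (seed_pair[1] == seed_pair[2])
    stop("half-map seeds must differ (independent noise)")
  h1 <- simulate_map(model, box, voxel, resolution, noise_sigma,
                     seed_pair[1], noise_rel, table)
  h2 <- simulate_map(model, box, voxel, resolution, noise_sigma,
                     seed_pair[2], noise_rel, table)
  h1$label <- "half map 1"; h2$label <- "half map 2"
  list(h1, h2)
}
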