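#' Density map container
#'
#' A 3D scalar grid on orthogonal axes.  Voxel centre `(i, j, k)` (1-based)
#' sits at `origin + (i-1, j-1, k-1) * voxel`, x fastest in memory.
#'
#' @param values 3D numeric array (nx, ny, nz), all finite
#' @param voxel voxel size per axis, Angstrom (length 1 or 3, > 0)
#' @param origin Cartesian position of the first voxel centre, Angstrom
#' @param label free-text label
#' @return an object of class `density_map`
#' @export
density_map <- function(values, voxel = 1, origin = c(0, 0, 0), label = "") {
  stopifnot(is.array(values), length(dim(values)) == 3)
  if (any(dim(values) < 2)) stop("grid must be at least 2 voxels per axis")
  if (!all(is.finite(values))) stop("map values must be finite")
  voxel <- rep(as.numeric(voxel), length.out = 3)
  if (any(voxel <= 0)) stop("voxel size must be positive")
  structure(list(values = values, voxel = voxel,
                 origin = as.numeric(origin), label = as.character(label)),
            class = "density_map")
}

#' @export
print.density_map <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<density_map> %dx%dx%d, voxel (%.3g, %.3g, %.3g) A, origin (%.4g, %.4g, %.4g)%s\n",
              d[1], d[2], d[3], x$voxel[1], x$voxel[2], x$voxel[3],
              x$origin[1], x$origin[2], x$origin[3],
              if (nzchar(x$label)) paste0(" [", x$label, "]") else ""))
  invisible(x)
}

map_dims <- function(map) dim(map$values)

same_grid <- function(a, b, tol = 1e-6) {
  all(map_dims(a) == map_dims(b)) &&
    max(abs(a$voxel - b$voxel)) < tol && max(abs(a$origin - b$origin)) < tol
}

#' Robust map statistics by modal-bin exclusion
#'
#' EM reconstructions sit in large boxes mostly filled with near-constant
#' solvent, which deflates the naive standard deviation of the signal.  The
#' values are histogrammed into finely sampled bins over the full range, the
#' voxels falling in the single modal bin are discarded, and the mean and
#' standard deviation are computed from the remainder.  The plain mean/sd
#' are returned alongside for comparison.
#'
#' @param map a [density_map()]
#' @param n_bins histogram bins (default 10000)
#' @return object of class `map_statistics`: `mean`, `sd`, `n_used`,
#'   `n_discarded`, `bin_width`, `raw_mean`, `raw_sd`
#' @export
robust_map_stats <- function(map, n_bins = 10000) {
  v <- as.vector(map$values)
  rng <- range(v)
  if (diff(rng) == 0) stop("degenerate map: all voxels identical")
  w <- diff(rng) / n_bins
  bin <- pmin(floor((v - rng[1]) / w) + 1L, n_bins)
  counts <- tabulate(bin, n_bins)
  modal <- which.max(counts)
  keep <- bin != modal
  if (sum(keep) < 2) stop("degenerate map: all voxels in the modal bin")
  m <- mean(v[keep]); s <- sd(v[keep])
  if (s == 0) stop("degenerate map: zero spread outside the modal bin")
  structure(list(mean = m, sd = s, n_used = sum(keep),
                 n_discarded = sum(!keep), bin_width = w,
                 raw_mean = mean(v), raw_sd = sd(v)),
            class = "map_statistics")
}

#' @export
print.map_statistics <- function(x, ...) {
  cat(sprintf("<map_statistics> robust mean %.4g sd %.4g (raw %.4g/%.4g), used %d, discarded %d\n",
              x$mean, x$sd, x$raw_mean, x$raw_sd, x$n_used, x$n_discarded))
  invisible(x)
}

#' Trilinear interpolation of map density
#'
#' Positions outside the grid bounding box return 0 and are flagged in the
#' `"oob"` attribute rather than raising an error: randomized pose searches
#' are allowed to wander into the solvent padding.
#'
#' @param map a [density_map()]
#' @param position length-3 vector or n x 3 matrix of Cartesian positions
#' @return numeric vector of interpolated values with attribute `oob`
#' @export
interpolate_map <- function(map, position) {
  if (is.null(dim(position))) position <- matrix(position, ncol = 3)
  r <- cpp_trilinear(map$values, dim(map$values),
                     map$origin, map$voxel, position)
  structure(r$value, oob = r$oob)
}

#' Z-weighted density score of a model in a map
#'
#' The sum over atoms of the standardized interpolated density,
#' `sum w_a (rho(x_a) - mean) / sd`, with weights equal to the atomic number
#' (default) or 1.  Statistics should come from [robust_map_stats()] of the
#' same map so the score is comparable between maps.  The number of atoms
#' falling outside the grid is attached as attribute `n_oob`.
#'
#' @param map a [density_map()]
#' @param stats a `map_statistics` for this map
#' @param model an [atomic_model()]
#' @param weight_mode `"atomic_number"` or `"unit"`
#' @export
z_weighted_score <- function(map, stats, model,
                             weight_mode = c("atomic_number", "unit")) {
  weight_mode <- match.arg(weight_mode)
  if (stats$sd == 0) stop("map statistics have zero sd")
  w <- if (weight_mode == "atomic_number") atomic_numbers(model) else
    rep(1, n_atoms(model))
  v <- interpolate_map(map, model_coords(model))
  structure(sum(w * (v - stats$mean)) / stats$sd, n_oob = sum(attr(v, "oob")))
}

#' Mask a map around a model
#'
#' Voxels farther than `radius + soft_edge` from every atom are zeroed;
#' retained voxels inside `radius` are unchanged and the soft edge applies a
#' cosine falloff.
#'
#' @param map a [density_map()]
#' @param model an [atomic_model()]
#' @param radius Angstrom (> 0)
#' @param soft_edge Angstrom (>= 0)
#' @export
mask_by_model <- function(map, model, radius, soft_edge = 0) {
  stopifnot(radius > 0, soft_edge >= 0)
  rmax <- radius + soft_edge + 1e-9
  d <- cpp_min_dist(dim(map$values), map$origin, map$voxel,
                    model_coords(model), rmax)
  f <- numeric(length(d))
  f[d <= radius] <- 1
  if (soft_edge > 0) {
    edge <- d > radius & d < radius + soft_edge
    f[edge] <- 0.5 * (1 + cos(pi * (d[edge] - radius) / soft_edge))
  }
  out <- map
  out$values <- array(as.vector(map$values) * f, dim(map$values))
  out
}

#' Spherical segment radii well suited to protein domains and RNA motifs
#' @param what `"protein"` (34 A) or `"rna"` (17 A)
#' @export
segment_radius <- function(what = c("protein", "rna")) {
  c(protein = 34, rna = 17)[[match.arg(what)]]
}

#' Cut a spherical segment out of a map
#'
#' Returns the minimal bounding sub-grid with voxels outside the sphere set
#' to zero; the origin is updated so world coordinates are preserved.
#'
#' @param map a [density_map()]
#' @param center sphere centre, Angstrom
#' @param radius sphere radius, Angstrom (> 0); see [segment_radius()]
#' @export
segment_sphere <- function(map, center, radius) {
  stopifnot(radius > 0, length(center) == 3)
  d <- dim(map$values)
  lo <- pmax(1, floor((center - radius - map$origin) / map$voxel) + 1)
  hi <- pmin(d, ceiling((center + radius - map$origin) / map$voxel) + 1)
  if (any(lo > hi)) stop("sphere does not intersect the map")
  vals <- map$values[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  origin <- map$origin + (lo - 1) * map$voxel
  nd <- dim(vals)
  gx <- origin[1] + (seq_len(nd[1]) - 1) * map$voxel[1] - center[1]
  gy <- origin[2] + (seq_len(nd[2]) - 1) * map$voxel[2] - center[2]
  gz <- origin[3] + (seq_len(nd[3]) - 1) * map$voxel[3] - center[3]
  r2 <- outer(outer(gx^2, gy^2, "+"), gz^2, "+")
  if (!any(r2 <= radius^2)) stop("sphere does not intersect the map")
  vals[r2 > radius^2] <- 0
  density_map(vals, map$voxel, origin, label = paste0(map$label, " [segment]"))
}

#' Density-weighted centroid of a map
#'
#' Centroid of voxel centres weighted by positive density; used as the
#' anchor point when screening folds against a segmented map.
#' @param map a [density_map()]
#' @export
map_centroid <- function(map) {
  d <- dim(map$values)
  w <- pmax(as.vector(map$values), 0)
  if (sum(w) == 0) w <- rep(1, length(w))
  gx <- map$origin[1] + (seq_len(d[1]) - 1) * map$voxel[1]
  gy <- map$origin[2] + (seq_len(d[2]) - 1) * map$voxel[2]
  gz <- map$origin[3] + (seq_len(d[3]) - 1) * map$voxel[3]
  idx <- arrayInd(seq_along(w), d)
  c(sum(w * gx[idx[, 1]]), sum(w * gy[idx[, 2]]), sum(w * gz[idx[, 3]])) / sum(w)
}

#' Voxelwise (weighted) average of maps on a common grid
#' @param maps list of [density_map()] with identical geometry
#' @param weights optional per-map weights (default equal)
#' @export
average_maps <- function(maps, weights = NULL) {
  stopifnot(length(maps) >= 1)
  for (m in maps[-1]) if (!same_grid(maps[[1]], m)) stop("grid mismatch")
  if (is.null(weights)) weights <- rep(1, length(maps))
  stopifnot(length(weights) == length(maps), sum(weights) > 0)
  acc <- array(0, dim(maps[[1]]$values))
  for (i in seq_along(maps)) acc <- acc + weights[i] * maps[[i]]$values
  density_map(acc / sum(weights), maps[[1]]$voxel, maps[[1]]$origin,
              label = "average")
}

#' Composite of maps with averaging only where masks overlap
#'
#' `sum(m_i * mask_i) / sum(mask_i)` where the mask sum is positive, 0
#' elsewhere.  With binary disjoint masks each region is copied verbatim;
#' averaging happens only at interfaces where masks overlap.
#'
#' @param maps list of [density_map()] with identical geometry
#' @param masks list of [density_map()] with values in `[0, 1]`
#' @export
composite_maps <- function(maps, masks) {
  stopifnot(length(maps) == length(masks), length(maps) >= 1)
  for (m in c(maps[-1], masks)) if (!same_grid(maps[[1]], m)) stop("grid mismatch")
  num <- array(0, dim(maps[[1]]$values)); den <- num
  for (i in seq_along(maps)) {
    mk <- masks[[i]]$values
    if (min(mk) < 0 || max(mk) > 1) stop("mask values must lie in [0, 1]")
    num <- num + maps[[i]]$values * mk
    den <- den + mk
  }
  out <- num
  out[den > 0] <- num[den > 0] / den[den > 0]
  out[den <= 0] <- 0
  density_map(out, maps[[1]]$voxel, maps[[1]]$origin, label = "composite")
}
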