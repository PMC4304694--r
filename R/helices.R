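#' Find alpha-helix placements in a map
#'
#' Six-dimensional search for helical density: seeds are the strongest
#' local maxima of a 5 Angstrom low-passed copy of the map (at least 5 A
#' apart); at each seed an ideal poly-alanine helix is scored over a
#' deterministic quasi-uniform set of orientations and the best is polished
#' by [rigid_body_refine()].  Overlapping placements (centroids closer than
#' 5 A) are suppressed, keeping the higher score.
#'
#' @param map a [density_map()]
#' @param helix_length residues in the probe helix (default 12)
#' @param n_seeds number of density seeds to try (default 5)
#' @param n_orientations orientations per seed (default 100)
#' @param stats optional precomputed [robust_map_stats()]
#' @return list of placements, each with `model`, `score`, `center`
#' @export
find_helices <- function(map, helix_length = 12, n_seeds = 5,
                         n_orientations = 100, stats = NULL) {
  if (is.null(stats)) stats <- robust_map_stats(map)
  lp <- lowpass_map(map, 5)
  seeds <- local_maxima(lp, n_seeds, min_sep = 5)
  probe <- center_model(build_ideal_helix(helix_length))
  X0 <- model_coords(probe)
  w <- atomic_numbers(probe)
  rots <- quasi_uniform_rotations(n_orientations)
  placements <- list()
  for (sd_i in seq_len(nrow(seeds))) {
    ctr <- seeds[sd_i, ]
    sc <- vapply(rots, function(R) {
      x <- sweep(X0 %*% t(R), 2, -ctr)
      r <- cpp_trilinear(map$values, dim(map$values), map$origin,
                         map$voxel, x)
      sum(w * (r$value - stats$mean)) / stats$sd
    }, 0)
    kbest <- which.max(sc)
    m0 <- probe
    model_coords(m0) <- sweep(X0 %*% t(rots[[kbest]]), 2, -ctr)
    fit <- rigid_body_refine(m0, map, stats)
    placements[[length(placements) + 1]] <-
      list(model = fit$model, score = fit$score,
           center = model_centroid(fit$model))
  }
  placements <- placements[order(vapply(placements, `[[`, 0, "score"),
                                 decreasing = TRUE)]
  kept <- list()
  for (p in placements) {
    clash <- any(vapply(kept, function(q)
      sqrt(sum((p$center - q$center)^2)) < 5, TRUE))
    if (!clash) kept[[length(kept) + 1]] <- p
  }
  kept
}

# Strongest local maxima of a map, at least min_sep apart (world coords).
local_maxima <- function(map, n, min_sep = 5) {
  v <- map$values
  d <- dim(v)
  inner <- v[2:(d[1] - 1), 2:(d[2] - 1), 2:(d[3] - 1)]
  is_max <- array(TRUE, dim(inner))
  for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
    if (dx == 0 && dy == 0 && dz == 0) next
    nb <- v[(2 + dx):(d[1] - 1 + dx), (2 + dy):(d[2] - 1 + dy),
            (2 + dz):(d[3] - 1 + dz)]
    is_max <- is_max & (inner >= nb)
  }
  idx <- which(is_max, arr.ind = TRUE) + 1L
  vals <- v[idx]
  ord <- order(vals, decreasing = TRUE)
  out <- matrix(0, 0, 3)
  for (k in ord) {
    p <- map$origin + (idx[k, ] - 1) * map$voxel
    if (nrow(out) &&
        any(sqrt(rowSums(sweep(out, 2, p)^2)) < min_sep)) next
    out <- rbind(out, p)
    if (nrow(out) >= n) break
  }
  out
}

#' Choose the orientation of a placed helix
#'
#' Builds the 180-degree flipped copy (rotation about an axis perpendicular
#' to the helix axis through the centroid), jiggle-fits both candidates and
#' returns the higher-scoring orientation together with both scores.  At
#' subnanometre resolution helices appear as nearly featureless tubes, so
#' the score gap shrinks as resolution worsens.
#'
#' @param helix an [atomic_model()] placed approximately in density
#' @param map a [density_map()]
#' @param seed seed forwarded to [jiggle_fit()]
#' @param ... further arguments to [jiggle_fit()]
#' @return list with `model`, `flipped` (logical), `score`, `score_other`
#' @export
orient_helix <- function(helix, map, seed = 1, ...) {
  ax <- helix_axis(helix)
  perp <- pracma_cross(ax, c(1, 0, 0))
  if (sqrt(sum(perp^2)) < 1e-6) perp <- pracma_cross(ax, c(0, 1, 0))
  ctr <- model_centroid(helix)
  R <- axis_rotation(perp, 180)
  flip <- helix
  model_coords(flip) <- sweep(sweep(model_coords(helix), 2, ctr) %*% t(R),
                              2, -ctr)
  f1 <- jiggle_fit(helix, map, seed = seed, ...)
  f2 <- jiggle_fit(flip, map, seed = seed, ...)
  if (f1$score >= f2$score)
    list(model = f1$model, flipped = FALSE, score = f1$score,
         score_other = f2$score)
  else
    list(model = f2$model, flipped = TRUE, score = f2$score,
         score_other = f1$score)
}
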