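#' Morph a model into density by averaged fragment fits
#'
#' Deforms a nearly correct model toward the density while preserving local
#' geometry.  For each residue a short fragment (default five residues,
#' truncated at termini) centred on it is rigid-body fitted to the map,
#' yielding a rotation-translation operator per residue.  Each residue then
#' receives the robust average of the operators of its spatial environment
#' (residues with atoms within `env_radius`): operators are sorted by the
#' mean displacement they induce on the central residue's atoms, the top
#' and bottom `trim_fraction` are discarded, and the rest are averaged
#' (quaternion mean with hemisphere alignment for rotations, arithmetic
#' mean of induced centroid displacements for translations).  Applying
#' these smoothed local shifts is repeated `n_iterations` times; serial
#' application is often needed for convergence, and larger environments
#' give smaller per-pass shifts.
#'
#' @param model an [atomic_model()]
#' @param map a [density_map()]
#' @param fragment_length odd fragment size >= 3 (default 5)
#' @param env_radius environment radius, Angstrom (default 10)
#' @param trim_fraction fraction trimmed from each end (default 0.25)
#' @param n_iterations morphing passes (default 1)
#' @param max_eval per-fragment refinement budget
#' @param frag_max_rot,frag_max_trans per-pass bounds on each fragment fit
#'   (degrees / Angstrom); morphing is meant to apply local shifts, and the
#'   bounds keep individual fragments from jumping helical-registry minima
#' @param stats optional precomputed [robust_map_stats()]
#' @return the morphed [atomic_model()]
#' @export
morph <- function(model, map, fragment_length = 5, env_radius = 10,
                  trim_fraction = 0.25, n_iterations = 1, max_eval = 600,
                  frag_max_rot = 15, frag_max_trans = 2, stats = NULL) {
  stopifnot(fragment_length >= 3, fragment_length %% 2 == 1,
            trim_fraction >= 0, trim_fraction < 0.5, n_iterations >= 1)
  if (is.null(stats)) stats <- robust_map_stats(map)
  half <- (fragment_length - 1) / 2
  for (iter in seq_len(n_iterations)) {
    a <- model$atoms
    x <- model_coords(model)
    rt <- residue_table(model)
    nr <- nrow(rt)
    res_rows <- split(seq_len(nrow(a)), a$res_index)
    res_centroid <- t(vapply(res_rows, function(r) colMeans(x[r, , drop = FALSE]),
                             numeric(3)))
    # per-residue fragment fit
    ops <- vector("list", nr)
    for (i in seq_len(nr)) {
      same_chain <- which(rt$chain == rt$chain[i])
      lo <- max(min(same_chain), i - half)
      hi <- min(max(same_chain), i + half)
      frag <- model_subset(model, res_index = lo:hi)
      fit <- rigid_body_refine(frag, map, stats, max_eval = max_eval,
                               max_rot = frag_max_rot,
                               max_trans = frag_max_trans)
      ops[[i]] <- fit$op
    }
    # environment averaging
    newx <- x
    for (i in seq_len(nr)) {
      rows_i <- res_rows[[i]]
      xi <- x[rows_i, , drop = FALSE]
      # environment: residues with centroid within env_radius + slack,
      # verified against atom distances
      d2c <- rowSums(sweep(res_centroid, 2, res_centroid[i, ])^2)
      cand <- which(d2c <= (env_radius + 8)^2)
      env <- cand[vapply(cand, function(j) {
        xj <- x[res_rows[[j]], , drop = FALSE]
        min_cross_dist2(xj, xi) <= env_radius^2
      }, TRUE)]
      if (!length(env)) {
        warning("residue ", i, " has an empty environment; identity applied")
        next
      }
      disp <- vapply(env, function(j) {
        mean(sqrt(rowSums((apply_rt(ops[[j]], xi) - xi)^2)))
      }, 0)
      ord <- env[order(disp)]
      ntrim <- floor(length(ord) * trim_fraction)
      keep <- ord[seq.int(ntrim + 1, length(ord) - ntrim)]
      Rbar <- mean_rotation(lapply(keep, function(j) ops[[j]]$R))
      ci <- res_centroid[i, ]
      dbar <- colMeans(do.call(rbind, lapply(keep, function(j)
        apply_rt(ops[[j]], ci) - ci)))
      newx[rows_i, ] <- sweep(sweep(xi, 2, ci) %*% t(Rbar), 2, -(ci + dbar))
    }
    model_coords(model) <- newx
  }
  model
}
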