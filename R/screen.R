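#' Screen a density segment against a library of candidate folds
#'
#' Rigid-body screening of each library domain against a (typically
#' spherically segmented) map: the map is low-passed to `d_limit`, each
#' domain is centred on the segment's density centroid and scored with the
#' Z-weighted density sum over a deterministic quasi-uniform orientation
#' ensemble, each orientation polished by translation-only rigid
#' refinement; the best orientation is then polished with the full
#' six-parameter refinement.  The contrast score of a domain is
#' `(S_max - mean(S)) / sd(S)` over its pose-score ensemble -- the
#' difference between the highest and the mean score expressed in standard
#' uncertainties.  A contrast above about 3 is a good indication of a
#' correct solution; domains are returned ranked by contrast.
#'
#' @param map_segment a [density_map()] (see [segment_sphere()])
#' @param library list of [atomic_model()] domains (optionally named)
#' @param n_orientations orientations per domain (>= 2, default 500)
#' @param d_limit high-resolution limit, Angstrom (default 5)
#' @param max_eval translation-refinement budget per orientation
#' @return list of results ranked by contrast, each with `domain_id`,
#'   `contrast`, `best_score`, `best_model`, `n_poses`, `scores` and a
#'   `flagged` marker when the score spread is zero
#' @export
fold_screen <- function(map_segment, library, n_orientations = 500,
                        d_limit = 5, max_eval = 120) {
  stopifnot(n_orientations >= 2, length(library) >= 1)
  lp <- lowpass_map(map_segment, d_limit)
  stats <- tryCatch(robust_map_stats(lp), error = function(e) NULL)
  ids <- names(library)
  if (is.null(ids)) ids <- sprintf("domain_%02d", seq_along(library))
  if (is.null(stats)) {
    # flat map: every domain flagged, no contrast defined
    return(lapply(ids, function(id)
      list(domain_id = id, contrast = NA_real_, best_score = NA_real_,
           best_model = NULL, n_poses = n_orientations, flagged = TRUE)))
  }
  ctr <- map_centroid(lp)
  rots <- quasi_uniform_rotations(n_orientations)
  out <- vector("list", length(library))
  for (di in seq_along(library)) {
    dom <- center_model(library[[di]], at = ctr)
    X0 <- sweep(model_coords(dom), 2, ctr)
    w <- atomic_numbers(dom)
    scores <- numeric(n_orientations)
    best <- list(score = -Inf, k = 1L)
    for (k in seq_along(rots)) {
      mk <- dom
      model_coords(mk) <- sweep(X0 %*% t(rots[[k]]), 2, -ctr)
      fit <- rigid_body_refine(mk, lp, stats, translate_only = TRUE,
                               max_eval = max_eval)
      scores[k] <- fit$score
      if (fit$score > best$score) best <- list(score = fit$score, k = k,
                                               model = fit$model)
    }
    polish <- rigid_body_refine(best$model, lp, stats)
    s_sd <- sd(scores)
    out[[di]] <- list(domain_id = ids[di],
                      contrast = if (s_sd > 0)
                        (max(polish$score, max(scores)) - mean(scores)) / s_sd
                      else NA_real_,
                      best_score = max(polish$score, max(scores)),
                      best_model = polish$model,
                      n_poses = n_orientations, scores = scores,
                      flagged = s_sd == 0)
  }
  out[order(vapply(out, function(r)
    if (is.na(r$contrast)) -Inf else r$contrast, 0), decreasing = TRUE)]
}
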