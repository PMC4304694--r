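# Rigid-body scoring and local refinement against density.

# Internal: score transformed coordinates.  X0 is centred on `center`;
# pose = (rx, ry, rz degrees, tx, ty, tz).
pose_score <- function(map, stats, X0, center, w, pose) {
  cpp_pose_score(map$values, dim(map$values), map$origin,
                 map$voxel, X0, center, w, pose, stats$mean, stats$sd)
}

pose_to_rt <- function(pose, center) {
  R <- rot_z(pose[3]) %*% rot_y(pose[2]) %*% rot_x(pose[1])
  t <- center + pose[4:6] - as.numeric(R %*% center)
  rt_op(R, t)
}

#' Locally refine a rigid-body pose against density
#'
#' Derivative-free coordinate search over the six rigid-body parameters
#' (rotations about the selection centroid, then translation), scored by
#' the Z-weighted density sum.  Steps start at 2 degrees / half a voxel and
#' shrink by half whenever a full sweep yields no improvement, terminating
#' below 0.1 degree and 0.01 A or after `max_eval` score evaluations.  The
#' returned score never falls below the starting score.
#'
#' @param model an [atomic_model()] (the selection to move)
#' @param map a [density_map()]
#' @param stats [robust_map_stats()] of the map (computed when `NULL`)
#' @param weight_mode passed to [z_weighted_score()]
#' @param translate_only restrict the search to translations
#' @param max_eval evaluation budget (default 200 per parameter)
#' @param max_rot,max_trans optional bounds on the net rotation (degrees per
#'   axis) and translation (Angstrom per axis) of the refined pose; used by
#'   [morph()] to keep fragment fits local
#' @return list with `op` (an [rt_op()]), `score`, `model` (refined), and
#'   `n_eval`
#' @export
rigid_body_refine <- function(model, map, stats = NULL,
                              weight_mode = c("atomic_number", "unit"),
                              translate_only = FALSE, max_eval = 1200,
                              max_rot = Inf, max_trans = Inf) {
  weight_mode <- match.arg(weight_mode)
  if (is.null(stats)) stats <- robust_map_stats(map)
  if (stats$sd <= 0) stop("degenerate map statistics")
  w <- if (weight_mode == "atomic_number") atomic_numbers(model) else
    rep(1, n_atoms(model))
  center <- model_centroid(model)
  X0 <- sweep(model_coords(model), 2, center)
  in_bounds <- function(p)
    all(abs(p[1:3]) <= max_rot) && all(abs(p[4:6]) <= max_trans)
  pose <- rep(0, 6)
  n_eval <- 0L
  score <- pose_score(map, stats, X0, center, w, pose)
  n_eval <- n_eval + 1L
  coord_stage <- function(params) {
    rot_step <- 2; trans_step <- 0.5 * min(map$voxel)
    repeat {
      improved <- FALSE
      for (p in params) {
        step <- if (p <= 3) rot_step else trans_step
        for (sgn in c(1, -1)) {
          cand <- pose; cand[p] <- cand[p] + sgn * step
          if (!in_bounds(cand)) next
          sc <- pose_score(map, stats, X0, center, w, cand)
          n_eval <<- n_eval + 1L
          if (sc > score) {
            score <<- sc; pose <<- cand; improved <- TRUE
            # pattern-search acceleration: ride an improving direction with
            # doubling steps so distant optima are reached within budget
            acc <- step
            while (n_eval < max_eval) {
              acc <- min(acc * 2, if (p <= 3) 30 else 3)
              cand <- pose; cand[p] <- cand[p] + sgn * acc
              if (!in_bounds(cand)) break
              sc <- pose_score(map, stats, X0, center, w, cand)
              n_eval <<- n_eval + 1L
              if (sc > score) { score <<- sc; pose <<- cand } else break
            }
            break
          }
        }
        if (n_eval >= max_eval) break
      }
      if (n_eval >= max_eval) break
      if (!improved) {
        rot_step <- rot_step / 2; trans_step <- trans_step / 2
        if (rot_step < 0.1 && trans_step < 0.01) break
      }
    }
  }
  nm_stage <- function() {
    # simplex stage: coordinate steps cannot follow curved valleys in the
    # rotation parameters, so alternate with Nelder-Mead from the best pose
    nm <- optim(pose, function(p) {
                  if (!in_bounds(p)) return(1e30)
                  -pose_score(map, stats, X0, center, w, p)
                }, method = "Nelder-Mead",
                control = list(maxit = min(400, max_eval - n_eval),
                               parscale = c(2, 2, 2, 0.5, 0.5, 0.5),
                               reltol = 1e-10))
    n_eval <<- n_eval + nm$counts[1]
    if (-nm$value > score) { score <<- -nm$value; pose <<- nm$par }
  }
  params <- if (translate_only) 4:6 else 1:6
  repeat {
    before <- score
    coord_stage(params)
    if (!translate_only && n_eval < max_eval) nm_stage()
    if (n_eval >= max_eval || score - before <= 1e-8 * (abs(before) + 1))
      break
  }
  op <- pose_to_rt(pose, center)
  list(op = op, score = score, model = apply_rt_model(op, model),
       n_eval = n_eval)
}

#' Jiggle-fit a selection into density
#'
#' Randomized rigid-body search: `n_trials` rotation-translation hypotheses
#' are drawn about the selection centroid, with per-trial ranges shrinking
#' linearly over the run (trial c uses a fraction `1 - c/N` of the full
#' rotation range and of `max_translation`) so late trials stay near the
#' original pose.  Each hypothesis is scored by the Z-weighted density sum;
#' the `n_top` best are polished by [rigid_body_refine()] and re-scored,
#' and the best refined pose replaces the input only if it beats the
#' input's own refined score.  Deterministic given `seed`.
#'
#' @param model an [atomic_model()] (the selection)
#' @param map a [density_map()]
#' @param n_trials number of random hypotheses N (default 200)
#' @param max_translation translation range s, Angstrom (default 5)
#' @param n_top hypotheses kept for refinement (default 20)
#' @param seed integer seed
#' @param weight_mode passed to [z_weighted_score()]
#' @param stats optional precomputed [robust_map_stats()]
#' @return list with `model`, `op`, `score`, `accepted` (whether the input
#'   was replaced) and `start_score`
#' @export
jiggle_fit <- function(model, map, n_trials = 200, max_translation = 5,
                       n_top = 20, seed = 1,
                       weight_mode = c("atomic_number", "unit"),
                       stats = NULL) {
  weight_mode <- match.arg(weight_mode)
  stopifnot(n_trials >= 1, max_translation >= 0, n_top >= 1,
            n_top <= n_trials, n_atoms(model) > 0)
  if (is.null(stats)) stats <- robust_map_stats(map)
  if (stats$sd <= 0) stop("degenerate map statistics")
  w <- if (weight_mode == "atomic_number") atomic_numbers(model) else
    rep(1, n_atoms(model))
  center <- model_centroid(model)
  X0 <- sweep(model_coords(model), 2, center)
  poses <- with_seed(seed, {
    lapply(seq_len(n_trials), function(cc) {
      f <- 1 - cc / n_trials
      c(runif(3, -180 * f, 180 * f), runif(3, -max_translation * f,
                                           max_translation * f))
    })
  })
  scores <- vapply(poses, function(p) pose_score(map, stats, X0, center, w, p),
                   0)
  top <- order(scores, decreasing = TRUE)[seq_len(n_top)]
  ref0 <- rigid_body_refine(model, map, stats, weight_mode)
  best <- NULL
  for (k in top) {
    start <- apply_rt_model(pose_to_rt(poses[[k]], center), model)
    r <- rigid_body_refine(start, map, stats, weight_mode)
    r$op <- rt_compose(r$op, pose_to_rt(poses[[k]], center))
    if (is.null(best) || r$score > best$score) best <- r
  }
  if (!is.null(best) && best$score > ref0$score) {
    list(model = best$model, op = best$op, score = best$score,
         accepted = TRUE, start_score = ref0$score)
  } else {
    # keep the original coordinates untouched when no pose beats them
    list(model = model, op = rt_identity(), score = ref0$score,
         accepted = FALSE, start_score = ref0$score)
  }
}
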