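#' Density-fit energy and gradient
#'
#' Real mode: `-w * mean_a w_a (rho(x_a) - mean)/sd`, the negated
#' Z-weighted density score per atom, with the trilinear gradient
#' backpropagated to atom positions.  Reciprocal mode:
#' `w * sum |alpha F_calc - F_obs|^2 / sum |F_obs|^2` over coefficients to
#' `d_cut`, with `F_calc` from the Gaussian rasterizer and the gradient
#' obtained by the chain rule through the atom-to-grid kernel; `alpha` is
#' the least-squares amplitude scale (at its optimum the envelope theorem
#' makes the fixed-alpha gradient exact).
#'
#' @param model an [atomic_model()]
#' @param map a [density_map()] (observed data)
#' @param mode `"real"` or `"reciprocal"`
#' @param weight data weight `w >= 0`
#' @param stats [robust_map_stats()] of the map (real mode; computed when
#'   `NULL`)
#' @param d_cut resolution cutoff for the reciprocal-mode sum, Angstrom
#' @param table a [scattering_table()]
#' @param weight_mode per-atom weights for real mode
#' @return list with `value`, `grad` (n x 3) and `n_oob` (real mode)
#' @export
density_energy <- function(model, map, mode = c("reciprocal", "real"),
                           weight = 1, stats = NULL, d_cut = NULL,
                           table = scattering_table("electron"),
                           weight_mode = c("atomic_number", "unit")) {
  mode <- match.arg(mode)
  weight_mode <- match.arg(weight_mode)
  stopifnot(weight >= 0)
  n <- n_atoms(model)
  if (weight == 0)
    return(list(value = 0, grad = matrix(0, n, 3), n_oob = 0L))
  if (mode == "real") {
    if (is.null(stats)) stats <- robust_map_stats(map)
    if (stats$sd <= 0) stop("degenerate map statistics")
    wa <- if (weight_mode == "atomic_number") atomic_numbers(model) else
      rep(1, n)
    r <- cpp_trilinear_grad(map$values, dim(map$values),
                            map$origin, map$voxel, model_coords(model))
    val <- -weight * sum(wa * (r$value - stats$mean)) / (stats$sd * n)
    grad <- -weight * (wa / (stats$sd * n)) * r$grad
    list(value = val, grad = grad, n_oob = sum(r$oob))
  } else {
    g <- list(dims = dim(map$values), voxel = map$voxel, origin = map$origin)
    if (!is.null(d_cut) && d_cut < 2 * max(map$voxel) - 1e-9)
      stop("d_cut finer than the Nyquist limit")
    p <- atom_gaussians(model, table)
    x <- model_coords(model)
    rho <- cpp_atom_density(g$dims, g$origin, g$voxel, x, p$amp, p$wexp,
                            p$rcut)
    Fc <- fft(array(rho, g$dims))
    Fo <- fft(map$values)
    if (!is.null(d_cut)) {
      s <- map_s_array(g$dims, g$voxel)
      mask <- s <= 1 / d_cut
      Fc[!mask] <- 0; Fo[!mask] <- 0
    }
    den <- sum(Mod(Fo)^2)
    if (den == 0) stop("observed coefficients are all zero")
    alpha <- sum(Re(Fo * Conj(Fc))) / max(sum(Mod(Fc)^2), 1e-300)
    D <- alpha * Fc - Fo
    val <- weight * sum(Mod(D)^2) / den
    dEdrho <- (2 * weight * alpha / den) * Re(fft(D, inverse = TRUE))
    grad <- cpp_atom_density_grad(as.numeric(dEdrho), g$dims, g$origin,
                                  g$voxel, x, p$amp, p$wexp, p$rcut)
    list(value = val, grad = grad, n_oob = 0L)
  }
}

# Nonbonded soft repulsion (quartic below dmin) among model atoms and
# against symmetry mates; excl is the set of "i j" keys to skip.
nonbonded_energy <- function(x, excl, symmetry_ops = NULL, dmin = 2.2,
                             k = 10) {
  n <- nrow(x)
  d2 <- outer(rowSums(x^2), rowSums(x^2), "+") - 2 * x %*% t(x)
  idx <- which(upper.tri(d2) & d2 < dmin^2, arr.ind = TRUE)
  if (nrow(idx)) {
    keys <- paste(idx[, 1], idx[, 2])
    idx <- idx[!(keys %in% excl), , drop = FALSE]
  }
  value <- 0; grad <- matrix(0, n, 3)
  if (nrow(idx)) {
    r <- cpp_repulsion(x, x, idx[, 1] - 1L, idx[, 2] - 1L, dmin, k)
    value <- value + r$value
    grad <- grad + r$grad
    r2 <- cpp_repulsion(x, x, idx[, 2] - 1L, idx[, 1] - 1L, dmin, k)
    grad <- grad + r2$grad
  }
  if (!is.null(symmetry_ops)) {
    for (op in symmetry_ops) {
      xm <- apply_rt(op, x)
      d2m <- outer(rowSums(x^2), rowSums(xm^2), "+") - 2 * x %*% t(xm)
      im <- which(d2m < dmin^2, arr.ind = TRUE)
      if (!nrow(im)) next
      r <- cpp_repulsion(x, xm, im[, 1] - 1L, im[, 2] - 1L, dmin, k)
      value <- value + r$value
      grad <- grad + r$grad
      # the mate moves with the model: add the back-transformed reaction
      rb <- cpp_repulsion(xm, x, im[, 2] - 1L, im[, 1] - 1L, dmin, k)
      grad <- grad + rb$grad %*% op$R
    }
  }
  list(value = value, grad = grad)
}

#' Restrained coordinate refinement against a density map
#'
#' Minimizes `geometry + density` by gradient descent with a per-cycle
#' maximum atom shift and backtracking: any step that would raise the
#' total score is halved, and the cycle is abandoned (convergence) when no
#' downhill step remains.  Each cycle first re-selects the best-agreeing
#' alternative of every multi-target restraint group, and, when a symmetry
#' group is supplied, includes nonbonded repulsion against the in-contact
#' symmetry mates so interfaces between asymmetric units stay physical.
#'
#' The density term is auto-balanced: at the first cycle its gradient RMS
#' is scaled to match the geometry gradient RMS, and `weight` multiplies
#' that balanced contribution, so `weight = 1` gives both components equal
#' pull and larger weights favour the data.
#'
#' @param model starting [atomic_model()]
#' @param map a [density_map()]
#' @param restraints a [restraint_set()] or `NULL`
#' @param n_cycles refinement cycles (default 20)
#' @param weight data weight `w` balancing density against geometry
#' @param inner_steps maximum capped gradient steps per cycle (default 15)
#' @param sigma_bond,sigma_angle covalent-term sigmas (Angstrom / degrees);
#'   raising them weakens the stereochemical weights, as in deliberate
#'   overfitting experiments
#' @param mode density mode, `"reciprocal"` (default) or `"real"`
#' @param d_cut resolution cutoff for reciprocal mode, Angstrom
#' @param gm_scale Geman-McClure scale for distance restraints
#' @param max_shift per-cycle maximum atom shift, Angstrom (default 0.5)
#' @param symmetry optional [symmetry_group()]
#' @param include_covalent include covalent bond/angle terms
#' @param table a [scattering_table()]
#' @param stats optional [robust_map_stats()] (real mode)
#' @param contact_cutoff symmetry-mate contact cutoff, Angstrom
#' @return list with `model`, `trajectory` (one row per cycle: scores,
#'   selected alternatives, realized shift) and `converged`
#' @export
refine_coords <- function(model, map, restraints = NULL, n_cycles = 20,
                          weight = 1, mode = c("reciprocal", "real"),
                          d_cut = NULL, gm_scale = 5, max_shift = 0.5,
                          symmetry = NULL, include_covalent = TRUE,
                          table = scattering_table("electron"),
                          stats = NULL, contact_cutoff = 4,
                          inner_steps = 15, sigma_bond = 0.02,
                          sigma_angle = 3) {
  mode <- match.arg(mode)
  stopifnot(n_cycles >= 1, weight >= 0, max_shift > 0)
  if (mode == "real" && !is.null(d_cut)) {
    # the resolution cutoff of a real-space run is applied to the map
    map <- lowpass_map(map, d_cut)
    stats <- NULL
  }
  if (mode == "real" && is.null(stats)) stats <- robust_map_stats(map)
  conn <- if (include_covalent) model_connectivity(model) else
    list(bonds = data.frame(i = integer(), j = integer(), d0 = numeric()),
         angles = data.frame(i = integer(), ctr = integer(), j = integer(),
                             a0 = numeric()))
  excl <- connectivity_exclusions(conn, n_atoms(model))
  sym_ops <- NULL
  if (!is.null(symmetry)) {
    mates <- expand_symmetry(model, symmetry, contact_cutoff)
    if (nrow(mates))
      sym_ops <- symmetry$operators[unique(mates$op)]
  }
  dscale <- 1   # density auto-balance factor (the user weight multiplies it)
  total_at <- function(m, active) {
    ge <- geometry_energy(m, restraints, gm_scale, include_covalent,
                          active = active, conn = conn,
                          sigma_bond = sigma_bond, sigma_angle = sigma_angle)
    # unit-weight density term; the balanced scale and user weight are
    # applied here so balancing cannot cancel the user weight
    de <- density_energy(m, map, mode, weight = if (weight > 0) 1 else 0,
                         stats, d_cut, table)
    fac <- dscale * weight
    nb <- nonbonded_energy(model_coords(m), excl, sym_ops)
    list(value = ge$value + fac * de$value + nb$value,
         grad = ge$grad + fac * de$grad + nb$grad,
         geom = ge$value, dens = fac * de$value, nonb = nb$value,
         ggrad = ge$grad, dgrad = de$grad,
         components = ge$components)
  }
  traj <- list()
  converged <- FALSE
  for (cyc in seq_len(n_cycles)) {
    active <- if (!is.null(restraints)) select_multi_targets(model, restraints)
      else integer()
    e0 <- total_at(model, active)
    if (cyc == 1 && weight > 0) {
      # balance once against the covalent (stereochemical) gradient only,
      # so external restraints strengthen the geometry side instead of
      # inflating the density scale; a fixed scale keeps one well-defined
      # objective whose accepted steps are monotone
      gref <- geometry_energy(model, NULL, gm_scale, include_covalent,
                              conn = conn, sigma_bond = sigma_bond,
                              sigma_angle = sigma_angle)$grad
      grms <- sqrt(mean(gref^2))
      if (grms == 0) grms <- sqrt(mean(e0$ggrad^2))
      drms <- sqrt(mean(e0$dgrad^2))
      if (grms > 0 && drms > 0) {
        dscale <- grms / drms
        e0 <- total_at(model, active)
      }
    }
    shift <- 0
    for (step in seq_len(inner_steps)) {
      gmax <- max(sqrt(rowSums(e0$grad^2)))
      if (gmax <= 1e-12) { converged <- TRUE; break }
      eta <- max_shift / gmax
      moved <- FALSE
      for (bt in 0:8) {
        cand <- model
        model_coords(cand) <- model_coords(model) - eta * e0$grad
        e1 <- total_at(cand, active)
        if (e1$value <= e0$value) {
          shift <- max(shift, eta * gmax)
          model <- cand
          e0 <- e1
          moved <- TRUE
          break
        }
        eta <- eta / 2
      }
      if (!moved) { converged <- TRUE; break }
    }
    sel <- attr(active, "labels")
    traj[[cyc]] <- data.frame(
      cycle = cyc, total = e0$value, geometry = e0$geom, density = e0$dens,
      nonbonded = e0$nonb, max_shift = shift,
      selected = if (length(sel)) paste(unlist(sel), collapse = ",") else "",
      stringsAsFactors = FALSE)
    if (converged) break
  }
  list(model = model, trajectory = do.call(rbind, traj),
       converged = converged)
}

#' Refine against the masked region of a map
#'
#' Masks the map around the model with [mask_by_model()] before
#' reciprocal-mode refinement, so the fit uses only the section of the map
#' explained by the model -- the strategy for refining one component or
#' repeat unit inside a larger reconstruction.
#'
#' @inheritParams refine_coords
#' @param mask_radius mask radius around the model's atoms, Angstrom
#' @param soft_edge cosine edge width, Angstrom
#' @param ... forwarded to [refine_coords()]
#' @export
refine_masked_region <- function(model, map, mask_radius = 3,
                                 soft_edge = 2, ...) {
  masked <- mask_by_model(map, model, mask_radius, soft_edge)
  refine_coords(model, masked, mode = "reciprocal", ...)
}
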