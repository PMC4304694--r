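test_that("geometry energy is zero at targets with analytic gradients", {
  h <- build_ideal_helix(8)
  rs <- generate_jelly_restraints(h)
  e0 <- geometry_energy(h, rs, include_covalent = FALSE)
  expect_lt(e0$value, 1e-12)
  expect_lt(max(abs(e0$grad)), 1e-8)
  # displaced single restraint matches the closed-form Geman-McClure value
  one <- rs
  one$distance <- rs$distance[1, , drop = FALSE]
  rows <- cryofit:::restraint_atom_rows(h, one$distance)
  hd <- h
  x <- model_coords(h)
  dir <- x[rows[1], ] - x[rows[2], ]
  x[rows[1], ] <- x[rows[1], ] + 0.1 * dir / sqrt(sum(dir^2))
  model_coords(hd) <- x
  tg <- one$distance$targets[[1]]
  e1 <- geometry_energy(hd, one, gm_scale = 5, include_covalent = FALSE)
  expect_equal(e1$value, geman_mcclure(0.1 / tg$sigma, 5)$value,
               tolerance = 1e-9)
})

test_that("all energy-term gradients match central finite differences", {
  h <- build_ideal_helix(5)
  hs <- shake_model(h, 0.15, seed = 3)
  fd_max_err <- function(f, model, grad, eps = 1e-5) {
    x0 <- model_coords(model)
    errs <- c()
    for (i in seq_len(nrow(x0))) for (k in 1:3) {
      xp <- x0; xp[i, k] <- xp[i, k] + eps
      xm <- x0; xm[i, k] <- xm[i, k] - eps
      mp <- model; model_coords(mp) <- xp
      mm <- model; model_coords(mm) <- xm
      num <- (f(mp) - f(mm)) / (2 * eps)
      errs <- c(errs, abs(num - grad[i, k]) /
                  max(abs(num), abs(grad[i, k]), 1e-6))
    }
    max(errs)
  }
  # covalent + robust distance restraints
  rs <- generate_jelly_restraints(h)
  ge <- geometry_energy(hs, rs)
  expect_lt(fd_max_err(function(m) geometry_energy(m, rs)$value, hs, ge$grad),
            1e-4)
  # torsion restraints
  tr <- data.frame(chain_1 = "A", seqid_1 = 1, ins_1 = "", atom_1 = "N",
                   chain_2 = "A", seqid_2 = 1, ins_2 = "", atom_2 = "CA",
                   chain_3 = "A", seqid_3 = 1, ins_3 = "", atom_3 = "C",
                   chain_4 = "A", seqid_4 = 2, ins_4 = "", atom_4 = "N",
                   angle = -47, sigma = 5, stringsAsFactors = FALSE)
  rs_t <- restraint_set(torsion = tr)
  te <- geometry_energy(hs, rs_t, include_covalent = FALSE)
  expect_lt(fd_max_err(function(m)
    geometry_energy(m, rs_t, include_covalent = FALSE)$value, hs, te$grad),
    1e-4)
  # parallel-plane restraints on a shaken duplex
  dup <- build_ideal_duplex("GC", "B", "RNA")
  dups <- shake_model(dup, 0.1, seed = 4)
  rs_p <- restraint_set(plane = detect_stacking(dup))
  pe <- geometry_energy(dups, rs_p, include_covalent = FALSE)
  expect_lt(fd_max_err(function(m)
    geometry_energy(m, rs_p, include_covalent = FALSE)$value, dups, pe$grad),
    1e-4)
  # density terms, both modes
  m3 <- center_model(build_ideal_helix(3), at = c(10, 10, 10))
  map3 <- simulate_map(m3, 20, 1, 3.5)
  m3s <- shake_model(m3, 0.2, seed = 5)
  for (mode in c("real", "reciprocal")) {
    de <- density_energy(m3s, map3, mode = mode, weight = 2,
                         d_cut = if (mode == "reciprocal") 3.5 else NULL)
    err <- fd_max_err(function(m)
      density_energy(m, map3, mode = mode, weight = 2,
                     d_cut = if (mode == "reciprocal") 3.5 else NULL)$value,
      m3s, de$grad, eps = 1e-4)
    expect_lt(err, 1e-4)
  }
  # zero weight: density term vanishes identically
  expect_equal(density_energy(m3s, map3, weight = 0)$value, 0)
})

test_that("density energy is stationary at the generating model", {
  m <- center_model(build_ideal_helix(5), at = c(11, 11, 11))
  map <- simulate_map(m, 22, 1, 3.5)
  de <- density_energy(m, map, mode = "reciprocal", weight = 1, d_cut = 3.5)
  # gradient per atom much smaller than after a displacement
  g0 <- max(sqrt(rowSums(de$grad^2)))
  moved <- m
  model_coords(moved) <- model_coords(m) + 0.3
  de1 <- density_energy(moved, map, mode = "reciprocal", weight = 1,
                        d_cut = 3.5)
  expect_lt(g0, 0.2 * max(sqrt(rowSums(de1$grad^2))))
  expect_lt(de$value, de1$value)
})

test_that("multi-target selection is stable through refinement", {
  pr <- cryofit:::build_base_pair("G", "U", "GU_wobble")
  m <- model_rbind(pr$first, (\(a) { a$atoms$chain <- "B"; a })(pr$second))
  m <- center_model(m, at = c(11, 11, 11))
  rs <- generate_base_pair_restraints(detect_base_pairs(m))
  map <- simulate_map(m, 22, 1, 3.5)
  run <- refine_coords(shake_model(m, 0.1, seed = 6), map, rs, n_cycles = 6,
                       weight = 1, d_cut = 3.5)
  sel <- run$trajectory$selected
  n <- length(sel)
  expect_equal(sel[n], sel[n - 1])       # stable at convergence
  expect_equal(sel[n], "GU_wobble")
})

test_that("restrained refinement recovers a shaken model monotonically", {
  truth <- center_model(build_ideal_helix(18), at = c(16, 16, 16))
  map <- simulate_map(truth, 32, 1, 3.5)
  shaken <- shake_model(truth, 0.3, seed = 7)
  rs <- restraints_rbind(generate_jelly_restraints(shaken),
                         generate_hbond_restraints(shaken))
  run <- refine_coords(shaken, map, rs, n_cycles = 12, weight = 1,
                       d_cut = 3.5)
  expect_true(all(diff(run$trajectory$total) <= 1e-9))
  expect_lt(rmsd_models(run$model, truth), rmsd_models(shaken, truth) / 2)
  # geometry-only refinement ignores the density entirely
  run_geo <- refine_coords(shaken, map, rs, n_cycles = 4, weight = 0,
                           d_cut = 3.5)
  expect_true(all(run_geo$trajectory$density == 0))
})

test_that("symmetry-aware refinement pushes clashing mates apart", {
  # helix along z, offset from a C2 axis so its symmetry mate clashes;
  # with the group the nonbonded term opens the interface, without it
  # nothing moves the monomer off the mate
  h <- build_ideal_helix(10)
  ax <- helix_axis(h)
  v <- cryofit:::pracma_cross(ax, c(0, 0, 1))
  R <- axis_rotation(v / sqrt(sum(v^2)),
                     acos(sum(ax * c(0, 0, 1))) * 180 / pi)
  model_coords(h) <- model_coords(h) %*% t(R)
  h <- center_model(h, at = c(13.4, 12, 12))
  g2 <- cyclic_group(2, axis = c(0, 0, 1), center = c(12, 12, 12))
  dmin_of <- function(m) {
    mates <- expand_symmetry(m, g2, 10)
    sqrt(cryofit:::min_cross_dist2(model_coords(m),
                                   cbind(mates$x, mates$y, mates$z)))
  }
  d0 <- dmin_of(h)
  expect_lt(d0, 1.5)   # constructed clash
  map <- simulate_map(h, 24, 1, 4)
  rs <- generate_jelly_restraints(h)
  run_sym <- refine_coords(h, map, rs, n_cycles = 6, weight = 0,
                           symmetry = g2)
  run_non <- refine_coords(h, map, rs, n_cycles = 6, weight = 0)
  expect_gt(dmin_of(run_sym$model), d0 + 0.3)
  expect_lt(dmin_of(run_non$model), d0 + 0.05)
})

test_that("masked-region refinement is local to the model", {
  # two well-separated components; refine A against its masked region only
  a <- center_model(build_ideal_helix(6), at = c(9, 14, 14))
  b <- center_model(build_ideal_helix(6), at = c(20, 14, 14))
  b$atoms$chain <- "B"
  both <- model_rbind(a, b)
  map <- simulate_map(both, 28, 1, 4)
  sa <- shake_model(a, 0.2, seed = 9)
  rs <- generate_jelly_restraints(sa)
  r1 <- refine_masked_region(sa, map, mask_radius = 3, soft_edge = 2,
                             restraints = rs, n_cycles = 5, weight = 1,
                             d_cut = 4)
  expect_lt(rmsd_models(r1$model, a), rmsd_models(sa, a))
  # insensitive to noise added far outside the mask
  noisy <- map
  d <- cryofit:::cpp_min_dist(dim(map$values), map$origin, map$voxel,
                              model_coords(a), 9)
  far <- array(d >= 8.9, dim(map$values))
  set.seed(71)
  noisy$values[far] <- noisy$values[far] + rnorm(sum(far), 0, 5)
  r2 <- refine_masked_region(sa, noisy, mask_radius = 3, soft_edge = 2,
                             restraints = rs, n_cycles = 5, weight = 1,
                             d_cut = 4)
  expect_lt(max(abs(model_coords(r1$model) - model_coords(r2$model))), 1e-6)
})
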