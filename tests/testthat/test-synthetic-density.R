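test_that("scattering factors evaluate the five-Gaussian form", {
  tab <- scattering_table("electron")
  expect_true(all(c("H", "C", "N", "O", "P", "S", "MG", "FE", "NI", "ZN")
                  %in% tab$element))
  # f(0) = sum of the amplitudes for every shipped element
  for (el in tab$element) {
    row <- tab[tab$element == el, ]
    expect_equal(form_factor(tab, el, 0), sum(row[paste0("a", 1:5)]),
                 tolerance = 1e-12)
  }
  # monotone non-increasing out to 1/A for the organic elements
  s <- seq(0, 1, 0.01)
  for (el in c("C", "N", "O", "P", "S")) {
    expect_true(all(diff(form_factor(tab, el, s)) <= 1e-12))
  }
  expect_error(form_factor(tab, "Xx", 0.1), "supported")
  # X-ray table is shipped too and differs
  xt <- scattering_table("xray")
  expect_false(isTRUE(all.equal(form_factor(xt, "C", 0.2),
                                form_factor(tab, "C", 0.2))))
})

test_that("structure factors obey the single-atom oracle and shift theorem", {
  atom <- atomic_model(data.frame(chain = "A", seqid = 1, ins = "",
                                  resname = "HOH", atom = "O", element = "O",
                                  x = 16, y = 16, z = 16, occ = 1, b = 30))
  g <- list(dims = c(32, 32, 32), voxel = c(1, 1, 1), origin = c(0, 0, 0))
  sf <- calc_structure_factors(atom, g, d_min = 3)
  tab <- scattering_table("electron")
  s <- cryofit:::map_s_array(g$dims, g$voxel)
  pred <- form_factor(tab, "O", as.vector(s)) * exp(-30 * as.vector(s)^2 / 4)
  sel <- as.vector(s) < 1 / 3 & as.vector(s) > 0
  rel <- abs(Mod(as.vector(sf$F))[sel] - pred[sel]) / pred[sel]
  expect_lt(max(rel), 0.05)
  expect_lt(median(rel), 0.02)
  # occupancy linearity
  half <- atom; half$atoms$occ <- 0.5
  sf_half <- calc_structure_factors(half, g, d_min = 3)
  expect_lt(max(Mod(sf_half$F - 0.5 * sf$F)), 1e-10)
  # translation multiplies F by a pure phase
  moved <- atom; model_coords(moved) <- model_coords(atom) + c(2, 0, 0)
  sf_m <- calc_structure_factors(moved, g, d_min = 3)
  ratio <- sf_m$F[2, 1, 1] / sf$F[2, 1, 1]
  expect_equal(Arg(ratio), 2 * pi * 2 / 32, tolerance = 1e-6)
  expect_equal(Mod(ratio), 1, tolerance = 1e-9)
  # Nyquist guard
  expect_error(calc_structure_factors(atom, g, d_min = 1.5), "Nyquist")
})

test_that("simulated maps are linear, Parseval-consistent and seeded", {
  a <- center_model(build_ideal_helix(4), at = c(8, 12, 12))
  b <- center_model(build_ideal_helix(4), at = c(16, 12, 12))
  ab <- model_rbind(a, within(b$atoms, chain <- "B") |>
                      (\(at) atomic_model(at))())
  m_a <- simulate_map(a, 24, 1, 4)
  m_b <- simulate_map(b, 24, 1, 4)
  m_ab <- simulate_map(ab, 24, 1, 4)
  expect_lt(max(abs(m_ab$values - m_a$values - m_b$values)) /
              max(abs(m_ab$values)), 1e-6)
  # Parseval on the untruncated transform
  g <- list(dims = c(24, 24, 24), voxel = c(1, 1, 1), origin = c(0, 0, 0))
  rho <- model_density(a, g)
  sf <- calc_structure_factors(a, g)
  lhs <- sum(rho$values^2) * prod(g$voxel)
  rhs <- sum(Mod(sf$F)^2) / (prod(g$dims) * prod(g$voxel))
  expect_equal(lhs, rhs, tolerance = 1e-9)
  # determinism and seeding
  expect_identical(simulate_map(a, 24, 1, 4)$values,
                   simulate_map(a, 24, 1, 4)$values)
  n1 <- simulate_map(a, 24, 1, 4, noise_sigma = 1, seed = 5)
  n1b <- simulate_map(a, 24, 1, 4, noise_sigma = 1, seed = 5)
  n2 <- simulate_map(a, 24, 1, 4, noise_sigma = 1, seed = 6)
  expect_identical(n1$values, n1b$values)
  expect_false(identical(n1$values, n2$values))
})

test_that("noise degrades correlation with the truth monotonically", {
  fx <- fix_helix15()
  truth <- fx$map
  sdsig <- fx$stats$sd
  cors <- vapply(c(0, 0.5, 1, 2), function(k) {
    noisy <- simulate_map(fx$model, 32, 1, 4, noise_sigma = k * sdsig,
                          seed = 21)
    cor(as.vector(noisy$values), as.vector(truth$values))
  }, 0)
  expect_true(all(diff(cors) < 0))
  expect_equal(cors[1], 1, tolerance = 1e-12)
})

test_that("half-map pairs share signal with independent noise", {
  fx <- fix_helix15()
  clean <- simulate_half_maps(fx$model, 32, 1, 4, noise_sigma = 0,
                              seed_pair = c(1, 2))
  expect_identical(clean[[1]]$values, clean[[2]]$values)
  expect_error(simulate_half_maps(fx$model, 32, 1, 4, seed_pair = c(3, 3)),
               "differ")
  # FSC near 1 at low resolution, decaying towards the band limit;
  # the 0.143 estimate coarsens as noise grows
  res <- vapply(c(0.3, 0.8, 1.6), function(nr) {
    hm <- simulate_half_maps(fx$model, 32, 1, 4, noise_rel = nr,
                             seed_pair = c(31, 32))
    curve <- fsc_between_maps(hm[[1]], hm[[2]])
    expect_gt(curve$fsc[1], 0.95)
    as.numeric(resolution_at_threshold(curve))
  }, 0)
  expect_true(all(diff(res) > 0))
})

test_that("ideal helix generator produces alpha-helical geometry", {
  h <- build_ideal_helix(10)
  ca <- model_coords(h)[h$atoms$atom == "CA", ]
  dca <- sqrt(rowSums(diff(ca)^2))
  expect_true(all(abs(dca - 3.8) < 0.1))
  h30 <- build_ideal_helix(30)
  ca30 <- model_coords(h30)[h30$atoms$atom == "CA", ]
  rise <- mean(diff(ca30 %*% helix_axis(h30)))
  expect_true(abs(rise - 1.5) < 0.1)
  # right-handed with the stated dihedrals
  a <- h30$atoms
  get <- function(i, nm) unlist(a[a$res_index == i & a$atom == nm,
                                  c("x", "y", "z")], use.names = FALSE)
  phi <- dihedral_angle(get(4, "C"), get(5, "N"), get(5, "CA"), get(5, "C"))
  psi <- dihedral_angle(get(5, "N"), get(5, "CA"), get(5, "C"), get(6, "N"))
  expect_equal(phi, -57, tolerance = 1e-6)
  expect_equal(psi, -47, tolerance = 1e-6)
})

test_that("ideal duplex generator pairs and counts correctly", {
  dup <- build_ideal_duplex("GC", "A", "RNA")
  expect_equal(n_residues(dup), 4)   # 2 x sequence length
  rt <- residue_table(dup)
  expect_equal(rt$resname[rt$chain == "A"], c("G", "C"))
  # strand B is the reverse complement read 5'->3'
  expect_equal(rt$resname[rt$chain == "B"][order(rt$seqid[rt$chain == "B"])],
               c("G", "C"))
  expect_error(build_ideal_duplex("GX", "A", "RNA"), "invalid")
  dup_b <- build_ideal_duplex("AT", "B", "DNA")
  expect_equal(sort(unique(dup_b$atoms$resname)), c("DA", "DT"))
  # A-form rise: successive intra-strand glycosidic N z-spacing ~ 2.81
  a <- dup$atoms
  n9 <- model_coords(dup)[a$chain == "A" & a$atom %in% c("N9", "N1") &
                            cryofit:::residue_kind(a$resname) == "rna" &
                            ((a$resname %in% c("A", "G") & a$atom == "N9") |
                             (a$resname %in% c("C", "U") & a$atom == "N1")), ]
  expect_equal(abs(diff(n9[, 3])), 2.81, tolerance = 1e-6)
})

test_that("shake_model displaces by the requested RMSD, reproducibly", {
  h <- build_ideal_helix(70)  # ~ 350 atoms
  expect_identical(shake_model(h, 0), h)
  s1 <- shake_model(h, 0.5, seed = 9)
  expect_equal(rmsd_models(s1, h), 0.5, tolerance = 0.05)
  expect_identical(shake_model(h, 0.5, seed = 9)$atoms, s1$atoms)
  expect_false(identical(shake_model(h, 0.5, seed = 10)$atoms, s1$atoms))
})

test_that("bend_model hinges rigidly about an interior residue", {
  h <- build_ideal_helix(30)
  expect_equal_coords(bend_model(h, 15, angle = 0), h, tol = 1e-12)
  bent <- bend_model(h, 15, axis = c(1, 0, 0), angle = 10)
  pre <- h$atoms$res_index <= 15
  expect_equal(model_coords(bent)[pre, ], model_coords(h)[pre, ])
  post_shift <- sqrt(rowSums((model_coords(bent) - model_coords(h))^2))
  expect_true(all(post_shift[!pre][h$atoms$atom[!pre] == "CA"] >= 0))
  # displacement grows with distance from the hinge
  ca_shift <- post_shift[h$atoms$atom == "CA"][16:30]
  expect_gt(mean(ca_shift[11:15]), mean(ca_shift[1:5]))
  # exact inverse
  back <- bend_model(bent, 15, axis = c(1, 0, 0), angle = -10)
  expect_equal_coords(back, h, tol = 1e-6)
  expect_error(bend_model(h, 1, angle = 5), "interior")
  expect_error(bend_model(h, 30, angle = 5), "interior")
})
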