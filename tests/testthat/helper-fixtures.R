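# Shared fixtures, built once per test run and cached.  All fixtures are
# generated in code; nothing is read from disk.

.fix <- new.env()

fixture <- function(name, build) {
  if (is.null(.fix[[name]])) .fix[[name]] <- build()
  .fix[[name]]
}

# 15-residue helix centred in a 32^3 box with its noiseless 4 A map
fix_helix15 <- function() fixture("helix15", function() {
  h <- center_model(build_ideal_helix(15), at = c(16, 16, 16))
  map <- simulate_map(h, 32, 1, 4)
  list(model = h, map = map, stats = robust_map_stats(map))
})

# place a model so its bounding box is centred in a cubic box of edge `box`
bbox_center <- function(model, box) {
  x <- model_coords(model)
  mid <- (apply(x, 2, max) + apply(x, 2, min)) / 2
  model_coords(model) <- sweep(x, 2, mid - box / 2)
  model
}

# compact three-arm domain (no helical screw or flip pseudo-symmetry)
fix_domain <- function(box = 42) {
  d <- build_ideal_helix(30)
  d <- bend_model(d, 9, axis = c(1, 0, 0), angle = 75)
  d <- bend_model(d, 19, axis = c(0, 0, 1), angle = 65)
  bbox_center(d, box)
}

random_rotation <- function() axis_rotation(rnorm(3), runif(1, 0, 360))

# rotate about the centroid and displace by up to `disp` (Angstrom, L2)
perturb_pose <- function(model, R, disp) {
  ctr <- model_centroid(model)
  shift <- runif(3, -disp / sqrt(3), disp / sqrt(3))
  model_coords(model) <- sweep(sweep(model_coords(model), 2, ctr) %*% t(R),
                               2, -(ctr + shift))
  model
}

expect_equal_coords <- function(a, b, tol = 1e-6) {
  expect_lt(max(abs(model_coords(a) - model_coords(b))), tol)
}

acute_angle_deg <- function(u, v) {
  cu <- abs(sum(u * v)) / sqrt(sum(u^2) * sum(v^2))
  acos(min(1, cu)) * 180 / pi
}

# ~60-residue three-helix bundle (the fold-screen study object)
make_bundle60 <- function() {
  h1 <- center_model(build_ideal_helix(20))
  ax <- helix_axis(h1)
  R <- axis_rotation(cryofit:::pracma_cross(ax, c(1, 0, 0)), 180)
  h2 <- h1; model_coords(h2) <- model_coords(h1) %*% t(R)
  perp <- cryofit:::unit(cryofit:::pracma_cross(ax, c(0, 0, 1)))
  perp2 <- cryofit:::unit(cryofit:::pracma_cross(ax, perp))
  m2 <- h2; model_coords(m2) <- sweep(model_coords(h2), 2, -10 * perp)
  m3 <- h1; model_coords(m3) <- sweep(model_coords(h1), 2, -10 * perp2)
  m2$atoms$chain <- "B"; m3$atoms$chain <- "C"
  model_rbind(h1, m2, m3)
}

# three-arm domain flanked by neighbour helices in a 48 A box: docking
# into one component of a crowded complex
make_crowded_scene <- function() {
  dom <- fix_domain(48)
  nb1 <- center_model(build_ideal_helix(18),
                      at = model_centroid(dom) + c(11, 5, 0))
  nb1$atoms$chain <- "X"
  nb2 <- center_model(build_ideal_helix(18),
                      at = model_centroid(dom) - c(7, 11, 2))
  nb2$atoms$chain <- "Y"
  list(domain = dom, scene = model_rbind(dom, nb1, nb2))
}
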