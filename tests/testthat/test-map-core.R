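test_that("MRC maps round-trip and honour header conventions", {
  set.seed(10)
  m <- density_map(array(rnorm(512), c(8, 8, 8)), voxel = 1.2,
                   origin = c(3, 4, 5), label = "ramp")
  f <- withr::local_tempfile(fileext = ".mrc")
  write_mrc(m, f)
  m2 <- read_mrc(f)
  expect_lt(max(abs(m$values - m2$values)), 1e-6)  # float32 storage
  expect_equal(m2$voxel, m$voxel, tolerance = 1e-6)
  expect_equal(m2$origin, m$origin, tolerance = 1e-5)

  # nstart-based origin when the origin record is zero
  con <- file(f, "r+b")
  seek(con, 4 * 4, rw = "write")
  writeBin(c(2L, 3L, 4L), con, size = 4, endian = "little")  # nstart
  seek(con, 49 * 4, rw = "write")
  writeBin(c(0, 0, 0), con, size = 4, endian = "little")     # origin = 0
  close(con)
  m3 <- read_mrc(f)
  expect_equal(m3$origin, c(2, 3, 4) * 1.2, tolerance = 1e-5)

  # unsupported mode is refused by name
  con <- file(f, "r+b")
  seek(con, 3 * 4, rw = "write")
  writeBin(1L, con, size = 4, endian = "little")
  close(con)
  expect_error(read_mrc(f), "mode 1")
})

test_that("our MRC writer is readable by an independent implementation", {
  py <- Sys.which("python")
  skip_if(py == "", "python not on PATH")
  m <- density_map(array(seq_len(4 * 5 * 6) / 10, c(4, 5, 6)), voxel = 1.5,
                   origin = c(1, 2, 3))
  f <- withr::local_tempfile(fileext = ".mrc")
  write_mrc(m, f)
  script <- paste(
    "import gemmi, sys",
    sprintf("g = gemmi.read_ccp4_map('%s')", f),
    "print(g.grid.nu, g.grid.nv, g.grid.nw)",
    "print(round(g.grid.get_value(1, 2, 3), 6))",
    "print(round(g.grid.unit_cell.a, 3))",
    sep = "\n")
  out <- tryCatch(system2(py, c("-c", shQuote(script)), stdout = TRUE,
                          stderr = TRUE),
                  warning = function(w) NULL, error = function(e) NULL)
  skip_if(is.null(out) || length(out) < 3, "gemmi unavailable")
  expect_equal(out[1], "4 5 6")
  expect_equal(as.numeric(out[2]), m$values[2, 3, 4], tolerance = 1e-6)
  expect_equal(as.numeric(out[3]), 4 * 1.5, tolerance = 1e-3)
})

test_that("robust map statistics discard the modal (solvent) bin", {
  set.seed(11)
  v <- c(rep(0, 9000), rnorm(1000, 5, 1))
  m <- density_map(array(sample(v), c(10, 10, 100)), 1)
  st <- robust_map_stats(m)
  expect_equal(st$mean, mean(v[v != 0]), tolerance = 0.1)
  expect_equal(st$n_used + st$n_discarded, 10000)
  expect_lt(abs(st$raw_mean - mean(v)), 1e-12)
  # plain N(0,1) map: no dominant bin, robust mean near 0
  m2 <- density_map(array(rnorm(4096), c(16, 16, 16)), 1)
  st2 <- robust_map_stats(m2)
  expect_lt(abs(st2$mean), 3 * st2$sd / sqrt(st2$n_used) + 0.05)
  expect_error(robust_map_stats(density_map(array(1, c(4, 4, 4)), 1)),
               "degenerate")
})

test_that("trilinear interpolation matches the direct formula", {
  set.seed(12)
  mp <- density_map(array(rnorm(216), c(6, 6, 6)), 1.5, c(1, 2, 3))
  # voxel-centre identity
  expect_equal(as.numeric(interpolate_map(mp, c(1, 2, 3) + 1.5 * c(2, 3, 1))),
               mp$values[3, 4, 2])
  # brute-force trilinear formula at random points
  pts <- cbind(runif(100, 1, 8.4), runif(100, 2, 9.4), runif(100, 3, 10.4))
  direct <- apply(pts, 1, function(p) {
    g <- (p - mp$origin) / mp$voxel
    i <- pmin(floor(g), dim(mp$values) - 2); f <- g - i
    s <- 0
    for (dx in 0:1) for (dy in 0:1) for (dz in 0:1)
      s <- s + prod(ifelse(c(dx, dy, dz) == 1, f, 1 - f)) *
        mp$values[i[1] + dx + 1, i[2] + dy + 1, i[3] + dz + 1]
    s
  })
  got <- interpolate_map(mp, pts)
  expect_lt(max(abs(got - direct)), 1e-12)
  # out of bounds: zero plus flag, not an error
  v <- interpolate_map(mp, c(-50, 0, 0))
  expect_equal(as.numeric(v), 0)
  expect_true(attr(v, "oob"))
})

test_that("Z-weighted scoring matches brute force and is affine invariant", {
  fx <- fix_helix15()
  sc <- z_weighted_score(fx$map, fx$stats, fx$model)
  v <- interpolate_map(fx$map, model_coords(fx$model))
  w <- atomic_numbers(fx$model)
  expect_equal(as.numeric(sc), sum(w * (v - fx$stats$mean)) / fx$stats$sd,
               tolerance = 1e-12)
  # affine invariance when stats are recomputed
  m2 <- fx$map; m2$values <- 3.7 * fx$map$values + 11
  sc2 <- z_weighted_score(m2, robust_map_stats(m2), fx$model)
  expect_equal(as.numeric(sc), as.numeric(sc2), tolerance = 1e-6)
  # unit weights: map with value mean+sd everywhere scores n_atoms
  flat <- fx$map
  flat$values[] <- fx$stats$mean + fx$stats$sd
  sc3 <- z_weighted_score(flat, fx$stats, fx$model, weight_mode = "unit")
  expect_equal(as.numeric(sc3), n_atoms(fx$model), tolerance = 1e-9)
})

test_that("model masking zeroes only distant voxels, monotonely in radius", {
  fx <- fix_helix15()
  mk3 <- mask_by_model(fx$map, fx$model, 3)
  d <- cryofit:::cpp_min_dist(dim(fx$map$values), fx$map$origin,
                              fx$map$voxel, model_coords(fx$model), 10)
  inside <- d <= 3
  expect_equal(as.vector(mk3$values)[inside],
               as.vector(fx$map$values)[inside])
  expect_true(all(as.vector(mk3$values)[!inside] == 0))
  counts <- vapply(c(2, 4, 6, 100), function(r)
    sum(mask_by_model(fx$map, fx$model, r)$values != 0), 0)
  expect_true(all(diff(counts) >= 0))
  expect_equal(mask_by_model(fx$map, fx$model, 100)$values, fx$map$values)
  # soft edge: values scaled, never amplified
  mks <- mask_by_model(fx$map, fx$model, 3, soft_edge = 2)
  expect_true(all(abs(mks$values) <= abs(fx$map$values) + 1e-12))
})

test_that("spherical segmentation preserves world coordinates", {
  fx <- fix_helix15()
  seg <- segment_sphere(fx$map, c(16, 16, 16), 10)
  set.seed(13)
  pts <- matrix(runif(150, 8, 24), ncol = 3)
  # keep clear of the sphere surface: interpolation within one voxel
  # diagonal of the boundary legitimately mixes in zeroed voxels
  pts <- pts[sqrt(rowSums(sweep(pts, 2, c(16, 16, 16))^2)) < 8, ,
             drop = FALSE]
  expect_lt(max(abs(interpolate_map(seg, pts) - interpolate_map(fx$map, pts))),
            1e-12)
  full <- segment_sphere(fx$map, c(16, 16, 16), 1000)
  expect_equal(full$values, fx$map$values)
  expect_error(segment_sphere(fx$map, c(500, 0, 0), 5), "intersect")
  expect_equal(segment_radius("protein"), 34)
  expect_equal(segment_radius("rna"), 17)
})

test_that("sharpening follows exp(-B s^2/4) and conserves F(0)", {
  fx <- fix_helix15()
  map <- fx$map
  expect_lt(max(abs(sharpen_map(map, 0)$values - map$values)) /
              max(abs(map$values)), 1e-6)
  fwd_back <- sharpen_map(sharpen_map(map, 40), -40)
  expect_lt(max(abs(fwd_back$values - map$values)) / max(abs(map$values)),
            1e-6)
  # per-coefficient amplitude ratio equals the temperature-factor kernel
  B <- 25
  Fa <- fft(map$values); Fb <- fft(sharpen_map(map, B)$values)
  s <- cryofit:::map_s_array(dim(map$values), map$voxel)
  sel <- Mod(Fa) > 1e-6 * max(Mod(Fa))
  expect_lt(max(abs(Mod(Fb)[sel] / Mod(Fa)[sel] - exp(-B * s[sel]^2 / 4))),
            1e-6)
  expect_equal(sum(sharpen_map(map, B)$values), sum(map$values),
               tolerance = 1e-9)  # F(0) unchanged
  expect_error(sharpen_map(map, NA), "finite")
})

test_that("amplitude scaling matches references per shell", {
  fx <- fix_helix15()
  map <- fx$map
  self <- scale_to_reference(map, map)
  expect_lt(max(abs(self$values - map$values)) / max(abs(map$values)), 1e-6)
  # sharpened map scaled back to the original recovers it closely
  rec <- scale_to_reference(sharpen_map(map, 10), map)
  expect_lt(max(abs(rec$values - map$values)) / max(abs(map$values)), 0.02)
  # independent-noise half maps on a common reference: equal shell profiles
  hm <- simulate_half_maps(fx$model, 32, 1, 4, noise_rel = 0.5,
                           seed_pair = c(3, 4))
  r1 <- radial_amplitude(scale_to_reference(hm[[1]], map))
  r2 <- radial_amplitude(scale_to_reference(hm[[2]], map))
  expect_lt(max(abs(r1$amplitude - r2$amplitude) /
                  pmax(r1$amplitude, 1e-9)), 1e-6)
})

test_that("map averaging and composites behave voxelwise", {
  fx <- fix_helix15()
  map <- fx$map
  expect_equal(average_maps(list(map, map))$values, map$values)
  m2 <- map; m2$values <- 2 * map$values
  d <- dim(map$values)
  half1 <- array(0, d); half1[1:16, , ] <- 1
  mask1 <- density_map(half1, 1); mask0 <- density_map(1 - half1, 1)
  comp <- composite_maps(list(map, m2), list(mask1, mask0))
  expect_equal(comp$values[1:16, , ], map$values[1:16, , ])
  expect_equal(comp$values[17:32, , ], m2$values[17:32, , ])
  # overlap voxel with 0.5/0.5 masks averages
  mhalf <- density_map(array(0.5, d), 1)
  over <- composite_maps(list(map, m2), list(mhalf, mhalf))
  expect_equal(over$values, (map$values + m2$values) / 2, tolerance = 1e-12)
  expect_error(average_maps(list(map, density_map(array(0, c(4, 4, 4)), 1))),
               "mismatch")
})
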