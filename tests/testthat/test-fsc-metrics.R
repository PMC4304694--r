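test_that("map-map FSC hits its analytic fixed points", {
  fx <- fix_helix15()
  map <- fx$map
  self <- fsc_between_maps(map, map)
  expect_true(all(abs(self$fsc - 1) < 1e-10))
  neg <- map; neg$values <- -map$values
  expect_true(all(abs(fsc_between_maps(map, neg)$fsc + 1) < 1e-10))
  # symmetry and bounds
  set.seed(41)
  a <- density_map(array(rnorm(4096), c(16, 16, 16)), 1)
  b <- density_map(array(rnorm(4096), c(16, 16, 16)), 1)
  f1 <- fsc_between_maps(a, b); f2 <- fsc_between_maps(b, a)
  expect_equal(f1$fsc, f2$fsc, tolerance = 1e-12)
  expect_true(all(f1$fsc >= -1 & f1$fsc <= 1))
  # independent noise: |FSC| within the null band in most shells
  expect_gte(mean(abs(f1$fsc) < 4 / sqrt(f1$n_coeffs)), 0.9)
  expect_error(fsc_between_maps(a, density_map(array(0, c(8, 8, 8)), 1)),
               "mismatch")
})

test_that("R's FFT agrees with a direct-sum DFT (oracle equivalence)", {
  set.seed(42)
  arr <- array(rnorm(16^3), c(16, 16, 16))
  Fa <- fft(arr)
  idx <- 0:15
  for (hkl in list(c(1, 2, 3), c(5, 0, 2), c(8, 8, 8))) {
    direct <- 0+0i
    for (x in idx) for (y in idx) {
      direct <- direct + sum(arr[x + 1, y + 1, ] *
                               exp(-2i * pi * (hkl[1] * x + hkl[2] * y +
                                                 hkl[3] * idx) / 16))
    }
    expect_lt(Mod(direct - Fa[hkl[1] + 1, hkl[2] + 1, hkl[3] + 1]),
              1e-10 * max(Mod(Fa)))
  }
})

test_that("model-map FSC is exact for a self-map and uses phases", {
  fx <- fix_helix15()
  curve <- fsc_model_map(fx$model, fx$map, d_min = 4)
  expect_true(all(curve$fsc > 0.99))
  expect_equal(fsc_average(curve), 1, tolerance = 1e-6)
  # unrelated model: FSC_average near zero
  far <- center_model(build_ideal_duplex("GCGC", "A", "RNA"),
                      at = c(16, 16, 16))
  null_curve <- fsc_model_map(far, fx$map, d_min = 4)
  expect_lt(abs(fsc_average(null_curve)), 0.35)
  # translating the model scrambles phases while leaving amplitudes
  # untouched: apply the shift theorem to the model coefficients directly
  sf0 <- calc_structure_factors(fx$model, fx$map, d_min = 4)
  hx <- cryofit:::signed_freq_index(32) / 32
  phase <- exp(2i * pi * 16 *
                 (array(rep(hx, 32 * 32), c(32, 32, 32)) +
                    aperm(array(rep(hx, 32 * 32), c(32, 32, 32)), c(2, 1, 3))))
  sf_shift <- sf0$F * phase
  expect_lt(weighted_r_factor(Mod(sf0$F), Mod(sf_shift)), 1e-12)
  shifted_curve <- suppressWarnings(
    cryofit:::fsc_between_sf(Conj(sf_shift), fft(fx$map$values),
                             sf0$dims, sf0$voxel))
  shifted_curve <- shifted_curve[shifted_curve$s_min < 0.25, ]
  expect_lt(fsc_average(shifted_curve), 0.5)
  expect_gt(fsc_average(curve), 0.99)
})

test_that("FSC_average weights shells by coefficient count", {
  curve <- data.frame(shell = 1:2, s_min = c(0, 0.1), s_max = c(0.1, 0.2),
                      s_mid = c(0.05, 0.15), fsc = c(1, 0),
                      n_coeffs = c(3L, 1L), d_max = c(Inf, 10),
                      d_min = c(10, 5))
  class(curve) <- c("fsc_curve", "data.frame")
  expect_equal(fsc_average(curve), 0.75)
  all_one <- curve; all_one$fsc <- c(1, 1)
  expect_equal(fsc_average(all_one), 1)
  expect_error(fsc_average(curve[0, ]), "empty")
  # bounded by the shell extremes
  fx <- fix_helix15()
  cv <- fsc_model_map(fx$model, fx$map)
  av <- fsc_average(cv)
  expect_gte(av, min(cv$fsc)); expect_lte(av, max(cv$fsc))
})

test_that("FSC_average is invariant to per-shell reweighting, R_w is not", {
  fx <- fix_helix15()
  map <- fx$map
  noisy <- simulate_map(fx$model, 32, 1, 4, noise_rel = 0.4, seed = 77)
  sf_a <- fft(map$values); sf_b <- fft(noisy$values)
  curve0 <- cryofit:::fsc_between_sf(sf_a, sf_b, dim(map$values), map$voxel)
  # per-shell-constant positive weights cancel inside every shell
  sh <- cryofit:::shell_assignment(dim(map$values), map$voxel)
  set.seed(78)
  wshell <- exp(rnorm(sh$n_shells))
  warr <- array(1, dim(map$values))
  ok <- !is.na(sh$shell)
  warr[ok] <- wshell[sh$shell[ok]]
  curve_w <- cryofit:::fsc_between_sf(sf_a * warr, sf_b * warr,
                                      dim(map$values), map$voxel)
  expect_lt(max(abs(curve0$fsc - curve_w$fsc)), 1e-10)
  expect_lt(abs(fsc_average(curve0) - fsc_average(curve_w)), 1e-10)
  # the weighted R factor does change under exp(-B s^2/4) reweighting when
  # the amplitude mismatch is resolution dependent
  s <- cryofit:::map_s_array(dim(map$values), map$voxel)
  fo <- Mod(as.vector(sf_a))
  fc <- fo * exp(-30 * as.vector(s)^2 / 4)
  wgt <- exp(-20 * as.vector(s)^2 / 4)
  r_plain <- weighted_r_factor(fo, fc)
  r_wgt <- weighted_r_factor(fo, fc, w = wgt)
  expect_gt(abs(r_plain - r_wgt), 1e-3)
})

test_that("weighted R factor follows its definition", {
  fo <- c(10, 5, 2); fc <- c(8, 5, 4)
  expect_equal(weighted_r_factor(fo, fo), 0)
  expect_equal(weighted_r_factor(fo, rep(0, 3)), 1)
  expect_equal(weighted_r_factor(fo, fc), (2 + 0 + 2) / 17)
  expect_equal(weighted_r_factor(fo, fc, w = c(1, 0, 0)), 2 / 10)
  expect_error(weighted_r_factor(c(0, 0), c(1, 1)), "zero")
})

test_that("resolution estimation interpolates the 0.143 crossing", {
  mk <- function(fsc, s_mid) {
    n <- length(fsc)
    w <- diff(s_mid[1:2])
    curve <- data.frame(shell = 1:n, s_min = s_mid - w / 2,
                        s_max = s_mid + w / 2, s_mid = s_mid, fsc = fsc,
                        n_coeffs = rep(10L, n))
    curve$d_max <- 1 / pmax(curve$s_min, 1e-9); curve$d_min <- 1 / curve$s_max
    class(curve) <- c("fsc_curve", "data.frame")
    curve
  }
  # constructed crossing: 1.0 until s_mid 0.25, then 0 -> d ~ 4 A near the
  # midpoint of the interpolated drop
  s_mid <- seq(0.05, 0.45, 0.05)
  fsc <- ifelse(s_mid <= 0.25, 1, 0)
  d <- resolution_at_threshold(mk(fsc, s_mid))
  expect_true(attr(d, "crossed"))
  expect_equal(1 / as.numeric(d), 0.25 + 0.05 * (1 - 0.143),
               tolerance = 1e-9)
  # never crossing: finest edge with flag
  d2 <- resolution_at_threshold(mk(rep(0.9, 9), s_mid))
  expect_false(attr(d2, "crossed"))
  expect_equal(as.numeric(d2), 1 / (0.45 + 0.025), tolerance = 1e-9)
  # sigma-0 fixture never crosses any threshold below 1
  fx <- fix_helix15()
  hm0 <- simulate_half_maps(fx$model, 32, 1, 4, seed_pair = c(1, 2))
  c0 <- fsc_between_maps(hm0[[1]], hm0[[2]])
  c0 <- c0[c0$s_max <= 1 / 4 + 1e-12, ]  # fully inside the signal band
  expect_false(attr(resolution_at_threshold(c0, 0.9), "crossed"))
})
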