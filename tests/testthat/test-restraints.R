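test_that("reference restraints respect the 4.2 A threshold and pairing", {
  h <- build_ideal_helix(5)
  rs <- generate_reference_restraints(h, h)
  d <- rs$distance
  expect_gt(nrow(d), 0)
  targets <- vapply(d$targets, function(t) t$d[1], 0)
  expect_true(all(targets < 4.2))
  # identical models: zero deviation, zero restraint energy
  e <- geometry_energy(h, rs, include_covalent = FALSE)
  expect_lt(e$value, 1e-12)
  expect_lt(max(abs(e$grad)), 1e-8)
  # brute-force enumeration of qualifying pairs
  sel <- cryofit:::restrainable_atoms(h)
  x <- model_coords(h)[sel, ]
  ri <- h$atoms$res_index[sel]
  cnt <- 0
  for (i in seq_along(sel)) for (j in seq_along(sel)) {
    if (j <= i) next
    if (abs(ri[i] - ri[j]) < 2) next
    if (sqrt(sum((x[i, ] - x[j, ])^2)) < 4.2) cnt <- cnt + 1
  }
  expect_equal(nrow(d), cnt)
  expect_error(generate_reference_restraints(h, h,
                                             correspondence = matrix(0, 0, 2)),
               "empty")
})

test_that("jelly restraints are self-referential stiffness", {
  h <- build_ideal_helix(6)
  jelly <- generate_jelly_restraints(h)
  refr <- generate_reference_restraints(h, h)
  expect_equal(nrow(jelly$distance), nrow(refr$distance))
  expect_lt(geometry_energy(h, jelly, include_covalent = FALSE)$value, 1e-12)
  # after shaking, energy is positive and the gradient is a descent
  # direction back toward the original geometry
  hs <- shake_model(h, 0.3, seed = 2)
  e <- geometry_energy(hs, jelly, include_covalent = FALSE)
  expect_gt(e$value, 0)
  stepped <- hs
  model_coords(stepped) <- model_coords(hs) - 1e-4 * e$grad
  e2 <- geometry_energy(stepped, jelly, include_covalent = FALSE)
  expect_lt(e2$value, e$value)
})

test_that("hydrogen-bond and helical-fragment restraints detect helices", {
  h12 <- build_ideal_helix(12)
  hb <- generate_hbond_restraints(h12)
  expect_equal(nrow(hb$distance), 8)   # O(i)-N(i+4), i = 1..8
  expect_true(all(vapply(hb$distance$targets, function(t) t$d[1], 0) == 2.9))
  frag <- generate_helix_fragment_restraints(h12)
  expect_gt(nrow(frag$distance), nrow(hb$distance))
  expect_true(all(vapply(frag$distance$targets, function(t) t$d[1], 0) < 4.2))
  # extended chain: nothing to restrain
  ext <- build_ideal_helix(12, phi = -140, psi = 140)
  expect_equal(nrow(generate_hbond_restraints(ext)$distance), 0)
  expect_equal(nrow(generate_helix_fragment_restraints(ext)$distance), 0)
  # gently bent helix: fragment detection is tolerant
  bent <- bend_model(h12, 6, axis = c(1, 0, 0), angle = 10)
  expect_gt(nrow(generate_helix_fragment_restraints(bent)$distance), 0)
})

test_that("base-pair detection classifies WC and G:U pairs on duplexes", {
  dup <- build_ideal_duplex("GCAU", "A", "RNA")
  bp <- detect_base_pairs(dup)
  expect_equal(nrow(bp), 4)
  # class follows the letters of each detected pair
  expected_cls <- ifelse(bp$resname_a %in% c("G", "C"), "WC_GC", "WC_AU")
  expect_equal(bp$class, expected_cls)
  # every sequence position is paired exactly once
  expect_equal(sort(c(bp$res_a, bp$res_b)), 1:8)
  # single strand: nothing
  single <- model_subset(dup, dup$atoms$chain == "A")
  expect_equal(nrow(detect_base_pairs(single)), 0)
  # random sequences: one pair per position with matching class
  set.seed(51)
  for (len in c(4, 6)) {
    seq_ <- paste(sample(c("A", "C", "G", "U"), len, replace = TRUE),
                  collapse = "")
    bp_i <- detect_base_pairs(build_ideal_duplex(seq_, "A", "RNA"))
    expect_equal(nrow(bp_i), len)
    expect_equal(bp_i$class,
                 ifelse(bp_i$resname_a %in% c("G", "C"), "WC_GC", "WC_AU"))
  }
})

test_that("constructed G:U geometries are recognized by class", {
  for (cls in c("GU_wobble", "GU_reverse_wobble")) {
    pr <- cryofit:::build_base_pair("G", "U", cls)
    m <- model_rbind(pr$first,
                     (\(a) { a$atoms$chain <- "B"; a })(pr$second))
    bp <- detect_base_pairs(m)
    expect_equal(nrow(bp), 1)
    expect_equal(bp$class, cls)
  }
})

test_that("base-pair restraints carry WC single targets and G:U alternatives", {
  dup <- build_ideal_duplex("GC", "A", "RNA")
  bp <- detect_base_pairs(dup)
  rs <- generate_base_pair_restraints(bp)
  # two G:C pairs -> 3 single-target restraints each
  expect_equal(nrow(rs$distance), 6)
  expect_true(all(vapply(rs$distance$targets, nrow, 0L) == 1))
  # G:U pair: every restraint carries exactly 2 alternatives, grouped
  pr <- cryofit:::build_base_pair("G", "U", "GU_wobble")
  m <- model_rbind(pr$first, (\(a) { a$atoms$chain <- "B"; a })(pr$second))
  rs_gu <- generate_base_pair_restraints(detect_base_pairs(m))
  expect_gt(nrow(rs_gu$distance), 0)
  expect_true(all(vapply(rs_gu$distance$targets, nrow, 0L) == 2))
  expect_true(all(!is.na(rs_gu$distance$alt_group)))
  # deterministic regeneration
  rs2 <- generate_base_pair_restraints(detect_base_pairs(dup))
  expect_identical(rs$distance[names(rs$distance) != "targets"],
                   rs2$distance[names(rs2$distance) != "targets"])
})

test_that("multi-target selection picks the configuration the model is in", {
  for (cls in c("GU_wobble", "GU_reverse_wobble")) {
    pr <- cryofit:::build_base_pair("G", "U", cls)
    m <- model_rbind(pr$first, (\(a) { a$atoms$chain <- "B"; a })(pr$second))
    rs <- generate_base_pair_restraints(detect_base_pairs(m))
    act <- select_multi_targets(m, rs)
    labels <- unlist(attr(act, "labels"))
    expect_true(all(labels == cls))
  }
  # single-target restraints are untouched
  h <- build_ideal_helix(6)
  rs_h <- generate_jelly_restraints(h)
  expect_true(all(select_multi_targets(h, rs_h) == 1L))
})

test_that("stacking detection separates stacks from coplanar neighbours", {
  dup <- build_ideal_duplex("GCAU", "A", "RNA")
  st <- detect_stacking(dup)
  rt <- residue_table(dup)
  # every successive intra-strand pair of bases is stacked (cross-strand
  # stacks at helical steps are genuine and may appear in addition)
  found <- vapply(st, function(s) paste(sort(c(s$res_a, s$res_b)),
                                        collapse = "-"), "")
  intra <- c(paste(1:3, 2:4, sep = "-"), paste(5:7, 6:8, sep = "-"))
  expect_true(all(intra %in% found))
  # two bases far apart are not stacked
  m1 <- ideal_monomer("A", chain = "A")
  m2 <- ideal_monomer("A", chain = "B")
  model_coords(m2) <- model_coords(m2) + c(10, 0, 0)
  expect_equal(length(detect_stacking(model_rbind(m1, m2))), 0)
  # coplanar side-by-side bases at stacking distance are rejected
  m3 <- cryofit:::monomer_in_base_frame("A")
  m4 <- cryofit:::monomer_in_base_frame("A")
  m4$atoms$chain <- "B"
  model_coords(m4) <- sweep(model_coords(m4), 2, c(-4, 0, 0))  # in-plane
  expect_equal(length(detect_stacking(model_rbind(m3, m4))), 0)
  # true stack: same base translated along the normal
  m5 <- cryofit:::monomer_in_base_frame("A")
  m5$atoms$chain <- "B"
  model_coords(m5) <- sweep(model_coords(m5), 2, c(0, 0, -3.4))
  expect_equal(length(detect_stacking(model_rbind(m3, m5))), 1)
})

test_that("Geman-McClure loss saturates with vanishing derivative", {
  g <- geman_mcclure(0, c = 2)
  expect_equal(g$value, 0); expect_equal(g$deriv, 0)
  expect_equal(geman_mcclure(2, c = 2)$value, 2)        # rho(c) = c^2/2
  big <- geman_mcclure(1e6, c = 2)
  expect_equal(big$value, 4, tolerance = 1e-9)          # -> c^2
  expect_lt(abs(big$deriv), 1e-10)
  # even, monotone for positive residuals, bounded by c^2
  d <- seq(-10, 10, 0.1)
  v <- geman_mcclure(d, c = 1.5)$value
  expect_equal(v, rev(v), tolerance = 1e-12)
  expect_true(all(diff(v[d >= 0]) >= -1e-12))
  expect_true(all(v <= 1.5^2))
  # derivative consistent with central differences
  num <- (geman_mcclure(1.3 + 1e-6, 2)$value -
            geman_mcclure(1.3 - 1e-6, 2)$value) / 2e-6
  expect_equal(geman_mcclure(1.3, 2)$deriv, num, tolerance = 1e-6)
  expect_error(geman_mcclure(1, c = -1), "positive")
})

test_that("restraints round-trip through the external-restraint dialect", {
  h <- build_ideal_helix(5)
  rs <- generate_hbond_restraints(build_ideal_helix(8))
  pr <- cryofit:::build_base_pair("G", "U", "GU_wobble")
  m <- model_rbind(pr$first, (\(a) { a$atoms$chain <- "B"; a })(pr$second))
  rs_gu <- generate_base_pair_restraints(detect_base_pairs(m))
  both <- restraints_rbind(rs, rs_gu)
  f <- withr::local_tempfile(fileext = ".txt")
  write_restraints(both, f)
  txt <- readLines(f)
  expect_match(txt[1], "^exte dist first chain . resi \\d+ atom")
  expect_true(any(grepl("alt group", txt)))
  back <- read_restraints(f)
  expect_equal(nrow(back$distance), nrow(both$distance))
  key <- function(d) order(paste(d$chain_a, d$seqid_a, d$atom_a,
                                 d$chain_b, d$seqid_b, d$atom_b))
  d0 <- both$distance[key(both$distance), ]
  d1 <- back$distance[key(back$distance), ]
  expect_equal(d1$atom_a, d0$atom_a)
  expect_equal(vapply(d1$targets, nrow, 0L), vapply(d0$targets, nrow, 0L))
  expect_equal(vapply(d1$targets, function(t) t$d[1], 0),
               vapply(d0$targets, function(t) round(t$d[1], 3), 0))
  # JSON serialization is parseable and complete
  js <- restraints_to_json(both)
  parsed <- jsonlite::fromJSON(js, simplifyVector = FALSE)
  expect_equal(length(parsed$distance), nrow(both$distance))
})

test_that("duplicate restraints within a kind are rejected", {
  df <- data.frame(kind = "reference", chain_a = "A", seqid_a = 1L,
                   ins_a = "", atom_a = "CA", chain_b = "A", seqid_b = 3L,
                   ins_b = "", atom_b = "CA", alt_group = NA_integer_,
                   stringsAsFactors = FALSE)
  df <- rbind(df, df)
  df$targets <- I(list(data.frame(d = 3.8, sigma = 0.1, label = "x"),
                       data.frame(d = 3.8, sigma = 0.1, label = "x")))
  expect_error(restraint_set(df), "duplicate")
})
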