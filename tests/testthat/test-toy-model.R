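test_that("pair energy has a well of depth -eps at d = sigma and vanishes beyond the cutoff", {
  # depth at the minimum: d = sigma = 2.4 for two 1.2 A beads, h = 0
  expect_equal(pair_energy(mk_rot(0, 0, 0), mk_rot(2.4, 0, 0)), -0.5)
  expect_identical(pair_energy(mk_rot(0, 0, 0), mk_rot(7, 0, 0)), 0)
  # direct evaluation of the closed form at d = 1.2 sigma
  expected <- 0.5 * ((1 / 1.2)^12 - 2 * (1 / 1.2)^6)
  expect_equal(pair_energy(mk_rot(0, 0, 0), mk_rot(2.88, 0, 0)), expected)
  # numerical minimum over d equals -eps at d = sigma
  d <- seq(2.0, 3.0, by = 1e-4)
  e <- vapply(d, function(x) pair_energy(mk_rot(0, 0, 0), mk_rot(x, 0, 0)), 1)
  expect_lt(abs(min(e) - (-0.5)), 1e-9)
  expect_lt(abs(d[which.min(e)] - 2.4), 1e-3)
  expect_error(pair_energy(mk_rot(0, 0, 0), mk_rot(0, 0, 0)), "coincident")
})

test_that("pair energy is exactly symmetric and hydrophobicity-weighted", {
  set.seed(1)
  for (i in 1:1000) {
    a <- random_rotamer(); b <- random_rotamer()
    expect_identical(pair_energy(a, b), pair_energy(b, a))
  }
  # like-signed hydrophobicity deepens the well: eps = eps0 * (1 + h_i h_j)
  e_hh <- pair_energy(mk_rot(0, 0, 0, h = 0.8), mk_rot(2.4, 0, 0, h = 0.5))
  expect_equal(e_hh, -0.5 * (1 + 0.4))
})

test_that("rotamer building follows the orientation-set and bead-geometry rules", {
  s <- toy_structure(chain = rep("A", 3), resnum = 1:3, aa = c("L", "G", "F"),
                     xyz = cbind(c(0, 4, 8), 0, 0))
  expect_equal(nrow(build_rotamers(s, 2, "G")), 1)           # c = 0: degenerate
  g <- build_rotamers(s, 2, "G")
  expect_equal(unlist(g[1, c("cx", "cy", "cz")], use.names = FALSE), c(4, 0, 0))
  expect_equal(nrow(build_rotamers(s, 1, "F")), 6)           # full 6-axis set
  expect_equal(nrow(build_rotamers(s, 1, c("F", "G", "L"))), 13)
  r <- build_rotamers(s, 1, "W")
  expect_equal(r$radius[1], 1.0 + 0.25 * 10^(1 / 3))
  expect_equal(r$hydrophobicity[1], -0.9 / 4.5)
  expect_error(build_rotamers(s, 1, "Z"), "unknown amino-acid")
})

test_that("bump check prunes backbone-clashing rotamers unless multistate mode is on", {
  # second residue close enough that inward-pointing rotamers clash
  s <- toy_structure(chain = rep("A", 2), resnum = 1:2, aa = c("F", "A"),
                     xyz = rbind(c(0, 0, 0), c(2.2, 0, 0)))
  all_rots <- build_rotamers(s, 1, "F", multistate_mode = TRUE)
  bb <- msdesign:::rotamer_backbone_energy(all_rots, s, 1,
                                           toy_energy_params())
  thr <- 5.0
  expect_true(any(bb > thr) && any(bb <= thr))  # fixture straddles threshold
  kept <- build_rotamers(s, 1, "F", bump_check = TRUE, bump_threshold = thr,
                         multistate_mode = FALSE)
  expect_equal(nrow(kept), sum(bb <= thr))
  # multistate mode forces the bump check off
  ms <- build_rotamers(s, 1, "F", bump_check = TRUE, bump_threshold = thr,
                       multistate_mode = TRUE)
  expect_equal(nrow(ms), 6)
})

test_that("identical (aa, local geometry) gives identical rotamer sets across structures", {
  xyz <- msdesign:::helix_anchors(8)
  s1 <- toy_structure(chain = rep("A", 8), resnum = 1:8, aa = rep("L", 8),
                      xyz = xyz)
  extra <- toy_structure(chain = c(rep("A", 8), "B"), resnum = c(1:8, 1),
                         aa = c(rep("L", 8), "F"),
                         xyz = rbind(xyz, c(30, 30, 30)))
  for (aa in c("G", "A", "F", "W")) {
    r1 <- build_rotamers(s1, 4, aa, multistate_mode = TRUE)
    r2 <- build_rotamers(extra, 4, aa, multistate_mode = TRUE)
    expect_equal(r1, r2)
  }
})

test_that("rms without superposition matches hand evaluation and the triangle inequality", {
  a <- matrix(rnorm(12), 4, 3)
  expect_identical(rms_no_superposition(a, a), 0)
  expect_equal(rms_no_superposition(a, sweep(a, 2, c(-3, 0, 0))), 3)
  b <- a; b[2, ] <- b[2, ] + c(0, 0, 2)
  expect_equal(rms_no_superposition(a, b), sqrt(4 / 4))
  expect_error(rms_no_superposition(a, a[1:3, ]), "equal")
  set.seed(2)
  for (i in 1:50) {
    x <- matrix(rnorm(15), 5, 3); y <- matrix(rnorm(15), 5, 3)
    z <- matrix(rnorm(15), 5, 3)
    expect_lte(rms_no_superposition(x, z),
               rms_no_superposition(x, y) + rms_no_superposition(y, z) + 1e-12)
  }
})

test_that("synthetic systems are deterministic and meet the interface contract", {
  s1 <- generate_synthetic_system("heterodimer_task", 8, seed = 3)
  s2 <- generate_synthetic_system("heterodimer_task", 8, seed = 3)
  expect_identical(s1, s2)
  expect_setequal(names(s1$structures), c("A", "B", "AB", "AA", "BB"))
  # designable cross-chain anchor pairs within the cutoff (brute force)
  cp <- msdesign:::cross_pairs_within(s1$structures$AB, "A", "B", 6.0)
  des <- cp$res1 %in% s1$designable & cp$res2 %in% s1$designable
  expect_gte(sum(des), 8)
  # monomers share backbone coordinates with their chains in the dimer
  expect_equal(msdesign:::anchors(s1$structures$A),
               msdesign:::anchors(extract_chains(s1$structures$AB, "A")))
  expect_equal(msdesign:::anchors(s1$structures$B),
               msdesign:::anchors(extract_chains(s1$structures$AB, "B")))
  o <- generate_synthetic_system("orthogonal_task", 3, seed = 5)
  expect_true(all(c("AB", "AC", "AD", "A_AB", "A_AC", "A_AD", "B", "C", "D")
                  %in% names(o$structures)))
  expect_error(generate_synthetic_system("nope"), "arg")
})

test_that("toy-structure and PDB-subset files round-trip", {
  sys <- small_hetero_system()
  s <- sys$structures$AB
  tf <- tempfile(fileext = ".toy")
  write_toy_structure(s, tf)
  s2 <- read_toy_structure(tf)
  expect_equal(s$residues, s2$residues)
  pf <- tempfile(fileext = ".pdb")
  write_pdb_subset(s, pf)
  s3 <- read_pdb_subset(pf)
  expect_equal(msdesign:::anchors(s3), msdesign:::anchors(s),
               tolerance = 1e-3)
  expect_identical(s3$residues$aa, s$residues$aa)
  expect_identical(s3$chains, s$chains)
})

test_that("structure invariants are enforced", {
  expect_error(toy_structure("A", 1, "L", matrix(c(1, Inf, 0), 1, 3)),
               "finite")
  expect_error(toy_structure(c("A", "A"), c(1, 1), c("L", "F"),
                             matrix(0:5, 2, 3)), "duplicate")
  expect_error(toy_structure("A", 0, "L", matrix(1:3, 1, 3)), ">= 1")
})
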