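# Oracle-checked behavior of the packer family.  Random instances are small
# enough for exhaustive enumeration, which is the ground truth throughout.

oracle_suite <- function(n, n_pos = 5, max_rot = 5, seed_base = 100) {
  lapply(seq_len(n), function(i)
    random_packing_problem(n_pos, max_rot, seed = seed_base + i))
}

test_that("bmec minimizes one-body terms independently with lowest-index ties", {
  p <- new_packing_problem("p1", list(rep("X", 3)), list(c(3, -1, 0.5)),
                           integer(0), integer(0), list())
  expect_equal(bmec(p), 2L)
  ptie <- new_packing_problem("p1", list(rep("X", 2)), list(c(0, 0)),
                              integer(0), integer(0), list())
  expect_equal(bmec(ptie), 1L)
  # with all pair energies zero the bmec is the GMEC
  p0 <- random_packing_problem(4, 4, seed = 1, pair_prob = 0)
  expect_equal(bmec(p0), pack_exhaustive(p0)$assignment$choice)
})

test_that("quench only descends and stops at local minima", {
  for (p in oracle_suite(25, 4, 4)) {
    gmec <- pack_exhaustive(p)
    q <- quench(p, gmec$assignment$choice)
    expect_same_assignment(q, gmec$assignment$choice)   # GMEC is stable
    start <- rep(1L, length(p$m))
    q2 <- quench(p, start)
    expect_lte(total_energy(p, q2), total_energy(p, start))
    expect_gte(total_energy(p, q2), gmec$energy - 1e-9)
  }
  p1 <- new_packing_problem("p1", list(rep("X", 4)),
                            list(c(2, -3, 0, 1)), integer(0), integer(0),
                            list())
  expect_equal(quench(p1, 1L), 2L)
})

test_that("faster relaxation starts from bmec and escapes pairwise clashes", {
  # no neighbor pairs: result is exactly the bmec
  p0 <- random_packing_problem(5, 5, seed = 3, pair_prob = 0)
  expect_same_assignment(pack_faster(p0)$assignment$choice, bmec(p0))
  # engineered instance: both bmec rotamers clash and must move jointly
  pc <- new_packing_problem(c("a", "b"), list(rep("X", 2), rep("X", 2)),
                            one_body = list(c(0, 0.5), c(0, 0.5)),
                            pi = 1L, pj = 2L,
                            mats = list(matrix(c(10, 0, 0, -1), 2, 2,
                                               byrow = TRUE)))
  expect_same_assignment(bmec(pc), c(1L, 1L))
  res <- pack_faster(pc)
  expect_lt(res$energy, total_energy(pc, bmec(pc)))
  expect_equal(res$energy, pack_exhaustive(pc)$energy)
})

test_that("every packer respects the exhaustive lower bound on 200 instances", {
  ids <- c("bmec_spr", "standard", "multicool", "sima5_spr", "sima5_spr_x8")
  at_gmec <- setNames(numeric(length(ids)), ids)
  suite <- oracle_suite(200, 6, 6)
  for (i in seq_along(suite)) {
    p <- suite[[i]]
    gmec <- pack_exhaustive(p)$energy
    for (id in ids) {
      res <- suppressWarnings(get_packer(id)(p, seed = stable_mix(1, id, i)))
      expect_gte(res$energy, gmec - 1e-9)
      if (res$energy - gmec <= 1e-6) at_gmec[id] <- at_gmec[id] + 1
    }
  }
  # qualitative ordering: restarts help, multicool beats the standard annealer
  expect_gte(at_gmec[["sima5_spr_x8"]], at_gmec[["sima5_spr"]])
  expect_gte(at_gmec[["multicool"]], at_gmec[["standard"]])
})

test_that("annealers return the unique assignment on single-rotamer problems", {
  p <- new_packing_problem(c("a", "b"), list("X", "X"), list(0.3, -1),
                           integer(0), integer(0), list(), e_const = 2)
  for (res in list(pack_standard_anneal(p, seed = 1),
                   suppressWarnings(pack_multicool(p, seed = 1)),
                   pack_faster(p), pack_exhaustive(p))) {
    expect_same_assignment(res$assignment$choice, c(1L, 1L))
    expect_equal(res$energy, 2 + 0.3 - 1)
  }
})

test_that("the metropolis acceptance rate matches exp(-dE/kT)", {
  # two-rotamer single position: every uphill proposal has dE = +1
  p <- new_packing_problem("p1", list(rep("X", 2)), list(c(0, 1)),
                           integer(0), integer(0), list())
  pr <- metropolis_probe(p, 1L, kT = 1, n_moves = 1e5, seed = 12)
  expect_gt(pr$uphill_proposed, 1e4)
  rate <- pr$uphill_accepted / pr$uphill_proposed
  sigma <- sqrt(exp(-1) * (1 - exp(-1)) / pr$uphill_proposed)
  expect_lt(abs(rate - exp(-1)), 3 * sigma)
})

test_that("multicool performs exactly sixty quench-and-restores in phase 1", {
  p <- random_packing_problem(6, 6, seed = 42)
  res <- suppressWarnings(pack_multicool(p, seed = 7))
  expect_equal(res$quench_restores, 60)
})

test_that("hybrid restarts extend, never reshuffle, the seed stream", {
  p <- random_packing_problem(6, 6, seed = 17)
  # restarts = 1 at fraction 1.0 is the standard anneal followed by sPR
  h1 <- pack_hybrid(p, fraction = 1.0, restarts = 1, seed = 5)
  sa <- pack_standard_anneal(p, anneal_schedule(),
                             seed = stable_mix(5, "hybrid", 1))
  spr <- pack_faster(p, start = sa$assignment$choice)
  expect_identical(h1$energy, spr$energy)
  expect_same_assignment(h1$assignment$choice, spr$assignment$choice)
  # best over restarts is monotone in the number of restarts
  e1 <- pack_hybrid(p, 0.05, 1, seed = 5)$energy
  e4 <- pack_hybrid(p, 0.05, 4, seed = 5)$energy
  e8 <- pack_hybrid(p, 0.05, 8, seed = 5)$energy
  expect_lte(e8, e4); expect_lte(e4, e1)
})

test_that("packers are deterministic and their traces are non-increasing", {
  p <- random_packing_problem(6, 6, seed = 23)
  for (id in c("standard", "multicool", "sima5_spr_x2", "bmec_spr")) {
    r1 <- suppressWarnings(get_packer(id)(p, seed = 9))
    r2 <- suppressWarnings(get_packer(id)(p, seed = 9))
    expect_identical(r1$energy, r2$energy)
    expect_same_assignment(r1$assignment$choice, r2$assignment$choice)
    tr <- r1$best_trace[, "best"]
    expect_true(all(diff(tr) <= 0))
    expect_equal(min(tr), r1$energy)
  }
})

test_that("exhaustive enumeration is exact, tie-stable and guarded", {
  p <- hand_problem()
  res <- pack_exhaustive(p)
  hand <- c(total_energy(p, c(1, 1)), total_energy(p, c(1, 2)),
            total_energy(p, c(2, 1)), total_energy(p, c(2, 2)))
  expect_equal(res$energy, min(hand))
  big <- new_packing_problem(paste0("p", 1:10),
                             rep(list(rep("X", 10)), 10),
                             rep(list(rnorm(10)), 10),
                             integer(0), integer(0), list())
  expect_error(pack_exhaustive(big), "too large")
})

test_that("standard annealer honors the quench-anneal composition on trivial moves", {
  # a problem whose quench from any start reaches the GMEC: annealer must too
  p <- random_packing_problem(3, 3, seed = 4, pair_prob = 0)
  g <- pack_exhaustive(p)$energy
  expect_equal(pack_standard_anneal(p, seed = 2)$energy, g)
})
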