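test_that("the expression grammar evaluates arithmetic, min/max and ite", {
  prog <- parse_fitness_file(c("SCALAR_EXPRESSION x = 1 + 2*3",
                               "SCALAR_EXPRESSION y = min(x, 5) + max(1, 2)",
                               "SCALAR_EXPRESSION z = ite(x > 5, 10, 20)",
                               "SCALAR_EXPRESSION w = pow(2, 3) / 4 - -1",
                               "FITNESS x + y + z + w"))
  det <- evaluate_fitness(prog, list(), details = TRUE)
  expect_equal(det$values$x, 7)
  expect_equal(det$values$y, 5 + 2)
  expect_equal(det$values$z, 10)
  expect_equal(det$values$w, 3)
  expect_equal(det$fitness, 7 + 7 + 10 + 3)
})

test_that("vector variables and reductions work over state ensembles", {
  prog <- parse_fitness_file(c("STATE_VECTOR v @",
                               "SCALAR_EXPRESSION lo = vmin(v)",
                               "SCALAR_EXPRESSION hi = vmax(v)",
                               "VECTOR_EXPRESSION shifted = v + 1",
                               "SCALAR_EXPRESSION s = vmin(shifted)",
                               "FITNESS lo + hi + s"))
  f <- evaluate_fitness(prog, list(v = c(-3, 2, 7)))
  expect_equal(f, -3 + 7 + (-2))
})

test_that("malformed fitness files are rejected with line context", {
  expect_error(parse_fitness_file("SCALAR_EXPRESSION x = 1"), "no FITNESS")
  expect_error(parse_fitness_file(c("FITNESS 1", "FITNESS 2")),
               "second FITNESS")
  expect_error(parse_fitness_file("FITNESS nope"), "undefined")
  expect_error(parse_fitness_file("SCALAR_EXPRESSION x = 1 +\nFITNESS x"),
               "syntax|expected")
  expect_error(parse_fitness_file(c("SCALAR_EXPRESSION x = 1",
                                    "SCALAR_EXPRESSION x = 2",
                                    "FITNESS x")), "redefined")
})

test_that("entity functions implement the stepped, clipped penalty rules", {
  pairs <- cbind(seq(1, 15, 2), seq(2, 16, 2))
  idp <- entity_function(list(identity_penalty(pairs, free = 6, step = 5)))
  seq7 <- "FFAALLAAGGLLVVVM"  # 7 of 8 pairs identical
  seq6 <- "FFAALLAAGGLLVMVM"  # 6 identical
  seq8 <- "FFAALLAAGGLLVVMM"  # all 8 identical
  expect_equal(evaluate_entity_function(idp, seq7), 5)
  expect_equal(evaluate_entity_function(idp, seq6), 0)
  expect_equal(evaluate_entity_function(idp, seq8), 10)
  wt <- strsplit("FALAGLVV", "")[[1]]
  mp <- entity_function(list(mutation_penalty(seq(1, 15, 2), wt,
                                              free = 5, step = 1)))
  mut_seq <- function(k) {
    l <- rep("A", 16)
    l[seq(1, 15, 2)] <- wt
    l[seq(1, 15, 2)][seq_len(k)] <- "W"
    paste(l, collapse = "")
  }
  expect_equal(evaluate_entity_function(mp, mut_seq(5)), 0)
  expect_equal(evaluate_entity_function(mp, mut_seq(6)), 1)
  expect_equal(evaluate_entity_function(mp, mut_seq(7)), 2)
})

test_that("entity-function files parse to the same scores", {
  txt <- c("IDENTITY_PENALTY free=6 step=5 pairs=1:2,3:4,5:6,7:8,9:10,11:12,13:14,15:16",
           "MUTATION_PENALTY free=5 step=1 positions=1,3,5,7,9,11,13,15 wildtype=FALAGLVV")
  def <- parse_entity_function(txt)
  built <- hetero_entity_function(16, "FfAaLlAaGgLlVvVv")
  for (s in c("FFAALLAAGGLLVVVM", "WWWWWWWWWWWWWWWW", "FfAaLlAaGgLlVvVv")) {
    expect_equal(evaluate_entity_function(def, s),
                 evaluate_entity_function(built, s) -
                   # built also penalizes the even-position chain
                   evaluate_entity_function(entity_function(list(
                     mutation_penalty(seq(2, 16, 2),
                                      strsplit("FALAGLVV", "")[[1]]))), s))
  }
})

test_that("entity functions are permutation-covariant", {
  set.seed(3)
  pairs <- cbind(c(1, 3, 5), c(2, 4, 6))
  def <- entity_function(list(identity_penalty(pairs, free = 1, step = 2)))
  for (i in 1:20) {
    seq <- sample(c("A", "F", "L"), 6, replace = TRUE)
    perm <- sample(6)
    inv <- order(perm)
    def_p <- entity_function(list(identity_penalty(
      cbind(inv[pairs[, 1]], inv[pairs[, 2]]), free = 1, step = 2)))
    expect_equal(evaluate_entity_function(def, seq),
                 evaluate_entity_function(def_p, seq[perm]))
  }
})

test_that("the gap fitness reproduces the hand-derived micro-case and the cap", {
  prog <- heterodimer_fitness(w = 2)
  # independently re-derived: dGAB = -20, capped gaps sum to -35,
  # F = -100 + 2*(-35) = -170
  expect_equal(evaluate_fitness(prog, hetero_energies()), -170)
  det <- evaluate_fitness(prog, hetero_energies(), details = TRUE)
  expect_equal(det$values$dGAA, -5)
  expect_equal(det$values$dGBB, 0)     # +2 raw, capped at 0
  # capping makes +3 and +1000 raw homodimer binding energies equivalent
  f3 <- evaluate_fitness(prog, hetero_energies(eAA = -77))      # raw +3
  f1000 <- evaluate_fitness(prog, hetero_energies(eAA = 920))   # raw +1000
  expect_identical(f3, f1000)
})

test_that("the gap weight trades total for binding energy neutrally at exactly 0.5", {
  # perturbation: heterodimer total +1 REU and binding -1 REU, with both
  # homodimer binding energies pinned in the capped (>= 0) regime so only
  # the heterodimer terms move
  delta <- function(w) {
    prog <- heterodimer_fitness(w = w)
    base <- evaluate_fitness(prog, hetero_energies(eAA = -60, eBB = -60))
    pert <- evaluate_fitness(prog, hetero_energies(eAB = -99, eA = -39,
                                                   eB = -39, eAA = -60,
                                                   eBB = -60))
    pert - base
  }
  root <- uniroot(delta, c(0.01, 5), tol = 1e-12)$root
  expect_equal(root, 0.5, tolerance = 1e-9)
  expect_gt(delta(0.4), 0)   # below 0.5: the trade worsens fitness
  expect_lt(delta(0.6), 0)   # above 0.5: the trade pays
})

test_that("the saturating fitness stops rewarding heterodimer binding below -24", {
  prog <- heterodimer_fitness(variant = 2, w2 = 1)
  f_at <- function(dgab) {
    # move eB to set dGAB; homodimer binding energies sit at -10, on the
    # zero-penalty side of the -12 target, so only the saturating
    # heterodimer term varies
    eA <- -40; eAB <- -100
    eB <- eAB - eA - dgab
    evaluate_fitness(prog, list(EA = eA, EB = eB, EAB = eAB,
                                EAA = 2 * eA - 10, EBB = 2 * eB - 10))
  }
  grid <- seq(-30, -18, by = 0.5)
  f <- vapply(grid, f_at, 1)
  d <- diff(f)
  # flat below the saturation point, strictly increasing above it
  expect_true(all(abs(d[grid[-1] <= -24]) < 1e-9))
  expect_true(all(d[grid[-length(grid)] >= -24] > 0))
})

test_that("the homodimer destabilization bonus vanishes exactly at -12", {
  prog <- heterodimer_fitness(variant = 2, w2 = 1)
  pen_at <- function(dgaa) {
    eA <- -40; eB <- -40; eAB <- -110   # dGAB = -30 < gate
    det <- evaluate_fitness(prog, list(EA = eA, EB = eB, EAB = eAB,
                                       EAA = 2 * eA + dgaa,
                                       EBB = 2 * eB - 14), details = TRUE)
    det$values$penAA
  }
  grid <- seq(-16, -6, by = 0.25)
  pen <- vapply(grid, pen_at, 1)
  # the bonus drives homodimers up toward -12: a homodimer still bound more
  # strongly than -12 is penalized, and the term hits zero exactly at -12
  expect_true(all(pen[grid >= -12] == 0))
  expect_true(all(pen[grid < -12] > 0))
  expect_equal(min(grid[pen == 0]), -12)
})

test_that("fitness is monotone where the caps dictate", {
  prog <- heterodimer_fitness(w = 3)
  # strictly decreasing in the heterodimer total energy
  f1 <- evaluate_fitness(prog, hetero_energies(eAB = -100))
  f2 <- evaluate_fitness(prog, hetero_energies(eAB = -101))
  expect_gt(f1, f2)
  # flat in a capped homodimer region above 0
  fa <- evaluate_fitness(prog, hetero_energies(eAA = -70))  # raw +10
  fb <- evaluate_fitness(prog, hetero_energies(eAA = -60))  # raw +20
  expect_identical(fa, fb)
})

test_that("the shipped fitness files reproduce the built-in definitions", {
  dir <- system.file("extdata", package = "msdesign")
  en <- hetero_energies()
  wt <- "FfAaLlAaGgLlVvVv"
  ent <- hetero_entity_function(16, wt)
  seqs <- c("HFAAGMMAGRLVMLFF", wt, "WWWWWWWWWWWWWWWW")
  f1_file <- parse_fitness_file(readLines(file.path(dir,
                                                    "fitness1_hetero.fit")),
                                dir = dir)
  f1_prog <- heterodimer_fitness(w = 2, entity_fn = ent)
  f2_file <- parse_fitness_file(readLines(file.path(dir,
                                                    "fitness2_hetero.fit")),
                                dir = dir)
  f2_prog <- heterodimer_fitness(variant = 2, w2 = 1, entity_fn = ent)
  for (s in seqs) {
    expect_equal(evaluate_fitness(f1_file, en, s),
                 evaluate_fitness(f1_prog, en, s))
    expect_equal(evaluate_fitness(f2_file, en, s),
                 evaluate_fitness(f2_prog, en, s))
  }
  ral_file <- parse_fitness_file(readLines(file.path(dir,
                                                     "ral_orthogonal.fit")),
                                 dir = dir)
  ral_en <- list(EAB = -90, EAC = -80, EAD = -70, EA_AB = -30, EA_AC = -31,
                 EA_AD = -32, EB = -25, EC = -26, ED = -27)
  expect_equal(evaluate_fitness(ral_file, ral_en),
               evaluate_fitness(orthogonal_fitness(w = 2), ral_en))
})

test_that("the one-against-many fitness uses matched-backbone monomers", {
  prog <- orthogonal_fitness(w = 2)
  en <- list(EAB = -90, EAC = -80, EAD = -70, EA_AB = -30, EA_AC = -31,
             EA_AD = -32, EB = -25, EC = -26, ED = -27)
  det <- evaluate_fitness(prog, en, details = TRUE)
  expect_equal(det$values$dGAB, -90 + 30 + 25)
  expect_equal(det$values$dGAC, min(-80 + 31 + 26, 0))
  expect_equal(det$values$dGAD, min(-70 + 32 + 27, 0))
  expect_equal(det$fitness, -90 + 2 * ((det$values$dGAB - det$values$dGAC) +
                                         (det$values$dGAB - det$values$dGAD)))
})
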