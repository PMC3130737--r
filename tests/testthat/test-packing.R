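test_that("total energy matches exhaustive hand evaluation on a printed 2x2 table", {
  p <- hand_problem()
  # hand sums: e_const + ob1[i] + ob2[j] + pair[i, j]
  expect_equal(total_energy(p, c(1, 1)), 0.5 + 1.0 - 0.5 + 0.1)
  expect_equal(total_energy(p, c(1, 2)), 0.5 + 1.0 + 0.25 - 0.3)
  expect_equal(total_energy(p, c(2, 1)), 0.5 + 2.0 - 0.5 + 0.7)
  expect_equal(total_energy(p, c(2, 2)), 0.5 + 2.0 + 0.25 + 0.2)
  expect_error(total_energy(p, c(3, 1)), "invalid")
  # with all pair energies zero the total is the one-body sum
  p0 <- new_packing_problem(p$positions, p$rotamer_aa, p$one_body,
                            integer(0), integer(0), list(), e_const = 0)
  expect_equal(total_energy(p0, c(2, 1)), 2.0 - 0.5)
})

test_that("problem construction validates its invariants", {
  expect_error(new_packing_problem("p1", list("X"), list(numeric(0)),
                                   integer(0), integer(0), list()),
               "at least one rotamer")
  expect_error(new_packing_problem(c("a", "b"), list("X", "X"),
                                   list(0, 0), 2L, 1L,
                                   list(matrix(0, 1, 1))), "pi < pj")
  expect_error(new_packing_problem(c("a", "b"), list("X", "X"),
                                   list(c(0, 0), 0), 1L, 2L,
                                   list(matrix(0, 1, 2))), "dimensions")
})

test_that("threaded problems carry only the assigned amino acid per position", {
  sys <- small_hetero_system()
  sp <- state_spec("AB", sys$structures$AB, sys$correspondences$AB,
                   sys$secondary$AB)
  ctx <- state_context(sp, allowed_aas = c("A", "M", "L", "F"))
  seq <- paste(rep("M", sys$entity_length), collapse = "")
  prob <- build_packing_problem(ctx, seq)
  pos <- ctx$universe$positions
  for (r in seq_len(nrow(pos))) {
    expected <- if (pos$kind[r] == "design") "M" else pos$wildtype[r]
    expect_true(all(prob$rotamer_aa[[r]] == expected))
  }
  # secondary positions repack at wildtype
  expect_true(any(pos$kind == "repack"))
})

test_that("a residue in neither file still contributes its backbone sphere to one-body energies", {
  # two close residues, only the first is designed
  s2 <- toy_structure(chain = c("A", "A"), resnum = 1:2, aa = c("L", "A"),
                      xyz = rbind(c(0, 0, 0), c(3.0, 0, 0)))
  s1 <- extract_chains(s2, "A")
  s1$residues <- s1$residues[1, , drop = FALSE]
  s1$frames <- s2$frames[, , 1, drop = FALSE]
  corr <- new_correspondence(data.frame(entity_position = 1, chain = "A",
                                        resnum = 1), 1)
  ctx2 <- state_context(state_spec("with", s2, corr), allowed_aas = "L")
  ctx1 <- state_context(state_spec("without", s1, corr), allowed_aas = "L")
  ob2 <- build_packing_problem(ctx2, "L")$one_body[[1]]
  ob1 <- build_packing_problem(ctx1, "L")$one_body[[1]]
  # direct summation oracle: the difference is the rotamer-vs-backbone term
  rots <- build_rotamers(s2, 1, "L")
  bbsphere <- list(center = c(3, 0, 0), radius = 1.7, hydrophobicity = 0)
  direct <- vapply(seq_len(nrow(rots)), function(i)
    pair_energy(list(center = unlist(rots[i, c("cx", "cy", "cz")]),
                     radius = rots$radius[i],
                     hydrophobicity = rots$hydrophobicity[i]), bbsphere), 1)
  expect_equal(ob2 - ob1, direct)
})

test_that("errors name the offending residue or overlap", {
  sys <- small_hetero_system()
  bad <- new_correspondence(data.frame(entity_position = 1, chain = "A",
                                       resnum = 999), 1)
  expect_error(state_context(state_spec("x", sys$structures$A, bad)),
               "A/999")
  ce <- sys$correspondences$AB$entries[1, ]
  expect_error(
    state_context(state_spec("y", sys$structures$AB, sys$correspondences$AB,
                             data.frame(chain = ce$chain, resnum = ce$resnum))),
    "overlap")
})

test_that("interaction graph caches, evicts least-recently-accessed, and recomputes transparently", {
  sys <- small_hetero_system()
  sp <- state_spec("AB", sys$structures$AB, sys$correspondences$AB,
                   sys$secondary$AB)
  u <- msdesign:::build_universe(sp$structure, sp$correspondence,
                                 sp$secondary, c("L", "F"),
                                 toy_energy_params())
  g <- interaction_graph(u, memory_ceiling = Inf)
  k <- cbind(u$cand_i[1:3], u$cand_j[1:3])
  A1 <- pair_submatrix(g, k[1, 1], "L", k[1, 2], "L")
  n_after_first <- g$computed
  A2 <- pair_submatrix(g, k[1, 1], "L", k[1, 2], "L")
  expect_identical(A1, A2)
  expect_identical(g$computed, n_after_first)   # no recomputation on hit
  # transposed access returns the transposed matrix, same cache entry
  At <- pair_submatrix(g, k[1, 2], "L", k[1, 1], "L")
  expect_identical(At, t(A1))
  # ceiling of one submatrix: A, then B evicts A, A recomputed bit-identical
  g1 <- interaction_graph(u, memory_ceiling = 8 * length(A1))
  B1 <- pair_submatrix(g1, k[1, 1], "L", k[1, 2], "L")
  pair_submatrix(g1, k[2, 1], "F", k[2, 2], "F")
  expect_equal(g1$evictions, 1)
  B2 <- pair_submatrix(g1, k[1, 1], "L", k[1, 2], "L")
  expect_identical(B1, B2)
  # access pattern A, B, C with room for exactly two evicts the least
  # recently accessed (A)
  sizes <- vapply(1:3, function(i)
    length(msdesign:::compute_submatrix(u, k[i, 1], "L", k[i, 2], "L")), 1L)
  g2 <- interaction_graph(u, memory_ceiling = 8 * (sizes[1] + sizes[2]))
  ka <- paste(k[1, 1], "L", k[1, 2], "L", sep = "|")
  kb <- paste(k[2, 1], "L", k[2, 2], "L", sep = "|")
  pair_submatrix(g2, k[1, 1], "L", k[1, 2], "L")
  pair_submatrix(g2, k[2, 1], "L", k[2, 2], "L")
  pair_submatrix(g2, k[3, 1], "L", k[3, 2], "L")
  expect_false(ka %in% names(g2$last))
  expect_true(kb %in% names(g2$last))
})

test_that("packing results are bit-identical under unlimited and tiny memory ceilings", {
  sys <- small_hetero_system()
  sp <- state_spec("AA", sys$structures$AA, sys$correspondences$AA,
                   sys$secondary$AA)
  seqs <- c("LFLFLMLMLALA", "MMMMMMMMMMMM")
  seqs <- vapply(seqs, function(s)
    paste(strsplit(s, "")[[1]][seq_len(sys$entity_length)], collapse = ""),
    "")
  for (seq in seqs) {
    ctx_big <- state_context(sp, c("A", "M", "L", "F"), memory_ceiling = Inf)
    ctx_tiny <- state_context(sp, c("A", "M", "L", "F"),
                              memory_ceiling = 8 * 36)
    e1 <- evaluate_state(sp, seq, context = ctx_big, global_seed = 4)
    e2 <- evaluate_state(sp, seq, context = ctx_tiny, global_seed = 4)
    expect_identical(e1$energy, e2$energy)
    expect_identical(e1$assignment, e2$assignment)
    expect_gt(msdesign:::graph_stats(ctx_tiny$graph)$evictions, 0)
  }
})

test_that("lazy pair-energy computation beats full precomputation on a design workload", {
  sys <- small_hetero_system()
  sp <- state_spec("AB", sys$structures$AB, sys$correspondences$AB,
                   sys$secondary$AB)
  ctx <- state_context(sp, allowed_aas = c("A", "M", "L", "F", "I", "V"))
  set.seed(9)
  for (i in 1:12) {
    seq <- paste(sample(c("A", "M", "L", "F", "I", "V"), sys$entity_length,
                        TRUE), collapse = "")
    invisible(build_packing_problem(ctx, seq))
  }
  st <- graph_stats(ctx$graph)
  expect_gt(st$savings_fraction, 0)
  expect_lt(st$distinct, st$full_count)
})

test_that("the debug dump is a faithful text table", {
  p <- hand_problem()
  tab <- dump_packing_problem(p)
  expect_equal(tab$n_rot, c(2L, 2L))
  expect_equal(tab$ob_min, c(1.0, -0.5))
  tf <- tempfile()
  dump_packing_problem(p, tf)
  expect_true(file.exists(tf))
})
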