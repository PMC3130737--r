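# Shared fixtures, all built in code.

# a bare rotamer for direct pair-energy calls
mk_rot <- function(x, y, z, radius = 1.2, h = 0)
  list(center = c(x, y, z), radius = radius, hydrophobicity = h)

# hand-specified two-position problem with a printed 2x2 pair table
hand_problem <- function() {
  new_packing_problem(
    positions = c("p1", "p2"),
    rotamer_aa = list(c("X", "X"), c("X", "X")),
    one_body = list(c(1.0, 2.0), c(-0.5, 0.25)),
    pi = 1L, pj = 2L,
    mats = list(matrix(c(0.1, -0.3, 0.7, 0.2), 2, 2, byrow = TRUE)),
    e_const = 0.5)
}

# the 8-residue-per-chain dimer layout used by the classic heterodimer
# decode convention (residues 21..48, odd entity positions on chain A)
decode_fixture <- function() {
  resnums <- c(21, 24, 25, 28, 32, 44, 46, 48)
  wt <- c("F", "A", "L", "A", "G", "L", "V", "V")
  st <- toy_structure(chain = rep(c("A", "B"), each = 8),
                      resnum = rep(resnums, 2), aa = rep(wt, 2),
                      xyz = cbind(seq_len(16) * 4, 0, 0))
  corr <- new_correspondence(
    data.frame(entity_position = c(seq(1, 15, 2), seq(2, 16, 2)),
               chain = rep(c("A", "B"), each = 8),
               resnum = rep(resnums, 2)), 16)
  state_spec("AB", st, corr)
}

# abstract heterodimer fitness over plain energies
hetero_energies <- function(eA = -40, eB = -40, eAB = -100, eAA = -85,
                            eBB = -78) {
  list(EA = eA, EB = eB, EAB = eAB, EAA = eAA, EBB = eBB)
}

random_rotamer <- function() {
  mk_rot(runif(1, -5, 5), runif(1, -5, 5), runif(1, -5, 5),
         radius = runif(1, 0.8, 1.8), h = runif(1, -1, 1))
}

expect_same_assignment <- function(a, b) {
  expect_identical(as.integer(a), as.integer(b))
}

small_hetero_system <- function(seed = 7)
  generate_synthetic_system("heterodimer_task", n_interface = 2, seed = seed)
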