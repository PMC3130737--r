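# Synthetic scaffolds and design systems.  Scaffolds are helical C-alpha
# traces; dimers are two helices placed face to face at a controlled gap, so
# interface density is tunable and every design/docking algorithm can be
# exercised without any external structure files.

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(as.integer(seed %% 2147483646) + 1L)
  force(code)
}

# alpha-helical C-alpha trace along +z
helix_anchors <- function(n_res, radius = 2.3, rise = 1.5, turn_deg = 100) {
  k <- seq_len(n_res) - 1
  th <- k * turn_deg * pi / 180
  cbind(radius * cos(th), radius * sin(th), rise * k)
}

rot_x180 <- matrix(c(1, 0, 0, 0, -1, 0, 0, 0, -1), 3, 3)

# two-helix dimer: chain 2 is chain 1 rotated 180 deg about x and shifted to
# axis distance `gap`, spanning the same z range
two_helix_dimer <- function(n_res, gap, chain_ids = c("A", "B"),
                            aa1 = rep("A", n_res), aa2 = aa1, zshift = 0) {
  a1 <- helix_anchors(n_res)
  a2 <- a1 %*% t(rot_x180)
  a2[, 1] <- a2[, 1] + gap
  a2[, 3] <- a2[, 3] + (n_res - 1) * 1.5 + zshift
  toy_structure(chain = rep(chain_ids, each = n_res),
                resnum = rep(seq_len(n_res), 2),
                aa = c(aa1, aa2),
                xyz = rbind(a1, a2))
}

cross_pairs_within <- function(s, chain1, chain2, cutoff) {
  r <- s$residues
  i1 <- which(r$chain == chain1); i2 <- which(r$chain == chain2)
  xyz <- anchors(s)
  d <- outer(rowSums(xyz[i1, , drop = FALSE]^2),
             rowSums(xyz[i2, , drop = FALSE]^2), `+`) -
    2 * xyz[i1, , drop = FALSE] %*% t(xyz[i2, , drop = FALSE])
  idx <- which(sqrt(pmax(d, 0)) <= cutoff, arr.ind = TRUE)
  data.frame(res1 = r$resnum[i1[idx[, 1]]], res2 = r$resnum[i2[idx[, 2]]])
}

#' Generate a synthetic design system
#'
#' Emulates the input layout of the two design tasks the framework targets,
#' with deterministic geometry and wildtype assignment under `seed`:
#'
#' * `"heterodimer_task"`: two chemical species A and B on a shared two-helix
#'   scaffold, with the five arrangements A, B, AB, AA and BB.  Entity
#'   positions follow the odd/even convention: odd positions belong to
#'   species A, even to species B, both indexed over the same designable
#'   residue numbers.  Monomer structures share backbone coordinates with
#'   their chains inside the dimers, so matched-backbone binding energies
#'   are exact.
#' * `"orthogonal_task"`: species A plus three partners B, C, D forming AB,
#'   AC and AD, with per-backbone monomer copies of A.  The partners contact
#'   overlapping subsets of A's interface.
#' * `"packing_instance"`: a single helix with a designable core, for
#'   exercising packers on structure-derived problems.
#'
#' @param kind one of `"heterodimer_task"`, `"orthogonal_task"`,
#'   `"packing_instance"`.
#' @param n_interface minimum number of designable cross-chain residue pairs
#'   within the interaction cutoff (for `packing_instance`, the number of
#'   designable residues).
#' @param seed integer seed; identical seeds give bit-identical coordinates.
#' @param params a [toy_energy_params()].
#' @return a list with `structures` (named list of [toy_structure()]),
#'   `designable` (residue numbers), `entity_length`, `wildtype_entity`,
#'   `correspondences` and `secondary` (per species), plus bookkeeping.
#' @export
generate_synthetic_system <- function(kind = c("heterodimer_task",
                                               "orthogonal_task",
                                               "packing_instance"),
                                      n_interface = 4, seed = 1,
                                      params = toy_energy_params()) {
  kind <- match.arg(kind)
  if (n_interface < 1) stop("n_interface must be >= 1")
  switch(kind,
         heterodimer_task = synth_heterodimer(n_interface, seed, params),
         orthogonal_task = synth_orthogonal(n_interface, seed, params),
         packing_instance = synth_packing_instance(n_interface, seed, params))
}

DESIGN_ALPHABET <- c("A", "F", "L", "M", "V", "I", "S", "K")

synth_heterodimer <- function(n_interface, seed, params) {
  n_res <- max(12, 3 * n_interface + 6)
  gap <- 10.0
  repeat {
    s <- two_helix_dimer(n_res, gap)
    cp <- cross_pairs_within(s, "A", "B", params$pair_cutoff)
    if (nrow(cp) >= n_interface) break
    gap <- gap - 0.25
    if (gap < 5) stop("cannot reach requested interface density")
  }
  designable <- sort(unique(c(cp$res1, cp$res2)))
  wt <- with_seed(stable_mix(seed, "hetero-wt"), {
    aa <- rep("A", n_res)
    aa[designable] <- sample(c("F", "L", "M", "V", "I"), length(designable),
                             replace = TRUE)
    aa
  })
  dimer <- two_helix_dimer(n_res, gap, aa1 = wt, aa2 = wt)
  n_des <- length(designable)
  L <- 2L * n_des
  # boundary residues: near the interface but not designed; repack only
  sec_res <- setdiff(sort(unique(unlist(lapply(designable, function(r)
    intersect(c(r - 1, r + 1), seq_len(n_res)))))), designable)
  secondary <- rbind(data.frame(chain = "A", resnum = sec_res),
                     data.frame(chain = "B", resnum = sec_res))
  corr_entry <- function(entity, chain, res)
    data.frame(entity_position = entity, chain = chain, resnum = res)
  odd <- 2L * seq_len(n_des) - 1L
  even <- 2L * seq_len(n_des)
  correspondences <- list(
    AB = new_correspondence(rbind(corr_entry(odd, "A", designable),
                                  corr_entry(even, "B", designable)), L),
    AA = new_correspondence(rbind(corr_entry(odd, "A", designable),
                                  corr_entry(odd, "B", designable)), L),
    BB = new_correspondence(rbind(corr_entry(even, "A", designable),
                                  corr_entry(even, "B", designable)), L),
    A = new_correspondence(corr_entry(odd, "A", designable), L),
    B = new_correspondence(corr_entry(even, "B", designable), L))
  structures <- list(A = extract_chains(dimer, "A"),
                     B = extract_chains(dimer, "B"),
                     AB = dimer, AA = dimer, BB = dimer)
  wl <- wt[designable]
  wildtype_entity <- paste(as.vector(rbind(wl, wl)), collapse = "")
  list(kind = "heterodimer_task", structures = structures,
       designable = designable, entity_length = L,
       wildtype_entity = wildtype_entity,
       correspondences = correspondences,
       secondary = list(AB = secondary, AA = secondary, BB = secondary,
                        A = secondary[secondary$chain == "A", ],
                        B = secondary[secondary$chain == "B", ]),
       gap = gap, n_res = n_res)
}

synth_orthogonal <- function(n_interface, seed, params) {
  n_res <- max(14, 3 * n_interface + 8)
  gap <- 10.0
  zsh <- c(B = -2, C = 0, D = 2)
  repeat {
    dims <- lapply(names(zsh), function(p)
      two_helix_dimer(n_res, gap, chain_ids = c("A", p), zshift = zsh[[p]]))
    names(dims) <- names(zsh)
    cps <- lapply(names(zsh), function(p)
      cross_pairs_within(dims[[p]], "A", p, params$pair_cutoff))
    if (all(vapply(cps, nrow, 1L) >= n_interface)) break
    gap <- gap - 0.25
    if (gap < 5) stop("cannot reach requested interface density")
  }
  designable <- sort(unique(unlist(lapply(cps, function(cp) cp$res1))))
  wt <- with_seed(stable_mix(seed, "ortho-wt"), {
    aa <- rep("A", n_res)
    aa[designable] <- sample(c("F", "L", "M", "V", "I"), length(designable),
                             replace = TRUE)
    aa
  })
  dimers <- lapply(names(zsh), function(p)
    two_helix_dimer(n_res, gap, chain_ids = c("A", p), aa1 = wt,
                    aa2 = rep("L", n_res), zshift = zsh[[p]]))
  names(dimers) <- paste0("A", names(zsh))
  n_des <- length(designable)
  L <- n_des
  corr_A <- new_correspondence(
    data.frame(entity_position = seq_len(n_des), chain = "A",
               resnum = designable), L)
  partner_sec <- function(p, cp) {
    pr <- sort(unique(cp$res2))
    data.frame(chain = p, resnum = pr)
  }
  secondary <- lapply(names(zsh), function(p) partner_sec(p, cps[[match(p, names(zsh))]]))
  names(secondary) <- paste0("A", names(zsh))
  structures <- c(dimers,
                  list(A_AB = extract_chains(dimers$AB, "A"),
                       A_AC = extract_chains(dimers$AC, "A"),
                       A_AD = extract_chains(dimers$AD, "A"),
                       B = extract_chains(dimers$AB, "B"),
                       C = extract_chains(dimers$AC, "C"),
                       D = extract_chains(dimers$AD, "D")))
  correspondences <- c(
    setNames(rep(list(corr_A), 3), c("AB", "AC", "AD")),
    setNames(rep(list(corr_A), 3), c("A_AB", "A_AC", "A_AD")),
    setNames(rep(list(new_correspondence(
      data.frame(entity_position = integer(0), chain = character(0),
                 resnum = integer(0)), L)), 3), c("B", "C", "D")))
  sec_all <- c(secondary,
               setNames(rep(list(data.frame(chain = character(0),
                                            resnum = integer(0))), 3),
                        c("A_AB", "A_AC", "A_AD")),
               list(B = secondary$AB, C = secondary$AC, D = secondary$AD))
  wildtype_entity <- paste(wt[designable], collapse = "")
  list(kind = "orthogonal_task", structures = structures,
       designable = designable, entity_length = L,
       wildtype_entity = wildtype_entity,
       correspondences = correspondences, secondary = sec_all,
       gap = gap, n_res = n_res)
}

synth_packing_instance <- function(n_interface, seed, params) {
  n_res <- max(10, n_interface + 6)
  a <- helix_anchors(n_res)
  wt <- with_seed(stable_mix(seed, "pack-wt"), {
    sample(c("F", "L", "M", "V", "I", "A"), n_res, replace = TRUE)
  })
  s <- toy_structure(chain = rep("A", n_res), resnum = seq_len(n_res),
                     aa = wt, xyz = a)
  start <- (n_res - n_interface) %/% 2 + 1
  designable <- seq(start, length.out = n_interface)
  L <- n_interface
  corr <- new_correspondence(
    data.frame(entity_position = seq_len(L), chain = "A",
               resnum = designable), L)
  list(kind = "packing_instance", structures = list(A = s),
       designable = designable, entity_length = L,
       wildtype_entity = paste(wt[designable], collapse = ""),
       correspondences = list(A = corr),
       secondary = list(A = data.frame(chain = character(0),
                                       resnum = integer(0))),
       n_res = n_res)
}

#' Random abstract packing instance
#'
#' Draws a small packing problem directly as energy tables: Gaussian
#' one-body energies, dense-ish neighbor pairs whose entries are mostly
#' small Gaussians with an occasional large positive clash.  These frustrate
#' hill-climbers enough to separate the optimization algorithms while
#' remaining exhaustively solvable.
#'
#' @param n_pos number of positions.
#' @param max_rot maximum rotamers per position (each position draws
#'   uniformly between 2 and `max_rot`).
#' @param seed integer seed.
#' @param pair_prob probability that a position pair interacts.
#' @param clash_prob probability that a pair entry is a +8 REU clash.
#' @return a `packing_problem`.
#' @export
random_packing_problem <- function(n_pos = 6, max_rot = 6, seed = 1,
                                   pair_prob = 0.6, clash_prob = 0.12) {
  with_seed(stable_mix(seed, "rpp", n_pos, max_rot), {
    m <- sample(2:max_rot, n_pos, replace = TRUE)
    one_body <- lapply(m, function(k) round(rnorm(k, 0, 2), 6))
    pi <- integer(0); pj <- integer(0); mats <- list()
    for (i in seq_len(n_pos - 1)) for (j in seq(i + 1, n_pos)) {
      if (runif(1) < pair_prob) {
        M <- matrix(rnorm(m[i] * m[j], 0, 1.5), m[i], m[j])
        M[matrix(runif(length(M)) < clash_prob, m[i], m[j])] <- 8
        pi <- c(pi, i); pj <- c(pj, j); mats <- c(mats, list(round(M, 6)))
      }
    }
    new_packing_problem(positions = paste0("p", seq_len(n_pos)),
                        rotamer_aa = lapply(m, function(k) rep("X", k)),
                        one_body = one_body, pi = pi, pj = pj, mats = mats,
                        e_const = 0)
  })
}
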