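# The iterative multistate-design protocol: rounds of design -> redock the
# undesired complexes -> add their low-energy docked conformations to the
# negative-state ensembles -> design again.  The per-round mean difference
# between the binding energy seen by design and the binding energy after
# redocking is the protocol's accuracy metric; it shrinks as the negative
# ensembles grow.

#' Run configuration for the iterative protocol
#'
#' All figure-level knobs of the protocol surface here with logged defaults.
#' The synthetic heterodimer system plays the role of the input crystal
#' structure.
#'
#' @param system a [generate_synthetic_system()] result
#'   (`heterodimer_task`).
#' @param weights binding-energy-gap weights to scan (one GA run per weight
#'   x positive conformation).
#' @param variant heterodimer fitness variant (1 or 2, see
#'   [heterodimer_fitness()]).
#' @param w2 variant-2 bonus weight.
#' @param alphabet amino acids available at design positions.
#' @param population,elite,generations GA size (see [ga_params()]).
#' @param packer packer id used for state evaluation.
#' @param replicates packing replicates for positive and monomer states.
#' @param n_designs designs per GA run carried into redocking.
#' @param dock list of [dock_pert()] parameters
#'   (`n_traj`, `refine_cycles`, `trans_sd`, `rot_sd`, `kT`).
#' @param filter list of [filter_conformations()] parameters
#'   (`dG_keep`, `rms_min`).
#' @param rounds number of design/redock rounds.
#' @param seed global seed; the entire run is a pure function of this
#'   configuration.
#' @param use_entity_fn include the sequence-constraint (homodimer +
#'   mutation penalty) term.
#' @return a list of class `msd_config`.
#' @export
msd_config <- function(system, weights = 1:6, variant = 1, w2 = 1,
                       alphabet = DESIGN_ALPHABET, population = 24,
                       elite = 12, generations = 15, packer = "bmec_spr",
                       replicates = 1, n_designs = 2,
                       dock = list(n_traj = 5, refine_cycles = 10,
                                   trans_sd = 3, rot_sd = 8, kT = 0.8),
                       filter = list(dG_keep = -1, rms_min = 0.5),
                       rounds = 3, seed = 1, use_entity_fn = TRUE) {
  stopifnot(rounds >= 1, length(weights) >= 1)
  structure(list(system = system, weights = weights, variant = variant,
                 w2 = w2, alphabet = alphabet, population = population,
                 elite = elite, generations = generations, packer = packer,
                 replicates = replicates, n_designs = n_designs,
                 dock = dock, filter = filter, rounds = rounds, seed = seed,
                 use_entity_fn = use_entity_fn),
            class = "msd_config")
}

#' The heterodimerization task's sequence constraint
#'
#' Identity penalty over the (odd, even) entity position pairs -- 5 REU per
#' identical pair beyond the sixth -- plus a 1 REU penalty per mutation
#' beyond the fifth on either chain.
#'
#' @param entity_length total entity length (2 positions per designed
#'   residue pair).
#' @param wildtype_entity wildtype entity sequence.
#' @param id_free,id_step identity-penalty shape.
#' @param mut_free,mut_step mutation-penalty shape.
#' @return an [entity_function()].
#' @export
hetero_entity_function <- function(entity_length, wildtype_entity,
                                   id_free = 6, id_step = 5,
                                   mut_free = 5, mut_step = 1) {
  odd <- seq(1, entity_length, by = 2)
  even <- seq(2, entity_length, by = 2)
  wl <- entity_letters(wildtype_entity)
  entity_function(list(
    identity_penalty(cbind(odd, even), free = id_free, step = id_step),
    mutation_penalty(odd, wl[odd], free = mut_free, step = mut_step),
    mutation_penalty(even, wl[even], free = mut_free, step = mut_step)))
}

hetero_states <- function(config, positive_conf, ensembles) {
  sys <- config$system
  spec_for <- function(name, structure, reps = 1)
    state_spec(name, structure, sys$correspondences[[sub("_.*", "", name)]],
               sys$secondary[[sub("_.*", "", name)]], replicates = reps)
  list(
    EA = spec_for("A", sys$structures$A, config$replicates),
    EB = spec_for("B", sys$structures$B, config$replicates),
    EAB = spec_for("AB", positive_conf, config$replicates),
    EAA = lapply(seq_along(ensembles$AA), function(i)
      spec_for(paste0("AA_", i), ensembles$AA[[i]])),
    EBB = lapply(seq_along(ensembles$BB), function(i)
      spec_for(paste0("BB_", i), ensembles$BB[[i]])))
}

#' Run one round of iterative multistate design
#'
#' One GA trajectory per (weight, positive-state conformation) combination
#' against the current negative-state ensembles; each trajectory's top
#' designs are redocked (both homodimers and the heterodimer), and the
#' difference between the binding energy as computed by design (the ensemble
#' minimum) and after redocking is recorded per species.
#'
#' @param config an [msd_config()].
#' @param ensembles list of conformation lists for the negative species
#'   (`AA`, `BB`).
#' @param positive_confs list of conformations for the heterodimer.
#' @param round round index (enters seed mixing only).
#' @return list with `report` (one row per design x run) and `docked`
#'   (all homodimer `dock_result`s, for ensemble expansion).
#' @export
run_round <- function(config, ensembles, positive_confs, round = 1) {
  sys <- config$system
  stopifnot(length(ensembles$AA) >= 1, length(ensembles$BB) >= 1)
  ent <- if (config$use_entity_fn)
    hetero_entity_function(sys$entity_length, sys$wildtype_entity) else NULL
  rows <- list()
  docked <- list(AA = list(), BB = list())
  for (w in config$weights) {
    for (pc in seq_along(positive_confs)) {
      states <- hetero_states(config, positive_confs[[pc]], ensembles)
      program <- heterodimer_fitness(w, variant = config$variant,
                                     w2 = config$w2, entity_fn = ent,
                                     states = states)
      gp <- ga_params(config$alphabet, entity_length = sys$entity_length,
                      population = config$population, elite = config$elite,
                      generations = config$generations,
                      seed = stable_mix(config$seed, "ga", round, w, pc))
      res <- run_ga(program, gp, packer = config$packer,
                    global_seed = stable_mix(config$seed, "eval", w, pc),
                    init = sys$wildtype_entity)
      picks <- which(!duplicated(res$population$seq))[
        seq_len(min(config$n_designs, nrow(res$population)))]
      shared <- shared_positions(res$population$seq)
      for (d in picks) {
        seqd <- res$population$seq[d]
        en <- res$energies[[d]]
        dG_design <- c(
          AB = en$EAB - en$EA - en$EB,
          AA = min(en$vEAA) - 2 * en$EA,
          BB = min(en$vEBB) - 2 * en$EB)
        start_AA <- ensembles$AA[[which.min(en$vEAA)]]
        start_BB <- ensembles$BB[[which.min(en$vEBB)]]
        dk <- config$dock
        redock <- function(nm, struct) {
          sp <- state_spec(nm, struct, sys$correspondences[[sub("_.*", "", nm)]],
                           sys$secondary[[sub("_.*", "", nm)]])
          dock_pert(sp, seqd, n_traj = dk$n_traj,
                    seed = stable_mix(config$seed, "redock", round, w, pc,
                                      seqd, nm),
                    trans_sd = dk$trans_sd, rot_sd = dk$rot_sd,
                    refine_cycles = dk$refine_cycles, kT = dk$kT)
        }
        r_AA <- redock("AA", start_AA)
        r_BB <- redock("BB", start_BB)
        r_AB <- redock("AB", positive_confs[[pc]])
        docked$AA[[length(docked$AA) + 1]] <- r_AA
        docked$BB[[length(docked$BB) + 1]] <- r_BB
        flag <- length(shared) > 0 && any(dG_design[c("AA", "BB")] > 50)
        if (flag)
          warning("possible systematic packing failure: final population ",
                  "shares letters at position(s) ",
                  paste(shared, collapse = ","),
                  " with strongly positive designed binding energy")
        rows[[length(rows) + 1]] <- data.frame(
          round = round, weight = w, conf = pc, seq = seqd,
          fitness = res$population$fitness[d],
          dG_design_AB = dG_design[["AB"]],
          dG_design_AA = dG_design[["AA"]],
          dG_design_BB = dG_design[["BB"]],
          dG_redock_AB = r_AB$binding_energy,
          dG_redock_AA = r_AA$binding_energy,
          dG_redock_BB = r_BB$binding_energy,
          err_AA = dG_design[["AA"]] - r_AA$binding_energy,
          err_BB = dG_design[["BB"]] - r_BB$binding_energy,
          packing_failure_flag = flag,
          stringsAsFactors = FALSE)
      }
    }
  }
  list(report = do.call(rbind, rows), docked = docked)
}

# designed positions at which every sequence in the set carries one letter
shared_positions <- function(seqs) {
  mat <- do.call(rbind, strsplit(seqs, ""))
  which(apply(mat, 2, function(col) length(unique(col)) == 1))
}

#' Run the full iterative design/redock protocol
#'
#' Round 1 designs against the input conformations only; after every round
#' the redocked homodimer conformations passing the energy + diversity
#' filter are added to the negative-state ensembles for the next round.
#' Reports signed and absolute mean binding-energy errors per round, and
#' the (non-decreasing) ensemble sizes.
#'
#' @param config an [msd_config()].
#' @return an object of class `msd_report` with `designs` (per-design rows)
#'   and `rounds` (per-round summary).
#' @export
run_iterative <- function(config) {
  sys <- config$system
  ensembles <- list(AA = list(sys$structures$AA),
                    BB = list(sys$structures$BB))
  positive_confs <- list(sys$structures$AB)
  designs <- list()
  per_round <- list()
  for (r in seq_len(config$rounds)) {
    rr <- run_round(config, ensembles, positive_confs, round = r)
    errs <- c(rr$report$err_AA, rr$report$err_BB)
    for (sp in c("AA", "BB")) {
      added <- filter_conformations(rr$docked[[sp]],
                                    dG_keep = config$filter$dG_keep,
                                    rms_min = config$filter$rms_min,
                                    existing = ensembles[[sp]])
      if (length(added) == 0 && length(rr$docked[[sp]]) > 0)
        message("round ", r, ": no new ", sp,
                " conformations passed the filter; ensemble unchanged")
      ensembles[[sp]] <- c(ensembles[[sp]], added)
    }
    designs[[r]] <- rr$report
    per_round[[r]] <- data.frame(
      round = r, mean_error = mean(errs),
      mean_abs_error = mean(abs(errs)),
      n_designs = nrow(rr$report),
      ensemble_AA = length(ensembles$AA),
      ensemble_BB = length(ensembles$BB))
  }
  structure(list(designs = do.call(rbind, designs),
                 rounds = do.call(rbind, per_round),
                 ensembles = ensembles, config = config),
            class = "msd_report")
}

#' @export
print.msd_report <- function(x, ...) {
  cat("msd_report:", nrow(x$designs), "designs over",
      nrow(x$rounds), "round(s)\n")
  print(x$rounds, row.names = FALSE)
  invisible(x)
}

#' @export
plot.msd_report <- function(x, ...) {
  plot(x$rounds$round, x$rounds$mean_error, type = "b",
       xlab = "round", ylab = "mean binding-energy error (REU)", ...)
  invisible(x)
}

# ---------------------------------------------------------------------------

#' Benchmark the packer family against the consensus energy
#'
#' Generates random packing instances, runs the fifteen algorithm variants
#' (plus the exhaustive oracle when feasible), defines the consensus energy
#' per instance as the lowest energy found by any algorithm, and tabulates
#' each algorithm's frequency of reaching the consensus, of landing within
#' 1e-3 / 0.1 / 1 REU of it, of failing by more than 100 REU, and its mean
#' and relative running times.
#'
#' @param instances number of random instances.
#' @param seed numeric seed.
#' @param n_pos,max_rot instance size (kept exhaustively solvable).
#' @param packers packer ids to compare.
#' @param include_oracle also run [pack_exhaustive()] (the consensus then
#'   equals the true GMEC).
#' @return a data.frame of class `packer_benchmark` (one row per packer).
#' @export
benchmark_packers <- function(instances = 200, seed = 1, n_pos = 6,
                              max_rot = 6, packers = all_packer_ids(),
                              include_oracle = TRUE) {
  stopifnot(instances >= 1)
  ids <- packers
  if (include_oracle) ids <- c(ids, "exhaustive")
  energies <- matrix(NA_real_, instances, length(ids),
                     dimnames = list(NULL, ids))
  times <- numeric(length(ids)); names(times) <- ids
  for (i in seq_len(instances)) {
    prob <- random_packing_problem(n_pos, max_rot,
                                   seed = stable_mix(seed, "bench", i))
    for (id in ids) {
      t0 <- proc.time()[["elapsed"]]
      res <- get_packer(id)(prob, seed = stable_mix(seed, "run", id, i))
      times[id] <- times[id] + (proc.time()[["elapsed"]] - t0)
      energies[i, id] <- res$energy
    }
  }
  cons <- apply(energies, 1, min)
  pct <- function(id, tol) 100 * mean(energies[, id] - cons <= tol)
  out <- data.frame(
    algorithm = ids,
    pct_at_consensus = vapply(ids, pct, 1, tol = 1e-6),
    pct_within_1e3 = vapply(ids, pct, 1, tol = 1e-3),
    pct_within_0.1 = vapply(ids, pct, 1, tol = 0.1),
    pct_within_1 = vapply(ids, pct, 1, tol = 1),
    pct_fail_100 = vapply(ids, function(id)
      100 * mean(energies[, id] - cons > 100), 1),
    time_avg = times / instances,
    rel_perf = times / times[["bmec_spr"]],
    row.names = NULL)
  attr(out, "energies") <- energies
  class(out) <- c("packer_benchmark", class(out))
  out
}

#' Write a benchmark table as TSV
#'
#' @param x a [benchmark_packers()] table.
#' @param path output file.
#' @export
write_benchmark <- function(x, path) {
  write.table(format(as.data.frame(x), digits = 4), path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}
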