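# Rotamer-optimization algorithms.  All of them consume a `packing_problem`
# and return a `packer_result`; the heavy lifting lives in compiled code.
# Every packer is a pure function of (problem, seed).

`%||%` <- function(a, b) if (is.null(a)) b else a

default_moves <- function(problem) 5L * sum(problem$m)

#' Annealing schedule
#'
#' @param kT_high,kT_low temperature bounds (energy units).
#' @param n_temps number of outer iterations / temperatures.
#' @param moves_per_temp substitutions attempted per temperature; defaults to
#'   five times the total rotamer count of the problem being packed.
#' @param geometric geometric decay (the only supported trajectory shape).
#' @return a list of class `anneal_schedule`.
#' @export
anneal_schedule <- function(kT_high = 100, kT_low = 0.3, n_temps = 19,
                            moves_per_temp = NULL, geometric = TRUE) {
  stopifnot(kT_high > kT_low, kT_low > 0, n_temps >= 2,
            is.null(moves_per_temp) || moves_per_temp >= 1)
  structure(list(kT_high = kT_high, kT_low = kT_low, n_temps = n_temps,
                 moves_per_temp = moves_per_temp, geometric = geometric),
            class = "anneal_schedule")
}

packer_result <- function(problem, raw) {
  energy <- raw$energy
  check <- cpp_total_energy(problem, raw$choice)
  if (abs(check - energy) > 1e-6)
    stop("cached energy drifted from recomputation: ", energy, " vs ", check)
  tr <- cbind(move = raw$trace_move, best = raw$trace_best)
  structure(list(assignment = list(choice = raw$choice, energy = energy),
                 energy = energy,
                 moves_attempted = raw$moves %||% 0,
                 quench_restores = raw$quench_restores %||% 0,
                 best_trace = tr),
            class = "packer_result")
}

#' @export
print.packer_result <- function(x, ...) {
  cat("packer_result: energy", format(x$energy, digits = 8), "REU,",
      x$moves_attempted, "moves attempted\n")
  invisible(x)
}

#' Backbone-minimum-energy conformation
#'
#' Each position independently takes its minimum one-body rotamer (ties to
#' the lowest index); side-chain/side-chain terms are ignored.  Used to seed
#' the FASTER-style optimizer.
#'
#' @param problem a `packing_problem`.
#' @return integer vector of 1-based rotamer choices.
#' @export
bmec <- function(problem) cpp_bmec(problem)

#' Zero-temperature quench
#'
#' Repeated fixed-order sweeps over (position, rotamer) accepting only
#' strictly energy-lowering single substitutions, until a full sweep accepts
#' nothing.
#'
#' @param problem a `packing_problem`.
#' @param start integer vector of 1-based rotamer choices.
#' @return integer vector of 1-based rotamer choices with energy no higher
#'   than the start's.
#' @export
quench <- function(problem, start) cpp_quench(problem, as.integer(start))

#' BMEC + single-residue perturbation/relaxation (FASTER-style)
#'
#' Starts from the backbone-minimum-energy conformation, then sweeps:
#' each rotamer at each position is tentatively fixed, the (at most ten)
#' neighbors with greatest-magnitude interaction with the perturbed rotamer
#' are relaxed by repeated single-residue optimal substitutions, and the
#' perturbation is kept only if the net energy strictly decreases.
#'
#' @param problem a `packing_problem`.
#' @param max_sweeps sweep cap guaranteeing termination.
#' @param start optional starting assignment (defaults to [bmec()]).
#' @return a `packer_result`.
#' @export
pack_faster <- function(problem, max_sweeps = 30, start = NULL) {
  a0 <- if (is.null(start)) bmec(problem) else as.integer(start)
  packer_result(problem, cpp_spr(problem, a0, max_sweeps = max_sweeps))
}

#' Standard simulated annealer
#'
#' Geometric cooling from `kT_high` to `kT_low` across `n_temps` outer
#' iterations of Metropolis single-rotamer substitutions, with reheat to
#' `kT_high` whenever the end-of-iteration energy plateaus (is not at least
#' 1 REU below the mean of the previous three iteration-final energies).
#' After the outer loop the best assignment seen is restored and quenched.
#'
#' @param problem a `packing_problem`.
#' @param schedule an [anneal_schedule()].
#' @param seed numeric seed (the packer has its own RNG stream).
#' @return a `packer_result`.
#' @export
pack_standard_anneal <- function(problem, schedule = anneal_schedule(),
                                 seed = 0) {
  mv <- schedule$moves_per_temp %||% default_moves(problem)
  packer_result(problem, cpp_anneal_standard(
    problem, seed, as.integer(mv), n_outer = schedule$n_temps,
    kT_high = schedule$kT_high, kT_low = schedule$kT_low))
}

#' Multi-cool annealer
#'
#' Phase 1 cools geometrically from kT = 10 to 0.2 in 20 iterations with
#' three quench-and-restore operations per temperature (60 in total),
#' retaining the 10 lowest-energy distinct quenched assignments.  Phase 2
#' runs six cooling trajectories from kT = 0.25 to 0.05 over 10
#' temperatures, each closing every temperature with a quench-and-restore,
#' started from the six best saved assignments in energy order (reusing the
#' best available, with a warning, if fewer than six distinct assignments
#' were saved).  The best assignment encountered anywhere is returned.
#'
#' @param problem a `packing_problem`.
#' @param seed numeric seed.
#' @param moves_per_temp substitutions per fixed temperature; defaults to
#'   five times the total rotamer count.
#' @return a `packer_result`.
#' @export
pack_multicool <- function(problem, seed = 0, moves_per_temp = NULL) {
  mv <- moves_per_temp %||% default_moves(problem)
  raw <- cpp_anneal_multicool(problem, seed, as.integer(mv))
  if (!is.null(raw$n_saved) && raw$n_saved < 6 && length(problem$m) > 0 &&
      any(problem$m > 1))
    warning("fewer than 6 distinct quenched assignments saved; ",
            "phase-2 trajectories reuse the best available")
  packer_result(problem, raw)
}

#' Shortened-annealing + relaxation hybrids with restarts
#'
#' Each restart runs the standard annealer with `fraction` of the normal
#' substitutions per temperature, then iterates single-residue
#' perturbation/relaxation to convergence; the best result over all restarts
#' is returned.  Restart `r` seeds its own stream via `stable_mix(seed, r)`,
#' so `restarts = 8` extends (never reshuffles) the work of `restarts = 4`.
#'
#' @param problem a `packing_problem`.
#' @param fraction fraction in (0, 1] of the standard per-temperature
#'   substitution count.
#' @param restarts number of independent trajectories.
#' @param seed numeric seed.
#' @param schedule an [anneal_schedule()].
#' @return a `packer_result`.
#' @export
pack_hybrid <- function(problem, fraction = 0.05, restarts = 1, seed = 0,
                        schedule = anneal_schedule()) {
  stopifnot(fraction > 0, fraction <= 1, restarts >= 1)
  base_mv <- schedule$moves_per_temp %||% default_moves(problem)
  mv <- max(1L, as.integer(round(fraction * base_mv)))
  best <- NULL
  total_moves <- 0
  for (r in seq_len(restarts)) {
    raw_a <- cpp_anneal_standard(problem, stable_mix(seed, "hybrid", r),
                                 mv, n_outer = schedule$n_temps,
                                 kT_high = schedule$kT_high,
                                 kT_low = schedule$kT_low)
    raw_s <- cpp_spr(problem, raw_a$choice)
    total_moves <- total_moves + raw_a$moves + raw_s$moves
    if (is.null(best) || raw_s$energy < best$energy) best <- raw_s
  }
  best$moves <- total_moves
  packer_result(problem, best)
}

#' Exhaustive global-minimum oracle
#'
#' Enumerates every rotamer assignment (state space capped at 1e7) and
#' returns the global minimum energy conformation, ties broken
#' lexicographically by choice vector.  Serves as the correctness oracle for
#' all other packers.
#'
#' @param problem a `packing_problem`.
#' @return a `packer_result`.
#' @export
pack_exhaustive <- function(problem) {
  raw <- cpp_exhaustive(problem)
  raw$trace_move <- 0; raw$trace_best <- raw$energy
  raw$moves <- prod(problem$m)
  packer_result(problem, raw)
}

#' Empirical Metropolis acceptance probe
#'
#' Runs fixed-temperature substitutions with the same move kernel the
#' annealers use and reports how many uphill proposals were made and
#' accepted, for validating the acceptance rule against `exp(-dE/kT)`.
#'
#' @param problem a `packing_problem`.
#' @param start 1-based starting assignment.
#' @param kT fixed temperature.
#' @param n_moves substitutions to attempt.
#' @param seed numeric seed.
#' @return list with `uphill_proposed` and `uphill_accepted`.
#' @export
metropolis_probe <- function(problem, start, kT, n_moves, seed = 0) {
  cpp_metropolis_probe(problem, as.integer(start), kT, as.integer(n_moves),
                       seed)
}

# ---------------------------------------------------------------------------
# Packer registry: the fifteen benchmark variants plus the oracle.

#' Names of the benchmark packer variants
#'
#' The fifteen algorithm variants compared by [benchmark_packers()]:
#' the standard and multi-cool annealers, BMEC+sPR, shortened-annealing
#' hybrids at 100/50/20/10/5/2.5% of the standard substitution count, and
#' 2x/4x/8x restart versions of the 5% and 2.5% hybrids.
#'
#' @return character vector of packer ids usable with [get_packer()].
#' @export
all_packer_ids <- function() {
  c("standard", "multicool",
    "sima100_spr", "sima50_spr", "sima20_spr", "sima10_spr",
    "sima5_spr_x8", "sima5_spr_x4", "sima5_spr_x2", "sima5_spr",
    "sima2.5_spr_x8", "sima2.5_spr_x4", "sima2.5_spr_x2", "sima2.5_spr",
    "bmec_spr")
}

#' Look up a packer by id
#'
#' @param id one of [all_packer_ids()], or `"exhaustive"`.
#' @return a function `(problem, seed) -> packer_result`.
#' @export
get_packer <- function(id) {
  if (id == "bmec_spr") return(function(problem, seed = 0) pack_faster(problem))
  if (id == "standard")
    return(function(problem, seed = 0) pack_standard_anneal(problem, seed = seed))
  if (id == "multicool")
    return(function(problem, seed = 0) pack_multicool(problem, seed = seed))
  if (id == "exhaustive")
    return(function(problem, seed = 0) pack_exhaustive(problem))
  m <- regmatches(id, regexec("^sima([0-9.]+)_spr(_x([0-9]+))?$", id))[[1]]
  if (length(m) > 0 && nzchar(m[1])) {
    frac <- as.numeric(m[2]) / 100
    nx <- if (nzchar(m[4])) as.integer(m[4]) else 1L
    return(function(problem, seed = 0)
      pack_hybrid(problem, fraction = frac, restarts = nx, seed = seed))
  }
  stop("unknown packer id: ", id)
}
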