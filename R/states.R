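# State definition: a fixed-backbone structure, a correspondence map from
# entity-sequence positions to residues, a secondary repack set, and a
# replicate count.  Threading assigns the entity sequence to residues; state
# evaluation packs the threaded sequence and returns the best replicate
# energy under the order-independent seed contract.

#' Construct a correspondence map
#'
#' @param entries data.frame with columns `entity_position`, `chain`,
#'   `resnum`.  One entity position may map to several residues (homodimer
#'   states); each residue may be targeted at most once.
#' @param entity_length length of the entity sequence; defaults to the
#'   largest entity position referenced.
#' @return an object of class `correspondence_map`.
#' @export
new_correspondence <- function(entries, entity_length = NULL) {
  entries <- as.data.frame(entries)
  if (nrow(entries) > 0) {
    key <- paste(entries$chain, entries$resnum)
    if (anyDuplicated(key))
      stop("duplicate correspondence target(s): ",
           paste(unique(key[duplicated(key)]), collapse = ", "))
    if (any(entries$entity_position < 1))
      stop("entity positions must be >= 1")
  }
  if (is.null(entity_length))
    entity_length <- if (nrow(entries) > 0) max(entries$entity_position) else 0L
  if (nrow(entries) > 0 && any(entries$entity_position > entity_length))
    stop("entity position beyond declared entity length")
  structure(list(entries = entries,
                 entity_length = as.integer(entity_length)),
            class = "correspondence_map")
}

#' Parse a correspondence file
#'
#' Whitespace-separated lines `entity_pos resnum chain`, `#` comments; an
#' optional `ENTITY_LENGTH n` line declares the entity length (otherwise the
#' maximum entity position is used).  Example: the line `3 24 A` states that
#' residue 24 on chain A takes its identity from position 3 of the sequence
#' the genetic algorithm optimizes.
#'
#' @param text character vector of lines, or a single string with newlines.
#' @return a `correspondence_map`.
#' @export
parse_correspondence <- function(text) {
  lines <- unlist(strsplit(text, "\n", fixed = TRUE))
  lines <- trimws(sub("#.*$", "", lines))
  keep <- nzchar(lines)
  entity_length <- NULL
  rows <- list()
  for (ln in which(keep)) {
    f <- strsplit(lines[ln], "[[:space:]]+")[[1]]
    if (toupper(f[1]) == "ENTITY_LENGTH") {
      entity_length <- as.integer(f[2])
      next
    }
    if (length(f) != 3)
      stop("line ", ln, ": expected 'entity_pos resnum chain'")
    ep <- suppressWarnings(as.integer(f[1]))
    rn <- suppressWarnings(as.integer(f[2]))
    if (is.na(ep) || is.na(rn))
      stop("line ", ln, ": non-integer entity position or residue number")
    rows[[length(rows) + 1]] <- data.frame(entity_position = ep,
                                           chain = f[3], resnum = rn,
                                           stringsAsFactors = FALSE)
  }
  entries <- if (length(rows) > 0) do.call(rbind, rows)
  else data.frame(entity_position = integer(0), chain = character(0),
                  resnum = integer(0))
  new_correspondence(entries, entity_length)
}

#' Parse a secondary resfile
#'
#' Lines `chain resnum` naming residues that are repacked at their wildtype
#' identity but never designed (boundary residues).  `#` comments allowed.
#'
#' @param text character vector of lines or a single string.
#' @return data.frame with columns `chain`, `resnum`.
#' @export
parse_secondary <- function(text) {
  lines <- unlist(strsplit(text, "\n", fixed = TRUE))
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0)
    return(data.frame(chain = character(0), resnum = integer(0)))
  f <- do.call(rbind, strsplit(lines, "[[:space:]]+"))
  if (ncol(f) != 2) stop("expected 'chain resnum' lines")
  data.frame(chain = f[, 1], resnum = as.integer(f[, 2]),
             stringsAsFactors = FALSE)
}

#' Write correspondence / secondary-resfile text
#'
#' Inverse of [parse_correspondence()] and [parse_secondary()].
#'
#' @param x a `correspondence_map` or a secondary data.frame.
#' @param path output file.
#' @export
write_correspondence <- function(x, path) {
  e <- x$entries
  writeLines(c(paste("ENTITY_LENGTH", x$entity_length),
               sprintf("%d %d %s", e$entity_position, e$resnum, e$chain)),
             path)
  invisible(path)
}

#' @rdname write_correspondence
#' @export
write_secondary <- function(x, path) {
  writeLines(sprintf("%s %d", x$chain, x$resnum), path)
  invisible(path)
}

#' Define a state
#'
#' @param name state name (used in fitness programs and for seed mixing).
#' @param structure a [toy_structure()] or a path to a toy-structure or PDB
#'   file.
#' @param correspondence a `correspondence_map` (or text parsed by
#'   [parse_correspondence()]).
#' @param secondary data.frame `chain`/`resnum` (or text parsed by
#'   [parse_secondary()]); may be empty.
#' @param replicates number of independent packing replicates per
#'   evaluation; the best (lowest) energy is kept.
#' @return an object of class `state_spec`.
#' @export
state_spec <- function(name, structure, correspondence,
                       secondary = NULL, replicates = 1) {
  if (is.character(structure) && length(structure) == 1) {
    structure <- if (grepl("\\.pdb$", structure, ignore.case = TRUE))
      read_pdb_subset(structure) else read_toy_structure(structure)
  }
  if (is.character(correspondence))
    correspondence <- parse_correspondence(correspondence)
  if (is.null(secondary))
    secondary <- data.frame(chain = character(0), resnum = integer(0))
  if (is.character(secondary)) secondary <- parse_secondary(secondary)
  stopifnot(replicates >= 1)
  structure(list(name = name, structure = structure,
                 correspondence = correspondence, secondary = secondary,
                 replicates = as.integer(replicates)),
            class = "state_spec")
}

#' @export
print.state_spec <- function(x, ...) {
  cat("state_spec '", x$name, "': ", nrow(x$correspondence$entries),
      " designed residue(s), ", nrow(x$secondary), " repack-only, ",
      x$replicates, " replicate(s)\n", sep = "")
  invisible(x)
}

entity_letters <- function(seq) {
  if (length(seq) == 1 && nchar(seq) > 1)
    seq <- strsplit(seq, "")[[1]]
  toupper(seq)
}

#' Thread an entity sequence onto a state
#'
#' Every correspondence target receives the amino acid at its entity
#' position; the mutation list records targets whose assigned amino acid
#' differs from the structure's wildtype, in `F21H` notation.
#'
#' @param spec a [state_spec()].
#' @param seq entity sequence (string or character vector).
#' @param structure optional override of the spec's structure.
#' @return list with `assignments` (chain, resnum, aa) and `mutations`
#'   (chain, resnum, from, to, label).
#' @export
thread_sequence <- function(spec, seq, structure = NULL) {
  s <- structure %||% spec$structure
  letters_ <- entity_letters(seq)
  ce <- spec$correspondence$entries
  if (spec$correspondence$entity_length > 0 &&
      length(letters_) != spec$correspondence$entity_length)
    stop("sequence length ", length(letters_),
         " does not match entity length ", spec$correspondence$entity_length)
  idx <- residue_index(s, ce$chain, ce$resnum)
  aa <- letters_[ce$entity_position]
  wt <- s$residues$aa[idx]
  mut <- aa != wt
  list(assignments = data.frame(chain = ce$chain, resnum = ce$resnum,
                                aa = aa, stringsAsFactors = FALSE),
       mutations = data.frame(chain = ce$chain[mut], resnum = ce$resnum[mut],
                              from = wt[mut], to = aa[mut],
                              label = paste0(wt[mut], ce$resnum[mut], aa[mut]),
                              stringsAsFactors = FALSE))
}

#' Prepare a state for repeated evaluation
#'
#' Builds the state's rotamer universe (all allowed amino acids at every
#' designed residue, wildtype at repack-only residues) and its interaction
#' graph once, so the genetic algorithm can evaluate many sequences cheaply.
#'
#' @param spec a [state_spec()].
#' @param allowed_aas character vector of amino acids available to design
#'   positions, or a list of such vectors indexed by entity position.
#' @param params a [toy_energy_params()].
#' @param memory_ceiling interaction-graph ceiling in bytes (`Inf` =
#'   unlimited).
#' @return an object of class `state_context`.
#' @export
state_context <- function(spec, allowed_aas = AA1,
                          params = toy_energy_params(),
                          memory_ceiling = Inf) {
  u <- build_universe(spec$structure, spec$correspondence, spec$secondary,
                      allowed_aas, params)
  ctx <- list(spec = spec, universe = u,
              graph = interaction_graph(u, memory_ceiling), params = params)
  class(ctx) <- "state_context"
  ctx
}

#' Evaluate one sequence on one state
#'
#' Builds the packing problem for the threaded sequence and packs it
#' `replicates` times, each replicate seeded by
#' `stable_mix(global_seed, state name, sequence, replicate)`, keeping the
#' minimum energy.  The seed contract makes the result independent of the
#' order in which states, sequences or replicates are evaluated.
#'
#' @param spec a [state_spec()] (ignored when `context` is given, except for
#'   `replicates`).
#' @param seq entity sequence.
#' @param packer packer id (see [all_packer_ids()]) or a function
#'   `(problem, seed) -> packer_result`.
#' @param global_seed numeric seed for the whole run.
#' @param context optional prebuilt [state_context()].
#' @param allowed_aas used only when `context` is `NULL`.
#' @param params a [toy_energy_params()].
#' @return list with `energy`, `assignment`, `problem`.
#' @export
evaluate_state <- function(spec, seq, packer = "bmec_spr", global_seed = 0,
                           context = NULL, allowed_aas = AA1,
                           params = toy_energy_params()) {
  if (is.null(context)) context <- state_context(spec, allowed_aas, params)
  spec <- context$spec
  if (nrow(context$universe$positions) == 0) {
    warning("state '", spec$name, "' has no packable positions; ",
            "returning fixed background energy")
    return(list(energy = context$universe$e_const, assignment = integer(0),
                problem = NULL))
  }
  problem <- build_packing_problem(context, seq)
  pk <- if (is.function(packer)) packer else get_packer(packer)
  seq_txt <- paste(entity_letters(seq), collapse = "")
  best <- NULL
  for (rep_i in seq_len(spec$replicates)) {
    res <- pk(problem, stable_mix(global_seed, spec$name, seq_txt, rep_i))
    if (is.null(best) || res$energy < best$energy) best <- res
  }
  list(energy = best$energy, assignment = best$assignment$choice,
       problem = problem)
}
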