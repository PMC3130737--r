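# Packing problems and the lazily computed, memory-capped interaction graph.
#
# A packing problem is the object every optimizer consumes: an ordered set of
# positions, per-position rotamer lists, one-body energies (side chain vs all
# backbone spheres, plus any folded-in background), and pair-energy matrices
# for neighboring positions.  Pair submatrices at (position, amino acid) x
# (position, amino acid) granularity are computed on first use and cached in
# an interaction graph whose memory use can be capped; eviction follows a
# least-recently-accessed policy and is semantically invisible because every
# submatrix is a pure function of geometry.

#' Construct a packing problem
#'
#' Low-level constructor; most users obtain problems from
#' [build_packing_problem()] or [random_packing_problem()].
#'
#' @param positions character vector of position labels.
#' @param rotamer_aa list of per-rotamer amino-acid labels per position.
#' @param one_body list of numeric one-body energy vectors per position.
#' @param pi,pj 1-based endpoints of neighbor pairs (`pi < pj`).
#' @param mats list of pair-energy matrices, `mats[[k]]` of dimension
#'   `length(one_body[[pi[k]]]) x length(one_body[[pj[k]]])`.
#' @param e_const constant background energy folded into every total.
#' @return an object of class `packing_problem`.
#' @export
new_packing_problem <- function(positions, rotamer_aa, one_body, pi, pj,
                                mats, e_const = 0) {
  m <- lengths(one_body)
  if (any(m < 1)) stop("every position needs at least one rotamer")
  stopifnot(length(pi) == length(pj), length(mats) == length(pi))
  for (k in seq_along(mats)) {
    if (pi[k] >= pj[k]) stop("neighbor pairs must satisfy pi < pj")
    if (!all(dim(mats[[k]]) == c(m[pi[k]], m[pj[k]])))
      stop("pair matrix ", k, " has wrong dimensions")
  }
  structure(list(positions = positions, rotamer_aa = rotamer_aa,
                 m = as.integer(m), one_body = one_body,
                 pi = as.integer(pi), pj = as.integer(pj), mats = mats,
                 e_const = as.numeric(e_const)),
            class = "packing_problem")
}

#' @export
print.packing_problem <- function(x, ...) {
  cat("packing_problem:", length(x$m), "positions,",
      sum(x$m), "rotamers,", length(x$pi), "neighbor pairs\n")
  invisible(x)
}

#' Total energy of a rotamer assignment
#'
#' Background constant + chosen one-body energies + each neighboring pair
#' energy counted once.
#'
#' @param problem a `packing_problem`.
#' @param assignment integer vector of 1-based rotamer choices (or a list
#'   with a `choice` element, as returned by the packers).
#' @return energy in REU.
#' @export
total_energy <- function(problem, assignment) {
  if (is.list(assignment)) assignment <- assignment$choice
  assignment <- as.integer(assignment)
  if (length(assignment) != length(problem$m) ||
      any(assignment < 1L | assignment > problem$m))
    stop("invalid rotamer assignment")
  cpp_total_energy(problem, assignment)
}

#' Debug dump of a packing problem
#'
#' Writes a plain-text table (position, rotamer count, min/max one-body) for
#' golden-file tests and inspection.
#'
#' @param problem a `packing_problem`.
#' @param path optional file; when `NULL` the table is returned.
#' @export
dump_packing_problem <- function(problem, path = NULL) {
  tab <- data.frame(position = problem$positions, n_rot = problem$m,
                    ob_min = vapply(problem$one_body, min, 1),
                    ob_max = vapply(problem$one_body, max, 1))
  if (is.null(path)) return(tab)
  write.table(format(tab, digits = 10), path, quote = FALSE,
              row.names = FALSE, sep = "\t")
  invisible(path)
}

# ---------------------------------------------------------------------------
# Rotamer universe: the fixed rotamer sets for all allowed amino acids at
# each packable residue of one state, built once at start of execution.

# positions table rows: pos_id, chain, resnum, kind, entity, wildtype
build_universe <- function(structure, correspondence, secondary,
                           allowed_aas, params = toy_energy_params()) {
  res <- structure$residues
  ce <- correspondence$entries
  pos <- list()
  if (nrow(ce) > 0) {
    i <- residue_index(structure, ce$chain, ce$resnum)
    pos[[1]] <- data.frame(chain = ce$chain, resnum = ce$resnum,
                           kind = "design", entity = ce$entity_position,
                           index = i, stringsAsFactors = FALSE)
  }
  if (!is.null(secondary) && nrow(secondary) > 0) {
    overlap <- intersect(paste(secondary$chain, secondary$resnum),
                         paste(ce$chain, ce$resnum))
    if (length(overlap) > 0)
      stop("secondary repack residues overlap correspondence targets: ",
           paste(overlap, collapse = ", "))
    i <- residue_index(structure, secondary$chain, secondary$resnum)
    pos[[length(pos) + 1]] <- data.frame(chain = secondary$chain,
                                         resnum = secondary$resnum,
                                         kind = "repack", entity = NA_integer_,
                                         index = i, stringsAsFactors = FALSE)
  }
  pos <- do.call(rbind, pos)
  if (is.null(pos) || nrow(pos) == 0) {
    return(list(structure = structure,
                positions = data.frame(chain = character(0),
                                       resnum = integer(0),
                                       kind = character(0),
                                       entity = integer(0),
                                       index = integer(0),
                                       pos_id = character(0),
                                       wildtype = character(0)),
                aa_sets = list(), rotsets = list(),
                cand_i = integer(0), cand_j = integer(0),
                e_const = backbone_background_energy(structure, params),
                params = params))
  }
  pos$pos_id <- paste0(pos$chain, ":", pos$resnum)
  pos$wildtype <- res$aa[pos$index]
  # per-position allowed amino acids
  aa_sets <- lapply(seq_len(nrow(pos)), function(r) {
    if (pos$kind[r] == "repack") pos$wildtype[r]
    else if (is.list(allowed_aas)) allowed_aas[[pos$entity[r]]]
    else allowed_aas
  })
  rotsets <- lapply(seq_len(nrow(pos)), function(r) {
    sets <- lapply(aa_sets[[r]], function(aa) {
      rots <- build_rotamers(structure, pos$index[r], aa,
                             multistate_mode = TRUE, params = params)
      list(aa = aa,
           centers = as.matrix(rots[, c("cx", "cy", "cz")]),
           radius = rots$radius, hydro = rots$hydrophobicity,
           one_body = rotamer_backbone_energy(rots, structure, pos$index[r],
                                              params))
    })
    names(sets) <- aa_sets[[r]]
    sets
  })
  # candidate neighbor pairs: anchors close enough that bead centers could
  # come within the cutoff given each side's maximum center offset
  xyz <- anchors(structure)[pos$index, , drop = FALSE]
  max_off <- vapply(aa_sets, function(aas)
    max(ifelse(AA_HEAVY[aas] == 0, 0, aa_offset(aas, params))), 1)
  np <- nrow(pos)
  cand_i <- integer(0); cand_j <- integer(0)
  if (np > 1) {
    for (i in seq_len(np - 1)) for (j in seq(i + 1, np)) {
      dij <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
      if (dij <= params$pair_cutoff + max_off[i] + max_off[j]) {
        cand_i <- c(cand_i, i); cand_j <- c(cand_j, j)
      }
    }
  }
  list(structure = structure, positions = pos, aa_sets = aa_sets,
       rotsets = rotsets, cand_i = cand_i, cand_j = cand_j,
       e_const = backbone_background_energy(structure, params),
       params = params)
}

#' Interaction graph: cached pair-energy submatrices with a memory ceiling
#'
#' Submatrices of rotamer-pair energies at amino-acid-pair granularity are
#' computed on first access and stored for reuse.  When a memory ceiling is
#' set (bytes; 8 bytes per stored entry), storing a new submatrix evicts the
#' submatrix whose most recent access lies furthest in the past until the
#' total is back under the ceiling.  Evicted submatrices are transparently
#' recomputed on the next access, so results never depend on the ceiling.
#'
#' @param universe a rotamer universe, from the internal state machinery
#'   (see [state_context()]).
#' @param memory_ceiling bytes, or `Inf` for unlimited.
#' @return an environment of class `interaction_graph`.
#' @export
interaction_graph <- function(universe, memory_ceiling = Inf) {
  g <- new.env(parent = emptyenv())
  g$universe <- universe
  g$cache <- new.env(parent = emptyenv())
  g$last <- numeric(0)         # key -> most recent access counter
  g$counter <- 0
  g$computed <- 0              # submatrix computations (incl. recomputes)
  g$distinct <- character(0)   # distinct keys ever computed
  g$requests <- 0
  g$bytes <- 0
  g$ceiling <- memory_ceiling
  g$evictions <- 0
  class(g) <- "interaction_graph"
  g
}

compute_submatrix <- function(universe, i, aa_i, j, aa_j) {
  ri <- universe$rotsets[[i]][[aa_i]]
  rj <- universe$rotsets[[j]][[aa_j]]
  if (is.null(ri) || is.null(rj))
    stop("amino acid not in universe at position ", i, " or ", j)
  pair_energy_block(ri$centers, ri$radius, ri$hydro,
                    rj$centers, rj$radius, rj$hydro, universe$params)
}

#' Fetch one pair-energy submatrix through the interaction graph
#'
#' @param graph an [interaction_graph()].
#' @param i,j position indices into the universe's position table.
#' @param aa_i,aa_j one-letter amino-acid codes.
#' @return the `n_i x n_j` pair-energy matrix for (position i, `aa_i`) vs
#'   (position j, `aa_j`).
#' @export
pair_submatrix <- function(graph, i, aa_i, j, aa_j) {
  if (i > j) return(t(pair_submatrix(graph, j, aa_j, i, aa_i)))
  key <- paste(i, aa_i, j, aa_j, sep = "|")
  graph$requests <- graph$requests + 1
  graph$counter <- graph$counter + 1
  M <- get0(key, envir = graph$cache)
  if (is.null(M)) {
    M <- compute_submatrix(graph$universe, i, aa_i, j, aa_j)
    graph$computed <- graph$computed + 1
    graph$distinct <- union(graph$distinct, key)
    assign(key, M, envir = graph$cache)
    graph$bytes <- graph$bytes + 8 * length(M)
    graph$last[key] <- graph$counter
    while (graph$bytes > graph$ceiling && length(graph$last) > 0) {
      victim <- names(graph$last)[which.min(graph$last)]
      vm <- get(victim, envir = graph$cache)
      graph$bytes <- graph$bytes - 8 * length(vm)
      rm(list = victim, envir = graph$cache)
      graph$last <- graph$last[names(graph$last) != victim]
      graph$evictions <- graph$evictions + 1
    }
  } else {
    graph$last[key] <- graph$counter
  }
  M
}

#' Interaction-graph statistics
#'
#' Reports cache behavior, including the fraction of the full up-front
#' pair-energy computation that lazy evaluation avoided (distinct submatrices
#' computed vs all amino-acid-pair submatrices of all candidate neighbor
#' pairs).
#'
#' @param graph an [interaction_graph()].
#' @return a list with `requests`, `computed`, `distinct`, `evictions`,
#'   `bytes`, `full_count` and `savings_fraction`.
#' @export
graph_stats <- function(graph) {
  u <- graph$universe
  full <- 0
  for (k in seq_along(u$cand_i)) {
    full <- full + length(u$aa_sets[[u$cand_i[k]]]) *
      length(u$aa_sets[[u$cand_j[k]]])
  }
  list(requests = graph$requests, computed = graph$computed,
       distinct = length(graph$distinct), evictions = graph$evictions,
       bytes = graph$bytes, full_count = full,
       savings_fraction = if (full > 0) 1 - length(graph$distinct) / full
       else NA_real_)
}

# ---------------------------------------------------------------------------

#' Build the packing problem for one sequence on one state
#'
#' Correspondence-mapped positions carry rotamers only of the amino acid the
#' entity sequence assigns them; secondary-repack positions carry rotamers of
#' their wildtype amino acid; every other residue contributes only its fixed
#' backbone sphere, folded into the one-body energies and the background
#' constant.
#'
#' @param context a [state_context()].
#' @param seq entity sequence (single string or character vector of length
#'   equal to the state's entity length).
#' @param graph optional [interaction_graph()] used to fetch pair
#'   submatrices (defaults to the context's own graph).
#' @return a `packing_problem`.
#' @export
build_packing_problem <- function(context, seq, graph = NULL) {
  u <- context$universe
  if (is.null(graph)) graph <- context$graph
  letters_ <- entity_letters(seq)
  pos <- u$positions
  aa <- character(nrow(pos))
  for (r in seq_len(nrow(pos))) {
    aa[r] <- if (pos$kind[r] == "design") {
      if (pos$entity[r] > length(letters_))
        stop("sequence shorter than entity length")
      letters_[pos$entity[r]]
    } else pos$wildtype[r]
    if (is.null(u$rotsets[[r]][[aa[r]]]))
      stop("no rotamers for amino acid ", aa[r], " at ", pos$pos_id[r])
  }
  one_body <- lapply(seq_len(nrow(pos)), function(r)
    u$rotsets[[r]][[aa[r]]]$one_body)
  rotamer_aa <- lapply(seq_len(nrow(pos)), function(r)
    rep(aa[r], length(one_body[[r]])))
  mats <- vector("list", length(u$cand_i))
  keep <- logical(length(u$cand_i))
  for (k in seq_along(u$cand_i)) {
    i <- u$cand_i[k]; j <- u$cand_j[k]
    M <- pair_submatrix(graph, i, aa[i], j, aa[j])
    if (any(M != 0)) { mats[[k]] <- M; keep[k] <- TRUE }
  }
  new_packing_problem(positions = pos$pos_id, rotamer_aa = rotamer_aa,
                      one_body = one_body,
                      pi = u$cand_i[keep], pj = u$cand_j[keep],
                      mats = mats[keep], e_const = u$e_const)
}
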