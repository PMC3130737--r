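# Outer-loop sequence search: an elitist genetic algorithm with point-mutant
# and uniform-crossover proposals and a by-sequence fitness cache.  All
# proposal randomness flows through one R RNG stream seeded at start; packer
# seeds are derived from (state, sequence, replicate) identity, so caching
# and evaluation order cannot change results.

#' Genetic-algorithm parameters
#'
#' @param allowed_aas list (one character vector of allowed amino acids per
#'   entity position) or a single vector applied at every position (then
#'   `entity_length` is required).
#' @param entity_length sequence length L when `allowed_aas` is a vector.
#' @param population population size.
#' @param elite number of best sequences propagated unchanged.
#' @param p_point probability that a new sequence is a single-position point
#'   mutant of an elite parent (`p_point + p_cross = 1`).
#' @param p_cross probability of a uniform crossover of two distinct members
#'   of the previous population.
#' @param generations number of generations; defaults to `15 * L`.
#' @param seed integer seed.
#' @return a list of class `ga_params`.
#' @export
ga_params <- function(allowed_aas, entity_length = NULL, population = 100,
                      elite = 50, p_point = 0.98, p_cross = 0.02,
                      generations = NULL, seed = 1) {
  if (!is.list(allowed_aas)) {
    if (is.null(entity_length))
      stop("entity_length required when allowed_aas is a single vector")
    allowed_aas <- rep(list(allowed_aas), entity_length)
  }
  L <- length(allowed_aas)
  generations <- generations %||% (15L * L)
  stopifnot(elite < population, generations >= 1,
            abs(p_point + p_cross - 1) < 1e-12)
  structure(list(allowed_aas = allowed_aas, L = L, population = population,
                 elite = as.integer(elite), p_point = p_point,
                 p_cross = p_cross, generations = as.integer(generations),
                 seed = seed),
            class = "ga_params")
}

random_sequence <- function(params) {
  paste(vapply(params$allowed_aas, function(aas)
    aas[sample.int(length(aas), 1)], character(1)), collapse = "")
}

point_mutant <- function(seq, params) {
  letters_ <- strsplit(seq, "")[[1]]
  for (try in 1:100) {
    p <- sample.int(params$L, 1)
    choices <- setdiff(params$allowed_aas[[p]], letters_[p])
    if (length(choices) > 0) {
      letters_[p] <- choices[sample.int(length(choices), 1)]
      return(paste(letters_, collapse = ""))
    }
  }
  stop("no mutable position found (all selected positions single-letter)")
}

uniform_crossover <- function(seq1, seq2) {
  a <- strsplit(seq1, "")[[1]]; b <- strsplit(seq2, "")[[1]]
  pick <- runif(length(a)) < 0.5
  paste(ifelse(pick, a, b), collapse = "")
}

#' Propose the next generation
#'
#' Elite sequences are carried unchanged; each of the remaining slots is
#' filled, with probability `p_point`, by a single-position mutant of a
#' uniformly chosen elite parent, otherwise by a per-position 50/50
#' crossover of two distinct uniformly chosen members of the whole previous
#' population.  Consumes the current R RNG stream.
#'
#' @param population data.frame with columns `seq` and `fitness` (size
#'   `params$population`, fitnesses computed).
#' @param params a [ga_params()].
#' @return character vector of `params$population` sequences (elite first).
#' @export
next_generation <- function(population, params) {
  stopifnot(nrow(population) == params$population,
            !anyNA(population$fitness))
  ord <- order(population$fitness)
  elite <- population$seq[ord[seq_len(params$elite)]]
  n_new <- params$population - params$elite
  children <- character(n_new)
  for (i in seq_len(n_new)) {
    if (runif(1) < params$p_point) {
      parent <- elite[sample.int(length(elite), 1)]
      children[i] <- point_mutant(parent, params)
    } else {
      idx <- sample.int(nrow(population), 2)
      children[i] <- uniform_crossover(population$seq[idx[1]],
                                       population$seq[idx[2]])
    }
  }
  c(elite, children)
}

#' Run the genetic algorithm
#'
#' For every new sequence, each state variable of the fitness program is
#' bound to the packed energy of that sequence on its state (the vector
#' minimum is available to STATE_VECTOR ensembles via `vmin`), and the
#' program yields the scalar fitness.  Fitnesses are cached by sequence
#' text; by the seed contract the cache is semantics-preserving.
#'
#' @param program a `fitness_program` whose states are bound to
#'   [state_spec()]s, or `NULL` when `fitness_fn` is given.
#' @param params a [ga_params()].
#' @param packer packer id or function (see [evaluate_state()]).
#' @param global_seed seed for the whole run (defaults to `params$seed`).
#' @param fitness_fn optional plain function `seq -> fitness` replacing the
#'   program (used for algorithm studies on analytic landscapes).
#' @param init optional character vector of starting sequences (e.g. the
#'   wildtype entity sequence); the remainder of the initial population is
#'   drawn uniformly from the allowed alphabet.
#' @param contexts optional prebuilt list of [state_context()]s (named as
#'   the program's state variables; lists of contexts for vectors).
#' @param cache use the by-sequence fitness cache.
#' @param verbose print per-generation progress lines.
#' @return an object of class `ga_result`: `history` (per-generation best /
#'   mean fitness and best sequence), `population` (final, ranked),
#'   `energies` (per-state energies of the final population), cache
#'   statistics and the winning sequence.
#' @export
run_ga <- function(program, params, packer = "bmec_spr", global_seed = NULL,
                   fitness_fn = NULL, init = NULL, contexts = NULL,
                   cache = TRUE, verbose = FALSE) {
  global_seed <- global_seed %||% params$seed
  if (is.null(fitness_fn) && is.null(program))
    stop("either a fitness program or fitness_fn is required")
  if (!is.null(program) && is.null(contexts) && is.null(fitness_fn))
    contexts <- build_contexts(program, params)
  cache_env <- new.env(parent = emptyenv())
  hits <- 0; misses <- 0
  eval_seq <- function(seq) {
    if (cache) {
      got <- get0(seq, envir = cache_env)
      if (!is.null(got)) { hits <<- hits + 1; return(got) }
    }
    misses <<- misses + 1
    out <- if (!is.null(fitness_fn)) {
      list(fitness = fitness_fn(seq), energies = NULL)
    } else {
      energies <- state_energies(program, contexts, seq, packer, global_seed)
      list(fitness = evaluate_fitness(program, energies, seq),
           energies = energies)
    }
    if (cache) assign(seq, out, envir = cache_env)
    out
  }
  with_seed(stable_mix(global_seed, "ga-proposals"), {
    pop <- unique(c(init, character(0)))
    pop <- c(pop, vapply(seq_len(params$population - length(pop)),
                         function(i) random_sequence(params), character(1)))
    history <- data.frame(generation = integer(0), best_fitness = numeric(0),
                          mean_fitness = numeric(0),
                          best_seq = character(0))
    fit <- vapply(pop, function(s) eval_seq(s)$fitness, 1, USE.NAMES = FALSE)
    for (g in seq_len(params$generations)) {
      df <- data.frame(seq = pop, fitness = fit, stringsAsFactors = FALSE)
      pop <- next_generation(df, params)
      fit <- vapply(pop, function(s) eval_seq(s)$fitness, 1,
                    USE.NAMES = FALSE)
      b <- which.min(fit)
      history <- rbind(history, data.frame(
        generation = g, best_fitness = fit[b], mean_fitness = mean(fit),
        best_seq = pop[b], stringsAsFactors = FALSE))
      if (verbose)
        cat(sprintf("gen %3d  best %10.4f  mean %10.4f  %s\n",
                    g, fit[b], mean(fit), pop[b]))
    }
    ord <- order(fit)
    final <- data.frame(seq = pop[ord], fitness = fit[ord],
                        stringsAsFactors = FALSE)
    energies <- if (is.null(fitness_fn))
      lapply(final$seq, function(s) eval_seq(s)$energies) else NULL
    structure(list(history = history, population = final,
                   energies = energies, best_seq = final$seq[1],
                   best_fitness = final$fitness[1],
                   cache = list(hits = hits, misses = misses),
                   params = params),
              class = "ga_result")
  })
}

build_contexts <- function(program, params, memory_ceiling = Inf) {
  out <- list()
  for (nm in names(program$state_vars)) {
    sv <- program$state_vars[[nm]]
    if (sv$kind == "state") {
      if (is.null(sv$spec)) stop("state '", nm, "' is abstract (no spec)")
      out[[nm]] <- state_context(sv$spec, params$allowed_aas,
                                 memory_ceiling = memory_ceiling)
    } else {
      out[[nm]] <- lapply(sv$specs, state_context,
                          allowed_aas = params$allowed_aas,
                          memory_ceiling = memory_ceiling)
    }
  }
  out
}

state_energies <- function(program, contexts, seq, packer, global_seed) {
  energies <- list()
  for (nm in names(program$state_vars)) {
    sv <- program$state_vars[[nm]]
    energies[[nm]] <- if (sv$kind == "state") {
      evaluate_state(sv$spec, seq, packer, global_seed,
                     context = contexts[[nm]])$energy
    } else {
      vapply(contexts[[nm]], function(ctx)
        evaluate_state(ctx$spec, seq, packer, global_seed,
                       context = ctx)$energy, 1)
    }
  }
  energies
}

#' @export
print.ga_result <- function(x, ...) {
  cat("ga_result:", nrow(x$history), "generations, best fitness",
      format(x$best_fitness, digits = 8), "\n")
  cat("best sequence:", x$best_seq, "\n")
  cat("fitness cache:", x$cache$hits, "hits /", x$cache$misses, "misses\n")
  invisible(x)
}

#' @export
plot.ga_result <- function(x, ...) {
  plot(x$history$generation, x$history$best_fitness, type = "l",
       xlab = "generation", ylab = "fitness",
       ylim = range(c(x$history$best_fitness, x$history$mean_fitness)), ...)
  graphics::lines(x$history$generation, x$history$mean_fitness, lty = 2)
  graphics::legend("topright", c("best", "mean"), lty = c(1, 2), bty = "n")
  invisible(x)
}

#' Write ranked designs, FASTA and a per-position profile
#'
#' @param x a `ga_result`.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_ga_outputs <- function(x, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ranked <- x$population
  if (!is.null(x$energies) && length(x$energies) > 0) {
    emat <- do.call(rbind, lapply(x$energies, function(e)
      vapply(e, function(v) min(v), 1)))
    ranked <- cbind(ranked, as.data.frame(emat))
  }
  write.table(ranked, file.path(dir, "designs.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  writeLines(unlist(lapply(seq_len(nrow(x$population)), function(i)
    c(sprintf(">design_%d fitness=%.4f", i, x$population$fitness[i]),
      x$population$seq[i]))), file.path(dir, "designs.fasta"))
  mat <- do.call(rbind, strsplit(x$population$seq, ""))
  prof <- sapply(seq_len(ncol(mat)), function(p) table(factor(mat[, p],
                                                              levels = AA1)))
  colnames(prof) <- paste0("pos", seq_len(ncol(mat)))
  write.table(cbind(aa = AA1, as.data.frame(prof)),
              file.path(dir, "profile.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(dir)
}
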