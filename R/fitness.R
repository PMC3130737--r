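# The fitness-function definition language.
#
# A fitness file combines per-state packed energies and sequence-only
# constraint terms into one scalar fitness (lower is better).  Seven
# commands: STATE, STATE_VECTOR, SCALAR_EXPRESSION, VECTOR_VARIABLE,
# VECTOR_EXPRESSION, ENTITY_FUNCTION, FITNESS.  Expressions support
# + - * /, unary minus, parentheses, comparisons (inside ite), and the
# functions min(a,b), max(a,b), vmin(v), vmax(v), abs(x), pow(x,y),
# ite(cond, a, b).

# -- tokenizer / recursive-descent expression parser ------------------------

tokenize_expr <- function(text) {
  pat <- paste0("([0-9]*\\.?[0-9]+([eE][+-]?[0-9]+)?)",  # number
                "|([A-Za-z_][A-Za-z0-9_.]*)",            # identifier
                "|(<=|>=|==|[-+*/(),<>])")               # operators
  toks <- list()
  rest <- text
  repeat {
    rest <- sub("^[[:space:]]+", "", rest)
    if (!nzchar(rest)) break
    m <- regexpr(pat, rest)
    if (m != 1) stop("syntax error near: ", substr(rest, 1, 20))
    tok <- regmatches(rest, m)
    toks[[length(toks) + 1]] <- tok
    rest <- substr(rest, attr(m, "match.length") + 1, nchar(rest))
  }
  unlist(toks)
}

parse_expr <- function(text) {
  toks <- tokenize_expr(text)
  pos <- 1L
  peek <- function() if (pos <= length(toks)) toks[pos] else ""
  advance <- function() { t <- peek(); pos <<- pos + 1L; t }
  expect <- function(t) {
    if (peek() != t) stop("expected '", t, "' near '", peek(), "' in: ", text)
    advance()
  }
  p_primary <- function() {
    t <- peek()
    if (t == "(") { advance(); e <- p_cmp(); expect(")"); return(e) }
    if (t == "-") { advance(); return(list(type = "neg", x = p_primary())) }
    if (grepl("^[0-9.]", t)) { advance(); return(list(type = "num", v = as.numeric(t))) }
    if (grepl("^[A-Za-z_]", t)) {
      advance()
      if (peek() == "(") {
        advance()
        args <- list(p_cmp())
        while (peek() == ",") { advance(); args[[length(args) + 1]] <- p_cmp() }
        expect(")")
        return(list(type = "call", fn = t, args = args))
      }
      return(list(type = "var", name = t))
    }
    stop("syntax error near '", t, "' in: ", text)
  }
  p_mul <- function() {
    e <- p_primary()
    while (peek() %in% c("*", "/")) {
      op <- advance()
      e <- list(type = "op", op = op, lhs = e, rhs = p_primary())
    }
    e
  }
  p_add <- function() {
    e <- p_mul()
    while (peek() %in% c("+", "-")) {
      op <- advance()
      e <- list(type = "op", op = op, lhs = e, rhs = p_mul())
    }
    e
  }
  p_cmp <- function() {
    e <- p_add()
    if (peek() %in% c("<", "<=", ">", ">=", "==")) {
      op <- advance()
      e <- list(type = "op", op = op, lhs = e, rhs = p_add())
    }
    e
  }
  out <- p_cmp()
  if (pos <= length(toks)) stop("trailing tokens in expression: ", text)
  out
}

ast_vars <- function(ast) {
  switch(ast$type,
         num = character(0),
         var = ast$name,
         neg = ast_vars(ast$x),
         op = c(ast_vars(ast$lhs), ast_vars(ast$rhs)),
         call = unlist(lapply(ast$args, ast_vars)))
}

binop <- function(op, a, b) {
  if (length(a) != length(b) && length(a) != 1 && length(b) != 1)
    stop("length mismatch in vector expression")
  switch(op,
         "+" = a + b, "-" = a - b, "*" = a * b,
         "/" = a / b,
         "<" = as.numeric(a < b), "<=" = as.numeric(a <= b),
         ">" = as.numeric(a > b), ">=" = as.numeric(a >= b),
         "==" = as.numeric(a == b))
}

eval_ast <- function(ast, env) {
  switch(ast$type,
         num = ast$v,
         var = {
           v <- env[[ast$name]]
           if (is.null(v)) stop("unbound variable: ", ast$name)
           v
         },
         neg = -eval_ast(ast$x, env),
         op = binop(ast$op, eval_ast(ast$lhs, env), eval_ast(ast$rhs, env)),
         call = {
           a <- lapply(ast$args, eval_ast, env = env)
           switch(ast$fn,
                  min = pmin(a[[1]], a[[2]]),
                  max = pmax(a[[1]], a[[2]]),
                  vmin = min(a[[1]]),
                  vmax = max(a[[1]]),
                  abs = abs(a[[1]]),
                  pow = a[[1]]^a[[2]],
                  ite = ifelse(a[[1]] != 0, a[[2]], a[[3]]),
                  stop("unknown function: ", ast$fn))
         })
}

# -- entity functions (sequence-only constraint terms) ----------------------

#' Entity-function definition
#'
#' Sequence-only scorers added to the fitness.  Two scorer types:
#'
#' * identity penalty: `step * max(0, k - free)` REU, `k` = number of listed
#'   position pairs carrying identical amino acids (pushes heterodimer
#'   designs away from symmetric, homodimer-prone sequences);
#' * mutation penalty: `step * max(0, m - free)` REU per scorer, `m` =
#'   mutations from the given wildtype letters at the listed positions
#'   (biases toward minimal mutation sets; one scorer per chain).
#'
#' @param scorers list of scorer definitions; see
#'   [identity_penalty()] / [mutation_penalty()].
#' @return an object of class `entity_function`.
#' @export
entity_function <- function(scorers) {
  structure(list(scorers = scorers), class = "entity_function")
}

#' @param pairs two-column matrix of entity position pairs.
#' @param free number of identical pairs tolerated at no cost.
#' @param step REU per identical pair beyond `free`.
#' @rdname entity_function
#' @export
identity_penalty <- function(pairs, free = 6, step = 5) {
  pairs <- matrix(as.integer(pairs), ncol = 2)
  stopifnot(free >= 0, step >= 0)
  list(type = "identity_penalty", pairs = pairs, free = free, step = step)
}

#' @param positions entity positions belonging to one chain.
#' @param wildtype wildtype letters at those positions.
#' @rdname entity_function
#' @export
mutation_penalty <- function(positions, wildtype, free = 5, step = 1) {
  stopifnot(length(positions) == length(wildtype), free >= 0, step >= 0)
  list(type = "mutation_penalty", positions = as.integer(positions),
       wildtype = toupper(wildtype), free = free, step = step)
}

#' Evaluate an entity function on a sequence
#'
#' @param def an [entity_function()].
#' @param seq entity sequence (string or character vector).
#' @return penalty in REU (sum over scorers).
#' @export
evaluate_entity_function <- function(def, seq) {
  letters_ <- entity_letters(seq)
  total <- 0
  for (sc in def$scorers) {
    total <- total + switch(sc$type,
      identity_penalty = {
        if (any(sc$pairs > length(letters_))) stop("pair position beyond L")
        k <- sum(letters_[sc$pairs[, 1]] == letters_[sc$pairs[, 2]])
        sc$step * max(0, k - sc$free)
      },
      mutation_penalty = {
        if (any(sc$positions > length(letters_)))
          stop("position beyond L")
        m <- sum(letters_[sc$positions] != sc$wildtype)
        sc$step * max(0, m - sc$free)
      },
      stop("unknown scorer type"))
  }
  total
}

#' Parse an entity-function file
#'
#' Lines of the form
#' `IDENTITY_PENALTY free=6 step=5 pairs=1:2,3:4,...` and
#' `MUTATION_PENALTY free=5 step=1 positions=1,3,5 wildtype=FAL`,
#' `#` comments allowed.
#'
#' @param text lines or a single string.
#' @return an [entity_function()].
#' @export
parse_entity_function <- function(text) {
  lines <- unlist(strsplit(text, "\n", fixed = TRUE))
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  kv <- function(f, key, default = NULL) {
    hit <- grep(paste0("^", key, "="), f, value = TRUE)
    if (length(hit) == 0) {
      if (is.null(default)) stop("missing ", key, " in entity function line")
      return(default)
    }
    sub(paste0("^", key, "="), "", hit[1])
  }
  scorers <- lapply(lines, function(line) {
    f <- strsplit(line, "[[:space:]]+")[[1]]
    if (f[1] == "IDENTITY_PENALTY") {
      pr <- do.call(rbind, lapply(strsplit(strsplit(kv(f, "pairs"), ",")[[1]],
                                           ":"), as.integer))
      identity_penalty(pr, free = as.numeric(kv(f, "free", "6")),
                       step = as.numeric(kv(f, "step", "5")))
    } else if (f[1] == "MUTATION_PENALTY") {
      mutation_penalty(as.integer(strsplit(kv(f, "positions"), ",")[[1]]),
                       strsplit(kv(f, "wildtype"), "")[[1]],
                       free = as.numeric(kv(f, "free", "5")),
                       step = as.numeric(kv(f, "step", "1")))
    } else stop("unknown entity-function scorer: ", f[1])
  })
  entity_function(scorers)
}

# -- the fitness program ----------------------------------------------------

#' Parse a fitness-function definition
#'
#' Recognizes the seven commands (one per line, `#` comments):
#' \preformatted{
#' STATE             name structure corr secondary [replicates]
#' STATE_VECTOR      name listfile
#' SCALAR_EXPRESSION name = expr
#' VECTOR_VARIABLE   name = member1 member2 ...
#' VECTOR_EXPRESSION name = expr
#' ENTITY_FUNCTION   name file
#' FITNESS           expr
#' }
#' File arguments may be `@` when states or entity functions are bound
#' programmatically through `bindings`.  Every identifier must be defined by
#' an earlier command (definitions are therefore acyclic) and exactly one
#' FITNESS command must appear.  Lower fitness is better.
#'
#' @param text lines or single string of the fitness file.
#' @param bindings named list supplying `state_spec`s (or lists of them for
#'   STATE_VECTOR) and [entity_function()]s for `@` file arguments.
#' @param dir directory against which relative file paths are resolved.
#' @return an object of class `fitness_program`.
#' @export
parse_fitness_file <- function(text, bindings = list(), dir = ".") {
  lines <- unlist(strsplit(text, "\n", fixed = TRUE))
  lines <- trimws(sub("#.*$", "", lines))
  resolve <- function(f) if (f == "@") NULL else file.path(dir, f)
  prog <- list(commands = list(), state_vars = list(), scalar_defs = list(),
               vector_defs = list(), entity_fns = list(),
               fitness_expr = NULL, order = character(0))
  defined <- character(0)
  check_defined <- function(ast, ln) {
    miss <- setdiff(ast_vars(ast), defined)
    if (length(miss) > 0)
      stop("line ", ln, ": undefined identifier(s): ",
           paste(miss, collapse = ", "))
  }
  for (ln in seq_along(lines)) {
    if (!nzchar(lines[ln])) next
    f <- strsplit(lines[ln], "[[:space:]]+")[[1]]
    cmd <- toupper(f[1])
    if (cmd %in% c("SCALAR_EXPRESSION", "VECTOR_VARIABLE",
                   "VECTOR_EXPRESSION")) {
      if (length(f) < 4 || f[3] != "=")
        stop("line ", ln, ": expected '", cmd, " name = ...'")
      name <- f[2]
      if (name %in% defined) stop("line ", ln, ": '", name, "' redefined")
      rhs <- sub("^[^=]*=", "", lines[ln])
      if (cmd == "VECTOR_VARIABLE") {
        members <- f[-(1:3)]
        miss <- setdiff(members, defined)
        if (length(miss) > 0)
          stop("line ", ln, ": undefined identifier(s): ",
               paste(miss, collapse = ", "))
        prog$vector_defs[[name]] <- list(kind = "collect", members = members)
      } else {
        ast <- parse_expr(rhs)
        check_defined(ast, ln)
        slot <- if (cmd == "SCALAR_EXPRESSION") "scalar_defs" else "vector_defs"
        prog[[slot]][[name]] <- if (cmd == "SCALAR_EXPRESSION") ast
        else list(kind = "expr", ast = ast)
      }
      defined <- c(defined, name)
      prog$order <- c(prog$order, name)
    } else if (cmd == "STATE") {
      name <- f[2]
      if (name %in% defined) stop("line ", ln, ": '", name, "' redefined")
      spec <- if (f[3] == "@") {
        # unbound `@` states are abstract: their energies are supplied
        # directly to evaluate_fitness (useful for fitness-algebra analysis)
        bindings[[name]]
      } else {
        state_spec(name, resolve(f[3]),
                   paste(readLines(resolve(f[4])), collapse = "\n"),
                   if (length(f) >= 5 && f[5] != "@")
                     paste(readLines(resolve(f[5])), collapse = "\n") else NULL,
                   replicates = if (length(f) >= 6) as.integer(f[6]) else 1)
      }
      prog$state_vars[[name]] <- list(kind = "state", spec = spec)
      defined <- c(defined, name)
    } else if (cmd == "STATE_VECTOR") {
      name <- f[2]
      if (name %in% defined) stop("line ", ln, ": '", name, "' redefined")
      specs <- if (f[3] == "@") {
        bindings[[name]]
      } else {
        vl <- readLines(resolve(f[3]))
        vl <- trimws(sub("#.*$", "", vl)); vl <- vl[nzchar(vl)]
        lapply(seq_along(vl), function(i) {
          g <- strsplit(vl[i], "[[:space:]]+")[[1]]
          state_spec(paste0(name, "_", i), resolve(g[1]),
                     paste(readLines(resolve(g[2])), collapse = "\n"),
                     if (length(g) >= 3)
                       paste(readLines(resolve(g[3])), collapse = "\n")
                     else NULL)
        })
      }
      prog$state_vars[[name]] <- list(kind = "vector", specs = specs)
      defined <- c(defined, name)
    } else if (cmd == "ENTITY_FUNCTION") {
      name <- f[2]
      if (name %in% defined) stop("line ", ln, ": '", name, "' redefined")
      def <- if (f[3] == "@") {
        if (is.null(bindings[[name]]))
          stop("line ", ln, ": no binding for entity function '", name, "'")
        bindings[[name]]
      } else parse_entity_function(readLines(resolve(f[3])))
      prog$entity_fns[[name]] <- def
      defined <- c(defined, name)
    } else if (cmd == "FITNESS") {
      if (!is.null(prog$fitness_expr))
        stop("line ", ln, ": second FITNESS command")
      ast <- parse_expr(sub("^[[:space:]]*FITNESS", "", lines[ln]))
      check_defined(ast, ln)
      prog$fitness_expr <- ast
    } else {
      stop("line ", ln, ": unknown command '", f[1], "'")
    }
    prog$commands[[length(prog$commands) + 1]] <- lines[ln]
  }
  if (is.null(prog$fitness_expr)) stop("fitness file has no FITNESS command")
  class(prog) <- "fitness_program"
  prog
}

#' @export
print.fitness_program <- function(x, ...) {
  cat("fitness_program:", length(x$state_vars), "state variable(s),",
      length(x$scalar_defs) + length(x$vector_defs), "expression(s),",
      length(x$entity_fns), "entity function(s)\n")
  invisible(x)
}

#' Evaluate a fitness program
#'
#' @param program a [parse_fitness_file()] result.
#' @param state_energies named list / vector binding every state variable to
#'   a packed energy (scalars for STATE, numeric vectors for STATE_VECTOR).
#' @param seq entity sequence; required when the program uses entity
#'   functions.
#' @param details when `TRUE`, also return every intermediate value.
#' @return the scalar fitness (lower is better), or, with
#'   `details = TRUE`, a list `(fitness, values)`.
#' @export
evaluate_fitness <- function(program, state_energies, seq = NULL,
                             details = FALSE) {
  env <- as.list(state_energies)
  for (nm in names(program$state_vars)) {
    if (is.null(env[[nm]]))
      stop("state variable '", nm, "' not bound to an energy")
  }
  for (nm in names(program$entity_fns)) {
    if (is.null(seq)) stop("entity function '", nm, "' needs a sequence")
    env[[nm]] <- evaluate_entity_function(program$entity_fns[[nm]], seq)
  }
  for (nm in program$order) {
    if (!is.null(program$scalar_defs[[nm]])) {
      v <- eval_ast(program$scalar_defs[[nm]], env)
      if (length(v) != 1) stop("SCALAR_EXPRESSION '", nm, "' is not scalar")
      env[[nm]] <- v
    } else if (!is.null(program$vector_defs[[nm]])) {
      vd <- program$vector_defs[[nm]]
      env[[nm]] <- if (vd$kind == "collect")
        unlist(lapply(vd$members, function(m) env[[m]]))
      else eval_ast(vd$ast, env)
    }
  }
  fit <- eval_ast(program$fitness_expr, env)
  if (length(fit) != 1) stop("FITNESS expression must be scalar")
  if (details) list(fitness = fit, values = env) else fit
}

# -- reconstructed task fitness definitions ---------------------------------

#' Heterodimerization-task fitness definitions
#'
#' Builds the fitness program for the two-species (A, B) task over the five
#' arrangements A, B, AB, AA, BB, with the homodimer binding energies capped
#' at 0 so that design cannot profit from driving an undesired complex to
#' arbitrarily positive binding energy.
#'
#' Variant 1 (the binding-energy-gap form):
#' `F = eAB + w * ((dGAB - min(dGAA,0)) + (dGAB - min(dGBB,0))) + Eseq`
#' with `dGAB = eAB - eA - eB` and `dGXX = eXX - 2 eX`.  At `w = 0.5` the
#' fitness is exactly indifferent between 1 REU of heterodimer total energy
#' and 1 REU of heterodimer binding energy; larger weights favor binding
#' energy.  Setting `w = 0` reduces it to single-state (positive-only)
#' design.
#'
#' Variant 2 (the saturating form): the heterodimer binding reward is capped
#' at `saturation` (-24 REU) and each homodimer is pushed toward `target`
#' (-12 REU) through a bonus gated on the heterodimer binding energy being
#' below `gate`:
#' `F = eAB + max(dGAB, saturation) + w2 * b * (max(target - dGAA, 0) +
#' max(target - dGBB, 0)) + Eseq`, `b = ite(dGAB < gate, 1, 0)`.
#'
#' @param w binding-energy-gap weight (variant 1).
#' @param variant 1 or 2.
#' @param w2 homodimer-destabilization bonus weight (variant 2).
#' @param saturation,target,gate variant-2 shape parameters (REU).
#' @param entity_fn an [entity_function()] (or `NULL` to omit the
#'   sequence-constraint term).
#' @param states named list binding `EA`, `EB`, `EAB`, `EAA`, `EBB` to
#'   [state_spec()]s, or to lists of specs (conformational ensembles; the
#'   per-species energy is then the vector minimum).
#' @return a `fitness_program`.
#' @export
heterodimer_fitness <- function(w = 2, variant = 1, w2 = 1,
                                saturation = -24, target = -12, gate = -20,
                                entity_fn = NULL, states = NULL) {
  vecs <- names(states)[vapply(states, function(s) !inherits(s, "state_spec"),
                               TRUE)]
  decl <- vapply(c("EA", "EB", "EAB", "EAA", "EBB"), function(nm) {
    if (nm %in% vecs)
      paste0("STATE_VECTOR v", nm, " @\nSCALAR_EXPRESSION ", nm,
             " = vmin(v", nm, ")")
    else paste0("STATE ", nm, " @")
  }, character(1))
  ent <- if (!is.null(entity_fn)) "ENTITY_FUNCTION Eseq @" else
    "SCALAR_EXPRESSION Eseq = 0"
  core <- c("SCALAR_EXPRESSION dGAB = EAB - EA - EB",
            "SCALAR_EXPRESSION dGAAraw = EAA - 2*EA",
            "SCALAR_EXPRESSION dGBBraw = EBB - 2*EB",
            "SCALAR_EXPRESSION dGAA = min(dGAAraw, 0)",
            "SCALAR_EXPRESSION dGBB = min(dGBBraw, 0)")
  body <- if (variant == 1) {
    c(core,
      "SCALAR_EXPRESSION gaps = (dGAB - dGAA) + (dGAB - dGBB)",
      sprintf("FITNESS EAB + %.17g*gaps + Eseq", w))
  } else {
    c(core,
      sprintf("SCALAR_EXPRESSION b = ite(dGAB < %.17g, 1, 0)", gate),
      sprintf("SCALAR_EXPRESSION penAA = max(%.17g - dGAAraw, 0)", target),
      sprintf("SCALAR_EXPRESSION penBB = max(%.17g - dGBBraw, 0)", target),
      sprintf("SCALAR_EXPRESSION bindterm = max(dGAB, %.17g)", saturation),
      sprintf("FITNESS EAB + bindterm + %.17g*b*(penAA + penBB) + Eseq", w2))
  }
  text <- paste(c(decl, ent, body), collapse = "\n")
  bindings <- states %||% list()
  names(bindings) <- ifelse(names(bindings) %in% vecs,
                            paste0("v", names(bindings)), names(bindings))
  if (!is.null(entity_fn)) bindings$Eseq <- entity_fn
  parse_fitness_file(text, bindings = bindings)
}

#' Orthogonal-interface (one-against-many) fitness definition
#'
#' For species A binding partner B but not C or D:
#' `F = eAB + w * ((dGAB - min(dGAC,0)) + (dGAB - min(dGAD,0)))`, where each
#' dimer's binding energy compares against monomer states sharing the same
#' backbone conformation (`dGAC = eAC - eA_AC - eC`, etc.).
#'
#' @param w binding-energy-gap weight.
#' @param states named list binding `EAB`, `EAC`, `EAD`, `EA_AB`, `EA_AC`,
#'   `EA_AD`, `EB`, `EC`, `ED` to [state_spec()]s or spec lists.
#' @return a `fitness_program`.
#' @export
orthogonal_fitness <- function(w = 2, states = NULL) {
  nms <- c("EAB", "EAC", "EAD", "EA_AB", "EA_AC", "EA_AD", "EB", "EC", "ED")
  decl <- paste0("STATE ", nms, " @")
  body <- c("SCALAR_EXPRESSION dGAB = EAB - EA_AB - EB",
            "SCALAR_EXPRESSION dGAC = min(EAC - EA_AC - EC, 0)",
            "SCALAR_EXPRESSION dGAD = min(EAD - EA_AD - ED, 0)",
            sprintf("FITNESS EAB + %.17g*((dGAB - dGAC) + (dGAB - dGAD))", w))
  parse_fitness_file(paste(c(decl, body), collapse = "\n"),
                     bindings = states %||% list())
}
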