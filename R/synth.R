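# Seeded synthetic pathway generation and perturbation. Every pipeline
# stage is testable on generated inputs, with no database downloads.

local_seed <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  set.seed(seed)
  function() {
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }
}

random_ec <- function() {
  paste(c(sample(7L, 1L), sample(20L, 1L), sample(20L, 1L), sample(50L, 1L)),
        collapse = ".")
}

#' Generate a seeded synthetic pathway
#'
#' Grows a branching tree of reactions: a single source compound feeds the
#' first reaction, and each subsequent reaction consumes one previously
#' produced (still unconsumed) compound and produces one or more fresh
#' compounds, up to the branching factor. Each reaction past the first is
#' reversible with probability `frac_reversible` (the first is kept
#' irreversible so the pathway always has a source compound). EC numbers are
#' sampled uniformly per reaction. Deterministic for a fixed seed, which is
#' recorded in the pathway id.
#'
#' The generated hypergraphs are acyclic apart from the two-way edges
#' introduced by reversible reactions, so path enumeration stays tractable;
#' they emulate the branching chain structure of catabolic pathways, not the
#' degree distribution or stoichiometry of real metabolic networks.
#'
#' @param n_reactions Number of raw reaction records (>= 1); reversible ones
#'   expand to two hyperedges.
#' @param branching Maximum number of product compounds per reaction.
#' @param frac_reversible Probability that a reaction is reversible.
#' @param seed Integer seed.
#' @param id Pathway id; default `"synth<seed>-<n_reactions>"`.
#' @return A `pathway_hypergraph`.
#' @export
generate_pathway <- function(n_reactions, branching = 1,
                             frac_reversible = 0, seed = 1,
                             id = NULL) {
  if (!is.numeric(n_reactions) || n_reactions < 1) {
    stop("n_reactions must be >= 1")
  }
  stopifnot(branching >= 1, frac_reversible >= 0, frac_reversible <= 1)
  restore <- local_seed(seed)
  on.exit(restore())

  if (is.null(id)) id <- paste0("synth", seed, "-", n_reactions)
  ncomp <- 0L
  newc <- function() {
    ncomp <<- ncomp + 1L
    sprintf("C%03d", ncomp)
  }
  open <- newc()  # produced-but-unconsumed compounds; starts with the source
  records <- vector("list", n_reactions)
  for (k in seq_len(n_reactions)) {
    pick <- if (length(open) == 1L) open else sample(open, 1L)
    open <- setdiff(open, pick)
    nout <- sample(seq_len(branching), 1L)
    outs <- replicate(nout, newc())
    open <- c(open, outs)
    records[[k]] <- reaction_record(
      id = sprintf("R%03d", k),
      inputs = pick, outputs = outs, ec = random_ec(),
      reversible = k > 1L && stats::runif(1) < frac_reversible)
  }
  h <- build_hypergraph(records, ubiquitous = character(), id = id)
  stopifnot(length(classify_compounds(h)$sources) >= 1L)
  h
}

#' Generate a linear chain pathway
#'
#' Convenience wrapper producing an n-reaction chain
#' C1 -> R001 -> C2 -> ... -> C(n+1) with seeded random EC numbers;
#' useful as a minimal connected fixture.
#'
#' @inheritParams generate_pathway
#' @return A `pathway_hypergraph`.
#' @export
generate_chain <- function(n_reactions, seed = 1, id = NULL) {
  generate_pathway(n_reactions, branching = 1, frac_reversible = 0,
                   seed = seed, id = id)
}

#' Perturb a pathway by seeded evolutionary operations
#'
#' Applies a list of operations emulating cross-species divergence (enzyme
#' gain/loss, compound substitution):
#' \describe{
#'   \item{`delete_reaction`}{drop the reaction with the given `id` (error
#'     if absent); compounds left unreferenced are removed.}
#'   \item{`mutate_ec_level`}{change component `level` (1-4) of the first EC
#'     number of reaction `id` (a random reaction when `id` is omitted) to a
#'     different random value, so the original and mutated enzymes share a
#'     prefix of length `level - 1`.}
#'   \item{`swap_compound`}{rename compound `compound` (random when omitted)
#'     to a fresh id everywhere it occurs.}
#'   \item{`add_reaction`}{append a new reaction consuming one random
#'     existing compound and producing a fresh one, with a random EC.}
#' }
#'
#' @param h A `pathway_hypergraph`.
#' @param ops List of operations, each a list with field `op` and the
#'   arguments above.
#' @param seed Integer seed driving the random choices.
#' @return A perturbed `pathway_hypergraph` with an `"evolution_log"`
#'   attribute (character vector of applied operations).
#' @export
perturb_pathway <- function(h, ops = list(), seed = 1) {
  stopifnot(inherits(h, "pathway_hypergraph"), is.list(ops))
  restore <- local_seed(seed)
  on.exit(restore())

  reactions <- h$reactions
  log <- character(0)
  fresh_compound <- function() {
    k <- 1L
    existing <- unique(unlist(lapply(reactions, function(r)
      c(r$inputs, r$outputs))))
    repeat {
      cand <- sprintf("X%03d", k)
      if (!cand %in% existing) return(cand)
      k <- k + 1L
    }
  }
  fresh_reaction <- function() {
    k <- 1L
    repeat {
      cand <- sprintf("A%03d", k)
      if (!cand %in% names(reactions)) return(cand)
      k <- k + 1L
    }
  }

  for (op in ops) {
    kind <- op$op
    if (identical(kind, "delete_reaction")) {
      if (is.null(op$id) || !op$id %in% names(reactions)) {
        stop("cannot delete non-existent reaction: ",
             op$id %||% "<missing id>")
      }
      reactions[[op$id]] <- NULL
      log <- c(log, paste("delete_reaction", op$id))
    } else if (identical(kind, "mutate_ec_level")) {
      ids_with_ec <- names(reactions)[vapply(reactions, function(r)
        length(r$ec) > 0L, logical(1))]
      rid <- op$id %||% sample(ids_with_ec, 1L)
      if (!rid %in% names(reactions)) stop("unknown reaction: ", rid)
      lev <- op$level %||% 4L
      stopifnot(lev %in% 1:4)
      parts <- parse_ec(reactions[[rid]]$ec[1])
      old <- parts[lev]
      repeat {
        parts[lev] <- as.character(sample(99L, 1L))
        if (parts[lev] != old) break
      }
      reactions[[rid]]$ec[1] <- paste(parts, collapse = ".")
      log <- c(log, paste("mutate_ec_level", rid, lev))
    } else if (identical(kind, "swap_compound")) {
      all_comp <- unique(unlist(lapply(reactions, function(r)
        c(r$inputs, r$outputs))))
      cp <- op$compound %||% sample(all_comp, 1L)
      if (!cp %in% all_comp) stop("unknown compound: ", cp)
      repl <- fresh_compound()
      for (rid in names(reactions)) {
        reactions[[rid]]$inputs[reactions[[rid]]$inputs == cp] <- repl
        reactions[[rid]]$outputs[reactions[[rid]]$outputs == cp] <- repl
      }
      log <- c(log, paste("swap_compound", cp, "->", repl))
    } else if (identical(kind, "add_reaction")) {
      all_comp <- unique(unlist(lapply(reactions, function(r)
        c(r$inputs, r$outputs))))
      rid <- fresh_reaction()
      reactions[[rid]] <- new_reaction(rid, sample(all_comp, 1L),
                                       fresh_compound(), random_ec(),
                                       reversible = FALSE,
                                       is_backward = FALSE)
      log <- c(log, paste("add_reaction", rid))
    } else {
      stop("unknown perturbation op: ", kind %||% "<missing>")
    }
  }

  out <- structure(
    list(id = paste0(h$id, "-perturbed"),
         reactions = reactions,
         compounds = sort(unique(as.character(unlist(lapply(reactions, function(r)
           c(r$inputs, r$outputs)))))),
         ubiquitous_filter = h$ubiquitous_filter),
    class = "pathway_hypergraph"
  )
  validate_hypergraph(out)
  attr(out, "evolution_log") <- log
  out
}
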