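# Enumeration of maximal simple reaction paths.

#' Reactions that can start a reaction path
#'
#' A reaction path must start at a reaction consuming at least one source
#' compound (a compound that is never produced within the pathway). One
#' source input suffices, even if the reaction also consumes internal
#' compounds.
#'
#' @param h A `pathway_hypergraph`.
#' @return Sorted character vector of reaction ids.
#' @export
source_reactions <- function(h) {
  stopifnot(inherits(h, "pathway_hypergraph"))
  sources <- classify_compounds(h)$sources
  ids <- names(h$reactions)[vapply(h$reactions, function(r)
    any(r$inputs %in% sources), logical(1))]
  sort(ids)
}

reaction_successors <- function(h) {
  # consumers[[compound]] -> reaction ids with that compound among inputs
  consumers <- new.env(parent = emptyenv())
  for (r in h$reactions) {
    for (cp in r$inputs) {
      assign(cp, c(get0(cp, envir = consumers, ifnotfound = character()),
                   r$id), envir = consumers)
    }
  }
  succ <- lapply(h$reactions, function(r) {
    sort(unique(unlist(lapply(r$outputs, function(cp)
      get0(cp, envir = consumers, ifnotfound = character())))))
  })
  names(succ) <- names(h$reactions)
  succ
}

#' Enumerate maximal simple reaction paths
#'
#' A reaction path R1, ..., Rk starts at a reaction with a source compound
#' among its inputs, never repeats a reaction, chains reactions whose
#' products feed the next reaction's substrates, and is maximal: no unused
#' connected reaction can extend it at its tail. The set of all such paths is
#' found by depth-first search from each source reaction; prefixes are
#' discarded during backtracking, so no returned path is a prefix of
#' another.
#'
#' Path enumeration is exponential in the worst case, so the search carries
#' caps on the number of paths and on path depth. Hitting a cap raises a
#' warning and sets the `"truncated"` attribute on the result; a path cut by
#' the depth cap is still returned.
#'
#' Reactions unreachable from every source reaction appear in no path and
#' can therefore never be matched during alignment.
#'
#' @param h A `pathway_hypergraph`.
#' @param max_paths Cap on the number of returned paths.
#' @param max_depth Cap on path length.
#' @return List of `reaction_path` objects (fields `pathway`, `reactions`),
#'   with attribute `"truncated"` (logical).
#' @export
enumerate_reaction_paths <- function(h, max_paths = 10000, max_depth = 100) {
  stopifnot(inherits(h, "pathway_hypergraph"),
            max_paths >= 1, max_depth >= 1)
  succ <- reaction_successors(h)
  paths <- vector("list", 0L)
  truncated <- FALSE

  emit <- function(stack) {
    paths[[length(paths) + 1L]] <<- structure(
      list(pathway = h$id, reactions = stack), class = "reaction_path")
  }

  dfs <- function(stack) {
    if (length(paths) >= max_paths) {
      truncated <<- TRUE
      return()
    }
    if (length(stack) >= max_depth) {
      truncated <<- TRUE
      emit(stack)
      return()
    }
    nxt <- setdiff(succ[[stack[length(stack)]]], stack)
    if (!length(nxt)) {
      emit(stack)
      return()
    }
    for (r in nxt) dfs(c(stack, r))
  }

  for (r0 in source_reactions(h)) {
    if (length(paths) >= max_paths) {
      truncated <- TRUE
      break
    }
    dfs(r0)
  }
  if (truncated) {
    warning("reaction-path enumeration truncated for pathway ", h$id,
            " (caps: max_paths=", max_paths, ", max_depth=", max_depth, ")")
  }
  attr(paths, "truncated") <- truncated
  paths
}

#' @export
print.reaction_path <- function(x, ...) {
  cat("reaction_path [", x$pathway, "]: ",
      paste(x$reactions, collapse = " -> "), "\n", sep = "")
  invisible(x)
}

#' Write reaction paths as TSV
#'
#' One path per line, reaction ids tab-separated; a debugging aid.
#'
#' @param paths Result of [enumerate_reaction_paths()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_paths_tsv <- function(paths, path) {
  lines <- vapply(paths, function(p) paste(p$reactions, collapse = "\t"),
                  character(1))
  writeLines(lines, path)
  invisible(path)
}
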