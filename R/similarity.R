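# Enzyme, compound-set and reaction similarity.

parse_ec <- function(x) {
  if (!is.character(x) || length(x) != 1L || is.na(x)) {
    stop("malformed EC number: ", deparse(x))
  }
  parts <- strsplit(x, ".", fixed = TRUE)[[1]]
  if (length(parts) != 4L) {
    stop("malformed EC number (need 4 components): ", x)
  }
  ok <- grepl("^[0-9]+$", parts) | parts == "-"
  if (!all(ok) || !grepl("^[0-9]+$", parts[1])) {
    stop("malformed EC number: ", x)
  }
  parts
}

#' Hierarchical EC-number similarity
#'
#' EC numbers classify enzyme function on a 4-level scheme d1.d2.d3.d4.
#' The similarity of two enzymes is the length of the longest common prefix
#' of their EC numbers divided by 4, so it takes values in
#' \{0, 0.25, 0.5, 0.75, 1\}. For example arginase (3.5.3.1) and creatinase
#' (3.5.3.3) score 0.75. A dash/wildcard component never matches, and a
#' mismatch at the first level gives 0.
#'
#' @param e,e2 EC numbers as strings, e.g. `"3.5.3.1"`; a component may be
#'   `"-"` (unknown).
#' @return Similarity in \{0, 0.25, 0.5, 0.75, 1\}.
#' @export
#' @examples
#' ec_similarity("3.5.3.1", "3.5.3.3")  # 0.75
ec_similarity <- function(e, e2) {
  a <- parse_ec(e)
  b <- parse_ec(e2)
  n <- 0L
  for (i in 1:4) {
    if (a[i] == "-" || b[i] == "-" || a[i] != b[i]) break
    n <- i
  }
  n / 4
}

#' Create a compound-similarity provider
#'
#' The provider maps pairs of compound ids to chemical-structure similarity
#' scores in \[0, 1\], typically precomputed by an external tool such as
#' SIMCOMP. It is symmetric; identical ids always score `self_similarity`
#' (default 1) and pairs absent from the table fall back to
#' `default_missing` (default 0, the conservative choice).
#'
#' @param scores Optional data frame with columns `compound_id_1`,
#'   `compound_id_2`, `score`, loaded symmetrically.
#' @param default_missing Score for pairs not in the table.
#' @param self_similarity Score for identical ids.
#' @return A `compound_similarity_provider`.
#' @export
compound_similarity_provider <- function(scores = NULL, default_missing = 0,
                                         self_similarity = 1) {
  stopifnot(default_missing >= 0, default_missing <= 1,
            self_similarity >= 0, self_similarity <= 1)
  tab <- new.env(parent = emptyenv())
  if (!is.null(scores)) {
    stopifnot(is.data.frame(scores),
              all(c("compound_id_1", "compound_id_2", "score") %in%
                    names(scores)))
    if (any(scores$score < 0 | scores$score > 1)) {
      stop("compound similarity scores must lie in [0, 1]")
    }
    for (k in seq_len(nrow(scores))) {
      a <- as.character(scores$compound_id_1[k])
      b <- as.character(scores$compound_id_2[k])
      key <- paste(sort(c(a, b)), collapse = "\t")
      assign(key, scores$score[k], envir = tab)
    }
  }
  structure(
    list(table = tab, default_missing = default_missing,
         self_similarity = self_similarity),
    class = "compound_similarity_provider"
  )
}

#' Identity compound-similarity provider
#'
#' Scores 1 for identical compound ids and 0 otherwise; the default when no
#' precomputed chemical-similarity table is available.
#'
#' @return A `compound_similarity_provider`.
#' @export
identity_provider <- function() compound_similarity_provider()

#' Load a compound-similarity cache file
#'
#' Reads a TSV with columns `compound_id_1`, `compound_id_2`, `score`
#' (e.g. exported SIMCOMP values) into a symmetric provider.
#'
#' @param path TSV file path.
#' @inheritParams compound_similarity_provider
#' @return A `compound_similarity_provider`.
#' @export
read_compound_scores <- function(path, default_missing = 0,
                                 self_similarity = 1) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  compound_similarity_provider(tab, default_missing = default_missing,
                               self_similarity = self_similarity)
}

#' Look up a pairwise compound score
#'
#' @param provider A `compound_similarity_provider`.
#' @param a,b Compound ids.
#' @return Score in \[0, 1\].
#' @export
compound_score <- function(provider, a, b) {
  stopifnot(inherits(provider, "compound_similarity_provider"))
  if (identical(a, b)) return(provider$self_similarity)
  key <- paste(sort(c(a, b)), collapse = "\t")
  if (exists(key, envir = provider$table, inherits = FALSE)) {
    get(key, envir = provider$table, inherits = FALSE)
  } else {
    provider$default_missing
  }
}

#' Reaction similarity weights
#'
#' Weights of the enzyme, substrate-set and product-set terms of the reaction
#' similarity score. The defaults w_e = 0.4, w_i = w_o = 0.3 balance enzyme
#' homology against chemical similarity of the compounds; weights are used as
#' given, with no renormalization.
#'
#' @param w_e Enzyme weight.
#' @param w_i Input (substrate set) weight.
#' @param w_o Output (product set) weight.
#' @return A `score_weights` list.
#' @export
score_weights <- function(w_e = 0.4, w_i = 0.3, w_o = 0.3) {
  stopifnot(w_e >= 0, w_i >= 0, w_o >= 0)
  structure(list(w_e = w_e, w_i = w_i, w_o = w_o), class = "score_weights")
}

#' Compound-set similarity via maximum-weight bipartite matching
#'
#' Builds the complete bipartite graph on X and Y weighted by the provider's
#' pairwise scores, finds a maximum-weight matching and returns the matched
#' weight divided by max(|X|, |Y|). Two empty sets are vacuously identical
#' (score 1); an empty set against a non-empty one scores 0.
#'
#' @param x,y Character vectors of compound ids (treated as sets).
#' @param provider A `compound_similarity_provider`.
#' @return Similarity in \[0, 1\].
#' @export
compound_set_similarity <- function(x, y, provider = identity_provider()) {
  x <- unique(as.character(x))
  y <- unique(as.character(y))
  if (length(x) == 0L && length(y) == 0L) return(1)
  if (length(x) == 0L || length(y) == 0L) return(0)
  w <- matrix(0, length(x), length(y), dimnames = list(x, y))
  for (i in seq_along(x)) {
    for (j in seq_along(y)) {
      w[i, j] <- compound_score(provider, x[i], y[j])
    }
  }
  m <- max_weight_matching(w)
  sum(m$weight) / max(length(x), length(y))
}

#' Reaction similarity score
#'
#' Combines enzyme and compound similarities of two reactions
#' R_i = (I_i, E_i, O_i) and R_j = (I_j, E_j, O_j):
#'
#'   SimReact = SimEnz(E_i, E_j) * w_e + SimComp(I_i, I_j) * w_i +
#'              SimComp(O_i, O_j) * w_o
#'
#' SimEnz is the maximum [ec_similarity()] over all enzyme pairs (0 when
#' either reaction has no annotated enzyme); SimComp is
#' [compound_set_similarity()].
#'
#' @param r1,r2 `pathway_reaction` objects (from a built hypergraph).
#' @param provider A `compound_similarity_provider`.
#' @param weights A [score_weights()] object.
#' @return Similarity in \[0, w_e + w_i + w_o\].
#' @export
reaction_similarity <- function(r1, r2, provider = identity_provider(),
                                weights = score_weights()) {
  stopifnot(inherits(weights, "score_weights"))
  sim_enz <- 0
  if (length(r1$ec) && length(r2$ec)) {
    sim_enz <- max(outer(r1$ec, r2$ec,
                         Vectorize(function(a, b) ec_similarity(a, b))))
  }
  sim_enz * weights$w_e +
    compound_set_similarity(r1$inputs, r2$inputs, provider) * weights$w_i +
    compound_set_similarity(r1$outputs, r2$outputs, provider) * weights$w_o
}
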