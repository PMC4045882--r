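# Steps 2-5 of the alignment algorithm: Smith-Waterman path alignment,
# path matching, match-frequency matrix, reaction matching, final score,
# relational graph and largest conserved subpathway.

#' Alignment configuration
#'
#' Bundles the tunable parameters of the pipeline. The defaults reproduce
#' the reference settings: enzyme/substrate/product weights 0.4/0.3/0.3,
#' zero gap penalty in the local path alignment, path-enumeration caps of
#' 10000 paths and depth 100, and the linear distance d = 2(1 - Score).
#'
#' @param weights A [score_weights()] object.
#' @param gap_penalty Non-negative linear gap penalty for the local path
#'   alignment.
#' @param max_paths,max_depth Caps passed to [enumerate_reaction_paths()].
#' @param distance `"linear"` for d = 2(1 - s) or `"sqrt"` for
#'   d = sqrt(2(1 - s)).
#' @param rev_style How backward-reaction ids are written in reports:
#'   `"rev"` (suffix as-is) or `"#rev"`.
#' @return An `align_config` list.
#' @export
align_config <- function(weights = score_weights(), gap_penalty = 0,
                         max_paths = 10000, max_depth = 100,
                         distance = c("linear", "sqrt"),
                         rev_style = c("rev", "#rev")) {
  stopifnot(gap_penalty >= 0)
  structure(
    list(weights = weights, gap_penalty = gap_penalty,
         max_paths = max_paths, max_depth = max_depth,
         distance = match.arg(distance), rev_style = match.arg(rev_style)),
    class = "align_config"
  )
}

#' Locally align two reaction paths (Smith-Waterman)
#'
#' Aligns two reaction paths with the Smith-Waterman local-alignment dynamic
#' program, using `sim(id1, id2)` as the substitution score and a linear gap
#' penalty. The normalized score is the optimal local score divided by the
#' length of the longer path, so a perfect end-to-end alignment of equal
#' paths scores 1 and a single match across paths of lengths 2 and 1 scores
#' 0.5. Traceback prefers diagonal over up over left moves, which fixes the
#' reported alignment among tied optima.
#'
#' The returned columns cover both full paths: reactions outside the local
#' aligned region appear against a gap (`NA`), and no column is gap-gap.
#'
#' @param p,q Reaction paths: `reaction_path` objects or character vectors
#'   of reaction ids.
#' @param sim Function of two reaction ids returning a similarity in
#'   \[0, 1\].
#' @param gap_penalty Non-negative linear gap penalty (default 0).
#' @return A `path_alignment`: list with `columns` (data frame `left`,
#'   `right`, `NA` = gap), `score_raw`, and normalized `score`.
#' @export
align_reaction_paths <- function(p, q, sim, gap_penalty = 0) {
  a <- if (inherits(p, "reaction_path")) p$reactions else as.character(p)
  b <- if (inherits(q, "reaction_path")) q$reactions else as.character(q)
  stopifnot(length(a) >= 1L, length(b) >= 1L, gap_penalty >= 0)
  # canonical argument order: aligning (q, p) yields the mirrored columns of
  # aligning (p, q), so results do not depend on which pathway comes first
  if (paste(a, collapse = "\r") > paste(b, collapse = "\r")) {
    al <- align_reaction_paths(b, a, function(x, y) sim(y, x), gap_penalty)
    al$columns <- data.frame(left = al$columns$right,
                             right = al$columns$left,
                             stringsAsFactors = FALSE)
    return(al)
  }
  n <- length(a)
  m <- length(b)
  H <- matrix(0, n + 1L, m + 1L)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      H[i + 1L, j + 1L] <- max(0,
                               H[i, j] + sim(a[i], b[j]),
                               H[i, j + 1L] - gap_penalty,
                               H[i + 1L, j] - gap_penalty)
    }
  }
  best <- max(H)
  score <- best / max(n, m)

  cols <- data.frame(left = character(), right = character(),
                     stringsAsFactors = FALSE)
  i_end <- 0L
  j_end <- 0L
  i_start <- n + 1L  # empty aligned region defaults
  j_start <- m + 1L
  if (best > 0) {
    hit <- which(H == best, arr.ind = TRUE)
    hit <- hit[order(hit[, 1L], hit[, 2L]), , drop = FALSE][1L, ]
    i <- hit[1L] - 1L
    j <- hit[2L] - 1L
    i_end <- i
    j_end <- j
    core <- list()
    while (i > 0L && j > 0L && H[i + 1L, j + 1L] > 0) {
      v <- H[i + 1L, j + 1L]
      tol <- 1e-9
      if (abs(v - (H[i, j] + sim(a[i], b[j]))) < tol) {
        core[[length(core) + 1L]] <- c(a[i], b[j])
        i <- i - 1L
        j <- j - 1L
      } else if (abs(v - (H[i, j + 1L] - gap_penalty)) < tol) {
        core[[length(core) + 1L]] <- c(a[i], NA)
        i <- i - 1L
      } else {
        core[[length(core) + 1L]] <- c(NA, b[j])
        j <- j - 1L
      }
    }
    i_start <- i + 1L
    j_start <- j + 1L
    core <- rev(core)
    cols <- data.frame(left = vapply(core, `[`, character(1), 1L),
                       right = vapply(core, `[`, character(1), 2L),
                       stringsAsFactors = FALSE)
  }

  pad <- function(side_left, ids) {
    if (!length(ids)) return(NULL)
    if (side_left) {
      data.frame(left = ids, right = NA_character_, stringsAsFactors = FALSE)
    } else {
      data.frame(left = NA_character_, right = ids, stringsAsFactors = FALSE)
    }
  }
  columns <- rbind(
    pad(TRUE, a[seq_len(i_start - 1L)]),
    pad(FALSE, b[seq_len(j_start - 1L)]),
    cols,
    pad(TRUE, if (i_end < n) a[(i_end + 1L):n] else character()),
    pad(FALSE, if (j_end < m) b[(j_end + 1L):m] else character())
  )
  rownames(columns) <- NULL
  structure(list(columns = columns, score_raw = best, score = score),
            class = "path_alignment")
}

#' Match reaction paths by maximum-weight matching (path matching)
#'
#' Given the all-against-all table of normalized path-alignment scores, the
#' path matching associates each reaction path of the first pathway with at
#' most one "most similar" path of the second, by maximum-weight bipartite
#' matching on the complete bipartite graph of paths.
#'
#' @param score_table Numeric matrix: rows = paths of pathway 1, columns =
#'   paths of pathway 2, entries = normalized path-alignment scores.
#' @return Data frame `left`, `right`, `weight` (path labels).
#' @export
match_paths <- function(score_table) {
  max_weight_matching(score_table)
}

#' Build the match-frequency matrix
#'
#' Over all matched path pairs, entry (i, j) counts the number of pairs in
#' whose alignment reaction R_i of pathway 1 occupies the same column as
#' reaction R_j of pathway 2. Gap columns contribute nothing.
#'
#' @param sigma Path matching from [match_paths()].
#' @param alignments Named list of `path_alignment` objects, keyed by
#'   `paste(left, right)` for each sigma pair.
#' @param reactions1,reactions2 Character vectors of all reaction ids of the
#'   two pathways (matrix dimnames).
#' @return Integer matrix with dimnames `reactions1` x `reactions2`.
#' @export
build_match_frequency <- function(sigma, alignments, reactions1, reactions2) {
  M <- matrix(0L, length(reactions1), length(reactions2),
              dimnames = list(reactions1, reactions2))
  for (k in seq_len(nrow(sigma))) {
    al <- alignments[[paste(sigma$left[k], sigma$right[k])]]
    cols <- al$columns
    both <- !is.na(cols$left) & !is.na(cols$right)
    if (any(both)) {
      M[cbind(cols$left[both], cols$right[both])] <-
        M[cbind(cols$left[both], cols$right[both])] + 1L
    }
  }
  M
}

#' Derive the reaction matching from the match-frequency matrix
#'
#' Maximum-weight bipartite matching on the match-frequency matrix: each
#' reaction of pathway 1 is paired with at most one reaction of pathway 2,
#' maximizing the total alignment frequency.
#'
#' @param M Match-frequency matrix from [build_match_frequency()].
#' @return Data frame `left`, `right`, `weight` (reaction ids).
#' @export
match_reactions <- function(M) {
  max_weight_matching(M)
}

#' Final pathway similarity score
#'
#' For each matched reaction pair (R, R'), maxscorePath is the best
#' normalized path-alignment score over the matched path pairs in which R
#' and R' occupy the same column; pairs with no such path pair contribute 0.
#' The score is the sum of these maxima divided by max(|E1|, |E2|), the
#' larger reaction count, and lies in \[0, 1\].
#'
#' @param rho Reaction matching from [match_reactions()].
#' @param sigma Path matching.
#' @param alignments Named list of `path_alignment`s (as in
#'   [build_match_frequency()]).
#' @param paths1,paths2 The path lists, named with the labels used in
#'   `sigma`.
#' @param n1,n2 Reaction counts |E1| and |E2|.
#' @return List with `score` and per-pair `max_score_path` (numeric vector
#'   parallel to the rows of `rho`).
#' @export
final_score <- function(rho, sigma, alignments, paths1, paths2, n1, n2) {
  stopifnot(n1 >= 0, n2 >= 0)
  msp <- numeric(nrow(rho))
  if (nrow(rho)) {
    for (k in seq_len(nrow(rho))) {
      r1 <- rho$left[k]
      r2 <- rho$right[k]
      best <- 0
      for (s in seq_len(nrow(sigma))) {
        if (!(r1 %in% paths1[[sigma$left[s]]]$reactions)) next
        if (!(r2 %in% paths2[[sigma$right[s]]]$reactions)) next
        al <- alignments[[paste(sigma$left[s], sigma$right[s])]]
        cols <- al$columns
        hit <- !is.na(cols$left) & !is.na(cols$right) &
          cols$left == r1 & cols$right == r2
        if (any(hit) && al$score > best) best <- al$score
      }
      msp[k] <- best
    }
  }
  denom <- max(n1, n2)
  list(score = if (denom > 0) sum(msp) / denom else 0,
       max_score_path = msp)
}

reaction_connectivity_edges <- function(h) {
  succ <- reaction_successors(h)
  from <- rep(names(succ), lengths(succ))
  to <- unlist(succ, use.names = FALSE)
  keep <- from != to
  cbind(from[keep], to[keep])
}

#' Reaction-connectivity graph of a pathway
#'
#' Directed graph on the reactions of a pathway with an edge R -> R'
#' whenever some product of R is a substrate of R'.
#'
#' @param h A `pathway_hypergraph`.
#' @return An igraph object.
#' @export
reaction_connectivity_graph <- function(h) {
  e <- reaction_connectivity_edges(h)
  g <- igraph::make_empty_graph(directed = TRUE) +
    igraph::vertices(names(h$reactions))
  if (nrow(e)) g <- igraph::add_edges(g, t(e))
  g
}

#' Build the relational graph of a reaction matching
#'
#' Nodes are the pathway-1 reactions in the domain of the reaction matching;
#' an edge (R_i, R_j) is present iff R_i and R_j are connected hyperedges in
#' pathway 1 (some product of R_i is a substrate of R_j) AND their images
#' are connected in pathway 2. The relational graph expresses which matched
#' connections are conserved on both sides.
#'
#' @param h1,h2 The two `pathway_hypergraph`s.
#' @param rho Reaction matching (data frame `left`, `right`).
#' @return A directed igraph on the matched pathway-1 reactions.
#' @export
build_relational_graph <- function(h1, h2, rho) {
  nodes <- sort(rho$left)
  g <- igraph::make_empty_graph(directed = TRUE) + igraph::vertices(nodes)
  if (!nrow(rho)) return(g)
  image <- stats::setNames(rho$right, rho$left)
  succ1 <- reaction_successors(h1)
  succ2 <- reaction_successors(h2)
  edges <- character(0)
  for (ri in nodes) {
    for (rj in intersect(succ1[[ri]], nodes)) {
      if (ri == rj) next
      if (image[[rj]] %in% succ2[[image[[ri]]]]) {
        edges <- c(edges, ri, rj)
      }
    }
  }
  if (length(edges)) g <- igraph::add_edges(g, edges)
  g
}

#' Largest conserved subpathway
#'
#' The largest (weakly) connected component of the relational graph is the
#' largest conserved substructure shared by the two pathways; it is returned
#' with the matched images of its reactions and constitutes the final
#' alignment. Size ties are broken in favour of the component containing the
#' lexicographically smallest reaction id.
#'
#' @param g Relational graph from [build_relational_graph()].
#' @param rho Reaction matching.
#' @return Data frame `reaction1`, `reaction2`, sorted by `reaction1`;
#'   zero rows when the graph is empty.
#' @export
largest_conserved_subpathway <- function(g, rho) {
  empty <- data.frame(reaction1 = character(), reaction2 = character(),
                      stringsAsFactors = FALSE)
  if (igraph::vcount(g) == 0L) return(empty)
  comp <- igraph::components(g, mode = "weak")
  sizes <- comp$csize
  best_size <- max(sizes)
  cand <- which(sizes == best_size)
  pick <- cand[1L]
  if (length(cand) > 1L) {
    nm <- igraph::V(g)$name
    mins <- vapply(cand, function(k) min(nm[comp$membership == k]),
                   character(1))
    pick <- cand[order(mins)][1L]
  }
  members <- sort(igraph::V(g)$name[comp$membership == pick])
  image <- stats::setNames(rho$right, rho$left)
  data.frame(reaction1 = members,
             reaction2 = unname(image[members]),
             stringsAsFactors = FALSE)
}

#' Align two metabolic pathways
#'
#' Runs the full five-step pipeline: (1) enumerate the maximal reaction
#' paths of both hypergraphs; (2) align all path pairs with Smith-Waterman
#' using the reaction similarity score; (3) match paths by maximum-weight
#' bipartite matching (sigma); (4) accumulate the match-frequency matrix and
#' derive the one-to-one reaction matching (rho); (5) compute the final
#' similarity score and extract the largest conserved subpathway from the
#' relational graph. Deterministic for fixed inputs and configuration.
#'
#' A pathway without any reaction path (no source compounds, e.g. a pure
#' cycle) produces score 0, an empty alignment and the diagnostic flag
#' `"no_paths"`.
#'
#' @param h1,h2 `pathway_hypergraph` objects.
#' @param provider A `compound_similarity_provider`.
#' @param config An [align_config()].
#' @return A `pathway_alignment` object: list with `score`, `distance`,
#'   `paths1`, `paths2`, `sigma`, `alignments`, `M`, `rho`,
#'   `max_score_path`, `graph`, `conserved`, `diagnostics`.
#' @export
align_pathways <- function(h1, h2, provider = identity_provider(),
                           config = align_config()) {
  stopifnot(inherits(h1, "pathway_hypergraph"),
            inherits(h2, "pathway_hypergraph"),
            inherits(config, "align_config"))
  paths1 <- enumerate_reaction_paths(h1, config$max_paths, config$max_depth)
  paths2 <- enumerate_reaction_paths(h2, config$max_paths, config$max_depth)
  # paths are labelled by their reaction content, so that matching
  # tie-breaks do not depend on enumeration order or pathway order
  path_label <- function(p) paste(p$reactions, collapse = ">")
  names(paths1) <- vapply(paths1, path_label, character(1))
  names(paths2) <- vapply(paths2, path_label, character(1))
  diagnostics <- character(0)
  if (isTRUE(attr(paths1, "truncated")) || isTRUE(attr(paths2, "truncated"))) {
    diagnostics <- c(diagnostics, "truncated_paths")
  }

  ids1 <- names(h1$reactions)
  ids2 <- names(h2$reactions)
  empty_res <- function() {
    structure(
      list(score = 0,
           distance = score_to_distance(0, config$distance),
           paths1 = paths1, paths2 = paths2,
           sigma = data.frame(left = character(), right = character(),
                              weight = numeric(), stringsAsFactors = FALSE),
           alignments = list(),
           M = matrix(0L, length(ids1), length(ids2),
                      dimnames = list(ids1, ids2)),
           rho = data.frame(left = character(), right = character(),
                            weight = numeric(), stringsAsFactors = FALSE),
           max_score_path = numeric(0),
           graph = igraph::make_empty_graph(directed = TRUE),
           conserved = data.frame(reaction1 = character(),
                                  reaction2 = character(),
                                  stringsAsFactors = FALSE),
           diagnostics = c(diagnostics, "no_paths"),
           h1_id = h1$id, h2_id = h2$id,
           n1 = length(ids1), n2 = length(ids2)),
      class = "pathway_alignment"
    )
  }
  if (!length(paths1) || !length(paths2)) return(empty_res())

  # precompute the reaction-similarity table once per pathway pair
  simtab <- matrix(0, length(ids1), length(ids2),
                   dimnames = list(ids1, ids2))
  for (i in ids1) {
    for (j in ids2) {
      simtab[i, j] <- reaction_similarity(h1$reactions[[i]],
                                          h2$reactions[[j]],
                                          provider, config$weights)
    }
  }
  simfun <- function(x, y) simtab[x, y]

  # step 2: all-against-all path alignment
  score_table <- matrix(0, length(paths1), length(paths2),
                        dimnames = list(names(paths1), names(paths2)))
  alignments <- list()
  for (i in names(paths1)) {
    for (j in names(paths2)) {
      al <- align_reaction_paths(paths1[[i]], paths2[[j]], simfun,
                                 config$gap_penalty)
      alignments[[paste(i, j)]] <- al
      score_table[i, j] <- al$score
    }
  }

  # step 3: path matching
  sigma <- match_paths(score_table)

  # step 4: match-frequency matrix and reaction matching
  M <- build_match_frequency(sigma, alignments, ids1, ids2)
  rho <- match_reactions(M)

  # step 5: final score, relational graph, conserved subpathway
  fs <- final_score(rho, sigma, alignments, paths1, paths2,
                    length(ids1), length(ids2))
  g <- build_relational_graph(h1, h2, rho)
  conserved <- largest_conserved_subpathway(g, rho)

  structure(
    list(score = fs$score,
         distance = score_to_distance(fs$score, config$distance),
         paths1 = paths1, paths2 = paths2,
         sigma = sigma, alignments = alignments,
         M = M, rho = rho, max_score_path = fs$max_score_path,
         graph = g, conserved = conserved,
         diagnostics = diagnostics,
         h1_id = h1$id, h2_id = h2$id,
         n1 = length(ids1), n2 = length(ids2)),
    class = "pathway_alignment"
  )
}

#' @export
print.pathway_alignment <- function(x, ...) {
  cat("pathway_alignment ", x$h1_id, " vs ", x$h2_id, "\n",
      "  score: ", format(x$score), "  distance: ", format(x$distance), "\n",
      "  paths: ", length(x$paths1), " vs ", length(x$paths2),
      "  matched reactions: ", nrow(x$rho),
      "  conserved subpathway: ", nrow(x$conserved), " reactions\n",
      sep = "")
  if (length(x$diagnostics)) {
    cat("  diagnostics:", paste(x$diagnostics, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Convert a similarity score to a distance
#'
#' The distance between two pathways with similarity score s is d = 2(1 - s)
#' (the default, as used for distance matrices and clustering); the variant
#' `"sqrt"` computes the Euclidean-style sqrt(2(1 - s)) instead.
#'
#' @param s Score in \[0, 1\].
#' @param variant `"linear"` or `"sqrt"`.
#' @return Distance >= 0.
#' @export
score_to_distance <- function(s, variant = c("linear", "sqrt")) {
  variant <- match.arg(variant)
  if (!is.numeric(s) || any(s < 0 | s > 1)) {
    stop("score must lie in [0, 1]")
  }
  if (variant == "linear") 2 * (1 - s) else sqrt(2 * (1 - s))
}
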