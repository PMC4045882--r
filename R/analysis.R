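# Multi-pathway comparative analyses: average organism scores, distance
# matrices, clustering export, cluster motif intersection.

#' Average similarity score over common pathways
#'
#' The average score between two organisms is the arithmetic mean of the
#' pairwise pathway scores over their k common pathways.
#'
#' @param scores Numeric vector of pathway similarity scores (length >= 1).
#' @return The mean score.
#' @export
average_score <- function(scores) {
  if (length(scores) == 0L) {
    stop("no common pathways: the organism pair is incomparable")
  }
  stopifnot(is.numeric(scores), all(scores >= 0 & scores <= 1))
  mean(scores)
}

#' Build an organism profile
#'
#' @param organism Organism identifier (e.g. a KEGG organism code).
#' @param pathways Named list of `pathway_hypergraph`s keyed by pathway id.
#' @return An `organism_profile`.
#' @export
organism_profile <- function(organism, pathways) {
  stopifnot(is.character(organism), length(organism) == 1L,
            is.list(pathways), !is.null(names(pathways)),
            !anyDuplicated(names(pathways)))
  structure(list(organism = organism, pathways = pathways),
            class = "organism_profile")
}

#' Pairwise organism distance matrix
#'
#' For each unordered pair of organisms, aligns every common pathway, takes
#' the [average_score()], and converts it to the distance
#' d = 2(1 - AverageScore) (or its sqrt variant per the configuration). The
#' result is symmetric with a zero diagonal.
#'
#' @param profiles List of [organism_profile()]s.
#' @param provider A `compound_similarity_provider`.
#' @param config An [align_config()].
#' @return Symmetric numeric matrix with organism labels.
#' @export
organism_distance_matrix <- function(profiles, provider = identity_provider(),
                                     config = align_config()) {
  stopifnot(length(profiles) >= 2L,
            all(vapply(profiles, inherits, logical(1), "organism_profile")))
  labs <- vapply(profiles, `[[`, character(1), "organism")
  if (anyDuplicated(labs)) stop("duplicate organism id: ",
                                labs[duplicated(labs)][1])
  d <- matrix(0, length(labs), length(labs), dimnames = list(labs, labs))
  for (i in seq_along(profiles)) {
    for (j in seq_len(i - 1L)) {
      common <- intersect(names(profiles[[i]]$pathways),
                          names(profiles[[j]]$pathways))
      if (!length(common)) {
        stop("organisms ", labs[j], " and ", labs[i],
             " share no common pathway")
      }
      scores <- vapply(common, function(pw) {
        align_pathways(profiles[[i]]$pathways[[pw]],
                       profiles[[j]]$pathways[[pw]],
                       provider, config)$score
      }, numeric(1))
      dv <- score_to_distance(average_score(scores), config$distance)
      d[i, j] <- dv
      d[j, i] <- dv
    }
  }
  stopifnot(isSymmetric(d), all(diag(d) == 0))
  d
}

#' Write a distance matrix to disk
#'
#' `"tsv"` writes a labeled square table with a header row; `"phylip"`
#' writes the PHYLIP square-matrix format (taxon count on the first line).
#'
#' @param d Labeled symmetric matrix.
#' @param path Output file.
#' @param format `"tsv"` or `"phylip"`.
#' @return `path`, invisibly.
#' @export
write_distance_matrix <- function(d, path, format = c("tsv", "phylip")) {
  format <- match.arg(format)
  if (format == "tsv") {
    tab <- data.frame(organism = rownames(d), d, check.names = FALSE)
    utils::write.table(tab, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    lines <- c(format(nrow(d)),
               vapply(seq_len(nrow(d)), function(i) {
                 paste(c(rownames(d)[i], format(d[i, ], trim = TRUE)),
                       collapse = "  ")
               }, character(1)))
    writeLines(lines, path)
  }
  invisible(path)
}

#' Hierarchical clustering of a distance matrix
#'
#' Thin wrapper around [stats::hclust()] on the exported distance matrix.
#'
#' @param d Labeled symmetric distance matrix.
#' @param method Linkage method (`"single"`, `"average"`, `"complete"`,
#'   `"ward.D2"`, ...).
#' @return An `hclust` object.
#' @export
distance_clustering <- function(d, method = "single") {
  stats::hclust(stats::as.dist(d), method = method)
}

#' Export a dendrogram as Newick
#'
#' @param hc An `hclust` object.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_newick <- function(hc, path) {
  ape::write.tree(ape::as.phylo(hc), file = path)
  invisible(path)
}

#' Common conserved motif of a cluster of pathways
#'
#' For a singleton cluster the motif is the reaction set of the largest
#' connected component of the pathway's reaction-connectivity graph. For a
#' larger cluster, pathways are aligned pairwise in the given order
#' (consecutively by default, or all pairs with `pairs = "all"`) and the
#' motif is the intersection of the first-pathway-side conserved reaction
#' sets, comparable across alignments by reaction id. Adding a pathway to a
#' cluster can only shrink the motif.
#'
#' @param pathways Ordered list of `pathway_hypergraph`s.
#' @param provider A `compound_similarity_provider`.
#' @param config An [align_config()].
#' @param pairs `"consecutive"` (default) or `"all"`.
#' @return Sorted character vector of reaction ids.
#' @export
cluster_common_motif <- function(pathways, provider = identity_provider(),
                                 config = align_config(),
                                 pairs = c("consecutive", "all")) {
  pairs <- match.arg(pairs)
  stopifnot(is.list(pathways), length(pathways) >= 1L)
  if (length(pathways) == 1L) {
    g <- reaction_connectivity_graph(pathways[[1]])
    if (igraph::vcount(g) == 0L) return(character(0))
    comp <- igraph::components(g, mode = "weak")
    return(sort(igraph::V(g)$name[comp$membership == which.max(comp$csize)]))
  }
  idx <- if (pairs == "consecutive") {
    cbind(seq_len(length(pathways) - 1L), seq_len(length(pathways) - 1L) + 1L)
  } else {
    t(utils::combn(length(pathways), 2L))
  }
  motif <- NULL
  for (k in seq_len(nrow(idx))) {
    res <- align_pathways(pathways[[idx[k, 1L]]], pathways[[idx[k, 2L]]],
                          provider, config)
    conserved <- res$conserved$reaction1
    motif <- if (is.null(motif)) conserved else intersect(motif, conserved)
    if (!length(motif)) break
  }
  sort(motif)
}
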