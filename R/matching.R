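# Stable hash of an unordered label pair, mapped into [0, 1). Used only to
# break ties between equally maximal matchings.
pair_hash <- function(a, b) {
  s <- paste(sort(c(a, b)), collapse = "\t")
  cs <- utf8ToInt(s)
  (sum(cs * 31^(seq_along(cs) %% 7)) %% 1000003) / 1000003
}

#' Maximum-weight bipartite matching
#'
#' Finds a matching of the rows and columns of a non-negative weight table
#' whose total weight is maximal: no row or column label appears twice, and
#' no other matching has a strictly greater total weight. The assignment is
#' solved on the bipartite graph spanned by the strictly positive entries
#' (igraph's weighted bipartite matching); zero-weight pairs can never
#' improve the total and are excluded from the result, so an all-zero table
#' yields the empty matching. Edges are laid out in row-major label order,
#' which fixes the solver's choice among tied optima and makes the output
#' deterministic.
#'
#' Ties between equally maximal matchings are resolved by adding a tiny
#' deterministic perturbation to each positive weight, derived from a stable
#' hash of the unordered label pair. Because the perturbation ignores which
#' side a label sits on, a table and its transpose resolve their ties to
#' mirrored matchings, which keeps downstream pathway scores symmetric in
#' the order of the two pathways. The perturbation is far below any genuine
#' weight difference, so the reported matching is always a true optimum of
#' the unperturbed table.
#'
#' @param w Numeric matrix of finite weights >= 0. Row and column names are
#'   the labels; unnamed dimensions get `L1..`/`R1..`.
#' @return Data frame with columns `left`, `right`, `weight`, sorted by
#'   (`left`, `right`).
#' @export
max_weight_matching <- function(w) {
  stopifnot(is.matrix(w), is.numeric(w))
  if (any(!is.finite(w))) stop("matching weights must be finite")
  if (any(w < 0)) stop("matching weights must be non-negative")
  if (is.null(rownames(w))) rownames(w) <- paste0("L", seq_len(nrow(w)))
  if (is.null(colnames(w))) colnames(w) <- paste0("R", seq_len(ncol(w)))
  empty <- data.frame(left = character(), right = character(),
                      weight = numeric(), stringsAsFactors = FALSE)
  pos <- which(w > 0, arr.ind = TRUE)
  if (nrow(w) == 0L || ncol(w) == 0L || nrow(pos) == 0L) return(empty)
  pos <- pos[order(pos[, 1L], pos[, 2L]), , drop = FALSE]

  left <- rownames(w)
  right <- colnames(w)
  eps <- max(w) * 1e-9
  wts <- w[pos] + eps * vapply(seq_len(nrow(pos)), function(k) {
    pair_hash(left[pos[k, 1L]], right[pos[k, 2L]])
  }, numeric(1))
  g <- igraph::make_bipartite_graph(
    types = c(rep(FALSE, length(left)), rep(TRUE, length(right))),
    edges = as.vector(rbind(pos[, 1L], length(left) + pos[, 2L]))
  )
  res <- igraph::max_bipartite_match(g, weights = wts)
  mate <- res$matching[seq_along(left)]
  matched <- which(!is.na(mate))
  if (!length(matched)) return(empty)
  out <- data.frame(
    left = left[matched],
    right = right[mate[matched] - length(left)],
    stringsAsFactors = FALSE
  )
  out$weight <- w[cbind(out$left, out$right)]
  out <- out[out$weight > 0, , drop = FALSE]
  out <- out[order(out$left, out$right), , drop = FALSE]
  rownames(out) <- NULL
  out
}
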