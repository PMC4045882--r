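# Independent brute-force oracles and small fixture builders.

# Exhaustive maximum-weight matching: recursion over rows, each row either
# skipped or assigned to an unused column. Returns the optimal total weight.
brute_force_matching_weight <- function(w) {
  n <- nrow(w)
  m <- ncol(w)
  if (n == 0L || m == 0L) return(0)
  rec <- function(i, used) {
    if (i > n) return(0)
    best <- rec(i + 1L, used) # leave row i unmatched
    for (j in seq_len(m)) {
      if (!used[j]) {
        used[j] <- TRUE
        best <- max(best, w[i, j] + rec(i + 1L, used))
        used[j] <- FALSE
      }
    }
    best
  }
  rec(1L, rep(FALSE, m))
}

brute_force_set_similarity <- function(x, y, provider) {
  x <- unique(x)
  y <- unique(y)
  if (!length(x) && !length(y)) return(1)
  if (!length(x) || !length(y)) return(0)
  w <- outer(x, y, Vectorize(function(a, b) compound_score(provider, a, b)))
  brute_force_matching_weight(w) / max(length(x), length(y))
}

# Exhaustive maximal-simple-path enumeration: tries every k-permutation of
# reactions, keeps sequences that start at a source reaction, chain products
# into substrates, and cannot be extended by any unused reaction. Only
# viable for small pathways.
exhaustive_maximal_paths <- function(h) {
  ids <- names(h$reactions)
  n <- length(ids)
  srcs <- source_reactions(h)
  connected <- function(a, b) {
    length(intersect(h$reactions[[a]]$outputs, h$reactions[[b]]$inputs)) > 0L
  }
  out <- list()
  grow <- function(seq) {
    ext <- Filter(function(r) connected(seq[length(seq)], r),
                  setdiff(ids, seq))
    if (!length(ext)) {
      out[[length(out) + 1L]] <<- seq
    } else {
      for (r in ext) grow(c(seq, r))
    }
  }
  for (s in srcs) grow(s)
  unique(out)
}

identity_sim <- function(a, b) as.numeric(a == b)

chain_records <- function(n, ec = NULL) {
  lapply(seq_len(n), function(k) {
    reaction_record(sprintf("R%d", k),
                    inputs = sprintf("C%d", k),
                    outputs = sprintf("C%d", k + 1L),
                    ec = if (is.null(ec)) character() else ec[[k]])
  })
}

chain_hypergraph <- function(n, id = "chain", ec = NULL) {
  build_hypergraph(chain_records(n, ec), ubiquitous = character(), id = id)
}

random_provider <- function(compounds, seed) {
  pairs <- t(utils::combn(compounds, 2L))
  set.seed(seed)
  compound_similarity_provider(data.frame(
    compound_id_1 = pairs[, 1L],
    compound_id_2 = pairs[, 2L],
    score = round(stats::runif(nrow(pairs)), 3L)))
}

new_reaction_for_test <- function(id, inputs, outputs, ec) {
  expand_reversible(reaction_record(id, inputs, outputs, ec))[[1]]
}
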