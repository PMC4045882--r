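test_that("local path alignment reproduces the anchor scores", {
  p3 <- c("R00178", "R01920", "R02869")
  al <- align_reaction_paths(p3, p3, identity_sim)
  expect_identical(al$score, 1)
  expect_equal(al$columns$left, p3)
  expect_equal(al$columns$right, p3)

  al2 <- align_reaction_paths(c("R05051", "R05052"), "R05052", identity_sim)
  expect_identical(al2$score, 0.5)
  expect_equal(al2$columns$left, c("R05051", "R05052"))
  expect_equal(al2$columns$right, c(NA, "R05052"))

  al0 <- align_reaction_paths(c("a", "b"), c("x", "y"),
                              function(...) 0)
  expect_identical(al0$score, 0)
  expect_true(all(is.na(al0$columns$left) | is.na(al0$columns$right)))
})

test_that("path alignment handles gaps, flanks and penalties", {
  # shared core with an insertion on one side
  al <- align_reaction_paths(c("A", "B", "C"), c("A", "X", "B", "C"),
                             identity_sim, gap_penalty = 0.1)
  expect_equal(al$score_raw, 3 - 0.1)
  both <- !is.na(al$columns$left) & !is.na(al$columns$right)
  expect_equal(al$columns$left[both], c("A", "B", "C"))
  # every reaction of both paths appears exactly once in the columns
  expect_equal(sort(al$columns$left[!is.na(al$columns$left)]),
               c("A", "B", "C"))
  expect_equal(sort(al$columns$right[!is.na(al$columns$right)]),
               c("A", "B", "C", "X"))
  expect_false(any(is.na(al$columns$left) & is.na(al$columns$right)))
  # symmetry of the normalized score
  expect_equal(al$score,
               align_reaction_paths(c("A", "X", "B", "C"), c("A", "B", "C"),
                                    identity_sim, gap_penalty = 0.1)$score)
})

test_that("path matching picks mutually most-similar paths", {
  s <- matrix(1, 1, 1, dimnames = list("p1", "q1"))
  expect_equal(match_paths(s)$left, "p1")

  s2 <- matrix(c(0.9, 0.3), 2, 1, dimnames = list(c("p1", "p2"), "q1"))
  m <- match_paths(s2)
  expect_equal(nrow(m), 1L)
  expect_equal(m$left, "p1")

  expect_equal(nrow(match_paths(matrix(0, 2, 2))), 0L)
})

test_that("match-frequency matrix counts same-column reaction pairs", {
  sigma <- data.frame(left = "p1", right = "q1", weight = 1)
  al <- align_reaction_paths("Ra", "Rx", function(...) 1)
  M <- build_match_frequency(sigma, list("p1 q1" = al), "Ra", "Rx")
  expect_equal(M["Ra", "Rx"], 1L)

  empty <- build_match_frequency(sigma[0, ], list(), c("Ra"), c("Rx"))
  expect_true(all(empty == 0L))
})

test_that("a reaction aligned in 2 of 3 matched paths gets frequency 2", {
  sim <- identity_sim
  sigma <- data.frame(left = c("p1", "p2", "p3"),
                      right = c("q1", "q2", "q3"), weight = 1)
  alignments <- list(
    "p1 q1" = align_reaction_paths(c("Ri", "Ra"), c("Rj", "Ra"),
                                   function(a, b) as.numeric(a == b |
                                                               (a == "Ri" & b == "Rj"))),
    "p2 q2" = align_reaction_paths(c("Ri", "Rb"), c("Rj", "Rb"),
                                   function(a, b) as.numeric(a == b |
                                                               (a == "Ri" & b == "Rj"))),
    "p3 q3" = align_reaction_paths(c("Ri", "Rc"), c("Rz", "Rq"),
                                   function(a, b) as.numeric(a == b))
  )
  M <- build_match_frequency(sigma, alignments,
                             c("Ri", "Ra", "Rb", "Rc"),
                             c("Rj", "Ra", "Rb", "Rz", "Rq"))
  expect_equal(M["Ri", "Rj"], 2L)
})

test_that("reaction matching maximizes total frequency", {
  M <- matrix(c(2, 1, 2, 0), 2, 2, byrow = TRUE,
              dimnames = list(c("R1", "R2"), c("C1", "C2")))
  rho <- match_reactions(M)
  expect_setequal(paste(rho$left, rho$right), c("R1 C2", "R2 C1"))
  expect_equal(sum(rho$weight), 3)

  diag_dom <- matrix(c(5, 1, 1, 5), 2, 2,
                     dimnames = list(c("R1", "R2"), c("S1", "S2")))
  rd <- match_reactions(diag_dom)
  expect_setequal(paste(rd$left, rd$right), c("R1 S1", "R2 S2"))

  expect_equal(nrow(match_reactions(matrix(0L, 2, 2))), 0L)
})

test_that("final score sums best path scores over matched reactions", {
  # two matched reactions, each with maxscorePath 0.5, |E1|=2, |E2|=4
  paths1 <- list(p1 = structure(list(pathway = "h1",
                                     reactions = c("Ra", "Rb")),
                                class = "reaction_path"))
  paths2 <- list(q1 = structure(list(pathway = "h2",
                                     reactions = c("Xa", "Xb")),
                                class = "reaction_path"))
  al <- align_reaction_paths(c("Ra", "Rb"), c("Xa", "Xb"),
                             function(a, b) 0.5)
  sigma <- data.frame(left = "p1", right = "q1", weight = al$score)
  rho <- data.frame(left = c("Ra", "Rb"), right = c("Xa", "Xb"), weight = 1)
  fs <- final_score(rho, sigma, list("p1 q1" = al), paths1, paths2, 2, 4)
  expect_equal(al$score, 0.5)
  expect_equal(fs$score, (0.5 + 0.5) / 4)

  empty_rho <- rho[0, ]
  expect_equal(final_score(empty_rho, sigma, list("p1 q1" = al),
                           paths1, paths2, 2, 4)$score, 0)
})

test_that("relational graph keeps only doubly-connected matched pairs", {
  h1 <- chain_hypergraph(3, id = "h1")
  h2 <- chain_hypergraph(3, id = "h2")
  rho <- data.frame(left = c("R1", "R2", "R3"),
                    right = c("R1", "R2", "R3"), weight = 1)
  g <- build_relational_graph(h1, h2, rho)
  expect_equal(igraph::vcount(g), 3L)
  expect_equal(igraph::ecount(g), 2L)  # R1->R2, R2->R3 on both sides

  # map H1-connected reactions onto H2-disconnected ones: no edge survives
  h2b <- build_hypergraph(list(reaction_record("R1", "A", "B"),
                               reaction_record("R2", "X", "Y"),
                               reaction_record("R3", "P", "Q")),
                          ubiquitous = character(), id = "h2b")
  g2 <- build_relational_graph(h1, h2b, rho)
  expect_equal(igraph::ecount(g2), 0L)

  g3 <- build_relational_graph(h1, h2, rho[0, ])
  expect_equal(igraph::vcount(g3), 0L)
})

test_that("largest conserved subpathway is the biggest component", {
  h1 <- build_hypergraph(list(reaction_record("R1", "A", "B"),
                              reaction_record("R2", "B", "C"),
                              reaction_record("R3", "C", "D"),
                              reaction_record("R9", "U", "V")),
                         ubiquitous = character(), id = "h1")
  rho <- data.frame(left = c("R1", "R2", "R3", "R9"),
                    right = c("S1", "S2", "S3", "S9"), weight = 1)
  h2 <- build_hypergraph(list(reaction_record("S1", "A", "B"),
                              reaction_record("S2", "B", "C"),
                              reaction_record("S3", "C", "D"),
                              reaction_record("S9", "U", "V")),
                         ubiquitous = character(), id = "h2")
  g <- build_relational_graph(h1, h2, rho)
  cons <- largest_conserved_subpathway(g, rho)
  expect_equal(cons$reaction1, c("R1", "R2", "R3"))
  expect_equal(cons$reaction2, c("S1", "S2", "S3"))

  empty <- largest_conserved_subpathway(
    igraph::make_empty_graph(directed = TRUE), rho[0, ])
  expect_equal(nrow(empty), 0L)
})

test_that("full pipeline: self-alignment of a connected chain scores 1", {
  h <- chain_hypergraph(4, ec = as.list(sprintf("1.1.1.%d", 1:4)))
  res <- align_pathways(h, h)
  expect_equal(res$score, 1)
  expect_equal(res$distance, 0)
  expect_equal(res$conserved$reaction1, c("R1", "R2", "R3", "R4"))
})

test_that("full pipeline: an extra side branch dilutes the score to 3/4", {
  recs <- list(reaction_record("R1", "A", "B", ec = "1.1.1.1"),
               reaction_record("R2", "B", "C", ec = "2.2.2.2"),
               reaction_record("R3", "C", "D", ec = "3.3.3.3"))
  h1 <- build_hypergraph(recs, ubiquitous = character(), id = "h1")
  h2 <- build_hypergraph(c(recs, list(reaction_record("R4", "B", "Z",
                                                      ec = "6.9.9.9"))),
                         ubiquitous = character(), id = "h2")
  res <- align_pathways(h1, h2)
  expect_equal(res$score, 0.75)
  expect_equal(res$conserved$reaction1, c("R1", "R2", "R3"))
})

test_that("full pipeline: pathways sharing nothing score 0", {
  h1 <- build_hypergraph(list(reaction_record("R1", "A", "B",
                                              ec = "1.1.1.1")),
                         ubiquitous = character(), id = "h1")
  h2 <- build_hypergraph(list(reaction_record("S1", "X", "Y",
                                              ec = "5.5.5.5")),
                         ubiquitous = character(), id = "h2")
  expect_equal(align_pathways(h1, h2)$score, 0)
})

test_that("a pathway without sources yields score 0 and a diagnostic", {
  cyc <- build_hypergraph(list(reaction_record("R1", "A", "B"),
                               reaction_record("R2", "B", "A")),
                          ubiquitous = character(), id = "cyc")
  h <- chain_hypergraph(2)
  res <- align_pathways(cyc, h)
  expect_equal(res$score, 0)
  expect_true("no_paths" %in% res$diagnostics)
  expect_equal(nrow(res$conserved), 0L)
})

test_that("score is symmetric and within [0, 1] on random pairs", {
  for (seed in 1:15) {
    h1 <- generate_pathway(6, branching = 2, frac_reversible = 0.3,
                           seed = seed)
    h2 <- generate_pathway(6, branching = 2, frac_reversible = 0.3,
                           seed = seed + 500)
    comp <- union(h1$compounds, h2$compounds)
    p <- random_provider(comp, seed)
    s12 <- align_pathways(h1, h2, p)$score
    s21 <- align_pathways(h2, h1, p)$score
    expect_equal(s12, s21, tolerance = 1e-9)
    expect_gte(s12, 0)
    expect_lte(s12, 1)
  }
})

test_that("self-score is 1 iff every reaction is path-reachable", {
  reachable <- chain_hypergraph(5, ec = as.list(sprintf("2.7.1.%d", 1:5)))
  expect_equal(align_pathways(reachable, reachable)$score, 1)

  # chain plus an unreachable two-reaction cycle
  part <- build_hypergraph(list(reaction_record("R1", "A", "B",
                                                ec = "1.1.1.1"),
                                reaction_record("R8", "U", "V",
                                                ec = "2.2.2.2"),
                                reaction_record("R9", "V", "U",
                                                ec = "3.3.3.3")),
                           ubiquitous = character(), id = "part")
  res <- align_pathways(part, part)
  expect_lt(res$score, 1)
  expect_equal(res$score, 1 / 3)  # only R1 lies on a path
})

test_that("deleting a reaction from a copy never increases the score", {
  h <- generate_chain(8, seed = 11)
  prev <- align_pathways(h, h)$score
  ids <- rev(names(h$reactions))
  mut <- h
  for (k in 1:4) {
    mut <- perturb_pathway(mut, list(list(op = "delete_reaction",
                                          id = ids[k])), seed = k)
    s <- align_pathways(h, mut)$score
    expect_lte(s, prev + 1e-12)
    prev <- s
  }
})

test_that("the conserved subpathway is connected on both sides", {
  for (seed in 1:8) {
    h1 <- generate_pathway(7, branching = 2, seed = seed)
    h2 <- perturb_pathway(h1, list(list(op = "mutate_ec_level", level = 4),
                                   list(op = "add_reaction")), seed = seed)
    res <- align_pathways(h1, h2)
    if (nrow(res$conserved) < 2L) next
    g1 <- igraph::induced_subgraph(reaction_connectivity_graph(h1),
                                   res$conserved$reaction1)
    g2 <- igraph::induced_subgraph(reaction_connectivity_graph(h2),
                                   res$conserved$reaction2)
    expect_true(igraph::is_connected(g1, mode = "weak"))
    expect_true(igraph::is_connected(g2, mode = "weak"))
  }
})

test_that("score converts to distance on both variants", {
  expect_equal(score_to_distance(1), 0)
  expect_equal(score_to_distance(0.5), 1)
  expect_equal(score_to_distance(0), 2)
  expect_equal(score_to_distance(0.5, "sqrt"), 1)
  expect_equal(score_to_distance(0, "sqrt"), sqrt(2))
  expect_error(score_to_distance(1.5), "\\[0, 1\\]")
  expect_error(score_to_distance(-0.1), "\\[0, 1\\]")
})
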