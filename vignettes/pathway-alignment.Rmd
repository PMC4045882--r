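---
title: "Aligning metabolic pathways as directed hypergraphs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Aligning metabolic pathways as directed hypergraphs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pathalign)
```

## The model

A metabolic pathway is represented as a directed hypergraph H = (V, E):
compounds are nodes and each reaction is a directed hyperedge R = (I, E, O)
from its substrate set I to its product set O, with the catalysing enzymes E
carried as an attribute rather than as nodes. Three modelling choices shape
the graph:

* **Ubiquitous compounds** (water, ATP, ADP, NAD(P)/NAD(P)H, phosphate,
  CO2, and similar currency metabolites) are removed from all substrate and
  product sets at build time. They take part in so many reactions that
  keeping them would connect essentially everything to everything and
  drown the pathway's real topology. The default list
  (`kegg_ubiquitous_compounds()`) covers the usual currency metabolites by
  KEGG id and can be replaced wholesale; there is no canonical list, so the
  default errs on the side of the compounds that appear in textbook
  presentations of currency metabolites. A reaction emptied on one side by
  this filter is kept (it becomes a path endpoint); one emptied on both
  sides is dropped, since a hyperedge needs at least one endpoint.
* **Reversible reactions** become two hyperedges: the forward copy keeps
  the reaction id, the backward copy swaps substrates with products and
  takes the suffix `rev`. Downstream, the two copies are ordinary,
  independent reactions.
* **Sources and sinks**: a compound appearing only as an input is a source
  (produced by other pathways), one appearing only as an output is a sink.
  These mark the pathway's exchange points and anchor path enumeration.

## Reaction similarity

Two reactions are compared by

SimReact(Ri, Rj) = SimEnz(Ei, Ej) · w_e + SimComp(Ii, Ij) · w_i +
SimComp(Oi, Oj) · w_o

with default weights w_e = 0.4, w_i = w_o = 0.3, which balance enzymatic
function against chemical similarity of the metabolites. Weights are used
exactly as supplied — there is no renormalization — so non-default weights
that do not sum to 1 rescale the score range accordingly.

* **SimEnz** uses the 4-level EC classification d1.d2.d3.d4: the
  similarity of two enzymes is the length of their longest common EC prefix
  divided by 4 (so 3.5.3.1 vs 3.5.3.3 gives 0.75, and a first-level
  mismatch gives 0). Wildcard components (`-`) never match: an
  incompletely classified enzyme should not look identical to another
  merely because both are unclassified at some level. When a reaction
  carries several EC numbers (KGML allows this), SimEnz is the maximum over
  all pairs — the formula assumes one enzyme per reaction, and the maximum
  preserves the [0, 1] range while rewarding any shared catalytic
  function. A reaction with no EC annotation contributes SimEnz = 0, so
  two identical enzyme-less reactions score at most w_i + w_o = 0.6; this
  is a property of the score, not a defect, and it is why fixtures used to
  demonstrate perfect self-similarity carry EC numbers.
* **SimComp** compares two compound sets by building the complete
  bipartite graph weighted with pairwise compound similarities, taking a
  maximum-weight matching, and dividing the matched weight by
  max(|X|, |Y|). Two empty sets score 1 (vacuously identical); an empty
  set against a non-empty one scores 0. Pairwise compound scores come from
  a provider object: identical ids always score 1, and other pairs are
  looked up in an optional precomputed table (e.g. exported SIMCOMP
  values, loaded from TSV) with a conservative default of 0 for absent
  pairs. Chemical-structure similarity itself is out of scope — the
  provider is the interface to whatever tool computed it.

## The alignment algorithm

`align_pathways()` runs five steps, deterministic for fixed inputs:

1. **Reaction paths.** All maximal simple reaction paths are enumerated by
   depth-first search from every reaction that consumes a source compound
   (one source input suffices). A path chains reactions whose products
   feed the next reaction's substrates, never repeats a reaction, and is
   maximal — prefixes are discarded during backtracking. Reactions
   unreachable from every source lie on no path and can never be matched;
   this is the designed behaviour, and it is why self-alignment of a
   pathway with an isolated cycle scores below 1. Enumeration is
   exponential in the worst case, so it carries caps (default 10 000 paths,
   depth 100) that raise an explicit truncation warning and flag — never a
   silent drop. The defaults are far above anything the test pathways
   produce; the caps exist for pathological inputs.
2. **Path alignment.** Every path of H1 is aligned against every path of
   H2 with the Smith-Waterman local-alignment dynamic program, using
   SimReact as the substitution score and a linear gap penalty. The
   normalized score is the optimal local score divided by the longer path
   length: aligning a path perfectly to itself gives 1, and a single exact
   match across paths of lengths 2 and 1 gives 0.5. This normalization is
   the only one consistent with both of those worked values, which is why
   it was adopted. The default gap penalty is 0 — consistent with the same
   worked values — and is exposed in `align_config()` for
   experimentation.
3. **Path matching (σ).** A maximum-weight bipartite matching over the
   table of normalized path scores pairs each path with at most one "most
   similar" partner.
4. **Reaction matching (ρ).** The match-frequency matrix M counts, over
   the matched path pairs, how often reaction Ri of H1 sits in the same
   alignment column as Rj of H2 (gap columns count for nothing). A second
   maximum-weight matching on M yields the one-to-one reaction matching ρ.
   Zero-weight pairs are pruned from every matching: a pairing that no
   alignment supports carries no information.
5. **Score and conserved subpathway.** For each (R, R′) in ρ,
   maxscorePath is the best normalized path score among the σ pairs in
   whose alignment R and R′ occupy the same column (0 if there is none,
   and such pairs are excluded from the conserved output). The pathway
   score is the sum of these maxima divided by max(|E1|, |E2|); it lies in
   [0, 1] and equals 1 exactly when every reaction lies on a path and the
   pathways coincide. The relational graph G then has the matched H1
   reactions as nodes and an edge (Ri, Rj) only where Ri feeds Rj in H1
   *and* ρ(Ri) feeds ρ(Rj) in H2; the largest weakly connected component
   of G, with its ρ-images, is the largest conserved subpathway and the
   final alignment. Component-size ties go to the component holding the
   lexicographically smallest reaction id.

The similarity score converts to a distance as d = 2(1 − Score). The
Euclidean-style variant √(2(1 − Score)) is also available
(`align_config(distance = "sqrt")`); the linear form is the default as the
one printed in the formula the package implements, though the radical
variant is retained in case a root was intended.

## Numerical and determinism choices

* **Matching tie-breaks.** Maximum-weight matchings are often degenerate
  (frequency matrices are small integers; path-score tables repeat
  values). Ties are resolved by adding a tiny deterministic perturbation
  (about 10⁻⁹ of the largest weight) to each positive entry, derived from
  a stable hash of the *unordered* label pair. Because the perturbation
  ignores which side a label sits on, a weight table and its transpose
  resolve ties to mirrored matchings — this is what makes
  Score(H1, H2) = Score(H2, H1) hold exactly even in degenerate cases,
  which a one-sided rule (e.g. lexicographic on the left label) would not
  guarantee. The perturbation is orders of magnitude below any genuine
  weight difference, so the result is always a true optimum of the
  unperturbed table.
* **Smith-Waterman determinism.** Traceback prefers diagonal over up over
  left moves and starts from the first maximal cell in row-major order;
  in addition, the two input paths are brought into a canonical order
  before alignment and the columns mirrored back, so aligning (p, q) and
  (q, p) yields mirrored columns by construction. σ operates on paths
  labelled by their reaction content, not by enumeration order, for the
  same reason.
* **Float comparisons** in the traceback use an absolute tolerance of
  10⁻⁹.

## The synthetic generator

`generate_pathway()` grows a branching tree of reactions from a single
source compound: each reaction consumes one previously produced, still
unconsumed compound and produces up to `branching` fresh ones; each
reaction past the first is reversible with probability `frac_reversible`
(the first stays irreversible so a source always exists); EC numbers are
sampled uniformly. The result is always a valid hypergraph with at least
one source, deterministic for a fixed seed, and acyclic apart from
reversible two-way edges — so path enumeration stays exact and cheap.

`perturb_pathway()` emulates cross-species divergence with seeded
operations: reaction deletion (enzyme loss), EC mutation at a chosen level
(functional drift — a level-4 mutation leaves a 0.75-similar enzyme),
compound renaming, and reaction gain. An evolution log of applied
operations accompanies the result.

What the generator does *not* emulate: realistic degree distributions,
stoichiometry, compartments, or the heavy compound reuse of real KEGG maps.
Tests passing on these fixtures demonstrate the algorithm's contracts
(symmetry, bounds, monotonicity, recoverable phylogenies), not performance
on organism-scale data.

## Comparative analyses

For organisms O1, O2 with k common pathways,
AverageScore = Σ Score(H1,i, H2,i) / k and d(O1, O2) =
2(1 − AverageScore). `organism_distance_matrix()` builds the symmetric,
zero-diagonal matrix; export goes to labelled TSV or PHYLIP, clustering to
`hclust` (single/average/complete/Ward) and Newick via ape. A pair of
organisms with no common pathway is an error from the matrix function and
a recorded-but-tolerated gap in the `cmd_matrix` driver.

`cluster_common_motif()` summarizes a cluster of pathways by the
intersection of conserved reaction sets over pairwise alignments taken in
the given order. The order and pairing scheme are genuinely open choices;
the package aligns consecutive pairs in the supplied (by convention
lexicographic) order, with an all-pairs variant behind the `pairs`
argument. A singleton cluster reports the largest connected component of
its own reaction-connectivity graph. The motif can only shrink as a
cluster grows.

## Problem sizes

The test suite and examples run on synthetic pathways of 5–10 reactions,
distance matrices of up to four organisms, and matching tables up to 5×5
against brute-force oracles — sizes at which every expected value can be
verified independently (exhaustive matching enumeration, exhaustive path
search) while the whole suite stays fast. The algorithms themselves carry
no such limits beyond the path-enumeration caps described above.

## Known limitations

* Path enumeration is exponential on densely interconnected hypergraphs;
  the caps make this safe but truncated runs lose the exactness
  guarantee (they say so via warning and flag).
* One-to-one reaction matching only; one-to-many correspondences between
  alternative enzymes are out of scope.
* The score compares reaction *sets* through path structure; two pathways
  with equal reaction content but different wiring can score high while
  their conserved subpathway is small — the conserved-motif machinery
  exists precisely to surface such cases.
* Composite reaction ids (e.g. `R00667-183rev`) are treated as opaque
  strings throughout.
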