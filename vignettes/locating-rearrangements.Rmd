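---
title: "Locating rearrangement events from a fragmented assembly"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Locating rearrangement events from a fragmented assembly}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

## The problem

Rearrangement inference normally needs complete genome assemblies: an
inversion can span an arbitrarily large chromosome segment, and
identifying it requires seeing both of its endpoints in context.  Draft
assemblies of non-model organisms instead consist of many short
scaffolds, so whole rearranged fragments are rarely observable.  What
*is* observable, scaffold by scaffold, is a **breakpoint**: a pair of
genes adjacent in one genome but not in another, as long as the
adjacency does not coincide with a scaffold end.

`fragphylo` asks how far breakpoints alone can go.  Given one fragmented
genome (the *designated* genome) and a set of completely assembled
relatives on a phylogeny, it infers on which branch each rearrangement
event occurred, and — run over every candidate topology — which tree
explains the breakpoints most parsimoniously.

## The model

Genomes are single linear chromosomes with identical single-copy gene
content, written as signed permutations of `1..n`; the sign is reading
orientation.  Evolution acts by **inversions**: a segment between two
inter-gene boundaries is reversed and every sign in it flipped.  An
adjacency `(a, b)` is identified with `(-b, -a)` — the same junction
read from the other strand — and chromosome ends carry no adjacency, so
an `n`-gene genome has `n - 1` adjacencies and an inversion with both
endpoints strictly inside the chromosome disrupts exactly two of them
(one, if an endpoint falls on a chromosome end).

The designated genome is observed only as `m` scaffolds.  For each
scaffold `s` and each other genome `g` we record one of three labels:

* **1 (split)** — at least one internal adjacency of `s` is absent from
  `g`.  Because the complete genomes are single chromosomes, a
  disrupted adjacency is the only observable sense in which the content
  of `s` can be "split" in `g`.
* **2 (not split)** — every internal adjacency of `s` is conserved in
  `g`.
* **3 (can't tell)** — no usable signal.  Single-gene scaffolds have no
  internal adjacency and always get label 3; the label can also be
  injected deliberately to emulate degraded real data (fractionated
  plant genomes being the motivating case).

The designated genome's own column is fixed at 2: a scaffold is
trivially unsplit in itself.

## Event parsimony with a wildcard state

Fix a scaffold and consider its leaf labels on a candidate tree.  Under
the no-coincidence assumption, a breakpoint shared by two genomes arose
on the path between them, and a conserved adjacency forbids any
disruption of the scaffold on the path between its two carriers.  An
**event** is therefore an edge whose endpoints are reconstructed with
different labels (1 on one side, 2 on the other), and the inference task
is classic small parsimony: assign 1 or 2 to every internal vertex — and
to every wildcard (label-3) leaf — minimising the number of event edges.

`min_events()` solves this with a two-state unit-cost dynamic programme
(the standard ancestral-state recursion): each vertex carries the cost
of its subtree when labelled 1 or 2, leaves with a fixed label have
infinite cost in the other state, wildcard leaves cost 0 in both, and a
unit is paid on each edge whose endpoints disagree.  The unrooted tree
is traversed from an arbitrary stored root; the optimum is
root-invariant, so no canonical rooting is needed.

`optimal_assignments()` then enumerates *all* optimal labellings by
backtracking over the DP choice points (trees here have at most a dozen
vertices, so explicit enumeration is exact and cheap).  From the
enumeration come:

* the **candidate edges** — branches that are an event in at least one
  optimal labelling, i.e. the set of branches on which the
  rearrangement could have occurred;
* **fractional edge weights** — the fraction of optimal labellings in
  which each edge is an event.  Weights sum to the event number, so an
  ambiguous event distributes its unit score over the alternative
  branches rather than being double-counted;
* the **conflict report** (`detect_conflict()`) — whether every optimal
  labelling places a split vertex on the path between two genomes
  labelled 2.  We deliberately expose the boolean and the offending
  leaf pairs (their union over optimal labellings) rather than invent a
  numeric conflict score, since minimising events already coincides
  with minimising conflicts when ranking trees.  Conflicts are a
  property of reconstructions, so only optimal labellings are
  consulted.

Scoring a whole dataset is additive: `score_tree()` sums the per-
scaffold event numbers (identical label rows are deduplicated and solved
once, in a vectorised pass).  With a moderate rearrangement rate this
total is exactly the weighted tally *count(1-event scaffolds) + 2 ×
count(2-event) + 3 × count(3-event)*; scaffolds needing more than three
events contribute their actual count.  `rank_trees()` scores every
candidate topology and reports **competition ranks** (1 + the number of
strictly better trees, ties sharing the best rank) — the optimistic
convention, chosen so that "the generating tree is best" is read off as
rank 1 even when equally-scoring rearrangements of its topology exist.

```{r}
library(fragphylo)
tr <- read_newick("((1,2),(3,4),((5,6),7));")
labs <- c(`1` = 1, `2` = 1, `3` = 2, `4` = 2, `5` = 2, `6` = 2, `7` = 3)
optimal_assignments(tr, labs)
```

## The simulator

`simulate_dataset()` reproduces the study conditions that the package's
experiments and tests run under:

* **7 genomes** on a uniform random unrooted binary topology (11
  branches: 7 terminal, 4 internal), generated by sequential leaf
  addition — each new leaf attaches to a uniformly chosen edge, which
  yields the uniform distribution over the `(2N-5)!!` labelled
  topologies (945 for `N = 7`).
* a **1000-gene** identity genome at a uniformly chosen internal root
  vertex (the root choice is immaterial by symmetry of inversion);
* exactly **k inversions per branch**, each with two distinct
  boundaries drawn uniformly from the `choose(n+1, 2)` pairs —
  endpoints may touch chromosome ends, which is why an inversion
  "generally", not always, makes two breakpoints.  Successive events on
  a branch are sampled independently;
* the designated leaf genome (leaf 1 by default; the choice is
  symmetric) split into **m scaffolds** by `m - 1` distinct uniform
  cuts, giving approximately geometric scaffold sizes for `m << n`
  while guaranteeing exactly `m` scaffolds;
* a complete **event log** (branch, cut boundaries, adjacencies
  destroyed and created), from which every leaf genome can be replayed
  exactly — the tests verify this round trip.

A single seed drives tree generation, evolution and fragmentation in a
fixed order, and the experiment runners derive each replicate's seed as
`seed + replicate offset`, so every figure-level experiment is exactly
reproducible and arms of a sweep are matched replicate-for-replicate
(the can't-tell sweep reuses identical datasets across masking levels).

What the generator does *not* emulate: gene loss and fractionation,
duplication, translocation and transposition, unequal gene content,
more than one fragmented genome, and rate heterogeneity across
branches.  Passing tests therefore demonstrate the combinatorial
machinery under the idealised inversion-only model, not robustness to
the annotation noise of real syntenic-block data, where identifying the
labels themselves is the hard step.

## Experiments

Four runners reproduce the package's standard experiments, each
returning per-replicate rows plus means:

* `run_rate_experiment()` — detected events on the true tree versus
  inversions per branch (default m = 100 scaffolds).  With one
  inversion per branch, 11 events can make at most 22 breakpoints; the
  detected total sits a little under 20 because some breakpoints land
  at scaffold boundaries or in single-gene scaffolds, and collinear
  events in one lineage can be explained by fewer event edges.
* `run_fragmentation_experiment()` — the fragmentation trade-off at 5
  inversions per branch: finer fragmentation reduces the chance that
  two events collide on one scaffold but sharply increases scaffolds
  with no breakpoint at all.
* `run_tree_ranking_experiment()` — the generating tree's competition
  rank among all 945 topologies (defaults m = 60, k = 3; 3 was chosen
  as the headline "small number of rearrangements per branch", and the
  runner exposes k for sweeps).
* `run_cant_tell_experiment()` — ranking accuracy after masking `c`
  genomes per scaffold as can't tell, matched-seed against the clean
  run.

Ground truth for recovery statements attributes an event to the
scaffolds containing an adjacency it destroyed *or created*: an event
off the designated lineage is visible in the designated genome through
the former, an event on the designated lineage only through the latter.
A true event counts as *located* when its scaffold's candidate edge set
on the true tree contains the branch it occurred on.

## Numerical and design choices

* Inversion boundaries are 0-based inter-gene positions in `[0, n]`;
  the inverted segment is the half-open gene range `(cut_left,
  cut_right]`.  Adjacent cuts give single-gene inversions (a pure
  orientation flip), which still disrupt two adjacencies.
* The DP uses a large finite penalty (1e9) rather than `Inf` for
  forbidden leaf states; with at most a dozen vertices the accumulated
  penalties stay far from overflow and comparisons stay exact, since
  all genuine costs are small integers.
* Degenerate inputs: an all-2 or all-3 pattern costs 0 events; a fully
  masked label matrix ties every topology at rank 1 — the ranking is
  then deliberately uninformative rather than erroneous.
* Topology identity is decided by the sorted set of edge bipartitions,
  each written from the side not containing the smallest leaf label;
  this key is invariant to vertex numbering, edge order and stored
  rooting, and certifies that the 945-tree enumeration is
  duplicate-free.
* Test problem sizes: the DP is checked against brute-force
  minimisation exhaustively for all trees and all `3^N` label patterns
  at `N = 4` and `5`, and on seeded random tree/pattern samples at
  `N = 6` and `7`; the headline experiments run at the study scale (100
  replicates for the rate curve, 30 for the 945-tree ranking).

## Limitations

Everything downstream of the labels assumes the labels are right.  On
real data, deciding "split / not split / can't tell" requires syntenic
blocks, orthology calls and a formal can't-tell criterion, none of
which this package attempts; its can't-tell handling is the injected,
label-level kind.  The model is unichromosomal and inversion-only, and
only one genome may be fragmented.  Scoring trees by total events is a
parsimony criterion: like all parsimony methods it can be misled when
many events stack on few branches.
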