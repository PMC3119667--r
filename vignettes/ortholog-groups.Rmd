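---
title: "Inferring one-to-one ortholog groups across multiple genomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring one-to-one ortholog groups across multiple genomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(multiortho)
```

## The problem

Orthologs are genes in different genomes that descend from one ancestral
gene through speciation alone. When several genomes are compared, repeated
gene duplication interleaves with speciation, and the useful unit becomes
the *ortholog group*: a maximal set of genes, at most one per genome, that
are direct descendants of a single ancestral gene and are never separated
by a duplication. Lineage-specific duplicates (inparalogs) do not belong to
the group of their source gene; they start groups of their own. This
one-to-one reading is stricter than the many-to-many orthology of tree
databases, but it validates cleanly and refines the many-to-many relation.

`multiortho` infers such groups for N genomes given, per genome, an ordered
gene list with sequences, plus a rooted binary species tree. It also
reports the gene births, duplications and losses implied by its
reconstruction, and ships a genome-evolution simulator with tracked ground
truth so the whole pipeline can be exercised closed-loop.

## Pipeline

1. **Similarity graph.** All-vs-all scoring of gene sequences
   (`score_all_pairs()`), or a user-supplied table of e.g. BLASTp bit
   scores (`read_similarity()`).
2. **Gene families.** Markov clustering of the similarity graph
   (`mcl_cluster()`): alternate expansion (matrix squaring) and inflation
   (elementwise power, column renormalization) of the column-stochastic
   transition matrix until convergence; clusters are read off the limit
   matrix's attractors. A family is the unit everything downstream
   partitions.
3. **Pairwise orthologs.** One-to-one ortholog pairs for every genome
   pair. On real data this input should come from a dedicated
   rearrangement-aware pairwise assigner and be dropped in as files
   (`read_pairwise_orthologs()`); for simulated data the package provides
   a bidirectional-best-hit stand-in within families (`bbh_orthologs()`),
   completed greedily by descending score to approximate one-to-one
   coverage. This stage is deliberately pluggable — see *Limitations*.
4. **Super ortholog groups (SOGs).** Each family is split into SOGs — at
   most one gene per genome — by heuristic maximum-weight multipartite
   matching (`partition_family()`): one stage of vertices per genome,
   dummy-padded to equal size; edges only between assigned ortholog pairs,
   weighted by their similarity score; stages merged pairwise with the
   Hungarian algorithm (`hungarian_max()`) following a post-order traversal
   of the species tree, so stages are always combined with phylogenetically
   close stages.
5. **TOG labeling.** Every SOG becomes a *tree of ortholog groups* (TOG):
   the species tree with leaf label 1 where the SOG has a gene. Internal
   nodes are labeled 0/1 (ancestral absence/presence) by minimizing the
   total number of *flips* — edges whose ends differ, each one a birth,
   duplication or loss — jointly over the family's K TOGs
   (`solve_labeling()`), subject to two biological constraints:
   * *intratree*: within a TOG, a gene lost below a presence node is never
     regained (no 0 with a 1-ancestor may have a 1-descendant);
   * *intertree*: a family is born only once, so nodes labeled 1 in at
     least one TOG must form a connected region of the species tree.
6. **Groups and events.** In each labeled TOG, every highest 1-node
   (a 1 whose parent is 0, or the root) anchors a group: the SOG genes at
   1-leaves below it; single-gene groups are discarded as inparalog-only
   (`extract_groups()`). Each 1→0 edge is a loss; each 0→1 edge is a birth
   if the parent is 0 in every other TOG of the family, else a duplication
   (`classify_events()`).

## The labeling problem and its three solvers

Minimum-flip labeling under the two constraints is the computational core.
Flips are counted over all K TOGs; the intertree constraint couples them,
which is what makes the problem hard — without it each TOG could be solved
independently by dynamic programming.

Two observations prune the search. If both children of a node are labeled
1 in a TOG, every optimal labeling labels the parent 1 (relabeling 0→1
removes two flips and adds at most one). Symmetrically, if both children
are 0, some optimal labeling has the parent 0 — a parent 1 over two 0s is
only ever forced by the intertree constraint. Returned labelings are
checked against both properties in the test suite.

* `label_exhaustive()` enumerates, per TOG, all intratree-feasible
  completions of the fixed leaf labels, then all combinations across TOGs,
  filtering on connectivity of the union 1-set. It is the reference oracle
  and is guarded to `K*(N-1) <= 24` label bits.
* `label_node_centric()` runs one post-order dynamic program over label
  *vectors*: each node carries one of three per-TOG states — 1, plain 0
  (whole subtree absent), or "0-pending" (0 here, but a 1 somewhere below).
  Per TOG only three parent/child state patterns are legal, and union
  connectivity becomes a local rule: a node with some 1-state may not have
  a child whose subtree holds detached presence, and a node with no
  1-state may have presence under at most one child. A pre-order backtrace
  recovers one optimum; pending states finalize to 0.
* `label_tree_centric()` processes TOGs sequentially, maintaining for
  every reachable *union TOG* (Boolean OR of labelings chosen so far) the
  minimum accumulated flips; the answer is the cheapest final union whose
  1-set is connected. It is insensitive to K and guarded to species trees
  of at most 20 nodes.

`solve_labeling(strategy = "auto")` uses the node-centric program when
`K <= N` and the tree-centric one otherwise; both always return the same
optimal flip count (property-tested against the exhaustive oracle on
hundreds of random instances). Where several optima exist the returned
labeling is a deterministic representative (ties prefer 0 at the root,
then lexicographically smallest label vectors); co-optimal labelings are
not enumerated.

Connectivity of the union 1-set is equivalent to the pathwise statement of
the intertree constraint ("every node on a path between two presence nodes
is present somewhere") because paths in a tree are unique; connectivity of
a vertex set S is checked as `|S| - |edges within S| == 1`.

## Tunable parameters

| Parameter | Where | Default | Meaning |
|---|---|---|---|
| `min_score` | `score_all_pairs()` | 50 | minimum similarity (score units of `2*matches - mismatches`) for a graph edge; 0 keeps everything with >1/3 ungapped identity |
| `inflation` | `mcl_cluster()` | 2 | Markov-clustering inflation; higher splits families more aggressively |
| `tol`, `max_iter` | `mcl_cluster()` | 1e-6, 100 | convergence of the expansion/inflation iteration |
| `strategy` | `solve_labeling()` | `auto` | labeling solver; `auto` crosses from node- to tree-centric at `K > N` |
| `n_species` | `sim_params()` | 5 | simulated genomes |
| `events_per_branch` | `sim_params()` | 20 | genome-level events per speciation branch |
| `mutation_branch_length` | `sim_params()` | 0.02 | expected substitutions/site per branch |
| `p_dup`, `p_birth`, `p_loss` | `sim_params()` | 0.4 / 0.2 / 0.2 | event mix; the remainder (0.2) are reversals |
| `tandem_fraction` | `sim_params()` | 0.5 | duplications inserted adjacent to the source |
| `root_genes`, `gene_length_nt` | `sim_params()` | 100, 3000 | root genome size and gene length |

MCL self-loops are set to each vertex's maximum incident weight and the
missing-edge weight in the multipartite graph is 0 — neutral under
maximization, letting dummy vertices absorb unmatched genes. Hungarian and
best-hit ties break deterministically (lowest index / lexicographic gene
id), so identical inputs and seeds give byte-identical outputs.

## What the simulator emulates — and what it does not

`evolve()` grows a root genome of `root_genes` random coding-like genes
(uniform non-stop codons) down a uniformly attached random rooted binary
tree. Each branch carries `events_per_branch` events drawn from the event
mix — duplication (tandem or random insertion), birth (fresh random gene),
loss (random deletion), reversal (random segment inverted with strands
flipped) — interleaved with `events_per_branch + 1` equal epochs of
Jukes-Cantor substitution summing to `mutation_branch_length` per branch
(a molecular clock; the even split is the package's choice). Lineage ids
implement the group definition directly: speciation copies ids, a
duplication gives the *new copy* a fresh id, a birth starts one; truth
groups are lineages with at least two leaf genes.

Real data differ in ways the simulator does not model: multiple
chromosomes and inter-chromosomal rearrangement (single chromosome only,
so reversals are the only rearrangement), codon-level selection and rate
heterogeneity (substitution is uniform Jukes-Cantor on nucleotides),
gene-length variation and partial homology (all genes share one length, so
scoring reduces to ungapped identity), and annotation noise. Passing
closed-loop tests therefore demonstrates algorithmic correctness of the
pipeline on content evolution, not robustness to real-genome artifacts.

## Numerical and degenerate-input choices

* Gene positions are 0-based ranks per chromosome; only relative order
  matters anywhere, so input coordinates may be sparse.
* The species tree must arrive rooted and strictly binary; there is no
  midpoint-rooting fallback because both labeling programs assume the
  rooted binary scaffold. Non-binary nodes and duplicate leaves are
  rejected at parse time.
* An all-zero TOG cannot arise (a SOG has at least one gene) and is
  rejected defensively; with at least one 1-leaf per TOG a feasible
  labeling always exists (label everything 1), so the solvers never report
  infeasibility on pipeline inputs.
* A gene loss drawn on an empty genome is skipped with a warning; a
  reversal needs at least two genes.
* MCL iterations prune entries below 1e-12 and detect attractors at 1e-6;
  non-convergence returns the current partition with a warning.
* Ortholog pairs that span two families (possible when an external
  pairwise tool disagrees with the clustering) are dropped with a warning;
  families are the partition unit.

## Limitations

The important one is the pairwise stage. The multipartite matching can
only choose among the pairs the pairwise stage proposes, and a
sequence-only bidirectional best hit carries no information about *which*
of two recent within-genome paralogs is the direct descendant: a copy
duplicated after a speciation is, in expectation, exactly as similar to
every ortholog as the original is (their histories are shared up to the
duplication), so the best-hit choice degenerates to a coin flip decided by
correlated mutation noise. Positional context — gene order and
rearrangement distance — is what breaks the tie, and that is precisely
what dedicated pairwise assigners contribute. The package's closed-loop
tests quantify both sides at the default simulation conditions: with
true-lineage pairs substituted for the stand-in, exact-match sensitivity
and specificity exceed 0.9; with the BBH stand-in they sit near 0.7, and
the acceptance script reports the honest stand-in figure. Runs on real
data should always feed `read_pairwise_orthologs()` with output from an
accurate pairwise tool rather than rely on the stand-in.

Other limitations: the multipartite matching is a sequential-merge
heuristic (exact for singleton stages; near-optimal on average — the test
suite guards the mean, not each instance — but single instances can fall
below 90% of the optimum); parsimony labelings need not be unique, and the
reported events are those of one deterministic optimum; losses are
tree-edge properties and are not attributed to specific gene copies;
event accuracy is scored at (branch, kind) granularity because an inferred
loss carries no gene id.

## Scales used by the shipped checks

The test suite solves labeling instances with N in 3..6 and K in 1..3
against the exhaustive oracle (hundreds of random instances), checks the
Hungarian solver against permutation enumeration up to 7x7, and runs the
closed-loop pipeline at the default conditions above; the acceptance
script averages 10 replicate simulations at those defaults. These sizes
keep a full run in minutes on one core while covering every code path.
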