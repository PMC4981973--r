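---
title: "Synteny-based orthology for concertedly evolving gene families"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Synteny-based orthology for concertedly evolving gene families}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trnaOrtho)
```

## The problem

Transfer RNAs are multicopy genes evolving under *concerted evolution*:
ectopic gene conversion keeps paralogous copies within a species nearly
identical over long evolutionary times.  Sequence divergence therefore
carries essentially no information about which copies in two species are
orthologs (descendants of one locus through speciation) and which are
paralogs (products of duplications).  Reciprocal-best-hit and
gene-tree/species-tree reconciliation methods all assume that divergence
time is readable from sequence distance, and all of them fail here.

What does survive concerted evolution is *synteny*: the relative order of
loci along the chromosome, read against flanking "anchor" elements — unique,
1:1-orthologous sequence intervals such as cleaned genome-alignment blocks
or orthologous protein-coding genes.  `trnaOrtho` turns that observation
into a stepwise refinement of a homology graph over annotated tRNA loci:

1. **Tight anchors.**  For a query gene and a target species, the *tight
   anchor pair* is the nearest pair of anchors flanking the gene that are
   both placed in the target.  Under the working assumptions (every gene has
   anchors on both sides; between nearby anchors the gene order evolves only
   by single-gene tandem duplications, gains and losses), the true orthologs
   of the gene must lie between the tight anchors' placements in the target.
2. **Candidate graph.**  Vertices are all annotated genes; a cross-species
   edge is drawn when each gene lies between the other's tight anchors.
   Genes sharing a flanking anchor interval form a *synteny cluster*
   (clusters are connected across species through candidate edges, so the
   construction also works when anchors carry species-pair-specific
   identities, as protein-pair anchors do).  The true orthology relation is
   a subgraph of this candidate graph.
3. **Distance pruning.**  Edges joining clearly different sequences —
   normalized distance at or above 10&nbsp;% of the sequence length — are
   removed.  The threshold is an upper bound on within-family divergence
   over the phylogenetic range of interest; it is deliberately generous so
   that anticodon mutations (three positions out of ~73, about 4&nbsp;%) do
   not disconnect remolded genes from their relatives.
4. **Duplication-aware list alignment.**  Within each cluster the ordered
   gene lists of every species pair are aligned by a modified
   Needleman–Wunsch recursion whose column repertoire includes 1:q and q:1
   duplication columns.  Superimposing all pairwise alignments — each
   duplication column contributing its complete bipartite edge set — yields
   the estimated orthology graph, a spanning subgraph of the pruned graph
   whose components are order-preserving.
5. **Cograph editing and cotrees.**  A valid orthology relation is a
   cograph (no induced path on four vertices).  Each connected component is
   edited to the nearest cograph and converted to its canonical cotree;
   series nodes are speciations, parallel nodes duplications, and each
   parallel node with *c* children records *c − 1* duplication events.
6. **Dollo event mapping.**  Each co-ortholog group is gained once on the
   branch above the last common ancestor of its species and lost on the
   minimal branch set pruning the absent species.  Duplications read off the
   cotree are assigned to the gain branch.  Anticodon changes within
   sequence-similar groups are reconstructed by parsimony and classified as
   isoacceptor (same amino acid) or alloacceptor (different amino acid)
   remoldings.

## Parameters that matter

| parameter | default | role |
|---|---|---|
| `threshold_fraction` | 0.10 | distance pruning and similarity grouping; fraction of sequence length |
| `metric` | `"edit"` | normalized edit distance; `"hamming"` available for equal lengths |
| `match_cost` | 20 | column cost of matching two similar genes |
| `gap_cost` | 25 | cost of leaving a gene unmatched |
| `dup_penalty` | 3 | extra cost per additional copy in a duplication column |
| `q_max` | 2 | largest 1:q duplication column |
| `exact_cograph_bound` | 10 | largest component edited by exact search |
| `k_proteins` | 10 | anchors considered per gene in the interpolation route |

The gap cost and duplication penalty are constrained jointly: a match must
beat two gaps (`match_cost < 2 * gap_cost`), and a duplication column over
similar genes must beat a match plus a gap
(`2 * match_cost + dup_penalty < match_cost + gap_cost`).  The second
constraint is what lets tandem duplications be recognized at all; its flip
side is discussed under limitations.  With the infinite cost for dissimilar
pairs, the alignment outcome is robust to the exact values — scoring is
dominated by which pairs are allowed to match.

`scoring_params()` and `distance_params()` validate these invariants;
`pipeline_config()` collects them with the cluster-joining switch, the
inversion-tolerant candidate-edge rule (off by default; orientation-
inconsistent anchor pairs are otherwise dropped per species pair), the
optional lineage-exception species pairs for Dollo gains, and the cograph
bounds.

## Coordinates and degenerate inputs

All coordinates are 0-based half-open forward-strand intervals internally;
the MAF, chain, BED and tRNAscan-SE readers convert at parse time
(tRNAscan's 1-based inclusive coordinates with strand implied by coordinate
order, MAF's reverse-strand offsets, chain files' strand-specific query
coordinates).  Linear interpolation between anchor points uses the offset
form: the gene's offset from the left anchor point is scaled by the ratio of
inter-anchor span lengths, which reproduces the identity map when the two
genomes agree and is exact up to rounding under any affine coordinate map.
A non-positive inter-anchor span is a hard error (corrupt anchors).  Genes
with a missing flank or with tight anchors on different target chromosomes
are flagged (`missing` / `split`), excluded from cluster edges, and carried
through as singletons so that event accounting still sees them.

Deterministic tie-breaks are fixed throughout: alignment traceback prefers
match over duplication-in-a over duplication-in-b over gaps; nearest-gene
selection in the interpolation route prefers the gene 5' of the estimated
position; cograph editing prefers edit sets with more insertions (missing
edges typically stem from pseudogenized pairs just past the distance
threshold), then lexicographic order; remolding parsimony breaks root-state
ties toward the more frequent, then lexicographically smaller anticodon and
flags the event ambiguous.

Cograph editing is NP-hard in general; components up to 10 vertices are
solved exactly by branch-and-bound over induced P4s (collecting all optima
at the minimal edit size), larger ones up to 40 fall back to greedy P4
destruction and are flagged non-optimal.  Observed deviations from cograph
structure are tiny in practice — most components are cliques — so the exact
bound is rarely binding.  Insertions between same-species genes are never
proposed: they could not be part of a valid orthology relation.

## What the simulator emulates

`simulate_evolution()` grows gene clusters along a species tree under
single-gene tandem duplication, loss, seeding of new loci, anticodon
remolding, pseudogenization and (optionally) anchor loss, with rates per
gene (or per genome, for seeding and anchor loss) per unit branch length.
Concerted evolution is modelled phenomenologically: every gene copy is
emitted from a per-species family consensus with small per-site noise
(default 0.5&nbsp;%), while the consensus itself drifts at 1&nbsp;% per site
per unit length.  This reproduces the one property the pipeline depends on —
within-species paralogs are nearly identical, families are well separated —
without simulating gene-conversion mechanics.  Coordinates are laid out by
concatenating elements with fixed spacers, so coordinate maps between
species are exactly affine between consecutive shared anchors.

Ground truth contains the gene genealogy, the raw event log, the simulated
remolding list and the *true orthology relation*: two extant genes of
different species are co-orthologs exactly when every duplication separating
their lineages postdates the speciation at their species' last common
ancestor.  The true per-branch event table is produced by applying the same
Dollo/cotree accounting to the true relation, so that
`score_reconstruction()` isolates graph-reconstruction fidelity from
accounting conventions; the raw log is available separately.

The simulator does **not** emulate genome rearrangements, multi-gene
duplications, realistic substitution models, gene conversion between
families, or assembly artifacts.  Passing the end-to-end tests therefore
shows that the pipeline recovers histories generated under its own working
assumptions; on real genomes, alignment coverage, spurious anchors from
unfiltered paralogy, and rearrangements will all erode the synteny map in
ways the simulation deliberately excludes.

## Validation sizes

The shipped test-suite problem sizes are the package's validation choices:
alignment optimality against exhaustive enumeration on 200 random list
pairs of lengths up to six; cograph-edit minimality against subset
enumeration on 200 random graphs (Erdős–Rényi up to six vertices, plus
perturbed random cographs up to eight — keeping the plain subset oracle
exact and fast); 500 cograph/cotree round trips; 500 Dollo placements
against brute force on ten-leaf trees; the full 61 × 61 sense-anticodon
grid against an independent genetic-code table; and 20 end-to-end simulator
replicates on the bundled six-species tree (~250 genes each, low rates,
intact anchors) scored as pooled edge precision/recall/F1, per-branch event
errors and remolding recovery.

## Known limitations

* **Surviving-copy blindness.**  When one copy of a multicopy family is
  lost in some species, the list alignment prefers a 1:q duplication column
  over match-plus-gap for the surviving copy (that preference is exactly
  what detects real duplications), merging paralog groups and inflating the
  duplication count at the component's ancestral branch by up to the family
  size.  Sequence cannot disambiguate this under concerted evolution; it is
  a property of the method, visible in simulation as occasional per-branch
  duplication errors of 2 while edge F1 stays above 0.99.
* 1:q columns are bounded by `q_max` (default 2); longer tandem runs
  created in one step are split into duplication plus gap columns.
* The interpolation route finds 1:1 orthologs only, by construction.
* Remolding direction is undecidable when parsimony leaves a tie at the
  root of a group's gene tree; events are then reported with the
  lexicographic convention and an ambiguity flag, and recovery is assessed
  on unordered anticodon pairs.
* Event placement inherits Dollo parsimony's bias: losses above the last
  common ancestor of the surviving species are invisible, and joined
  clusters shift events toward older branches (reconstructing larger
  ancestral clusters implies more subsequent deletions) — the reason the
  cluster-joining switch is off by default.
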