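---
title: "Tree-based homology refinement and orthology inference with orthoprune"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tree-based homology refinement and orthology inference with orthoprune}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orthoprune)
```

## The problem

Phylogenomic data sets built from transcriptomes and low-coverage genomes
are incomplete and noisy: assemblies carry isoforms of the same gene,
chimeric or frameshifted contigs, and partial sequences. Similarity-based
orthology heuristics (reciprocal best hits and their descendants) assume
complete, error-free gene complements and break down on such data.
`orthoprune` implements a two-stage, tree-based alternative: first infer
*homologs* (gene families) from filtered all-by-all similarity searches
plus Markov clustering, clean the homolog trees of artifacts, and only
then separate *orthologs* from paralogs using the tree topology itself.
No species tree is assumed — these data sets are usually built precisely
to estimate one.

External tools are deliberately out of scope: BLAST, MCL, aligners and
tree builders are run by the user, and the package reads and writes
their standard formats (tabular hits, `abc` edge lists and cluster
lines, FASTA, newick). Every stage is independently invokable, as a
function or via the `inst/cli/orthoprune.R` subcommand script.

## Homology: filtering, clustering, cleaning

**Hit filtering.** A similarity hit is kept when its *hit fraction* — the
covered proportion of the sequences, after merging HSP intervals by union
— reaches `min_fraction` (default 0.4) and its E value is at most
`evalue_cutoff` (default `1e-5`). "Coverage of either sequence" is
ambiguous in the field's usage; the default `"min"` mode demands that
*both* sequences reach the threshold, the stricter reading, because
one-sided coverage is what lets conserved domains snowball gigantic
clusters. `--hit-frac-mode max` flips this. Edge weights for MCL are
`-log10(E)` capped at 180, the floor at which BLAST reports E = 0.

**Cluster hygiene.** Sequence ends never covered by any retained hit are
presumed misassembly or frameshift and are cut off (interior uncovered
stretches are kept — they are spanned by real alignments). Filters apply
in the order end-trim, then the 40-residue length filter, then the
eight-taxon cluster filter, because trimming can push a sequence under
the length minimum.

**Tree cleaning** (`refine_homolog()`) runs three passes on each homolog
tree, in this order:

1. `trim_spurious_tips()`: a tip is deleted when its pendant branch is
   *both* longer than `tip_relative_factor` (default 10) times the mean
   distance from its attachment node to the tips of its sister clade
   *and* longer than `tip_absolute_cutoff`. The sister-clade mean
   includes the sibling edge — the suspect branch is judged against the
   local depth of the tree, measured from the point where it attaches;
   at a basal trifurcation the co-child subtrees are pooled. Tips are
   processed worst-first and all statistics recomputed after each
   removal, to a fixpoint.
2. `mask_redundant_tips()`: monophyletic *and* paraphyletic same-taxon
   tips (isoforms) are collapsed to the single member with the most
   unambiguous characters in the trimmed alignment — keeping the
   longest-aligned isoform maximises retained signal, whereas a random
   isoform may carry misassembled stretches and the shortest-branch one
   is often just the most incomplete. The collapse is pairwise and
   iterated: same-taxon tips sharing a parent, or a tip and a same-taxon
   tip child of its grandparent, are reduced to the better member until
   no such pair remains. At the fixpoint no tip's sister subtree
   consists entirely of its own taxon.
3. `cut_long_internal_branches()`: internal edges longer than
   `internal_branch_cutoff` separate deep paralogs whose divergence
   predates the radiation under study; each cut component becomes its
   own homolog. Cutting is re-applied after unifurcation suppression, so
   merged edges are re-checked and no surviving subtree contains an
   over-cutoff internal edge. Components with fewer than
   `min_subtree_taxa` (default 8) distinct taxa are dropped.

**Units and published values.** All cutoffs are in expected
substitutions per site. The per-dataset values used in the three
published reanalyses ship as `dataset_preset("HYM" | "GRP" | "MIL")`:
internal-branch cutoffs 1.0 / 0.3 / 1.5, absolute tip cutoffs 0.6 / 0.1
/ 0.75 (0.3 / 0.1 / 0.4 at the MI stage), occupancy cleaning 0.1 for
homologs and 0.3 for ortholog alignments, locus minima of 100 aa or 300
nt, and a 200-replicate jackknife at 10%, 30% or 20 loci. These values
were calibrated by their authors against the empirical branch-length
distributions of each data set; that calibration-to-scale procedure is
the method, and the package defaults (`internal_branch_cutoff = 1`,
`tip_absolute_cutoff = 0.05`) are likewise calibrated to the simulator's
unit-depth trees rather than copied from any one data set.

**Degenerate inputs.** Missing branch lengths are a distinct state, never
silently zero; cutoff comparisons treat them as zero with a warning.
Trees reduced below three tips by trimming are returned with a warning;
masking that would leave fewer than two tips yields `NULL` and the
homolog is dropped. A newick whose root has two children is taken as
rooted, three or more as unrooted, matching ML-tree output conventions.

## Orthology: four extraction strategies

Let a *taxon duplication* be two tips of the same taxon in one tree —
the signature of paralogy (or unmasked isoforms).

* **MI (maximum inclusion)**, `prune_mi()`: repeatedly cut out the
  edge-delimited subtree with the most distinct taxa and no taxon
  duplication (both orientations of every edge are candidates, so
  rooting is irrelevant), trim leftover spurious tips from the
  remainder with the MI-stage cutoffs, and repeat while a
  duplication-free subtree with `min_taxa` taxa exists. Needs no
  outgroup, but fragments orthologs under genome duplication.
* **RT (rooted ingroup clades)**, `extract_rooted_ingroup_clades()` +
  `prune_paralogs_rt()`: user-declared outgroups orient the tree; the
  largest clades containing only ingroup taxa are cut out as rooted
  trees, then traversed root-to-tip. Wherever the two sides of a node
  share a taxon, a gene duplication is inferred and the side with fewer
  distinct taxa is pruned (maximising matrix occupancy — deliberately
  not a reconciliation-distance criterion, which would import noise
  from a reference homolog). Pruned sides re-enter the pool and are
  decomposed the same way (`reprocess = TRUE`; the alternative reading,
  discarding them, is a switch). Outgroups are absent from RT
  orthologs. Homologs without outgroup tips are kept only if
  duplication-free; with duplications but no outgroup they are skipped
  — without a root the duplication locations are unknowable.
* **MO (monophyletic outgroup)**, `prune_paralogs_mo()`: only homologs
  whose outgroup tips are non-repeating and monophyletic (some edge
  separates them from every ingroup tip) are used; the tree is rooted on
  that edge and pruned as in RT but keeping only the larger side at each
  duplication, so exactly one ortholog — including the full outgroup
  clade — survives per homolog.
* **1to1**, `filter_1to1()`: homologs already free of taxon duplication,
  the tree-based analogue of strict reciprocal criteria. Useful as a
  conservative baseline; discards most of the signal in duplicated
  families.

On a duplication-free homolog with a monophyletic, non-repeating
outgroup all four agree on the ingroup (RT alone strips the outgroup
tips).

**Determinism.** Every tie — between candidate subtrees, between sides
at a duplication, between isoform representatives — is broken by the
same ladder: more distinct taxa, more tips, more total unambiguous
characters, then the lexicographically smallest sorted tip-identifier
tuple, compared byte-wise so results do not depend on the locale.
Polytomies are handled by comparing all child pairs and pruning one
child at a time.

**Ingroup-clade enumeration.** RT extraction enumerates clades of the
stored rooted structure rather than both orientations of every edge:
with complements included, a maximal "subtree" of ingroup tips would
often be the complement of a single outgroup pendant — a set spanning
the root that mixes every duplication in the homolog and defeats the
purpose of extracting oriented clades.

## Supermatrix assembly and conflict evaluation

Per-ortholog alignments are pulled from their homolog alignment rows
(`extract_ortholog_alignment()`), relabelled by taxon, cleaned of
all-gap columns, and trimmed by column occupancy
(`trim_columns_by_occupancy()`, the `-clean` convention: a column
survives when the fraction of cells that are not `-` and not `?` reaches
the threshold; ambiguity codes count as occupied). Loci passing the
length and missing-taxon filters are concatenated in lexicographic
locus-id order — an arbitrary but reproducible convention — with absent
taxon blocks gap-filled, and exported as FASTA or relaxed PHYLIP with a
RAxML-style partition file (`WAG` for amino acids, `DNA` for
nucleotides, per locus; tree inference itself is external).

Conflict among loci is evaluated by a jackknife that keeps each locus
intact (`jackknife_by_locus()`): 200 replicates drawing a fixed
proportion (rounded half-up, at least one locus) or a fixed count of
loci without replacement. Resampling whole loci, never columns, is what
makes the support values interpretable as among-locus conflict.
`bipartition_support()` annotates a reference topology with the
percentage of replicate trees containing each internal edge's unordered
bipartition (counted by `ape::prop.clades` on the shared taxon set).

## What the simulator emulates — and what it does not

`sim_config()` / `emit_fixture_set()` generate gene families with known
ground truth so that every stage is testable without downloads:

* **Species trees**: pure-birth (Yule) topologies rescaled to unit
  root-to-tip depth — the tree *shape* is irrelevant to the algorithms
  under test, and ultrametric trees make the tip-trimming rule exactly
  discriminating (every true pendant equals its sister-clade mean, so
  the 10× relative test can never fire on a true tip). Optionally the
  first `n_outgroup` taxa form a basal grade, the arrangement
  outgroup-based inference assumes. The ingroup radiation then spans
  60% of the depth.
* **Gene families**: birth–death of gene lineages along the species
  tree (defaults: duplication 0.2, loss 0.1 per unit branch length —
  rates that leave most families single-copy while exercising the
  duplication machinery). Internal nodes are labelled `S`/`D`, and each
  tip carries a signature of the duplications on its path, so
  ground-truth orthology of any tip pair is the label of their MRCA.
* **Artifacts**: with probability 0.1 a tip gains an isoform — a
  same-taxon sister at near-zero branch length with strictly fewer
  unambiguous characters than its template; with probability 0.04 (the
  chimera rate reported for de novo Trinity assemblies) a tip's pendant
  branch is multiplied by 20. At most one artifact per tip.
* **Sequences** are placeholders: random residues at a configured
  ambiguity fraction (default 0.05). Only lengths and
  unambiguous-character counts reach the algorithms; no substitution
  process is simulated, which is exactly why the package never computes
  alignments or trees itself.
* **Pseudo-BLAST hits** cover each within-family pair in full, with E
  values decaying deterministically with patristic distance, so the
  intended clusters survive `filter_hits()` defaults and the whole CLI
  chain runs on fixture output alone.

Passing recovery tests on these fixtures therefore shows that the
*algorithms* do what their definitions say on trees with known events;
it does not show robustness to alignment error, rate heterogeneity
(non-ultrametric trees can defeat the relative tip test in both
directions), model misspecification in the input gene trees, or
contamination. Two blind spots of the published trimming rule are
reproduced faithfully rather than patched: a pair of misassembled
sister tips inflate each other's sister-clade mean and escape the
relative test, and a misassembled tip whose original pendant is shorter
than `tip_absolute_cutoff / multiplier` stays under the absolute
cutoff. Both are visible as the few percent of injected misassemblies
the validation deliberately reports as missed.

## Validation problem sizes

The shipped test-suite experiments use: 500 random trees of up to 12
tips against a brute-force maximum-inclusion oracle; 200 simulated
families per recovery experiment (four-method agreement, paralog-mixing
containment for RT/MO on loss-free duplications, artifact recovery at
default cutoffs with the false-removal check at five times the
simulated branch scale); 100 random locus sets for supermatrix
invariants; and a 200-replicate jackknife over 50 loci. The same
quantities are recomputed from scratch, at any seed, by
`scripts/acceptance.R`.

```{r, eval = FALSE}
# the whole pipeline on a synthetic fixture set
fx <- emit_fixture_set(sim_config(n_taxa = 10, n_families = 6, seed = 5),
                       "fixtures")
res <- run_pipeline(
  out_dir = "run",
  blast = "fixtures/blast_hits.tsv",
  sequences = "fixtures/all.fa",
  mcl_clusters = "fixtures/mcl_clusters.txt",
  trees_dir = "fixtures/trees",
  alignments_dir = "fixtures/alignments",
  method = "MI", outgroups = "T1", min_taxa = 4,
  jackknife = list(mode = "proportion", value = 0.1, replicates = 200,
                   seed = 1))
res$report
```

## Known limitations

* No realignment after cutting: the published procedure realigns and
  re-estimates trees after deep-paralog cutting; here those steps are
  external, so `refine_homolog()` output should be realigned by the
  user before final tree inference.
* `prune_mi()` enumerates all edge-delimited subtrees each iteration;
  fine into the hundreds of tips, but not written for the
  thousands-of-tips clusters that motivate coarse MCL settings.
* Support values summarise bipartition presence only; branch lengths
  and rate variation in replicates are ignored.
* NEXUS, alignment computation and tree inference are out of scope by
  design.
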