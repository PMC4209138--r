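# orthoprune

Tree-based homology refinement and orthology inference for phylogenomic
data sets built from transcriptomes and low-coverage genomes.

Such data are incomplete and carry isoforms, chimeric contigs and
frameshifts, which break the assumptions of similarity-based orthology
heuristics (reciprocal best hits, core-ortholog mapping). `orthoprune`
instead uses gene trees at both stages, without assuming a species tree:

1. **Homology** — filter all-by-all similarity hits by *hit fraction*
   (covered fraction of both sequences ≥ 0.4) and E value (≤ 1e-5),
   prepare MCL input with edge weights `-log10 E` capped at 180, parse
   MCL clusters through length (≥ 40 residues) and taxon-count (≥ 8)
   filters, then clean each homolog tree: cut internal branches longer
   than a per-dataset cutoff (deep paralogs), delete tips more than 10×
   longer than the mean distance to their sister clade's tips *and*
   longer than an absolute cutoff (misassemblies), and collapse
   monophyletic or paraphyletic same-taxon tips to the isoform with the
   most unambiguous aligned characters.
2. **Orthology** — extract ortholog trees by four strategies:
   * **MI** (maximum inclusion): iteratively cut the subtree with the
     most distinct taxa and no taxon duplication; no outgroup needed.
   * **RT**: extract the largest ingroup-only clades as rooted trees
     using declared outgroups, then prune root-to-tip at every node
     whose two sides share a taxon (a gene duplication), keeping the
     side with more taxa; pruned sides are decomposed in turn.
   * **MO**: as RT, but only for homologs whose outgroups are
     monophyletic and non-repeating; the tree is rooted on that edge
     and one ortholog per homolog survives, outgroups included.
   * **1to1**: homolog trees already free of taxon duplication.
3. **Supermatrix** — per-ortholog alignments extracted from homolog
   alignments, occupancy-trimmed (`-clean` convention), filtered by
   length and missing taxa, concatenated with RAxML-style per-locus
   partitions, plus locus-intact jackknife resampling (200 replicates
   at 10%/30%/20 loci) and bipartition-support annotation.

A simulator (`sim_config()`, `emit_fixture_set()`) generates gene
families with known duplication/loss histories, isoform and misassembly
artifacts, and ground-truth event labels, so the whole pipeline is
testable offline. External tools (BLAST, MCL, MAFFT, RAxML) are never
executed: the package reads and writes their formats and prints the
command expected next.

## Worked example

Pruning a homolog with a deep duplication of taxa A and B (taxa are the
`@`-prefix of each sequence id):

```r
library(orthoprune)
tr <- read_newick("((A@1:.1,B@1:.1):.1,(A@2:.1,(B@2:.1,C@1:.1):.1):.1,D@1:.1);")
orths <- prune_mi(tr, min_taxa = 2,
                  refine_config(tip_absolute_cutoff = 0.3, min_subtree_taxa = 2))
for (o in orths) cat(write_newick(o), "\n")
#> ((A@2:0.1,(B@2:0.1,C@1:0.1):0.1):0.1,D@1:0.1);
#> (A@1:0.1,B@1:0.1);
```

MI first cuts the duplication-free subtree with the most taxa
({A@2, B@2, C@1, D@1}), then the remaining {A@1, B@1} — two orthologs,
no taxon repeated in either.

The full pipeline on a simulated fixture set (8 families, 10 taxa,
duplication rate 0.3, outgroup T1):

```r
fx <- emit_fixture_set(sim_config(n_taxa = 10, n_families = 8,
                                  dup_rate = 0.3, loss_rate = 0, seed = 5),
                       "fixtures")
write_fasta(unlist(unname(fx$alignments)), "fixtures/all.fa")
res <- run_pipeline(
  out_dir = "run",
  blast = "fixtures/blast_hits.tsv",
  sequences = "fixtures/all.fa",
  mcl_clusters = "fixtures/mcl_clusters.txt",
  trees_dir = "fixtures/trees",
  alignments_dir = "fixtures/alignments",
  method = "MI", outgroups = "T1", min_taxa = 4,
  cfg = refine_config(min_subtree_taxa = 4),
  mi_cfg = refine_config(tip_absolute_cutoff = 0.3, min_subtree_taxa = 4),
  ortholog_clean = 0.3, locus_min_length = 50, max_missing_taxa = 6,
  jackknife = list(mode = "proportion", value = 0.25, replicates = 200,
                   seed = 1))
res$report
#>            stage n_in n_out
#> 1    filter_hits 1736   810
#> 2       end_trim  116   116
#> 3 parse_clusters    8     8
#> 4         refine    8     8
#> 5          prune    8     8
#> 6    filter_loci    8     8
#> 7    supermatrix    8     8
#> 8      jackknife    8   200
```

1736 directed hits collapse to 810 undirected edges; all 8 clusters
survive the taxon filter, each yields one cleaned homolog and one MI
ortholog, and all 8 loci enter the supermatrix. The occupancy
statistics give the data behind a taxon-occupancy curve — loci ranked
by how many of the 10 taxa they contain:

```r
st <- res$outputs$occupancy_stats
sprintf("overall occupancy: %.1f%%", 100 * st$overall)
#> "overall occupancy: 91.9%"
st$locus_taxon_counts
#> fam001.1 fam002.1 fam004.1 fam006.1 fam007.1 fam003.1 fam008.1 fam005.1
#>       10       10       10       10       10        9        9        4
head(readLines("run/partitions.txt"), 2)
#> WAG, fam001.1 = 1-426
#> WAG, fam002.1 = 427-787
```

`run/` also holds the supermatrix in relaxed PHYLIP and FASTA, the
per-homolog pruning report, the ortholog-by-taxon occupancy table and
the 200 jackknife manifests. The same stages are available as shell
subcommands via `Rscript inst/cli/orthoprune.R <stage> ...`
(`filter-blast`, `mcl-input`, `parse-clusters`, `refine`, `prune`,
`supermatrix`, `jackknife`, `support`, `simulate`, `pipeline`).

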