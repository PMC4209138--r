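test_that("simulate_species_tree yields scaled ultrametric Yule trees", {
  expect_error(simulate_species_tree(2), "at least 3")
  t3 <- simulate_species_tree(3, depth = 2, seed = 1)
  expect_identical(t3$Nnode, 2L)
  expect_length(t3$tip.label, 3L)
  expect_equal(max(ape::node.depth.edgelength(t3)), 2)
  expect_identical(write_newick(simulate_species_tree(6, seed = 5)),
                   write_newick(simulate_species_tree(6, seed = 5)))
  t16 <- simulate_species_tree(16, seed = 2)
  expect_identical(nrow(t16$edge), 30L)                    # 2n - 2 rooted
  expect_identical(sum(t16$edge[, 2] > 16L), 14L)          # n - 2 internal
})

test_that("rate-zero gene families are congruent with the species tree", {
  sp <- simulate_species_tree(8, seed = 3)
  fam <- simulate_gene_family(sp, 0, 0, seed = 4)
  expect_setequal(parse_taxon(fam$tree$tip.label), sp$tip.label)
  expect_identical(fam$n_dup, 0L)
  relab <- fam$tree
  relab$tip.label <- parse_taxon(relab$tip.label)
  expect_equal(as.numeric(ape::dist.topo(ape::unroot(relab),
                                         ape::unroot(sp))), 0)
  expect_true(all(fam$tips$group == fam$tips$group[1]))
})

test_that("duplication events are logged and groups split at duplications", {
  set.seed(6)
  sp <- simulate_species_tree(10)
  fam <- NULL
  while (is.null(fam) || fam$n_dup == 0)
    fam <- simulate_gene_family(sp, 0.8, 0)
  # loss-free with duplications: every taxon appears at least once
  expect_setequal(unique(parse_taxon(fam$tree$tip.label)), sp$tip.label)
  expect_gte(fam$n_dup, 1L)
  expect_gt(length(unique(fam$tips$group)), 1L)
  # same seed reproduces the family byte for byte
  f1 <- simulate_gene_family(sp, 0.5, 0.2, seed = 9)
  f2 <- simulate_gene_family(sp, 0.5, 0.2, seed = 9)
  expect_identical(write_newick(f1$tree), write_newick(f2$tree))
  expect_identical(f1$tips, f2$tips)
})

test_that("inject_artifacts adds isoform sisters and inflates misassemblies", {
  sp <- simulate_species_tree(4, seed = 8)
  fam <- simulate_gene_family(sp, 0, 0, seed = 8)
  iso <- inject_artifacts(fam, sim_config(iso_prob = 1, mis_prob = 0),
                          seed = 1)
  expect_length(iso$tree$tip.label, 8L)
  expect_identical(sum(iso$tips$artifact == "isoform"), 4L)
  # each isoform sits as sister of its template at a near-zero distance
  d <- ape::cophenetic.phylo(iso$tree)
  for (t in fam$tree$tip.label)
    expect_lt(d[t, paste0(t, "i1")], 1e-3)
  pend <- function(tr, lab) {
    tr$edge.length[tr$edge[, 2] == match(lab, tr$tip.label)]
  }
  mis <- inject_artifacts(fam, sim_config(iso_prob = 0, mis_prob = 1),
                          seed = 2)
  for (t in fam$tree$tip.label)
    expect_equal(pend(mis$tree, t), 20 * pend(fam$tree, t))
  none <- inject_artifacts(fam, sim_config(iso_prob = 0, mis_prob = 0),
                           seed = 3)
  expect_identical(write_newick(none$tree), write_newick(fam$tree))
})

test_that("emit_fixture_set writes a self-consistent, reproducible bundle", {
  cfg <- sim_config(n_taxa = 8L, n_families = 4L, seed = 77L)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  emit_fixture_set(cfg, d1)
  emit_fixture_set(cfg, d2)
  for (f in c("species_tree.nwk", "mcl_clusters.txt", "event_log.tsv",
              "blast_hits.tsv"))
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  # every stage parses the files without error
  seqs <- unlist(lapply(list.files(file.path(d1, "alignments"),
                                   full.names = TRUE), read_fasta))
  hits <- read_blast_table(file.path(d1, "blast_hits.tsv"))
  edges <- filter_hits(hits)
  expect_gt(nrow(edges), 0L)
  cl <- parse_mcl_clusters(file.path(d1, "mcl_clusters.txt"), seqs,
                           min_taxa = 2L)
  expect_length(cl, 4L)
  # the pseudo-hit graph reproduces the intended cluster structure: every
  # within-family pair survives the default filters
  fam_of <- rep(seq_along(cl), vapply(cl, function(x) length(x$members),
                                      integer(1)))
  names(fam_of) <- unlist(lapply(cl, `[[`, "members"))
  expect_true(all(fam_of[edges$id1] == fam_of[edges$id2]))
  trees <- lapply(list.files(file.path(d1, "trees"), full.names = TRUE),
                  read_newick)
  expect_length(trees, 4L)
  # alignment ambiguity matches the configured fraction binomially
  aln <- read_fasta(list.files(file.path(d1, "alignments"),
                               full.names = TRUE)[1])
  log <- read.delim(file.path(d1, "event_log.tsv"))
  plain <- names(aln)[names(aln) %in% log$tip[log$artifact != "isoform"]]
  w <- nchar(aln[[1]])
  for (r in aln[plain]) {
    n_amb <- w - count_unambiguous(r, "aa")
    expect_equal(n_amb, round(0.05 * w), tolerance = 1e-8)
  }
  # isoform rows always carry fewer unambiguous characters than templates
  iso_rows <- log$tip[log$artifact == "isoform"]
  for (ir in intersect(iso_rows, names(aln))) {
    template <- sub("i1$", "", ir)
    expect_lt(count_unambiguous(aln[[ir]], "aa"),
              count_unambiguous(aln[[template]], "aa"))
  }
})

test_that("with no events and no artifacts all four methods agree exactly", {
  set.seed(15)
  roles <- taxon_roles(paste0("T", 2:10), "T1")
  micfg2 <- refine_config(tip_absolute_cutoff = 0.3, min_subtree_taxa = 2L)
  for (i in 1:10) {
    fam <- sim_family(10, n_outgroup = 1L)
    full <- sort(fam$tree$tip.label)
    mi <- prune_mi(fam$tree, 8L, micfg2)
    expect_identical(tipset_keys(mi), paste(full, collapse = "|"))
    oto <- filter_1to1(fam$tree, 8L)
    expect_identical(sort(oto$tip.label), full)
    mo <- prune_paralogs_mo(fam$tree, roles, 8L)
    expect_identical(sort(mo$tip.label), full)
    rt <- run_method(list(h = fam$tree), "RT", roles, 8L, micfg2)$orthologs
    expect_length(rt, 1L)
    ingroup <- setdiff(full, full[parse_taxon(full) == "T1"])
    expect_identical(sort(rt[[1]]$tip.label), ingroup)
  }
})
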