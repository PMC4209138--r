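micfg <- refine_config(tip_absolute_cutoff = 0.3, min_subtree_taxa = 2L)

test_that("has_taxon_duplication detects repeated taxa", {
  expect_false(has_taxon_duplication(read_newick("(A@1,B@1,C@1);")))
  expect_true(has_taxon_duplication(read_newick("(A@1,A@2,B@1);")))
})

test_that("prune_mi extracts maximal duplication-free subtrees greedily", {
  tr <- read_newick("((A@1:.1,B@1:.1):.1,(A@2:.1,(B@2:.1,C@1:.1):.1):.1,D@1:.1);")
  mi <- prune_mi(tr, min_taxa = 2L, micfg)
  expect_identical(lapply(mi, function(x) sort(x$tip.label)),
                   list(c("A@2", "B@2", "C@1", "D@1"), c("A@1", "B@1")))
  # duplication-free tree: one ortholog, the whole tree
  clean <- read_newick("((A@1,B@1),(C@1,D@1),(E@1,(F@1,(G@1,H@1))));")
  one <- suppressWarnings(prune_mi(clean, min_taxa = 8L, micfg))
  expect_length(one, 1L)
  expect_setequal(one[[1]]$tip.label, clean$tip.label)
  # fully interleaved duplications: nothing qualifies
  inter <- read_newick("((A@1:.1,B@1:.1):.1,(A@2:.1,B@2:.1):.1,(A@3:.1,B@3:.1):.1);")
  expect_length(prune_mi(inter, min_taxa = 3L, micfg), 0L)
})

test_that("MI outputs are tip-disjoint subsets with no duplication", {
  set.seed(13)
  for (i in 1:40) {
    phy <- random_labelled_tree(sample(6:14, 1))
    mi <- suppressWarnings(prune_mi(phy, min_taxa = 2L, micfg))
    tips <- unlist(lapply(mi, `[[`, "tip.label"))
    expect_false(anyDuplicated(tips) > 0)
    expect_true(all(tips %in% phy$tip.label))
    for (o in mi) expect_false(has_taxon_duplication(o))
  }
})

test_that("extract_rooted_ingroup_clades iterates maximal ingroup clades", {
  tr <- read_newick("((A@1:.1,(B@1:.1,C@1:.1):.1):.1,O@1:.1,(A@2:.1,B@2:.1):.1);")
  roles <- taxon_roles(c("A", "B", "C"), "O")
  cl <- extract_rooted_ingroup_clades(tr, roles, min_ingroup_taxa = 2L)
  expect_identical(lapply(cl, function(x) sort(x$tip.label)),
                   list(c("A@1", "B@1", "C@1"), c("A@2", "B@2")))
  # all tips ingroup: nothing extractable
  noog <- read_newick("((A@1,B@1),(C@1,D@1));")
  expect_length(extract_rooted_ingroup_clades(noog, roles, 2L), 0L)
  # one maximal clade holding all ingroup tips
  single <- read_newick("(((A@1,B@1),C@1),O@1);")
  cl2 <- extract_rooted_ingroup_clades(single, roles, 2L)
  expect_length(cl2, 1L)
  expect_setequal(cl2[[1]]$tip.label, c("A@1", "B@1", "C@1"))
})

test_that("prune_paralogs_rt splits at duplication nodes, larger side first", {
  rt <- prune_paralogs_rt(read_newick("((A@1,(B@1,C@1)),(A@2,B@2));"),
                          min_taxa = 2L)
  expect_setequal(tipset_keys(rt), c("A@1|B@1|C@1", "A@2|B@2"))
  # duplication-free input returns itself
  clean <- read_newick("((A@1,B@1),(C@1,D@1));")
  self <- prune_paralogs_rt(clean, min_taxa = 2L)
  expect_length(self, 1L)
  expect_setequal(self[[1]]$tip.label, clean$tip.label)
  # interleaved cherries: pruned singles fail min_taxa, the remainder with
  # one tip per taxon survives
  rt2 <- prune_paralogs_rt(read_newick("((A@1,A@2),(B@1,B@2));"),
                           min_taxa = 2L)
  expect_identical(tipset_keys(rt2), "A@1|B@1")
  # unrooted input violates the contract
  expect_error(prune_paralogs_rt(read_newick("(A@1,B@1,C@1);"), 2L), "rooted")
})

test_that("prune_paralogs_mo enforces monophyletic nonrepeating outgroups", {
  roles <- taxon_roles(c("A", "B"), c("O1", "O2"))
  cc <- c("A@1" = 300, "B@1" = 300, "A@2" = 200, "B@2" = 200,
          "O1@1" = 1, "O2@1" = 1)
  tr <- read_newick("(((A@1:.1,B@1:.1):.1,(A@2:.1,B@2:.1):.1):.1,(O1@1:.1,O2@1:.1):.1);")
  mo <- prune_paralogs_mo(tr, roles, min_taxa = 2L, counts = cc)
  expect_setequal(mo$tip.label, c("A@1", "B@1", "O1@1", "O2@1"))
  expect_true(ape::is.rooted(mo))
  # repeated outgroup taxon
  rep_og <- read_newick("(((A@1,B@1),O1@2),(O1@1,O2@1));")
  expect_null(prune_paralogs_mo(rep_og, roles, 2L))
  # non-monophyletic outgroups
  para_og <- read_newick("(((A@1,O1@1),B@1),(A@2,O2@1));")
  expect_null(prune_paralogs_mo(para_og, roles, 2L))
  # no outgroup tips at all
  expect_null(prune_paralogs_mo(read_newick("((A@1,B@1),(A@2,B@2));"),
                                roles, 2L))
})

test_that("filter_1to1 keeps only duplication-free trees above the minimum", {
  clean8 <- read_newick("((A@1,B@1),(C@1,D@1),((E@1,F@1),(G@1,H@1)));")
  expect_setequal(filter_1to1(clean8, 8L)$tip.label, clean8$tip.label)
  expect_null(filter_1to1(read_newick("((A@1,A@2),(B@1,C@1));"), 2L))
  expect_null(filter_1to1(read_newick("((A@1,B@1),(C@1,D@1));"), 8L))
})

test_that("raising min_taxa never increases the number of orthologs", {
  set.seed(17)
  roles <- taxon_roles(paste0("T", 2:8), "T1")
  for (i in 1:15) {
    phy <- random_labelled_tree(sample(8:14, 1), n_taxa_pool = 8L)
    counts <- setNames(rep(100, length(phy$tip.label)), phy$tip.label)
    prev <- rep(Inf, 4)
    for (mt in 2:5) {
      n_mi <- length(suppressWarnings(prune_mi(phy, mt, micfg)))
      n_rt <- length(run_method(list(h = phy), "RT", roles, mt,
                                micfg)$orthologs)
      mo <- prune_paralogs_mo(phy, roles, mt, counts)
      n_mo <- length(Filter(Negate(is.null), list(mo)))
      n_11 <- length(Filter(Negate(is.null), list(filter_1to1(phy, mt))))
      now <- c(n_mi, n_rt, n_mo, n_11)
      expect_true(all(now <= prev))
      prev <- now
    }
  }
})

test_that("1to1 equals MI's first extraction on duplication-free homologs", {
  set.seed(19)
  for (i in 1:20) {
    fam <- sim_family(sample(8:12, 1))
    mi <- prune_mi(fam$tree, min_taxa = 8L, micfg)
    oto <- filter_1to1(fam$tree, min_taxa = 8L)
    expect_length(mi, 1L)
    expect_setequal(mi[[1]]$tip.label, oto$tip.label)
  }
})

test_that("run_method dispatches and reports; RT follows the outgroup rules", {
  set.seed(23)
  fams <- lapply(1:5, function(i) sim_family(10, dup = 0.5)$tree)
  names(fams) <- paste0("h", 1:5)
  roles <- taxon_roles(paste0("T", 2:10), "T1")
  for (m in c("MI", "RT", "MO", "1to1")) {
    res <- run_method(fams, m, roles, min_taxa = 4L, micfg)
    expect_identical(nrow(res$report), 5L)
    for (o in res$orthologs) expect_false(has_taxon_duplication(o))
    expect_identical(sort(rownames(res$occupancy)), sort(names(res$orthologs)))
  }
  # duplicated taxa but no outgroup: RT ignores the homolog
  dup_no_og <- read_newick("((T2@a,T2@b),(T3@a,T4@a));")
  expect_length(run_method(list(h = dup_no_og), "RT", roles, 2L,
                           micfg)$orthologs, 0L)
  # duplication-free without outgroup: RT keeps it as an unrooted ortholog
  clean_no_og <- read_newick("((T2@a,T3@a),(T4@a,T5@a));")
  rt <- run_method(list(h = clean_no_og), "RT", roles, 4L, micfg)$orthologs
  expect_length(rt, 1L)
  expect_error(run_method(list(h = clean_no_og), "XX", roles), "arg")
})
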