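test_that("extract_ortholog_alignment selects, relabels and drops gap columns", {
  aln <- c("T1@a" = "MK-V", "T2@b" = "MK-V", "T3@c" = "MKAV",
           "T4@d" = "MK-V", "T5@e" = "MKAV", "T6@f" = "MKAV")
  loc <- extract_ortholog_alignment(aln, c("T1@a", "T2@b", "T4@d"), id = "x",
                                    type = "aa")
  expect_identical(names(loc$aln), c("T1", "T2", "T4"))
  expect_identical(loc$length, 3L)               # all-gap column dropped
  expect_identical(unname(loc$aln[1]), "MKV")
  expect_error(extract_ortholog_alignment(aln, c("T1@a", "nope@x")), "nope@x")
  expect_error(extract_ortholog_alignment(aln, c("T1@a", "T1@a")) , "duplicate",
               ignore.case = TRUE)
})

test_that("trim_columns_by_occupancy removes sparse columns, idempotently", {
  aln <- c(A = "M-KV", B = "M--V", C = "M--V", D = "M-AV")
  loc <- list(id = "x", aln = aln, length = 4L, type = "aa")
  tr <- trim_columns_by_occupancy(loc, 0.3)
  expect_identical(tr$length, 3L)   # column 2 empty; column 3 has 2/4 kept
  expect_identical(trim_columns_by_occupancy(tr, 0.3)$aln, tr$aln)
  # 1/4 occupied < 0.3: dropped
  loc2 <- list(id = "y", aln = c(A = "MA", B = "M-", C = "M-", D = "M-"),
               length = 2L, type = "aa")
  expect_identical(trim_columns_by_occupancy(loc2, 0.3)$length, 1L)
  # min 1.0 on a gapless alignment is the identity
  loc3 <- list(id = "z", aln = c(A = "MA", B = "CC"), length = 2L, type = "aa")
  expect_identical(trim_columns_by_occupancy(loc3, 1.0)$aln, loc3$aln)
})

test_that("filter_loci applies length and missing-taxon thresholds", {
  taxa <- paste0("T", 1:12)
  mk <- function(id, len, tx) list(id = id, aln = setNames(rep(strrep("A", len),
                                                               length(tx)), tx),
                                   length = len, type = "aa")
  loci <- list(mk("a", 99, taxa), mk("b", 300, taxa),
               mk("c", 150, taxa[1:10]), mk("d", 150, taxa[1:11]))
  expect_identical(vapply(filter_loci(loci, 100, 1, taxa), `[[`, "", "id"),
                   c("b", "d"))
  expect_identical(vapply(filter_loci(loci, 100, 0, taxa), `[[`, "", "id"), "b")
})

test_that("concatenation conserves length, partitions and padding", {
  taxa <- c("T1", "T2", "T3")
  l1 <- list(id = "locB", aln = c(T1 = strrep("A", 100), T2 = strrep("C", 100),
                                  T3 = strrep("G", 100)), length = 100L,
             type = "nt")
  l2 <- list(id = "locA", aln = c(T1 = strrep("T", 200), T3 = strrep("A", 200)),
             length = 200L, type = "nt")
  sm <- concatenate_loci(list(l1, l2), taxa)
  expect_identical(unique(nchar(sm$seqs)), 300L)
  expect_identical(sm$partitions$locus, c("locA", "locB"))   # id-sorted
  expect_identical(sm$partitions$start, c(1L, 201L))
  expect_identical(sm$partitions$end, c(200L, 300L))
  expect_identical(substr(sm$seqs[["T2"]], 1, 200), strrep("-", 200))
  expect_error(concatenate_loci(list(), taxa), "nothing")
  l3 <- list(id = "locC", aln = c(T1 = "MK"), length = 2L, type = "aa")
  expect_error(concatenate_loci(list(l1, l3), taxa), "mixed")
})

test_that("occupancy_stats matches hand counts and the ranked curve", {
  sm <- structure(list(
    seqs = c(T1 = "AAAAA-----", T2 = "AAAAAAAAAA", T3 = "AA--AAAA--"),
    partitions = data.frame(locus = c("l1", "l2"), start = c(1L, 6L),
                            end = c(5L, 10L)),
    type = "nt"), class = "supermatrix")
  st <- occupancy_stats(sm)
  expect_equal(st$overall, 21 / 30)
  expect_equal(unname(st$per_taxon), c(0.5, 1.0, 0.6))
  expect_equal(unname(st$locus_taxon_counts), c(3, 2))
})

test_that("supermatrix properties hold over random locus sets", {
  set.seed(29)
  taxa <- paste0("T", 1:10)
  for (i in 1:100) {
    loci <- lapply(seq_len(sample(2:8, 1)),
                   function(k) random_locus(sprintf("L%02d", k), taxa))
    sm <- concatenate_loci(loci, taxa)
    expect_identical(nchar(sm$seqs[[1]]),
                     sum(vapply(loci, `[[`, integer(1), "length")))
    p <- sm$partitions
    expect_identical(p$start[1], 1L)
    expect_identical(p$end[nrow(p)], nchar(sm$seqs[[1]]))
    if (nrow(p) > 1) expect_identical(p$start[-1], p$end[-nrow(p)] + 1L)
    expect_equal(occupancy_stats(sm)$overall, oracle_occupancy(sm$seqs))
  }
})

test_that("jackknife manifests are sized, seeded and locus-intact", {
  ids <- sprintf("L%02d", 1:50)
  man <- jackknife_by_locus(ids, "proportion", 0.1, replicates = 200L,
                            seed = 11L)
  expect_length(man, 200L)
  expect_true(all(lengths(man) == 5L))
  expect_true(all(vapply(man, anyDuplicated, integer(1)) == 0L))
  man2 <- jackknife_by_locus(ids, "proportion", 0.1, replicates = 200L,
                             seed = 11L)
  expect_identical(man, man2)
  cnt <- jackknife_by_locus(ids, "count", 20, replicates = 10L, seed = 1L)
  expect_true(all(lengths(cnt) == 20L))
  expect_error(jackknife_by_locus(ids, "count", 51, seed = 1L), "exceeds")
  # round-half-up replicate size
  expect_identical(attr(jackknife_by_locus(ids[1:25], "proportion", 0.1,
                                           replicates = 1L, seed = 1L),
                        "size"), 3L)   # 2.5 rounds up
})

test_that("bipartition_support annotates edges with replicate frequencies", {
  ref <- read_newick("((A@1,B@1),(C@1,D@1),E@1);")
  reps <- list(ref, ref, ref)
  ann <- bipartition_support(ref, reps)
  expect_true(all(attr(ann, "support")[-1] == 100))
  # an edge absent from every replicate scores 0
  other <- read_newick("((A@1,C@1),(B@1,D@1),E@1);")
  ann2 <- bipartition_support(ref, list(other, other))
  sup <- attr(ann2, "support")
  expect_true(any(sup == 0))
  expect_error(bipartition_support(ref, list()), "at least one")
  # 4-taxon frequencies match topology counts exactly
  set.seed(3)
  quartets <- c("((A@1,B@1),(C@1,D@1));", "((A@1,C@1),(B@1,D@1));",
                "((A@1,D@1),(B@1,C@1));")
  picks <- sample(1:3, 200, replace = TRUE)
  reps4 <- lapply(quartets[picks], read_newick)
  ref4 <- read_newick(quartets[1])
  sup4 <- attr(bipartition_support(ref4, reps4), "support")
  # both non-root clades of the reference carry the AB|CD bipartition
  expect_equal(unname(sup4[-1]), rep(100 * mean(picks == 1), 2))
})

test_that("supermatrix and partition files are written in standard dialects", {
  taxa <- c("T1", "T2")
  l1 <- list(id = "a", aln = c(T1 = "ACGT", T2 = "AC-T"), length = 4L,
             type = "nt")
  sm <- concatenate_loci(list(l1), taxa)
  fp <- withr::local_tempfile()
  write_supermatrix(sm, fp, "phylip")
  expect_identical(readLines(fp), c("2 4", "T1 ACGT", "T2 AC-T"))
  pf <- withr::local_tempfile()
  write_partitions(sm, pf)
  expect_identical(readLines(pf), "DNA, a = 1-4")
})
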