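# Shared fixtures and independent oracles, built in code at test time.

# A random gene tree with controllable taxon duplication: topology from
# ape::rtree, tips relabelled taxon@s<i> with taxa drawn from a small pool.
random_labelled_tree <- function(n_tips, n_taxa_pool = max(2L, n_tips %/% 2L)) {
  phy <- ape::rtree(n_tips)
  taxa <- sample(paste0("T", seq_len(n_taxa_pool)), n_tips, replace = TRUE)
  phy$tip.label <- paste0(taxa, "@s", seq_len(n_tips))
  phy
}

# ---- brute-force MI oracle -------------------------------------------------
# Independent of prune_mi: subtree enumeration by igraph edge deletion and
# component membership; greedy selection and tie-breaking coded from the
# method definition. Shares only keep/drop-tip plumbing (ape) and
# trim_spurious_tips (unit-tested separately) with the implementation.

oracle_subtree_sets <- function(phy) {
  n <- length(phy$tip.label)
  g <- igraph::graph_from_edgelist(
    matrix(as.character(phy$edge), ncol = 2L), directed = FALSE)
  sets <- list(sort(phy$tip.label))
  for (e in seq_len(nrow(phy$edge))) {
    eid <- igraph::get_edge_ids(g, as.character(phy$edge[e, ]))
    g2 <- igraph::delete_edges(g, eid)
    memb <- igraph::components(g2)$membership
    for (side in unique(memb)) {
      nodes <- as.integer(names(memb)[memb == side])
      tips <- phy$tip.label[nodes[nodes <= n]]
      if (length(tips)) sets[[length(sets) + 1L]] <- sort(tips)
    }
  }
  sets[!duplicated(vapply(sets, paste, character(1L), collapse = "|"))]
}

# Elementwise comparison of two sorted label tuples: -1 if a < b.
tuple_cmp <- function(a, b) {
  for (i in seq_len(min(length(a), length(b)))) {
    ca <- utf8ToInt(paste0(a[i], "\001"))
    cb <- utf8ToInt(paste0(b[i], "\001"))
    for (j in seq_len(min(length(ca), length(cb)))) {
      if (ca[j] != cb[j]) return(sign(ca[j] - cb[j]))
    }
  }
  sign(length(a) - length(b))
}

oracle_pick <- function(sets) {
  taxa <- vapply(sets, function(s) length(unique(sub("@.*$", "", s))),
                 integer(1L))
  ntip <- lengths(sets)
  best <- 1L
  for (i in seq_along(sets)[-1L]) {
    if (taxa[i] > taxa[best] ||
        (taxa[i] == taxa[best] && ntip[i] > ntip[best]) ||
        (taxa[i] == taxa[best] && ntip[i] == ntip[best] &&
           tuple_cmp(sets[[i]], sets[[best]]) < 0)) best <- i
  }
  sets[[best]]
}

oracle_mi <- function(phy, min_taxa, cfg) {
  out <- list()
  work <- phy
  repeat {
    if (is.null(work) || length(work$tip.label) < 2L) break
    sets <- oracle_subtree_sets(work)
    ok <- vapply(sets, function(s) {
      tx <- sub("@.*$", "", s)
      !anyDuplicated(tx) && length(unique(tx)) >= min_taxa
    }, logical(1L))
    if (!any(ok)) break
    best <- oracle_pick(sets[ok])
    out[[length(out) + 1L]] <- best
    remaining <- setdiff(work$tip.label, best)
    work <- if (length(remaining) >= 2L) ape::keep.tip(work, remaining) else NULL
    if (!is.null(work) && length(work$tip.label) >= 3L)
      work <- suppressWarnings(trim_spurious_tips(work, cfg))
  }
  out
}

tipset_keys <- function(trees) {
  sort(vapply(trees, function(t) {
    labs <- if (inherits(t, "phylo")) t$tip.label else t
    paste(sort(labs), collapse = "|")
  }, character(1L)))
}

# A clean loss-free family on its own fresh species tree.
sim_family <- function(n_taxa = 12L, dup = 0, loss = 0, depth = 1,
                       n_outgroup = 0L) {
  repeat {
    sp <- simulate_species_tree(n_taxa, depth, n_outgroup = n_outgroup)
    fam <- simulate_gene_family(sp, dup, loss)
    if (!is.null(fam)) return(fam)
  }
}

# Random locus fixture for supermatrix property tests.
random_locus <- function(id, taxa_pool, alphabet = c("A", "C", "G", "T")) {
  k <- sample(2:length(taxa_pool), 1L)
  taxa <- sort(sample(taxa_pool, k))
  len <- sample(5:40, 1L)
  rows <- vapply(taxa, function(t) {
    ch <- sample(alphabet, len, replace = TRUE)
    gaps <- runif(len) < 0.2
    ch[gaps] <- "-"
    paste(ch, collapse = "")
  }, character(1L))
  list(id = id, aln = rows, length = len, type = "nt")
}

# Ground truth for paralog mixing: TRUE when any pair of the given tips
# has a duplication node ("D" label from the simulator) as its MRCA.
mixes_paralogs <- function(tree, tips) {
  tips <- intersect(tips, tree$tip.label)
  if (length(tips) < 2L) return(FALSE)
  M <- ape::mrca(tree)[tips, tips, drop = FALSE]
  n <- length(tree$tip.label)
  labs <- tree$node.label
  any(labs[M[upper.tri(M)] - n] == "D")
}

# Independent occupancy count: plain character loop over the rows.
oracle_occupancy <- function(seqs) {
  cells <- unlist(strsplit(seqs, ""))
  sum(!(cells %in% c("-", "?"))) / length(cells)
}
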