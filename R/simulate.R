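# Gene families with known evolutionary histories and injected artifacts:
# the ground truth against which every cleaning and pruning stage is
# validated. Sequence content is placeholder (lengths and ambiguity counts
# are what the algorithms consume); no substitution model is simulated.

#' Simulation configuration
#'
#' Defaults emulate a moderately sized transcriptome study: a dozen taxa,
#' unit tree depth, occasional gene duplication and loss, roughly one tip
#' in ten carrying an extra isoform and one in twenty misassembled with a
#' 20-fold inflated pendant branch. See the methods vignette for the
#' rationale behind each value.
#'
#' @param n_taxa number of taxa (>= 3), default 12.
#' @param depth species-tree root-to-tip length (substitutions/site),
#'   default 1.
#' @param dup_rate,loss_rate gene duplication/loss rates per unit branch
#'   length, defaults 0.2 and 0.1.
#' @param iso_prob per-tip isoform injection probability, default 0.1.
#' @param mis_prob per-tip misassembly injection probability, default 0.04
#'   (the chimera rate reported for de novo transcriptome assemblies).
#' @param mis_multiplier misassembly pendant-length multiplier, default 20.
#' @param aln_length_meanlog,aln_length_sdlog lognormal parameters of the
#'   fake alignment width; defaults give a median near 300 columns.
#' @param ambiguity fraction of ambiguous characters per row, default 0.05.
#' @param n_families number of families emitted by [emit_fixture_set()].
#' @param seed RNG seed.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_taxa = 12L, depth = 1.0, dup_rate = 0.2,
                       loss_rate = 0.1, iso_prob = 0.1, mis_prob = 0.04,
                       mis_multiplier = 20, aln_length_meanlog = log(300),
                       aln_length_sdlog = 0.25, ambiguity = 0.05,
                       n_families = 20L, seed = NULL) {
  stopifnot(n_taxa >= 3L, depth > 0, dup_rate >= 0, loss_rate >= 0,
            iso_prob >= 0, iso_prob <= 1, mis_prob >= 0, mis_prob <= 1,
            iso_prob + mis_prob <= 1, mis_multiplier > 1,
            ambiguity >= 0, ambiguity < 1)
  structure(as.list(environment()), class = "sim_config")
}

#' Simulate a species tree
#'
#' Pure-birth (Yule) topology with branch lengths rescaled so that the
#' root-to-tip length equals `depth` (the tree is ultrametric). Tips are
#' labelled `T1..Tn`. With `n_outgroup > 0` the first `n_outgroup` taxa
#' form a basal grade of successive outgroups diverging before the
#' ingroup radiation (which then spans 60% of `depth`), the arrangement
#' outgroup-based orthology inference assumes.
#'
#' @param n_taxa number of taxa (>= 3).
#' @param depth root-to-tip length.
#' @param seed RNG seed.
#' @param n_outgroup number of basal outgroup taxa (`T1..Tk`), default 0.
#' @return A `phylo`.
#' @export
simulate_species_tree <- function(n_taxa, depth = 1.0, seed = NULL,
                                  n_outgroup = 0L) {
  if (n_taxa < 3L) stop("n_taxa must be at least 3", call. = FALSE)
  stopifnot(n_outgroup >= 0L, n_taxa - n_outgroup >= 3L)
  .with_seed(seed, {
    k <- as.integer(n_outgroup)
    n_in <- n_taxa - k
    phy <- ape::rphylo(n_in, birth = 1, death = 0)
    h <- max(ape::node.depth.edgelength(phy))
    h_in <- if (k > 0L) 0.6 * depth else depth
    phy$edge.length <- phy$edge.length * h_in / h
    phy$tip.label <- paste0("T", seq.int(k + 1L, n_taxa))
    if (k == 0L) return(phy)
    text <- sub(";$", "", write_newick(phy))
    cur_h <- h_in
    for (j in seq.int(k, 1L)) {
      H <- depth * (0.6 + 0.4 * (k - j + 1L) / k)
      text <- sprintf("(%s:%.10g,T%d:%.10g)", text, H - cur_h, j, H)
      cur_h <- H
    }
    ape::read.tree(text = paste0(text, ";"))
  })
}

# Nested-list gene tree -> newick fragment. Internal nodes carry their
# event tag ("S" speciation, "D" duplication) as the node label.
.gtree_newick <- function(node) {
  if (!is.null(node$label)) {
    sprintf("%s:%.10g", node$label, node$len)
  } else {
    sprintf("(%s)%s:%.10g",
            paste(vapply(node$children, .gtree_newick, character(1L)),
                  collapse = ","),
            node$tag, node$len)
  }
}

#' Simulate a gene family along a species tree
#'
#' Birth--death process of gene lineages along the species tree: a single
#' lineage enters at the root; along each branch it duplicates at
#' `dup_rate` and is lost at `loss_rate` (events per unit branch length);
#' at speciation nodes every surviving lineage is copied into both
#' daughters. Tips are named `taxon@g<k>`. With both rates 0 the gene tree
#' is congruent with the species tree with exactly one tip per taxon.
#'
#' The event log records every duplication and loss. Each tip carries a
#' `group` signature encoding the duplication choices on its root-to-tip
#' path (tips with equal signatures form speciation-only subtrees), and
#' every internal node of the returned tree is labelled `"S"` (speciation)
#' or `"D"` (duplication), so that ground-truth orthology of any tip pair
#' --- whether their most recent common ancestor is a speciation --- can be
#' read off the tree.
#'
#' @param sp_tree species tree from [simulate_species_tree()].
#' @param dup_rate,loss_rate event rates per unit branch length.
#' @param seed RNG seed.
#' @return `list(tree, tips, n_dup, n_loss)` where `tips` is a data.frame
#'   with `tip`, `taxon`, `group`, `artifact`; or `NULL` when fewer than
#'   two lineages survive (caller resamples).
#' @export
simulate_gene_family <- function(sp_tree, dup_rate = 0, loss_rate = 0,
                                 seed = NULL) {
  stopifnot(is.finite(dup_rate), is.finite(loss_rate),
            dup_rate >= 0, loss_rate >= 0)
  .with_seed(seed, {
    env <- new.env()
    env$tip_k <- 0L
    env$dup_k <- 0L
    env$n_loss <- 0L
    env$tips <- list()
    n <- .n_tip(sp_tree)
    el <- sp_tree$edge.length
    edge_of <- match(seq_len(n + sp_tree$Nnode), sp_tree$edge[, 2L])
    total <- dup_rate + loss_rate

    at_node <- function(v, sig) {
      if (v <= n) {
        env$tip_k <- env$tip_k + 1L
        label <- paste0(sp_tree$tip.label[v], "@g", env$tip_k)
        env$tips[[label]] <- sig
        return(list(label = label, len = 0))
      }
      kids <- list()
      for (c in .children(sp_tree, v)) {
        k <- sim_edge(c, el[edge_of[c]], sig)
        if (!is.null(k)) kids[[length(kids) + 1L]] <- k
      }
      if (length(kids) == 0L) return(NULL)
      if (length(kids) == 1L) return(kids[[1L]])
      list(children = kids, len = 0, tag = "S")
    }

    sim_edge <- function(v, len, sig) {
      t <- if (total > 0) rexp(1L, total) else Inf
      if (t >= len) {
        res <- at_node(v, sig)
        if (is.null(res)) return(NULL)
        res$len <- res$len + len
        return(res)
      }
      if (runif(1L) < loss_rate / total) {
        env$n_loss <- env$n_loss + 1L
        return(NULL)
      }
      env$dup_k <- env$dup_k + 1L
      k <- env$dup_k
      a <- sim_edge(v, len - t, paste0(sig, "/", k, "a"))
      b <- sim_edge(v, len - t, paste0(sig, "/", k, "b"))
      both <- Filter(Negate(is.null), list(a, b))
      if (length(both) == 0L) return(NULL)
      if (length(both) == 1L) {
        x <- both[[1L]]
        x$len <- x$len + t
        return(x)
      }
      list(children = both, len = t, tag = "D")
    }

    res <- at_node(n + 1L, "r")
    if (is.null(res) || length(env$tips) < 2L) return(NULL)
    text <- if (!is.null(res$label)) {
      NULL   # single surviving lineage: not a tree
    } else {
      paste0("(", paste(vapply(res$children, .gtree_newick, character(1L)),
                        collapse = ","), ")", res$tag, ";")
    }
    if (is.null(text)) return(NULL)
    tree <- ape::read.tree(text = text)
    tips <- data.frame(tip = names(env$tips),
                       taxon = parse_taxon(names(env$tips)),
                       group = unlist(env$tips, use.names = FALSE),
                       artifact = "none", stringsAsFactors = FALSE)
    list(tree = tree, tips = tips, n_dup = env$dup_k, n_loss = env$n_loss)
  })
}

#' Inject isoform and misassembly artifacts into a gene tree
#'
#' Each original tip independently receives at most one artifact: with
#' probability `iso_prob` an isoform --- a same-taxon sister tip attached at
#' a near-zero branch length --- and otherwise with probability `mis_prob` a
#' misassembly, which multiplies the tip's pendant branch by
#' `mis_multiplier`. The family's tip table is updated: isoform tips carry
#' `artifact = "isoform"` (same true ortholog group as their template) and
#' misassembled tips `artifact = "misassembly"`.
#'
#' @param fam a family as from [simulate_gene_family()].
#' @param cfg a [sim_config()].
#' @param seed RNG seed.
#' @param eps isoform pendant branch length, default `1e-4 * cfg$depth`.
#' @return The family with updated `tree` and `tips`.
#' @export
inject_artifacts <- function(fam, cfg = sim_config(), seed = NULL,
                             eps = 1e-4 * cfg$depth) {
  .with_seed(seed, {
    tree <- fam$tree
    tips <- fam$tips
    originals <- tips$tip
    u <- runif(length(originals))
    iso <- originals[u < cfg$iso_prob]
    mis <- originals[u >= cfg$iso_prob & u < cfg$iso_prob + cfg$mis_prob]
    for (tp in iso) {
      idx <- match(tp, tree$tip.label)
      pend <- tree$edge.length[tree$edge[, 2L] == idx]
      new_label <- paste0(tp, "i1")
      tree <- phytools::bind.tip(tree, new_label, edge.length = eps,
                                 where = idx, position = min(eps, pend / 2))
      row <- tips[tips$tip == tp, ]
      row$tip <- new_label
      row$artifact <- "isoform"
      tips <- rbind(tips, row)
    }
    for (tp in mis) {
      idx <- match(tp, tree$tip.label)
      e <- which(tree$edge[, 2L] == idx)
      tree$edge.length[e] <- tree$edge.length[e] * cfg$mis_multiplier
      tips$artifact[tips$tip == tp] <- "misassembly"
    }
    fam$tree <- tree
    fam$tips <- tips[order(tips$tip), , drop = FALSE]
    rownames(fam$tips) <- NULL
    fam
  })
}

# Placeholder alignment for a family: fixed width, amino-acid residues,
# a configured fraction of ambiguity ('X'); isoform rows get extra
# ambiguity so the template always carries more unambiguous characters,
# and misassembled rows are unchanged (their signal is the branch length).
.sim_alignment <- function(fam, cfg) {
  width <- max(50L, as.integer(round(rlnorm(1L, cfg$aln_length_meanlog,
                                            cfg$aln_length_sdlog))))
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]]
  rows <- character(nrow(fam$tips))
  names(rows) <- fam$tips$tip
  for (i in seq_len(nrow(fam$tips))) {
    ch <- sample(aa, width, replace = TRUE)
    n_amb <- round(cfg$ambiguity * width)
    extra <- if (fam$tips$artifact[i] == "isoform") round(0.15 * width) else 0L
    amb_pos <- sample.int(width, min(width, n_amb + extra))
    ch[amb_pos] <- "X"
    rows[i] <- paste(ch, collapse = "")
  }
  rows
}

#' Emit a complete synthetic fixture set to disk
#'
#' Writes, for `cfg$n_families` simulated families: newick gene trees,
#' placeholder FASTA alignments whose unambiguous-character counts match
#' what masking expects, a pseudo-BLAST tabular hit file whose pairs are
#' consistent with family membership (full-coverage hits, E values mapped
#' from tree distance, all passing [filter_hits()] defaults), an MCL-style
#' cluster file with one family per line, the species tree, and a
#' ground-truth tip table (`event_log.tsv`). Outputs are byte-identical
#' under the same seed.
#'
#' @param cfg a [sim_config()].
#' @param dir output directory (created if needed).
#' @return Invisibly, a list with the simulated families and the file
#'   paths.
#' @export
emit_fixture_set <- function(cfg = sim_config(), dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "trees"), showWarnings = FALSE)
  dir.create(file.path(dir, "alignments"), showWarnings = FALSE)
  .with_seed(cfg$seed, {
    sp <- simulate_species_tree(cfg$n_taxa, cfg$depth)
    write_newick(sp, file.path(dir, "species_tree.nwk"))
    fams <- vector("list", cfg$n_families)
    alns <- vector("list", cfg$n_families)
    hit_rows <- list()
    mcl_lines <- character(cfg$n_families)
    logs <- list()
    for (i in seq_len(cfg$n_families)) {
      fam <- NULL
      for (try in 1:50) {
        fam <- simulate_gene_family(sp, cfg$dup_rate, cfg$loss_rate)
        if (!is.null(fam)) break
      }
      if (is.null(fam)) stop("family simulation kept going extinct")
      fam <- inject_artifacts(fam, cfg)
      fam$id <- sprintf("fam%03d", i)
      # family-qualify sequence ids so they are unique across the set
      qual <- function(x) sub("@g", paste0("@", fam$id, "g"), x, fixed = TRUE)
      fam$tree$tip.label <- qual(fam$tree$tip.label)
      fam$tips$tip <- qual(fam$tips$tip)
      fams[[i]] <- fam
      write_newick(fam$tree, file.path(dir, "trees", paste0(fam$id, ".nwk")))
      aln <- .sim_alignment(fam, cfg)
      alns[[i]] <- aln
      write_fasta(aln, file.path(dir, "alignments", paste0(fam$id, ".fa")))
      hit_rows[[i]] <- .sim_hits(fam, aln)
      mcl_lines[i] <- paste(sort(fam$tips$tip), collapse = "\t")
      logs[[i]] <- cbind(family = fam$id, fam$tips)
    }
    hits <- data.table::rbindlist(hit_rows)
    data.table::fwrite(hits, file.path(dir, "blast_hits.tsv"), sep = "\t",
                       col.names = FALSE)
    writeLines(mcl_lines, file.path(dir, "mcl_clusters.txt"))
    log <- do.call(rbind, logs)
    utils::write.table(log, file.path(dir, "event_log.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    invisible(list(species_tree = sp, families = fams, alignments = alns,
                   dir = dir))
  })
}

# Pseudo-BLAST rows for one family: all ordered pairs, full-coverage
# intervals, E value decaying with patristic distance (always passing the
# default 1e-5 cutoff), plus self hits.
.sim_hits <- function(fam, aln) {
  ids <- fam$tips$tip
  len <- setNames(nchar(aln[ids]), ids)
  d <- ape::cophenetic.phylo(fam$tree)[ids, ids, drop = FALSE]
  pairs <- expand.grid(q = ids, s = ids, stringsAsFactors = FALSE)
  ev <- pmin(1e-6, 10^-(pmax(6, 180 - 30 * d[cbind(pairs$q, pairs$s)])))
  diag_self <- pairs$q == pairs$s
  ev[diag_self] <- 0
  data.table::data.table(
    query = pairs$q, subject = pairs$s, pident = 90, length = len[pairs$q],
    mismatch = 0L, gapopen = 0L, qstart = 1L, qend = len[pairs$q],
    sstart = 1L, send = len[pairs$s], evalue = ev,
    bitscore = round(500 - 20 * d[cbind(pairs$q, pairs$s)], 1),
    qlen = len[pairs$q], slen = len[pairs$s])
}
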