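# Ortholog extraction from cleaned homolog trees by four strategies:
# maximum inclusion (MI), rooted ingroup-clade duplication pruning (RT),
# monophyletic outgroup rooting (MO), and strict one-to-one (1to1).

#' Ingroup/outgroup taxon roles
#'
#' @param ingroup character vector of ingroup taxa.
#' @param outgroup character vector of outgroup taxa (may be empty; MI and
#'   1to1 need none).
#' @return An object of class `taxon_roles`.
#' @export
taxon_roles <- function(ingroup, outgroup = character()) {
  if (length(intersect(ingroup, outgroup)))
    stop("ingroup and outgroup taxa must be disjoint", call. = FALSE)
  structure(list(ingroup = unique(ingroup), outgroup = unique(outgroup)),
            class = "taxon_roles")
}

#' Does a tree contain a taxon duplication?
#'
#' `TRUE` iff two or more tips share a taxon - the signature of paralogy or
#' unmasked isoforms.
#'
#' @param phy a `phylo`.
#' @param scheme a [taxon_scheme()].
#' @return Logical scalar.
#' @export
has_taxon_duplication <- function(phy, scheme = taxon_scheme()) {
  anyDuplicated(.tip_taxa(phy, scheme)) > 0L
}

# Tag an extracted tree with its provenance.
.as_ortholog <- function(phy, method, source = NA_character_) {
  attr(phy, "method") <- method
  attr(phy, "source_homolog") <- source
  phy
}

# All candidate edge-delimited tip sets of a tree: every clade, every clade
# complement, and the full tip set (the tree itself). Root orientation is
# ignored, so rooted and unrooted inputs are handled alike. Returns a list
# of character vectors, deduplicated.
.candidate_sets <- function(phy) {
  labels <- phy$tip.label
  clades <- .clade_tips(phy)
  sets <- list(labels)
  for (s in clades) {
    a <- labels[s]
    sets[[length(sets) + 1L]] <- a
    b <- setdiff(labels, a)
    if (length(b)) sets[[length(sets) + 1L]] <- b
  }
  sets[!duplicated(vapply(sets, .set_key, character(1L)))]
}

# Deterministic selection among candidate tip sets: most distinct taxa,
# then most tips, then highest total unambiguous characters, then the
# lexicographically smallest sorted tip-id tuple.
.best_set <- function(sets, scheme, counts = NULL) {
  taxa <- vapply(sets, function(s) length(unique(parse_taxon(s, scheme))),
                 integer(1L))
  tips <- lengths(sets)
  chars <- vapply(sets, function(s) {
    if (is.null(counts)) 0 else sum(counts[s], na.rm = TRUE)
  }, numeric(1L))
  keys <- vapply(sets, .set_key, character(1L))
  sets[[order(-taxa, -tips, -chars, keys, method = "radix")[1L]]]
}

#' Maximum-inclusion (MI) ortholog extraction
#'
#' Iteratively cuts out the edge-delimited subtree with the highest number
#' of distinct taxa and no taxon duplication, removes its tips from the
#' working tree, trims leftover spurious tips on the remainder (the MI
#' stage uses its own, typically lower, absolute tip cutoff), and repeats
#' until no duplication-free subtree with at least `min_taxa` taxa
#' remains. Works on rooted or unrooted trees; both orientations of every
#' edge are considered. Emitted tip sets are pairwise disjoint.
#'
#' @param phy a cleaned homolog tree.
#' @param min_taxa minimum number of distinct taxa per ortholog (>= 2),
#'   default 8.
#' @param cfg a [refine_config()] providing the MI-stage tip cutoffs used
#'   to trim the remainder between extractions.
#' @param counts optional named unambiguous-character counts for
#'   tie-breaking.
#' @param scheme a [taxon_scheme()].
#' @return List of ortholog trees (method tag `"MI"`).
#' @export
prune_mi <- function(phy, min_taxa = 8L, cfg = refine_config(),
                     counts = NULL, scheme = taxon_scheme()) {
  stopifnot(min_taxa >= 2L)
  out <- list()
  work <- phy
  repeat {
    if (is.null(work) || .n_tip(work) < 2L) break
    sets <- .candidate_sets(work)
    ok <- vapply(sets, function(s) {
      tx <- parse_taxon(s, scheme)
      anyDuplicated(tx) == 0L && length(unique(tx)) >= min_taxa
    }, logical(1L))
    if (!any(ok)) break
    best <- .best_set(sets[ok], scheme, counts)
    sub <- .keep_tips(work, best)
    if (is.null(sub)) break
    out[[length(out) + 1L]] <- .as_ortholog(sub, "MI")
    work <- .drop_tips(work, best)
    if (!is.null(work) && .n_tip(work) >= 3L)
      work <- trim_spurious_tips(work, cfg)
  }
  out
}

#' Extract rooted ingroup clades using outgroups
#'
#' First stage of the RT strategy: iteratively finds the clade with the
#' highest number of distinct ingroup taxa that contains only ingroup tips
#' (the outgroup tips left in the remainder orient the clade, so it is cut
#' out as a rooted tree), removes it, and repeats. Clades with fewer than
#' `min_ingroup_taxa` distinct taxa are cut but not returned.
#'
#' @param phy a homolog tree containing at least one outgroup tip.
#' @param roles a [taxon_roles()] with non-empty outgroup.
#' @param min_ingroup_taxa minimum distinct ingroup taxa per clade.
#' @param counts,scheme see [prune_mi()].
#' @return List of rooted ingroup trees (empty when no outgroup tip is
#'   present).
#' @export
extract_rooted_ingroup_clades <- function(phy, roles, min_ingroup_taxa = 8L,
                                          counts = NULL,
                                          scheme = taxon_scheme()) {
  stopifnot(inherits(roles, "taxon_roles"))
  out <- list()
  work <- phy
  repeat {
    if (is.null(work)) break
    taxa <- .tip_taxa(work, scheme)
    is_og <- taxa %in% roles$outgroup
    if (!any(is_og) || all(is_og)) break
    labels <- work$tip.label
    clades <- .clade_tips(work)
    sets <- list()
    for (node in seq_along(clades)) {
      if (node == .root_node(work)) next
      s <- clades[[node]]
      if (all(!is_og[s])) sets[[length(sets) + 1L]] <- labels[s]
    }
    sets <- sets[!duplicated(vapply(sets, .set_key, character(1L)))]
    if (length(sets) == 0L) break
    best <- .best_set(sets, scheme, counts)
    sub <- .keep_tips(work, best)
    if (!is.null(sub) &&
        length(unique(parse_taxon(best, scheme))) >= min_ingroup_taxa)
      out[[length(out) + 1L]] <- sub
    work <- .drop_tips(work, best)
  }
  out
}

# Taxon multiset of the tips under each child of `node`; used for
# duplication detection. Returns the child to prune at a duplication, or 0
# when the node is duplication-free between its children.
.dup_prune_child <- function(phy, node, clades, taxa, counts) {
  ch <- .children(phy, node)
  if (length(ch) < 2L) return(0L)
  sets <- lapply(ch, function(c) taxa[clades[[c]]])
  overlap <- FALSE
  for (i in seq_along(ch)) {
    for (j in seq_along(ch)) {
      if (i < j && length(intersect(sets[[i]], sets[[j]]))) overlap <- TRUE
    }
  }
  if (!overlap) return(0L)
  # pick the side to prune: fewest distinct taxa, then fewest tips, then
  # fewest total unambiguous characters, then lexicographically largest
  # tip-id tuple (so the smallest-id side survives)
  ntaxa <- vapply(sets, function(s) length(unique(s)), integer(1L))
  ntips <- lengths(sets)
  chars <- vapply(ch, function(c) {
    if (is.null(counts)) 0 else
      sum(counts[phy$tip.label[clades[[c]]]], na.rm = TRUE)
  }, numeric(1L))
  keys <- vapply(ch, function(c) .set_key(phy$tip.label[clades[[c]]]),
                 character(1L))
  ch[order(ntaxa, ntips, chars, keys, decreasing = c(FALSE, FALSE, FALSE, TRUE),
           method = "radix")[1L]]
}

# Preorder internal nodes (root first) of a phylo.
.preorder_internal <- function(phy) {
  eo <- ape::reorder.phylo(phy, "cladewise")$edge
  unique(eo[, 1L])
}

#' Prune paralogs from a rooted tree (RT)
#'
#' Traverses a rooted ingroup tree from the root toward the tips. At the
#' first node whose child subtrees share at least one taxon (a gene
#' duplication), the side with fewer distinct taxa is pruned to maximise
#' taxon occupancy in the remainder. When `reprocess` is `TRUE` the pruned
#' side re-enters the candidate pool as its own rooted subtree and is
#' decomposed in the same way; with `FALSE` pruned sides are discarded.
#' Pruning repeats until no candidate contains a taxon duplication; all
#' duplication-free candidates with at least `min_taxa` distinct taxa are
#' returned. Ties for the smaller side break by fewer tips, then fewer
#' total unambiguous characters, then lexicographically (the side with the
#' smallest identifiers survives). Polytomies are handled by pruning one
#' child at a time until no pairwise overlap remains.
#'
#' @param phy a rooted tree (from [extract_rooted_ingroup_clades()]).
#' @param min_taxa minimum distinct taxa per ortholog, default 8.
#' @param counts,scheme see [prune_mi()].
#' @param reprocess reprocess pruned sides (default `TRUE`).
#' @param check_rooted error on unrooted input (default `TRUE`). Internal
#'   callers pass `FALSE` for clades that are rooted by construction even
#'   when their root is a polytomy.
#' @return List of ortholog trees (method tag `"RT"`).
#' @export
prune_paralogs_rt <- function(phy, min_taxa = 8L, counts = NULL,
                              scheme = taxon_scheme(), reprocess = TRUE,
                              check_rooted = TRUE) {
  if (check_rooted && !ape::is.rooted(phy))
    stop("prune_paralogs_rt requires a rooted tree", call. = FALSE)
  queue <- list(phy)
  out <- list()
  while (length(queue)) {
    t <- queue[[1L]]
    queue <- queue[-1L]
    if (is.null(t) || .n_tip(t) < 2L) next
    taxa <- .tip_taxa(t, scheme)
    if (anyDuplicated(taxa) == 0L) {
      if (length(unique(taxa)) >= min_taxa)
        out[[length(out) + 1L]] <- .as_ortholog(t, "RT")
      next
    }
    clades <- .clade_tips(t)
    pruned <- FALSE
    for (node in .preorder_internal(t)) {
      victim <- .dup_prune_child(t, node, clades, taxa, counts)
      if (victim == 0L) next
      side <- t$tip.label[clades[[victim]]]
      if (reprocess) {
        sub <- .keep_tips(t, side)
        if (!is.null(sub)) queue[[length(queue) + 1L]] <- sub
      }
      queue[[length(queue) + 1L]] <- .drop_tips(t, side)
      pruned <- TRUE
      break
    }
    if (!pruned) {
      # duplication exists but only between... cannot happen: a duplicated
      # taxon always shows overlap at the MRCA of two of its tips
      stop("internal error: duplication not localised", call. = FALSE)
    }
  }
  out
}

#' Monophyletic-outgroup (MO) ortholog extraction
#'
#' Requires the outgroup tips to be non-repeating (no outgroup taxon
#' appears twice) and monophyletic in the unrooted sense (some edge
#' separates exactly the outgroup tips from all ingroup tips); otherwise
#' nothing is returned. The tree is rooted on that edge and the RT
#' root-to-tip duplication pruning is run on the ingroup side, keeping the
#' larger side at each duplication and discarding pruned sides, so at most
#' one ortholog is produced per homolog; the surviving ingroup taxa plus
#' the full outgroup clade are retained.
#'
#' @param phy a homolog tree containing at least one outgroup tip.
#' @param roles a [taxon_roles()].
#' @param min_taxa minimum distinct taxa (ingroup + outgroup) to return.
#' @param counts,scheme see [prune_mi()].
#' @return A rooted ortholog tree (method tag `"MO"`), or `NULL`.
#' @export
prune_paralogs_mo <- function(phy, roles, min_taxa = 8L, counts = NULL,
                              scheme = taxon_scheme()) {
  stopifnot(inherits(roles, "taxon_roles"))
  taxa <- .tip_taxa(phy, scheme)
  og_tips <- phy$tip.label[taxa %in% roles$outgroup]
  if (length(og_tips) == 0L) return(NULL)
  in_tips <- setdiff(phy$tip.label, og_tips)
  if (length(in_tips) == 0L) return(NULL)
  if (anyDuplicated(parse_taxon(og_tips, scheme)) > 0L) return(NULL)
  # unrooted monophyly: some edge-delimited set equals the outgroup tips
  clades <- .clade_tips(phy)
  sets <- lapply(clades, function(s) phy$tip.label[s])
  og_key <- .set_key(og_tips)
  in_key <- .set_key(in_tips)
  keys <- vapply(sets, .set_key, character(1L))
  if (!(og_key %in% keys || in_key %in% keys)) return(NULL)
  rooted <- if (length(og_tips) == 1L || og_key %in% keys) {
    ape::root(phy, outgroup = og_tips, resolve.root = TRUE)
  } else {
    # outgroup spans the stored root; rooting on the ingroup clade edge
    # yields the same unrooted split
    ape::root(phy, outgroup = in_tips, resolve.root = TRUE)
  }
  in_sub <- if (length(in_tips) >= 2L) .keep_tips(rooted, in_tips) else NULL
  if (is.null(in_sub)) {
    survivors <- in_tips
  } else {
    t <- in_sub
    repeat {
      tx <- .tip_taxa(t, scheme)
      if (anyDuplicated(tx) == 0L) break
      cl <- .clade_tips(t)
      done <- FALSE
      for (node in .preorder_internal(t)) {
        victim <- .dup_prune_child(t, node, cl, tx, counts)
        if (victim == 0L) next
        t2 <- .drop_tips(t, t$tip.label[cl[[victim]]])
        if (is.null(t2)) return(NULL)
        t <- t2
        done <- TRUE
        break
      }
      if (!done) stop("internal error: duplication not localised", call. = FALSE)
    }
    survivors <- t$tip.label
  }
  keep <- c(survivors, og_tips)
  if (length(unique(parse_taxon(keep, scheme))) < min_taxa) return(NULL)
  res <- .keep_tips(rooted, keep)
  if (is.null(res)) return(NULL)
  .as_ortholog(res, "MO")
}

#' Strict one-to-one ortholog filter
#'
#' Returns the whole homolog tree iff it contains no taxon duplication and
#' at least `min_taxa` distinct taxa.
#'
#' @param phy a cleaned homolog tree.
#' @param min_taxa minimum distinct taxa, default 8.
#' @param scheme a [taxon_scheme()].
#' @return The tree (method tag `"1to1"`), or `NULL`.
#' @export
filter_1to1 <- function(phy, min_taxa = 8L, scheme = taxon_scheme()) {
  taxa <- .tip_taxa(phy, scheme)
  if (anyDuplicated(taxa) > 0L) return(NULL)
  if (length(unique(taxa)) < min_taxa) return(NULL)
  .as_ortholog(phy, "1to1")
}

#' Run one orthology-inference method over a homolog set
#'
#' Dispatches MI, RT, MO or 1to1 over a named list of cleaned homolog
#' trees and assembles a per-homolog report plus an ortholog-by-taxon
#' occupancy table (the data behind taxon-occupancy curves). RT handling
#' of outgroup-free homologs follows the published rule: duplication-free
#' ones are included as unrooted ortholog trees; homologs with duplicated
#' taxa but no outgroup taxa are skipped.
#'
#' @param homologs named list of `phylo` trees.
#' @param method one of `"MI"`, `"RT"`, `"MO"`, `"1to1"`.
#' @param roles a [taxon_roles()]; required for RT and MO.
#' @param min_taxa minimum distinct taxa per ortholog.
#' @param cfg a [refine_config()] (MI remainder trimming).
#' @param counts_list optional named list of per-homolog character counts.
#' @param scheme a [taxon_scheme()].
#' @param rt_reprocess reprocess pruned sides in RT (default `TRUE`).
#' @return `list(orthologs, report, occupancy)`: a named list of ortholog
#'   trees (`<homolog>.<k>`), a data.frame with per-homolog ortholog and
#'   tip counts, and a logical ortholog-by-taxon matrix.
#' @export
run_method <- function(homologs, method = c("MI", "RT", "MO", "1to1"),
                       roles = NULL, min_taxa = 8L, cfg = refine_config(),
                       counts_list = NULL, scheme = taxon_scheme(),
                       rt_reprocess = TRUE) {
  method <- match.arg(method)
  if (method %in% c("RT", "MO") && is.null(roles))
    stop(method, " requires taxon roles (outgroups)", call. = FALSE)
  if (is.null(names(homologs)) && length(homologs))
    names(homologs) <- paste0("homolog", seq_along(homologs))
  orthologs <- list()
  rows <- list()
  for (h in names(homologs)) {
    phy <- homologs[[h]]
    counts <- if (is.null(counts_list)) NULL else counts_list[[h]]
    res <- switch(method,
      MI = prune_mi(phy, min_taxa, cfg, counts, scheme),
      `1to1` = {
        r <- filter_1to1(phy, min_taxa, scheme)
        if (is.null(r)) list() else list(r)
      },
      MO = {
        r <- prune_paralogs_mo(phy, roles, min_taxa, counts, scheme)
        if (is.null(r)) list() else list(r)
      },
      RT = {
        taxa <- .tip_taxa(phy, scheme)
        if (!any(taxa %in% roles$outgroup)) {
          if (anyDuplicated(taxa) == 0L &&
              length(unique(taxa)) >= min_taxa) {
            list(.as_ortholog(phy, "RT"))
          } else list()      # duplicated taxa, no outgroup: ignored
        } else {
          clades <- extract_rooted_ingroup_clades(phy, roles, min_taxa,
                                                  counts, scheme)
          do.call(c, c(list(list()), lapply(clades, prune_paralogs_rt,
                                            min_taxa = min_taxa,
                                            counts = counts, scheme = scheme,
                                            reprocess = rt_reprocess,
                                            check_rooted = FALSE)))
        }
      })
    if (length(res)) {
      names(res) <- paste0(h, ".", seq_along(res))
      for (k in names(res)) attr(res[[k]], "source_homolog") <- h
      orthologs <- c(orthologs, res)
    }
    rows[[h]] <- data.frame(
      homolog = h, method = method, tips_in = .n_tip(phy),
      n_orthologs = length(res),
      tips_emitted = sum(vapply(res, .n_tip, integer(1L))),
      stringsAsFactors = FALSE)
  }
  report <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  all_taxa <- sort(unique(unlist(lapply(homologs, .tip_taxa, scheme = scheme))))
  occ <- matrix(FALSE, nrow = length(orthologs), ncol = length(all_taxa),
                dimnames = list(names(orthologs), all_taxa))
  for (k in names(orthologs))
    occ[k, unique(.tip_taxa(orthologs[[k]], scheme))] <- TRUE
  list(orthologs = orthologs, report = report, occupancy = occ)
}
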