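# Homolog-tree cleaning: cut deep paralogs at long internal branches, trim
# spurious long tips, and mask monophyletic/paraphyletic same-taxon
# (isoform) tips.

#' Refinement configuration
#'
#' Numeric cutoffs for homolog-tree cleaning. The branch-length units are
#' substitutions per site. Published per-dataset values are available via
#' [dataset_preset()]; the package defaults here are tuned to the
#' simulator's unit tree depth (see the methods vignette).
#'
#' @param internal_branch_cutoff internal edges longer than this are cut,
#'   separating deep paralogs (e.g. 1.5 MIL / 1.0 HYM / 0.3 GRP).
#' @param tip_absolute_cutoff minimum absolute pendant length for a tip to
#'   be considered spurious (e.g. 0.75 MIL / 0.6 HYM / 0.1 GRP).
#' @param tip_relative_factor a tip must also be more than this many times
#'   longer than the mean distance to the tips of its sister clade.
#'   Default 10.
#' @param min_subtree_taxa subtrees with fewer distinct taxa are discarded.
#'   Default 8.
#' @param mask_paraphyletic mask paraphyletic same-taxon grades as well as
#'   monophyletic clades. Default `TRUE`.
#' @param scheme a [taxon_scheme()].
#' @return An object of class `refine_config`.
#' @export
refine_config <- function(internal_branch_cutoff = 1.0,
                          tip_absolute_cutoff = 0.05,
                          tip_relative_factor = 10,
                          min_subtree_taxa = 8L,
                          mask_paraphyletic = TRUE,
                          scheme = taxon_scheme()) {
  stopifnot(internal_branch_cutoff > 0, tip_absolute_cutoff > 0,
            tip_relative_factor >= 1, min_subtree_taxa >= 1)
  structure(list(internal_branch_cutoff = internal_branch_cutoff,
                 tip_absolute_cutoff = tip_absolute_cutoff,
                 tip_relative_factor = tip_relative_factor,
                 min_subtree_taxa = as.integer(min_subtree_taxa),
                 mask_paraphyletic = isTRUE(mask_paraphyletic),
                 scheme = scheme),
            class = "refine_config")
}

#' Cut long internal branches into subtrees
#'
#' Removes every internal edge longer than `cfg$internal_branch_cutoff`;
#' each resulting connected component becomes its own subtree. The cut is
#' applied recursively, so merged edges created by suppressing
#' unifurcations are re-checked: no retained subtree contains an internal
#' edge above the cutoff. Components with fewer than `cfg$min_subtree_taxa`
#' distinct taxa (or fewer than two tips) are discarded.
#'
#' @param phy a `phylo` with branch lengths (missing lengths are treated as
#'   0 with a warning).
#' @param cfg a [refine_config()].
#' @return List of `phylo` subtrees (possibly empty).
#' @export
cut_long_internal_branches <- function(phy, cfg = refine_config()) {
  pieces <- .cut_recurse(phy, cfg$internal_branch_cutoff)
  keep <- vapply(pieces, function(p) {
    length(unique(.tip_taxa(p, cfg$scheme))) >= cfg$min_subtree_taxa
  }, logical(1L))
  pieces[keep]
}

.cut_recurse <- function(phy, cutoff) {
  if (is.null(phy) || .n_tip(phy) < 2L) return(list())
  el <- .len_or_zero(phy)
  internal <- phy$edge[, 2L] > .n_tip(phy)
  long <- which(internal & el > cutoff)
  if (length(long) == 0L) return(list(phy))
  child <- phy$edge[long[1L], 2L]
  clade <- phy$tip.label[.clade_tips(phy)[[child]]]
  c(.cut_recurse(.keep_tips(phy, clade), cutoff),
    .cut_recurse(.drop_tips(phy, clade), cutoff))
}

# Mean path length from a tip's attachment node to every tip of its sister
# clade(s), including the sibling edge. At a basal polytomy all co-child
# subtrees are pooled.
.sister_mean_depth <- function(phy, tip, parents, depths, clades) {
  a <- parents[tip]
  sibs <- setdiff(clades[[a]], tip)
  if (length(sibs) == 0L) return(NA_real_)
  mean(depths[sibs] - depths[a])
}

#' Trim spurious long tips
#'
#' A tip is removed when its pendant branch is both more than
#' `tip_relative_factor` times the mean distance from its attachment node
#' to the tips of its sister clade (sibling edge included) and longer than
#' `tip_absolute_cutoff`. Tips are processed worst-first (longest pendant)
#' and the tree statistics are recomputed after each removal, iterating to
#' a fixpoint. Unifurcations left behind are suppressed with branch lengths
#' merged additively.
#'
#' @param phy a `phylo` with at least 3 tips.
#' @param cfg a [refine_config()].
#' @return The trimmed tree, with the removed labels in
#'   `attr(, "trimmed_tips")`. If trimming reduces the tree below 3 tips
#'   the remainder is returned with a warning.
#' @export
trim_spurious_tips <- function(phy, cfg = refine_config()) {
  removed <- character()
  repeat {
    if (.n_tip(phy) < 3L) {
      if (length(removed)) warning("tree reduced below 3 tips by trimming",
                                   call. = FALSE)
      break
    }
    el <- .len_or_zero(phy, "tip branch")
    parents <- .parents(phy)
    depths <- .node_depths(phy)
    clades <- .clade_tips(phy)
    pend <- .pendant_len(phy, el)
    victim <- NA_integer_
    for (tip in order(pend, decreasing = TRUE)) {
      m <- .sister_mean_depth(phy, tip, parents, depths, clades)
      if (is.na(m)) next
      if (pend[tip] > cfg$tip_relative_factor * m &&
          pend[tip] > cfg$tip_absolute_cutoff) {
        victim <- tip
        break
      }
    }
    if (is.na(victim)) break
    removed <- c(removed, phy$tip.label[victim])
    nxt <- .drop_tips(phy, phy$tip.label[victim])
    if (is.null(nxt)) {
      warning("tree reduced below 2 tips by trimming", call. = FALSE)
      break
    }
    phy <- nxt
  }
  attr(phy, "trimmed_tips") <- removed
  phy
}

#' Mask redundant same-taxon (isoform) tips
#'
#' De novo transcriptomes carry isoforms that appear as monophyletic or
#' paraphyletic same-taxon tips. These are collapsed to the single member
#' with the highest number of unambiguous characters in the trimmed
#' alignment (ties break to the lexicographically smallest identifier),
#' iterating to a fixpoint:
#'
#' * monophyletic: two same-taxon tips attached to the same node collapse
#'   to the better one (repeated application collapses whole same-taxon
#'   clades);
#' * paraphyletic (when `cfg$mask_paraphyletic`): a tip whose grandparent
#'   has a same-taxon tip child collapses with it, so same-taxon grades
#'   walking up the tree are reduced to one representative.
#'
#' At the fixpoint no tip's sister subtree consists entirely of its own
#' taxon.
#'
#' @param phy a `phylo`.
#' @param char_counts named numeric vector of unambiguous character counts
#'   (see [count_unambiguous()]) covering every tip.
#' @param cfg a [refine_config()].
#' @return The masked tree with removed labels in `attr(, "masked_tips")`,
#'   or `NULL` if masking would leave fewer than two tips.
#' @export
mask_redundant_tips <- function(phy, char_counts, cfg = refine_config()) {
  miss <- setdiff(phy$tip.label, names(char_counts))
  if (length(miss))
    stop("tip(s) missing from char_counts: ",
         paste(utils::head(miss, 5L), collapse = ", "), call. = FALSE)
  removed <- character()
  repeat {
    if (is.null(phy) || .n_tip(phy) < 2L) break
    loser <- .find_mask_victim(phy, char_counts, cfg)
    if (is.null(loser)) break
    removed <- c(removed, loser)
    phy <- .drop_tips(phy, loser)
  }
  if (!is.null(phy)) attr(phy, "masked_tips") <- removed
  phy
}

# One masking step: returns the label to remove, or NULL at fixpoint.
.find_mask_victim <- function(phy, counts, cfg) {
  taxa <- .tip_taxa(phy, cfg$scheme)
  parents <- .parents(phy)
  n <- .n_tip(phy)
  ord <- order(phy$tip.label)
  worse <- function(i, j) {
    # returns the label of the worse of tips i, j
    ci <- counts[[phy$tip.label[i]]]; cj <- counts[[phy$tip.label[j]]]
    if (ci != cj) return(phy$tip.label[if (ci < cj) i else j])
    if (phy$tip.label[i] < phy$tip.label[j]) phy$tip.label[j] else phy$tip.label[i]
  }
  # monophyletic: same-taxon tip co-children
  for (t in ord) {
    sibs <- .children(phy, parents[t])
    for (s in sibs) {
      if (s != t && s <= n && taxa[s] == taxa[t]) return(worse(t, s))
    }
  }
  if (!cfg$mask_paraphyletic) return(NULL)
  # paraphyletic: tip vs same-taxon tip child of its grandparent
  for (t in ord) {
    p <- parents[t]
    if (p == 0L) next
    g <- parents[p]
    if (g == 0L) next
    uncles <- setdiff(.children(phy, g), p)
    for (u in uncles) {
      if (u <= n && taxa[u] == taxa[t]) return(worse(t, u))
    }
  }
  NULL
}

#' Clean one homolog tree
#'
#' Full refinement pipeline: [trim_spurious_tips()], then
#' [mask_redundant_tips()], then [cut_long_internal_branches()], then the
#' minimum-taxa size filter. Character counts are computed from the trimmed
#' homolog alignment when one is supplied.
#'
#' @param phy a `phylo` whose tips are a subset of the alignment rows.
#' @param alignment named character vector (aligned rows), or `NULL` when
#'   `char_counts` is given directly.
#' @param cfg a [refine_config()].
#' @param char_counts optional named numeric vector overriding the counts
#'   derived from `alignment`; when both are absent all counts are 0 and
#'   masking ties break lexicographically.
#' @param alphabet alphabet tag for [count_unambiguous()].
#' @return List of cleaned homolog trees (possibly empty), with a decision
#'   log in `attr(, "log")`: a data.frame of actions (`trim`, `mask`,
#'   `cut`) with the affected tips.
#' @export
refine_homolog <- function(phy, alignment = NULL, cfg = refine_config(),
                           char_counts = NULL, alphabet = "aa") {
  if (is.null(char_counts)) {
    char_counts <- if (is.null(alignment)) {
      setNames(numeric(length(phy$tip.label)), phy$tip.label)
    } else {
      .check_alignment(alignment)
      setNames(count_unambiguous(alignment, alphabet), names(alignment))
    }
  }
  log <- data.frame(action = character(), tip = character(),
                    stringsAsFactors = FALSE)
  t1 <- trim_spurious_tips(phy, cfg)
  trimmed <- attr(t1, "trimmed_tips")
  if (length(trimmed))
    log <- rbind(log, data.frame(action = "trim", tip = trimmed))
  t2 <- mask_redundant_tips(t1, char_counts, cfg)
  if (is.null(t2)) {
    out <- list()
    attr(out, "log") <- log
    return(out)
  }
  masked <- attr(t2, "masked_tips")
  if (length(masked))
    log <- rbind(log, data.frame(action = "mask", tip = masked))
  out <- cut_long_internal_branches(t2, cfg)
  cut_away <- setdiff(t2$tip.label, unlist(lapply(out, `[[`, "tip.label")))
  if (length(cut_away))
    log <- rbind(log, data.frame(action = "cut", tip = cut_away))
  attr(out, "log") <- log
  out
}
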