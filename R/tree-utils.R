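# Internal helpers over ape::phylo objects. All pruning algorithms in the
# package go through these so that edge bookkeeping (ape renumbers nodes on
# every drop/keep) stays in one place.

.n_tip <- function(phy) length(phy$tip.label)

.root_node <- function(phy) .n_tip(phy) + 1L

# Parent of every node (0 for the root), indexed by node number.
.parents <- function(phy) {
  par <- integer(.n_tip(phy) + phy$Nnode)
  par[phy$edge[, 2L]] <- phy$edge[, 1L]
  par
}

.children <- function(phy, node) phy$edge[phy$edge[, 1L] == node, 2L]

# Edge lengths with a distinct missing state preserved (NA), never silent 0.
.edge_len <- function(phy) {
  if (is.null(phy$edge.length)) rep(NA_real_, nrow(phy$edge)) else phy$edge.length
}

# Lengths for cutoff comparisons: missing treated as 0 with a warning.
.len_or_zero <- function(phy, what = "branch") {
  el <- .edge_len(phy)
  if (anyNA(el)) {
    warning(sprintf("missing %s lengths treated as 0 for cutoff comparisons", what),
            call. = FALSE)
    el[is.na(el)] <- 0
  }
  el
}

# Tip indices under each node (node's own index for tips), as a list over
# 1..(Ntip + Nnode). One postorder pass over the edge matrix.
.clade_tips <- function(phy) {
  n <- .n_tip(phy)
  res <- vector("list", n + phy$Nnode)
  for (i in seq_len(n)) res[[i]] <- i
  eo <- ape::reorder.phylo(phy, "postorder")$edge
  for (k in seq_len(nrow(eo))) {
    res[[eo[k, 1L]]] <- c(res[[eo[k, 1L]]], res[[eo[k, 2L]]])
  }
  res
}

# Root-to-node path lengths (missing lengths as 0, no warning: callers that
# care about missingness warn via .len_or_zero first).
.node_depths <- function(phy) {
  el <- .edge_len(phy)
  el[is.na(el)] <- 0
  tmp <- phy
  tmp$edge.length <- el
  ape::node.depth.edgelength(tmp)
}

# Keep exactly `labels`; returns NULL when fewer than 2 tips would remain
# (a phylo cannot represent them).
.keep_tips <- function(phy, labels) {
  labels <- unique(labels)
  if (length(labels) < 2L) return(NULL)
  if (length(labels) == .n_tip(phy)) return(phy)
  ape::keep.tip(phy, labels)
}

.drop_tips <- function(phy, labels) {
  .keep_tips(phy, setdiff(phy$tip.label, labels))
}

# Pendant edge length of a tip (by index), missing as 0.
.pendant_len <- function(phy, el = .edge_len(phy)) {
  n <- .n_tip(phy)
  out <- numeric(n)
  idx <- match(seq_len(n), phy$edge[, 2L])
  out[] <- el[idx]
  out[is.na(out)] <- 0
  out
}

# Deterministic, locale-independent ordering key for a tip-label set.
# Joining with a separator below all printable characters makes string
# comparison of keys equivalent to elementwise tuple comparison.
.set_key <- function(labels) {
  paste(sort(labels, method = "radix"), collapse = "\r")
}

# Internal seeded-evaluation helper: runs expr with a local RNG state.
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
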