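# Per-ortholog alignments, occupancy trimming and filtering, supermatrix
# concatenation with per-locus partitions, locus-intact jackknife
# resampling, and bipartition support summaries.

.gapchars <- c("-", "?")

# Logical matrix of occupied (non-gap, non-'?') cells, shape-preserving.
.occupied <- function(m) {
  matrix(!(m %in% .gapchars), nrow = nrow(m), dimnames = dimnames(m))
}

#' Extract a per-ortholog alignment from its homolog alignment
#'
#' Keeps only the ortholog's rows, relabels each row by its taxon, and
#' removes columns that became all-gap in the kept rows.
#'
#' @param alignment named character vector (the homolog alignment).
#' @param tip_ids the ortholog's tip identifiers (must be alignment rows,
#'   one per taxon).
#' @param id locus identifier.
#' @param type character type, `"aa"` or `"nt"`.
#' @param scheme a [taxon_scheme()].
#' @return A locus: `list(id, aln, length, type)` where `aln` is a named
#'   character vector with taxa as names.
#' @export
extract_ortholog_alignment <- function(alignment, tip_ids, id = "locus",
                                       type = c("aa", "nt"),
                                       scheme = taxon_scheme()) {
  type <- match.arg(type)
  .check_alignment(alignment)
  miss <- setdiff(tip_ids, names(alignment))
  if (length(miss))
    stop("ortholog tip(s) absent from alignment: ",
         paste(utils::head(miss, 5L), collapse = ", "), call. = FALSE)
  rows <- alignment[tip_ids]
  taxa <- parse_taxon(tip_ids, scheme)
  if (anyDuplicated(taxa))
    stop("duplicate taxon after relabelling; the ortholog invariant was ",
         "violated upstream", call. = FALSE)
  names(rows) <- taxa
  m <- .aln_matrix(rows)
  keep <- colSums(.occupied(m)) > 0L
  m <- m[, keep, drop = FALSE]
  list(id = id, aln = .matrix_aln(m), length = ncol(m), type = type)
}

#' Trim alignment columns by occupancy
#'
#' Removes every column whose fraction of occupied cells (not `-`, not
#' `?`; ambiguity codes count as occupied) is below `min_fraction` --- the
#' interpretation of Phyutility's `-clean` threshold. Idempotent; row
#' order preserved.
#'
#' @param locus a locus as from [extract_ortholog_alignment()].
#' @param min_fraction minimum occupied fraction in (0, 1].
#' @return The trimmed locus (possibly of length 0, flagged for downstream
#'   filtering).
#' @export
trim_columns_by_occupancy <- function(locus, min_fraction) {
  stopifnot(min_fraction > 0, min_fraction <= 1)
  if (locus$length == 0L) return(locus)
  m <- .aln_matrix(locus$aln)
  occ <- colMeans(.occupied(m))
  m <- m[, occ >= min_fraction, drop = FALSE]
  locus$aln <- .matrix_aln(m)
  locus$length <- ncol(m)
  locus
}

#' Filter loci by trimmed length and taxon occupancy
#'
#' @param loci list of (trimmed) loci.
#' @param min_length minimum trimmed length (e.g. 100 aa or 300 nt).
#' @param max_missing_taxa maximum number of taxa a locus may miss out of
#'   `taxa` (0 requires the full taxon set).
#' @param taxa the full taxon set.
#' @return The loci that pass both filters.
#' @export
filter_loci <- function(loci, min_length, max_missing_taxa, taxa) {
  keep <- vapply(loci, function(l) {
    l$length >= min_length &&
      (length(taxa) - sum(taxa %in% names(l$aln))) <= max_missing_taxa
  }, logical(1L))
  loci[keep]
}

#' Concatenate loci into a partitioned supermatrix
#'
#' Loci are concatenated in lexicographic locus-id order; taxon-by-locus
#' blocks absent from a locus are filled with `-`. The partition table
#' gives each locus a contiguous 1-based inclusive column interval and the
#' intervals cover `1..total` without overlap.
#'
#' @param loci list of loci of a uniform character type.
#' @param taxa the full taxon set (matrix rows).
#' @return A supermatrix: `list(seqs, partitions, type)` with `seqs` a
#'   named character vector over `taxa` and `partitions` a data.frame with
#'   `locus`, `start`, `end`.
#' @export
concatenate_loci <- function(loci, taxa) {
  if (length(loci) == 0L) stop("nothing to concatenate", call. = FALSE)
  types <- unique(vapply(loci, `[[`, character(1L), "type"))
  if (length(types) != 1L)
    stop("cannot concatenate mixed character types: ",
         paste(types, collapse = ", "), call. = FALSE)
  ids <- vapply(loci, `[[`, character(1L), "id")
  if (anyDuplicated(ids)) stop("duplicate locus ids", call. = FALSE)
  loci <- loci[order(ids)]
  parts <- data.frame(locus = sort(ids),
                      start = NA_integer_, end = NA_integer_)
  blocks <- vector("list", length(loci))
  pos <- 0L
  for (i in seq_along(loci)) {
    l <- loci[[i]]
    parts$start[i] <- pos + 1L
    parts$end[i] <- pos + l$length
    pos <- pos + l$length
    filler <- strrep("-", l$length)
    block <- setNames(rep(filler, length(taxa)), taxa)
    present <- intersect(taxa, names(l$aln))
    block[present] <- l$aln[present]
    blocks[[i]] <- block
  }
  seqs <- setNames(do.call(paste0, blocks), taxa)
  structure(list(seqs = seqs, partitions = parts, type = types),
            class = "supermatrix")
}

#' Occupancy statistics of a supermatrix
#'
#' @param sm a supermatrix from [concatenate_loci()].
#' @return `list(overall, per_taxon, locus_taxon_counts)`: the fraction of
#'   non-gap, non-`?` cells overall and per taxon, and the per-locus
#'   distinct-taxon counts sorted descending (the taxon-occupancy curve).
#' @export
occupancy_stats <- function(sm) {
  m <- .aln_matrix(sm$seqs)
  occ <- .occupied(m)
  per_taxon <- rowMeans(occ)
  names(per_taxon) <- rownames(m)
  counts <- integer(nrow(sm$partitions))
  names(counts) <- sm$partitions$locus
  for (i in seq_len(nrow(sm$partitions))) {
    cols <- seq.int(sm$partitions$start[i], sm$partitions$end[i])
    counts[i] <- sum(rowSums(occ[, cols, drop = FALSE]) > 0L)
  }
  list(overall = mean(occ), per_taxon = per_taxon,
       locus_taxon_counts = sort(counts, decreasing = TRUE))
}

#' Locus-intact jackknife resampling
#'
#' Draws `replicates` manifests of distinct loci without replacement,
#' keeping every locus intact (columns are never resampled). In
#' `"proportion"` mode each replicate holds `round(value * n)` loci
#' (round half up, at least 1); in `"count"` mode exactly `value` loci.
#'
#' @param loci list of loci, or a character vector of locus ids.
#' @param mode `"proportion"` or `"count"`.
#' @param value proportion in (0, 1\] or a positive integer count.
#' @param replicates number of replicates, default 200.
#' @param seed RNG seed for reproducible manifests.
#' @return List of `replicates` character vectors of locus ids, with the
#'   replicate size in `attr(, "size")`.
#' @export
jackknife_by_locus <- function(loci, mode = c("proportion", "count"),
                               value, replicates = 200L, seed = NULL) {
  mode <- match.arg(mode)
  ids <- if (is.character(loci)) loci else
    vapply(loci, `[[`, character(1L), "id")
  n <- length(ids)
  size <- if (mode == "proportion") {
    stopifnot(value > 0, value <= 1)
    max(1L, as.integer(floor(value * n + 0.5)))
  } else {
    v <- as.integer(value)
    if (v > n) stop("count exceeds the number of loci", call. = FALSE)
    stopifnot(v >= 1L)
    v
  }
  manifests <- .with_seed(seed, {
    lapply(seq_len(replicates), function(r) sort(sample(ids, size)))
  })
  attr(manifests, "size") <- size
  manifests
}

#' Materialise jackknife replicate supermatrices
#'
#' @param loci list of loci.
#' @param manifests output of [jackknife_by_locus()].
#' @param taxa full taxon set.
#' @return List of supermatrices, one per manifest.
#' @export
materialize_jackknife <- function(loci, manifests, taxa) {
  ids <- vapply(loci, `[[`, character(1L), "id")
  lapply(manifests, function(m) concatenate_loci(loci[ids %in% m], taxa))
}

#' Annotate a reference tree with jackknife bipartition support
#'
#' Each internal edge of the reference is labelled with the percentage of
#' replicate trees containing the same unordered bipartition (unrooted
#' comparison). Trees are pruned to the taxa shared by the reference and
#' all replicates.
#'
#' @param ref reference `phylo`.
#' @param replicates list of replicate `phylo` trees (at least one).
#' @return The reference tree with support percentages as `node.label` and
#'   the numeric vector in `attr(, "support")`.
#' @export
bipartition_support <- function(ref, replicates) {
  if (inherits(replicates, "phylo")) replicates <- list(replicates)
  if (length(replicates) < 1L)
    stop("at least one replicate tree is required", call. = FALSE)
  shared <- Reduce(intersect, c(list(ref$tip.label),
                                lapply(replicates, `[[`, "tip.label")))
  if (length(shared) < 4L)
    stop("fewer than 4 shared taxa across trees", call. = FALSE)
  ref2 <- .keep_tips(ref, shared)
  reps <- lapply(replicates, .keep_tips, labels = shared)
  counts <- ape::prop.clades(ref2, reps, rooted = FALSE)
  counts[is.na(counts)] <- 0L
  pct <- 100 * counts / length(reps)
  lab <- format(round(pct, 1L), trim = TRUE)
  lab[1L] <- ""   # root "clade" carries no bipartition
  ref2$node.label <- lab
  attr(ref2, "support") <- pct
  ref2
}

#' Write a supermatrix to FASTA or relaxed PHYLIP
#'
#' @param sm a supermatrix.
#' @param file output path.
#' @param format `"fasta"` or `"phylip"`.
#' @return `file`, invisibly.
#' @export
write_supermatrix <- function(sm, file, format = c("fasta", "phylip")) {
  format <- match.arg(format)
  if (format == "fasta") {
    write_fasta(sm$seqs, file)
  } else {
    ncol <- nchar(sm$seqs[[1L]])
    con <- file(file, "w")
    on.exit(close(con))
    writeLines(paste(length(sm$seqs), ncol), con)
    writeLines(paste(names(sm$seqs), sm$seqs), con)
  }
  invisible(file)
}

#' Write a RAxML-style partition file
#'
#' One line per locus, `MODEL, locus = start-end`.
#'
#' @param sm a supermatrix.
#' @param file output path.
#' @param model model token; defaults to `WAG` for amino acids and `DNA`
#'   for nucleotides.
#' @return `file`, invisibly.
#' @export
write_partitions <- function(sm, file, model = NULL) {
  if (is.null(model)) model <- if (sm$type == "aa") "WAG" else "DNA"
  lines <- sprintf("%s, %s = %d-%d", model, sm$partitions$locus,
                   sm$partitions$start, sm$partitions$end)
  writeLines(lines, file)
  invisible(file)
}
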