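# From raw all-by-all similarity hits to MCL-ready graphs and filtered
# clusters. BLAST and MCL themselves are external; this module reads and
# writes their formats.

.blast_cols <- c("query", "subject", "pident", "length", "mismatch",
                 "gapopen", "qstart", "qend", "sstart", "send",
                 "evalue", "bitscore", "qlen", "slen")

#' Read an all-by-all similarity table (BLAST outfmt 6 style)
#'
#' Expects the standard 12 tabular columns plus `qlen` and `slen` appended
#' (i.e. `-outfmt "6 std qlen slen"`). Reversed subject intervals (minus
#' strand) are normalised so that start <= end. Plain and gzip input are
#' both accepted.
#'
#' @param file path to the tabular file.
#' @param col_names column names in file order; override for non-standard
#'   column maps. Must include `query`, `subject`, `qstart`, `qend`,
#'   `sstart`, `send`, `evalue`, `bitscore`, `qlen`, `slen`.
#' @return A `data.table`, one row per HSP.
#' @export
read_blast_table <- function(file, col_names = .blast_cols) {
  dt <- data.table::fread(file, header = FALSE, col.names = col_names,
                          sep = "\t")
  need <- c("query", "subject", "qstart", "qend", "sstart", "send",
            "evalue", "bitscore", "qlen", "slen")
  miss <- setdiff(need, names(dt))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  sstart <- send <- qstart <- qend <- NULL
  dt[sstart > send, c("sstart", "send") := .(send, sstart)]
  dt[qstart > qend, c("qstart", "qend") := .(qend, qstart)]
  dt[]
}

# Total residues covered by the union of 1-based inclusive intervals.
.covered <- function(starts, ends) {
  if (length(starts) == 0L) return(0L)
  sum(IRanges::width(IRanges::reduce(IRanges::IRanges(start = starts, end = ends))))
}

#' Coverage fraction of a query--subject hit
#'
#' Multiple HSPs for one pair are merged by interval union on each sequence
#' before computing the covered fraction. The default `"min"` mode requires
#' both sequences to reach the threshold (the stricter reading, which best
#' prevents snowballing clusters); `"max"` accepts coverage of either.
#'
#' @param hsps data.frame of the HSPs for one query--subject pair, with
#'   columns `qstart`, `qend`, `sstart`, `send`, `qlen`, `slen`.
#' @param mode `"min"` (both sequences) or `"max"` (either sequence).
#' @return A single value in \[0, 1\].
#' @export
hit_fraction <- function(hsps, mode = c("min", "max")) {
  mode <- match.arg(mode)
  qlen <- hsps$qlen[1L]
  slen <- hsps$slen[1L]
  if (is.na(qlen) || is.na(slen) || qlen <= 0 || slen <= 0)
    stop("sequence lengths must be positive", call. = FALSE)
  fq <- .covered(hsps$qstart, hsps$qend) / qlen
  fs <- .covered(hsps$sstart, hsps$send) / slen
  if (mode == "min") min(fq, fs) else max(fq, fs)
}

#' Filter similarity hits by hit fraction and E value
#'
#' Aggregates HSPs per query--subject pair (interval union for coverage,
#' best E value and bit score), drops self hits, keeps pairs with
#' `hit_fraction >= min_fraction` and `E <= evalue_cutoff`, and collapses
#' reciprocal duplicates to one undirected edge keeping the lowest-E
#' record.
#'
#' @param hits data.table/data.frame of HSPs as from [read_blast_table()].
#' @param min_fraction minimum hit fraction, default 0.4.
#' @param evalue_cutoff maximum E value, default 1e-5.
#' @param mode hit-fraction mode, see [hit_fraction()].
#' @return A `data.table` with one row per undirected edge: `id1`, `id2`
#'   (lexicographically ordered), `evalue`, `bitscore`, `hit_fraction`.
#' @export
filter_hits <- function(hits, min_fraction = 0.4, evalue_cutoff = 1e-5,
                        mode = c("min", "max")) {
  mode <- match.arg(mode)
  dt <- data.table::as.data.table(hits)
  empty <- data.table::data.table(id1 = character(), id2 = character(),
                                  evalue = numeric(), bitscore = numeric(),
                                  hit_fraction = numeric())
  if (nrow(dt) == 0L) return(empty)
  query <- subject <- qstart <- qend <- sstart <- send <- NULL
  qlen <- slen <- evalue <- bitscore <- frac <- id1 <- id2 <- NULL
  dt <- dt[query != subject]
  if (nrow(dt) == 0L) return(empty)
  agg <- dt[, .(
    evalue = min(evalue), bitscore = max(bitscore),
    frac = hit_fraction(.SD, mode = mode)
  ), by = .(query, subject),
  .SDcols = c("qstart", "qend", "sstart", "send", "qlen", "slen")]
  agg <- agg[frac >= min_fraction & evalue <= evalue_cutoff]
  if (nrow(agg) == 0L) return(empty)
  agg[, `:=`(id1 = pmin(query, subject), id2 = pmax(query, subject))]
  data.table::setorder(agg, id1, id2, evalue, -bitscore)
  und <- agg[, .(evalue = evalue[1L], bitscore = bitscore[1L],
                 hit_fraction = frac[1L]), by = .(id1, id2)]
  und[]
}

#' Write an MCL "abc" edge list
#'
#' One line per undirected edge, `id1 TAB id2 TAB weight`, with weight
#' `-log10(E)` capped at 180 (BLAST E values floor at 1e-180, so E = 0 maps
#' to 180) and floored at 0.
#'
#' @param edges output of [filter_hits()].
#' @param file output path.
#' @return The edge table with a `weight` column, invisibly.
#' @export
write_mcl_input <- function(edges, file) {
  w <- ifelse(edges$evalue <= 0, 180, pmin(180, pmax(0, -log10(edges$evalue))))
  out <- data.table::data.table(id1 = edges$id1, id2 = edges$id2, weight = w)
  data.table::fwrite(out, file, sep = "\t", col.names = FALSE)
  invisible(out)
}

#' Parse MCL cluster output into size- and length-filtered clusters
#'
#' MCL writes one tab-separated cluster per line. Members shorter than
#' `min_seq_length` residues (lengths measured on the supplied, typically
#' end-trimmed, sequences) are removed first; clusters left with fewer than
#' `min_taxa` distinct taxa are then dropped. Cluster ids are stable: they
#' index the input line.
#'
#' @param x path to the MCL output file, or a character vector of its
#'   lines.
#' @param sequences named character vector of residues (or named numeric
#'   lengths) covering every member id.
#' @param min_taxa minimum number of distinct taxa per cluster, default 8.
#' @param min_seq_length minimum member length in residues, default 40.
#' @param scheme a [taxon_scheme()].
#' @return A list of clusters; each is `list(id, members, taxa)`.
#' @export
parse_mcl_clusters <- function(x, sequences, min_taxa = 8L,
                               min_seq_length = 40L,
                               scheme = taxon_scheme()) {
  lines <- if (length(x) == 1L && file.exists(x)) readLines(x, warn = FALSE) else x
  lines <- lines[nzchar(trimws(lines))]
  lens <- if (is.character(sequences)) {
    setNames(nchar(sequences), names(sequences))
  } else {
    sequences
  }
  out <- list()
  for (i in seq_along(lines)) {
    members <- strsplit(trimws(lines[i]), "[\t ]+")[[1L]]
    miss <- setdiff(members, names(lens))
    if (length(miss))
      stop("cluster member(s) absent from sequences: ",
           paste(utils::head(miss, 5L), collapse = ", "), call. = FALSE)
    members <- members[lens[members] >= min_seq_length]
    if (length(members) == 0L) next
    taxa <- unique(parse_taxon(members, scheme))
    if (length(taxa) < min_taxa) next
    out[[length(out) + 1L]] <- list(id = paste0("cluster", i),
                                    members = members, taxa = taxa)
  }
  out
}

#' Trim sequence ends with no similarity support
#'
#' Ends without any hit are presumed misassembly or frameshift and are cut
#' off: the retained subsequence runs from the minimum covered start to the
#' maximum covered end. Interior uncovered gaps are kept. A sequence with
#' no hits at all becomes empty (and is then removed by the length filter
#' in [parse_mcl_clusters()]).
#'
#' @param seq a single residue string.
#' @param intervals two-column matrix/data.frame of 1-based inclusive
#'   covered ranges on `seq` (may be empty).
#' @return The trimmed residue string.
#' @export
trim_unsupported_ends <- function(seq, intervals) {
  iv <- as.matrix(intervals)
  if (length(iv) == 0L || nrow(iv) == 0L) return("")
  s <- max(1L, min(iv[, 1L]))
  e <- min(nchar(seq), max(iv[, 2L]))
  if (e < s) return("")
  substr(seq, s, e)
}

#' End-trim a sequence set using retained hits
#'
#' Convenience wrapper applying [trim_unsupported_ends()] to every
#' sequence, with per-sequence coverage pooled from the query and subject
#' intervals of the supplied (filtered) directed hit table.
#'
#' @param seqs named character vector of residues.
#' @param hits HSP table as from [read_blast_table()] (typically restricted
#'   to hits that survived [filter_hits()]).
#' @return Named character vector of trimmed sequences (possibly empty
#'   strings).
#' @export
end_trim_sequences <- function(seqs, hits) {
  dt <- data.table::as.data.table(hits)
  cov <- rbind(
    data.table::data.table(id = dt$query, start = dt$qstart, end = dt$qend),
    data.table::data.table(id = dt$subject, start = dt$sstart, end = dt$send)
  )
  out <- setNames(character(length(seqs)), names(seqs))
  covs <- split(cov, cov$id)
  for (id in names(seqs)) {
    iv <- covs[[id]]
    out[id] <- if (is.null(iv)) "" else
      trim_unsupported_ends(seqs[[id]], iv[, c("start", "end"), with = FALSE])
  }
  out
}
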