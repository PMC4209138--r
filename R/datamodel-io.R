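#' Taxon naming scheme for sequence identifiers
#'
#' Sequence identifiers carry their taxon as a prefix before the first
#' delimiter, e.g. `"Vitis@contig_12"` belongs to taxon `"Vitis"`. This is
#' the convention used throughout the package; the delimiter is
#' configurable.
#'
#' @param delimiter single string separating the taxon token from the rest
#'   of the identifier. Default `"@"`.
#' @param fallback logical; when `TRUE`, an identifier without the
#'   delimiter is treated as being its own taxon instead of an error.
#' @return An object of class `taxon_scheme`.
#' @examples
#' parse_taxon("Vitis@contig_12", taxon_scheme())
#' @export
taxon_scheme <- function(delimiter = "@", fallback = FALSE) {
  stopifnot(is.character(delimiter), length(delimiter) == 1L, nchar(delimiter) > 0L)
  structure(list(delimiter = delimiter, fallback = isTRUE(fallback)),
            class = "taxon_scheme")
}

#' Parse the taxon token out of sequence identifiers
#'
#' Returns the token before the first delimiter of each identifier
#' (first-delimiter rule, so `"A@x@y"` parses to `"A"`).
#'
#' @param ids character vector of sequence identifiers.
#' @param scheme a [taxon_scheme()].
#' @return Character vector of taxa, same length as `ids`.
#' @export
parse_taxon <- function(ids, scheme = taxon_scheme()) {
  stopifnot(inherits(scheme, "taxon_scheme"))
  has <- grepl(scheme$delimiter, ids, fixed = TRUE)
  if (!all(has) && !scheme$fallback) {
    stop("identifier(s) without taxon delimiter '", scheme$delimiter, "': ",
         paste(utils::head(ids[!has], 5L), collapse = ", "), call. = FALSE)
  }
  out <- ids
  out[has] <- vapply(strsplit(ids[has], scheme$delimiter, fixed = TRUE),
                     `[[`, character(1L), 1L)
  out
}

# Taxa of a tree's tips.
.tip_taxa <- function(phy, scheme = taxon_scheme()) parse_taxon(phy$tip.label, scheme)

#' Read a newick tree
#'
#' Thin validating wrapper around [ape::read.tree()]. Accepts a file path
#' (plain or gzip) or a literal newick string. A tree whose root has
#' exactly two children is treated as rooted; three or more children as
#' unrooted, matching maximum-likelihood tree output conventions. Absent
#' branch lengths are kept as a distinct missing state (`NA`), never
#' silently 0.
#'
#' @param x file path or newick string (must end in `;`).
#' @return A `phylo` object (or a list of them when the file holds several
#'   trees).
#' @export
read_newick <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  if (grepl("\\(", x) || grepl(";", x, fixed = TRUE)) {
    text <- x
  } else {
    if (!file.exists(x)) stop("no such file: ", x, call. = FALSE)
    text <- paste(readLines(x, warn = FALSE), collapse = "\n")
  }
  .check_newick_syntax(text)
  phy <- ape::read.tree(text = text)
  trees <- if (inherits(phy, "multiPhylo")) unclass(phy) else list(phy)
  if (length(trees) == 0L || is.null(trees[[1L]]))
    stop("could not parse newick input", call. = FALSE)
  for (t in trees) {
    dup <- t$tip.label[duplicated(t$tip.label)]
    if (length(dup))
      stop("duplicate tip labels: ", paste(unique(dup), collapse = ", "),
           call. = FALSE)
  }
  if (length(trees) == 1L) trees[[1L]] else trees
}

# Parenthesis/semicolon validation with a character offset in the message.
.check_newick_syntax <- function(text) {
  chars <- strsplit(text, "")[[1L]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L)
        stop("malformed newick: unmatched ')' at character ", i, call. = FALSE)
    }
  }
  if (depth != 0L)
    stop("malformed newick: ", depth, " unclosed '(' by character ",
         length(chars), call. = FALSE)
  if (!grepl(";", text, fixed = TRUE))
    stop("malformed newick: missing ';' terminator at character ",
         length(chars), call. = FALSE)
  invisible(TRUE)
}

#' Write a tree (or trees) as newick
#'
#' @param phy a `phylo` object or list of them.
#' @param file optional path; when `NULL` the newick string(s) are
#'   returned.
#' @param digits significant digits for branch lengths.
#' @return The newick string(s), invisibly when written to file.
#' @export
write_newick <- function(phy, file = NULL, digits = 10) {
  trees <- if (inherits(phy, "phylo")) list(phy) else phy
  out <- vapply(trees, function(t) {
    if (!is.null(t$edge.length) && all(is.na(t$edge.length))) t$edge.length <- NULL
    s <- ape::write.tree(t, digits = digits)
    gsub(":NA", "", s, fixed = TRUE)
  }, character(1L))
  if (is.null(file)) return(out)
  writeLines(out, file)
  invisible(out)
}

#' Count unambiguous characters in an aligned row
#'
#' Counts alignment positions that are not gaps (`-`), not `?`, not stop
#' (`*`), and not the alphabet's total-ambiguity code (`X` for amino acids,
#' `N` for nucleotides). IUPAC partial ambiguity codes (R, Y, ...) still
#' carry signal and are counted as unambiguous. This count is what decides
#' which isoform survives masking (see [mask_redundant_tips()]).
#'
#' @param rows character vector of aligned sequences.
#' @param alphabet `"aa"` or `"nt"`.
#' @return Integer vector of counts, one per row.
#' @examples
#' count_unambiguous("AC-GT?N", "nt")  # 4
#' count_unambiguous("MKXV", "aa")     # 3
#' @export
count_unambiguous <- function(rows, alphabet = c("aa", "nt")) {
  alphabet <- match.arg(alphabet)
  amb <- c("-", "?", "*", if (alphabet == "aa") "X" else "N")
  vapply(strsplit(toupper(rows), ""), function(ch) sum(!(ch %in% amb)),
         integer(1L))
}

#' Read sequences or an alignment from FASTA
#'
#' Reads plain or gzip-compressed FASTA into a named character vector of
#' residue strings. Identifiers are taken up to the first whitespace.
#'
#' @param file path to a FASTA file (optionally `.gz`).
#' @return Named character vector.
#' @export
read_fasta <- function(file) {
  set <- Biostrings::readBStringSet(file)
  out <- as.character(set)
  names(out) <- sub("\\s.*$", "", names(set))
  out
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector of residue strings.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_fasta <- function(seqs, file) {
  stopifnot(!is.null(names(seqs)), !anyNA(names(seqs)))
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, filepath = file)
  invisible(file)
}

# Alignment rows as a per-position character matrix (rows = sequences).
.aln_matrix <- function(seqs) {
  len <- unique(nchar(seqs))
  if (length(len) != 1L)
    stop("alignment rows differ in length", call. = FALSE)
  m <- do.call(rbind, strsplit(seqs, ""))
  rownames(m) <- names(seqs)
  m
}

.matrix_aln <- function(m) {
  setNames(apply(m, 1L, paste, collapse = ""), rownames(m))
}

# Validate an alignment: equal lengths, unique ids.
.check_alignment <- function(seqs) {
  if (is.null(names(seqs)) || anyDuplicated(names(seqs)))
    stop("alignment rows must carry unique identifiers", call. = FALSE)
  if (length(unique(nchar(seqs))) > 1L)
    stop("alignment rows differ in length", call. = FALSE)
  invisible(seqs)
}
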