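# Stage orchestration mirroring the flow: filter similarity hits ->
# MCL input -> [external MCL] -> parse clusters -> [external align/tree]
# -> refine homolog trees -> prune orthologs -> supermatrix -> jackknife.
# Every stage is independently invokable through the exported functions;
# run_pipeline() chains whichever stages have inputs available and
# records counts in and out per stage.

#' Run the homology/orthology pipeline over prepared inputs
#'
#' Runs the stages for which inputs are supplied, in pipeline order, and
#' writes stage outputs under `out_dir`. External tools (BLAST, MCL,
#' aligners, tree builders) are never executed: the pipeline consumes
#' their outputs and, where one is required but absent, reports the
#' expected file instead.
#'
#' @param out_dir output directory.
#' @param blast path to an all-by-all tabular hit file (outfmt 6 + qlen,
#'   slen), or `NULL` to skip hit filtering.
#' @param sequences path to a FASTA of all sequences (used for end
#'   trimming and cluster length filters), or `NULL`.
#' @param mcl_clusters path to MCL cluster output, or `NULL`.
#' @param trees_dir directory of homolog newick files, or `NULL`.
#' @param alignments_dir directory of homolog FASTA alignments matching
#'   `trees_dir` by base name, or `NULL`.
#' @param method orthology method for the pruning stage.
#' @param outgroups character vector of outgroup taxa (RT/MO).
#' @param preset optional [dataset_preset()] name or list; fills every
#'   cutoff below.
#' @param min_taxa,cfg,mi_cfg,ortholog_clean,locus_min_length,max_missing_taxa
#'   stage parameters (overridden by `preset` when given).
#' @param char_type `"aa"` or `"nt"`.
#' @param jackknife list with `mode`, `value`, `replicates`, `seed`, or
#'   `NULL` to skip.
#' @param scheme a [taxon_scheme()].
#' @return `list(report, outputs)`: a per-stage data.frame of counts
#'   in/out and a named list of produced paths/objects.
#' @export
run_pipeline <- function(out_dir,
                         blast = NULL, sequences = NULL, mcl_clusters = NULL,
                         trees_dir = NULL, alignments_dir = NULL,
                         method = "MI", outgroups = character(),
                         preset = NULL,
                         min_taxa = 8L, cfg = refine_config(),
                         mi_cfg = NULL, ortholog_clean = 0.3,
                         locus_min_length = 100L, max_missing_taxa = 0L,
                         char_type = "aa", jackknife = NULL,
                         scheme = taxon_scheme()) {
  if (is.character(preset)) preset <- dataset_preset(preset)
  if (!is.null(preset)) {
    min_taxa <- preset$min_taxa
    cfg <- preset_refine_config(preset, scheme = scheme)
    mi_cfg <- preset_refine_config(preset, mi = TRUE, scheme = scheme)
    ortholog_clean <- preset$ortholog_clean
    locus_min_length <- preset$locus_min_length
    max_missing_taxa <- preset$max_missing_taxa
    char_type <- preset$char_type
  }
  if (is.null(mi_cfg)) mi_cfg <- cfg
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  report <- list()
  outputs <- list()
  note <- function(stage, n_in, n_out) {
    report[[length(report) + 1L]] <<- data.frame(
      stage = stage, n_in = n_in, n_out = n_out, stringsAsFactors = FALSE)
  }

  seqs <- if (!is.null(sequences)) read_fasta(sequences) else NULL

  if (!is.null(blast)) {
    hits <- read_blast_table(blast)
    edges <- filter_hits(hits, min_fraction = if (is.null(preset)) 0.4
                         else preset$hit_fraction,
                         evalue_cutoff = if (is.null(preset)) 1e-5
                         else preset$evalue_cutoff)
    note("filter_hits", nrow(hits), nrow(edges))
    outputs$mcl_input <- file.path(out_dir, "mcl_input.abc")
    write_mcl_input(edges, outputs$mcl_input)
    if (!is.null(seqs)) {
      kept <- unique(c(edges$id1, edges$id2))
      sub <- hits[hits$query %in% kept & hits$subject %in% kept, ]
      trimmed <- end_trim_sequences(seqs, sub)
      note("end_trim", length(seqs), sum(nchar(trimmed) > 0L))
      seqs <- trimmed
      outputs$trimmed_fasta <- file.path(out_dir, "trimmed.fa")
      write_fasta(seqs[nchar(seqs) > 0L], outputs$trimmed_fasta)
    }
    if (is.null(mcl_clusters))
      message("next: run `mcl ", outputs$mcl_input,
              " --abc -I 1.4 -o clusters.txt` and re-run with mcl_clusters=")
  }

  clusters <- NULL
  if (!is.null(mcl_clusters)) {
    if (is.null(seqs))
      stop("parse-clusters needs `sequences` to apply the length filter",
           call. = FALSE)
    n_lines <- length(readLines(mcl_clusters, warn = FALSE))
    clusters <- parse_mcl_clusters(
      mcl_clusters, seqs,
      min_taxa = min_taxa,
      min_seq_length = if (is.null(preset)) 40L else preset$min_seq_length,
      scheme = scheme)
    note("parse_clusters", n_lines, length(clusters))
    outputs$clusters <- clusters
  }

  homologs <- NULL
  counts_list <- NULL
  alns <- NULL
  if (!is.null(trees_dir)) {
    tree_files <- sort(list.files(trees_dir, pattern = "\\.nwk$|\\.tre$",
                                  full.names = TRUE))
    homologs <- list()
    counts_list <- list()
    alns <- list()
    n_in <- length(tree_files)
    for (f in tree_files) {
      base <- sub("\\.(nwk|tre)$", "", basename(f))
      phy <- read_newick(f)
      aln <- NULL
      if (!is.null(alignments_dir)) {
        af <- list.files(alignments_dir, pattern = paste0("^", base, "\\."),
                         full.names = TRUE)
        if (length(af)) aln <- read_fasta(af[1L])
      }
      cleaned <- refine_homolog(phy, aln, cfg, alphabet = char_type)
      if (length(cleaned)) {
        nm <- paste0(base, if (length(cleaned) > 1L)
          paste0("_", seq_along(cleaned)) else "")
        for (k in seq_along(cleaned)) {
          homologs[[nm[k]]] <- cleaned[[k]]
          alns[[nm[k]]] <- aln
          counts_list[[nm[k]]] <- if (is.null(aln)) NULL else
            setNames(count_unambiguous(aln, char_type), names(aln))
        }
      }
    }
    note("refine", n_in, length(homologs))
    dir.create(file.path(out_dir, "homologs"), showWarnings = FALSE)
    for (nm in names(homologs))
      write_newick(homologs[[nm]],
                   file.path(out_dir, "homologs", paste0(nm, ".nwk")))
  }

  orthologs <- NULL
  if (!is.null(homologs) && length(homologs)) {
    all_taxa <- unique(unlist(lapply(homologs, .tip_taxa, scheme = scheme)))
    roles <- if (length(outgroups))
      taxon_roles(setdiff(all_taxa, outgroups), outgroups) else NULL
    pruned <- run_method(homologs, method, roles, min_taxa, mi_cfg,
                         counts_list, scheme)
    orthologs <- pruned$orthologs
    note("prune", length(homologs), length(orthologs))
    dir.create(file.path(out_dir, "orthologs"), showWarnings = FALSE)
    for (nm in names(orthologs))
      write_newick(orthologs[[nm]],
                   file.path(out_dir, "orthologs", paste0(nm, ".nwk")))
    outputs$prune_report <- pruned$report
    outputs$occupancy <- pruned$occupancy
    utils::write.table(
      data.frame(ortholog = rownames(pruned$occupancy),
                 pruned$occupancy * 1L, check.names = FALSE),
      file.path(out_dir, "occupancy.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
  }

  if (!is.null(orthologs) && length(orthologs) && !is.null(alns)) {
    all_taxa <- sort(unique(unlist(lapply(homologs, .tip_taxa,
                                          scheme = scheme))))
    loci <- list()
    for (nm in names(orthologs)) {
      src <- attr(orthologs[[nm]], "source_homolog")
      aln <- alns[[src]]
      if (is.null(aln)) next
      loc <- extract_ortholog_alignment(aln, orthologs[[nm]]$tip.label,
                                        id = nm, type = char_type,
                                        scheme = scheme)
      loci[[nm]] <- trim_columns_by_occupancy(loc, ortholog_clean)
    }
    mat_taxa <- if (method == "RT") setdiff(all_taxa, outgroups) else all_taxa
    kept <- filter_loci(loci, locus_min_length, max_missing_taxa, mat_taxa)
    note("filter_loci", length(loci), length(kept))
    if (length(kept)) {
      sm <- concatenate_loci(kept, mat_taxa)
      outputs$supermatrix <- file.path(out_dir, "supermatrix.phy")
      write_supermatrix(sm, outputs$supermatrix, "phylip")
      write_supermatrix(sm, file.path(out_dir, "supermatrix.fa"), "fasta")
      write_partitions(sm, file.path(out_dir, "partitions.txt"))
      outputs$occupancy_stats <- occupancy_stats(sm)
      note("supermatrix", length(kept), nrow(sm$partitions))
      if (!is.null(jackknife)) {
        man <- jackknife_by_locus(kept, mode = jackknife$mode,
                                  value = jackknife$value,
                                  replicates = jackknife$replicates %||% 200L,
                                  seed = jackknife$seed)
        outputs$jackknife_manifests <- man
        mf <- file.path(out_dir, "jackknife_manifests.tsv")
        writeLines(vapply(man, paste, character(1L), collapse = "\t"), mf)
        note("jackknife", length(kept), length(man))
      }
    }
  }

  list(report = do.call(rbind, report), outputs = outputs)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
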