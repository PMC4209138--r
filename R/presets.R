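# Published per-dataset cutoff presets. HYM = aculeate Hymenoptera
# (peptides), GRP = grape family Vitaceae (CDS), MIL = millipedes
# (peptides).

.presets <- list(
  HYM = list(dataset = "HYM", char_type = "aa",
             hit_fraction = 0.4, evalue_cutoff = 1e-5,
             min_seq_length = 40L, min_taxa = 8L,
             internal_branch_cutoff = 1.0, tip_absolute_cutoff = 0.6,
             mi_tip_absolute_cutoff = 0.3, tip_relative_factor = 10,
             homolog_clean = 0.1, ortholog_clean = 0.3,
             locus_min_length = 100L, max_missing_taxa = 0L,
             rt_min_taxa = 8L,
             jackknife_replicates = 200L,
             jackknife_proportions = c(0.1, 0.3), jackknife_count = 20L),
  GRP = list(dataset = "GRP", char_type = "nt",
             hit_fraction = 0.4, evalue_cutoff = 1e-5,
             min_seq_length = 40L, min_taxa = 8L,
             internal_branch_cutoff = 0.3, tip_absolute_cutoff = 0.1,
             mi_tip_absolute_cutoff = 0.1, tip_relative_factor = 10,
             homolog_clean = 0.1, ortholog_clean = 0.3,
             locus_min_length = 300L, max_missing_taxa = 0L,
             rt_min_taxa = 8L,
             jackknife_replicates = 200L,
             jackknife_proportions = c(0.1, 0.3), jackknife_count = 20L),
  MIL = list(dataset = "MIL", char_type = "aa",
             hit_fraction = 0.4, evalue_cutoff = 1e-5,
             min_seq_length = 40L, min_taxa = 8L,
             internal_branch_cutoff = 1.5, tip_absolute_cutoff = 0.75,
             mi_tip_absolute_cutoff = 0.4, tip_relative_factor = 10,
             homolog_clean = 0.1, ortholog_clean = 0.3,
             locus_min_length = 100L, max_missing_taxa = 1L,
             rt_min_taxa = 6L,
             jackknife_replicates = 200L,
             jackknife_proportions = c(0.1, 0.3), jackknife_count = 20L)
)

#' Published per-dataset cutoff presets
#'
#' Returns the full cutoff quadruple set used for one of the three
#' published datasets: `"HYM"` (aculeate Hymenoptera, amino acids),
#' `"GRP"` (grape family, CDS), or `"MIL"` (millipedes, amino acids).
#' Values include the hit-fraction and E-value filters, sequence-length
#' and taxon-count minima, the internal-branch and tip-length cutoffs for
#' homolog refinement, the (lower) MI-stage tip cutoffs, alignment
#' occupancy cleaning thresholds, supermatrix locus filters, and the
#' jackknife scheme. MIL allowed one missing taxon per locus and used a
#' six-taxon minimum for RT orthologs.
#'
#' @param dataset `"HYM"`, `"GRP"` or `"MIL"`.
#' @return Named list of preset values.
#' @export
dataset_preset <- function(dataset = c("HYM", "GRP", "MIL")) {
  .presets[[match.arg(dataset)]]
}

#' Refinement configuration from a preset
#'
#' @param preset a preset list from [dataset_preset()].
#' @param mi use the MI-stage tip cutoff instead of the homolog-stage one.
#' @param scheme a [taxon_scheme()].
#' @return A [refine_config()].
#' @export
preset_refine_config <- function(preset, mi = FALSE, scheme = taxon_scheme()) {
  refine_config(
    internal_branch_cutoff = preset$internal_branch_cutoff,
    tip_absolute_cutoff = if (mi) preset$mi_tip_absolute_cutoff
                          else preset$tip_absolute_cutoff,
    tip_relative_factor = preset$tip_relative_factor,
    min_subtree_taxa = preset$min_taxa,
    scheme = scheme)
}
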