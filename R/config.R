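#' Pipeline configuration
#'
#' Collects every threshold the discovery pipeline applies, with the defaults
#' used throughout: genes need at least 10 reads to count as expressed, ORFs
#' must encode proteins of at least 50 aa, peptides must carry at least 9
#' residues and differ from every background protein by at least 2
#' mismatches/indels, the small-protein database keeps entries under 25 kDa,
#' and near-AUG folding uses 39-nt (+/- 19 nt) windows.
#'
#' @param min_read_count Minimum read count for a gene to be called expressed.
#' @param rpkm_threshold Active RPKM detection threshold; the pipeline uses
#'   0.1 by default, 1.0 as the stricter alternative.
#' @param min_protein_aa Minimum predicted protein length (aa, initiator Met
#'   included, stop excluded) for an ORF to qualify.
#' @param min_peptide_len Minimum residues for a peptide to support an
#'   identification.
#' @param min_alignment_diffs Minimum mismatches+indels against every
#'   background protein (other than a peptide's own source) for a peptide to
#'   be accepted as truly unique.
#' @param small_db_max_mw Upper molecular-weight bound (Da, exclusive) for the
#'   small-protein database subset.
#' @param small_db_min_mw Lower molecular-weight bound (Da, inclusive) for the
#'   small-protein subset; 0 keeps everything below the upper bound.
#' @param missed_cleavages Missed tryptic cleavages allowed in digestion.
#' @param folding_window_half Half-width (nt) of the sliding folding window.
#' @param homology_min_pct Minimum homology percent for a cross-species hit.
#' @param ubiquity_min_samples Minimum number of samples a gene must be
#'   detected in to be classed ubiquitous.
#' @param min_transitions Minimum co-detected transitions for targeted-MS
#'   verification.
#' @param min_transition_sn Signal-to-noise each counted transition must
#'   exceed (strict).
#' @param max_ratio_deviation Maximum tolerated fractional deviation of each
#'   light/heavy transition ratio from the precursor mean (strict).
#' @param random_seed Seed recorded with the configuration.
#'
#' @return An object of class `pipeline_config` (a validated named list).
#' @examples
#' cfg <- pipeline_config()
#' cfg$min_peptide_len
#' @export
pipeline_config <- function(min_read_count = 10,
                            rpkm_threshold = 0.1,
                            min_protein_aa = 50,
                            min_peptide_len = 9,
                            min_alignment_diffs = 2,
                            small_db_max_mw = 25000,
                            small_db_min_mw = 0,
                            missed_cleavages = 2,
                            folding_window_half = 19,
                            homology_min_pct = 10,
                            ubiquity_min_samples = 8,
                            min_transitions = 3,
                            min_transition_sn = 3,
                            max_ratio_deviation = 0.20,
                            random_seed = 1L) {
  cfg <- list(
    min_read_count = min_read_count,
    rpkm_threshold = rpkm_threshold,
    min_protein_aa = min_protein_aa,
    min_peptide_len = min_peptide_len,
    min_alignment_diffs = min_alignment_diffs,
    small_db_max_mw = small_db_max_mw,
    small_db_min_mw = small_db_min_mw,
    missed_cleavages = missed_cleavages,
    folding_window_half = folding_window_half,
    homology_min_pct = homology_min_pct,
    ubiquity_min_samples = ubiquity_min_samples,
    min_transitions = min_transitions,
    min_transition_sn = min_transition_sn,
    max_ratio_deviation = max_ratio_deviation,
    random_seed = as.integer(random_seed)
  )
  strict_pos <- c("min_read_count", "rpkm_threshold", "min_protein_aa",
                  "min_peptide_len", "min_alignment_diffs", "small_db_max_mw",
                  "folding_window_half", "homology_min_pct",
                  "ubiquity_min_samples", "min_transitions",
                  "min_transition_sn", "max_ratio_deviation")
  for (nm in strict_pos) {
    v <- cfg[[nm]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v <= 0)
      stop(sprintf("config '%s' must be a single strictly positive number", nm))
  }
  if (cfg$small_db_min_mw < 0) stop("small_db_min_mw must be >= 0")
  if (cfg$missed_cleavages < 0) stop("missed_cleavages must be >= 0")
  class(cfg) <- "pipeline_config"
  cfg
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("proteolnc pipeline configuration\n")
  for (nm in setdiff(names(x), "random_seed"))
    cat(sprintf("  %-22s %s\n", nm, format(x[[nm]])))
  cat(sprintf("  %-22s %d\n", "random_seed", x$random_seed))
  invisible(x)
}
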