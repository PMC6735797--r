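#' Homology percent between two proteins
#'
#' Best local alignment (BLOSUM62, affine gaps) between query and subject;
#' the reported percent folds identity and query coverage into one number:
#' identical aligned residues / query length x 100. Alignments scoring
#' below `min_score` report 0 (no detectable homology); the default of 60
#' sits well above the score null of unrelated ~100-aa proteins (whose best
#' local scores rarely exceed ~50 under these penalties) while genuine
#' homologs retaining 40% identity score well over 100.
#'
#' @param query_protein,subject_protein Amino-acid strings (non-empty).
#' @param min_score Minimum local alignment score for a hit.
#' @param gap_opening,gap_extension Affine gap penalties.
#' @return Percent in `[0, 100]`.
#' @export
homology_percent <- function(query_protein, subject_protein, min_score = 60,
                             gap_opening = 10, gap_extension = 0.5) {
  stopifnot(nchar(query_protein) > 0, nchar(subject_protein) > 0)
  pa <- Biostrings::pairwiseAlignment(
    pattern = query_protein, subject = subject_protein, type = "local",
    substitutionMatrix = "BLOSUM62", gapOpening = gap_opening,
    gapExtension = gap_extension)
  if (Biostrings::score(pa) < min_score) return(0)
  min(100, 100 * Biostrings::nmatch(pa) / nchar(query_protein))
}

#' Phylostratigraphic assignment over ordered proteome sets
#'
#' Finds the oldest clade whose proteome contains a subject with homology
#' percent at least `min_pct` (default 10); a protein matching nothing is
#' assigned no stratum (it emerged in the query's own clade).
#'
#' @param protein Query protein sequence.
#' @param proteome_sets Named list of character vectors of protein
#'   sequences, ordered oldest clade first.
#' @param min_pct Minimum homology percent for a hit.
#' @param ... Passed to [homology_percent()].
#' @return List with `per_clade` (named vector of best homology percent per
#'   clade) and `oldest_clade_with_hit` (clade name or `NA`).
#' @export
assign_phylostratum <- function(protein, proteome_sets, min_pct = 10, ...) {
  if (!length(proteome_sets)) stop("empty clade proteome set")
  best <- vapply(proteome_sets, function(set) {
    if (!length(set)) return(0)
    max(vapply(set, function(s) homology_percent(protein, s, ...), 0))
  }, 0)
  hit <- which(best >= min_pct)
  list(per_clade = best,
       oldest_clade_with_hit = if (length(hit)) names(proteome_sets)[hit[1L]]
                               else NA_character_)
}

# do two genomic interval sets (same chromosome assumed checked) overlap?
intervals_overlap <- function(starts1, ends1, starts2, ends2) {
  for (i in seq_along(starts1))
    if (any(starts2 <= ends1[i] & ends2 >= starts1[i])) return(TRUE)
  FALSE
}

#' Classify the genomic/evolutionary origin of a new protein
#'
#' Precedence: `splice_variant` when the new gene's exons overlap a known
#' coding gene's locus on the same strand; else `homologous_copy` when the
#' best homology percent against the known proteome reaches
#' `copy_min_pct`; else `microbial` when the best microbial-set hit reaches
#' `microbial_min_pct`; else `unknown`.
#'
#' @param new_protein Protein sequence of the new gene.
#' @param gene_model Single row of a `gene_models$transcripts` data.frame
#'   for the new gene plus its exons (`exons` data.frame with `start`,
#'   `end`); pass as a list with `transcript`, `exons`.
#' @param known_coding_models A `gene_models` object restricted to known
#'   coding genes (needs genomic coordinates).
#' @param known_proteome,microbial_proteome Character vectors of protein
#'   sequences.
#' @param copy_min_pct,microbial_min_pct Homology thresholds (percent).
#' @return One of `"splice_variant"`, `"homologous_copy"`, `"microbial"`,
#'   `"unknown"`.
#' @export
classify_origin <- function(new_protein, gene_model, known_coding_models,
                            known_proteome, microbial_proteome = character(),
                            copy_min_pct = 30, microbial_min_pct = 30) {
  tx <- gene_model$transcript
  ex <- gene_model$exons
  if (is.null(tx) || is.null(ex) || anyNA(ex$start) || anyNA(ex$end))
    stop("gene model coordinates required for the overlap check")
  ktx <- known_coding_models$transcripts
  kex <- known_coding_models$exons
  for (i in seq_len(nrow(ktx))) {
    if (ktx$chromosome[i] != tx$chromosome || ktx$strand[i] != tx$strand) next
    ke <- kex[kex$transcript_id == ktx$transcript_id[i], , drop = FALSE]
    # locus overlap: transcript spans intersect
    if (min(ke$start) <= max(ex$end) && max(ke$end) >= min(ex$start))
      return("splice_variant")
  }
  if (length(known_proteome)) {
    best <- max(vapply(known_proteome,
                       function(s) homology_percent(new_protein, s), 0))
    if (best >= copy_min_pct) return("homologous_copy")
  }
  if (length(microbial_proteome)) {
    best <- max(vapply(microbial_proteome,
                       function(s) homology_percent(new_protein, s), 0))
    if (best >= microbial_min_pct) return("microbial")
  }
  "unknown"
}

#' Exon count of a transcript model
#'
#' @param models A `gene_models` object.
#' @param transcript_id Transcript to count exons for (all when `NULL`).
#' @return Named integer vector of exon counts.
#' @export
exon_count <- function(models, transcript_id = NULL) {
  tx <- models$transcripts
  if (!is.null(transcript_id)) tx <- tx[tx$transcript_id %in% transcript_id, ]
  setNames(tx$n_exons, tx$transcript_id)
}

#' Fraction of single-exon genes in a set
#'
#' @param exon_counts Integer vector of per-gene exon counts.
#' @return Fraction with exactly one exon.
#' @export
single_exon_fraction <- function(exon_counts) {
  stopifnot(length(exon_counts) > 0)
  mean(exon_counts == 1L)
}
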