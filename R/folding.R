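#' Nearest-neighbor stacking energy table
#'
#' Stacking increments (kcal/mol) for an outer base pair directly enclosing
#' an inner pair, indexed by pair type (AU, UA, CG, GC, GU, UG). This is a
#' simplified nearest-neighbor model: only stacked pairs carry energy, so
#' the minimum free energy is bounded above by 0 (the empty structure).
#' Values follow the usual ordering of nearest-neighbor parameter sets
#' (CG/GC stacks strongest, wobble stacks weakest); absolute energies from a
#' full loop-based model will differ, but the near-AUG stability contrasts
#' the pipeline reports depend only on relative values.
#'
#' @return A 6x6 numeric matrix (rows = outer pair, cols = inner pair).
#' @export
stacking_energy_table <- function() {
  pt <- c("AU", "UA", "CG", "GC", "GU", "UG")
  m <- matrix(c(
    # inner:  AU    UA    CG    GC    GU    UG
    -0.9, -1.1, -2.2, -2.1, -0.6, -1.4,   # outer AU
    -1.3, -0.9, -2.4, -2.1, -1.0, -1.3,   # outer UA
    -2.1, -2.1, -3.3, -2.4, -1.4, -2.1,   # outer CG
    -2.4, -2.2, -3.4, -3.3, -1.5, -2.5,   # outer GC
    -1.3, -1.4, -2.5, -2.1, -0.5, -0.5,   # outer GU
    -1.0, -0.6, -1.4, -1.5, -0.3, -0.5),  # outer UG
    nrow = 6, byrow = TRUE, dimnames = list(pt, pt))
  m
}

#' Minimum free energy of an RNA window
#'
#' Dynamic-programming minimum over nested structures with Watson-Crick and
#' GU wobble pairs, a minimum hairpin loop of 3 unpaired bases, and the
#' stacking energies of [stacking_energy_table()]. A sequence admitting no
#' pairs (e.g. poly-A) folds to exactly 0; results are always <= 0.
#'
#' @param rna_window RNA string over A, C, G, U.
#' @param stack Stacking-energy matrix (6x6, see
#'   [stacking_energy_table()]).
#' @param min_loop Minimum unpaired bases in a hairpin loop.
#' @return Free-energy estimate (kcal/mol, <= 0).
#' @export
mfe <- function(rna_window, stack = stacking_energy_table(), min_loop = 3L) {
  stopifnot(is.character(rna_window), length(rna_window) == 1L,
            nchar(rna_window) >= 1L)
  if (grepl("[^ACGU]", rna_window))
    stop("invalid RNA alphabet in window (expected A/C/G/U): ", rna_window)
  .fold_mfe_dp(rna_window, stack, as.integer(min_loop))
}

#' Sliding-window folding profile around a start codon
#'
#' For each center offset c (relative to the A of the AUG, position 0 = A),
#' folds the +/- `window_half` nt window (39 nt by default) and records its
#' minimum free energy. Windows that would run past either transcript end
#' are skipped, not padded.
#'
#' @param sequence Transcript sequence (DNA or RNA alphabet; T is converted
#'   to U at this boundary).
#' @param start_codon_pos 0-based offset of the A of the AUG.
#' @param window_half Half window width in nt (default 19).
#' @param centers Integer offsets of window centers relative to the start
#'   codon (default -50..50).
#' @param transcript_id Identifier carried into the output.
#' @return Data.frame of class `folding_profile` with `transcript_id`,
#'   `center`, `dg`; empty (with a warning) when no full window fits.
#' @export
window_scan <- function(sequence, start_codon_pos, window_half = 19L,
                        centers = -50:50, transcript_id = "tx") {
  stopifnot(start_codon_pos >= 0, start_codon_pos < nchar(sequence))
  rna <- chartr("Tt", "Uu", toupper(sequence))
  n <- nchar(rna)
  abs_center <- start_codon_pos + centers
  lo <- abs_center - window_half       # 0-based inclusive
  hi <- abs_center + window_half
  keep <- lo >= 0L & hi <= n - 1L
  if (!any(keep)) {
    warning("transcript shorter than one full folding window; empty profile")
    out <- data.frame(transcript_id = character(), center = integer(),
                      dg = numeric(), stringsAsFactors = FALSE)
    class(out) <- c("folding_profile", class(out))
    return(out)
  }
  centers <- centers[keep]; lo <- lo[keep]; hi <- hi[keep]
  dg <- vapply(seq_along(centers), function(i) {
    mfe(substr(rna, lo[i] + 1L, hi[i] + 1L))
  }, 0)
  out <- data.frame(transcript_id = transcript_id, center = centers, dg = dg,
                    stringsAsFactors = FALSE)
  class(out) <- c("folding_profile", class(out))
  out
}

#' Aggregate folding profiles over a set of transcripts
#'
#' Mean, minimum and maximum free energy per window center across profiles,
#' the summary-curve format used to contrast near-AUG stability between
#' protein classes.
#'
#' @param profiles List of [window_scan()] results.
#' @return Data.frame with `center`, `mean_dg`, `lower_dg`, `upper_dg`, `n`.
#' @export
aggregate_folding_profiles <- function(profiles) {
  all <- do.call(rbind, profiles)
  sp <- split(all$dg, all$center)
  data.frame(center = as.integer(names(sp)),
             mean_dg = vapply(sp, mean, 0),
             lower_dg = vapply(sp, min, 0),
             upper_dg = vapply(sp, max, 0),
             n = lengths(sp), row.names = NULL)
}
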