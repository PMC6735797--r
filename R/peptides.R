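STANDARD_AA <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Residue-equivalence table for alignment scoring
#'
#' Symmetric residue pairs treated as identical during peptide/protein
#' comparison. Isoleucine and leucine are always equivalent (identical
#' residue mass); the default adds the deamidation mass twins N/D and Q/E,
#' the canonical post-translational-modification confusions. The PTM set is
#' fully configurable.
#'
#' @param ptm_pairs List of length-2 character vectors of additional
#'   equivalent residue pairs (symmetric, irreflexive).
#' @param include_il Keep the I/L equivalence (on by default).
#' @return Object of class `equivalence_table`: a named character vector
#'   mapping each standard residue to its class representative.
#' @examples
#' eq <- equivalence_table()
#' eq[["I"]] == eq[["L"]]
#' @export
equivalence_table <- function(ptm_pairs = list(c("N", "D"), c("Q", "E")),
                              include_il = TRUE) {
  pairs <- ptm_pairs
  if (include_il) pairs <- c(list(c("I", "L")), pairs)
  rep_of <- setNames(STANDARD_AA, STANDARD_AA)
  find <- function(x) { while (rep_of[[x]] != x) x <- rep_of[[x]]; x }
  for (p in pairs) {
    if (length(p) != 2L || p[1] == p[2] || !all(p %in% STANDARD_AA))
      stop("equivalence pairs must be two distinct standard residues")
    ra <- find(p[1]); rb <- find(p[2])
    if (ra != rb) rep_of[[max(ra, rb)]] <- min(ra, rb)
  }
  tbl <- vapply(STANDARD_AA, find, "")
  class(tbl) <- "equivalence_table"
  tbl
}

# map a sequence through the equivalence classes (class representatives)
map_equivalences <- function(seqs, equivalences) {
  chartr(paste(names(equivalences), collapse = ""),
         paste(unname(unclass(equivalences)), collapse = ""), seqs)
}

# I/L-only collapse used for substring matching during peptide assignment
collapse_il <- function(seqs) chartr("I", "L", seqs)

#' Minimum alignment difference between a peptide and a protein
#'
#' The minimum, over all placements of the FULL peptide against any region
#' of the protein (semi-global alignment: peptide global, protein local), of
#' substitutions + insertions + deletions, with equivalence-table residue
#' pairs counting as matches. This is the edit-count reading of the
#' Smith-Waterman similarity inspection: a peptide equal to a substring
#' scores 0, a single-substitution near-miss scores 1.
#'
#' @param peptide Peptide string (length >= 1).
#' @param protein Protein string (may be empty: result is the peptide
#'   length, all insertions).
#' @param equivalences An [equivalence_table()].
#' @return Non-negative integer edit count.
#' @export
min_alignment_diffs <- function(peptide, protein,
                                equivalences = equivalence_table()) {
  stopifnot(nchar(peptide) >= 1L)
  .semi_global_edit(map_equivalences(peptide, equivalences),
                    map_equivalences(protein, equivalences))
}

#' Assign peptides to reference-database entries
#'
#' A peptide's assignments are the database entries containing it as an
#' exact substring with I and L collapsed. A peptide is unique when exactly
#' one entry matches after collapsing entries whose full sequences are
#' identical under I/L; a non-unique peptide assigned to an identification
#' is a supportive peptide.
#'
#' @param peptides Character vector of peptide sequences.
#' @param db A `reference_db`.
#' @return Data.frame with `peptide`, `assigned_accessions` (comma-joined),
#'   `n_assigned` (distinct entries under I/L collapse), `is_unique`,
#'   `rejected_reason` (`NA` or a message for non-standard residues).
#' @export
assign_peptides <- function(peptides, db) {
  stopifnot(inherits(db, "reference_db"))
  prot_c <- collapse_il(db$entries$protein)
  acc <- db$entries$accession
  res <- lapply(peptides, function(p) {
    if (grepl(paste0("[^", paste(STANDARD_AA, collapse = ""), "]"), p)) {
      return(data.frame(peptide = p, assigned_accessions = "",
                        n_assigned = 0L, is_unique = FALSE,
                        rejected_reason = "non-standard residue",
                        stringsAsFactors = FALSE))
    }
    pc <- collapse_il(p)
    hit <- which(vapply(prot_c, function(s) grepl(pc, s, fixed = TRUE),
                        TRUE, USE.NAMES = FALSE))
    n_distinct <- length(unique(prot_c[hit]))
    data.frame(peptide = p,
               assigned_accessions = paste(acc[hit], collapse = ","),
               n_assigned = n_distinct,
               is_unique = n_distinct == 1L,
               rejected_reason = NA_character_, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Alignment-based uniqueness filter for candidate peptides
#'
#' Adjudicates assigned peptides against a background protein collection
#' (known proteome + three-frame ORF collection + any curated set). A
#' candidate unique peptide is accepted only when it has at least
#' `min_peptide_len` residues and differs by at least `min_alignment_diffs`
#' mismatches/indels from every background protein other than its own
#' source entry (and entries identical to it under I/L) — otherwise a
#' single-residue variant of a known protein could masquerade as new.
#'
#' @param evidence Output of [assign_peptides()].
#' @param background Data.frame with `accession`, `protein`: the full
#'   background collection (must contain the peptides' source entries for
#'   own-source exclusion to apply).
#' @param config A [pipeline_config()].
#' @param equivalences An [equivalence_table()].
#' @return `evidence` with added columns `min_diffs` (edit distance to the
#'   closest non-self background protein; `NA` where not computed) and
#'   `verdict` in `accepted_unique`, `rejected_similar`, `rejected_short`,
#'   `supportive`, `unassigned`.
#' @export
sw_uniqueness_filter <- function(evidence, background,
                                 config = pipeline_config(),
                                 equivalences = equivalence_table()) {
  bg_mapped <- map_equivalences(background$protein, equivalences)
  bg_il <- collapse_il(background$protein)
  evidence$min_diffs <- NA_integer_
  evidence$verdict <- NA_character_
  for (i in seq_len(nrow(evidence))) {
    if (!is.na(evidence$rejected_reason[i])) {
      evidence$verdict[i] <- "unassigned"; next
    }
    if (evidence$n_assigned[i] == 0L) {
      evidence$verdict[i] <- "unassigned"; next
    }
    if (!evidence$is_unique[i]) {
      evidence$verdict[i] <- "supportive"; next
    }
    if (nchar(evidence$peptide[i]) < config$min_peptide_len) {
      evidence$verdict[i] <- "rejected_short"; next
    }
    own <- strsplit(evidence$assigned_accessions[i], ",", fixed = TRUE)[[1]]
    own_seq_il <- bg_il[background$accession %in% own]
    excl <- background$accession %in% own | bg_il %in% own_seq_il
    pep_m <- map_equivalences(evidence$peptide[i], equivalences)
    d <- if (all(excl)) nchar(evidence$peptide[i]) else {
      .semi_global_edit_min(pep_m, bg_mapped[!excl], -1L)
    }
    evidence$min_diffs[i] <- d
    evidence$verdict[i] <- if (d >= config$min_alignment_diffs)
      "accepted_unique" else "rejected_similar"
  }
  evidence
}

#' Evidence tier of a protein identification
#'
#' @param n_unique Accepted unique peptides supporting the protein.
#' @param n_supportive Supportive (non-unique, engine-assigned) peptides.
#' @return Character vector: `two_plus_unique`, `one_unique_plus_supportive`,
#'   `one_unique_only` or `insufficient`.
#' @export
evidence_tier <- function(n_unique, n_supportive) {
  ifelse(n_unique >= 2L, "two_plus_unique",
         ifelse(n_unique == 1L & n_supportive >= 1L, "one_unique_plus_supportive",
                ifelse(n_unique == 1L, "one_unique_only", "insufficient")))
}

#' Call new proteins from adjudicated peptide evidence
#'
#' A database entry classified as new (outside PE1-PE5) is called when it
#' carries at least one accepted unique peptide; each call reports its
#' evidence tier and peptide provenance.
#'
#' @param evidence Output of [sw_uniqueness_filter()].
#' @param db A `reference_db`.
#' @param classification Output of [classify_new_protein()] over `db`.
#' @return Data.frame with `accession`, `gene_id`, `n_unique`,
#'   `n_supportive`, `tier`, `unique_peptides` (comma-joined), `protein`.
#' @export
validate_new_proteins <- function(evidence, db, classification) {
  stopifnot(inherits(db, "reference_db"))
  new_acc <- names(classification)[classification == "new"]
  assigned <- strsplit(evidence$assigned_accessions, ",", fixed = TRUE)
  calls <- lapply(new_acc, function(a) {
    has <- vapply(assigned, function(x) a %in% x, TRUE)
    uniq <- has & evidence$verdict == "accepted_unique"
    supp <- has & evidence$verdict == "supportive"
    if (!any(uniq)) return(NULL)
    entry <- db$entries[db$entries$accession == a, , drop = FALSE]
    data.frame(accession = a, gene_id = entry$gene_id,
               n_unique = sum(uniq), n_supportive = sum(supp),
               tier = evidence_tier(sum(uniq), sum(supp)),
               unique_peptides = paste(evidence$peptide[uniq], collapse = ","),
               protein = entry$protein, stringsAsFactors = FALSE)
  })
  calls <- calls[!vapply(calls, is.null, TRUE)]
  if (!length(calls)) {
    return(data.frame(accession = character(), gene_id = character(),
                      n_unique = integer(), n_supportive = integer(),
                      tier = character(), unique_peptides = character(),
                      protein = character(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, calls)
  rownames(out) <- NULL
  out
}

#' Transition-level verification of one targeted-MS precursor
#'
#' An endogenous (light) peptide is verified against its heavy-labeled
#' standard when (a) every transition pair co-elutes, (b) at least
#' `min_transitions` transitions have light S/N above `min_transition_sn`
#' (strict), and (c) every transition pair's light/heavy ratio deviates by
#' less than `max_ratio_deviation` from the precursor's mean ratio; a pair
#' with zero heavy area fails (c).
#'
#' @param measurements Data.frame for one precursor: `fragment_id`,
#'   `light_area`, `heavy_area`, `light_sn`, `coelutes`.
#' @param config A [pipeline_config()].
#' @return List with `status` (`"verified"`/`"not_verified"`) and `reasons`
#'   (character vector naming every failed criterion; empty when verified).
#' @export
check_targeted_verification <- function(measurements,
                                        config = pipeline_config()) {
  stopifnot(nrow(measurements) >= 1L)
  reasons <- character(0)
  if (!all(measurements$coelutes))
    reasons <- c(reasons, "coelution: not all transition pairs share the light/heavy elution profile")
  n_sn <- sum(measurements$light_sn > config$min_transition_sn)
  if (n_sn < config$min_transitions)
    reasons <- c(reasons, sprintf(
      "transitions: only %d transition(s) with S/N > %g (need >= %d)",
      n_sn, config$min_transition_sn, config$min_transitions))
  zero_heavy <- measurements$heavy_area <= 0
  ratios <- ifelse(zero_heavy, NA_real_,
                   measurements$light_area / measurements$heavy_area)
  if (any(zero_heavy)) {
    reasons <- c(reasons, "ratio: transition pair(s) with zero heavy area")
  }
  if (any(!is.na(ratios))) {
    mean_ratio <- mean(ratios, na.rm = TRUE)
    dev <- abs(ratios - mean_ratio) / mean_ratio
    if (any(dev[!is.na(dev)] >= config$max_ratio_deviation))
      reasons <- c(reasons, sprintf(
        "ratio: light/heavy deviation >= %g%% from the precursor mean",
        100 * config$max_ratio_deviation))
  }
  list(status = if (length(reasons)) "not_verified" else "verified",
       reasons = reasons)
}

#' Verify every precursor in a transition table
#'
#' @param transitions Data.frame with `precursor_id` plus the columns of
#'   [check_targeted_verification()].
#' @param config A [pipeline_config()].
#' @return Data.frame with `precursor_id`, `status`, `reasons` (joined).
#' @export
verify_transitions <- function(transitions, config = pipeline_config()) {
  sp <- split(transitions, transitions$precursor_id)
  out <- do.call(rbind, lapply(names(sp), function(pid) {
    v <- check_targeted_verification(sp[[pid]], config)
    data.frame(precursor_id = pid, status = v$status,
               reasons = paste(v$reasons, collapse = "; "),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
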