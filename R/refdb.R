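#' Build a cell-specific protein reference database
#'
#' The search database for one cell line holds the protein products of all
#' translating genes: known proteins whose genes pass the translation
#' (RNC-seq) expression call, plus the predicted ORF proteins (>= the
#' minimum length rule) of translating lncRNAs. Exact duplicate sequences
#' are collapsed with provenance retained.
#'
#' @param translating_gene_ids Gene IDs called truly expressed in the RNC
#'   library.
#' @param known_proteins Data.frame with `accession`, `gene_id`, `protein`
#'   and optionally `pe_status` (`PE1`..`PE5`).
#' @param lncrna_orf_proteins Data.frame with `accession`, `gene_id`,
#'   `protein` for predicted lncRNA ORFs (accessions in
#'   `transcriptID|frame|start-end` form). ORFs below the length rule are
#'   rejected with a message.
#' @param config A [pipeline_config()].
#' @return An object of class `reference_db`: list with `entries`
#'   (`accession`, `source` = `known_translating`/`lncrna_orf`, `gene_id`,
#'   `protein`, `pe_status`) and `duplicates` (provenance of collapsed
#'   exact-duplicate sequences).
#' @export
build_reference_db <- function(translating_gene_ids, known_proteins,
                               lncrna_orf_proteins,
                               config = pipeline_config()) {
  kp <- known_proteins[known_proteins$gene_id %in% translating_gene_ids, ,
                       drop = FALSE]
  if (!"pe_status" %in% names(kp)) kp$pe_status <- NA_character_
  kp <- data.frame(accession = kp$accession, source = "known_translating",
                   gene_id = kp$gene_id, protein = kp$protein,
                   pe_status = kp$pe_status, stringsAsFactors = FALSE)
  lo <- lncrna_orf_proteins
  if (is.null(lo) || nrow(lo) == 0L) {
    lo <- data.frame(accession = character(), source = character(),
                     gene_id = character(), protein = character(),
                     pe_status = character(), stringsAsFactors = FALSE)
  } else {
    short <- nchar(lo$protein) < config$min_protein_aa
    if (any(short)) {
      message("rejected ", sum(short),
              " lncRNA ORF(s) below the minimum protein length (",
              config$min_protein_aa, " aa): ",
              paste(head(lo$accession[short], 5L), collapse = ", "))
      lo <- lo[!short, , drop = FALSE]
    }
    lo <- lo[lo$gene_id %in% translating_gene_ids, , drop = FALSE]
    lo <- data.frame(accession = lo$accession, source = "lncrna_orf",
                     gene_id = lo$gene_id, protein = lo$protein,
                     pe_status = NA_character_, stringsAsFactors = FALSE)
  }
  entries <- rbind(kp, lo)
  if (anyDuplicated(entries$accession))
    stop("duplicate accessions in database inputs: ",
         paste(unique(entries$accession[duplicated(entries$accession)]),
               collapse = ", "))
  dup <- duplicated(entries$protein)
  duplicates <- data.frame(accession = character(),
                           kept_accession = character(),
                           stringsAsFactors = FALSE)
  if (any(dup)) {
    first_acc <- setNames(entries$accession[!duplicated(entries$protein)],
                          entries$protein[!duplicated(entries$protein)])
    duplicates <- data.frame(
      accession = entries$accession[dup],
      kept_accession = unname(first_acc[entries$protein[dup]]),
      stringsAsFactors = FALSE)
    entries <- entries[!dup, , drop = FALSE]
  }
  rownames(entries) <- NULL
  structure(list(entries = entries, duplicates = duplicates,
                 config = config), class = "reference_db")
}

#' @export
print.reference_db <- function(x, ...) {
  tab <- table(x$entries$source)
  cat("proteolnc reference database:", nrow(x$entries), "entries (",
      paste(sprintf("%s=%d", names(tab), as.integer(tab)), collapse = ", "),
      ")\n")
  invisible(x)
}

#' Low-molecular-weight subset of a reference database
#'
#' Keeps entries with average molecular mass strictly below `max_mw`
#' (default 25 kDa) and at least `min_mw`. Idempotent.
#'
#' @param db A `reference_db`.
#' @param max_mw Exclusive upper mass bound in Da.
#' @param min_mw Inclusive lower mass bound in Da.
#' @return A `reference_db` restricted to the mass window.
#' @export
small_protein_subset <- function(db, max_mw = 25000, min_mw = 0) {
  stopifnot(inherits(db, "reference_db"))
  mw <- vapply(db$entries$protein, molecular_weight, 0, USE.NAMES = FALSE)
  keep <- mw < max_mw & mw >= min_mw
  out <- db
  out$entries <- db$entries[keep, , drop = FALSE]
  rownames(out$entries) <- NULL
  out
}

#' Classify a database entry as a known protein or a new protein
#'
#' New proteins are those not belonging to the PE1-PE5 set (the protein
#' products of known coding genes). A sequence-level match beats the
#' accession: an lncRNA ORF whose protein is identical to any PE1-PE5
#' protein is classified known.
#'
#' @param db A `reference_db`.
#' @param known_pe_accessions Accessions of PE1-PE5 proteins.
#' @param known_pe_sequences Optional character vector of PE1-PE5 protein
#'   sequences for the sequence-level match.
#' @return Named character vector over db accessions: `"known"` or `"new"`.
#' @export
classify_new_protein <- function(db, known_pe_accessions,
                                 known_pe_sequences = character()) {
  stopifnot(inherits(db, "reference_db"))
  e <- db$entries
  known <- e$accession %in% known_pe_accessions |
    (!is.na(e$pe_status) & e$pe_status %in% paste0("PE", 1:5)) |
    e$protein %in% known_pe_sequences
  setNames(ifelse(known, "known", "new"), e$accession)
}

#' Write a reference database as FASTA plus a TSV manifest
#'
#' @param db A `reference_db`.
#' @param fasta_path,manifest_path Output paths (`NULL` skips either).
#' @return Invisibly, the manifest data.frame (`accession`, `source`,
#'   `length_aa`, `mw_da`).
#' @export
write_reference_db <- function(db, fasta_path = NULL, manifest_path = NULL) {
  stopifnot(inherits(db, "reference_db"))
  manifest <- data.frame(
    accession = db$entries$accession,
    source = db$entries$source,
    length_aa = nchar(db$entries$protein),
    mw_da = vapply(db$entries$protein, molecular_weight, 0, USE.NAMES = FALSE),
    stringsAsFactors = FALSE)
  if (!is.null(fasta_path))
    write_fasta(data.frame(id = db$entries$accession,
                           description = db$entries$source,
                           sequence = db$entries$protein), fasta_path)
  if (!is.null(manifest_path))
    write.table(manifest, manifest_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  invisible(manifest)
}
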