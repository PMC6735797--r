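GENETIC_CODE_TABLE <- Biostrings::GENETIC_CODE

#' Translate a nucleotide sequence
#'
#' Standard genetic code; codons containing N (or any non-ACGT symbol)
#' translate to `X`, stop codons to `*`.
#'
#' @param nt_seq DNA string (length divisible by 3, alphabet ACGTN).
#' @return Amino-acid string.
#' @examples
#' translate_nt("ATGAAATAG")  # "MK*"
#' @export
translate_nt <- function(nt_seq) {
  stopifnot(is.character(nt_seq), length(nt_seq) == 1L)
  n <- nchar(nt_seq)
  if (n %% 3L != 0L) stop("sequence length not divisible by 3")
  if (n == 0L) return("")
  codons <- substring(nt_seq, seq(1L, n, 3L), seq(3L, n, 3L))
  aa <- GENETIC_CODE_TABLE[codons]
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

orf_accession <- function(transcript_id, frame, start_nt, end_nt) {
  sprintf("%s|%d|%d-%d", transcript_id, frame, start_nt, end_nt)
}

#' Find canonical AUG-initiated open reading frames
#'
#' Scans the three forward (sense) frames of a spliced transcript. An ORF
#' runs from an AUG to the first in-frame stop codon, which must lie within
#' the transcript; run-off ORFs are excluded (`require_stop = FALSE` keeps
#' them, with `end_nt` at the last complete codon). By default only the
#' 5'-most AUG per (frame, stop) is reported so nested fragments do not flood
#' the database; `all_aug = TRUE` reports every internal AUG as well.
#'
#' @param sequence Transcript sequence (sense strand, DNA alphabet) or a
#'   single-row transcript data.frame with `transcript_id` and `sequence`.
#' @param min_protein_aa Minimum protein length in aa, counting the initiator
#'   Met and excluding the stop (default 50, i.e. coding length >= 150 nt).
#' @param transcript_id Identifier recorded in the output when `sequence` is
#'   a bare string.
#' @param all_aug Report every AUG per stop instead of only the 5'-most.
#' @param require_stop Require an in-frame stop within the transcript.
#' @return Data.frame with columns `transcript_id`, `frame` (0/1/2),
#'   `start_nt` (0-based offset of the A of AUG), `end_nt` (one past the stop
#'   codon), `length_aa`, `protein`, sorted by protein length descending then
#'   5'-most start.
#' @export
find_orfs <- function(sequence, min_protein_aa = 50L, transcript_id = "tx",
                      all_aug = FALSE, require_stop = TRUE) {
  if (is.data.frame(sequence)) {
    stopifnot(nrow(sequence) == 1L)
    transcript_id <- sequence$transcript_id
    sequence <- sequence$sequence
  }
  stopifnot(nchar(sequence) > 0L)
  seq <- toupper(chartr("U", "T", sequence))
  n <- nchar(seq)
  out <- list()
  stop_codons <- c("TAA", "TAG", "TGA")
  for (frame in 0:2) {
    ncod <- (n - frame) %/% 3L
    if (ncod < 2L) next
    starts <- frame + 3L * (seq_len(ncod) - 1L) + 1L  # 1-based codon starts
    codons <- substring(seq, starts, starts + 2L)
    atg_idx <- which(codons == "ATG")
    if (!length(atg_idx)) next
    stop_idx <- which(codons %in% stop_codons)
    # index (within this frame's codon list) of the first stop after each ATG
    nxt <- findInterval(atg_idx, stop_idx) + 1L
    has_stop <- nxt <= length(stop_idx)
    if (require_stop) {
      keep <- has_stop
      atg_idx <- atg_idx[keep]
      nxt <- nxt[keep]
      if (!length(atg_idx)) next
      stop_at <- stop_idx[nxt]
    } else {
      stop_at <- ifelse(has_stop, stop_idx[nxt], ncod + 1L)
    }
    len_aa <- stop_at - atg_idx
    keep <- len_aa >= min_protein_aa
    atg_idx <- atg_idx[keep]; stop_at <- stop_at[keep]; len_aa <- len_aa[keep]
    if (!length(atg_idx)) next
    if (!all_aug) {
      first <- !duplicated(stop_at)   # atg_idx ascending => first is 5'-most
      atg_idx <- atg_idx[first]; stop_at <- stop_at[first]; len_aa <- len_aa[first]
    }
    start_nt <- frame + 3L * (atg_idx - 1L)
    end_nt <- frame + 3L * stop_at  # one past the stop codon (or last codon)
    prot <- vapply(seq_along(atg_idx), function(i) {
      translate_nt(substr(seq, start_nt[i] + 1L, start_nt[i] + 3L * len_aa[i]))
    }, "")
    out[[length(out) + 1L]] <- data.frame(
      transcript_id = transcript_id, frame = frame, start_nt = start_nt,
      end_nt = end_nt, length_aa = len_aa, protein = prot,
      stringsAsFactors = FALSE)
  }
  if (!length(out)) {
    return(data.frame(transcript_id = character(), frame = integer(),
                      start_nt = integer(), end_nt = integer(),
                      length_aa = integer(), protein = character(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res <- res[order(-res$length_aa, res$start_nt, res$frame), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Select the canonical ORF of a transcript
#'
#' The longest qualifying ORF; ties broken by 5'-most start, then by lowest
#' frame index.
#'
#' @param orfs Data.frame from [find_orfs()] for one transcript.
#' @return A single-row data.frame with `is_canonical = TRUE`, or `NULL` when
#'   `orfs` is empty.
#' @export
canonical_orf <- function(orfs) {
  if (is.null(orfs) || nrow(orfs) == 0L) return(NULL)
  ord <- order(-orfs$length_aa, orfs$start_nt, orfs$frame)
  res <- orfs[ord[1L], , drop = FALSE]
  res$is_canonical <- TRUE
  rownames(res) <- NULL
  res
}

#' Three-frame ORF proteome over a transcript set
#'
#' Collects all qualifying ORF proteins (not only canonical ones) across the
#' three forward frames of every transcript, deduplicated by exact protein
#' sequence with provenance retained.
#'
#' @param transcripts Data.frame with `transcript_id` and `sequence` columns.
#' @param min_protein_aa Minimum protein length (aa).
#' @param all_aug Passed to [find_orfs()].
#' @return List with `proteins` (data.frame `accession`, `protein`; accession
#'   is the first provenance record's `transcriptID|frame|start-end`) and
#'   `provenance` (data.frame `accession`, `transcript_id`, `frame`,
#'   `start_nt`, `end_nt`).
#' @export
three_frame_proteome <- function(transcripts, min_protein_aa = 50L,
                                 all_aug = FALSE) {
  stopifnot(nrow(transcripts) > 0L)
  orfs <- do.call(rbind, lapply(seq_len(nrow(transcripts)), function(i) {
    find_orfs(transcripts$sequence[i], min_protein_aa,
              transcript_id = transcripts$transcript_id[i], all_aug = all_aug)
  }))
  if (is.null(orfs) || nrow(orfs) == 0L) {
    return(list(proteins = data.frame(accession = character(),
                                      protein = character(),
                                      stringsAsFactors = FALSE),
                provenance = data.frame(accession = character(),
                                        transcript_id = character(),
                                        frame = integer(), start_nt = integer(),
                                        end_nt = integer(),
                                        stringsAsFactors = FALSE)))
  }
  orfs$self_acc <- orf_accession(orfs$transcript_id, orfs$frame,
                                 orfs$start_nt, orfs$end_nt)
  first <- !duplicated(orfs$protein)
  acc_of <- setNames(orfs$self_acc[first], orfs$protein[first])
  proteins <- data.frame(accession = unname(acc_of[orfs$protein[first]]),
                         protein = orfs$protein[first],
                         stringsAsFactors = FALSE)
  provenance <- data.frame(accession = unname(acc_of[orfs$protein]),
                           transcript_id = orfs$transcript_id,
                           frame = orfs$frame, start_nt = orfs$start_nt,
                           end_nt = orfs$end_nt, stringsAsFactors = FALSE)
  list(proteins = proteins, provenance = provenance)
}
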