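#' Read a FASTA file
#'
#' Thin wrapper around [Biostrings::readBStringSet()] that enforces the
#' pipeline's contract: record order preserved, sequences uppercased,
#' duplicate identifiers rejected, optional U->T normalization so that all
#' internal nucleotide handling uses the DNA alphabet.
#'
#' @param path Path to a FASTA file.
#' @param u_to_t If `TRUE`, replace U with T (RNA input normalized to the
#'   internal DNA alphabet).
#' @return A data.frame with columns `id`, `description`, `sequence`.
#' @export
read_fasta <- function(path, u_to_t = FALSE) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  hdr <- names(set)
  id <- sub("\\s.*$", "", hdr)
  desc <- ifelse(grepl("\\s", hdr), sub("^\\S+\\s+", "", hdr), "")
  seqs <- toupper(as.character(set))
  if (u_to_t) seqs <- chartr("U", "T", seqs)
  if (any(nchar(seqs) == 0L))
    stop("empty FASTA record(s): ", paste(id[nchar(seqs) == 0L], collapse = ", "))
  dup <- unique(id[duplicated(id)])
  if (length(dup))
    stop("duplicate FASTA identifiers: ", paste(dup, collapse = ", "))
  data.frame(id = id, description = desc, sequence = unname(seqs),
             stringsAsFactors = FALSE)
}

#' Write sequences to FASTA
#'
#' @param records Data.frame with `id`, `sequence` and optionally
#'   `description` columns (as returned by [read_fasta()]), or a named
#'   character vector of sequences.
#' @param path Output path.
#' @param width Line width for wrapping sequences.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 70L) {
  if (is.character(records)) {
    records <- data.frame(id = names(records), description = "",
                          sequence = unname(records), stringsAsFactors = FALSE)
  }
  stopifnot(all(c("id", "sequence") %in% names(records)))
  desc <- if ("description" %in% names(records)) records$description
          else rep("", nrow(records))
  hdr <- ifelse(nzchar(desc), paste(records$id, desc), records$id)
  set <- Biostrings::BStringSet(records$sequence)
  names(set) <- hdr
  Biostrings::writeXStringSet(set, filepath = path, width = width)
  invisible(path)
}

# ---- coordinate conventions ---------------------------------------------
# GTF intervals are 1-based inclusive; everything internal is 0-based
# half-open.  These two helpers are the single conversion point.

#' Convert GTF coordinates to internal 0-based half-open intervals
#' @param start,end 1-based inclusive coordinates (vectors).
#' @return A data.frame with 0-based half-open `start`, `end`.
#' @export
gtf_to_internal <- function(start, end) {
  stopifnot(all(end >= start))
  data.frame(start = start - 1L, end = end)
}

#' Convert internal 0-based half-open intervals back to GTF coordinates
#' @param start,end 0-based half-open coordinates (vectors).
#' @return A data.frame with 1-based inclusive `start`, `end`.
#' @export
internal_to_gtf <- function(start, end) {
  stopifnot(all(end > start))
  data.frame(start = start + 1L, end = end)
}

#' Read gene models from a GTF file
#'
#' Parses exon features and assembles per-transcript models. Coordinates are
#' kept 1-based inclusive exactly as in the file; exons are ordered 5'->3'
#' along the transcript (reverse genomic order on the minus strand).
#'
#' @param path Path to a GTF file whose exon features carry `gene_id` and
#'   `transcript_id` attributes; a `biotype` (or `gene_biotype`) attribute is
#'   picked up when present.
#' @return An object of class `gene_models`: a list with `transcripts` (one
#'   row per transcript: `transcript_id`, `gene_id`, `chromosome`, `strand`,
#'   `biotype`, `n_exons`, `length`) and `exons` (one row per exon in
#'   transcript 5'->3' order: `transcript_id`, `start`, `end`).
#' @export
read_gtf <- function(path) {
  if (!file.exists(path)) stop("GTF file not found: ", path)
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  if (!length(lines)) {
    warning("empty GTF: no features found")
    return(empty_gene_models())
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 9L)
  if (length(bad))
    stop("malformed GTF line(s): ", paste(bad, collapse = ", "))
  feat <- vapply(fields, `[[`, "", 3L)
  keep <- feat == "exon"
  if (!any(keep)) {
    warning("GTF contains no exon features")
    return(empty_gene_models())
  }
  fields <- fields[keep]
  attr_of <- function(attrs, key) {
    m <- regmatches(attrs, regexec(paste0(key, ' "([^"]*)"'), attrs))
    vapply(m, function(x) if (length(x) == 2L) x[2L] else NA_character_, "")
  }
  attrs <- vapply(fields, `[[`, "", 9L)
  ex <- data.frame(
    chromosome = vapply(fields, `[[`, "", 1L),
    start = as.integer(vapply(fields, `[[`, "", 4L)),
    end = as.integer(vapply(fields, `[[`, "", 5L)),
    strand = vapply(fields, `[[`, "", 7L),
    gene_id = attr_of(attrs, "gene_id"),
    transcript_id = attr_of(attrs, "transcript_id"),
    biotype = attr_of(attrs, "biotype"),
    stringsAsFactors = FALSE
  )
  gb <- attr_of(attrs, "gene_biotype")
  ex$biotype[is.na(ex$biotype)] <- gb[is.na(ex$biotype)]
  if (anyNA(ex$transcript_id))
    stop("exon feature(s) without transcript_id attribute")
  if (anyNA(ex$gene_id))
    stop("exon feature(s) without gene_id attribute")
  split_tx <- split(ex, ex$transcript_id)
  tx_rows <- lapply(split_tx, function(d) {
    if (length(unique(d$strand)) != 1L)
      stop("mixed strands within transcript ", d$transcript_id[1L])
    data.frame(transcript_id = d$transcript_id[1L],
               gene_id = d$gene_id[1L],
               chromosome = d$chromosome[1L],
               strand = d$strand[1L],
               biotype = if (all(is.na(d$biotype))) NA_character_ else d$biotype[!is.na(d$biotype)][1L],
               n_exons = nrow(d),
               length = sum(d$end - d$start + 1L),
               stringsAsFactors = FALSE)
  })
  transcripts <- do.call(rbind, tx_rows)
  rownames(transcripts) <- NULL
  exons <- do.call(rbind, lapply(split_tx, function(d) {
    d <- d[order(d$start), , drop = FALSE]
    if (d$strand[1L] == "-") d <- d[rev(seq_len(nrow(d))), , drop = FALSE]
    d[, c("transcript_id", "start", "end")]
  }))
  rownames(exons) <- NULL
  structure(list(transcripts = transcripts, exons = exons),
            class = "gene_models")
}

empty_gene_models <- function() {
  structure(list(
    transcripts = data.frame(transcript_id = character(), gene_id = character(),
                             chromosome = character(), strand = character(),
                             biotype = character(), n_exons = integer(),
                             length = integer(), stringsAsFactors = FALSE),
    exons = data.frame(transcript_id = character(), start = integer(),
                       end = integer(), stringsAsFactors = FALSE)),
    class = "gene_models")
}

#' Write gene models as GTF
#'
#' Emits one exon feature per exon with `gene_id`, `transcript_id` and
#' `biotype` attributes; round-trips with [read_gtf()].
#'
#' @param models A `gene_models` object (or the list returned by
#'   [simulate_transcriptome()], which contains one).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(models, path) {
  tx <- models$transcripts
  ex <- models$exons
  rows <- character(0)
  for (i in seq_len(nrow(tx))) {
    e <- ex[ex$transcript_id == tx$transcript_id[i], , drop = FALSE]
    e <- e[order(e$start), , drop = FALSE]
    attrs <- sprintf('gene_id "%s"; transcript_id "%s"; biotype "%s";',
                     tx$gene_id[i], tx$transcript_id[i], tx$biotype[i])
    rows <- c(rows, sprintf("%s\tproteolnc\texon\t%d\t%d\t.\t%s\t.\t%s",
                            tx$chromosome[i], e$start, e$end, tx$strand[i],
                            attrs))
  }
  writeLines(rows, path)
  invisible(path)
}

#' Read a read-count table
#'
#' @param path TSV with header columns `gene_id`, `sample_id`, `library`,
#'   `read_count` and optionally `rpkm`.
#' @return A data.frame of expression records; `rpkm` is `NA` when absent
#'   (recomputed downstream from transcript lengths and library sizes).
#' @export
read_count_table <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("gene_id", "sample_id", "library", "read_count")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("count table missing column(s): ",
                         paste(miss, collapse = ", "))
  bad_lib <- setdiff(unique(d$library), c("mRNA", "RNC", "RFP"))
  if (length(bad_lib))
    stop("unknown library tag(s): ", paste(bad_lib, collapse = ", "))
  rc <- suppressWarnings(as.numeric(d$read_count))
  bad <- which(is.na(rc) | rc != floor(rc) | rc < 0)
  if (length(bad))
    stop("invalid read_count at data line(s): ", paste(bad, collapse = ", "))
  d$read_count <- as.integer(rc)
  if (!"rpkm" %in% names(d)) d$rpkm <- NA_real_
  d[, c("gene_id", "sample_id", "library", "read_count", "rpkm")]
}

#' Write a read-count table
#' @param records Data.frame of expression records.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_count_table <- function(records, path) {
  write.table(records, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
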