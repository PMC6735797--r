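#' Reads per kilobase per million mapped reads
#'
#' `rpkm = read_count * 1e9 / (transcript_len_nt * total_mapped_reads)`.
#'
#' @param read_count Non-negative read count (vectorized).
#' @param transcript_len_nt Transcript length in nt (> 0).
#' @param total_mapped_reads Library size (> 0).
#' @return RPKM value(s).
#' @export
compute_rpkm <- function(read_count, transcript_len_nt, total_mapped_reads) {
  if (any(transcript_len_nt <= 0)) stop("transcript length must be > 0")
  if (any(total_mapped_reads <= 0)) stop("total mapped reads must be > 0")
  read_count * 1e9 / (transcript_len_nt * total_mapped_reads)
}

#' True-expression call for one expression record
#'
#' A gene counts as truly expressed when its read count reaches the minimum
#' (default 10 reads) AND its RPKM reaches the active detection threshold
#' (0.1 by default; 1.0 is the stricter alternative). Both comparisons are
#' inclusive.
#'
#' @param read_count,rpkm Observed count and RPKM (vectorized).
#' @param config A [pipeline_config()].
#' @return Logical vector.
#' @export
is_true_expression <- function(read_count, rpkm, config = pipeline_config()) {
  read_count >= config$min_read_count & rpkm >= config$rpkm_threshold
}

#' Translation ratio
#'
#' TR of a gene = translating-mRNA (RNC) abundance over total mRNA abundance,
#' both as RPKM so the ratio is library-size invariant. Undefined (NA) when
#' the mRNA RPKM is zero.
#'
#' @param rnc_rpkm,mrna_rpkm RPKM values (vectorized).
#' @return TR values; `NA` where `mrna_rpkm == 0`.
#' @export
compute_tr <- function(rnc_rpkm, mrna_rpkm) {
  ifelse(mrna_rpkm > 0, rnc_rpkm / mrna_rpkm, NA_real_)
}

#' Detection pattern of genes across samples
#'
#' Builds the genes x samples binary detection matrix at a given RPKM
#' threshold and classifies each gene as ubiquitous (detected in at least
#' `ubiquity_min_samples` samples) or cell-specific.
#'
#' @param records Expression records (one library type) with `gene_id`,
#'   `sample_id`, `read_count`, `rpkm`.
#' @param config A [pipeline_config()]; `rpkm_threshold` is the active
#'   detection threshold and `ubiquity_min_samples` the ubiquity rule.
#' @return List with `matrix` (0/1 genes x samples) and `class` (named
#'   character vector, `"ubiquitous"` or `"cell_specific"`).
#' @export
detection_pattern <- function(records, config = pipeline_config()) {
  genes <- sort(unique(records$gene_id))
  samples <- sort(unique(records$sample_id))
  m <- matrix(0L, nrow = length(genes), ncol = length(samples),
              dimnames = list(genes, samples))
  det <- is_true_expression(records$read_count, records$rpkm, config)
  m[cbind(match(records$gene_id, genes), match(records$sample_id, samples))] <-
    as.integer(det)
  cls <- ifelse(rowSums(m) >= config$ubiquity_min_samples,
                "ubiquitous", "cell_specific")
  list(matrix = m, class = setNames(cls, genes))
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Exact two-sided p-value by probability-mass ordering: the sum of
#' hypergeometric probabilities of all tables with the same margins whose
#' probability does not exceed that of the observed table (with the
#' conventional (1 + 1e-7) tie tolerance). All-zero margins give p = 1.
#'
#' @param a,b,c,d Cell counts, row-wise: `a,b` top row, `c,d` bottom row.
#' @return Two-sided p-value in (0, 1].
#' @export
fisher_exact_2x2 <- function(a, b, c, d) {
  stopifnot(a >= 0, b >= 0, c >= 0, d >= 0)
  m <- a + c          # first-column margin
  n <- b + d
  k <- a + b          # first-row margin
  if (m + n == 0L || k == 0L || k == m + n) return(1.0)
  support <- max(0L, k - n):min(k, m)
  probs <- dhyper(support, m, n, k)
  p_obs <- dhyper(a, m, n, k)
  p <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  min(1.0, p)
}

#' Chromosome enrichment of a gene set against a background
#'
#' For each chromosome in the background, tests the 2x2 table (new genes on
#' the chromosome / new genes elsewhere / background on it / background
#' elsewhere) with the two-sided Fisher exact test. Raw p-values are the
#' default (matching figure-style reporting); Benjamini-Hochberg adjusted
#' values can be added.
#'
#' @param new_gene_chroms Character vector: chromosome of each new gene.
#' @param background_gene_chroms Chromosome of each background gene.
#' @param adjust Add a BH-adjusted column.
#' @return Data.frame with `chromosome`, `n_new`, `n_background`, `p` (and
#'   `p_bh` when requested).
#' @export
chromosome_enrichment <- function(new_gene_chroms, background_gene_chroms,
                                  adjust = FALSE) {
  missing_chr <- setdiff(unique(new_gene_chroms),
                         unique(background_gene_chroms))
  if (length(missing_chr))
    stop("chromosome(s) absent from background: ",
         paste(missing_chr, collapse = ", "))
  chroms <- sort(unique(background_gene_chroms))
  n_new_tot <- length(new_gene_chroms)
  n_bg_tot <- length(background_gene_chroms)
  res <- do.call(rbind, lapply(chroms, function(ch) {
    a <- sum(new_gene_chroms == ch)
    b <- n_new_tot - a
    c <- sum(background_gene_chroms == ch)
    d <- n_bg_tot - c
    data.frame(chromosome = ch, n_new = a, n_background = c,
               p = fisher_exact_2x2(a, b, c, d), stringsAsFactors = FALSE)
  }))
  if (adjust) res$p_bh <- stats::p.adjust(res$p, method = "BH")
  rownames(res) <- NULL
  res
}

#' Ribosome-footprint coverage of a predicted CDS
#'
#' Footprint intervals are in transcript coordinates (0-based half-open,
#' like the ORF coordinates). Coverage is the fraction of CDS positions
#' covered by at least one footprint; the density ratio compares per-nt
#' footprint 5'-end (start) density inside vs outside the CDS.
#'
#' @param orf Single-row data.frame with `start_nt`, `end_nt` (0-based
#'   half-open CDS on the transcript).
#' @param footprints Data.frame with `start`, `end` (0-based half-open) in
#'   transcript coordinates; may be empty.
#' @param transcript_len Transcript length in nt.
#' @return List with `fraction_cds_covered` and `inside_outside_density_ratio`
#'   (`Inf` when the outside density is zero but the inside density is not;
#'   `NA` when there are no footprints).
#' @export
rfp_coverage <- function(orf, footprints, transcript_len) {
  cds_len <- orf$end_nt - orf$start_nt
  stopifnot(cds_len > 0, transcript_len >= orf$end_nt)
  if (is.null(footprints) || nrow(footprints) == 0L)
    return(list(fraction_cds_covered = 0,
                inside_outside_density_ratio = NA_real_))
  cov <- logical(transcript_len)
  for (i in seq_len(nrow(footprints))) {
    s <- max(0L, footprints$start[i]); e <- min(transcript_len, footprints$end[i])
    if (e > s) cov[(s + 1L):e] <- TRUE
  }
  cds_idx <- (orf$start_nt + 1L):orf$end_nt
  frac <- mean(cov[cds_idx])
  inside <- sum(footprints$start >= orf$start_nt & footprints$start < orf$end_nt)
  outside <- nrow(footprints) - inside
  out_len <- transcript_len - cds_len
  d_in <- inside / cds_len
  d_out <- if (out_len > 0) outside / out_len else 0
  ratio <- if (d_out == 0) {
    if (d_in > 0) Inf else NA_real_
  } else d_in / d_out
  list(fraction_cds_covered = frac, inside_outside_density_ratio = ratio)
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' D is the supremum distance between the two empirical CDFs; the p-value is
#' exact (network algorithm) when n*m <= 1e4 and asymptotic otherwise, as in
#' [stats::ks.test()].
#'
#' @param x,y Numeric samples (each of size >= 1).
#' @return List with `D` and `p`.
#' @export
ks_two_sample <- function(x, y) {
  if (!length(x) || !length(y)) stop("both samples must be non-empty")
  exact <- length(x) * length(y) <= 1e4
  res <- suppressWarnings(ks.test(x, y, exact = exact))
  list(D = unname(res$statistic), p = res$p.value)
}

#' Per-gene translation profiles from paired count tables
#'
#' Joins mRNA and RNC records of one sample, computes RPKM from transcript
#' lengths and realized library sizes when not supplied, and derives TR and
#' detection flags.
#'
#' @param records Expression records for one sample, libraries `mRNA` and
#'   `RNC` (`rpkm` may be `NA`; it is then computed from `lengths`).
#' @param lengths Named vector of transcript/gene lengths (nt).
#' @param config A [pipeline_config()].
#' @return Data.frame with `gene_id`, `mrna_rpkm`, `rnc_rpkm`, `tr`,
#'   `detected_mrna`, `detected_rnc`.
#' @export
translation_profiles <- function(records, lengths, config = pipeline_config()) {
  one <- function(lib) {
    d <- records[records$library == lib, , drop = FALSE]
    if (!nrow(d)) stop("no ", lib, " records")
    if (anyNA(d$rpkm)) {
      tot <- sum(d$read_count)
      d$rpkm <- compute_rpkm(d$read_count, lengths[d$gene_id], tot)
    }
    d
  }
  m <- one("mRNA"); r <- one("RNC")
  genes <- sort(union(m$gene_id, r$gene_id))
  mi <- match(genes, m$gene_id); ri <- match(genes, r$gene_id)
  mrna_rpkm <- ifelse(is.na(mi), 0, m$rpkm[mi])
  rnc_rpkm <- ifelse(is.na(ri), 0, r$rpkm[ri])
  mrna_count <- ifelse(is.na(mi), 0L, m$read_count[mi])
  rnc_count <- ifelse(is.na(ri), 0L, r$read_count[ri])
  data.frame(
    gene_id = genes,
    mrna_rpkm = mrna_rpkm, rnc_rpkm = rnc_rpkm,
    tr = compute_tr(rnc_rpkm, mrna_rpkm),
    detected_mrna = is_true_expression(mrna_count, mrna_rpkm, config),
    detected_rnc = is_true_expression(rnc_count, rnc_rpkm, config),
    stringsAsFactors = FALSE)
}
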