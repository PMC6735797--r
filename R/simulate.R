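CODON_OPTIONS <- local({
  gc <- Biostrings::GENETIC_CODE
  split(names(gc), gc)[setdiff(unique(gc), "*")]
})
STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Parameters for the synthetic study generator
#'
#' Defines the conditions the synthetic benchmark emulates: a mixed
#' transcriptome of coding genes and lncRNAs with a configurable fraction of
#' lncRNAs carrying planted AUG-initiated ORFs, overdispersed count
#' libraries with controllable translation-ratio shifts, peptide
#' identification lists with planted true, shared and near-miss contaminant
#' peptides, and light/heavy transition tables with controllable noise.
#' Identical seeds give bit-identical outputs.
#'
#' @param n_coding_genes,n_lncrnas Transcriptome composition.
#' @param frac_lncrna_with_orf Fraction of lncRNAs carrying a planted
#'   AUG-initiated ORF of at least `min_protein_aa` aa.
#' @param frac_single_exon Fraction of single-exon gene models (new coding
#'   genes are overwhelmingly single-exon; default 0.88).
#' @param min_protein_aa Minimum planted protein length (aa).
#' @param orf_extra_aa Upper bound on extra length above the minimum.
#' @param transcript_length_range Length range (nt) for ORF-free lncRNAs.
#' @param library_sizes Named vector of total mapped reads per library.
#' @param dispersion Negative-binomial overdispersion (variance =
#'   mu + dispersion * mu^2); 0 gives Poisson counts.
#' @param tr_shift Multiplicative RNC enrichment applied to the designated
#'   high-TR gene subset.
#' @param frac_high_tr Fraction of genes designated high-TR.
#' @param n_samples Number of samples (cell lines) to simulate.
#' @param peptides_per_protein True unique peptides emitted per planted
#'   protein.
#' @param n_shared_peptides Planted ORFs receiving an embedded exact copy of
#'   a known-protein tryptic peptide (supportive/shared evidence).
#' @param n_nearmiss_peptides Planted ORFs receiving an embedded
#'   single-substitution variant of a known tryptic peptide (distance-1
#'   contaminants the alignment filter must reject).
#' @param n_edit2_peptides Planted ORFs receiving a two-substitution variant
#'   (at the acceptance boundary: two mismatches pass the filter).
#' @param n_contaminant_d0 Exact known-protein peptides emitted in the
#'   identification list (distance-0 contaminants).
#' @param n_transitions Transition pairs per precursor in targeted-MS
#'   simulation.
#' @param sn_range Light signal-to-noise range for passing transitions.
#' @param ratio_deviation_half Half-width of per-pair ratio jitter for
#'   verified precursors.
#' @param frac_verified Fraction of precursors constructed to verify.
#' @param seed Integer seed; all generators derive their streams from it.
#' @return Object of class `simulation_params`.
#' @export
simulation_params <- function(n_coding_genes = 200L,
                              n_lncrnas = 50L,
                              frac_lncrna_with_orf = 0.4,
                              frac_single_exon = 0.88,
                              min_protein_aa = 50L,
                              orf_extra_aa = 60L,
                              transcript_length_range = c(500L, 1500L),
                              library_sizes = c(mRNA = 2e6, RNC = 2e6,
                                                RFP = 5e5),
                              dispersion = 0.3,
                              tr_shift = 1,
                              frac_high_tr = 0.1,
                              n_samples = 1L,
                              peptides_per_protein = 2L,
                              n_shared_peptides = 0L,
                              n_nearmiss_peptides = 0L,
                              n_edit2_peptides = 0L,
                              n_contaminant_d0 = 0L,
                              n_transitions = 4L,
                              sn_range = c(5, 20),
                              ratio_deviation_half = 0.08,
                              frac_verified = 0.7,
                              seed = 1L) {
  p <- mget(names(formals()))
  for (f in c("frac_lncrna_with_orf", "frac_single_exon", "frac_high_tr",
              "frac_verified"))
    if (p[[f]] < 0 || p[[f]] > 1) stop(f, " must be in [0, 1]")
  if (any(p$library_sizes <= 0)) stop("library sizes must be positive")
  if (p$dispersion < 0) stop("dispersion must be >= 0")
  n_planted <- round(p$frac_lncrna_with_orf * p$n_lncrnas)
  n_embed <- p$n_shared_peptides + p$n_nearmiss_peptides + p$n_edit2_peptides
  if (n_embed > n_planted)
    stop("embedded peptide count (", n_embed,
         ") exceeds the number of planted ORFs (", n_planted, ")")
  if (3 * (p$min_protein_aa + 1) + 60 > max(p$transcript_length_range))
    stop("transcript length range cannot accommodate the minimum ORF")
  p$seed <- as.integer(p$seed)
  class(p) <- "simulation_params"
  p
}

random_aa <- function(n) paste(sample(STANDARD_AA, n, replace = TRUE),
                               collapse = "")

# random nucleotides
random_nt <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                      replace = TRUE), collapse = "")

# reverse-translate a protein with uniformly sampled synonymous codons
reverse_translate <- function(protein) {
  res <- strsplit(protein, "")[[1]]
  paste(vapply(res, function(a) {
    opts <- CODON_OPTIONS[[a]]
    opts[sample.int(length(opts), 1L)]
  }, ""), collapse = "")
}

# a tryptic-friendly protein: initiator M, then blocks of 8..14 non-K/R
# residues each terminated by K or R, ending with a short C-terminal tail
random_tryptic_protein <- function(len_aa) {
  aa_pool <- setdiff(STANDARD_AA, c("K", "R", "P", "M"))
  out <- "M"
  n <- 1L
  while (n < len_aa - 4L) {
    block <- min(sample(8:14, 1L), len_aa - 4L - n)
    if (block < 1L) break
    piece <- paste(sample(aa_pool, block, replace = TRUE), collapse = "")
    out <- paste0(out, piece, sample(c("K", "R"), 1L))
    n <- n + block + 1L
  }
  if (n < len_aa)
    out <- paste0(out, paste(sample(aa_pool, len_aa - n, replace = TRUE),
                             collapse = ""))
  out
}

# substitute one internal residue avoiding K/R/P and the residue's own
# equivalence class, so the edit truly counts as a difference
substitute_residue <- function(peptide, n_subs = 1L,
                               equivalences = equivalence_table()) {
  res <- strsplit(peptide, "")[[1]]
  pos_ok <- which(seq_along(res) > 1 & seq_along(res) < length(res) &
                    !res %in% c("K", "R"))
  pos <- sample(pos_ok, n_subs)
  for (p in pos) {
    cls <- unclass(equivalences)
    same_class <- names(cls)[cls == cls[[res[p]]]]
    choices <- setdiff(STANDARD_AA, c(same_class, "K", "R", "P"))
    res[p] <- sample(choices, 1L)
  }
  paste(res, collapse = "")
}

# candidate tryptic peptides of a protein suitable for embedding: fully
# cleaved, 9-15 aa, K/R C-terminus, no leading P
embeddable_peptides <- function(protein) {
  peps <- tryptic_digest(protein, 0L, 9L, 15L)
  peps[grepl("[KR]$", peps) & !grepl("^P", peps)]
}

#' Simulate a mixed transcriptome with planted lncRNA ORFs
#'
#' Generates coding transcripts (whose CDS products form the known PE1
#' proteome), lncRNAs with planted AUG-initiated ORFs of at least
#' `min_protein_aa` aa, and ORF-free lncRNAs (rejection-sampled so they
#' contain no qualifying ORF). Planted transcripts are rejection-sampled so
#' the planted ORF is exactly the transcript's qualifying ORF set. A subset
#' of planted proteins carries embedded known-peptide copies (shared
#' evidence) or near-miss variants (contaminant bait) as configured.
#'
#' @param params A [simulation_params()].
#' @return List with `transcripts` (data.frame incl. `sequence`), `models`
#'   (a `gene_models`), `known_proteins` (accession, gene_id, protein,
#'   pe_status), `truth` (per-lncRNA plant record) and `params`.
#' @export
simulate_transcriptome <- function(params = simulation_params()) {
  stopifnot(inherits(params, "simulation_params"))
  set.seed(params$seed)
  n_cod <- params$n_coding_genes
  n_lnc <- params$n_lncrnas
  n_orf <- round(params$frac_lncrna_with_orf * n_lnc)
  chroms <- paste0("chr", c(1:22, "X"))

  # ---- coding genes: known PE1 proteome -------------------------------
  known <- vector("list", n_cod)
  cod_seq <- character(n_cod)
  for (i in seq_len(n_cod)) {
    len_aa <- sample(60:250, 1L)
    prot <- random_tryptic_protein(len_aa)
    cds <- paste0(reverse_translate(prot), sample(STOP_CODONS, 1L))
    tx_seq <- paste0(random_nt(sample(30:100, 1L)), cds,
                     random_nt(sample(30:100, 1L)))
    cod_seq[i] <- tx_seq
    known[[i]] <- data.frame(accession = sprintf("KP%04d", i),
                             gene_id = sprintf("CG%04d", i),
                             protein = prot, pe_status = "PE1",
                             stringsAsFactors = FALSE)
  }
  known <- do.call(rbind, known)

  # ---- embedding plan for planted ORFs --------------------------------
  embed_kind <- rep("none", n_orf)
  if (n_orf > 0L) {
    kinds <- c(rep("shared", params$n_shared_peptides),
               rep("nearmiss", params$n_nearmiss_peptides),
               rep("edit2", params$n_edit2_peptides))
    if (length(kinds)) embed_kind[seq_along(kinds)] <- kinds
  }

  # ---- lncRNAs --------------------------------------------------------
  lnc <- vector("list", n_lnc)
  truth <- vector("list", n_lnc)
  lnc_seq <- character(n_lnc)
  for (i in seq_len(n_lnc)) {
    tid <- sprintf("LNC%04d", i)
    gid <- sprintf("LG%04d", i)
    if (i <= n_orf) {
      kind <- embed_kind[i]
      ok <- FALSE
      for (try in 1:200) {
        len_aa <- params$min_protein_aa + sample.int(params$orf_extra_aa, 1L)
        prot <- random_tryptic_protein(len_aa)
        emb_pep <- NA_character_; emb_parent <- NA_character_
        if (kind != "none") {
          src <- NULL
          for (ktry in 1:50) {
            cand_row <- sample.int(nrow(known), 1L)
            cands <- embeddable_peptides(known$protein[cand_row])
            if (length(cands)) { src <- cands[sample.int(length(cands), 1L)]
                                 emb_parent <- known$accession[cand_row]
                                 break }
          }
          if (is.null(src)) stop("could not find an embeddable known peptide")
          emb_pep <- switch(kind, shared = src,
                            nearmiss = substitute_residue(src, 1L),
                            edit2 = substitute_residue(src, 2L))
          # replace an internal tryptic block with the embedded peptide
          frags <- tryptic_digest(prot, 0L)
          if (length(frags) < 4L) next
          slot <- sample(2:(length(frags) - 1L), 1L)
          frags[slot] <- emb_pep
          prot <- paste(frags, collapse = "")
        }
        cds <- paste0(reverse_translate(prot), sample(STOP_CODONS, 1L))
        utr5 <- random_nt(sample(30:100, 1L))
        tx_seq <- paste0(utr5, cds, random_nt(sample(30:100, 1L)))
        orfs <- find_orfs(tx_seq, params$min_protein_aa, transcript_id = tid)
        start_nt <- nchar(utr5)
        if (nrow(orfs) == 1L && orfs$start_nt == start_nt &&
            orfs$protein == prot) { ok <- TRUE; break }
      }
      if (!ok) stop("failed to plant a clean ORF for ", tid,
                    " within the retry budget")
      lnc_seq[i] <- tx_seq
      truth[[i]] <- data.frame(
        transcript_id = tid, gene_id = gid, has_orf = TRUE,
        orf_start = start_nt, orf_end = start_nt + 3L * (nchar(prot) + 1L),
        frame = start_nt %% 3L, protein = prot,
        accession = orf_accession(tid, start_nt %% 3L, start_nt,
                                  start_nt + 3L * (nchar(prot) + 1L)),
        embed_kind = kind, embedded_peptide = emb_pep,
        embedded_parent = emb_parent, stringsAsFactors = FALSE)
    } else {
      ok <- FALSE
      for (try in 1:500) {
        len <- sample(params$transcript_length_range[1]:
                        params$transcript_length_range[2], 1L)
        tx_seq <- random_nt(len)
        if (nrow(find_orfs(tx_seq, params$min_protein_aa)) == 0L) {
          ok <- TRUE; break
        }
      }
      if (!ok) stop("failed to sample an ORF-free lncRNA within the retry budget")
      lnc_seq[i] <- tx_seq
      truth[[i]] <- data.frame(
        transcript_id = tid, gene_id = gid, has_orf = FALSE,
        orf_start = NA_integer_, orf_end = NA_integer_, frame = NA_integer_,
        protein = NA_character_, accession = NA_character_,
        embed_kind = "none", embedded_peptide = NA_character_,
        embedded_parent = NA_character_, stringsAsFactors = FALSE)
    }
    lnc[[i]] <- data.frame(transcript_id = tid, gene_id = gid,
                           stringsAsFactors = FALSE)
  }
  truth <- do.call(rbind, truth)

  # ---- assemble transcript table and gene models ----------------------
  transcripts <- data.frame(
    transcript_id = c(sprintf("CTX%04d", seq_len(n_cod)),
                      truth$transcript_id),
    gene_id = c(known$gene_id, truth$gene_id),
    biotype = c(rep("coding", n_cod), rep("lncRNA", n_lnc)),
    sequence = c(cod_seq, lnc_seq),
    pe_status = c(known$pe_status, rep(NA_character_, n_lnc)),
    stringsAsFactors = FALSE)
  n_tx <- nrow(transcripts)
  transcripts$chromosome <- sample(chroms, n_tx, replace = TRUE)
  transcripts$strand <- sample(c("+", "-"), n_tx, replace = TRUE)
  single <- runif(n_tx) < params$frac_single_exon
  # exact planting of the single-exon fraction among lncRNA gene models
  lnc_idx <- which(transcripts$biotype == "lncRNA")
  n_single <- round(params$frac_single_exon * length(lnc_idx))
  single[lnc_idx] <- FALSE
  single[sample(lnc_idx, n_single)] <- TRUE

  exons <- vector("list", n_tx)
  offset <- 1000L
  for (i in seq_len(n_tx)) {
    len <- nchar(transcripts$sequence[i])
    if (single[i]) {
      starts <- offset; ends <- offset + len - 1L
    } else {
      k <- sample(2:4, 1L)
      cuts <- sort(sample(seq_len(len - 1L), k - 1L))
      piece_len <- diff(c(0L, cuts, len))
      starts <- integer(k); ends <- integer(k)
      pos <- offset
      for (j in seq_len(k)) {
        starts[j] <- pos
        ends[j] <- pos + piece_len[j] - 1L
        pos <- ends[j] + sample(100:500, 1L)  # intron
      }
    }
    exons[[i]] <- data.frame(transcript_id = transcripts$transcript_id[i],
                             start = starts, end = ends,
                             stringsAsFactors = FALSE)
    offset <- max(ends) + sample(2000:5000, 1L)
  }
  exons <- do.call(rbind, exons)
  models <- structure(list(
    transcripts = data.frame(
      transcript_id = transcripts$transcript_id,
      gene_id = transcripts$gene_id,
      chromosome = transcripts$chromosome,
      strand = transcripts$strand,
      biotype = transcripts$biotype,
      n_exons = vapply(split(exons$start, exons$transcript_id), length,
                       0L)[transcripts$transcript_id],
      length = nchar(transcripts$sequence),
      stringsAsFactors = FALSE),
    exons = exons), class = "gene_models")
  rownames(models$transcripts) <- NULL

  list(transcripts = transcripts, models = models, known_proteins = known,
       truth = truth, params = params)
}

#' Simulate paired mRNA / RNC / RFP count libraries
#'
#' Per-gene expected expression is log-normal; counts are negative-binomial
#' with shared overdispersion. The designated high-TR subset receives the
#' `tr_shift` multiplier on its RNC means, so the planted translation-ratio
#' contrast is recoverable from the RPKM ratio.
#'
#' @param sim Output of [simulate_transcriptome()].
#' @param params A [simulation_params()] (defaults to `sim$params`).
#' @return List with `counts` (a count table as read by
#'   [read_count_table()], RPKM included), `truth_tr` (per-gene expected TR
#'   multiplier and high-TR flag) and `library_sizes` (realized totals per
#'   sample and library, matching the column sums).
#' @export
simulate_expression <- function(sim, params = sim$params) {
  set.seed(params$seed + 1L)
  tx <- sim$transcripts
  n <- nrow(tx)
  lens <- nchar(tx$sequence)
  expr <- rlnorm(n, meanlog = 3, sdlog = 1)
  high <- runif(n) < params$frac_high_tr
  mult <- ifelse(high, params$tr_shift, 1)
  draw <- function(mu) {
    if (params$dispersion < 1e-12) rpois(n, mu)
    else rnbinom(n, mu = mu, size = 1 / params$dispersion)
  }
  out <- list(); realized <- list()
  for (s in seq_len(params$n_samples)) {
    sid <- sprintf("s%d", s)
    mu_mrna <- expr / sum(expr) * params$library_sizes[["mRNA"]]
    w_rnc <- expr * mult
    mu_rnc <- w_rnc / sum(w_rnc) * params$library_sizes[["RNC"]]
    mu_rfp <- w_rnc / sum(w_rnc) * params$library_sizes[["RFP"]]
    for (lib in c("mRNA", "RNC", "RFP")) {
      mu <- switch(lib, mRNA = mu_mrna, RNC = mu_rnc, RFP = mu_rfp)
      cnt <- draw(mu)
      tot <- sum(cnt)
      out[[paste(sid, lib)]] <- data.frame(
        gene_id = tx$gene_id, sample_id = sid, library = lib,
        read_count = as.integer(cnt),
        rpkm = if (tot > 0) compute_rpkm(cnt, lens, tot) else 0,
        stringsAsFactors = FALSE)
      realized[[paste(sid, lib)]] <- data.frame(
        sample_id = sid, library = lib, total_reads = tot,
        stringsAsFactors = FALSE)
    }
  }
  list(counts = do.call(rbind, c(out, list(make.row.names = FALSE))),
       truth_tr = data.frame(gene_id = tx$gene_id, high_tr = high,
                             tr_multiplier = mult, stringsAsFactors = FALSE),
       library_sizes = do.call(rbind, c(realized,
                                        list(make.row.names = FALSE))))
}

#' Simulate ribosome footprints over planted ORFs
#'
#' Places ~28-32 nt footprints on each ORF-bearing transcript with a
#' configurable inside-CDS : outside-CDS start-density ratio.
#'
#' @param sim Output of [simulate_transcriptome()].
#' @param density_ratio Per-nt footprint-start density inside the CDS
#'   relative to outside (`Inf` places all footprints inside).
#' @param footprints_per_orf Footprints per ORF-bearing transcript.
#' @param params A [simulation_params()] (seed source).
#' @return Data.frame with `transcript_id`, `start`, `end` (0-based
#'   half-open, transcript coordinates).
#' @export
simulate_footprints <- function(sim, density_ratio = 10,
                                footprints_per_orf = 200L,
                                params = sim$params) {
  set.seed(params$seed + 2L)
  planted <- sim$truth[sim$truth$has_orf, , drop = FALSE]
  out <- list()
  for (i in seq_len(nrow(planted))) {
    tid <- planted$transcript_id[i]
    tlen <- nchar(sim$transcripts$sequence[
      sim$transcripts$transcript_id == tid])
    cds <- c(planted$orf_start[i], planted$orf_end[i])
    cds_len <- cds[2] - cds[1]
    out_len <- tlen - cds_len
    w_in <- if (is.infinite(density_ratio)) 1 else {
      density_ratio * cds_len / (density_ratio * cds_len + out_len)
    }
    inside <- runif(footprints_per_orf) < w_in
    fl <- sample(28:32, footprints_per_orf, replace = TRUE)
    starts <- integer(footprints_per_orf)
    out_pos <- c(seq_len(cds[1]) - 1L,
                 if (cds[2] < tlen) cds[2]:(tlen - 1L) else integer(0))
    for (j in seq_len(footprints_per_orf)) {
      starts[j] <- if (inside[j]) sample(cds[1]:(cds[2] - 1L), 1L)
                   else out_pos[sample.int(length(out_pos), 1L)]
    }
    out[[i]] <- data.frame(transcript_id = tid, start = starts,
                           end = pmin(starts + fl, tlen),
                           stringsAsFactors = FALSE)
  }
  if (!length(out)) return(data.frame(transcript_id = character(),
                                      start = integer(), end = integer(),
                                      stringsAsFactors = FALSE))
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Simulate a peptide identification list
#'
#' Emits fully tryptic true peptides of planted proteins, the embedded
#' shared peptides (supportive evidence also present in known proteins),
#' embedded near-miss variants and exact known-protein peptides
#' (distance-1 and distance-0 contaminants that the downstream filters must
#' reject), each labeled in `truth_class`.
#'
#' @param sim Output of [simulate_transcriptome()].
#' @param params A [simulation_params()].
#' @param include_true Emit the true unique peptides (set `FALSE` for
#'   contaminant-only runs).
#' @param min_len,max_len Peptide length window for emitted peptides.
#' @return Data.frame with `peptide`, `truth_class`
#'   (`true_unique`/`shared`/`contaminant_d1`/`variant_d2`/`contaminant_d0`)
#'   and `truth_source` (planted accession or known accession).
#' @export
simulate_peptides <- function(sim, params = sim$params, include_true = TRUE,
                              min_len = 9L, max_len = 25L) {
  set.seed(params$seed + 3L)
  planted <- sim$truth[sim$truth$has_orf, , drop = FALSE]
  rows <- list()
  for (i in seq_len(nrow(planted))) {
    prot <- planted$protein[i]
    emb <- planted$embedded_peptide[i]
    if (include_true) {
      peps <- tryptic_digest(prot, 0L, min_len, max_len)
      if (!is.na(emb)) peps <- setdiff(peps, emb)
      if (!length(peps))
        stop("planted protein without usable tryptic peptide: ",
             planted$accession[i])
      take <- peps[seq_len(min(params$peptides_per_protein, length(peps)))]
      rows[[length(rows) + 1L]] <- data.frame(
        peptide = take, truth_class = "true_unique",
        truth_source = planted$accession[i], stringsAsFactors = FALSE)
    }
    if (!is.na(emb)) {
      cls <- switch(planted$embed_kind[i], shared = "shared",
                    nearmiss = "contaminant_d1", edit2 = "variant_d2")
      rows[[length(rows) + 1L]] <- data.frame(
        peptide = emb, truth_class = cls,
        truth_source = planted$accession[i], stringsAsFactors = FALSE)
    }
  }
  if (params$n_contaminant_d0 > 0L) {
    kp <- sim$known_proteins
    got <- 0L
    while (got < params$n_contaminant_d0) {
      j <- sample.int(nrow(kp), 1L)
      peps <- tryptic_digest(kp$protein[j], 0L, min_len, max_len)
      if (!length(peps)) next
      rows[[length(rows) + 1L]] <- data.frame(
        peptide = peps[sample.int(length(peps), 1L)],
        truth_class = "contaminant_d0", truth_source = kp$accession[j],
        stringsAsFactors = FALSE)
      got <- got + 1L
    }
  }
  if (!length(rows))
    return(data.frame(peptide = character(), truth_class = character(),
                      truth_source = character(), stringsAsFactors = FALSE))
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  out[!duplicated(out$peptide), , drop = FALSE]
}

#' Simulate light/heavy transition measurement tables
#'
#' Constructs per-precursor transition pairs with an intended verification
#' outcome: verified precursors satisfy co-elution, the transition-count /
#' signal-to-noise rule and the ratio-deviation rule; failing precursors
#' violate exactly one sampled criterion. The intended outcome is recorded
#' in `truth_status`.
#'
#' @param peptides Character vector of precursor peptide sequences.
#' @param params A [simulation_params()].
#' @return List with `transitions` (data.frame `precursor_id`,
#'   `fragment_id`, `light_area`, `heavy_area`, `light_sn`, `coelutes`) and
#'   `truth` (`precursor_id`, `truth_status`, `failure_mode`).
#' @export
simulate_transitions <- function(peptides, params = simulation_params()) {
  set.seed(params$seed + 4L)
  rows <- list(); truths <- list()
  modes <- c("fail_count", "fail_sn", "fail_deviation", "fail_coelution")
  for (pep in peptides) {
    verified <- runif(1) < params$frac_verified
    mode <- if (verified) "none" else sample(modes, 1L)
    k <- if (mode == "fail_count") 2L else params$n_transitions
    base_ratio <- runif(1, 0.5, 2)
    dev <- runif(k, -params$ratio_deviation_half, params$ratio_deviation_half)
    if (mode == "fail_deviation") dev[1L] <- 0.5
    heavy <- rlnorm(k, meanlog = 10, sdlog = 0.5)
    light <- heavy * base_ratio * (1 + dev)
    sn <- runif(k, max(3.5, params$sn_range[1]), max(4, params$sn_range[2]))
    if (mode == "fail_sn") sn[seq_len(k - 2L)] <- runif(k - 2L, 0.5, 2.5)
    coel <- rep(TRUE, k)
    if (mode == "fail_coelution") coel[1L] <- FALSE
    rows[[length(rows) + 1L]] <- data.frame(
      precursor_id = pep, fragment_id = sprintf("y%d", seq_len(k) + 2L),
      light_area = light, heavy_area = heavy, light_sn = sn,
      coelutes = coel, stringsAsFactors = FALSE)
    truths[[length(truths) + 1L]] <- data.frame(
      precursor_id = pep,
      truth_status = if (mode == "none") "verified" else "not_verified",
      failure_mode = mode, stringsAsFactors = FALSE)
  }
  list(transitions = do.call(rbind, c(rows, list(make.row.names = FALSE))),
       truth = do.call(rbind, c(truths, list(make.row.names = FALSE))))
}
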