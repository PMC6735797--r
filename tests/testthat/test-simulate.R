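test_that("identical seeds give bit-identical simulations", {
  p <- simulation_params(n_coding_genes = 15L, n_lncrnas = 10L,
                         frac_lncrna_with_orf = 0.5, n_shared_peptides = 1L,
                         n_nearmiss_peptides = 1L, seed = 99L)
  a <- simulate_transcriptome(p)
  b <- simulate_transcriptome(p)
  expect_identical(a$transcripts$sequence, b$transcripts$sequence)
  expect_identical(a$truth, b$truth)
  expect_identical(simulate_expression(a)$counts, simulate_expression(b)$counts)
  expect_identical(simulate_peptides(a), simulate_peptides(b))
})

test_that("no planted ORFs means no qualifying ORF on any lncRNA", {
  p <- simulation_params(n_coding_genes = 5L, n_lncrnas = 15L,
                         frac_lncrna_with_orf = 0, seed = 13L)
  sim <- simulate_transcriptome(p)
  lnc <- sim$transcripts[sim$transcripts$biotype == "lncRNA", ]
  for (i in seq_len(nrow(lnc)))
    expect_equal(nrow(find_orfs(lnc$sequence[i], p$min_protein_aa)), 0L)
})

test_that("every planted ORF is recovered exactly by the ORF scan", {
  p <- simulation_params(n_coding_genes = 5L, n_lncrnas = 20L,
                         frac_lncrna_with_orf = 1, seed = 7L)
  sim <- simulate_transcriptome(p)
  expect_equal(sum(sim$truth$has_orf), 20L)
  for (i in seq_len(nrow(sim$truth))) {
    tr <- sim$transcripts[sim$transcripts$transcript_id ==
                            sim$truth$transcript_id[i], ]
    o <- find_orfs(tr$sequence, p$min_protein_aa)
    expect_equal(nrow(o), 1L)
    expect_equal(o$start_nt, sim$truth$orf_start[i])
    expect_equal(o$end_nt, sim$truth$orf_end[i])
    expect_equal(o$protein, sim$truth$protein[i])
  }
})

test_that("infeasible planting constraints are rejected up front", {
  expect_error(simulation_params(min_protein_aa = 600L,
                                 transcript_length_range = c(100L, 500L)),
               "accommodate")
  expect_error(simulation_params(frac_lncrna_with_orf = 1.2), "in \\[0, 1\\]")
  expect_error(simulation_params(n_lncrnas = 10L, frac_lncrna_with_orf = 0.1,
                                 n_shared_peptides = 5L), "exceeds")
})

test_that("counts conserve the realized library-size bookkeeping", {
  p <- simulation_params(n_coding_genes = 50L, n_lncrnas = 10L,
                         frac_lncrna_with_orf = 0.5, seed = 31L)
  sim <- simulate_transcriptome(p)
  expr <- simulate_expression(sim)
  agg <- aggregate(read_count ~ sample_id + library, expr$counts, sum)
  for (r in seq_len(nrow(agg))) {
    ls <- expr$library_sizes
    want <- ls$total_reads[ls$sample_id == agg$sample_id[r] &
                             ls$library == agg$library[r]]
    expect_equal(agg$read_count[r], want)
  }
})

test_that("a null simulation (no shift, no dispersion) gives TR near 1", {
  p <- simulation_params(n_coding_genes = 300L, n_lncrnas = 10L,
                         frac_lncrna_with_orf = 0.5, dispersion = 0,
                         tr_shift = 1, seed = 17L)
  sim <- simulate_transcriptome(p)
  expr <- simulate_expression(sim)
  prof <- translation_profiles(expr$counts[expr$counts$sample_id == "s1", ],
                               setNames(nchar(sim$transcripts$sequence),
                                        sim$transcripts$gene_id))
  expect_equal(median(prof$tr, na.rm = TRUE), 1, tolerance = 0.05)
})

test_that("footprints follow the requested inside/outside density", {
  p <- simulation_params(n_coding_genes = 2L, n_lncrnas = 4L,
                         frac_lncrna_with_orf = 1, seed = 23L)
  sim <- simulate_transcriptome(p)
  fp_all_in <- simulate_footprints(sim, density_ratio = Inf,
                                   footprints_per_orf = 150L)
  tr1 <- sim$truth[1, ]
  fps <- fp_all_in[fp_all_in$transcript_id == tr1$transcript_id, ]
  expect_true(all(fps$start >= tr1$orf_start & fps$start < tr1$orf_end))
  tlen <- nchar(sim$transcripts$sequence[
    sim$transcripts$transcript_id == tr1$transcript_id])
  cov <- rfp_coverage(data.frame(start_nt = tr1$orf_start,
                                 end_nt = tr1$orf_end), fps, tlen)
  expect_identical(cov$inside_outside_density_ratio, Inf)
  # no footprints at all
  cov0 <- rfp_coverage(data.frame(start_nt = tr1$orf_start,
                                  end_nt = tr1$orf_end),
                       fps[0, ], tlen)
  expect_equal(cov0$fraction_cds_covered, 0)
  expect_true(is.na(cov0$inside_outside_density_ratio))
})

test_that("emitted peptides respect the length window and truth labels", {
  p <- simulation_params(n_coding_genes = 20L, n_lncrnas = 10L,
                         frac_lncrna_with_orf = 0.8, n_shared_peptides = 2L,
                         n_nearmiss_peptides = 2L, n_contaminant_d0 = 3L,
                         seed = 41L)
  sim <- simulate_transcriptome(p)
  peps <- simulate_peptides(sim)
  expect_true(all(nchar(peps$peptide) >= 9L))
  expect_setequal(unique(peps$truth_class),
                  c("true_unique", "shared", "contaminant_d1",
                    "contaminant_d0"))
  # shared peptides really are substrings of both their host and a known
  shared <- peps[peps$truth_class == "shared", ]
  for (i in seq_len(nrow(shared))) {
    host <- sim$truth$protein[which(sim$truth$accession ==
                                      shared$truth_source[i])]
    expect_true(grepl(shared$peptide[i], host, fixed = TRUE))
    expect_true(any(grepl(shared$peptide[i], sim$known_proteins$protein,
                          fixed = TRUE)))
  }
  # near-miss contaminants are within one substitution of a known protein
  nm <- peps[peps$truth_class == "contaminant_d1", ]
  for (i in seq_len(nrow(nm))) {
    d <- min(vapply(sim$known_proteins$protein, function(pr)
      min_alignment_diffs(nm$peptide[i], pr), 0L))
    expect_equal(d, 1L)
  }
})

test_that("transition construction matches its intended verdicts", {
  p <- simulation_params(frac_verified = 0.5, seed = 53L)
  tm <- simulate_transitions(sprintf("PEPTIDE%02dK", 1:40), p)
  got <- verify_transitions(tm$transitions)
  expect_equal(setNames(got$status, got$precursor_id)[tm$truth$precursor_id],
               setNames(tm$truth$truth_status, tm$truth$precursor_id))
})
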