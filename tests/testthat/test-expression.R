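test_that("RPKM definition and invariances hold", {
  expect_equal(compute_rpkm(10, 1000, 1e6), 10.0)
  expect_equal(compute_rpkm(0, 500, 1e7), 0.0)
  expect_equal(compute_rpkm(30, 1200, 2e6),
               compute_rpkm(30 * 7, 1200, 2e6 * 7))
  expect_error(compute_rpkm(1, 0, 1e6), "length")
  expect_error(compute_rpkm(1, 100, 0), "total")
})

test_that("true-expression thresholds are inclusive exactly as printed", {
  cfg <- pipeline_config(rpkm_threshold = 0.1)
  expect_false(is_true_expression(9L, 100, cfg))      # count below 10
  expect_false(is_true_expression(10L, 0.05, cfg))    # rpkm below 0.1
  expect_true(is_true_expression(10L, 0.1, cfg))      # both boundaries pass
})

test_that("translation ratio is an RPKM ratio, undefined at zero mRNA", {
  expect_equal(compute_tr(4, 2), 2)
  expect_equal(compute_tr(3.3, 3.3), 1)
  expect_true(is.na(compute_tr(5, 0)))
  # library-size invariance: scaling both RPKMs cancels
  expect_equal(compute_tr(4 * 3, 2 * 3), compute_tr(4, 2))
})

test_that("detection patterns classify ubiquitous vs cell-specific genes", {
  mk <- function(gene, detected) {
    data.frame(gene_id = gene, sample_id = sprintf("c%02d", 1:9),
               library = "RNC",
               read_count = ifelse(detected, 50L, 2L),
               rpkm = ifelse(detected, 5, 0.01), stringsAsFactors = FALSE)
  }
  rec <- rbind(mk("g_ubi", rep(TRUE, 9)),
               mk("g_spec", c(TRUE, rep(FALSE, 8))),
               mk("g_mid", c(rep(TRUE, 8), FALSE)))
  pat <- detection_pattern(rec, pipeline_config(ubiquity_min_samples = 8))
  expect_equal(sum(pat$matrix["g_ubi", ]), 9)
  expect_equal(sum(pat$matrix["g_spec", ]), 1)
  expect_equal(unname(pat$class[c("g_ubi", "g_mid", "g_spec")]),
               c("ubiquitous", "ubiquitous", "cell_specific"))
})

test_that("raising the RPKM threshold never increases detections", {
  set.seed(19)
  rec <- data.frame(gene_id = rep(sprintf("g%03d", 1:40), each = 9),
                    sample_id = rep(sprintf("c%d", 1:9), 40),
                    library = "RNC",
                    read_count = rpois(360, 30),
                    rpkm = rlnorm(360, -1, 1.5), stringsAsFactors = FALSE)
  lo <- detection_pattern(rec, pipeline_config(rpkm_threshold = 0.1))
  hi <- detection_pattern(rec, pipeline_config(rpkm_threshold = 1.0))
  expect_true(all(rowSums(hi$matrix) <= rowSums(lo$matrix)))
})

test_that("Fisher exact test matches enumeration and the stats oracle", {
  expect_equal(fisher_exact_2x2(0, 0, 0, 0), 1.0)
  expect_equal(fisher_exact_2x2(3, 3, 3, 3), 1.0)
  set.seed(5)
  for (rep in 1:60) {
    a <- sample(0:8, 1); b <- sample(0:8, 1)
    c <- sample(0:8, 1); d <- sample(0:8, 1)
    got <- fisher_exact_2x2(a, b, c, d)
    expect_equal(got, oracle_fisher_two_sided(a, b, c, d), tolerance = 1e-10)
    if (a + b > 0 && c + d > 0 && a + c > 0 && b + d > 0) {
      ref <- stats::fisher.test(matrix(c(a, c, b, d), 2))$p.value
      expect_equal(got, ref, tolerance = 1e-7)
    }
  }
})

test_that("chromosome enrichment flags a planted concentration and conserves counts", {
  set.seed(4)
  bg <- sample(paste0("chr", 1:10), 2000, replace = TRUE)
  new <- c(rep("chr1", 60), sample(paste0("chr", 2:10), 40, replace = TRUE))
  res <- chromosome_enrichment(new, bg)
  expect_lt(res$p[res$chromosome == "chr1"], 1e-6)
  expect_equal(sum(res$n_new), length(new))
  expect_error(chromosome_enrichment(c(new, "chrZ"), bg), "chrZ")
  res_bh <- chromosome_enrichment(new, bg, adjust = TRUE)
  expect_true(all(res_bh$p_bh >= res_bh$p - 1e-12))
})

test_that("footprint coverage handles full, empty and boundary cases", {
  orf <- data.frame(start_nt = 100L, end_nt = 250L)
  one <- data.frame(start = 100L, end = 250L)
  cov <- rfp_coverage(orf, one, 400L)
  expect_equal(cov$fraction_cds_covered, 1.0)
  expect_identical(cov$inside_outside_density_ratio, Inf)
})

test_that("KS statistic and exact p match a permutation oracle", {
  expect_equal(ks_two_sample(1:5, 1:5)$D, 0)
  expect_equal(ks_two_sample(1:5, 11:20)$D, 1)
  expect_error(ks_two_sample(numeric(0), 1:3), "non-empty")
  set.seed(33)
  for (rep in 1:5) {
    x <- runif(5); y <- runif(5, 0.3, 1.4)
    got <- ks_two_sample(x, y)
    expect_equal(got$p, oracle_ks_perm_p(x, y), tolerance = 1e-10)
  }
})

test_that("translation profiles recover a planted TR shift at small scale", {
  p <- simulation_params(n_coding_genes = 400L, n_lncrnas = 10L,
                         frac_lncrna_with_orf = 0.5, tr_shift = 4,
                         frac_high_tr = 0.15, dispersion = 0.1, seed = 71L)
  sim <- simulate_transcriptome(p)
  expr <- simulate_expression(sim)
  prof <- translation_profiles(expr$counts[expr$counts$sample_id == "s1", ],
                               setNames(nchar(sim$transcripts$sequence),
                                        sim$transcripts$gene_id))
  hi <- expr$truth_tr$gene_id[expr$truth_tr$high_tr]
  ratio <- median(prof$tr[prof$gene_id %in% hi], na.rm = TRUE) /
    median(prof$tr[!prof$gene_id %in% hi], na.rm = TRUE)
  expect_gt(ratio, 3); expect_lt(ratio, 5)
})
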