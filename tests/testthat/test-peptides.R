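test_that("equivalence classes collapse I/L and the deamidation twins", {
  eq <- equivalence_table()
  expect_equal(unname(eq[["I"]]), unname(eq[["L"]]))
  expect_equal(unname(eq[["N"]]), unname(eq[["D"]]))
  expect_equal(unname(eq[["Q"]]), unname(eq[["E"]]))
  expect_false(eq[["A"]] == eq[["G"]])
  none <- equivalence_table(ptm_pairs = list(), include_il = FALSE)
  expect_true(all(unclass(none) == names(none)))
  expect_error(equivalence_table(ptm_pairs = list(c("A", "A"))), "distinct")
})

test_that("alignment differences count substitutions and indels over regions", {
  expect_equal(min_alignment_diffs("PEPTIDE", "XXXPEPTIDEYYY"), 0L)
  expect_equal(min_alignment_diffs("PEPTIDE", "XXXPEPTKDEYYY"), 1L)
  # N vs D counts as a match under the default table, not without it
  expect_equal(min_alignment_diffs("PENTIDE", "XXPEDTIDEXX"), 0L)
  expect_equal(min_alignment_diffs("PENTIDE", "XXPEDTIDEXX",
                                   equivalence_table(ptm_pairs = list())), 1L)
  # empty protein: every peptide residue is an insertion
  expect_equal(min_alignment_diffs("PEPTIDE", ""), 7L)
})

test_that("alignment differences equal the exhaustive substring oracle", {
  set.seed(61)
  for (rep in 1:60) {
    pep <- rand_protein(sample(6:12, 1))
    prot <- rand_protein(sample(20:60, 1))
    expect_equal(min_alignment_diffs(pep, prot), oracle_min_diffs(pep, prot))
  }
})

test_that("substituting equivalent residues leaves the distance unchanged", {
  set.seed(62)
  for (rep in 1:20) {
    pep <- rand_protein(10)
    prot <- rand_protein(40)
    swapped <- chartr("ILND", "LIDN", pep)
    expect_equal(min_alignment_diffs(pep, prot),
                 min_alignment_diffs(swapped, prot))
  }
})

make_db <- function(entries) {
  known <- data.frame(accession = names(entries), gene_id = names(entries),
                      protein = unname(entries), pe_status = NA_character_,
                      stringsAsFactors = FALSE)
  build_reference_db(names(entries), known, NULL)
}

test_that("peptide assignment uses I/L-collapsed substring matching", {
  db <- make_db(c(orf1 = paste0("MAAA", "WIDEPEPTIDEK", strrep("GVS", 20)),
                  pe1 = paste0("MCCC", "WIDEPEPTIDEK", strrep("HTY", 20)),
                  other = strrep("MPW", 30)))
  ev <- assign_peptides(c("WIDEPEPTIDEK",   # in two entries -> supportive
                          "WLDEPEPTLDEK",   # matches only via I/L collapse
                          "QQQQQQQQQ",      # matches nothing
                          "BADPEP#"), db)
  expect_equal(ev$n_assigned, c(2L, 2L, 0L, 0L))
  expect_false(ev$is_unique[1])
  expect_equal(ev$rejected_reason[4], "non-standard residue")
  uniq <- assign_peptides("GVSGVSGVSG", db)
  expect_true(uniq$is_unique)
  expect_equal(uniq$assigned_accessions, "orf1")
})

test_that("the uniqueness filter applies the 9-residue and 2-difference rules", {
  target <- paste0("M", strrep("AGV", 10), "SPECIFICWR", strrep("TY", 10))
  # near-miss region SPECIFKCWD: 1 difference from the 9-mer SPECIFICW,
  # 2 differences from the 10-mer SPECIFICWR
  near <- paste0("M", strrep("CPH", 10), "SPECIFKCWD", strrep("DF", 10))
  db <- make_db(c(tgt = target))
  bg <- data.frame(accession = c("tgt", "near"),
                   protein = c(target, near), stringsAsFactors = FALSE)
  cfg <- pipeline_config()
  # 8-mer: rejected on length alone
  ev8 <- sw_uniqueness_filter(assign_peptides("SPECIFIC", db), bg, cfg)
  expect_equal(ev8$verdict, "rejected_short")
  # 9-mer one substitution away from the near protein: rejected as similar
  ev9 <- sw_uniqueness_filter(assign_peptides("SPECIFICW", db), bg, cfg)
  expect_equal(ev9$verdict, "rejected_similar")
  expect_equal(ev9$min_diffs, 1L)
  # two differences from everything else: accepted (boundary inclusive)
  ev10 <- sw_uniqueness_filter(assign_peptides("SPECIFICWR", db), bg, cfg)
  expect_equal(ev10$verdict, "accepted_unique")
  expect_equal(ev10$min_diffs, 2L)
})

test_that("raising the difference threshold never accepts a rejected peptide", {
  p <- simulation_params(n_coding_genes = 25L, n_lncrnas = 10L,
                         frac_lncrna_with_orf = 0.8, n_nearmiss_peptides = 3L,
                         seed = 77L)
  verdicts <- function(min_diffs) {
    res <- run_discovery_pipeline(p, pipeline_config(
      min_alignment_diffs = min_diffs))
    setNames(res$evidence$verdict, res$evidence$peptide)
  }
  v2 <- verdicts(2); v4 <- verdicts(4)
  accepted4 <- names(v4)[v4 == "accepted_unique"]
  expect_true(all(v2[accepted4] == "accepted_unique"))
})

test_that("own-source exclusion keeps a protein from vetoing its own peptides", {
  target <- paste0("M", strrep("AGV", 10), "SPECIFICWR", strrep("TY", 10))
  db <- make_db(c(tgt = target))
  bg <- data.frame(accession = "tgt", protein = target,
                   stringsAsFactors = FALSE)
  ev <- sw_uniqueness_filter(assign_peptides("SPECIFICWR", db), bg)
  expect_equal(ev$verdict, "accepted_unique")   # nothing else to compare to
})

test_that("evidence tiers follow the unique/supportive counting rules", {
  expect_equal(evidence_tier(2L, 0L), "two_plus_unique")
  expect_equal(evidence_tier(1L, 1L), "one_unique_plus_supportive")
  expect_equal(evidence_tier(1L, 0L), "one_unique_only")
  expect_equal(evidence_tier(0L, 3L), "insufficient")
})

test_that("noise-free calls equal the planted truth; contaminants give none", {
  p <- simulation_params(n_coding_genes = 40L, n_lncrnas = 20L,
                         frac_lncrna_with_orf = 0.5, seed = 19L)
  clean <- run_discovery_pipeline(p)
  expect_setequal(clean$calls$accession, clean$expected_accessions)
  # with only distance-0/1 contaminant peptides in the list: zero calls
  p_noise <- simulation_params(n_coding_genes = 40L, n_lncrnas = 20L,
                               frac_lncrna_with_orf = 0.5,
                               n_nearmiss_peptides = 4L,
                               n_contaminant_d0 = 6L, seed = 19L)
  dirty <- run_discovery_pipeline(p_noise, include_true = FALSE)
  expect_equal(nrow(dirty$calls), 0L)
})

test_that("disabling the similarity filter flips a near-miss into a call", {
  p <- simulation_params(n_coding_genes = 30L, n_lncrnas = 10L,
                         frac_lncrna_with_orf = 0.6, n_nearmiss_peptides = 2L,
                         seed = 83L)
  strict <- run_discovery_pipeline(p, pipeline_config(min_alignment_diffs = 2),
                                   include_true = FALSE)
  lax <- run_discovery_pipeline(p, pipeline_config(min_alignment_diffs = 1),
                                include_true = FALSE)
  expect_equal(nrow(strict$calls), 0L)
  expect_gt(nrow(lax$calls), 0L)
})

test_that("shared peptides surface as supportive evidence in tiers", {
  p <- simulation_params(n_coding_genes = 30L, n_lncrnas = 10L,
                         frac_lncrna_with_orf = 0.6, n_shared_peptides = 3L,
                         peptides_per_protein = 1L, seed = 29L)
  res <- run_discovery_pipeline(p)
  shared_hosts <- res$sim$truth$accession[res$sim$truth$embed_kind == "shared"]
  called <- res$calls[res$calls$accession %in% shared_hosts, ]
  expect_true(all(called$tier == "one_unique_plus_supportive"))
  expect_true(all(called$n_supportive >= 1L))
})

test_that("two-substitution variants sit exactly at the acceptance boundary", {
  p <- simulation_params(n_coding_genes = 30L, n_lncrnas = 10L,
                         frac_lncrna_with_orf = 0.6, n_edit2_peptides = 2L,
                         seed = 37L)
  res <- run_discovery_pipeline(p, include_true = FALSE)
  ev <- res$evidence
  expect_true(all(ev$verdict == "accepted_unique"))
  expect_true(all(ev$min_diffs == 2L))
})

test_that("targeted verification enforces its three criteria", {
  cfg <- pipeline_config()
  good <- data.frame(fragment_id = c("y3", "y4", "y5"),
                     light_area = c(1050, 2000, 2950),
                     heavy_area = c(1000, 2000, 3100),
                     light_sn = c(5, 6, 7), coelutes = TRUE,
                     stringsAsFactors = FALSE)
  expect_equal(check_targeted_verification(good, cfg)$status, "verified")
  # only two transitions
  two <- good[1:2, ]
  v2 <- check_targeted_verification(two, cfg)
  expect_equal(v2$status, "not_verified")
  expect_match(v2$reasons, "transition", all = FALSE)
  # one ratio deviating far from the mean
  dev <- good; dev$light_area[1] <- dev$heavy_area[1] * 2
  vd <- check_targeted_verification(dev, cfg)
  expect_equal(vd$status, "not_verified")
  expect_match(vd$reasons, "deviation", all = FALSE)
  # S/N at the boundary is strict: exactly 3 does not count
  sn <- good; sn$light_sn <- c(3, 6, 7)
  expect_equal(check_targeted_verification(sn, cfg)$status, "not_verified")
  # zero heavy area fails the ratio criterion with a reason
  zh <- good; zh$heavy_area[2] <- 0
  vz <- check_targeted_verification(zh, cfg)
  expect_equal(vz$status, "not_verified")
  expect_match(vz$reasons, "zero heavy", all = FALSE)
  # failed co-elution is reported
  ce <- good; ce$coelutes[3] <- FALSE
  expect_match(check_targeted_verification(ce, cfg)$reasons, "elution",
               all = FALSE)
})
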