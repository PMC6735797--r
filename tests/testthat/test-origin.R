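mutate_protein <- function(p, frac) {
  res <- strsplit(p, "")[[1]]
  idx <- sample(length(res), round(frac * length(res)))
  aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  for (i in idx) res[i] <- sample(setdiff(aas, res[i]), 1)
  paste(res, collapse = "")
}

# plant a query protein into clades from `stratum` (oldest -> youngest) with
# the requested mutational divergence; older clades hold unrelated proteins
plant_stratum_case <- function(stratum, n_clades = 4, divergence = 0.6,
                               len = 90) {
  query <- rand_protein(len)
  sets <- lapply(seq_len(n_clades), function(k) {
    set <- vapply(1:4, function(i) rand_protein(len), "")
    if (k >= stratum) set[1] <- mutate_protein(query, divergence)
    set
  })
  names(sets) <- paste0("clade", seq_len(n_clades))
  list(query = query, sets = sets, truth = paste0("clade", stratum))
}

test_that("homology percent is identity x query coverage", {
  p <- rand_protein(60)
  expect_equal(homology_percent(p, p), 100)
  # query fully contained in a 2x longer subject still scores 100
  expect_equal(homology_percent(p, paste0(rand_protein(30), p,
                                          rand_protein(30))), 100)
  # unrelated short random proteins fall below the score threshold
  set.seed(91)
  hits <- vapply(1:20, function(i)
    homology_percent(rand_protein(80), rand_protein(80)), 0)
  expect_true(mean(hits == 0) >= 0.9)
  # percent is asymmetric (query-length denominator): the long query only
  # half-covered by the short subject scores ~50, not 100
  long <- paste0(p, rand_protein(60))
  expect_equal(homology_percent(p, long), 100)
  expect_equal(homology_percent(long, p), 50, tolerance = 0.1)
})

test_that("phylostratum assignment finds the oldest clade with a hit", {
  set.seed(92)
  case <- plant_stratum_case(2)
  # verbatim presence in the oldest set wins
  sets <- case$sets
  sets$clade1[2] <- case$query
  expect_equal(assign_phylostratum(case$query, sets)$oldest_clade_with_hit,
               "clade1")
  # matching nothing: no stratum (emerged in the query's own clade)
  none <- assign_phylostratum(rand_protein(90),
                              lapply(1:3, function(i)
                                vapply(1:3, function(j) rand_protein(90), "")))
  expect_true(is.na(none$oldest_clade_with_hit))
  expect_error(assign_phylostratum("MAAA", list()), "empty")
})

test_that("planted strata are recovered despite 60% divergence", {
  set.seed(93)
  n <- 40
  ok <- 0
  for (i in seq_len(n)) {
    case <- plant_stratum_case(sample(1:4, 1))
    got <- assign_phylostratum(case$query, case$sets, min_pct = 10)
    if (identical(got$oldest_clade_with_hit, case$truth)) ok <- ok + 1
  }
  expect_gte(ok / n, 0.95)
})

mk_models <- function(tx, ex) structure(list(transcripts = tx, exons = ex),
                                        class = "gene_models")

test_that("origin classification follows its precedence order", {
  known_models <- mk_models(
    data.frame(transcript_id = "ct1", gene_id = "cg1", chromosome = "chr2",
               strand = "+", biotype = "coding", n_exons = 2L, length = 300L,
               stringsAsFactors = FALSE),
    data.frame(transcript_id = "ct1", start = c(1000L, 1400L),
               end = c(1150L, 1550L), stringsAsFactors = FALSE))
  known_prot <- vapply(1:5, function(i) rand_protein(100), "")
  microbial <- vapply(1:3, function(i) rand_protein(100), "")

  # intron-resident ORF overlapping the known locus: splice variant
  gm_overlap <- list(
    transcript = data.frame(chromosome = "chr2", strand = "+",
                            stringsAsFactors = FALSE),
    exons = data.frame(start = 1200L, end = 1350L))
  set.seed(94)
  expect_equal(classify_origin(rand_protein(50), gm_overlap, known_models,
                               known_prot, microbial), "splice_variant")

  gm_distinct <- list(
    transcript = data.frame(chromosome = "chr9", strand = "+",
                            stringsAsFactors = FALSE),
    exons = data.frame(start = 5000L, end = 5300L))
  # diverged paralog of a known protein at a distinct locus
  paralog <- mutate_protein(known_prot[1], 0.4)
  expect_equal(classify_origin(paralog, gm_distinct, known_models,
                               known_prot, microbial), "homologous_copy")
  # microbial homolog
  expect_equal(classify_origin(mutate_protein(microbial[1], 0.3), gm_distinct,
                               known_models, known_prot, microbial),
               "microbial")
  # random protein: unknown origin
  expect_equal(classify_origin(rand_protein(90), gm_distinct, known_models,
                               known_prot, microbial), "unknown")
  # coordinates are mandatory for the overlap check
  expect_error(classify_origin(rand_protein(50),
                               list(transcript = NULL, exons = NULL),
                               known_models, known_prot), "coordinates")
})

test_that("exon counting and the single-exon fraction are exact", {
  tx <- data.frame(transcript_id = c("t1", "t2", "t3", "t4"),
                   gene_id = c("g1", "g2", "g3", "g4"),
                   chromosome = "chr1", strand = "+", biotype = "lncRNA",
                   n_exons = c(1L, 1L, 1L, 2L), length = 100L,
                   stringsAsFactors = FALSE)
  models <- mk_models(tx, data.frame(transcript_id = character(),
                                     start = integer(), end = integer()))
  expect_equal(unname(exon_count(models, "t4")), 2L)
  expect_equal(single_exon_fraction(exon_count(models)), 0.75)
})

test_that("the generator plants the single-exon fraction exactly", {
  p <- simulation_params(n_coding_genes = 5L, n_lncrnas = 50L,
                         frac_lncrna_with_orf = 0.4, frac_single_exon = 0.88,
                         seed = 95L)
  sim <- simulate_transcriptome(p)
  lnc_ids <- sim$transcripts$transcript_id[sim$transcripts$biotype == "lncRNA"]
  expect_equal(single_exon_fraction(exon_count(sim$models, lnc_ids)), 0.88)
})
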