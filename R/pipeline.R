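#' Run the full discovery pipeline on synthetic data
#'
#' Convenience wrapper chaining the stages: simulate a transcriptome with
#' planted lncRNA ORFs, simulate expression libraries, call translating
#' genes from the RNC library, build the cell-specific reference database,
#' simulate the peptide identification list, adjudicate peptides
#' (assignment, length rule, alignment-based uniqueness filter) and call
#' new proteins.
#'
#' @param params A [simulation_params()].
#' @param config A [pipeline_config()].
#' @param include_true Emit true peptides (set `FALSE` for a
#'   contaminant-only run).
#' @return List with `sim`, `expression`, `translating_genes`, `db`,
#'   `classification`, `peptides`, `evidence`, `calls` and
#'   `expected_accessions` (planted ORFs of translating lncRNA genes — the
#'   truth set a noise-free run must recover exactly).
#' @export
run_discovery_pipeline <- function(params = simulation_params(),
                                   config = pipeline_config(),
                                   include_true = TRUE) {
  sim <- simulate_transcriptome(params)
  expr <- simulate_expression(sim)
  rnc <- expr$counts[expr$counts$library == "RNC" &
                       expr$counts$sample_id == "s1", , drop = FALSE]
  translating <- rnc$gene_id[is_true_expression(rnc$read_count, rnc$rpkm,
                                                config)]
  planted <- sim$truth[sim$truth$has_orf, , drop = FALSE]
  lnc_orfs <- data.frame(accession = planted$accession,
                         gene_id = planted$gene_id,
                         protein = planted$protein, stringsAsFactors = FALSE)
  db <- build_reference_db(translating, sim$known_proteins, lnc_orfs, config)
  classification <- classify_new_protein(db, sim$known_proteins$accession,
                                         sim$known_proteins$protein)
  peptides <- simulate_peptides(sim, params, include_true = include_true)
  lnc_tx <- sim$transcripts[sim$transcripts$biotype == "lncRNA", ,
                            drop = FALSE]
  orf_bg <- three_frame_proteome(lnc_tx, config$min_protein_aa)
  background <- rbind(
    data.frame(accession = sim$known_proteins$accession,
               protein = sim$known_proteins$protein,
               stringsAsFactors = FALSE),
    data.frame(accession = orf_bg$proteins$accession,
               protein = orf_bg$proteins$protein, stringsAsFactors = FALSE))
  evidence <- assign_peptides(peptides$peptide, db)
  evidence <- sw_uniqueness_filter(evidence, background, config)
  calls <- validate_new_proteins(evidence, db, classification)
  expected <- planted$accession[planted$gene_id %in% translating]
  list(sim = sim, expression = expr, translating_genes = translating,
       db = db, classification = classification, peptides = peptides,
       evidence = evidence, calls = calls, expected_accessions = expected)
}
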