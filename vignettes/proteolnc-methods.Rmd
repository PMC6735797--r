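---
title: "Methods: discovering lncRNA-encoded proteins with proteolnc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: discovering lncRNA-encoded proteins with proteolnc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(proteolnc)
```

## The inference chain

`proteolnc` treats the discovery of proteins encoded by purported long
non-coding RNAs as a chain of falsifiable steps, each with an explicit
decision rule:

1. **Translation detection.** A gene counts as truly expressed in a library
   when `read_count >= 10` **and** `RPKM >= 0.1` (both inclusive; 1.0 is
   the strict alternative threshold). Genes passing this call in the
   translating-mRNA (RNC-seq) library are *translating genes*. Both
   thresholds live in `pipeline_config()` and are applied by
   `is_true_expression()`.
2. **ORF prediction.** `find_orfs()` scans the three sense frames of the
   spliced transcript. An ORF runs from an AUG to the first in-frame stop;
   the stop must lie within the transcript. The protein must be at least
   50 aa, counting the initiator Met and excluding the stop — equivalently
   a coding length of at least 150 nt. One ORF is reported per
   (frame, stop), anchored at the 5'-most AUG; `all_aug = TRUE` reports
   nested starts too.
3. **Database construction.** `build_reference_db()` collects known
   proteins of translating genes plus predicted ORF proteins of translating
   lncRNAs, deduplicated by exact sequence with provenance retained.
   `small_protein_subset()` keeps entries with average molecular mass
   strictly below 25 kDa. Entries outside PE1–PE5 are *new proteins*.
4. **Peptide adjudication.** `assign_peptides()` matches peptides to
   entries as exact substrings with I/L collapsed; a peptide assigned to
   exactly one entry (after collapsing I/L-identical entries) is a
   candidate unique peptide, a multiply-assigned one is supportive.
   `sw_uniqueness_filter()` then requires `length >= 9` and
   `min_alignment_diffs >= 2` against every background protein other than
   the peptide's own source. `validate_new_proteins()` calls a new protein
   when at least one accepted unique peptide supports it, and reports the
   evidence tier (two or more unique; one unique plus supportive; one
   unique only).
5. **Targeted verification.** `check_targeted_verification()` verifies a
   precursor when (a) all transition pairs co-elute, (b) at least 3
   transitions have light S/N strictly above 3, and (c) every light/heavy
   ratio deviates by less than 20% from the precursor's mean ratio.

## The alignment filter

The similarity inspection is the pipeline's core safeguard: a peptide that
is within one substitution or indel of a known protein may simply be a
single-amino-acid variant or an indistinguishable pseudogene product, not
evidence for a new protein.

We operationalize "mismatches/indels" as an *edit count* computed by
semi-global dynamic programming: the full peptide is aligned against any
region of the protein (free protein ends), minimizing
substitutions + insertions + deletions. This removes all dependence on
match/gap score parameters that a score-maximizing local alignment would
introduce, while preserving the best-region search. Residue pairs in the
equivalence table count as matches: I≡L always (identical residue mass),
plus the deamidation mass twins N≡D and Q≡E by default. The PTM set is a
deliberate, configurable assumption — sets of modification-induced mass
coincidences differ between instruments and tolerance settings, and the
deamidation pair is the canonical confusion. Equivalence classes are
applied by mapping both sequences to class representatives before the DP
(`src/edit_dp.cpp`), which is exact because the default pairs form disjoint
classes.

A peptide is never compared against the entry it identifies (nor entries
I/L-identical to it); otherwise its own source would force a distance of 0.
The filter is monotone in the threshold: raising `min_alignment_diffs`
never accepts a previously rejected peptide (property-tested).

## Synthetic data: what it emulates, and what it does not

`simulation_params()` fixes the study conditions; the defaults are chosen
once as realistic values for a cell-line translatome experiment and are not
tuned per run:

* Transcriptome: 200 coding genes and 50 lncRNAs by default, lncRNAs
  500–1500 nt, planted proteins 50–110 aa (the minimum length rule plus up
  to 60 aa). Planted transcripts are rejection-sampled until the planted
  ORF is *exactly* the transcript's qualifying ORF set; ORF-free lncRNAs
  are rejection-sampled to contain no qualifying ORF (bounded retries,
  error on exhaustion — masking could leave residual AUGs).
* Counts: per-gene expression is log-normal (meanlog 3, sdlog 1); counts
  are negative-binomial with shared overdispersion 0.3
  (variance = mu + 0.3 mu²), the simplest model reproducing the
  overdispersion real libraries show; dispersion 0 degenerates to Poisson.
  Library sizes default to 2×10⁶ (mRNA, RNC) and 5×10⁵ (RFP). The
  designated high-TR subset receives a multiplicative shift on its RNC
  means; because TR is an RPKM ratio, the planted shift is recovered as the
  ratio of median TRs regardless of the normalization factor.
* Peptides: planted proteins are built from tryptic blocks (8–14 non-K/R
  residues ending in K/R) so every protein yields well-sized fully tryptic
  peptides. Shared peptides are exact copies of known-protein tryptic
  peptides spliced into a planted protein; near-miss contaminants are
  single substitutions of known peptides (at internal, non-K/R positions,
  avoiding the equivalence classes so the edit genuinely counts);
  two-substitution variants sit exactly at the acceptance boundary.
* Transitions: each precursor is constructed to satisfy all three
  verification criteria or to violate exactly one sampled criterion, and
  the intended outcome is recorded as truth.

With the default library sizes every simulated gene passes the translation
call, so a noise-free run must recover the planted set exactly
(sensitivity 1, zero false calls) — dropout is induced by lowering library
sizes or raising dispersion, not assumed. The generator does **not**
simulate spectra, retention times, search-engine scoring or mapping
ambiguity; passing tests demonstrate the correctness of the inference
rules, not the behavior of upstream search engines on real spectra.

## Numerical and design choices

* **Coordinates.** Internal intervals are 0-based half-open; GTF stays
  1-based inclusive with a single property-tested conversion point
  (`gtf_to_internal()` / `internal_to_gtf()`). Transcript sequences are
  stored sense-strand and already spliced; strand affects genomic
  annotation only, never ORF scanning.
* **Fisher exact test.** Two-sided p by probability-mass ordering (sum of
  hypergeometric probabilities not exceeding the observed table's, with the
  conventional 1+1e-7 tie tolerance), computed from `dhyper()`. Other
  two-sided conventions differ on ties. Chromosome enrichment reports raw p
  by default; Benjamini–Hochberg is available but off.
* **KS test.** `stats::ks.test()` with exact small-sample p when
  `n·m <= 1e4`; checked against a full permutation enumeration at
  n = m = 5.
* **pI.** Henderson–Hasselbalch sum over termini and D/E/C/Y/H/K/R side
  chains; bisection on [0, 14] to |charge| < 1e-4; validated against a
  1e-4-step pH grid to 1e-3. The Bjellqvist pKa set is the default, EMBOSS
  selectable; absolute pI shifts ~0.2 between tables, distribution
  contrasts are robust.
* **Instability index.** (10/L) × sum of DIWV dipeptide weights
  (Guruprasad–Reddy–Pandit table); the table is directional, and values are
  cross-checked against an independent implementation on frozen fixtures.
  Unstable means II > 40.
* **Masses.** Average residue masses throughout (the 25 kDa gate mimics
  gel-based size selection, which is average-mass-like); the gate is strict
  ("less than"), with a configurable lower bound defaulting to 0. The
  digestion-count statistic uses fully cleaved peptides of length 7–50; the
  iBAQ denominator uses the 6–30 aa observable window. Both windows are
  conventions, configurable and logged in the property functions'
  arguments.
* **Folding.** `mfe()` minimizes over nested structures with Watson–Crick
  plus GU wobble pairs, minimum hairpin loop 3, and stacking-only energies:
  only directly stacked pairs contribute (negative) energy, so the empty
  structure bounds the MFE at 0. This simplified nearest-neighbor model is
  deliberately not the full Turner model: the pipeline uses folding only
  for *relative* near-AUG stability contrasts, and absolute kcal/mol differ
  from loop-based implementations. Windows are 39 nt (±19 nt) centered at
  offsets −50..+50 relative to the A of the AUG; clipped windows are
  skipped, not padded. The window anchor and slide range are configuration,
  since reasonable alternatives exist.
* **Homology.** `homology_percent()` folds identity and query coverage into
  one number (identical aligned residues / query length × 100) from a
  BLOSUM62 local alignment with gap open 10 / extend 0.5. Alignments
  scoring below 60 report 0: unrelated ~100-aa proteins rarely exceed a
  local score of ~50 under these penalties, while homologs retaining 40%
  identity score above 100, so the threshold cleanly separates the score
  null from genuine hits. Phylostratum assignment takes the oldest clade
  with a hit at ≥ 10%; the homologous-copy call uses ≥ 30%, a
  twilight-zone convention. These percents are interpretations — the
  package documents them as such rather than claiming equivalence to any
  particular BLAST pipeline.
* **Targeted verification.** The ratio deviation is measured against the
  precursor's mean light/heavy ratio across its transition pairs, since no
  external reference ratio is available to the rule; a pair with zero heavy
  area fails the ratio criterion with an explicit reason.
* **TR.** Computed as an RPKM ratio (library-size invariant) rather than a
  raw-count ratio; undefined (NA, excluded from distributions) when the
  mRNA RPKM is 0.
* **Ubiquity.** "Detected in almost all samples" is operationalized as
  ≥ 8 of 9 samples by default; configurable.

## Problem sizes and verification

The test suite verifies each stage against an independent oracle: a
brute-force every-start ORF scan on 100 random 2-kb transcripts; exhaustive
substring-edit enumeration on 500 random peptide/protein pairs (peptides
≤ 12 aa, proteins ≤ 60 aa); full hypergeometric enumeration of all 2×2
tables with cells ≤ 6; exhaustive nested-structure enumeration for 200
folding windows of 8–18 nt; a 1e-4 pH grid for pI; substring enumeration
for tryptic digestion. End-to-end, a 200-coding/50-lncRNA run with 20
planted ORFs is recovered exactly, a contaminant-only run yields zero
calls, a 4× TR shift over 2000 genes is recovered within [3, 5], a planted
88% single-exon fraction is recovered exactly, and planted phylostrata are
recovered in ≥ 95% of 100 cases at 60% divergence. `scripts/acceptance.R`
recomputes all of these from scratch under a caller-supplied seed.

## Limitations

* The package consumes search-engine peptide lists assumed FDR-controlled
  upstream; it does not re-estimate FDR, score spectra, or parse raw MS
  formats.
* Footprints are consumed as transcript-coordinate interval tables, not
  BAM; read mapping is out of scope.
* The folding model's absolute energies are not comparable to Turner-model
  implementations; only within-package contrasts are meaningful.
* Genome-scale phylostratigraphy is supported only over user-supplied
  proteome sets; the origin-class thresholds are conventions, not
  reconstructions of any particular annotation pipeline.
```{r}
sessionInfo()
```
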