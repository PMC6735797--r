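# Dipeptide instability weight values (DIWV) of Guruprasad, Reddy & Pandit
# (1990); rows index the first residue of a dipeptide, columns the second.
DIWV <- local({
  aas <- c("A","C","D","E","F","G","H","I","K","L",
           "M","N","P","Q","R","S","T","V","W","Y")
  m <- matrix(c(
    #  A      C      D      E      F      G      H      I      K      L      M      N      P      Q      R      S      T      V      W      Y
     1.00, 44.94, -7.49,  1.00,  1.00,  1.00, -7.49,  1.00,  1.00,  1.00,  1.00,  1.00, 20.26,  1.00,  1.00,  1.00,  1.00,  1.00,  1.00,  1.00, # A
     1.00,  1.00, 20.26,  1.00,  1.00,  1.00, 33.60,  1.00,  1.00, 20.26, 33.60,  1.00, 20.26, -6.54,  1.00,  1.00, 33.60, -6.54, 24.68,  1.00, # C
     1.00,  1.00,  1.00,  1.00, -6.54,  1.00,  1.00,  1.00, -7.49,  1.00,  1.00,  1.00,  1.00,  1.00, -6.54, 20.26, -14.03, 1.00,  1.00,  1.00, # D
     1.00, 44.94, 20.26, 33.60,  1.00,  1.00, -6.54, 20.26,  1.00,  1.00,  1.00,  1.00, 20.26, 20.26,  1.00, 20.26,  1.00,  1.00, -14.03, 1.00, # E
     1.00,  1.00, 13.34,  1.00,  1.00,  1.00,  1.00,  1.00, -14.03, 1.00,  1.00,  1.00, 20.26,  1.00,  1.00,  1.00,  1.00,  1.00,  1.00, 33.60, # F
    -7.49,  1.00,  1.00, -6.54,  1.00, 13.34,  1.00, -7.49, -7.49,  1.00,  1.00, -7.49,  1.00,  1.00,  1.00,  1.00, -7.49,  1.00, 13.34, -7.49, # G
     1.00,  1.00,  1.00,  1.00, -9.37, -9.37,  1.00, 44.94, 24.68,  1.00,  1.00, 24.68, -1.88,  1.00,  1.00,  1.00, -6.54,  1.00, -1.88, 44.94, # H
     1.00,  1.00,  1.00, 44.94,  1.00,  1.00, 13.34,  1.00, -7.49, 20.26,  1.00,  1.00, -1.88,  1.00,  1.00,  1.00,  1.00, -7.49,  1.00,  1.00, # I
     1.00,  1.00,  1.00,  1.00,  1.00, -7.49,  1.00, -7.49,  1.00, -7.49, 33.60,  1.00, -6.54, 24.64, 33.60,  1.00,  1.00, -7.49,  1.00,  1.00, # K
     1.00,  1.00,  1.00,  1.00,  1.00,  1.00,  1.00,  1.00, -7.49,  1.00,  1.00,  1.00, 20.26, 33.60, 20.26,  1.00,  1.00,  1.00, 24.68,  1.00, # L
    13.34,  1.00,  1.00,  1.00,  1.00,  1.00, 58.28,  1.00,  1.00,  1.00, -1.88,  1.00, 44.94, -6.54, -6.54, 44.94, -1.88,  1.00,  1.00, 24.68, # M
     1.00, -1.88,  1.00,  1.00, -14.03, -14.03, 1.00, 44.94, 24.68,  1.00,  1.00,  1.00, -1.88, -6.54,  1.00,  1.00, -7.49,  1.00, -9.37,  1.00, # N
    20.26, -6.54, -6.54, 18.38, 20.26,  1.00,  1.00,  1.00,  1.00,  1.00, -6.54,  1.00, 20.26, 20.26, -6.54, 20.26,  1.00, 20.26, -1.88,  1.00, # P
     1.00, -6.54, 20.26, 20.26, -6.54,  1.00,  1.00,  1.00,  1.00,  1.00,  1.00,  1.00, 20.26, 20.26,  1.00, 44.94,  1.00, -6.54,  1.00, -6.54, # Q
     1.00,  1.00,  1.00,  1.00,  1.00, -7.49, 20.26,  1.00,  1.00,  1.00,  1.00, 13.34, 20.26, 20.26, 58.28, 44.94,  1.00,  1.00, 58.28, -6.54, # R
     1.00, 33.60,  1.00, 20.26,  1.00,  1.00,  1.00,  1.00,  1.00,  1.00,  1.00,  1.00, 44.94, 20.26, 20.26, 20.26,  1.00,  1.00,  1.00,  1.00, # S
     1.00,  1.00,  1.00, 20.26, 13.34, -7.49,  1.00,  1.00,  1.00,  1.00,  1.00, -14.03, 1.00, -6.54,  1.00,  1.00,  1.00,  1.00, -14.03, 1.00, # T
     1.00,  1.00, -14.03, 1.00,  1.00, -7.49,  1.00,  1.00, -1.88,  1.00,  1.00,  1.00, 20.26,  1.00,  1.00,  1.00, -7.49,  1.00,  1.00, -6.54, # V
   -14.03,  1.00,  1.00,  1.00,  1.00, -9.37, 24.68,  1.00,  1.00, 13.34, 24.68, 13.34,  1.00,  1.00,  1.00,  1.00, -14.03, -7.49,  1.00,  1.00, # W
    24.68,  1.00, 24.68, -6.54,  1.00, -7.49, 13.34,  1.00,  1.00,  1.00, 44.94,  1.00, 13.34,  1.00, -15.91,  1.00, -7.49,  1.00, -9.37, 13.34  # Y
  ), nrow = 20, byrow = TRUE, dimnames = list(aas, aas))
  m
})

# Average residue masses (Da): average masses of the free amino acids minus
# one water; summing residues and adding one water back gives the protein's
# average molecular weight.
WATER_MW <- 18.0153
AVG_RESIDUE_MASS <- c(
  A = 89.0932, C = 121.1582, D = 133.1027, E = 147.1293, F = 165.1891,
  G = 75.0666, H = 155.1546, I = 131.1729, K = 146.1876, L = 131.1729,
  M = 149.2113, N = 132.1179, P = 115.1305, Q = 146.1445, R = 174.2010,
  S = 105.0926, T = 119.1192, V = 117.1463, W = 204.2252, Y = 181.1885
) - WATER_MW

#' Ionizable-group pKa tables
#'
#' `"bjellqvist"` (default, the de-facto proteomics convention) or
#' `"emboss"`. Both cover the N- and C-terminus and the D, E, C, Y, H, K, R
#' side chains. Absolute pI values shift by roughly 0.2 units between
#' tables; distribution contrasts are robust to the choice.
#'
#' @param name `"bjellqvist"` or `"emboss"`.
#' @return Named numeric vector with elements `Nterm`, `Cterm`, `D`, `E`,
#'   `C`, `Y`, `H`, `K`, `R`.
#' @export
pka_table <- function(name = c("bjellqvist", "emboss")) {
  name <- match.arg(name)
  switch(name,
    bjellqvist = c(Nterm = 7.50, Cterm = 3.55, D = 4.05, E = 4.45, C = 9.00,
                   Y = 10.00, H = 5.98, K = 10.00, R = 12.00),
    emboss = c(Nterm = 8.6, Cterm = 3.6, D = 3.9, E = 4.1, C = 8.5,
               Y = 10.1, H = 6.5, K = 10.8, R = 12.5))
}

#' Amino-acid class composition
#'
#' Fractions of the four-way residue partition used to contrast new
#' proteins with the canonical proteome: nonpolar (A, V, L, I, P, F, W, M),
#' uncharged polar (S, T, Y, Q, N, C, G), negatively charged (D, E) and
#' positively charged (R, K, H). Non-standard symbols (e.g. X) are ignored.
#'
#' @param protein Amino-acid string.
#' @return Named numeric vector `(nonpolar, uncharged_polar, negative,
#'   positive)` summing to 1 over classified residues.
#' @export
aa_class_composition <- function(protein) {
  res <- strsplit(protein, "")[[1]]
  classes <- list(nonpolar = c("A","V","L","I","P","F","W","M"),
                  uncharged_polar = c("S","T","Y","Q","N","C","G"),
                  negative = c("D","E"),
                  positive = c("R","K","H"))
  counts <- vapply(classes, function(cl) sum(res %in% cl), 0)
  tot <- sum(counts)
  if (tot == 0) stop("no classifiable residues in protein")
  counts / tot
}

#' Net charge of a protein at a given pH
#'
#' Henderson-Hasselbalch sum over the N-terminus, C-terminus and the
#' ionizable side chains (D, E, C, Y, H, K, R). Vectorized over `ph`.
#'
#' @param protein Amino-acid string.
#' @param ph pH value(s) in `[0, 14]`.
#' @param pka A [pka_table()].
#' @return Net charge at each `ph`.
#' @export
net_charge <- function(protein, ph, pka = pka_table()) {
  stopifnot(all(ph >= 0), all(ph <= 14))
  res <- strsplit(protein, "")[[1]]
  n_of <- function(a) sum(res == a)
  pos_frac <- function(pk) 1 / (1 + 10^(ph - pk))      # protonated fraction
  neg_frac <- function(pk) -1 / (1 + 10^(pk - ph))     # deprotonated
  charge <- pos_frac(pka[["Nterm"]]) + neg_frac(pka[["Cterm"]])
  for (a in c("K", "R", "H")) charge <- charge + n_of(a) * pos_frac(pka[[a]])
  for (a in c("D", "E", "C", "Y")) charge <- charge + n_of(a) * neg_frac(pka[[a]])
  charge
}

#' Isoelectric point by bisection
#'
#' The pH at which [net_charge()] crosses zero, located by bisection on
#' `[0, 14]` until the absolute charge falls below `tol`.
#'
#' @param protein Amino-acid string (non-empty).
#' @param pka A [pka_table()].
#' @param tol Charge tolerance at convergence.
#' @return pI estimate in (0, 14).
#' @export
isoelectric_point <- function(protein, pka = pka_table(), tol = 1e-4) {
  stopifnot(nchar(protein) >= 1L)
  lo <- 0; hi <- 14
  c_lo <- net_charge(protein, lo, pka)
  c_hi <- net_charge(protein, hi, pka)
  if (c_lo < 0 || c_hi > 0)
    stop("net charge does not cross zero on [0, 14] with this pKa table")
  repeat {
    mid <- (lo + hi) / 2
    c_mid <- net_charge(protein, mid, pka)
    if (abs(c_mid) < tol) return(mid)
    if (c_mid > 0) lo <- mid else hi <- mid
    if (hi - lo < 1e-12) return(mid)
  }
}

#' Instability index
#'
#' `II = (10 / L) * sum of DIWV weights over the L - 1 dipeptides`
#' (Guruprasad-type dipeptide weighting). Proteins with II > 40 are
#' conventionally predicted unstable in vivo.
#'
#' @param protein Amino-acid string of length >= 2 over the standard 20
#'   residues.
#' @return List with `ii` and `unstable` (`ii > 40`).
#' @export
instability_index <- function(protein) {
  res <- strsplit(protein, "")[[1]]
  L <- length(res)
  if (L < 2L) stop("instability index needs length >= 2")
  bad <- setdiff(unique(res), rownames(DIWV))
  if (length(bad))
    stop("residue(s) outside the DIWV alphabet: ", paste(bad, collapse = ", "))
  ii <- (10 / L) * sum(DIWV[cbind(res[-L], res[-1L])])
  list(ii = ii, unstable = ii > 40)
}

#' In-silico tryptic digestion
#'
#' Cleaves C-terminal to K or R except when the next residue is P. With
#' `missed_cleavages = m`, returns every run of up to `m + 1` consecutive
#' fully-cleaved fragments.
#'
#' @param protein Amino-acid string.
#' @param missed_cleavages Maximum missed cleavage sites (>= 0).
#' @param min_len,max_len Optional peptide-length window applied to the
#'   output (`NULL` = no bound).
#' @return Character vector of peptides, in N-to-C order of their starts.
#' @export
tryptic_digest <- function(protein, missed_cleavages = 0L,
                           min_len = NULL, max_len = NULL) {
  stopifnot(missed_cleavages >= 0L)
  res <- strsplit(protein, "")[[1]]
  n <- length(res)
  if (n == 0L) return(character(0))
  cut_after <- which(res %in% c("K", "R"))
  cut_after <- cut_after[cut_after < n & res[pmin(cut_after + 1L, n)] != "P"]
  bounds <- c(0L, cut_after, n)            # fragment boundaries
  nfrag <- length(bounds) - 1L
  frags <- substring(protein, bounds[-length(bounds)] + 1L, bounds[-1L])
  out <- character(0)
  for (i in seq_len(nfrag)) {
    for (m in 0:missed_cleavages) {
      j <- i + m
      if (j > nfrag) break
      out <- c(out, paste(frags[i:j], collapse = ""))
    }
  }
  if (!is.null(min_len)) out <- out[nchar(out) >= min_len]
  if (!is.null(max_len)) out <- out[nchar(out) <= max_len]
  out
}

#' Average molecular weight of a protein
#'
#' Sum of average residue masses plus one water.
#'
#' @param protein Amino-acid string (non-empty, standard residues).
#' @return Molecular weight in Da.
#' @export
molecular_weight <- function(protein) {
  res <- strsplit(protein, "")[[1]]
  if (!length(res)) stop("empty protein")
  bad <- setdiff(unique(res), names(AVG_RESIDUE_MASS))
  if (length(bad))
    stop("non-standard residue(s): ", paste(bad, collapse = ", "))
  sum(AVG_RESIDUE_MASS[res]) + WATER_MW
}

#' Intensity-based absolute quantification (iBAQ)
#'
#' Summed peptide intensity divided by the number of theoretically
#' observable peptides: fully tryptic peptides (0 missed cleavages) within
#' the observable length window (default 6-30 aa).
#'
#' @param summed_peptide_intensity Total intensity (>= 0).
#' @param protein Amino-acid string.
#' @param min_len,max_len Observable peptide-length window.
#' @return List with `ibaq`, `log10_ibaq` (`NA` when intensity is 0) and
#'   `n_observable`. A protein with zero observable peptides returns `NA`
#'   ibaq with a warning.
#' @export
compute_ibaq <- function(summed_peptide_intensity, protein,
                         min_len = 6L, max_len = 30L) {
  stopifnot(summed_peptide_intensity >= 0)
  n_obs <- length(tryptic_digest(protein, 0L, min_len, max_len))
  if (n_obs == 0L) {
    warning("protein has no observable tryptic peptides; iBAQ undefined")
    return(list(ibaq = NA_real_, log10_ibaq = NA_real_, n_observable = 0L))
  }
  ibaq <- summed_peptide_intensity / n_obs
  list(ibaq = ibaq,
       log10_ibaq = if (ibaq > 0) log10(ibaq) else NA_real_,
       n_observable = n_obs)
}

#' Property vector of a protein
#'
#' @param protein Amino-acid string.
#' @param config A [pipeline_config()] (digestion settings).
#' @param pka A [pka_table()].
#' @return Named numeric vector: `length_aa`, `mw_da`, `pi`,
#'   `instability_index`, the four class fractions, `n_tryptic_peptides`
#'   (fully cleaved peptides of length 7-50, the counting mode for
#'   per-protein digestion statistics).
#' @export
protein_properties <- function(protein, config = pipeline_config(),
                               pka = pka_table()) {
  comp <- aa_class_composition(protein)
  c(length_aa = nchar(protein),
    mw_da = molecular_weight(protein),
    pi = isoelectric_point(protein, pka),
    instability_index = instability_index(protein)$ii,
    comp,
    n_tryptic_peptides = length(tryptic_digest(protein, 0L, 7L, 50L)))
}

#' Compare property distributions between two protein sets
#'
#' Applies the two-sample KS test per property (pI, instability index,
#' number of tryptic peptides, length, molecular weight, class fractions)
#' to contrast, e.g., new proteins against PE1 proteins.
#'
#' @param new_set,pe1_set Character vectors of protein sequences.
#' @param properties Which property columns to compare.
#' @param config,pka Passed to [protein_properties()].
#' @return Data.frame with `property`, `D`, `p`, `median_new`, `median_ref`.
#' @export
compare_property_distributions <- function(new_set, pe1_set,
                                           properties = c("pi",
                                                          "instability_index",
                                                          "n_tryptic_peptides",
                                                          "length_aa"),
                                           config = pipeline_config(),
                                           pka = pka_table()) {
  stopifnot(length(new_set) > 0, length(pe1_set) > 0)
  mat_of <- function(set) t(vapply(set, protein_properties, numeric(9),
                                   config = config, pka = pka))
  a <- mat_of(new_set); b <- mat_of(pe1_set)
  out <- do.call(rbind, lapply(properties, function(p) {
    ks <- ks_two_sample(a[, p], b[, p])
    data.frame(property = p, D = ks$D, p = ks$p,
               median_new = median(a[, p]), median_ref = median(b[, p]),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
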