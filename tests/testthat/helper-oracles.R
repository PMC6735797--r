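# Independent oracles used across the suite.  Each one recomputes a result
# by brute force / enumeration, never through the code path it checks.

# --- ORF scan: test every position as a start, then apply the
#     5'-most-AUG-per-(frame, stop) convention ------------------------------
oracle_orf_scan <- function(seq, min_aa) {
  seq <- toupper(seq)
  n <- nchar(seq)
  stops <- c("TAA", "TAG", "TGA")
  hits <- list()
  for (i in 0:(n - 3)) {
    if (substr(seq, i + 1, i + 3) != "ATG") next
    j <- i
    found <- NA
    while (j + 3 <= n) {
      cod <- substr(seq, j + 1, j + 3)
      if (j > i && cod %in% stops) { found <- j; break }
      j <- j + 3
    }
    if (is.na(found)) next
    len_aa <- (found - i) / 3
    if (len_aa >= min_aa)
      hits[[length(hits) + 1L]] <- c(frame = i %% 3, start = i,
                                     end = found + 3, len = len_aa)
  }
  if (!length(hits))
    return(data.frame(frame = integer(), start_nt = integer(),
                      end_nt = integer(), length_aa = integer()))
  h <- as.data.frame(do.call(rbind, hits))
  # 5'-most AUG per (frame, stop)
  h <- h[order(h$start), , drop = FALSE]
  h <- h[!duplicated(h[, c("frame", "end")]), , drop = FALSE]
  out <- data.frame(frame = h$frame, start_nt = h$start, end_nt = h$end,
                    length_aa = h$len)
  out[order(out$start_nt, out$frame), , drop = FALSE]
}

# --- minimum alignment differences: min full-string edit distance (adist,
#     an independent C implementation) over every substring of the protein,
#     plus the all-insertions placement --------------------------------------
oracle_min_diffs <- function(peptide, protein, equiv_map = c(I = "L",
                                                             N = "D",
                                                             Q = "E")) {
  mp <- function(s) chartr(paste(names(equiv_map), collapse = ""),
                           paste(equiv_map, collapse = ""), s)
  pep <- mp(peptide); prot <- mp(protein)
  best <- nchar(pep)  # aligning against nothing: all insertions
  n <- nchar(prot)
  for (i in seq_len(n)) {
    for (j in i:n) {
      d <- utils::adist(pep, substr(prot, i, j))[1, 1]
      if (d < best) best <- d
    }
  }
  best
}

# --- Fisher exact: enumerate all tables with the observed margins, with
#     probabilities from factorials directly --------------------------------
oracle_fisher_two_sided <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c; c2 <- b + d; n <- a + b + c + d
  if (n == 0 || r1 == 0 || r1 == n) return(1)
  lp_table <- function(x) {
    # log P of table with top-left cell x under fixed margins
    (lfactorial(r1) + lfactorial(r2) + lfactorial(c1) + lfactorial(c2) -
       lfactorial(n) - lfactorial(x) - lfactorial(r1 - x) -
       lfactorial(c1 - x) - lfactorial(n - r1 - c1 + x))
  }
  support <- max(0, c1 - r2):min(r1, c1)
  probs <- exp(vapply(support, lp_table, 0))
  p_obs <- exp(lp_table(a))
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

# --- KS permutation oracle (exact for small n, no ties assumed) ------------
oracle_ks_perm_p <- function(x, y) {
  ks_D <- function(x, y) {
    v <- sort(unique(c(x, y)))
    max(abs(ecdf(x)(v) - ecdf(y)(v)))
  }
  pooled <- c(x, y)
  n <- length(x)
  d_obs <- ks_D(x, y)
  idx <- utils::combn(length(pooled), n)
  ds <- apply(idx, 2, function(ii) ks_D(pooled[ii], pooled[-ii]))
  mean(ds >= d_obs - 1e-12)
}

# --- RNA folding: enumerate every nested structure and score it with the
#     same stacking rules, independent of the DP ----------------------------
oracle_mfe <- function(seq, stack = proteolnc::stacking_energy_table(),
                       min_loop = 3L) {
  bases <- strsplit(seq, "")[[1]]
  n <- length(bases)
  pt <- function(i, j) {
    key <- paste0(bases[i], bases[j])
    m <- c(AU = 1, UA = 2, CG = 3, GC = 4, GU = 5, UG = 6)
    if (key %in% names(m)) m[[key]] else NA_integer_
  }
  # all structures on [i, j] as lists of pair matrices
  structures <- function(i, j) {
    if (j - i < min_loop + 1) return(list(matrix(0L, 0, 2)))
    res <- structures(i + 1, j)  # i unpaired
    for (k in (i + min_loop + 1):j) {
      if (is.na(pt(i, k))) next
      inner <- structures(i + 1, k - 1)
      outer <- if (k + 1 <= j) structures(k + 1, j) else list(matrix(0L, 0, 2))
      for (si in inner) for (so in outer)
        res[[length(res) + 1L]] <- rbind(si, so, c(i, k))
    }
    res
  }
  energy <- function(prs) {
    if (!nrow(prs)) return(0)
    key <- paste(prs[, 1], prs[, 2])
    e <- 0
    for (r in seq_len(nrow(prs))) {
      inner <- paste(prs[r, 1] + 1, prs[r, 2] - 1)
      if (inner %in% key)
        e <- e + stack[pt(prs[r, 1], prs[r, 2]),
                       pt(prs[r, 1] + 1, prs[r, 2] - 1)]
    }
    e
  }
  min(0, min(vapply(structures(1, n), energy, 0)))
}

# --- tryptic digestion: a substring is a valid peptide iff its boundaries
#     are cleavage boundaries and it spans <= m internal cleavage sites ------
oracle_tryptic <- function(protein, m) {
  res <- strsplit(protein, "")[[1]]
  n <- length(res)
  is_cut <- function(pos) {  # cleavage after position pos?
    pos >= 1 && pos < n && res[pos] %in% c("K", "R") && res[pos + 1] != "P"
  }
  out <- character(0)
  for (i in seq_len(n)) {
    for (j in i:n) {
      left_ok <- (i == 1) || is_cut(i - 1)
      right_ok <- (j == n) || is_cut(j)
      if (!left_ok || !right_ok) next
      internal <- sum(vapply(i:(j - 1), is_cut, TRUE)[seq_len(max(0, j - i))])
      if (j == i) internal <- 0
      if (internal <= m) out <- c(out, paste(res[i:j], collapse = ""))
    }
  }
  out
}

# random sequence helpers (tests fix their own seeds)
rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                              collapse = "")
rand_rna <- function(n) paste(sample(c("A", "C", "G", "U"), n, TRUE),
                              collapse = "")
rand_protein <- function(n) paste(sample(strsplit(
  "ACDEFGHIKLMNPQRSTVWY", "")[[1]], n, TRUE), collapse = "")
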