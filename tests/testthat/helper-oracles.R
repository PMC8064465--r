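# Independent brute-force oracles, written as plain loops so they share no
# code path with the package implementation.

# Per-residue conservation c, wobble s, selection z, residue r and window w
# computed directly from the aligned sequences.
oracle_track <- function(seqs, ref = 1L, half_width = 10L) {
  gc_map <- Biostrings::GENETIC_CODE
  n <- length(seqs)
  L <- nchar(seqs[[1]]) %/% 3L
  c_vec <- numeric(L)
  s_vec <- numeric(L)
  for (j in seq_len(L)) {
    cod <- character(n)
    for (i in seq_len(n)) cod[i] <- substr(seqs[[i]], 3 * j - 2, 3 * j)
    aa <- unname(gc_map[cod])
    aa[cod == "---"] <- NA
    nongap <- sum(!is.na(aa))
    ref_aa <- aa[ref]
    c_vec[j] <- if (nongap == 0 || is.na(ref_aa)) 0 else {
      sum(aa == ref_aa, na.rm = TRUE) / nongap
    }
    if (nongap == 0) { s_vec[j] <- 0; next }
    tab <- table(aa[!is.na(aa)])
    modal <- sort(names(tab)[tab == max(tab)])[1]
    possible <- sum(gc_map == modal)
    if (possible <= 1) { s_vec[j] <- 0; next }
    observed <- length(unique(cod[!is.na(aa) & aa == modal]))
    s_vec[j] <- (observed - 1) / (possible - 1)
  }
  mu <- mean(s_vec)
  sd_pop <- sqrt(sum((s_vec - mu)^2) / L)
  z_vec <- if (sd_pop == 0) rep(0, L) else (s_vec - mu) / sd_pop
  r_vec <- c_vec + pmin(pmax(z_vec / 2, 0), 1)
  w_vec <- numeric(L)
  for (j in seq_len(L)) {
    lo <- max(1L, j - half_width)
    hi <- min(L, j + half_width)
    w_vec[j] <- sum(r_vec[lo:hi]) / (hi - lo + 1)
  }
  list(c = c_vec, s = s_vec, z = z_vec, r = r_vec, w = w_vec)
}

# Exhaustive O(n*m) overlap scan: 1-based variant positions against
# 0-based half-open intervals.
oracle_overlap_counts <- function(chrom, pos, iv_chrom, iv_start0, iv_end0) {
  out <- integer(length(pos))
  for (i in seq_along(pos)) {
    p0 <- pos[i] - 1L
    hits <- 0L
    for (k in seq_along(iv_start0)) {
      if (chrom[i] == iv_chrom[k] && iv_start0[k] <= p0 && p0 < iv_end0[k]) {
        hits <- hits + 1L
      }
    }
    out[i] <- hits
  }
  out
}

# Random in-frame alignment over raw codons (no planted structure), for
# oracle-equivalence and permutation checks.
random_alignment <- function(n_seq, n_codons, gap_prob = 0, seed = 1L) {
  withr::with_seed(seed, {
    codons <- names(Biostrings::GENETIC_CODE)
    rows <- vapply(seq_len(n_seq), function(i) {
      cod <- sample(codons, n_codons, replace = TRUE)
      if (gap_prob > 0 && i > 1) cod[stats::runif(n_codons) < gap_prob] <- "---"
      paste(cod, collapse = "")
    }, character(1))
    codon_alignment(sprintf("s%02d", seq_len(n_seq)), rows)
  })
}

# Alignment from an explicit codon matrix (rows = sequences).
alignment_from_codons <- function(codon_rows, ids = NULL) {
  seqs <- vapply(codon_rows, paste, character(1), collapse = "")
  if (is.null(ids)) ids <- sprintf("s%02d", seq_along(seqs))
  codon_alignment(ids, seqs)
}
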