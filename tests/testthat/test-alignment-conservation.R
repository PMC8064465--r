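test_that("column profiles tally amino acids, codons and gaps correctly", {
  # mixed column {GGA x3, GGC x2, AGA x1} plus an all-gap column
  rows <- list(
    c("GGA", "---"), c("GGA", "---"), c("GGA", "---"),
    c("GGC", "---"), c("GGC", "---"), c("AGA", "---")
  )
  aln <- alignment_from_codons(rows)
  prof <- profile_columns(aln)
  expect_length(prof, 2L)
  expect_equal(prof[[1]]$aa_counts, c(G = 5L, R = 1L))
  expect_length(prof[[1]]$codon_counts, 3L)
  expect_equal(prof[[1]]$gap_count, 0L)
  expect_equal(prof[[2]]$gap_count, 6L)
  expect_length(prof[[2]]$aa_counts, 0L)
  # a fully conserved column in all rows
  aln2 <- alignment_from_codons(rep(list(c("GGA", "GGA")), 220))
  p2 <- profile_columns(aln2)
  expect_equal(unname(p2[[1]]$aa_counts["G"]), 220L)
})

test_that("malformed alignments are rejected with named rows", {
  expect_error(codon_alignment(c("a", "b"), c("ATGGGA", "ATG")),
               class = "varprior_format_error")
  expect_error(codon_alignment("a", "ATGG"), class = "varprior_format_error")
  # gap breaking a codon
  expect_error(codon_alignment(c("a", "b"), c("ATGGGA", "AT-GGA")),
               class = "varprior_format_error")
  expect_error(codon_alignment(c("a", "b"), c("ATGGGA", "ATGGGA"),
                               reference_id = "zz"),
               class = "varprior_format_error")
  expect_error(codon_alignment(c("a", "a"), c("ATG", "ATG")),
               class = "varprior_format_error")
})

test_that("conservation fraction excludes gap rows and handles edge cases", {
  aln <- alignment_from_codons(c(rep(list("GGA"), 150),
                                 rep(list("TGC"), 50),
                                 rep(list("---"), 20)))
  p <- profile_columns(aln)[[1]]
  expect_equal(conservation_fraction(p, "G"), 0.75) # 150 of 200 non-gap
  expect_equal(conservation_fraction(p, "K"), 0)    # absent residue
  all_conserved <- profile_columns(
    alignment_from_codons(rep(list("GGA"), 220)))[[1]]
  expect_equal(conservation_fraction(all_conserved, "G"), 1.0)
  all_gap <- list(codon_index = 0L,
                  aa_counts = stats::setNames(integer(0), character(0)),
                  codon_counts = stats::setNames(integer(0), character(0)),
                  gap_count = 5L, ref_aa = NA_character_)
  expect_equal(conservation_fraction(all_gap), 0)
})

test_that("selection z standardizes the wobble statistic gene-wide", {
  # all columns share one codon -> s identical -> degenerate variance, z = 0
  flat <- alignment_from_codons(rep(list(rep("ATG", 4)), 5))
  expect_equal(selection_z(profile_columns(flat)), rep(0, 4))
  # a column with all four glycine codons while the residue is fixed has
  # s = 1 and the maximal z of the track
  rows <- lapply(c("GGA", "GGC", "GGG", "GGT"), function(g) {
    c(g, "ATG", "TGC", "AAA")
  })
  aln <- alignment_from_codons(rows)
  z <- selection_z(profile_columns(aln))
  expect_equal(which.max(z), 1L)
  s_oracle <- oracle_track(aln$seqs)$s
  expect_equal(s_oracle[1], 1)
  expect_equal(z, oracle_track(aln$seqs)$z, tolerance = 1e-12)
  expect_error(selection_z(profile_columns(alignment_from_codons(list("ATG", "ATG")))),
               class = "varprior_insufficient_data")
})

test_that("residue score is the calibrated conservation + selection sum", {
  expect_equal(residue_score(1.0, 0.5), 1.25)
  expect_equal(residue_score(0, -3), 0)
  expect_equal(residue_score(0, 0), 0)
  expect_equal(residue_score(1.0, 2), 2.0)
  expect_equal(residue_score(1.0, 10), 2.0) # saturation
  expect_error(residue_score(1.2, 0), class = "varprior_domain_error")
})

test_that("window scores truncate at termini and average the window", {
  r <- rep(1.25, 100)
  expect_equal(window_score(r), rep(1.25, 100))
  r2 <- seq(0, 1, length.out = 100)
  expect_equal(window_score(r2, position = 1), mean(r2[1:11]))
  expect_equal(window_score(r2, position = 100), mean(r2[90:100]))
  expect_equal(window_score(r2, position = 50), mean(r2[40:60]))
  # widening the window to the whole protein makes w constant = mean(r)
  expect_equal(window_score(r2, half_width = 100L), rep(mean(r2), 100))
  expect_error(window_score(r2, position = 0), class = "varprior_domain_error")
})

test_that("scores match the brute-force oracle on small alignments", {
  for (seed in 1:8) {
    aln <- random_alignment(n_seq = sample(2:10, 1), n_codons = sample(5:30, 1),
                            gap_prob = ifelse(seed %% 2 == 0, 0.1, 0),
                            seed = seed)
    tr <- score_track(aln)
    orc <- oracle_track(aln$seqs)
    expect_equal(tr$c, orc$c, tolerance = 1e-12)
    expect_equal(tr$z, orc$z, tolerance = 1e-12)
    expect_equal(tr$r, orc$r, tolerance = 1e-12)
    expect_equal(tr$w, orc$w, tolerance = 1e-12)
    expect_true(all(tr$c >= 0 & tr$c <= 1))
    expect_true(all(tr$r >= 0 & tr$r <= 2))
    expect_true(all(tr$w >= 0 & tr$w <= 2))
  }
})

test_that("scoring is invariant to sequence row order", {
  aln <- random_alignment(8, 25, gap_prob = 0.05, seed = 42)
  tr <- score_track(aln)
  withr::with_seed(99, {
    perm <- sample(seq_along(aln$ids))
  })
  shuffled <- codon_alignment(aln$ids[perm], aln$seqs[perm],
                              reference_id = aln$reference_id)
  expect_equal(score_track(shuffled), tr)
})

test_that("motif calling is greedy, deterministic and tie-broken low", {
  flat <- tibble::tibble(residue = 1:60, ref_aa = "A",
                         c = 1, z = 0, r = 1, w = 1)
  calls <- call_motifs(flat, top_k = 6)
  # ties break toward the lower codon index: first call is the N-terminal
  # truncated window
  expect_equal(calls$start_residue[1], 1L)
  expect_true(nrow(calls) >= 1)
  # non-overlapping
  for (i in seq_len(nrow(calls))) {
    for (j in seq_len(nrow(calls))) {
      if (i < j) {
        expect_true(calls$end_residue[i] < calls$start_residue[j] ||
                      calls$end_residue[j] < calls$start_residue[i])
      }
    }
  }
  expect_identical(call_motifs(flat, top_k = 6), calls)
  expect_error(call_motifs(flat, top_k = 0), class = "varprior_parameter_error")
})

test_that("a single planted motif is the top call", {
  cfg <- synth_config(seed = 11, n_sequences = 80, n_codons = 100,
                      motif_spans = list(c(50L, 70L, 1)),
                      wobble_columns = integer())
  out <- synth_alignment(cfg)
  tr <- score_track(out$alignment)
  calls <- call_motifs(tr, top_k = 1)
  # call #1 overlaps the planted span (1-based residues 51..70)
  expect_true(calls$start_residue[1] <= 70 && calls$end_residue[1] >= 51)
})

test_that("six planted motifs are all recovered by the top-six calls", {
  cfg <- synth_config(seed = 3, n_sequences = 120, n_codons = 461)
  out <- synth_alignment(cfg)
  tr <- score_track(out$alignment)
  calls <- call_motifs(tr, top_k = 6)
  spans <- cfg$motif_spans
  hit <- vapply(spans, function(sp) {
    any(calls$start_residue <= sp[[2]] & calls$end_residue >= sp[[1]] + 1L)
  }, logical(1))
  expect_true(all(hit))
})

test_that("planted wobble columns rank in the top decile of selection z", {
  cfg <- synth_config(seed = 5, n_sequences = 150, n_codons = 200)
  out <- synth_alignment(cfg)
  tr <- score_track(out$alignment)
  decile <- stats::quantile(tr$z, 0.9)
  expect_true(all(tr$z[cfg$wobble_columns + 1L] >= decile))
})
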