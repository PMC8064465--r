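test_that("invalid configurations are rejected", {
  expect_error(synth_config(n_sequences = 1), class = "varprior_config_error")
  expect_error(synth_config(n_codons = 50, motif_spans = list(c(40L, 60L, 1))),
               class = "varprior_config_error")
  expect_error(synth_config(motif_spans = list(c(10L, 30L, 1.4))),
               class = "varprior_config_error")
  expect_error(synth_config(n_coding_variants = 0),
               class = "varprior_config_error")
  expect_error(synth_config(planted_enrichment_fold = -1),
               class = "varprior_config_error")
  expect_error(synth_config(n_codons = 100, wobble_columns = 100L),
               class = "varprior_config_error")
})

test_that("identical configurations give byte-identical outputs", {
  cfg <- synth_config(seed = 7, n_sequences = 30, n_codons = 60,
                      n_coding_variants = 15, n_noncoding_variants = 40,
                      n_peaks_per_track = 10)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  p1 <- synth_write_fixtures(cfg, d1)
  p2 <- synth_write_fixtures(cfg, d2)
  for (nm in names(p1)) {
    expect_identical(unname(tools::md5sum(p1[[nm]])),
                     unname(tools::md5sum(p2[[nm]])),
                     label = paste("fixture", nm))
  }
})

test_that("a fully conserved configuration yields single-residue columns", {
  cfg <- synth_config(seed = 2, n_sequences = 40, n_codons = 30,
                      background_conservation = 1,
                      motif_spans = list(), wobble_columns = integer())
  out <- synth_alignment(cfg)
  expect_true(all(out$truth$modal_fraction == 1.0))
  prof <- profile_columns(out$alignment)
  expect_true(all(vapply(prof, function(p) length(p$aa_counts) == 1L,
                         logical(1))))
})

test_that("planted motif conservation separates from background", {
  cfg <- synth_config(seed = 13, n_sequences = 100, n_codons = 100,
                      motif_spans = list(c(50L, 70L, 1)),
                      wobble_columns = integer(),
                      background_conservation = 0.4)
  out <- synth_alignment(cfg)
  # independent tally straight off the sequences
  orc_c <- oracle_track(out$alignment$seqs)$c
  modal_frac <- out$truth$modal_fraction
  in_motif <- out$truth$in_motif
  expect_true(all(modal_frac[in_motif] >= 0.95))
  expect_true(all(modal_frac[!in_motif] <= 0.6))
  # reference-residue conservation agrees with the planted structure
  expect_true(all(orc_c[in_motif] >= 0.95))
})

test_that("wobble columns contain at least two synonymous codons", {
  cfg <- synth_config(seed = 21, n_sequences = 50, n_codons = 80)
  out <- synth_alignment(cfg)
  prof <- profile_columns(out$alignment)
  for (j in cfg$wobble_columns) {
    p <- prof[[j + 1L]]
    expect_length(p$aa_counts, 1L) # amino acid fully conserved
    expect_gte(length(p$codon_counts), 2L)
  }
})

test_that("gap planting produces whole-codon gaps that still validate", {
  cfg <- synth_config(seed = 4, n_sequences = 20, n_codons = 40,
                      gap_rate = 0.15, motif_spans = list(),
                      wobble_columns = integer())
  out <- synth_alignment(cfg)
  expect_s3_class(validate_codon_alignment(out$alignment), "codon_alignment")
  expect_true(any(grepl("---", out$alignment$seqs)))
})

test_that("coding-variant generator plants an all-maximal hit", {
  cfg <- synth_config(seed = 8, n_sequences = 60, n_codons = 120,
                      n_coding_variants = 40)
  cv <- synth_coding_variants(cfg)
  hit <- cv[cv$variant_id == "hit0001", ]
  expect_equal(nrow(hit), 1L)
  # forced by the category map: tool points are maximal, so the additive
  # ground truth is 4 + the conservation component
  r <- 1.6
  s <- additive_score(c(polyphen2 = hit$polyphen2, provean = hit$provean,
                        sift = hit$sift, align_gvgd = hit$align_gvgd), r = r)
  expect_equal(as.numeric(s), 4 + r)
  expect_true(all(cv$af_gnomAD > 0 & cv$af_gnomAD < 1))
  expect_true(all(cv$cohort_carriers >= 0))
})

test_that("category marginals are consistent with uniform sampling", {
  cfg <- synth_config(seed = 31, n_codons = 200, n_coding_variants = 1000)
  cv <- synth_coding_variants(cfg)
  # independent tally, chi-square against uniform (drop the planted row)
  bg <- cv[-1, ]
  for (col in c("polyphen2", "provean", "sift", "align_gvgd")) {
    tab <- table(bg[[col]])
    p <- stats::chisq.test(tab)$p.value
    expect_gt(p, 1e-4)
  }
})

test_that("peak-track truth equals an exhaustive overlap scan", {
  cfg <- synth_config(seed = 17, n_noncoding_variants = 60,
                      n_peaks_per_track = 25)
  reg <- synth_regulatory_variants(cfg)
  pk <- synth_peak_tracks(cfg, reg$variants)
  for (src in names(pk$tracks)) {
    gr <- pk$tracks[[src]]
    truth <- pk$truth[pk$truth$source == src, ]
    oracle <- oracle_overlap_counts(
      reg$variants$chrom, reg$variants$pos,
      as.character(GenomicRanges::seqnames(gr)),
      GenomicRanges::start(gr) - 1L, GenomicRanges::end(gr))
    expect_equal(truth$overlap_count, oracle)
  }
})

test_that("zero peaks per track gives all-zero truth counts", {
  cfg <- synth_config(seed = 6, n_noncoding_variants = 10,
                      n_peaks_per_track = 0)
  pk <- synth_peak_tracks(cfg)
  expect_true(all(pk$truth$overlap_count == 0L))
})

test_that("cohort generator plants the configured enrichment fold", {
  # worked carrier arithmetic: fold 3.24 at mean AF 0.21% in 17,928
  # phenotyped individuals gives 122 carriers
  cfg <- synth_config(seed = 9)
  co <- synth_cohort(cfg)
  expect_equal(co$truth$planted_carriers, 122L)
  et <- enrichment_table(co$cohort)
  hit <- et[et$variant_id == "hit0001", ]
  expect_equal(hit$carrier_freq_pct, 0.68)
  expect_equal(hit$mean_pop_af_pct, 0.21)
  expect_equal(hit$fold, 3.24)

  # hand arithmetic: fold 2 at 0.5% in 10,000 individuals -> 100 carriers
  cfg2 <- synth_config(seed = 9, cohort_size = 10000L,
                       planted_enrichment_fold = 2,
                       planted_af = c(gnomAD = 0.005, TOPMed = 0.005))
  co2 <- synth_cohort(cfg2)
  expect_equal(co2$truth$planted_carriers, 100L)

  # neutral fold recovers ~1 within carrier rounding
  cfg3 <- synth_config(seed = 10, planted_enrichment_fold = 1)
  co3 <- synth_cohort(cfg3)
  et3 <- enrichment_table(co3$cohort)
  hit3 <- et3[et3$variant_id == "hit0001", ]
  step <- 100 * 0.5 / cfg3$cohort_size / hit3$mean_pop_af_pct + 0.02
  expect_lt(abs(hit3$fold - 1), max(step, 0.05))
  expect_true(all(co3$cohort$hpo_profile_count >= 0))
})
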