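#!/usr/bin/env Rscript

# Stage 3: additive and combined impact scoring of coding variants.
#
# Maps the categorical calls of the four missense effect predictors to
# points (PolyPhen2 probably = 1 / possibly = 0.5; Provean Deleterious =
# 1; SIFT Damaging = 1; align-GVGD C65/55 = 1, C45/35 = 0.5, C25/15 =
# 0.25), adds the evolutionary residue score (max 2) for an additive
# score out of 6, and multiplies by the 21-codon window conservation and
# the gnomAD allele frequency for the combined impact score used to rank.

suppressPackageStartupMessages(library(varprior))

track <- read_variant_table("results/score_track.tsv")
variants <- read_variant_table("results/synthetic/coding_variants.tsv", "coding")

scored <- rank_variants(score_coding_variants(variants, track,
                                              freq_db = "gnomAD"))
write_table_tsv(scored, "results/coding_scored.tsv")

top <- scored[1, ]
frac <- score_quantile(scored$additive, top$additive)
cat(sprintf("Scored %d coding variants (max additive %.2f/6)\n",
            nrow(scored), max(scored$additive, na.rm = TRUE)))
cat(sprintf("Top-ranked variant: %s (additive %.2f, window %.2f, AF %.4f%%, combined %.4g)\n",
            top$variant_id, top$additive, top$w, 100 * top$af_gnomAD,
            top$combined))
cat(sprintf("%.1f%% of variants score at or above the top variant's additive score\n",
            100 * frac))
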