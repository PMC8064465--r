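#!/usr/bin/env Rscript

# Stage 5: rare-disease-cohort enrichment and region outliers.
#
# For every variant: the cohort carrier frequency (percent of phenotyped
# individuals carrying the variant), the mean of the gnomAD and TOPMed
# population allele frequencies, and their ratio as the fold enrichment,
# all on 2-decimal rounded percentages. Variants exceeding the region's
# 99th percentile on both HPO profile count and CADD are flagged as
# phenotype-burden outliers. Note the documented caveat: the fold
# compares an individual-level frequency to an allele-level one
# (freq_basis_mismatch).

suppressPackageStartupMessages(library(varprior))

cohort <- read_variant_table("results/synthetic/cohort.tsv", "cohort")

enrich <- enrichment_table(cohort, databases = c("gnomAD", "TOPMed"))
outliers <- region_outliers(cohort)

write_table_tsv(enrich, "results/enrichment.tsv")
write_table_tsv(outliers, "results/outliers.tsv")

top <- enrich[order(-enrich$fold), ][1, ]
cat(sprintf("Enrichment computed for %d variants in a cohort of %d\n",
            nrow(enrich), cohort$cohort_size[[1]]))
cat(sprintf("Top enrichment: %s at %.2f%% carriers vs %.2f%% population = %.2f-fold\n",
            top$variant_id, top$carrier_freq_pct, top$mean_pop_af_pct,
            top$fold))
cat(sprintf("Region outliers (HPO count x CADD, 99th percentile): %s\n",
            paste(outliers$variant_id, collapse = ", ")))
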