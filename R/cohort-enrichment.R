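#' Cohort carrier frequency
#'
#' Percent of phenotyped-cohort individuals carrying at least one
#' alternate allele, rounded half away from zero to two decimals (the
#' precision of the reporting layer; the enrichment ratio is computed on
#' these rounded percentages, see [enrichment_fold()]).
#'
#' @param carriers Integer count of carrier individuals.
#' @param cohort_size Total phenotyped individuals (> 0).
#' @return Carrier frequency in percent, two decimals.
#' @examples
#' carrier_frequency(122, 17928) # 0.68
#' @export
carrier_frequency <- function(carriers, cohort_size) {
  if (any(cohort_size <= 0)) {
    rlang::abort("`cohort_size` must be positive.",
                 class = "varprior_domain_error")
  }
  if (any(carriers < 0 | carriers > cohort_size)) {
    rlang::abort("`carriers` must lie in [0, cohort_size].",
                 class = "varprior_domain_error")
  }
  round_half_away(100 * carriers / cohort_size, 2)
}

#' Mean population allele frequency
#'
#' Unweighted mean of the selected per-database allele frequencies,
#' reported in percent and rounded half away from zero to two decimals
#' (so 0.205% prints as 0.21%).
#'
#' @param afs Named numeric vector of allele frequencies as fractions,
#'   one per database.
#' @param databases Character vector of database names to average
#'   (default: all of `afs`).
#' @return Mean allele frequency in percent, two decimals.
#' @examples
#' mean_population_af(c(gnomAD = 0.0023, TOPMed = 0.0018)) # 0.21
#' @export
mean_population_af <- function(afs, databases = names(afs)) {
  if (length(databases) == 0L) {
    rlang::abort("At least one database must be selected.",
                 class = "varprior_parameter_error")
  }
  missing_db <- setdiff(databases, names(afs))
  if (length(missing_db)) {
    rlang::abort(sprintf("Database(s) not present: %s",
                         paste(missing_db, collapse = ", ")),
                 class = "varprior_parameter_error")
  }
  sel <- as.numeric(afs[databases])
  if (any(sel < 0 | sel > 1, na.rm = TRUE)) {
    rlang::abort("Allele frequencies must be fractions in [0, 1].",
                 class = "varprior_domain_error")
  }
  round_half_away(100 * mean(sel), 2)
}

#' Fold enrichment of cohort carriers over population frequency
#'
#' Ratio of the cohort carrier frequency (percent) to the mean population
#' allele frequency (percent), computed on the two-decimal rounded
#' percentages and itself rounded to two decimals. A zero denominator
#' yields `NA` with a warning.
#'
#' Note the caveat: the numerator counts individuals while the
#' denominator counts alleles; tables produced by [enrichment_table()]
#' carry a `freq_basis_mismatch` flag for this.
#'
#' @param carrier_freq_pct Carrier frequency in percent (already rounded
#'   to 2 decimals).
#' @param mean_pop_af_pct Mean population allele frequency in percent
#'   (already rounded to 2 decimals).
#' @return Fold enrichment, two decimals; `NA` when the denominator is 0.
#' @examples
#' enrichment_fold(0.68, 0.21) # 3.24
#' @export
enrichment_fold <- function(carrier_freq_pct, mean_pop_af_pct) {
  out <- ifelse(mean_pop_af_pct > 0,
                round_half_away(carrier_freq_pct / mean_pop_af_pct, 2),
                NA_real_)
  if (anyNA(out)) {
    rlang::warn("Zero population frequency: fold reported as missing.")
  }
  out
}

#' Per-variant enrichment table for a phenotyped cohort
#'
#' Computes, for every variant in a cohort summary table, the carrier
#' frequency, the mean population allele frequency over the selected
#' databases, and the fold enrichment.
#'
#' @param cohort Tibble with `variant_id`, `cohort_carriers`,
#'   `cohort_size`, and per-database allele-frequency columns `af_<db>`
#'   as fractions.
#' @param databases Databases to average (default `c("gnomAD", "TOPMed")`).
#' @return Tibble `variant_id`, `carrier_freq_pct`, `mean_pop_af_pct`,
#'   `fold`, `freq_basis_mismatch` (always `TRUE`: the ratio compares an
#'   individual-level frequency to an allele-level one, as the screening
#'   convention does; documented, not corrected).
#' @export
enrichment_table <- function(cohort, databases = c("gnomAD", "TOPMed")) {
  af_cols <- paste0("af_", databases)
  missing_col <- setdiff(af_cols, names(cohort))
  if (length(missing_col)) {
    rlang::abort(sprintf("Missing allele-frequency column(s): %s",
                         paste(missing_col, collapse = ", ")),
                 class = "varprior_parameter_error")
  }
  carrier <- carrier_frequency(cohort$cohort_carriers, cohort$cohort_size)
  pop <- vapply(seq_len(nrow(cohort)), function(i) {
    afs <- stats::setNames(as.numeric(cohort[i, af_cols]), databases)
    mean_population_af(afs, databases)
  }, numeric(1))
  fold <- suppressWarnings(enrichment_fold(carrier, pop))
  tibble::tibble(
    variant_id = cohort$variant_id,
    carrier_freq_pct = carrier,
    mean_pop_af_pct = pop,
    fold = fold,
    freq_basis_mismatch = TRUE
  )
}

#' Flag HPO-count x CADD outliers within a region
#'
#' Flags variants whose phenotyped-individual (HPO profile) count AND
#' CADD score both strictly exceed the region's empirical quantiles
#' (linear-interpolation quantiles, [stats::quantile()] type 7). The
#' joint screen picks out variants that are simultaneously common among
#' phenotyped patients and predicted damaging.
#'
#' @param cohort Tibble with `variant_id`, `hpo_profile_count`, `cadd`.
#' @param hpo_quantile,cadd_quantile Quantile levels (default 0.99 each).
#' @return The subset of flagged rows, with threshold columns
#'   `hpo_threshold` and `cadd_threshold` attached.
#' @export
region_outliers <- function(cohort, hpo_quantile = 0.99, cadd_quantile = 0.99) {
  if (nrow(cohort) < 10L) {
    rlang::abort("At least 10 variants are required for outlier calling.",
                 class = "varprior_insufficient_data")
  }
  hpo_thr <- stats::quantile(cohort$hpo_profile_count, hpo_quantile,
                             type = 7, names = FALSE)
  cadd_thr <- stats::quantile(cohort$cadd, cadd_quantile,
                              type = 7, names = FALSE)
  flagged <- dplyr::filter(cohort,
                           .data$hpo_profile_count > hpo_thr,
                           .data$cadd > cadd_thr)
  dplyr::mutate(flagged, hpo_threshold = hpo_thr, cadd_threshold = cadd_thr)
}
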