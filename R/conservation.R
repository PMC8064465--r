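#' Per-column amino-acid and codon profiles
#'
#' Tallies each codon column of the alignment: counts per amino acid
#' (standard nuclear code, stops as `"*"`), counts per codon, and gap
#' count. These tallies underlie all downstream evolutionary scores.
#'
#' @param aln A [codon_alignment()].
#' @return A list of column profiles, one per codon column; each profile
#'   is a list with `codon_index` (0-based), `aa_counts` (named integer),
#'   `codon_counts` (named integer), `gap_count`, and `ref_aa` (the
#'   reference row's amino acid, `NA` where the reference is gapped).
#' @export
profile_columns <- function(aln) {
  validate_codon_alignment(aln)
  cm <- codon_matrix(aln)
  ref_row <- match(aln$reference_id, aln$ids)
  lapply(seq_len(ncol(cm)), function(j) {
    codons <- cm[, j]
    aa <- translate_codons(codons)
    gap <- sum(is.na(aa))
    list(
      codon_index = j - 1L,
      aa_counts = table_to_int(aa[!is.na(aa)]),
      codon_counts = table_to_int(codons[codons != "---"]),
      gap_count = gap,
      ref_aa = aa[[ref_row]]
    )
  })
}

table_to_int <- function(x) {
  if (length(x) == 0L) return(stats::setNames(integer(0), character(0)))
  tb <- table(x)
  stats::setNames(as.integer(tb), names(tb))
}

#' Conservation fraction of the reference residue
#'
#' Fraction of non-gap rows carrying `ref_aa` at the column. Gap rows are
#' excluded from the denominator: missing data is not evidence of
#' divergence. An all-gap column scores 0 by convention.
#'
#' @param profile A single column profile from [profile_columns()].
#' @param ref_aa Single-letter amino acid to measure (defaults to the
#'   profile's reference residue).
#' @return Conservation fraction `c` in `[0, 1]`.
#' @export
conservation_fraction <- function(profile, ref_aa = profile$ref_aa) {
  n_nongap <- sum(profile$aa_counts)
  if (n_nongap == 0L || is.na(ref_aa)) return(0)
  cnt <- profile$aa_counts[ref_aa]
  if (is.na(cnt)) cnt <- 0L
  unname(cnt / n_nongap)
}

# Wobble statistic of one column: synonymous-codon diversity of the modal
# amino acid, normalized so 2-codon and 6-codon amino acids are
# comparable. s = (distinct synonymous codons observed - 1) /
# (synonymous codons possible - 1); 0 for single-codon amino acids (M, W)
# and for all-gap columns. Modal ties break to the alphabetically first
# amino acid.
wobble_statistic <- function(profile) {
  if (sum(profile$aa_counts) == 0L) return(0)
  aa_counts <- profile$aa_counts
  modal_aa <- sort(names(aa_counts)[aa_counts == max(aa_counts)])[[1]]
  possible <- as.integer(synonymous_codon_counts()[modal_aa])
  if (possible <= 1L) return(0)
  syn <- codons_for_aa(modal_aa)
  observed <- sum(names(profile$codon_counts) %in% syn)
  (observed - 1) / (possible - 1)
}

#' Codon-usage selection z-scores
#'
#' Standardizes the per-column synonymous-wobble statistic against the
#' gene-wide distribution. A high z marks a residue whose codon wobbled
#' across species while the amino acid stayed fixed -- the signature of
#' purifying selection on the protein rather than the DNA.
#'
#' The wobble statistic for a column is the number of distinct synonymous
#' codons observed for the modal amino acid minus one, divided by the
#' number possible minus one (0 for methionine/tryptophan and all-gap
#' columns). z uses the population (n-denominator) standard deviation over
#' all columns; a zero-variance track gives z = 0 everywhere.
#'
#' @param profiles Output of [profile_columns()].
#' @return Numeric vector of per-column z-scores.
#' @export
selection_z <- function(profiles) {
  if (length(profiles) < 2L) {
    rlang::abort("At least 2 columns are required for selection z-scores.",
                 class = "varprior_insufficient_data")
  }
  s <- vapply(profiles, wobble_statistic, numeric(1))
  mu <- mean(s)
  sd_pop <- sqrt(mean((s - mu)^2))
  if (sd_pop == 0) return(rep(0, length(s)))
  (s - mu) / sd_pop
}

#' Per-residue evolutionary score
#'
#' Combines conservation and selection into a single residue score on
#' `[0, 2]`: `r = c + clamp(z/2, 0, 1)`. A fully conserved residue with a
#' selection z of 0.5 scores 1.25. The linear `z/2` map with saturation is
#' a calibration consistent with the maximum of 2 and that anchor point,
#' not a canonical form; see the methods vignette.
#'
#' @param c Conservation fraction in `[0, 1]`.
#' @param z Selection z-score (any real).
#' @return Residue score `r` in `[0, 2]`. Vectorized.
#' @examples
#' residue_score(1.0, 0.5) # 1.25
#' @export
residue_score <- function(c, z) {
  if (any(c < 0 | c > 1, na.rm = TRUE)) {
    rlang::abort("Conservation fraction must lie in [0, 1].",
                 class = "varprior_domain_error")
  }
  c + clamp(z / 2, 0, 1)
}

#' 21-codon sliding-window conservation score
#'
#' Mean residue score over a window of `half_width` codons before the
#' site, the site, and `half_width` codons after (21 codons at the
#' default). Windows truncate at the termini rather than padding with
#' zeros, so terminal motifs are not artifactually depressed.
#'
#' @param r Numeric vector of per-residue scores.
#' @param position Optional 1-based residue position(s); if `NULL`, the
#'   whole window track is returned.
#' @param half_width Codons on each side of the site (default 10).
#' @return Window score(s) `w`, same bounds as `r`.
#' @export
window_score <- function(r, position = NULL, half_width = 10L) {
  n <- length(r)
  stopifnot(n >= 1L, half_width >= 0L)
  cs <- cumsum(c(0, r))
  idx <- if (is.null(position)) seq_len(n) else as.integer(position)
  if (any(idx < 1L | idx > n)) {
    rlang::abort("Window position outside the protein.",
                 class = "varprior_domain_error")
  }
  lo <- pmax(idx - half_width, 1L)
  hi <- pmin(idx + half_width, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Full per-residue score track
#'
#' Runs the whole evolutionary scoring chain over an alignment: column
#' profiles, conservation fraction of the reference residue, selection
#' z-score, residue score, and sliding-window score.
#'
#' @param aln A [codon_alignment()].
#' @param half_width Window half-width in codons (default 10, i.e. the
#'   21-codon window).
#' @return A tibble with one row per codon: `residue` (1-based reference
#'   numbering), `ref_aa`, `c`, `z`, `r`, `w`.
#' @export
score_track <- function(aln, half_width = 10L) {
  profiles <- profile_columns(aln)
  c_vec <- vapply(profiles, conservation_fraction, numeric(1))
  z_vec <- selection_z(profiles)
  r_vec <- residue_score(c_vec, z_vec)
  w_vec <- window_score(r_vec, half_width = half_width)
  stopifnot(all(c_vec >= 0 & c_vec <= 1),
            all(r_vec >= 0 & r_vec <= 2),
            all(w_vec >= 0 & w_vec <= 2))
  tibble::tibble(
    residue = seq_along(profiles),
    ref_aa = vapply(profiles, function(p) {
      if (is.na(p$ref_aa)) "-" else p$ref_aa
    }, character(1)),
    c = c_vec, z = z_vec, r = r_vec, w = w_vec
  )
}

#' Call conserved motifs from a window-score track
#'
#' Greedy selection of the `top_k` non-overlapping windows of maximal
#' sliding-window score. Each call spans the (truncated) window around its
#' peak position, clipped against previously selected calls, and reports
#' the highest-scoring residue within its span. All ties break toward the
#' lower codon index, so calls are deterministic.
#'
#' @param track Score track from [score_track()] (columns `residue`, `r`,
#'   `w` required).
#' @param top_k Maximum number of motifs to call (default 6).
#' @param min_span Minimum span length in codons for a call to be kept
#'   (default 5).
#' @param half_width Window half-width used to span calls (default 10).
#' @return A tibble of motif calls ordered by rank: `rank`, `start_codon`
#'   and `end_codon` (0-based half-open), `start_residue` and
#'   `end_residue` (1-based inclusive), `peak_residue` (1-based),
#'   `peak_aa`, `peak_r`, `peak_window_score`.
#' @export
call_motifs <- function(track, top_k = 6L, min_span = 5L, half_width = 10L) {
  if (top_k <= 0L) {
    rlang::abort("`top_k` must be positive.", class = "varprior_parameter_error")
  }
  n <- nrow(track)
  if (n == 0L) {
    rlang::abort("Empty score track.", class = "varprior_insufficient_data")
  }
  w <- track$w
  r <- track$r
  taken <- rep(FALSE, n)
  avail <- rep(TRUE, n)
  calls <- list()
  while (length(calls) < top_k && any(avail)) {
    cand <- which(avail)
    peak <- cand[which.max(w[cand])] # which.max: first max = lower index
    span <- seq.int(max(1L, peak - half_width), min(n, peak + half_width))
    span <- span[!taken[span]]
    runs <- split(span, cumsum(c(1L, diff(span) != 1L)))
    span <- runs[[which(vapply(runs, function(s) peak %in% s, logical(1)))]]
    avail[span] <- FALSE
    avail[peak] <- FALSE
    if (length(span) < min_span) next
    taken[span] <- TRUE
    peak_res <- span[which.max(r[span])]
    calls[[length(calls) + 1L]] <- tibble::tibble(
      start_codon = min(span) - 1L,
      end_codon = max(span),
      start_residue = min(span),
      end_residue = max(span),
      peak_residue = peak_res,
      peak_aa = if ("ref_aa" %in% names(track)) track$ref_aa[[peak_res]] else NA_character_,
      peak_r = r[[peak_res]],
      peak_window_score = w[[peak]]
    )
  }
  out <- dplyr::bind_rows(calls)
  if (nrow(out)) out <- tibble::add_column(out, rank = seq_len(nrow(out)), .before = 1L)
  out
}
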