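#' Category-to-points map for missense effect predictors
#'
#' Points awarded per categorical call: PolyPhen2 (probably damaging = 1,
#' possibly damaging = 0.5), Provean (Deleterious = 1), SIFT (Damaging =
#' 1), align-GVGD (C65/C55 = 1, C45/C35 = 0.5, C25/C15 = 0.25, C0 = 0).
#' The four tools contribute at most 4 points; with the evolutionary
#' residue score (maximum 2) the additive variant score tops out at 6.
#'
#' @return A named list of named numeric vectors, one per predictor; the
#'   names of each vector are that predictor's legal categories.
#' @export
default_category_map <- function() {
  list(
    polyphen2 = c(probably = 1, possibly = 0.5, benign = 0),
    provean = c(Deleterious = 1, Neutral = 0),
    sift = c(Damaging = 1, Tolerated = 0),
    align_gvgd = c(C65 = 1, C55 = 1, C45 = 0.5, C35 = 0.5,
                   C25 = 0.25, C15 = 0.25, C0 = 0)
  )
}

# Points for one predictor call; NA/missing imputes 0 points, an unknown
# category string is an annotation error naming predictor and value.
predictor_points <- function(predictor, category, map) {
  legal <- map[[predictor]]
  if (is.null(legal)) {
    rlang::abort(sprintf("Unknown predictor '%s'.", predictor),
                 class = "varprior_annotation_error")
  }
  if (is.na(category) || !nzchar(category)) return(NA_real_)
  pts <- legal[category]
  if (is.na(pts)) {
    rlang::abort(
      sprintf("Unknown %s category '%s' (legal: %s).",
              predictor, category, paste(names(legal), collapse = ", ")),
      class = "varprior_annotation_error")
  }
  unname(pts)
}

#' Additive variant score (maximum 6)
#'
#' Sums the mapped points of the four categorical predictor calls and the
#' per-residue evolutionary score `r`. A missing predictor call
#' contributes 0 points (the caller can count imputations via
#' `attr(, "n_imputed")`).
#'
#' @param annotations Named character vector or list of categorical calls;
#'   recognized names are `polyphen2`, `provean`, `sift`, `align_gvgd`.
#'   `NA` or absent predictors impute 0 points.
#' @param r Evolutionary residue score at the variant position, in `[0, 2]`.
#' @param map Category-to-points map (default [default_category_map()]).
#' @return Additive score in `[0, 6]`, with attribute `n_imputed` giving
#'   the number of predictors imputed to 0.
#' @examples
#' additive_score(
#'   c(polyphen2 = "probably", provean = "Deleterious",
#'     sift = "Damaging", align_gvgd = "C65"),
#'   r = 1.25
#' ) # 5.25
#' @export
additive_score <- function(annotations, r, map = default_category_map()) {
  if (is.na(r) || r < 0 || r > 2) {
    rlang::abort("Residue score `r` must lie in [0, 2].",
                 class = "varprior_domain_error")
  }
  pts <- vapply(names(map), function(p) {
    val <- if (p %in% names(annotations)) as.character(annotations[[p]]) else NA_character_
    predictor_points(p, val, map)
  }, numeric(1))
  n_imputed <- sum(is.na(pts))
  score <- sum(pts, na.rm = TRUE) + r
  structure(score, n_imputed = n_imputed)
}

#' Combined impact score
#'
#' Multiplies the additive variant score by the 21-codon window
#' conservation and the population allele frequency:
#' `combined = additive * w * f`. The product prioritizes variants that
#' are predicted damaging, sit in conserved neighborhoods, and are common
#' enough in the population to matter; any zero factor annihilates it.
#'
#' @param additive Additive score in `[0, 6]`.
#' @param w Window conservation score in `[0, 2]`.
#' @param f Allele frequency as a fraction in `[0, 1]`.
#' @return Combined impact score, non-negative. Vectorized.
#' @export
combined_impact <- function(additive, w, f) {
  if (any(additive < 0 | additive > 6, na.rm = TRUE) ||
      any(w < 0 | w > 2, na.rm = TRUE) ||
      any(f < 0 | f > 1, na.rm = TRUE)) {
    rlang::abort("combined_impact factors outside their domains.",
                 class = "varprior_domain_error")
  }
  additive * w * f
}

#' Fraction of variants at or above a score threshold
#'
#' @param scores Numeric vector of additive scores (`NA` dropped).
#' @param threshold Score threshold; ties count as at-or-above.
#' @return Fraction in `[0, 1]`.
#' @export
score_quantile <- function(scores, threshold) {
  scores <- scores[!is.na(scores)]
  if (length(scores) == 0L) {
    rlang::abort("No scored variants.", class = "varprior_insufficient_data")
  }
  mean(scores >= threshold)
}

#' Score a table of coding variants
#'
#' Joins each variant to the residue score track at its protein position,
#' computes the additive score from its categorical predictor calls, and
#' the combined impact score using the window conservation and the
#' designated allele-frequency database column (`af_<freq_db>`).
#'
#' Non-missense variants (nonsense or frameshift: `alt_aa` of `"*"` or
#' not a single residue) receive no additive score -- the predictors are
#' missense-only -- and pass through flagged `non_missense`. CADD, if
#' present, is carried through unmodified; it is not a summand.
#'
#' @param variants Tibble of coding variants: `variant_id`,
#'   `protein_position` (1-based), `ref_aa`, `alt_aa`, predictor columns
#'   `polyphen2`, `provean`, `sift`, `align_gvgd`, and per-database allele
#'   frequency columns `af_<db>` as fractions.
#' @param track Residue score track from [score_track()].
#' @param map Category map (default [default_category_map()]).
#' @param freq_db Database whose allele frequency enters the combined
#'   score (default `"gnomAD"`).
#' @return The input tibble with columns `r`, `w`, `additive`,
#'   `n_imputed`, `non_missense`, `combined` added.
#' @export
score_coding_variants <- function(variants, track,
                                  map = default_category_map(),
                                  freq_db = "gnomAD") {
  af_col <- paste0("af_", freq_db)
  if (!af_col %in% names(variants)) {
    rlang::abort(sprintf("Frequency column '%s' not found.", af_col),
                 class = "varprior_parameter_error")
  }
  pos <- variants$protein_position
  if (any(pos < 1L | pos > nrow(track))) {
    rlang::abort("Variant protein_position outside the score track.",
                 class = "varprior_domain_error")
  }
  non_missense <- is.na(variants$alt_aa) | variants$alt_aa == "*" |
    nchar(variants$alt_aa) != 1L
  r <- track$r[pos]
  w <- track$w[pos]
  addv <- rep(NA_real_, nrow(variants))
  n_imp <- rep(NA_integer_, nrow(variants))
  for (i in which(!non_missense)) {
    ann <- c(polyphen2 = as.character(variants$polyphen2[[i]]),
             provean = as.character(variants$provean[[i]]),
             sift = as.character(variants$sift[[i]]),
             align_gvgd = as.character(variants$align_gvgd[[i]]))
    s <- additive_score(ann, r[[i]], map)
    addv[[i]] <- as.numeric(s)
    n_imp[[i]] <- attr(s, "n_imputed")
  }
  f <- variants[[af_col]]
  combined <- ifelse(non_missense, NA_real_, combined_impact(
    ifelse(non_missense, 0, addv), w, f))
  dplyr::mutate(variants,
                r = r, w = w, additive = addv, n_imputed = n_imp,
                non_missense = non_missense, combined = combined)
}

#' Rank scored variants by combined impact
#'
#' Descending combined impact, ties broken by additive score (descending)
#' then `variant_id` lexicographically, so the order is total and
#' deterministic. Unscored (non-missense) variants sort last.
#'
#' @param scored Output of [score_coding_variants()].
#' @return The table re-ordered, with a `rank` column prepended.
#' @export
rank_variants <- function(scored) {
  scored$rank <- NULL # re-ranking a previously ranked table is fine
  out <- dplyr::arrange(scored,
                        dplyr::desc(!is.na(.data$combined)),
                        dplyr::desc(.data$combined),
                        dplyr::desc(.data$additive),
                        .data$variant_id)
  tibble::add_column(out, rank = seq_len(nrow(out)), .before = 1L)
}
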