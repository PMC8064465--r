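#' Read a BED peak track
#'
#' Loads a BED (0-based half-open) annotation track into a `GRanges`,
#' validating coordinates and reporting the offending line on failure.
#' Intervals may overlap each other; they are sorted on load.
#'
#' @param path Path to a BED file (3+ columns).
#' @param source Track/source name stored in `metadata(gr)$source`
#'   (default: file name without extension).
#' @return A sorted `GRanges`.
#' @export
read_bed_track <- function(path, source = NULL) {
  if (!file.exists(path)) {
    rlang::abort(sprintf("BED file not found: %s", path),
                 class = "varprior_io_error")
  }
  # pre-validate so errors carry a line number (rtracklayer's do not)
  lines <- readLines(path)
  body <- which(!grepl("^(#|track|browser)", lines) & nzchar(lines))
  for (i in body) {
    f <- strsplit(lines[[i]], "\t")[[1]]
    if (length(f) < 3L || is.na(suppressWarnings(as.numeric(f[[2]]))) ||
        is.na(suppressWarnings(as.numeric(f[[3]])))) {
      rlang::abort(sprintf("Malformed BED line %d in %s.", i, path),
                   class = "varprior_format_error")
    }
    if (as.numeric(f[[2]]) >= as.numeric(f[[3]]) || as.numeric(f[[2]]) < 0) {
      rlang::abort(sprintf("BED line %d in %s has start >= end (or start < 0).",
                           i, path),
                   class = "varprior_format_error")
    }
  }
  gr <- rtracklayer::import(path, format = "BED")
  gr <- GenomicRanges::sort(gr)
  if (is.null(source)) source <- sub("\\.bed$", "", basename(path))
  S4Vectors::metadata(gr)$source <- source
  gr
}

#' Write a peak track as BED
#'
#' Emits sorted 0-based half-open intervals.
#'
#' @param gr A `GRanges` (or a tibble with `chrom`, `start0`, `end0`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed_track <- function(gr, path) {
  if (!methods::is(gr, "GRanges")) {
    gr <- GenomicRanges::GRanges(gr$chrom,
                                 IRanges::IRanges(gr$start0 + 1L, gr$end0))
  }
  rtracklayer::export(GenomicRanges::sort(gr), path, format = "BED")
  invisible(path)
}

# 1-based variant positions -> width-1 GRanges (central coordinate
# conversion: a VCF-style position pos corresponds to 0-based point
# pos - 1, which lies in BED interval [start0, end0) iff the 1-based
# GRanges ranges overlap).
variant_points <- function(variants) {
  GenomicRanges::GRanges(variants$chrom,
                         IRanges::IRanges(variants$pos, width = 1L))
}

#' Count peak overlaps for noncoding variants
#'
#' Number of intervals of one track covering each variant's position,
#' under the half-open BED convention: a point on an interval's start is
#' inside, a point on its end is not. Indels are anchored at their
#' leftmost reference base (`pos`).
#'
#' @param variants Tibble with `chrom` and 1-based `pos`.
#' @param track A `GRanges` peak track.
#' @return Integer vector of overlap counts, one per variant.
#' @export
count_peak_overlaps <- function(variants, track) {
  GenomicRanges::countOverlaps(variant_points(variants), track)
}

#' Regulatory-evidence impact score
#'
#' For each noncoding variant, sums the number of overlapping peaks
#' across all interval tracks plus any precomputed per-source evidence
#' counts (columns `evidence_*`, e.g. RegulomeDB evidence lines supplied
#' as integers), then multiplies the total by the variant's CADD score:
#' `score = evidence_total * cadd`. The score is zero exactly when the
#' evidence total or CADD is zero, and is invariant to track order.
#'
#' @param variants Tibble with `chrom`, `pos` (1-based), `cadd`, optional
#'   `evidence_*` integer columns, and any carry-through columns
#'   (`variant_id`, `ld_block`, ...).
#' @param tracks Named list of `GRanges` peak tracks.
#' @return The input tibble with per-track overlap columns
#'   (`peaks_<source>`), `evidence_total`, and `score` added.
#' @export
regulatory_score <- function(variants, tracks = list()) {
  if (!"cadd" %in% names(variants) || anyNA(variants$cadd)) {
    rlang::abort("Every variant needs a CADD score.",
                 class = "varprior_annotation_error")
  }
  if (any(variants$cadd < 0)) {
    rlang::abort("CADD scores must be non-negative.",
                 class = "varprior_domain_error")
  }
  out <- variants
  peak_total <- rep(0L, nrow(variants))
  for (nm in names(tracks)) {
    cnt <- count_peak_overlaps(variants, tracks[[nm]])
    out[[paste0("peaks_", nm)]] <- cnt
    peak_total <- peak_total + cnt
  }
  ev_cols <- grep("^evidence_", names(variants), value = TRUE)
  table_total <- if (length(ev_cols)) {
    rowSums(as.matrix(variants[ev_cols]))
  } else 0
  if (any(table_total < 0)) {
    rlang::abort("Evidence counts must be non-negative.",
                 class = "varprior_domain_error")
  }
  out$evidence_total <- as.integer(peak_total + table_total)
  out$score <- out$evidence_total * out$cadd
  out
}

#' Top regulatory variant per LD block
#'
#' Within each linkage-disequilibrium block, keeps the variant(s)
#' achieving the block-maximal impact score. Association signals cannot
#' distinguish members of one block, so the functional evidence score is
#' what singles a candidate out. Ties (including all-zero blocks, which
#' are flagged) are all reported, ordered by `(chrom, pos)`.
#'
#' @param scored Output of [regulatory_score()]; needs `ld_block`,
#'   `score`, `chrom`, `pos`.
#' @return Tibble of per-block top variants with a `zero_score` flag.
#' @export
top_per_block <- function(scored) {
  if (!"ld_block" %in% names(scored) || anyNA(scored$ld_block)) {
    rlang::abort("Every variant needs an `ld_block` id.",
                 class = "varprior_annotation_error")
  }
  scored |>
    dplyr::group_by(.data$ld_block) |>
    dplyr::filter(.data$score == max(.data$score)) |>
    dplyr::mutate(zero_score = max(.data$score) == 0) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$chrom, .data$pos)
}

#' Tally eQTL tissue multiplicity
#'
#' Histogram of how many variants appear as an eQTL in exactly k tissues.
#' Duplicate (variant, tissue) rows are collapsed with a warning.
#'
#' @param eqtl Tibble with columns `variant_id` and `tissue` (additional
#'   columns such as `pvalue`, `nes` are ignored).
#' @return Tibble `n_tissues`, `n_variants`; `sum(n_variants)` equals the
#'   number of distinct variants.
#' @export
tissue_eqtl_tally <- function(eqtl) {
  if (nrow(eqtl) == 0L) {
    rlang::abort("Empty eQTL table.", class = "varprior_insufficient_data")
  }
  pairs <- dplyr::distinct(eqtl, .data$variant_id, .data$tissue)
  if (nrow(pairs) < nrow(eqtl)) {
    rlang::warn("Duplicate (variant, tissue) rows collapsed.")
  }
  pairs |>
    dplyr::count(.data$variant_id, name = "n_tissues") |>
    dplyr::count(.data$n_tissues, name = "n_variants") |>
    dplyr::arrange(.data$n_tissues)
}
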