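#' Configuration for the synthetic-data generators
#'
#' One seeded configuration drives every generator, so a single object
#' describes a complete synthetic study: a codon alignment with planted
#' conserved motifs and synonymous-wobble columns, coding- and
#' noncoding-variant tables with a planted top hit, peak tracks with
#' exhaustively computed truth overlaps, and a phenotyped cohort with a
#' planted enrichment fold. Identical configurations produce byte-identical
#' outputs.
#'
#' Defaults emulate the scale of a single-gene vertebrate screen: 220
#' aligned sequences over a 461-codon protein, six planted motifs, a
#' 17,928-individual phenotyped cohort, and a planted hit at 3.24-fold
#' cohort enrichment over a 0.205% mean population allele frequency.
#'
#' @param seed Integer seed; every generator derives its stream from it.
#' @param n_sequences Number of aligned sequences (>= 2).
#' @param n_codons Alignment length in codons (>= 1).
#' @param motif_spans List of `c(start, end, level)` triples: 0-based
#'   half-open codon spans held at conservation `level` in `[0, 1]`.
#' @param wobble_columns 0-based codon indices where synonymous wobble is
#'   planted (amino acid fully conserved, codons cycling the synonymous
#'   set).
#' @param background_conservation Conservation level outside motifs.
#' @param gap_rate Per-row, per-column probability of a planted
#'   whole-codon gap in non-reference rows.
#' @param codon_usage Optional named weights over codons used when a
#'   column's codon is drawn (default: uniform over synonymous codons).
#' @param n_coding_variants,n_noncoding_variants Row counts for the
#'   variant generators (coding >= 1).
#' @param n_peaks_per_track Intervals per peak track (>= 0).
#' @param n_ld_blocks Number of LD blocks for noncoding variants.
#' @param cohort_size Phenotyped-cohort size (>= 1).
#' @param planted_enrichment_fold Carrier-frequency fold planted on the
#'   hit variant relative to its mean population allele frequency (> 0).
#' @param planted_af Named fractions giving the planted hit's population
#'   allele frequencies per database.
#' @param hpo_nb_size,hpo_nb_mu Negative-binomial parameters for HPO
#'   profile counts (opaque labels with counts; no ontology semantics).
#' @return A validated list of class `synth_config`.
#' @export
synth_config <- function(seed = 1L,
                         n_sequences = 220L,
                         n_codons = 461L,
                         motif_spans = default_motif_spans(n_codons),
                         wobble_columns = default_wobble_columns(motif_spans),
                         background_conservation = 0.4,
                         gap_rate = 0,
                         codon_usage = NULL,
                         n_coding_variants = 100L,
                         n_noncoding_variants = 200L,
                         n_peaks_per_track = 50L,
                         n_ld_blocks = 10L,
                         cohort_size = 17928L,
                         planted_enrichment_fold = 3.24,
                         planted_af = c(gnomAD = 0.0023, TOPMed = 0.0018),
                         hpo_nb_size = 1, hpo_nb_mu = 2) {
  cfg <- structure(as.list(environment()), class = "synth_config")
  validate_synth_config(cfg)
}

# Up to six 21-codon spans at full conservation against the background,
# spread evenly over the protein (fewer when the protein is short).
default_motif_spans <- function(n_codons) {
  width <- 21L
  k <- min(6L, n_codons %/% (2L * width))
  if (k == 0L) return(list())
  starts <- round(seq(from = n_codons * 0.08, to = n_codons * 0.9 - width,
                      length.out = k))
  lapply(starts, function(s) c(as.integer(s), as.integer(s) + width, 1))
}

# One wobble column at the centre of each planted motif.
default_wobble_columns <- function(motif_spans) {
  if (!length(motif_spans)) return(integer())
  vapply(motif_spans, function(sp) as.integer((sp[[1]] + sp[[2]]) %/% 2),
         integer(1))
}

#' @rdname synth_config
#' @param cfg A `synth_config`.
#' @export
validate_synth_config <- function(cfg) {
  bad <- function(msg) rlang::abort(msg, class = "varprior_config_error")
  if (cfg$n_sequences < 2L) bad("n_sequences must be >= 2.")
  if (cfg$n_codons < 1L) bad("n_codons must be >= 1.")
  for (sp in cfg$motif_spans) {
    if (length(sp) != 3L) bad("Each motif span must be c(start, end, level).")
    if (sp[[1]] < 0 || sp[[2]] > cfg$n_codons || sp[[1]] >= sp[[2]]) {
      bad("Motif spans must satisfy 0 <= start < end <= n_codons.")
    }
    if (sp[[3]] < 0 || sp[[3]] > 1) bad("conservation_level must lie in [0, 1].")
  }
  if (any(cfg$wobble_columns < 0 | cfg$wobble_columns >= cfg$n_codons)) {
    bad("wobble_columns must lie in [0, n_codons).")
  }
  if (cfg$background_conservation < 0 || cfg$background_conservation > 1) {
    bad("background_conservation must lie in [0, 1].")
  }
  if (cfg$gap_rate < 0 || cfg$gap_rate >= 1) bad("gap_rate must lie in [0, 1).")
  if (cfg$n_coding_variants < 1L) bad("n_coding_variants must be >= 1.")
  if (cfg$n_noncoding_variants < 0L) bad("n_noncoding_variants must be >= 0.")
  if (cfg$n_peaks_per_track < 0L) bad("n_peaks_per_track must be >= 0.")
  if (cfg$cohort_size < 1L) bad("cohort_size must be >= 1.")
  if (cfg$planted_enrichment_fold <= 0) bad("planted_enrichment_fold must be > 0.")
  if (any(cfg$planted_af < 0 | cfg$planted_af > 1)) bad("planted_af must lie in [0, 1].")
  invisible(cfg)
}

# Draw one codon for an amino acid under the configured usage weights.
sample_codon <- function(syn, usage) {
  if (length(syn) == 1L) return(syn)
  if (is.null(usage)) return(sample(syn, 1L))
  wt <- usage[syn]
  wt[is.na(wt)] <- 0
  if (sum(wt) == 0) return(sample(syn, 1L))
  sample(syn, 1L, prob = wt)
}

#' Generate a codon alignment with planted motifs and wobble columns
#'
#' Builds an aligned set of in-frame coding sequences column by column.
#' Each column has a planted modal amino acid; every row carries it with
#' probability equal to the column's conservation level and otherwise
#' diverges to a uniformly drawn different residue. Outside wobble
#' columns the modal amino acid keeps one codon for the whole column (no
#' synonymous divergence, the selection null); wobble columns hold the
#' amino acid at full conservation while cycling through its entire
#' synonymous codon set, the planted purifying-selection signature.
#'
#' @param cfg A [synth_config()].
#' @return A list: `alignment` (a [codon_alignment()], reference row
#'   `"reference"`) and `truth`, a tibble of per-column ground truth
#'   (`codon_index` 0-based, `level_requested`, `planted_aa`, `modal_aa`,
#'   `modal_fraction` realized over non-gap rows, `in_motif`,
#'   `is_wobble`).
#' @export
synth_alignment <- function(cfg) {
  validate_synth_config(cfg)
  withr::with_seed(cfg$seed, {
    n <- cfg$n_sequences
    L <- cfg$n_codons
    aas <- sort(setdiff(unique(Biostrings::GENETIC_CODE), "*"))
    syn_counts <- synonymous_codon_counts()
    wobble_aas <- sort(names(syn_counts)[syn_counts >= 2 &
                                           names(syn_counts) != "*"])
    level <- rep(cfg$background_conservation, L)
    in_motif <- rep(FALSE, L)
    for (sp in cfg$motif_spans) {
      idx <- seq.int(sp[[1]] + 1L, sp[[2]])
      level[idx] <- sp[[3]]
      in_motif[idx] <- TRUE
    }
    is_wobble <- (seq_len(L) - 1L) %in% cfg$wobble_columns
    level[is_wobble] <- 1
    codons <- matrix("", nrow = n, ncol = L)
    planted_aa <- character(L)
    modal_fraction <- numeric(L)
    modal_aa <- character(L)
    for (j in seq_len(L)) {
      aa_j <- if (is_wobble[[j]]) sample(wobble_aas, 1L) else sample(aas, 1L)
      planted_aa[[j]] <- aa_j
      syn <- codons_for_aa(aa_j)
      col_codon <- sample_codon(syn, cfg$codon_usage)
      conserved <- c(TRUE, stats::runif(n - 1L) < level[[j]]) # row 1 = reference
      col <- character(n)
      if (is_wobble[[j]]) {
        col[conserved] <- syn[(seq_len(sum(conserved)) - 1L) %% length(syn) + 1L]
      } else {
        col[conserved] <- col_codon
      }
      n_div <- sum(!conserved)
      if (n_div > 0L) {
        div_aa <- sample(setdiff(aas, aa_j), n_div, replace = TRUE)
        col[!conserved] <- vapply(div_aa, function(a) {
          sample_codon(codons_for_aa(a), cfg$codon_usage)
        }, character(1))
      }
      if (cfg$gap_rate > 0) {
        gap <- c(FALSE, stats::runif(n - 1L) < cfg$gap_rate)
        col[gap] <- "---"
      }
      codons[, j] <- col
      col_aa <- translate_codons(col)
      col_aa <- col_aa[!is.na(col_aa)]
      tb <- table(col_aa)
      modal_aa[[j]] <- sort(names(tb)[tb == max(tb)])[[1]]
      modal_fraction[[j]] <- max(tb) / length(col_aa)
    }
    ids <- c("reference", sprintf("seq%03d", seq_len(n - 1L)))
    seqs <- apply(codons, 1L, paste, collapse = "")
    list(
      alignment = codon_alignment(ids, seqs, reference_id = "reference"),
      truth = tibble::tibble(
        codon_index = seq_len(L) - 1L,
        level_requested = level,
        planted_aa = planted_aa,
        modal_aa = modal_aa,
        modal_fraction = modal_fraction,
        in_motif = in_motif,
        is_wobble = is_wobble
      )
    )
  })
}

# Legal predictor categories for sampling.
legal_categories <- function() {
  lapply(default_category_map(), names)
}

#' Generate a coding-variant annotation table
#'
#' Random missense variants with categorical calls drawn uniformly from
#' each predictor's legal set, log-uniform allele frequencies, binomial
#' cohort carrier counts, and negative-binomial HPO profile counts. Row 1
#' is the planted hit (`variant_id` `"hit0001"`): all-maximal predictor
#' categories (4 tool points), a position at the center of the first
#' planted motif, and a cohort carrier count elevated to the configured
#' enrichment fold.
#'
#' @param cfg A [synth_config()].
#' @return A tibble of coding variants (`variant_id`, `protein_position`,
#'   `ref_aa`, `alt_aa`, `polyphen2`, `provean`, `sift`, `align_gvgd`,
#'   `af_gnomAD`, `af_TOPMed`, `cohort_carriers`, `hpo_profile_count`,
#'   `cadd`).
#' @export
synth_coding_variants <- function(cfg) {
  validate_synth_config(cfg)
  withr::with_seed(cfg$seed + 1001L, {
    n <- cfg$n_coding_variants
    cats <- legal_categories()
    aas <- sort(setdiff(unique(Biostrings::GENETIC_CODE), "*"))
    tbl <- tibble::tibble(
      variant_id = sprintf("var%04d", seq_len(n)),
      protein_position = sample.int(cfg$n_codons, n, replace = TRUE),
      ref_aa = sample(aas, n, replace = TRUE),
      alt_aa = sample(aas, n, replace = TRUE),
      polyphen2 = sample(cats$polyphen2, n, replace = TRUE),
      provean = sample(cats$provean, n, replace = TRUE),
      sift = sample(cats$sift, n, replace = TRUE),
      align_gvgd = sample(cats$align_gvgd, n, replace = TRUE),
      af_gnomAD = 10^stats::runif(n, -5, -3),
      af_TOPMed = 10^stats::runif(n, -5, -3),
      cadd = round(stats::runif(n, 0, 30), 1),
      hpo_profile_count = stats::rnbinom(n, size = cfg$hpo_nb_size,
                                         mu = cfg$hpo_nb_mu)
    )
    tbl$cohort_carriers <- stats::rbinom(n, cfg$cohort_size,
                                         pmin(2 * tbl$af_gnomAD, 1))
    # planted hit: maximal categories, motif-center position, enriched cohort
    hit_pos <- if (length(cfg$motif_spans)) {
      sp <- cfg$motif_spans[[1]]
      as.integer((sp[[1]] + sp[[2]]) %/% 2) + 1L
    } else 1L
    tbl$variant_id[[1]] <- "hit0001"
    tbl$protein_position[[1]] <- hit_pos
    tbl$polyphen2[[1]] <- "probably"
    tbl$provean[[1]] <- "Deleterious"
    tbl$sift[[1]] <- "Damaging"
    tbl$align_gvgd[[1]] <- "C65"
    tbl$af_gnomAD[[1]] <- cfg$planted_af[["gnomAD"]]
    tbl$af_TOPMed[[1]] <- cfg$planted_af[["TOPMed"]]
    tbl$cohort_carriers[[1]] <- planted_carrier_count(cfg)
    tbl$hpo_profile_count[[1]] <- max(tbl$hpo_profile_count) + 20L
    tbl$cadd[[1]] <- max(tbl$cadd) + 5
    tbl
  })
}

# Carrier count of the planted hit: the target carrier frequency is
# planted_enrichment_fold times the reported (2-decimal percent) mean
# population allele frequency, converted to individuals and rounded half
# away from zero.
planted_carrier_count <- function(cfg) {
  af_pct <- mean_population_af(cfg$planted_af)
  as.integer(round_half_away(
    cfg$cohort_size * cfg$planted_enrichment_fold * af_pct / 100, 0))
}

#' Generate noncoding regulatory variants with LD blocks
#'
#' Variants are placed at distinct positions across a 1.4-Mb region and
#' grouped into contiguous LD blocks (block ids are opaque labels; no LD
#' structure beyond membership is simulated). Each block's first variant
#' is the planted functional candidate, with boosted tabulated evidence
#' and CADD so it carries the block-maximal impact score.
#'
#' @param cfg A [synth_config()].
#' @param chrom Chromosome label.
#' @param region_start,region_width Region placement (1-based start).
#' @return A list: `variants` (tibble `variant_id`, `chrom`, `pos`,
#'   `ref`, `alt`, `cadd`, `ld_block`, `evidence_regulomedb`,
#'   `allele_frequency`) and `truth` (tibble `ld_block`,
#'   `top_variant_id`).
#' @export
synth_regulatory_variants <- function(cfg, chrom = "chr2",
                                      region_start = 10000000L,
                                      region_width = 1400000L) {
  validate_synth_config(cfg)
  withr::with_seed(cfg$seed + 2002L, {
    n <- cfg$n_noncoding_variants
    if (n == 0L) {
      return(list(variants = tibble::tibble(
        variant_id = character(), chrom = character(), pos = integer(),
        ref = character(), alt = character(), cadd = numeric(),
        ld_block = character(), evidence_regulomedb = integer(),
        allele_frequency = numeric()),
        truth = tibble::tibble(ld_block = character(),
                               top_variant_id = character())))
    }
    pos <- sort(sample.int(region_width, n)) + region_start - 1L
    n_blocks <- max(1L, min(cfg$n_ld_blocks, n))
    block <- sprintf("LD%02d", as.integer(cut(seq_len(n), n_blocks)))
    bases <- c("A", "C", "G", "T")
    ref <- sample(bases, n, replace = TRUE)
    alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1L), character(1))
    tbl <- tibble::tibble(
      variant_id = sprintf("ncv%04d", seq_len(n)),
      chrom = chrom, pos = pos, ref = ref, alt = alt,
      cadd = round(stats::rgamma(n, shape = 2, scale = 4), 2),
      ld_block = block,
      evidence_regulomedb = stats::rpois(n, 2),
      allele_frequency = 10^stats::runif(n, -4, -0.5)
    )
    first_of_block <- !duplicated(tbl$ld_block)
    tbl$evidence_regulomedb[first_of_block] <-
      tbl$evidence_regulomedb[first_of_block] + 50L
    tbl$cadd[first_of_block] <- max(tbl$cadd) + 5
    list(
      variants = tbl,
      truth = tibble::tibble(ld_block = unique(tbl$ld_block),
                             top_variant_id = tbl$variant_id[first_of_block])
    )
  })
}

#' Generate annotation peak tracks with truth overlap counts
#'
#' Random 0-based half-open intervals per evidence source over the
#' variants' region, plus a truth table giving, for every supplied
#' noncoding variant, the exact overlap count per track computed by an
#' exhaustive scan at generation time.
#'
#' @param cfg A [synth_config()].
#' @param variants Noncoding-variant tibble (`variant_id`, `chrom`,
#'   `pos`); defaults to `synth_regulatory_variants(cfg)$variants`.
#' @param sources Track names.
#' @param chrom,region_start,region_width Region placement.
#' @return A list: `tracks` (named list of sorted `GRanges`) and `truth`
#'   (tibble `variant_id`, `source`, `overlap_count`).
#' @export
synth_peak_tracks <- function(cfg, variants = NULL,
                              sources = c("ENCODE", "Roadmap", "GeneHancer"),
                              chrom = "chr2",
                              region_start = 10000000L,
                              region_width = 1400000L) {
  validate_synth_config(cfg)
  if (is.null(variants)) {
    variants <- synth_regulatory_variants(cfg, chrom, region_start,
                                          region_width)$variants
  }
  withr::with_seed(cfg$seed + 3003L, {
    m <- cfg$n_peaks_per_track
    tracks <- list()
    truths <- list()
    for (src in sources) {
      start0 <- sort(sample.int(region_width, max(m, 0L), replace = TRUE)) +
        region_start - 2L # 0-based starts within the region
      width <- sample(200:2000, max(m, 0L), replace = TRUE)
      end0 <- start0 + width
      gr <- GenomicRanges::GRanges(rep(chrom, m),
                                   IRanges::IRanges(start = start0 + 1L,
                                                    end = end0))
      gr <- GenomicRanges::sort(gr)
      S4Vectors::metadata(gr)$source <- src
      tracks[[src]] <- gr
      # exhaustive truth scan over the 0-based half-open intervals
      p0 <- variants$pos - 1L
      cnt <- vapply(seq_along(p0), function(i) {
        if (m == 0L) return(0L)
        sum(variants$chrom[[i]] == chrom & start0 <= p0[[i]] & p0[[i]] < end0)
      }, integer(1))
      truths[[src]] <- tibble::tibble(variant_id = variants$variant_id,
                                      source = src, overlap_count = cnt)
    }
    list(tracks = tracks, truth = dplyr::bind_rows(truths))
  })
}

#' Generate a phenotyped-cohort summary table
#'
#' Carrier counts over a cohort of `cohort_size` phenotyped individuals
#' against per-database population allele frequencies, with
#' negative-binomial HPO profile counts. Row 1 is the planted hit: its
#' carrier frequency equals `planted_enrichment_fold` times its mean
#' population allele frequency before integer rounding of carriers
#' (rounding half away from zero), and it carries the cohort's maximal
#' HPO count and CADD so the region outlier screen can recover it.
#'
#' @param cfg A [synth_config()].
#' @return A list: `cohort` (tibble `variant_id`, `cohort_carriers`,
#'   `cohort_size`, `af_gnomAD`, `af_TOPMed`, `hpo_profile_count`,
#'   `cadd`) and `truth` (planted variant id, fold, and exact planted
#'   carrier count).
#' @export
synth_cohort <- function(cfg) {
  validate_synth_config(cfg)
  withr::with_seed(cfg$seed + 4004L, {
    n <- cfg$n_coding_variants
    af_g <- 10^stats::runif(n, -5, -2.5)
    af_t <- af_g * stats::runif(n, 0.5, 1.5)
    tbl <- tibble::tibble(
      variant_id = sprintf("cvar%04d", seq_len(n)),
      cohort_carriers = stats::rbinom(n, cfg$cohort_size, af_g),
      cohort_size = cfg$cohort_size,
      af_gnomAD = af_g,
      af_TOPMed = af_t,
      hpo_profile_count = stats::rnbinom(n, size = cfg$hpo_nb_size,
                                         mu = cfg$hpo_nb_mu),
      cadd = round(stats::runif(n, 0, 20), 1)
    )
    planted_carriers <- planted_carrier_count(cfg)
    tbl$variant_id[[1]] <- "hit0001"
    tbl$af_gnomAD[[1]] <- cfg$planted_af[["gnomAD"]]
    tbl$af_TOPMed[[1]] <- cfg$planted_af[["TOPMed"]]
    tbl$cohort_carriers[[1]] <- planted_carriers
    tbl$hpo_profile_count[[1]] <- max(tbl$hpo_profile_count) + 20L
    tbl$cadd[[1]] <- max(tbl$cadd) + 5
    list(
      cohort = tbl,
      truth = tibble::tibble(variant_id = "hit0001",
                             planted_fold = cfg$planted_enrichment_fold,
                             planted_carriers = planted_carriers)
    )
  })
}

#' Write the full synthetic fixture set to a directory
#'
#' Emits every generated artifact as plain text: the alignment FASTA, one
#' BED per peak track, and TSVs for the variant tables, cohort table, and
#' all truth tables. Outputs are byte-identical for identical
#' configurations.
#'
#' @param cfg A [synth_config()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of written paths, invisibly.
#' @export
synth_write_fixtures <- function(cfg, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  aln <- synth_alignment(cfg)
  coding <- synth_coding_variants(cfg)
  reg <- synth_regulatory_variants(cfg)
  peaks <- synth_peak_tracks(cfg, reg$variants)
  cohort <- synth_cohort(cfg)
  paths <- c(
    alignment = file.path(dir, "alignment.fasta"),
    alignment_truth = file.path(dir, "alignment_truth.tsv"),
    coding_variants = file.path(dir, "coding_variants.tsv"),
    regulatory_variants = file.path(dir, "regulatory_variants.tsv"),
    regulatory_truth = file.path(dir, "regulatory_truth.tsv"),
    overlap_truth = file.path(dir, "overlap_truth.tsv"),
    cohort = file.path(dir, "cohort.tsv"),
    cohort_truth = file.path(dir, "cohort_truth.tsv")
  )
  write_codon_alignment(aln$alignment, paths[["alignment"]])
  write_table_tsv(aln$truth, paths[["alignment_truth"]])
  write_table_tsv(coding, paths[["coding_variants"]])
  write_table_tsv(reg$variants, paths[["regulatory_variants"]])
  write_table_tsv(reg$truth, paths[["regulatory_truth"]])
  write_table_tsv(peaks$truth, paths[["overlap_truth"]])
  write_table_tsv(cohort$cohort, paths[["cohort"]])
  write_table_tsv(cohort$truth, paths[["cohort_truth"]])
  for (src in names(peaks$tracks)) {
    p <- file.path(dir, paste0("track_", src, ".bed"))
    write_bed_track(peaks$tracks[[src]], p)
    paths[[paste0("track_", src)]] <- p
  }
  invisible(paths)
}
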