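#' Write a table as TSV with stable formatting
#'
#' Header-first, tab-separated, UTF-8; non-integer numeric columns are
#' serialized at 6 significant digits so outputs are diff-able and
#' byte-stable across runs.
#'
#' @param tbl A data frame or tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_table_tsv <- function(tbl, path) {
  out <- dplyr::mutate(tbl, dplyr::across(
    dplyr::where(function(x) is.double(x) && !all(x == round(x), na.rm = TRUE)),
    format_num))
  readr::write_tsv(out, path, na = "NA", progress = FALSE)
  invisible(path)
}

#' Read a typed variant/cohort table
#'
#' Reads a header-first TSV and validates the schema's required columns
#' and value ranges; malformed input raises a diagnostic naming the file
#' and the problem rather than silently coercing.
#'
#' @param path Path to a TSV with a header row.
#' @param schema One of `"coding"`, `"regulatory"`, `"cohort"`,
#'   `"eqtl"`, or `"none"` (no validation).
#' @return A tibble.
#' @export
read_variant_table <- function(path,
                               schema = c("none", "coding", "regulatory",
                                          "cohort", "eqtl")) {
  schema <- match.arg(schema)
  if (!file.exists(path)) {
    rlang::abort(sprintf("Table not found: %s", path),
                 class = "varprior_io_error")
  }
  tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  required <- switch(schema,
    none = character(),
    coding = c("variant_id", "protein_position", "polyphen2", "provean",
               "sift", "align_gvgd"),
    regulatory = c("variant_id", "chrom", "pos", "cadd", "ld_block"),
    cohort = c("variant_id", "cohort_carriers", "cohort_size",
               "hpo_profile_count", "cadd"),
    eqtl = c("variant_id", "tissue"))
  missing_col <- setdiff(required, names(tbl))
  if (length(missing_col)) {
    rlang::abort(sprintf("%s: missing required column(s): %s", path,
                         paste(missing_col, collapse = ", ")),
                 class = "varprior_format_error")
  }
  af_cols <- grep("^af_", names(tbl), value = TRUE)
  for (col in af_cols) {
    if (any(tbl[[col]] < 0 | tbl[[col]] > 1, na.rm = TRUE)) {
      rlang::abort(sprintf("%s: column %s has frequencies outside [0, 1].",
                           path, col),
                   class = "varprior_format_error")
    }
  }
  if (schema == "regulatory" && any(tbl$pos < 1L)) {
    rlang::abort(sprintf("%s: positions must be 1-based (>= 1).", path),
                 class = "varprior_format_error")
  }
  if (schema == "coding" && any(tbl$protein_position < 1L)) {
    rlang::abort(sprintf("%s: protein_position must be >= 1.", path),
                 class = "varprior_format_error")
  }
  tbl
}

#' Pipeline configuration
#'
#' Collects input paths and parameter overrides for [run_pipeline()].
#' Paths are validated up front so a missing input fails before any stage
#' runs. Can also be populated from a YAML file via
#' [read_pipeline_config()].
#'
#' @param alignment Path to the aligned codon FASTA.
#' @param coding_variants Path to the coding-variant TSV.
#' @param regulatory_variants Path to the noncoding-variant TSV (optional).
#' @param tracks Named character vector of BED paths (optional).
#' @param cohort Path to the cohort TSV (optional).
#' @param out_dir Output directory.
#' @param reference_id Reference row id in the alignment (default: first
#'   record).
#' @param half_width Window half-width in codons (default 10).
#' @param top_k Motifs to call (default 6).
#' @param freq_db Allele-frequency database for the combined impact score
#'   (default `"gnomAD"`).
#' @param pop_databases Databases averaged for enrichment
#'   (default `c("gnomAD", "TOPMed")`).
#' @param high_score_threshold Regulatory-score reporting threshold
#'   (default 500).
#' @param hpo_quantile,cadd_quantile Outlier quantiles (default 0.99).
#' @param seed Seed recorded in the run log.
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(alignment,
                            coding_variants,
                            regulatory_variants = NULL,
                            tracks = character(),
                            cohort = NULL,
                            out_dir = "varprior_out",
                            reference_id = NULL,
                            half_width = 10L,
                            top_k = 6L,
                            freq_db = "gnomAD",
                            pop_databases = c("gnomAD", "TOPMed"),
                            high_score_threshold = 500,
                            hpo_quantile = 0.99,
                            cadd_quantile = 0.99,
                            seed = 1L) {
  cfg <- structure(as.list(environment()), class = "pipeline_config")
  inputs <- c(alignment, coding_variants, regulatory_variants,
              unname(tracks), cohort)
  missing_in <- inputs[!file.exists(inputs)]
  if (length(missing_in)) {
    rlang::abort(sprintf("Input file(s) not found: %s",
                         paste(missing_in, collapse = ", ")),
                 class = "varprior_config_error")
  }
  if (half_width < 0 || top_k <= 0 ||
      hpo_quantile < 0 || hpo_quantile > 1 ||
      cadd_quantile < 0 || cadd_quantile > 1) {
    rlang::abort("Pipeline parameter outside its documented range.",
                 class = "varprior_config_error")
  }
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' @param path Path to a YAML file whose keys match the arguments of
#'   [pipeline_config()]; relative input paths are resolved against the
#'   YAML file's directory.
#' @return A validated `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  fix <- function(p) {
    if (is.null(p)) return(NULL)
    ifelse(file.exists(p), p, file.path(base, p))
  }
  for (key in c("alignment", "coding_variants", "regulatory_variants", "cohort")) {
    y[[key]] <- fix(y[[key]])
  }
  if (!is.null(y$tracks)) y$tracks <- vapply(y$tracks, fix, character(1))
  do.call(pipeline_config, y)
}

#' Run the full prioritization pipeline
#'
#' Chains the stages end to end: evolutionary score track and motif calls
#' from the alignment; additive/combined scoring and ranking of coding
#' variants; evidence x CADD scoring and per-LD-block reduction of
#' noncoding variants (when supplied); cohort enrichment and region
#' outliers (when supplied). All outputs are TSVs in `out_dir`, plus a
#' run log recording every resolved parameter, the seed, and the category
#' map. Inputs are never mutated; outputs are deterministic given the
#' configuration.
#'
#' @param config A [pipeline_config()] or path to a YAML file.
#' @return Named character vector of output paths, invisibly.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      rlang::abort(sprintf("Pipeline stage '%s' failed: %s", name,
                           conditionMessage(e)),
                   class = "varprior_pipeline_error", parent = e)
    })
  }
  outputs <- c()
  emit <- function(tbl, file) {
    p <- file.path(config$out_dir, file)
    write_table_tsv(tbl, p)
    outputs[[file]] <<- p
  }

  aln <- stage("alignment", read_codon_alignment(config$alignment,
                                                 config$reference_id))
  track <- stage("conservation", score_track(aln, config$half_width))
  emit(track, "score_track.tsv")
  motifs <- stage("motifs", call_motifs(track, top_k = config$top_k,
                                        half_width = config$half_width))
  emit(motifs, "motif_calls.tsv")

  coding <- stage("coding_variants",
                  read_variant_table(config$coding_variants, "coding"))
  scored <- stage("coding_scoring",
                  rank_variants(score_coding_variants(
                    coding, track, freq_db = config$freq_db)))
  emit(scored, "coding_scored.tsv")

  if (!is.null(config$regulatory_variants)) {
    reg <- stage("regulatory_variants",
                 read_variant_table(config$regulatory_variants, "regulatory"))
    tracks <- lapply(config$tracks, read_bed_track)
    reg_scored <- stage("regulatory_scoring", regulatory_score(reg, tracks))
    reg_scored$high_score <- reg_scored$score > config$high_score_threshold
    emit(reg_scored, "regulatory_scored.tsv")
    emit(stage("ld_blocks", top_per_block(reg_scored)), "top_per_block.tsv")
  }

  if (!is.null(config$cohort)) {
    cohort <- stage("cohort", read_variant_table(config$cohort, "cohort"))
    emit(stage("enrichment",
               enrichment_table(cohort, config$pop_databases)),
         "enrichment.tsv")
    emit(stage("outliers",
               region_outliers(cohort, config$hpo_quantile,
                               config$cadd_quantile)),
         "outliers.tsv")
  }

  log_path <- file.path(config$out_dir, "run_log.txt")
  params <- config[setdiff(names(config), NULL)]
  cmap <- default_category_map()
  writeLines(c(
    "varprior run log",
    paste0(utils::capture.output(utils::str(params, give.attr = FALSE)),
           collapse = "\n"),
    "category map:",
    paste0(utils::capture.output(utils::str(cmap)), collapse = "\n")
  ), log_path)
  outputs[["run_log.txt"]] <- log_path
  invisible(unlist(outputs))
}
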