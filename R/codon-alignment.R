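#' In-frame codon alignment
#'
#' A `codon_alignment` holds aligned coding sequences kept in frame, so
#' that each column triple encodes one amino-acid position, together with
#' a designated reference row (the human sequence, whose residue numbering
#' all reports use). Gap characters must occur in whole-codon triples
#' (`"---"`): a gap that breaks a codon has no in-frame interpretation.
#'
#' @param ids Character vector of sequence identifiers (unique).
#' @param seqs Character vector of aligned sequences over `{A,C,G,T,-}`,
#'   all the same length, length divisible by 3.
#' @param reference_id Identifier of the reference row; defaults to the
#'   first sequence.
#' @return An object of class `codon_alignment`: a list with elements
#'   `ids`, `seqs`, `reference_id`, `n_codons`.
#' @examples
#' aln <- codon_alignment(c("hs", "mm"), c("ATGGGA", "ATGGGC"))
#' aln$n_codons
#' @export
codon_alignment <- function(ids, seqs, reference_id = ids[[1]]) {
  ids <- as.character(ids)
  seqs <- toupper(as.character(seqs))
  if (length(ids) != length(seqs)) {
    rlang::abort("`ids` and `seqs` must have the same length.",
                 class = "varprior_format_error")
  }
  if (anyDuplicated(ids)) {
    rlang::abort("Sequence identifiers must be unique.",
                 class = "varprior_format_error")
  }
  aln <- structure(
    list(ids = ids, seqs = seqs, reference_id = reference_id,
         n_codons = nchar(seqs[[1]]) %/% 3L),
    class = "codon_alignment"
  )
  validate_codon_alignment(aln)
}

#' Validate a codon alignment
#'
#' Checks the class invariants: equal row lengths divisible by 3, an
#' alphabet restricted to `A,C,G,T,-`, gaps only as whole codons, and a
#' reference id present among the rows. Errors name the offending row.
#'
#' @param aln A `codon_alignment`.
#' @return `aln`, invisibly unchanged, if valid.
#' @export
validate_codon_alignment <- function(aln) {
  widths <- nchar(aln$seqs)
  if (length(unique(widths)) != 1L) {
    bad <- aln$ids[widths != widths[[1]]][[1]]
    rlang::abort(
      sprintf("Alignment rows have unequal lengths (e.g. row '%s').", bad),
      class = "varprior_format_error")
  }
  if (widths[[1]] %% 3L != 0L) {
    rlang::abort("Alignment length is not divisible by 3.",
                 class = "varprior_format_error")
  }
  bad_alpha <- grepl("[^ACGT-]", aln$seqs)
  if (any(bad_alpha)) {
    rlang::abort(
      sprintf("Row '%s' contains characters outside {A,C,G,T,-}.",
              aln$ids[bad_alpha][[1]]),
      class = "varprior_format_error")
  }
  # gaps must tile whole codons: any codon mixing '-' with a base is invalid
  cm <- codon_matrix(aln)
  mixed <- grepl("-", cm) & cm != "---"
  if (any(mixed)) {
    bad_row <- aln$ids[which(rowSums(mixed) > 0)[[1]]]
    rlang::abort(
      sprintf("Row '%s' has a gap that is not a whole codon triple.", bad_row),
      class = "varprior_format_error")
  }
  if (!aln$reference_id %in% aln$ids) {
    rlang::abort(sprintf("Reference id '%s' not found in alignment.",
                         aln$reference_id),
                 class = "varprior_format_error")
  }
  invisible(aln)
}

#' @export
print.codon_alignment <- function(x, ...) {
  cat(sprintf("<codon_alignment> %d sequences x %d codons (reference: %s)\n",
              length(x$ids), x$n_codons, x$reference_id))
  invisible(x)
}

# Rows-by-codons character matrix of an alignment.
codon_matrix <- function(aln) {
  n_col <- nchar(aln$seqs[[1]]) %/% 3L
  starts <- 3L * seq_len(n_col) - 2L
  m <- vapply(aln$seqs, function(s) substring(s, starts, starts + 2L),
              character(n_col))
  if (n_col == 1L) m <- matrix(m, nrow = 1L)
  t(m) # rows = sequences, columns = codons
}

#' Translate codons under the standard nuclear code
#'
#' Stop codons translate to `"*"` (treated downstream as a 21st residue
#' class), full-codon gaps to `NA`.
#'
#' @param codons Character vector of codon triplets over `{A,C,G,T,-}`.
#' @return Character vector of single-letter amino acids (`"*"` for stop,
#'   `NA` for `"---"`).
#' @export
translate_codons <- function(codons) {
  gc <- Biostrings::GENETIC_CODE
  aa <- unname(gc[codons])
  aa[codons == "---"] <- NA_character_
  bad <- is.na(aa) & codons != "---"
  if (any(bad)) {
    rlang::abort(sprintf("Untranslatable codon '%s'.", codons[bad][[1]]),
                 class = "varprior_format_error")
  }
  aa
}

# Number of synonymous codons per amino acid under the standard code
# (includes "*" with its 3 stop codons).
synonymous_codon_counts <- function() {
  table(Biostrings::GENETIC_CODE)
}

# Codons encoding one amino acid.
codons_for_aa <- function(aa) {
  gc <- Biostrings::GENETIC_CODE
  names(gc)[gc == aa]
}

#' Read an aligned codon FASTA
#'
#' @param path Path to an aligned FASTA file of in-frame coding sequences.
#' @param reference_id Reference row id; defaults to the first record.
#' @return A [codon_alignment()].
#' @export
read_codon_alignment <- function(path, reference_id = NULL) {
  if (!file.exists(path)) {
    rlang::abort(sprintf("Alignment file not found: %s", path),
                 class = "varprior_io_error")
  }
  ss <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(ss))
  seqs <- as.character(ss)
  if (is.null(reference_id)) reference_id <- ids[[1]]
  codon_alignment(ids, seqs, reference_id)
}

#' Write a codon alignment as aligned FASTA
#'
#' @param aln A [codon_alignment()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_codon_alignment <- function(aln, path) {
  ss <- Biostrings::BStringSet(stats::setNames(aln$seqs, aln$ids))
  Biostrings::writeXStringSet(ss, path, width = 60L)
  invisible(path)
}
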