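#' Recode a sequence with regularly spaced single-nucleotide changes
#'
#' Introduces a single-nucleotide polymorphism every `spacing` bases into a
#' DNA sequence, emulating the synthetic RNAi trigger used to discriminate
#' primary siRNAs (which carry the recoded bases) from secondary siRNAs
#' (which match the original sensor exactly). Substitutions follow the fixed
#' transversion map A->C, C->A, G->T, T->G, so no position is ever left
#' unchanged and any read spanning a SNP mismatches the original sequence at
#' exactly that base.
#'
#' @param seq DNA string over `A,C,G,T`.
#' @param spacing Positive integer distance between consecutive SNPs.
#' @param phase Non-negative integer offset: SNPs are placed at 1-based
#'   positions `phase + spacing`, `phase + 2*spacing`, ... up to the sequence
#'   length. The default `phase = 0` puts them at exact multiples of
#'   `spacing`.
#' @return A list with `recoded` (the substituted sequence) and
#'   `snp_positions` (ordered 1-based positions of the substitutions).
#' @examples
#' recode_sequence(strrep("ACGT", 11), spacing = 21)
#' @export
recode_sequence <- function(seq, spacing, phase = 0L) {
  stopifnot(length(seq) == 1L, is.character(seq))
  if (!is.numeric(spacing) || length(spacing) != 1L || spacing < 1 ||
      spacing != as.integer(spacing)) {
    .stopf("'spacing' must be a positive integer")
  }
  if (!is.numeric(phase) || length(phase) != 1L || phase < 0) {
    .stopf("'phase' must be a non-negative integer")
  }
  .check_alphabet(seq, allow_n = FALSE, what = "sequence to recode")
  len <- nchar(seq)
  pos <- seq.int(phase + spacing, by = spacing,
                 length.out = max(0L, (len - phase) %/% spacing))
  pos <- as.integer(pos[pos >= 1 & pos <= len])
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  chars[pos] <- chartr("ACGT", "CATG", chars[pos])
  list(recoded = paste(chars, collapse = ""), snp_positions = pos)
}
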