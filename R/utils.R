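# Internal helpers shared across modules. Sequences are plain upper-case
# character scalars in DNA space (sequencers report T, not U); coordinates are
# 0-based half-open internally and converted at the GFF3 boundary.

DNA_ALPHABET <- c("A", "C", "G", "T")

#' Reverse complement of a DNA string
#'
#' @param seq Character vector of sequences over `A,C,G,T,N`.
#' @return Character vector of reverse complements.
#' @examples
#' reverse_complement("ACGTT")
#' @export
reverse_complement <- function(seq) {
  stopifnot(is.character(seq))
  vapply(seq, function(s) {
    rc <- chartr("ACGTN", "TGCAN", s)
    paste(rev(strsplit(rc, "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

.check_alphabet <- function(seq, allow_n = FALSE, what = "sequence") {
  allowed <- if (allow_n) "ACGTN" else "ACGT"
  bad <- gsub(sprintf("[%s]", allowed), "", seq)
  if (any(nzchar(bad))) {
    offending <- substr(bad[nzchar(bad)][1], 1, 1)
    stop(sprintf("invalid character '%s' in %s (allowed: %s)",
                 offending, what, allowed), call. = FALSE)
  }
  invisible(TRUE)
}

# Raw-byte view of a sequence with N remapped so that it can never match
# anything (N in a read counts as a mismatch at every position).
.seq_raw <- function(seq, query = FALSE) {
  r <- charToRaw(seq)
  n <- r == charToRaw("N")
  if (any(n)) r[n] <- if (query) as.raw(1L) else as.raw(2L)
  r
}

# Random sequence helper used by the generators (relies on the caller's RNG
# state; all public generators take an explicit seed).
.random_seq <- function(n) {
  paste(sample(DNA_ALPHABET, n, replace = TRUE), collapse = "")
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
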