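# Shared fixtures and independent oracles. The reference world is built once
# per test run; everything is generated in code, no stored data.

.fixture_env <- new.env(parent = emptyenv())

test_bundle <- function() {
  if (is.null(.fixture_env$bundle)) {
    .fixture_env$bundle <- build_reference(reference_config(), seed = 42L)
  }
  .fixture_env$bundle
}

# Expected cascade compartment / small RNA class for each simulator label.
TRUTH_TO_COMPARTMENT <- c(
  mirna = "mirna", pirna_21u = "genome", sirna_22g = "genome",
  sirna_26g = "genome", sirna_other = "genome", sense_degradation = "genome",
  gfp_primary = "recoded_gfp", gfp_secondary = "sensor_gfp",
  contaminant = "contaminant", structural = "structural")

TRUTH_TO_CLASS <- c(
  mirna = "mirna", pirna_21u = "pirna", sirna_22g = "sirna_22g",
  sirna_26g = "sirna_26g", sirna_other = "sirna_other_antisense",
  sense_degradation = "sense_read", gfp_primary = "gfp_primary",
  gfp_secondary = "gfp_secondary")

# Brute-force alignment oracle: byte comparison at every offset and strand,
# independent of the package's scan/tie-break code path. Returns the full
# per-strand mismatch profiles so one pass serves every k.
oracle_profiles <- function(query, ref) {
  query <- unname(query)
  lapply(c(sense = query, antisense = reverse_complement(query)),
         function(q) {
           qraw <- charToRaw(q)
           rraw <- charToRaw(ref)
           L <- length(qraw)
           n_off <- length(rraw) - L + 1L
           vapply(seq_len(max(n_off, 0L)), function(o) {
             sum(rraw[o:(o + L - 1L)] != qraw)
           }, integer(1))
         })
}

# Best hit from oracle profiles for a single reference under the package's
# documented tie-break (fewest mismatches, smallest offset, sense first).
oracle_best_hit <- function(profiles, k) {
  cand <- NULL
  for (strand in c("sense", "antisense")) {
    mm <- profiles[[strand]]
    if (!length(mm)) next
    m <- min(mm)
    if (m > k) next
    off <- which(mm == m)[1] - 1L
    h <- list(offset = off, strand = strand, mismatches = m)
    if (is.null(cand) || h$mismatches < cand$mismatches ||
        (h$mismatches == cand$mismatches && h$offset < cand$offset)) {
      cand <- h
    }
  }
  cand
}

# Exact two-sided Wilcoxon rank-sum p by full enumeration of the
# C(m+n, m) group assignments, mirroring R's two-sided convention.
enum_wilcox_p <- function(a, b) {
  m <- length(a); n <- length(b)
  pooled <- c(a, b)
  stopifnot(!anyDuplicated(pooled))
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  splits <- utils::combn(m + n, m)
  u_all <- apply(splits, 2L, function(idx) sum(r[idx]) - m * (m + 1) / 2)
  if (u_obs > m * n / 2) {
    p <- 2 * mean(u_all >= u_obs)
  } else {
    p <- 2 * mean(u_all <= u_obs)
  }
  min(1, p)
}

# Welch t-test by direct formula evaluation.
welch_oracle <- function(a, b) {
  va <- stats::var(a) / length(a)
  vb <- stats::var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  list(t = t, p = 2 * stats::pt(-abs(t), df))
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
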