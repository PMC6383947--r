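#' Join 22G and mRNA tables and compute the targeted fraction
#'
#' Joins per-gene mean normalized antisense 22G counts with per-gene mean
#' normalized mRNA counts and reports the percentage of expressed mRNAs
#' (mRNA >= `min_reads`) that are targeted by 22G RNAs (22G >= `min_reads`).
#'
#' @param counts_22g,mrna Named numeric vectors (gene -> mean normalized
#'   reads) or two-column data frames (`gene_id`, value).
#' @param min_reads Minimum reads of each RNA type.
#' @return List with `joined` (data frame `gene_id`, `reads_22g`,
#'   `reads_mrna`) and `targeted_pct`.
#' @export
join_and_targeted_fraction <- function(counts_22g, mrna, min_reads = 10) {
  as_vec <- function(x, what) {
    if (is.data.frame(x)) {
      stopifnot(ncol(x) >= 2)
      return(stats::setNames(x[[2]], x[[1]]))
    }
    if (is.null(names(x))) .stopf("%s must be named by gene id", what)
    x
  }
  g22 <- as_vec(counts_22g, "counts_22g")
  mr <- as_vec(mrna, "mrna")
  genes <- intersect(names(g22), names(mr))
  if (!length(genes)) .stopf("empty join: no shared gene identifiers")
  joined <- data.frame(gene_id = genes, reads_22g = unname(g22[genes]),
                       reads_mrna = unname(mr[genes]))
  expressed <- joined$reads_mrna >= min_reads
  if (!any(expressed)) .stopf("no gene reaches %g mRNA reads", min_reads)
  targeted_pct <- 100 * sum(expressed & joined$reads_22g >= min_reads) /
    sum(expressed)
  list(joined = joined, targeted_pct = targeted_pct)
}

#' Equal-count expression bins
#'
#' Sorts genes ascending by the bin variable (ties broken by stable input
#' order) and splits them into `n_bins` contiguous groups whose sizes differ
#' by at most one gene; the top bin holds the highest values.
#'
#' @param values Numeric vector (one value per gene).
#' @param n_bins Number of bins (20 = 5% percentiles).
#' @return List of class `bin_scheme`: `bin` (bin index per input element),
#'   `n_bins`, `sizes`.
#' @export
bin_by_expression <- function(values, n_bins = 20L) {
  n <- length(values)
  n_bins <- as.integer(n_bins)
  if (n_bins < 1L) .stopf("n_bins must be >= 1")
  if (n_bins > n) .stopf("n_bins (%d) exceeds the number of genes (%d)",
                         n_bins, n)
  base <- n %/% n_bins
  sizes <- rep(base, n_bins)
  extra <- n %% n_bins
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  ord <- order(values)  # radix: stable for ties
  bin <- integer(n)
  bin[ord] <- rep.int(seq_len(n_bins), sizes)
  structure(list(bin = bin, n_bins = n_bins, sizes = sizes),
            class = "bin_scheme")
}

#' Per-bin linear association between mRNA and 22G levels
#'
#' Within each bin, ordinary least squares of `log10(mRNA + 1)` on
#' `log10(22G + 1)` with a two-sided t-test of slope = 0. Bins with fewer
#' than 3 genes, or with no variance in the predictor, are reported `na`.
#' A perfect fit (zero residual variance) reports p = 0 for a nonzero
#' slope and p = 1 for a zero slope.
#'
#' @param joined Data frame with `reads_22g` and `reads_mrna`.
#' @param scheme A [bin_by_expression()] scheme over the same genes.
#' @return Data frame: `bin`, `n_genes`, `slope`, `p`, `status`
#'   (`"ok"`/`"na"`).
#' @export
bin_slope_test <- function(joined, scheme) {
  stopifnot(inherits(scheme, "bin_scheme"),
            nrow(joined) == length(scheme$bin))
  x_all <- log10(joined$reads_22g + 1)
  y_all <- log10(joined$reads_mrna + 1)
  out <- lapply(seq_len(scheme$n_bins), function(b) {
    sel <- scheme$bin == b
    n <- sum(sel)
    if (n < 3L)
      return(data.frame(bin = b, n_genes = n, slope = NA_real_, p = NA_real_,
                        status = "na"))
    x <- x_all[sel]; y <- y_all[sel]
    if (stats::var(x) == 0)
      return(data.frame(bin = b, n_genes = n, slope = NA_real_, p = NA_real_,
                        status = "na"))
    if (stats::var(y) == 0)  # a flat response carries no association
      return(data.frame(bin = b, n_genes = n, slope = 0, p = 1,
                        status = "ok"))
    fit <- stats::lm(y ~ x)
    cf <- suppressWarnings(summary(fit))$coefficients  # exact fits warn
    slope <- cf["x", "Estimate"]
    p <- cf["x", "Pr(>|t|)"]
    if (is.nan(p)) p <- if (abs(slope) < 1e-12) 1 else 0  # zero residual var
    data.frame(bin = b, n_genes = n, slope = slope, p = p, status = "ok")
  })
  do.call(rbind, out)
}

.bin_wilcox <- function(values, flag, bins, n_bins, alpha,
                        lower_label = "lower_in_targets",
                        higher_label = "higher_in_targets") {
  rows <- lapply(seq_len(n_bins), function(b) {
    sel <- bins == b
    v <- values[sel]; f <- flag[sel]
    if (!any(f) || all(f) || !any(sel)) {
      return(data.frame(bin = b, n_genes = sum(sel), n_targets = sum(f),
                        p = NA_real_, direction = NA_character_,
                        verdict = "na"))
    }
    p <- suppressWarnings(stats::wilcox.test(v[f], v[!f],
                                             correct = TRUE)$p.value)
    if (is.na(p)) p <- 1  # all values tied: no evidence of a difference
    direction <- if (stats::median(v[f]) < stats::median(v[!f]))
      lower_label else higher_label
    data.frame(bin = b, n_genes = sum(sel), n_targets = sum(f), p = p,
               direction = direction, verdict = "ns")
  })
  out <- do.call(rbind, rows)
  eligible <- out$verdict != "na"
  out$q <- NA_real_
  out$q[eligible] <- pmin(1, out$p[eligible] * sum(eligible))  # Bonferroni
  out$verdict[eligible] <- ifelse(out$q[eligible] < alpha, "significant", "ns")
  out
}

#' Within-bin comparison of mRNA between target and non-target genes
#'
#' For each 22G-level bin, a two-sided Wilcoxon rank-sum test of mRNA
#' between genes flagged as Argonaute targets and the rest, Bonferroni
#' corrected across the eligible bins (bins holding a single category are
#' `na` and excluded from the correction denominator).
#'
#' @param joined Data frame with `reads_mrna`.
#' @param scheme Bin scheme over the same genes (typically on 22G level).
#' @param group_flag Logical vector: target-set membership per gene.
#' @param alpha Cutoff on the Bonferroni-corrected q.
#' @return Data frame of class `bin_summary`: per bin gene/target counts,
#'   `p`, `q`, `direction` and `verdict` (`significant`/`ns`/`na`).
#' @export
bin_group_compare <- function(joined, scheme, group_flag, alpha = 0.01) {
  stopifnot(inherits(scheme, "bin_scheme"),
            nrow(joined) == length(scheme$bin),
            length(group_flag) == nrow(joined), is.logical(group_flag))
  out <- .bin_wilcox(joined$reads_mrna, group_flag, scheme$bin,
                     scheme$n_bins, alpha)
  structure(out, class = c("bin_summary", "data.frame"))
}

#' @export
print.bin_summary <- function(x, ...) {
  elig <- sum(x$verdict != "na")
  cat(sprintf("Per-bin comparison: %d significant of %d eligible bins (%d na)\n",
              sum(x$verdict == "significant"), elig, sum(x$verdict == "na")))
  NextMethod()
}

#' Cross-sex comparison of 22G levels at matched mRNA abundance
#'
#' Pools the two sexes' gene tables, bins the pooled genes by mRNA
#' abundance so that genes of similar expression are compared, and tests
#' per bin whether 22G levels differ between the sexes (two-sided Wilcoxon,
#' Bonferroni across eligible bins). Bins lacking genes from either sex are
#' `na`.
#'
#' @param joined_a,joined_b Data frames with `reads_22g` and `reads_mrna`
#'   for the two sexes.
#' @param n_bins Number of matched-abundance bins.
#' @param alpha Cutoff on the corrected q.
#' @return `bin_summary` data frame; `direction` is relative to the first
#'   sex.
#' @export
matched_abundance_compare <- function(joined_a, joined_b, n_bins = 20L,
                                      alpha = 0.01) {
  pooled_mrna <- c(joined_a$reads_mrna, joined_b$reads_mrna)
  scheme <- bin_by_expression(pooled_mrna, n_bins)
  is_a <- c(rep(TRUE, nrow(joined_a)), rep(FALSE, nrow(joined_b)))
  out <- .bin_wilcox(c(joined_a$reads_22g, joined_b$reads_22g), is_a,
                     scheme$bin, n_bins, alpha,
                     lower_label = "lower_in_a", higher_label = "higher_in_a")
  names(out)[names(out) == "n_targets"] <- "n_sex_a"
  structure(out, class = c("bin_summary", "data.frame"))
}

#' Simulate a joined 22G/mRNA expression table with a silencing signature
#'
#' Generates genes whose mRNA level rises with 22G level except for the
#' fraction with the very highest 22G load, where mRNA drops steeply with
#' further 22G — the negative-feedback signature of siRNA-mediated
#' silencing. Optional disjoint WAGO-like (silencing, mRNA scaled down) and
#' CSR-1-like (licensing, mRNA scaled up) target sets are planted uniformly
#' across bins.
#'
#' @param n_genes Number of genes.
#' @param silenced_frac Fraction of genes (top of the 22G range) under the
#'   silencing regime.
#' @param slope Baseline slope of log10 mRNA on log10 22G.
#' @param silencing_slope Negative slope magnitude beyond the silencing
#'   threshold; the default gives a mean ~4-fold mRNA drop over the top 5%.
#' @param noise_sd Gaussian noise on log10 mRNA.
#' @param lg22_range Range of log10(22G + 1).
#' @param wago_frac,wago_effect,csr_frac,csr_effect Target-set fractions and
#'   mRNA multipliers.
#' @param seed Integer seed.
#' @return Data frame `gene_id`, `reads_22g`, `reads_mrna`, `wago`, `csr`.
#' @export
simulate_expression_association <- function(n_genes = 2000L,
                                            silenced_frac = 0.05,
                                            slope = 1, silencing_slope = 6,
                                            noise_sd = 0.2,
                                            lg22_range = c(0, 4),
                                            wago_frac = 0.3,
                                            wago_effect = 0.25,
                                            csr_frac = 0.2, csr_effect = 4,
                                            seed = 1L) {
  set.seed(seed)
  lg22 <- stats::runif(n_genes, lg22_range[1], lg22_range[2])
  thr <- stats::quantile(lg22, 1 - silenced_frac)
  lmrna <- 1 + slope * pmin(lg22, thr) -
    silencing_slope * pmax(lg22 - thr, 0) +
    stats::rnorm(n_genes, 0, noise_sd)
  wago <- csr <- rep(FALSE, n_genes)
  n_wago <- round(wago_frac * n_genes)
  n_csr <- round(csr_frac * n_genes)
  picks <- sample.int(n_genes, n_wago + n_csr)
  wago[picks[seq_len(n_wago)]] <- TRUE
  csr[picks[n_wago + seq_len(n_csr)]] <- TRUE
  mrna <- pmax(10^lmrna - 1, 0)
  mrna[wago] <- mrna[wago] * wago_effect
  mrna[csr] <- mrna[csr] * csr_effect
  data.frame(gene_id = sprintf("g%05d", seq_len(n_genes)),
             reads_22g = pmax(10^lg22 - 1, 0), reads_mrna = mrna,
             wago = wago, csr = csr)
}

#' Simulate per-gene 22G/mRNA detection for the targeted-fraction statistic
#'
#' Every gene is expressed at the mRNA level (>= `min_reads`); a fraction
#' of genes carry detectable 22G RNAs, the rest fall below the detection
#' threshold.
#'
#' @param n_genes Number of genes.
#' @param targeted_frac Fraction of expressed genes with detectable 22G.
#' @param min_reads Detection threshold used downstream.
#' @param seed Integer seed.
#' @return List with `counts_22g` and `mrna` named vectors.
#' @export
simulate_targeted_fraction <- function(n_genes = 2000L, targeted_frac = 0.8,
                                       min_reads = 10, seed = 1L) {
  set.seed(seed)
  ids <- sprintf("g%05d", seq_len(n_genes))
  mrna <- stats::setNames(min_reads + stats::rlnorm(n_genes, log(50), 1), ids)
  targeted <- stats::runif(n_genes) < targeted_frac
  g22 <- ifelse(targeted,
                min_reads + stats::rlnorm(n_genes, log(30), 1),
                stats::runif(n_genes, 0, min_reads * 0.9))
  list(counts_22g = stats::setNames(g22, ids), mrna = mrna)
}
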