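#' Median-of-ratios size factors
#'
#' Per-library scaling constants from the median-of-ratios estimator: the
#' factor of library j is the median, over features with a positive
#' geometric mean across libraries, of `count_ij / geometric_mean_i`.
#' Sense and antisense matrices must be normalized independently, because
#' different biological processes generate the two orientations.
#'
#' @param matrix Raw count matrix (features x samples).
#' @return Named numeric vector of positive size factors.
#' @export
size_factors <- function(matrix) {
  stopifnot(is.matrix(matrix), ncol(matrix) >= 1)
  logg <- rowMeans(log(matrix))
  usable <- is.finite(logg)
  if (!any(usable))
    .stopf("size factors undefined: no feature has a nonzero count in every sample")
  sf <- apply(matrix, 2L, function(col) {
    exp(stats::median(log(col[usable]) - logg[usable]))
  })
  stats::setNames(sf, colnames(matrix))
}

#' Normalize a count matrix by size factors
#'
#' @param matrix Raw count matrix.
#' @param sf Size factors; computed with [size_factors()] when omitted.
#' @return Matrix of normalized counts.
#' @export
normalize_counts <- function(matrix, sf = size_factors(matrix)) {
  sweep(matrix, 2L, sf, "/")
}

.fold_change <- function(mean_a, mean_b, pseudocount = 0.5) {
  log2((mean_b + pseudocount) / (mean_a + pseudocount))
}

#' Sex-bias calling between two replicate groups
#'
#' Tests each feature for differential abundance between two groups. The
#' default route is the rank-based test reported with the published figures:
#' a two-sided Wilcoxon rank-sum test per feature (exact for small tie-free
#' samples, normal approximation with continuity correction otherwise) on
#' normalized counts, with Benjamini-Hochberg adjustment across features. A
#' feature is called significant iff its fold change reaches
#' `fold_threshold` in either direction AND its adjusted p is below `alpha`.
#' Fold changes are computed on group means with a pseudocount of 0.5 so
#' that features detected exclusively in one group remain callable.
#'
#' `method = "deseq2"` instead fits the negative-binomial Wald test of the
#' DESeq2 package on *raw* counts (DESeq2 applies its own median-of-ratios
#' normalization internally). The rank test is essentially powerless at
#' adjusted p < 0.01 with two or three replicates per group — the smallest
#' exact two-sided p for a 3-vs-3 comparison is 0.1 — so the NB route is the
#' one that can reproduce genome-wide calling at those depths.
#'
#' @param group_a,group_b Matrices (features x replicates) with identical
#'   row names: normalized counts for `method = "wilcoxon"`, raw counts for
#'   `method = "deseq2"`.
#' @param fold_threshold Minimum fold difference (4 = two units of log2).
#' @param alpha Adjusted-p cutoff (1% false-discovery rate).
#' @param method `"wilcoxon"` or `"deseq2"`.
#' @param pseudocount Added to group means before the fold-change ratio.
#' @return Data frame of class `diff_calls`: `feature_id`, `log2fc`
#'   (group B over group A), `p`, `padj`, `significant`, `direction`.
#' @export
sex_bias_test <- function(group_a, group_b, fold_threshold = 4, alpha = 0.01,
                          method = c("wilcoxon", "deseq2"),
                          pseudocount = 0.5) {
  method <- match.arg(method)
  stopifnot(is.matrix(group_a), is.matrix(group_b))
  if (!identical(rownames(group_a), rownames(group_b)))
    .stopf("group matrices must cover the same features in the same order")
  if (ncol(group_a) < 2L || ncol(group_b) < 2L)
    .stopf("each group needs at least 2 replicates")

  if (method == "wilcoxon") {
    p <- vapply(seq_len(nrow(group_a)), function(i) {
      suppressWarnings(
        stats::wilcox.test(group_a[i, ], group_b[i, ], correct = TRUE)$p.value)
    }, numeric(1))
    l2fc <- .fold_change(rowMeans(group_a), rowMeans(group_b), pseudocount)
  } else {
    if (!requireNamespace("DESeq2", quietly = TRUE))
      .stopf("method='deseq2' requires the DESeq2 package")
    counts <- cbind(group_a, group_b)
    mode(counts) <- "integer"
    coldata <- data.frame(group = factor(rep(c("A", "B"),
                                             c(ncol(group_a), ncol(group_b)))))
    dds <- DESeq2::DESeqDataSetFromMatrix(counts, coldata, design = ~ group)
    dds <- DESeq2::DESeq(dds, quiet = TRUE)
    res <- DESeq2::results(dds, contrast = c("group", "B", "A"),
                           independentFiltering = FALSE, cooksCutoff = FALSE)
    p <- res$pvalue
    l2fc <- res$log2FoldChange
  }
  padj <- stats::p.adjust(p, method = "BH")
  significant <- !is.na(padj) & abs(l2fc) >= log2(fold_threshold) &
    padj < alpha
  direction <- ifelse(l2fc > 0, "higher_in_b",
                      ifelse(l2fc < 0, "higher_in_a", "none"))
  structure(data.frame(feature_id = rownames(group_a), log2fc = l2fc,
                       p = p, padj = padj, significant = significant,
                       direction = direction, row.names = NULL),
            class = c("diff_calls", "data.frame"))
}

#' @export
print.diff_calls <- function(x, ...) {
  cat(sprintf("Differential calls: %d features, %d significant (%d higher in B, %d in A)\n",
              nrow(x), sum(x$significant),
              sum(x$significant & x$direction == "higher_in_b"),
              sum(x$significant & x$direction == "higher_in_a")))
  NextMethod()
}

#' MA-style view of differential calls
#'
#' @param x A `diff_calls` object.
#' @param means Optional per-feature mean abundance for the x axis; ranks
#'   are used when omitted.
#' @param ... Passed to [plot()].
#' @method plot diff_calls
#' @export
plot.diff_calls <- function(x, means = NULL, ...) {
  xv <- if (is.null(means)) rank(x$padj) else log10(means + 1)
  plot(xv, x$log2fc, pch = 20, cex = 0.5,
       col = ifelse(x$significant, "firebrick", "grey60"),
       xlab = if (is.null(means)) "rank(adjusted p)" else "log10(mean + 1)",
       ylab = "log2 fold change (B/A)", ...)
  graphics::abline(h = c(-2, 0, 2), lty = c(2, 1, 2), col = "grey40")
  invisible(x)
}

TISSUE_CATEGORIES <- c("female_germline_biased", "male_germline_biased",
                       "female_somatic_biased", "male_somatic_biased",
                       "gonad_biased_unresolved", "not_biased")

#' Attribute sex-biased expression to germline or somatic gonad
#'
#' Combines three comparisons: hermaphrodite vs control male (`calls_hm`,
#' group A = hermaphrodite), control male vs feminized (`fog-3`) male
#' (`calls_mf`, group A = male, group B = fog-3) and hermaphrodite vs
#' feminized male (`calls_hf`, group A = hermaphrodite). Control and
#' feminized males share a male somatic gonad, so a difference between them
#' must stem from the germline; hermaphrodites and feminized males share a
#' female germline, so a difference between them must stem from the somatic
#' gonad. A feature significant between the sexes and between the male
#' genotypes is germline-biased (toward the female germline when higher in
#' fog-3); significant between the sexes and between hermaphrodite and
#' fog-3 it is somatic-biased (toward the female soma when higher in the
#' hermaphrodite); significant between the sexes only, it stays
#' `gonad_biased_unresolved`. When a feature qualifies for both the
#' germline comparison takes precedence. With `germline_only = TRUE`
#' (the piRNA convention — piRNAs are germline-specific) only `calls_hm`
#' is used and its direction maps straight to germline bias.
#'
#' @param calls_hm,calls_mf,calls_hf `diff_calls` for the three comparisons;
#'   `calls_mf`/`calls_hf` may be omitted when `germline_only`.
#' @param germline_only Attribute from the sex comparison alone.
#' @return Data frame `feature_id`, `category` (factor over the six
#'   categories).
#' @export
attribute_tissue <- function(calls_hm, calls_mf = NULL, calls_hf = NULL,
                             germline_only = FALSE) {
  stopifnot(inherits(calls_hm, "data.frame"))
  feats <- calls_hm$feature_id
  if (germline_only) {
    category <- ifelse(!calls_hm$significant, "not_biased",
                ifelse(calls_hm$direction == "higher_in_a",
                       "female_germline_biased", "male_germline_biased"))
    return(data.frame(feature_id = feats,
                      category = factor(category, TISSUE_CATEGORIES)))
  }
  if (is.null(calls_mf) || is.null(calls_hf))
    .stopf("calls_mf and calls_hf are required unless germline_only = TRUE")
  if (!identical(feats, calls_mf$feature_id) ||
      !identical(feats, calls_hf$feature_id))
    .stopf("the three call sets must cover the same features in the same order")
  category <- rep("not_biased", length(feats))
  sig_hm <- calls_hm$significant
  germ <- sig_hm & calls_mf$significant
  soma <- sig_hm & calls_hf$significant & !germ
  unres <- sig_hm & !germ & !soma
  # fog-3 is group B in both mutant comparisons
  category[germ] <- ifelse(calls_mf$direction[germ] == "higher_in_b",
                           "female_germline_biased", "male_germline_biased")
  category[soma] <- ifelse(calls_hf$direction[soma] == "higher_in_a",
                           "female_somatic_biased", "male_somatic_biased")
  category[unres] <- "gonad_biased_unresolved"
  data.frame(feature_id = feats,
             category = factor(category, TISSUE_CATEGORIES))
}

#' Simulate two-group count data with planted fold changes
#'
#' Negative-binomial counts for two replicate groups with a subset of
#' features carrying a planted fold change (half higher in each group).
#' Baseline means are log-normal around typical per-gene gonadal siRNA
#' depths (a few hundred reads).
#'
#' @param n_features Total features.
#' @param n_biased Features with a planted effect.
#' @param fold Planted fold change.
#' @param reps Replicates per group, length 2.
#' @param base_meanlog,base_sdlog Log-normal baseline-mean parameters.
#' @param dispersion NB dispersion (1/size).
#' @param seed Integer seed.
#' @return List with `group_a`, `group_b` (count matrices) and `biased`
#'   (planted feature ids).
#' @export
simulate_sex_counts <- function(n_features = 2000L, n_biased = 50L,
                                fold = 10, reps = c(3L, 3L),
                                base_meanlog = log(200), base_sdlog = 1,
                                dispersion = 0.1, seed = 1L) {
  set.seed(seed)
  ids <- sprintf("f%04d", seq_len(n_features))
  base <- stats::rlnorm(n_features, base_meanlog, base_sdlog)
  biased <- sample(ids, n_biased)
  eff <- rep(1, n_features)
  up_b <- sample(biased, floor(n_biased / 2))
  eff[match(up_b, ids)] <- fold
  eff[match(setdiff(biased, up_b), ids)] <- 1 / fold
  draw <- function(mu, n) {
    t(vapply(mu, function(m) stats::rnbinom(n, mu = m, size = 1 / dispersion),
             numeric(n)))
  }
  ga <- draw(base, reps[1])
  gb <- draw(base * eff, reps[2])
  dimnames(ga) <- list(ids, sprintf("a%d", seq_len(reps[1])))
  dimnames(gb) <- list(ids, sprintf("b%d", seq_len(reps[2])))
  list(group_a = ga, group_b = gb, biased = sort(biased))
}
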