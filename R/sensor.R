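#' Quantify primary and secondary GFP-sensor siRNAs
#'
#' In the SNP assay the cascade aligns reads to the worm GFP sensor first
#' (no mismatches) and to the recoded RNAi trigger second (no mismatches):
#' reads carrying a recoded SNP are primary siRNAs processed from the
#' trigger, reads matching the sensor exactly are worm-made secondary
#' siRNAs. Counts are scaled per million reads retained after trimming and
#' length filtering.
#'
#' @param result A `cascade_result` run with the sensor stage before the
#'   recoded stage, both at k = 0.
#' @param sample_id Library label.
#' @return One-row data frame of class `sensor_quant`: counts, per-million
#'   rates and the secondary/primary ratio (`NA` when no primary reads).
#' @export
quantify_sensor_sirna <- function(result, sample_id = "sample") {
  stopifnot(inherits(result, "cascade_result"))
  if (result$retained_total == 0L)
    .stopf("no reads retained; per-million rates undefined")
  primary <- unname(result$totals[["recoded_gfp"]])
  secondary <- unname(result$totals[["sensor_gfp"]])
  denom <- result$retained_total
  structure(data.frame(sample_id = sample_id,
                       primary_count = primary, secondary_count = secondary,
                       retained_total = denom,
                       primary_per_million = primary / denom * 1e6,
                       secondary_per_million = secondary / denom * 1e6,
                       ratio = if (primary > 0) secondary / primary else NA_real_),
            class = c("sensor_quant", "data.frame"))
}

#' Summarize sensor quantifications across replicate libraries
#'
#' Group rates are means of per-library rates; the group ratio is the mean
#' of per-library secondary/primary ratios (not the ratio of mean rates).
#' Libraries with no primary reads have an undefined ratio and are excluded
#' from the ratio mean.
#'
#' @param quants A `sensor_quant` or list/row-bound set of them.
#' @return One-row data frame with mean rates, mean ratio and `n_libraries`.
#' @export
sensor_group_summary <- function(quants) {
  if (is.list(quants) && !is.data.frame(quants))
    quants <- do.call(rbind, quants)
  data.frame(n_libraries = nrow(quants),
             primary_per_million = mean(quants$primary_per_million),
             secondary_per_million = mean(quants$secondary_per_million),
             ratio = mean(quants$ratio, na.rm = TRUE))
}

#' Welch two-sample t-test
#'
#' Two-sided Welch t-test between two groups of replicate values, with the
#' convention that two groups with zero variance and equal means give p = 1.
#'
#' @param group_a,group_b Numeric vectors (at least 2 values each).
#' @return List with `t` and `p`.
#' @export
compare_means_ttest <- function(group_a, group_b) {
  if (length(group_a) < 2L || length(group_b) < 2L)
    .stopf("each group needs at least 2 values")
  if (stats::var(group_a) == 0 && stats::var(group_b) == 0) {
    if (mean(group_a) == mean(group_b)) return(list(t = 0, p = 1))
    return(list(t = if (mean(group_b) > mean(group_a)) -Inf else Inf, p = 0))
  }
  ht <- stats::t.test(group_a, group_b)
  list(t = unname(ht$statistic), p = ht$p.value)
}

#' Percentage of animals silencing the GFP sensor
#'
#' Binary phenotype scoring: the silenced percentage per group with its
#' binomial standard error of the mean.
#'
#' @param table Data frame with columns `group`, `n_scored`, `n_silenced`.
#' @return The input with `percent` (1 decimal) and `sem` columns added.
#' @export
silencing_fraction <- function(table) {
  stopifnot(is.data.frame(table),
            all(c("group", "n_scored", "n_silenced") %in% names(table)))
  if (any(table$n_scored <= 0))
    .stopf("n_scored must be positive for every group")
  if (any(table$n_silenced < 0 | table$n_silenced > table$n_scored))
    .stopf("n_silenced must lie in [0, n_scored]")
  phat <- table$n_silenced / table$n_scored
  table$percent <- round(100 * phat, 1)
  table$sem <- 100 * sqrt(phat * (1 - phat) / table$n_scored)
  table
}

#' Pearson chi-square test on a 2x2 table (Yates-corrected)
#'
#' @param table 2x2 matrix of non-negative counts; all marginals must be
#'   positive.
#' @return List with `statistic` and `p` (df = 1, two-sided).
#' @export
chisq_2x2 <- function(table) {
  table <- as.matrix(table)
  stopifnot(nrow(table) == 2L, ncol(table) == 2L, all(table >= 0))
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    .stopf("chi-square undefined: a marginal of the 2x2 table is zero")
  ht <- suppressWarnings(stats::chisq.test(table, correct = TRUE))
  list(statistic = unname(ht$statistic), p = ht$p.value)
}
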