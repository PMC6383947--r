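test_that("the targeted fraction counts expressed genes with both RNA types", {
  g22 <- stats::setNames(rep(50, 5), paste0("g", 1:5))
  mrna <- stats::setNames(rep(50, 5), paste0("g", 1:5))
  expect_equal(join_and_targeted_fraction(g22, mrna)$targeted_pct, 100)
  # 10 expressed mRNAs, 7 of them with >= 10 reads of 22G
  g22b <- stats::setNames(c(rep(20, 7), rep(2, 3)), paste0("g", 1:10))
  mrnab <- stats::setNames(rep(15, 10), paste0("g", 1:10))
  expect_equal(join_and_targeted_fraction(g22b, mrnab)$targeted_pct, 70)
  expect_error(join_and_targeted_fraction(stats::setNames(1, "a"),
                                          stats::setNames(1, "b")),
               "empty join")
})

test_that("the generator's targeted fraction is recovered within binomial error", {
  tf <- simulate_targeted_fraction(n_genes = 2000, targeted_frac = 0.8,
                                   seed = 81)
  got <- join_and_targeted_fraction(tf$counts_22g, tf$mrna)$targeted_pct
  expect_lt(abs(got - 80), 100 * 3 * sqrt(0.8 * 0.2 / 2000))
})

test_that("equal-count binning partitions genes with sizes differing by at most one", {
  s40 <- bin_by_expression(stats::runif(40), 20)
  expect_true(all(s40$sizes == 2))
  s41 <- bin_by_expression(stats::runif(41), 20)
  expect_identical(sort(unique(s41$sizes)), c(2L, 3L))
  expect_identical(sum(s41$sizes == 3L), 1L)
  expect_identical(length(s41$bin), 41L)
  # sorted input gets non-decreasing bin indices; top bin holds the maxima
  v <- sort(stats::rlnorm(100))
  sch <- bin_by_expression(v, 10)
  expect_true(all(diff(sch$bin) >= 0))
  expect_identical(sch$bin[100], 10L)
  expect_error(bin_by_expression(1:5, 0), "n_bins")
  expect_error(bin_by_expression(1:5, 6), "exceeds")
})

test_that("per-bin slopes match a closed-form least-squares oracle", {
  set.seed(82)
  joined <- data.frame(reads_22g = rlnorm(60, 2, 1),
                       reads_mrna = rlnorm(60, 3, 1))
  scheme <- bin_by_expression(joined$reads_22g, 6)
  got <- bin_slope_test(joined, scheme)
  for (bn in 1:6) {
    sel <- scheme$bin == bn
    x <- log10(joined$reads_22g[sel] + 1)
    y <- log10(joined$reads_mrna[sel] + 1)
    n <- sum(sel)
    sxx <- sum((x - mean(x))^2)
    slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
    resid <- y - mean(y) - slope * (x - mean(x))
    se <- sqrt(sum(resid^2) / (n - 2) / sxx)
    t <- slope / se
    expect_equal(got$slope[bn], slope)
    expect_equal(got$p[bn], 2 * stats::pt(-abs(t), n - 2))
  }
})

test_that("degenerate bins are handled: constant response, perfect fit, tiny bins", {
  joined <- data.frame(reads_22g = c(1, 2, 3, 4, 10, 20, 30, 40),
                       reads_mrna = c(5, 5, 5, 5, 1, 10, 100, 1000))
  scheme <- bin_by_expression(joined$reads_22g, 2)
  out <- bin_slope_test(joined, scheme)
  expect_equal(out$slope[1], 0)          # constant mRNA
  expect_equal(out$p[1], 1)
  expect_gt(out$slope[2], 0)
  # a perfect linear relation has p ~ 0
  j2 <- data.frame(reads_22g = 10^(1:5) - 1, reads_mrna = 10^(2 * (1:5)) - 1)
  s2 <- bin_by_expression(j2$reads_22g, 1)
  o2 <- bin_slope_test(j2, s2)
  expect_equal(o2$slope[1], 2)
  expect_equal(o2$p[1], 0)
  # a constant predictor (bin 1) or fewer than 3 genes (bin 2) is na
  j3 <- data.frame(reads_22g = c(5, 5, 5, 10, 20),
                   reads_mrna = c(1, 2, 3, 4, 5))
  s3 <- bin_by_expression(j3$reads_22g, 2)
  o3 <- bin_slope_test(j3, s3)
  expect_identical(o3$status, c("na", "na"))
})

test_that("the silencing signature appears only in the top 22G bin", {
  j <- simulate_expression_association(seed = 83)
  scheme <- bin_by_expression(j$reads_22g, 20)
  st <- bin_slope_test(j, scheme)
  expect_identical(st$status, rep("ok", 20))
  expect_lt(st$slope[20], 0)
  expect_lt(st$p[20], 0.01)
  neg_sig <- which(st$slope < 0 & st$p < 0.01)
  expect_true(20 %in% neg_sig)
  expect_lte(length(setdiff(neg_sig, 20)), 2)
})

test_that("bins with a single category are na; identical values are ns", {
  joined <- data.frame(reads_22g = 1:40, reads_mrna = rep(5, 40))
  scheme <- bin_by_expression(joined$reads_22g, 4)
  flag <- c(rep(TRUE, 10), rep(c(TRUE, FALSE), 15))
  out <- bin_group_compare(joined, scheme, flag)
  expect_identical(out$verdict[1], "na")          # all targets
  expect_true(all(out$verdict[2:4] == "ns"))      # identical mRNA values
  expect_identical(sum(!is.na(out$q)), 3L)        # Bonferroni over eligible
})

test_that("planted silencing and licensing targets separate in opposite directions", {
  j <- simulate_expression_association(seed = 84)
  scheme <- bin_by_expression(j$reads_22g, 20)
  wago <- bin_group_compare(j, scheme, j$wago)
  elig <- wago$verdict != "na"
  sig_lower <- wago$verdict == "significant" &
    wago$direction == "lower_in_targets"
  expect_gte(sum(sig_lower) / sum(elig), 0.8)
  csr <- bin_group_compare(j, scheme, j$csr)
  sig_csr <- csr$verdict == "significant"
  expect_true(any(sig_csr))
  expect_true(all(csr$direction[sig_csr] == "higher_in_targets"))
})

test_that("matched-abundance comparison flags only the planted bin", {
  set.seed(85)
  n <- 400
  mk <- function() data.frame(reads_22g = rlnorm(n, 3, 1),
                              reads_mrna = rlnorm(n, 4, 1))
  a <- mk(); b <- mk()
  same <- matched_abundance_compare(a, b, 10)
  expect_true(all(same$verdict %in% c("ns", "na")))
  # scale one sex's 22G tenfold in the lowest mRNA bin only
  pooled <- bin_by_expression(c(a$reads_mrna, b$reads_mrna), 10)
  bin_b <- pooled$bin[(n + 1):(2 * n)]
  b2 <- b
  b2$reads_22g[bin_b == 1] <- b2$reads_22g[bin_b == 1] * 10
  shifted <- matched_abundance_compare(a, b2, 10)
  expect_identical(shifted$verdict[1], "significant")
  expect_identical(shifted$direction[1], "lower_in_a")
  expect_true(all(shifted$verdict[-1] %in% c("ns", "na")))
})

test_that("the null rate of significant matched-abundance bins honours alpha", {
  set.seed(86)
  n_sig <- 0L
  for (i in 1:50) {
    a <- data.frame(reads_22g = rlnorm(120, 3, 1),
                    reads_mrna = rlnorm(120, 4, 1))
    b <- data.frame(reads_22g = rlnorm(120, 3, 1),
                    reads_mrna = rlnorm(120, 4, 1))
    out <- matched_abundance_compare(a, b, 8)
    n_sig <- n_sig + sum(out$verdict == "significant")
  }
  # Bonferroni at q < 0.01 keeps the family-wise rate near 1% per repeat
  expect_lte(n_sig, 5L)
})
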