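test_that("identical libraries get unit size factors", {
  m <- cbind(a = c(3, 10, 25), b = c(3, 10, 25))
  rownames(m) <- paste0("f", 1:3)
  expect_equal(unname(size_factors(m)), c(1, 1))
})

test_that("a doubled library splits the scaling symmetrically", {
  m <- cbind(a = c(10, 20, 30), b = c(20, 40, 60))
  rownames(m) <- paste0("f", 1:3)
  sf <- size_factors(m)
  expect_equal(unname(sf), c(1 / sqrt(2), sqrt(2)))
  norm <- normalize_counts(m, sf)
  expect_equal(norm[, "a"], norm[, "b"])
})

test_that("rescaling one library leaves the others' normalized counts proportional", {
  set.seed(61)
  m <- matrix(rpois(50 * 4, 40), 50, 4,
              dimnames = list(sprintf("f%02d", 1:50), letters[1:4]))
  m2 <- m
  m2[, 2] <- m2[, 2] * 3
  n1 <- normalize_counts(m)
  n2 <- normalize_counts(m2)
  ratio <- n2[, c(1, 3, 4)] / n1[, c(1, 3, 4)]
  expect_lt(diff(range(ratio)), 1e-9)  # a single global constant
})

test_that("size factors need a feature detected in every sample", {
  m <- cbind(a = c(5, 0), b = c(0, 7))
  rownames(m) <- c("f1", "f2")
  expect_error(size_factors(m), "nonzero count in every sample")
})

test_that("the estimator matches the DESeq2 implementation", {
  skip_if_not_installed("DESeq2")
  set.seed(62)
  m <- matrix(rnbinom(200 * 5, mu = 60, size = 4), 200, 5,
              dimnames = list(sprintf("f%03d", 1:200), letters[1:5]))
  expect_equal(unname(size_factors(m)),
               unname(DESeq2::estimateSizeFactorsForMatrix(m)))
})

test_that("identical groups produce fold 1 and no calls", {
  m <- matrix(rep(c(8, 10, 12), 10), nrow = 10, byrow = TRUE)
  rownames(m) <- sprintf("f%02d", 1:10)
  calls <- sex_bias_test(m, m)
  expect_true(all(calls$log2fc == 0))
  expect_false(any(calls$significant))
})

test_that("the rank test reproduces exact enumeration p-values", {
  expect_equal(suppressWarnings(
    stats::wilcox.test(c(1, 2, 3), c(4, 5, 6))$p.value), 0.1)
  set.seed(63)
  for (i in 1:12) {
    m <- sample(2:8, 1); n <- sample(2:8, 1)
    vals <- sample(seq(0.5, 200, by = 0.5), m + n)  # tie-free
    a <- vals[seq_len(m)]; b <- vals[-seq_len(m)]
    expect_equal(suppressWarnings(stats::wilcox.test(a, b)$p.value),
                 enum_wilcox_p(a, b))
  }
  # the calling route uses the same test per feature
  ga <- matrix(c(1, 2, 3), 1, dimnames = list("f1", NULL))
  gb <- matrix(c(4, 5, 6), 1, dimnames = list("f1", NULL))
  expect_equal(sex_bias_test(ga, gb)$p, 0.1)
})

test_that("the four-fold threshold is enforced on top of the adjusted p", {
  set.seed(64)
  jit <- function(center, n) center + seq(-0.2, 0.2, length.out = n)
  ga <- rbind(f1 = jit(3.5, 8), f2 = jit(3.5, 8))
  # f1 sits exactly at 4-fold (with the 0.5 pseudocount), f2 just below
  gb <- rbind(f1 = jit(15.5, 8), f2 = jit(15.1, 8))
  calls <- sex_bias_test(ga, gb)
  expect_true(all(calls$padj < 0.01))
  expect_identical(calls$significant, c(TRUE, FALSE))
  expect_equal(calls$log2fc[1], 2)
})

test_that("groups need at least two replicates", {
  m1 <- matrix(1:5, 5, 1, dimnames = list(paste0("f", 1:5), NULL))
  m3 <- matrix(1, 5, 3, dimnames = list(paste0("f", 1:5), NULL))
  expect_error(sex_bias_test(m1, m3), "at least 2 replicates")
})

test_that("tissue attribution follows the three-way truth table", {
  mk <- function(sig, dir) {
    structure(data.frame(feature_id = "f", log2fc = 0, p = 0.5, padj = 0.5,
                         significant = sig, direction = dir),
              class = c("diff_calls", "data.frame"))
  }
  cases <- list(
    # sig_hm, dir_hm, sig_mf, dir_mf, sig_hf, dir_hf, expected
    list(TRUE, "higher_in_a", TRUE, "higher_in_b", FALSE, "none",
         "female_germline_biased"),
    list(TRUE, "higher_in_b", TRUE, "higher_in_a", FALSE, "none",
         "male_germline_biased"),
    list(TRUE, "higher_in_a", FALSE, "none", TRUE, "higher_in_a",
         "female_somatic_biased"),
    list(TRUE, "higher_in_b", FALSE, "none", TRUE, "higher_in_b",
         "male_somatic_biased"),
    list(TRUE, "higher_in_a", FALSE, "none", FALSE, "none",
         "gonad_biased_unresolved"),
    list(FALSE, "none", TRUE, "higher_in_b", FALSE, "none", "not_biased"),
    list(FALSE, "none", FALSE, "none", TRUE, "higher_in_a", "not_biased"),
    list(FALSE, "none", FALSE, "none", FALSE, "none", "not_biased"))
  for (cs in cases) {
    out <- attribute_tissue(mk(cs[[1]], cs[[2]]), mk(cs[[3]], cs[[4]]),
                            mk(cs[[5]], cs[[6]]))
    expect_identical(as.character(out$category), cs[[7]])
  }
  # germline takes precedence when all three comparisons are significant
  out <- attribute_tissue(mk(TRUE, "higher_in_a"), mk(TRUE, "higher_in_b"),
                          mk(TRUE, "higher_in_a"))
  expect_identical(as.character(out$category), "female_germline_biased")
})

test_that("piRNA-style attribution uses the sex comparison alone", {
  calls <- structure(
    data.frame(feature_id = c("p1", "p2", "p3"), log2fc = c(-3, 3, 0),
               p = 0, padj = 0, significant = c(TRUE, TRUE, FALSE),
               direction = c("higher_in_a", "higher_in_b", "none")),
    class = c("diff_calls", "data.frame"))
  out <- attribute_tissue(calls, germline_only = TRUE)
  expect_identical(as.character(out$category),
                   c("female_germline_biased", "male_germline_biased",
                     "not_biased"))
})

test_that("mismatched feature universes are rejected", {
  mk <- function(ids) structure(
    data.frame(feature_id = ids, log2fc = 0, p = 1, padj = 1,
               significant = FALSE, direction = "none"),
    class = c("diff_calls", "data.frame"))
  expect_error(attribute_tissue(mk("f1"), mk("f2"), mk("f1")),
               "same features")
})

test_that("the NB route recovers planted ten-fold effects at 3v3", {
  skip_if_not_installed("DESeq2")
  sim <- simulate_sex_counts(n_features = 1000L, n_biased = 30L, seed = 65)
  calls <- sex_bias_test(sim$group_a, sim$group_b, method = "deseq2")
  called <- calls$feature_id[calls$significant]
  expect_gte(mean(sim$biased %in% called), 0.9)
  expect_lte(sum(!(called %in% sim$biased)), max(1, 0.05 * length(called)))
})

test_that("the rank route cannot reach a 1% FDR with three replicates per group", {
  # the most extreme exact two-sided p for 3v3 is 2/choose(6,3) = 0.1,
  # and BH-adjusted p >= raw p, so even complete separation yields no call
  sim <- simulate_sex_counts(n_features = 200L, n_biased = 20L, fold = 1000,
                             seed = 66)
  calls <- sex_bias_test(normalize_counts(sim$group_a + 1L),
                         normalize_counts(sim$group_b + 1L))
  expect_gte(min(calls$p), 0.1 - 1e-12)
  expect_identical(sum(calls$significant), 0L)
})
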