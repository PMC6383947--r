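adapter <- cascade_config()$adapter

test_that("a full adapter after the insert is removed", {
  insert <- paste0(strrep("ACGTA", 4), "GT")  # 22 nt
  tf <- trim_and_filter(c(r = paste0(insert, adapter)), cascade_config())
  expect_identical(tf$kept$sequence, insert)
})

test_that("inserts outside the 21-34 nt window are discarded with a reason", {
  inserts <- vapply(c(18L, 21L, 34L, 35L), function(n) {
    substr(strrep("ACGTG", 8), 1, n)
  }, character(1))
  reads <- stats::setNames(paste0(inserts, adapter), paste0("r", c(18, 21, 34, 35)))
  tf <- trim_and_filter(reads, cascade_config())
  expect_setequal(tf$kept$read_id, c("r21", "r34"))
  expect_identical(tf$discarded$reason[tf$discarded$read_id == "r18"], "too_short")
  expect_identical(tf$discarded$reason[tf$discarded$read_id == "r35"], "too_long")
})

test_that("reads without an adapter occurrence are kept untrimmed", {
  r <- random_with_no_adapter <- strrep("CA", 12)  # 24 nt, no adapter inside
  tf <- trim_and_filter(c(x = r), cascade_config())
  expect_identical(tf$kept$sequence, r)
})

test_that("a truncated adapter at the 3' end is still removed", {
  insert <- substr(strrep("ACGTG", 7), 1, 25)
  read <- paste0(insert, substr(adapter, 1, 8))  # read ends mid-adapter
  tf <- trim_and_filter(c(x = read), cascade_config())
  expect_identical(tf$kept$sequence, insert)
})

test_that("exact substrings align sense and reverse complements antisense", {
  set.seed(21)
  ref <- c(refA = random_dna(500))
  q <- substr(ref, 101, 122)
  hit <- align_k_mismatch(q, ref, k = 0)
  expect_identical(hit$offset, 100L)
  expect_identical(hit$strand, "sense")
  expect_identical(hit$mismatches, 0L)
  hit_rc <- align_k_mismatch(reverse_complement(q), ref, k = 0)
  expect_identical(hit_rc$offset, 100L)
  expect_identical(hit_rc$strand, "antisense")
})

test_that("ties break by reference order, then offset, then sense strand", {
  set.seed(22)
  q <- random_dna(22)
  filler <- function(n) random_dna(n)
  refs <- c(first = paste0(filler(50), q, filler(30)),
            second = paste0(q, filler(60)))
  hit <- align_k_mismatch(q, refs, k = 0)
  expect_identical(hit$reference_id, "first")   # declaration order wins
  ref2 <- c(r = paste0(filler(10), q, filler(5), q, filler(10)))
  expect_identical(align_k_mismatch(q, ref2, k = 0)$offset, 10L)  # leftmost
  # a reverse-complement palindrome matches both strands at one offset
  half <- random_dna(11)
  pal <- paste0(half, reverse_complement(half))
  ref3 <- c(r = paste0(filler(10), pal, filler(10)))
  expect_identical(align_k_mismatch(pal, ref3, k = 0)$strand, "sense")
  # antisense at a smaller offset beats sense at a larger one
  ref4 <- c(r = paste0(reverse_complement(q), filler(5), q))
  h4 <- align_k_mismatch(q, ref4, k = 0)
  expect_identical(h4$strand, "antisense")
  expect_identical(h4$offset, 0L)
})

test_that("N in a read counts as a mismatch at every position", {
  set.seed(23)
  ref <- c(r = random_dna(200))
  q <- substr(ref, 51, 72)
  substr(q, 5, 5) <- "N"
  expect_null(align_k_mismatch(q, ref, k = 0))
  hit <- align_k_mismatch(q, ref, k = 1)
  expect_identical(hit$mismatches, 1L)
  expect_identical(hit$offset, 50L)
})

test_that("the scan agrees with a brute-force oracle at k = 0, 1, 2", {
  set.seed(24)
  ref <- c(ref2kb = random_dna(2000))
  for (i in 1:100) {
    L <- sample(21:30, 1)
    q <- if (i %% 2 == 0) {
      random_dna(L)
    } else {
      off <- sample(2000 - L, 1)
      s <- substr(ref, off, off + L - 1)
      pos <- sample(L, sample(0:3, 1))
      if (length(pos)) {
        substring(s, pos, pos) <- sample(c("A", "C", "G", "T"), length(pos),
                                         replace = TRUE)
      }
      if (i %% 3 == 0) reverse_complement(s) else s
    }
    prof <- oracle_profiles(q, ref[[1]])
    for (k in 0:2) {
      expected <- oracle_best_hit(prof, k)
      got <- align_k_mismatch(q, ref, k)
      if (is.null(expected)) {
        expect_null(got)
      } else {
        expect_identical(got$offset, as.integer(expected$offset))
        expect_identical(got$strand, expected$strand)
        expect_identical(got$mismatches, as.integer(expected$mismatches))
      }
    }
  }
})

test_that("the first matching stage claims the read", {
  b <- test_bundle()
  # a genome read embedded into the sensor must be claimed by the sensor stage
  exon <- b$annotation[b$annotation$kind == "gene_coding_exon", ][1, ]
  read <- substr(b$genome[[exon$chrom]], exon$start + 1, exon$start + 22)
  b2 <- b
  b2$sensor_gfp <- c(sensor_gfp = paste0(read, substr(b$sensor_gfp, 23, 720)))
  res <- run_cascade(c(q = paste0(read, cascade_config()$adapter)), b2)
  expect_identical(res$assignments$compartment, "sensor_gfp")
  res_orig <- run_cascade(c(q = paste0(read, cascade_config()$adapter)), b)
  expect_identical(res_orig$assignments$compartment, "genome")
})

test_that("an empty read set produces all-zero totals", {
  res <- run_cascade(character(0), test_bundle())
  expect_true(all(res$totals == 0))
  expect_identical(res$n_input, 0L)
})

test_that("a stage without reference sequences is a configuration error", {
  b <- test_bundle()
  b$hairpins <- character(0)
  expect_error(run_cascade(c(x = strrep("ACGTA", 5)), b),
               "configuration error")
})

test_that("compartments partition the input and recover the ground truth", {
  b <- test_bundle()
  reads <- simulate_reads(b, read_mixture(n_reads = 1500, seed = 31))
  res <- run_cascade(reads, b)
  expect_identical(sum(res$totals), nrow(reads))
  a <- res$assignments
  expect_identical(nrow(a) + nrow(res$discarded), nrow(reads))
  expect_true(all(a$compartment == TRUTH_TO_COMPARTMENT[a$truth_label]))
})

test_that("trigger reads between SNPs are misassigned to the sensor, spanning reads never", {
  cfg <- reference_config(snp_phase = 10L)
  b <- build_reference(cfg, seed = 13)
  # deliberately ambiguous: 21 nt windows of the trigger that span no SNP
  mx_amb <- read_mixture(c(gfp_primary = 1), n_reads = 30, seed = 14,
                         lengths = list(gfp_primary = 21L),
                         ambiguous_primary = TRUE)
  res_amb <- run_cascade(simulate_reads(b, mx_amb), b)
  expect_true(all(res_amb$assignments$compartment == "sensor_gfp"))
  # SNP-spanning trigger reads can never match the sensor at k = 0
  mx <- read_mixture(c(gfp_primary = 1), n_reads = 30, seed = 15)
  res <- run_cascade(simulate_reads(b, mx), b)
  expect_true(all(res$assignments$compartment == "recoded_gfp"))
})
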