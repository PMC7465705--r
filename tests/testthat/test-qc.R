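# QC filters: allele statistics, exact HWE test, filter semantics,
# LD pruning.

test_that("allele statistics count alleles and calls correctly", {
  s <- allele_stats(c(0, 0, 1, 2))
  expect_equal(s$maf, 0.375)        # alt freq 3/8
  expect_equal(s$call_rate, 1.0)
  expect_equal(unname(s$counts), c(2L, 1L, 1L))
  expect_equal(allele_stats(c(0, 0, 0, 0))$maf, 0)
  s <- allele_stats(c(0, NA, 2))
  expect_equal(s$call_rate, 2 / 3)
  s <- allele_stats(c(NA, NA))
  expect_true(is.na(s$maf))
  expect_equal(s$call_rate, 0)
})

test_that("exact HWE test equals the enumeration oracle", {
  # the spotlight tables
  expect_equal(hwe_test(5, 0, 5), hwe_enum_oracle(5, 0, 5), tolerance = 1e-12)
  expect_equal(hwe_test(0, 0, 100), 1)            # monomorphic
  expect_gte(hwe_test(25, 50, 25), 0.5)           # perfect HWE proportions
  # random sweep of tables
  set.seed(77)
  for (i in 1:200) {
    n <- sample(1:40, 1)
    k <- stats::rmultinom(1, n, c(0.4, 0.3, 0.3))
    expect_equal(hwe_test(k[1], k[2], k[3]),
                 hwe_enum_oracle(k[1], k[2], k[3]), tolerance = 1e-12)
  }
  expect_error(hwe_test(0, 0, 0), "must be > 0")
})

test_that("filters remove SNPs per criterion with samples filtered first", {
  set.seed(5)
  n <- 60
  m <- 30
  dos <- matrix(rbinom(n * m, 2, 0.3), n, m)
  dos[, 2] <- 0                              # monomorphic -> maf filter
  dos[sample(2:n, 3), 3] <- NA               # call rate 0.95 -> <= 0.97 fails
  dos[, 4] <- rep(c(0, 2), n / 2)            # extreme HWE deviation
  G <- genotype_matrix(dos, toy_snps(m), samples = sprintf("i%03d", 1:n))
  # one sample with very low call rate; it must go before SNP stats
  G$dosage[1, 1:20] <- NA
  res <- apply_filters(G, qc_thresholds())
  expect_equal(res$report$samples_removed_call_rate, 1L)
  expect_true("i001" %in% res$report$removed_samples)
  expect_true("s002" %in% res$report$removed_snps)   # monomorphic
  expect_true("s003" %in% res$report$removed_snps)   # call rate 0.95 <= 0.97
  expect_true("s004" %in% res$report$removed_snps)   # HWE
  expect_false("s001" %in% res$report$removed_snps)
  # idempotence
  res2 <- apply_filters(res$G, qc_thresholds())
  expect_equal(res2$G$dosage, res$G$dosage)
  expect_equal(res2$report$samples_removed_call_rate, 0L)
  # disabled thresholds leave G unchanged
  off <- qc_thresholds(maf_min = NULL, snp_call_rate_min = NULL,
                       hwe_p_min = NULL, sample_call_rate_min = NULL)
  expect_equal(apply_filters(G, off)$G$dosage, G$dosage)
})

test_that("boundary semantics: a SNP exactly at the threshold is removed", {
  # call rate exactly 0.97 on 100 samples (3 missing); enough SNPs that the
  # affected samples stay above the sample call-rate threshold
  set.seed(6)
  dos <- matrix(rbinom(100 * 30, 2, 0.4), 100, 30)
  dos[1:3, 1] <- NA
  G <- genotype_matrix(dos, toy_snps(30), samples = sprintf("i%03d", 1:100))
  strict <- apply_filters(G, qc_thresholds(hwe_p_min = NULL))
  expect_true("s001" %in% strict$report$removed_snps)
  lax <- apply_filters(G, qc_thresholds(hwe_p_min = NULL,
                                        strict_boundaries = FALSE))
  expect_false("s001" %in% lax$report$removed_snps)
})

test_that("LD pruning keeps one representative per correlated set", {
  set.seed(8)
  n <- 80
  base <- rbinom(n, 2, 0.4)
  dos <- cbind(base, base, base, rbinom(n, 2, 0.3), rbinom(n, 2, 0.3))
  G <- genotype_matrix(dos, toy_snps(5), samples = sprintf("i%03d", 1:n))
  kept <- ld_prune(G, window = 5, step = 2, r2_max = 0.2)
  expect_equal(sum(kept %in% 1:3), 1L)    # three mutual duplicates -> one
  # post-condition: kept set has max pairwise r2 <= r2_max (brute force)
  X <- G$dosage[, kept, drop = FALSE]
  cc <- cor(X)^2
  diag(cc) <- 0
  expect_lte(max(cc), 0.2)
  # independent SNPs survive
  set.seed(9)
  G2 <- toy_genotypes(400, 12, seed = 10)
  expect_equal(ld_prune(G2, window = 6, step = 3, r2_max = 0.9), 1:12)
  expect_warning(k <- ld_prune(G2, window = 1), "window")
  expect_equal(k, 1:12)
})

test_that("pruning is deterministic and windows restart per chromosome", {
  set.seed(11)
  n <- 60
  b1 <- rbinom(n, 2, 0.4)
  b2 <- rbinom(n, 2, 0.4)
  dos <- cbind(b1, b1, b2, b2)
  snps <- toy_snps(4)
  snps$chrom <- c("1", "1", "2", "2")
  G <- genotype_matrix(dos, snps, samples = sprintf("i%03d", 1:n))
  k1 <- ld_prune(G, window = 4, step = 2, r2_max = 0.2)
  k2 <- ld_prune(G, window = 4, step = 2, r2_max = 0.2)
  expect_identical(k1, k2)
  expect_equal(length(intersect(k1, 1:2)), 1L)
  expect_equal(length(intersect(k1, 3:4)), 1L)
})
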