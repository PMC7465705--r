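# Permutation null of maximum peak heights and QTL calling.

perm_fixture <- function(seed = 51, n = 80, m = 300) {
  sp <- sim_spec(n_samples = n, n_snps = m, n_chrom = 3,
                 h2_polygenic = 0.2, seed = seed)
  G <- simulate_genotypes(sp)
  ph <- simulate_phenotype(G, sp)
  K <- compute_grm(G)
  W <- matrix(1, n, 1)
  fit <- fit_null_reml(ph$value, W, K)
  list(G = G, fit = fit, y = ph$value, K = K, W = W)
}

test_that("constant phenotype gives an all-zero null and threshold zero", {
  fx <- perm_fixture()
  fitc <- suppressWarnings(fit_null_reml(rep(1.7, 80), fx$W, fx$K))
  pn <- suppressWarnings(permutation_null(fx$G, fitc, B = 25, seed = 1))
  expect_true(all(abs(pn$heights) < 1e-8))
  expect_equal(pn$threshold, 0, tolerance = 1e-8)
})

test_that("the null distribution is reproducible bit-exactly by seed", {
  fx <- perm_fixture()
  p1 <- permutation_null(fx$G, fx$fit, B = 30, seed = 7)
  p2 <- permutation_null(fx$G, fx$fit, B = 30, seed = 7)
  expect_identical(p1$heights, p2$heights)
  p3 <- permutation_null(fx$G, fx$fit, B = 30, seed = 8)
  expect_false(identical(p1$heights, p3$heights))
  # threshold is the type-7 95th percentile and sits inside the sample
  expect_equal(p1$threshold,
               unname(quantile(p1$heights, 0.95, type = 7)))
  expect_gte(p1$threshold, min(p1$heights))
  expect_lte(p1$threshold, max(p1$heights))
})

test_that("few permutations trigger the instability warning", {
  fx <- perm_fixture()
  expect_warning(permutation_null(fx$G, fx$fit, B = 10, seed = 1),
                 "unstable")
})

test_that("QTL calling is strict at the threshold and SNP-anchored", {
  snps <- toy_snps(20, start = 1000L, step = 100L)
  peaks <- data.frame(chrom = "1",
                      left = c(1050, 2350), right = c(1720, 2760),
                      apex_pos = c(1400, 2500), height = c(10, 3),
                      n_snps = c(7L, 5L), boundary = FALSE,
                      stringsAsFactors = FALSE)
  q <- call_qtls(peaks, list(threshold = 5), snps, trait = "tr")
  expect_equal(nrow(q), 1L)
  # SNP-anchored bounds: leftmost/rightmost SNP inside (1050, 1720)
  expect_equal(q$start, 1100L)
  expect_equal(q$end, 1700L)
  expect_equal(q$n_snps, 7L)
  expect_equal(q$trait, "tr")
  # height exactly equal to the threshold is not a QTL
  q2 <- call_qtls(peaks, list(threshold = 10), snps)
  expect_equal(nrow(q2), 0L)
  # empty peaks give an empty QTL frame
  expect_equal(nrow(call_qtls(peaks[0, ], list(threshold = 1), snps)), 0L)
})

test_that("observed-data spline path and engine produce coherent QTLs", {
  # plant a strong QTL (15% of variance) so the observed peak clears the
  # null comfortably at this problem size
  n <- 300
  sp <- sim_spec(n_samples = n, n_snps = 400, n_chrom = 4,
                 h2_polygenic = 0.1, noise_sd = 1,
                 qtl_list = data.frame(snp_index = 150,
                                       beta = qtl_beta(0.15, 0.1, 1)),
                 seed = 53)
  G <- simulate_genotypes(sp)
  ph <- simulate_phenotype(G, sp)
  K <- compute_grm(G)
  fit <- fit_null_reml(ph$value, matrix(1, n, 1), K)
  sc <- gwas_scan(G, fit)
  peaks <- do.call(rbind, lapply(unique(G$snps$chrom), function(chr) {
    idx <- G$snps$chrom == chr
    call_peaks(fit_spline(G$snps$pos[idx], sc$wald[idx], chrom = chr))
  }))
  pn <- permutation_null(G, fit, B = 60, seed = 54)
  q <- call_qtls(peaks, pn, G$snps)
  expect_gte(nrow(q), 1L)
  causal <- G$snps[150, ]
  hit <- any(q$chrom == causal$chrom & q$start <= causal$pos &
               q$end >= causal$pos)
  expect_true(hit)
  # contained SNP ids are consistent with the bounds
  ids <- strsplit(q$snp_ids[1], ",")[[1]]
  pos <- G$snps$pos[match(ids, G$snps$snp_id)]
  expect_true(all(pos >= q$start[1] & pos <= q$end[1]))
  expect_equal(length(ids), q$n_snps[1])
})
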