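# Synthetic-data generator: LD-block structure, planted effects,
# polygenic background, reproducibility.

test_that("generator output is a pure function of the spec", {
  sp <- sim_spec(n_samples = 50, n_snps = 40, n_chrom = 2, seed = 33,
                 missing_rate = 0.02)
  G1 <- simulate_genotypes(sp)
  G2 <- simulate_genotypes(sp)
  expect_identical(G1$dosage, G2$dosage)
  ph1 <- simulate_phenotype(G1, sp)
  ph2 <- simulate_phenotype(G2, sp)
  expect_identical(ph1$value, ph2$value)
  expect_equal(mean(is.na(G1$dosage)), 0.02, tolerance = 0.5)
})

test_that("within_block_r2 = 1 with mutation off gives perfect block LD", {
  sp <- sim_spec(n_samples = 120, n_snps = 30, n_chrom = 1,
                 block_length = 10, within_block_r2 = 1, seed = 4)
  G <- simulate_genotypes(sp)
  for (b in list(1:10, 11:20, 21:30)) {
    cc <- cor(G$dosage[, b])^2
    expect_true(all(abs(cc - 1) < 1e-12))
  }
})

test_that("block_length = 1 gives essentially independent SNPs", {
  rs <- numeric(10)
  for (s in 1:10) {
    sp <- sim_spec(n_samples = 200, n_snps = 30, n_chrom = 1,
                   block_length = 1, seed = 100 + s)
    G <- simulate_genotypes(sp)
    cc <- cor(G$dosage)
    rs[s] <- mean(abs(cc[upper.tri(cc)]))
  }
  expect_lt(mean(rs), 3 / sqrt(200))
})

test_that("realized MAFs stay inside the requested range", {
  sp <- sim_spec(n_samples = 300, n_snps = 200, n_chrom = 2,
                 maf_range = c(0.1, 0.4), within_block_r2 = 0.5, seed = 12)
  G <- simulate_genotypes(sp)
  freq <- colMeans(G$dosage) / 2
  maf <- pmin(freq, 1 - freq)
  expect_true(all(maf >= 0.1 - 1e-9 & maf <= 0.4 + 1e-9))
})

test_that("phenotype variance components behave as specified", {
  # no QTLs, h2 = 0: var(y) ~ noise_sd^2
  v <- sapply(1:10, function(s) {
    sp <- sim_spec(n_samples = 400, n_snps = 20, h2_polygenic = 0,
                   noise_sd = 2, seed = 200 + s)
    var(simulate_phenotype(simulate_genotypes(sp), sp)$value)
  })
  expect_equal(mean(v), 4, tolerance = 3 * sd(v) / sqrt(10) / 4 + 0.05)
  # noise_sd = 0, one QTL, h2 = 0: y is the standardized causal dosage
  sp <- sim_spec(n_samples = 100, n_snps = 20, h2_polygenic = 0,
                 noise_sd = 0,
                 qtl_list = data.frame(snp_index = 7, beta = 1.5), seed = 5)
  G <- simulate_genotypes(sp)
  ph <- simulate_phenotype(G, sp)
  expect_equal(abs(cor(ph$value, G$dosage[, 7])), 1, tolerance = 1e-12)
  vc <- attr(ph, "variance_components")
  expect_equal(unname(vc["v_qtl"]), 2.25)
  expect_equal(unname(vc["vg"]), 0)
})

test_that("spec validation rejects inconsistent requests", {
  expect_error(sim_spec(qtl_list = data.frame(snp_index = 5000, beta = 1),
                        n_snps = 100), "out of range")
  expect_error(sim_spec(maf_range = c(0, 0.5)))
  expect_error(sim_spec(h2_polygenic = 1))
  # variance fractions are a partition of the total by construction
  sp <- sim_spec(h2_polygenic = 0.3, noise_sd = 2,
                 qtl_list = data.frame(snp_index = c(1, 2),
                                       beta = c(0.5, 0.4)))
  G <- simulate_genotypes(sim_spec(n_samples = 50, n_snps = 10, seed = 1))
  vc <- attr(simulate_phenotype(G, sim_spec(n_samples = 50, n_snps = 10,
                                            h2_polygenic = 0.3, seed = 1)),
             "variance_components")
  expect_equal(unname(vc["vg"] + vc["ve"]), unname(vc["total"]),
               tolerance = 1e-12)
})

test_that("null generator yields uniform GWAS p-values", {
  # no QTLs, h2 = 0: scan p-values vs U(0,1), KS at alpha = 0.01
  nonsig <- 0L
  n_seeds <- 25L
  for (s in seq_len(n_seeds)) {
    sp <- sim_spec(n_samples = 120, n_snps = 300, n_chrom = 3,
                   block_length = 1,   # independent SNPs: KS assumes iid
                   h2_polygenic = 0, seed = 300 + s)
    G <- simulate_genotypes(sp)
    ph <- simulate_phenotype(G, sp)
    K <- compute_grm(G)
    W <- matrix(1, 120, 1)
    # h2 = 0: the variance ratio sits at the search boundary by design
    fit <- suppressWarnings(fit_null_reml(ph$value, W, K))
    sc <- gwas_scan(G, fit)
    ks <- suppressWarnings(stats::ks.test(sc$p, "punif"))
    nonsig <- nonsig + (ks$p.value > 0.01)
  }
  expect_gte(nonsig, ceiling(0.88 * n_seeds))
})
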