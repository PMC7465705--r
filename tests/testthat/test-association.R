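# Mixed-model association: GRM, PCA covariates, REML, Wald scan, simpleM,
# genomic inflation.

test_that("GRM is symmetric with unit-scale diagonal and honors duplicates", {
  G <- toy_genotypes(100, 500, seed = 21)
  K <- compute_grm(G)
  expect_equal(K, t(K))
  expect_equal(mean(diag(K)), 1, tolerance = 0.1)
  # two identical samples: off-diagonal equals the shared diagonal
  G2 <- G
  G2$dosage[2, ] <- G2$dosage[1, ]
  K2 <- compute_grm(G2)
  expect_equal(K2[1, 2], K2[1, 1], tolerance = 1e-12)
  expect_equal(K2[2, 2], K2[1, 1], tolerance = 1e-12)
  # monomorphic-only input errors
  Gm <- genotype_matrix(matrix(1, 5, 3), toy_snps(3),
                        samples = paste0("i", 1:5))
  expect_error(compute_grm(Gm), "polymorphic")
})

test_that("PC covariates are orthogonal, sign-fixed and track structure", {
  G <- toy_genotypes(60, 200, seed = 22)
  W <- pca_covariates(G, k = 5)
  expect_equal(dim(W), c(60L, 6L))
  cp <- crossprod(W[, -1])
  expect_true(max(abs(cp - diag(diag(cp)))) < 1e-8)
  # duplicated dataset rows give duplicated score rows
  G2 <- G
  G2$dosage[5, ] <- G2$dosage[4, ]
  W2 <- pca_covariates(G2, k = 3)
  expect_equal(W2[5, ], W2[4, ], tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_error(pca_covariates(toy_genotypes(4, 10), k = 5), "smaller")
  # two divergent populations separate on PC1 (independent SNPs within
  # each population, so the split dominates the leading component)
  sa <- sim_spec(n_samples = 80, n_snps = 300, n_chrom = 3,
                 block_length = 1, seed = 71)
  sb <- sim_spec(n_samples = 80, n_snps = 300, n_chrom = 3,
                 block_length = 1, seed = 72)
  Ga <- simulate_genotypes(sa)
  Gb <- simulate_genotypes(sb)
  dos <- rbind(Ga$dosage, Gb$dosage)
  rownames(dos) <- sprintf("i%03d", 1:160)
  Gab <- genotype_matrix(dos, Ga$snps)
  Wab <- pca_covariates(Gab, k = 2)
  grp <- rep(c(0, 1), each = 80)
  expect_gt(abs(cor(Wab[, "PC1"], grp)), 0.9)
})

test_that("REML with identity kinship matches OLS residual variance", {
  set.seed(23)
  n <- 150
  W <- cbind(1, rnorm(n))
  y <- drop(W %*% c(2, 0.5)) + rnorm(n)
  # Vg and Ve are not separately identified when K = I; only their sum is.
  fit <- suppressWarnings(fit_null_reml(y, W, diag(n)))
  ols_var <- sum(lm.fit(W, y)$residuals^2) / (n - 2)
  expect_equal(fit$vg + fit$ve, ols_var, tolerance = 1e-3)
})

test_that("REML recovers heritability and shrinks under permutation", {
  sp <- sim_spec(n_samples = 250, n_snps = 500, n_chrom = 5,
                 h2_polygenic = 0.5, seed = 24)
  G <- simulate_genotypes(sp)
  ph <- simulate_phenotype(G, sp)
  K <- compute_grm(G)
  W <- matrix(1, 250, 1)
  fit <- fit_null_reml(ph$value, W, K)
  expect_gt(fit$h2, 0.15)
  expect_lt(fit$h2, 0.85)
  set.seed(25)
  perm_vg <- replicate(30, {
    fp <- suppressWarnings(fit_null_reml(sample(ph$value), W, K))
    fp$vg
  })
  expect_lt(median(perm_vg), fit$vg)
})

test_that("the scan matches dense GLS on the printed fixture", {
  fx <- printed_gls_fixture()
  fit <- make_null_fit(fx$y, fx$W, fx$K, vg = 0.4, ve = 0.8)
  sc <- gwas_scan(fx$G, fit)
  for (j in seq_len(nrow(fx$G$snps))) {
    o <- dense_gls_oracle(fx$y, fx$W, fx$G$dosage[, j], fx$K, 0.4, 0.8)
    expect_equal(sc$beta[j], o$beta, tolerance = 1e-8)
    expect_equal(sc$var_beta[j], o$var_beta, tolerance = 1e-8)
    expect_equal(sc$wald[j], o$wald, tolerance = 1e-8)
  }
})

test_that("with Vg = 0 the scan reduces to ordinary least squares", {
  set.seed(26)
  G <- toy_genotypes(40, 6, seed = 26)
  y <- rnorm(40)
  W <- matrix(1, 40, 1)
  fit <- make_null_fit(y, W, diag(40), vg = 0, ve = 1.3)
  sc <- gwas_scan(G, fit)
  for (j in 1:6) {
    cf <- coef(lm(y ~ G$dosage[, j]))
    expect_equal(sc$beta[j], unname(cf[2]), tolerance = 1e-8)
    # Var(beta) under known sigma^2 = ve
    xc <- G$dosage[, j] - mean(G$dosage[, j])
    expect_equal(sc$var_beta[j], 1.3 / sum(xc^2), tolerance = 1e-8)
  }
})

test_that("scan handles degenerate inputs and is order-invariant", {
  G <- toy_genotypes(50, 8, seed = 27)
  G$dosage[, 3] <- 1                     # monomorphic
  y <- rnorm(50)
  K <- compute_grm(toy_genotypes(50, 100, seed = 28))
  W <- matrix(1, 50, 1)
  fit <- suppressWarnings(fit_null_reml(y, W, K))
  sc <- gwas_scan(G, fit)
  expect_equal(sc$wald[3], 0)
  expect_equal(sc$p[3], 1)
  expect_true(sc$monomorphic[3])
  # constant phenotype: all betas and Wald statistics zero
  fitc <- suppressWarnings(fit_null_reml(rep(2, 50), W, K))
  scc <- gwas_scan(G, fitc)
  expect_true(all(abs(scc$beta) < 1e-8))
  expect_true(all(scc$wald < 1e-8))
  # sample-order permutation leaves records unchanged
  set.seed(29)
  o <- sample(50)
  Gp <- G[o, ]
  fitp <- make_null_fit(y[o], W[o, , drop = FALSE], K[o, o],
                        vg = fit$vg, ve = fit$ve)
  fit0 <- make_null_fit(y, W, K, vg = fit$vg, ve = fit$ve)
  expect_equal(gwas_scan(Gp, fitp)$wald, gwas_scan(G, fit0)$wald,
               tolerance = 1e-7)
  # p strictly decreasing in the Wald statistic
  w <- sort(unique(sc$wald[sc$wald > 0]))
  if (length(w) > 1) {
    p <- pchisq(w, 1, lower.tail = FALSE)
    expect_true(all(diff(p) < 0))
  }
})

test_that("simpleM collapses duplicates and preserves independence", {
  # all-duplicate block: m_eff = 1
  set.seed(30)
  base <- rbinom(200, 2, 0.4)
  dup <- genotype_matrix(matrix(base, 200, 12), toy_snps(12),
                         samples = sprintf("i%03d", 1:200))
  th <- simple_m(dup)
  expect_equal(th$m_eff, 1L)
  # threshold ratio is exactly 20
  expect_equal(th$suggestive_p / th$genomewide_p, 20)
  # independent SNPs: m_eff within 5% of m
  sp <- sim_spec(n_samples = 1500, n_snps = 150, n_chrom = 1,
                 block_length = 1, seed = 31)
  G <- simulate_genotypes(sp)
  th2 <- simple_m(G)
  expect_gte(th2$m_eff, ceiling(0.95 * 150))
  expect_lte(th2$m_eff, 150L)
})

test_that("genomic inflation is 1 for uniform p-values", {
  p <- seq(1e-6, 1 - 1e-6, length.out = 10001)
  expect_equal(genomic_inflation(p), 1, tolerance = 0.01)
  expect_equal(genomic_inflation(rep(0.5, 10)), 1, tolerance = 1e-12)
  expect_error(genomic_inflation(numeric(0)), "no p-values")
})
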