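# Shared fixture builders and independent oracles for the test suite.
# Everything is generated in code; the only stored file is the frozen
# smoothing-spline reference (spline_oracle_reference.tsv), computed with
# an independent reference implementation on the fixtures defined below.

# ---- small genotype fixtures -------------------------------------------

toy_snps <- function(m, chrom = "1", start = 1000L, step = 1000L) {
  data.frame(snp_id = sprintf("s%03d", seq_len(m)), chrom = chrom,
             pos = as.integer(start + (seq_len(m) - 1L) * step),
             ref_allele = "A", alt_allele = "G", stringsAsFactors = FALSE)
}

toy_genotypes <- function(n, m, seed = 1, maf = 0.3, chrom = "1") {
  set.seed(seed)
  dos <- matrix(rbinom(n * m, 2L, maf), n, m)
  genotype_matrix(dos, toy_snps(m, chrom = chrom),
                  samples = sprintf("i%03d", seq_len(n)))
}

# ---- spline oracle fixtures (mirrored in the frozen-reference script) ---

fx_line <- function() {
  x <- seq(0, 10, length.out = 20)
  list(name = "line", x = x, y = 2 + 0.5 * x, lambda = 1e-2)
}

fx_sine <- function() {
  set.seed(421)
  x <- seq(0, 2 * pi, length.out = 200)
  list(name = "sine", x = x, y = sin(x) + rnorm(200, 0, 0.1), lambda = 1e-4)
}

fx_twobump <- function() {
  set.seed(422)
  x <- seq(0, 10, length.out = 150)
  y <- dnorm(x, 3, 0.5) + dnorm(x, 7, 0.5) + rnorm(150, 0, 0.02)
  list(name = "twobump", x = x, y = y, lambda = 1e-5)
}

load_spline_reference <- function() {
  read.table(test_path("spline_oracle_reference.tsv"), header = TRUE,
             sep = "\t", stringsAsFactors = FALSE)
}

# ---- dense GLS oracle ---------------------------------------------------

# Brute-force generalized least squares of y on [W | x] under
# Sigma = vg K + ve I; returns beta, var(beta) and the Wald statistic for
# the SNP term. Entirely independent of the scan implementation.
dense_gls_oracle <- function(y, W, x, K, vg, ve) {
  n <- length(y)
  Sigma <- vg * K + ve * diag(n)
  Si <- solve(Sigma)
  X <- cbind(W, x)
  A <- t(X) %*% Si %*% X
  b <- solve(A, t(X) %*% Si %*% y)
  v <- solve(A)[ncol(X), ncol(X)]
  beta <- b[ncol(X)]
  list(beta = beta, var_beta = v, wald = beta^2 / v)
}

# Build a pf_null_fit with prescribed variance components (bypassing REML)
# so the scan can be tested against the oracle at exact (vg, ve).
make_null_fit <- function(y, W, K, vg, ve) {
  ek <- eigen((K + t(K)) / 2, symmetric = TRUE)
  S <- pmax(ek$values, 0)
  Ut <- t(ek$vectors)
  structure(list(vg = vg, ve = ve, delta = ve / vg,
                 h2 = vg / (vg + ve), loglik = NA_real_, boundary = FALSE,
                 U = ek$vectors, Ut = Ut, S = S, Wt = Ut %*% W,
                 yt = drop(Ut %*% y), W = W, y = y),
            class = "pf_null_fit")
}

# The printed n = 8 fixture used for the GLS-oracle equivalence test.
printed_gls_fixture <- function() {
  dosage <- matrix(c(0, 1, 2, 1, 0, 2, 1, 0,
                     2, 2, 1, 0, 1, 1, 0, 2,
                     1, 0, 0, 2, 2, 1, 2, 1,
                     0, 2, 1, 1, 2, 0, 0, 1), nrow = 8)
  y <- c(1.62, -0.31, 2.48, 0.73, -1.05, 1.94, 0.21, -0.58)
  W <- cbind(1, c(0.5, -1.2, 0.3, 2.1, -0.7, 0.0, 1.4, -0.9))
  Zk <- matrix(c(0, 1, 2, 2, 1, 0, 1, 2,
                 1, 1, 0, 2, 0, 2, 2, 0,
                 2, 0, 1, 1, 2, 1, 0, 1,
                 1, 2, 2, 0, 1, 0, 1, 2,
                 0, 0, 1, 1, 2, 2, 1, 0,
                 2, 1, 0, 2, 0, 1, 2, 1), nrow = 8)
  Zs <- scale(Zk)
  K <- tcrossprod(Zs) / ncol(Zs)
  K <- (K + t(K)) / 2
  G <- genotype_matrix(dosage, toy_snps(4), samples = sprintf("i%d", 1:8))
  list(G = G, y = y, W = W, K = K)
}

# ---- HWE enumeration oracle --------------------------------------------

# Exact conditional HWE test by direct enumeration over all genotype
# tables with the observed allele counts, using the closed-form
# probability  P(het = h) = n! / (nr! h! na!) * 2^h * r! (2n-r)! / (2n)!
# computed per table (no recurrence, no normalization trick).
hwe_enum_oracle <- function(n_ref_hom, n_het, n_alt_hom) {
  n <- n_ref_hom + n_het + n_alt_hom
  rare <- min(2 * n_ref_hom + n_het, 2 * n_alt_hom + n_het)
  if (rare == 0) return(1)
  hets <- seq(rare %% 2, rare, by = 2)
  logp <- vapply(hets, function(h) {
    nr <- (rare - h) / 2
    na_ <- (2 * n - rare - h) / 2
    lgamma(n + 1) - lgamma(nr + 1) - lgamma(h + 1) - lgamma(na_ + 1) +
      h * log(2) + lgamma(rare + 1) + lgamma(2 * n - rare + 1) -
      lgamma(2 * n + 1)
  }, numeric(1))
  prob <- exp(logp)
  obs <- prob[match(n_het, hets)]
  min(1, sum(prob[prob <= obs * (1 + 1e-12)]))
}

# ---- tiny text-format writers ------------------------------------------

write_mini_vcf <- function(path, samples, snps, gt) {
  con <- file(path, "w")
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", samples), collapse = "\t")), con)
  for (r in seq_len(nrow(snps))) {
    writeLines(paste(c(snps$chrom[r], snps$pos[r], snps$snp_id[r],
                       snps$ref_allele[r], snps$alt_allele[r], ".", "PASS",
                       ".", "GT", gt[r, ]), collapse = "\t"), con)
  }
  close(con)
  path
}

write_mini_plink <- function(prefix, samples, snps, a1, a2) {
  map <- data.frame(snps$chrom, snps$snp_id, 0, snps$pos)
  write.table(map, paste0(prefix, ".map"), row.names = FALSE,
              col.names = FALSE, quote = FALSE, sep = "\t")
  ped <- cbind(paste0("F", seq_along(samples)), samples, 0, 0, 0, -9)
  geno <- matrix("", length(samples), 2 * nrow(snps))
  for (j in seq_len(nrow(snps))) {
    geno[, 2 * j - 1] <- a1[, j]
    geno[, 2 * j] <- a2[, j]
  }
  write.table(cbind(ped, geno), paste0(prefix, ".ped"), row.names = FALSE,
              col.names = FALSE, quote = FALSE, sep = " ")
  prefix
}
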