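# association module: Phase 1 of the framework. PCA covariates from pruned
# genotypes, genomic relationship matrix, restricted-maximum-likelihood fit
# of the variance components of the mixed model
#   y = W alpha + x beta + u + eps,  u ~ N(0, K Vg),  eps ~ N(0, I Ve),
# and the single-SNP generalized-least-squares Wald scan with the variance
# ratio fixed from the null model (EMMAX-style).

#' Genomic relationship matrix
#'
#' `K = Z Z' / m` where `Z` is the column-standardized (mean 0, unit
#' variance), mean-imputed dosage matrix; monomorphic columns are skipped.
#'
#' @param G a [genotype_matrix()].
#' @return symmetric n x n matrix with sample dimnames.
#' @export
compute_grm <- function(G) {
  stopifnot(inherits(G, "genotype_matrix"))
  Z <- standardize_dosage(G$dosage)
  mono <- attr(Z, "monomorphic")
  if (all(mono)) pf_stop("no polymorphic SNPs; cannot compute GRM")
  Z <- Z[, !mono, drop = FALSE]
  if (ncol(Z) < 2L) pf_stop("need >= 2 polymorphic SNPs for the GRM")
  K <- tcrossprod(Z) / ncol(Z)
  K <- (K + t(K)) / 2
  dimnames(K) <- list(G$samples, G$samples)
  K
}

#' Principal-component covariate matrix
#'
#' PCA of the standardized dosage matrix of LD-pruned genotypes; the top
#' `k` PC score vectors are returned together with an intercept column.
#' Sign convention: the largest-magnitude loading of each PC is positive.
#'
#' @param G_pruned pruned [genotype_matrix()] (see [ld_prune()]).
#' @param k number of leading principal components (default 5).
#' @return n x (k+1) matrix `[intercept | PC1..PCk]`.
#' @export
pca_covariates <- function(G_pruned, k = 5) {
  stopifnot(inherits(G_pruned, "genotype_matrix"))
  n <- length(G_pruned$samples)
  if (k >= n) pf_stop("k must be smaller than the number of samples")
  Z <- standardize_dosage(G_pruned$dosage)
  sv <- svd(Z, nu = k, nv = k)
  scores <- sv$u %*% diag(sv$d[seq_len(k)], k, k)
  for (j in seq_len(k)) {
    i <- which.max(abs(sv$v[, j]))
    if (sv$v[i, j] < 0) scores[, j] <- -scores[, j]
  }
  W <- cbind(intercept = 1, scores)
  colnames(W) <- c("intercept", paste0("PC", seq_len(k)))
  rownames(W) <- G_pruned$samples
  W
}

#' Fit the null mixed model by restricted maximum likelihood
#'
#' Eigendecomposes `K` once and maximizes the restricted log-likelihood of
#' `y = W alpha + u + eps` over the variance ratio `delta = Ve/Vg` by a
#' log-grid search with golden-section refinement (`delta` in
#' `[1e-5, 1e5]`). The returned object caches the rotation so it can be
#' reused across SNPs and permutations.
#'
#' @param y phenotype vector.
#' @param W covariate matrix including the intercept.
#' @param K genomic relationship matrix from [compute_grm()].
#' @return object of class `pf_null_fit` with elements `vg`, `ve`, `delta`,
#'   `loglik`, `h2` (`vg/(vg+ve)`), `boundary` flag, and the spectral cache
#'   (`U`, `S`, `Ut`, `Wt`, `yt`).
#' @export
fit_null_reml <- function(y, W, K) {
  y <- as.numeric(y)
  W <- as.matrix(W)
  n <- length(y)
  stopifnot(nrow(W) == n, nrow(K) == n, ncol(K) == n)
  if (qr(W)$rank < ncol(W)) pf_stop("covariate matrix W is rank deficient")
  ek <- eigen((K + t(K)) / 2, symmetric = TRUE)
  if (min(ek$values) < -1e-8 * max(1, abs(ek$values[1]))) {
    pf_stop("K is not positive semi-definite within tolerance")
  }
  S <- pmax(ek$values, 0)
  Ut <- t(ek$vectors)
  Wt <- Ut %*% W
  yt <- drop(Ut %*% y)
  fit <- reml_delta_cpp(Wt, yt, S, seq(-5, 5, by = 1 / 6))
  if (fit$boundary) {
    pf_warn("REML variance ratio at the search boundary (delta = ",
            signif(fit$delta, 3), "); variance components weakly identified")
  }
  structure(list(vg = fit$vg, ve = fit$ve, delta = fit$delta,
                 h2 = fit$vg / (fit$vg + fit$ve), loglik = fit$loglik,
                 boundary = fit$boundary, U = ek$vectors, Ut = Ut, S = S,
                 Wt = Wt, yt = yt, W = W, y = y),
            class = "pf_null_fit")
}

#' @export
print.pf_null_fit <- function(x, ...) {
  cat(sprintf("mixed-model null fit: Vg = %.4g, Ve = %.4g, h2 = %.3f%s\n",
              x$vg, x$ve, x$h2,
              if (x$boundary) " (boundary)" else ""))
  invisible(x)
}

#' Single-SNP mixed-model Wald scan
#'
#' For each SNP, generalized least squares of `y` on `[W | x]` under
#' `Sigma = Vg K + Ve I` with the variance components fixed from the null
#' fit (EMMAX-style single fit). Missing dosages are mean-imputed per SNP.
#' With `exact_per_snp = TRUE` the variance components are re-estimated by
#' REML for every SNP (slow; for small data). Reports the Wald statistic
#' `F_Wald = beta^2 / Var(beta)` and its chi-squared(1) upper-tail p-value.
#' Monomorphic SNPs get `wald = 0`, `p = 1` and are flagged.
#'
#' @param G a [genotype_matrix()].
#' @param null_fit a [fit_null_reml()] result on the same samples.
#' @param exact_per_snp re-estimate variance components per SNP.
#' @return data.frame with one row per SNP: `snp_id`, `chrom`, `pos`,
#'   `beta`, `var_beta`, `wald`, `p`, `monomorphic`.
#' @export
gwas_scan <- function(G, null_fit, exact_per_snp = FALSE) {
  stopifnot(inherits(G, "genotype_matrix"), inherits(null_fit, "pf_null_fit"))
  X <- impute_mean(G$dosage)
  mono <- apply(X, 2L, function(v) max(v) - min(v) < .Machine$double.eps^0.5)
  Gt <- null_fit$Ut %*% X
  if (!exact_per_snp) {
    sc <- wald_scan_cpp(Gt, null_fit$Wt, null_fit$yt, null_fit$S,
                        null_fit$vg, null_fit$ve)
  } else {
    m <- ncol(Gt)
    sc <- matrix(NA_real_, m, 3)
    grid <- seq(-5, 5, by = 1 / 6)
    for (j in seq_len(m)) {
      Wj <- cbind(null_fit$Wt, Gt[, j])
      fj <- reml_delta_cpp(Wj, null_fit$yt, null_fit$S, grid)
      sc[j, ] <- wald_scan_cpp(Gt[, j, drop = FALSE], null_fit$Wt,
                               null_fit$yt, null_fit$S, fj$vg, fj$ve)
    }
  }
  wald <- sc[, 3]
  wald[mono] <- 0
  beta <- sc[, 1]
  beta[mono] <- 0
  out <- data.frame(snp_id = G$snps$snp_id, chrom = G$snps$chrom,
                    pos = G$snps$pos, beta = beta, var_beta = sc[, 2],
                    wald = wald,
                    p = stats::pchisq(wald, df = 1, lower.tail = FALSE),
                    monomorphic = mono, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Effective number of tests (simpleM) and significance thresholds
#'
#' Per non-overlapping block of at most `block_size` consecutive SNPs, the
#' SNP x SNP Pearson correlation matrix of (mean-imputed) dosages is
#' eigendecomposed and the block's effective test count is the smallest
#' number of leading eigenvalues whose sum reaches `C` times the total.
#' `m_eff` is the sum over blocks; the genome-wide threshold is
#' `0.05 / m_eff` and the suggestive threshold `1 / m_eff` (their ratio is
#' exactly 20).
#'
#' @param G a [genotype_matrix()].
#' @param C fraction of the eigenvalue sum to capture (default 0.995).
#' @param block_size block length in SNPs (default 1000).
#' @return list with `m_eff`, `genomewide_p`, `suggestive_p`, `C`,
#'   `block_size`.
#' @export
simple_m <- function(G, C = 0.995, block_size = 1000) {
  stopifnot(inherits(G, "genotype_matrix"), C > 0, C <= 1)
  m <- nrow(G$snps)
  X <- impute_mean(G$dosage)
  m_eff <- 0L
  starts <- seq(1L, m, by = block_size)
  for (s in starts) {
    e <- min(s + block_size - 1L, m)
    idx <- s:e
    sds <- apply(X[, idx, drop = FALSE], 2L, stats::sd)
    poly <- sds > .Machine$double.eps^0.5
    # monomorphic SNPs carry no correlation structure; count them directly
    m_eff <- m_eff + sum(!poly)
    idx <- idx[poly]
    if (length(idx) < 2L) {
      m_eff <- m_eff + length(idx)
      next
    }
    cc <- stats::cor(X[, idx, drop = FALSE])
    ev <- eigen(cc, symmetric = TRUE, only.values = TRUE)$values
    ev <- pmax(ev, 0)
    k <- which(cumsum(ev) >= C * sum(ev))[1]
    m_eff <- m_eff + k
  }
  list(m_eff = as.integer(m_eff), genomewide_p = 0.05 / m_eff,
       suggestive_p = 1 / m_eff, C = C, block_size = as.integer(block_size))
}

#' Genomic inflation factor
#'
#' Median of the chi-squared(1) quantiles implied by the scan p-values,
#' divided by the null median 0.4549364.
#'
#' @param records association data.frame from [gwas_scan()], or a numeric
#'   vector of p-values.
#' @return the genomic inflation factor (GIF).
#' @export
genomic_inflation <- function(records) {
  p <- if (is.data.frame(records)) records$p else as.numeric(records)
  p <- p[!is.na(p)]
  if (!length(p)) pf_stop("no p-values supplied")
  chisq <- stats::qchisq(p, df = 1, lower.tail = FALSE)
  stats::median(chisq) / stats::qchisq(0.5, df = 1)
}
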