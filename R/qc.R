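# qc module: variant and sample filters (MAF, call rate, exact HWE,
# sample call rate) and the greedy windowed LD pruning used before PCA.

#' QC thresholds
#'
#' Defaults follow standard chip-GWAS practice: SNPs are removed when
#' `maf <= 0.01`, call rate `<= 0.97`, or exact HWE p `< 1e-6`; samples are
#' removed when their call rate is `< 0.95`. With
#' `strict_boundaries = FALSE` the MAF/call-rate comparisons use strict `<`
#' instead of `<=`.
#'
#' @param maf_min,snp_call_rate_min,hwe_p_min,sample_call_rate_min filter
#'   thresholds; set to `NULL` to disable a filter.
#' @param prune_window,prune_step,prune_r2 LD-pruning parameters (window
#'   size in SNPs, step in SNPs, maximum pairwise r-squared).
#' @param strict_boundaries remove SNPs at exactly the MAF/call-rate
#'   threshold (default `TRUE`).
#' @return object of class `qc_thresholds`.
#' @export
qc_thresholds <- function(maf_min = 0.01, snp_call_rate_min = 0.97,
                          hwe_p_min = 1e-6, sample_call_rate_min = 0.95,
                          prune_window = 25, prune_step = 5, prune_r2 = 0.2,
                          strict_boundaries = TRUE) {
  structure(list(maf_min = maf_min, snp_call_rate_min = snp_call_rate_min,
                 hwe_p_min = hwe_p_min,
                 sample_call_rate_min = sample_call_rate_min,
                 prune_window = as.integer(prune_window),
                 prune_step = as.integer(prune_step), prune_r2 = prune_r2,
                 strict_boundaries = isTRUE(strict_boundaries)),
            class = "qc_thresholds")
}

#' Per-SNP allele statistics
#'
#' @param dosage numeric dosage vector (0/1/2/`NA`) for one SNP.
#' @return list with `maf` (minor allele frequency over non-missing
#'   entries; `NA` if all entries are missing), `call_rate`, and `counts`
#'   (`n_ref_hom`, `n_het`, `n_alt_hom`).
#' @export
allele_stats <- function(dosage) {
  ok <- !is.na(dosage)
  n <- sum(ok)
  counts <- c(n_ref_hom = sum(dosage[ok] == 0),
              n_het = sum(dosage[ok] == 1),
              n_alt_hom = sum(dosage[ok] == 2))
  if (n == 0L) {
    return(list(maf = NA_real_, call_rate = 0, counts = counts))
  }
  p_alt <- sum(dosage[ok]) / (2 * n)
  list(maf = min(p_alt, 1 - p_alt), call_rate = n / length(dosage),
       counts = counts)
}

#' Exact Hardy-Weinberg equilibrium test
#'
#' Exact conditional test: given the observed allele counts, the p-value is
#' the sum of the probabilities of all heterozygote counts whose
#' probability does not exceed that of the observed configuration
#' (the two-sided convention of Wigginton et al., as used by PLINK).
#' Monomorphic SNPs return p = 1.
#'
#' @param n_ref_hom,n_het,n_alt_hom genotype counts.
#' @return exact p-value in (0, 1].
#' @export
hwe_test <- function(n_ref_hom, n_het, n_alt_hom) {
  stopifnot(n_ref_hom >= 0, n_het >= 0, n_alt_hom >= 0)
  n <- n_ref_hom + n_het + n_alt_hom
  if (n == 0L) pf_stop("total genotype count must be > 0")
  rare <- min(2 * n_ref_hom + n_het, 2 * n_alt_hom + n_het)
  if (rare == 0L) return(1)
  # heterozygote counts share the parity of the rare-allele count
  hets <- seq(rare %% 2L, rare, by = 2L)
  # log P(het = h | allele counts) up to a shared constant:
  #   log(n!) - log(nr!) - log(nh!) - log(na!) + h*log(2)
  nr <- (rare - hets) / 2
  na_ <- (2 * n - rare - hets) / 2
  logp <- hets * log(2) - lgamma(nr + 1) - lgamma(hets + 1) - lgamma(na_ + 1)
  logp <- logp - max(logp)
  prob <- exp(logp)
  prob <- prob / sum(prob)
  obs <- match(n_het, hets)
  if (is.na(obs)) pf_stop("inconsistent genotype counts for HWE test")
  min(1, sum(prob[prob <= prob[obs] * (1 + 1e-12)]))
}

# Vectorized per-SNP stats over a dosage matrix.
snp_stats <- function(dosage) {
  ok <- !is.na(dosage)
  n_called <- colSums(ok)
  alt <- colSums(dosage, na.rm = TRUE)
  p_alt <- ifelse(n_called > 0, alt / (2 * n_called), NA_real_)
  maf <- pmin(p_alt, 1 - p_alt)
  data.frame(
    maf = maf,
    call_rate = n_called / nrow(dosage),
    n_ref_hom = colSums(dosage == 0, na.rm = TRUE),
    n_het = colSums(dosage == 1, na.rm = TRUE),
    n_alt_hom = colSums(dosage == 2, na.rm = TRUE))
}

#' Apply QC filters to a genotype matrix
#'
#' Order of operations is fixed: (1) samples below the sample call-rate
#' threshold are dropped; (2) per-SNP statistics are recomputed on the
#' remaining samples and SNPs failing the MAF, call-rate or HWE filter are
#' dropped. The attached report counts removals per criterion.
#'
#' @param G a [genotype_matrix()].
#' @param thresholds a [qc_thresholds()].
#' @return list with elements `G` (filtered genotype matrix) and `report`
#'   (named list of removal counts plus per-criterion id vectors).
#' @export
apply_filters <- function(G, thresholds = qc_thresholds()) {
  stopifnot(inherits(G, "genotype_matrix"))
  th <- thresholds
  # (1) sample call rate ("smaller than" the threshold is removed)
  sample_cr <- rowMeans(!is.na(G$dosage))
  drop_samples <- if (!is.null(th$sample_call_rate_min)) {
    sample_cr < th$sample_call_rate_min
  } else rep(FALSE, length(sample_cr))
  G1 <- if (any(drop_samples)) G[!drop_samples, ] else G
  # (2) per-SNP filters on the remaining samples
  st <- snp_stats(G1$dosage)
  leq <- if (th$strict_boundaries) `<=` else `<`
  fail_maf <- if (!is.null(th$maf_min)) {
    is.na(st$maf) | leq(st$maf, th$maf_min)
  } else rep(FALSE, nrow(st))
  fail_cr <- if (!is.null(th$snp_call_rate_min)) {
    leq(st$call_rate, th$snp_call_rate_min)
  } else rep(FALSE, nrow(st))
  fail_hwe <- rep(FALSE, nrow(st))
  if (!is.null(th$hwe_p_min)) {
    # only SNPs not already failed need the exact test
    todo <- which(!(fail_maf | fail_cr))
    for (j in todo) {
      tot <- st$n_ref_hom[j] + st$n_het[j] + st$n_alt_hom[j]
      if (tot == 0L) next
      p <- hwe_test(st$n_ref_hom[j], st$n_het[j], st$n_alt_hom[j])
      fail_hwe[j] <- p < th$hwe_p_min
    }
  }
  keep <- !(fail_maf | fail_cr | fail_hwe)
  report <- list(
    n_samples_in = length(G$samples), n_snps_in = nrow(G$snps),
    samples_removed_call_rate = sum(drop_samples),
    snps_removed_maf = sum(fail_maf),
    snps_removed_call_rate = sum(fail_cr & !fail_maf),
    snps_removed_hwe = sum(fail_hwe),
    n_samples_out = length(G1$samples), n_snps_out = sum(keep),
    removed_samples = G$samples[drop_samples],
    removed_snps = G1$snps$snp_id[!keep])
  if (!any(keep)) {
    pf_stop("all SNPs removed by QC (maf: ", report$snps_removed_maf,
            ", call rate: ", report$snps_removed_call_rate,
            ", HWE: ", report$snps_removed_hwe, ")")
  }
  list(G = G1[, keep], report = report)
}

#' Greedy windowed LD pruning
#'
#' Mirrors PLINK's `--indep-pairwise` scheme: within each window of
#' `window` consecutive SNPs, while any pair of kept SNPs has squared
#' Pearson correlation (on mean-imputed dosages) above `r2_max`, the member
#' of the offending pair with the lower MAF is removed (ties: the later
#' position); the window then slides by `step`. Deterministic.
#'
#' @param G a [genotype_matrix()].
#' @param window,step window size and slide step, in SNPs.
#' @param r2_max maximum allowed pairwise r-squared.
#' @return integer vector of kept SNP column indices (ascending).
#' @export
ld_prune <- function(G, window = 25, step = 5, r2_max = 0.2) {
  stopifnot(inherits(G, "genotype_matrix"))
  m <- nrow(G$snps)
  if (window < 2) {
    pf_warn("ld_prune window < 2; no pruning performed")
    return(seq_len(m))
  }
  X <- impute_mean(G$dosage)
  maf <- snp_stats(G$dosage)$maf
  maf[is.na(maf)] <- 0
  keep <- rep(TRUE, m)
  # windows restart per chromosome, as pruning is positional
  for (chr in unique(G$snps$chrom)) {
    idx <- which(G$snps$chrom == chr)
    starts <- seq(1L, max(1L, length(idx)), by = step)
    for (s in starts) {
      w <- idx[s:min(s + window - 1L, length(idx))]
      w <- w[keep[w]]
      if (length(w) < 2L) next
      cc <- suppressWarnings(stats::cor(X[, w, drop = FALSE]))
      cc[is.na(cc)] <- 0
      r2 <- cc^2
      diag(r2) <- 0
      while (length(w) >= 2L && max(r2) > r2_max) {
        ij <- which(r2 == max(r2), arr.ind = TRUE)[1L, ]
        a <- w[ij[1]]; b <- w[ij[2]]
        # drop lower MAF; on ties, the later position
        drop <- if (maf[a] < maf[b]) a
        else if (maf[b] < maf[a]) b
        else max(a, b)
        keep[drop] <- FALSE
        at <- match(drop, w)
        w <- w[-at]
        r2 <- r2[-at, -at, drop = FALSE]
      }
      if (s + window - 1L >= length(idx)) break
    }
  }
  which(keep)
}
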