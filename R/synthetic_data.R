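# synthetic_data module: genotype/phenotype generator with the statistical
# structure the framework assumes -- LD blocks from a small haplotype pool,
# planted QTL effects on standardized dosages, a polygenic term drawn with
# covariance proportional to the genomic relationship matrix, and Gaussian
# noise.

#' Simulation specification
#'
#' Defines the study conditions for the synthetic genotype/phenotype
#' generator. Genotypes follow a haplotype-pool model: each LD block has a
#' small pool of haplotypes (all-reference or all-alternate across the
#' block), every sample copies two pool haplotypes, and a per-SNP mutation
#' rate -- solved from `within_block_r2` -- decays the within-block LD to
#' the requested level. Blocks are mutually independent.
#'
#' @param n_samples,n_snps dimensions of the simulated dataset.
#' @param n_chrom number of chromosomes; SNPs are split into `n_chrom`
#'   contiguous, equally sized chromosomes.
#' @param block_length SNPs per LD block.
#' @param within_block_r2 target mean pairwise r-squared inside a block,
#'   in `[0, 1]`.
#' @param maf_range allowed minor-allele-frequency interval (realized MAFs
#'   are enforced by block-level rejection resampling).
#' @param qtl_list data.frame with columns `snp_index`, `beta`: planted
#'   additive effects applied to the standardized dosage of each causal
#'   SNP, so `beta^2` is the variance contributed by that QTL.
#' @param h2_polygenic fraction of the total phenotypic variance explained
#'   by the polygenic term `u ~ N(0, Vg K)`.
#' @param noise_sd residual standard deviation (`Ve = noise_sd^2`).
#' @param missing_rate uniform dosage missingness rate.
#' @param pool_size haplotypes per block pool.
#' @param seed global integer seed; all stage-local generators are derived
#'   from it deterministically.
#' @return object of class `sim_spec`.
#' @export
sim_spec <- function(n_samples = 500, n_snps = 2000, n_chrom = 10,
                     block_length = 20, within_block_r2 = 0.6,
                     maf_range = c(0.05, 0.5), qtl_list = NULL,
                     h2_polygenic = 0.3, noise_sd = 1, missing_rate = 0,
                     pool_size = 8, seed = 1) {
  if (is.null(qtl_list)) {
    qtl_list <- data.frame(snp_index = integer(), beta = numeric())
  }
  qtl_list <- as.data.frame(qtl_list)
  stopifnot(n_samples >= 2, n_snps >= 1, n_chrom >= 1, block_length >= 1,
            within_block_r2 >= 0, within_block_r2 <= 1,
            length(maf_range) == 2L, maf_range[1] > 0, maf_range[2] <= 0.5,
            maf_range[1] <= maf_range[2],
            h2_polygenic >= 0, h2_polygenic < 1, noise_sd >= 0,
            missing_rate >= 0, missing_rate < 1, pool_size >= 2)
  if (nrow(qtl_list) && any(qtl_list$snp_index > n_snps | qtl_list$snp_index < 1)) {
    pf_stop("qtl_list snp_index out of range 1..n_snps")
  }
  spec <- list(n_samples = as.integer(n_samples), n_snps = as.integer(n_snps),
               n_chrom = as.integer(n_chrom),
               block_length = as.integer(block_length),
               within_block_r2 = within_block_r2, maf_range = maf_range,
               qtl_list = qtl_list, h2_polygenic = h2_polygenic,
               noise_sd = noise_sd, missing_rate = missing_rate,
               pool_size = as.integer(pool_size), seed = as.integer(seed))
  # implied variance fractions must leave room for the residual
  tot <- sim_total_variance(spec)
  if (h2_polygenic + sum(qtl_list$beta^2) / tot >= 1 + 1e-12) {
    pf_stop("h2_polygenic + planted QTL variance fraction must be < 1")
  }
  structure(spec, class = "sim_spec")
}

# Total phenotypic variance implied by the spec:
#   T = (sum(beta^2) + Ve) / (1 - h2), so that Vg = h2 * T and the QTL
#   fractions beta^2 / T, h2 and Ve/T sum to one.
sim_total_variance <- function(spec) {
  (sum(spec$qtl_list$beta^2) + spec$noise_sd^2) / (1 - spec$h2_polygenic)
}

#' Effect size for a planted QTL of a given variance fraction
#'
#' Converts a desired fraction of the total phenotypic variance into the
#' `beta` coefficient (on the standardized-dosage scale) to put into
#' `qtl_list`, consistently with `h2_polygenic` and `noise_sd`.
#'
#' @param frac desired variance fraction of the single QTL (e.g. 0.02).
#' @param h2_polygenic,noise_sd as in [sim_spec()].
#' @return numeric `beta`.
#' @export
qtl_beta <- function(frac, h2_polygenic = 0.3, noise_sd = 1) {
  stopifnot(frac >= 0, frac + h2_polygenic < 1)
  if (frac == 0) return(0)
  total <- noise_sd^2 / (1 - h2_polygenic - frac)
  sqrt(frac * total)
}

# Per-SNP mutation rate mu such that the expected pairwise r^2 between two
# SNPs of a block with base alt-haplotype frequency p equals the target:
#   sqrt(r2) = (1-2mu)^2 p q / (p' q'),  p' = p(1-2mu) + mu.
solve_mutation_rate <- function(r2, p) {
  if (r2 >= 1) return(0)
  f <- function(mu) {
    pp <- p * (1 - 2 * mu) + mu
    ((1 - 2 * mu)^2 * p * (1 - p) / (pp * (1 - pp)))^2 - r2
  }
  if (f(0.5) >= 0) return(0.5)
  stats::uniroot(f, c(0, 0.5), tol = 1e-10)$root
}

#' Simulate genotypes under the haplotype-pool LD-block model
#'
#' @param spec a [sim_spec()].
#' @return a [genotype_matrix()] with chromosomes `"1"..n_chrom"`, SNP ids
#'   `snp<j>`, and positions spaced ~3 kb apart.
#' @export
simulate_genotypes <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  set.seed(derive_seed(spec$seed, "genotypes"))
  n <- spec$n_samples
  m <- spec$n_snps
  H <- spec$pool_size
  blk_starts <- seq(1L, m, by = spec$block_length)
  dosage <- matrix(NA_real_, n, m)
  max_retries <- 50L
  for (bs in blk_starts) {
    be <- min(bs + spec$block_length - 1L, m)
    L <- be - bs + 1L
    for (try in seq_len(max_retries + 1L)) {
      if (try > max_retries) {
        pf_stop("could not realize MAFs in [", spec$maf_range[1], ", ",
                spec$maf_range[2], "] for block at SNP ", bs,
                " after ", max_retries, " retries")
      }
      p_target <- stats::runif(1, spec$maf_range[1], spec$maf_range[2])
      k_alt <- max(1L, min(H - 1L, round(H * p_target)))
      p_base <- k_alt / H
      mu <- solve_mutation_rate(spec$within_block_r2, p_base)
      # pool haplotypes: all-alt or all-ref across the block
      pool_alt <- sample(rep(c(1, 0), c(k_alt, H - k_alt)))
      hap_a <- pool_alt[sample.int(H, n, replace = TRUE)]
      hap_b <- pool_alt[sample.int(H, n, replace = TRUE)]
      base <- matrix(hap_a, n, L) + matrix(hap_b, n, L)
      if (mu > 0) {
        flips_a <- matrix(stats::rbinom(n * L, 1L, mu), n, L)
        flips_b <- matrix(stats::rbinom(n * L, 1L, mu), n, L)
        base <- abs(matrix(hap_a, n, L) - flips_a) +
          abs(matrix(hap_b, n, L) - flips_b)
      }
      freq <- colMeans(base) / 2
      maf <- pmin(freq, 1 - freq)
      if (all(maf >= spec$maf_range[1] - 1e-12 &
              maf <= spec$maf_range[2] + 1e-12)) {
        dosage[, bs:be] <- base
        break
      }
    }
  }
  if (spec$missing_rate > 0) {
    mask <- matrix(stats::runif(n * m) < spec$missing_rate, n, m)
    dosage[mask] <- NA_real_
  }
  per_chrom <- ceiling(m / spec$n_chrom)
  chrom <- as.character((seq_len(m) - 1L) %/% per_chrom + 1L)
  pos_in_chrom <- (seq_len(m) - 1L) %% per_chrom
  pos <- as.integer(1000L + pos_in_chrom * 3000L)
  snps <- data.frame(snp_id = sprintf("snp%05d", seq_len(m)), chrom = chrom,
                     pos = pos, ref_allele = "A", alt_allele = "G",
                     stringsAsFactors = FALSE)
  genotype_matrix(dosage, snps,
                  samples = sprintf("s%04d", seq_len(n)), sort = FALSE)
}

#' Simulate a phenotype over a genotype matrix
#'
#' `y = sum_j beta_j z_j + u + eps` with `z_j` the standardized dosage of
#' causal SNP `j`, `u ~ N(0, Vg K)` (K from [compute_grm()], `Vg` set so the
#' polygenic variance fraction equals `h2_polygenic`), and
#' `eps ~ N(0, noise_sd^2 I)`. The realized variance components are
#' attached as the `"variance_components"` attribute.
#'
#' @param G a [genotype_matrix()] (from [simulate_genotypes()] or external).
#' @param spec a [sim_spec()].
#' @return data.frame (`sample_id`, `value`) as accepted by the pipeline.
#' @export
simulate_phenotype <- function(G, spec) {
  stopifnot(inherits(G, "genotype_matrix"), inherits(spec, "sim_spec"))
  set.seed(derive_seed(spec$seed, "phenotype"))
  n <- length(G$samples)
  y <- numeric(n)
  total <- sim_total_variance(spec)
  vg <- spec$h2_polygenic * total
  ve <- spec$noise_sd^2
  if (nrow(spec$qtl_list)) {
    Z <- standardize_dosage(G$dosage[, spec$qtl_list$snp_index, drop = FALSE])
    y <- y + drop(Z %*% spec$qtl_list$beta)
  }
  if (vg > 0) {
    K <- compute_grm(G)
    ek <- eigen(K, symmetric = TRUE)
    lam <- ek$values
    if (min(lam) < -1e-8 * max(abs(lam))) {
      pf_warn("GRM not PSD within tolerance; clamping negative eigenvalues")
    }
    lam <- pmax(lam, 0)
    if (all(lam <= 0)) {
      pf_warn("singular GRM with Vg > 0; jittering diagonal")
      lam <- lam + 1e-8
    }
    u <- drop(ek$vectors %*% (sqrt(lam * vg) * stats::rnorm(n)))
    y <- y + u
  }
  y <- y + stats::rnorm(n, sd = spec$noise_sd)
  out <- data.frame(sample_id = G$samples, value = y,
                    stringsAsFactors = FALSE)
  attr(out, "variance_components") <-
    c(vg = vg, ve = ve, v_qtl = sum(spec$qtl_list$beta^2), total = total)
  out
}

#' Write the causal-SNP truth table for a simulation
#'
#' @param G the simulated [genotype_matrix()].
#' @param spec the [sim_spec()] used.
#' @param path output TSV path (`snp_id`, `chrom`, `pos`, `beta`).
#' @return `path`, invisibly.
#' @export
write_truth_table <- function(G, spec, path) {
  idx <- spec$qtl_list$snp_index
  out <- data.frame(snp_id = G$snps$snp_id[idx], chrom = G$snps$chrom[idx],
                    pos = G$snps$pos[idx], beta = spec$qtl_list$beta,
                    stringsAsFactors = FALSE)
  data.table::fwrite(out, path, sep = "\t", quote = FALSE)
  invisible(path)
}
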