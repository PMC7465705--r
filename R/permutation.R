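# signal_detection module, phase 4: permutation null of genome-wide
# maximum peak heights and the 95th-percentile QTL call.

# Build the per-chromosome penalty structures used by both the observed
# fits and the permutation engine. Chromosomes with fewer than min_snps
# SNPs are skipped with a warning (consistently in both paths).
chrom_structures <- function(snps, min_snps = 10L) {
  out <- list()
  for (chr in unique(snps$chrom)) {
    idx <- which(snps$chrom == chr)
    if (length(idx) < min_snps) {
      pf_warn("chromosome ", chr, " has ", length(idx),
              " SNP(s) < ", min_snps, "; skipped in signal detection")
      next
    }
    pos <- as.numeric(snps$pos[idx])
    while (any(dup <- duplicated(pos))) pos[dup] <- pos[dup] + 1
    o <- order(pos)   # positions are sorted upstream; defensive
    pos <- pos[o]
    xs <- (pos - pos[1]) / (pos[length(pos)] - pos[1])
    ps <- penalty_structure(xs)
    out[[chr]] <- list(chrom = chr, V = ps$V, d = ps$d, Mg = ps$Mg,
                       x = xs, pos = pos[o],
                       idx = c(min(idx), max(idx)))
  }
  out
}

#' Permutation null distribution of maximum peak heights
#'
#' For each of `B` permutations the phenotype is shuffled uniformly at
#' random (genotypes, covariates and kinship unchanged), the null-model
#' variance ratio is re-estimated by REML on the permuted phenotype (cheap
#' via the cached eigendecomposition), the Wald scan is re-run, a GCV
#' smoothing spline is re-fitted per chromosome (lambda re-selected, the
#' same policy as for observed data) and the genome-wide maximum peak
#' height is recorded. The QTL threshold is the 95th percentile of these
#' maxima (linear interpolation between order statistics, R quantile
#' type 7).
#'
#' @param G a [genotype_matrix()] (QC-filtered).
#' @param null_fit a [fit_null_reml()] result on the same samples.
#' @param B number of permutations (default 1000).
#' @param seed integer seed for the permutation stream.
#' @param qtl_quantile percentile defining the threshold (default 0.95).
#' @param min_snps_per_chrom chromosomes with fewer SNPs are skipped.
#' @param lambda_grid GCV grid (scaled axis), as in [fit_spline()].
#' @return object of class `perm_null`: `heights` (B maxima), `threshold`,
#'   `B`, `qtl_quantile`, `seed`.
#' @export
permutation_null <- function(G, null_fit, B = 1000, seed = 1,
                             qtl_quantile = 0.95, min_snps_per_chrom = 10,
                             lambda_grid = default_lambda_grid()) {
  stopifnot(inherits(G, "genotype_matrix"), inherits(null_fit, "pf_null_fit"))
  if (B < 1) pf_stop("B must be >= 1")
  if (B < 20) {
    pf_warn("B = ", B, " permutations: the 95th percentile is unstable")
  }
  structs <- chrom_structures(G$snps, min_snps = min_snps_per_chrom)
  if (!length(structs)) {
    pf_stop("no chromosome with >= ", min_snps_per_chrom,
            " SNPs; cannot build a permutation null")
  }
  n <- length(null_fit$y)
  set.seed(derive_seed(seed, "permutation"))
  perms <- matrix(0L, n, B)
  for (b in seq_len(B)) perms[, b] <- sample.int(n)
  X <- impute_mean(G$dosage)
  Gt <- null_fit$Ut %*% X
  heights <- drop(perm_null_cpp(null_fit$Ut, null_fit$Wt, Gt, null_fit$S,
                                null_fit$y, perms, unname(structs),
                                lambda_grid, seq(-5, 5, by = 1 / 6)))
  threshold <- unname(stats::quantile(heights, qtl_quantile, type = 7))
  structure(list(heights = heights, threshold = threshold, B = as.integer(B),
                 qtl_quantile = qtl_quantile, seed = as.integer(seed)),
            class = "perm_null")
}

#' @export
print.perm_null <- function(x, ...) {
  cat(sprintf(
    "permutation null: B = %d max peak heights, %.0fth percentile = %.4g\n",
    x$B, 100 * x$qtl_quantile, x$threshold))
  invisible(x)
}

#' Call QTLs from observed peaks and a permutation null
#'
#' Peaks whose height strictly exceeds the null threshold are QTLs
#' ("exceeds" is read as strict). QTL start/end are reported as the
#' positions of the leftmost/rightmost SNP inside the inflection interval
#' (SNP-anchored, matching the result-table convention), and `n_snps`
#' counts the contained SNPs.
#'
#' @param peaks data.frame of peaks from [call_peaks()] (rows from several
#'   chromosomes may be concatenated).
#' @param null a [permutation_null()] result (or a list with element
#'   `threshold`).
#' @param snps SNP metadata data.frame (`snp_id`, `chrom`, `pos`) used to
#'   anchor the QTL bounds; typically `G$snps`.
#' @param trait trait label carried into the QTL table.
#' @return data.frame with columns `qtl_id`, `chrom`, `start`, `end`,
#'   `left`, `right`, `apex_pos`, `height`, `n_snps`, `snp_ids`
#'   (comma-separated), `trait`.
#' @export
call_qtls <- function(peaks, null, snps, trait = "trait") {
  threshold <- if (is.list(null)) null$threshold else as.numeric(null)
  empty <- data.frame(qtl_id = character(), chrom = character(),
                      start = integer(), end = integer(), left = numeric(),
                      right = numeric(), apex_pos = numeric(),
                      height = numeric(), n_snps = integer(),
                      snp_ids = character(), trait = character(),
                      stringsAsFactors = FALSE)
  if (is.null(peaks) || nrow(peaks) == 0L) return(empty)
  keep <- peaks$height > threshold
  if (!any(keep)) return(empty)
  pk <- peaks[keep, , drop = FALSE]
  rows <- lapply(seq_len(nrow(pk)), function(i) {
    inside <- snps$chrom == pk$chrom[i] &
      snps$pos >= pk$left[i] & snps$pos <= pk$right[i]
    ids <- snps$snp_id[inside]
    pos <- snps$pos[inside]
    if (!length(pos)) return(NULL)   # peak with no SNP inside: not reportable
    data.frame(chrom = pk$chrom[i], start = min(pos), end = max(pos),
               left = pk$left[i], right = pk$right[i],
               apex_pos = pk$apex_pos[i], height = pk$height[i],
               n_snps = length(pos),
               snp_ids = paste(ids, collapse = ","),
               trait = trait, stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  out <- out[order(chrom_rank(out$chrom), out$start), , drop = FALSE]
  out <- cbind(qtl_id = paste0("QTL", seq_len(nrow(out))), out,
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
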