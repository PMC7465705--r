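# End-to-end orchestration of the six phases: QC -> LD pruning + PCA ->
# GRM + REML null fit -> Wald scan (+ simpleM thresholds, GIF) ->
# per-chromosome splines, peaks, permutation null, QTL calls -> Boruta ->
# robust SNPs and gene annotation.

#' Pipeline configuration
#'
#' @param qc a [qc_thresholds()].
#' @param n_pcs principal components used as covariates (default 5).
#' @param simplem_C,simplem_block simpleM parameters (see [simple_m()]).
#' @param B permutations for the peak-height null (default 1000).
#' @param qtl_quantile null percentile defining the QTL threshold.
#' @param min_snps_per_chrom chromosomes with fewer SNPs are skipped in
#'   signal detection.
#' @param lambda `"gcv"` or a fixed spline penalty (scaled axis).
#' @param exact_per_snp re-estimate variance components per SNP in the scan.
#' @param run_boruta run phase 5 (can be disabled for signal-detection-only
#'   studies).
#' @param boruta a [boruta_config()].
#' @param seed integer seed driving the permutation and forest streams.
#' @return object of class `pf_config`.
#' @export
pf_config <- function(qc = qc_thresholds(), n_pcs = 5, simplem_C = 0.995,
                      simplem_block = 1000, B = 1000, qtl_quantile = 0.95,
                      min_snps_per_chrom = 10, lambda = "gcv",
                      exact_per_snp = FALSE, run_boruta = TRUE,
                      boruta = NULL, seed = 1) {
  boruta <- boruta %||% boruta_config(seed = seed)
  structure(list(qc = qc, n_pcs = as.integer(n_pcs), simplem_C = simplem_C,
                 simplem_block = as.integer(simplem_block), B = as.integer(B),
                 qtl_quantile = qtl_quantile,
                 min_snps_per_chrom = as.integer(min_snps_per_chrom),
                 lambda = lambda, exact_per_snp = isTRUE(exact_per_snp),
                 run_boruta = isTRUE(run_boruta), boruta = boruta,
                 seed = as.integer(seed)),
            class = "pf_config")
}

#' Run the full association framework
#'
#' @param G a [genotype_matrix()].
#' @param phenotypes data.frame (`sample_id`, `value`) as returned by
#'   [read_phenotypes()] or [simulate_phenotype()].
#' @param gene_intervals optional gene intervals from
#'   [read_gene_intervals()].
#' @param config a [pf_config()].
#' @param trait trait label used in the QTL table.
#' @return object of class `pf_result` with elements `qc_report`, `G`
#'   (filtered), `W`, `null_fit`, `assoc`, `thresholds` (simpleM), `gif`,
#'   `curves` (per-chromosome [fit_spline()] objects), `peaks`, `null`
#'   ([permutation_null()]), `qtls`, `boruta`, `robust`, `genes`, `config`.
#' @export
run_pipeline <- function(G, phenotypes, gene_intervals = NULL,
                         config = pf_config(), trait = "trait") {
  stopifnot(inherits(G, "genotype_matrix"), inherits(config, "pf_config"))
  # Phase 0: QC
  qc_res <- apply_filters(G, config$qc)
  Gf <- qc_res$G
  y <- align_phenotype(Gf, phenotypes)
  # Phase 1: pruning, PCA covariates, GRM, REML, Wald scan
  kept <- ld_prune(Gf, window = config$qc$prune_window,
                   step = config$qc$prune_step, r2_max = config$qc$prune_r2)
  W <- pca_covariates(Gf[, kept], k = config$n_pcs)
  K <- compute_grm(Gf)
  null_fit <- fit_null_reml(y, W, K)
  assoc <- gwas_scan(Gf, null_fit, exact_per_snp = config$exact_per_snp)
  thresholds <- simple_m(Gf, C = config$simplem_C,
                         block_size = config$simplem_block)
  gif <- genomic_inflation(assoc)
  # Phases 2-3: per-chromosome splines and peaks
  curves <- list()
  peaks <- list()
  for (chr in unique(Gf$snps$chrom)) {
    idx <- Gf$snps$chrom == chr
    if (sum(idx) < config$min_snps_per_chrom) next
    cv <- fit_spline(Gf$snps$pos[idx], assoc$wald[idx],
                     lambda = config$lambda, chrom = chr)
    curves[[chr]] <- cv
    peaks[[chr]] <- call_peaks(cv)
  }
  peaks <- if (length(peaks)) do.call(rbind, unname(peaks)) else NULL
  # Phase 4: permutation null and QTL calls
  null <- permutation_null(Gf, null_fit, B = config$B, seed = config$seed,
                           qtl_quantile = config$qtl_quantile,
                           min_snps_per_chrom = config$min_snps_per_chrom)
  qtls <- call_qtls(peaks, null, Gf$snps, trait = trait)
  # Phase 5: Boruta
  bres <- NULL
  if (config$run_boruta) {
    bres <- boruta(Gf, y, config$boruta)
  }
  # Phase 6: robust SNPs and genes
  robust <- if (!is.null(bres)) {
    robust_snps(bres, qtls, Gf$snps, assoc = assoc)
  } else {
    NULL
  }
  genes <- if (!is.null(robust)) {
    annotate_genes(robust, gene_intervals)
  } else {
    NULL
  }
  if (nrow(qtls)) {
    qtls$n_genes <- if (!is.null(genes)) genes_per_qtl(qtls, genes) else 0L
  }
  structure(list(qc_report = qc_res$report, G = Gf, W = W,
                 null_fit = null_fit, assoc = assoc,
                 thresholds = thresholds, gif = gif, curves = curves,
                 peaks = peaks, null = null, qtls = qtls, boruta = bres,
                 robust = robust, genes = genes, config = config,
                 trait = trait),
            class = "pf_result")
}

#' @export
print.pf_result <- function(x, ...) {
  cat("peakforest pipeline result\n")
  cat(sprintf("  samples: %d, SNPs after QC: %d\n",
              length(x$G$samples), nrow(x$G$snps)))
  cat(sprintf("  null model: Vg = %.3g, Ve = %.3g (h2 = %.2f); GIF = %.3f\n",
              x$null_fit$vg, x$null_fit$ve, x$null_fit$h2, x$gif))
  cat(sprintf("  simpleM m_eff = %d (genome-wide p <= %.3g)\n",
              x$thresholds$m_eff, x$thresholds$genomewide_p))
  cat(sprintf("  peaks: %d; QTL threshold = %.4g; QTLs: %d\n",
              if (is.null(x$peaks)) 0L else nrow(x$peaks),
              x$null$threshold, nrow(x$qtls)))
  if (!is.null(x$boruta)) {
    nc <- sum(x$boruta$decisions$decision == "Confirmed")
    cat(sprintf("  Boruta: %d Confirmed; robust SNPs: %d; genes: %d\n",
                nc, nrow(x$robust),
                if (is.null(x$genes)) 0L else nrow(x$genes)))
  }
  invisible(x)
}

#' Write all pipeline result tables
#'
#' Writes the association TSV, peaks TSV, null-distribution TSV, QTL table,
#' and (when present) the robust-SNP and gene TSVs into a directory.
#'
#' @param result a [run_pipeline()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_results <- function(result, dir) {
  stopifnot(inherits(result, "pf_result"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_assoc_table(result$assoc, file.path(dir, "association.tsv"))
  if (!is.null(result$peaks)) {
    data.table::fwrite(result$peaks, file.path(dir, "peaks.tsv"), sep = "\t")
  }
  data.table::fwrite(data.frame(max_peak_height = result$null$heights),
                     file.path(dir, "null_distribution.tsv"), sep = "\t")
  write_qtl_table(result$qtls, file.path(dir, "qtl_table.tsv"),
                  trait = result$trait)
  if (!is.null(result$robust)) {
    data.table::fwrite(result$robust, file.path(dir, "robust_snps.tsv"),
                       sep = "\t")
  }
  if (!is.null(result$genes)) {
    data.table::fwrite(result$genes, file.path(dir, "genes.tsv"), sep = "\t")
  }
  invisible(dir)
}
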