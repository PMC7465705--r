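#' Genotype matrix container
#'
#' The central data structure of the package: an `n` samples by `m` SNPs
#' dosage matrix coded as the count of alternate alleles (0, 1, 2, or `NA`
#' for missing), together with per-SNP metadata.
#'
#' @param dosage numeric matrix, samples in rows, SNPs in columns; entries
#'   must be 0, 1, 2 or `NA`.
#' @param snps data.frame of SNP metadata with columns `snp_id`, `chrom`
#'   (character), `pos` (1-based bp), `ref_allele`, `alt_allele`.
#' @param samples character vector of unique sample ids (defaults to the
#'   rownames of `dosage`).
#' @param sort logical; sort SNPs by (chromosome, position) as required by
#'   the downstream per-chromosome analyses. Default `TRUE`.
#'
#' @return An object of class `genotype_matrix`: a list with elements
#'   `dosage` (matrix with sample rownames and snp_id colnames), `snps`
#'   (metadata data.frame) and `samples`.
#' @export
genotype_matrix <- function(dosage, snps, samples = rownames(dosage),
                            sort = TRUE) {
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "double"
  if (is.null(samples)) {
    pf_stop("sample ids are required (rownames of `dosage` or `samples`)")
  }
  samples <- as.character(samples)
  if (anyDuplicated(samples)) {
    pf_stop("duplicate sample ids: ",
            paste(unique(samples[duplicated(samples)]), collapse = ", "))
  }
  snps <- as.data.frame(snps, stringsAsFactors = FALSE)
  req <- c("snp_id", "chrom", "pos", "ref_allele", "alt_allele")
  miss <- setdiff(req, names(snps))
  if (length(miss)) {
    pf_stop("snps metadata lacks column(s): ", paste(miss, collapse = ", "))
  }
  snps$snp_id <- as.character(snps$snp_id)
  snps$chrom <- as.character(snps$chrom)
  snps$pos <- as.integer(snps$pos)
  if (anyDuplicated(snps$snp_id)) {
    pf_stop("duplicate snp_id: ",
            paste(unique(snps$snp_id[duplicated(snps$snp_id)]), collapse = ", "))
  }
  if (any(snps$pos < 1L, na.rm = TRUE)) pf_stop("SNP positions must be >= 1")
  if (nrow(dosage) != length(samples)) {
    pf_stop("nrow(dosage) != number of samples")
  }
  if (ncol(dosage) != nrow(snps)) {
    pf_stop("ncol(dosage) != number of SNPs")
  }
  bad <- dosage[!is.na(dosage)]
  if (length(bad) && !all(bad %in% c(0, 1, 2))) {
    pf_stop("dosage entries must be 0, 1, 2 or NA")
  }
  if (sort) {
    o <- order(chrom_rank(snps$chrom), snps$pos)
    snps <- snps[o, , drop = FALSE]
    dosage <- dosage[, o, drop = FALSE]
  }
  rownames(snps) <- NULL
  dimnames(dosage) <- list(samples, snps$snp_id)
  structure(list(dosage = dosage, snps = snps, samples = samples),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d SNPs on %d chromosome(s)\n",
              length(x$samples), nrow(x$snps), length(unique(x$snps$chrom))))
  miss <- mean(is.na(x$dosage))
  cat(sprintf("  missing dosage fraction: %.4f\n", miss))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosage)

#' Subset a genotype matrix
#'
#' @param x a `genotype_matrix`.
#' @param i sample index (logical, integer or character).
#' @param j SNP index (logical, integer or character snp_id).
#' @param ... unused.
#' @return a `genotype_matrix` restricted to the selected samples/SNPs.
#' @export
`[.genotype_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_along(x$samples)
  if (missing(j)) j <- seq_len(nrow(x$snps))
  if (is.character(j)) j <- match(j, x$snps$snp_id)
  dos <- x$dosage[i, j, drop = FALSE]
  genotype_matrix(dos, x$snps[j, , drop = FALSE],
                  samples = rownames(dos), sort = FALSE)
}

# Align a phenotype table against a genotype matrix: returns the phenotype
# vector in G's sample order, erroring on samples without a phenotype.
align_phenotype <- function(G, phenotypes) {
  stopifnot(inherits(G, "genotype_matrix"))
  idx <- match(G$samples, phenotypes$sample_id)
  if (anyNA(idx)) {
    pf_stop("no phenotype for sample(s): ",
            paste(utils::head(G$samples[is.na(idx)], 5L), collapse = ", "))
  }
  y <- phenotypes$value[idx]
  names(y) <- G$samples
  y
}
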