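# integration module, phase 6: robust SNPs = Boruta-Confirmed SNPs inside
# permutation-validated QTLs; LD profiles around peaks; genotype-class
# phenotype comparisons; gene-interval annotation.

#' Robust SNPs: Boruta-Confirmed and inside a QTL
#'
#' @param boruta_result a [boruta()] result (or its `decisions`
#'   data.frame).
#' @param qtls QTL data.frame from [call_qtls()].
#' @param snps SNP metadata (`snp_id`, `chrom`, `pos`); typically `G$snps`.
#' @param assoc optional association data.frame from [gwas_scan()]; adds
#'   the Wald statistic of each robust SNP.
#' @return data.frame of robust SNPs sorted by (chrom, pos): `snp_id`,
#'   `chrom`, `pos`, `qtl_id`, `decision`, `wald`.
#' @export
robust_snps <- function(boruta_result, qtls, snps, assoc = NULL) {
  dec <- if (inherits(boruta_result, "boruta_result")) {
    boruta_result$decisions
  } else {
    boruta_result
  }
  confirmed <- dec$snp_id[dec$decision == "Confirmed"]
  empty <- data.frame(snp_id = character(), chrom = character(),
                      pos = integer(), qtl_id = character(),
                      decision = character(), wald = numeric(),
                      stringsAsFactors = FALSE)
  if (!length(confirmed) || is.null(qtls) || nrow(qtls) == 0L) return(empty)
  meta <- snps[match(confirmed, snps$snp_id), , drop = FALSE]
  rows <- list()
  for (i in seq_len(nrow(qtls))) {
    inside <- !is.na(meta$pos) & meta$chrom == qtls$chrom[i] &
      meta$pos >= qtls$start[i] & meta$pos <= qtls$end[i]   # inclusive bounds
    if (!any(inside)) next
    rows[[length(rows) + 1L]] <- data.frame(
      snp_id = meta$snp_id[inside], chrom = meta$chrom[inside],
      pos = meta$pos[inside], qtl_id = qtls$qtl_id[i],
      decision = "Confirmed", stringsAsFactors = FALSE)
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  out <- out[!duplicated(out$snp_id), , drop = FALSE]
  out$wald <- if (!is.null(assoc)) {
    assoc$wald[match(out$snp_id, assoc$snp_id)]
  } else {
    NA_real_
  }
  out <- out[order(chrom_rank(out$chrom), out$pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' LD profile around an anchor SNP
#'
#' Squared Pearson correlation (on mean-imputed dosages) between the
#' anchor SNP and every SNP within `window_bp` of it on the same
#' chromosome. Monomorphic companions get `NA`.
#'
#' @param G a [genotype_matrix()].
#' @param anchor_snp snp_id of the anchor (e.g. the top-Wald SNP inside a
#'   peak).
#' @param window_bp half-window in bp around the anchor position.
#' @return data.frame `snp_id`, `chrom`, `pos`, `r2`.
#' @export
ld_profile <- function(G, anchor_snp, window_bp = 1e6) {
  stopifnot(inherits(G, "genotype_matrix"))
  a <- match(anchor_snp, G$snps$snp_id)
  if (is.na(a)) pf_stop("anchor SNP ", anchor_snp, " not found")
  ach <- G$snps$chrom[a]
  apos <- G$snps$pos[a]
  idx <- which(G$snps$chrom == ach & abs(G$snps$pos - apos) <= window_bp)
  X <- impute_mean(G$dosage[, idx, drop = FALSE])
  va <- X[, match(a, idx)]
  r2 <- rep(NA_real_, length(idx))
  sa <- stats::sd(va)
  if (sa > 0) {
    sds <- apply(X, 2L, stats::sd)
    ok <- sds > 0
    r2[ok] <- suppressWarnings(stats::cor(va, X[, ok, drop = FALSE]))^2
  }
  data.frame(snp_id = G$snps$snp_id[idx], chrom = G$snps$chrom[idx],
             pos = G$snps$pos[idx], r2 = drop(r2), stringsAsFactors = FALSE)
}

star_code <- function(p) {
  if (!is.finite(p)) return("ns")
  if (p < 0.001) "***" else if (p < 0.01) "**" else if (p < 0.05) "*" else "ns"
}

#' Phenotype comparison across genotype classes
#'
#' Class means of the phenotype for dosage classes 0/1/2 and pairwise
#' tests with significance stars (`*` p < 0.05, `**` p < 0.01, `***`
#' p < 0.001, `ns` otherwise). Pairwise Welch t-tests by default; with
#' `method = "tukey"`, Tukey HSD after a one-way ANOVA.
#'
#' @param dosage dosage vector (0/1/2/`NA`) of one SNP.
#' @param y phenotype vector aligned with `dosage`.
#' @param min_class_size pairs involving a smaller class are skipped with a
#'   note (default 3).
#' @param method `"welch"` (default) or `"tukey"`.
#' @return list with `classes` (`class`, `n`, `mean`, `sd`) and `pairs`
#'   (`class_a`, `class_b`, `p`, `stars`, `note`).
#' @export
genotype_class_test <- function(dosage, y, min_class_size = 3,
                                method = c("welch", "tukey")) {
  method <- match.arg(method)
  ok <- !is.na(dosage) & is.finite(y)
  d <- dosage[ok]
  yy <- y[ok]
  lv <- sort(unique(d))
  classes <- data.frame(
    class = lv,
    n = vapply(lv, function(g) sum(d == g), integer(1)),
    mean = vapply(lv, function(g) mean(yy[d == g]), numeric(1)),
    sd = vapply(lv, function(g) stats::sd(yy[d == g]), numeric(1)))
  big <- classes$class[classes$n >= min_class_size]
  if (length(big) < 2L) {
    pf_stop("need >= 2 genotype classes with >= ", min_class_size,
            " samples each")
  }
  pair_idx <- utils::combn(lv, 2L)
  pairs <- data.frame(class_a = pair_idx[1, ], class_b = pair_idx[2, ],
                      p = NA_real_, stars = "ns", note = "",
                      stringsAsFactors = FALSE)
  tuk <- NULL
  if (method == "tukey") {
    f <- factor(d)
    tuk <- stats::TukeyHSD(stats::aov(yy ~ f))$f
  }
  for (i in seq_len(nrow(pairs))) {
    a <- pairs$class_a[i]; b <- pairs$class_b[i]
    na_ <- sum(d == a); nb <- sum(d == b)
    if (na_ < min_class_size || nb < min_class_size) {
      pairs$note[i] <- sprintf("class below minimum size (%d vs %d)", na_, nb)
      next
    }
    if (method == "tukey") {
      key <- paste0(b, "-", a)
      if (key %in% rownames(tuk)) pairs$p[i] <- tuk[key, "p adj"]
    } else {
      ya <- yy[d == a]; yb <- yy[d == b]
      if (stats::sd(ya) == 0 && stats::sd(yb) == 0) {
        pairs$note[i] <- "zero variance in both classes; test undefined"
        next
      }
      pairs$p[i] <- tryCatch(stats::t.test(ya, yb)$p.value,
                             error = function(e) NA_real_)
    }
    pairs$stars[i] <- star_code(pairs$p[i])
  }
  list(classes = classes, pairs = pairs)
}

#' Annotate robust SNPs with gene intervals
#'
#' Genes containing at least one robust SNP within their boundaries
#' (1-based inclusive containment); genes overlapping a QTL but containing
#' no robust SNP are not reported.
#'
#' @param robust robust-SNP data.frame from [robust_snps()].
#' @param gene_intervals data.frame from [read_gene_intervals()].
#' @return data.frame `gene_id`, `chrom`, `start`, `end`, `n_robust_snps`,
#'   `snp_ids`, `qtl_ids`.
#' @export
annotate_genes <- function(robust, gene_intervals) {
  empty <- data.frame(gene_id = character(), chrom = character(),
                      start = integer(), end = integer(),
                      n_robust_snps = integer(), snp_ids = character(),
                      qtl_ids = character(), stringsAsFactors = FALSE)
  if (is.null(robust) || nrow(robust) == 0L ||
      is.null(gene_intervals) || nrow(gene_intervals) == 0L) {
    return(empty)
  }
  rows <- list()
  for (i in seq_len(nrow(gene_intervals))) {
    gi <- gene_intervals[i, ]
    inside <- robust$chrom == gi$chrom &
      robust$pos >= gi$start & robust$pos <= gi$end
    if (!any(inside)) next
    rows[[length(rows) + 1L]] <- data.frame(
      gene_id = gi$gene_id, chrom = gi$chrom, start = gi$start, end = gi$end,
      n_robust_snps = sum(inside),
      snp_ids = paste(robust$snp_id[inside], collapse = ","),
      qtl_ids = paste(sort(unique(robust$qtl_id[inside])), collapse = ","),
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  out <- out[order(chrom_rank(out$chrom), out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Genes-with-robust-SNPs count per QTL, for the "No. of Genes" column of
# the QTL table.
genes_per_qtl <- function(qtls, gene_table) {
  if (is.null(qtls) || nrow(qtls) == 0L) return(integer(0))
  vapply(qtls$qtl_id, function(id) {
    if (is.null(gene_table) || nrow(gene_table) == 0L) return(0L)
    sum(vapply(strsplit(gene_table$qtl_ids, ","), function(v) id %in% v,
               logical(1)))
  }, integer(1))
}
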