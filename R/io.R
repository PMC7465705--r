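# io module: readers/writers for the standard formats the pipeline touches
# and the package's own result-table dialects.

#' Read genotypes into a genotype matrix
#'
#' Supported formats: VCF 4.x (`format = "vcf"`, parsed with vcfR), PLINK
#' whitespace-delimited text (`"plink_text"`, a `.ped`/`.map` pair), and the
#' package's plain dosage TSV dialect (`"dosage_tsv"`, see
#' [write_dosage_tsv()]). Dosages are coded as alternate-allele counts
#' (0/1/2, `NA` missing) and SNPs are sorted by (chromosome, position).
#'
#' @param path file path. For `plink_text`, either the `.ped` file or the
#'   common prefix of the `.ped`/`.map` pair.
#' @param format one of `"vcf"`, `"plink_text"`, `"dosage_tsv"`.
#' @param multiallelic how to handle multiallelic VCF records: `"error"`
#'   (default) or `"split"` into one biallelic record per alternate allele.
#' @return a [genotype_matrix()].
#' @export
read_genotypes <- function(path, format = c("vcf", "plink_text", "dosage_tsv"),
                           multiallelic = c("error", "split")) {
  format <- match.arg(format)
  multiallelic <- match.arg(multiallelic)
  switch(format,
         vcf = read_genotypes_vcf(path, multiallelic),
         plink_text = read_genotypes_plink(path),
         dosage_tsv = read_genotypes_dosage(path))
}

read_genotypes_vcf <- function(path, multiallelic) {
  if (!file.exists(path)) pf_stop("file not found: ", path)
  v <- tryCatch(vcfR::read.vcfR(path, verbose = FALSE),
                error = function(e) pf_stop("VCF parse error in ", path, ": ",
                                            conditionMessage(e)))
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1L,
                                       dimnames = list(NULL, names(fix)))
  alt <- fix[, "ALT"]
  multi <- grepl(",", alt, fixed = TRUE)
  if (any(multi) && multiallelic == "error") {
    pf_stop("multiallelic record(s) at line(s) for ",
            paste(utils::head(fix[multi, "ID"], 5L), collapse = ", "),
            "; use multiallelic = \"split\"")
  }
  pre_ids <- fix[, "ID"]
  pre_ids <- pre_ids[!is.na(pre_ids) & pre_ids != "."]
  if (anyDuplicated(pre_ids)) {
    pf_stop("duplicate snp_id in ", path, ": ",
            paste(unique(pre_ids[duplicated(pre_ids)]), collapse = ", "))
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = 1L,
                                     dimnames = list(rownames(v@gt)[0], colnames(v@gt)[-1]))
  samples <- colnames(gt)
  ids <- fix[, "ID"]
  noid <- is.na(ids) | ids == "."
  ids[noid] <- paste0(fix[noid, "CHROM"], "_", fix[noid, "POS"])

  rows <- vector("list", nrow(fix))
  for (r in seq_len(nrow(fix))) {
    alts <- strsplit(alt[r], ",", fixed = TRUE)[[1]]
    g <- gt[r, ]
    toks <- strsplit(g, "[/|]")
    for (a in seq_along(alts)) {
      dos <- vapply(toks, function(tk) {
        if (length(tk) == 0L || any(tk == ".") || anyNA(tk)) return(NA_real_)
        sum(tk == as.character(a))
      }, numeric(1))
      rows[[r]] <- c(rows[[r]], list(list(
        snp_id = if (length(alts) > 1L) paste0(ids[r], "_alt", a) else ids[r],
        chrom = fix[r, "CHROM"], pos = as.integer(fix[r, "POS"]),
        ref_allele = fix[r, "REF"], alt_allele = alts[a], dosage = dos)))
    }
  }
  rows <- unlist(rows, recursive = FALSE)
  snps <- do.call(rbind, lapply(rows, function(x)
    data.frame(snp_id = x$snp_id, chrom = x$chrom, pos = x$pos,
               ref_allele = x$ref_allele, alt_allele = x$alt_allele,
               stringsAsFactors = FALSE)))
  dosage <- do.call(cbind, lapply(rows, `[[`, "dosage"))
  rownames(dosage) <- samples
  genotype_matrix(dosage, snps)
}

read_genotypes_plink <- function(path) {
  prefix <- sub("\\.(ped|map)$", "", path)
  ped_path <- paste0(prefix, ".ped")
  map_path <- paste0(prefix, ".map")
  for (p in c(ped_path, map_path)) {
    if (!file.exists(p)) pf_stop("file not found: ", p)
  }
  map <- tryCatch(
    data.table::fread(map_path, header = FALSE, data.table = FALSE,
                      colClasses = "character"),
    error = function(e) pf_stop("parse error in ", map_path, ": ",
                                conditionMessage(e)))
  if (ncol(map) < 4L) pf_stop(".map must have 4 columns (chrom id cM bp)")
  names(map)[1:4] <- c("chrom", "snp_id", "cm", "pos")
  m <- nrow(map)
  ped <- tryCatch(
    data.table::fread(ped_path, header = FALSE, data.table = FALSE,
                      colClasses = "character"),
    error = function(e) pf_stop("parse error in ", ped_path, ": ",
                                conditionMessage(e)))
  if (ncol(ped) != 6L + 2L * m) {
    pf_stop(".ped line width ", ncol(ped), " does not match 6 + 2*",
            m, " expected from ", map_path)
  }
  samples <- ped[[2]]
  a1 <- as.matrix(ped[, 6L + 2L * seq_len(m) - 1L, drop = FALSE])
  a2 <- as.matrix(ped[, 6L + 2L * seq_len(m), drop = FALSE])
  a1[a1 == "0"] <- NA
  a2[a2 == "0"] <- NA
  dosage <- matrix(NA_real_, nrow(ped), m)
  ref <- alt <- character(m)
  for (j in seq_len(m)) {
    als <- c(a1[, j], a2[, j])
    tab <- sort(table(als))   # ascending frequency; ties resolved below
    lev <- names(tab)
    if (length(lev) == 0L) {
      ref[j] <- "N"; alt[j] <- "N"
      next
    }
    if (length(lev) > 2L) {
      pf_stop("SNP ", map$snp_id[j], " has >2 alleles in ", ped_path)
    }
    if (length(lev) == 1L) {
      ref[j] <- lev; alt[j] <- lev
      dosage[, j] <- ifelse(is.na(a1[, j]) | is.na(a2[, j]), NA_real_, 0)
      next
    }
    # alt = minor allele; frequency ties broken by ASCII-later allele
    if (tab[[1]] == tab[[2]]) {
      s <- sort(lev)
      ref[j] <- s[1]; alt[j] <- s[2]
    } else {
      alt[j] <- lev[1]; ref[j] <- lev[2]
    }
    dosage[, j] <- (a1[, j] == alt[j]) + (a2[, j] == alt[j])
  }
  snps <- data.frame(snp_id = map$snp_id, chrom = map$chrom,
                     pos = as.integer(map$pos), ref_allele = ref,
                     alt_allele = alt, stringsAsFactors = FALSE)
  rownames(dosage) <- samples
  genotype_matrix(dosage, snps)
}

read_genotypes_dosage <- function(path) {
  if (!file.exists(path)) pf_stop("file not found: ", path)
  meta_path <- paste0(path, ".meta")
  if (!file.exists(meta_path)) {
    pf_stop("companion metadata file not found: ", meta_path)
  }
  d <- tryCatch(
    data.table::fread(path, header = TRUE, sep = "\t", data.table = FALSE,
                      na.strings = "NA"),
    error = function(e) pf_stop("parse error in ", path, ": ",
                                conditionMessage(e)))
  if (ncol(d) < 2L) pf_stop("dosage TSV needs sample_id plus >=1 SNP column")
  samples <- as.character(d[[1]])
  dosage <- as.matrix(d[, -1L, drop = FALSE])
  storage.mode(dosage) <- "double"
  rownames(dosage) <- samples
  meta <- data.table::fread(meta_path, header = TRUE, sep = "\t",
                            data.table = FALSE,
                            colClasses = list(character = c("snp_id", "chrom")))
  idx <- match(colnames(dosage), meta$snp_id)
  if (anyNA(idx)) {
    pf_stop("snp_id(s) missing from ", meta_path, ": ",
            paste(utils::head(colnames(dosage)[is.na(idx)], 5L), collapse = ", "))
  }
  genotype_matrix(dosage, meta[idx, , drop = FALSE])
}

#' Write a genotype matrix as dosage TSV
#'
#' The dialect is a header row of snp_ids and one row per sample
#' (`sample_id` followed by the integer dosages, missing written as `NA`),
#' with SNP metadata in a companion `<path>.meta` TSV
#' (`snp_id chrom pos ref_allele alt_allele`). Reading the pair back with
#' [read_genotypes()] reproduces the genotype matrix exactly.
#'
#' @param G a [genotype_matrix()].
#' @param path output TSV path; `<path>.meta` is written alongside.
#' @return `path`, invisibly.
#' @export
write_dosage_tsv <- function(G, path) {
  stopifnot(inherits(G, "genotype_matrix"))
  d <- data.frame(sample_id = G$samples, G$dosage, check.names = FALSE,
                  stringsAsFactors = FALSE)
  data.table::fwrite(d, path, sep = "\t", na = "NA", quote = FALSE)
  data.table::fwrite(G$snps, paste0(path, ".meta"), sep = "\t", quote = FALSE)
  invisible(path)
}

#' Read a two-column phenotype TSV
#'
#' @param path TSV with columns (sample_id, value).
#' @param header `"auto"` (default) detects a header row by checking whether
#'   the second field of the first line is numeric; `TRUE`/`FALSE` force it.
#' @param na_action `"drop"` (default) drops non-finite/`NA` values with a
#'   warning; `"error"` fails instead.
#' @return data.frame with columns `sample_id`, `value`.
#' @export
read_phenotypes <- function(path, header = "auto",
                            na_action = c("drop", "error")) {
  na_action <- match.arg(na_action)
  if (!file.exists(path)) pf_stop("file not found: ", path)
  if (file.size(path) == 0L) pf_stop("empty phenotype file: ", path)
  if (identical(header, "auto")) {
    first <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
    header <- length(first) >= 2L &&
      is.na(suppressWarnings(as.numeric(first[2]))) &&
      !(first[2] %in% c("NA", "NaN"))
  }
  d <- data.table::fread(path, header = header, sep = "\t",
                         data.table = FALSE, colClasses = list(character = 1L))
  if (nrow(d) == 0L) pf_stop("empty phenotype file: ", path)
  if (ncol(d) < 2L) pf_stop("phenotype TSV needs two columns (sample_id, value)")
  val <- d[[2]]
  if (is.character(val)) {
    num <- suppressWarnings(as.numeric(val))
    bad <- which(is.na(num) & !(val %in% c("NA", "NaN", "")))
    if (length(bad)) {
      pf_stop("non-numeric phenotype value '", val[bad[1]], "' at data row ",
              bad[1])
    }
    val <- num
  }
  out <- data.frame(sample_id = as.character(d[[1]]), value = as.double(val),
                    stringsAsFactors = FALSE)
  if (anyDuplicated(out$sample_id)) {
    pf_stop("duplicate sample id in phenotypes: ",
            paste(unique(out$sample_id[duplicated(out$sample_id)]),
                  collapse = ", "))
  }
  drop <- !is.finite(out$value)
  if (any(drop)) {
    if (na_action == "error") {
      pf_stop(sum(drop), " missing/non-finite phenotype value(s)")
    }
    pf_warn("dropping ", sum(drop), " sample(s) with missing phenotype")
    out <- out[!drop, , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Read gene intervals from a BED file
#'
#' BED 0-based half-open coordinates are converted to the package-internal
#' 1-based inclusive convention at this boundary (via rtracklayer). Records
#' without a name column get auto ids `gene_<k>`.
#'
#' @param path BED3+name file.
#' @return data.frame with columns `gene_id`, `chrom`, `start`, `end`
#'   (1-based inclusive, `start <= end`).
#' @export
read_gene_intervals <- function(path) {
  if (!file.exists(path)) pf_stop("file not found: ", path)
  if (file.size(path) == 0L ||
      all(!nzchar(trimws(readLines(path, warn = FALSE))))) {
    return(data.frame(gene_id = character(), chrom = character(),
                      start = integer(), end = integer(),
                      stringsAsFactors = FALSE))
  }
  gr <- tryCatch(rtracklayer::import(path, format = "BED"),
                 error = function(e) pf_stop("BED parse error in ", path, ": ",
                                             conditionMessage(e)))
  ids <- gr$name
  if (is.null(ids)) ids <- rep(NA_character_, length(gr))
  noid <- is.na(ids) | ids == ""
  ids[noid] <- paste0("gene_", which(noid))
  out <- data.frame(gene_id = ids,
                    chrom = as.character(GenomicRanges::seqnames(gr)),
                    start = GenomicRanges::start(gr),
                    end = GenomicRanges::end(gr),
                    stringsAsFactors = FALSE)
  if (any(out$start > out$end)) {
    pf_stop("gene interval with start > end in ", path)
  }
  rownames(out) <- NULL
  out
}

#' Write the QTL result table
#'
#' Writes a TSV with the column set `Chromosome`, `No. of SNPs`,
#' `Start Position`, `End Position`, `No. of Genes`, `Trait`, one row per
#' QTL, ordered by (chromosome, start position). Positions are written as
#' plain integers.
#'
#' @param qtls a QTL data.frame as returned by [call_qtls()] (columns
#'   `chrom`, `n_snps`, `start`, `end`, and optionally `n_genes`, `trait`).
#' @param path output path.
#' @param trait default trait label used when `qtls` has no `trait` column.
#' @return `path`, invisibly.
#' @export
write_qtl_table <- function(qtls, path, trait = "trait") {
  cols <- c("Chromosome", "No. of SNPs", "Start Position", "End Position",
            "No. of Genes", "Trait")
  if (is.null(qtls) || nrow(qtls) == 0L) {
    tab <- as.data.frame(setNames(rep(list(character(0)), length(cols)), cols),
                         check.names = FALSE)
  } else {
    tab <- data.frame(
      qtls$chrom,
      as.integer(qtls$n_snps),
      as.integer(qtls$start),
      as.integer(qtls$end),
      as.integer(qtls$n_genes %||% rep(0L, nrow(qtls))),
      as.character(qtls$trait %||% rep(trait, nrow(qtls))),
      check.names = FALSE, stringsAsFactors = FALSE)
    names(tab) <- cols
    tab <- tab[order(chrom_rank(tab$Chromosome), tab$`Start Position`), ,
               drop = FALSE]
  }
  ok <- tryCatch({
    data.table::fwrite(tab, path, sep = "\t", quote = FALSE)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) pf_stop("cannot write QTL table to ", path)
  invisible(path)
}

#' Write the per-SNP association table
#'
#' @param records association data.frame from [gwas_scan()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_assoc_table <- function(records, path) {
  cols <- c("snp_id", "chrom", "pos", "beta", "se", "wald", "p")
  out <- data.frame(snp_id = records$snp_id, chrom = records$chrom,
                    pos = records$pos, beta = records$beta,
                    se = sqrt(records$var_beta), wald = records$wald,
                    p = records$p, stringsAsFactors = FALSE)
  names(out) <- cols
  data.table::fwrite(out, path, sep = "\t", quote = FALSE)
  invisible(path)
}
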