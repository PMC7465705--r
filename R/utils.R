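# Internal helpers shared across modules.

#' Order chromosome identifiers
#'
#' Chromosome ids are kept as strings throughout; ordering is numeric where
#' all ids parse as numbers, lexicographic otherwise.
#'
#' @param chrom character vector of chromosome ids.
#' @return integer rank order usable with `order()`.
#' @keywords internal
chrom_rank <- function(chrom) {
  u <- unique(chrom)
  num <- suppressWarnings(as.numeric(u))
  if (!anyNA(num)) {
    lev <- u[order(num)]
  } else {
    lev <- sort(u)
  }
  match(chrom, lev)
}

# Mean-impute missing entries of a dosage matrix, column-wise.
# All-missing columns are imputed to 0 (flagged upstream by QC).
impute_mean <- function(dosage) {
  if (!anyNA(dosage)) {
    return(dosage)
  }
  cm <- colMeans(dosage, na.rm = TRUE)
  cm[is.nan(cm)] <- 0
  idx <- which(is.na(dosage))
  dosage[idx] <- cm[(idx - 1L) %/% nrow(dosage) + 1L]
  dosage
}

# Column-standardize a dosage matrix: mean-impute, centre, scale to unit
# sample variance. Zero-variance (monomorphic) columns are returned as all
# zeros and reported via the "monomorphic" attribute.
standardize_dosage <- function(dosage) {
  x <- impute_mean(dosage)
  mu <- colMeans(x)
  x <- sweep(x, 2L, mu, "-")
  sd <- sqrt(colSums(x^2) / max(1L, nrow(x) - 1L))
  mono <- sd < .Machine$double.eps^0.5
  sd[mono] <- 1
  x <- sweep(x, 2L, sd, "/")
  if (any(mono)) x[, mono] <- 0
  attr(x, "monomorphic") <- mono
  x
}

# Derive a stage-local RNG seed from a global integer seed. Keeps results
# reproducible while decoupling the random streams of different stages.
# Result stays below 2^31 - 1.
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  offset <- sum(utf8ToInt(stage) * seq_len(nchar(stage)))
  as.integer((as.double(seed) * 7919 + offset) %% 2147483629)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

pf_stop <- function(...) stop(..., call. = FALSE)

pf_warn <- function(...) warning(..., call. = FALSE)
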