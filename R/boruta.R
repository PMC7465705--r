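# feature_selection module, phase 5: random-forest SNP importance and the
# Boruta all-relevant wrapper (Kursa & Rudnicki 2010) yielding a
# Confirmed/Tentative/Rejected decision per SNP. Regression forests are
# used throughout (the phenotype is continuous); SNPs enter as numeric
# additive dosages, mean-imputed.

#' Boruta configuration
#'
#' @param n_trees trees per forest (default 500).
#' @param max_iterations maximum Boruta iterations (default 100, minimum
#'   10).
#' @param alpha decision significance level for the running binomial tests
#'   (default 0.01), Bonferroni-corrected over the original feature count.
#' @param min_shadow minimum number of shadow features per forest.
#' @param mtry_frac fraction `mtry = max(1, floor(mtry_frac * sqrt(p)))`;
#'   default 1 gives the usual `sqrt(p)`.
#' @param seed integer seed.
#' @return object of class `boruta_config`.
#' @export
boruta_config <- function(n_trees = 500, max_iterations = 100, alpha = 0.01,
                          min_shadow = 5, mtry_frac = 1, seed = 1) {
  if (max_iterations < 10) pf_stop("max_iterations must be >= 10")
  if (alpha <= 0 || alpha >= 0.5) pf_stop("alpha must be in (0, 0.5)")
  structure(list(n_trees = as.integer(n_trees),
                 max_iterations = as.integer(max_iterations), alpha = alpha,
                 min_shadow = as.integer(min_shadow), mtry_frac = mtry_frac,
                 seed = as.integer(seed)),
            class = "boruta_config")
}

#' Random-forest SNP importance
#'
#' Out-of-bag permutation importance from a regression random forest on
#' the mean-imputed dosage matrix. Deterministic given `seed`.
#'
#' @param G a [genotype_matrix()] (or a plain dosage matrix).
#' @param y continuous phenotype vector aligned with the samples.
#' @param n_trees number of trees.
#' @param seed integer seed.
#' @param mtry variables tried per split; default `floor(sqrt(m))`.
#' @return named numeric vector of importances (one per SNP).
#' @export
rf_importance <- function(G, y, n_trees = 500, seed = 1, mtry = NULL) {
  X <- if (inherits(G, "genotype_matrix")) G$dosage else as.matrix(G)
  if (nrow(X) < 10L) pf_stop("need >= 10 samples for a random forest")
  stopifnot(length(y) == nrow(X))
  X <- impute_mean(X)
  mtry <- mtry %||% max(1L, floor(sqrt(ncol(X))))
  fit <- ranger::ranger(x = X, y = as.numeric(y), num.trees = n_trees,
                        mtry = mtry, importance = "permutation",
                        seed = seed, num.threads = 1L,
                        write.forest = FALSE, verbose = FALSE)
  imp <- fit$variable.importance
  names(imp) <- colnames(X)
  imp
}

#' Boruta all-relevant SNP selection
#'
#' Iterates: (1) append a shuffled "shadow" copy of every feature still in
#' play; (2) fit a regression random forest and extract permutation
#' importances; (3) a feature scores a hit when its importance exceeds the
#' maximum shadow importance; (4) two-sided binomial tests on the
#' accumulated hit counts (at `alpha`, Bonferroni-corrected over the
#' feature count) Confirm features with significantly more hits than the
#' chance rate 1/2 and Reject those with significantly fewer; (5) Rejected
#' features are dropped and the loop repeats up to `max_iterations`.
#' Features still undecided at the end are Tentative. Shadow features are
#' never reported.
#'
#' @param G a [genotype_matrix()] (or plain dosage matrix).
#' @param y continuous phenotype vector aligned with the samples.
#' @param config a [boruta_config()].
#' @return object of class `boruta_result`: data.frame `decisions`
#'   (`snp_id`, `decision`, `hits`, `n_iter`, `median_importance`,
#'   `hit_fraction`), matrix `importance_history` (features x iterations,
#'   `NA` once decided), `n_iterations`, `config`.
#' @export
boruta <- function(G, y, config = boruta_config()) {
  stopifnot(inherits(config, "boruta_config"))
  X <- if (inherits(G, "genotype_matrix")) G$dosage else as.matrix(G)
  if (nrow(X) < 10L) pf_stop("need >= 10 samples for a random forest")
  stopifnot(length(y) == nrow(X))
  X <- impute_mean(X)
  m <- ncol(X)
  ids <- colnames(X) %||% paste0("V", seq_len(m))
  colnames(X) <- ids
  y <- as.numeric(y)

  set.seed(derive_seed(config$seed, "boruta"))
  decision <- rep("Tentative", m)
  hits <- integer(m)
  tested <- integer(m)         # iterations each feature took part in
  hist <- matrix(NA_real_, m, config$max_iterations,
                 dimnames = list(ids, NULL))
  alpha_adj <- config$alpha / m   # Bonferroni over the original features

  iter <- 0L
  while (iter < config$max_iterations && any(decision == "Tentative")) {
    iter <- iter + 1L
    active <- which(decision != "Rejected")
    Xa <- X[, active, drop = FALSE]
    # shadows: shuffled copies of the active features, padded to min_shadow
    n_sh <- max(length(active), config$min_shadow)
    sh_src <- active[((seq_len(n_sh) - 1L) %% length(active)) + 1L]
    Xs <- apply(X[, sh_src, drop = FALSE], 2L, sample)
    colnames(Xs) <- paste0("shadow_", seq_len(n_sh))
    mtry <- max(1L, floor(config$mtry_frac * sqrt(ncol(Xa) + n_sh)))
    # Z-score importance (raw permutation importance scaled by its SD over
    # trees), as in the original algorithm; stabler against in-sample
    # noise correlations than the raw measure
    fit <- ranger::ranger(x = cbind(Xa, Xs), y = y,
                          num.trees = config$n_trees, mtry = mtry,
                          importance = "permutation",
                          scale.permutation.importance = TRUE,
                          seed = derive_seed(config$seed, "forest") + iter,
                          num.threads = 1L, write.forest = FALSE,
                          verbose = FALSE)
    imp <- fit$variable.importance
    imp_active <- imp[seq_along(active)]
    max_shadow <- max(imp[-seq_along(active)])
    undec <- decision[active] == "Tentative"
    u_idx <- active[undec]
    hist[u_idx, iter] <- imp_active[undec]
    hits[u_idx] <- hits[u_idx] + (imp_active[undec] > max_shadow)
    tested[u_idx] <- tested[u_idx] + 1L
    # running two-sided binomial decisions on the undecided features:
    # each tail is tested at half the Bonferroni-corrected level
    for (j in u_idx) {
      p_more <- stats::pbinom(hits[j] - 1L, tested[j], 0.5,
                              lower.tail = FALSE)
      p_less <- stats::pbinom(hits[j], tested[j], 0.5)
      if (2 * p_more < alpha_adj) decision[j] <- "Confirmed"
      else if (2 * p_less < alpha_adj) decision[j] <- "Rejected"
    }
  }
  if (iter == 1L && all(decision == "Rejected")) {
    pf_warn("all features rejected in the first Boruta iteration")
  }
  med_imp <- apply(hist[, seq_len(iter), drop = FALSE], 1L,
                   stats::median, na.rm = TRUE)
  out <- data.frame(snp_id = ids, decision = decision, hits = hits,
                    n_iter = tested, median_importance = med_imp,
                    hit_fraction = ifelse(tested > 0, hits / tested, NA_real_),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(list(decisions = out,
                 importance_history = hist[, seq_len(iter), drop = FALSE],
                 n_iterations = iter, config = config),
            class = "boruta_result")
}

#' @export
print.boruta_result <- function(x, ...) {
  tab <- table(factor(x$decisions$decision,
                      levels = c("Confirmed", "Tentative", "Rejected")))
  cat(sprintf(
    "boruta_result: %d iterations; %d Confirmed, %d Tentative, %d Rejected\n",
    x$n_iterations, tab[["Confirmed"]], tab[["Tentative"]],
    tab[["Rejected"]]))
  invisible(x)
}
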