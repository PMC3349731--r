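#' Residualise expression on sample covariates
#'
#' Replaces each row by its OLS residuals on the encoded covariates
#' (library batch and multiplexing tag in the standard pipeline).
#'
#' @param mat expression matrix (RNA x sample).
#' @param covariates per-sample covariate data.frame.
#' @return residual matrix of the same shape.
#' @export
residualise <- function(mat, covariates) {
  C <- encode_covariates(covariates)
  X <- cbind(`(Intercept)` = rep(1, ncol(mat)), C)
  qx <- qr(X)
  if (qx$rank < ncol(X)) stop("rank-deficient covariate design")
  t(qr.resid(qx, t(mat)))
}

#' Cross-tissue specificity Z tests
#'
#' For each RNA and comparison tissue, `Z = (mu_a - mu_t) /
#' sqrt(var_a / n_a + var_t / n_t)` (Welch standard error), a two-tailed
#' normal p, and q-values across RNAs per tissue.  An RNA is flagged
#' tissue-specific if Z > 0 and q < `q_cut` against every other tissue.
#'
#' @param adipose data.frame with `rna_id`, `mean`, `var`, `n` for the
#'   focal tissue.
#' @param others named list of equally shaped summaries for the other
#'   tissues.
#' @param q_cut specificity threshold on q.
#' @return list with `tests` (long table) and `specific` (per-RNA flag).
#' @export
tissue_specificity <- function(adipose, others, q_cut = 0.1) {
  rows <- list()
  for (tn in names(others)) {
    o <- others[[tn]]
    shared <- intersect(adipose$rna_id, o$rna_id)
    a <- adipose[match(shared, adipose$rna_id), ]
    b <- o[match(shared, o$rna_id), ]
    se <- sqrt(a$var / a$n + b$var / b$n)
    bad <- se == 0
    if (any(bad)) warning(sum(bad), " RNA(s) with zero variance skipped")
    z <- ifelse(bad, NA, (a$mean - b$mean) / se)
    p <- 2 * pnorm(-abs(z))
    ok <- !is.na(p)
    q <- rep(NA_real_, length(p))
    q[ok] <- qvalues(pmax(p[ok], 1e-300))
    rows[[tn]] <- data.frame(rna_id = shared, tissue = tn, z = z, p = p,
                             q = q, stringsAsFactors = FALSE)
  }
  tests <- do.call(rbind, rows)
  rownames(tests) <- NULL
  spec <- tapply(seq_len(nrow(tests)), tests$rna_id, function(ix) {
    all(!is.na(tests$z[ix]) & tests$z[ix] > 0 & tests$q[ix] < q_cut)
  })
  list(tests = tests,
       specific = data.frame(rna_id = names(spec),
                             specific = as.logical(spec),
                             stringsAsFactors = FALSE))
}

#' Conservation vs expression contingency tests
#'
#' Pearson chi-squared (1 df) for the deviation of the fraction of highly
#' expressed, unconserved genes from independence; run once with the
#' mean-expression split and once with the expression-variance split.
#'
#' @param mean_expr,var_expr per-RNA mean and variance of log expression.
#' @param conservation per-RNA conservation scores (same order).
#' @param expr_cut high-expression threshold on the mean (log scale).
#' @param var_cut high-variability threshold on the variance (log scale).
#' @param cons_cut conservation threshold; below = unconserved.
#' @return data.frame with one row per split (`split`, `stat`, `p`, and
#'   the observed high-and-unconserved count).
#' @export
conservation_expression_test <- function(mean_expr, var_expr, conservation,
                                         expr_cut = 10, var_cut = 5,
                                         cons_cut = 0) {
  uncons <- conservation < cons_cut
  one <- function(high, label) {
    tab <- table(factor(high, levels = c(TRUE, FALSE)),
                 factor(uncons, levels = c(TRUE, FALSE)))
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
      stop("degenerate margin in contingency table")
    ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
    data.frame(split = label, stat = unname(ct$statistic),
               p = unname(ct$p.value),
               high_unconserved = tab[1, 1], stringsAsFactors = FALSE)
  }
  rbind(one(mean_expr > expr_cut, "mean"),
        one(var_expr > var_cut, "variance"))
}

#' Cluster co-expression enrichment
#'
#' Median of per-cluster median pairwise Pearson correlations
#' (covariate-residualised expression), compared to size-matched random
#' RNA sets by a two-sided Mann-Whitney U test.
#'
#' @param expr residualised expression matrix.
#' @param clusters data.frame with `cluster_id`, `rna_id`; clusters with
#'   fewer than two expressed members are ignored.
#' @param n_random number of random size-matched sets.
#' @param seed RNG seed for the random draws.
#' @return list with `cluster_median`, `random_median`, `p`,
#'   `cluster_medians`, `random_medians`.
#' @export
cluster_correlation_enrichment <- function(expr, clusters, n_random = 1000,
                                           seed = 1L) {
  set.seed(seed)
  med_pair_cor <- function(ids) {
    cm <- cor(t(expr[ids, , drop = FALSE]))
    median(cm[upper.tri(cm)])
  }
  cl <- split(clusters$rna_id, clusters$cluster_id)
  cl <- lapply(cl, intersect, rownames(expr))
  cl <- cl[vapply(cl, length, integer(1)) >= 2L]
  if (length(cl) < 2L) stop("need at least two clusters with >= 2 members")
  cmed <- vapply(cl, med_pair_cor, numeric(1))
  sizes <- vapply(cl, length, integer(1))
  rmed <- vapply(seq_len(n_random), function(i) {
    sz <- sizes[((i - 1L) %% length(sizes)) + 1L]
    med_pair_cor(sample(rownames(expr), sz))
  }, numeric(1))
  wt <- wilcox.test(cmed, rmed, exact = FALSE)
  list(cluster_median = median(cmed), random_median = median(rmed),
       p = wt$p.value, cluster_medians = cmed, random_medians = rmed)
}

#' miRNA-target correlation summary
#'
#' Pearson correlation per (miRNA, target) pair on residualised data, a
#' one-sample t-test of the mean correlation against zero, and a
#' Mann-Whitney comparison of the pair correlations against random pairs.
#'
#' @param mirna_expr miRNA expression matrix (residualised).
#' @param mrna_expr mRNA expression matrix (residualised), samples
#'   aligned.
#' @param pairs data.frame with `mirna`, `probe` target pairs.
#' @param n_background random background pairs drawn per observed pair.
#' @param seed RNG seed.
#' @return list with `mean_r`, `t_p`, `mw_p`, `pair_r`, `background_r`.
#' @export
target_correlation_summary <- function(mirna_expr, mrna_expr, pairs,
                                       n_background = 1000, seed = 1L) {
  if (nrow(pairs) == 0L) stop("empty pair list")
  set.seed(seed)
  stopifnot(all(pairs$mirna %in% rownames(mirna_expr)),
            all(pairs$probe %in% rownames(mrna_expr)))
  pr <- vapply(seq_len(nrow(pairs)), function(i)
    cor(mirna_expr[pairs$mirna[i], ], mrna_expr[pairs$probe[i], ]),
    numeric(1))
  bg <- vapply(seq_len(n_background), function(i)
    cor(mirna_expr[sample(nrow(mirna_expr), 1), ],
        mrna_expr[sample(nrow(mrna_expr), 1), ]),
    numeric(1))
  tt <- t.test(pr, mu = 0)
  mw <- wilcox.test(pr, bg, exact = FALSE)
  list(mean_r = mean(pr), t_p = tt$p.value, mw_p = mw$p.value,
       pair_r = pr, background_r = bg)
}
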