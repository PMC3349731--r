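#' Median-of-ratios size factors
#'
#' For library j, `s_j` is the median over genes g of `n_gj / GM_g`, where
#' `GM_g` is the geometric mean of gene g's counts across samples.  Genes
#' with a zero count in any sample are excluded from the median.  Factors
#' are rescaled to unit geometric mean so that corrected libraries are
#' directly comparable and the estimator is a fixed point on corrected
#' counts.
#'
#' @param counts count matrix (RNA x sample).
#' @return named numeric vector of positive size factors.
#' @export
size_factors <- function(counts) {
  if (ncol(counts) < 2L) stop("need at least two samples")
  pos <- rowSums(counts <= 0) == 0L
  if (!any(pos))
    stop("normalisation error: no gene with all-positive counts")
  m <- counts[pos, , drop = FALSE]
  log_gm <- rowMeans(log(m))
  s <- apply(exp(sweep(log(m), 1L, log_gm, "-")), 2L, median)
  if (any(!is.finite(s) | s <= 0))
    stop("normalisation error: non-positive size factor")
  s / exp(mean(log(s)))
}

#' Log2 size-factor-corrected expression
#'
#' `log2((n_gj + pseudocount) / s_j)`; the pseudocount (default 0.5) keeps
#' zero counts finite.
#'
#' @param counts count matrix.
#' @param s size factors from [size_factors()].
#' @param pseudocount added to every count before the log.
#' @return log2 expression matrix.
#' @export
log_normalise <- function(counts, s = size_factors(counts),
                          pseudocount = 0.5) {
  if (any(s <= 0)) stop("size factors must be positive")
  log2(sweep(counts + pseudocount, 2L, s, "/"))
}

#' Principal-component / covariate screen for batch effects
#'
#' Decomposes the centred expression matrix into sample-space principal
#' components and correlates each screened PC with each covariate.  The
#' statistic `t = r * sqrt((n - 2) / (1 - r^2))` is referred to a
#' two-tailed t distribution on `n - 2` degrees of freedom, Bonferroni
#' corrected over `n_tests` tests (by default one per sample, mirroring a
#' screen over every possible component).  Categorical covariates enter
#' one-hot; the reported r is the largest-magnitude level correlation.
#'
#' @param expr log expression matrix (RNA x sample).
#' @param covariates data.frame of per-sample covariates (numeric or
#'   categorical), rows aligned with `colnames(expr)`.
#' @param n_pcs number of components screened (default `min(n, 20)`).
#' @param alpha family-wise significance level.
#' @param n_tests Bonferroni denominator.
#' @return data.frame with `pc`, `covariate`, `r`, `t`, `p`, `p_adj`,
#'   `significant`.
#' @export
pc_covariate_screen <- function(expr, covariates,
                                n_pcs = min(ncol(expr), 20L),
                                alpha = 0.05, n_tests = ncol(expr)) {
  n <- ncol(expr)
  if (n < 3L) stop("need at least three samples")
  pcs <- prcomp(t(expr), center = TRUE, scale. = FALSE)$x
  n_pcs <- min(n_pcs, ncol(pcs))
  covariates <- as.data.frame(covariates)
  rows <- list()
  for (cv in names(covariates)) {
    v <- covariates[[cv]]
    if (is.numeric(v)) {
      if (sd(v) == 0) { warning("constant covariate skipped: ", cv); next }
      cols <- matrix(v, ncol = 1)
    } else {
      f <- factor(v)
      if (nlevels(f) < 2L) { warning("constant covariate skipped: ", cv); next }
      cols <- vapply(levels(f), function(l) as.numeric(f == l), numeric(n))
    }
    for (i in seq_len(n_pcs)) {
      rs <- suppressWarnings(cor(pcs[, i], cols))
      r <- rs[which.max(abs(rs))]
      tt <- r * sqrt((n - 2) / (1 - r^2))
      p <- 2 * pt(-abs(tt), df = n - 2)
      rows[[length(rows) + 1L]] <- data.frame(
        pc = paste0("PC", i), covariate = cv, r = r, t = tt, p = p,
        p_adj = min(1, p * n_tests), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$significant <- out$p_adj < alpha
  out
}
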