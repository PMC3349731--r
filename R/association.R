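#' Gaussian likelihood-ratio test for a linear predictor
#'
#' Fits nested Gaussian linear models (covariates only vs covariates plus
#' predictor) by least squares and refers `-2 log(likelihood ratio) =
#' n * ln(RSS_null / RSS_full)` to a chi-squared distribution with one
#' degree of freedom.
#'
#' @param y response vector (no missing values).
#' @param x predictor vector.
#' @param covariates optional data.frame of adjustment covariates
#'   (numeric, or categorical entering one-hot).
#' @return list with `stat`, `p`, `sign` (sign of the fitted predictor
#'   coefficient) and `beta`; NULL if the predictor is collinear with the
#'   covariates (with a warning).
#' @export
lrt_linear <- function(y, x, covariates = NULL) {
  stopifnot(!anyNA(y), length(x) == length(y))
  n <- length(y)
  C <- encode_covariates(covariates)
  X0 <- cbind(`(Intercept)` = rep(1, n), C)
  q0 <- qr(X0)
  X1 <- cbind(X0, x = x)
  q1 <- qr(X1)
  if (q1$rank <= q0$rank) {
    warning("predictor collinear with covariates; skipped")
    return(NULL)
  }
  r0 <- qr.resid(q0, y)
  r1 <- qr.resid(q1, y)
  rss0 <- sum(r0^2)
  rss1 <- sum(r1^2)
  beta <- qr.coef(q1, y)[["x"]]
  if (rss1 <= .Machine$double.eps * rss0 || rss1 == 0) {
    return(list(stat = Inf, p = .Machine$double.xmin, sign = sign(beta),
                beta = beta))
  }
  stat <- n * log(rss0 / rss1)
  list(stat = stat, p = pchisq(stat, df = 1, lower.tail = FALSE),
       sign = sign(beta), beta = beta)
}

#' Storey q-values
#'
#' FDR-adjusted significance over a family of p-values: `pi0` is estimated
#' by the smoother method (natural cubic spline of `pi0(lambda)` over a
#' lambda grid, evaluated at the largest lambda) or by the bootstrap
#' method, and `q_i = min_{p_j >= p_i} pi0 * m * p_j / rank(p_j)`, capped
#' at 1.
#'
#' @param p p-values in (0, 1].
#' @param lambda grid for pi0 estimation.
#' @param pi0_method "smoother" or "bootstrap".
#' @param pi0 optionally force pi0 (e.g. 1 reproduces Benjamini-Hochberg).
#' @return q-values in the order of `p`.
#' @export
qvalues <- function(p, lambda = seq(0.05, 0.95, 0.05),
                    pi0_method = c("smoother", "bootstrap"), pi0 = NULL) {
  if (!length(p)) stop("empty p-value vector")
  if (any(p <= 0 | p > 1 | is.na(p))) stop("p-values must lie in (0, 1]")
  pi0_method <- match.arg(pi0_method)
  m <- length(p)
  if (is.null(pi0)) {
    if (m < 100 || max(p) < max(lambda)) {
      pi0 <- 1
    } else {
      pi0_l <- vapply(lambda, function(l) mean(p > l) / (1 - l), numeric(1))
      if (pi0_method == "smoother") {
        fit <- smooth.spline(lambda, pi0_l, df = 3)
        pi0 <- stats::predict(fit, x = max(lambda))$y
      } else {
        mse <- vapply(seq_along(lambda), function(i) {
          boot <- vapply(1:100, function(b) {
            pb <- sample(p, m, replace = TRUE)
            mean(pb > lambda[i]) / (1 - lambda[i])
          }, numeric(1))
          mean((boot - min(pi0_l))^2)
        }, numeric(1))
        pi0 <- pi0_l[which.min(mse)]
      }
      pi0 <- min(max(pi0, .Machine$double.eps), 1)
    }
  }
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  q <- pmin(1, cummin(pi0 * m * p[o] / rank(p, ties.method = "max")[o]))
  q[ro]
}

#' Cis-eQTL likelihood-ratio scan
#'
#' Tests every retained SNP (MAF > `maf_min`, info > `info_min`) whose
#' position falls within `window` bases of an RNA's annotated interval
#' against that RNA's expression, adjusting for the covariates.  q-values
#' are computed over the pooled list of all tests.
#'
#' @param expr log2 expression matrix (RNA x sample).
#' @param genotypes dosage matrix (SNP x sample) in `[0, 2]`.
#' @param snp_info data.frame with `snp`, `pos`, `maf`, `info`.
#' @param annotation data.frame with `rna_id`, `start`, `end`.
#' @param covariates per-sample covariate data.frame, or NULL.
#' @param window cis window in bases either side of the transcript.
#' @param maf_min,info_min SNP retention thresholds.
#' @return data.frame of association results (`rna`, `snp`, `beta`,
#'   `sign`, `stat`, `p`, `q`), ordered by p.
#' @export
cis_eqtl_scan <- function(expr, genotypes, snp_info, annotation,
                          covariates = NULL, window = 100000,
                          maf_min = 0.05, info_min = 0.8) {
  samples <- intersect(colnames(expr), colnames(genotypes))
  if (!length(samples)) stop("expression and genotype samples disjoint")
  keep <- snp_info$maf > maf_min & snp_info$info > info_min
  si <- snp_info[keep, , drop = FALSE]
  rows <- list()
  for (rna in rownames(expr)) {
    a <- annotation[annotation$rna_id == rna, , drop = FALSE]
    if (nrow(a) == 0L) {
      warning("no annotation for ", rna, "; skipped")
      next
    }
    cis <- si$pos >= a$start[1] - window & si$pos <= a$end[1] + window
    for (snp in si$snp[cis]) {
      fit <- lrt_linear(expr[rna, samples], genotypes[snp, samples],
                        if (!is.null(covariates))
                          covariates[match(samples, covariates$sample_id),
                                     setdiff(names(covariates), "sample_id"),
                                     drop = FALSE])
      if (is.null(fit)) next
      rows[[length(rows) + 1L]] <- data.frame(
        rna = rna, snp = snp, beta = fit$beta, sign = fit$sign,
        stat = fit$stat, p = fit$p, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(rna = character(0), snp = character(0),
                      beta = numeric(0), sign = numeric(0),
                      stat = numeric(0), p = numeric(0), q = numeric(0)))
  out <- do.call(rbind, rows)
  out$q <- qvalues(out$p)
  out[order(out$p), ]
}

#' Phenotype association scan
#'
#' One likelihood-ratio test per (RNA, trait) with covariate adjustment;
#' q-values are computed per trait.  Insulin-like assay floors can be
#' applied (values below the detection limit reset to a fixed value).
#' Traits with more than `max_missing` missing values are skipped.
#'
#' @param expr log2 expression matrix (RNA x sample).
#' @param phenotypes data.frame with `sample_id` and trait columns.
#' @param covariates covariate data.frame with `sample_id`.
#' @param traits which phenotype columns to test.
#' @param floor_traits traits to floor; values below `floor_detect` are
#'   set to `floor_value`.
#' @param floor_detect,floor_value assay floor parameters.
#' @param max_missing maximal tolerated missing fraction per trait.
#' @return named list of per-trait association tables.
#' @export
phenotype_assoc <- function(expr, phenotypes, covariates = NULL,
                            traits = setdiff(names(phenotypes), "sample_id"),
                            floor_traits = "insulin", floor_detect = 13,
                            floor_value = 12, max_missing = 0.2) {
  samples <- intersect(colnames(expr), phenotypes$sample_id)
  ph <- phenotypes[match(samples, phenotypes$sample_id), , drop = FALSE]
  res <- list()
  for (tr in traits) {
    v <- ph[[tr]]
    if (mean(is.na(v)) > max_missing) {
      warning("trait ", tr, " skipped: too many missing values")
      next
    }
    if (tr %in% floor_traits) v[!is.na(v) & v < floor_detect] <- floor_value
    ok <- !is.na(v)
    if (sd(v[ok]) == 0) stop("constant trait: ", tr)
    rows <- list()
    for (rna in rownames(expr)) {
      fit <- lrt_linear(expr[rna, samples][ok], v[ok],
                        if (!is.null(covariates))
                          covariates[match(samples[ok],
                                           covariates$sample_id),
                                     setdiff(names(covariates), "sample_id"),
                                     drop = FALSE])
      if (is.null(fit)) next
      rows[[length(rows) + 1L]] <- data.frame(
        rna = rna, trait = tr, beta = fit$beta, sign = fit$sign,
        stat = fit$stat, p = fit$p, stringsAsFactors = FALSE)
    }
    tab <- do.call(rbind, rows)
    tab$q <- qvalues(tab$p)
    res[[tr]] <- tab[order(tab$p), ]
  }
  res
}

#' Lean/obese group contrast
#'
#' Subjects are dichotomised as lean (BMI < `lean_max`) or obese
#' (BMI > `obese_min`); everyone in between is excluded.  Each RNA's
#' expression is tested against the binary group with a likelihood-ratio
#' test, adjusting for covariates; q-values over the tested RNAs.
#'
#' @param expr log2 expression matrix.
#' @param bmi named BMI vector (names = sample ids) or vector aligned
#'   with `colnames(expr)`.
#' @param covariates covariate data.frame with `sample_id`, or NULL.
#' @param lean_max,obese_min group cut-offs.
#' @return association table with `rna`, `beta`, `stat`, `p`, `q`.
#' @export
group_contrast <- function(expr, bmi, covariates = NULL, lean_max = 25,
                           obese_min = 30) {
  if (is.null(names(bmi))) names(bmi) <- colnames(expr)
  samples <- intersect(colnames(expr), names(bmi))
  b <- bmi[samples]
  grp <- ifelse(b < lean_max, 0, ifelse(b > obese_min, 1, NA))
  use <- !is.na(grp)
  if (sum(grp[use] == 0) == 0 || sum(grp[use] == 1) == 0)
    stop("a BMI group is empty")
  rows <- list()
  for (rna in rownames(expr)) {
    fit <- lrt_linear(expr[rna, samples][use], grp[use],
                      if (!is.null(covariates))
                        covariates[match(samples[use],
                                         covariates$sample_id),
                                   setdiff(names(covariates), "sample_id"),
                                   drop = FALSE])
    if (is.null(fit)) next
    rows[[length(rows) + 1L]] <- data.frame(
      rna = rna, beta = fit$beta, stat = fit$stat, p = fit$p,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out$q <- qvalues(out$p)
  out <- out[order(out$p), ]
  attr(out, "n_lean") <- sum(grp[use] == 0)
  attr(out, "n_obese") <- sum(grp[use] == 1)
  attr(out, "n_excluded") <- sum(!use)
  out
}

#' Mature/star arm correlation and arm-difference QTL scan
#'
#' Spearman correlation between each mature arm and its alternate (star)
#' arm, flagging |rho| > 0.4, followed by a cis QTL scan on the
#' (mature - star) log2 expression difference using the eQTL machinery.
#'
#' @param expr log2 expression matrix containing both arms.
#' @param arm_pairs data.frame with `mature_id`, `star_id`.
#' @param genotypes,snp_info,annotation,covariates,window as in
#'   [cis_eqtl_scan()]; annotation must cover the mature arms.
#' @param rho_flag flag threshold on |rho|.
#' @return list with `correlations` and `qtl` tables.
#' @export
arm_analysis <- function(expr, arm_pairs, genotypes = NULL,
                         snp_info = NULL, annotation = NULL,
                         covariates = NULL, window = 100000,
                         rho_flag = 0.4) {
  rows <- list()
  diffs <- list()
  for (i in seq_len(nrow(arm_pairs))) {
    m <- arm_pairs$mature_id[i]; s <- arm_pairs$star_id[i]
    if (!m %in% rownames(expr) || !s %in% rownames(expr)) next
    if (sd(expr[m, ]) == 0 || sd(expr[s, ]) == 0) {
      warning("arm pair skipped (constant expression): ", m)
      next
    }
    ct <- suppressWarnings(
      cor.test(expr[m, ], expr[s, ], method = "spearman", exact = FALSE))
    rows[[length(rows) + 1L]] <- data.frame(
      mature_id = m, star_id = s, rho = unname(ct$estimate),
      p = ct$p.value, flagged = abs(ct$estimate) > rho_flag,
      stringsAsFactors = FALSE)
    diffs[[m]] <- expr[m, ] - expr[s, ]
  }
  correlations <- if (length(rows)) do.call(rbind, rows) else
    data.frame(mature_id = character(0), star_id = character(0),
               rho = numeric(0), p = numeric(0), flagged = logical(0))
  qtl <- NULL
  if (!is.null(genotypes) && length(diffs)) {
    dmat <- do.call(rbind, diffs)
    rownames(dmat) <- names(diffs)
    qtl <- cis_eqtl_scan(dmat, genotypes, snp_info, annotation,
                         covariates, window = window)
  }
  list(correlations = correlations, qtl = qtl)
}
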