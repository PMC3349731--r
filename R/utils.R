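#' @useDynLib srnapop, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import data.table
#' @importFrom stats cor cor.test chisq.test coef lm lm.fit median optim
#'   p.adjust pbinom pchisq phyper pnorm prcomp pt qnorm qt quantile rbinom
#'   rlnorm rmultinom rnorm rpois runif sd setNames smooth.spline t.test
#'   wilcox.test rgamma complete.cases ks.test var
#' @importFrom utils head tail write.table read.table
NULL

# quiet R CMD check notes for data.table NSE columns
utils::globalVariables(c(
  ".", "read", "target", "stratum", "rank_", "dist", "k", "sample_id",
  "cnt", "word", "utr", "rnk", "N_", "count", "weight", "offset", "subs",
  "gaps", "strand", "rna", "base", "depth", "nonref", "locus"
))

BASES <- c("A", "C", "G", "T")

# minimal IUPAC code covering a set of bases
IUPAC_FROM_SET <- c(
  A = "A", C = "C", G = "G", T = "T",
  AG = "R", CT = "Y", CG = "S", AT = "W", GT = "K", AC = "M",
  CGT = "B", AGT = "D", ACT = "H", ACG = "V", ACGT = "N"
)

iupac_code <- function(bases) {
  key <- paste(sort(unique(toupper(bases))), collapse = "")
  code <- IUPAC_FROM_SET[key]
  if (is.na(code)) stop("not a set of DNA bases: ", key)
  unname(code)
}

# allele set of an IUPAC symbol
IUPAC_SET <- list(
  A = "A", C = "C", G = "G", T = "T", U = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"), B = c("C", "G", "T"),
  D = c("A", "G", "T"), H = c("A", "C", "T"), V = c("A", "C", "G"),
  N = c("A", "C", "G", "T")
)

revcomp <- function(x) {
  chartr("ACGTUacgtu", "TGCAAtgcaa",
         vapply(strsplit(x, ""), function(s) paste(rev(s), collapse = ""),
                character(1)))
}

rand_dna <- function(n, len) {
  vapply(seq_len(n), function(i)
    paste(sample(BASES, len, replace = TRUE), collapse = ""), character(1))
}

# split sequences into an n x width character matrix ("" padded)
seq_char_matrix <- function(seqs, width = max(nchar(seqs), 1L)) {
  n <- length(seqs)
  m <- matrix("", nrow = n, ncol = width)
  sp <- strsplit(seqs, "")
  for (i in seq_len(n)) {
    s <- sp[[i]]
    if (length(s)) m[i, seq_along(s)] <- s
  }
  m
}

#' Significance boundary of the PC-covariate correlation screen
#'
#' Smallest absolute Pearson correlation that remains significant when
#' `t = r * sqrt((n - 2) / (1 - r^2))` is referred to a two-tailed t
#' distribution on `n - 2` degrees of freedom and Bonferroni-corrected over
#' `n_tests` tests at level `alpha`.
#'
#' @param n number of samples.
#' @param n_tests Bonferroni denominator (one test per component screened).
#' @param alpha family-wise significance level.
#' @return the critical |r|.
#' @export
critical_r <- function(n, n_tests = n, alpha = 0.05) {
  tcrit <- qt(1 - (alpha / n_tests) / 2, df = n - 2)
  tcrit / sqrt(n - 2 + tcrit^2)
}

#' Average per-sample read count at a total-count detection floor
#'
#' The matrix filter keeps an RNA observed at least `min_total` times across
#' the cohort; this is the per-sample average that corresponds to.
#'
#' @param min_total total-count threshold across all samples.
#' @param n_samples cohort size.
#' @return average reads per sample at the threshold.
#' @export
reads_per_sample <- function(min_total, n_samples) {
  min_total / n_samples
}

# one-hot / numeric encoding of a covariate data.frame (no intercept column)
encode_covariates <- function(covariates) {
  if (is.null(covariates) || ncol(as.data.frame(covariates)) == 0L)
    return(NULL)
  covariates <- as.data.frame(covariates)
  cols <- lapply(names(covariates), function(nm) {
    v <- covariates[[nm]]
    if (is.numeric(v)) {
      m <- matrix(v, ncol = 1)
      colnames(m) <- nm
      m
    } else {
      f <- factor(v)
      if (nlevels(f) < 2L)
        return(NULL)
      m <- stats::model.matrix(~ f)[, -1, drop = FALSE]
      colnames(m) <- paste0(nm, levels(f)[-1])
      m
    }
  })
  cols <- cols[!vapply(cols, is.null, logical(1))]
  if (!length(cols)) return(NULL)
  do.call(cbind, cols)
}
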