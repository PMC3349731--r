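#' Seed word family of an adenosine-ending 8-mer
#'
#' For an 8-mer `s8` ending in A: the middle 6-mer, the two constituent
#' 7-mers and the 8-mer itself.
#'
#' @param s8 an 8-character DNA string ending in "A".
#' @return list with `s8`, `s6`, `s7_1`, `s7_2`.
#' @export
seed_family <- function(s8) {
  if (nchar(s8) != 8L || substr(s8, 8, 8) != "A")
    stop("s8 must be an 8-mer ending in A")
  list(s8 = s8, s6 = substr(s8, 2, 7), s7_1 = substr(s8, 1, 7),
       s7_2 = substr(s8, 2, 8))
}

#' Rank 3'UTRs by correlation with a miRNA
#'
#' Orders probes (and their UTRs) by the Pearson correlation of probe
#' expression with the miRNA expression, most negative first.  Constant
#' probes are dropped with a warning; ties break by stable probe-id order.
#'
#' @param mirna_expr per-sample miRNA expression vector.
#' @param mrna_expr probe x sample expression matrix.
#' @param utrs named character vector of UTR sequences (names = probe
#'   ids).
#' @return data.frame with `probe`, `r`, `utr` in rank order.
#' @export
rank_utrs <- function(mirna_expr, mrna_expr, utrs) {
  probes <- intersect(rownames(mrna_expr), names(utrs))
  if (length(probes) < 10L) stop("need at least 10 UTRs with expression")
  m <- mrna_expr[probes, , drop = FALSE]
  const <- apply(m, 1L, sd) == 0
  if (any(const)) {
    warning(sum(const), " constant probe(s) dropped")
    probes <- probes[!const]
    m <- m[probes, , drop = FALSE]
  }
  r <- as.numeric(cor(t(m), mirna_expr))
  o <- order(r, probes)
  data.frame(probe = probes[o], r = r[o], utr = unname(utrs[probes[o]]),
             stringsAsFactors = FALSE)
}

# per-UTR overlapping occurrence counts of every word of a given length
utr_word_table <- function(utrs, wlen) {
  rows <- lapply(seq_along(utrs), function(i) {
    u <- utrs[i]
    L <- nchar(u)
    if (L < wlen) return(NULL)
    w <- substring(u, 1:(L - wlen + 1L), wlen:L)
    tt <- table(w)
    data.table::data.table(word = names(tt), utr = i,
                           cnt = as.integer(tt))
  })
  data.table::rbindlist(rows[!vapply(rows, is.null, logical(1))])
}

#' Precompute per-UTR word occurrence tables for lengths 6-8
#'
#' @param utrs UTR sequences (any order; `utr` indexes this vector).
#' @return list with `words` (per-length data.tables of word, utr, cnt),
#'   `windows` (per-length window counts) and `n_utr`.
#' @export
utr_word_tables <- function(utrs) {
  words <- list()
  windows <- list()
  for (wl in 6:8) {
    words[[as.character(wl)]] <- utr_word_table(utrs, wl)
    windows[[as.character(wl)]] <- pmax(nchar(utrs) - wl + 1L, 0L)
  }
  list(words = words, windows = windows, n_utr = length(utrs))
}

# per-UTR word probability under a third-order Markov chain fitted on the
# UTR itself (pseudocount-smoothed); used to rescale expected counts
markov_word_prob <- function(utrs, word, pc = 0.5) {
  wlen <- nchar(word)
  stopifnot(wlen >= 4L)
  dna <- Biostrings::DNAStringSet(utrs)
  C3 <- Biostrings::oligonucleotideFrequency(dna, 3L)
  C4 <- Biostrings::oligonucleotideFrequency(dna, 4L)
  n3 <- rowSums(C3); n4 <- rowSums(C4)
  first3 <- substr(word, 1, 3)
  p <- (C3[, first3] + pc) / (n3 + pc * 64)
  for (i in 4:wlen) {
    ctx4 <- substr(word, i - 3, i)
    ctx3 <- substr(word, i - 3, i - 1)
    p <- p * (C4[, ctx4] + pc) / (C3[, ctx3] + pc * 4)
  }
  as.numeric(p)
}

#' Hypergeometric word-enrichment landscape over a ranked UTR list
#'
#' For each leading-list size n in the grid, the one-sided upper
#' hypergeometric tail of the word's occurrence count in the top-n UTRs
#' against the full set, counting overlapping occurrences in sliding
#' windows.  The optional third-order Markov correction rescales each
#' UTR's effective window count by the ratio of its own Markov word
#' probability to the pooled occurrence rate, damping composition bias.
#'
#' @param ordered_utrs UTR sequences in rank order (see [rank_utrs()]).
#' @param word the seed word (length 6-8).
#' @param grid leading-list sizes n; defaults to 20 evenly spaced cut
#'   points (values beyond the list length are truncated).
#' @param markov apply the composition correction.
#' @return data.frame with `n`, `count`, `p`.
#' @export
word_landscape <- function(ordered_utrs, word, grid = NULL,
                           markov = FALSE) {
  wlen <- nchar(word)
  if (!wlen %in% 6:8) stop("word length must be 6, 7 or 8")
  nu <- length(ordered_utrs)
  if (is.null(grid))
    grid <- unique(round(seq(1, nu, length.out = min(20L, nu))))
  grid <- sort(unique(pmin(grid, nu)))
  x <- Biostrings::vcountPattern(word, Biostrings::DNAStringSet(ordered_utrs))
  windows <- pmax(nchar(ordered_utrs) - wlen + 1L, 0L)
  K <- sum(x)
  if (markov && K > 0) {
    pm <- markov_word_prob(ordered_utrs, word)
    pool_rate <- K / sum(windows)
    eff <- windows * pm / pool_rate
    eff <- eff * sum(windows) / sum(eff)  # keep the universe size
    windows <- eff
  }
  N <- round(sum(windows))
  cx <- cumsum(x)
  cw <- cumsum(windows)
  p <- vapply(grid, function(n) {
    draws <- min(round(cw[n]), N)
    phyper(cx[n] - 1, K, N - K, draws, lower.tail = FALSE)
  }, numeric(1))
  data.frame(n = grid, count = cx[grid], p = p)
}

#' Combined multi-length seed-enrichment score
#'
#' `max_n [ -log10 p_n(s6) - log10 p_n(s7_1) - log10 p_n(s7_2)
#' - log10 p_n(s8) ]` over the grid of leading-list sizes, with each
#' -log10 p capped at `cap` to avoid underflow infinities.
#'
#' @inheritParams word_landscape
#' @param s8 adenosine-ending 8-mer seed.
#' @param cap cap on each -log10 p.
#' @return list with `score`, `argmax_n` and the per-word landscapes.
#' @export
seed_score <- function(ordered_utrs, s8, grid = NULL, markov = FALSE,
                       cap = 320) {
  fam <- seed_family(s8)
  words <- c(fam$s6, fam$s7_1, fam$s7_2, fam$s8)
  ls <- lapply(words, function(w)
    word_landscape(ordered_utrs, w, grid, markov))
  combined <- Reduce(`+`, lapply(ls, function(d)
    pmin(-log10(pmax(d$p, 1e-320)), cap)))
  i <- which.max(combined)
  list(score = combined[i], argmax_n = ls[[1]]$n[i],
       combined = data.frame(n = ls[[1]]$n, score = combined),
       landscapes = setNames(ls, c("s6", "s7_1", "s7_2", "s8")))
}

#' Scores for many adenosine-ending 8-mers at once
#'
#' Batch path used to build the score background: word occurrence tables
#' for lengths 6-8 are computed once and cumulated at the grid cut points,
#' so scoring thousands of 8-mers (or re-scoring permuted rankings) costs
#' only lookups.  Uncorrected hypergeometric tails (the oracle-tested
#' path).
#'
#' @param ordered_utrs UTR sequences in rank order.
#' @param s8s character vector of 8-mers ending in A.
#' @param grid leading-list sizes (default 20 cut points).
#' @param cap cap on each -log10 p.
#' @param tables precomputed [utr_word_tables()] (avoids recounting when
#'   re-scoring the same UTR set under a different ranking).
#' @param ranks optional integer vector giving each UTR's rank (permuted
#'   rankings of the same UTR set); identity by default.
#' @return data.frame with `s8`, `score`, `argmax_n`.
#' @export
seed_score_batch <- function(ordered_utrs, s8s, grid = NULL, cap = 320,
                             tables = NULL, ranks = NULL) {
  if (is.null(tables)) tables <- utr_word_tables(ordered_utrs)
  nu <- tables$n_utr
  if (is.null(ranks)) ranks <- seq_len(nu)
  if (is.null(grid))
    grid <- unique(round(seq(1, nu, length.out = min(20L, nu))))
  grid <- sort(unique(pmin(grid, nu)))
  fams <- lapply(s8s, seed_family)
  need <- list(
    `6` = unique(vapply(fams, `[[`, character(1), "s6")),
    `7` = unique(c(vapply(fams, `[[`, character(1), "s7_1"),
                   vapply(fams, `[[`, character(1), "s7_2"))),
    `8` = unique(vapply(fams, `[[`, character(1), "s8")))
  per_len <- list()
  for (wl in 6:8) {
    wt <- tables$words[[as.character(wl)]]
    wt <- wt[word %in% need[[as.character(wl)]]]
    wt <- wt[, .(word, utr = ranks[utr], cnt)]
    windows <- tables$windows[[as.character(wl)]][order(ranks)]
    N <- sum(windows)
    cw <- cumsum(windows)
    Ks <- wt[, .(K = sum(cnt)), by = word]
    cum <- matrix(0L, nrow = nrow(Ks), ncol = length(grid),
                  dimnames = list(Ks$word, NULL))
    for (gi in seq_along(grid)) {
      agg <- wt[utr <= grid[gi], .(x = sum(cnt)), by = word]
      cum[agg$word, gi] <- agg$x
    }
    # -log10 upper tail for every (word, grid) cell
    lp <- matrix(0, nrow = nrow(cum), ncol = ncol(cum),
                 dimnames = dimnames(cum))
    for (gi in seq_along(grid)) {
      draws <- cw[grid[gi]]
      pv <- phyper(cum[, gi] - 1, Ks$K, N - Ks$K, draws,
                   lower.tail = FALSE)
      lp[, gi] <- pmin(-log10(pmax(pv, 1e-320)), cap)
    }
    per_len[[as.character(wl)]] <- lp
  }
  look <- function(lp, w) {
    if (w %in% rownames(lp)) lp[w, ] else rep(0, length(grid))
  }
  res <- lapply(fams, function(f) {
    tot <- look(per_len[["6"]], f$s6) + look(per_len[["7"]], f$s7_1) +
      look(per_len[["7"]], f$s7_2) + look(per_len[["8"]], f$s8)
    i <- which.max(tot)
    c(score = tot[i], argmax_n = grid[i])
  })
  out <- do.call(rbind, res)
  data.frame(s8 = s8s, score = out[, "score"], argmax_n = out[, "argmax_n"],
             stringsAsFactors = FALSE)
}

#' All adenosine-ending 8-mers (or a seeded random subset)
#'
#' @param n optional subset size (sampled without replacement).
#' @return character vector of 8-mers ending in A.
#' @export
a_ending_8mers <- function(n = NULL) {
  w7 <- do.call(paste0, expand.grid(rep(list(BASES), 7),
                                    stringsAsFactors = FALSE))
  all8 <- paste0(w7, "A")
  if (is.null(n) || n >= length(all8)) all8 else sample(all8, n)
}

# ---- generalized extreme-value distribution -------------------------------

#' GEV density, distribution, quantile and simulation
#'
#' Standard generalized extreme-value parametrisation with location `loc`,
#' scale `scale` and shape `shape` (shape 0 is Gumbel).
#'
#' @param x,q,p,n usual distribution arguments.
#' @param loc,scale,shape GEV parameters.
#' @param log,lower.tail usual switches.
#' @name gev
#' @export
dgev <- function(x, loc = 0, scale = 1, shape = 0, log = FALSE) {
  z <- (x - loc) / scale
  if (abs(shape) < 1e-9) {
    ld <- -log(scale) - z - exp(-z)
  } else {
    t <- 1 + shape * z
    ld <- ifelse(t > 0,
                 -log(scale) - (1 / shape + 1) * log(pmax(t, 1e-320)) -
                   pmax(t, 1e-320)^(-1 / shape),
                 -Inf)
  }
  if (log) ld else exp(ld)
}

#' @rdname gev
#' @export
pgev <- function(q, loc = 0, scale = 1, shape = 0, lower.tail = TRUE) {
  z <- (q - loc) / scale
  if (abs(shape) < 1e-9) {
    p <- exp(-exp(-z))
  } else {
    t <- 1 + shape * z
    p <- ifelse(t > 0, exp(-t^(-1 / shape)),
                ifelse(shape > 0, 0, 1))
  }
  if (lower.tail) p else 1 - p
}

#' @rdname gev
#' @export
qgev <- function(p, loc = 0, scale = 1, shape = 0) {
  if (abs(shape) < 1e-9) loc - scale * log(-log(p))
  else loc + scale * ((-log(p))^(-shape) - 1) / shape
}

#' @rdname gev
#' @export
rgev <- function(n, loc = 0, scale = 1, shape = 0) {
  qgev(runif(n), loc, scale, shape)
}

#' Maximum-likelihood GEV fit
#'
#' Fits location, scale and shape by numerical likelihood maximisation,
#' initialised from Gumbel moment estimates.
#'
#' @param x numeric sample.
#' @return list with `loc`, `scale`, `shape`, `convergence`, `nll`.
#' @export
fit_gev <- function(x) {
  stopifnot(length(x) >= 10)
  s0 <- sd(x) * sqrt(6) / pi
  m0 <- mean(x) - 0.5772157 * s0
  nll <- function(par) {
    ld <- dgev(x, par[1], exp(par[2]), par[3], log = TRUE)
    if (any(!is.finite(ld))) return(1e10)
    -sum(ld)
  }
  fit <- optim(c(m0, log(s0), 0.1), nll, method = "Nelder-Mead",
               control = list(maxit = 2000, reltol = 1e-10))
  list(loc = fit$par[1], scale = exp(fit$par[2]), shape = fit$par[3],
       convergence = fit$convergence, nll = fit$value)
}

#' Extreme-value significance of focal seed scores
#'
#' Fits a GEV null to the background of adenosine-ending 8-mer scores and
#' evaluates each focal miRNA's own seed score against its upper tail;
#' q-values across the focal miRNAs.  If the ML fit fails, the empirical
#' upper tail is used with a warning.
#'
#' @param background_scores scores of background 8-mers (>= 100).
#' @param focal_scores named vector of focal miRNA seed scores.
#' @return list with `results` (data.frame: `mirna`, `score`, `p`, `q`)
#'   and the fitted `null` parameters.
#' @export
evd_test <- function(background_scores, focal_scores) {
  if (length(background_scores) < 100)
    stop("need at least 100 background scores")
  fit <- tryCatch(fit_gev(background_scores), error = function(e) NULL)
  if (is.null(fit) || fit$convergence != 0 || !is.finite(fit$nll)) {
    warning("GEV fit did not converge; using empirical tail")
    p <- vapply(focal_scores, function(s)
      (1 + sum(background_scores >= s)) / (1 + length(background_scores)),
      numeric(1))
    fit <- NULL
  } else {
    p <- pgev(focal_scores, fit$loc, fit$scale, fit$shape,
              lower.tail = FALSE)
  }
  p <- pmin(pmax(p, 1e-300), 1)
  res <- data.frame(
    mirna = if (!is.null(names(focal_scores))) names(focal_scores)
            else paste0("mir", seq_along(focal_scores)),
    score = unname(focal_scores), p = unname(p),
    q = qvalues(unname(p)), stringsAsFactors = FALSE)
  list(results = res, null = fit)
}
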