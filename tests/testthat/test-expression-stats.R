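test_that("residualisation removes covariate structure exactly", {
  set.seed(50)
  n <- 30
  covs <- data.frame(batch = rep(c("a", "b", "c"), each = 10),
                     tag = rep(c("t1", "t2"), 15))
  X <- encode_covariates(covs)
  m <- matrix(rnorm(5 * n), nrow = 5, dimnames = list(paste0("r", 1:5)))
  res <- residualise(m, covs)
  # residuals orthogonal to every design column
  expect_lt(max(abs(res %*% cbind(1, X))), 1e-10)
  # a row equal to exact batch means residualises to zero
  bm <- c(a = 1, b = 5, c = -2)[covs$batch]
  m2 <- rbind(m, bm = bm)
  expect_lt(max(abs(residualise(m2, covs)["bm", ])), 1e-10)
  # a row orthogonal to the design is unchanged up to its mean
  v <- residuals(lm(rnorm(n) ~ X))
  m3 <- matrix(v, 1)
  expect_equal(as.numeric(residualise(m3, covs)), as.numeric(v - mean(v)),
               tolerance = 1e-10)
  expect_error(residualise(m, data.frame(b1 = covs$batch,
                                         b2 = covs$batch)),
               "rank-deficient")
})

test_that("tissue Z-tests are Welch-style and antisymmetric", {
  a <- data.frame(rna_id = c("r1", "r2"), mean = c(5, 8),
                  var = c(1, 2), n = 20)
  t1 <- data.frame(rna_id = c("r1", "r2"), mean = c(5, 8),
                   var = c(1, 2), n = 20)
  ts <- tissue_specificity(a, list(t1 = t1))
  expect_equal(ts$tests$z, c(0, 0))
  expect_equal(ts$tests$p, c(1, 1))

  # a 3-standard-error difference gives Z = 3, p ~ 0.0027
  se <- sqrt(1 / 20 + 1 / 20)
  t2 <- data.frame(rna_id = "r1", mean = 5 - 3 * se, var = 1, n = 20)
  a2 <- data.frame(rna_id = "r1", mean = 5, var = 1, n = 20)
  ts2 <- tissue_specificity(a2, list(t2 = t2))
  expect_equal(ts2$tests$z, 3, tolerance = 1e-12)
  expect_equal(ts2$tests$p, 0.0027, tolerance = 0.01)

  # swapping the tissues negates Z
  ts3 <- tissue_specificity(t2, list(adipose = a2))
  expect_equal(ts3$tests$z, -ts2$tests$z)
})

test_that("a planted adipose-specific RNA is flagged across tissues", {
  set.seed(51)
  mk <- function(shift) data.frame(
    rna_id = paste0("r", 1:10),
    mean = c(10 + shift, rnorm(9, 5)), var = 0.5, n = 25)
  adip <- mk(0)
  others <- list(liver = mk(-4), muscle = mk(-5), spleen = mk(-4.5))
  sp <- tissue_specificity(adip, others)
  expect_true(sp$specific$specific[sp$specific$rna_id == "r1"])
})

test_that("the conservation contingency test matches direct arithmetic", {
  # proportional rows give exactly zero
  high <- rep(c(TRUE, FALSE), c(20, 80))
  uncons <- rep(c(TRUE, FALSE, TRUE, FALSE), c(5, 15, 20, 60))
  r0 <- conservation_expression_test(
    ifelse(high, 11, 1), ifelse(high, 11, 1) - 6,
    ifelse(uncons, -1, 1), expr_cut = 10, var_cut = 4)
  expect_equal(r0$stat[1], 0, tolerance = 1e-12)

  # the 2x2 table [[0,30],[20,50]]: X2 = 36/6 + 36/24 + 36/14 + 36/56
  high2 <- rep(c(TRUE, FALSE), c(30, 70))
  uncons2 <- rep(c(TRUE, FALSE, TRUE, FALSE), c(0, 30, 20, 50))
  r2 <- conservation_expression_test(
    ifelse(high2, 11, 1), ifelse(high2, 11, 1), ifelse(uncons2, -1, 1))
  expect_equal(r2$stat[1], 36 / 6 + 36 / 24 + 36 / 14 + 36 / 56,
               tolerance = 1e-9)
  expect_equal(r2$high_unconserved[1], 0)

  expect_error(conservation_expression_test(rep(1, 10), rep(1, 10),
                                            rep(1, 10)),
               "degenerate")
})

test_that("cluster co-expression enrichment detects planted factors", {
  set.seed(52)
  n <- 40
  expr <- matrix(rnorm(60 * n), nrow = 60,
                 dimnames = list(paste0("g", 1:60), paste0("s", 1:n)))
  # 10 clusters of 3 members sharing a latent factor (loading 0.7)
  cl <- data.frame(cluster_id = rep(paste0("c", 1:10), each = 3),
                   rna_id = paste0("g", 1:30))
  for (k in 1:10) {
    f <- rnorm(n)
    ix <- (k - 1) * 3 + 1:3
    expr[ix, ] <- 0.7 * matrix(f, 3, n, byrow = TRUE) +
      sqrt(1 - 0.49) * expr[ix, ]
  }
  en <- cluster_correlation_enrichment(expr, cl, n_random = 400, seed = 7)
  expect_gt(en$cluster_median, en$random_median)
  expect_lt(en$p, 0.001)

  # duplicated profiles correlate perfectly
  dup <- rbind(a = expr[31, ], b = expr[31, ], expr[32:60, ])
  rownames(dup)[1:2] <- c("a", "b")
  cl2 <- data.frame(cluster_id = c("c1", "c1", "c2", "c2"),
                    rna_id = c("a", "b", rownames(dup)[3:4]))
  en2 <- cluster_correlation_enrichment(dup, cl2, n_random = 50, seed = 1)
  expect_equal(max(en2$cluster_medians), 1, tolerance = 1e-12)

  # random clusters over i.i.d. data are usually non-significant
  set.seed(53)
  null_expr <- matrix(rnorm(60 * n), nrow = 60,
                      dimnames = list(paste0("g", 1:60)))
  hits <- vapply(1:20, function(i) {
    clr <- data.frame(cluster_id = rep(paste0("c", 1:8), each = 3),
                      rna_id = sample(rownames(null_expr), 24))
    cluster_correlation_enrichment(null_expr, clr, n_random = 100,
                                   seed = i)$p < 0.05
  }, logical(1))
  expect_gte(mean(!hits), 0.7)
})

test_that("target correlation summaries match direct formulas", {
  set.seed(54)
  n <- 50
  mir <- matrix(rnorm(5 * n), nrow = 5,
                dimnames = list(paste0("m", 1:5), paste0("s", 1:n)))
  mrna <- matrix(rnorm(40 * n), nrow = 40,
                 dimnames = list(paste0("p", 1:40), paste0("s", 1:n)))
  pairs <- data.frame(mirna = "m1", probe = paste0("p", 1:10))
  ts <- target_correlation_summary(mir, mrna, pairs, n_background = 200)
  direct <- vapply(1:10, function(i) cor(mir["m1", ], mrna[i, ]),
                   numeric(1))
  expect_equal(ts$pair_r, direct, tolerance = 1e-12)
  # null coupling: mean r within 2 SE of zero
  expect_lt(abs(ts$mean_r), 2 * sd(ts$pair_r) / sqrt(10))

  # planted coupling -0.3 over 200 pairs
  set.seed(55)
  m2 <- matrix(rnorm(n), nrow = 1, dimnames = list("m", paste0("s", 1:n)))
  targ <- -0.3 * matrix(m2, 200, n, byrow = TRUE) +
    sqrt(1 - 0.09) * matrix(rnorm(200 * n), 200)
  rownames(targ) <- paste0("t", 1:200)
  colnames(targ) <- paste0("s", 1:n)
  ts2 <- target_correlation_summary(
    m2, targ, data.frame(mirna = "m", probe = rownames(targ)))
  expect_lt(ts2$mean_r, -0.2)
  expect_lt(ts2$t_p, 1e-6)
  expect_error(target_correlation_summary(mir, mrna, pairs[0, ]), "empty")
})
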