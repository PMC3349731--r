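test_that("the likelihood-ratio test behaves at the null and perfect fit", {
  set.seed(30)
  y <- rnorm(60)
  x <- rnorm(60)
  x_orth <- residuals(lm(x ~ y))  # orthogonal to y
  f <- lrt_linear(y, x_orth)
  expect_lt(f$stat, 1e-20)
  expect_equal(f$p, 1, tolerance = 1e-6)
  # perfect fit: p capped, not NaN
  f2 <- lrt_linear(y, y)
  expect_true(is.finite(f2$stat) || is.infinite(f2$stat))
  expect_gt(f2$stat, 0)
  expect_lt(f2$p, 1e-100)
  expect_equal(f2$sign, 1)
  # collinear predictor is skipped with a warning
  cov <- data.frame(z = x)
  expect_warning(out <- lrt_linear(y, x, cov), "collinear")
  expect_null(out)
})

test_that("LRT p-values are uniform under the null and match the F test", {
  set.seed(31)
  n <- 80
  ps <- vapply(1:800, function(i)
    lrt_linear(rnorm(n), rnorm(n))$p, numeric(1))
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)

  # asymptotic equivalence with the F-test transform
  for (i in 1:20) {
    y <- rnorm(n); x <- rnorm(n)
    p_lrt <- lrt_linear(y, x)$p
    p_f <- anova(lm(y ~ x))[["Pr(>F)"]][1]
    expect_lt(abs(p_lrt - p_f) / p_f, 0.1)
  }
})

test_that("an orthogonal covariate leaves the LRT statistic unchanged", {
  set.seed(32)
  n <- 50
  y <- rnorm(n); x <- rnorm(n)
  base <- lrt_linear(y, x)$stat
  z <- rnorm(n)
  z <- residuals(lm(z ~ x + y))  # orthogonal to both
  with_cov <- lrt_linear(y, x, data.frame(z = z))$stat
  expect_lt(abs(base - with_cov), 1e-8)
})

test_that("q-values reproduce BH with pi0 = 1 and stay monotone", {
  expect_equal(qvalues(rep(1, 20)), rep(1, 20))
  set.seed(33)
  p <- c(rep(0.001, 10), runif(990))
  expect_equal(qvalues(p, pi0 = 1), p.adjust(p, "BH"), tolerance = 1e-10)
  p2 <- runif(1000)
  expect_equal(qvalues(p2, pi0 = 1), p.adjust(p2, "BH"),
               tolerance = 1e-10)
  q <- qvalues(p)
  expect_true(all(diff(q[order(p)]) >= -1e-12))
  expect_true(all(q > 0 & q <= 1))
  expect_error(qvalues(numeric(0)), "empty")
  expect_error(qvalues(c(0.5, 0)), "0, 1")
})

test_that("the cis window is respected to the base", {
  set.seed(34)
  n <- 40
  expr <- matrix(rnorm(n), nrow = 1,
                 dimnames = list("rna1", paste0("s", 1:n)))
  anno <- data.frame(rna_id = "rna1", start = 200000, end = 200022)
  geno <- matrix(rbinom(3 * n, 2, 0.4), nrow = 3,
                 dimnames = list(c("in1", "edge", "out1"),
                                 paste0("s", 1:n)))
  si <- data.frame(snp = c("in1", "edge", "out1"),
                   pos = c(150000, 100000, 99999),
                   maf = 0.4, info = 0.99)
  res <- cis_eqtl_scan(expr, geno, si, anno)
  expect_setequal(res$snp, c("in1", "edge"))  # 100,001 bases away: excluded
})

test_that("planted cis-eQTLs are recovered with covariate adjustment", {
  cfg <- sim_config(n_samples = 100L, n_mirna = 15L, n_snorna = 5L,
                    n_other = 0L, read_depth_mean = 20000, seed = 35L,
                    eqtl_effects = data.frame(rna = "mir002-5p",
                                              snp = "rs_eqtl", beta = 1,
                                              maf = 0.3))
  cat <- make_reference_catalogue(cfg)
  truth <- simulate_cohort(cat, cfg)
  expr <- log_normalise(truth$counts)
  covs <- truth$covariates[, c("sample_id", "age", "batch", "tag")]
  res <- cis_eqtl_scan(expr, truth$genotypes, truth$snp_info,
                       truth$annotation, covs)
  hit <- res[res$rna == "mir002-5p" & res$snp == "rs_eqtl", ]
  expect_equal(nrow(hit), 1L)
  expect_lt(hit$q, 0.05)
  expect_equal(hit$sign, 1)
})

test_that("phenotype scans floor insulin and control the null", {
  set.seed(36)
  n <- 60
  expr <- matrix(rnorm(20 * n), nrow = 20,
                 dimnames = list(paste0("r", 1:20), paste0("s", 1:n)))
  ph <- data.frame(sample_id = paste0("s", 1:n),
                   insulin = round(runif(n, 5, 60)),
                   bmi = rnorm(n, 26, 4))
  res <- phenotype_assoc(expr, ph)
  expect_named(res, c("insulin", "bmi"))
  # permuted phenotype: about 5% of tests nominally significant
  many <- matrix(rnorm(400 * n), nrow = 400,
                 dimnames = list(paste0("g", 1:400), paste0("s", 1:n)))
  r2 <- phenotype_assoc(many, ph[, c("sample_id", "bmi")], traits = "bmi")
  expect_lt(abs(mean(r2$bmi$p < 0.05) - 0.05), 0.035)
  expect_error(
    phenotype_assoc(expr, data.frame(sample_id = paste0("s", 1:n),
                                     flat = rep(1, n))),
    "constant trait")
})

test_that("the insulin assay floor resets sub-detection values", {
  set.seed(37)
  n <- 40
  expr <- matrix(rnorm(n), nrow = 1,
                 dimnames = list("r1", paste0("s", 1:n)))
  ins <- c(rep(5, 10), runif(30, 20, 60))
  ph <- data.frame(sample_id = paste0("s", 1:n), insulin = ins)
  ph_floored <- data.frame(sample_id = paste0("s", 1:n),
                           insulin = c(rep(12, 10), ins[11:40]))
  r1 <- phenotype_assoc(expr, ph)$insulin
  r2 <- phenotype_assoc(expr, ph_floored,
                        floor_traits = character(0))$insulin
  expect_equal(r1$p, r2$p)
})

test_that("group contrast excludes the middle BMI range", {
  set.seed(38)
  n <- 60
  bmi <- c(rep(22, 20), rep(25, 5), rep(27, 5), rep(30, 5), rep(33, 25))
  grp <- c(rep(0, 20), rep(NA, 15), rep(1, 25))
  expr <- matrix(rnorm(2 * n), nrow = 2,
                 dimnames = list(c("null1", "diff1"), paste0("s", 1:n)))
  expr["diff1", !is.na(grp) & grp == 1] <-
    expr["diff1", !is.na(grp) & grp == 1] + 3
  names(bmi) <- paste0("s", 1:n)
  res <- group_contrast(expr, bmi)
  expect_equal(attr(res, "n_lean"), 20L)
  expect_equal(attr(res, "n_obese"), 25L)
  expect_equal(attr(res, "n_excluded"), 15L)  # BMI 25 and 30 excluded
  expect_lt(res$p[res$rna == "diff1"], 1e-6)
  expect_gt(res$p[res$rna == "null1"], 0.01)
  expect_error(group_contrast(expr, bmi, lean_max = 10), "empty")
})

test_that("arm correlations and difference QTLs behave", {
  set.seed(39)
  n <- 50
  mature <- rnorm(n)
  expr <- rbind(m = mature, s = mature + 2)
  colnames(expr) <- paste0("x", 1:n)
  res <- arm_analysis(expr, data.frame(mature_id = "m", star_id = "s"))
  expect_equal(res$correlations$rho, 1)
  expect_true(res$correlations$flagged)

  # independent arms: the |rho| > 0.4 flag rate matches the Spearman null
  flags <- vapply(1:300, function(i) {
    e <- rbind(m = rnorm(30), s = rnorm(30))
    colnames(e) <- paste0("x", 1:30)
    arm_analysis(e, data.frame(mature_id = "m",
                               star_id = "s"))$correlations$flagged
  }, logical(1))
  # analytic null tail: P(|rho| > 0.4) at n = 30 via t approximation
  t40 <- 0.4 * sqrt((30 - 2) / (1 - 0.16))
  p_null <- 2 * pt(-t40, 28)
  expect_lt(abs(mean(flags) - p_null), 3 * sqrt(p_null / 300))

  # a planted arm-preference SNP is found in the difference scan
  g <- rbinom(n, 2, 0.4)
  e2 <- rbind(m = rnorm(n, sd = 0.2) + g, s = rnorm(n, sd = 0.2))
  colnames(e2) <- paste0("x", 1:n)
  qtl <- arm_analysis(
    e2, data.frame(mature_id = "m", star_id = "s"),
    genotypes = matrix(g, 1, dimnames = list("snp1", colnames(e2))),
    snp_info = data.frame(snp = "snp1", pos = 1000, maf = 0.4,
                          info = 0.99),
    annotation = data.frame(rna_id = "m", start = 900, end = 922))$qtl
  expect_lt(qtl$q[1], 0.05)
})
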