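test_that("catalogue construction honours counts, arms and determinism", {
  cfg <- sim_config(n_samples = 6L, n_mirna = 50L, n_snorna = 5L,
                    n_other = 2L, read_depth_mean = 500, seed = 11L)
  cat1 <- make_reference_catalogue(cfg)
  expect_length(cat1$hairpins, 50L)
  # every hairpin has a mature arm; at least 10 have both arms
  expect_setequal(unique(cat1$arms$hairpin_id), names(cat1$hairpins))
  expect_gte(sum(table(cat1$arms$hairpin_id) == 2L), 10L)
  # mature/star intervals lie within their hairpins
  hl <- nchar(cat1$hairpins)[cat1$arms$hairpin_id]
  expect_true(all(cat1$arms$start >= 0 & cat1$arms$end <= hl))
  # same cfg + seed: byte-identical output
  cat2 <- make_reference_catalogue(cfg)
  expect_identical(cat1, cat2)
})

test_that("cluster table follows the 10 kb block rule on placed loci", {
  cat <- make_reference_catalogue(small_cfg())
  hp <- cat$coord[cat$coord$type == "hairpin" &
                    !duplicated(cat$coord$seq_id), ]
  hp <- hp[order(hp$start), ]
  cl <- cat$clusters$cluster_id[match(hp$seq_id, cat$clusters$hairpin_id)]
  gap <- diff(hp$start)
  same <- cl[-1] == cl[-length(cl)]
  expect_true(all(gap[same] <= 10000))
  expect_true(all(gap[!same] > 10000))
  # clusters with >= 2 members exist under the default cluster fraction
  expect_true(any(table(cl) >= 2L))
})

test_that("cohort truth recovers planted eQTL effects by OLS", {
  cfg <- sim_config(n_samples = 100L, n_mirna = 10L, n_snorna = 2L,
                    n_other = 0L, read_depth_mean = 5000, seed = 5L,
                    eqtl_effects = data.frame(rna = "mir001-5p",
                                              snp = "rs1", beta = 1,
                                              maf = 0.3))
  cat <- make_reference_catalogue(cfg)
  truth <- simulate_cohort(cat, cfg)
  fit <- lm(truth$log2_mu["mir001-5p", ] ~ truth$genotypes["rs1", ])
  est <- summary(fit)$coefficients[2, ]
  expect_lt(abs(est["Estimate"] - 1), 3 * est["Std. Error"])
  # genotypes roughly Hardy-Weinberg at the stated MAF
  expect_lt(abs(mean(truth$genotypes["rs1", ]) / 2 - 0.3), 0.12)
})

test_that("SNPs failing the MAF/info filters are flagged for exclusion", {
  cfg <- small_cfg()
  truth <- simulate_cohort(make_reference_catalogue(cfg), cfg)
  si <- truth$snp_info
  expect_true(any(!si$pass))
  expect_identical(si$pass, si$maf > 0.05 & si$info > 0.8)
})

test_that("unknown RNA in an effect table raises a reference error", {
  cfg <- small_cfg(eqtl_effects = data.frame(rna = "nosuch", snp = "s",
                                             beta = 1))
  cat <- make_reference_catalogue(small_cfg())
  expect_error(simulate_cohort(cat, cfg), "reference error")
})

test_that("reads carry planted edits, variants and contaminants", {
  cfg0 <- sim_config(
    n_samples = 4L, n_mirna = 4L, n_snorna = 0L, n_other = 0L,
    n_unannotated = 0L, read_depth_mean = 3000, seed = 9L,
    error_rate = 0, contaminant_fraction = 0.1)
  cat <- make_reference_catalogue(cfg0)
  mir1 <- cat$arms$arm_id[grep("^mir001", cat$arms$arm_id)][1]
  site <- edit_site_candidates(cat, mir1)[3]
  cfg <- cfg0
  cfg$edit_sites <- data.frame(rna = mir1, offset = site, rate = 0.25)
  truth <- simulate_cohort(cat, cfg)
  sc <- generate_reads(truth, cat, cfg)

  # provenance covers every emitted read exactly once
  main <- sc[sc$source != "contaminant", ]
  tab <- table(main$source, main$sample_id)
  for (s in colnames(truth$counts))
    for (r in rownames(tab))
      expect_equal(unname(tab[r, s]), unname(truth$counts[r, s]))

  # contaminant fraction close to 10%
  expect_lt(abs(mean(sc$source == "contaminant") - 0.1), 0.03)

  # observed edit fraction within binomial 99% bounds of the rate
  er <- sc[sc$source == mir1, ]
  n <- nrow(er)
  phat <- mean(er$edited == as.character(site))
  expect_gt(n, 500)
  bounds <- qbinom(c(0.005, 0.995), n, 0.25) / n
  expect_gte(phat, bounds[1])
  expect_lte(phat, bounds[2])
})

test_that("heterozygous planted variants split reads about 50/50", {
  cfg <- sim_config(
    n_samples = 8L, n_mirna = 3L, n_snorna = 0L, n_other = 0L,
    n_unannotated = 0L, read_depth_mean = 2500, seed = 13L,
    error_rate = 0, contaminant_fraction = 0,
    variant_sites = data.frame(rna = "mir001-5p", offset = 4L,
                               ref = NA, alt = NA, af = 0.5))
  cat <- make_reference_catalogue(cfg)
  mir <- cat$products$seq[cat$products$product_id == "mir001-5p"]
  ref <- substr(mir, 5, 5)
  alt <- setdiff(c("A", "C", "G", "T"), ref)[1]
  cfg$variant_sites$ref <- ref
  cfg$variant_sites$alt <- alt
  truth <- simulate_cohort(cat, cfg)
  sc <- generate_reads(truth, cat, cfg)
  g <- truth$variant_genotypes[paste0("mir001-5p:4"), ]
  het <- names(g)[g == 1]
  expect_gt(length(het), 0)
  for (s in het) {
    rr <- sc[sc$sample_id == s & sc$source == "mir001-5p", ]
    frac <- mean(rr$allele == alt)
    n <- nrow(rr)
    bounds <- qbinom(c(0.005, 0.995), n, 0.5) / n
    expect_gte(frac, bounds[1])
    expect_lte(frac, bounds[2])
  }
})

test_that("fastq output is deterministic and 12-plex pooled", {
  cfg <- small_cfg()
  cat <- make_reference_catalogue(cfg)
  truth <- simulate_cohort(cat, cfg)
  d1 <- file.path(tempdir(), "fq1"); d2 <- file.path(tempdir(), "fq2")
  w1 <- write_fastq(truth, cat, cfg, d1)
  w2 <- write_fastq(truth, cat, cfg, d2)
  expect_identical(readLines(w1$fastq[[1]]), readLines(w2$fastq[[1]]))
  # reads are fixed length with the sample's tag up front
  expect_true(all(nchar(w1$sidecar$seq) == cfg$read_length))
  noerr <- w1$sidecar[w1$sidecar$n_errors == 0, ]
  expect_true(all(substr(noerr$seq, 1, 6) == noerr$tag))
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("mRNA panel plants seed sites and the stated coupling", {
  cfg <- sim_config(n_samples = 60L, n_mirna = 5L, n_snorna = 0L,
                    n_other = 0L, read_depth_mean = 2000, seed = 21L)
  cat <- make_reference_catalogue(cfg)
  truth <- simulate_cohort(cat, cfg)

  pan0 <- simulate_mrna_matrix(truth, cat, cfg, "mir001-5p",
                               n_probes = 150L, n_targets = 50L,
                               coupling = 0)
  mir <- truth$log2_mu["mir001-5p", ]
  r0 <- cor(t(pan0$mrna[pan0$targets, ]), mir)
  expect_lt(abs(mean(r0)), 0.1)

  pan <- simulate_mrna_matrix(truth, cat, cfg, "mir001-5p",
                              n_probes = 200L, n_targets = 200L,
                              coupling = -0.5)
  r <- cor(t(pan$mrna[pan$targets, ]), mir)
  expect_lt(mean(r), -0.3)
  # the planted seed word appears in every target UTR
  expect_true(all(vapply(pan$utrs[pan$targets], function(u)
    grepl(pan$seed_word, u, fixed = TRUE), logical(1))))
})

test_that("all-null cohorts give uniform association p-values", {
  cfg <- sim_config(n_samples = 80L, n_mirna = 40L, n_snorna = 10L,
                    n_other = 0L, read_depth_mean = 20000, seed = 31L)
  cat <- make_reference_catalogue(cfg)
  truth <- simulate_cohort(cat, cfg, n_background_snps = 100L)
  expr <- log_normalise(truth$counts + 0)
  keep <- truth$snp_info$pass
  ps <- c()
  set.seed(1)
  snps <- truth$snp_info$snp[keep]
  for (rna in rownames(expr)) {
    for (snp in sample(snps, 10)) {
      f <- lrt_linear(expr[rna, ], truth$genotypes[snp, ])
      ps <- c(ps, f$p)
    }
  }
  expect_gt(length(ps), 400)
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
})
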