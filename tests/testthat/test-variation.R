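make_aln <- function(n, target = "m1", offset = 0L)
  data.frame(read = seq_len(n), target = rep(target, n),
             offset = rep(offset, n), gaps = rep(0L, n))

test_that("pileups count alleles per sample from covering reads", {
  ref <- "ACGTACGTACGTACGTACGTAC"
  reads <- rep(ref, 10)
  pu <- build_pileup(make_aln(10), reads, rep("s1", 10),
                     data.frame(rna = "m1", offset = 3L, ref = "T"),
                     c(m1 = 22L))
  expect_equal(pu$T, 10)
  expect_equal(pu$nonref, 0)
  expect_equal(pu$depth, 10)

  # planted heterozygote at depth 100: alt fraction in binomial 99% bounds
  set.seed(20)
  alt <- ref
  substr(alt, 4, 4) <- "C"
  is_alt <- runif(100) < 0.5
  pu2 <- build_pileup(make_aln(100), ifelse(is_alt, alt, ref),
                      rep("s1", 100),
                      data.frame(rna = "m1", offset = 3L, ref = "T"),
                      c(m1 = 22L))
  frac <- pu2$C / pu2$depth
  bounds <- qbinom(c(0.005, 0.995), 100, 0.5) / 100
  expect_gte(frac, bounds[1])
  expect_lte(frac, bounds[2])

  # no coverage: the sample contributes no information
  pu3 <- build_pileup(make_aln(0)[0, ], character(0), character(0),
                      data.frame(rna = "m1", offset = 3L, ref = "T"),
                      c(m1 = 22L))
  expect_equal(nrow(pu3), 0L)
  expect_error(
    build_pileup(make_aln(1), ref, "s1",
                 data.frame(rna = "m1", offset = 40L, ref = "T"),
                 c(m1 = 22L)),
    "outside transcript")
})

test_that("site filters require informative samples, depth and non-ref", {
  mk <- function(n_samples, depth, nonref_reads) {
    data.frame(rna = "m1", offset = 5L, ref = "A",
               sample_id = paste0("s", seq_len(n_samples)),
               A = depth - nonref_reads, C = 0, G = nonref_reads, T = 0,
               N = 0, depth = depth, nonref = nonref_reads)
  }
  # 19 informative samples: rejected
  f1 <- filter_sites(mk(19, 10, 3))
  expect_false(f1$pass)
  # one sample with 10 alleles of which 2 non-ref (20%): passes both
  f2 <- filter_sites(mk(20, 10, 2))
  expect_true(f2$pass)
  # 20% is the boundary; below it fails
  f3 <- filter_sites(mk(20, 10, 1))
  expect_false(f3$pass)
  # variant at the last mature base is flagged artefact
  p <- mk(20, 10, 2)
  p$offset <- 21L
  f4 <- filter_sites(p, last_base = c(m1 = 21L))
  expect_true(f4$artefact)

  # optional outlier rule: non-reference evidence piled into one sample
  p5 <- mk(20, 30, 0)
  p5$G[1] <- 16; p5$A[1] <- 14
  p5$depth <- p5$A + p5$G
  p5$nonref <- p5$G
  f5 <- filter_sites(p5, outlier_concentration = 0.7)
  expect_true(f5$outlier)
  p6 <- mk(20, 30, 6)  # spread across samples
  f6 <- filter_sites(p6, outlier_concentration = 0.7)
  expect_false(f6$outlier)
})

test_that("classification separates polymorphisms, edits and unresolved", {
  rna_rows <- data.frame(
    rna = "m1", offset = 6L, ref = "A",
    sample_id = paste0("s", 1:30),
    A = 20, C = 0, G = 8, T = 0, N = 0, depth = 28, nonref = 8)
  dna_poly <- data.frame(rna = "m1", offset = 6L, ref = "A",
                         sample_id = "s1", A = 10, C = 0, G = 5, T = 0,
                         N = 0)
  expect_equal(classify_site(rna_rows, dna_poly)$class, "polymorphism")

  # 3 DNA G reads: too many for an edit, too few for a polymorphism
  dna_3g <- dna_poly; dna_3g$G <- 3
  expect_equal(classify_site(rna_rows, dna_3g)$class, "unresolved")

  # clean DNA, both alleles in >= 90% of samples: an A-to-I edit
  dna_clean <- dna_poly; dna_clean$G <- 0
  expect_equal(classify_site(rna_rows, dna_clean)$class, "editing")

  # both alleles in only 89% of samples: not an edit
  rna89 <- rna_rows
  rna89$G[1:4] <- 0
  rna89$depth <- rna89$A + rna89$G
  rna89$nonref <- rna89$G
  expect_lt(mean(rna89$G > 0), 0.9)
  expect_equal(classify_site(rna89, dna_clean)$class, "unresolved")

  # no DNA at all never yields an edit call
  expect_equal(classify_site(rna_rows, NULL)$class, "unresolved")
})

test_that("end modification scan reports terminal mismatches only", {
  ref <- c(m1 = "ACGTACGTACGTACGTACGT")
  reads <- rep(ref[[1]], 10)
  em <- end_modification_scan(make_aln(10), reads, rep("s1", 10), ref)
  expect_equal(nrow(em), 0L)

  # non-templated 3' A on 30% of reads across libraries
  set.seed(21)
  modded <- ref[[1]]
  substr(modded, 20, 20) <- "A"
  libs <- rep(c("s1", "s2"), each = 10)
  pick <- c(rep(c(TRUE, FALSE), c(3, 7)), rep(c(TRUE, FALSE), c(3, 7)))
  em2 <- end_modification_scan(make_aln(20),
                               ifelse(pick, modded, ref[[1]]),
                               libs, ref)
  row <- em2[em2$end == "3p" & em2$mod_seq == "A", ]
  expect_equal(row$n_libraries, 2L)
  expect_equal(row$median_freq, 0.3, tolerance = 1e-9)

  # internal mismatch is not an end modification
  internal <- ref[[1]]
  substr(internal, 10, 10) <- "C"
  em3 <- end_modification_scan(make_aln(1), internal, "s1", ref)
  expect_equal(nrow(em3), 0L)
})

test_that("expected discovery integrates carrier and depth probabilities", {
  expect_equal(expected_discovery(0, 1000, 100), 0)
  expect_equal(expected_discovery(0.5, 0, 100), 0)
  # MAF 0.5 at depth 1000 in 100 samples: essentially certain discovery
  e <- expected_discovery(0.5, 1000, 100)
  expect_gt(e, 0.999)
  expect_lte(e, 1)
  # low MAF, low depth: compare against direct per-sample arithmetic
  p <- 0.1; d <- 15; n <- 10
  det <- 2 * p * (1 - p) * pbinom(9, d, 0.5, lower.tail = FALSE) +
    p^2 * 1
  expect_equal(expected_discovery(p, d, n), 1 - (1 - det)^n,
               tolerance = 1e-12)
})

test_that("planted variants and edits are recovered; null sites are not", {
  set.seed(22)
  n_runs <- 15
  ok_var <- ok_edit <- logical(n_runs)
  null_calls <- 0; null_total <- 0
  for (run in seq_len(n_runs)) {
    n_samp <- 25
    depth <- 40  # per-sample coverage of the tested RNA
    af <- 0.3; edit_rate <- 0.25
    g <- rbinom(n_samp, 2, af)
    while (sum(g) == 0) g <- rbinom(n_samp, 2, af)
    samples <- paste0("s", seq_len(n_samp))
    pile <- function(alt_frac_per_sample, ref = "A", alt = "G") {
      alt_n <- rbinom(n_samp, depth, alt_frac_per_sample)
      out <- data.frame(rna = "m1", offset = 5L, ref = ref,
                        sample_id = samples, A = 0, C = 0, G = 0, T = 0,
                        N = 0)
      out[[ref]] <- depth - alt_n
      out[[alt]] <- out[[alt]] + alt_n
      out$depth <- depth
      out$nonref <- alt_n
      out
    }
    # polymorphism carried by genotype; DNA pileups confirm carriers
    pv <- pile(g / 2, ref = "A", alt = "C")
    dna_v <- data.frame(rna = "m1", offset = 5L, ref = "A",
                        sample_id = samples, A = 30 - 15 * g, C = 15 * g,
                        G = 0, T = 0, N = 0)
    fv <- filter_sites(pv)
    cv <- if (fv$pass) classify_site(pv, dna_v)$class else "none"
    ok_var[run] <- cv == "polymorphism"
    # editing at fixed per-read rate; DNA is homozygous reference
    pe <- pile(rep(edit_rate, n_samp))
    dna_e <- data.frame(rna = "m1", offset = 5L, ref = "A",
                        sample_id = samples, A = 30, C = 0, G = 0, T = 0,
                        N = 0)
    fe <- filter_sites(pe)
    ce <- if (fe$pass) classify_site(pe, dna_e)$class else "none"
    ok_edit[run] <- ce == "editing"
    # null sites: sequencing error only
    for (i in 1:5) {
      pn <- pile(rep(0.002, n_samp))
      fn <- filter_sites(pn)
      null_total <- null_total + 1
      if (fn$pass && classify_site(pn, dna_e)$class %in%
            c("polymorphism", "editing"))
        null_calls <- null_calls + 1
    }
  }
  expect_gte(mean(ok_var), 0.95)
  expect_gte(mean(ok_edit), 0.95)
  expect_lte(null_calls / null_total, 0.01)
})
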