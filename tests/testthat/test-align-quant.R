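test_that("both matchers honour the IUPAC matching contract", {
  ref <- c(hp = "AAACCCGGGTTTACGTACGTACGTAAACCCGGGTTT")
  read <- substr(ref[[1]], 5, 26)
  for (m in c("exhaustive", "seeded")) {
    h <- match_iupac(read, ref, method = m)
    expect_true(any(h$offset == 4 & h$dist == 0))
  }
  # a read base matching an ambiguity code costs nothing
  amb <- ref
  substr(amb, 10, 10) <- "R"  # A/G
  readG <- read
  substr(readG, 6, 6) <- "G"  # position 10 of the reference
  h <- match_iupac(readG, c(hp = amb[[1]]))
  expect_true(any(h$offset == 4 & h$dist == 0))
  # three substitutions exceed the budget
  read3 <- read
  for (p in c(3, 9, 15)) {
    old <- substr(read3, p, p)
    substr(read3, p, p) <- setdiff(c("A", "C", "G", "T"), old)[1]
  }
  expect_equal(nrow(match_iupac(read3, ref)), 0L)
  # N in the read matches nothing and costs a substitution
  readN <- read
  substr(readN, 4, 4) <- "N"
  h <- match_iupac(readN, ref)
  expect_true(any(h$offset == 4 & h$subs == 1))
})

test_that("matchers agree with each other on corrupted reads, both strands", {
  set.seed(4)
  ref <- paste(sample(c("A", "C", "G", "T"), 5000, TRUE), collapse = "")
  substr(ref, 1000, 1000) <- "R"
  reads <- vapply(1:150, function(i) {
    o <- sample(1:4900, 1)
    rr <- strsplit(substr(ref, o, o + sample(16:31, 1) - 1), "")[[1]]
    rr[rr == "R"] <- "A"
    ne <- sample(0:3, 1)
    if (ne > 0) {
      at <- sample(length(rr), ne)
      for (a in at) rr[a] <- sample(c("A", "C", "G", "T"), 1)
    }
    if (runif(1) < 0.3) rr <- rr[-sample(2:(length(rr) - 1), 1)]
    paste(rr, collapse = "")
  }, character(1))
  ex <- match_iupac(reads, c(chr = ref), both_strands = TRUE,
                    method = "exhaustive")
  se <- match_iupac(reads, c(chr = ref), both_strands = TRUE,
                    method = "seeded")
  key <- function(d) paste(d$read, d$offset, d$strand, d$subs, d$gaps)
  expect_setequal(key(ex), key(se))
})

test_that("consensus keeps reads only when location sets agree", {
  a <- data.frame(read = c(1L, 2L, 2L, 3L),
                  target = c("x", "x", "y", "x"),
                  offset = c(0L, 5L, 9L, 2L), strand = "+",
                  subs = 0L, gaps = 0L, dist = 0L)
  b <- a[c(1, 2, 4), ]  # read 2 lost one location in matcher B
  kept <- consensus(a, b)
  expect_setequal(unique(kept$read), c(1L, 3L))
  # both matchers empty for a read: it is simply unmapped, not retained
  expect_equal(nrow(consensus(a[0, ], b[0, ])), 0L)
})

test_that("stratum resolution follows priority then edit distance", {
  mk <- function(read, target, dist, offset = 0L)
    data.frame(read = read, target = target, offset = offset,
               strand = "+", subs = dist, gaps = 0L, dist = dist)
  # mature hit at distance 1 beats genome hit at distance 0
  res <- resolve_strata(list(mature_mirna = mk(1L, "m1", 1L),
                             genome = mk(1L, "chr", 0L)))
  expect_equal(res$alignments$stratum, "mature_mirna")
  expect_equal(res$alignments$k, 1L)
  # any contaminant hit excludes the read entirely
  res2 <- resolve_strata(list(contaminant = mk(1L, "c1", 0L),
                              mature_mirna = mk(1L, "m1", 0L)))
  expect_equal(nrow(res2$alignments), 0L)
  expect_equal(res2$status$status, "contaminant")
  # within the winning stratum only minimum-distance locations are kept
  g <- rbind(mk(1L, "chr", 0L, 10L), mk(1L, "chr", 1L, 50L),
             mk(1L, "chr", 1L, 90L))
  res3 <- resolve_strata(list(genome = g))
  expect_equal(nrow(res3$alignments), 1L)
  expect_equal(res3$alignments$offset, 10L)
  expect_equal(res3$alignments$k, 1L)
})

test_that("fractional counts conserve read mass", {
  res <- data.frame(read = c(1L, 1L, 2L), target = c("a", "b", "a"),
                    k = c(2L, 2L, 1L))
  m <- fractional_count(res, c("s1", "s1"))
  expect_equal(m["a", "s1"], 1.5)
  expect_equal(m["b", "s1"], 0.5)
  expect_equal(sum(m), 2)
})

test_that("unannotated loci are gap-free pooled coverage runs", {
  # two reads overlapping by one base merge into one locus
  aln <- data.frame(read = c(1L, 2L), offset = c(0L, 21L))
  loci <- call_unannotated_loci(aln, c(22L, 22L), min_reads = 2L)
  expect_equal(nrow(loci), 1L)
  expect_equal(loci$width, 43L)
  # reads separated by one uncovered base stay apart
  aln2 <- data.frame(read = c(1L, 2L), offset = c(0L, 23L))
  loci2 <- call_unannotated_loci(aln2, c(22L, 22L), min_reads = 1L)
  expect_equal(nrow(loci2), 2L)
  # short subset: < 100 bp and >= threshold reads
  aln3 <- data.frame(read = 1:1200, offset = rep(c(0L, 500L), c(1200 - 3, 3)))
  lens3 <- rep(c(80L, 120L), c(1200 - 3, 3))
  loci3 <- call_unannotated_loci(aln3, lens3)
  expect_equal(loci3$short, c(TRUE, FALSE))
})

test_that("matrix filters keep RNAs by total or single-sample evidence", {
  n <- 50
  m <- rbind(
    bysingle = c(100, rep(899 / (n - 1), n - 1)),  # total 999, max 100
    bytotal  = rep(20, n),                         # total 1000, max 20
    weak     = c(99, rep(900 / (n - 1), n - 1)))   # total 999, max 99
  f <- filter_matrix(m, min_sample_reads = 0)
  expect_true(all(c("bysingle", "bytotal") %in% rownames(f)))
  expect_false("weak" %in% rownames(f))

  # sample with 499,999 mapped reads is discarded
  m2 <- rbind(big = c(6e5, 6e5, 5e5 - 1))
  f2 <- filter_matrix(m2, min_total = 0, min_single = 0)
  expect_equal(ncol(f2), 2L)

  expect_error(filter_matrix(m, min_sample_reads = 1e9), "empty-output")
})

test_that("locus/track overlap uses the exact binomial tail", {
  loci <- data.frame(start = seq(0, 900, 100), end = seq(20, 920, 100))
  whole <- data.frame(start = 0, end = 1000)
  r <- overlap_binomial_test(loci, whole, 1000)
  expect_equal(r$overlaps, 10L)
  expect_equal(r$p, 1)
  none <- data.frame(start = 950, end = 960)
  r2 <- overlap_binomial_test(loci[1:3, ], none, 1000)
  expect_equal(r2$overlaps, 0L)
  expect_equal(r2$p, 1)
  # n = 10, track fraction 0.1, 5 observed: exact upper binomial tail
  track <- data.frame(start = 0, end = 100)
  lo <- data.frame(start = c(rep(50, 5), seq(200, 600, 100)),
                   end = c(rep(60, 5), seq(210, 610, 100)))
  r3 <- overlap_binomial_test(lo, track, 1000)
  expect_equal(r3$overlaps, 5L)
  expect_equal(r3$p, sum(dbinom(5:10, 10, 0.1)), tolerance = 1e-12)
  expect_equal(r3$p, 1.63494e-3, tolerance = 1e-4)
})
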