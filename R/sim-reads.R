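#' Generate the raw reads of a simulated cohort
#'
#' Expands the true molecule counts into sequencer reads: each read is the
#' sample's six-base index tag, the RNA product sequence (with alleles drawn
#' from the sample's planted variant genotype, A-to-G edits applied at the
#' configured per-read rates), the 3' adaptor and linker fill, truncated to
#' the read length.  Per-base substitution errors are applied over the whole
#' assembled read.  A configurable fraction of adaptor-dimer contaminant
#' reads is added per library.  Every read is recorded in a truth sidecar.
#'
#' @param truth a [simulate_cohort()] result.
#' @param catalogue the matching [make_reference_catalogue()].
#' @param cfg the [sim_config()].
#' @return data.frame sidecar with one row per emitted read: `read_id`,
#'   `sample_id`, `pool`, `tag`, `source` (product id or "contaminant"),
#'   `allele`, `edited` (";"-separated edited offsets), `n_errors`, and the
#'   final read `seq`.
#' @export
generate_reads <- function(truth, catalogue, cfg) {
  stopifnot(inherits(truth, "sim_cohort"))
  set.seed(cfg$seed + 2L)
  products <- catalogue$products
  prod_seq <- setNames(products$seq, products$product_id)
  samples <- colnames(truth$counts)
  ba <- cfg$batch_assignments
  rl <- cfg$read_length
  suffix <- paste0(cfg$adapter3, LINKER_DEFAULT,
                   strrep("A", rl))  # always long enough to truncate

  out <- vector("list", length(samples))
  for (js in seq_along(samples)) {
    s <- samples[js]
    cnt <- truth$counts[, s]
    cnt <- cnt[cnt > 0]
    rows <- vector("list", length(cnt) + 1L)
    for (ip in seq_along(cnt)) {
      pid <- names(cnt)[ip]
      c_i <- as.integer(cnt[ip])
      base_seq <- prod_seq[[pid]]
      chars <- strsplit(base_seq, "")[[1]]
      mat <- matrix(rep(chars, each = c_i), nrow = c_i)
      allele <- rep(NA_character_, c_i)
      # planted variant carried by this sample's genotype
      if (!is.null(cfg$variant_sites)) {
        vs <- cfg$variant_sites[cfg$variant_sites$rna == pid, , drop = FALSE]
        for (iv in seq_len(nrow(vs))) {
          g <- truth$variant_genotypes[paste0(pid, ":", vs$offset[iv]), s]
          is_alt <- runif(c_i) < g / 2
          mat[is_alt, vs$offset[iv] + 1L] <- vs$alt[iv]
          allele <- ifelse(is_alt, vs$alt[iv], vs$ref[iv])
        }
      }
      edited <- rep("", c_i)
      if (!is.null(cfg$edit_sites)) {
        es <- cfg$edit_sites[cfg$edit_sites$rna == pid, , drop = FALSE]
        for (ie in seq_len(nrow(es))) {
          hit <- runif(c_i) < es$rate[ie] &
            mat[, es$offset[ie] + 1L] == "A"
          mat[hit, es$offset[ie] + 1L] <- "G"
          edited[hit] <- paste0(edited[hit], ifelse(nzchar(edited[hit]),
                                                    ";", ""), es$offset[ie])
        }
      }
      ins <- apply(mat, 1L, paste, collapse = "")
      rows[[ip]] <- data.frame(
        sample_id = s, source = pid, allele = allele, edited = edited,
        insert = ins, stringsAsFactors = FALSE)
    }
    # adaptor-dimer contaminants
    n_main <- sum(as.integer(cnt))
    f <- cfg$contaminant_fraction
    n_cont <- if (f > 0) rpois(1, n_main * f / (1 - f)) else 0L
    if (n_cont > 0)
      rows[[length(cnt) + 1L]] <- data.frame(
        sample_id = s, source = "contaminant", allele = NA_character_,
        edited = "", insert = rep("", n_cont), stringsAsFactors = FALSE)
    out[[js]] <- do.call(rbind, rows)
  }
  sidecar <- do.call(rbind, out)
  rownames(sidecar) <- NULL

  tag <- ba$tag[match(sidecar$sample_id, ba$sample_id)]
  pool <- ba$batch[match(sidecar$sample_id, ba$sample_id)]
  reads <- substr(paste0(tag, sidecar$insert, suffix), 1L, rl)

  # sequencing errors over the whole assembled read
  nr <- length(reads)
  n_err_tot <- rbinom(1, nr * rl, cfg$error_rate)
  n_errors <- integer(nr)
  if (n_err_tot > 0) {
    flat <- sample.int(nr * rl, n_err_tot)
    ridx <- (flat - 1L) %% nr + 1L
    pidx <- (flat - 1L) %/% nr + 1L
    mat <- seq_char_matrix(reads, rl)
    for (k in seq_len(n_err_tot)) {
      old <- mat[ridx[k], pidx[k]]
      mat[ridx[k], pidx[k]] <- sample(setdiff(BASES, old), 1)
    }
    reads <- apply(mat, 1L, paste, collapse = "")
    n_errors <- tabulate(ridx, nbins = nr)
  }

  data.frame(
    read_id = sprintf("r%07d", seq_len(nr)),
    sample_id = sidecar$sample_id, pool = pool, tag = tag,
    source = sidecar$source, allele = sidecar$allele,
    edited = sidecar$edited, n_errors = n_errors, seq = reads,
    stringsAsFactors = FALSE)
}

#' Write simulated reads as pooled FASTQ
#'
#' Emits one FASTQ file per 12-plex pool (a single file when all samples
#' share one pool) plus a tab-separated per-read truth sidecar.  Qualities
#' are constant high Phred (the pipeline never uses them).
#'
#' @inheritParams generate_reads
#' @param outdir output directory (created if missing).
#' @return invisibly, a list with `fastq` (named paths per pool),
#'   `sidecar_path`, and the sidecar data.frame.
#' @export
write_fastq <- function(truth, catalogue, cfg, outdir) {
  sidecar <- generate_reads(truth, catalogue, cfg)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- c()
  for (p in unique(sidecar$pool)) {
    sub <- sidecar[sidecar$pool == p, ]
    path <- file.path(outdir, paste0("pool_", p, ".fastq"))
    dna <- Biostrings::DNAStringSet(sub$seq)
    names(dna) <- sub$read_id
    qual <- Biostrings::BStringSet(strrep("I", nchar(sub$seq)))
    Biostrings::writeXStringSet(dna, path, format = "fastq",
                                qualities = qual)
    paths[p] <- path
  }
  sidecar_path <- file.path(outdir, "truth_sidecar.tsv")
  write.table(sidecar, sidecar_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(list(fastq = paths, sidecar_path = sidecar_path,
                 sidecar = sidecar))
}

#' Simulate a 3'UTR / mRNA expression panel with planted miRNA targets
#'
#' Generates an mRNA probe expression matrix over the cohort's samples and a
#' 3'UTR sequence per probe.  A chosen set of target probes carries the
#' focal miRNA's seed-complementary 8-mer (1-3 planted copies per UTR) and
#' has expression negatively coupled to the miRNA at the stated coupling;
#' non-target UTRs are drawn from the same base composition.
#'
#' @param truth a [simulate_cohort()] result.
#' @param catalogue the matching catalogue.
#' @param cfg the [sim_config()].
#' @param mirna focal product id (mature arm).
#' @param n_probes number of mRNA probes.
#' @param n_targets number of target probes.
#' @param coupling correlation between miRNA log2 expression and target
#'   probe expression (negative for repression; 0 for a null panel).
#' @param utr_length UTR length in nt.
#' @return list with `mrna` (probe x sample matrix), `utrs` (named
#'   character), `targets`, `seed_word` (the planted 8-mer, ends in A) and
#'   `mirna`.
#' @export
simulate_mrna_matrix <- function(truth, catalogue, cfg, mirna,
                                 n_probes = 300L, n_targets = 60L,
                                 coupling = -0.5, utr_length = 500L) {
  stopifnot(mirna %in% catalogue$products$product_id,
            n_targets <= n_probes, abs(coupling) <= 1)
  set.seed(cfg$seed + 3L)
  mir_seq <- catalogue$products$seq[
    catalogue$products$product_id == mirna]
  seed_word <- paste0(revcomp(substr(mir_seq, 2, 8)), "A")

  samples <- colnames(truth$counts)
  n <- length(samples)
  mir_z <- as.numeric(scale(truth$log2_mu[mirna, ]))
  probes <- sprintf("P%04d", seq_len(n_probes))
  targets <- probes[seq_len(n_targets)]

  mrna <- matrix(rnorm(n_probes * n), nrow = n_probes,
                 dimnames = list(probes, samples))
  if (n_targets > 0 && coupling != 0) {
    noise <- mrna[seq_len(n_targets), , drop = FALSE]
    mrna[seq_len(n_targets), ] <-
      coupling * matrix(mir_z, nrow = n_targets, ncol = n, byrow = TRUE) +
      sqrt(1 - coupling^2) * noise
  }

  utrs <- rand_dna(n_probes, utr_length)
  names(utrs) <- probes
  for (i in seq_len(n_targets)) {
    k <- sample(1:3, 1)
    pos <- sample(seq_len(utr_length - 8L), k)
    u <- utrs[[i]]
    for (p in pos) u <- paste0(substr(u, 1, p - 1), seed_word,
                               substr(u, p + 8, utr_length))
    utrs[[i]] <- u
  }
  list(mrna = mrna, utrs = utrs, targets = targets,
       seed_word = seed_word, mirna = mirna)
}
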