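#' Ambiguity-aware read matching against a reference set
#'
#' Finds every alignment of each read with at most `max_sub` substitutions
#' and at most `max_gap` single-base gaps.  A read base matches an IUPAC
#' reference symbol iff it belongs to the symbol's allele set; an N in a
#' read matches nothing and always costs a substitution.  Two independent
#' matchers honour this contract: `"exhaustive"` scans every offset with a
#' banded early-exit check, `"seeded"` uses pigeonhole q-gram seeding with
#' verification.  Gap placements tying at equal edit distance collapse to
#' one record per (target, offset, strand).
#'
#' @param reads character vector of read sequences (length 16-63).
#' @param subject a `ref_stratum` or named character vector of reference
#'   sequences.
#' @param max_sub,max_gap substitution and gap budgets.
#' @param both_strands search the reverse complement too (genome stratum);
#'   transcript strata are searched forward only.
#' @param method which matcher to run.
#' @return data.frame with `read` (index into `reads`), `target` (name),
#'   `offset` (0-based), `strand`, `subs`, `gaps`, `dist`.
#' @export
match_iupac <- function(reads, subject, max_sub = 2L, max_gap = 1L,
                        both_strands = FALSE,
                        method = c("exhaustive", "seeded")) {
  method <- match.arg(method)
  seqs <- if (inherits(subject, "ref_stratum")) subject$seqs else subject
  if (is.null(names(seqs))) names(seqs) <- paste0("t", seq_along(seqs))
  fn <- if (method == "exhaustive") .match_exhaustive_cpp
        else .match_seeded_cpp
  hits <- fn(as.character(reads), as.character(unname(seqs)),
             as.integer(max_sub), as.integer(max_gap), both_strands)
  hits$target <- names(seqs)[hits$target]
  # one record per (read, target, offset, strand), minimal edit distance
  if (nrow(hits)) {
    dt <- data.table::as.data.table(hits)
    dt <- dt[order(dist)][
      , .SD[1L], by = .(read, target, offset, strand)]
    hits <- as.data.frame(dt[order(read, target, offset, strand)])
  }
  hits
}

#' Dual-matcher consensus
#'
#' A read's alignments are retained only if both matchers agree on all its
#' aligned locations (target, offset, strand); otherwise the read is
#' dropped from quantification.
#'
#' @param alignments_a,alignments_b alignment tables from [match_iupac()]
#'   run with the two methods.
#' @return the retained alignment rows (from `alignments_a`).
#' @export
consensus <- function(alignments_a, alignments_b) {
  key <- function(d) paste(d$target, d$offset, d$strand, sep = "\r")
  sets_a <- split(key(alignments_a), alignments_a$read)
  sets_b <- split(key(alignments_b), alignments_b$read)
  reads <- union(names(sets_a), names(sets_b))
  agreed <- vapply(reads, function(r) {
    setequal(sets_a[[r]] %||% character(0), sets_b[[r]] %||% character(0))
  }, logical(1))
  alignments_a[alignments_a$read %in% as.integer(reads[agreed]), ,
               drop = FALSE]
}

#' Resolve alignments across reference strata
#'
#' A read with any contaminant hit is excluded entirely.  Otherwise its
#' winning stratum is the highest-priority stratum with hits
#' (miRNA > ncRNA > pseudogene > genome) and only minimum-edit-distance
#' alignments within it are kept; `k` is their count.
#'
#' @param aln_by_stratum named list of alignment tables, one per stratum,
#'   in any order; names must be stratum names.
#' @param ranks named integer vector of stratum priorities (lower wins).
#' @return list with `alignments` (kept rows plus `stratum` and `k`) and
#'   `status` (data.frame: `read`, `status` in
#'   contaminant/mapped/unmapped).
#' @export
resolve_strata <- function(aln_by_stratum,
                           ranks = c(contaminant = 0L, mature_mirna = 1L,
                                     ncrna = 2L, pseudogene = 3L,
                                     genome = 4L)) {
  tabs <- lapply(names(aln_by_stratum), function(nm) {
    d <- aln_by_stratum[[nm]]
    if (is.null(d) || nrow(d) == 0L) return(NULL)
    d$stratum <- nm
    d
  })
  tabs <- tabs[!vapply(tabs, is.null, logical(1))]
  if (!length(tabs))
    return(list(alignments = data.frame(), status = data.frame(
      read = integer(0), status = character(0))))
  all_aln <- data.table::rbindlist(tabs)
  all_aln[, rank_ := ranks[stratum]]
  contam_reads <- unique(all_aln$read[all_aln$rank_ == min(ranks)&
                                      all_aln$stratum == "contaminant"])
  keep <- all_aln[!read %in% contam_reads]
  if (nrow(keep)) {
    keep <- keep[, .SD[rank_ == min(rank_)], by = read]
    keep <- keep[, .SD[dist == min(dist)], by = read]
    keep[, k := .N, by = read]
  }
  status <- data.frame(read = unique(all_aln$read),
                       stringsAsFactors = FALSE)
  status$status <- ifelse(status$read %in% contam_reads, "contaminant",
                          "mapped")
  list(alignments = as.data.frame(keep[, rank_ := NULL]), status = status)
}

#' Fractional counting of resolved reads
#'
#' Each retained read adds `1/k` to each of its `k` winning targets in its
#' sample's column, so every read contributes total weight exactly one.
#'
#' @param resolved resolved alignment table (with `k`), where `read`
#'   indexes `read_samples`.
#' @param read_samples per-read sample assignment (vector indexed by read).
#' @param rna_ids,samples optional row/column universe of the matrix.
#' @return matrix of fractional counts (RNA x sample).
#' @export
fractional_count <- function(resolved, read_samples, rna_ids = NULL,
                             samples = NULL) {
  if (is.null(samples)) samples <- sort(unique(read_samples))
  if (is.null(rna_ids)) rna_ids <- sort(unique(resolved$target))
  m <- matrix(0, nrow = length(rna_ids), ncol = length(samples),
              dimnames = list(rna_ids, samples))
  if (!nrow(resolved)) return(m)
  dt <- data.table::as.data.table(resolved)
  dt[, sample_id := read_samples[read]]
  agg <- dt[, .(weight = sum(1 / k)), by = .(target, sample_id)]
  m[cbind(match(agg$target, rna_ids), match(agg$sample_id, samples))] <-
    agg$weight
  m
}

#' Unannotated locus discovery from genome-resolved reads
#'
#' Loci are maximal runs of gap-free pooled coverage across all samples;
#' the short subset keeps loci shorter than `max_len` bases with at least
#' `min_reads` total mapped reads.
#'
#' @param genome_aln resolved alignments in the genome stratum; needs
#'   `offset` and `read`.
#' @param read_lengths per-read length (vector indexed by read).
#' @param max_len,min_reads short-subset thresholds.
#' @return data.frame of loci (`start`, `end` 0-based half-open, `width`,
#'   `reads`, `short`).
#' @export
call_unannotated_loci <- function(genome_aln, read_lengths,
                                  max_len = 100L, min_reads = 1000L) {
  if (is.null(genome_aln) || nrow(genome_aln) == 0L)
    return(data.frame(start = integer(0), end = integer(0),
                      width = integer(0), reads = integer(0),
                      short = logical(0)))
  ir <- IRanges::IRanges(start = genome_aln$offset + 1L,
                         width = read_lengths[genome_aln$read])
  loci <- IRanges::reduce(ir)
  nreads <- IRanges::countOverlaps(loci, ir)
  data.frame(start = IRanges::start(loci) - 1L,
             end = IRanges::end(loci),
             width = IRanges::width(loci),
             reads = nreads,
             short = IRanges::width(loci) < max_len & nreads >= min_reads)
}

#' Filter the count matrix
#'
#' Keeps an RNA observed at least `min_total` times across all samples or
#' at least `min_single` times in a single sample, and drops samples with
#' fewer than `min_sample_reads` mapped reads.  Thresholds are configurable
#' so scaled-down cohorts can use proportional values.
#'
#' @param counts fractional count matrix (RNA x sample).
#' @param min_total,min_single,min_sample_reads thresholds.
#' @return the filtered matrix.
#' @export
filter_matrix <- function(counts, min_total = 1000, min_single = 100,
                          min_sample_reads = 500000) {
  keep_sample <- colSums(counts) >= min_sample_reads
  if (!any(keep_sample))
    stop("empty-output error: all samples fall below min_sample_reads")
  m <- counts[, keep_sample, drop = FALSE]
  keep_rna <- rowSums(m) >= min_total |
    apply(m, 1L, max) >= min_single
  m[keep_rna, , drop = FALSE]
}

#' Binomial enrichment of loci in an annotation track
#'
#' One-tailed probability of observing at least as many locus/track
#' overlaps as seen, with the per-locus overlap probability equal to the
#' fraction of genome bases covered by the track.  Overlap means any shared
#' base.
#'
#' @param loci data.frame with `start`, `end` (0-based half-open).
#' @param track data.frame with `start`, `end` (same convention).
#' @param genome_length genome size in bases.
#' @return list with `n_loci`, `overlaps`, `track_fraction`, `p`.
#' @export
overlap_binomial_test <- function(loci, track, genome_length) {
  if (nrow(loci) == 0L) stop("empty locus set")
  tr <- IRanges::reduce(IRanges::IRanges(track$start + 1L, track$end))
  lo <- IRanges::IRanges(loci$start + 1L, loci$end)
  frac <- sum(IRanges::width(tr)) / genome_length
  obs <- sum(IRanges::countOverlaps(lo, tr) > 0L)
  p <- pbinom(obs - 1L, nrow(loci), frac, lower.tail = FALSE)
  list(n_loci = nrow(loci), overlaps = obs, track_fraction = frac, p = p)
}

#' Quantify cleaned reads against the reference strata
#'
#' The full mapping stage: unique read sequences are aligned to every
#' stratum with both matchers, the dual-matcher consensus is applied per
#' stratum, strata are resolved (contaminants excluded, highest stratum
#' wins, minimum edit distance within it), and fractional counts are
#' accumulated per sample.  Genome-stratum matching searches both strands;
#' transcript strata are forward-only.
#'
#' @param read_table data.frame with `read_id`, `sample_id`, `seq`
#'   (cleaned reads).
#' @param refs stratum list from [build_references()].
#' @param max_sub,max_gap alignment budgets.
#' @return list with `counts` (fractional count matrix over resolved
#'   targets), `resolved` (per-read winning alignments), `status` per
#'   read, `mapped_per_sample`, and `genome_reads` (alignments of reads
#'   whose winning stratum is the genome, for locus discovery).
#' @export
quantify_reads <- function(read_table, refs, max_sub = 2L, max_gap = 1L) {
  stopifnot(all(c("read_id", "sample_id", "seq") %in% names(read_table)))
  useq <- unique(read_table$seq)
  aln <- list()
  for (nm in names(refs)) {
    bs <- nm == "genome"
    a <- match_iupac(useq, refs[[nm]], max_sub, max_gap,
                     both_strands = bs, method = "exhaustive")
    b <- match_iupac(useq, refs[[nm]], max_sub, max_gap,
                     both_strands = bs, method = "seeded")
    aln[[nm]] <- consensus(a, b)
  }
  res <- resolve_strata(aln)
  # expand unique-sequence alignments back to reads
  seq_ix <- match(read_table$seq, useq)
  rs <- res$alignments
  per_read_status <- res$status$status[match(seq_ix, res$status$read)]
  per_read_status[is.na(per_read_status)] <- "unmapped"

  expand <- data.table::as.data.table(rs)
  reads_dt <- data.table::data.table(
    read = seq_ix, read_id = read_table$read_id,
    sample_id = read_table$sample_id)
  merged <- merge(reads_dt, expand, by = "read", allow.cartesian = TRUE)
  counts <- fractional_count(
    as.data.frame(merged[, .(read = read_id, target, k)]),
    setNames(read_table$sample_id, read_table$read_id),
    samples = sort(unique(read_table$sample_id)))
  mapped <- colSums(counts)
  genome_reads <- as.data.frame(
    merged[stratum == "genome",
           .(read_id, sample_id, target, offset, strand, dist, k)])
  list(counts = counts,
       resolved = as.data.frame(merged),
       status = data.frame(read_id = read_table$read_id,
                           status = per_read_status,
                           stringsAsFactors = FALSE),
       mapped_per_sample = mapped,
       genome_reads = genome_reads)
}
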