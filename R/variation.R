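#' Build per-sample allele pileups at transcript sites
#'
#' Counts A/C/G/T/N observations per sample at each requested transcript
#' position from the covering reads.  Gapped alignments are excluded so
#' every read base maps unambiguously to a transcript offset.
#'
#' @param alignments resolved alignments with columns `read`, `target`,
#'   `offset`, `gaps` (0 rows allowed).
#' @param read_seqs per-read sequences (vector indexed by `read`).
#' @param read_samples per-read sample ids (vector indexed by `read`).
#' @param sites data.frame with `rna`, `offset` (0-based transcript
#'   position) and `ref`.
#' @param target_lengths named lengths of the targets (for range checks).
#' @return data.frame with one row per (site, sample):
#'   `rna`, `offset`, `ref`, `sample_id`, `A`, `C`, `G`, `T`, `N`,
#'   `depth`, `nonref`.
#' @export
build_pileup <- function(alignments, read_seqs, read_samples, sites,
                         target_lengths) {
  bad <- sites$offset < 0 |
    sites$offset >= target_lengths[sites$rna]
  if (any(is.na(bad)) || any(bad))
    stop("site outside transcript")
  aln <- alignments[alignments$gaps == 0L, , drop = FALSE]
  rows <- list()
  for (i in seq_len(nrow(sites))) {
    a <- aln[aln$target == sites$rna[i], , drop = FALSE]
    if (nrow(a)) {
      rp <- sites$offset[i] - a$offset  # 0-based position within read
      cover <- rp >= 0L & rp < nchar(read_seqs[a$read])
      a <- a[cover, , drop = FALSE]
      rp <- rp[cover]
    }
    if (nrow(a) == 0L) {
      rows[[i]] <- data.frame(rna = character(0), offset = integer(0),
                              ref = character(0),
                              sample_id = character(0), A = numeric(0),
                              C = numeric(0), G = numeric(0),
                              T = numeric(0), N = numeric(0))
      next
    }
    base <- substr(read_seqs[a$read], rp + 1L, rp + 1L)
    smp <- read_samples[a$read]
    tab <- table(factor(smp), factor(base, levels = c(BASES, "N")))
    rows[[i]] <- data.frame(
      rna = sites$rna[i], offset = sites$offset[i], ref = sites$ref[i],
      sample_id = rownames(tab),
      A = as.numeric(tab[, "A"]), C = as.numeric(tab[, "C"]),
      G = as.numeric(tab[, "G"]), T = as.numeric(tab[, "T"]),
      N = as.numeric(tab[, "N"]), stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (nrow(out)) {
    out$depth <- out$A + out$C + out$G + out$T + out$N
    refc <- vapply(seq_len(nrow(out)), function(i) out[[out$ref[i]]][i],
                   numeric(1))
    out$nonref <- out$depth - out$N - refc
  } else {
    out$depth <- numeric(0); out$nonref <- numeric(0)
  }
  rownames(out) <- NULL
  out
}

#' Filter pileup sites to reliable candidates
#'
#' Keeps sites with information from at least `min_samples` samples, at
#' least one sample with at least `min_alleles` observed alleles (read
#' depth), and at least one sample with at least `min_nonref_frac`
#' non-reference allele frequency.  A site falling on the final base of a
#' mature product is flagged as a likely modified degradation product
#' (artefact), not a variant.
#'
#' @param pileup a [build_pileup()] result.
#' @param min_samples,min_alleles,min_nonref_frac filter thresholds.
#' @param last_base optional named vector: for each RNA, the 0-based
#'   offset of the final mature base (sites there are flagged artefact).
#' @param outlier_concentration optional fraction in (0, 1]; a site whose
#'   non-reference observations concentrate beyond this fraction in a
#'   single sample is flagged as a likely per-sample artefact (`outlier`
#'   column), mirroring the manual exclusion of single-sample-driven
#'   candidate sites.
#' @return per-site summary with `pass`, `artefact` and (optionally)
#'   `outlier` flags.
#' @export
filter_sites <- function(pileup, min_samples = 20L, min_alleles = 10L,
                         min_nonref_frac = 0.2, last_base = NULL,
                         outlier_concentration = NULL) {
  dt <- data.table::as.data.table(pileup)
  agg <- dt[, .(
    n_informative = sum(depth > 0),
    max_depth = if (.N) max(depth) else 0,
    max_nonref_frac = {
      d <- depth > 0
      if (any(d)) max(nonref[d] / depth[d]) else 0
    },
    nonref_total = sum(nonref),
    nonref_top_sample = if (.N) max(nonref) else 0
    ), by = .(rna, offset, ref)]
  agg[, `:=`(pass = n_informative >= min_samples &
               max_depth >= min_alleles &
               max_nonref_frac >= min_nonref_frac)]
  out <- as.data.frame(agg)
  out$artefact <- FALSE
  if (!is.null(last_base)) {
    lb <- last_base[out$rna]
    out$artefact <- !is.na(lb) & out$offset == lb
  }
  if (!is.null(outlier_concentration)) {
    out$outlier <- out$nonref_total > 0 &
      out$nonref_top_sample / pmax(out$nonref_total, 1) >
        outlier_concentration
  }
  out
}

#' Classify a candidate site using DNA pileup validation
#'
#' A site is a DNA polymorphism if any sample's DNA pileup shows at least
#' `min_dna_alt` reads supporting the non-reference allele.  It is an
#' A-to-I edit if the reference base is A, no sample has more than
#' `max_dna_g` DNA reads with a G allele, and both A and G are observed in
#' at least `min_sample_frac` of the RNA-informative samples.  Anything
#' else (including sites without DNA evidence) is unresolved.
#'
#' @param site_pileup the per-sample pileup rows of one site.
#' @param dna_pileup per-sample DNA allele counts at the same site (same
#'   columns as the RNA pileup; may cover only a subset of samples or be
#'   NULL).
#' @param min_dna_alt,max_dna_g,min_sample_frac classification thresholds.
#' @return one-row data.frame: `rna`, `offset`, `ref`, `class`,
#'   `derived_allele`, `derived_sample_frac`, `derived_read_frac`.
#' @export
classify_site <- function(site_pileup, dna_pileup = NULL,
                          min_dna_alt = 5L, max_dna_g = 2L,
                          min_sample_frac = 0.9) {
  stopifnot(length(unique(site_pileup$rna)) == 1L)
  ref <- site_pileup$ref[1]
  alts <- setdiff(BASES, ref)
  alt_tot <- vapply(alts, function(b) sum(site_pileup[[b]]), numeric(1))
  derived <- alts[which.max(alt_tot)]
  inf <- site_pileup[site_pileup$depth > 0, , drop = FALSE]
  derived_sample_frac <-
    if (nrow(inf)) mean(inf[[derived]] > 0) else NA_real_
  tot_reads <- sum(site_pileup$depth - site_pileup$N)
  derived_read_frac <-
    if (tot_reads > 0) sum(site_pileup[[derived]]) / tot_reads else NA_real_

  cls <- "unresolved"
  if (!is.null(dna_pileup) && nrow(dna_pileup)) {
    dna_alt_max <- max(vapply(seq_len(nrow(dna_pileup)), function(i)
      sum(vapply(alts, function(b) dna_pileup[[b]][i], numeric(1))),
      numeric(1)))
    if (dna_alt_max >= min_dna_alt) {
      cls <- "polymorphism"
    } else if (ref == "A" && max(dna_pileup$G) <= max_dna_g) {
      both <- nrow(inf) > 0 &&
        mean(inf$A > 0 & inf$G > 0) >= min_sample_frac
      if (both && derived == "G") cls <- "editing"
    }
  }
  data.frame(rna = site_pileup$rna[1], offset = site_pileup$offset[1],
             ref = ref, class = cls, derived_allele = derived,
             derived_sample_frac = derived_sample_frac,
             derived_read_frac = derived_read_frac,
             stringsAsFactors = FALSE)
}

#' Classify every passing candidate site
#'
#' @param pileup full pileup table.
#' @param site_filter [filter_sites()] output.
#' @param dna_pileups optional pileup-shaped table of DNA allele counts
#'   (subset of samples with DNA sequencing).
#' @param ... thresholds passed to [classify_site()].
#' @return table of variant calls; artefact-flagged sites are labelled
#'   artefact regardless of DNA evidence.
#' @export
classify_sites <- function(pileup, site_filter, dna_pileups = NULL, ...) {
  cand <- site_filter[site_filter$pass, , drop = FALSE]
  rows <- lapply(seq_len(nrow(cand)), function(i) {
    sp <- pileup[pileup$rna == cand$rna[i] &
                   pileup$offset == cand$offset[i], , drop = FALSE]
    dp <- if (!is.null(dna_pileups))
      dna_pileups[dna_pileups$rna == cand$rna[i] &
                    dna_pileups$offset == cand$offset[i], , drop = FALSE]
    out <- classify_site(sp, dp, ...)
    if (cand$artefact[i]) out$class <- "artefact"
    out
  })
  if (!length(rows))
    return(data.frame(rna = character(0), offset = integer(0),
                      ref = character(0), class = character(0),
                      derived_allele = character(0),
                      derived_sample_frac = numeric(0),
                      derived_read_frac = numeric(0)))
  do.call(rbind, rows)
}

#' Scan for non-genomic read end bases
#'
#' For each RNA and end (5'/3'), tallies reads whose terminal bases do not
#' match the reference (after de-ambiguating IUPAC codes), the per-library
#' modification frequency, its median across libraries, and the number of
#' libraries the modification was observed in.  Internal mismatches are
#' not reported here.
#'
#' @param alignments gap-free resolved alignments (`read`, `target`,
#'   `offset`).
#' @param read_seqs,read_samples per-read sequence and sample vectors.
#' @param ref_seqs named reference sequences (IUPAC allowed).
#' @return data.frame with `rna`, `end` ("5p"/"3p"), `mod_seq`,
#'   `n_libraries`, `median_freq`.
#' @export
end_modification_scan <- function(alignments, read_seqs, read_samples,
                                  ref_seqs) {
  aln <- alignments[alignments$gaps == 0L, , drop = FALSE]
  if (!nrow(aln))
    return(data.frame(rna = character(0), end = character(0),
                      mod_seq = character(0), n_libraries = integer(0),
                      median_freq = numeric(0)))
  rows <- list()
  for (tgt in unique(aln$target)) {
    a <- aln[aln$target == tgt, , drop = FALSE]
    refc <- strsplit(ref_seqs[[tgt]], "")[[1]]
    libs <- read_samples[a$read]
    ends <- list()
    for (i in seq_len(nrow(a))) {
      rc <- strsplit(read_seqs[[a$read[i]]], "")[[1]]
      ref_here <- refc[a$offset[i] + seq_along(rc)]
      mism <- !mapply(function(r, f)
        !is.na(f) && r %in% IUPAC_SET[[f]], rc, ref_here)
      run5 <- if (mism[1]) which.min(mism) - 1L else 0L
      if (all(mism)) run5 <- length(mism)
      run3 <- if (mism[length(mism)]) which.min(rev(mism)) - 1L else 0L
      if (all(mism)) run3 <- length(mism)
      ends[[i]] <- data.frame(
        lib = libs[i],
        mod5 = if (run5 > 0) paste(rc[seq_len(run5)], collapse = "") else "",
        mod3 = if (run3 > 0)
          paste(rc[(length(rc) - run3 + 1L):length(rc)], collapse = "")
          else "",
        stringsAsFactors = FALSE)
    }
    ed <- do.call(rbind, ends)
    for (side in c("5p", "3p")) {
      mod <- if (side == "5p") ed$mod5 else ed$mod3
      for (ms in setdiff(unique(mod), "")) {
        freq_by_lib <- tapply(mod == ms, ed$lib, mean)
        obs <- freq_by_lib[freq_by_lib > 0]
        rows[[length(rows) + 1L]] <- data.frame(
          rna = tgt, end = side, mod_seq = ms,
          n_libraries = length(obs),
          median_freq = median(obs), stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows))
    return(data.frame(rna = character(0), end = character(0),
                      mod_seq = character(0), n_libraries = integer(0),
                      median_freq = numeric(0)))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Expected number of discoverable variant sites
#'
#' For each known DNA variant with population MAF and per-sample expected
#' read depth, the probability that at least one sample both carries the
#' alternative allele (Hardy-Weinberg) and shows it on at least
#' `min_reads` reads (binomial given carrier genotype, equal expression of
#' both gene copies), summed over sites.
#'
#' @param maf per-site minor allele frequencies.
#' @param depth per-site expected read depth per sample (recycled).
#' @param n_samples cohort size.
#' @param min_reads detection threshold on alternative reads.
#' @return expected number of discoverable sites.
#' @export
expected_discovery <- function(maf, depth, n_samples, min_reads = 10L) {
  depth <- rep_len(depth, length(maf))
  per_site <- vapply(seq_along(maf), function(i) {
    p <- maf[i]; d <- round(depth[i])
    if (p <= 0 || d <= 0) return(0)
    p_het <- 2 * p * (1 - p)
    p_hom <- p^2
    det_het <- pbinom(min_reads - 1L, d, 0.5, lower.tail = FALSE)
    det_hom <- as.numeric(d >= min_reads)
    p_det <- p_het * det_het + p_hom * det_hom
    1 - (1 - p_det)^n_samples
  }, numeric(1))
  sum(per_site)
}
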