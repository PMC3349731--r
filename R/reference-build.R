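#' Enumerate kit contaminant sequences
#'
#' Every base sequence plus all single-nucleotide alterations: each
#' substitution (3 per position), each single-base insertion (4 per gap)
#' and each single-base deletion, deduplicated.
#'
#' @param base_seqs character vector of kit sequences (adaptors, linkers,
#'   adaptor-linker and adaptor-tag combinations).
#' @return character vector of distinct contaminant sequences.
#' @export
enumerate_contaminants <- function(base_seqs) {
  if (!length(base_seqs)) stop("need at least one base sequence")
  one <- function(s) {
    ch <- strsplit(s, "")[[1]]
    L <- length(ch)
    subs <- unlist(lapply(seq_len(L), function(i)
      vapply(setdiff(BASES, ch[i]), function(b) {
        x <- ch; x[i] <- b; paste(x, collapse = "")
      }, character(1))))
    ins <- unlist(lapply(0:L, function(i)
      vapply(BASES, function(b)
        paste(c(head(ch, i), b, tail(ch, L - i)), collapse = ""),
        character(1))))
    del <- if (L > 1)
      vapply(seq_len(L), function(i) paste(ch[-i], collapse = ""),
             character(1))
    else character(0)
    c(s, subs, ins, del)
  }
  unique(unlist(lapply(unique(base_seqs), one)))
}

# standard adaptor/linker/tag combination set for the contaminant stratum
kit_contaminant_bases <- function(adapters, tags = character(0),
                                  linkers = character(0)) {
  combos <- c(adapters, linkers)
  for (a in adapters) {
    for (l in linkers) combos <- c(combos, paste0(a, l), paste0(l, a))
    for (t in tags) combos <- c(combos, paste0(t, a), paste0(a, t))
  }
  unique(combos)
}

#' Extend a mature interval into its hairpin
#'
#' Mature and star sequences are extended by up to 3 bases at the 5' end
#' and 5 bases at the 3' end, truncated at the hairpin boundaries.
#'
#' @param hairpin_length length of the hairpin.
#' @param start,end 0-based half-open mature interval within the hairpin.
#' @param five,three maximal extensions.
#' @return integer vector `c(start, end)` of the extended interval.
#' @export
extend_mature <- function(hairpin_length, start, end, five = 3L,
                          three = 5L) {
  if (start < 0 || end > hairpin_length || start >= end)
    stop("reference error: mature interval outside hairpin")
  c(max(0L, start - five), min(hairpin_length, end + three))
}

#' Replace known variant positions with IUPAC ambiguity codes
#'
#' @param sequence a DNA string.
#' @param sites data.frame with `offset` (0-based), `ref`, `alt` (alt may be
#'   comma-separated for multi-allelic sites).
#' @return the sequence with each variant position replaced by the minimal
#'   IUPAC code covering ref and alt alleles.
#' @export
inject_ambiguity <- function(sequence, sites) {
  if (is.null(sites) || nrow(sites) == 0L) return(sequence)
  ch <- strsplit(sequence, "")[[1]]
  for (i in seq_len(nrow(sites))) {
    off <- sites$offset[i]
    if (off < 0 || off >= length(ch))
      stop("variant offset out of range")
    alts <- strsplit(sites$alt[i], ",")[[1]]
    if (ch[off + 1L] != sites$ref[i])
      stop("ref base mismatch at offset ", off, ": sequence has ",
           ch[off + 1L], ", site says ", sites$ref[i])
    if (all(alts == sites$ref[i]))
      stop("alt equals ref at offset ", off)
    ch[off + 1L] <- iupac_code(c(sites$ref[i], alts))
  }
  paste(ch, collapse = "")
}

.new_stratum <- function(name, rank, seqs, coord = NULL) {
  structure(list(name = name, rank = rank, seqs = seqs, coord = coord),
            class = "ref_stratum")
}

#' Build the five prioritised reference strata
#'
#' Constructs, in priority order: (0) kit contaminants with all single
#' nucleotide alterations; (1) mature miRNA and star sequences extended
#' into their hairpins (up to 3 nt 5', 5 nt 3'); (2) all ncRNA sequences
#' together with full-length hairpins; (3) ncRNA pseudogenes; (4) the
#' genome.  Known variant sites are written into every stratum as IUPAC
#' ambiguity codes.  RNAs with multiple genomic placements keep every
#' placement in the coordinate map.
#'
#' @param catalogue a [make_reference_catalogue()] result.
#' @param variants data.frame of transcript variant sites with `rna`
#'   (product id), `offset` (0-based in the product), `ref`, `alt`, or
#'   NULL.
#' @param kit_sequences list with `adapters`, and optionally `tags` and
#'   `linkers`.
#' @return named list of five `ref_stratum` objects: `contaminant`,
#'   `mature_mirna`, `ncrna`, `pseudogene`, `genome`.
#' @export
build_references <- function(catalogue, variants = NULL,
                             kit_sequences = list(
                               adapters = ADAPTER3_DEFAULT,
                               tags = TAGS_DEFAULT,
                               linkers = LINKER_DEFAULT)) {
  stopifnot(inherits(catalogue, "sim_catalogue"))
  if (is.null(kit_sequences$adapters))
    stop("configuration error: kit adaptor sequences missing")

  contam <- enumerate_contaminants(kit_contaminant_bases(
    kit_sequences$adapters, kit_sequences$tags %||% character(0),
    kit_sequences$linkers %||% character(0)))
  names(contam) <- sprintf("contam%05d", seq_along(contam))

  arms <- catalogue$arms
  hp <- catalogue$hairpins
  # variant sites are specified on the (unextended) product; shift into the
  # extended sequence, the hairpin and the genome
  mature_seqs <- character(nrow(arms))
  mature_coord <- list()
  first_coord <- catalogue$coord[!duplicated(catalogue$coord$seq_id), ]
  rownames(first_coord) <- first_coord$seq_id
  for (i in seq_len(nrow(arms))) {
    hlen <- nchar(hp[[arms$hairpin_id[i]]])
    ext <- extend_mature(hlen, arms$start[i], arms$end[i])
    s <- substr(hp[[arms$hairpin_id[i]]], ext[1] + 1L, ext[2])
    if (!is.null(variants)) {
      v <- variants[variants$rna == arms$arm_id[i], , drop = FALSE]
      if (nrow(v)) {
        v$offset <- v$offset + (arms$start[i] - ext[1])
        s <- inject_ambiguity(s, v)
      }
    }
    mature_seqs[i] <- s
    pc <- first_coord[arms$hairpin_id[i], ]
    mature_coord[[i]] <- data.frame(
      seq_id = arms$arm_id[i], chrom = pc$chrom,
      start = pc$start + ext[1], end = pc$start + ext[2], strand = "+",
      ext_start = ext[1], stringsAsFactors = FALSE)
  }
  names(mature_seqs) <- arms$arm_id
  mature_coord <- do.call(rbind, mature_coord)

  # hairpin and genome copies of each variant
  hp_var <- NULL
  if (!is.null(variants) && nrow(variants)) {
    ai <- match(variants$rna, arms$arm_id)
    known <- !is.na(ai)
    hp_var <- data.frame(
      hairpin_id = arms$hairpin_id[ai[known]],
      offset = variants$offset[known] + arms$start[ai[known]],
      ref = variants$ref[known], alt = variants$alt[known],
      stringsAsFactors = FALSE)
  }
  hp_amb <- hp
  if (!is.null(hp_var) && nrow(hp_var)) {
    for (h in unique(hp_var$hairpin_id))
      hp_amb[[h]] <- inject_ambiguity(
        hp_amb[[h]], hp_var[hp_var$hairpin_id == h, , drop = FALSE])
  }

  ncrna_seqs <- c(catalogue$ncrna, hp_amb)
  ncrna_coord <- catalogue$coord[
    catalogue$coord$seq_id %in% names(ncrna_seqs), , drop = FALSE]

  genome <- catalogue$genome
  if (!is.null(hp_var) && nrow(hp_var)) {
    gsites <- list()
    for (i in seq_len(nrow(hp_var))) {
      placements <- catalogue$coord[
        catalogue$coord$seq_id == hp_var$hairpin_id[i], , drop = FALSE]
      for (j in seq_len(nrow(placements)))
        gsites[[length(gsites) + 1L]] <- data.frame(
          offset = placements$start[j] + hp_var$offset[i],
          ref = hp_var$ref[i], alt = hp_var$alt[i],
          stringsAsFactors = FALSE)
    }
    genome <- inject_ambiguity(genome, do.call(rbind, gsites))
  }

  list(
    contaminant = .new_stratum("contaminant", 0L, contam),
    mature_mirna = .new_stratum("mature_mirna", 1L, mature_seqs,
                                mature_coord),
    ncrna = .new_stratum("ncrna", 2L, ncrna_seqs, ncrna_coord),
    pseudogene = .new_stratum("pseudogene", 3L, catalogue$pseudogenes,
                              catalogue$coord[
                                catalogue$coord$type == "pseudogene", ,
                                drop = FALSE]),
    genome = .new_stratum("genome", 4L,
                          setNames(genome, "chrS"),
                          data.frame(seq_id = "chrS", chrom = "chrS",
                                     start = 0L,
                                     end = catalogue$genome_length,
                                     strand = "+"))
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
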