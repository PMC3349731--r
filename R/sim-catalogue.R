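#' Generate the synthetic reference catalogue
#'
#' Builds a miniature annotated genome for the cohort simulator: miRNA
#' hairpins with mature (and for a fixed fraction, star) arm coordinates,
#' snoRNA and other ncRNA genes with characteristic ~22 nt expressed
#' fragments, ncRNA pseudogenes, a set of expressed but unannotated short
#' loci, and a single-chromosome genome backbone in which every element is
#' embedded at a known locus.  miRNA clusters are defined from the placed
#' coordinates by the 10 kb block rule.  Coordinates are 0-based half-open
#' internally.
#'
#' @param cfg a [sim_config()].
#' @return a `sim_catalogue` list with hairpin/ncRNA/pseudogene sequences,
#'   arm and fragment tables, genome string, coordinate map, cluster table,
#'   per-RNA conservation scores and a DNase-like interval track.
#' @export
make_reference_catalogue <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  if (cfg$locus_spacing < 500)
    stop("sizing error: locus_spacing too small to fit gene loci")

  n_mir <- cfg$n_mirna
  hairpin_len <- sample(70:110, n_mir, replace = TRUE)
  hairpins <- vapply(hairpin_len, function(L)
    paste(sample(BASES, L, replace = TRUE), collapse = ""), character(1))
  hp_ids <- sprintf("mir%03d", seq_len(n_mir))
  names(hairpins) <- hp_ids

  # arms: every hairpin has a mature arm; a fixed 40% also have a star arm
  n_both <- max(min(n_mir, 10L), round(0.4 * n_mir))
  both <- seq_len(n_mir) <= n_both
  arm_rows <- list()
  for (i in seq_len(n_mir)) {
    L <- hairpin_len[i]
    len5 <- sample(21:23, 1)
    len3 <- sample(21:23, 1)
    s5 <- sample(4:10, 1)
    e3 <- L - sample(2:8, 1)
    arms_i <- data.frame(
      hairpin_id = hp_ids[i],
      arm = c("5p", "3p"),
      start = c(s5, e3 - len3),
      end = c(s5 + len5, e3),
      stringsAsFactors = FALSE)
    mature_arm <- sample(c("5p", "3p"), 1)
    if (both[i]) {
      arms_i$role <- ifelse(arms_i$arm == mature_arm, "mature", "star")
    } else {
      arms_i <- arms_i[arms_i$arm == mature_arm, , drop = FALSE]
      arms_i$role <- "mature"
    }
    arm_rows[[i]] <- arms_i
  }
  arms <- do.call(rbind, arm_rows)
  arms$arm_id <- paste0(arms$hairpin_id, "-", arms$arm)
  arms <- arms[, c("arm_id", "hairpin_id", "arm", "role", "start", "end")]
  rownames(arms) <- NULL

  # snoRNA / other ncRNA genes with fixed expressed fragment windows
  make_ncrna <- function(n, prefix, len_range) {
    if (n == 0)
      return(list(seqs = setNames(character(0), character(0)),
                  frag = data.frame(rna_id = character(0), start = integer(0),
                                    end = integer(0))))
    lens <- sample(len_range, n, replace = TRUE)
    seqs <- vapply(lens, function(L)
      paste(sample(BASES, L, replace = TRUE), collapse = ""), character(1))
    ids <- sprintf("%s%03d", prefix, seq_len(n))
    names(seqs) <- ids
    fl <- sample(20:24, n, replace = TRUE)
    fs <- vapply(seq_len(n), function(i) sample(0:(lens[i] - fl[i]), 1),
                 numeric(1))
    list(seqs = seqs,
         frag = data.frame(rna_id = ids, start = as.integer(fs),
                           end = as.integer(fs + fl),
                           stringsAsFactors = FALSE))
  }
  sno <- make_ncrna(cfg$n_snorna, "sno", 60:100)
  onc <- make_ncrna(cfg$n_other, "onc", 50:90)
  ncrna <- c(sno$seqs, onc$seqs)
  ncrna_frag <- rbind(sno$frag, onc$frag)

  # pseudogenes: mutated copies of random hairpins (~5% substitutions)
  n_pseudo <- max(3L, round(0.15 * n_mir))
  pseudo <- vapply(seq_len(n_pseudo), function(i) {
    src <- strsplit(hairpins[[sample(n_mir, 1)]], "")[[1]]
    nmut <- max(2L, round(0.05 * length(src)))
    at <- sample(length(src), nmut)
    src[at] <- vapply(src[at], function(b) sample(setdiff(BASES, b), 1),
                      character(1))
    paste(src, collapse = "")
  }, character(1))
  names(pseudo) <- sprintf("psg%03d", seq_len(n_pseudo))

  # unannotated expressed loci: short regions with a fixed 22 nt product
  n_un <- cfg$n_unannotated
  un_len <- if (n_un) sample(40:80, n_un, replace = TRUE) else integer(0)
  un_seq <- vapply(un_len, function(L)
    paste(sample(BASES, L, replace = TRUE), collapse = ""), character(1))
  un_ids <- if (n_un) sprintf("una%02d", seq_len(n_un)) else character(0)

  # --- genome layout ---------------------------------------------------
  # miRNA hairpins first: a fraction in clusters of 2-3 (gaps 2-5 kb),
  # everything else separated by locus_spacing (+/- jitter, > 10 kb apart)
  n_clustered <- round(cfg$cluster_fraction * n_mir)
  cluster_sizes <- integer(0)
  left <- n_clustered
  while (left >= 2) {
    s <- min(left, sample(2:3, 1))
    cluster_sizes <- c(cluster_sizes, s)
    left <- left - s
  }
  mir_order <- seq_len(n_mir)  # placement order = id order
  blocks <- list()             # each block: vector of hairpin indices
  idx <- 1L
  for (s in cluster_sizes) {
    blocks[[length(blocks) + 1L]] <- mir_order[idx:(idx + s - 1L)]
    idx <- idx + s
  }
  while (idx <= n_mir) {
    blocks[[length(blocks) + 1L]] <- mir_order[idx]
    idx <- idx + 1L
  }

  chunks <- character(0)
  coord <- list()
  pos <- 0L
  gap_big <- function() cfg$locus_spacing + sample(0:2000, 1)
  gap_small <- function() sample(2000:5000, 1)
  add_gap <- function(g) {
    if (g < 50) stop("sizing error: genome capacity exceeded")
    chunks[[length(chunks) + 1L]] <<-
      paste(sample(BASES, g, replace = TRUE), collapse = "")
    pos <<- pos + as.integer(g)
  }
  add_seq <- function(id, type, s) {
    chunks[[length(chunks) + 1L]] <<- s
    coord[[length(coord) + 1L]] <<- data.frame(
      seq_id = id, type = type, chrom = "chrS", start = pos,
      end = pos + nchar(s), strand = "+", stringsAsFactors = FALSE)
    pos <<- pos + nchar(s)
  }
  for (b in blocks) {
    add_gap(gap_big())
    for (j in seq_along(b)) {
      if (j > 1) add_gap(gap_small())
      add_seq(hp_ids[b[j]], "hairpin", hairpins[[b[j]]])
    }
  }
  for (id in names(ncrna)) { add_gap(gap_big()); add_seq(id, "ncrna", ncrna[[id]]) }
  for (id in names(pseudo)) { add_gap(gap_big()); add_seq(id, "pseudogene", pseudo[[id]]) }
  for (i in seq_len(n_un)) { add_gap(gap_big()); add_seq(un_ids[i], "unannotated", un_seq[i]) }
  # duplicate genomic placements for a fraction of hairpins
  n_multi <- round(cfg$multilocus_fraction * n_mir)
  multi <- if (n_multi) sample(n_mir, n_multi) else integer(0)
  for (i in multi) { add_gap(gap_big()); add_seq(hp_ids[i], "hairpin", hairpins[[i]]) }
  add_gap(gap_big())
  genome <- paste(chunks, collapse = "")
  coord <- do.call(rbind, coord)
  rownames(coord) <- NULL

  # clusters from placed coordinates: successive miRNA loci within 10 kb
  hp_first <- coord[coord$type == "hairpin" & !duplicated(coord$seq_id), ]
  hp_first <- hp_first[order(hp_first$start), ]
  cl <- integer(nrow(hp_first))
  cid <- 0L
  for (i in seq_len(nrow(hp_first))) {
    if (i == 1L || hp_first$start[i] - hp_first$start[i - 1L] > 10000) {
      cid <- cid + 1L
    }
    cl[i] <- cid
  }
  clusters <- data.frame(hairpin_id = hp_first$seq_id,
                         cluster_id = sprintf("cl%03d", cl),
                         stringsAsFactors = FALSE)

  # product table: the sequences that become reads
  arm_seq <- substr(hairpins[arms$hairpin_id], arms$start + 1L, arms$end)
  frag_seq <- substr(ncrna[ncrna_frag$rna_id], ncrna_frag$start + 1L,
                     ncrna_frag$end)
  un_ps <- if (n_un) pmin(10L, un_len - 22L) else integer(0)
  un_prod <- if (n_un) substr(un_seq, un_ps + 1L, un_ps + 22L) else character(0)
  products <- data.frame(product_id = arms$arm_id, source_type = "mirna",
                         parent_id = arms$hairpin_id, role = arms$role,
                         seq = unname(arm_seq), stringsAsFactors = FALSE)
  if (nrow(ncrna_frag))
    products <- rbind(products, data.frame(
      product_id = ncrna_frag$rna_id,
      source_type = ifelse(grepl("^sno", ncrna_frag$rna_id),
                           "snorna", "other"),
      parent_id = ncrna_frag$rna_id, role = "mature",
      seq = unname(frag_seq), stringsAsFactors = FALSE))
  if (n_un)
    products <- rbind(products, data.frame(
      product_id = un_ids, source_type = "unannotated", parent_id = un_ids,
      role = "mature", seq = un_prod, stringsAsFactors = FALSE))

  conservation <- data.frame(
    rna_id = products$product_id,
    score = rnorm(nrow(products), mean = 2, sd = 2),
    stringsAsFactors = FALSE)

  # DNase-like open-chromatin track: covers ~60% of unannotated loci plus
  # random background intervals
  dnase <- list()
  un_coord <- coord[coord$type == "unannotated", , drop = FALSE]
  for (i in seq_len(nrow(un_coord))) {
    if (runif(1) < 0.6)
      dnase[[length(dnase) + 1L]] <- data.frame(
        start = max(0L, un_coord$start[i] - 50L),
        end = min(nchar(genome), un_coord$end[i] + 50L))
  }
  n_rand_iv <- max(3L, round(nchar(genome) / 20000))
  for (i in seq_len(n_rand_iv)) {
    s <- sample(0:(nchar(genome) - 500L), 1)
    dnase[[length(dnase) + 1L]] <- data.frame(start = s, end = s + 500L)
  }
  dnase <- do.call(rbind, dnase)
  dnase <- dnase[order(dnase$start), , drop = FALSE]
  rownames(dnase) <- NULL

  structure(list(
    hairpins = hairpins, arms = arms, ncrna = ncrna,
    ncrna_frag = ncrna_frag, pseudogenes = pseudo,
    genome = genome, genome_length = nchar(genome),
    coord = coord, clusters = clusters,
    unannotated = if (n_un) data.frame(locus_id = un_ids,
                                       stringsAsFactors = FALSE)
                  else data.frame(locus_id = character(0)),
    products = products, conservation = conservation, dnase = dnase,
    config = cfg
  ), class = "sim_catalogue")
}
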