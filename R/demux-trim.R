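#' Distance between a read prefix and an index tag
#'
#' Position-wise distance over the six bases: matching bases contribute 0,
#' an N against anything contributes 0.25, any other mismatch 1.
#'
#' @param prefix six-base read prefix.
#' @param tag six-base index tag.
#' @return non-negative distance (multiple of 0.25).
#' @export
tag_distance <- function(prefix, tag) {
  if (nchar(prefix) != 6L || nchar(tag) != 6L)
    stop("tag_distance operates on length-6 strings")
  a <- strsplit(prefix, "")[[1]]
  b <- strsplit(tag, "")[[1]]
  sum(ifelse(a == b, 0, ifelse(a == "N" | b == "N", 0.25, 1)))
}

#' Assign pooled reads to libraries by index tag
#'
#' Computes the tag distance of each read's first six bases to all tags.  A
#' read is assigned to the unique minimum-distance tag if that minimum is
#' below 2.75; reads at distance >= 2.75 to every tag, or tied between
#' tags, stay unassigned.  The six tag bases are stripped on assignment.
#'
#' @param seqs character vector of read sequences (length >= 7).
#' @param tags the twelve index tags.
#' @return data.frame with `tag` (tag sequence or NA), `seq` (tag-stripped
#'   sequence for assigned reads, original otherwise) and `min_dist`.
#' @export
demultiplex <- function(seqs, tags = TAGS_DEFAULT) {
  if (any(nchar(seqs) < 7L)) stop("reads must have length >= 7")
  n <- length(seqs)
  pre <- seq_char_matrix(substr(seqs, 1L, 6L), 6L)
  D <- matrix(0, nrow = n, ncol = length(tags))
  for (t in seq_along(tags)) {
    tg <- strsplit(tags[t], "")[[1]]
    d <- numeric(n)
    for (p in 1:6) {
      cp <- pre[, p]
      d <- d + ifelse(cp == tg[p], 0, ifelse(cp == "N" | tg[p] == "N",
                                             0.25, 1))
    }
    D[, t] <- d
  }
  mind <- apply(D, 1L, min)
  nmin <- rowSums(D == mind)
  assigned <- mind < 2.75 & nmin == 1L
  which_tag <- max.col(-D, ties.method = "first")
  data.frame(
    tag = ifelse(assigned, tags[which_tag], NA_character_),
    seq = ifelse(assigned, substr(seqs, 7L, nchar(seqs)), seqs),
    min_dist = mind,
    stringsAsFactors = FALSE)
}

# mismatch budget: floor of 20% of the alignment length
.mm_budget <- function(L) floor(0.2 * L)

#' Trim the 3' adaptor from reads
#'
#' Two-stage search mirroring an internal-then-anchored adaptor trim.
#' Stage 1 slides the adaptor's first 12 bases over every internal position
#' and trims from the leftmost position matching with at most
#' `floor(0.2 * 12)` mismatches.  If stage 1 finds nothing, stage 2 aligns
#' adaptor prefixes of length L = 12 down to 1, anchored to the read's 3'
#' end, and trims at the first (longest) L whose mismatch count is at most
#' `floor(0.2 * L)`.  The two stages repeat until no further trimming
#' occurs, so the operation is idempotent.
#'
#' @param seqs character vector of read sequences.
#' @param adapter3 adaptor sequence (>= 12 bases).
#' @return character vector of trimmed sequences (possibly "").
#' @export
trim_adapter <- function(seqs, adapter3 = ADAPTER3_DEFAULT) {
  out <- seqs
  repeat {
    nxt <- .trim_adapter_once(out, adapter3)
    if (identical(nxt, out)) return(nxt)
    out <- nxt
  }
}

.trim_adapter_once <- function(seqs, adapter3) {
  if (nchar(adapter3) < 12L) stop("adaptor must be at least 12 bases")
  a12 <- strsplit(substr(adapter3, 1L, 12L), "")[[1]]
  n <- length(seqs)
  len <- nchar(seqs)
  out <- seqs
  pending <- rep(TRUE, n)
  if (n == 0) return(out)
  w <- max(len)
  M <- seq_char_matrix(seqs, w)

  # stage 1: leftmost internal match of the 12-base adaptor prefix
  trim_at <- rep(NA_integer_, n)
  for (p in seq_len(max(0L, w - 11L))) {
    rows <- which(pending & is.na(trim_at) & len >= p + 11L)
    if (!length(rows)) next
    mm <- integer(length(rows))
    for (j in 1:12)
      mm <- mm + (M[rows, p + j - 1L] != a12[j])
    hit <- mm <= .mm_budget(12L)
    trim_at[rows[hit]] <- p
  }
  has1 <- !is.na(trim_at)
  out[has1] <- substr(seqs[has1], 1L, trim_at[has1] - 1L)
  pending <- pending & !has1

  # stage 2: adaptor prefix anchored at the 3' end, longest overlap first
  for (L in 12:1) {
    rows <- which(pending & len >= L)
    if (!length(rows)) next
    budget <- .mm_budget(L)
    for (g in unique(len[rows])) {
      rg <- rows[len[rows] == g]
      cols <- (g - L + 1L):g
      mm <- integer(length(rg))
      for (j in seq_len(L))
        mm <- mm + (M[rg, cols[j]] != a12[j])
      hit <- mm <= budget
      out[rg[hit]] <- substr(seqs[rg[hit]], 1L, g - L)
      pending[rg[hit]] <- FALSE
    }
  }
  out
}

#' Clean up a trimmed read
#'
#' Applies, in order: (1) truncation at the first N of any five-base window
#' containing at least three Ns; (2) trimming at any N occurring within the
#' last two bases (applied repeatedly); (3) discarding low-complexity reads
#' in which a single base makes up at least 90% of the remaining length;
#' (4) discarding reads shorter than 16 bases.
#'
#' @param seqs character vector of read sequences.
#' @return data.frame with `seq` (cleaned sequence, NA if discarded),
#'   `discarded` and `reason` ("low_complexity", "too_short" or NA).
#' @export
clean_read <- function(seqs) {
  n <- length(seqs)
  out <- character(n)
  reason <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    s <- strsplit(seqs[i], "")[[1]]
    # rule 1: five-base window with >= 3 Ns truncates at its first N
    if (length(s) >= 5L) {
      isn <- s == "N"
      cs <- cumsum(isn)
      wins <- cs[5:length(s)] - c(0, cs)[1:(length(s) - 4L)]
      w <- which(wins >= 3L)
      if (length(w)) {
        first_n <- which(isn[w[1]:(w[1] + 4L)])[1] + w[1] - 1L
        s <- s[seq_len(first_n - 1L)]
      }
    }
    # rule 2: N within two bases of the 3' end trims from that N
    repeat {
      L <- length(s)
      if (L == 0L) break
      lastN <- which(s == "N" & seq_along(s) >= L - 1L)
      if (!length(lastN)) break
      s <- s[seq_len(min(lastN) - 1L)]
    }
    L <- length(s)
    if (L > 0L && max(table(s)) >= 0.9 * L) {
      reason[i] <- "low_complexity"
      out[i] <- NA_character_
    } else if (L < 16L) {
      reason[i] <- "too_short"
      out[i] <- NA_character_
    } else {
      out[i] <- paste(s, collapse = "")
    }
  }
  data.frame(seq = out, discarded = is.na(out), reason = reason,
             stringsAsFactors = FALSE)
}

#' Length histogram of cleaned reads
#'
#' @param seqs character vector of retained (cleaned) read sequences.
#' @param min_len,max_len histogram range; retained reads are at least 16
#'   bases and at most the post-tag read length.
#' @return named integer vector of counts by length.
#' @export
length_histogram <- function(seqs, min_len = 16L, max_len = 31L) {
  lens <- nchar(seqs)
  counts <- vapply(min_len:max_len, function(L) sum(lens == L), integer(1))
  names(counts) <- min_len:max_len
  counts
}

#' Demultiplex, trim and clean one pooled read set
#'
#' Full raw-data pipeline for a pool: tag assignment, adaptor trimming and
#' cleanup filters, with a per-rule report.
#'
#' @param seqs character vector of raw reads (or a FASTQ path).
#' @param tags index tags.
#' @param adapter3 3' adaptor.
#' @return list with `reads` (data.frame: `read_id`, `tag`, `seq`,
#'   `status`) and `report` (named counts).
#' @export
process_pool <- function(seqs, tags = TAGS_DEFAULT,
                         adapter3 = ADAPTER3_DEFAULT) {
  if (length(seqs) == 1L && file.exists(seqs)) {
    x <- Biostrings::readDNAStringSet(seqs, format = "fastq")
    ids <- names(x)
    seqs <- as.character(x)
  } else {
    ids <- names(seqs)
    if (is.null(ids)) ids <- sprintf("r%07d", seq_along(seqs))
  }
  dm <- demultiplex(seqs, tags)
  assigned <- !is.na(dm$tag)
  trimmed <- rep(NA_character_, length(seqs))
  trimmed[assigned] <- trim_adapter(dm$seq[assigned], adapter3)
  cl <- data.frame(seq = rep(NA_character_, length(seqs)),
                   discarded = TRUE, reason = NA_character_)
  cl[assigned, ] <- clean_read(trimmed[assigned])
  status <- ifelse(!assigned, "unassigned",
                   ifelse(cl$discarded, paste0("discarded_", cl$reason),
                          "retained"))
  list(
    reads = data.frame(read_id = ids, tag = dm$tag, seq = cl$seq,
                       status = status, stringsAsFactors = FALSE),
    report = c(input = length(seqs),
               assigned = sum(assigned),
               unassigned = sum(!assigned),
               discarded_low_complexity =
                 sum(cl$reason %in% "low_complexity"),
               discarded_too_short = sum(cl$reason %in% "too_short"),
               retained = sum(!cl$discarded & assigned)))
}
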