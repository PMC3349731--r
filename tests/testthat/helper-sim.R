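# small study configurations used across tests; sizes chosen so the whole
# suite exercises every stage quickly while preserving the study design
# (12-plex six-base tags, 37-base reads, v1.5-style 3' adaptor)

small_cfg <- function(...) {
  sim_config(n_samples = 6L, n_mirna = 12L, n_snorna = 4L, n_other = 2L,
             n_unannotated = 2L, read_depth_mean = 600,
             locus_spacing = 12000L, seed = 42L, ...)
}

# brute-force edit-distance <= 1 neighbourhood via base adist over the
# full string universe; exponential, so only usable for very short strings
edit1_neighbourhood <- function(s) {
  L <- nchar(s)
  stopifnot(L <= 6L)
  lens <- max(1L, L - 1L):(L + 1L)
  cand <- unlist(lapply(lens, function(k)
    apply(expand.grid(rep(list(c("A", "C", "G", "T")), k),
                      stringsAsFactors = FALSE), 1, paste, collapse = "")))
  cand[utils::adist(s, cand) <= 1L]
}

# exact one-sided hypergeometric upper tail by direct dhyper summation
hyper_tail_oracle <- function(x, K, N, draws) {
  sum(stats::dhyper(x:min(K, draws), K, N - K, draws))
}
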