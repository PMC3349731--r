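#' Illumina v1.5-style small RNA 3' adaptor used throughout the simulations
#' @export
ADAPTER3_DEFAULT <- "ATCTCGTATGCCGTCTTCTGCTTG"

# linker-like filler that follows the adaptor in adaptor-dimer reads
LINKER_DEFAULT <- "TCGGAAGAGCGTCGTGTAGG"

#' The twelve six-base library index tags
#' @export
TAGS_DEFAULT <- c(
  "ACGTAC", "CTAGCT", "GTCAGA", "TGACTG", "AAGGTC", "CCTTAG",
  "GGAACT", "TTCCGA", "AGCTGT", "CATGCA", "GCATAG", "TCGATC"
)

#' Configuration of a synthetic small RNA sequencing cohort
#'
#' Defines the study design the generator emulates: a cohort of multiplexed
#' 12-plex small RNA libraries sequenced as 37-base single-end reads with a
#' six-base index tag and a 3' adaptor, with known (planted) genetic
#' variants, A-to-I editing sites, cis-eQTL effects, batch and tag effects
#' and phenotype couplings.
#'
#' @param n_samples cohort size; samples are assigned to 12-plex pools.
#' @param n_mirna,n_snorna,n_other number of miRNA hairpins, snoRNA genes
#'   and other ncRNA genes in the synthetic catalogue.
#' @param n_unannotated number of expressed, unannotated short loci planted
#'   on the genome backbone.
#' @param read_depth_mean expected reads per sample (Poisson mean).
#' @param tag_set twelve distinct six-base index tags.
#' @param adapter3 3' adaptor sequence (>= 12 bases).
#' @param seed integer RNG seed; a fixed seed makes every generated output
#'   byte-identical.
#' @param eqtl_effects data.frame with columns `rna`, `snp`, `beta` (log2
#'   units per dosage unit), or NULL.
#' @param edit_sites data.frame with columns `rna`, `offset` (0-based in the
#'   mature product), `rate` (per-read editing rate in `[0,1]`), or NULL.
#' @param variant_sites data.frame with columns `rna`, `offset`, `ref`,
#'   `alt`, `af` (population allele frequency), or NULL.
#' @param pheno_links data.frame with columns `rna`, `trait`, `beta`, or
#'   NULL.
#' @param batch_assignments optional data.frame with columns `sample_id`,
#'   `batch`, `tag`; by default samples fill consecutive 12-plex pools.
#' @param error_rate per-base sequencing substitution probability.
#' @param contaminant_fraction fraction of adaptor-dimer reads per library.
#' @param abundance_meanlog2,abundance_sdlog2 log2-normal parameters of
#'   baseline RNA abundance (heavy-tailed library composition).
#' @param expr_sd residual SD of log2 expression across samples.
#' @param batch_sd,tag_sd SDs of per-batch and per-tag additive effects on
#'   log2 expression.
#' @param read_length sequencer read length.
#' @param locus_spacing genomic distance between neighbouring gene loci;
#'   miRNAs inside a cluster sit much closer (within 10 kb).
#' @param cluster_fraction fraction of miRNA hairpins placed in genomic
#'   clusters of 2-3 members.
#' @param multilocus_fraction fraction of hairpins duplicated at a second
#'   genomic locus.
#' @return a validated `sim_config` list.
#' @export
sim_config <- function(n_samples = 131L,
                       n_mirna = 50L, n_snorna = 20L, n_other = 10L,
                       n_unannotated = 5L,
                       read_depth_mean = 5000,
                       tag_set = TAGS_DEFAULT,
                       adapter3 = ADAPTER3_DEFAULT,
                       seed = 1L,
                       eqtl_effects = NULL,
                       edit_sites = NULL,
                       variant_sites = NULL,
                       pheno_links = NULL,
                       batch_assignments = NULL,
                       error_rate = 0.001,
                       contaminant_fraction = 0.05,
                       abundance_meanlog2 = 6, abundance_sdlog2 = 2,
                       expr_sd = 0.5,
                       batch_sd = 0.5, tag_sd = 0.25,
                       read_length = 37L,
                       locus_spacing = 12000L,
                       cluster_fraction = 0.3,
                       multilocus_fraction = 0.1) {
  stopifnot(n_samples >= 1, n_mirna >= 1,
            read_depth_mean > 0, nchar(adapter3) >= 12)
  if (length(tag_set) != 12L || any(nchar(tag_set) != 6L) ||
      anyDuplicated(tag_set))
    stop("tag_set must be 12 pairwise-distinct strings of length 6")
  rates <- c(error_rate, contaminant_fraction,
             if (!is.null(edit_sites)) edit_sites$rate,
             if (!is.null(variant_sites)) variant_sites$af)
  if (any(rates < 0 | rates > 1))
    stop("all rates and frequencies must lie in [0, 1]")
  if (is.null(batch_assignments)) {
    pool <- (seq_len(n_samples) - 1L) %/% 12L + 1L
    tag <- tag_set[(seq_len(n_samples) - 1L) %% 12L + 1L]
    batch_assignments <- data.frame(
      sample_id = sprintf("S%03d", seq_len(n_samples)),
      batch = paste0("B", pool), tag = tag,
      stringsAsFactors = FALSE)
  }
  structure(list(
    n_samples = as.integer(n_samples), n_mirna = as.integer(n_mirna),
    n_snorna = as.integer(n_snorna), n_other = as.integer(n_other),
    n_unannotated = as.integer(n_unannotated),
    read_depth_mean = read_depth_mean, tag_set = tag_set,
    adapter3 = adapter3, seed = as.integer(seed),
    eqtl_effects = eqtl_effects, edit_sites = edit_sites,
    variant_sites = variant_sites, pheno_links = pheno_links,
    batch_assignments = batch_assignments, error_rate = error_rate,
    contaminant_fraction = contaminant_fraction,
    abundance_meanlog2 = abundance_meanlog2,
    abundance_sdlog2 = abundance_sdlog2, expr_sd = expr_sd,
    batch_sd = batch_sd, tag_sd = tag_sd,
    read_length = as.integer(read_length),
    locus_spacing = as.integer(locus_spacing),
    cluster_fraction = cluster_fraction,
    multilocus_fraction = multilocus_fraction
  ), class = "sim_config")
}
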