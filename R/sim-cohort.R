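#' Genomic annotation of the simulated RNA products
#'
#' First genomic placement of every expressed product (arm, ncRNA fragment,
#' unannotated product), 0-based half-open.
#'
#' @param catalogue a [make_reference_catalogue()] result.
#' @return data.frame with `rna_id`, `chrom`, `start`, `end`.
#' @export
rna_annotation <- function(catalogue) {
  co <- catalogue$coord[!duplicated(catalogue$coord$seq_id), ]
  rownames(co) <- co$seq_id
  pr <- catalogue$products
  parent <- co[pr$parent_id, ]
  off <- integer(nrow(pr))
  arm_ix <- match(pr$product_id, catalogue$arms$arm_id)
  off[!is.na(arm_ix)] <- catalogue$arms$start[arm_ix[!is.na(arm_ix)]]
  frag_ix <- match(pr$product_id, catalogue$ncrna_frag$rna_id)
  off[!is.na(frag_ix)] <- catalogue$ncrna_frag$start[frag_ix[!is.na(frag_ix)]]
  data.frame(rna_id = pr$product_id, chrom = parent$chrom,
             start = parent$start + off,
             end = parent$start + off + nchar(pr$seq),
             stringsAsFactors = FALSE)
}

#' Adenosine offsets of a product (candidate A-to-I edit sites)
#'
#' @param catalogue a [make_reference_catalogue()] result.
#' @param rna product id.
#' @return 0-based offsets of A bases in the product sequence.
#' @export
edit_site_candidates <- function(catalogue, rna) {
  s <- catalogue$products$seq[catalogue$products$product_id == rna]
  if (!length(s)) stop("reference error: unknown RNA id: ", rna)
  which(strsplit(s, "")[[1]] == "A") - 1L
}

#' Simulate a cohort over a synthetic catalogue
#'
#' Draws the cohort-level ground truth: per-sample per-RNA true molecule
#' counts (log2-normal baseline abundances with additive cis-eQTL, batch and
#' tag effects on the log2 scale), Hardy-Weinberg genotype dosages with MAF
#' and imputation-info annotations, sample covariates, and metabolic
#' phenotypes linearly coupled to chosen RNAs.
#'
#' @param catalogue a [make_reference_catalogue()] result.
#' @param cfg the [sim_config()] used to build the catalogue.
#' @param n_background_snps SNPs with no effect placed at random genomic
#'   positions (a few deliberately fail the MAF/info retention filters).
#' @return a `sim_cohort` list: `counts` (RNA x sample true molecule
#'   counts), `log2_mu` (expected log2 expression), `genotypes`,
#'   `snp_info`, `variant_genotypes`, `covariates`, `phenotypes`,
#'   `annotation`, and the effect tables echoed back.
#' @export
simulate_cohort <- function(catalogue, cfg, n_background_snps = 50L) {
  stopifnot(inherits(catalogue, "sim_catalogue"), inherits(cfg, "sim_config"))
  set.seed(cfg$seed + 1L)
  samples <- cfg$batch_assignments$sample_id
  n <- length(samples)
  products <- catalogue$products
  rnas <- products$product_id
  anno <- rna_annotation(catalogue)

  bad <- setdiff(c(cfg$eqtl_effects$rna, cfg$edit_sites$rna,
                   cfg$variant_sites$rna, cfg$pheno_links$rna), rnas)
  if (length(bad))
    stop("reference error: unknown RNA id(s): ", paste(bad, collapse = ", "))
  if (!is.null(cfg$edit_sites) && nrow(cfg$edit_sites)) {
    es <- cfg$edit_sites
    base <- substr(products$seq[match(es$rna, products$product_id)],
                   es$offset + 1L, es$offset + 1L)
    if (any(base != "A"))
      stop("A-to-I edit sites must sit on an A: ",
           paste(es$rna[base != "A"], es$offset[base != "A"],
                 collapse = ", "))
  }

  # expression-model draws come first so baseline abundances depend only on
  # the catalogue and seed, not on which effects or sites are planted
  baseline <- rnorm(length(rnas), cfg$abundance_meanlog2, cfg$abundance_sdlog2)
  names(baseline) <- rnas
  batches <- unique(cfg$batch_assignments$batch)
  batch_eff <- setNames(rnorm(length(batches), 0, cfg$batch_sd), batches)
  tag_eff <- setNames(rnorm(12, 0, cfg$tag_sd), cfg$tag_set)
  noise <- matrix(rnorm(length(rnas) * n, 0, cfg$expr_sd),
                  nrow = length(rnas))

  # --- genotypes -------------------------------------------------------
  glen <- catalogue$genome_length
  snp_rows <- list()
  if (!is.null(cfg$eqtl_effects)) {
    ee <- cfg$eqtl_effects
    if (is.null(ee$maf)) ee$maf <- runif(nrow(ee), 0.1, 0.5)
    for (i in seq_len(nrow(ee))) {
      rs <- anno$start[anno$rna_id == ee$rna[i]]
      snp_rows[[length(snp_rows) + 1L]] <- data.frame(
        snp = ee$snp[i],
        pos = max(0L, rs + sample(-50000:50000, 1)),
        maf = ee$maf[i], info = runif(1, 0.85, 1),
        stringsAsFactors = FALSE)
    }
  }
  for (i in seq_len(n_background_snps)) {
    snp_rows[[length(snp_rows) + 1L]] <- data.frame(
      snp = sprintf("bg%04d", i), pos = sample(0:glen, 1),
      maf = runif(1, if (i %% 10 == 0) 0.01 else 0.06,
                  if (i %% 10 == 0) 0.049 else 0.5),
      info = if (i %% 11 == 0) runif(1, 0.5, 0.79) else runif(1, 0.85, 1),
      stringsAsFactors = FALSE)
  }
  snp_info <- do.call(rbind, snp_rows)
  snp_info$pass <- snp_info$maf > 0.05 & snp_info$info > 0.8
  genotypes <- t(vapply(seq_len(nrow(snp_info)), function(i)
    rbinom(n, 2L, snp_info$maf[i]), numeric(n)))
  dimnames(genotypes) <- list(snp_info$snp, samples)

  # planted transcript variants are carried by their own genotype
  variant_genotypes <- NULL
  if (!is.null(cfg$variant_sites) && nrow(cfg$variant_sites)) {
    vs <- cfg$variant_sites
    variant_genotypes <- t(vapply(seq_len(nrow(vs)), function(i)
      rbinom(n, 2L, vs$af[i]), numeric(n)))
    dimnames(variant_genotypes) <- list(
      paste0(vs$rna, ":", vs$offset), samples)
  }

  # --- expression ------------------------------------------------------
  mu <- matrix(baseline, nrow = length(rnas), ncol = n,
               dimnames = list(rnas, samples))
  mu <- sweep(mu, 2, batch_eff[cfg$batch_assignments$batch], "+")
  mu <- sweep(mu, 2, tag_eff[cfg$batch_assignments$tag], "+")
  if (!is.null(cfg$eqtl_effects)) {
    for (i in seq_len(nrow(cfg$eqtl_effects))) {
      e <- cfg$eqtl_effects[i, ]
      mu[e$rna, ] <- mu[e$rna, ] + e$beta * genotypes[e$snp, ]
    }
  }
  mu <- mu + noise

  counts <- matrix(0, nrow = length(rnas), ncol = n,
                   dimnames = list(rnas, samples))
  for (j in seq_len(n)) {
    tot <- rpois(1, cfg$read_depth_mean)
    w <- 2^mu[, j]
    counts[, j] <- as.numeric(rmultinom(1, tot, w / sum(w)))
  }

  # --- covariates and phenotypes --------------------------------------
  covariates <- data.frame(
    sample_id = samples,
    age = round(runif(n, 35, 75)),
    batch = cfg$batch_assignments$batch,
    tag = cfg$batch_assignments$tag,
    rin = round(runif(n, 6.7, 10), 1),
    stringsAsFactors = FALSE)

  z <- function(v) as.numeric(scale(v))
  phenotypes <- data.frame(
    sample_id = samples,
    bmi = 26 + 4 * rnorm(n),
    ptfm = 38 + 8 * rnorm(n),
    insulin = round(pmax(5, 30 * exp(rnorm(n, 0, 0.6)))),
    glucose = 5 + 0.5 * rnorm(n),
    stringsAsFactors = FALSE)
  if (!is.null(cfg$pheno_links)) {
    for (i in seq_len(nrow(cfg$pheno_links))) {
      l <- cfg$pheno_links[i, ]
      if (!l$trait %in% names(phenotypes))
        stop("reference error: unknown trait ", l$trait)
      phenotypes[[l$trait]] <-
        phenotypes[[l$trait]] + l$beta * z(mu[l$rna, ])
    }
  }

  structure(list(
    counts = counts, log2_mu = mu, genotypes = genotypes,
    snp_info = snp_info, variant_genotypes = variant_genotypes,
    covariates = covariates, phenotypes = phenotypes, annotation = anno,
    eqtl_effects = cfg$eqtl_effects, pheno_links = cfg$pheno_links,
    config = cfg
  ), class = "sim_cohort")
}
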