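#!/usr/bin/env Rscript

# cis-eQTL scan (100 kb window, LRT, pooled q-values), obesity-phenotype
# associations (per-trait FDR), the lean/obese contrast, and the
# mature/star arm analysis.

library(srnapop)

state <- readRDS("results/cohort/state.rds")
truth <- state$truth
expr_tab <- read.table("results/expression_log2.tsv", header = TRUE,
                       sep = "\t", check.names = FALSE)
expr <- as.matrix(expr_tab[, -1])
rownames(expr) <- expr_tab$rna
# at this cohort scale (24 samples) the 12-level tag covariate would
# nearly saturate the linear model, so adjustment is age + batch; the
# full-scale analysis (131 samples) affords tag as well
covs <- truth$covariates[, c("sample_id", "age", "batch")]

# annotate unannotated loci from their coordinates so they are scanned too
loc_rows <- grep("^chrS_", rownames(expr), value = TRUE)
anno <- truth$annotation
if (length(loc_rows)) {
  parts <- do.call(rbind, strsplit(sub("^chrS_", "", loc_rows), "_"))
  anno <- rbind(anno, data.frame(
    rna_id = loc_rows, chrom = "chrS",
    start = as.integer(parts[, 1]), end = as.integer(parts[, 2])))
}

eqtl <- cis_eqtl_scan(expr, truth$genotypes, truth$snp_info,
                      anno, covs)
write.table(eqtl, "results/eqtl.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
sig <- eqtl[eqtl$q < 0.05, ]
message(sprintf("eQTL: %d tests, %d at q < 0.05 (top: %s ~ %s, p = %.2g)",
                nrow(eqtl), nrow(sig), eqtl$rna[1], eqtl$snp[1],
                eqtl$p[1]))

ph <- phenotype_assoc(expr, truth$phenotypes, covs)
for (tr in names(ph)) {
  write.table(ph[[tr]], sprintf("results/pheno_%s.tsv", tr), sep = "\t",
              quote = FALSE, row.names = FALSE)
  message(sprintf("phenotype %s: %d RNAs at per-trait FDR 5%%; top %s (p = %.2g)",
                  tr, sum(ph[[tr]]$q < 0.05), ph[[tr]]$rna[1],
                  ph[[tr]]$p[1]))
}
if (!is.null(state$cfg$pheno_links)) {
  pl <- state$cfg$pheno_links
  for (i in seq_len(nrow(pl))) {
    tab <- ph[[pl$trait[i]]]
    message(sprintf("planted %s link on %s ranks %d/%d (p = %.2g)",
                    pl$trait[i], pl$rna[i],
                    which(tab$rna == pl$rna[i]), nrow(tab),
                    tab$p[tab$rna == pl$rna[i]]))
  }
}

bmi <- setNames(truth$phenotypes$bmi, truth$phenotypes$sample_id)
gc <- tryCatch(group_contrast(expr, bmi, covs),
               error = function(e) { message("group contrast: ",
                                             conditionMessage(e)); NULL })
if (!is.null(gc)) {
  write.table(gc, "results/lean_obese.tsv", sep = "\t", quote = FALSE,
              row.names = FALSE)
  message(sprintf("lean/obese: %d lean, %d obese, %d excluded; %d at q < 0.05",
                  attr(gc, "n_lean"), attr(gc, "n_obese"),
                  attr(gc, "n_excluded"), sum(gc$q < 0.05)))
}

arms <- state$catalogue$arms
pairs <- merge(arms[arms$role == "mature", c("hairpin_id", "arm_id")],
               arms[arms$role == "star", c("hairpin_id", "arm_id")],
               by = "hairpin_id", suffixes = c("_m", "_s"))
arm <- arm_analysis(expr,
                    data.frame(mature_id = pairs$arm_id_m,
                               star_id = pairs$arm_id_s),
                    truth$genotypes, truth$snp_info, truth$annotation,
                    covs)
write.table(arm$correlations, "results/arm_correlations.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
if (!is.null(arm$qtl))
  write.table(arm$qtl, "results/arm_qtl.tsv", sep = "\t", quote = FALSE,
              row.names = FALSE)
message(sprintf("arms: %d pairs quantified, %d with |rho| > 0.4",
                nrow(arm$correlations), sum(arm$correlations$flagged)))
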