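#!/usr/bin/env Rscript

# Median-of-ratios normalisation, log2 transform, and the principal
# component / covariate screen for batch effects.

library(srnapop)

counts_tab <- read.table("results/counts.tsv", header = TRUE, sep = "\t",
                         check.names = FALSE)
counts <- as.matrix(counts_tab[, -1])
rownames(counts) <- counts_tab$rna
covs <- read.table("results/cohort/covariates.tsv", header = TRUE,
                   sep = "\t", stringsAsFactors = FALSE)
covs <- covs[match(colnames(counts), covs$sample_id), ]

s <- size_factors(counts)
expr <- log_normalise(counts, s)

screen <- pc_covariate_screen(
  expr, covs[, c("age", "batch", "tag", "rin")],
  n_pcs = min(ncol(expr), 20L), n_tests = ncol(expr))

write.table(data.frame(sample_id = names(s), size_factor = s),
            "results/size_factors.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(data.frame(rna = rownames(expr), round(expr, 4),
                       check.names = FALSE),
            "results/expression_log2.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(screen, "results/pc_covariate_screen.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

sig <- screen[screen$significant, ]
message(sprintf("size factors span %.2f-%.2f; %d significant PC-covariate pairs",
                min(s), max(s), nrow(sig)))
if (nrow(sig))
  message(paste(sprintf("  %s ~ %s (r = %.2f)", sig$pc, sig$covariate,
                        sig$r), collapse = "\n"))
message(sprintf("critical |r| at this n (Bonferroni over %d): %.2f",
                ncol(expr), critical_r(ncol(expr), ncol(expr))))
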