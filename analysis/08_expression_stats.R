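#!/usr/bin/env Rscript

# Expression-variation statistics: cross-tissue specificity Z tests against
# synthetic comparison tissues, conservation/expression contingency tests,
# cluster co-expression enrichment, and miRNA-target correlation summaries.

library(srnapop)

state <- readRDS("results/cohort/state.rds")
catg <- state$catalogue
truth <- state$truth
expr_tab <- read.table("results/expression_log2.tsv", header = TRUE,
                       sep = "\t", check.names = FALSE)
expr <- as.matrix(expr_tab[, -1])
rownames(expr) <- expr_tab$rna
covs <- truth$covariates[match(colnames(expr),
                               truth$covariates$sample_id),
                         c("batch", "tag")]
res_expr <- residualise(expr, covs)

# cross-tissue panel: three synthetic tissues sharing most of the adipose
# profile, with the two most adipose-abundant RNAs knocked down elsewhere
set.seed(state$cfg$seed + 8L)
adip <- data.frame(rna_id = rownames(expr), mean = rowMeans(expr),
                   var = apply(expr, 1, var), n = ncol(expr))
top2 <- adip$rna_id[order(-adip$mean)][1:2]
others <- lapply(c(liver = 1, muscle = 2, spleen = 3), function(i) {
  m <- adip
  m$mean <- m$mean + rnorm(nrow(m), 0, 0.3)
  m$mean[m$rna_id %in% top2] <- m$mean[m$rna_id %in% top2] - 4
  m
})
ts <- tissue_specificity(adip, others)
write.table(ts$tests, "results/tissue_tests.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
message(sprintf("tissue specificity: %d RNA(s) adipose-specific (q < 0.1): %s",
                sum(ts$specific$specific),
                paste(ts$specific$rna_id[ts$specific$specific],
                      collapse = ", ")))

# conservation vs expression (thresholds scaled to the synthetic range)
cons <- catg$conservation$score[match(rownames(expr),
                                      catg$conservation$rna_id)]
ct <- conservation_expression_test(rowMeans(expr), apply(expr, 1, var),
                                   cons,
                                   expr_cut = median(rowMeans(expr)),
                                   var_cut = median(apply(expr, 1, var)))
write.table(ct, "results/conservation_tests.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
message(sprintf("conservation: mean-split X2 = %.2f (p = %.3g), var-split X2 = %.2f (p = %.3g)",
                ct$stat[1], ct$p[1], ct$stat[2], ct$p[2]))

# cluster co-expression (clusters from the 10 kb rule; members are the
# mature arms of clustered hairpins)
cl <- merge(catg$clusters, catg$arms[catg$arms$role == "mature",
                                     c("hairpin_id", "arm_id")])
cl <- data.frame(cluster_id = cl$cluster_id, rna_id = cl$arm_id)
en <- tryCatch(
  cluster_correlation_enrichment(res_expr, cl, n_random = 500,
                                 seed = state$cfg$seed),
  error = function(e) { message("cluster enrichment: ",
                                conditionMessage(e)); NULL })
if (!is.null(en))
  message(sprintf("clusters: median r %.2f vs %.2f random (MWU p = %.3g)",
                  en$cluster_median, en$random_median, en$p))

# miRNA-target correlations against the planted panel
pan <- simulate_mrna_matrix(truth, catg, state$cfg, "mir001-5p",
                            n_probes = 250L, n_targets = 60L,
                            coupling = -0.5)
mir_rows <- intersect(rownames(res_expr), "mir001-5p")
tc <- target_correlation_summary(
  res_expr[mir_rows, , drop = FALSE], pan$mrna,
  data.frame(mirna = "mir001-5p", probe = pan$targets),
  n_background = 500, seed = state$cfg$seed)
message(sprintf("targets: mean r = %.3f (t-test p = %.2g, MWU p = %.2g)",
                tc$mean_r, tc$t_p, tc$mw_p))
write.table(data.frame(probe = pan$targets, r = tc$pair_r),
            "results/target_correlations.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
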