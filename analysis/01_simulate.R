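#!/usr/bin/env Rscript

# Build the synthetic cohort the rest of the analysis runs on: an annotated
# mini-genome (miRNA hairpins with mature/star arms, snoRNAs, other ncRNA,
# pseudogenes, unannotated loci), a 24-sample 12-plex cohort with one
# planted cis-eQTL, one transcript polymorphism, one A-to-I editing site
# and a BMI link, and the pooled FASTQ files with a per-read truth sidecar.

library(srnapop)

dir.create("results", showWarnings = FALSE)
dir.create("results/cohort", showWarnings = FALSE)

cfg0 <- sim_config(n_samples = 24L, n_mirna = 30L, n_snorna = 8L,
                   n_other = 4L, n_unannotated = 3L,
                   read_depth_mean = 4000, seed = 20260901L)
cat0 <- make_reference_catalogue(cfg0)

# pilot pass to learn the abundance ranking (baselines depend only on the
# catalogue and seed, so they carry over to the final cohort), then plant
# the variant and edit on abundant arms so per-sample pileup depth
# supports the full-scale calling filters
pilot <- simulate_cohort(cat0, cfg0)
arm_rank <- names(sort(rowSums(pilot$counts), decreasing = TRUE))
arm_rank <- arm_rank[grepl("^mir", arm_rank)]
eqtl_arm <- arm_rank[1]
pheno_arm <- arm_rank[2]
edit_arm <- arm_rank[-(1:2)][which(vapply(arm_rank[-(1:2)], function(a)
  length(edit_site_candidates(cat0, a)), integer(1)) >= 4)[1]]
var_arm <- setdiff(arm_rank[-(1:2)], edit_arm)[1]
var_ref <- substr(cat0$products$seq[
  cat0$products$product_id == var_arm], 4, 4)

cfg <- cfg0
cfg$eqtl_effects <- data.frame(rna = eqtl_arm, snp = "rs_sim1",
                               beta = 1, maf = 0.3)
cfg$variant_sites <- data.frame(
  rna = var_arm, offset = 3L, ref = var_ref,
  alt = setdiff(c("A", "C", "G", "T"), var_ref)[1], af = 0.25)
cfg$edit_sites <- data.frame(rna = edit_arm,
                             offset = edit_site_candidates(cat0, edit_arm)[2],
                             rate = 0.2)
# coupling sized to stay detectable through count noise at this cohort
# scale (24 samples; BMI SD is 4)
cfg$pheno_links <- data.frame(rna = pheno_arm, trait = "bmi", beta = 6)

truth <- simulate_cohort(cat0, cfg)
fq <- write_fastq(truth, cat0, cfg, "results/cohort")

write.table(truth$covariates, "results/cohort/covariates.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(truth$phenotypes, "results/cohort/phenotypes.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(data.frame(snp = rownames(truth$genotypes), truth$genotypes,
                       check.names = FALSE),
            "results/cohort/genotypes.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(truth$snp_info, "results/cohort/snp_info.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(truth$annotation, "results/cohort/annotation.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
saveRDS(list(cfg = cfg, catalogue = cat0, truth = truth),
        "results/cohort/state.rds")

message(sprintf("cohort: %d samples, %d products, %d reads in %d pools",
                cfg$n_samples, nrow(cat0$products), nrow(fq$sidecar),
                length(fq$fastq)))
message("planted: eQTL on ", eqtl_arm, "; variant on ", var_arm,
        "; editing on ", edit_arm, "; BMI link on ", pheno_arm)
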