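#!/usr/bin/env Rscript

# Call sequence variants and A-to-I editing from read pileups over the
# mature products, validate against simulated DNA pileups, and scan for
# non-genomic end bases.  Filters follow the full-scale rules (>= 20
# informative samples, >= 10 alleles in one sample, >= 20% non-reference
# in one sample) except the informative-sample floor, which is capped at
# the cohort size.

library(srnapop)

state <- readRDS("results/cohort/state.rds")
q <- readRDS("results/quant.rds")
reads <- read.table("results/reads_processed.tsv", header = TRUE,
                    sep = "\t", stringsAsFactors = FALSE)
catg <- state$catalogue
cfg <- state$cfg

res <- q$resolved[q$resolved$stratum == "mature_mirna" &
                    q$resolved$gaps == 0, ]
seqs <- setNames(reads$seq, reads$read_id)
samples <- setNames(reads$sample_id, reads$read_id)

# mature-stratum alignments are in extended-arm coordinates (up to 3 nt of
# hairpin on the 5' side); shift them into product coordinates
refs <- build_references(catg, variants = cfg$variant_sites)
mc <- refs$mature_mirna$coord
ext5 <- setNames(catg$arms$start[match(mc$seq_id, catg$arms$arm_id)] -
                   mc$ext_start, mc$seq_id)
res$offset <- res$offset - ext5[res$target]

# pile every position of every quantified mature product
prod <- catg$products[catg$products$product_id %in% unique(res$target), ]
sites <- do.call(rbind, lapply(seq_len(nrow(prod)), function(i)
  data.frame(rna = prod$product_id[i],
             offset = seq_len(nchar(prod$seq[i])) - 1L,
             ref = strsplit(prod$seq[i], "")[[1]])))
prod_len <- setNames(nchar(catg$products$seq), catg$products$product_id)

aln <- data.frame(read = res$read_id, target = res$target,
                  offset = res$offset, gaps = res$gaps)
pu <- build_pileup(aln, seqs, samples, sites, prod_len)
last_base <- setNames(prod_len[prod$product_id] - 1L, prod$product_id)
flt <- filter_sites(pu, min_samples = min(20L, cfg$n_samples),
                    last_base = last_base)

# simulated DNA pileups: 30 reads per sample, alleles from the planted
# variant genotypes (editing leaves DNA homozygous reference)
dna <- NULL
if (!is.null(cfg$variant_sites)) {
  vs <- cfg$variant_sites
  g <- state$truth$variant_genotypes[paste0(vs$rna, ":", vs$offset), ]
  dna <- data.frame(rna = vs$rna, offset = vs$offset, ref = vs$ref,
                    sample_id = names(g), A = 0, C = 0, G = 0, T = 0,
                    N = 0)
  dna[[vs$ref]] <- 30 - 15 * g
  dna[[vs$alt]] <- dna[[vs$alt]] + 15 * g
}
cand <- flt[flt$pass & !flt$artefact, ]
ref_dna <- data.frame(rna = cand$rna, offset = cand$offset,
                      ref = cand$ref,
                      sample_id = rep(colnames(state$truth$counts),
                                      each = nrow(cand)),
                      A = 0, C = 0, G = 0, T = 0, N = 0)
for (b in c("A", "C", "G", "T"))
  ref_dna[[b]] <- ifelse(ref_dna$ref == b, 30, 0)
keyed <- paste(ref_dna$rna, ref_dna$offset, ref_dna$sample_id)
if (!is.null(dna))
  ref_dna <- rbind(dna, ref_dna[!keyed %in%
                                  paste(dna$rna, dna$offset,
                                        dna$sample_id), ])
calls <- classify_sites(pu, flt, ref_dna)

em <- end_modification_scan(aln, seqs, samples,
                            setNames(catg$products$seq,
                                     catg$products$product_id))

write.table(flt, "results/site_filter.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(calls, "results/variant_calls.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(em, "results/end_modifications.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

message(sprintf("%d sites piled, %d pass filters (%d artefact-flagged)",
                nrow(flt), sum(flt$pass), sum(flt$artefact)))
for (cl in c("polymorphism", "editing", "unresolved"))
  message(sprintf("  %s: %d", cl, sum(calls$class == cl)))
message(sprintf("planted truth: variant %s:%d, edit %s:%d",
                cfg$variant_sites$rna, cfg$variant_sites$offset,
                cfg$edit_sites$rna, cfg$edit_sites$offset))
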