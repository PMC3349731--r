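#!/usr/bin/env Rscript

# Demultiplex the pooled FASTQ files by index tag, trim the 3' adaptor and
# apply the cleanup filters; write per-read outcomes, a per-pool trim
# report and the read length histogram (expected to peak near 22 nt).

library(srnapop)

state <- readRDS("results/cohort/state.rds")
cfg <- state$cfg

fastqs <- list.files("results/cohort", pattern = "^pool_.*\\.fastq$",
                     full.names = TRUE)
all_reads <- list()
reports <- list()
for (fq in fastqs) {
  pool <- sub("^pool_(.*)\\.fastq$", "\\1", basename(fq))
  pr <- process_pool(fq, tags = cfg$tag_set, adapter3 = cfg$adapter3)
  r <- pr$reads
  r$pool <- pool
  r$sample_id <- cfg$batch_assignments$sample_id[
    match(paste(pool, r$tag),
          paste(cfg$batch_assignments$batch, cfg$batch_assignments$tag))]
  all_reads[[pool]] <- r
  reports[[pool]] <- data.frame(pool = pool, t(pr$report))
}
reads <- do.call(rbind, all_reads)
report <- do.call(rbind, reports)

retained <- reads[reads$status == "retained", ]
hist22 <- length_histogram(retained$seq)

write.table(reads, "results/reads_processed.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(report, "results/trim_report.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(data.frame(length = names(hist22), reads = hist22),
            "results/length_histogram.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

message(sprintf("%d reads in, %d retained (%.1f%%); modal length %s nt",
                nrow(reads), nrow(retained),
                100 * nrow(retained) / nrow(reads),
                names(hist22)[which.max(hist22)]))
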