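#!/usr/bin/env Rscript
# TF motif enrichment over differential chromatin accessibility: simulate an
# ATAC-like peak set in which peaks carrying one motif lose accessibility
# 4-fold in the condition group, quantile-normalize the raw counts, score
# per-peak differential accessibility, and rank motifs by top/bottom-tail
# hypergeometric enrichment (module-map-style integration).

suppressPackageStartupMessages(library(oncoscreen))
dir.create("results", showWarnings = FALSE)
seed <- 20260924L

set.seed(seed)
pfms <- c(make_random_pfms(1, 8, prefix = "TARGET"),
          make_random_pfms(5, 8, prefix = "DECOY"))
write_jaspar(pfms, "results/motifs.jaspar")

ps <- make_peakset(generator_spec(seed), pfms[[1]])
write_bed(ps$peaks, "results/peaks.bed")
write_counts_tsv(ps$counts, "results/peak_counts.tsv")

pm <- peak_motif_matrix(ps$peaks, pfms)
message("peak x motif occurrence column sums: ",
        paste(sprintf("%s=%d", colnames(pm), colSums(pm)), collapse = ", "))

scores <- differential_peaks(ps$counts, ps$condition)
en <- module_map_enrichment(pm, scores, top_frac = 0.05)
print(en)
message(sprintf("top-ranked motif: %s (direction %s, q = %.3g)",
                en$motif_id[1], en$direction[1], en$q[1]))
utils::write.table(en, "results/motif_enrichment.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
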