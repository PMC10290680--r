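#!/usr/bin/env Rscript
# Step 4: QC of the protein table — per-channel intensity distributions,
# PCA of log2 relative profiles with channels as observations, and
# average-linkage hierarchical clustering of channels. Replicate channels
# of the same line should co-locate; blanks should separate from samples.

library(ppbscreen)

layout <- read_layout("results/layout.json")
proteins <- utils::read.delim("results/proteins.tsv", check.names = FALSE)

qc <- qc_summary(proteins, layout)
write_table_tsv(qc$channel_summary, "results/qc_channel_summary.tsv")
write_table_tsv(qc$pca$coords, "results/qc_pca.tsv")
message(sprintf("PC1/PC2 carry %.0f%% / %.0f%% of channel variance",
                100 * qc$pca$variance_fraction[1],
                100 * qc$pca$variance_fraction[2]))

merged <- stats::cutree(qc$clustering, k = 2)
message("deepest channel split: {",
        paste(names(merged)[merged == 1], collapse = ", "), "} vs {",
        paste(names(merged)[merged == 2], collapse = ", "), "}")

grDevices::pdf("results/qc.pdf", width = 9, height = 4.5)
plot(qc)
grDevices::dev.off()
message("wrote results/qc_channel_summary.tsv, qc_pca.tsv, qc.pdf")
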