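#!/usr/bin/env Rscript
# Step 2: reporter quantification and loading-bias normalization.
# Impurity-corrects the raw PSM intensities, excludes very-low-intensity
# PSMs (min >= 1000, median >= 5000), estimates per-channel loading factors
# from cross-species-specific peptides, rescales, mean-centers, summarizes
# shared-peptide PSMs to proteins and attaches absolute intensities.

library(ppbscreen)

layout <- read_layout("results/layout.json")
psms <- read_psm_table("results/psms.tsv", layout)
M <- read_impurity_matrix("results/impurity.csv")

psms <- correct_impurity(psms, M, layout)
message(sprintf("impurity correction clamped %d/%d PSMs at zero",
                sum(psms$impurity_clamped), nrow(psms)))
psms <- filter_psms(psms, layout)

factors <- compute_loading_factors(psms, layout)
write_loading_factors(factors, "results/factors.tsv")
message(sprintf("loading factors span %.2f-%.2f (reference %s)",
                min(factors$factor), max(factors$factor),
                attr(factors, "reference")))
psms <- apply_loading_factors(psms, factors, layout)

centered <- mean_center(psms, layout)
proteins <- summarize_proteins(centered, layout)
proteins <- scale_absolute(proteins, psms, layout)
write_table_tsv(proteins, "results/proteins.tsv")
message(sprintf("quantified %d proteins from shared peptides; median %d PSMs each",
                nrow(proteins), stats::median(proteins$n_psms_used)))
message("wrote results/factors.tsv, proteins.tsv")
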