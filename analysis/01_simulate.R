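#!/usr/bin/env Rscript
# Step 1: generate one synthetic 11-plex pulldown under the study design
# (4 cell lines x 2 replicates + 3 blanks; 1000 proteins, 5% binders at
# log2FC 3, noise SD 0.15, loading biases in [0.5, 2]), with reporter
# isotope spill-over applied, and write the raw inputs the rest of the
# workflow consumes.

library(ppbscreen)

dir.create("results", showWarnings = FALSE)
layout <- layout_11plex()
M <- tmt_impurity_matrix(11)
cfg <- sim_config(impurity = M, seed = 17)
sim <- simulate_experiment(cfg, layout)

write_layout(layout, "results/layout.json")
utils::write.table(matrix(sprintf("%.17g", M), nrow(M)),
                   "results/impurity.csv", sep = ",", quote = FALSE,
                   col.names = FALSE, row.names = FALSE)
write_psm_table(sim$psms, layout, "results/psms.tsv")
write_truth(sim$truth, "results/truth.tsv")

n_binders <- length(unique(sim$truth$proteins$protein[sim$truth$proteins$is_binder]))
message(sprintf("simulated %d PSMs over %d proteins (%d true binders, %.1f%%)",
                nrow(sim$psms), cfg$n_proteins, n_binders,
                100 * n_binders / cfg$n_proteins))
message(sprintf("peptide classes: %s",
                paste(sprintf("%s=%d", names(table(sim$psms$species_specificity)),
                              table(sim$psms$species_specificity)),
                      collapse = ", ")))
message("wrote results/layout.json, impurity.csv, psms.tsv, truth.tsv")
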