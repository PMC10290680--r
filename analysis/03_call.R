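#!/usr/bin/env Rscript
# Step 3: interaction-candidate calling. Fits the null model from replicate
# log2 ratios, runs the per-line one-tailed t-tests against the three
# blanks, combines them by Fisher's method, adjusts by BH, and gates on the
# fold-change z-score. Compares the calls against the simulation truth.

library(ppbscreen)

layout <- read_layout("results/layout.json")
proteins <- utils::read.delim("results/proteins.tsv", check.names = FALSE)
truth <- utils::read.delim("results/truth.tsv")

null <- estimate_null_model(proteins, layout, estimator = "mle")
print(null)
cand <- call_candidates(proteins, layout, null,
                        fdr_threshold = 0.01, z_threshold = 3,
                        fc_rule = "max")
write_table_tsv(cand, "results/candidates.tsv")

called <- cand$protein[cand$is_candidate]
binders <- unique(truth$protein[truth$is_binder])
quantifiable <- intersect(binders, cand$protein)
message(sprintf("called %d candidates (FDR < 0.01, z > 3) of %d proteins",
                length(called), nrow(cand)))
message(sprintf("vs truth: %d/%d quantifiable binders recovered (sensitivity %.3f), %d false positives (FDP %.4f)",
                sum(quantifiable %in% called), length(quantifiable),
                mean(quantifiable %in% called),
                sum(!called %in% binders),
                sum(!called %in% binders) / max(1, length(called))))
message("wrote results/candidates.tsv")
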