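#!/usr/bin/env Rscript
# Step 1: generate the synthetic monogenic-disorder variant table.
#
# The generator stands in for the real database download and the external
# stability/accessibility predictor runs: each variant gets a latent "true"
# ddG (pathogenic variants: 70% destabilising), three noisy predictor
# readouts of it (one emitted in the opposite sign convention, one
# deliberately weak), an RSA value weakly coupled to ddG, population
# frequencies, conflict flags and per-gene grouping with planted curation
# violations.  A ground-truth sidecar records what was planted.

library(stabpath)

seed <- 20260922
dir.create("results", showWarnings = FALSE)

cfg <- synthetic_config()   # 3000 benign + 3000 pathogenic, 150 genes
g <- generate_variant_table(cfg, seed = seed)

write_variant_table(g$records, "results/variants.tsv")
write_truth_sidecar(g$truth, "results/variants.truth.json")

message("variants: ", nrow(g$records),
        " (benign-class ", sum(g$truth$base_class == "benign"),
        ", pathogenic-class ", sum(g$truth$base_class == "pathogenic"), ")")
message("planted: ", sum(g$truth$freq_violation), " frequency violations, ",
        sum(g$truth$conflict), " conflicts, ",
        sum(!g$truth$survives_strict), " records that should not survive strict curation")
message("wrote results/variants.tsv (+ .truth.json sidecar)")
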