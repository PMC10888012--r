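#!/usr/bin/env Rscript
# Step 2: normalise predictor sign conventions and curate the table.
#
# Filters, in order: resolve clinical labels to binary (the strict policy
# drops likely_* records; the inclusive policy folds them in), exclude
# benign variants with population frequency < 0.01 and pathogenic variants
# with frequency > 0.01, drop records with conflicting clinical
# significance, then drop whole genes whose benign or pathogenic fraction
# is not strictly above 10%.

library(stabpath)

conventions <- list(saafec = TRUE, imutant = FALSE, inps = TRUE)
recs <- normalize_variant_ddg(read_variant_table("results/variants.tsv"),
                              conventions)

for (policy in c("strict", "with_likely")) {
  cfg <- curation_config(include_likely = policy == "with_likely")
  res <- curate(recs, cfg)
  rep <- res$report
  message(sprintf(
    "%s: %d -> %d (label %d, frequency %d, conflict %d, gene balance %d dropped; %d/%d genes kept)",
    policy, rep$n_input, rep$n_output, rep$n_dropped_label,
    rep$n_dropped_frequency, rep$n_dropped_conflict,
    rep$n_dropped_gene_balance, sum(rep$gene_status$kept),
    nrow(rep$gene_status)))
  write_variant_table(res$records,
                      sprintf("results/curated_%s.tsv", policy))
  write_curation_report(rep, sprintf("results/curation_report_%s.json", policy))
}
message("wrote results/curated_{strict,with_likely}.tsv and curation reports")
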