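#!/usr/bin/env Rscript
# Step 3: categorise substitutions by chemical nature and ask, per
# category, how well the ensemble ddG separates benign from pathogenic.
#
# Each substitution is placed on up to four axes (hydropathy, size, ring,
# charge); categories with 100 cases or fewer are set aside, mirroring the
# sparsity rule used for category-level analyses.

library(stabpath)

d <- read_variant_table("results/curated_strict.tsv")
d$ddg_ens <- ensemble_average(d, c("saafec", "inps"))

counts <- count_by_category(d)
kept <- filter_by_min_count(counts, min_total = 100)
write.table(counts, "results/category_counts.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
message(nrow(counts), " directed categories observed; ",
        nrow(kept), " have > 100 cases")

# per-category AUC of the ensemble ddG score
kept$auc <- NA_real_
for (i in seq_len(nrow(kept))) {
  in_cat <- vapply(seq_len(nrow(d)), function(j) {
    cc <- classify_substitution(d$wt[j], d$mut[j])
    any(cc$axis == kept$axis[i] & cc$from_group == kept$from_group[i] &
          cc$to_group == kept$to_group[i])
  }, logical(1))
  sub <- d[in_cat, ]
  if (length(unique(sub$label)) == 2) {
    kept$auc[i] <- roc_curve(sub$ddg_ens, sub$label)$auc
  }
}
kept <- kept[order(-kept$auc), ]
write.table(kept, "results/category_auc.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
message("top categories by ensemble-ddG AUC:")
for (i in seq_len(min(5, nrow(kept)))) {
  message(sprintf("  %s %s->%s: AUC %.3f (n=%d)", kept$axis[i],
                  kept$from_group[i], kept$to_group[i], kept$auc[i],
                  kept$n_benign[i] + kept$n_pathogenic[i]))
}
message("wrote results/category_counts.tsv and results/category_auc.tsv")
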