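#!/usr/bin/env Rscript
# Step 4: threshold analyses of the ddG and RSA scores.
#
# For each score: the stabilising/destabilising census at the common
# magnitude cutoffs, the full ROC curve with AUC, the optimal-MCC cutoff
# from a grid scan, and a balanced-resampling performance report at that
# cutoff (100 draws of equal benign/pathogenic samples).

library(stabpath)

seed <- 20260924
d <- read_variant_table("results/curated_strict.tsv")
d$ddg_ens <- ensemble_average(d, c("saafec", "inps"))
d$ddg_abs <- absolute_transform(d$ddg_ens)

## census of stability changes among pathogenic variants
path <- d[d$label == "pathogenic", ]
cen <- do.call(rbind, lapply(c(1.0, 1.1, 2.0), function(cc) {
  s <- stability_census(path$ddg_ens, cc)
  data.frame(cutoff = cc, n_stabilizing = s$n_stabilizing,
             n_destabilizing = s$n_destabilizing)
}))
write.table(cen, "results/stability_census.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
message(sprintf("pathogenic variants destabilised (ddG < 0): %.1f%%",
                100 * fraction_destabilizing(path, c("saafec", "inps"))))

## ROC curves + MCC scans
specs <- list(
  list(name = "ddg_saafec", col = "ddg_saafec", dir = "le", grid = ddg_grid()),
  list(name = "ddg_imutant", col = "ddg_imutant", dir = "le", grid = ddg_grid()),
  list(name = "ddg_inps", col = "ddg_inps", dir = "le", grid = ddg_grid()),
  list(name = "ddg_ensemble", col = "ddg_ens", dir = "le", grid = ddg_grid()),
  list(name = "ddg_absolute", col = "ddg_abs", dir = "ge", grid = round(seq(0, 5, 0.1), 10)),
  list(name = "rsa", col = "rsa", dir = "le", grid = rsa_grid()))

scan_rows <- list()
roc_rows <- list()
for (s in specs) {
  sc <- d[[s$col]]
  roc <- roc_curve(sc, d$label, direction = s$dir)
  scan <- mcc_scan(sc, d$label, s$grid, direction = s$dir)
  scan_rows[[s$name]] <- data.frame(
    method = s$name, auc = roc$auc, optimal_cutoff = scan$optimal_cutoff,
    optimal_mcc = scan$optimal_mcc)
  roc_rows[[s$name]] <- cbind(method = s$name, roc$points)
  message(sprintf("%-13s AUC %.3f  best MCC %.3f at cutoff %+.2f",
                  s$name, roc$auc, scan$optimal_mcc, scan$optimal_cutoff))
}
write.table(do.call(rbind, scan_rows), "results/threshold_scans.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(do.call(rbind, roc_rows), "results/roc_points.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

## balanced-resampling comparison at each method's optimal cutoff
methods <- lapply(specs, function(s)
  list(name = s$name, score = s$col, direction = s$dir,
       cutoff = "mcc_opt", grid = s$grid))
tab <- compare_methods(d, methods, n_reps = 100, seed = seed)
write.table(tab, "results/method_comparison.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
message("wrote census, scans, ROC points and the method comparison table")
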