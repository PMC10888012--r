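#!/usr/bin/env Rscript
# Step 5: logistic pathogenicity models on (ddG, RSA) features.
#
# For each feature pairing (one predictor or ensemble, always with RSA):
# balance the classes, split 80/20 stratified, select the inverse
# regularisation strength c by 100 repetitions of stratified 5-fold
# cross-validation on the training portion, refit at the selected c, and
# report AUC and MCC (probability cutoff 0.5) on both portions.

library(stabpath)

seed <- 20260925
cv_reps <- 25   # per-model CV repetitions here; see the methods vignette
d <- read_variant_table("results/curated_strict.tsv")
d$ddg_avg_saafec_imutant <- ensemble_average(d, c("saafec", "imutant"))
d$ddg_avg_saafec_inps <- ensemble_average(d, c("saafec", "inps"))
d$ddg_avg_all <- ensemble_average(d, c("saafec", "imutant", "inps"))

feature_sets <- list(
  "saafec+rsa" = c("ddg_saafec", "rsa"),
  "imutant+rsa" = c("ddg_imutant", "rsa"),
  "inps+rsa" = c("ddg_inps", "rsa"),
  "avg(saafec,imutant)+rsa" = c("ddg_avg_saafec_imutant", "rsa"),
  "avg(saafec,inps)+rsa" = c("ddg_avg_saafec_inps", "rsa"),
  "avg(all)+rsa" = c("ddg_avg_all", "rsa"))

rows <- list()
for (nm in names(feature_sets)) {
  res <- train_full_protocol(d, feature_sets[[nm]], seed = seed,
                             cv_reps = cv_reps)
  rows[[nm]] <- data.frame(model = nm, c = res$cv$selected_c,
                           train_auc = res$train$auc, train_mcc = res$train$mcc,
                           test_auc = res$test$auc, test_mcc = res$test$mcc)
  message(sprintf("%-24s c=%-6g train AUC %.2f MCC %.2f | test AUC %.2f MCC %.2f",
                  nm, res$cv$selected_c, res$train$auc, res$train$mcc,
                  res$test$auc, res$test$mcc))
  if (nm == "avg(saafec,inps)+rsa") {
    write_model_json(res$model, "results/model_avg_saafec_inps_rsa.json")
  }
}
tab <- do.call(rbind, rows)
write.table(tab, "results/logistic_models.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
message("wrote results/logistic_models.tsv and the serialised best model")
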