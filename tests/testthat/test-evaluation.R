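test_that("confusion counts at a cutoff match the brute-force tally", {
  cc <- confusion_at_cutoff(c(-3, 1), c("pathogenic", "benign"), -1)
  expect_equal(cc, list(tp = 1L, tn = 1L, fp = 0L, fn = 0L))
  cc2 <- confusion_at_cutoff(c(-3, 1), c("pathogenic", "benign"), 2)
  expect_equal(cc2, list(tp = 1L, tn = 0L, fp = 1L, fn = 0L))
  for (s in 1:5) {
    d <- random_scored(80, seed = 1000 + s)
    cut <- withr::with_seed(s, rnorm(1))
    for (dir in c("le", "ge")) {
      expect_equal(confusion_at_cutoff(d$score, d$label, cut, dir),
                   oracle_confusion(d$score, d$label, cut, dir))
    }
  }
  expect_error(confusion_at_cutoff(numeric(0), character(0), 0), "empty")
  expect_error(confusion_at_cutoff(NA_real_, "benign", 0), "finite")
})

test_that("metrics match their defining formulas", {
  perfect <- classification_metrics(list(tp = 10, tn = 10, fp = 0, fn = 0))
  expect_equal(perfect, list(tpr = 1, fpr = 0, fnr = 0, accuracy = 1, mcc = 1))
  m <- classification_metrics(list(tp = 3, tn = 4, fp = 1, fn = 2))
  expect_equal(m$accuracy, 0.7)
  expect_equal(m$tpr, 0.6)
  expect_equal(m$fpr, 0.2)
  expect_equal(m$fnr, 0.4)
  expect_equal(m$mcc, 10 / sqrt(600), tolerance = 1e-12)
  # swapping classes and predictions leaves MCC unchanged
  expect_equal(classification_metrics(list(tp = 4, tn = 3, fp = 2, fn = 1))$mcc,
               m$mcc)
  expect_error(classification_metrics(list(tp = 0, tn = 5, fp = 2, fn = 0)),
               "both classes")
})

test_that("ROC curve has the required shape and frozen AUC values", {
  perfect <- roc_curve(c(-3, -2, 1, 2),
                       c("pathogenic", "pathogenic", "benign", "benign"))
  expect_equal(perfect$auc, 1)
  ties <- roc_curve(rep(0.5, 6), rep(c("benign", "pathogenic"), 3))
  expect_equal(ties$auc, 0.5)
  mixed <- roc_curve(c(-2, -1, 0, -1.5, 0.5, 1),
                     c(rep("pathogenic", 3), rep("benign", 3)))
  expect_equal(mixed$auc, 7 / 9, tolerance = 1e-12)
  # curve runs (0,0) -> (1,1), both coordinates non-decreasing
  pts <- mixed$points
  expect_equal(c(pts$tpr[1], pts$fpr[1]), c(0, 0))
  expect_equal(c(pts$tpr[nrow(pts)], pts$fpr[nrow(pts)]), c(1, 1))
  expect_true(all(diff(pts$tpr) >= 0))
  expect_true(all(diff(pts$fpr) >= 0))
  expect_error(roc_curve(1:3, rep("benign", 3)), "both classes")
})

test_that("trapezoid AUC equals the concordance-pair AUC, and flips sum to 1", {
  for (s in 1:10) {
    d <- random_scored(120, seed = 2000 + s,
                       lattice = if (s %% 2) round(seq(-2, 2, 0.5), 10) else NULL)
    a_tr <- roc_curve(d$score, d$label)$auc
    expect_equal(a_tr, oracle_auc_pairs(d$score, d$label), tolerance = 1e-9)
    expect_equal(a_tr, auc_by_pairs(d$score, d$label), tolerance = 1e-12)
    a_ge <- roc_curve(d$score, d$label, direction = "ge")$auc
    expect_equal(a_tr + a_ge, 1, tolerance = 1e-9)
  }
})

test_that("pROC agrees with the sweep AUC on untied scores", {
  skip_if_not_installed("pROC")
  d <- random_scored(200, seed = 31)
  got <- roc_curve(d$score, d$label)$auc
  ref <- suppressMessages(pROC::auc(pROC::roc(
    response = d$label, predictor = d$score,
    levels = c("pathogenic", "benign"), direction = "<")))
  expect_equal(got, as.numeric(ref), tolerance = 1e-12)
})

test_that("MCC scan finds the grid optimum with the tie-break rules", {
  sep <- mcc_scan(c(-3, -2, 1, 2),
                  c("pathogenic", "pathogenic", "benign", "benign"),
                  ddg_grid())
  expect_equal(sep$optimal_mcc, 1)
  expect_gt(sep$optimal_cutoff, -2)
  expect_lt(sep$optimal_cutoff, 1)
  # smallest-magnitude tie-break: perfect separation straddling zero
  tie <- mcc_scan(c(-1, 1), c("pathogenic", "benign"), round(seq(-0.5, 0.5, 0.1), 10))
  expect_equal(tie$optimal_cutoff, 0)
  single <- mcc_scan(c(-1, 1), c("pathogenic", "benign"), 0.3)
  expect_equal(single$optimal_cutoff, 0.3)
  expect_error(mcc_scan(c(-1, 1), c("pathogenic", "benign"), numeric(0)),
               "empty")
})

test_that("scan optimum dominates every grid point and matches midpoints", {
  lattice <- round(seq(-3, 3, 0.2), 10)
  for (s in 1:5) {
    d <- random_scored(60, seed = 3000 + s, lattice = lattice)
    scan <- mcc_scan(d$score, d$label, ddg_grid())
    expect_true(all(scan$mcc_at <= scan$optimal_mcc + 1e-12))
    expect_equal(scan$optimal_mcc, oracle_best_mcc(d$score, d$label),
                 tolerance = 1e-12)
  }
})

test_that("balanced resampling draws N = floor(min class / 2) per class", {
  lab <- c(rep("benign", 1405), rep("pathogenic", 1934))
  sc <- withr::with_seed(1, rnorm(length(lab)))
  res <- balanced_resampling_eval(sc, lab, cutoff = 0, n_reps = 5, seed = 2)
  expect_equal(res$sample_n_per_class, 702)
})

test_that("resampling is seed-reproducible and exact on separable data", {
  d <- random_scored(300, seed = 88)
  a <- balanced_resampling_eval(d$score, d$label, 0, n_reps = 20, seed = 9)
  b <- balanced_resampling_eval(d$score, d$label, 0, n_reps = 20, seed = 9)
  expect_identical(a, b)
  # label-determined constant score: accuracy 1, sd 0
  lab <- rep(c("benign", "pathogenic"), each = 50)
  sc <- ifelse(lab == "pathogenic", -2, 2)
  res <- balanced_resampling_eval(sc, lab, 0, n_reps = 20, seed = 1)
  expect_equal(unname(res$mean["accuracy"]), 1)
  expect_equal(unname(res$sd["accuracy"]), 0)
})

test_that("resampled accuracy matches the closed form for balanced draws", {
  # class-conditional exceedance probabilities at the cutoff are known
  withr::with_seed(42, {
    n <- 4000
    lab <- rep(c("benign", "pathogenic"), each = n / 2)
    sc <- ifelse(lab == "pathogenic", rnorm(n / 2, -1), rnorm(n / 2, 1))
  })
  cut <- 0
  # empirical class-conditional exceedance rates of the realised sample
  p_hat <- mean(sc[lab == "pathogenic"] <= cut)
  q_hat <- mean(sc[lab == "benign"] <= cut)
  res <- balanced_resampling_eval(sc, lab, cut, n_reps = 100, seed = 7)
  expected <- (p_hat + (1 - q_hat)) / 2
  mc_se <- unname(res$sd["accuracy"]) / sqrt(res$n_reps)
  expect_lt(abs(unname(res$mean["accuracy"]) - expected), 3 * mc_se + 1e-6)
})

test_that("compare_methods ranks an informative score above a random one", {
  d <- paper_shaped_small()
  recs <- curate(d$records, curation_config(include_likely = TRUE))$records
  recs$ddg_ens <- ensemble_average(recs, c("saafec", "inps"))
  recs$noise <- withr::with_seed(17, rnorm(nrow(recs)))
  tab <- compare_methods(recs, list(
    list(name = "ensemble", score = "ddg_ens", direction = "le",
         cutoff = "mcc_opt"),
    list(name = "noise", score = "noise", direction = "le", cutoff = 0),
    list(name = "rsa35", score = "rsa", direction = "le", cutoff = 0.35)),
    n_reps = 30, seed = 4)
  expect_gt(tab$accuracy_mean[tab$method == "ensemble"],
            tab$accuracy_mean[tab$method == "noise"])
  expect_gt(tab$accuracy_mean[tab$method == "rsa35"], 0.5)
  # mcc_opt delegation: the stored cutoff is the scan optimum
  keep <- !is.na(recs$ddg_ens)
  opt <- mcc_scan(recs$ddg_ens[keep], recs$label[keep], ddg_grid())$optimal_cutoff
  expect_equal(tab$cutoff[tab$method == "ensemble"], opt)
})

test_that("compare_methods accepts precomputed classifier calls", {
  lab <- rep(c("benign", "pathogenic"), each = 40)
  recs <- data.frame(label = lab,
                     ext = ifelse(lab == "pathogenic", "pathogenic", "benign"),
                     stringsAsFactors = FALSE)
  tab <- compare_methods(recs, list(list(name = "external", calls = "ext")),
                         n_reps = 5, seed = 1)
  expect_equal(tab$accuracy_mean, 1)
  expect_error(compare_methods(recs, list(list(name = "m", calls = "nope")),
                               n_reps = 2, seed = 1), "missing calls")
})
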