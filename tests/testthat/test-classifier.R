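test_that("class balancing downsamples the majority class exactly", {
  recs <- data.frame(label = c(rep("benign", 1405), rep("pathogenic", 1934)))
  bal <- balance_classes(recs, seed = 1)
  expect_equal(unname(table(bal$label)["benign"]), 1405)
  expect_equal(unname(table(bal$label)["pathogenic"]), 1405)
  expect_identical(balance_classes(recs, seed = 5), balance_classes(recs, seed = 5))
  even <- data.frame(label = rep(c("benign", "pathogenic"), 10))
  expect_equal(nrow(balance_classes(even, seed = 1)), 20)
  expect_error(balance_classes(data.frame(label = rep("benign", 4))),
               "both classes")
})

test_that("train/test split is stratified, disjoint and exhaustive", {
  recs <- data.frame(id = 1:100, label = rep(c("benign", "pathogenic"), each = 50))
  sp <- split_train_test(recs, 0.8, seed = 3)
  expect_equal(nrow(sp$train), 80)
  expect_equal(nrow(sp$test), 20)
  expect_equal(as.vector(table(sp$train$label)), c(40L, 40L))
  expect_equal(as.vector(table(sp$test$label)), c(10L, 10L))
  expect_length(intersect(sp$train$id, sp$test$id), 0)
  expect_setequal(c(sp$train$id, sp$test$id), recs$id)
  expect_error(split_train_test(recs, 1.0), "strictly between")
  expect_error(split_train_test(recs[1:3, ], 0.8), "too few")
})

test_that("logistic fit on mirror-symmetric data has zero intercept", {
  X <- withr::with_seed(61, cbind(rnorm(200, 1), rnorm(200, 0.5)))
  X <- rbind(X, -X)  # exact mirror with swapped labels
  y <- c(rep(1, 200), rep(0, 200))
  fit <- fit_logistic(X, y, c_value = 1)
  expect_lt(abs(fit$intercept), 1e-6)
})

test_that("penalised fit matches glm at very weak regularisation", {
  d <- generate_logistic_dataset(-0.5, c(1.2, -0.7), n = 2000, seed = 21)
  fit <- fit_logistic(d$features, d$labels, c_value = 1e8)
  ref <- glm(d$labels ~ d$features, family = binomial)
  # convert standardized-scale coefficients back to the original scale
  b_orig <- fit$coef / fit$feature_scales
  a_orig <- fit$intercept - sum(fit$coef * fit$feature_means / fit$feature_scales)
  expect_equal(unname(b_orig), unname(coef(ref)[-1]), tolerance = 1e-5)
  expect_equal(a_orig, unname(coef(ref)[1]), tolerance = 1e-5)
})

test_that("planted logistic parameters are recovered within 3 SE", {
  d <- generate_logistic_dataset(-0.5, c(1.0, -0.8), n = 10000, seed = 33)
  ref <- glm(d$labels ~ d$features, family = binomial)
  se <- sqrt(diag(vcov(ref)))
  est <- coef(ref)
  planted <- c(d$intercept, d$coefficients)
  expect_true(all(abs(est - planted) <= 3 * se))
  # our penalised fit agrees with glm at weak regularisation
  fit <- fit_logistic(d$features, d$labels, c_value = 1e8)
  b_orig <- fit$coef / fit$feature_scales
  expect_equal(unname(b_orig), unname(est[-1]), tolerance = 1e-4)
})

test_that("the gradient vanishes at the optimum (finite differences)", {
  d <- generate_logistic_dataset(0.3, c(0.8, -0.5), n = 1500, seed = 11)
  c_val <- 10
  fit <- fit_logistic(d$features, d$labels, c_val)
  expect_lte(fit$grad_norm, 1e-8)
  # central finite differences of the penalised objective on the
  # standardised scale
  Xs <- scale(d$features)
  X1 <- cbind(1, Xs)
  beta <- c(fit$intercept, fit$coef)
  obj <- function(b) {
    z <- drop(X1 %*% b)
    sum(log1p(exp(-abs(z))) + pmax(z, 0) - d$labels * z) +
      sum(b[-1]^2) / (2 * c_val)
  }
  h <- 1e-5
  for (j in seq_along(beta)) {
    e <- numeric(length(beta)); e[j] <- h
    fd <- (obj(beta + e) - obj(beta - e)) / (2 * h)
    expect_lt(abs(fd), 1e-6)
  }
})

test_that("the penalised objective is monotone over iterations", {
  d <- generate_logistic_dataset(0, c(2, -2), n = 800, seed = 2)
  fit <- fit_logistic(d$features, d$labels, c_value = 100)
  expect_true(all(diff(fit$objective) <= 1e-8))
})

test_that("fit validation rejects degenerate inputs", {
  X <- matrix(rnorm(20), 10, 2)
  expect_error(fit_logistic(X, rep(1, 10), 1), "per class")
  expect_error(fit_logistic(X, rep(0:1, 5), -1), "positive")
  X[1, 1] <- Inf
  expect_error(fit_logistic(X, rep(0:1, 5), 1), "finite")
})

test_that("predicted probabilities are the sigmoid of the linear score", {
  d <- generate_logistic_dataset(0.2, c(0.9, -0.4), n = 500, seed = 8)
  fit <- fit_logistic(d$features, d$labels, 1)
  Xnew <- matrix(rnorm(40), 20, 2)
  pr <- predict_proba(fit, Xnew)
  Xs <- sweep(sweep(Xnew, 2, fit$feature_means), 2, fit$feature_scales, "/")
  z <- fit$intercept + drop(Xs %*% fit$coef)
  expect_equal(pr, 1 / (1 + exp(-z)))
  expect_true(all(pr > 0 & pr < 1))
  # monotone in each feature according to the coefficient sign
  base <- matrix(0, 1, 2)
  for (j in 1:2) {
    up <- base; up[1, j] <- 1
    dn <- base; dn[1, j] <- -1
    expect_equal(sign(predict_proba(fit, up) - predict_proba(fit, dn)),
                 sign(fit$coef[[j]]))
  }
  expect_error(predict_proba(fit, matrix(0, 1, 3)), "mismatch")
})

test_that("predictions are invariant to affine feature rescaling at large c", {
  d <- generate_logistic_dataset(0, c(1, -1), n = 600, seed = 14)
  f1 <- fit_logistic(d$features, d$labels, 1e8)
  X2 <- sweep(sweep(d$features, 2, c(10, 0.1), "*"), 2, c(-3, 5), "+")
  f2 <- fit_logistic(X2, d$labels, 1e8)
  Xnew <- matrix(rnorm(60), 30, 2)
  X2new <- sweep(sweep(Xnew, 2, c(10, 0.1), "*"), 2, c(-3, 5), "+")
  expect_equal(predict_proba(f1, Xnew), predict_proba(f2, X2new),
               tolerance = 1e-6)
})

test_that("cross-validated c selection is deterministic and well-behaved", {
  d <- generate_logistic_dataset(0, c(1.5, -1), n = 400, seed = 5)
  one <- cv_select_c(d$features, d$labels, c_grid = 1, reps = 2, seed = 3)
  expect_equal(one$selected_c, 1)
  cv1 <- cv_select_c(d$features, d$labels, c_grid = c(0.01, 1, 100),
                     reps = 3, seed = 9)
  cv2 <- cv_select_c(d$features, d$labels, c_grid = c(0.01, 1, 100),
                     reps = 3, seed = 9)
  expect_identical(cv1, cv2)
  expect_equal(cv1$selected_c,
               cv1$c_grid[which.max(cv1$mean_auc)])
})

test_that("label shuffling destroys the signal (test AUC near 0.5)", {
  d <- paper_shaped_small()
  recs <- curate(d$records, curation_config(include_likely = TRUE))$records
  recs$ddg_ens <- ensemble_average(recs, c("saafec", "inps"))
  recs$label <- withr::with_seed(55, sample(recs$label))
  res <- train_full_protocol(recs, c("ddg_ens", "rsa"),
                             c_grid = c(0.1, 1), seed = 6, cv_reps = 2)
  expect_lt(abs(res$test$auc - 0.5), 0.08)
})

test_that("train and test metrics agree on a large sample (no overfit)", {
  big <- generate_variant_table(
    synthetic_config(n_benign = 5000, n_pathogenic = 5000, n_genes = 100,
                     likely_fraction = 0, freq_violation_rate = 0,
                     conflict_rate = 0, n_unbalanced_genes = 0),
    seed = 77)
  recs <- normalize_variant_ddg(big$records,
                                list(saafec = TRUE, imutant = FALSE, inps = TRUE))
  recs$ddg_ens <- ensemble_average(recs, c("saafec", "inps"))
  res <- train_full_protocol(recs, c("ddg_ens", "rsa"),
                             c_grid = c(1), seed = 10, cv_reps = 1)
  expect_lt(abs(res$train$auc - res$test$auc), 0.05)
  expect_lt(abs(res$train$mcc - res$test$mcc), 0.05)
})

test_that("model JSON serialisation round-trips the parameters", {
  d <- generate_logistic_dataset(0.1, c(1, -0.5), n = 300, seed = 4)
  fit <- fit_logistic(d$features, d$labels, 2)
  path <- withr::local_tempfile(fileext = ".json")
  write_model_json(fit, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$intercept, fit$intercept)
  expect_equal(unlist(back$coef), fit$coef)
  expect_equal(back$c_value, 2)
})
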