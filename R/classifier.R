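#' Downsample the majority class to balance a dataset
#'
#' @param records data.frame with a binary `label` column.
#' @param seed integer seed (sampling is without replacement).
#' @return data.frame with equal benign and pathogenic counts.
#' @export
balance_classes <- function(records, seed = 1) {
  idx_b <- which(records$label == "benign")
  idx_p <- which(records$label == "pathogenic")
  if (length(idx_b) == 0 || length(idx_p) == 0) {
    stop("both classes must be present", call. = FALSE)
  }
  n <- min(length(idx_b), length(idx_p))
  keep <- withr::with_seed(seed, c(sample(idx_b, n), sample(idx_p, n)))
  records[sort(keep), , drop = FALSE]
}

#' Stratified train/test split
#'
#' Splits by label so each class contributes `fraction` of its records to
#' the training set (within one record of the exact fraction).
#'
#' @param records data.frame with a binary `label` column.
#' @param fraction training fraction in (0, 1); default 0.8.
#' @param seed integer seed.
#' @return list with `train` and `test` data.frames.
#' @export
split_train_test <- function(records, fraction = 0.8, seed = 1) {
  if (nrow(records) < 5) stop("too few records to split", call. = FALSE)
  if (fraction <= 0 || fraction >= 1) {
    stop("fraction must be strictly between 0 and 1", call. = FALSE)
  }
  train_idx <- withr::with_seed(seed, {
    unlist(lapply(unique(records$label), function(cl) {
      idx <- which(records$label == cl)
      sample(idx, round(fraction * length(idx)))
    }))
  })
  list(train = records[sort(train_idx), , drop = FALSE],
       test = records[-sort(train_idx), , drop = FALSE])
}

logistic <- function(z) 1 / (1 + exp(-z))

penalized_nll <- function(beta, X1, y, c_value) {
  z <- drop(X1 %*% beta)
  # numerically stable -loglik: sum(log(1+exp(z)) - y*z)
  nll <- sum(ifelse(z > 0, z + log1p(exp(-z)), log1p(exp(z))) - y * z)
  nll + sum(beta[-1]^2) / (2 * c_value)
}

penalized_grad <- function(beta, X1, y, c_value) {
  p <- logistic(drop(X1 %*% beta))
  g <- drop(crossprod(X1, p - y))
  g[-1] <- g[-1] + beta[-1] / c_value
  g
}

#' Fit an L2-penalised logistic model
#'
#' Maximises the binomial log-likelihood penalised by
#' `||coefficients||^2 / (2c)` (intercept unpenalised), where `c` is the
#' inverse regularisation strength: small `c` = strong shrinkage.  Features
#' are standardised to zero mean and unit scale on the training data before
#' fitting, so `c` is comparable across feature sets; the standardisation
#' constants are stored on the model and re-applied at prediction time.
#' Optimisation is damped Newton-Raphson run to a gradient norm of 1e-8;
#' the penalised objective decreases monotonically across iterations.
#'
#' @param features numeric matrix (or data.frame) of predictors, e.g.
#'   columns (ddG, RSA); finite values.
#' @param labels binary labels: `"benign"`/`"pathogenic"` or 0/1 with 1 =
#'   pathogenic.
#' @param c_value positive inverse regularisation strength.
#' @param max_iter iteration cap.
#' @param tol gradient-norm convergence tolerance.
#' @return list of class `ddg_logistic`: `intercept`, `coef` (on the
#'   standardised scale), `c_value`, `feature_means`, `feature_scales`,
#'   `feature_names`, `converged`, `grad_norm`, `n_iter`, `objective`.
#' @export
fit_logistic <- function(features, labels, c_value = 1,
                         max_iter = 200, tol = 1e-8) {
  X <- as.matrix(features)
  storage.mode(X) <- "double"
  if (any(!is.finite(X))) stop("features must be finite", call. = FALSE)
  if (c_value <= 0) stop("c_value must be positive", call. = FALSE)
  y <- to_binary(labels)
  if (sum(y) < 2 || sum(1 - y) < 2) {
    stop("need at least 2 records per class", call. = FALSE)
  }
  mu <- colMeans(X)
  sc <- apply(X, 2, stats::sd)
  sc[sc == 0] <- 1
  Xs <- sweep(sweep(X, 2, mu), 2, sc, "/")
  X1 <- cbind(1, Xs)
  p <- ncol(X1)
  beta <- numeric(p)
  obj <- penalized_nll(beta, X1, y, c_value)
  objectives <- obj
  converged <- FALSE
  iter <- 0
  g <- penalized_grad(beta, X1, y, c_value)
  while (iter < max_iter) {
    iter <- iter + 1
    pr <- logistic(drop(X1 %*% beta))
    w <- pmax(pr * (1 - pr), 1e-10)
    H <- crossprod(X1 * w, X1)
    diag(H)[-1] <- diag(H)[-1] + 1 / c_value
    step <- solve(H, g)
    # Newton decrement; once the predicted decrease is below objective
    # rounding noise, take the full step (quadratic convergence regime)
    if (sum(g * step) / 2 < 1e-9 * (1 + abs(obj))) {
      beta <- beta - step
      obj <- penalized_nll(beta, X1, y, c_value)
    } else {
      # step-halving keeps the objective monotone far from the optimum
      t <- 1
      repeat {
        beta_new <- beta - t * step
        obj_new <- penalized_nll(beta_new, X1, y, c_value)
        if (obj_new <= obj || t < 1e-12) break
        t <- t / 2
      }
      beta <- beta_new
      obj <- obj_new
    }
    objectives <- c(objectives, obj)
    g <- penalized_grad(beta, X1, y, c_value)
    if (sqrt(sum(g^2)) <= tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    stop(sprintf("logistic fit did not converge: gradient norm %.3e after %d iterations",
                 sqrt(sum(g^2)), iter), call. = FALSE)
  }
  fnames <- colnames(X)
  if (is.null(fnames)) fnames <- paste0("x", seq_len(ncol(X)))
  structure(list(intercept = unname(beta[1]),
                 coef = stats::setNames(unname(beta[-1]), fnames),
                 c_value = c_value, feature_means = stats::setNames(mu, fnames),
                 feature_scales = stats::setNames(sc, fnames),
                 feature_names = fnames, converged = converged,
                 grad_norm = sqrt(sum(g^2)), n_iter = iter,
                 objective = objectives),
            class = "ddg_logistic")
}

to_binary <- function(labels) {
  if (is.numeric(labels)) {
    if (!all(labels %in% c(0, 1))) stop("numeric labels must be 0/1", call. = FALSE)
    return(as.numeric(labels))
  }
  if (!all(labels %in% c("benign", "pathogenic"))) {
    stop("labels must be benign/pathogenic or 0/1", call. = FALSE)
  }
  as.numeric(labels == "pathogenic")
}

#' Predicted pathogenicity probabilities
#'
#' @param model a fitted [fit_logistic()] model.
#' @param features matrix/data.frame with the model's feature columns.
#' @return numeric vector of P(pathogenic) in (0, 1).
#' @export
predict_proba <- function(model, features) {
  stopifnot(inherits(model, "ddg_logistic"))
  X <- as.matrix(features)
  if (ncol(X) != length(model$coef)) {
    stop("feature count mismatch: model has ", length(model$coef),
         " features, input has ", ncol(X), call. = FALSE)
  }
  Xs <- sweep(sweep(X, 2, model$feature_means), 2, model$feature_scales, "/")
  unname(logistic(model$intercept + drop(Xs %*% model$coef)))
}

#' Select the regularisation strength by repeated cross-validation
#'
#' For each repetition a stratified k-fold partition is drawn; for each
#' candidate `c` the AUC of held-out predictions is computed per fold and
#' averaged over all folds and repetitions.  The selected `c` attains the
#' maximal mean AUC; ties go to the smaller `c` (stronger regularisation).
#' A fold that ends up single-class is repartitioned with a fresh sub-seed
#' (logged via `message()`).
#'
#' @param features,labels training data (balanced).
#' @param c_grid positive candidate values, default
#'   `c(0.001, 0.01, 0.1, 1, 10, 100, 1000)`.
#' @param k folds (default 5).
#' @param reps repetitions of the k-fold partition (default 100).
#' @param seed integer seed.
#' @return list of class `cv_report`: `c_grid`, `mean_auc`, `selected_c`.
#' @export
cv_select_c <- function(features, labels,
                        c_grid = c(0.001, 0.01, 0.1, 1, 10, 100, 1000),
                        k = 5, reps = 100, seed = 1) {
  if (length(c_grid) == 0) stop("empty c grid", call. = FALSE)
  X <- as.matrix(features)
  y <- to_binary(labels)
  lab <- ifelse(y == 1, "pathogenic", "benign")
  n <- nrow(X)
  auc_sum <- numeric(length(c_grid))
  n_folds_used <- 0
  withr::with_seed(seed, {
    for (r in seq_len(reps)) {
      folds <- stratified_folds(y, k)
      attempt <- 0
      while (any(vapply(seq_len(k), function(f)
        length(unique(y[folds == f])) < 2, logical(1))) && attempt < 10) {
        attempt <- attempt + 1
        message("repartitioning fold with single class (rep ", r, ")")
        folds <- stratified_folds(y, k)
      }
      for (f in seq_len(k)) {
        hold <- folds == f
        for (ci in seq_along(c_grid)) {
          fit <- fit_logistic(X[!hold, , drop = FALSE], y[!hold], c_grid[ci])
          pr <- predict_proba(fit, X[hold, , drop = FALSE])
          auc_sum[ci] <- auc_sum[ci] +
            roc_curve(pr, lab[hold], direction = "ge")$auc
        }
        n_folds_used <- n_folds_used + 1
      }
    }
  })
  mean_auc <- auc_sum / n_folds_used
  best <- max(mean_auc)
  selected <- min(c_grid[mean_auc >= best - 1e-12])
  structure(list(c_grid = c_grid, mean_auc = mean_auc, selected_c = selected,
                 k = k, reps = reps),
            class = "cv_report")
}

stratified_folds <- function(y, k) {
  folds <- integer(length(y))
  for (cl in unique(y)) {
    idx <- sample(which(y == cl))
    folds[idx] <- rep_len(seq_len(k), length(idx))
  }
  folds
}

#' Full training protocol for the (ddG, RSA) pathogenicity model
#'
#' Balances the classes, splits 80/20 stratified, selects the
#' regularisation strength by repeated stratified 5-fold cross-validation on
#' the training portion, refits on the full training portion at the selected
#' `c`, and reports AUC and MCC (at probability cutoff 0.5) on the training
#' and held-out test sets.
#'
#' @param records data.frame with a binary `label` column and the feature
#'   columns.
#' @param feature_cols character vector naming the feature columns (e.g. an
#'   ensemble ddG column plus `"rsa"`); rows with missing features are
#'   dropped.
#' @param c_grid candidate inverse regularisation strengths.
#' @param seed integer seed driving balancing, splitting and CV.
#' @param cv_reps repetitions of the 5-fold partition (default 100).
#' @param train_fraction training fraction (default 0.8).
#' @return list: `model`, `cv`, `train` and `test` (each with `auc`, `mcc`,
#'   `n`), and the row counts used.
#' @export
train_full_protocol <- function(records, feature_cols,
                                c_grid = c(0.001, 0.01, 0.1, 1, 10, 100, 1000),
                                seed = 1, cv_reps = 100, train_fraction = 0.8) {
  keep <- stats::complete.cases(records[, feature_cols, drop = FALSE])
  records <- records[keep, , drop = FALSE]
  seeds <- withr::with_seed(seed, sample.int(.Machine$integer.max, 3))
  balanced <- balance_classes(records, seed = seeds[1])
  sp <- split_train_test(balanced, fraction = train_fraction, seed = seeds[2])
  Xtr <- as.matrix(sp$train[, feature_cols, drop = FALSE])
  Xte <- as.matrix(sp$test[, feature_cols, drop = FALSE])
  cv <- cv_select_c(Xtr, sp$train$label, c_grid = c_grid, reps = cv_reps,
                    seed = seeds[3])
  model <- fit_logistic(Xtr, sp$train$label, cv$selected_c)
  eval_set <- function(X, lab) {
    pr <- predict_proba(model, X)
    list(auc = roc_curve(pr, lab, direction = "ge")$auc,
         mcc = classification_metrics(
           confusion_at_cutoff(pr, lab, 0.5, direction = "ge"))$mcc,
         n = length(lab))
  }
  list(model = model, cv = cv,
       train = eval_set(Xtr, sp$train$label),
       test = eval_set(Xte, sp$test$label),
       n_balanced = nrow(balanced))
}

#' Serialise a fitted logistic model to JSON
#'
#' @param model a `ddg_logistic` model.
#' @param path output path.
#' @export
write_model_json <- function(model, path) {
  jsonlite::write_json(
    list(intercept = model$intercept, coef = as.list(model$coef),
         c_value = model$c_value,
         feature_means = as.list(model$feature_means),
         feature_scales = as.list(model$feature_scales),
         feature_names = model$feature_names),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
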