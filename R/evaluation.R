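#' Confusion counts at a fixed score cutoff
#'
#' Scores follow the stability convention: lower score = more pathogenic
#' (destabilising ddG, buried RSA), so with `direction = "le"` a record is
#' predicted pathogenic when its score is <= the cutoff.  `direction = "ge"`
#' reverses this (used for absolute-ddG scores, where larger = more
#' pathogenic).
#'
#' @param score numeric scores, finite.
#' @param label character labels, `"benign"`/`"pathogenic"`.
#' @param cutoff decision cutoff.
#' @param direction `"le"` (predict pathogenic if score <= cutoff) or
#'   `"ge"`.
#' @return list with integer counts `tp`, `tn`, `fp`, `fn`.
#' @export
confusion_at_cutoff <- function(score, label, cutoff,
                                direction = c("le", "ge")) {
  direction <- match.arg(direction)
  check_scored_labels(score, label)
  pred <- if (direction == "le") score <= cutoff else score >= cutoff
  pos <- label == "pathogenic"
  list(tp = sum(pred & pos), tn = sum(!pred & !pos),
       fp = sum(pred & !pos), fn = sum(!pred & pos))
}

check_scored_labels <- function(score, label) {
  if (length(score) == 0) stop("empty data", call. = FALSE)
  if (length(score) != length(label)) stop("score/label length mismatch", call. = FALSE)
  if (any(!is.finite(score))) stop("scores must be finite", call. = FALSE)
  if (!all(label %in% c("benign", "pathogenic"))) {
    stop("labels must be 'benign' or 'pathogenic'", call. = FALSE)
  }
  invisible(TRUE)
}

#' Classification metrics from confusion counts
#'
#' TPR = tp/(tp+fn), FPR = fp/(fp+tn), FNR = fn/(tp+fn),
#' accuracy = (tp+tn)/n, and the Matthews correlation coefficient
#' MCC = (tp*tn - fp*fn) / sqrt((tp+fp)(tp+fn)(tn+fp)(tn+fn)), defined as 0
#' when any factor of the denominator vanishes.  The rate metrics require
#' both classes to be present.
#'
#' @param counts list with `tp`, `tn`, `fp`, `fn` (see
#'   [confusion_at_cutoff()]).
#' @return named list: `tpr`, `fpr`, `fnr`, `accuracy`, `mcc`.
#' @export
classification_metrics <- function(counts) {
  tp <- as.numeric(counts$tp); tn <- as.numeric(counts$tn)
  fp <- as.numeric(counts$fp); fn <- as.numeric(counts$fn)
  if (tp + fn == 0 || tn + fp == 0) {
    stop("both classes must be present for rate metrics", call. = FALSE)
  }
  denom2 <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  mcc <- if (denom2 == 0) 0 else (tp * tn - fp * fn) / sqrt(denom2)
  list(tpr = tp / (tp + fn),
       fpr = fp / (fp + tn),
       fnr = fn / (tp + fn),
       accuracy = (tp + tn) / (tp + tn + fp + fn),
       mcc = mcc)
}

#' ROC curve by cutoff sweep
#'
#' Sweeps the decision cutoff over every distinct score (equal scores
#' collapse into a single step), tallying TPR and FPR at each, and computes
#' the AUC by the trapezoid rule over (FPR, TPR).  This tie convention makes
#' the trapezoid AUC equal the concordance probability with ties scoring
#' one half.  The curve runs from (0, 0) to (1, 1) and both coordinates are
#' non-decreasing along the sweep.
#'
#' @inheritParams confusion_at_cutoff
#' @return list of class `roc_curve`: `points` (data.frame cutoff/tpr/fpr)
#'   and `auc`.
#' @export
roc_curve <- function(score, label, direction = c("le", "ge")) {
  direction <- match.arg(direction)
  check_scored_labels(score, label)
  if (length(unique(label)) < 2) {
    stop("both classes required for a ROC curve", call. = FALSE)
  }
  s <- if (direction == "le") score else -score
  pos <- label == "pathogenic"
  n_pos <- sum(pos); n_neg <- sum(!pos)
  cuts <- sort(unique(s))
  # cumulative counts of each class at score <= cut
  tp <- cumsum(tapply(pos, factor(s, levels = cuts), sum))
  fp <- cumsum(tapply(!pos, factor(s, levels = cuts), sum))
  tpr <- c(0, tp / n_pos)
  fpr <- c(0, fp / n_neg)
  cutoffs <- c(-Inf, cuts)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  out_cut <- if (direction == "le") cutoffs else -cutoffs
  structure(list(points = data.frame(cutoff = out_cut, tpr = unname(tpr),
                                     fpr = unname(fpr)),
                 auc = unname(auc)),
            class = "roc_curve")
}

#' AUC by concordance-pair counting
#'
#' Independent of the sweep construction: the fraction of
#' (pathogenic, benign) pairs ranked concordantly (pathogenic scored as more
#' pathogenic), ties counting one half.  Quadratic in n; intended as a
#' cross-check at small n.
#'
#' @inheritParams confusion_at_cutoff
#' @export
auc_by_pairs <- function(score, label, direction = c("le", "ge")) {
  direction <- match.arg(direction)
  check_scored_labels(score, label)
  s <- if (direction == "le") score else -score
  sp <- s[label == "pathogenic"]
  sb <- s[label == "benign"]
  if (length(sp) == 0 || length(sb) == 0) {
    stop("both classes required", call. = FALSE)
  }
  total <- 0
  for (x in sp) total <- total + sum(x < sb) + 0.5 * sum(x == sb)
  total / (length(sp) * length(sb))
}

#' MCC threshold scan over a cutoff grid
#'
#' Evaluates the Matthews correlation coefficient at every grid cutoff and
#' reports the optimum.  Ties are broken toward the cutoff of smallest
#' absolute value, then toward the smaller cutoff.
#'
#' @inheritParams confusion_at_cutoff
#' @param grid numeric vector of cutoffs, e.g. `seq(-5, 5, by = 0.1)` for
#'   ddG in kcal/mol or `seq(0, 1, by = 0.01)` for RSA.
#' @return list of class `threshold_scan`: `grid`, `mcc_at`,
#'   `optimal_cutoff`, `optimal_mcc`.
#' @export
mcc_scan <- function(score, label, grid, direction = c("le", "ge")) {
  direction <- match.arg(direction)
  if (length(grid) == 0) stop("empty cutoff grid", call. = FALSE)
  check_scored_labels(score, label)
  if (length(unique(label)) < 2) stop("both classes required", call. = FALSE)
  mcc_at <- vapply(grid, function(cut) {
    classification_metrics(confusion_at_cutoff(score, label, cut, direction))$mcc
  }, numeric(1))
  best <- max(mcc_at)
  cand <- grid[mcc_at == best]
  opt <- cand[order(abs(cand), cand)][1]
  structure(list(grid = grid, mcc_at = mcc_at,
                 optimal_cutoff = opt, optimal_mcc = best),
            class = "threshold_scan")
}

#' Default cutoff grids
#'
#' One-decimal ddG grid over -5..5 kcal/mol and a two-decimal RSA grid over
#' 0..1, matching the granularity at which optimal cutoffs are reported.
#'
#' @name default_grids
#' @export
ddg_grid <- function() round(seq(-5, 5, by = 0.1), 10)

#' @rdname default_grids
#' @export
rsa_grid <- function() round(seq(0, 1, by = 0.01), 10)

#' Balanced resampling assessment at a fixed cutoff
#'
#' Draws `N = floor(0.5 * min(n_benign, n_pathogenic))` records of each
#' class without replacement, computes TPR/FPR/FNR/accuracy at the fixed
#' cutoff, repeats `n_reps` times, and reports mean and standard deviation
#' of each metric.  Equal class representation removes class-imbalance bias
#' from the accuracy.
#'
#' @inheritParams confusion_at_cutoff
#' @param n_reps number of independent repetitions (default 100).
#' @param seed integer seed; the same seed reproduces the summary exactly.
#' @return list of class `resampling_summary` with `n_reps`,
#'   `sample_n_per_class`, and `mean`/`sd` named vectors over
#'   tpr, fpr, fnr, accuracy.
#' @export
balanced_resampling_eval <- function(score, label, cutoff,
                                     direction = c("le", "ge"),
                                     n_reps = 100, seed = 1) {
  direction <- match.arg(direction)
  check_scored_labels(score, label)
  idx_b <- which(label == "benign")
  idx_p <- which(label == "pathogenic")
  n_draw <- floor(0.5 * min(length(idx_b), length(idx_p)))
  if (n_draw < 1) stop("too few records per class for balanced resampling", call. = FALSE)
  mets <- withr::with_seed(seed, {
    vapply(seq_len(n_reps), function(r) {
      take <- c(sample(idx_b, n_draw), sample(idx_p, n_draw))
      m <- classification_metrics(
        confusion_at_cutoff(score[take], label[take], cutoff, direction))
      c(tpr = m$tpr, fpr = m$fpr, fnr = m$fnr, accuracy = m$accuracy)
    }, numeric(4))
  })
  structure(list(n_reps = n_reps, sample_n_per_class = n_draw,
                 mean = rowMeans(mets), sd = apply(mets, 1, stats::sd)),
            class = "resampling_summary")
}

#' Compare scoring methods under a shared balanced-resampling protocol
#'
#' Each method is a list with `name`, and either a `score` column name with
#' a `direction` and a `cutoff` (a number, or `"mcc_opt"` to use the
#' [mcc_scan()] optimum on the full data over `grid`), or a `calls` column
#' holding precomputed `"benign"`/`"pathogenic"` predictions from an
#' external classifier.  All methods are evaluated on the SAME drawn sample
#' in each repetition, which removes sampling noise from between-method
#' contrasts.
#'
#' @param records data.frame with a binary `label` column and the referenced
#'   score/call columns.
#' @param methods list of method specifications (see Details).
#' @param n_reps repetitions (default 100).
#' @param seed integer seed.
#' @return data.frame, one row per method: method, cutoff, and
#'   mean/sd of tpr, fpr, fnr, accuracy.
#' @export
compare_methods <- function(records, methods, n_reps = 100, seed = 1) {
  label <- records$label
  if (!all(label %in% c("benign", "pathogenic"))) {
    stop("labels must be binary", call. = FALSE)
  }
  # resolve each method to a prediction function over row indices
  resolved <- lapply(methods, function(m) {
    if (!is.null(m$calls)) {
      calls <- records[[m$calls]]
      if (is.null(calls)) stop("missing calls column: ", m$calls, call. = FALSE)
      list(name = m$name, cutoff = NA_real_,
           predict = function(idx) calls[idx] == "pathogenic")
    } else {
      sc <- records[[m$score]]
      if (is.null(sc)) stop("missing score column: ", m$score, call. = FALSE)
      dir <- if (is.null(m$direction)) "le" else m$direction
      keep <- !is.na(sc)
      cutoff <- m$cutoff
      if (identical(cutoff, "mcc_opt")) {
        grid <- if (is.null(m$grid)) ddg_grid() else m$grid
        cutoff <- mcc_scan(sc[keep], label[keep], grid, dir)$optimal_cutoff
      }
      force(dir); force(cutoff)
      list(name = m$name, cutoff = cutoff,
           predict = function(idx) {
             if (dir == "le") sc[idx] <= cutoff else sc[idx] >= cutoff
           })
    }
  })
  idx_b <- which(label == "benign")
  idx_p <- which(label == "pathogenic")
  n_draw <- floor(0.5 * min(length(idx_b), length(idx_p)))
  if (n_draw < 1) stop("too few records per class", call. = FALSE)
  res <- withr::with_seed(seed, {
    lapply(seq_len(n_reps), function(r) {
      take <- c(sample(idx_b, n_draw), sample(idx_p, n_draw))
      pos <- label[take] == "pathogenic"
      vapply(resolved, function(m) {
        pred <- m$predict(take)
        ok <- !is.na(pred)
        met <- classification_metrics(list(
          tp = sum(pred[ok] & pos[ok]), tn = sum(!pred[ok] & !pos[ok]),
          fp = sum(pred[ok] & !pos[ok]), fn = sum(!pred[ok] & pos[ok])))
        c(met$tpr, met$fpr, met$fnr, met$accuracy)
      }, numeric(4))
    })
  })
  arr <- simplify2array(res)  # 4 x n_methods x n_reps
  if (length(resolved) == 1) dim(arr) <- c(4, 1, n_reps)
  mu <- apply(arr, c(1, 2), mean)
  sdv <- apply(arr, c(1, 2), stats::sd)
  data.frame(method = vapply(resolved, `[[`, character(1), "name"),
             cutoff = vapply(resolved, `[[`, numeric(1), "cutoff"),
             tpr_mean = mu[1, ], tpr_sd = sdv[1, ],
             fpr_mean = mu[2, ], fpr_sd = sdv[2, ],
             fnr_mean = mu[3, ], fnr_sd = sdv[3, ],
             accuracy_mean = mu[4, ], accuracy_sd = sdv[4, ],
             stringsAsFactors = FALSE)
}
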