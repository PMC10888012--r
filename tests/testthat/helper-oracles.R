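# Independent oracles used across the suite.  These deliberately avoid the
# package's own data structures and code paths.

# Hand-written residue property lookup, transcribed directly from the
# grouping scheme: hydropathy and size for all 20 residues; ring and charge
# with explicit "neither"/"neutral".
RESIDUE_LOOKUP <- data.frame(
  code       = c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                 "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V"),
  hydropathy = c("hydrophobic", "polar", "polar", "polar", "hydrophobic",
                 "polar", "polar", "hydrophobic", "polar", "hydrophobic",
                 "hydrophobic", "polar", "hydrophobic", "hydrophobic",
                 "hydrophobic", "polar", "polar", "hydrophobic", "polar",
                 "hydrophobic"),
  size       = c("small", "large", "small", "small", "small", "large",
                 "large", "small", "large", "large", "large", "large",
                 "large", "large", "small", "small", "small", "large",
                 "large", "small"),
  ring       = c("aliphatic", "neither", "neither", "neither", "neither",
                 "neither", "neither", "neither", "aromatic", "aliphatic",
                 "aliphatic", "aliphatic", "aliphatic", "aromatic",
                 "aliphatic", "neither", "neither", "aromatic", "aromatic",
                 "aliphatic"),
  charge     = c("neutral", "positive", "neutral", "negative", "neutral",
                 "neutral", "negative", "neutral", "positive", "neutral",
                 "neutral", "positive", "neutral", "neutral", "neutral",
                 "neutral", "neutral", "neutral", "neutral", "neutral"),
  stringsAsFactors = FALSE
)

# oracle categorisation of a directed pair from the lookup table
oracle_classify <- function(wt, mut) {
  rw <- RESIDUE_LOOKUP[RESIDUE_LOOKUP$code == wt, ]
  rm_ <- RESIDUE_LOOKUP[RESIDUE_LOOKUP$code == mut, ]
  out <- list()
  for (ax in c("hydropathy", "size", "ring", "charge")) {
    f <- rw[[ax]]; t <- rm_[[ax]]
    if (!f %in% c("neither", "neutral") && !t %in% c("neither", "neutral")) {
      out[[ax]] <- data.frame(axis = ax, from_group = f, to_group = t,
                              stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0) {
    return(data.frame(axis = character(), from_group = character(),
                      to_group = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, unname(out))
}

# direct per-record confusion tally
oracle_confusion <- function(score, label, cutoff, direction = "le") {
  tp <- tn <- fp <- fn <- 0L
  for (i in seq_along(score)) {
    pred <- if (direction == "le") score[i] <= cutoff else score[i] >= cutoff
    if (label[i] == "pathogenic") {
      if (pred) tp <- tp + 1L else fn <- fn + 1L
    } else {
      if (pred) fp <- fp + 1L else tn <- tn + 1L
    }
  }
  list(tp = tp, tn = tn, fp = fp, fn = fn)
}

# direct formula evaluation of the metrics
oracle_metrics <- function(cc) {
  tp <- cc$tp; tn <- cc$tn; fp <- cc$fp; fn <- cc$fn
  den <- as.numeric(tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  list(tpr = tp / (tp + fn), fpr = fp / (fp + tn), fnr = fn / (tp + fn),
       accuracy = (tp + tn) / (tp + tn + fp + fn),
       mcc = if (den == 0) 0 else
         (as.numeric(tp) * tn - as.numeric(fp) * fn) / sqrt(den))
}

# concordance-pair AUC with ties scoring one half (lower = pathogenic)
oracle_auc_pairs <- function(score, label) {
  sp <- score[label == "pathogenic"]
  sb <- score[label == "benign"]
  tot <- 0
  for (x in sp) for (y in sb) {
    tot <- tot + (x < y) + 0.5 * (x == y)
  }
  tot / (length(sp) * length(sb))
}

# exhaustive MCC optimum over all achievable splits: cutoffs at every
# midpoint between adjacent distinct scores plus sentinels
oracle_best_mcc <- function(score, label) {
  u <- sort(unique(score))
  cands <- c(u[1] - 1, u, if (length(u) > 1) (u[-1] + u[-length(u)]) / 2,
             u[length(u)] + 1)
  best <- -Inf
  for (cut in cands) {
    m <- oracle_metrics(oracle_confusion(score, label, cut))$mcc
    if (m > best) best <- m
  }
  best
}

random_scored <- function(n, seed, lattice = NULL) {
  withr::with_seed(seed, {
    score <- if (is.null(lattice)) round(stats::rnorm(n), 2) else
      sample(lattice, n, replace = TRUE)
    label <- sample(c("benign", "pathogenic"), n, replace = TRUE)
    # guarantee both classes
    label[1] <- "benign"; label[2] <- "pathogenic"
    data.frame(score = score, label = label, stringsAsFactors = FALSE)
  })
}

# small paper-shaped table, cached per session to keep tests fast
paper_shaped_small <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      g <- generate_variant_table(
        synthetic_config(n_benign = 1200, n_pathogenic = 1200, n_genes = 60),
        seed = 424242)
      recs <- normalize_variant_ddg(
        g$records, list(saafec = TRUE, imutant = FALSE, inps = TRUE))
      cache <<- list(records = recs, truth = g$truth)
    }
    cache
  }
})
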