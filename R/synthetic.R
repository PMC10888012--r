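#' Configuration for the synthetic variant-table generator
#'
#' The generator emulates the statistical structure of a curated
#' monogenic-disorder variant table: a latent "true" ddG per variant drawn
#' from class-conditional truncated-normal mixtures (the pathogenic mixture
#' places exactly `p_destab` of its mass below 0 kcal/mol, 0.70 by default);
#' several predictor readouts of that shared latent value with
#' predictor-specific noise and declared sign conventions (one predictor is
#' deliberately noisy, emulating a weak stability predictor); class-
#' conditional RSA from Beta laws with the pathogenic mode buried (below
#' 0.35) and the benign mode exposed; a weak ddG-RSA coupling through a
#' Gaussian copula; population frequencies and conflict flags with planted
#' curation violations; and per-gene grouping including a few deliberately
#' one-sided genes that fail the class-balance filter.
#'
#' @param n_benign,n_pathogenic class sizes (default 3000 each).
#' @param n_genes number of genes; the first `n_unbalanced_genes` are filled
#'   with pathogenic records only.
#' @param likely_fraction fraction of each class labelled `likely_*`.
#' @param ddg_pathogenic,ddg_benign class-conditional mixtures: lists with
#'   `p_destab` (mass strictly below 0), `destab = c(mean, sd)` and
#'   `stab = c(mean, sd)` for the truncated components.
#' @param predictors named list; each entry has `noise_sd` (kcal/mol) and
#'   `negative_is_destabilizing` (the emitted sign convention).
#' @param rsa_pathogenic,rsa_benign Beta shape pairs `c(shape1, shape2)`.
#' @param ddg_rsa_correlation within-class copula correlation between latent
#'   ddG and RSA; magnitude must stay below 0.3 (the two quantities are
#'   nearly independent).
#' @param freq_violation_rate fraction of records planted with a
#'   frequency-rule violation.
#' @param conflict_rate fraction flagged as clinically conflicting.
#' @param n_unbalanced_genes genes planted to fail the 10% balance rule.
#' @param missing_ddg_rate per-predictor rate of missing values.
#' @return list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_benign = 3000, n_pathogenic = 3000,
                             n_genes = 150, likely_fraction = 0.15,
                             ddg_pathogenic = list(p_destab = 0.70,
                                                   destab = c(mean = -1.6, sd = 1.2),
                                                   stab = c(mean = 0.4, sd = 0.8)),
                             ddg_benign = list(p_destab = 0.45,
                                               destab = c(mean = -0.5, sd = 0.8),
                                               stab = c(mean = 0.6, sd = 0.9)),
                             predictors = list(
                               saafec = list(noise_sd = 0.6, negative_is_destabilizing = TRUE),
                               imutant = list(noise_sd = 1.5, negative_is_destabilizing = FALSE),
                               inps = list(noise_sd = 0.8, negative_is_destabilizing = TRUE)),
                             rsa_pathogenic = c(shape1 = 2, shape2 = 3.8),
                             rsa_benign = c(shape1 = 2.6, shape2 = 2.1),
                             ddg_rsa_correlation = 0.1,
                             freq_violation_rate = 0.05,
                             conflict_rate = 0.03,
                             n_unbalanced_genes = 5,
                             missing_ddg_rate = 0) {
  stopifnot(n_benign > 0, n_pathogenic > 0, n_genes > 0,
            n_genes <= n_benign + n_pathogenic,
            likely_fraction >= 0, likely_fraction < 1,
            ddg_pathogenic$p_destab >= 0, ddg_pathogenic$p_destab <= 1,
            ddg_benign$p_destab >= 0, ddg_benign$p_destab <= 1,
            abs(ddg_rsa_correlation) < 0.3,
            freq_violation_rate >= 0, freq_violation_rate < 1,
            conflict_rate >= 0, conflict_rate < 1,
            n_unbalanced_genes >= 0, n_unbalanced_genes < n_genes,
            missing_ddg_rate >= 0, missing_ddg_rate < 1)
  structure(as.list(environment()), class = "synthetic_config")
}

# truncated-normal draws via inverse CDF
rtnorm_neg <- function(n, mean, sd) {
  stats::qnorm(stats::runif(n, 0, stats::pnorm(0, mean, sd)), mean, sd)
}
rtnorm_pos <- function(n, mean, sd) {
  stats::qnorm(stats::runif(n, stats::pnorm(0, mean, sd), 1), mean, sd)
}

r_ddg_mixture <- function(n, mix) {
  below <- stats::runif(n) < mix$p_destab
  out <- numeric(n)
  out[below] <- rtnorm_neg(sum(below), mix$destab["mean"], mix$destab["sd"])
  out[!below] <- rtnorm_pos(sum(!below), mix$stab["mean"], mix$stab["sd"])
  out
}

# RSA coupled to latent ddG through a rank-based Gaussian copula;
# marginal stays exactly Beta(shape1, shape2)
r_rsa_coupled <- function(latent, shapes, rho) {
  n <- length(latent)
  z_d <- stats::qnorm(rank(latent, ties.method = "random") / (n + 1))
  z <- rho * z_d + sqrt(1 - rho^2) * stats::rnorm(n)
  stats::qbeta(stats::pnorm(z), shapes[1], shapes[2])
}

#' Generate a synthetic variant table with ground-truth sidecar
#'
#' See [synthetic_config()] for what is emulated.  The sidecar (`truth`)
#' records, per output row, the planted latent ddG and violation flags, and
#' the survivor status under both label policies, computed at generation
#' time by a plain counting pass (independent of the curation module), so
#' curation tests can compare against it exactly.
#'
#' @param config a [synthetic_config()].
#' @param seed integer seed; the same seed reproduces the table exactly.
#' @return list with `records` (a valid variant data.frame) and `truth`
#'   (row-aligned data.frame: `latent_ddg`, `is_likely`, `freq_violation`,
#'   `conflict`, `survives_strict`, `survives_with_likely`).
#' @export
generate_variant_table <- function(config = synthetic_config(), seed = 1) {
  stopifnot(inherits(config, "synthetic_config"))
  withr::with_seed(seed, {
    nb <- config$n_benign
    np <- config$n_pathogenic
    n <- nb + np
    base_class <- c(rep("benign", nb), rep("pathogenic", np))

    # clinical labels: a fraction of each class is "likely_*"
    likely <- stats::runif(n) < config$likely_fraction
    label <- ifelse(likely, paste0("likely_", base_class), base_class)

    # genes: the first n_unbalanced are pathogenic-only; the rest get a
    # random mix of both classes
    genes <- sprintf("GENE%03d", seq_len(config$n_genes))
    n_unbal <- config$n_unbalanced_genes
    gene_id <- character(n)
    path_idx <- which(base_class == "pathogenic")
    unbal_rows <- integer(0)
    if (n_unbal > 0) {
      per_gene <- min(20, floor(length(path_idx) / (2 * n_unbal)))
      unbal_rows <- sample(path_idx, n_unbal * per_gene)
      gene_id[unbal_rows] <- rep(genes[seq_len(n_unbal)], each = per_gene)
    }
    rest <- setdiff(seq_len(n), unbal_rows)
    gene_id[rest] <- sample(genes[(n_unbal + 1):config$n_genes],
                            length(rest), replace = TRUE)

    # residues and positions
    wt <- sample(AA_CODES, n, replace = TRUE)
    mut <- vapply(wt, function(w) sample(setdiff(AA_CODES, w), 1), character(1))
    position <- sample.int(500, n, replace = TRUE)

    # latent ddG and coupled RSA, per class
    latent <- numeric(n)
    rsa <- numeric(n)
    ib <- base_class == "benign"
    latent[ib] <- r_ddg_mixture(nb, config$ddg_benign)
    latent[!ib] <- r_ddg_mixture(np, config$ddg_pathogenic)
    rsa[ib] <- r_rsa_coupled(latent[ib], config$rsa_benign,
                             config$ddg_rsa_correlation)
    rsa[!ib] <- r_rsa_coupled(latent[!ib], config$rsa_pathogenic,
                              config$ddg_rsa_correlation)

    # predictor readouts of the shared latent value
    records <- data.frame(gene_id = gene_id,
                          protein_id = paste0("NP_", gene_id),
                          position = position, wt = wt, mut = mut,
                          label = label, stringsAsFactors = FALSE)
    for (p in names(config$predictors)) {
      spec <- config$predictors[[p]]
      v <- latent + stats::rnorm(n, 0, spec$noise_sd)
      if (!isTRUE(spec$negative_is_destabilizing)) v <- -v
      if (config$missing_ddg_rate > 0) {
        v[stats::runif(n) < config$missing_ddg_rate] <- NA_real_
      }
      records[[paste0("ddg_", p)]] <- v
    }
    records$rsa <- rsa

    # population frequency: compliant draws stay clear of the 0.01
    # boundary; planted violations sit on the wrong side of it
    freq_viol <- stats::runif(n) < config$freq_violation_rate
    freq <- rep(NA_real_, n)
    cb <- ib & !freq_viol
    cp <- !ib & !freq_viol
    freq[cb] <- stats::runif(sum(cb), 0.011, 0.08)
    freq[cp] <- ifelse(stats::runif(sum(cp)) < 0.5, NA_real_,
                       stats::runif(sum(cp), 0, 0.0095))
    freq[ib & freq_viol] <- stats::runif(sum(ib & freq_viol), 0, 0.0095)
    freq[!ib & freq_viol] <- stats::runif(sum(!ib & freq_viol), 0.0105, 0.05)
    records$population_frequency <- freq

    records$conflict <- stats::runif(n) < config$conflict_rate
    records$functional_category <- sample(
      c("enzyme", "transport", "transcription_regulation", "receptor",
        "structural", "signaling"), n, replace = TRUE)

    truth <- data.frame(latent_ddg = latent, is_likely = likely,
                        freq_violation = freq_viol,
                        conflict = records$conflict,
                        base_class = base_class,
                        stringsAsFactors = FALSE)
    truth$survives_strict <- planted_survivors(records, truth, include_likely = FALSE)
    truth$survives_with_likely <- planted_survivors(records, truth, include_likely = TRUE)
    list(records = validate_variants(records), truth = truth)
  })
}

# survivor status by a direct counting pass over the planted flags,
# mirroring the filter order: labels, frequency, conflict, gene balance
planted_survivors <- function(records, truth, include_likely) {
  alive <- rep(TRUE, nrow(records))
  if (!include_likely) alive[truth$is_likely] <- FALSE
  alive[alive & truth$freq_violation] <- FALSE
  alive[alive & truth$conflict] <- FALSE
  for (g in unique(records$gene_id[alive])) {
    rows <- alive & records$gene_id == g
    nb <- sum(truth$base_class[rows] == "benign")
    np <- sum(truth$base_class[rows] == "pathogenic")
    if (!(nb / (nb + np) > 0.10 && np / (nb + np) > 0.10)) alive[rows] <- FALSE
  }
  alive
}

#' Simulate data from a known logistic law
#'
#' Standard-normal features and Bernoulli labels with exactly the logistic
#' success probability; used for parameter-recovery tests of the classifier.
#'
#' @param intercept planted intercept.
#' @param coefficients planted coefficient vector.
#' @param n rows (>= 100).
#' @param seed integer seed.
#' @return list: `features` (matrix), `labels` (0/1), `prob`, and the
#'   planted parameters.
#' @export
generate_logistic_dataset <- function(intercept, coefficients, n, seed = 1) {
  stopifnot(n >= 100)
  withr::with_seed(seed, {
    p <- length(coefficients)
    X <- matrix(stats::rnorm(n * p), n, p,
                dimnames = list(NULL, paste0("x", seq_len(p))))
    prob <- 1 / (1 + exp(-(intercept + drop(X %*% coefficients))))
    y <- stats::rbinom(n, 1, prob)
    list(features = X, labels = y, prob = prob,
         intercept = intercept, coefficients = coefficients)
  })
}

#' Synthetic ddG oracle for a saturation grid
#'
#' Draws one ddG per substitution of the sequence so that the probability
#' of lying at or below the cutoff is exactly `pathogenic_mass` (by
#' construction with exponential tails on either side of the cutoff; with
#' mass 0 no value falls below).
#'
#' @param sequence protein sequence; if `NULL`, a random canonical sequence
#'   of length `length` is drawn.
#' @param length sequence length when `sequence` is `NULL`.
#' @param pathogenic_mass target probability of ddG <= cutoff.
#' @param cutoff decision cutoff in kcal/mol (default -1.1).
#' @param seed integer seed.
#' @return list: `sequence`, `entries` (position/wt/mut/ddg),
#'   `pathogenic_mass`, `cutoff`.
#' @export
generate_saturation_oracle <- function(sequence = NULL, length = NULL,
                                       pathogenic_mass = 0.37,
                                       cutoff = -1.1, seed = 1) {
  stopifnot(pathogenic_mass >= 0, pathogenic_mass <= 1)
  withr::with_seed(seed, {
    if (is.null(sequence)) {
      stopifnot(!is.null(length), length >= 1)
      sequence <- paste(sample(AA_CODES, length, replace = TRUE), collapse = "")
    }
    entries <- enumerate_mutations(sequence)
    n <- nrow(entries)
    below <- stats::runif(n) < pathogenic_mass
    ddg <- numeric(n)
    ddg[below] <- cutoff - stats::rexp(sum(below), rate = 1)
    ddg[!below] <- cutoff + stats::rexp(sum(!below), rate = 0.7)
    entries$ddg <- ddg
    list(sequence = sequence, entries = entries,
         pathogenic_mass = pathogenic_mass, cutoff = cutoff)
  })
}

#' Write the ground-truth sidecar as JSON
#'
#' @param truth the `truth` element of [generate_variant_table()].
#' @param path output path (conventionally `<table>.truth.json`).
#' @export
write_truth_sidecar <- function(truth, path) {
  jsonlite::write_json(truth, path, dataframe = "columns", digits = NA)
  invisible(path)
}
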