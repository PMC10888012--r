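#' Folding free energy sign conventions
#'
#' The convention used throughout this package is ddG = dG_wt - dG_mut, so a
#' NEGATIVE value means the mutation destabilises the protein.  Predictors
#' that report the opposite sign are declared with
#' `negative_is_destabilizing = FALSE` and flipped on ingestion.
#'
#' @param name predictor or source name.
#' @param negative_is_destabilizing logical; `TRUE` for the convention used
#'   here.
#' @export
sign_convention <- function(name, negative_is_destabilizing = TRUE) {
  stopifnot(is.character(name), length(name) == 1,
            is.logical(negative_is_destabilizing))
  structure(list(name = name,
                 negative_is_destabilizing = negative_is_destabilizing),
            class = "sign_convention")
}

#' Normalise ddG values into the package sign convention
#'
#' Identity for sources already using negative-is-destabilizing; a sign flip
#' otherwise (an involution: flipping twice restores the input).
#'
#' @param values numeric ddG values in kcal/mol; must be finite.
#' @param convention a [sign_convention()].
#' @return values in the package convention (negative = destabilising).
#' @export
normalize_sign <- function(values, convention) {
  stopifnot(inherits(convention, "sign_convention"))
  if (any(is.nan(values) | is.infinite(values))) {
    stop("non-finite ddG value(s)", call. = FALSE)
  }
  if (convention$negative_is_destabilizing) values else -values
}

#' Normalise the ddG columns of a variant table
#'
#' @param records variant data.frame with `ddg_<predictor>` columns.
#' @param conventions named list mapping predictor name to
#'   `negative_is_destabilizing` (logical) or a [sign_convention()].
#' @return records with all ddG columns in the package convention.
#' @export
normalize_variant_ddg <- function(records, conventions) {
  for (p in names(conventions)) {
    col <- paste0("ddg_", p)
    if (!col %in% names(records)) {
      stop("no column ", col, " for declared predictor ", p, call. = FALSE)
    }
    conv <- conventions[[p]]
    if (!inherits(conv, "sign_convention")) {
      nid <- if (is.list(conv)) isTRUE(conv$negative_is_destabilizing) else isTRUE(conv)
      conv <- sign_convention(p, nid)
    }
    records[[col]] <- normalize_sign(records[[col]], conv)
  }
  records
}

#' Ensemble average of predictor ddG values
#'
#' Arithmetic mean over the requested predictors, per record.  Records
#' missing any requested value get `NA` and are reported in a single
#' warning; they are skipped by downstream computations.
#'
#' @param records variant data.frame with normalised `ddg_<predictor>`
#'   columns.
#' @param predictors character vector of predictor names.
#' @return numeric vector, one mean ddG per record.
#' @export
ensemble_average <- function(records, predictors) {
  cols <- paste0("ddg_", predictors)
  miss <- setdiff(cols, names(records))
  if (length(miss) > 0) {
    stop("missing predictor column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  m <- as.matrix(records[, cols, drop = FALSE])
  out <- rowMeans(m)
  n_na <- sum(is.na(out))
  if (n_na > 0) {
    warning(sprintf("%d record(s) missing a requested ddG value; skipped", n_na),
            call. = FALSE)
  }
  out
}

#' Census of stabilising and destabilising mutations
#'
#' A magnitude cutoff applied symmetrically: destabilising means
#' ddG < -cutoff, stabilising means ddG > +cutoff; values inside the band
#' (and missing values) are counted in neither.
#'
#' @param ddg_values numeric ddG values (package convention).
#' @param cutoff non-negative magnitude in kcal/mol.
#' @return list with `cutoff`, `n_stabilizing`, `n_destabilizing`.
#' @export
stability_census <- function(ddg_values, cutoff) {
  if (length(cutoff) != 1 || is.na(cutoff) || cutoff < 0) {
    stop("cutoff must be a single non-negative magnitude", call. = FALSE)
  }
  v <- ddg_values[!is.na(ddg_values)]
  list(cutoff = cutoff,
       n_stabilizing = sum(v > cutoff),
       n_destabilizing = sum(v < -cutoff))
}

#' Fraction of records with destabilising ensemble ddG
#'
#' @param records variant data.frame.
#' @param predictors predictor names for [ensemble_average()].
#' @param threshold non-negative magnitude; a record counts as destabilised
#'   when its ensemble ddG < -threshold (default 0: any stability loss).
#' @return fraction among records with a defined ensemble value.
#' @export
fraction_destabilizing <- function(records, predictors, threshold = 0) {
  stopifnot(threshold >= 0)
  v <- suppressWarnings(ensemble_average(records, predictors))
  v <- v[!is.na(v)]
  if (length(v) == 0) stop("no records with complete ddG values", call. = FALSE)
  mean(v < -threshold)
}

#' Absolute ddG transform
#'
#' Elementwise absolute value, for use as an alternative score in which
#' any large stability change (either direction) flags pathogenicity.
#'
#' @param ddg_values numeric vector.
#' @export
absolute_transform <- function(ddg_values) abs(ddg_values)
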