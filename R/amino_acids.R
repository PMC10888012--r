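#' Canonical amino-acid alphabet and physicochemical group definitions
#'
#' The 20 canonical one-letter residue codes, and their assignment to groups
#' on four property axes: hydropathy (hydrophobic/polar), size (small/large),
#' ring character (aromatic/aliphatic/neither) and charge
#' (positive/negative/neutral).  Hydropathy and size partition the alphabet;
#' ring and charge leave some residues ungrouped ("neither"/"neutral").
#'
#' @format `AA_CODES` is a character vector of 20 one-letter codes;
#'   `AA_GROUPS` is a named list of axes, each a named list of residue-code
#'   vectors.
#' @export
AA_CODES <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
              "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' @rdname AA_CODES
#' @export
AA_GROUPS <- list(
  hydropathy = list(
    hydrophobic = c("A", "C", "G", "I", "L", "M", "F", "P", "W", "V"),
    polar       = c("D", "E", "K", "R", "H", "N", "Q", "S", "T", "Y")
  ),
  size = list(
    small = c("A", "C", "G", "S", "N", "D", "P", "T", "V"),
    large = c("R", "Q", "E", "H", "I", "L", "K", "M", "F", "W", "Y")
  ),
  ring = list(
    # Lys sits in the aliphatic group in the grouping scheme adopted here.
    aromatic  = c("H", "F", "W", "Y"),
    aliphatic = c("A", "I", "K", "L", "M", "P", "V")
  ),
  charge = list(
    positive = c("H", "K", "R"),
    negative = c("D", "E")
  )
)

#' Validate one-letter residue codes
#'
#' @param x character vector of residue codes.
#' @param what label used in error messages.
#' @return `x`, invisibly, if all codes are canonical.
#' @export
validate_residues <- function(x, what = "residue") {
  bad <- setdiff(unique(as.character(x)), AA_CODES)
  if (length(bad) > 0) {
    stop(sprintf("non-canonical %s code(s): %s", what,
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  invisible(x)
}

#' Group membership of a residue on one property axis
#'
#' @param code one-letter residue code(s).
#' @param axis one of `"hydropathy"`, `"size"`, `"ring"`, `"charge"`.
#' @return character vector of group names; `NA` where the residue has no
#'   named group on that axis (the "neither"/"neutral" residues).
#' @export
aa_group <- function(code, axis) {
  axis <- match.arg(axis, names(AA_GROUPS))
  validate_residues(code)
  groups <- AA_GROUPS[[axis]]
  out <- rep(NA_character_, length(code))
  for (g in names(groups)) out[code %in% groups[[g]]] <- g
  out
}

#' Categorise a directed amino-acid substitution
#'
#' A substitution wt -> mut is assigned one directed category per property
#' axis on which both residues belong to a named group.  Hydropathy and size
#' always contribute (they partition the alphabet); ring and charge
#' contribute only when neither residue is ungrouped on that axis, so the
#' result has between 2 and 4 rows.
#'
#' @param wt,mut single one-letter residue codes; must differ.
#' @return data.frame with columns `axis`, `from_group`, `to_group`, one row
#'   per applicable axis.
#' @examples
#' classify_substitution("D", "K")  # polar-polar, small-large, negative-positive
#' @export
classify_substitution <- function(wt, mut) {
  if (length(wt) != 1L || length(mut) != 1L) {
    stop("classify_substitution() takes a single wt and mut residue", call. = FALSE)
  }
  validate_residues(c(wt, mut))
  if (wt == mut) stop("wt and mut must differ (missense only)", call. = FALSE)
  axes <- names(AA_GROUPS)
  from <- vapply(axes, function(a) aa_group(wt, a), character(1))
  to   <- vapply(axes, function(a) aa_group(mut, a), character(1))
  keep <- !is.na(from) & !is.na(to)
  data.frame(axis = axes[keep], from_group = unname(from[keep]),
             to_group = unname(to[keep]), stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Count variants per substitution category and clinical class
#'
#' Each record contributes one count to every directed category its
#' wt -> mut substitution belongs to, split by its (binary) clinical label.
#'
#' @param records variant data.frame with columns `wt`, `mut`, `label`
#'   (labels already resolved to `benign`/`pathogenic`).
#' @return data.frame with columns `axis`, `from_group`, `to_group`,
#'   `n_benign`, `n_pathogenic`; empty for empty input.
#' @export
count_by_category <- function(records) {
  empty <- data.frame(axis = character(), from_group = character(),
                      to_group = character(), n_benign = integer(),
                      n_pathogenic = integer(), stringsAsFactors = FALSE)
  if (nrow(records) == 0) return(empty)
  if (!all(records$label %in% c("benign", "pathogenic"))) {
    stop("count_by_category() expects binary labels; run resolve_labels() first",
         call. = FALSE)
  }
  validate_residues(records$wt, "wt")
  validate_residues(records$mut, "mut")
  # classify each distinct ordered pair once, then tally records onto pairs
  pairs <- unique(records[, c("wt", "mut")])
  cats <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(i) {
    cc <- classify_substitution(pairs$wt[i], pairs$mut[i])
    cc$wt <- pairs$wt[i]
    cc$mut <- pairs$mut[i]
    cc
  }))
  key <- paste(records$wt, records$mut)
  nb <- table(factor(key[records$label == "benign"], levels = unique(key)))
  np <- table(factor(key[records$label == "pathogenic"], levels = unique(key)))
  cats$n_benign <- as.integer(nb[paste(cats$wt, cats$mut)])
  cats$n_pathogenic <- as.integer(np[paste(cats$wt, cats$mut)])
  agg <- stats::aggregate(cbind(n_benign, n_pathogenic) ~ axis + from_group + to_group,
                          data = cats, FUN = sum)
  agg <- agg[order(match(agg$axis, names(AA_GROUPS)), agg$from_group, agg$to_group), ]
  rownames(agg) <- NULL
  agg
}

#' Drop sparsely populated substitution categories
#'
#' Retains only categories whose total count strictly exceeds `min_total`,
#' so a category with exactly `min_total` cases is dropped.
#'
#' @param category_table output of [count_by_category()].
#' @param min_total minimum total (benign + pathogenic) count; default 100.
#' @export
filter_by_min_count <- function(category_table, min_total = 100) {
  keep <- (category_table$n_benign + category_table$n_pathogenic) > min_total
  out <- category_table[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read and validate a variant table
#'
#' Variant tables are TSV with header; required columns `gene_id`,
#' `protein_id`, `position`, `wt`, `mut`, `label`; optional
#' `population_frequency`, `conflict`, `rsa`, `functional_category`, and one
#' `ddg_<predictor>` column per stability predictor.  `"."` or empty fields
#' are missing values.
#'
#' @param path path to a TSV file.
#' @return validated data.frame.
#' @export
read_variant_table <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          na.strings = c("NA", ".", ""),
                          stringsAsFactors = FALSE)
  validate_variants(df)
}

#' Write a variant table as TSV
#'
#' @param records variant data.frame.
#' @param path output path; missing values are written as `"."`.
#' @export
write_variant_table <- function(records, path) {
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = ".")
  invisible(path)
}

VARIANT_LABELS <- c("benign", "likely_benign", "pathogenic", "likely_pathogenic")

#' Validate a variant data.frame
#'
#' Checks required columns, canonical residues, wt != mut, known clinical
#' labels, and that frequencies and RSA lie in [0, 1].  A missing `conflict`
#' column is added as all-FALSE.
#'
#' @param df data.frame to validate.
#' @return the validated (lightly normalised) data.frame.
#' @export
validate_variants <- function(df) {
  required <- c("gene_id", "protein_id", "position", "wt", "mut", "label")
  miss <- setdiff(required, names(df))
  if (length(miss) > 0) {
    stop("variant table lacks required column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  validate_residues(df$wt, "wt")
  validate_residues(df$mut, "mut")
  if (any(df$wt == df$mut)) stop("synonymous rows (wt == mut) are not allowed", call. = FALSE)
  if (any(df$position < 1 | df$position != round(df$position))) {
    stop("positions must be 1-based integers", call. = FALSE)
  }
  bad_lab <- setdiff(unique(df$label), c(VARIANT_LABELS, "benign", "pathogenic"))
  if (length(bad_lab) > 0) {
    stop("unknown clinical label(s): ", paste(bad_lab, collapse = ", "), call. = FALSE)
  }
  if (is.null(df$conflict)) df$conflict <- FALSE
  df$conflict <- df$conflict %in% c(TRUE, "TRUE", "true", 1)
  if (!is.null(df$population_frequency)) {
    f <- df$population_frequency
    if (any(!is.na(f) & (f < 0 | f > 1))) {
      stop("population_frequency outside [0, 1]", call. = FALSE)
    }
  }
  if (!is.null(df$rsa)) {
    r <- df$rsa
    if (any(!is.na(r) & (r < 0 | r > 1))) stop("rsa outside [0, 1]", call. = FALSE)
  }
  df
}
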