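#' Curation configuration
#'
#' Settings for the dataset-construction filters applied to a ClinVar-style
#' variant table: the population-frequency rules, the per-gene class-balance
#' criterion, and the label policy (whether `likely_*` records are folded
#' into their parent class or dropped).
#'
#' @param freq_low benign records with population frequency strictly below
#'   this are excluded (default 0.01).
#' @param freq_high pathogenic records with frequency strictly above this
#'   are excluded (default 0.01).
#' @param gene_balance_min a gene is kept only if both its benign and its
#'   pathogenic fraction strictly exceed this (default 0.10).
#' @param include_likely `FALSE`: drop `likely_*` records (the stricter
#'   label policy); `TRUE`: map `likely_benign` to benign and
#'   `likely_pathogenic` to pathogenic.
#' @return a list of class `curation_config`.
#' @export
curation_config <- function(freq_low = 0.01, freq_high = 0.01,
                            gene_balance_min = 0.10, include_likely = FALSE) {
  stopifnot(freq_low >= 0, freq_high >= freq_low, freq_high <= 1,
            gene_balance_min >= 0, gene_balance_min <= 0.5,
            is.logical(include_likely))
  structure(list(freq_low = freq_low, freq_high = freq_high,
                 gene_balance_min = gene_balance_min,
                 include_likely = include_likely),
            class = "curation_config")
}

#' Resolve four-class clinical labels to binary
#'
#' @param records variant data.frame with a `label` column in the four
#'   ClinVar-style classes.
#' @param include_likely see [curation_config()].
#' @return list with `records` (binary labels) and `n_dropped`.
#' @export
resolve_labels <- function(records, include_likely = FALSE) {
  bad <- setdiff(unique(records$label), VARIANT_LABELS)
  if (length(bad) > 0) {
    stop("unknown clinical label(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  if (include_likely) {
    records$label <- sub("^likely_", "", records$label)
    list(records = records, n_dropped = 0L)
  } else {
    keep <- records$label %in% c("benign", "pathogenic")
    list(records = records[keep, , drop = FALSE], n_dropped = sum(!keep))
  }
}

#' Population-frequency filter
#'
#' Excludes benign records whose population frequency is strictly below
#' `freq_low` and pathogenic records strictly above `freq_high`; a frequency
#' exactly on the boundary is retained by either rule, and records with a
#' missing frequency are always retained.
#'
#' @param records variant data.frame with binary labels.
#' @param config a [curation_config()].
#' @return list with `records` and `n_dropped`.
#' @export
frequency_filter <- function(records, config = curation_config()) {
  f <- records$population_frequency
  if (is.null(f)) f <- rep(NA_real_, nrow(records))
  if (any(!is.na(f) & (f < 0 | f > 1))) {
    stop("population_frequency outside [0, 1]", call. = FALSE)
  }
  drop <- (!is.na(f)) &
    ((records$label == "benign" & f < config$freq_low) |
     (records$label == "pathogenic" & f > config$freq_high))
  list(records = records[!drop, , drop = FALSE], n_dropped = sum(drop))
}

#' Clinical-significance conflict filter
#'
#' Drops records flagged as having discrepant clinical significance across
#' sources; a missing flag counts as no conflict.
#'
#' @inheritParams frequency_filter
#' @export
conflict_filter <- function(records) {
  flag <- records$conflict
  if (is.null(flag)) flag <- rep(FALSE, nrow(records))
  flag[is.na(flag)] <- FALSE
  list(records = records[!flag, , drop = FALSE], n_dropped = sum(flag))
}

#' Per-gene class-balance filter
#'
#' Keeps all records of a gene only if, among that gene's records, the
#' benign fraction AND the pathogenic fraction both strictly exceed
#' `gene_balance_min`; otherwise every record of the gene is dropped.  With
#' the default 0.10, a gene with 9 pathogenic and 1 benign record (benign
#' fraction exactly 0.10) is dropped.
#'
#' @inheritParams frequency_filter
#' @return list with `records`, `n_dropped`, and `gene_status`
#'   (data.frame: gene_id, n_benign, n_pathogenic, kept).
#' @export
gene_balance_filter <- function(records, config = curation_config()) {
  if (nrow(records) == 0) {
    return(list(records = records, n_dropped = 0L,
                gene_status = data.frame(gene_id = character(),
                                         n_benign = integer(),
                                         n_pathogenic = integer(),
                                         kept = logical())))
  }
  nb <- tapply(records$label == "benign", records$gene_id, sum)
  np <- tapply(records$label == "pathogenic", records$gene_id, sum)
  tot <- nb + np
  kept <- (nb / tot > config$gene_balance_min) & (np / tot > config$gene_balance_min)
  status <- data.frame(gene_id = names(kept), n_benign = as.integer(nb),
                       n_pathogenic = as.integer(np), kept = as.logical(kept),
                       stringsAsFactors = FALSE, row.names = NULL)
  keep_row <- records$gene_id %in% status$gene_id[status$kept]
  list(records = records[keep_row, , drop = FALSE], n_dropped = sum(!keep_row),
       gene_status = status)
}

#' Curate a variant table
#'
#' Applies the full filter pipeline in fixed order: label resolution,
#' population-frequency filter, conflict filter, gene-balance filter (so
#' gene balance is assessed on the records surviving the earlier filters).
#' Each input record lands in exactly one drop bucket or in the output, and
#' the report counts reconcile: `n_input = n_output + sum(drops)`.
#'
#' @param records raw variant data.frame (validated).
#' @param config a [curation_config()].
#' @return list with `records` (curated) and `report` (named list of counts
#'   plus the per-gene status table).
#' @export
curate <- function(records, config = curation_config()) {
  n_input <- nrow(records)
  s1 <- resolve_labels(records, config$include_likely)
  s2 <- frequency_filter(s1$records, config)
  s3 <- conflict_filter(s2$records)
  s4 <- gene_balance_filter(s3$records, config)
  report <- list(
    n_input = n_input,
    n_dropped_label = s1$n_dropped,
    n_dropped_frequency = s2$n_dropped,
    n_dropped_conflict = s3$n_dropped,
    n_dropped_gene_balance = s4$n_dropped,
    n_output = nrow(s4$records),
    gene_status = s4$gene_status
  )
  stopifnot(report$n_input == report$n_output + report$n_dropped_label +
              report$n_dropped_frequency + report$n_dropped_conflict +
              report$n_dropped_gene_balance)
  list(records = s4$records, report = report)
}

#' Write a curation report as JSON
#'
#' @param report the `report` element returned by [curate()].
#' @param path output path.
#' @export
write_curation_report <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
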