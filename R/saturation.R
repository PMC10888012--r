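#' Enumerate all single substitutions of a protein sequence
#'
#' Every canonical position yields the 19 substitutions to the other amino
#' acids, ordered by position then mutant residue alphabetically.  Positions
#' holding a non-canonical residue are skipped with a warning and recorded
#' in the result's `skipped_positions` attribute.
#'
#' @param sequence protein sequence as a single character string.
#' @return data.frame with columns `position`, `wt`, `mut`;
#'   19 x (number of canonical positions) rows.
#' @export
enumerate_mutations <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1, nchar(sequence) > 0)
  res <- strsplit(toupper(sequence), "")[[1]]
  canon <- res %in% AA_CODES
  if (any(!canon)) {
    warning(sprintf("skipping %d position(s) with non-canonical residue(s): %s",
                    sum(!canon),
                    paste(unique(res[!canon]), collapse = ", ")),
            call. = FALSE)
  }
  pos <- which(canon)
  out <- do.call(rbind, lapply(pos, function(i) {
    muts <- setdiff(AA_CODES, res[i])
    data.frame(position = i, wt = res[i], mut = sort(muts),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  attr(out, "skipped_positions") <- which(!canon)
  out
}

#' Call pathogenicity over a saturation grid from ddG values
#'
#' An entry is called pathogenic when its ddG (package convention, negative
#' = destabilising) is at or below the cutoff; the boundary value itself is
#' called pathogenic.  Entries with missing ddG are left uncalled and are
#' excluded from the called total.
#'
#' @param entries data.frame with columns `position`, `wt`, `mut`, `ddg`
#'   (kcal/mol) and optionally `protein_id`.
#' @param cutoff decision cutoff in kcal/mol (default -1.1).
#' @param protein_id identifier stored on the profile; defaults to the
#'   entries' `protein_id` column if present.
#' @return list of class `saturation_profile`: `protein_id`, `length`
#'   (distinct positions), `entries` (with logical `pathogenic`, NA where
#'   uncalled), `n_total` (called entries), `n_pathogenic`, `cutoff`.
#' @export
call_pathogenic <- function(entries, cutoff = -1.1, protein_id = NULL) {
  stopifnot(all(c("position", "wt", "mut", "ddg") %in% names(entries)))
  if (is.null(protein_id)) {
    protein_id <- if (!is.null(entries$protein_id)) entries$protein_id[1] else "protein"
  }
  entries$pathogenic <- entries$ddg <= cutoff
  called <- !is.na(entries$ddg)
  structure(list(protein_id = protein_id,
                 length = length(unique(entries$position)),
                 entries = entries,
                 n_total = sum(called),
                 n_pathogenic = sum(entries$pathogenic[called]),
                 cutoff = cutoff),
            class = "saturation_profile")
}

#' Aggregate saturation profiles across a proteome
#'
#' @param profiles list of `saturation_profile` objects.
#' @return list with `n_total`, `n_pathogenic`, `fraction`.
#' @export
proteome_summary <- function(profiles) {
  if (length(profiles) == 0) stop("need at least one profile", call. = FALSE)
  if (inherits(profiles, "saturation_profile")) profiles <- list(profiles)
  n_total <- sum(vapply(profiles, `[[`, numeric(1), "n_total"))
  n_path <- sum(vapply(profiles, `[[`, numeric(1), "n_pathogenic"))
  list(n_total = n_total, n_pathogenic = n_path,
       fraction = if (n_total > 0) n_path / n_total else NA_real_)
}

#' Read protein sequences from a FASTA file
#'
#' Minimal FASTA reader for the profiler: headers give sequence names (text
#' up to the first whitespace); sequence lines are concatenated and
#' upper-cased.
#'
#' @param path FASTA file path.
#' @return named character vector of sequences.
#' @export
read_protein_fasta <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- grepl("^>", lines)
  if (!any(hdr) || !hdr[1]) stop("not a FASTA file: ", path, call. = FALSE)
  grp <- cumsum(hdr)
  names_out <- sub("^>\\s*(\\S+).*$", "\\1", lines[hdr])
  seqs <- vapply(split(lines[!hdr], grp[!hdr]),
                 function(x) toupper(paste(x, collapse = "")), character(1))
  stats::setNames(unname(seqs), names_out)
}
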