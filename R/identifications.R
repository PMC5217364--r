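#' Filter peptide-spectrum matches by E-value
#'
#' Discards PSMs whose E-value is strictly greater than the threshold, so a
#' match scoring exactly at the threshold is retained. Row order is preserved.
#'
#' @param psms A PSM tibble (see [read_psm_table()]).
#' @param threshold E-value cutoff; matches with `e_value > threshold` are
#'   discarded. Default 0.05.
#' @return The retained PSMs, in input order.
#' @export
#' @examples
#' filter_psms(example_psms(), threshold = 0.03)
filter_psms <- function(psms, threshold = 0.05) {
  stopifnot(is.numeric(threshold), length(threshold) == 1, threshold > 0)
  dplyr::filter(psms, .data$e_value <= threshold)
}

#' Assemble protein identifications from filtered PSMs
#'
#' Groups PSMs by protein accession, applies the two-peptide rule (proteins
#' supported by fewer than `min_distinct_peptides` distinct peptide sequences
#' are discarded), and computes array-based sequence coverage against the
#' database.
#'
#' @param psms Filtered PSM tibble.
#' @param database Protein-database tibble from [read_protein_db()]
#'   (`accession`, `species`, `sequence`, optionally `is_decoy`).
#' @param min_distinct_peptides Minimum number of distinct peptide sequences
#'   required to accept a protein. Default 2.
#' @return A tibble with one row per accepted protein: `accession`, `species`,
#'   `is_decoy`, `n_peptides`, `n_spectra`, `coverage_percent`, and list
#'   columns `peptides` (distinct peptide sequences) and `spectra` (sorted
#'   supporting spectrum ids).
#' @export
assemble_proteins <- function(psms, database, min_distinct_peptides = 2) {
  if (nrow(psms) == 0) {
    return(tibble::tibble(
      accession = character(), species = character(), is_decoy = logical(),
      n_peptides = integer(), n_spectra = integer(),
      coverage_percent = double(),
      peptides = list(), spectra = list()
    ))
  }
  unresolved <- setdiff(unique(psms$accession), database$accession)
  if (length(unresolved) > 0) {
    stop("PSM accession(s) not present in the database: ",
         paste(unresolved, collapse = ", "), call. = FALSE)
  }
  if (!"is_decoy" %in% names(database)) database$is_decoy <- FALSE
  psms |>
    dplyr::group_by(.data$accession) |>
    dplyr::summarise(
      peptides = list(unique(.data$peptide)),
      spectra = list(sort(unique(.data$spectrum_id))),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      n_peptides = lengths(.data$peptides),
      n_spectra = lengths(.data$spectra)
    ) |>
    dplyr::filter(.data$n_peptides >= min_distinct_peptides) |>
    dplyr::left_join(
      dplyr::select(database, "accession", "species", "sequence", "is_decoy"),
      by = "accession"
    ) |>
    dplyr::mutate(
      coverage_percent = purrr::map2_dbl(.data$sequence, .data$peptides,
                                         compute_coverage)
    ) |>
    dplyr::select(
      "accession", "species", "is_decoy", "n_peptides", "n_spectra",
      "coverage_percent", "peptides", "spectra"
    )
}

#' Sequence coverage by the zero-array method
#'
#' An array of zeros the length of the protein is created; for every
#' occurrence of every peptide in the sequence (exact, case-sensitive string
#' matching, all match positions) the covered positions are set to one.
#' Coverage is 100 times the number of marked residues divided by the
#' sequence length. Overlapping peptides mark each residue once; a peptide
#' that does not occur in the sequence contributes nothing.
#'
#' @param sequence Protein amino-acid sequence (nonempty string).
#' @param peptides Character vector (or list) of peptide sequences.
#' @return Coverage as a percentage in \[0, 100\].
#' @export
#' @examples
#' compute_coverage("ABCDEFGHIJ", c("ABCD", "CDEF")) # 60
compute_coverage <- function(sequence, peptides) {
  peptides <- unlist(peptides, use.names = FALSE)
  n <- nchar(sequence)
  stopifnot(n > 0)
  covered <- logical(n)
  for (pep in unique(peptides)) {
    w <- nchar(pep)
    if (w == 0 || w > n) next
    # zero-width lookahead finds overlapping occurrences too
    starts <- gregexpr(paste0("(?=", pep, ")"), sequence, perl = TRUE)[[1]]
    if (starts[1] == -1L) next
    for (s in starts) covered[s:(s + w - 1L)] <- TRUE
  }
  100 * sum(covered) / n
}

#' Estimate the false discovery rate from a target-decoy comparison
#'
#' The decoy database (a randomized version of the target database) is
#' processed with identical filtering logic; the protein-level FDR is the
#' number of decoy proteins passing all criteria divided by the number of
#' target proteins passing. A PSM-level estimate (decoy / target PSM counts)
#' is available via `level = "psm"`, in which case the inputs are PSM tibbles
#' rather than protein tibbles.
#'
#' @param targets Accepted target proteins (or PSMs for `level = "psm"`).
#' @param decoys Accepted decoy proteins (or PSMs), produced by the same
#'   thresholds and rules.
#' @param level `"protein"` (default) or `"psm"`; only affects how the inputs
#'   are described, the estimate is the row-count ratio either way.
#' @return FDR estimate in \[0, 1\]. Zero passing targets with passing decoys
#'   returns 1 with a warning.
#' @export
estimate_fdr <- function(targets, decoys, level = c("protein", "psm")) {
  level <- match.arg(level)
  n_t <- nrow(targets)
  n_d <- nrow(decoys)
  if (n_t == 0) {
    if (n_d > 0) {
      warning("No passing targets but ", n_d, " passing decoys; FDR set to 1",
              call. = FALSE)
      return(1)
    }
    return(0)
  }
  min(1, n_d / n_t)
}
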