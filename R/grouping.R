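#' Group proteins identified by identical spectra sets
#'
#' Orthologs from related species are often matched by exactly the same
#' spectra; such proteins carry no independent evidence and are collapsed
#' into a group. Proteins whose spectra sets are identical (exact set
#' equality on spectrum ids; subset relations do not group) form one group.
#' Within a group:
#'
#' * if at least one member is from the preferred species, all
#'   preferred-species members are retained (they may be isoforms) and the
#'   lexicographically smallest of them is the representative;
#' * otherwise a single member, the lexicographically smallest accession, is
#'   retained as representative.
#'
#' Grouping is invariant under permutation of the input rows.
#'
#' @param proteins Protein tibble from [assemble_proteins()] (needs
#'   `accession`, `species`, and the `spectra` list column).
#' @param preferred_species Species whose entries are preferentially
#'   retained. Default `"Gossypium hirsutum"`.
#' @return A tibble with one row per group: `group_id`, `representative`,
#'   `n_spectra`, and list columns `members` and `retained` (accession
#'   vectors, sorted).
#' @export
group_proteins <- function(proteins, preferred_species = "Gossypium hirsutum") {
  if (nrow(proteins) == 0) {
    return(tibble::tibble(
      group_id = integer(), representative = character(),
      n_spectra = integer(), members = list(), retained = list()
    ))
  }
  stopifnot(all(lengths(proteins$spectra) > 0))
  key <- vapply(proteins$spectra,
                function(s) paste(sort(unique(s)), collapse = "\r"),
                character(1))
  groups <- proteins |>
    dplyr::mutate(.key = key) |>
    dplyr::group_by(.data$.key) |>
    dplyr::summarise(
      members = list(sort(.data$accession)),
      preferred = list(sort(.data$accession[.data$species %in% preferred_species])),
      n_spectra = length(unique(unlist(.data$spectra))),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      retained = purrr::map2(.data$preferred, .data$members, function(pref, mem) {
        if (length(pref) > 0) pref else mem[1]
      }),
      representative = purrr::map_chr(.data$retained, 1)
    ) |>
    dplyr::arrange(.data$representative) |>
    dplyr::mutate(group_id = dplyr::row_number()) |>
    dplyr::select("group_id", "representative", "n_spectra", "members", "retained")
  groups
}

#' Flatten groups into the retained protein list
#'
#' Concatenates the retained members across groups in stable (group, then
#' accession) order and returns the corresponding rows of the original
#' protein table. Only proteins retained after grouping are considered for
#' quantification.
#'
#' @param groups Group tibble from [group_proteins()].
#' @param proteins The protein tibble the groups were built from.
#' @return The subset of `proteins` that was retained, one row per retained
#'   accession, ordered by group then accession.
#' @export
retained_proteins <- function(groups, proteins) {
  kept <- unlist(groups$retained, use.names = FALSE)
  proteins[match(kept, proteins$accession), , drop = FALSE]
}

#' Write the group report TSV
#'
#' One row per group: `group_id`, `representative`, `retained` and `members`
#' as semicolon-joined accession lists, `n_spectra`.
#'
#' @param groups Group tibble from [group_proteins()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_group_report <- function(groups, path) {
  out <- groups |>
    dplyr::mutate(
      retained = purrr::map_chr(.data$retained, paste, collapse = ";"),
      members = purrr::map_chr(.data$members, paste, collapse = ";")
    ) |>
    dplyr::select("group_id", "representative", "retained", "members", "n_spectra")
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}
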