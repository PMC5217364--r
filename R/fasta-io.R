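#' Read a protein sequence database from FASTA
#'
#' Loads a FASTA protein database into a tidy table. The species is parsed
#' from the header line: by default the UniProt `OS=<species>` token is used
#' when present; otherwise `species_pattern` (a regex with one capture group)
#' is tried, and failing both the species is `NA`.
#'
#' The accession is the first whitespace-delimited token of the header.
#' Decoy entries are recognised by an accession prefix (default `"DECOY_"`),
#' following target-decoy convention.
#'
#' @param path Path to a FASTA file.
#' @param species_pattern Fallback regex with one capture group applied to the
#'   full header when no `OS=` token is found.
#' @param decoy_prefix Accession prefix marking decoy entries.
#' @return A tibble with columns `accession`, `species`, `sequence`,
#'   `is_decoy`.
#' @export
read_protein_db <- function(path, species_pattern = NULL,
                            decoy_prefix = "DECOY_") {
  seqs <- Biostrings::readAAStringSet(path)
  headers <- names(seqs)
  accession <- sub("\\s.*$", "", headers)
  species <- extract_species(headers, species_pattern)
  tibble::tibble(
    accession = accession,
    species = species,
    sequence = as.character(seqs),
    is_decoy = startsWith(accession, decoy_prefix)
  )
}

extract_species <- function(headers, species_pattern = NULL) {
  m <- regmatches(headers, regexpr("OS=[^=]+?(?= [A-Z]{2}=|$)", headers, perl = TRUE))
  out <- rep(NA_character_, length(headers))
  hit <- grepl("OS=", headers, fixed = TRUE)
  out[hit] <- sub("^OS=", "", m)
  if (!is.null(species_pattern)) {
    miss <- which(!hit)
    mm <- regmatches(headers[miss], regexec(species_pattern, headers[miss]))
    out[miss] <- vapply(mm, function(x) if (length(x) >= 2) x[2] else NA_character_,
                        character(1))
  }
  trimws(out)
}

#' Write a protein database to FASTA
#'
#' Headers are written as `<accession> OS=<species>` (the `OS=` token is
#' omitted when species is `NA`).
#'
#' @param db A protein-database tibble (`accession`, `species`, `sequence`).
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_protein_db <- function(db, path) {
  seqs <- Biostrings::AAStringSet(db$sequence)
  names(seqs) <- ifelse(
    is.na(db$species),
    db$accession,
    paste0(db$accession, " OS=", db$species)
  )
  Biostrings::writeXStringSet(seqs, path, width = 60L)
  invisible(path)
}
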