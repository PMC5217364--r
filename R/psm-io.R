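#' Read a peptide-spectrum-match (PSM) table
#'
#' Reads PSMs from the package's tab-separated exchange format, or from an
#' X!Tandem XML results file mapped onto the same record type. The TSV dialect
#' has a header row and one row per (PSM, accession) pair with columns
#' `spectrum_id`, `replicate_id`, `condition_id`, `scan_number`,
#' `precursor_mz`, `peptide`, `accession`, `e_value`.
#'
#' @param path Path to the PSM file.
#' @param dialect `"tsv"` (default) or `"xtandem-xml"`.
#' @return A tibble with one row per PSM, in input order, with the eight
#'   columns above. `scan_number` is integer; `precursor_mz` and `e_value`
#'   are double.
#' @export
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' write_psm_table(example_psms(), tf)
#' read_psm_table(tf)
read_psm_table <- function(path, dialect = c("tsv", "xtandem-xml")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) {
    stop("PSM file does not exist: ", path, call. = FALSE)
  }
  psms <- switch(dialect,
    "tsv" = read_psm_tsv(path),
    "xtandem-xml" = read_psm_xtandem(path)
  )
  validate_psms(psms)
  psms
}

psm_columns <- c(
  "spectrum_id", "replicate_id", "condition_id", "scan_number",
  "precursor_mz", "peptide", "accession", "e_value"
)

read_psm_tsv <- function(path) {
  header <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
  missing <- setdiff(psm_columns, header)
  if (length(missing) > 0) {
    stop("PSM table ", path, " is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  tab <- suppressWarnings(readr::read_tsv(
    path,
    col_types = readr::cols(
      spectrum_id = readr::col_character(),
      replicate_id = readr::col_character(),
      condition_id = readr::col_character(),
      scan_number = readr::col_integer(),
      precursor_mz = readr::col_double(),
      peptide = readr::col_character(),
      accession = readr::col_character(),
      e_value = readr::col_double(),
      .default = readr::col_character()
    ),
    progress = FALSE
  ))
  probs <- readr::problems(tab)
  if (nrow(probs) > 0) {
    stop("Unparseable field(s) in ", path, ": row ", probs$row[1],
         ", column ", probs$col[1], " (expected ", probs$expected[1], ")",
         call. = FALSE)
  }
  dplyr::select(tab, dplyr::all_of(psm_columns))
}

# X!Tandem output XML: one <group type="model"> per spectrum, <protein>
# children each carrying a <peptide><domain> with seq/expect, plus fields
# for the precursor. Replicate/condition labels are not part of the format
# and default to the file's base name / "unknown".
read_psm_xtandem <- function(path) {
  doc <- xml2::read_xml(path)
  groups <- xml2::xml_find_all(doc, "//group[@type='model']")
  rows <- purrr::map_dfr(groups, function(g) {
    gid <- xml2::xml_attr(g, "id")
    mh <- as.numeric(xml2::xml_attr(g, "mh"))
    z <- as.numeric(xml2::xml_attr(g, "z"))
    doms <- xml2::xml_find_all(g, ".//protein")
    purrr::map_dfr(doms, function(p) {
      dom <- xml2::xml_find_first(p, ".//domain")
      tibble::tibble(
        spectrum_id = paste0("spectrum_", gid),
        replicate_id = tools::file_path_sans_ext(basename(path)),
        condition_id = "unknown",
        scan_number = as.integer(gid),
        precursor_mz = (mh + (z - 1) * proton_mass()) / z,
        peptide = xml2::xml_attr(dom, "seq"),
        accession = xml2::xml_attr(p, "label"),
        e_value = as.numeric(xml2::xml_attr(dom, "expect"))
      )
    })
  })
  if (nrow(rows) == 0) rows <- empty_psms()
  rows
}

empty_psms <- function() {
  tibble::tibble(
    spectrum_id = character(), replicate_id = character(),
    condition_id = character(), scan_number = integer(),
    precursor_mz = double(), peptide = character(),
    accession = character(), e_value = double()
  )
}

validate_psms <- function(psms) {
  if (nrow(psms) == 0) return(invisible(psms))
  bad <- which(psms$e_value < 0 | psms$precursor_mz <= 0 | psms$scan_number < 1)
  if (length(bad) > 0) {
    stop("Invalid PSM record at row ", bad[1],
         ": e_value must be >= 0, precursor_mz > 0, scan_number >= 1",
         call. = FALSE)
  }
  if (any(!grepl("^[ACDEFGHIKLMNPQRSTVWY]+$", psms$peptide))) {
    stop("PSM peptide sequences must be nonempty uppercase strings over the ",
         "20 standard amino acids", call. = FALSE)
  }
  invisible(psms)
}

#' Write a PSM table in the TSV exchange dialect
#'
#' @param psms A PSM tibble as returned by [read_psm_table()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_psm_table <- function(psms, path) {
  readr::write_tsv(psms[, psm_columns], path, progress = FALSE)
  invisible(path)
}

#' A tiny example PSM table
#'
#' Three peptide-spectrum matches for two proteins in one replicate; used in
#' examples.
#'
#' @return A PSM tibble.
#' @export
example_psms <- function() {
  tibble::tibble(
    spectrum_id = c("s1", "s2", "s3"),
    replicate_id = "rep1",
    condition_id = "A",
    scan_number = c(101L, 205L, 310L),
    precursor_mz = c(500.25, 612.80, 444.90),
    peptide = c("AAEELAK", "VLDPFTR", "GGSSEPK"),
    accession = c("P1", "P1", "P2"),
    e_value = c(0.001, 0.02, 0.04)
  )
}
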