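#' Read an MS1 precursor-spectra file
#'
#' Parses the MS1 text format produced by msConvert: optional `H` header
#' lines, then for each survey scan an `S` line (scan number repeated),
#' optional `I` lines (only `I RTime <seconds>` is interpreted), and one
#' whitespace-separated `m/z intensity` pair per peak line. Scans with no
#' peak lines yield empty peak lists.
#'
#' @param path Path to an MS1 text file.
#' @param replicate_id Replicate label to attach; defaults to the file's base
#'   name without extension.
#' @return An `ms1_run` object: a list with `replicate_id`, `scans` (tibble
#'   `scan_number`, `retention_time`) and `peaks` (tibble `scan_number`,
#'   `mz`, `intensity`).
#' @export
read_ms1 <- function(path, replicate_id = NULL) {
  if (is.null(replicate_id)) {
    replicate_id <- tools::file_path_sans_ext(basename(path))
  }
  lines <- readLines(path)
  tag <- substr(lines, 1L, 1L)
  is_s <- tag == "S"
  is_meta <- tag %in% c("H", "I", "Z")
  is_blank <- !nzchar(trimws(lines))
  is_peak <- !(is_s | is_meta | is_blank)
  if (any(is_peak & cumsum(is_s) == 0)) {
    stop("Peak line before first S line in ", path, " (line ",
         which(is_peak & cumsum(is_s) == 0)[1], ")", call. = FALSE)
  }

  s_fields <- strsplit(trimws(lines[is_s]), "[ \t]+")
  scan_number <- vapply(s_fields, function(f) suppressWarnings(as.integer(f[2])),
                        integer(1))
  if (anyNA(scan_number)) {
    stop("Unparseable S line in ", path, " (line ",
         which(is_s)[which(is.na(scan_number))[1]], ")", call. = FALSE)
  }
  if (is.unsorted(scan_number, strictly = TRUE)) {
    stop("Scan numbers in ", path, " are not strictly increasing",
         call. = FALSE)
  }

  scan_idx <- cumsum(is_s)
  rt <- rep(NA_real_, length(scan_number))
  is_rt <- tag == "I" & grepl("^I[ \t]+RTime", lines)
  if (any(is_rt)) {
    rt_vals <- vapply(strsplit(trimws(lines[is_rt]), "[ \t]+"),
                      function(f) suppressWarnings(as.numeric(f[3])), double(1))
    rt[scan_idx[is_rt]] <- rt_vals
  }

  peak_lines <- which(is_peak)
  if (length(peak_lines) > 0) {
    pf <- strsplit(trimws(lines[peak_lines]), "[ \t]+")
    ok <- lengths(pf) == 2L
    if (!all(ok)) {
      stop("Unparseable peak line in ", path, " (line ",
           peak_lines[which(!ok)[1]], ")", call. = FALSE)
    }
    m <- matrix(suppressWarnings(as.numeric(unlist(pf))), ncol = 2, byrow = TRUE)
    if (anyNA(m)) {
      stop("Non-numeric peak value in ", path, " (line ",
           peak_lines[which(is.na(rowSums(m)))[1]], ")", call. = FALSE)
    }
    peaks <- tibble::tibble(
      scan_number = scan_number[scan_idx[peak_lines]],
      mz = m[, 1],
      intensity = m[, 2]
    )
  } else {
    peaks <- tibble::tibble(scan_number = integer(), mz = double(),
                            intensity = double())
  }
  if (any(peaks$intensity < 0)) {
    stop("Negative peak intensity in ", path, call. = FALSE)
  }

  new_ms1_run(replicate_id,
              tibble::tibble(scan_number = scan_number, retention_time = rt),
              peaks)
}

new_ms1_run <- function(replicate_id, scans, peaks) {
  structure(
    list(replicate_id = replicate_id, scans = scans, peaks = peaks),
    class = "ms1_run"
  )
}

#' @export
print.ms1_run <- function(x, ...) {
  cat("<ms1_run> replicate ", x$replicate_id, ": ", nrow(x$scans),
      " scans, ", nrow(x$peaks), " peaks\n", sep = "")
  invisible(x)
}

#' Write an MS1 run to the MS1 text format
#'
#' Numeric fields are written with 17 significant digits so that a
#' write/read round trip reproduces the run exactly and repeated writes are
#' byte-identical.
#'
#' @param run An `ms1_run` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ms1 <- function(run, path) {
  stopifnot(inherits(run, "ms1_run"))
  num <- function(x) sprintf("%.17g", x)
  header <- "H\tCreationDate\t1970-01-01T00:00:00"
  peak_text <- paste(num(run$peaks$mz), num(run$peaks$intensity))
  by_scan <- split(peak_text,
                   factor(run$peaks$scan_number, levels = run$scans$scan_number))
  scan_blocks <- purrr::map_chr(seq_len(nrow(run$scans)), function(i) {
    sn <- run$scans$scan_number[i]
    block <- sprintf("S\t%06d\t%06d", sn, sn)
    rt <- run$scans$retention_time[i]
    if (!is.na(rt)) block <- c(block, sprintf("I\tRTime\t%s", num(rt)))
    paste(c(block, by_scan[[i]]), collapse = "\n")
  })
  writeLines(c(header, scan_blocks), path)
  invisible(path)
}
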