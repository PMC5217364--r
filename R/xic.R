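#' Estimate the noise level of a chromatogram
#'
#' A single scalar per run serves as the trace stopping level, the
#' missing-value substitute, and the Monte Carlo lower bound. It is computed
#' as a low quantile of all nonzero peak intensities in the run, using the
#' inverse-empirical-CDF convention: the value at sorted position
#' `ceiling(quantile * n)`.
#'
#' @param run An `ms1_run`.
#' @param quantile Quantile of nonzero intensities; default 0.05.
#' @return A nonnegative scalar; 0 (with a warning) when the run has no
#'   nonzero intensity.
#' @export
estimate_noise <- function(run, quantile = 0.05) {
  stopifnot(inherits(run, "ms1_run"), quantile > 0, quantile <= 1)
  x <- run$peaks$intensity
  x <- x[x > 0]
  if (length(x) == 0) {
    warning("Run ", run$replicate_id, " has no nonzero intensity; ",
            "noise level set to 0", call. = FALSE)
    return(0)
  }
  sort(x)[ceiling(quantile * length(x))]
}

channel_intensity <- function(run, precursor_mz, halfwidth, index = NULL) {
  pk <- run$peaks
  if (is.null(index)) {
    hit <- which(abs(pk$mz - precursor_mz) <= halfwidth)
  } else {
    # index = list(ord, mz_sorted) from run_mz_index(); binary-search the
    # m/z window instead of scanning every peak
    lo <- findInterval(precursor_mz - halfwidth, index$mz_sorted,
                       left.open = TRUE) + 1L
    hi <- findInterval(precursor_mz + halfwidth, index$mz_sorted)
    hit <- if (lo > hi) integer(0) else index$ord[lo:hi]
  }
  out <- numeric(nrow(run$scans))
  if (length(hit) > 0) {
    idx <- match(pk$scan_number[hit], run$scans$scan_number)
    sums <- rowsum(pk$intensity[hit], idx)
    out[as.integer(rownames(sums))] <- sums[, 1]
  }
  out
}

run_mz_index <- function(run) {
  ord <- order(run$peaks$mz)
  list(ord = ord, mz_sorted = run$peaks$mz[ord])
}

#' Extract and integrate one elution trace
#'
#' The ion current for the target m/z channel (all peaks within
#' `halfwidth` of `precursor_mz`) is summed per scan. Starting at the PSM's
#' scan, the trace walks backward and forward, including each scan whose
#' channel intensity exceeds the noise level, and stops (exclusive) at the
#' first scan at or below noise, after `max_extent` scans, or at the
#' chromatogram edge. The start scan is always included. The area is the sum
#' of channel intensities over the included scans — the integral of the
#' elution profile.
#'
#' @param run An `ms1_run`.
#' @param precursor_mz Target m/z in Th.
#' @param start_scan Scan number where the peptide was matched; must exist in
#'   the run.
#' @param noise Noise level (see [estimate_noise()]).
#' @param halfwidth Channel half-width in Th; default 0.5 (a 1-Da-wide
#'   window).
#' @param max_extent Maximum walk distance per direction, in scans; default
#'   250.
#' @return A one-row tibble: `precursor_mz`, `start_scan`, `low_scan`,
#'   `high_scan` (scan numbers of the inclusive bounds reached), `n_scans`,
#'   `area`, and `stopped_low`/`stopped_high` (one of `"noise"`,
#'   `"extent-limit"`, `"chromatogram-edge"`).
#' @export
extract_trace <- function(run, precursor_mz, start_scan, noise,
                          halfwidth = 0.5, max_extent = 250) {
  stopifnot(inherits(run, "ms1_run"))
  i0 <- match(start_scan, run$scans$scan_number)
  if (is.na(i0)) {
    stop("start_scan ", start_scan, " not present in run ",
         run$replicate_id, call. = FALSE)
  }
  chan <- channel_intensity(run, precursor_mz, halfwidth)
  lo <- trace_walk(chan, i0, noise, max_extent, -1L)
  hi <- trace_walk(chan, i0, noise, max_extent, +1L)

  tibble::tibble(
    precursor_mz = precursor_mz,
    start_scan = start_scan,
    low_scan = run$scans$scan_number[lo$i],
    high_scan = run$scans$scan_number[hi$i],
    n_scans = hi$i - lo$i + 1L,
    area = sum(chan[lo$i:hi$i]),
    stopped_low = lo$stop,
    stopped_high = hi$stop
  )
}

trace_walk <- function(chan, i0, noise, max_extent, step) {
  n <- length(chan)
  i <- i0
  repeat {
    j <- i + step
    if (abs(j - i0) > max_extent) return(list(i = i, stop = "extent-limit"))
    if (j < 1 || j > n) return(list(i = i, stop = "chromatogram-edge"))
    if (chan[j] <= noise) return(list(i = i, stop = "noise"))
    i <- j
  }
}

# Area only, for a precomputed channel vector.
integrate_channel <- function(chan, run, start_scan, noise, max_extent) {
  i0 <- match(start_scan, run$scans$scan_number)
  if (is.na(i0)) {
    stop("start_scan ", start_scan, " not present in run ",
         run$replicate_id, call. = FALSE)
  }
  lo <- trace_walk(chan, i0, noise, max_extent, -1L)
  hi <- trace_walk(chan, i0, noise, max_extent, +1L)
  sum(chan[lo$i:hi$i])
}

# Greedy deduplication of PSMs sharing a precursor m/z: classes are formed on
# ascending m/z (a new class opens when the gap from the class anchor exceeds
# the tolerance); the earliest-scan PSM of each class is kept.
dedupe_psms_by_mz <- function(psms, tolerance = 0.01) {
  if (nrow(psms) <= 1) return(psms)
  ord <- order(psms$precursor_mz, psms$scan_number)
  mz <- psms$precursor_mz[ord]
  class_id <- integer(length(mz))
  cls <- 1L
  anchor <- mz[1]
  class_id[1] <- cls
  for (k in seq_along(mz)[-1]) {
    if (mz[k] - anchor > tolerance) {
      cls <- cls + 1L
      anchor <- mz[k]
    }
    class_id[k] <- cls
  }
  keep <- tapply(seq_along(ord), class_id, function(ix) {
    ix[which.min(psms$scan_number[ord][ix])]
  })
  psms[sort(ord[unlist(keep)]), , drop = FALSE]
}

#' Quantify proteins by XIC integration across replicates
#'
#' For every (protein, replicate) pair, the replicate's PSMs for that protein
#' are deduplicated by precursor m/z (matches within `dedupe_tolerance` are
#' counted once so the same elution integral is not summed twice), one trace
#' is extracted per retained PSM, and the trace areas are summed. Proteins
#' with no PSM in a replicate (or whose traces integrate to zero) receive the
#' replicate's noise level and are flagged as imputed, which keeps every cell
#' strictly positive for downstream ratios.
#'
#' @param psms Filtered PSM tibble, restricted to quantifiable proteins
#'   upstream or not (rows for accessions missing from `proteins` are
#'   dropped).
#' @param proteins Protein tibble (the retained list from
#'   [retained_proteins()]); only its `accession` column is used.
#' @param runs Named list of `ms1_run` objects, one per replicate; names (or
#'   the runs' `replicate_id` fields) must cover every replicate in
#'   `replicates`.
#' @param replicates Tibble with `replicate_id` and `condition_id` giving the
#'   full replicate roster; defaults to the distinct pairs present in `psms`.
#' @param halfwidth,max_extent Trace parameters, see [extract_trace()].
#' @param noise_quantile Quantile for [estimate_noise()]; default 0.05.
#' @param dedupe_tolerance m/z tolerance (Th) under which two PSMs are "the
#'   same precursor"; default 0.01.
#' @return An `lfq_intensities` tibble with columns `accession`,
#'   `replicate_id`, `condition_id`, `intensity`, `imputed`, carrying the
#'   per-replicate noise levels in `attr(, "noise_levels")`.
#' @export
quantify_proteins <- function(psms, proteins, runs,
                              replicates = NULL,
                              halfwidth = 0.5, max_extent = 250,
                              noise_quantile = 0.05,
                              dedupe_tolerance = 0.01) {
  runs <- stats::setNames(runs, purrr::map_chr(runs, "replicate_id"))
  if (is.null(replicates)) {
    replicates <- dplyr::distinct(psms, .data$replicate_id, .data$condition_id)
  }
  missing_runs <- setdiff(replicates$replicate_id, names(runs))
  if (length(missing_runs) > 0) {
    stop("No MS1 run supplied for replicate(s): ",
         paste(missing_runs, collapse = ", "), call. = FALSE)
  }
  noise <- purrr::map_dbl(runs[replicates$replicate_id], estimate_noise,
                          quantile = noise_quantile)
  noise_levels <- tibble::tibble(replicate_id = replicates$replicate_id,
                                 noise_level = unname(noise))

  psms <- dplyr::semi_join(psms, proteins, by = "accession")
  cells <- tidyr::expand_grid(
    accession = proteins$accession,
    replicate_id = replicates$replicate_id
  )
  observed <- purrr::map_dfr(split(psms, psms$replicate_id), function(dr) {
    rep_id <- dr$replicate_id[1]
    run <- runs[[rep_id]]
    nz <- noise_levels$noise_level[noise_levels$replicate_id == rep_id]
    # orthologs quantified from the same spectra reuse the cached channel
    mz_index <- run_mz_index(run)
    chan_cache <- new.env(parent = emptyenv())
    channel <- function(mz) {
      key <- sprintf("%.6f", mz)
      if (is.null(chan_cache[[key]])) {
        chan_cache[[key]] <- channel_intensity(run, mz, halfwidth, mz_index)
      }
      chan_cache[[key]]
    }
    purrr::map_dfr(split(dr, dr$accession), function(d) {
      d <- dedupe_psms_by_mz(d, dedupe_tolerance)
      areas <- purrr::map2_dbl(d$precursor_mz, d$scan_number, function(mz, sc) {
        integrate_channel(channel(mz), run, sc, nz, max_extent)
      })
      tibble::tibble(accession = d$accession[1], replicate_id = rep_id,
                     intensity = sum(areas))
    })
  })

  out <- cells |>
    dplyr::left_join(observed, by = c("accession", "replicate_id")) |>
    dplyr::left_join(noise_levels, by = "replicate_id") |>
    dplyr::left_join(dplyr::select(replicates, "replicate_id", "condition_id"),
                     by = "replicate_id") |>
    dplyr::mutate(
      imputed = is.na(.data$intensity) | .data$intensity <= 0,
      intensity = dplyr::if_else(.data$imputed, .data$noise_level,
                                 .data$intensity)
    ) |>
    dplyr::select("accession", "replicate_id", "condition_id", "intensity",
                  "imputed")
  structure(out, noise_levels = noise_levels,
            class = c("lfq_intensities", class(out)))
}

#' Write an intensity matrix and its imputation mask as TSV
#'
#' Rows are proteins, columns are replicates; a parallel mask file marks the
#' imputed cells.
#'
#' @param x An `lfq_intensities` tibble.
#' @param path Output TSV for intensities.
#' @param mask_path Output TSV for the imputation mask; default derives from
#'   `path`.
#' @return `path`, invisibly.
#' @export
write_intensity_matrix <- function(x, path,
                                   mask_path = sub("(\\.[^.]+)?$", ".mask\\1",
                                                   path)) {
  wide <- tidyr::pivot_wider(x, id_cols = "accession",
                             names_from = "replicate_id",
                             values_from = "intensity")
  mask <- tidyr::pivot_wider(x, id_cols = "accession",
                             names_from = "replicate_id",
                             values_from = "imputed")
  readr::write_tsv(wide, path, progress = FALSE)
  readr::write_tsv(mask, mask_path, progress = FALSE)
  invisible(path)
}
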