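#' Mode of a replicate's protein intensities
#'
#' The mode — the most commonly occurring protein intensity — is estimated by
#' histogramming the log10 intensities with fixed-width bins anchored at 0
#' and returning 10 to the center of the most populated bin (ties broken
#' toward the lower bin). Being a modal statistic it is insensitive to the
#' extreme minimum and maximum intensities, which can vary tremendously
#' between replicates.
#'
#' @param intensities Strictly positive numeric vector (one replicate's
#'   protein intensities).
#' @param bin_width Histogram bin width in log10 units; default 0.1.
#' @return The mode estimate (positive scalar, a bin center on the raw
#'   scale).
#' @export
#' @examples
#' replicate_mode(c(1, 1, 1, 1000)) # 10^0.05, the center of the bin of 1s
replicate_mode <- function(intensities, bin_width = 0.1) {
  if (any(intensities <= 0) || length(intensities) == 0) {
    stop("replicate_mode() requires strictly positive intensities",
         call. = FALSE)
  }
  bin <- floor(log10(intensities) / bin_width)
  counts <- table(bin)
  modal_bin <- as.numeric(names(counts)[which.max(counts)]) # ties: lower bin
  10^((modal_bin + 0.5) * bin_width)
}

#' Mode-based normalization of an intensity matrix
#'
#' Each replicate's intensities are divided by that replicate's mode
#' ([replicate_mode()]), so the modal bin of every normalized replicate
#' contains 1. Normalization is per replicate, never global.
#'
#' @param x An `lfq_intensities` tibble from [quantify_proteins()] (every
#'   cell must be strictly positive).
#' @param bin_width Bin width for the mode histogram; default 0.1 log10
#'   units.
#' @return An `lfq_normalization` object: list with `normalized` (same shape
#'   as `x`, intensities divided by the replicate mode), `modes` (tibble
#'   `replicate_id`, `mode_value`), `noise_levels` (normalized per-replicate
#'   noise levels when `x` carries raw ones), and `bin_width`.
#' @export
normalize_intensities <- function(x, bin_width = 0.1) {
  if (any(x$intensity <= 0)) {
    stop("All intensities must be > 0 before normalization (noise-level ",
         "imputation guarantees this upstream)", call. = FALSE)
  }
  modes <- x |>
    dplyr::group_by(.data$replicate_id) |>
    dplyr::summarise(mode_value = replicate_mode(.data$intensity, bin_width),
                     .groups = "drop")
  if (any(modes$mode_value <= 0)) stop("Zero mode", call. = FALSE)
  normalized <- x |>
    dplyr::left_join(modes, by = "replicate_id") |>
    dplyr::mutate(intensity = .data$intensity / .data$mode_value) |>
    dplyr::select(-"mode_value")
  noise_levels <- attr(x, "noise_levels")
  if (!is.null(noise_levels)) {
    noise_levels <- noise_levels |>
      dplyr::left_join(modes, by = "replicate_id") |>
      dplyr::mutate(noise_level = .data$noise_level / .data$mode_value) |>
      dplyr::select("replicate_id", "noise_level")
  }
  structure(
    list(normalized = normalized, modes = modes,
         noise_levels = noise_levels, bin_width = bin_width),
    class = "lfq_normalization"
  )
}

#' @export
print.lfq_normalization <- function(x, ...) {
  cat("<lfq_normalization> ", nrow(x$modes), " replicates, bin width ",
      x$bin_width, " log10 units\n", sep = "")
  print(x$modes)
  invisible(x)
}

#' Between-condition expression ratio
#'
#' Ratio of the mean normalized intensity in condition A over condition B.
#'
#' @param a,b Positive numeric vectors of replicate intensities for the two
#'   conditions (at least one replicate each).
#' @return The ratio `mean(a) / mean(b)`.
#' @export
expression_ratio <- function(a, b) {
  if (length(a) == 0 || length(b) == 0) {
    stop("Both conditions need at least one replicate", call. = FALSE)
  }
  if (any(c(a, b) <= 0)) {
    stop("Replicate intensities must be > 0", call. = FALSE)
  }
  mean(a) / mean(b)
}

#' Monte Carlo resampling p-value for one protein's expression ratio
#'
#' Per iteration, one uniform random intensity is drawn for every replicate
#' between (and including) the noise floor and the maximum intensity; the
#' random condition-A-over-B ratio is compared with the experimental ratio
#' and the counts of random ratios above and below it are recorded (exact
#' ties count as neither). The two-sided p-value is
#' `min(1, 2 * (min(above, below) + 1) / (n_iterations + 1))`; the +1 guard
#' keeps p strictly positive. Deterministic given `seed`.
#'
#' @param a,b Observed (normalized) replicate intensities for the two
#'   conditions.
#' @param noise_min Lower draw bound (> 0), the minimum noise level.
#' @param intensity_max Upper draw bound, `>= noise_min`.
#' @param n_iterations Number of random draws; default one million.
#' @param seed Integer seed for the draws.
#' @return A one-row tibble: `ratio`, `count_above`, `count_below`,
#'   `n_iterations`, `p_value`, `seed`.
#' @export
monte_carlo_p <- function(a, b, noise_min, intensity_max,
                          n_iterations = 1e6, seed = 1L) {
  stopifnot(noise_min > 0, n_iterations >= 1)
  if (intensity_max < noise_min) {
    stop("intensity_max must be >= noise_min", call. = FALSE)
  }
  ratio <- expression_ratio(a, b)
  na <- length(a)
  nb <- length(b)
  above <- 0L
  below <- 0L
  withr::with_seed(seed, {
    chunk <- 100000L
    done <- 0L
    while (done < n_iterations) {
      m <- min(chunk, n_iterations - done)
      ra <- matrix(stats::runif(m * na, noise_min, intensity_max), nrow = m)
      rb <- matrix(stats::runif(m * nb, noise_min, intensity_max), nrow = m)
      rr <- rowMeans(ra) / rowMeans(rb)
      above <- above + sum(rr > ratio)
      below <- below + sum(rr < ratio)
      done <- done + m
    }
  })
  tibble::tibble(
    ratio = ratio,
    count_above = above,
    count_below = below,
    n_iterations = as.integer(n_iterations),
    p_value = min(1, 2 * (min(above, below) + 1) / (n_iterations + 1)),
    seed = as.integer(seed)
  )
}

#' Differential-expression test over a normalized intensity matrix
#'
#' Computes the between-condition ratio and Monte Carlo resampling p-value
#' ([monte_carlo_p()]) for every protein, and calls significance at
#' `p <= alpha`. Draw bounds are per protein by default (the minimum
#' normalized noise level among its replicates and its maximum observed
#' normalized intensity); `bounds = "global"` uses the matrix-wide bounds
#' instead. Per-protein Monte Carlo seeds are derived from `seed` and the
#' protein's position so results do not depend on evaluation order.
#'
#' @param norm An `lfq_normalization` object (or an `lfq_intensities` tibble,
#'   which is normalized first with default bin width).
#' @param condition_a,condition_b The two condition labels to compare
#'   (ratio is A over B).
#' @param n_iterations Monte Carlo iterations per protein; default one
#'   million.
#' @param seed Integer master seed.
#' @param alpha Significance threshold on the p-value; default 0.05.
#' @param bounds `"per-protein"` (default) or `"global"` draw bounds.
#' @return An `lfq_diffexpr` object; see [tidy.lfq_diffexpr()] and
#'   [glance.lfq_diffexpr()].
#' @export
test_differential <- function(norm, condition_a, condition_b,
                              n_iterations = 1e6, seed = 1L, alpha = 0.05,
                              bounds = c("per-protein", "global")) {
  bounds <- match.arg(bounds)
  if (inherits(norm, "lfq_intensities")) norm <- normalize_intensities(norm)
  stopifnot(inherits(norm, "lfq_normalization"))
  x <- norm$normalized
  if (!all(c(condition_a, condition_b) %in% x$condition_id)) {
    stop("Conditions not found in the intensity matrix: ",
         paste(setdiff(c(condition_a, condition_b), x$condition_id),
               collapse = ", "), call. = FALSE)
  }
  x <- dplyr::filter(x, .data$condition_id %in% c(condition_a, condition_b))
  nl <- norm$noise_levels
  if (is.null(nl)) {
    # fall back to the smallest observed value when no noise levels travelled
    # with the matrix
    nl <- x |>
      dplyr::group_by(.data$replicate_id) |>
      dplyr::summarise(noise_level = min(.data$intensity), .groups = "drop")
  }
  nl <- dplyr::filter(nl, .data$replicate_id %in% unique(x$replicate_id))
  noise_min_all <- min(nl$noise_level)
  intensity_max_all <- max(x$intensity)

  accs <- sort(unique(x$accession))
  per_acc <- split(x, x$accession)
  results <- purrr::imap_dfr(per_acc[accs], function(d, acc) {
    i <- match(acc, accs)
    a <- d$intensity[d$condition_id == condition_a]
    b <- d$intensity[d$condition_id == condition_b]
    if (bounds == "per-protein") {
      lo <- noise_min_all
      hi <- max(d$intensity)
    } else {
      lo <- noise_min_all
      hi <- intensity_max_all
    }
    mc <- monte_carlo_p(a, b, lo, hi, n_iterations,
                        seed = (as.numeric(seed) + i) %% (2^31 - 1))
    dplyr::bind_cols(
      tibble::tibble(accession = acc, noise_min = lo, intensity_max = hi),
      mc
    )
  })
  results <- results |>
    dplyr::mutate(
      significant = .data$p_value <= alpha & .data$ratio != 1,
      direction = dplyr::case_when(
        !.data$significant ~ "unchanged",
        .data$ratio > 1 ~ "up",
        .data$ratio < 1 ~ "down"
      )
    ) |>
    dplyr::select("accession", "ratio", "count_above", "count_below",
                  "n_iterations", "p_value", "significant", "direction",
                  "noise_min", "intensity_max", "seed")
  structure(
    list(results = results, condition_a = condition_a,
         condition_b = condition_b, alpha = alpha,
         n_iterations = as.integer(n_iterations), seed = as.integer(seed),
         bounds = bounds, modes = norm$modes, bin_width = norm$bin_width),
    class = "lfq_diffexpr"
  )
}

#' Partition differential results by significance and direction
#'
#' A protein is significantly differentially expressed when its Monte Carlo
#' p-value is at most `alpha` (inclusive threshold); direction follows the
#' ratio. A ratio of exactly 1 with `p <= alpha` is classified unchanged,
#' with a warning.
#'
#' @param results A results tibble ([tidy.lfq_diffexpr()]) or an
#'   `lfq_diffexpr` object.
#' @param alpha Significance threshold; default 0.05.
#' @return A named list of three tibbles: `up`, `down`, `unchanged`.
#' @export
call_differential <- function(results, alpha = 0.05) {
  if (inherits(results, "lfq_diffexpr")) results <- results$results
  if (nrow(results) == 0) {
    return(list(up = results, down = results, unchanged = results))
  }
  sig <- results$p_value <= alpha
  tied <- sig & results$ratio == 1
  if (any(tied)) {
    warning(sum(tied), " protein(s) with p <= ", alpha,
            " but ratio exactly 1; classified unchanged", call. = FALSE)
  }
  list(
    up = results[sig & results$ratio > 1, , drop = FALSE],
    down = results[sig & results$ratio < 1, , drop = FALSE],
    unchanged = results[!sig | tied, , drop = FALSE]
  )
}

#' @export
print.lfq_diffexpr <- function(x, ...) {
  cat("<lfq_diffexpr> ", x$condition_a, " vs ", x$condition_b, ": ",
      nrow(x$results), " proteins, ", sum(x$results$significant),
      " significant at p <= ", x$alpha, " (", x$n_iterations,
      " Monte Carlo iterations)\n", sep = "")
  invisible(x)
}

#' Tidy a differential-expression fit
#'
#' @param x An `lfq_diffexpr` object.
#' @param ... Unused.
#' @return The per-protein results tibble: `accession`, `ratio`,
#'   `count_above`, `count_below`, `n_iterations`, `p_value`, `significant`,
#'   `direction`, draw bounds, and the per-protein seed.
#' @method tidy lfq_diffexpr
#' @export
tidy.lfq_diffexpr <- function(x, ...) {
  x$results
}

#' One-row summary of a differential-expression fit
#'
#' @param x An `lfq_diffexpr` object.
#' @param ... Unused.
#' @return A one-row tibble: protein counts by call, `alpha`,
#'   `n_iterations`, `seed`, `bounds`.
#' @method glance lfq_diffexpr
#' @export
glance.lfq_diffexpr <- function(x, ...) {
  calls <- call_differential(x, x$alpha)
  tibble::tibble(
    n_proteins = nrow(x$results),
    n_significant = sum(x$results$significant),
    n_up = nrow(calls$up),
    n_down = nrow(calls$down),
    alpha = x$alpha,
    n_iterations = x$n_iterations,
    seed = x$seed,
    bounds = x$bounds
  )
}

#' Volcano-style plot of a differential-expression fit
#'
#' log2 expression ratio against -log10 Monte Carlo p-value, colored by
#' call.
#'
#' @param object An `lfq_diffexpr` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot lfq_diffexpr
#' @export
autoplot.lfq_diffexpr <- function(object, ...) {
  d <- object$results
  ggplot2::ggplot(d, ggplot2::aes(x = log2(.data$ratio),
                                  y = -log10(.data$p_value),
                                  color = .data$direction)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_hline(yintercept = -log10(object$alpha),
                        linetype = "dashed") +
    ggplot2::labs(
      x = sprintf("log2(%s / %s)", object$condition_a, object$condition_b),
      y = "-log10 Monte Carlo p",
      color = "call",
      title = "Differential protein expression"
    ) +
    ggplot2::theme_minimal()
}

#' Write the differential report and its run metadata
#'
#' The per-protein table is written as TSV; the run metadata (seed, bounds
#' mode, bin width, alpha, iteration count, conditions, replicate modes) as a
#' YAML sidecar.
#'
#' @param fit An `lfq_diffexpr` object.
#' @param path Output TSV path.
#' @param meta_path Sidecar YAML path; defaults to `path` with a `.meta.yaml`
#'   suffix.
#' @return `path`, invisibly.
#' @export
write_differential_report <- function(fit, path,
                                      meta_path = paste0(path, ".meta.yaml")) {
  readr::write_tsv(fit$results, path, progress = FALSE)
  meta <- list(
    condition_a = fit$condition_a, condition_b = fit$condition_b,
    alpha = fit$alpha, n_iterations = fit$n_iterations, seed = fit$seed,
    bounds = fit$bounds, mode_bin_width = fit$bin_width,
    modes = as.list(stats::setNames(fit$modes$mode_value,
                                    fit$modes$replicate_id))
  )
  yaml::write_yaml(meta, meta_path)
  invisible(path)
}
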