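#' Read and validate a pipeline configuration
#'
#' The configuration is a single YAML file (or an equivalent nested list)
#' covering paths, thresholds, quantification and statistics parameters, and
#' the condition-to-replicate map. Missing fields fall back to the documented
#' defaults; referenced input paths must exist at validation time.
#'
#' @param config Path to a YAML file, or a nested list.
#' @param base_dir Directory relative paths are resolved against; defaults to
#'   the config file's directory (or the working directory for list input).
#' @return A validated config list with all defaults filled in.
#' @export
read_pipeline_config <- function(config, base_dir = NULL) {
  if (is.character(config)) {
    if (is.null(base_dir)) base_dir <- dirname(config)
    config <- yaml::read_yaml(config)
  }
  if (is.null(base_dir)) base_dir <- "."
  defaults <- list(
    thresholds = list(e_value = 0.05, min_distinct_peptides = 2,
                      alpha = 0.05),
    quantification = list(halfwidth = 0.5, max_extent = 250,
                          noise_quantile = 0.05, dedupe_tolerance = 0.01),
    statistics = list(n_iterations = 1e6, seed = 1, bounds = "per-protein",
                      mode_bin_width = 0.1),
    preferred_species = "Gossypium hirsutum"
  )
  cfg <- utils::modifyList(defaults, config)
  resolve <- function(p) {
    if (is.null(p)) return(NULL)
    if (!grepl("^(/|[A-Za-z]:)", p)) file.path(base_dir, p) else p
  }
  cfg$paths$database <- resolve(cfg$paths$database)
  cfg$paths$psms <- resolve(cfg$paths$psms)
  cfg$paths$ms1_dir <- resolve(cfg$paths$ms1_dir)
  cfg$paths$output_dir <- resolve(cfg$paths$output_dir)

  required <- c("database", "psms", "ms1_dir")
  for (f in required) {
    if (is.null(cfg$paths[[f]])) {
      stop("Config validation: paths$", f, " is required", call. = FALSE)
    }
    if (!file.exists(cfg$paths[[f]])) {
      stop("Config validation: paths$", f, " does not exist: ",
           cfg$paths[[f]], call. = FALSE)
    }
  }
  if (is.null(cfg$paths$output_dir)) {
    stop("Config validation: paths$output_dir is required", call. = FALSE)
  }
  if (is.null(cfg$conditions) || length(cfg$conditions) < 2) {
    stop("Config validation: conditions must map >= 2 condition ids to ",
         "replicate ids", call. = FALSE)
  }
  with(cfg$thresholds, stopifnot(e_value > 0, min_distinct_peptides >= 1,
                                 alpha > 0, alpha < 1))
  with(cfg$quantification, stopifnot(halfwidth > 0, max_extent >= 1,
                                     noise_quantile > 0, noise_quantile <= 1,
                                     dedupe_tolerance >= 0))
  stopifnot(cfg$statistics$n_iterations >= 1,
            cfg$statistics$bounds %in% c("per-protein", "global"))
  if (is.null(cfg$compare)) cfg$compare <- names(cfg$conditions)[1:2]
  cfg
}

#' Run the full label-free quantification pipeline
#'
#' Executes identification (E-value filter, two-peptide rule, decoy FDR,
#' coverage), spectra-set protein grouping, XIC quantification with
#' noise-level imputation, mode normalization, and the Monte Carlo
#' differential-expression test, writing every intermediate artifact plus a
#' machine-readable run manifest into the configured output directory.
#'
#' Artifacts: `filtered_psms.tsv`, `proteins.tsv`, `groups.tsv`,
#' `intensity_matrix.tsv` (+ `.mask`), `normalization.yaml`,
#' `differential.tsv` (+ `.meta.yaml`), `manifest.yaml`.
#'
#' @param config Path to a YAML config or a config list; see
#'   [read_pipeline_config()].
#' @return Invisibly, a list with the in-memory stage results: `psms`,
#'   `proteins` (targets), `fdr`, `groups`, `retained`, `intensities`,
#'   `normalization`, `fit`, `calls`, and `manifest`.
#' @export
run_pipeline <- function(config) {
  cfg <- read_pipeline_config(config)
  out_dir <- cfg$paths$output_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  counts <- list()

  # --- identify ---
  db <- read_protein_db(cfg$paths$database)
  psms <- read_psm_table(cfg$paths$psms)
  counts$psms_in <- nrow(psms)
  kept <- filter_psms(psms, cfg$thresholds$e_value)
  counts$psms_filtered <- nrow(kept)
  message("identify: ", nrow(kept), "/", nrow(psms), " PSMs pass E-value <= ",
          cfg$thresholds$e_value)
  proteins_all <- assemble_proteins(kept, db,
                                    cfg$thresholds$min_distinct_peptides)
  targets <- proteins_all[!proteins_all$is_decoy, , drop = FALSE]
  decoys <- proteins_all[proteins_all$is_decoy, , drop = FALSE]
  fdr <- estimate_fdr(targets, decoys)
  counts$proteins_target <- nrow(targets)
  counts$proteins_decoy <- nrow(decoys)
  counts$fdr <- fdr
  message("identify: ", nrow(targets), " target proteins (two-peptide rule), ",
          nrow(decoys), " decoys; FDR = ", signif(fdr, 3))
  write_psm_table(kept, file.path(out_dir, "filtered_psms.tsv"))
  readr::write_tsv(
    dplyr::select(targets, -"peptides", -"spectra"),
    file.path(out_dir, "proteins.tsv"), progress = FALSE
  )

  # --- group ---
  groups <- group_proteins(targets, cfg$preferred_species)
  retained <- retained_proteins(groups, targets)
  counts$groups <- nrow(groups)
  counts$proteins_retained <- nrow(retained)
  message("group: ", nrow(groups), " groups; ", nrow(retained),
          " proteins retained")
  write_group_report(groups, file.path(out_dir, "groups.tsv"))

  # --- quantify ---
  replicates <- purrr::imap_dfr(cfg$conditions, function(reps, cond) {
    tibble::tibble(replicate_id = unlist(reps), condition_id = cond)
  })
  ms1_files <- list.files(cfg$paths$ms1_dir, pattern = "\\.ms1$",
                          full.names = TRUE)
  runs <- purrr::map(ms1_files, read_ms1)
  names(runs) <- purrr::map_chr(runs, "replicate_id")
  q <- cfg$quantification
  intensities <- quantify_proteins(
    kept, retained, runs, replicates,
    halfwidth = q$halfwidth, max_extent = q$max_extent,
    noise_quantile = q$noise_quantile, dedupe_tolerance = q$dedupe_tolerance
  )
  counts$cells_imputed <- sum(intensities$imputed)
  message("quantify: ", nrow(retained), " proteins x ", nrow(replicates),
          " replicates; ", sum(intensities$imputed), " cells imputed at the ",
          "noise level")
  write_intensity_matrix(intensities, file.path(out_dir, "intensity_matrix.tsv"))

  # --- diffexpr ---
  s <- cfg$statistics
  norm <- normalize_intensities(intensities, s$mode_bin_width)
  yaml::write_yaml(
    list(bin_width = norm$bin_width,
         modes = as.list(stats::setNames(norm$modes$mode_value,
                                         norm$modes$replicate_id))),
    file.path(out_dir, "normalization.yaml")
  )
  fit <- test_differential(norm, cfg$compare[1], cfg$compare[2],
                           n_iterations = s$n_iterations, seed = s$seed,
                           alpha = cfg$thresholds$alpha, bounds = s$bounds)
  calls <- call_differential(fit, cfg$thresholds$alpha)
  counts$significant <- sum(fit$results$significant)
  counts$up <- nrow(calls$up)
  counts$down <- nrow(calls$down)
  message("diffexpr: ", counts$significant, " of ", nrow(fit$results),
          " proteins significant at p <= ", cfg$thresholds$alpha,
          " (", counts$up, " up, ", counts$down, " down in ",
          cfg$compare[1], ")")
  write_differential_report(fit, file.path(out_dir, "differential.tsv"))

  manifest <- list(
    package = "lfqmc",
    version = as.character(utils::packageVersion("lfqmc")),
    seed = s$seed,
    config = cfg,
    counts = counts
  )
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))

  invisible(list(psms = kept, proteins = targets, decoys = decoys, fdr = fdr,
                 groups = groups, retained = retained,
                 intensities = intensities, normalization = norm, fit = fit,
                 calls = calls, manifest = manifest))
}

#' Compare protein catalogs from multiple runs
#'
#' Numeric Venn report for two or more named protein lists: one row per
#' pair with intersection and per-side difference counts, plus a final
#' `<all>` row with the union size and the count common to every list.
#'
#' @param catalogs Named list (length >= 2) of character vectors of
#'   accessions.
#' @return A tibble: `comparison`, `n_left`, `n_right`, `n_intersection`,
#'   `n_only_left`, `n_only_right`.
#' @export
compare_catalogs <- function(catalogs) {
  stopifnot(is.list(catalogs), length(catalogs) >= 2,
            !is.null(names(catalogs)))
  catalogs <- purrr::map(catalogs, unique)
  nm <- names(catalogs)
  pairs <- utils::combn(nm, 2, simplify = FALSE)
  rows <- purrr::map_dfr(pairs, function(p) {
    a <- catalogs[[p[1]]]
    b <- catalogs[[p[2]]]
    tibble::tibble(
      comparison = paste(p[1], "vs", p[2]),
      n_left = length(a), n_right = length(b),
      n_intersection = length(intersect(a, b)),
      n_only_left = length(setdiff(a, b)),
      n_only_right = length(setdiff(b, a))
    )
  })
  common <- purrr::reduce(catalogs, intersect)
  all_union <- purrr::reduce(catalogs, union)
  dplyr::bind_rows(rows, tibble::tibble(
    comparison = "<all>",
    n_left = length(all_union), n_right = NA_integer_,
    n_intersection = length(common),
    n_only_left = NA_integer_, n_only_right = NA_integer_
  ))
}
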