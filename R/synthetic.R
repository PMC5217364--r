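#' @name synthetic
#' @title Synthetic label-free proteomics data
#' @description
#' Generators for ground-truth inputs with the statistical structure the
#' pipeline assumes: a protein database with randomized decoys, tryptic
#' peptides with computed precursor m/z, multi-replicate two-condition MS1
#' chromatograms with Gaussian elution peaks on a uniform noise floor, and
#' PSM tables whose target/decoy E-value distributions straddle the 0.05
#' filter. All randomness flows from the seed arguments; identical seeds
#' give bit-identical outputs.
NULL

amino_acids <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# monoisotopic residue masses (Da)
residue_masses <- c(
  A = 71.03711, C = 103.00919, D = 115.02694, E = 129.04259, F = 147.06841,
  G = 57.02146, H = 137.05891, I = 113.08406, K = 128.09496, L = 113.08406,
  M = 131.04049, N = 114.04293, P = 97.05276, Q = 128.05858, R = 156.10111,
  S = 87.03203, T = 101.04768, V = 99.06841, W = 186.07931, Y = 163.06333
)
water_mass <- function() 18.010565
proton_mass <- function() 1.007276

#' Precursor m/z of a peptide
#'
#' Monoisotopic peptide mass (residue masses plus water) with proton adducts:
#' `(M + z * proton) / z`.
#'
#' @param peptide Peptide sequence over the 20 standard amino acids.
#' @param charge Charge state (positive integer, typically 2 or 3).
#' @return Precursor m/z in Th.
#' @export
peptide_mz <- function(peptide, charge = 2L) {
  vapply(peptide, function(p) {
    res <- strsplit(p, "")[[1]]
    m <- sum(residue_masses[res]) + water_mass()
    (m + charge * proton_mass()) / charge
  }, double(1), USE.NAMES = FALSE)
}

#' In silico tryptic digestion
#'
#' Cleaves after every K or R (no proline exception) and emits all fragments
#' spanning 0 to `missed_cleavages` internal cleavage sites, then filters by
#' peptide length. A sequence without K/R yields itself as one peptide.
#'
#' @param sequence Protein sequence.
#' @param missed_cleavages Maximum internal missed cleavage sites; default 2.
#' @param min_length,max_length Peptide length filter; defaults 6 and 30.
#' @return Character vector of distinct peptides, in order of first
#'   occurrence.
#' @export
digest_tryptic <- function(sequence, missed_cleavages = 2,
                           min_length = 6, max_length = 30) {
  stopifnot(nchar(sequence) > 0)
  res <- strsplit(sequence, "")[[1]]
  cut_after <- which(res %in% c("K", "R"))
  bounds <- unique(c(0L, cut_after, length(res)))
  starts <- bounds[-length(bounds)] + 1L
  ends <- bounds[-1]
  frags <- substring(sequence, starts, ends)
  n <- length(frags)
  out <- character(0)
  for (i in seq_len(n)) {
    for (mc in 0:missed_cleavages) {
      j <- i + mc
      if (j > n) break
      out <- c(out, paste(frags[i:j], collapse = ""))
    }
  }
  out <- unique(out)
  len <- nchar(out)
  out[len >= min_length & len <= max_length]
}

#' Generate a protein database with randomized decoys
#'
#' Target sequences are uniform random strings over the 20-letter amino-acid
#' alphabet with species tags drawn from `species_mix`. Decoys are
#' residue-shuffled copies of target sequences (same residue composition),
#' flagged with the `DECOY_` accession prefix. A fraction of targets gains an
#' exact-sequence ortholog entry in a different species, so that
#' identical-evidence protein grouping is exercised downstream.
#'
#' @param n_proteins Total number of entries (targets + decoys) before
#'   ortholog duplication.
#' @param decoy_fraction Fraction of entries that are decoys; default 0.5
#'   (one decoy per target, as in a standard decoy search).
#' @param length_range Sequence length range; default 120–400 residues.
#' @param species_mix Named probability vector over species tags.
#' @param ortholog_fraction Fraction of targets duplicated as same-sequence
#'   orthologs under another species; default 0.
#' @param seed Integer seed.
#' @return A tibble `accession`, `species`, `sequence`, `is_decoy`,
#'   `ortholog_of` (`NA` except for ortholog entries).
#' @export
generate_database <- function(n_proteins, decoy_fraction = 0.5,
                              length_range = c(120, 400),
                              species_mix = c("Gossypium hirsutum" = 0.6,
                                              "Gossypium barbadense" = 0.25,
                                              "Gossypium arboreum" = 0.15),
                              ortholog_fraction = 0,
                              seed = 1L) {
  stopifnot(n_proteins >= 1)
  if (decoy_fraction < 0 || decoy_fraction > 1) {
    stop("decoy_fraction must be in [0, 1]", call. = FALSE)
  }
  withr::with_seed(seed, {
    n_decoy <- round(n_proteins * decoy_fraction)
    n_target <- n_proteins - n_decoy
    lens <- sample(length_range[1]:length_range[2], n_target, replace = TRUE)
    seqs <- vapply(lens, function(L) {
      paste(sample(amino_acids, L, replace = TRUE), collapse = "")
    }, character(1))
    species <- sample(names(species_mix), n_target, replace = TRUE,
                      prob = species_mix)
    db <- tibble::tibble(
      accession = sprintf("SYN%04d", seq_len(n_target)),
      species = species,
      sequence = seqs,
      is_decoy = FALSE,
      ortholog_of = NA_character_
    )
    if (ortholog_fraction > 0 && n_target > 0) {
      n_ort <- round(n_target * ortholog_fraction)
      idx <- sample.int(n_target, n_ort)
      other <- vapply(db$species[idx], function(sp) {
        pool <- setdiff(names(species_mix), sp)
        if (length(pool) == 0) sp else sample(pool, 1)
      }, character(1), USE.NAMES = FALSE)
      db <- dplyr::bind_rows(db, tibble::tibble(
        accession = paste0(db$accession[idx], "_ORT"),
        species = other,
        sequence = db$sequence[idx],
        is_decoy = FALSE,
        ortholog_of = db$accession[idx]
      ))
    }
    if (n_decoy > 0) {
      src <- rep_len(seq_len(max(n_target, 1L)), n_decoy)
      dseqs <- vapply(db$sequence[src], function(s) {
        paste(sample(strsplit(s, "")[[1]]), collapse = "")
      }, character(1), USE.NAMES = FALSE)
      db <- dplyr::bind_rows(db, tibble::tibble(
        accession = paste0("DECOY_", db$accession[src]),
        species = db$species[src],
        sequence = dseqs,
        is_decoy = TRUE,
        ortholog_of = NA_character_
      ))
    }
    db
  })
}

#' Generate the full ground truth for a two-condition experiment
#'
#' Assigns each target protein a base abundance (lognormal across proteins)
#' and a fold change (condition A over condition B): a `differential_fraction`
#' of targets receive `fold_change`, the rest 1. Up to
#' `peptides_per_protein` tryptic peptides per target are selected for
#' detection, each given a precursor m/z (charge 2 or 3), a fixed elution
#' width, an apex scan, and per-replicate apex intensities
#' (abundance x response factor x lognormal replicate noise at the stated
#' CV).
#'
#' @param db Database tibble from [generate_database()].
#' @param n_replicates Replicates per condition; default 3.
#' @param scans Number of MS1 scans per run; default 600 (must be >= 100).
#' @param differential_fraction Fraction of target proteins with a true fold
#'   change; default 0.2.
#' @param fold_change True A/B ratio for differential proteins; default 5.
#' @param cv Coefficient of variation of the lognormal replicate noise;
#'   default 0.1.
#' @param abundance_meanlog,abundance_sdlog Lognormal abundance parameters
#'   across proteins; defaults `log(1e6)` and 0.5.
#' @param response_factor Ion-response scale converting abundance to apex ion
#'   counts; default 1e-3.
#' @param noise_range Uniform noise-floor intensity range; default
#'   `c(0.5, 2)` ion counts, placing detected apexes at >= 50x the noise
#'   level.
#' @param peptides_per_protein Maximum detected peptides per protein;
#'   default 3.
#' @param seed Integer seed.
#' @return A `synthetic_truth` list: `db`, `proteins` (accession, abundances,
#'   `fold_change`, `is_differential`), `peptides`, `peaks` (per peptide per
#'   replicate elution parameters), `replicates`, `params`.
#' @export
generate_truth <- function(db, n_replicates = 3, scans = 600,
                           differential_fraction = 0.2, fold_change = 5,
                           cv = 0.1,
                           abundance_meanlog = log(1e6),
                           abundance_sdlog = 0.5,
                           response_factor = 1e-3,
                           noise_range = c(0.5, 2),
                           peptides_per_protein = 3,
                           seed = 1L) {
  stopifnot(scans >= 100, n_replicates >= 1, fold_change > 0)
  targets <- db[!db$is_decoy & is.na(db$ortholog_of), , drop = FALSE]
  withr::with_seed(seed, {
    n <- nrow(targets)
    abundance_b <- stats::rlnorm(n, abundance_meanlog, abundance_sdlog)
    is_diff <- seq_len(n) %in% sample.int(n, round(n * differential_fraction))
    fc <- ifelse(is_diff, fold_change, 1)
    proteins <- tibble::tibble(
      accession = targets$accession,
      abundance_a = abundance_b * fc,
      abundance_b = abundance_b,
      fold_change = fc,
      is_differential = is_diff
    )
    replicates <- tibble::tibble(
      replicate_id = c(paste0("A", seq_len(n_replicates)),
                       paste0("B", seq_len(n_replicates))),
      condition_id = rep(c("A", "B"), each = n_replicates)
    )
    peptides <- purrr::map_dfr(seq_len(n), function(i) {
      peps <- digest_tryptic(targets$sequence[i])
      if (length(peps) == 0) return(NULL)
      peps <- peps[sample.int(length(peps),
                              min(peptides_per_protein, length(peps)))]
      charge <- sample(2:3, length(peps), replace = TRUE)
      tibble::tibble(
        accession = targets$accession[i],
        peptide = peps,
        charge = charge,
        precursor_mz = unname(mapply(peptide_mz, peps, charge)),
        response = stats::runif(length(peps), 0.7, 1.3),
        width_scans = stats::runif(length(peps), 4, 6),
        apex_scan = sample(50:(scans - 50), length(peps), replace = TRUE)
      )
    })
    peaks <- tidyr::expand_grid(
      peptides[, c("accession", "peptide", "precursor_mz", "response",
                   "width_scans", "apex_scan")],
      replicates
    ) |>
      dplyr::left_join(proteins[, c("accession", "abundance_a", "abundance_b")],
                       by = "accession") |>
      dplyr::mutate(
        abundance = dplyr::if_else(.data$condition_id == "A",
                                   .data$abundance_a, .data$abundance_b),
        rep_noise = stats::rlnorm(dplyr::n(),
                                  meanlog = -log(1 + cv^2) / 2,
                                  sdlog = sqrt(log(1 + cv^2))),
        apex_intensity = .data$abundance * response_factor * .data$response *
          .data$rep_noise
      ) |>
      dplyr::select("accession", "peptide", "precursor_mz", "replicate_id",
                    "condition_id", "apex_scan", "width_scans",
                    "apex_intensity")
    structure(
      list(db = db, proteins = proteins, peptides = peptides,
           replicates = replicates, peaks = peaks,
           params = list(scans = scans, cv = cv, noise_range = noise_range,
                         response_factor = response_factor,
                         fold_change = fold_change,
                         differential_fraction = differential_fraction,
                         seed = seed)),
      class = "synthetic_truth"
    )
  })
}

#' Generate MS1 chromatograms from a ground truth
#'
#' Each peptide contributes a Gaussian elution profile at its precursor m/z
#' (apex at `apex_scan`, standard deviation `width_scans`, height
#' `apex_intensity`; peaks are emitted out to six standard deviations from
#' the apex). A noise floor of uniform-intensity peaks scattered at random
#' m/z positions — as instrument noise is in real survey scans, not aligned
#' with analyte channels — populates every scan, at an average of
#' `noise_peaks_per_scan` peaks per scan over the run's m/z range. One run
#' per replicate.
#'
#' @param truth A `synthetic_truth` from [generate_truth()].
#' @param noise_peaks_per_scan Expected noise-floor peaks per scan; defaults
#'   to the number of distinct peptide channels.
#' @param seed Integer seed (noise floor realization).
#' @return Named list of `ms1_run` objects, one per replicate.
#' @export
generate_ms1 <- function(truth, noise_peaks_per_scan = NULL, seed = 1L) {
  params <- truth$params
  scans <- params$scans
  channels <- sort(unique(truth$peaks$precursor_mz))
  if (is.null(noise_peaks_per_scan)) {
    noise_peaks_per_scan <- max(50L, length(channels))
  }
  mz_range <- if (length(channels) > 0) {
    c(min(channels) - 5, max(channels) + 5)
  } else {
    c(400, 1200)
  }
  withr::with_seed(seed, {
    runs <- purrr::map(seq_len(nrow(truth$replicates)), function(r) {
      rep_id <- truth$replicates$replicate_id[r]
      n_noise <- stats::rpois(scans, noise_peaks_per_scan)
      noise <- tibble::tibble(
        scan_number = rep(seq_len(scans), times = n_noise),
        mz = stats::runif(sum(n_noise), mz_range[1], mz_range[2]),
        intensity = stats::runif(sum(n_noise), params$noise_range[1],
                                 params$noise_range[2])
      )
      pk <- truth$peaks[truth$peaks$replicate_id == rep_id, , drop = FALSE]
      signal <- purrr::map_dfr(seq_len(nrow(pk)), function(k) {
        halfspan <- ceiling(6 * pk$width_scans[k])
        sc <- max(1, pk$apex_scan[k] - halfspan):
          min(scans, pk$apex_scan[k] + halfspan)
        tibble::tibble(
          scan_number = sc,
          mz = pk$precursor_mz[k],
          intensity = pk$apex_intensity[k] *
            exp(-((sc - pk$apex_scan[k])^2) / (2 * pk$width_scans[k]^2))
        )
      })
      peaks <- dplyr::bind_rows(noise, signal)
      peaks <- peaks[peaks$intensity > 0, , drop = FALSE]
      peaks <- peaks[order(peaks$scan_number, peaks$mz), , drop = FALSE]
      new_ms1_run(
        rep_id,
        tibble::tibble(scan_number = seq_len(scans),
                       retention_time = as.numeric(seq_len(scans))),
        peaks
      )
    })
    stats::setNames(runs, truth$replicates$replicate_id)
  })
}

#' Generate a PSM table from a ground truth
#'
#' One target PSM is emitted per (peptide, replicate) whose apex intensity
#' exceeds the detection threshold, with the scan number at the peak apex and
#' an E-value drawn from an exponential with mean `target_e_mean` (targets
#' overwhelmingly pass the 0.05 filter). Ortholog database entries replicate
#' their source protein's PSM rows with identical spectrum ids, so grouping
#' sees identical evidence. Decoy proteins receive sparse chance matches
#' (`Poisson(decoy_psm_rate)` PSMs each, random peptide and replicate) with
#' lognormal E-values centered well above the filter threshold, as random
#' matches score in practice; the tail probability of a decoy PSM passing an
#' E-value cutoff has the closed form
#' `pnorm((log(cutoff) - decoy_e_meanlog) / decoy_e_sdlog)`.
#'
#' @param truth A `synthetic_truth`.
#' @param detection_threshold Minimum apex intensity for a peptide to be
#'   matched; default 50x the mean noise-floor intensity.
#' @param target_e_mean Mean of the exponential target E-value distribution;
#'   default 0.005.
#' @param decoy_psm_rate Expected chance PSMs per decoy protein; default 2.
#' @param decoy_e_meanlog,decoy_e_sdlog Lognormal parameters of the decoy
#'   E-value distribution; defaults `log(2)` and 1.2 put about 0.1% of decoy
#'   PSMs under the 0.05 cutoff.
#' @param seed Integer seed.
#' @return A PSM tibble in the exchange dialect (see [read_psm_table()]).
#' @export
generate_psms <- function(truth,
                          detection_threshold = 50 * mean(truth$params$noise_range),
                          target_e_mean = 0.005,
                          decoy_psm_rate = 2,
                          decoy_e_meanlog = log(2),
                          decoy_e_sdlog = 1.2,
                          seed = 1L) {
  withr::with_seed(seed, {
    det <- truth$peaks[truth$peaks$apex_intensity > detection_threshold, ,
                       drop = FALSE]
    target_psms <- if (nrow(det) > 0) {
      tibble::tibble(
        spectrum_id = sprintf("%s_s%05d_%.4f", det$replicate_id,
                              det$apex_scan, det$precursor_mz),
        replicate_id = det$replicate_id,
        condition_id = det$condition_id,
        scan_number = as.integer(det$apex_scan),
        precursor_mz = det$precursor_mz,
        peptide = det$peptide,
        accession = det$accession,
        e_value = stats::rexp(nrow(det), rate = 1 / target_e_mean)
      )
    } else {
      empty_psms()
    }
    orts <- truth$db[!is.na(truth$db$ortholog_of), , drop = FALSE]
    if (nrow(orts) > 0 && nrow(target_psms) > 0) {
      dup <- target_psms[target_psms$accession %in% orts$ortholog_of, ,
                         drop = FALSE]
      dup$accession <- orts$accession[match(dup$accession, orts$ortholog_of)]
      target_psms <- dplyr::bind_rows(target_psms, dup)
    }
    decoys <- truth$db[truth$db$is_decoy, , drop = FALSE]
    decoy_psms <- purrr::map_dfr(seq_len(nrow(decoys)), function(i) {
      k <- stats::rpois(1, decoy_psm_rate)
      if (k == 0) return(NULL)
      peps <- digest_tryptic(decoys$sequence[i])
      if (length(peps) == 0) return(NULL)
      pep <- sample(peps, k, replace = TRUE)
      rep_idx <- sample.int(nrow(truth$replicates), k, replace = TRUE)
      sc <- sample.int(truth$params$scans, k, replace = TRUE)
      charge <- sample(2:3, k, replace = TRUE)
      tibble::tibble(
        spectrum_id = sprintf("%s_d%05d_%d",
                              truth$replicates$replicate_id[rep_idx], sc,
                              seq_len(k)),
        replicate_id = truth$replicates$replicate_id[rep_idx],
        condition_id = truth$replicates$condition_id[rep_idx],
        scan_number = as.integer(sc),
        precursor_mz = unname(mapply(peptide_mz, pep, charge)),
        peptide = pep,
        accession = decoys$accession[i],
        e_value = stats::rlnorm(k, decoy_e_meanlog, decoy_e_sdlog)
      )
    })
    out <- dplyr::bind_rows(target_psms, decoy_psms)
    out[order(out$replicate_id, out$scan_number, out$accession), ,
        drop = FALSE]
  })
}

#' Simulate a complete two-condition experiment
#'
#' Convenience wrapper chaining [generate_database()], [generate_truth()],
#' [generate_ms1()] and [generate_psms()]; sub-seeds are derived from the
#' single master seed.
#'
#' @param n_proteins,decoy_fraction,ortholog_fraction Database parameters.
#' @param seed Master seed; all randomness derives from it.
#' @param ... Further parameters passed to [generate_truth()].
#' @return A list `db`, `truth`, `runs`, `psms`.
#' @export
simulate_dataset <- function(n_proteins = 100, decoy_fraction = 0.5,
                             ortholog_fraction = 0, seed = 1L, ...) {
  base <- as.numeric(seed) %% (2^31 - 10)
  db <- generate_database(n_proteins, decoy_fraction = decoy_fraction,
                          ortholog_fraction = ortholog_fraction,
                          seed = base + 1)
  truth <- generate_truth(db, seed = base + 2, ...)
  runs <- generate_ms1(truth, seed = base + 3)
  psms <- generate_psms(truth, seed = base + 4)
  list(db = db, truth = truth, runs = runs, psms = psms)
}

#' Simulate an intensity matrix directly from abundances
#'
#' Bypasses chromatogram simulation: per-protein, per-replicate intensities
#' are the true abundances under lognormal replicate noise at the stated CV,
#' with a constant noise level attached. Useful for testing normalization and
#' the Monte Carlo test at scale.
#'
#' @param n_proteins Number of proteins.
#' @param n_replicates Replicates per condition.
#' @param differential_fraction,fold_change,cv As in [generate_truth()].
#' @param abundance_meanlog,abundance_sdlog Lognormal abundance parameters.
#' @param noise_level Constant noise level attached to every replicate.
#' @param seed Integer seed.
#' @return A list: `intensities` (an `lfq_intensities` tibble) and `truth`
#'   (accession, fold_change, is_differential).
#' @export
simulate_intensities <- function(n_proteins = 100, n_replicates = 3,
                                 differential_fraction = 0, fold_change = 5,
                                 cv = 0.1,
                                 abundance_meanlog = log(1e4),
                                 abundance_sdlog = 0.5,
                                 noise_level = 1,
                                 seed = 1L) {
  withr::with_seed(seed, {
    accession <- sprintf("SYN%04d", seq_len(n_proteins))
    ab_b <- stats::rlnorm(n_proteins, abundance_meanlog, abundance_sdlog)
    is_diff <- seq_len(n_proteins) %in%
      sample.int(n_proteins, round(n_proteins * differential_fraction))
    fc <- ifelse(is_diff, fold_change, 1)
    replicates <- tibble::tibble(
      replicate_id = c(paste0("A", seq_len(n_replicates)),
                       paste0("B", seq_len(n_replicates))),
      condition_id = rep(c("A", "B"), each = n_replicates)
    )
    cells <- tidyr::expand_grid(
      tibble::tibble(accession = accession, ab_b = ab_b, fc = fc),
      replicates
    ) |>
      dplyr::mutate(
        mean_ab = dplyr::if_else(.data$condition_id == "A",
                                 .data$ab_b * .data$fc, .data$ab_b),
        intensity = .data$mean_ab * stats::rlnorm(
          dplyr::n(), -log(1 + cv^2) / 2, sqrt(log(1 + cv^2))),
        imputed = FALSE
      ) |>
      dplyr::select("accession", "replicate_id", "condition_id", "intensity",
                    "imputed")
    noise_levels <- tibble::tibble(replicate_id = replicates$replicate_id,
                                   noise_level = noise_level)
    intensities <- structure(cells, noise_levels = noise_levels,
                             class = c("lfq_intensities", class(cells)))
    list(
      intensities = intensities,
      truth = tibble::tibble(accession = accession, fold_change = fc,
                             is_differential = is_diff)
    )
  })
}

#' Write a simulated dataset to disk
#'
#' Writes the database FASTA, the PSM TSV, one MS1 text file per replicate,
#' and a truth table TSV into `dir`.
#'
#' @param sim Result of [simulate_dataset()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_protein_db(sim$db, file.path(dir, "database.fasta"))
  write_psm_table(sim$psms, file.path(dir, "psms.tsv"))
  ms1_dir <- file.path(dir, "ms1")
  dir.create(ms1_dir, showWarnings = FALSE)
  purrr::walk(sim$runs, function(run) {
    write_ms1(run, file.path(ms1_dir, paste0(run$replicate_id, ".ms1")))
  })
  truth <- dplyr::left_join(
    sim$truth$proteins,
    dplyr::select(sim$db, "accession", "is_decoy"),
    by = "accession"
  )
  readr::write_tsv(truth, file.path(dir, "truth.tsv"), progress = FALSE)
  readr::write_tsv(sim$truth$replicates, file.path(dir, "replicates.tsv"),
                   progress = FALSE)
  invisible(dir)
}
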