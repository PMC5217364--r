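test_that("peptide m/z matches reference monoisotopic values", {
  # frozen from an independent proteomics mass calculator
  expect_equal(peptide_mz("PEPTIDE", 2), 400.687258, tolerance = 1e-6)
  expect_equal(peptide_mz("AAEELAK", 2), 366.200336, tolerance = 1e-6)
  expect_equal(peptide_mz("VLDPFTR", 3), 283.160594, tolerance = 1e-6)
})

test_that("tryptic digestion follows the cleave-after-K/R rule", {
  expect_equal(digest_tryptic("AAAKBBBRCCC", missed_cleavages = 0,
                              min_length = 1, max_length = 100),
               c("AAAK", "BBBR", "CCC"))
  expect_equal(
    digest_tryptic("AAAKBBBRCCC", missed_cleavages = 1, min_length = 1,
                   max_length = 100),
    c("AAAK", "AAAKBBBR", "BBBR", "BBBRCCC", "CCC")
  )
  # no K/R: the whole sequence is one peptide
  expect_equal(digest_tryptic("AAACDDD", min_length = 1), "AAACDDD")
  # default length filter 6-30
  expect_equal(digest_tryptic("AAAKBBBRCCC", missed_cleavages = 1),
               c("AAAKBBBR", "BBBRCCC"))
})

test_that("digestion equals an exhaustive enumeration oracle", {
  oracle_digest <- function(sq, mc) {
    res <- strsplit(sq, "")[[1]]
    cuts <- c(0, which(res %in% c("K", "R")), length(res))
    cuts <- unique(cuts)
    peps <- character(0)
    for (i in seq_len(length(cuts) - 1)) {
      for (j in (i + 1):length(cuts)) {
        if (j - i - 1 > mc) next
        peps <- c(peps, substr(sq, cuts[i] + 1, cuts[j]))
      }
    }
    unique(peps[nzchar(peps)])
  }
  withr::with_seed(61, {
    for (i in 1:25) {
      sq <- paste(sample(c("A", "G", "K", "R", "P", "S"),
                         sample(10:40, 1), replace = TRUE), collapse = "")
      mc <- sample(0:3, 1)
      got <- digest_tryptic(sq, missed_cleavages = mc, min_length = 1,
                            max_length = 1000)
      expect_setequal(got, oracle_digest(sq, mc))
    }
  })
})

test_that("the database splits targets and decoys as configured", {
  db <- generate_database(10, decoy_fraction = 0.5, seed = 3)
  expect_equal(sum(!db$is_decoy), 5)
  expect_equal(sum(db$is_decoy), 5)
  expect_error(generate_database(10, decoy_fraction = 1.5), "decoy_fraction")
})

test_that("decoys are residue permutations of their targets", {
  db <- generate_database(20, decoy_fraction = 0.5, seed = 13)
  decoys <- db[db$is_decoy, ]
  src <- sub("^DECOY_", "", decoys$accession)
  for (i in seq_len(nrow(decoys))) {
    target_seq <- db$sequence[db$accession == src[i]]
    expect_equal(sort(strsplit(decoys$sequence[i], "")[[1]]),
                 sort(strsplit(target_seq, "")[[1]]))
    expect_false(identical(decoys$sequence[i], target_seq))
  }
})

test_that("generation is byte-deterministic given the seed", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  sim1 <- simulate_dataset(n_proteins = 8, seed = 77, scans = 100)
  sim2 <- simulate_dataset(n_proteins = 8, seed = 77, scans = 100)
  write_dataset(sim1, d1)
  write_dataset(sim2, d2)
  for (f in c("database.fasta", "psms.tsv", "truth.tsv",
              file.path("ms1", paste0(sim1$truth$replicates$replicate_id,
                                      ".ms1")))) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
  sim3 <- simulate_dataset(n_proteins = 8, seed = 78, scans = 100)
  expect_false(identical(sim1$db$sequence, sim3$db$sequence))
})

test_that("generated MS1 files round-trip through the reader", {
  sim <- simulate_dataset(n_proteins = 6, seed = 19, scans = 100)
  d <- withr::local_tempdir()
  run <- sim$runs[[1]]
  f <- file.path(d, paste0(run$replicate_id, ".ms1"))
  write_ms1(run, f)
  back <- read_ms1(f)
  expect_equal(back$scans, run$scans)
  expect_equal(back$peaks$mz, run$peaks$mz)
  expect_equal(back$peaks$intensity, run$peaks$intensity)
})

test_that("a generated Gaussian peak integrates to its closed form", {
  db <- generate_database(4, decoy_fraction = 0, seed = 23)
  truth <- generate_truth(db, n_replicates = 1, scans = 300, cv = 0,
                          differential_fraction = 0,
                          noise_range = c(1e-9, 2e-9), seed = 23)
  runs <- generate_ms1(truth, seed = 23)
  pk <- truth$peaks[truth$peaks$replicate_id == "A1", ]
  run <- runs[["A1"]]
  for (i in seq_len(min(4, nrow(pk)))) {
    tr <- extract_trace(run, pk$precursor_mz[i], pk$apex_scan[i],
                        noise = 1e-6, max_extent = 250)
    expected <- pk$apex_intensity[i] * pk$width_scans[i] * sqrt(2 * pi)
    expect_equal(tr$area, expected, tolerance = 0.02)
  }
})

test_that("zero-abundance proteins contribute nothing beyond the noise floor", {
  db <- generate_database(4, decoy_fraction = 0, seed = 29)
  truth <- generate_truth(db, n_replicates = 1, scans = 100,
                          differential_fraction = 0, seed = 29)
  truth$peaks$apex_intensity <- 0
  runs <- generate_ms1(truth, seed = 29)
  expect_lte(max(runs[["A1"]]$peaks$intensity),
             truth$params$noise_range[2])
  # detection threshold above every apex -> empty PSM table
  psms <- generate_psms(truth, detection_threshold = 1, seed = 29)
  expect_equal(nrow(psms), 0)
})

test_that("ortholog entries duplicate their source protein's spectra", {
  sim <- simulate_dataset(n_proteins = 20, decoy_fraction = 0,
                          ortholog_fraction = 0.3, seed = 37, scans = 100)
  orts <- sim$db[!is.na(sim$db$ortholog_of), ]
  expect_gt(nrow(orts), 0)
  for (i in seq_len(nrow(orts))) {
    s_ort <- sort(sim$psms$spectrum_id[sim$psms$accession == orts$accession[i]])
    s_src <- sort(sim$psms$spectrum_id[sim$psms$accession == orts$ortholog_of[i]])
    expect_identical(s_ort, s_src)
  }
})

test_that("decoy PSMs pass the filter at the closed-form lognormal tail rate", {
  db <- generate_database(200, decoy_fraction = 0.5, seed = 43)
  truth <- generate_truth(db, scans = 100, seed = 43)
  # high chance-match rate to pin the tail fraction tightly
  psms <- generate_psms(truth, decoy_psm_rate = 50, seed = 43)
  dec <- psms[grepl("^DECOY_", psms$accession), ]
  expect_gt(nrow(dec), 3000)
  # tails at two cutoffs against the analytic lognormal CDF
  for (cutoff in c(0.05, 0.5)) {
    p_tail <- pnorm((log(cutoff) - log(2)) / 1.2)
    se <- sqrt(p_tail * (1 - p_tail) / nrow(dec)) + 1e-4
    expect_lt(abs(mean(dec$e_value <= cutoff) - p_tail), 5 * se)
  }
})

test_that("direct intensity simulation carries truth and noise levels", {
  sim <- simulate_intensities(n_proteins = 25, differential_fraction = 0.2,
                              fold_change = 4, seed = 53)
  expect_equal(nrow(sim$intensities), 25 * 6)
  expect_equal(sum(sim$truth$is_differential), 5)
  expect_true(all(sim$intensities$intensity > 0))
  nl <- attr(sim$intensities, "noise_levels")
  expect_equal(nrow(nl), 6)
  # replicate intensities track the true fold change
  agg <- dplyr::summarise(
    dplyr::group_by(sim$intensities, .data$accession, .data$condition_id),
    m = mean(.data$intensity), .groups = "drop"
  )
  wide <- tidyr::pivot_wider(agg, names_from = "condition_id",
                             values_from = "m")
  ratio <- wide$A / wide$B
  truth_fc <- sim$truth$fold_change[match(wide$accession,
                                          sim$truth$accession)]
  expect_equal(median(ratio[truth_fc == 4]), 4, tolerance = 0.2)
})
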