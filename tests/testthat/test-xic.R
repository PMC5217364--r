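test_that("noise estimate follows the sort-and-index quantile convention", {
  run <- make_run(data.frame(scan = rep(1:10, each = 10),
                             mz = rep(400 + 1:10, 10),
                             intensity = as.numeric(sample(1:100))))
  expect_equal(estimate_noise(run, quantile = 0.05), 5) # 5th of 1..100
  run2 <- make_run(data.frame(scan = 1:4, mz = rep(500, 4),
                              intensity = rep(7, 4)))
  expect_equal(estimate_noise(run2), 7) # all equal c -> c
  run0 <- make_run(data.frame(scan = 1:2, mz = c(500, 500),
                              intensity = c(0, 0)))
  expect_warning(nz <- estimate_noise(run0), "no nonzero")
  expect_equal(nz, 0)
})

test_that("a constant above-noise channel integrates over 2 x 250 + 1 scans", {
  run <- make_run(data.frame(scan = 1:600, mz = rep(500, 600),
                             intensity = rep(3, 600)))
  tr <- extract_trace(run, 500, start_scan = 300, noise = 1)
  expect_equal(tr$n_scans, 501L)
  expect_equal(tr$area, 501 * 3)
  expect_equal(tr$stopped_low, "extent-limit")
  expect_equal(tr$stopped_high, "extent-limit")
})

test_that("an isolated spike stops immediately in both directions", {
  peaks <- data.frame(scan = 1:20, mz = rep(500, 20),
                      intensity = c(rep(0.5, 9), 40, rep(0.5, 10)))
  run <- make_run(peaks)
  tr <- extract_trace(run, 500, start_scan = 10, noise = 1)
  expect_equal(tr$area, 40)
  expect_equal(tr$low_scan, 10L)
  expect_equal(tr$high_scan, 10L)
  expect_equal(tr$stopped_low, "noise")
})

test_that("a trace starting at the first scan stops at the chromatogram edge", {
  run <- make_run(data.frame(scan = 1:5, mz = rep(500, 5),
                             intensity = rep(10, 5)))
  tr <- extract_trace(run, 500, start_scan = 1, noise = 1)
  expect_equal(tr$stopped_low, "chromatogram-edge")
  expect_equal(tr$low_scan, 1L)
  expect_equal(tr$area, 50)
  expect_error(extract_trace(run, 500, start_scan = 99, noise = 1),
               "start_scan")
})

random_small_run <- function() {
  n_scans <- sample(5:50, 1)
  n_peaks <- sample(1:20, 1)
  peaks <- data.frame(
    scan = sample(n_scans, n_scans * n_peaks, replace = TRUE),
    mz = runif(n_scans * n_peaks, 400, 410),
    intensity = rexp(n_scans * n_peaks, 0.2)
  )
  make_run(peaks, n_scans = n_scans)
}

test_that("trace areas equal the brute-force double-loop oracle", {
  withr::with_seed(21, {
    for (i in 1:50) {
      run <- random_small_run()
      mz <- runif(1, 400, 410)
      start <- sample(nrow(run$scans), 1)
      noise <- runif(1, 0, 5)
      hw <- sample(c(0.2, 0.5, 1), 1)
      me <- sample(c(3, 10, 250), 1)
      tr <- extract_trace(run, mz, start, noise, halfwidth = hw,
                          max_extent = me)
      expect_equal(tr$area, oracle_trace_area(run, mz, start, noise, hw, me))
    }
  })
})

test_that("trace area is monotone in halfwidth and max_extent", {
  withr::with_seed(22, {
    for (i in 1:15) {
      run <- random_small_run()
      mz <- runif(1, 400, 410)
      start <- sample(nrow(run$scans), 1)
      a1 <- extract_trace(run, mz, start, 0.1, halfwidth = 0.2)$area
      a2 <- extract_trace(run, mz, start, 0.1, halfwidth = 0.8)$area
      expect_gte(a2, a1)
      b1 <- extract_trace(run, mz, start, 0.1, max_extent = 2)$area
      b2 <- extract_trace(run, mz, start, 0.1, max_extent = 30)$area
      expect_gte(b2, b1)
    }
  })
})

test_that("same-m/z PSMs are integrated once and dedup is idempotent", {
  peaks <- data.frame(scan = 1:30, mz = rep(500, 30),
                      intensity = c(rep(0, 10), 5, 50, 90, 50, 5,
                                    rep(0, 15)))
  run <- make_run(peaks, replicate_id = "rep1")
  db <- tibble::tibble(accession = "P1", species = "Gossypium hirsutum",
                       sequence = "AAEELAKVLDPFTR", is_decoy = FALSE)
  psms <- dplyr::bind_rows(
    make_psm("s1", "AAEELAK", "P1", scan_number = 12, precursor_mz = 500),
    make_psm("s2", "AAEELAK", "P1", scan_number = 13, precursor_mz = 500.005)
  )
  prot <- tibble::tibble(accession = "P1")
  reps <- tibble::tibble(replicate_id = "rep1", condition_id = "A")
  one <- quantify_proteins(psms, prot, list(run), reps, noise_quantile = 0.5)
  single <- quantify_proteins(psms[1, ], prot, list(run), reps,
                              noise_quantile = 0.5)
  expect_equal(one$intensity, single$intensity) # second PSM added nothing
  # distinct m/z channels DO sum
  run2 <- make_run(data.frame(scan = rep(1:30, 2), mz = rep(c(500, 600), each = 30),
                              intensity = rep(c(rep(0, 10), 5, 50, 90, 50, 5,
                                                rep(0, 15)), 2)),
                   replicate_id = "rep1")
  psms2 <- dplyr::bind_rows(
    psms[1, ],
    make_psm("s3", "VLDPFTR", "P1", scan_number = 13, precursor_mz = 600)
  )
  both <- quantify_proteins(psms2, prot, list(run2), reps,
                            noise_quantile = 0.5)
  expect_gt(both$intensity, one$intensity)
  nz <- estimate_noise(run2, 0.5)
  expect_equal(both$intensity,
               oracle_trace_area(run2, 500, 12, nz) +
                 oracle_trace_area(run2, 600, 13, nz))
})

test_that("proteins absent from a replicate are imputed at its noise level", {
  run_a <- make_run(data.frame(scan = 1:20, mz = rep(500, 20),
                               intensity = c(rep(2, 9), 100, 80, rep(2, 9))),
                    replicate_id = "A1")
  run_b <- make_run(data.frame(scan = 1:20, mz = rep(500, 20),
                               intensity = rep(4, 20)),
                    replicate_id = "B1")
  psms <- make_psm("s1", "AAEELAK", "P1", replicate_id = "A1",
                   scan_number = 10, precursor_mz = 500) |>
    dplyr::bind_rows(make_psm("s2", "VLDPFTR", "P1", replicate_id = "A1",
                              scan_number = 11, precursor_mz = 500.9))
  prot <- tibble::tibble(accession = "P1")
  reps <- tibble::tibble(replicate_id = c("A1", "B1"),
                         condition_id = c("A", "B"))
  out <- quantify_proteins(psms, prot, list(run_a, run_b), reps,
                           noise_quantile = 0.5)
  b_cell <- out[out$replicate_id == "B1", ]
  expect_true(b_cell$imputed)
  expect_equal(b_cell$intensity, 4) # the replicate's noise level
  expect_false(out$imputed[out$replicate_id == "A1"])
  # every cell strictly positive when noise > 0
  expect_true(all(out$intensity > 0))
})
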