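# Independent brute-force oracles and small fixture builders. These share no
# logic with the implementation: coverage marks coordinates by exhaustive
# position scan, trace areas come from a double loop over scans and peaks,
# and grouping buckets by frozen spectra-set keys.

# Build an ms1_run from a scans x n matrix-like spec: `peaks` is a data frame
# with scan, mz, intensity; scan numbers default to 1..n_scans.
make_run <- function(peaks, n_scans = max(peaks$scan), replicate_id = "r1",
                     scan_numbers = seq_len(n_scans)) {
  new_ms1_run <- getFromNamespace("new_ms1_run", "lfqmc")
  new_ms1_run(
    replicate_id,
    tibble::tibble(scan_number = scan_numbers,
                   retention_time = as.numeric(scan_numbers)),
    tibble::tibble(scan_number = scan_numbers[peaks$scan], mz = peaks$mz,
                   intensity = peaks$intensity)
  )
}

# Exhaustive position-marking coverage oracle.
oracle_coverage <- function(sequence, peptides) {
  n <- nchar(sequence)
  marked <- rep(0L, n)
  for (pep in peptides) {
    w <- nchar(pep)
    if (w == 0 || w > n) next
    for (s in seq_len(n - w + 1)) {
      if (substr(sequence, s, s + w - 1) == pep) {
        marked[s:(s + w - 1)] <- 1L
      }
    }
  }
  100 * sum(marked) / n
}

# Brute-force trace-area oracle: double loop over scans and peaks, walking
# outward one scan at a time with no shared helper code.
oracle_trace_area <- function(run, mz, start_scan, noise, halfwidth = 0.5,
                              max_extent = 250) {
  sn <- run$scans$scan_number
  chan <- vapply(sn, function(s) {
    tot <- 0
    for (i in seq_len(nrow(run$peaks))) {
      if (run$peaks$scan_number[i] == s &&
          abs(run$peaks$mz[i] - mz) <= halfwidth) {
        tot <- tot + run$peaks$intensity[i]
      }
    }
    tot
  }, double(1))
  i0 <- which(sn == start_scan)
  area <- chan[i0]
  for (d in seq_len(max_extent)) {       # backward
    j <- i0 - d
    if (j < 1 || chan[j] <= noise) break
    area <- area + chan[j]
  }
  for (d in seq_len(max_extent)) {       # forward
    j <- i0 + d
    if (j > length(sn) || chan[j] <= noise) break
    area <- area + chan[j]
  }
  area
}

# Brute-force grouping oracle: bucket proteins by frozen spectra-set key and
# apply the retention rules exhaustively.
oracle_groups <- function(proteins, preferred = "Gossypium hirsutum") {
  keys <- sapply(proteins$spectra, function(s) paste(sort(s), collapse = "|"))
  buckets <- split(seq_len(nrow(proteins)), keys)
  res <- lapply(buckets, function(ix) {
    accs <- sort(proteins$accession[ix])
    pref <- sort(proteins$accession[ix][proteins$species[ix] == preferred])
    retained <- if (length(pref) > 0) pref else accs[1]
    list(members = accs, retained = retained, representative = retained[1])
  })
  res[order(sapply(res, `[[`, "representative"))]
}

# Random protein list with deliberately shared spectra sets.
random_protein_list <- function(n, species_pool = c("Gossypium hirsutum",
                                                    "Gossypium barbadense",
                                                    "Gossypium arboreum")) {
  n_sets <- max(1, rbinom(1, n, 0.6))
  sets <- lapply(seq_len(n_sets), function(i) {
    paste0("spec", sample(1000, sample(2:6, 1)))
  })
  tibble::tibble(
    accession = sprintf("P%03d", sample(999, n)),
    species = sample(species_pool, n, replace = TRUE),
    spectra = sets[sample(n_sets, n, replace = TRUE)]
  )
}

# Tiny in-memory protein database for assembly tests.
tiny_db <- function() {
  tibble::tibble(
    accession = c("P1", "P2", "P3"),
    species = c("Gossypium hirsutum", "Gossypium barbadense",
                "Gossypium hirsutum"),
    sequence = c("AAEELAKVLDPFTRGGSSEPK", "GGSSEPKAAEELAK",
                 "MKTAYIAKQRQISFVK"),
    is_decoy = FALSE
  )
}

make_psm <- function(spectrum_id, peptide, accession, e_value = 0.01,
                     replicate_id = "rep1", condition_id = "A",
                     scan_number = 100L, precursor_mz = 500.0) {
  tibble::tibble(
    spectrum_id = spectrum_id, replicate_id = replicate_id,
    condition_id = condition_id, scan_number = as.integer(scan_number),
    precursor_mz = precursor_mz, peptide = peptide, accession = accession,
    e_value = e_value
  )
}
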