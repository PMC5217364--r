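---
title: "Label-free quantification and Monte Carlo differential expression: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Label-free quantification and Monte Carlo differential expression: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lfqmc)
```

`lfqmc` implements a post-search workflow for label-free shotgun
proteomics: PSM filtering with target-decoy FDR, protein assembly and
grouping, extracted-ion-chromatogram (XIC) quantification, mode-based
normalization, and a Monte Carlo resampling test for differential
expression. This vignette explains the model behind each stage, the
tunable parameters and their defaults, the numerical choices made where
the procedure is underdetermined, and what the synthetic-data generator
does and does not emulate.

## Identification

PSMs arrive as a table (one row per PSM-accession pair) carrying the
peptide sequence, protein accession, precursor m/z, scan number, and an
E-value from the search engine. Two filters apply:

* **E-value filter** (`filter_psms()`, default threshold 0.05). The
  discard rule is *strictly greater than*: a PSM at exactly the threshold
  is retained. The boundary matters only for ties, but it is fixed and
  tested.
* **Two-peptide rule** (`assemble_proteins()`, default
  `min_distinct_peptides = 2`). "Single-peptide" is read as a single
  *distinct peptide sequence*: three spectra all matching one peptide do
  not rescue a protein. Requiring two independent sequences is the
  standard guard against one-hit wonders.

The decoy FDR (`estimate_fdr()`) is the ratio of decoy to target proteins
passing identical filters, computed at the protein level because the
filters themselves operate on the assembled protein list; a PSM-level
variant is available via `level = "psm"`. Coverage uses the zero-array
method — mark every residue covered by any *occurrence* (overlapping
occurrences included) of any matched peptide — with exact, case-sensitive
matching; isoleucine and leucine are not equated.

## Grouping

Database entries matched by an identical *set of spectrum ids* are
redundant: `group_proteins()` partitions proteins on exact spectra-set
equality. A group with members from the preferred species (default
`"Gossypium hirsutum"`) retains all of them, since same-species entries
with identical evidence are plausibly isoforms; otherwise one
representative is retained. Subset relations between spectra sets do
**not** group — parsimony inference is deliberately out of scope. Where
the retention rule is underdetermined (which member represents the
group), the lexicographically smallest accession wins, making the output
invariant under input permutation.

## XIC quantification

For a PSM with precursor m/z $m$ and scan $s_0$, the channel intensity at
scan $s$ is the sum of peak intensities within $|mz - m| \le h$ (default
half-width $h = 0.5$ Th, i.e. a 1-Da-wide window: "within a 1-Da
tolerance" is read as bounding the window's total width, and $h$ is
configurable). The trace walks from $s_0$ outward in both directions,
including scans while the channel exceeds the run's noise level, and
stopping — exclusively, the terminating scan is not counted — at the first
scan at or below noise, after 250 scans per direction, or at the
chromatogram edge. The start scan is always included, so the area is
positive whenever the identified scan has signal.

Choices worth knowing:

* **Noise level** (`estimate_noise()`): the procedure needs a
  "chromatogram noise level" without defining an estimator. We use the
  5th percentile (inverse-empirical-CDF convention) of all nonzero peak
  intensities of the run — one scalar per replicate that serves three
  roles: trace stopping, missing-value substitution, and the Monte Carlo
  lower draw bound. The quantile is configurable.
* **Deduplication**: PSMs whose precursor m/z differ by at most 0.01 Th
  (configurable) are the "same precursor"; classes are formed greedily on
  ascending m/z and the earliest-scan PSM represents each class, so the
  same elution integral is never summed twice. Deduplication can only
  decrease a protein's intensity and is idempotent.
* **Distance is counted in scan indices**, not retention time.
* **Imputation**: a protein with no PSM in a replicate — or whose traces
  integrate to zero — receives the replicate's noise level and is flagged
  in the imputation mask. The substitution reflects that an unidentified
  peptide may sit at or below the noise floor, and it keeps every cell
  strictly positive so downstream ratios never divide by zero.

## Normalization

Each replicate is divided by its intensity mode. For continuous
intensities the mode must be estimated: we histogram $\log_{10}$
intensities in fixed bins of width 0.1 anchored at 0 and return
$10^{\text{center of the most populated bin}}$, ties broken toward the
lower bin. Consequences: (i) the mode is insensitive to the extreme
minimum and maximum intensities, which is the point of mode-based
normalization; (ii) the raw modal bin maps onto
$[10^{-0.05}, 10^{0.05})$ around 1 after normalization; (iii) the
normalized value of an all-equal replicate is 1 only up to bin
granularity (about ±12%), a deliberate trade for a deterministic,
binning-based estimator; (iv) scaling a replicate by an integer power of
ten shifts its bins exactly, so such scaling leaves every downstream
ratio and p-value unchanged (tested). Bin width is configurable.

## Monte Carlo differential expression

For each protein the observed ratio is $\bar{x}_A / \bar{x}_B$ over
normalized replicate intensities. Under the resampling null, each
iteration draws one uniform value per replicate from
$[\text{noise}_{\min}, \text{intensity}_{\max}]$ and forms the random
ratio; the tallies of random ratios strictly above and strictly below the
observed one are recorded (exact ties count as neither). The procedure's
published description does not fix the p-value formula; we use the
two-sided, add-one-guarded form

$$p = \min\!\Big(1,\; \frac{2(\min(c_{\text{above}}, c_{\text{below}}) + 1)}{n + 1}\Big),$$

which cannot reach 0, is symmetric in direction, and converges to the
analytic exceedance probability (verified against numerical integration
for the 1-vs-1 design). The draw bounds are per protein by default — the
minimum normalized noise level among its replicates and its own maximum
normalized intensity — because the comparison is per protein; a
`bounds = "global"` switch uses matrix-wide bounds instead. Per-protein
seeds derive from the master seed and the protein's position in sorted
accession order, so results are reproducible and independent of row
order. Significance is `p <= alpha` (default 0.05, inclusive); no
multiple-testing correction is applied, matching the original procedure.
The default iteration count is one million; the test suite uses 2,000 to
10,000 iterations, which changes only the p-value granularity, not the
procedure.

## The synthetic-data generator

Because no raw spectra are deposited for the study this workflow
originates from, the generator produces every input with known ground
truth:

* **Database**: uniform random sequences over the 20-letter alphabet
  (120–400 residues), species tags drawn from a configurable *Gossypium*
  mix, decoys as residue-shuffled copies (same composition, `DECOY_`
  prefix), and optionally same-sequence ortholog entries under another
  species to exercise grouping.
* **Truth**: per-protein abundances lognormal across proteins
  (`meanlog = log(1e6)`, `sdlog = 0.5`); a configurable fraction of
  proteins (default 0.2) carries a true fold change (default 5); replicate
  noise is lognormal with CV 10% — a typical technical-replicate spread
  for label-free LC-MS. Three replicates per condition by default.
* **Chromatograms**: each detected peptide contributes a Gaussian elution
  peak (σ of 4–6 scans, apex ∝ abundance) at its computed precursor m/z
  (monoisotopic residue masses, charge 2 or 3). The noise floor consists
  of uniform-intensity peaks (0.5–2 counts) scattered at *random* m/z
  positions, as instrument noise is in real survey scans — deliberately
  not aligned with analyte channels, since a channel-aligned floor would
  sum to more than the per-peak noise estimate inside every 1-Da window
  and traces would never terminate. Default response scaling places
  detected apexes at ≥ 50× the mean noise intensity.
* **PSMs**: one per (peptide, replicate) above the detection threshold,
  at the apex scan; target E-values exponential with mean 0.005 (passing
  the 0.05 filter almost surely), decoy E-values lognormal
  (`meanlog = log 2`, `sdlog = 1.2`), putting roughly 0.1% of decoy PSMs
  under the cutoff — random matches overwhelmingly fail, as in a real
  well-separated search. Tails of both distributions are closed-form and
  tested.
* **Digestion** cleaves after K/R with up to 2 missed cleavages and a
  6–30 residue length filter; the proline exception and modifications are
  ignored — the generator exists to exercise quantification, not search
  realism.

All randomness flows from explicit seeds; identical seeds give
byte-identical files.

What the generator does **not** emulate — and therefore what passing
tests do not establish about real data: retention-time drift and
alignment, isotope envelopes and charge-state coelution, peak tailing,
interference between coeluting peptides of similar m/z (possible but rare
under the default channel density), intensity-dependent detection
(missingness is threshold-based, not stochastic), and search-engine score
calibration.

## Problem sizes and calibration checks

The suite checks, among others: exact equivalence of the trace integrator
and the coverage calculator against brute-force oracles (500 randomized
cases each); grouping against an exhaustive bucketing oracle (200
randomized lists, with permutation invariance); a 200-protein null
calibration at 3 vs 3 replicates and 10,000 iterations (fraction called
at α = 0.05 stays under 0.10 — the bounded-uniform null is conservative,
so p-values lean high rather than uniform); and recovery of 50 truly
5-fold-changed proteins through the full MS1 pipeline at CV 10%
(sensitivity ≥ 80%, median ratio within ±30% of 5). The recovery dataset
embeds the changed proteins in a majority of unchanged ones: mode
normalization estimates the typical intensity from the bulk, so a fold
change shared by *every* protein would be absorbed into the mode — a
known property of any bulk-anchored normalization, not a defect of the
implementation. The background is also what stabilizes the mode itself:
with bins of width 0.1 log10 units, a histogram over only ~100 proteins
has modal-bin noise of one or two bins (a 25–60% multiplicative swing),
so recovery runs use 600 database entries (300 targets) and 500 scans —
large enough for stable modes, small enough that the whole suite runs
comfortably on a laptop.

## Known limitations

* Mode binning quantizes the normalization factor to factors of
  $10^{0.1}$; ratio estimates inherit up to one-bin jitter per replicate
  (visible as ±10–20% spread in recovered fold changes).
* The bounded-uniform Monte Carlo null is conservative: for small true
  changes its power is low, and null p-values concentrate near 1 rather
  than being uniform. It matches the original procedure; it is not a
  calibrated frequentist test.
* No retention-time alignment, peak-shape fitting, or isotope
  deconvolution: quantification trusts the PSM's scan and m/z.
* Protein inference is identity-of-evidence grouping only; shared-peptide
  (subset) relationships are not resolved.
* No multiple-testing correction, by design; treat the significant list
  as the original procedure's `p ≤ 0.05` call, not an FDR-controlled set.
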