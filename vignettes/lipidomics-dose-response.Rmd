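---
title: "Semi-quantitative lipidomics and the dose-response biomarker screen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Semi-quantitative lipidomics and the dose-response biomarker screen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lipidscreen)
```

## The measurement model

`lipidscreen` processes centroided, polarity-switching LC-MS acquisitions in
which lipids are semi-quantified against a panel of thirteen deuterated
internal standards spiked at a known working concentration (5 µM). The chain
has five stages, each of which is an exported function so that every
intermediate can be inspected:

1. **Target construction** (`build_target_list()`). Each analyte or standard
   is represented by the set of ions it is expected to produce. For labelled
   standards these are computed from the elemental formula: the monoisotopic
   mass with `n_deuterium` H positions replaced by D, each listed adduct
   ([M+H]^+^, [M+H-H~2~O]^+^, [M+NH~4~]^+^, [M+Na]^+^, [M+K]^+^, [M-H]^-^),
   and a deuterium-loss isotopologue series (commercial labels are mixtures of
   label counts; consecutive isotopologues differ by
   m~D~ - m~H~ = 1.0062767 Da). Standards with 30 or more deuteriums get a
   three-ion series per adduct, lighter labels a single ion; this depth
   reproduces the ion counts of the packaged standard sheet, which also
   carries the instrument's explicit product lists and is used verbatim when
   present. Endogenous analytes' formulas are not modelled; their product m/z
   values are supplied directly in the analyte sheet.
2. **EIC extraction** (`extract_eic()`). Per scan of the matching polarity,
   intensities of all centroids within a ppm window of any product ion are
   summed into one trace. The default window is ±10 ppm, a conventional
   choice for Orbitrap-class resolution (25,000 at m/z 200); the instrument
   resolution bounds it but no sharper value is identifiable from the assay
   description, so it is a tunable argument.
3. **Peak integration** (`integrate_peak()`). The apex is the trace maximum
   within ±0.5 min of the expected retention time. An apex drifting more than
   the tolerance (default ±0.1 min) from the expected time means the signal
   cannot be attributed to the analyte: the result is *Not Found* (zero area,
   zero concentration), not an error. Integration bounds walk outward from
   the apex while the trace is non-increasing — descending through plateaus,
   stopping at the valley before a neighbouring peak — capped at ±0.2 min
   (4 peak sigmas at the default chromatography width), and the area is the
   trapezoidal integral. The non-increasing (rather than strictly
   decreasing) walk matters: a symmetric peak sampled symmetrically produces
   two equal apex points, and a strict walk would stop between them.
4. **Normalisation** (`area_ratio()`, `blank_correct()`). Analyte areas are
   divided by the class-matched internal standard's area in the same
   injection, cancelling extraction and instrument variation. Area ratios
   below 3× the blank level are censored to zero; the blank statistic is the
   mean of the blank injections by default ("max" is available as a more
   conservative option, since only "the blank samples" is specified). The
   drift rule is applied before blank correction: a *Not Found* from drift is
   an integration outcome, not a background subtraction. Blank correction
   operates on area ratios (the object the normalisation step produces); the
   assay description mixes "ratios" and "intensities" in one sentence, and
   the ratio reading is the one consistent with correcting after
   normalisation.
5. **Concentration** (`to_concentration()`). Single-point semi-quantitation:
   ratio × c~IS~; tissue samples are divided by the extracted mass (units
   amount per mg), fluid samples stay molar. The packaged study table is in
   nM/mg; the pipeline keeps an explicit unit field rather than silently
   rescaling between the µM/mg and nM/mg readings that appear in different
   places.

Atomic masses are pinned in-code (C 12, H 1.0078250319, D 2.0141017780, N
14.0030740052, O 15.9949146221, P 30.97376151, Na 22.98976928, K
38.9637064864) and charge carriers use the proton-mass convention
([M+H]^+^ = +1.007276, [M+NH~4~]^+^ = +18.033823, ...): these choices
reproduce the packaged standards' printed ions to ≤1 mDa. Three printed
values resist any adduct/isotopologue decomposition from the formulas (the
phosphocholine standard's protonated pair, one sphingomyelin protonated ion,
and one phosphoethanolamine entry that equals the neutral mass); each
standard's designated primary ion is therefore the full-label ion of an
adduct that does verify, recorded explicitly in the standards sheet.

## Lipid nomenclature

Species are named in summed-composition shorthand, `Class_(C:D)`: total
fatty-acyl carbons, a colon, total double bonds, with `-OH` and `-2COOH`
modifier suffixes. Acyl-carnitines zero-pad and C-prefix the carbon count
(`Carn_(C03:0)`) and count only the acyl chain, not the carnitine backbone.
One plasmalogen dialect occurs (`PC_C18(plas)-18:1`, treated as PC with 36
carbons, 1 double bond). `format_lipid_name()` preserves the zero-padding of
the original spelling, so parsing round-trips every name in the packaged
table bit-identically.

A species is *odd-chain* when its summed carbon count is odd. With only
summed compositions, an odd total implies at least one odd-chain fatty acyl;
the converse does not hold (two odd chains sum to even), so the odd total is
a conservative proxy — the standard one for this nomenclature, though no
explicit rule accompanies the study table.

Classes map to internal standards one-to-one except acyl-carnitines, which
list a short-chain (d7 butyryl) and a long-chain (d3 palmitoyl) standard with
no stated split; the package assigns acyl chains of ≤8 carbons to the
short-chain standard (hydrophobicity match), configurable via
`carnitine_cutoff`.

## The dose-response screen

`lipid_screen()` is the package's model-fitting core, in the classic R
idiom: it returns a classed object with `print()`, `summary()`, `coef()`,
`predict()`, `residuals()` and `plot()` methods. Per lipid it fits ordinary
least squares of the *group mean* concentrations on the dietary beef-tallow
percentage (3.6, 6.3, 9.0, 11.7). The choice of group means rather than
per-animal values — hence df = 2 with four groups — is deliberate: the
printed slope ± SE pairs and their significance values (0.197, 0.0189,
0.0195) are reproduced exactly by t = slope/SE at df = 2, and the packaged
table's trendlines are recovered at printed precision from the group means
alone. Slope significance is the two-sided Student-t tail; all-equal means
take the degenerate convention slope 0, R² = 0, p = 1.

A biomarker call requires all of:

* slope p < 0.05 (two-sided, df = n_groups − 2),
* R² strictly greater than 0.75,
* strictly monotone group means across *all* groups ("successive change").

Not-detected (ND) group means are missing, never zero: a lipid is fitted only
when at least three group means are observed, and any ND disqualifies the
successive-change criterion, because monotonicity across the full dose range
cannot be established. The printed table is not fully self-consistent on
this point (rows with a trailing ND sometimes carry a direction label, rows
with an interior ND do not); requiring a complete group vector is the rule
that reproduces the printed highlight set exactly — 100 lipids flagged, 35
increasing, 65 decreasing — and is the stricter, more defensible choice. No
multiple-testing correction is applied (matching the source analysis); the
object records the number of tests so users can apply their own.

`compare_groups()` provides the companion two-group statistics (percent
difference of means, per-group CVs, Welch's t, and the `*`/`**`/`***` star
convention at 0.05/0.01/0.001).

## Mol% and the closure artifact

Expressing lipid data as relative compositions (Mol%) normalises each sample
to its total lipid, but closes the data: the components become
interdependent, and a real change in one part induces opposite apparent
changes in the others. `artifact_report()` makes this concrete for the
odd/even-chain split. Mol% is computed per sample over the two-part closure
(odd + even = 100) and then averaged per group; computing shares before
averaging is the order that respects per-sample normalisation, and for the
two-part case the fitted slopes are identical under either order. Because
each sample's two shares sum to 100, the fitted Mol% slopes are exactly
equal and opposite with identical R² and p — so when the even-chain pool
genuinely falls and the odd-chain pool is flat, the odd-chain Mol% trend is
significantly *positive*: a pure artifact. The screen therefore operates in
absolute concentration space; log-ratio (CLR/ILR) methods are out of scope,
as the point here is the contrast between absolute and Mol% readings, not a
compositional reanalysis.

## Synthetic data: what it emulates and what it does not

`simulate_concentrations()` generates per-animal cohorts: value =
max(0, intercept + slope × dose + N(0, sd)), with per-group SDs available so
cohorts can mirror the packaged table's mean ± SD structure (see
`trend_specs_from_fixture()`), and ND censoring recorded as missing. The
truncation at zero is needed because several printed SDs are comparable to
their means; it biases low-mean groups slightly upward, which the recovery
tests allow for. A log-normal option matches mean and SD on the natural
scale for strictly positive data. `simulate_scan_series()` emulates the
acquisition: alternating-polarity scans every 0.25 s per mode (a 4 Hz
instrument over a 10 min run by default), Gaussian elution profiles
(sigma 0.05 min by default) at every product m/z with height proportional to
amount, an optional uniform noise floor, and per-analyte retention-time
shifts for drift scenarios; blanks are series whose amounts are the
contamination level.

The generators are deliberately idealised: no ion suppression or matrix
effects, no extraction-efficiency differences between protocols, no
natural-abundance isotope patterns, no m/z calibration error, single charge
states only. Tests passing on this synthetic data therefore demonstrate the
correctness of the processing arithmetic and decision rules — linearity,
censoring semantics, recovery of configured amounts to within integration
error — not robustness to real-matrix pathologies.

Problem sizes in the shipped tests are chosen for tight feedback: cohorts of
9 animals × 4 groups (the study design), 100-replicate seed sweeps for the
stochastic properties, a 1000-lipid null table for the false-positive rate,
and an end-to-end assay of six analytes, five standards and three injections
over a 6.5 min synthetic run.

## Numerical choices and degenerate inputs

* Trapezoidal integration on the simulated sampling grid recovers a Gaussian
  peak area to well under 2%.
* Strictness: R² > 0.75 and p < 0.05 are strict inequalities; a fit at
  exactly the threshold fails. Ties in group means break monotonicity.
* Zero-variance responses: slope 0, R² 0, p 1 (avoids 0/0).
* Exactly collinear three-point fits (possible with ND rows) have zero
  residual variance; the t statistic is then infinite and p effectively 0,
  which is accepted rather than warned about.
* Blank correction with all-zero blanks censors nothing; with no blanks it
  warns and is skipped, recorded in the run provenance.
* `area_ratio()` treats a missing internal standard as a sample-level
  quantitation failure (error / `is_missing` flag), never as a zero.
* The packaged study table is checksummed (MD5) and refused on mismatch.

## Known limitations

* Quantitation is single-point (one internal standard per class, unit
  response assumed); no calibration curves, so accuracy across classes
  depends on response-factor similarity, as in any semi-quantitative assay.
* The screen models group means, not per-animal variation: it reproduces the
  source analysis but discards within-group information a mixed model would
  use.
* The odd-chain proxy misclassifies species whose two odd chains sum to an
  even total.
* mzML reading requires centroided MS1 data and takes polarity from the scan
  headers; profile-mode centroiding and cross-run retention-time alignment
  are out of scope.
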