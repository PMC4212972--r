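---
title: "Functional analysis of camera-trap emissions: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Functional analysis of camera-trap emissions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(camtrapemit)
```

## The measurement model

A sound analyser pointed at a triggered camera trap reports, for each
one-third-octave band, the maximum unweighted level observed during the
recording window (L_ZFmax, dB re 20 µPa). One recording therefore yields a
*curve*: level as a function of band center frequency. `camtrapemit` treats
that curve as the unit of observation. Replicate units of the same camera
model form a `curve_set`; the background noise floor of the measurement room
is just another group of curves recorded with no camera present.

The band grid is the nominal preferred-number series (12.5, 16, 20, 25,
31.5, ... Hz), not the exact base-ten centers (12.589...), because that is
how analysers label bands and how levels are reported in the acoustics
literature. The default grid spans 12.5 Hz to 20 kHz and has exactly 33
centers. Instrument documentation sometimes quotes other counts for partial
ranges; the package fixes the audible-range grid at 33 bands and validates
every input file against it, so a missing or off-grid band is a hard format
error naming the unit and frequency rather than a silently shorter curve.

Working on the discrete band grid is a deliberate choice: no basis
expansion or smoothing is applied. The curves are already band-integrated
by the instrument, and 33 points per curve is too coarse for spline
machinery to add anything but assumptions.

## Bootstrap envelopes

`bootstrap_envelope()` resamples **whole curves** with replacement
(`n_boot = 9999` by default) and takes pointwise empirical quantiles
(α/2, 1 − α/2) of the bootstrap mean curves. Resampling curves rather than
individual band values preserves the within-curve correlation structure
without modelling it.

Two consequences of the percentile construction are worth knowing:

* The bands are **pointwise**, not simultaneous: the probability that the
  envelope covers the true mean at any *given* band is about 95%, but the
  probability that it covers the whole curve everywhere at once is lower.
  Per-frequency envelopes are the standard presentation for spectral data
  and are what the plotting conventions in this field show.
* At small sample sizes percentile intervals run **narrow**. The bootstrap
  distribution of the mean has SD ≈ s·√((n−1)/n)/√n and s itself is biased
  low, so at n = 10 Gaussian curves the realized per-band coverage of a
  nominal 95% envelope is about 0.89–0.90, approaching 0.95 as n grows.
  The test suite checks coverage against this *achievable* value (computed
  with an independent Monte-Carlo oracle), not against the nominal label.

Degenerate cases are defined, not excluded: a single curve yields a
zero-width envelope equal to itself, as do identical replicates. The
pointwise ordering lower ≤ mean ≤ upper is enforced by construction.

## Permutation t-max tests

`functional_t_test()` uses the Welch (unpooled) absolute t statistic per
band. Unpooled variances were chosen because replicate counts per camera
model are routinely unequal (10 units of one model, 3 of another), where a
pooled statistic would let the better-replicated group dominate the
denominator.

The global statistic is t_max, the maximum of |t(f)| over bands. Group
labels are randomly permuted (`n_perm = 999` by default); the test returns

* a **critical curve** — the per-band (1 − α) quantile of permuted |t(f)|,
  useful for seeing *where* along the spectrum two groups separate, and
* a **global p-value** with the add-one convention,
  p = (1 + #{perm: max |t| ≥ t_max}) / (n_perm + 1), whose floor is
  1/(n_perm + 1). The observed labelling counts as one permutation; p = 0
  is impossible by design. Note that random permutation can re-draw the
  original labelling, so even totally separated groups can report a value
  one notch above the floor.

Permutations are always random, never exhaustive, even when the group sizes
would allow enumeration — the exhaustive enumeration exists in the test
suite as an independent oracle instead. Rows are put in a canonical order
before permuting, so the result is invariant to how the replicate units
happen to be listed in the input file.

Zero-variance bands (possible with synthetic or quantised data) contribute
t = 0 when the group means agree; when they disagree the formally infinite
statistic is capped at the largest finite |t| in the same curve, which
preserves "this band separates the groups maximally" without propagating
infinities into quantiles.

`run_pairwise_contrasts()` runs every unordered pair (k(k−1)/2 rows, input
order) and adjusts the global p-values with the Benjamini–Hochberg step-up
rule via `stats::p.adjust`. BH rather than the more conservative
Benjamini–Yekutieli form: the contrasts share data between rows, but BH is
the field's default for this kind of screening table and is what "false
discovery rate adjustment" means in practice. Per-pair seeds are derived as
`seed + pair index`, so one integer reproduces the entire table.

## Comparing emissions with hearing

Species-level hearing data come in two fidelities, and the package keeps
them distinct:

* **Hearing ranges** (an audible interval in Hz). `hearing_overlap()`
  intersects the interval with the analysis band. One bundled species has
  an unknown lower bound; it is conservatively assumed to hear down to the
  bottom of the analysis band and the result carries an `assumed_low` flag.
* **Audiograms** (threshold in dB versus frequency).
  `audibility_margin()` interpolates the threshold onto the band grid
  *linearly in log₁₀ frequency* — audiograms are measured at roughly
  log-spaced frequencies, so linear-in-Hz interpolation would bow the curve
  between low-frequency points — and never extrapolates beyond the
  audiogram's support: bands outside it are reported as NA, not guessed.
  The margin is mean emission level minus threshold; a band is audible only
  when the margin is **strictly** positive (an emission exactly at
  threshold is not counted). By default the envelope's mean curve is
  compared; `use_upper = TRUE` switches to the upper confidence curve for
  a worst-case variant.

`wilcoxon_camera_vs_hearing()` is the paired signed-rank test of emission
levels against interpolated thresholds over the shared bands (pairing by
frequency is what makes the comparison meaningful; a rank-sum test would
discard it). Zero differences are dropped per the standard definition, and
an all-zero comparison is a reported error rather than a p-value.

For species with no measured audiogram, `proxy_hearing_range()` builds a
minimal estimate from recorded call frequencies, on the assumption that a
species hears at least the frequencies it vocalises at. The full range is
the span of the call sample; the "optimum band" is the shortest interval
containing a `coverage` fraction of the calls (default 0.5 — the modal
half of the sample, a deliberately simple order-statistics rule). This is
a declared rule, chosen here because published fox-call compilations state
no reproducible rule for their quoted optimum band; estimates derived this
way are lower bounds on true hearing range, not measurements.

## Ultrasonic, infrared and attenuation summaries

Bat-detector recordings report only a detection band (lower and upper kHz)
per trial. A trial with a zero upper bound is a *non-detection* and is
excluded before any statistic; rows are otherwise kept verbatim, including
the occasional nonzero-lower/zero-upper oddity, which is loaded as recorded
and treated as a non-detection in summaries. Medians and sample SDs
(n − 1) are computed over detections only — both conventions are required
to reproduce the bundled table's published summary (median 52.5 kHz,
SD 13.4 for the front-facing detections of the most replicated model).

Infrared peak wavelengths use the ordinary t-based interval:
half-width = t₍(1+conf)/2, n−1₎ · sd/√n. The Student quantile matters at
these sample sizes (n = 8–10): it reproduces all three published
half-widths (1.3, 3.4, 0.5 nm) from the published SDs, which the normal
quantile does not.

`spreading_loss()` implements spherical spreading, 20·log₁₀(d/d_ref) —
about 6 dB per *doubling* of distance. Field reports sometimes paraphrase
this as "6 dB per metre away", which happens to agree at the bench geometry
(50 cm reference, first metre) but not beyond; the physically standard
doubling form is implemented. Atmospheric absorption, terrain and foliage
effects are out of scope; real-world attenuation will exceed this bound.

## The synthetic generator

No raw replicate spectra are publicly available for camera traps, so the
package ships a generator rather than data. A `model_signature` is a mean
curve, an SD curve and an adjacent-band noise correlation; curves are drawn
as mean + sd·e with e a standardized AR(1) sequence along the band axis
(marginal SD exactly 1, lag-one correlation ρ, default 0.5). The AR(1)
choice mimics the smooth oscillating deviations seen in measured spectra —
independent per-band noise produces implausibly jagged replicates — while
keeping the pointwise SD exactly equal to the signature's SD curve, which
is what the recovery tests verify.

`default_signatures()` bundles three signatures pinned to the magnitudes
reported for real equipment: a background envelope with mean 8.8–28.4 dB
loudest at the very low bands, a quiet camera with mean 7.6–27.1 dB whose
loudest band is 12.5 kHz (SD up to 17.2 dB), and a louder camera with mean
14.3–41 dB peaking in the mid-frequencies. Only these published min/max and
peak-location facts are pinned; the curve shapes between them are smooth
interpolations, not traced figures.

What the generator does **not** emulate: instrument quantisation, the
frequency-dependent accuracy of the analyser at very low bands, heavy-tailed
or skewed level distributions, and any dependence between a unit's sound
and its infrared or ultrasonic behaviour (the scenario bundle draws them
independently). Passing tests therefore demonstrate that the statistical
machinery is correct and calibrated under a Gaussian-AR(1) curve model of
realistic magnitude — not that any particular hardware behaves this way.

## Problem sizes and calibration checks

The property suites use sizes chosen to make Monte-Carlo error small
relative to the tolerance being asserted: 500 null replicates with
n_perm = 199 for the type-I error check (band 0.05 ± 0.03), 2000
replicates at n_boot = 199 for envelope coverage (compared against the
oracle-computed achievable coverage, ±0.03), 1000 random vectors for the
BH oracle comparison, n = 5000 units for generator recovery (per-band 2%
for the mean; the SD check applies 2% to the across-band average relative
error, since the per-band SD estimate itself carries ~1% sampling error at
this n), and 40–50 replicates for power under a 3 SD shift across five
contiguous bands (threshold 0.9). Larger sizes sharpen the estimates but
do not change any conclusion.

## Known limitations

* Pointwise envelopes and per-band critical curves do not control
  family-wise error across bands; only t_max and its permutation p-value
  are globally calibrated.
* The signed-rank comparison treats interpolated thresholds as data;
  audiogram measurement error is not propagated.
* The proxy hearing range is a lower bound with a user-declared coverage
  rule, not an estimate of true audibility limits.
* Ultrasonic summaries inherit the bat detector's coarse reporting: only
  band edges, no levels, so no formal between-model test is offered there.
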