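---
title: "Activity-index screening: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Activity-index screening: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cardioscreen)
```

## The screening problem

Bioassay-guided fractionation asks which constituents of a complex herbal
extract carry its activity. The extract is split chromatographically into
*m* fractions, each fraction is bioassayed, and each of *p* constituents is
quantified (LC peak area) in each fraction. `cardioscreen` implements this
workflow for a cardioprotection screen: the bioassay is heart-rate rescue
in terfenadine-treated Cmlc2-GFP zebrafish larvae (GFP restricted to
myocardium makes the heart segmentable in fluorescence video), with an MTT
cardiomyocyte-protection assay as a second axis, and an LC-HRMS compound
catalog supplying the constituent list.

## The score

Three formulas drive the analysis.

**Per-fraction recovery.** With group-mean beat rates $B_C$ (control),
$B_M$ (terfenadine model), and $B_i$ (model plus fraction $i$):

$$R_i = \frac{B_i - B_M}{B_C - B_M} \times 100\%$$

$R_i$ is deliberately unclamped: a fraction that depresses the rate below
the model's yields a negative recovery, which must propagate into the
scores (some late fractions genuinely worsen bradycardia).
`recovery_rate()` errors when $B_C = B_M$, i.e. when the model is
indistinguishable from control and the scale is undefined. We compute $R_i$
from group means, matching the scalar definition; per-larva recovery
distributions are available from the per-larva rate table as a diagnostic
only.

**Abundance shares.** Peak areas $A_{i,j}$ of compound $j$ are normalised
per compound across fractions, $\tilde A_{i,j} = A_{i,j} / \sum_{i=1}^{m}
A_{i,j}$, so each retained column is a probability vector
(`normalize_areas()`). The normalisation is column-stochastic — per
compound, not per fraction — because the score below is a weighted mean
over fractions. Raw areas enter untransformed (no log), and compounds
absent from every fraction are dropped with a warning rather than scored 0,
because 0 sits ambiguously between "harmful" and "absent". Multiplying a
compound's areas by any positive constant leaves its score unchanged, so
ionisation-efficiency differences between compounds cancel (differences
between fractions for the same compound do not — a known limitation of the
design).

**Activity index.**

$$AI_j = \sum_{i=1}^{m} R_i \, \tilde A_{i,j}$$

an abundance-weighted mean of fraction recoveries, hence bounded by
$[\min_i R_i, \max_i R_i]$; a compound wholly contained in fraction $k$
scores exactly $R_k$. Compounds with $AI_j > 0$ are candidate actives;
ranking is by descending $AI$ with lexicographic id tie-breaks for
determinism. `bioactive_map()` returns the matrix $R_i \tilde A_{i,j}$
whose column sums are the $AI_j$ — the "bio-active map" view of the content
heatmap.

**The cell axis.** The MTT assay gives survival
($100 \cdot OD_t/OD_c$) and protection
($100 \cdot (OD_m - OD_t)/(OD_m - OD_c)$) rates. For the dual-score plot
the cell-protection coefficient per fraction is fed through the same
weighted-mean machinery to give a cell-side AI (x axis) against the
zebrafish AI (y axis). The source description does not pin down whether
survival or protection is the x-axis coefficient; we use protection
because it is normalised to the same 0–100 endpoints as $R_i$
(`dual_scores()` accepts any `activity_scores` pair, so survival-based
coefficients are a one-line switch). No dose correction is applied to
either axis: fractions tested at reduced concentrations for toxicity
reasons carry their concentration as metadata only, matching the original
definition of the score. No multiple-testing correction is applied to the
per-fraction ANOVA p-values (none is applied in the source protocol); they
are descriptive here.

## Heartbeat quantification from fluorescence video

A recording is ~100 frames at 10 or 20 frames/s. Each frame is thresholded
(Otsu's criterion on the min–max-normalised frame, so detection is
invariant to uniform intensity scaling), and the largest 8-connected
component is kept as the ventricle; its pixel count over frames is the
area trace. Beats are the diastolic maxima of that trace.

`detect_beats()` parameters, with defaults and rationale:

| parameter | default | rationale |
|---|---|---|
| `min_prominence_frac` | 0.3 | floor = 0.3 × (p95 − p5) of the detrended signal; rejects noise bumps while tolerating sampled-off-peak maxima at 10 fps |
| `min_separation_s` | 0.15 s | caps detectable rate at 400 beats/min, above larval physiology |
| `smooth_window_s` | 0.1 s | suppresses pixel-level segmentation flicker; well under a cycle |
| `detrend_window_s` | `Inf` | global median subtract; see below |

Three numerical choices deserve explanation.

*Detrending.* A short running-median window (of order 1 s) seems natural
for drift removal, but it destroys exactly the signal feature the model
condition produces: a blocked (skipped) ventricular beat appears as a
diastolic plateau lasting about two cycle lengths (~1.3 s at 1.5 Hz
pacing), and a running median whose window is comparable to the plateau
absorbs the plateau into the baseline; `runmed`'s shrinking edge windows
make this worse near the start and end of a 5 s clip. Recordings here are a
few seconds and drift-free, so the default detrend is the whole-record
median (the infinite-window limit of the running median); for long
recordings with focus or bleaching drift, set a finite window of at least
several cycle lengths.

*Quantisation and plateau merging.* The smoothed trace is quantised to 1/50
of its amplitude before peak finding. On a held-diastole plateau the
segmentation noise otherwise places the local maximum at a random position
inside the plateau, which randomises the adjacent inter-beat intervals and
halves the detectability of blocked beats; after quantisation the plateau
is an exact tie, resolved deterministically at its leftmost sample.
Candidates separated only by a dip shallower than two quanta are merged as
one (noisy) plateau. The cost is a peak-localisation granularity of a few
hundredths of a second, below the frame interval.

*Rate definition.* `heart_rate()` is $60(n-1)/(t_n - t_1)$ over detected
peaks rather than $n/\mathrm{duration}$: partial cycles at the clip edges
then do not bias the estimate, and for peaks at exact spacing $\Delta$ the
result is exactly $60/\Delta$. Fewer than two peaks yields rate 0 with a
`no_rhythm` flag instead of an exception so plate-scale batch runs never
abort. Rhythm metrics follow the interval series: `ibi_cv` (SD/mean of
inter-beat intervals, needing ≥ 3 peaks), `irregular` when the CV exceeds
0.15, and a dropped-beat count for intervals above 1.75 × the median
interval — a 2:1 block doubles one interval, comfortably above that
threshold as long as blocked beats are a minority of intervals.

`detect_beats_ecg()` applies the same contract to an electrocardiogram
voltage series with two morphology-driven adjustments: a 0.01 s smoothing
window (a QRS complex is ~50 ms wide and must not be blurred away) and an
amplitude reference of max − p5 instead of p95 − p5, because QRS complexes
occupy a few percent of samples and upper percentiles of a sparse spike
train sit in the noise floor at low rates.

## What the synthetic generators emulate

`generate_heart_video()` renders the geometry the segmentation relies on: a
bright filled ellipse (8-bit, 128×128 default, foreground 200 on background
20) whose **area** follows
$\mathrm{baseline} \times (1 + \mathrm{pf}\cos\phi)$ — modulating in area
rather than axis space keeps the ground-truth area analytic. Phase advances
by per-cycle periods drawn with a configurable CV; a dropped cycle holds
the diastolic (maximal-area) state for one full cycle, emulating
atrioventricular block as a skipped ventricular contraction (a single
region is modelled; beat counting is ventricular throughout, and no
two-chamber conduction is simulated). Acquisition starts half-way through a
cycle, as a real recording would at arbitrary cardiac phase, which also
keeps diastolic maxima in the interior of the trace. Gaussian intensity
noise is added and values are clipped to the 8-bit range.

Presets encode the study conditions as measured phenotypes:

* `control-larva` — 3 Hz pacing (180 beats/min), CV 0.02, no drops:
  fast regular rhythm.
* `model-larva` — 1.5 Hz pacing (90 beats/min, the middle of the reported
  80–100 beats/min band for the terfenadine condition), interval CV 0.3,
  drop probability 0.05 per cycle. The reported condition gives a rate
  band and "irregular rhythm, some with AV block", not waveform
  statistics, so the jitter and drop values are this package's choices;
  they were set so that the *measured* phenotype matches the description:
  the median detected rate over seeds falls in the band (blocked cycles
  reduce the counted rate below pacing) and the median detected interval
  CV clears the 0.15 irregularity threshold. Detected CV runs below the
  generating CV because boundary maxima are pulled toward the slower of
  the two adjacent cycles, so the generating CV must exceed the flag
  threshold by a margin.
* `adult-normal` / `adult-terfenadine` ECG presets — 100/60 Hz and 1.2 Hz
  with CV 0.03 / 0.25, 10 s at 1 kHz, biphasic QRS-like template.

`generate_fraction_assay()` plants ground truth for the scoring stage:
inactive compounds draw log-normal areas (σ = 0.5) independently across
fractions; each planted active concentrates 85% of its total area in its
assigned high-recovery fraction (the ≥ 80% concentration the recovery
property requires). The default recovery profile (60, 75, 40, 20, 10, 0,
−10, −20, 5, 15) mirrors a typical screen: early fractions beneficial,
late fractions harmful. `generate_mtt()` draws Gaussian OD replicates
truncated at zero.

What the generators deliberately do **not** emulate: optical blur,
photobleaching, two-chamber geometry, motion of the larva, real
chromatographic co-elution structure, or pharmacokinetics. Passing the
packaged tests therefore demonstrates that the *pipeline arithmetic and
detection logic* recover planted truth under idealised imaging; it does
not validate segmentation against real microscope data.

## Mass-spectral catalog validation

The packaged catalog (`inst/extdata/wxkl_catalog.csv`) transcribes the
negative-mode LC-HRMS table of 71 constituents (53 identified) of the
multi-herb preparation, flattened to ASCII. Validation recomputes each
row's mass error: monoisotopic mass from the printed formula (C 12 exactly,
H 1.00782503207, N 14.0030740048, O 15.9949146196 Da), deprotonated-ion
m/z as $M - 1.00727646$ (proton mass; the electron mass is neglected — the
convention that reproduces the printed errors to the printed decimal),
formate adduct as $M + 46.00548 - 1.00727646$. Candidate adducts are tried
in the order [M−H]⁻ then [M−H+FA]⁻ within a 20 ppm search window, because
several rows print the formate-adduct mass in the detected column
(lobetyol, for instance, verifies only under the formate adduct). Signed
ppm errors are rounded half-away-from-zero to one decimal for comparison.

Rows whose printed name, formula, mass, or error are mutually inconsistent
are reported, not corrected: the sidecar
`wxkl_catalog_discrepancies.csv` lists them with one-line diagnoses (a
formula inconsistent with its detected mass; a printed error that does not
recompute; names implying different formulas than printed; one
saponin-named row with an unexpected source code). 69 of the 70
formula-bearing rows verify; the table is reproduced as printed.

Fragment annotation searches multisets (size ≤ 3 by default) over a
neutral-loss library of glycoside chemistry — anhydro-glucose 162.05282,
anhydro-rhamnose 146.05791, anhydro-pentose 132.04226 (xylose and apiose
are isomeric, so annotation reports the mass class, not the sugar
identity), water, CO₂, formaldehyde, formic acid — choosing the smallest
multiset, then the smallest absolute deviation, within 0.02 Da. The
tolerance is absolute rather than ppm because printed fragment masses
deviate from exact loss arithmetic by up to ~10 ppm.

## Validation problem sizes

The packaged checks run at desk scale: the planted-active recovery
property uses 200 seeded screens of 71 compounds × 10 fractions and
requires the active in the top 3 in ≥ 95% of them; the rate-recovery sweep
covers pacing {1, 1.5, 2, 3} Hz × {10, 20} fps × 20 seeds at 10% intensity
noise and requires ±5% rate accuracy in ≥ 95% of replicates per cell; the
model-condition band check summarises 15 seeded replicates by their
median. The end-to-end demo (`run_demo_screen()`) defaults to 8 larvae per
group and five fractions, writing per-larva rates, recoveries, ranked
scores, the bio-active map, dual scores, and a manifest with file
checksums; it is byte-deterministic for a fixed seed.

## Known limitations

* Five-second clips contain ~7 model-condition intervals, so the interval
  CV is a noisy statistic and a blocked beat in the first or last cycle is
  intrinsically undetectable (no flanking peak); multiple blocks in one
  short clip corrupt the median interval that the dropped-beat rule is
  anchored to. Longer recordings resolve both.
* The counted ventricular rate includes blocked cycles, so heavy block
  pushes the measured rate below the pacing rate — that is the measurement
  the screen relies on, not an artefact, but it means pacing and measured
  rate must not be conflated when configuring presets.
* AI significance is not assessed (the score has no null model); ranks and
  signs are the deliverables.
* The fraction × compound matrix is an input; real peak-area integration
  from fraction spectra is out of scope, and the synthetic generator
  stands in for it.
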