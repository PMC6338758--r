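---
title: "Methods and design notes for flycourt"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes for flycourt}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flycourt)
```

## The measurement problem

A single virgin female and a single male are placed in an 8-mm circular
chamber and video-recorded for one hour. The questions asked of such an
assay are behavioral (does the male court? how quickly? does he achieve
copulation?) and reproductive (does the pairing yield offspring?), and —
for males whose genitalia stopped at a deviated dorsoventral angle —
how those outcomes depend on the deviation. `flycourt` implements the
four analysis stages: angle classification, video copulation detection,
behavioral metrics, and the statistical comparisons, plus a simulator
that generates all inputs with known ground truth.

## Angle measurement and classification

The deviation is the signed angle between two directed lines read off a
posterior-view photograph: the abdomen midline (anterior → posterior,
through two user-placed midline points) and the genitalia axis (anus →
penis, the penis taken as the middle of the claspers). We compute it as
`atan2` of the cross and dot products of the two direction vectors, in
double precision, reported to 0.1°. Coordinates are in the image frame
(y increases downward); positive angles denote deviation toward the
fly's right viewed from the posterior end. The measurement is invariant
under translation, rotation and uniform scaling of the four landmarks,
which the test suite verifies on random similarity transforms.

The eight classes use these boundaries (degrees, R = right, L = left):
0° = (L22, R22), R45 = [22, 67), R90 = [67, 112), R135 = [112, 157),
180° = [157, 180] ∪ (−180, −157], L135 = (−157, −112],
L90 = (−112, −67], L45 = (−67, −22]. The printed class limits share
endpoints (22 appears in both the 0° and R45 classes), so a tie rule is
needed to make the bins a partition: each shared boundary is assigned to
the class *farther from 0°*. The resulting widths are 44° (the 0°
class), 46° (the 180° class, which absorbs both approaches to ±180°),
and 45° for the remaining six — we keep the printed endpoints verbatim
rather than forcing eight equal bins.

Rotation arithmetic: for a counterclockwise rotator a final deviation of
Left *d* is reached by *d* degrees of rotation and Right *d* by 360 −
*d*; clockwise is the mirror. A 0°-class male is genuinely ambiguous —
the final angle cannot distinguish no rotation from full circumversion —
so `rotation_amounts("0", ...)` returns the two-valued set {0, 360} and
`rotation_difference()` refuses 0°-class inputs rather than guessing.

## Copulation detection

The detector reproduces a deliberately simple image-analysis chain:

1. **Sampling.** Frames are collected every `interval_s` (default 10 s)
   starting at the first frame.
2. **Binarization.** Flies are dark on a light background; each sampled
   frame is inverted and thresholded. The thresholding method is a
   design choice (the original chain did not state one): we use Otsu's
   method per frame, parameter-free and well suited to the strongly
   bimodal arena images; a fixed threshold can be supplied instead.
3. **Components.** 8-connected components (diagonal contact counts —
   two flies touching at a pixel corner are one shape) of at least
   `min_area_px` (default 25% of the expected single-fly area) are kept.
4. **Merge rule.** A sample is *merged* when exactly one fly-sized
   component is present **and** its area is at least `merge_factor`
   (default 1.4) times the single-fly reference area. The original
   operator confirmed merges by eye; this dual rule is our explicit
   proxy, robust both to a fly disappearing behind the chamber edge
   (small single blob: not merged) and to partial occlusion. The
   reference area, if not given, is estimated as the median of the two
   largest component areas over frames showing ≥ 2 components.
5. **Calling.** Maximal runs of consecutive merged samples become
   copulation intervals when their *occupancy span* — last sample time −
   first sample time + one sampling interval — strictly exceeds
   `min_duration_s` (default 60 s). "More than one minute" is strict: at
   10-s sampling a run of 7 merged samples (span 70 s) qualifies, 6
   samples (60 s) does not. No gap tolerance by default ("continuously"
   is taken literally); `allow_gap_samples` can relax it. A run still
   merged at the final sample is emitted with a truncation flag and
   counts as success regardless of span, because the live assay is
   extended to the end of copulation in that situation.

The binarized stack can be assembled into a space-time volume
(`build_volume()`, written as a multi-page TIFF) whose slice lookup is
the digital analog of scrubbing a synchronized time bar through the
3-D rendering used for visual review.

## Behavioral metrics

* **Courtship latency** — start time of the first wing-vibration event.
  Males that do not initiate within 600 s are excluded. The CI exclusion
  wording in the original protocol ("did not copulate for 10 minutes")
  conflicts with the latency exclusion ("did not start wing vibration
  within 10 minutes") used everywhere else; we read the former as a slip
  for the latter and apply a single initiation-based exclusion,
  recording a per-assay `excluded_reason`.
* **Courtship index (CI)** — the percentage of the first 600 s spent in
  *any* of the six courtship components (orientation, tapping,
  following, wing vibration, licking, attempted copulation). Overlapping
  component intervals are counted once (interval union) — the stopwatch
  protocol measures total engaged time — so CI ≤ 100 by construction.
  Copulation itself is not a courtship component.
* **Copulation success** — a qualifying interval (span > 60 s, or
  truncated at recording end) starting within the 3600-s window, from
  the detector, a ground-truth event log, or both (which must agree).
* **Rates** — per-stratum success counts with exact rates; displayed at
  three significant figures (66.2, 7.14, 1.96 style).

## Statistics

Success rates are compared by Fisher's exact test (two-sided,
point-probability convention — the sum of hypergeometric point
probabilities no larger than the observed table's, matching the R
implementation the field uses; a central/doubling convention is
available). Latency uses Kruskal–Wallis (tie-corrected H, χ² reference)
with Steel–Dwass all-pairs post hoc; CI uses one-way ANOVA with Tukey
HSD (Tukey–Kramer under unequal n). α = 0.05 throughout; p-values for
separate planned contrasts are deliberately *not* multiplicity-adjusted,
matching the original analysis design (a Holm option would be a
one-liner with `p.adjust` but is intentionally not applied by default).

Fisher, Kruskal–Wallis and ANOVA/Tukey are delegated to the standard R
implementations; Steel–Dwass, which base R lacks, is implemented
directly: for each pair the Wilcoxon rank sum is computed on that pair
alone, standardized with the tie-corrected null variance
E = n₁(N+1)/2, V = n₁n₂/(N(N−1)) · (Σr² − N(N+1)²/4), and √2·|t| is
referred to the studentized-range distribution with k groups and
infinite degrees of freedom. An exact per-pair permutation reference is
available for tiny samples as a diagnostic (it enumerates all splits and
carries no family adjustment). The test suite validates the battery
against independent oracles: exhaustive hypergeometric enumeration for
every 2×2 table with N ≤ 40, a hand rank computation and the
two-group H = t² identity for Kruskal–Wallis, F = t² and hand-computed
sums of squares for ANOVA, permutation-order agreement for Steel–Dwass,
plus seeded null simulations (Fisher rejection ≤ 5%, Kruskal–Wallis
p-uniformity, Steel–Dwass family-wise error ≤ 6% at k = 4, n = 10).

## The simulator: what it emulates and what it does not

The generator's defaults are the assay's stated conditions: an 8-mm ×
3-mm chamber, one-hour recordings, 10-s analysis sampling, the >60-s
copulation rule, the 600-s initiation window. Quantities the assay
description does not fix are set once to field-plausible values and are
configurable: fly body length 2.8 mm (female) / 2.3 mm (male) with a
0.42 aspect ratio, rendering at 6 px/mm (a fly spans ≈ 14 px), native
frame interval 1 s (finer than the 10-s analysis cadence so the
sampling step is actually exercised), walking speeds ≈ 1 mm/s, and
additive Gaussian pixel noise σ = 0.03 on a [0, 1] gray scale — at
which Otsu binarization recovers ≥ 99% of true fly pixels, as the test
suite checks against the rendered ground-truth masks.

Flies are filled ellipses, dark on light; wings are not rendered (the
detector is not meant to resolve courtship steps, only copulation).
Behavior is a semi-Markov state machine over idle plus the six courtship
components and copulation, with exponential dwells; an attempted
copulation escalates to copulation with probability 0.25, and a
completed copulation is followed by permanent refractory idling, so at
most one copulation occurs per assay — the pattern seen in the real
assays. During copulation the male ellipse rides the female's posterior
with strong overlap, guaranteeing a single connected component; outside
copulation a minimum separation of 1.15 body lengths is enforced so that
non-copulating pairs never render as merged. Scripted schedules
(`scripted_events`) bypass the state machine for exact ground truth.

Outcome tables draw each male's copulation and offspring outcomes from
one shared uniform variable (`u < p_copulation`, `u < p_offspring`),
which makes offspring a subset of copulations — matching the
observation that males that failed to copulate never left offspring —
while keeping both marginal rates exactly recoverable. The default
class probabilities are the observed reproduction success rates per
deviation class (66.2, 33.9, 1.96, 3.18, 0, 0, 3.03, 46.2% with
wild-type females; 75.0, 60.0, 9.80, 0, 0, 0, 0, 65.0% with mutant
females); per-class copulation probabilities are not fully tabulated in
the source data, so the default sets them to `p_offspring / 0.95`
(capped at 1), justified by the 93.8–100% fecundity observed among
copulating males.

**What passing tests do and do not show.** The simulator produces
high-contrast, occlusion-free, two-animal scenes with stationary
lighting. Perfect detector recall/precision on it validates the
algorithmic chain (sampling, thresholding, connectivity, run logic), not
robustness to real-video nuisances — reflections at the chamber wall,
grooming postures, wing extension changing the apparent area, flies
climbing the wall out of the focal plane. On real footage the
`merge_factor`, `min_area_px` and a fixed threshold are the knobs to
revisit.

## Numerical choices and degenerate inputs

* Angles in double precision throughout; classification happens on the
  exact value, display rounds to 0.1°.
* Coincident landmarks or zero-length axes raise a degenerate-geometry
  error rather than returning NaN.
* A constant frame binarizes to an empty mask with a warning; an
  all-merged series (no frame with two separate flies) cannot estimate
  the single-fly area and errors with instructions to supply it.
* All-identical samples give Kruskal–Wallis H = 0, p = 1 with a
  warning; everywhere-zero within-group variance makes ANOVA error.
* Every generator takes an explicit integer seed and restores the
  caller's RNG state; `run_pipeline()` fans one global seed out to
  per-stage seeds via `(seed·69069 + stage·12345) mod (2³¹ − 1)` so
  stages can be rerun independently. Identical config + seed
  regenerates reports byte for byte.
* Configuration files use YAML; run reports serialize to JSON with
  unbounded digits so that round trips are exact.

## Problem sizes used by the test suite

The validation suite runs at desk scale, chosen as the smallest sizes
that still exercise every rule: detector ground-truth agreement uses 50
seeded 420-s assays with scripted copulations of 120–200 s (boundary
error ≤ one 10-s sampling interval) plus 8 + 8 assays with 50-s and
70-s mounts straddling the one-minute rule; the Fisher oracle enumerates
all 2×2 tables with N ≤ 40; null simulations use 2000–5000 replicates;
parameter recovery uses 100 outcome tables at n = 60 males per class.
One-hour, full-resolution simulations are supported but not needed to
validate the logic.

## Known limitations

* The detector identifies *that* and *when* the pair merged, not which
  fly is which; no identity tracking or orientation estimation.
* Landmark placement is upstream of this package (done manually in an
  image viewer); only the coordinates are consumed.
* The Steel–Dwass reference distribution is asymptotic; at very small
  group sizes (n < 5) its family-wise error control is approximate and
  the permutation diagnostic is recommended.
* The 0°-class rotation ambiguity is irreducible from end-state
  anatomy; any analysis needing a single rotation amount must exclude
  that class, as `rotation_difference()` enforces.
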