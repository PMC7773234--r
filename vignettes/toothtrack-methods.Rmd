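---
title: "Validating motion-tracked toothbrushing against video observation: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating motion-tracked toothbrushing against video observation: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(toothtrack)
```

## The problem

Video observation (VO) is the established way to study how people actually
brush their teeth: a trained coder assigns, for every moment of a filmed
session, the area of the dentition the brush is acting on. It is accurate but
subjective, slow, and blind whenever the brush is occluded. Automated motion
tracking (MT) of the brush promises objective, high-frequency area labels —
but has to be validated against the human gold standard before it can replace
it. toothtrack implements that validation pipeline: it reconciles the two
differently sampled coded streams onto a common grid, quantifies their
agreement, and computes the behavioural outcome measures (per-area durations,
events, and the Toothbrushing Systematics Index) from either source, together
with the nonparametric statistics used to compare them.

## The area coding scheme

The dentition is divided into six sextants (01 upper right posterior, 02
upper anterior, 03 upper left posterior, 04 lower left posterior, 05 lower
anterior, 06 lower right posterior) and three surfaces per sextant (01
occlusal/incisal, 02 vestibular, 03 oral), giving the 18 areas of
`enumerate_areas()`. Three combined codes — 16, 25, 34 — mark closed-jaw
vestibular brushing across the vertically opposing sextant pairs (01,06),
(02,05), (03,04); because closed jaws expose only the cheek side, combined
sextants are valid with surface 02 only. When durations are accumulated, a
combined code's time is split evenly (50/50) onto its two member sextants'
vestibular areas.

Time not covered by any coding is carried as the explicit `"uncoded"`
sentinel. It is excluded from agreement denominators and duration sums but
never silently dropped; real exports can have gaps even when a study codes
sessions exhaustively.

## From streams to a common grid

MT produces area-labelled samples at 100 Hz (plus a brush-angle channel); VO
produces timed events derived from 50 fps video. Both are reduced to
half-second intervals:

1. VO events are expanded to the 50 Hz frame grid (`rasterize_events()`); a
   frame takes the label of the event covering its midpoint, which avoids
   double-labelling at event boundaries.
2. Each 0.5 s interval `[k·0.5, (k+1)·0.5)` is labelled by majority vote over
   its samples (`bin_stream()`). Ties go to the label occurring first in time
   within the interval. A trailing partial interval is kept and labelled from
   its available samples — dropping it would break duration conservation.
3. MT surfaces are re-derived from the brush angle before voting
   (`classify_stream_surfaces()`): at or below the regional threshold (20° on
   molars, 13° on anterior teeth) the brush is occlusal/incisal, above it on
   a smooth surface. The inequality direction is this package's convention
   (small inclination relative to the occlusal plane = occlusal contact); the
   side of a smooth classification comes from the sample's recorded surface,
   with vestibular as the fallback for occlusal-recorded samples, and
   combined-code samples are exempt. Classification happens per sample, then
   the vote — the alternative order (vote first) is not offered because the
   vote should summarise the best per-sample information available.
   `threshold_sensitivity()` reports how many labels change when both
   thresholds shift by ±3°, the robustness probe for this decision.
4. `pair_streams()` aligns the two interval sequences by index over the
   intersection of their coded spans (surplus intervals of the longer stream
   are dropped with a warning); pairs with an uncoded side are flagged and
   excluded from every agreement denominator.

## Agreement measures

* `matching_proportion()` — the percentage of coded interval pairs with the
  identical area (sextant *and* surface correct).
* `confusion_matrix()` / `heatmap_table()` — VO-by-MT cross-tabulation over
  all 21 codes; the heat-map export drops the diagonal and zero cells and
  grades each mismatch by `adjacency_class()`.
* `adjacency_class()` — the mismatch-severity grading needed a full formal
  rule, which is interpretive: *adjacent* are same-surface neighbours
  (consecutive sextants within an arch, or the vertically opposing closed-jaw
  pairs — included because closed-jaw brushing physically spans them),
  occlusal versus a smooth surface of the same sextant, and a combined code
  versus a member sextant's vestibular area; everything else — notably
  vestibular versus oral and opposite mouth sides — is *non-adjacent*.
* `cohen_kappa()` — unweighted kappa on the full area code or its sextant or
  surface projection, computed on the 0.5 s grid (the reproducible choice;
  coding tools compute kappa on their own internal units).
* `matching_distribution()` — median (min; max), the inclusive fractions of
  sessions with ≥80% and ≥90% matches, and a 2.5-point histogram.

## Systematics metrics

All systematics scores use the 12 smooth (vestibular + oral) areas only,
ignoring occlusal/incisal brushing. With `b` the number of changes between
areas, `x` the total brushing duration in seconds, `i` the number of reached
areas and `n = 12`:

$$C = \max\left(0,\; \left(1 - \frac{b}{x}\right)\cdot\frac{i}{n}\right),
\qquad
I = 1 - \frac{n}{2(n-1)} \sum_{i=1}^{n}\left|\frac{d_i}{x} - \frac{1}{n}\right|,
\qquad \mathrm{TSI} = C + I,$$

where $d_i$ is the seconds brushed in area $i$ (after the combined-code
split). Both sub-scores live in [0, 1], the TSI in [0, 2]. Conventions the
formulas leave open, fixed here:

* `x` is smooth-surface time, not whole-session time — consistent with
  ignoring occlusal brushing throughout.
* `b` is counted on the aggregated grid after removing occlusal and uncoded
  intervals and collapsing runs, so an occlusal interruption that returns to
  the same smooth area is not a change. Combined codes count as their own
  labels for `b` (moving from a single-sextant stretch into closed-jaw
  brushing is a movement of the brush).
* `i` counts areas with strictly positive duration (no minimum dwell).
* The reported `events` column is the same count over all areas on the grid;
  the TSI-internal `b` is the 12-area restriction. Both are emitted.

Numerically, `isochronicity()` evaluates
$1 - \sum_i |d_i n - x| \,/\, (2(n-1)x)$, which is algebraically identical
but exact in floating point at the two closed-form extremes (perfectly even:
1; fully concentrated: 0).

## The synthetic session generator

The study's raw streams are not bundled, so `simulate_session()` /
`simulate_study()` generate paired VO/MT sessions with known ground truth.
The generator is deliberately minimal — a semi-Markov walk, not a kinematic
simulation:

* **Ground truth** — dwell times are truncated normal (lower bound 0.5 s, the
  smallest stretch the coding scheme treats as a behaviour unit); the next
  area is drawn from visit weights excluding the current area (a
  single-positive-weight profile therefore never leaves its area). Habitual
  profiles are vestibular-heavy with strong oral neglect (Beta(5,2) per
  subject) and occasional closed-jaw combined codes (probability 0.15);
  instructed profiles follow `systematic_sequence()` — the canonical
  instruction order, oral surfaces first, occlusal last — with near-equal
  dwell and a 12% chance of skipping each sequence area (imperfect
  adherence). Transition times are snapped to the 0.02 s video frame grid:
  changes finer than a frame are unobservable by either source, and the
  common grid makes the two samplings (100 Hz ticks, 50 fps frame midpoints)
  exactly commensurable, so a noise-free session yields 100% agreement by
  construction rather than approximately.
* **MT errors** — (i) after an area change, with probability 0.45 a 0.1–0.4 s
  block is attributed to a neighbouring sextant (boundary imprecision);
  (ii) spurious micro-transitions: candidate excursions arrive at 14 per
  minute but materialise only within 1.25 s of a ground-truth boundary —
  tracker flicker is a border-region phenomenon, which ties MT event
  inflation to how much the subject switches; (iii) the angle channel sits
  8° below (occlusal) or above (smooth) the regional threshold with a
  per-stretch N(0, 6°) offset plus 1° per-sample noise, so occasional
  stretches cross the threshold and produce occlusal/smooth confusions once
  the classifier runs.
* **VO imperfection** — stretches shorter than 0.5 s are merged into their
  neighbours before events are emitted (the human coder does not code them
  separately).
* **Seeds** — per-subject/session seeds are derived from the master seed by a
  fixed affine counter rule, so any subset of a study reproduces
  independently; identical seeds give bit-identical streams.

The error magnitudes are free parameters (no quantitative values exist for
them); the defaults were fixed once so that the simulated baseline study sits
at the reported operating point of such validations — per-session matching
median in the high 80s with a wide spread, mismatches clustered at neighbour
sextants and occlusal/smooth pairs, and MT event counts well above VO even
after aggregation. What the generator does **not** emulate: within-stretch
brush kinematics, autocorrelated angle drift, coder-specific biases,
left/right handedness asymmetries, or any brushing-technique structure
(circling, scrubbing, jiggling). Passing tests therefore demonstrate that the
pipeline measures what it claims on streams with this error structure — not
that any particular tracker meets the gold standard.

## Inferential layer

Group comparisons use the classical nonparametric battery: Mann–Whitney *U*
for independent groups, Wilcoxon signed-rank for paired data (zero
differences dropped — the classical convention; the original software's
convention is unknown), Spearman's ρ for correlations, Holm's step-down
adjustment over the 18 per-area duration comparisons, significance level
0.05. Exact null distributions are used where tractable (U: smaller group ≤ 8
untied observations; signed-rank: ≤ 25 untied non-zero differences),
otherwise tie-corrected normal approximations with continuity correction.
`equivalence_ci()` implements the tracker-effect check: a t-based two-sided
90% confidence interval of the mean paired difference (dual to two one-sided
tests at 5%), equivalent when contained in ±8 s. The t construction on paired
differences is this package's choice; the original report does not name one.
`run_study_analysis()` assembles the full comparison battery and lists any
comparison skipped for lack of sessions rather than failing.

## Problem sizes used by the test suite

The shipped tests exercise the formula oracles on 1,000 randomized draws
(tolerance 1e-12), the majority-vote oracle on 1,000 random streams, the
chance-level kappa null on 1,000 shuffles of 1,000-sample sequences, a
200-replicate permutation null for type-I control of the group comparison
(bound 0.09 = nominal 0.05 plus its 99% binomial sampling margin), and 100
study replicates of 5+5 subjects (10 instructed) for the direction-of-effect
checks. `scripts/acceptance.R` runs the full default design (51/52/46).
These sizes are the package's own balance of statistical resolution against
a test suite that stays pleasant to run.

## Known limitations

* The adjacency rule and the angle-threshold direction are documented
  interpretations, not measured facts.
* Kappa is unweighted and reported without confidence intervals; no
  chance-corrected alternatives (AC1, weighted kappa) are offered.
* The generator's noise parameters are qualitative calibrations; parameter
  *recovery* is verified, parameter *values* are not identifiable from the
  outputs.
* Sessions are assumed synchronised up to the per-file `sync_offset_s`
  header; clock drift within a session is not modelled or corrected.
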