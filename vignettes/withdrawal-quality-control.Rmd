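---
title: "Frame-level accounting of effective withdrawal time"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Frame-level accounting of effective withdrawal time}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ewtqc)
```

## The accounting model

Withdrawal time (WT) runs from the moment the colonoscope reaches the
ileocecal region to its complete withdrawal. Two components of WT do not
contribute to mucosal inspection: instrument operations (biopsy,
polypectomy, chromoendoscopy — *Time 1*) and non-interpretable footage
(irrigation, darkened screens, motion blur — *Time 2*). The effective
withdrawal time is the remainder:

$$\mathrm{EWT} = \mathrm{WT} - \mathrm{Time\,1} - \mathrm{Time\,2}.$$

`ewtqc` operationalizes this identity at frame resolution. Every processed
frame is assigned to exactly one bucket:

1. `pre_withdrawal` until the start is detected;
2. `time1` if the classifier labels it `instrument`;
3. `time2` if it is not an instrument frame and the blur detector fires;
4. `effective` otherwise (including ileocecal-labelled frames after the
   start — the mucosa is visible on them, and no third exclusion is
   defined).

Instrument priority over blur is not cosmetic: it makes the buckets
disjoint, which is what lets the identity hold *exactly* in frame counts
(`wt_frames = ewt_frames + time1_frames + time2_frames`) and, after
division by the frame rate, in seconds. The test suite asserts this
conservation on every engine run.

The withdrawal start is the first frame of the first run of at least
`start_run_length` consecutive ileocecal-classified frames. A run, rather
than a single detection, debounces isolated false positives; the default
of 5 frames is deliberately short (0.2 s at 25 fps) and configurable.
Whether blurred ileocecal frames should be allowed to interrupt a start
run is genuinely open; here blur plays no role in start detection, only in
Time 2. The withdrawal end is pinned to the last frame of the stream: no
anal-withdrawal detector is defined, and the expected inputs end at
withdrawal.

## Per-frame signals

**Blur.** Sharpness is scored as the variance of the response of the 3×3
4-neighbour discrete Laplacian (centre −4), computed on the native frame
after BT.601 luminance conversion, with borders handled by edge
replication and the variance taken as a population variance over all
pixels. A frame is blurred when the score falls strictly below the
threshold (default 50, in squared 8-bit intensity units). The Laplacian
annihilates constants, so the score is invariant to uniform brightness
offsets, and it scales quadratically with pattern amplitude — both are
asserted as properties, and the default boundary is recovered empirically
by binary search over an amplitude-controlled image family
(`recover_blur_boundary()`). The score is resolution-dependent: the
default 50 is calibrated for roughly SD-resolution 8-bit frames, and the
threshold is a configuration knob rather than a constant.

**Speed.** Each frame is fingerprinted with a 64-bit DCT perceptual hash;
the Hamming distance $D$ between consecutive processed frames proxies
scope speed without positional tracking. The pinned hash dialect:
luminance, 32×32 area-average (block-mean) resize, full 2-D DCT-II,
top-left 8×8 coefficient block, each coefficient thresholded against the
median of those 64 values (DC term included), ties mapping to bit 0. The
resize filter is the one place reference implementations differ; the
area average is pinned here because it is exactly reproducible from first
principles (the test suite recomputes the hash with an independent naive
double-loop DCT and requires bit-for-bit agreement). Zone cut points
follow the colour scheme: normal $D \le 20$, warning $21 \le D \le 30$,
danger $D > 30$; the three zones partition $[0, 64]$, which is asserted by
exhaustive sweep. Distances are computed between strictly consecutive
*processed* frames; no smoothing is applied before zoning, and the first
processed frame has no distance and never enters the occupancy counts.

**Classification.** The three-class contract (`ileocecal`, `instrument`,
`normal`, each with a confidence in $[0,1]$) is an interface. The package
ships a ground-truth sidecar stub and a marker heuristic keyed to the
synthetic generator's signatures; a trained model plugs in through
`adapter_classifier()` without any training code here. The engine's
correctness is established independently of classifier quality — that is
the point of the stub. `letterbox_resize()` provides the standard
preprocessing contract for detector-family models (scale by
`min(target/w, target/h)`, round half-up, centre on a 114-gray canvas);
the pad value and rounding rule are pinned so the operation is idempotent
and bit-exactly testable.

## What the synthetic generator emulates

`generate_scenario()` renders a withdrawal-like video from a seeded
specification: segment kinds (`pre_insertion`, `ileocecal`, `effective`,
`instrument`, `blurred`), durations, a per-segment motion plan (target
speed zone) and per-episode blur strength. It emits, tri-consistently,
the frames, a per-frame ground-truth timeline and the stub sidecar.

The texture is engineered for controllability rather than realism:

* The moving background is a sum of window-aligned 2-D cosine components
  with period twice the frame side (96 px frames, 192 px period, on a
  960 px toroidal canvas). Translating the viewing window by multiples of
  the frame side *exactly negates* chosen cells of the frame's 8×8
  low-frequency DCT block, so the perceptual-hash distance between
  consecutive frames is deterministic by construction: a small diagonal
  drift yields $D \approx 4$–$12$ (normal), a one-frame diagonal jump
  flips the 22 strong cells with exactly one odd index (warning), and a
  one-frame vertical jump flips the 32 odd-column cells (danger).
* High-frequency detail is a frame-anchored grain-plus-vignette layer — a
  fixed sensor/illumination pattern that keeps sharp frames at a Laplacian
  variance of roughly 300 (comfortably above twice the blur threshold)
  while contributing nothing to frame-to-frame hash changes.
* Each segment begins at a fresh lattice-aligned canvas position (a scene
  repositioning), so within-segment distances follow the motion plan;
  segment-boundary frames are flagged in the timeline and excluded from
  zone-plan comparisons.

`calibrate_motion()` still *measures* rather than assumes: candidate
translations are evaluated on a trial path and accepted only when at
least 90% of realized distances fall in the requested zone, with a
diagnostic error otherwise. Blur episodes are Gaussian-smoothed
(default σ = 3 px) and the generator enforces a safety margin — blurred
frames must score below 25 and sharp frames at or above 100 — rejecting
any blur plan that would straddle the decision boundary at 50. Marker
signatures (a bright/dark annulus for the ileocecal landmark, a bright
chord for instruments) are frame-anchored and shared, as documented
geometry, with the heuristic classifier.

What the generator does **not** emulate: photorealistic mucosa, lesions,
fluid and irrigation dynamics, illumination flicker, interlacing, codec
artefacts, or classifier uncertainty (sidecar confidences are 1.0).
Passing the parameter-recovery suite therefore demonstrates that the
*accounting machinery* is exact given correct per-frame signals; it says
nothing about how a trained classifier or the pinned thresholds behave on
clinical video.

## Agreement and evaluation statistics

For two paired timing series (AI vs. a rater group), `agreement()`
reports:

* **ICC(A,1)** — single-measure, absolute-agreement, two-way
  random-effects intraclass correlation, computed from the two-way ANOVA
  mean squares with the Satterthwaite F-based 95% CI. It is implemented
  from the mean-square formulas directly and validated against a
  closed-form oracle: for two raters that each measure a common truth with
  independent noise, the expected ICC is
  $\sigma_s^2 / (\sigma_s^2 + \sigma_e^2)$; a simulated study (n = 200
  videos, truth SD 20 s, rater noise SD 5 s — values chosen as a plausible
  EWT spread) must recover 400/425 within ±0.05.
* **Bland–Altman** — bias as mean(a − b) (the AI-minus-comparator
  direction, so an AI undercount is a negative bias) with 95% limits of
  agreement at bias ± 1.96 SD of the differences.
* **Pearson r** (flagged undefined for zero-variance series) and the
  **Wilcoxon signed-rank** test (exact for ≤ 25 non-zero differences,
  normal approximation with continuity correction above, zero differences
  dropped).

Classifier evaluation follows the per-class one-vs-rest layout with a
sample-weighted summary row: sensitivity, specificity, precision,
accuracy and F1 from the confusion counts (zero-denominator metrics are
reported as 0 and flagged, keeping weighted averages defined); ROC by
descending-score thresholding with ties grouped and AUC by the trapezoid
rule (equal, provably and by test, to the Mann–Whitney pairwise
probability); AP by trapezoidal integration of precision over recall —
the direct discretization of the area under p(r), not the 11-point or
step-interpolated variants.

## Numerical choices and problem sizes

* All generator randomness flows from the scenario seed through a
  save/restore wrapper, so generation never perturbs the caller's RNG
  stream and identical seeds give pixel-identical frames.
* Blur-boundary recovery brackets the amplitude from above at 4× the
  threshold and bisects until the variance bracket is below `tol`
  (default 1e-3 intensity²; the acceptance script uses 1e-4).
* Hash ties (coefficient equal to the median) map to bit 0; median over
  an even count is the usual midpoint of the two central order
  statistics.
* The test and acceptance suites use 96×96-px frames, scenarios of
  roughly 150–300 frames (20 seeds) plus one 1,590-frame worked example,
  50 random 32×32 frames for the convolution oracle and n = 30 instances
  for the ranking-metric oracles — sizes chosen so the full suite runs in
  well under a minute while every check stays exact rather than sampled.

## Known limitations

* No video codec I/O: inputs are PNG frame directories or in-memory frame
  lists; annotated output is likewise a PNG directory. Frame rate must be
  supplied (or the engine falls back to 25 fps with a warning).
* The blur threshold's resolution dependence is documented but not
  auto-calibrated; applying the default 50 to very low- or
  high-resolution video will misclassify.
* Withdrawal end detection, cecal-intubation scoring, bowel-prep scoring
  and polyp detection are out of scope.
* With `frame_stride > 1` the time accounting scales counts by the
  stride; this is an approximation, exact only when bucket membership is
  constant within each stride window.
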