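---
title: "Methods: video-based grooming detection and circadian analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: video-based grooming detection and circadian analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(groomr)
```

# Overview

`groomr` classifies the behavior of a single fruit fly confined to a
glass activity-monitor tube, from 8-bit grayscale video recorded at
10 Hz and analyzed at 5 Hz (every second frame). Each analyzed frame
pair is mapped to a three-dimensional feature vector and labeled
grooming, locomotion or rest by a k-nearest-neighbors classifier; a
sliding-window filter then removes short grooming-like bursts. Feeding
and sleep rules extend the labels to a five-behavior ethogram whose
binned fraction-of-time series feed the circadian stages.

This vignette documents the model, every tunable parameter, the
numerical conventions chosen where more than one reading was defensible,
and what the synthetic benchmarks do and do not demonstrate.

# Segmentation model

**Background.** A fly is always darker than its surroundings. The
background for each 1000-second stretch of video is built from one
template frame and seven contrast frames drawn uniformly at random from
that stretch: any template pixel darker than the contrast pixel by more
than `C0 = 10` gray levels is replaced by the contrast value, so the
dark fly is erased wherever it moved at least once among the eight
frames. The 1000-s refresh accommodates slow scene changes (food level,
debris). A fly that does not move for longer than a refresh interval is
absorbed into the background and temporarily undetected; such frames
inherit the last detected observation (`hold_last_position()`), i.e.
the fly is taken to be stationary where it was last seen.

The replacement rule is deliberately one-sided — dark objects are
erased from the template, never imported into it — because that is the
only direction consistent with the stated purpose of removing a dark
moving fly from a light scene. The package's synthetic fixtures confirm
that the built background equals the clean scene exactly at zero noise
and deviates by at most `C0` under 2-gray-level sensor noise.

**Foreground.** A pixel is foreground when `background − frame > C0`.
At `C0 = 10` with ~2 gray levels of sensor noise, spurious activations
are isolated single pixels; every 8-connected component smaller than
`C1 = 25` pixels is then erased, leaving the ~300-pixel fly silhouette.
Components are labeled with 8-connectivity (the package's own compiled
flood fill; the standard choice for blob extraction).

**Core/periphery split.** The fly's gray histogram is bimodal: a dark
core (thorax/abdomen, around level 40) and a lighter periphery (legs,
head, wing edges, around 90). The median of the fly's own pixel grays —
recomputed per fly and per analyzed frame, so slow illumination drift
cannot bias the split — divides the body into halves of near-equal
size. Median-valued pixels are assigned to the core in pixel-index
order until the core holds `ceiling(area/2)` pixels; a constant-gray
blob degenerates to an index-order split. This keeps
`|area − 2·|core|| ≤ 1` for every input, giving the two movement
features equal weight.

# Features

For each pair of consecutive analyzed frames:

* **PM, CM** — the number of non-overlapping periphery (resp. core)
  pixels between the two frames, read as the symmetric difference of
  the part's pixel sets. A one-sided count would weight appearing and
  disappearing pixels asymmetrically; the symmetric difference is the
  natural two-sided reading and is the package's single biggest
  interpretive choice in the feature stage. Parts correspond across
  frames by label (core to core, periphery to periphery).
* **CD** — the absolute displacement of the body centroid projected on
  the tube's long axis (perpendicular motion is ignored; the tube is
  effectively one-dimensional). Displacements below 0.5 px are zeroed
  as noise.

PM and CM are areas while CD is a length, so PM and CM enter as square
roots; all three are divided by the scale parameter `SP = sqrt(area)`,
making the features dimensionless and size-invariant (doubling the fly
and all raw counts leaves the vector unchanged). The alternative
reading that divides the raw counts by `SP` without the square root is
available as `sqrt_transform = FALSE`, but the homogenized default is
recommended and used everywhere in the package.

In this space the three classes occupy distinct regions: rest at the
origin, locomotion at high nCD with both parts turning over, grooming
at high nPM with small nCM and nCD.

# Classifier

A kNN classifier with `k = 10` and Euclidean distance labels each
feature vector by the majority label of its k nearest training samples.
Neighbors are found through a k-d tree whose answers are exactly those
of exhaustive search, with distance ties broken toward the lower
training index; vote ties fall back to the single nearest neighbor's
label and then to the fixed class order grooming < locomotion < rest.
These tie rules are not scientifically meaningful — they exist so that
every run is bit-reproducible and testable. No re-standardization is
applied before the distance: the axes were constructed to be
commensurate. `cross_validate()` reports stratified 10-fold accuracy
over k = 1..50 to support re-choosing k.

**Pruning.** Features from a single frame pair cannot distinguish
grooming from brief grooming-like motion (stretching, ~1 s), whereas a
typical grooming bout lasts over 3 s (15 analyzed frames). A frame
keeps a grooming label only if it lies in at least one 15-frame window
(sliding by one frame) containing at least 12 raw grooming labels;
failing frames are relabeled locomotion, and other labels never change.
The window is interpreted as any contiguous sliding window, not
disjoint blocks. Streams shorter than one window are treated as a
single window of their own length (`strict = TRUE` instead relabels all
grooming). The implementation is cumulative-sum based and is tested for
exact equality against brute-force window enumeration.

# Ethogram

Feeding is inferred from prolonged food proximity: centroid within one
body length of the food end for strictly more than 3 s. Body length is
estimated as the median per-frame extent of the fly along the tube axis
— a robust estimator chosen by this package. Rest runs of at least
5 min (300 s, inclusive) are sleep; shorter quiescence is short rest.
Precedence per frame: sleep first (it is defined purely by quiescence
length), then feeding, which overrides only locomotion and short-rest
frames — feeding shows up as centroid movement and is initially
classified as locomotion, while grooming labels carry more specific
evidence and are preserved. Whether feeding should also override
grooming near the food end is genuinely open; the chosen precedence is
conservative about grooming time, and feeding never overlaps sleep by
construction.

Fractions of time per behavior are computed in 30-min bins (the final
partial bin normalized by its own length), so the five fractions sum to
one per bin and wake = 1 − sleep exactly. Bout statistics report
per-bout durations and the longest inter-bout pause per behavior.

# Rhythm analysis

**Periodogram.** The classical normalized Lomb-Scargle periodogram
(power normalized by the series variance) is evaluated on periods of
1–48 h with 16-fold frequency oversampling. The dense grid matters for
period estimation: with 4 days of data the natural frequency spacing
corresponds to roughly 1 h of period near 19 h, so a lightly sampled
grid quantizes the reported period by up to half of that; 16-fold
oversampling brings the grid error well under 0.1 h at circadian
periods while leaving the significance calibration unchanged (the
effective number of independent frequencies does not depend on the
oversampling). Analytic significance
thresholds use `Power = −ln(1 − (1 − p)^(1/N))`, the level exceeded by
the maximum of `N` independent unit-exponential powers.

The value of `N` deserves care. With an oversampled grid, neighboring
frequencies are correlated, so neither the raw grid size nor the
unoversampled frequency count is the right effective number. The
package uses `N_eff = n · (f_max − f_min) / f_Nyquist` (an effective
independent-frequency count in the spirit of Horne & Baliunas 1986),
and validates it by Monte Carlo: over 2000 white-noise series (4 days,
30-min bins) the analytic p = 0.05 threshold matches the empirical 95th
percentile of peak power to within 0.3 power units (an acceptance-suite
test). Finer binning raises the peak power of a fixed rhythm roughly
linearly in the number of points while the threshold grows only
logarithmically, so small bins separate peak from cutoff more clearly.

**Two-peak activity model.** Daily activity is summarized by a periodic
template with morning and evening peaks, parameterized by rise/decay
rates (`b_MR`, `b_MD`, `b_ER`, `b_ED`, in 1/h), plateau durations
(`T_M`, `T_E`, hours), heights (`H_M`, `H_E`) and the period `T0`. The
defining equations of this model live in prior literature that fixes
only the parameter list, so the package fixes its own explicit
template: each peak is a plateau of width `T` and height `H`, approached
as `H·exp(b_rise·(s + T/2))` for phase distance `s < −T/2` and left as
`H·exp(−b_decay·(s − T/2))` for `s > T/2`; the morning plateau is
centered at circadian phase 0 and the evening plateau at `T0/2`, and
the two components are summed. This template is a documented stand-in,
used consistently for generation and fitting. Fitting is
Levenberg-Marquardt least squares (`minpack.lm`) with data-driven
starting values (period from the circadian periodogram peak, heights
from morning/evening maxima); the reported error is
`RSS / (n · var(y))`, the fraction of variance left unexplained.
Parameter recovery from template data with 5% multiplicative noise is
verified to within 10% on rates and heights and 0.5 h on durations and
the period.

**Shuffling and correlations.** The shuffling experiment permutes the
grooming bins uniformly at random and compensates either locomotion or
wakefulness via
`modified = original companion + original grooming − randomized grooming`,
re-drawing the permutation until every modified bin lies in [0, 1].
The conservation identity holds bin-wise to machine precision by
construction. Pearson correlations between behaviors are tested by
re-pairing: the null distribution of r is built from `n_resamples`
(default 100 000) random permutations of one margin, and the two-tailed
p-value is `(1 + #{|r_null| ≥ |r_obs|}) / (n_resamples + 1)` — the +1
continuity correction keeps p strictly positive.

# Synthetic ground truth

The generator defines the study conditions for every test:

* **Scripts.** Behaviors alternate in bouts with exponential durations
  (floored at one analyzed frame). The exponential is a stand-in: the
  observed statistics available are mean event durations (~0.23 min
  grooming, ~0.44 min locomotion), and a renewal process with those
  means is the simplest generator matching them — no claim about the
  true bout-length law of flies is intended. Rest bouts default to a
  20-s mean capped just below 5 min; sleep bouts are 300 s plus an
  exponential excess (mean total 25 min), so sleep is ≥ 5 min and short
  rest < 5 min by construction. An optional two-peak circadian profile
  modulates the probability of starting an active bout.
* **Rendering.** The fly is an elongated two-tone ellipse (~300 px,
  core gray 40, periphery 90) on a uniform background of gray 180 with
  i.i.d. Gaussian pixel noise of sd 2 — at `C0 = 10` (5 noise sd of a
  frame difference) the threshold removes essentially all of it,
  mirroring the empirical property that motivates `C0`. The background
  level is the renderer's own choice: an infrared-illuminated arena is
  much brighter than the fly, and 180 keeps even the lightest periphery
  tested (gray 105) some 75 levels below the background, so
  segmentability reflects the algorithm rather than an artificially
  starved contrast. Rest leaves pixels unchanged;
  locomotion translates the body at 0.75–2.5 px per native frame with
  reflection at the tube ends; grooming redraws a random contiguous
  10–40% of periphery pixels one step outward each frame in two
  antipodal arcs, so the periphery churns (the PM ≫ CM signature) while
  the rendered centroid stays within half a pixel; feeding parks the
  fly at the food end.
* **Not emulated:** limb kinematics and grooming subtypes, perspective
  and lens distortion, occlusion, condensation and food-debris
  artifacts, gradual lighting changes beyond a uniform drift option.
  Consequently the synthetic benchmarks demonstrate that the pipeline's
  logic is correct and robust to size/contrast variation — they do not
  certify performance on any particular recording rig, which depends on
  optics and husbandry outside the algorithm's control.

# Benchmark sizes and numerical choices

The packaged benchmarks use 10 synthetic videos of 10 min at 10 Hz per
condition (plus a disjoint 4-video training fixture), four appearance
variants spanning ±30% body area (210 and 390 px) and ±15 gray levels
(25/75 and 55/105), 2000 Monte-Carlo white-noise series for the
threshold check, and 100 permutation seeds for the loss-of-rhythm
check. These sizes keep the whole suite comfortably reproducible on a
single CPU while leaving the statistical checks well-powered; all seeds
are fixed and every stochastic stage takes an explicit seed argument.

Degenerate inputs are handled explicitly rather than silently: constant
series are rejected by the periodogram, zero-variance vectors by the
correlation functions, constant-gray blobs fall back to an index-order
split, a never-detected fly raises an error naming the fly, and
non-convergence of the two-peak fit is reported with the optimizer's
message rather than replaced by a fallback.

# Known limitations

* One fly per ROI by construction; no cross-tube identity tracking.
* The three-class feature space cannot separate grooming subtypes
  (head vs wing grooming), and feeding is a proximity proxy, not
  proboscis detection.
* The two-peak template is this package's fixed convention; fitted
  rate signs are comparable within the package but not directly to
  parameter tables produced under other template conventions.
* Video I/O is PNG frame sequences (plus in-memory arrays); container
  formats such as AVI should be unpacked to frames first.
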