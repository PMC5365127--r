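---
title: "Motion morphing and reverse-rating analysis: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Motion morphing and reverse-rating analysis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kinemorph)
```

## The paradigm

In a reverse-rating experiment the participant does not rate a fixed
stimulus; they *build* one. A gesturing stick figure (or a single moving
dot) is shown together with three sliders controlling vertical amplitude,
horizontal amplitude and playback velocity, and the participant adjusts the
sliders until the motion matches a verbal item such as "very aggressive" or
"not trustworthy". The slider triplet at the moment the round is completed
is the response. Analysing which slider settings discriminate the "high"
from the "low" version of each item reveals which motion cues carry which
social meaning.

This package implements the full machinery of that paradigm headlessly:
stimulus preparation from landmark trajectories, the morphing engine, the
session protocol, simulated participants, and the statistical pipeline.

## Data model

A motion sequence is a tidy tibble (`frame`, `landmark`, `x`, `y`) over a
fixed skeleton of 12 named landmarks (`km_landmarks()`), with the frame rate
(default 25 fps), a desk reference line and a label carried as attributes.
Coordinates are in pixels with **y increasing upward**, so distances above
the desk grow as hands rise; the desk is a horizontal line below the hands.
The canonical landmark list is a package convention: the measures below only
require forehead, throat, both hands and the centre of gravity; the
remaining joints exist so a connected figure can be drawn and morphed.

Files round-trip through a tidy CSV dialect (`#fps=` header comments) or
JSON (bit-exact coordinate round-trip, written with 17 significant digits).

## Standardization

Figures differ in body height and screen position, which would confound
amplitude measures. Height is defined as the maximal vertical
forehead-to-centre-of-gravity distance over the sequence ("maximum
stretch"); all coordinates are scaled uniformly about the origin so this
equals 275 px, then translated rigidly so the centre of gravity sits at
(345, 341) in the maximum-stretch frame. Ties for the maximum-stretch frame
break toward the earliest frame. The desk line is scaled and translated with
the figure. Scaling is deliberately uniform — per-axis scaling would distort
the horizontal amplitudes the study manipulates. The combined operation is
idempotent to 1e-9.

## Expansiveness and prototype selection

Per-frame expansiveness estimators:

* vertical: `E_v(t) = |y_rh − d| + |y_lh − d| + |y_throat − d|` (heights of
  both hands and the throat above the desk line `d`);
* horizontal: `E_h(t) = |x_rh − x_th| + |x_lh − x_th| + |x_th|` (hand
  offsets from the throat plus the throat's offset from the origin, i.e.
  body sway).

For each sequence the contiguous five-second window (125 frames at 25 fps,
stride 1) maximising the *windowed sum* of per-frame scores is located; the
sum rather than the peak is used because it rewards sustained expansive
movement, and ties break toward the earliest start. Window starts are
reported 1-based, the R convention. Sequences are ranked by that window
score and the top ten per axis become prototype material; per-landmark
max-minus-min amplitudes within a window are reported for plausibility
checks only.

## The morphing engine

Prototypes isolate one axis: a vertical prototype keeps a sequence's
y-tracks and replaces every frame's x-coordinates with those of the
*standard figure* — a neutral posture standing centred on the desk with
both hands held close together at navel height (`standard_figure()`; the
exact coordinates are a documented package convention, also shipped as
`inst/extdata/standard_figure.csv`). Composition inverts that split: the
stimulus takes its y-track from the vertical prototype interpolated toward
the standard posture at weight `s_v/10`, its x-track from the horizontal
prototype at weight `s_h/10`,

$$y'_{i,t} = w\, y_{i,t} + (1-w)\,\bar y_i,$$

so weight 0 damps an axis completely to the standard posture and weight 1
reproduces the prototype. Interpolation is linear in the weight; the
vertical slider provably never changes an x-coordinate and vice versa.

The velocity slider changes only the playback frame rate. Both printed
anchor rates — 25 fps at the far left and 58 fps at the far right — are
honoured exactly by a linear map with half-away-from-zero rounding,
`fps = round(25 + s·33/10)`. A fixed step of three frames per second over
eleven slider positions would end at 55 fps and cannot reproduce the 58 fps
anchor; the two anchors were judged the binding constants, and the linear
map is the minimal mapping honouring both. (A twelve-position velocity
slider would reconcile the two descriptions; the adjacent sliders have
eleven.)

Paired prototypes of unequal length are truncated to the shorter with a
warning; in the intended workflow all windows are five seconds long, so the
case only arises with user-supplied material.

Rendering is headless: `render_animation()` writes a stack of PNG frames on
a 768 × 432 canvas (the animation-window size of the rating interface) plus
a `manifest.json` carrying the frame count and the playback fps; stick mode
connects `km_edges()`, dot mode draws one disc. The frame stack with its
manifest is the package's export container for animations; any encoder can
assemble it into a movie.

## The session protocol

One session is ten rounds: each of the five categories (dominant,
trustworthy, friendly, aggressive, competent) in a high and a low version
exactly once, in seeded-random order. Every round starts from a freshly
drawn vertical × horizontal prototype pairing (independent uniform draws
from the two pools of ten, a support of 100 combinations) and centred
sliders (5, 5, 5). A round can be finalized only after all three sliders
have been *touched*; touching is interaction, so deliberately keeping the
centred value 5 still counts — requiring a changed value would bias
responses away from the centre. The finalized record codes the item's high
version as 1 and the low version as 0.

## Synthetic data

Two generators make the pipeline testable end to end.

**Gestures.** `synth_motion()` emulates a speaker behind a desk: hands
oscillate smoothly (two incommensurate sinusoids plus low-amplitude smooth
jitter) and the torso sways and bobs at a fraction of the hand amplitudes.
Hands rest near the standard posture and gesture *one-sidedly* — upward on
the vertical axis, outward on the horizontal axis — which is the kinematics
the expansiveness estimators presume: a gesture departs from the rest pose
and returns to it, rather than oscillating symmetrically below the resting
hands through the desk. Realized hand excursions (max − min) are rescaled
to equal the requested amplitudes exactly. Corpus amplitudes are drawn from
plausibility ranges for expansive speaker material (right-hand vertical
137–204 px, horizontal 92–243 px). Everything is deterministic per seed.

**Participants.** `response_profile()` describes, per (category, polarity),
target medians for the three sliders on the 0–10 scale; the built-in
profiles use the observed median slider settings of the stick-figure and
dot experiments. A response is the target median plus Gaussian noise,
rounded and clipped to 0..10. Two dispersion choices matter:

* `sigma = 3` by default: the observed interquartile ranges are typically
  about four slider steps wide, and IQR/1.349 ≈ 3 for a Gaussian.
* a lapse rate of 5%: each slider draw is, with probability 0.05, uniform
  on 0..10 instead. Real samples always contain occasional inattentive or
  contrarian settings; without this component, well-separated target
  medians (e.g. aggressiveness, (9, 10, 10) against (2.5, 2, 2)) produce
  high/low groups that are *linearly separable*, a structure no real
  dataset of this kind exhibits and on which maximum-likelihood logistic
  regression is undefined.

Noise is independent across sliders within a round; the inter-slider
correlations seen in real data (r ≈ .5 for dominance) emerge in analysis
through the high/low contrast, not from built-in correlation.

What the generator does **not** emulate: adjustment dynamics (trajectories
of slider moves within a round), participant-level response styles beyond
the shared lapse rate, within-round dependence between sliders, and the
idiosyncratic kinematics of real speakers. Passing tests therefore show
that the pipeline recovers the structure this generative model puts in —
they do not validate claims about human behaviour.

## Statistical pipeline

**Descriptives** are medians with first and third quartiles per (category,
polarity, slider) cell, using the linear-interpolation quantile definition
(R type 7); responses are bounded and skewed, so medians are the central
tendency of choice.

**Logistic models.** Per category, the high/low coding is regressed on the
sliders (all three, and singly) by maximum likelihood with intercept.
Confidence intervals are profile-likelihood based — the sampling
distributions of these coefficients are visibly asymmetric — with a Wald
fallback and warning if profiling fails. p-values are two-sided Wald tests,
flagged against a Bonferroni-adjusted alpha of 0.05/30 (5 categories × 3
predictors × 2 model families per experiment). Each participant contributes
one high and one low record per category, and this repeated-measures
dependence is deliberately ignored (no random effect), matching the
paradigm's standard analysis; n per model is twice the sample size.

**Separation.** Complete or quasi-complete separation makes the MLE
diverge. `fit_logistic()` detects it (ordered linear predictor with
collapsed deviance, or diverging coefficients) and raises an explicit
error rather than returning a silently meaningless fit. `build_report()`
omits such a category with a warning and reports the rest. Under the
default generator conditions this genuinely happens for the aggressiveness
profile in roughly half of simulated replicates — its printed target
medians are extreme — which is itself a useful reminder that simulated
data can be cleaner than any human sample.

**Relative weights.** Standardize X; take the SVD X = PΔQᵀ; form the
orthogonal surrogate Z = √(n−1)·PQᵀ (unit-variance, mutually orthogonal,
closest to X in least squares) and the loadings Λ = QΔQᵀ/√(n−1), the
symmetric square root of the predictor correlation matrix, so
λ_jk = cor(x_j, z_k); regress the outcome on Z; then
ε_j = Σ_k λ²_jk β*²_k. Because ΛᵀΛ is the correlation matrix with unit
diagonal, Σε_j equals the model's R² exactly in the linear case, and with
exactly orthogonal predictors ε_j reduces to the squared zero-order
correlation. Weights are invariant to predictor order.

For a binary outcome the surrogate regression is logistic and "explained
variance" needs a pseudo-R² analog for the weights to sum to. The analog is
not uniquely determined by the sum property; the package defaults to the
squared Pearson correlation between the outcome and the fitted
probabilities — the analog closest in spirit to "variance of the outcome
explained" — and offers McFadden's ratio as an alternative. The analog in
use is named in every output (`r2_type`).

**Interval overlap.** Following the Cumming–Finch guideline, two 95%
intervals that are disjoint or touch at a single point are labelled as a
difference at roughly p < .01; overlapping intervals support no claim. The
verdict is pure interval arithmetic and symmetric in its arguments.

## Numerical conventions and degenerate inputs

* Quantiles: type 7 (linear interpolation), stated in the descriptives
  documentation.
* Window search: ties toward the earliest start; 1-based start indices.
* Rounding of the fps map: half away from zero, so both anchors are exact.
* Figures whose forehead and centre of gravity coincide in every frame have
  no height and are rejected.
* Zero-variance predictors are a rank error for models and flagged `NA`
  entries (with a warning) in correlation matrices.
* Rank-deficient predictor matrices (singular-value ratio below 1e-9) are
  rejected before the surrogate decomposition.
* The chi-square uniformity check of the pairing distribution and every
  other stochastic test run under fixed seeds.

## Problem sizes in the test suite

The suite mirrors the design sizes of the paradigm: simulated experiments
use 42 (stick) and 40 (dot) participants; direction-recovery and
null-calibration properties use 100 seeded replicates of 42 participants;
pairing uniformity uses 2,000 seeded sessions against the 100-pair support;
oracle checks of the window search use 50 random series against brute-force
enumeration; interpolation contracts are verified over 100 random
prototypes. Under a null response profile the summed relative weights of a
3-predictor model at n = 84 follow roughly a χ²₃/n distribution (mean
≈ 0.036, 95th percentile ≈ 0.093), and the null-calibration test bounds
that distribution rather than a single hard cutoff.

## Known limitations

* The analysis ignores participant-level dependence by design; a
  mixed-effects reanalysis is out of scope.
* Only Bonferroni correction is provided.
* The renderer exports frame stacks, not encoded movie containers.
* The 12-landmark skeleton is fixed; data with other marker sets must be
  mapped onto it first.
* Simulated participants share one response model; heterogeneity across
  people is limited to seed-driven sampling noise.
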