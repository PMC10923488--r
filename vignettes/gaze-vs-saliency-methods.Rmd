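---
title: "Comparing gaze attention and classifier saliency: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing gaze attention and classifier saliency: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the models and their assumptions, the parameters that matter, what the
synthetic-data generator does and does not emulate, and the choices made
where the design was genuinely open. It states no empirical result that the
test suite or `scripts/acceptance.R` does not itself compute.

## The analysis chain

The pipeline compares two-dimensional nonnegative intensity maps. On the
human side these are gaze attention maps; on the model side,
occlusion-saliency maps. Both are reduced to a comparable form before any
metric is computed:

1. **Rendering.** A fixation at pixel $(x, y)$ with duration $d$ ms
   deposits $d \cdot k(\lVert u - (x,y)\rVert)$, where $k$ is a Gaussian
   with $\sigma = r/2$ truncated at radius $r$ (default $r = 25$ px at
   720-pixel image scale). Deposits from all fixations of one
   participant-image trial sum. Consequence (tested): total map mass is
   proportional to total fixation time whenever no kernel is clipped by the
   frame border, and map construction is linear in duration. The linearity
   of rendered intensity in fixation duration is an assumption: commercial
   eye-tracking renderers do not document their transfer function.
2. **Common-attention subtraction.** Humans concentrate on eyes, nose and
   mouth regardless of diagnosis. Each group's mean map over *all*
   participants and *all* images is subtracted from each individual map,
   clipping negatives at zero, so that what remains is attention specific
   to the image. Clipping at subtraction time (rather than deferring it)
   keeps nonnegativity a global invariant of every public operation.
   Subtraction is applied per participant map and the results averaged;
   when no pixel clips, this is exactly equal to subtracting from the
   average (a tested commutation property), so the order is a presentation
   choice, not a modelling one.
3. **Smoothing.** A uniform box filter (default 15 px at study scale;
   shrink-to-valid windows at the borders so edge mass is averaged over
   fewer cells, never padded) followed by a global rescale to the
   pre-smoothing maximum. The rescale implements "intensity boosting"
   deterministically: smoothing spreads peaks, the rescale restores their
   height, making mid-range attention visible without moving the argmax.
   Whether such boosting is display-only or part of the quantitative chain
   is ambiguous in practice; here it is kept quantitative but
   max-preserving, so it never changes which pixels survive a
   coverage-based threshold (only their retained magnitudes).
4. **Noise thresholding.** Pixels strictly below a cutoff are zeroed;
   survivors keep their values. Three cutoff modes exist (`absolute`,
   `fraction_of_max`, `coverage_fraction`). The study-level defaults are
   coverage fractions of the face region: 0.07 (low) and 0.035 (high).
   These values are the observed coverages of human maps after low/high
   noise removal (6–8% and 3–4% respectively), so the saliency side can be
   matched to them; the numeric cutoffs the eye-tracking software itself
   uses are not published, which is why coverage is the primary
   parameterisation here.

On the saliency side, for a classifier satisfying the probability contract
(labels plus a deterministic `image -> probability vector` function), a
$20 \times 20$ occluder slides at stride 10, only at positions fully inside
the image; each placement zeroes the covered pixels (raw 0, the value the
quoted occlusion method uses, not a channel mean) and records
$\max(0, p_t^{0} - p_t^{\text{occ}})$ for the target label $t$. Negative
drops — occlusion *raising* the target probability — are clipped because the
method measures positive contribution. Per-pixel saliency is the **mean
drop over covering boxes**: with stride < box, pixels are covered by up to
$(\text{box}/\text{stride})^2$ boxes, and averaging keeps the scale
independent of that multiplicity (summing would inflate interior pixels
fourfold). Pixels within box-size of the right/bottom border that no full
box reaches are 0; at study scale that strip lies outside the face region.
The target probability on the intact image must exceed $10^{-4}$ (hard
refusal, mirroring the exclusion of an image whose ground-truth probability
collapsed) and warns below $10^{-2}$. Ensemble saliency is the pixel mean
over the (default 5) member models. When a classifier declares an input
resolution different from the map resolution, images are nearest-neighbour
resized in and the saliency grid mapped back the same way.

**Coverage matching.** Saliency maps are much denser than thresholded human
maps, and IoU/KL are unreliable when the two inputs contribute very unequal
numbers of active pixels. The cutoff is therefore chosen by rank selection
on the sorted in-mask values so the retained nonzero count is as close as
possible to the reference's — equivalent to a grid search over cutoffs but
exact and $O(n \log n)$. Tie handling at the cutoff value: keep all tied
pixels if that lands closer to the target count, otherwise drop them; when
equidistant, prefer the sparser map. Human-versus-human comparisons are
*never* coverage-matched (their coverages are genuinely different and that
difference is informative); human-versus-saliency comparisons always are.
Both behaviours are asserted in the integration tests.

## Metrics

* **IoU** binarizes (nonzero → 1) and returns
  $|A \cap B| / |A \cup B| \in [0, 1]$. When both maps are empty the value
  is undefined and returned as `NA` — never 0 or 1 — and the image is
  dropped from pooling with a logged exclusion.
* **Symmetric KL** restricts both maps to the union of their supports
  (intersected with the face mask in pipeline use), adds $\varepsilon$,
  renormalises, and returns
  $\tfrac12[\mathrm{KL}(p\|q) + \mathrm{KL}(q\|p)]$ in **nats** (the base
  is a convention choice; no published unit exists to match).
  $\varepsilon$ defaults to $10^{-9}$ times the mean nonzero intensity of
  the two maps: with disjoint support regions KL is infinite, and
  data-scaled smoothing keeps the metric finite, approximately
  scale-invariant, and continuous as $b \to a$ (all tested properties).
  $\varepsilon = 0$ is accepted only for identical supports.
* **Bootstrap SD.** The participant is the independent unit, so replicates
  resample participants with replacement (never pixels), rebuild the group
  map through the full subtract–average–smooth–threshold chain, and
  recompute the metric against the fixed second map; the SD over `B`
  replicates (default 1000 for the standalone function, 200 inside the
  pipeline where dozens of cells are computed) is the reported uncertainty.
  Replicates with an undefined metric are dropped with a warning. A fixed
  seed makes the whole path deterministic; for 3 participants the result is
  checked against exhaustive enumeration of all $3^3$ resamples.
* **Random-effects pooling.** DerSimonian–Laird was chosen as the standard
  non-iterative forest-plot default; the installed `metafor`
  implementation serves as an independent cross-check in the tests, not as
  the implementation. Within-image variances are the squared bootstrap SDs,
  floored at $10^{-8}$ so an all-identical bootstrap cannot produce an
  infinite weight. Metrics are pooled on their raw scale (no logit/log
  transform), matching how such results are plotted. The Pearson chi-square
  on the 2×2 accuracy table uses **no continuity correction**: on the
  bundled answer-sheet totals the uncorrected statistic reproduces the
  reference p-value to its printed precision while the Yates-corrected one
  does not — the package tests document that check.

## AOI metrics

Areas of interest are polygons over dysmorphic features. Per AOI the
pipeline reports total fixation duration inside the polygon and the onset
of the earliest fixation inside it. Point-in-polygon is ray casting with
points on an edge or vertex counted inside — the inclusive boundary is the
deliberate choice, since AOIs are drawn tightly around small features. A
"whole" fixation is approximated as any fixation event whose point lies in
the AOI; sample-level gaze traces are out of scope.

## The synthetic-data generator

No raw eye-tracking recordings are distributable, so the generator produces
complete studies with known ground truth:

* **Layout** — landmarks (eyes, nose, mouth, ears, forehead, chin) at
  canonical positions on a 720×720 frame with small seeded jitter, an
  elliptical face mask (~52% of the frame), and one condition-feature disc
  per affected image drawn from a bank of plausible dysmorphic-feature
  locations (brows, philtrum, nasal bridge, jaw, ears, ...). Default image
  set: 10 affected + 6 unaffected, the emulated study design.
* **Gaze profiles** — a mixture over landmarks plus the image's feature
  region. Clinician defaults put weight 0.26 on the feature and the rest on
  landmarks; non-clinicians 0.08 on the feature with more on eyes/nose/
  mouth. Both groups therefore share the common-attention structure and
  differ mainly where the diagnosis lives, which is what produces the
  tested low-versus-high threshold trend (IoU falls, KL rises). Spatial
  spread is σ = 0.045·min(H, W) per fixation; ~18 fixations per 7-second
  trial (≈2.5/s, an ordinary free-viewing rate); response accuracies
  default to the reference group rates 0.856 and 0.769.
* **Idiosyncrasy** — each participant receives a fixed gaze translation
  (sd 0.03·min(H, W)) and a multiplicative jitter of the mixture weights,
  emulating stable personal viewing styles.
* **Substreams** — every participant×image trial derives its own seed from
  the master seed through a hash whose final step runs through the RNG
  itself; adding participants or images never perturbs existing streams.
  (A purely linear hash demonstrably produces correlated sibling streams;
  the mixture goodness-of-fit test in the suite guards this.)
* **Toy classifier** — per-label prototype images; prediction is a softmax
  over negative mean-squared distance at temperature $8 \times 10^{-4}$.
  Prototypes of different labels differ *only* inside feature regions, so
  occluding anything else changes all label distances equally and yields
  exactly zero saliency — the truly salient region is known by
  construction, and the suite checks that ≥80% of ensemble saliency mass
  falls inside it. Five ensemble members differ by a shared per-model noise
  field, which preserves that property.

**What the generator does not emulate:** photorealistic faces, saccade
dynamics, pupillometry, calibration drift, the partial binarization of
commercial heat-map renders, correlations between viewing behaviour and
response correctness, or a classifier with real generalisation behaviour.
Passing tests therefore demonstrate that the *analysis chain* is correct
and recovers known ground truth — not that any particular human dataset
would yield particular metric values. Published headline magnitudes depend
on undeposited recordings and a GPU-trained ensemble and are out of reach
at desk scale by design.

## Problem sizes and defaults

`generate_cohort()` defaults to the emulated study design (22 + 22
participants, 16 images, 720×720 frames, kernel radius 25, 7000 ms trials).
`generate_toy_study()` — the end-to-end fixture used by the examples, the
integration tests and the acceptance script — is the same geometry at
one-third scale: 240×240 frames, radius 8, smoothing kernel 5, 8 + 8
participants, 5 affected + 3 unaffected images, toy classifier at native
resolution. These sizes were chosen once so that a complete
simulate-to-pooling run is a single-CPU, few-minute computation while every
stage still operates far from degenerate regimes (hundreds of in-mask
pixels above threshold, subgroups large enough to bootstrap). The pipeline
bootstrap default is B = 200 per cell; the standalone `bootstrap_sd()`
keeps B = 1000.

## Numerical and degenerate-input choices

* Negative intensities are clipped at object creation; every public
  operation preserves nonnegativity and shape.
* Stage labels (`raw → common_subtracted → smoothed → thresholded_*`) only
  move forward; backwards transitions error.
* All-zero subgroup maps (possible when an underperformer matches the
  common pattern exactly) are excluded cells, logged with a reason, and the
  accounting invariant `rows + exclusions = images × pairs × levels` is
  asserted per run.
* A 2×2 accuracy table with a zero margin yields `NA` chi-square values in
  pipeline output rather than an error (toy cohorts can be all-correct).
* Comparison cells are only computed when both subgroups have ≥2
  participants (the bootstrap minimum); smaller cells are logged
  exclusions.
* Result tables are written with deterministic formatting; rerunning a
  configuration reproduces byte-identical files, which the suite asserts.
* Within-group success-versus-underperforming comparisons are computed at
  both threshold levels (not only the low one) so the exclusion accounting
  stays uniform across pairs.
* Map storage: dense TSV matrices are the lossless quantitative format;
  PNG export is 8-bit (the encoder's depth) and intended for visual
  inspection, with the intensity scale carried alongside.

## Known limitations

* The fixation-rendering kernel is a modelling stand-in for proprietary
  renderers; only its radius is anchored to the emulated hardware setting.
* KL values depend (weakly, via $\varepsilon$) on the smoothing constant
  when supports are nearly disjoint; reported values should always be read
  together with the coverage level.
* DerSimonian–Laird τ² is noisy at small k (here k ≤ 16 images); the
  recovery test quantifies, rather than eliminates, that noise.
* The CLI covers the study pipeline; it is not a general eye-tracking
  toolbox (no fixation detection from raw gaze samples, no AOI editor).
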