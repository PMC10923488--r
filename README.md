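# gazemetrics

Quantitative comparison of human eye-gaze attention and deep-learning
saliency on facial images of genetic conditions.

When clinicians examine a facial photograph for signs of a genetic syndrome,
where do they look — and does a computer-vision classifier "look" at the
same places? `gazemetrics` implements the full analysis chain needed to
answer that question quantitatively: it turns eye-tracking fixations into
attention heat maps, removes the generic face-viewing bias every human
shares, thresholds the maps at two noise levels, computes occlusion saliency
for any image classifier behind a simple probability contract, equalises map
coverages so the comparison is fair, scores map pairs with
Intersection-over-Union and symmetric Kullback–Leibler divergence, attaches
participant-level bootstrap standard errors, and pools the per-image results
with a random-effects meta-analysis. A synthetic-cohort generator with known
ground truth makes every stage testable without access to recorded
eye-tracking data.

It is aimed at researchers in dysmorphology, medical-image AI evaluation and
eye-tracking methodology who need a reproducible, tested pipeline for
human-versus-model (or group-versus-group) visual attention comparisons.

## The methods in brief

**Attention maps.** Each fixation deposits a truncated Gaussian kernel
(support radius *r* = 25 px, σ = *r*/2) scaled by its duration; deposits sum
into a per-participant, per-image map. The group's *common attention* — the
mean map over all participants and images, dominated by eyes, nose and
mouth — is subtracted from each individual map (clipped at 0) to expose
condition-specific attention. Subgroup averages (successful/underperforming
× clinician/non-clinician, per image) are box-filter smoothed and
noise-thresholded at a *low* level (keeping ≈7% of the face region) and a
*high* level (≈3.5%).

**Occlusion saliency.** For a classifier `p = f(image)` and target label
*t*, a `20 × 20` box slides at stride 10; each placement zeroes the covered
pixels and records the drop `max(0, p_t(original) − p_t(occluded))`.
Per-pixel saliency is the mean drop over all covering boxes. Maps from an
ensemble of models are averaged, then *coverage-matched*: a cutoff is chosen
by rank selection so the saliency map keeps the same number of nonzero
face-region pixels as the human reference map.

**Comparison metrics.** For binarized maps `A`, `B`:
`IoU = |A ∩ B| / |A ∪ B|` ∈ [0, 1]. For maps rescaled to probability
distributions on the union support (ε-smoothed):
`KL_sym = ½[KL(p‖q) + KL(q‖p)]` in nats. Bootstrap SDs resample
participants (not pixels) and rebuild the group map per replicate.

**Pooling.** Per-image estimates are combined with the DerSimonian–Laird
random-effects model: `τ² = max(0, (Q − (k−1))/C)`, weights
`wᵢ = 1/(vᵢ + τ²)`, pooled mean `Σwᵢyᵢ/Σwᵢ` with `SE = (Σwᵢ)^(−1/2)`.
Group response accuracy is tabulated per image and compared with a Pearson
chi-square (no continuity correction).

## Worked example

The bundled per-image answer counts reproduce the group accuracy contrast:

```r
library(gazemetrics)
counts <- read.delim(system.file("extdata", "response_counts.tsv",
                                 package = "gazemetrics"))
acc <- accuracy_table(counts_to_records(counts))
acc$overall
#>          group correct incorrect percent_correct
#> 1    clinician     297        50        85.59078
#> 2 nonclinician     269        81        76.85714

ov <- acc$overall
cs <- chi_square_2x2(ov$correct[1], ov$incorrect[1],
                     ov$correct[2], ov$incorrect[2])
sprintf("chi-square = %.2f, p = %.4f", cs$statistic, cs$p_value)
#> "chi-square = 8.71, p = 0.0032"
```

Clinicians identified affected/unaffected status in 85.6% of image views,
non-clinicians in 76.9%, a difference unlikely under independence
(p = 0.0032).

A complete synthetic study — generation, preprocessing, saliency,
comparison, pooling — runs in a few minutes on one CPU:

```r
study <- generate_toy_study(seed = 1)          # 240x240, 8+8 participants
cfg   <- study_config(smooth_kernel = 5, seed = 1)
res   <- run_study(study, cfg)

subset(res$pooled, metric == "iou" & pair == "clin_success_vs_nonclin_success")
#>                             pair level metric     pooled         se k
#>  clin_success_vs_nonclin_success   low    iou 0.13456867 0.01808489 8
#>  clin_success_vs_nonclin_success  high    iou 0.05990719 0.01441946 8
```

The pooled IoU between successful clinicians and successful non-clinicians
drops from 0.135 at the low noise-threshold to 0.060 at the high one (and
the pooled symmetric KL rises from 15.8 to 18.5 nats): with this generator's
profiles the two groups share landmark attention but diverge exactly where
the condition-specific features are, and the high threshold isolates that
divergence. The clinician-versus-saliency comparison at the low threshold
pools to IoU 0.250 / KL 9.35 over the 5 affected images. Absolute magnitudes
are properties of the synthetic cohort, not of any human dataset; the
qualitative low-versus-high ordering is the behaviour the pipeline is
designed to expose.

A shell driver with `simulate`, `preprocess`, `saliency`, `compare`, `pool`,
`report` and `all` verbs wraps the same functions:

```sh
Rscript inst/cli/gazemetrics.R simulate --dir study/ --seed 1
Rscript inst/cli/gazemetrics.R all --dir study/ --out study/results --seed 1
```

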