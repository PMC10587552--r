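---
title: "Methods: severity grading with lesion-count priors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: severity grading with lesion-count priors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Acne severity drives treatment choice, but image-based severity grading is
noisy: dermatologists disagree with each other, and lesion counting alone
ignores inflammation depth, scarring and pigmentation. `acnegrade`
implements a grading pipeline built around one idea: the counts of
inflammatory lesions (papules, pustules, nodules/cysts) do not determine a
grade, but they *constrain* it. The pipeline therefore

1. detects and counts lesions on a facial image,
2. maps the inflammatory counts to a **grading interval** — a sub-range
   `[lo, hi]` of the 8-level treatment-intensity scale — through an explicit
   prior rule, and
3. fuses that interval with the probability output of an ordinal image
   classifier, either as a fixed binary mask or as learnable per-interval
   weights.

The severity scale itself is expressed as treatment intensity
(`severity_scale()`), from "No treatment necessary" (grade 1) to "Should be
on isotretinoin" (grade 8); the top level pools the rare severe and very
severe presentations.

## The grading rule

`counts_to_interval()` pools papules and pustules into an inflammatory
count I and treats the nodule/cyst count N separately, because deep
inflammatory lesions escalate treatment regardless of superficial counts.
The default table (first match wins) is:

| condition      | interval |
|----------------|----------|
| N >= 2         | [6, 8]   |
| N = 1          | [5, 7]   |
| I >= 30        | [5, 6]   |
| 15 <= I <= 29  | [4, 5]   |
| 5 <= I <= 14   | [3, 4]   |
| 1 <= I <= 4    | [2, 3]   |
| I = 0          | [1, 2]   |

Published count-based scales stop at a grade; the interval form is what lets
a classifier arbitrate *within* the constraint. Every interval has width at
least 2 so the prior guides rather than dictates. The table is monotone
(raising I or N never lowers the interval), exhaustive by construction —
both properties are fuzz-tested — and fully overrideable from YAML
(`load_grading_rule()`), which validates exhaustiveness at load time.
Whether counts come from ground truth or from the detector is an explicit
pipeline flag (`counts_source`), never an implicit default.

## The grader and the fusion

The grader is a compact softmax network: images are preprocessed
(resize, crop, optional flip/rotation augmentation), pooled onto a
`grid x grid` grid of per-cell mean RGB values, standardised, and passed
through one hidden ReLU layer to an 8-way softmax. Training uses Adam with
weight decay, cross-entropy loss, and a single-cycle cosine-annealed
learning rate from `lr_init` to `lr_final`. At desk scale
(64 px images, `grader_config()` defaults: grid 8, hidden 48, 80 epochs,
batch 32, lr 1e-3 -> 1e-4, weight decay 1e-4) this trains in seconds on one
CPU. A full-resolution preset (`paper_mode_config()`: resize 256, crop 224,
200 epochs, batch 32) carries the same protocol to photographic inputs.
Horizontal-flip augmentation is applied in feature space — for grid-pooled
features a flip is exactly a column permutation — which keeps augmented
epochs cheap; rotation augmentation is implemented in `preprocess()`
(bilinear, corners filled with the skin tone rather than black, to avoid
trivial rotation artefacts) for users training at higher resolution.

Fusion operates on the classifier's probability vector `p`:

* **Fixed weights** (`fuse_fixed`): `fused[g] = p[g] * m[g]` with the binary
  interval mask `m`, renormalised over the surviving support;
  the predicted grade is the argmax. Out-of-interval grades are impossible
  by construction, so every prediction lands inside the interval.
* **Learnable weights** (`fuse_learnable`): each *distinct* interval of the
  rule (7 under the default table) owns an 8-vector of non-negative weights
  `w`, applied the same way. During training (`fusion_mode = "learnable"`)
  the weights are softplus-parameterised and learned jointly with the
  network by noting that `p * w` renormalised is exactly
  `softmax(z + log w)` for logits `z` — gradients are standard softmax
  cross-entropy gradients with an extra `d log w / d u = sigmoid(u) / w`
  factor for the weight parameters. Weights are initialised to the binary
  mask softened by `epsilon = 1e-4` (in-interval 1, out-of-interval
  `epsilon`), so an untrained learnable fuser reproduces fixed fusion; the
  floor keeps gradients alive on masked-out grades. The fixed path uses
  exact zeros.

Ties in the argmax break toward the lowest grade — the conservative
(least aggressive treatment) choice. Renormalisation cannot change the
argmax; it is kept because the fused vector is reported as a probability.
In `"none"`/`"fixed"` modes the training loss is cross entropy on the raw
probabilities and the mask is applied only at inference; in `"learnable"`
mode the loss is cross entropy on the fused, renormalised probabilities.

Whether weights are shared across intervals or per-interval is a genuinely
open design point; per-interval weights were chosen because intervals of
different widths plausibly need different sharpening, and 7 x 8 parameters
add negligible capacity.

## The synthetic data generator

The generator exists so every downstream stage is testable without clinical
images. `generate_face_canvas()` draws an elliptical face on a neutral
background with mild Gaussian pixel noise; the ellipse is partitioned into
forehead (top 30% of face height), a 30–70% middle band split into a
central midface third and lateral cheek thirds, and jaw (bottom 20%).
`sample_lesions()` places category-specific ellipses by rejection sampling
from a mixture of the category's zone prior (weight 0.8) and a
face-uniform component (0.2), reflecting the qualitative facial
distribution of lesion types: closed comedones on forehead and midface,
open comedones on the forehead, atrophic scars on the cheeks, hypertrophic
scars on the jaw, inflammatory lesions diffusely. Placements whose box IoU
with any existing lesion exceeds 0.3 are rejected (the cap and its scope
are configurable); categories render with distinct colours and styles
(`lesion_palette()`) deliberately separable by a classical colour detector.

Severity is generated *from* counts through the same rule the pipeline
uses: the grade is the interval midpoint plus Gaussian jitter
(`jitter_sd = 0.7` by default — enough to occupy both interval endpoints
without degenerating to uniform noise), rounded and clamped to the
interval; midpoint ties on even-width intervals round half down, toward the
milder grade. The default severity mix draws the seven rule rows uniformly,
then samples counts inside the row's predicate, so all eight grades occur
with useful frequency — unlike clinic populations, which thin out at both
extremes. Non-inflammatory counts scale mildly with tier so images look
plausible, but by construction they cannot move the interval.

Rater panels (`simulate_raters()`) perturb true grades with per-rater bias
and Gaussian noise, rounded and clamped to 1..8.

Seeding is counter-based: one master seed, per-subject seeds derived by a
fixed integer mix (`derive_seed`), so any subject can be regenerated alone
and identical seeds give byte-identical datasets.

**What the generator does not emulate:** photorealistic skin, lesion
ambiguity (the classes are colour-separable by design), lighting and pose
variation, comorbid dermatoses, and rater behaviour beyond
bias-plus-noise. Green tests on synthetic data therefore validate the
*machinery* — metrics, rule, fusion, agreement statistics — not clinical
performance; real photographs require a learned detector plugged in behind
`detect_lesions()`'s contract.

## Detection and its evaluation

The reference detector classifies pixels by Euclidean RGB distance
(tolerance 0.07) to each category's key colour, labels connected
components (8-connected), and splits components whose area is a multiple of
the expected single-lesion footprint via k-means on pixel coordinates —
touching same-category lesions are the dominant failure mode at desk
resolution. Component boxes are scored by colour fidelity.

`evaluate_detection()` follows detection-benchmark convention: greedy
per-image, per-category matching in descending score order at IoU >= 0.5
(the threshold is configurable; 0.5 is the conventional choice), one
detection per truth; pooled ranked detections give a precision–recall
curve, and AP is the area under the all-point interpolated curve (monotone
precision envelope), not the older 11-point approximation. Per-class means
exclude classes absent from the ground truth instead of counting them as
zero, avoiding dataset-composition artefacts. The implementation is tested
to 1e-12 against an independent brute-force enumeration.

## Agreement statistics

`linear_weighted_kappa()` uses the agreement-weight form with
`w(i,j) = 1 - |i-j|/(n_levels-1)`; the algebraically identical
disagreement form serves as the test oracle, and the implementation matches
scikit-learn's linearly weighted kappa on random panels. Two identical
constant raters return 1.0 by documented convention (with a warning); any
other zero-expected-disagreement case errors. Rater selection ranks raters
by mean off-diagonal pairwise kappa and takes the top k (ties by column
order); consensus labels are per-subject medians of an odd-sized panel, so
integer ratings give an integer consensus.

The ICC is ICC(A,k): two-way random effects, absolute agreement, average
measures — chosen because the panel rates all subjects and the consensus
is an average-of-raters judgment; `type = "single"` gives ICC(A,1). Both
use the standard mean-squares decomposition with the F-based confidence
interval (average-measures bounds via the Spearman-Brown step-up), and
match `pingouin.intraclass_corr` to printed precision. Missing ratings are
dropped pairwise for kappa; the ICC requires a complete matrix.

One property worth understanding: recovering exactly the three least-noisy
raters from a 7-rater panel (noise sd 0.2–2.0) with only 40 subjects is at
the edge of what the mean-pairwise-kappa statistic can resolve — the gap
between the third- and fourth-noisiest raters (sd 0.8 vs 1.1) is comparable
to the estimator's own sampling error at that panel size, so occasional
swaps between exactly those two raters are expected rather than a defect.
The package's recovery check reports the replicate fraction so this margin
is visible.

## Benchmark sizes and numerical choices

The default synthetic benchmark trains on 600 and tests on 150 images at
64 px — large enough for stable kappa estimates, small enough for a
single-CPU run in seconds; the fusion-improvement property is evaluated
over five seeds and asks for a directionally consistent improvement
(fixed >= unfused in at least 4 of 5 seeds, learnable in at least 3 of 5),
not a fixed kappa value. The quickstart experiment (60 subjects, 64 px,
short schedule) completes in a few seconds and is the determinism fixture.
Grades round half down wherever a tie is possible, for consistency with
the midpoint rule. All stochastic entry points take explicit seeds and
restore the caller's RNG state; reproducibility is promised at the level
of predictions and serialized artefacts on a fixed platform, not
cross-platform bit-identity of trained weights.

## Known limitations

* The grader's grid-pooled colour features are matched to the synthetic
  rendering; real photographs need both a learned detector and a stronger
  backbone (the configuration surface anticipates this, tests do not
  require it).
* The rule's thresholds encode a lesion-counting convention, not a fitted
  model; they are data for the YAML override, not estimates.
* Learnable fusion is trained jointly from scratch; warm-starting from a
  fitted unfused model is not implemented.
* Severity modifiers beyond counts (inflammation degree, pigmentation,
  scarring extent) are deliberately left to the image pathway.
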