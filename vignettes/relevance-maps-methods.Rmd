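---
title: "Relevance maps for 3D classifiers: model, assumptions and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Relevance maps for 3D classifiers: model, assumptions and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

A classifier trained on 3D medical volumes (say, discriminating
high-grade from low-grade gliomas on multi-sequence MRI) learns *where*
the disease is without ever being told: the lesion is what drives its
prediction. Relevance maps recover that spatial knowledge from global
labels alone — weak supervision — by systematically occluding parts of
the input and watching the prediction move. The classifier is treated as
a black box throughout: the only thing the method touches is
`predict_prob(classifier, volume)`, a map from a volume to a probability
in $[0,1]$.

## The method

1. **Superpixels.** The volume is partitioned into $K$ compact,
   spatially connected clusters (SLIC supervoxels) computed on one
   configured channel. The partition is the resolution of the
   explanation: one score per superpixel.
2. **Perturbation.** Each superpixel in turn is perturbed:
   *blank* (voxels set to 0), *min*/*max* (voxels set to the superpixel's
   own per-channel extremum), or *optimal* — a learned multiplicative
   mask in $[0,1]$ emitted by a U-net-shaped generator.
3. **Scoring.** Superpixel $i$ receives
   $s_i = |y_{np} - y_p^{(i)}|$, the absolute change in predicted
   probability. Scores are normalized to $[0,100]$ via
   $100\,(s_i - \min s)/(\max s - \min s)$ and ranked descending.
   Unions of top-ranked superpixels are the candidate segmentations,
   evaluated against a reference with the Dice coefficient
   $\mathrm{DSC} = 2|X \cap Y|/(|X|+|Y|)$.

The learned perturbation is trained with the **perturbation loss**

$$L = \frac{1}{n}\sum_{i=1}^{n} \frac{1}{|y_{np,i} - y_{p,i}| + \varepsilon},$$

whose minimization maximizes prediction disruption. The published form
has $\varepsilon = 0$ and is singular when perturbed and unperturbed
predictions coincide; the default $\varepsilon = 10^{-6}$ makes the loss
total without moving its optimum.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `n_superpixels_requested` | 100 | requested SLIC clusters; the realized $K \le$ requested (similar clusters merge). The reference setting for 128³ volumes; phantoms at 32³ typically use ~30. |
| `compactness` | 0.1 | SLIC intensity/space trade-off on *normalized* intensities; smaller follows intensity boundaries more closely. The source study does not report its value; 0.1 keeps lesion boundaries crisp on the phantom world. |
| `superpixel_channel` | `"T2w"` | the single channel clustered on (the sequence found most separable in the reference study). |
| `perturbation_kind` | `"blank"` | the strongest naive perturbation in the reference results. |
| `epsilon` | 1e-6 | perturbation-loss regularizer (see above). |
| generator `lr`, `epochs` | 0.01, 25 | the published training setting; the *last* epoch is kept (published selection rule), with `checkpoint = "best"` as an override. |

## The phantom world

`generate_phantom()` emulates the structure of the reference dataset at
desk scale: multi-channel 32³ volumes, one ellipsoidal lesion per
volume at a random interior position (semi-axes drawn from 4–6 voxels),
correlated background texture (Gaussian-smoothed noise, smoothing
length 3 voxels, sd 0.08 around a 0.35 base level), additive noise
(sd 0.05), and a class-dependent lesion contrast: 0.3 for class 0, 0.6
for class 1, with the configured superpixel channel carrying the full
contrast and other channels half of it — mirroring the finding that one
sequence carries the most separable tumour signal. Datasets are 60%
class 1, mirroring the 60/40 class ratio of the reference cohort.

Two deliberate choices:

* **Normalization is clipping, not per-sample min-max.** Per-sample
  min-max maps each volume's own lesion peak to 1, which destroys the
  invariant that the class label is recoverable from lesion intensity
  (verified empirically during development). Phantom intensities are
  therefore constructed on a fixed $[0,1]$ scale and clipped. External
  data still goes through `normalize_minmax()` in preprocessing.
* **Lesions are single connected ellipsoids**, so oracle geometry
  (voxel counts, overlap fractions) is exactly computable in tests.

What a green test on phantoms does *not* establish: anatomical realism,
multi-focal disease, MRI physics (bias fields, partial volume), or the
reference study's absolute DSC levels, which depend on its dataset and
large pre-trained model.

## The classifiers

The pipeline only requires the `predict_prob` contract. Two
implementations ship:

* `oracle_region_classifier(region, channel)` predicts the clamped mean
  of one channel over a fixed region. Because it depends on *nothing*
  outside the region, relevance assertions become exact: a perturbation
  disjoint from the region changes the prediction by exactly zero. This
  is the keystone test fixture.
* `train_toy_classifier()` trains a small 3-block 3D CNN with Adam
  (lr 0.01) and binary cross-entropy, returning the epoch with the best
  validation AUC. The reference study's large residual network is
  deliberately not reproduced — the method is model-agnostic, and the
  contract, not the architecture, is normative. Two design points were
  forced by the phantom world: a **global max-pool head** (a compact
  lesion occupying ~2% of the volume vanishes in a global average;
  per-feature maxima see it) and **leaky ReLU** (slope 0.1: image
  intensities are all-positive, so plain ReLU units die globally when a
  bias drifts negative — observed as validation AUC pinned at 0.5).

## Generator training: numerical choices

The mask generator is a small U-net-shaped encoder–decoder (two
down/up levels with skip connections) whose output nonlinearity is a
**hard-sigmoid** — chosen over the logistic because it attains 0 and 1
exactly, so the learned mask family contains the blank perturbation as
an interior point of its range rather than an asymptote.

The reciprocal loss is numerically violent: its gradient scales as
$1/(|\Delta p| + \varepsilon)^2 \approx 10^{10}$ when predictions are
near-equal, and its *sign* flips noisily there. Left alone, Adam
random-walks the masks onto the all-ones boundary, where the perturbed
input equals the original, $|\Delta p| = 0$, the hard-sigmoid gradient
is zero, and training is dead — an absorbing state observed directly
during development. Three choices fix this:

1. **Gradient-norm clipping** (`clip_norm = 5`) caps the violent steps.
2. **Blank warm-start**: the output bias is initialized at $-1.9$, so
   initial masks are near 0 — training starts at (approximately) the
   strongest naive perturbation and moves away only where that
   *increases* disruption.
3. **Leaky saturation**: the backward pass keeps a 0.05 slope through
   the hard-sigmoid's flat zones, so boundaries are not absorbing.

On the phantom world the trained generator converges to the blank
optimum (masks → 0; mean $|\Delta p|$ under the optimal perturbation
equals blank's exactly). That is the honest desk-scale reading of the
"optimal ≥ naive" direction: with a multiplicative mask on a
monotone-responding classifier, blanking is already extremal, and the
learned perturbation discovers it rather than beating it. Whether it
can strictly beat blanking (as reported at full scale) depends on the
classifier's non-monotone responses, which this small world only weakly
excites.

## Other numerical conventions

* Ties in raw relevance scores break by ascending superpixel label;
  when *all* scores are equal the map is all-zero with a warning ("no
  region distinguished") rather than all-100.
* `DSC(\varnothing, \varnothing) = 0` with a warning, keeping aggregate
  means finite.
* The best-grouping search is prefix-based over the ranking
  ($k = 1..K$, smallest $k$ on ties), matching "iterate from highest
  ranked to lowest"; per-$k$ DSC values are returned so subset-style
  re-analysis stays possible.
* Center crops use `floor((size - crop)/2)` offsets (0-based,
  half-open); constant channels min-max-normalize to all zeros.
* Normalization order (the source is silent): this implementation
  normalizes *after* cropping by default, configurable via
  `normalize_order`.
* SLIC here is fully deterministic (grid-initialized); the `seed`
  argument exists for interface symmetry and is ignored.
* All randomness flows from one config seed through named substreams
  (phantom, split, shuffle, SLIC, generator), so identical seeds
  reproduce bit-identical artifacts.

## Known limitations

* The hand-rolled networks (no deep-learning framework exists in this
  R stack) are small and CPU-bound; 32³ volumes train in minutes, 128³
  volumes would not be practical.
* Superpixels are computed on one channel; multichannel SLIC is out of
  scope.
* Gradient-based baselines (Grad-CAM, LIME) are out of scope; the
  evaluation protocols cover the perturbation family only.
* The NIfTI reader handles the common scalar dtypes and pixdim spacing
  but does not interpret qform/sform orientation: axes are taken as
  stored.
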