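---
title: "Methods: tile-based scoring of NAFLD/NASH histology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tile-based scoring of NAFLD/NASH histology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The scoring problem

Preclinical NAFLD/NASH studies are read out with discrete histological
scores assigned by a pathologist on Masson's-trichrome liver sections:
ballooning (0–2), lobular inflammation (0–3) and steatosis (0–3) — the
Kleiner/NAS sub-scores — plus a separate fibrosis stage (0–4). Expert
scoring is slow, coarse (few unique values) and shows inter- and
intra-rater variability. `nashscoreR` implements an automated pipeline
that produces a *continuous* per-liver severity readout for each of the
four features and, where discrete scores are required, maps the
continuous value to a pathologist-like score through fitted thresholds.

The pipeline is: whole-slide image → two-scale tile grids → per-feature
tile classifier → per-tile softmax confidence vectors → ignore filtering
and renormalization → per-tile weighted class → per-liver mean
(continuous score x) → threshold mapping s(x) (discrete score).

# Tiling geometry

Tiles are 299 px squares, matching the input size of the Inception-V3
family of backbones. Two scales are used:

* **high**: 299 × 299 px source regions at 0.44 µm/px, exported
  unmodified — ballooning, inflammation, steatosis;
* **low**: 897 × 897 px source regions downscaled 1:3 to 299 × 299 px
  (1.32 µm/px) — fibrosis, whose diagnostic structures (bridging bands,
  cirrhotic nodules) need the larger field of view.

Grids are non-overlapping and axis-aligned with 0-based, half-open pixel
intervals; an image of W × H px yields ⌊W/s⌋·⌊H/s⌋ tiles. Partial border
tiles are *dropped*, not padded: padding would fabricate tissue content.
The 1:3 downscaling uses exact 3 × 3 block (area) averaging, a
deterministic choice that matches export-style decimation and admits an
exact round-trip test (a 3× pixel-replicated image block-averages back to
its original). Input slides are assumed to already be at 0.44 µm/px; a
declared µm/px off by more than 1% is rejected rather than silently
rescaled.

# Classifier and head

Each feature has its own classifier over its tile classes plus a trailing
**ignore** class for non-tissue content (mostly empty border, out of
focus, mostly blood, staining artifacts), so the softmax output lengths
are: fibrosis 6, ballooning 3, inflammation 4, steatosis 5. The head is
always: global average pooling of the backbone's last convolutional
feature maps `f_kxy` to pooled features `F_k`, dropout at rate 0.5, one
dense layer with weights `w_ck`, softmax.

Two backbones satisfy this contract:

* `reference_small` — a three-layer convolution stack written in base R
  matrix code (13×13/stride 13 patchify → 23×23×16; 3×3/stride 2 →
  11×11×32; 3×3/stride 1 → 9×9×48; ReLU throughout; He initialisation;
  inputs standardised to mean 0.5, sd 0.25). It trains in minutes on one
  CPU and exists so that the whole pipeline is testable end to end.
* `inception_v3_contract` — accepts any user function producing an
  `f_kxy` tensor (8 × 8 × 2048 for Inception-V3), training and applying
  only the head. This keeps the full-scale architecture as a contract
  without shipping pretrained weights.

Training uses stochastic gradient descent with momentum 0.9 and
categorical cross-entropy, monitored on a stratified ~10% validation
split. When the validation loss fails to decrease for more than two
epochs, the learning rate is multiplied by 0.2, floored at 1e-7. Class
imbalance is equalised by oversampling minority classes to parity per
epoch. Augmentation applies random rotations in [−π/4, π/4], horizontal
and vertical flips, and width/height shifts in [−30, 30] px; vacated
pixels are filled by reflection (one standard choice among several; the
effect is confined to a thin border). The default initial learning rate
is 0.5e-4 — appropriate for *fine-tuning a pretrained backbone*. Training
`reference_small` from random weights at that rate moves the parameters
imperceptibly within any reasonable epoch budget; the package's worked
examples and tests therefore train the reference backbone at 2e-2 with a
global gradient-norm clip of 5 (a deliberate, documented deviation for
the from-scratch regime; the schedule object keeps the fine-tuning default
so that fine-tuning scenarios are faithful). Batch size (32) and epoch
budget (max 50 with early stopping) are configuration defaults, as they
are not pinned by the recipe this package follows.

## Steatosis pre-labeling by classical computer vision

Steatosis tile classes are definable directly from the vacuole area
fraction, so tiles can be pre-labeled without a pathologist: bright
regions are segmented (Otsu threshold on luminance by default), connected
components are filtered by roundness 4πA/P² ≥ 0.5 and size 30–3000 px²,
and the retained area fraction assigns the class by the half-open
intervals 0: <5%, 1: ≥5% <33%, 2: ≥33% <66%, 3: ≥66%. The roundness and
size windows and the threshold are configurable; the defaults were chosen
for 299 px tiles at 0.44 µm/px, where single lipid vacuoles span roughly
5–60 px diameter.

# From confidences to one score per liver

A tile's softmax output is a confidence vector
q = (q_0 … q_{C−2}, q_ignore). Per tile:

1. **Ignore filtering** — a tile is retained iff ignore is not the argmax
   of q (ties break toward the lowest index, so a tie retains the tile).
   Filtering is applied per tile.
2. **Renormalization** — retained vectors are renormalized over the
   non-ignore classes: p_j = q_j / Σ_{i≤C−2} q_i. This corrects tiles
   that contain some ignore content alongside real pathology.
3. **Weighted class** — ⟨ip_i⟩ = Σ_i i·p_i, the expectation of the class
   index, a real number in [0, C−2]. The summation runs over the
   non-ignore classes only: p is undefined for the ignore class, so a
   printed upper bound that appears to include it is read as excluding
   it. This is flagged here rather than silently hidden.
4. **Aggregation** — the liver's continuous score x is the arithmetic
   mean of ⟨ip_i⟩ over retained tiles. Its range is 0–1 (ballooning),
   0–2 (inflammation), 0–3 (steatosis), 0–4 (fibrosis).

A liver whose every tile is ignore-dominated yields an explicit
"no tissue" error rather than a score; livers with fewer than 10 retained
tiles (configurable) carry a low-retention warning flag, since a mean
over a handful of tiles is unstable. For noise-free one-hot confidences
drawn from a tile-class mixture with mean m, x equals m exactly; this
identity anchors the aggregation tests.

# Threshold mapping and the Monte Carlo fit

Discrete scores come from ordered cuts t_0 < t_1 < …, one fewer than the
score set size: s(x) = a for t_{a−1} ≤ x < t_a, with the intervals
half-open (x exactly at a cut maps upward) and the top interval unbounded
(x ≥ t_last gives the maximal score).

Cuts are fitted against pathologist ground truth g_k over K livers by
minimising the class-weighted quadratic error

E = Σ_{a∈A} f_a Σ_{g_k=a} (s_k(x) − g_k)², with f_a = K/k_a,

where k_a counts livers with ground truth a; the weights compensate for
imbalanced score distributions. Score values absent from the ground truth
are excluded from the sum with a warning. The search is Monte Carlo:
initialise each t_a at the 75th percentile (linear interpolation between
order statistics, `quantile` type 7 — quantile conventions differ, so the
choice is pinned) of the x values with ground truth a; then repeatedly
perturb the incumbent best set with independent N(0, σ²) noise
(σ = 0.15), sort the proposal and separate exact collisions by 1e-6,
and accept only strict improvements in E. Strict acceptance guarantees a
strictly decreasing error trace. Convergence is declared after 2 000
consecutive rejected proposals (hard cap 100 000), both configurable:
the error landscape is piecewise constant with finitely many values, so
a long rejection streak at σ = 0.15 means the local neighbourhood is
exhausted. Held-back evaluation fits on a training cohort only and
reports MAE, Cohen's κ (unweighted — the convention of the inter-rater
literature this score family is compared against), weighted
precision/recall/F1, accuracy and the confusion matrix on both splits.

# Class activation maps

For any backbone exposing `f_kxy`, the class evidence map is
M_c(x,y) = Σ_k w_ck f_kxy, bias omitted. Because the pooling layer is a
true average while the map is a plain sum, the identity linking the map
to the pre-softmax score carries the spatial count H·W:
Σ_{x,y} M_c(x,y) / (H·W) = s_c. The constant is stored with every map so
the identity is testable exactly (to floating-point tolerance). Maps are
upscaled to the 299 px tile by bilinear interpolation (the interpolation
is not prescribed anywhere; bilinear is the common choice) and rendered
as alpha blends under a perceptually uniform colormap (viridis default,
configurable), with the class output probability printed in the corner.

# The synthetic data generator

No slide data ships with the package; every stage is exercised against a
synthetic generator with exact ground truth.

**Tiles** are geometric caricatures of trichrome appearance, not
photorealistic histology — downstream math consumes only confidences and
labels, so fidelity of the *class geometry* is what matters: steatosis
tiles place non-touching white vacuoles until the pixel-counted area
fraction lands inside the class interval (scattered circles at low
coverage; a jittered grid of rounded-square vacuoles at high coverage,
mimicking packed-vacuole morphology, each component inside the CV
labeler's size/roundness window); ballooning class 1 has 1–3 enlarged
pale cells with a dark rim; inflammation tiles draw dark cell clusters
and disseminated dots with counts inside the class definitions (the
printed class-0/1 boundary overlaps at exactly five disseminated cells
and is resolved half-open: class 0 strictly <5, class 1 includes 5);
fibrosis draws blue collagen in the staged topologies (single-region
strands; both periportal- and perisinusoidal-like positions; a band
bridging two nodes; a nodule fully enclosed by a band). Ignore tiles are
mostly-empty borders, out-of-focus washes (smooth, brightened toward the
illumination background, as defocused bright-field regions are), or
blood-dominant blobs. What passing tests on these tiles shows is that
the *pipeline machinery* is correct and that the reference classifier can
learn class geometry/colour statistics; they say nothing about
performance on real stained tissue, which varies in ways the caricature
does not model (stain intensity, compression artifacts, species
differences, transitional morphologies).

**Confidence vectors** are Dirichlet draws centred on the one-hot vector
of the true class, with one concentration parameter as the single
confusion knob (the true class has concentration κ, all others 1; κ → ∞
recovers one-hot).

**Cohorts** give each liver a latent severity u ∈ [0, m] and realise its
tiles from the two-point class mixture on ⌊u⌋/⌈u⌉ with weights (1 −
frac(u), frac(u)), whose mean is exactly u — so threshold recovery is
exact in expectation and the discrete ground truth is u mapped through
known cuts. By default the realised tile composition matches the mixture
weights exactly (integer rounding aside): then the only score noise is
confidence noise, which is what the aggregation identity and threshold
recovery properties assume; binomial per-tile sampling is available as an
option. Severity distributions: uniform, fixed, explicit values, or
*clustered* — normal around a uniformly drawn integer disease state
(default sd 0.25), reproducing the stair-like continuous-vs-discrete
structure of real cohorts in which most livers sit near a prototypical
state and thresholds fall in low-density gaps. Per-liver tile count
defaults to 500 high-magnification tiles; real sections yield from a few
hundred to several thousand tiles depending on section area, and the
properties tested here are insensitive to the exact count.

# Numerical and design choices

* Confidence rows must sum to 1 within 1e-6 on input; renormalized rows
  sum to 1 within 1e-9 by construction.
* `map_score` uses `findInterval` semantics matching the half-open
  definition; unordered cuts are an error, never silently sorted (only
  the MC proposal repair sorts, by design).
* Degenerate MC inputs (all x identical) return the initialization with
  a warning rather than iterating.
* The reference CNN's gradients are exact (im2col convolutions with
  matrix algebra); dropout uses inverted scaling so inference needs no
  correction; inference is deterministic.
* Checkpoints serialize weights plus an embedded JSON metadata block
  (feature, class order, scale, backbone, seed).
* All stochastic entry points take a `seed` and restore the caller's RNG
  state, so cohort regeneration is bit-identical and test order cannot
  leak randomness.

# Problem sizes used by the test-suite experiments

The test suite chooses desk-scale problem sizes: 200 seeded tiles per
steatosis class for the area-fraction property; 10 000 random vectors for
the renormalization oracle; 25 two-cut instances of 30–60 livers
(clustered severities on a 0.5 lattice, concentration 200, 200 tiles per
liver) for the grid-search equivalence — clustered instances keep every
optimal cut inside a data gap wider than the 0.01 grid step, which makes
the exhaustive grid attain the true minimum and the equality check
well-posed; 20 replicates of a 300-liver fibrosis cohort (clustered
severities sd 0.2, concentration 2000, 500 tiles per liver) for threshold
recovery, conditions under which the per-liver score noise is small
relative to the inter-cluster gaps; and classifier training at 60 tiles
per class with held-out sets of 20 per class, 2e-2 learning rate, at most
30 epochs for the learning surrogate. These sizes are the package's own
choices for a reproducible desk-scale experiment; the operations
themselves scale to arbitrarily larger cohorts and tile sets.

# Known limitations

* The synthetic appearance gap: classifiers trained on caricature tiles
  do not transfer to real slides; the reference backbone exists for
  pipeline verification and as a template, not as a shipped diagnostic
  model.
* Defocus detection rests on the brightness/texture contrast of the
  synthetic blur model; genuinely subtle focus gradients are harder.
* The Monte Carlo fit, like any local search with finite patience, can
  in principle terminate above the global minimum on adversarial,
  densely packed score distributions; on stair-like cohorts (the
  realistic regime) it matches exhaustive search, as the tests verify.
* Pyramid-level selection, stain normalization and tissue masking are
  out of scope; the ignore class carries the masking role.
* Only single-plane TIFF/BigTIFF and PNG inputs are read; vendor WSI
  container formats are not supported.
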