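---
title: "Contour-guided, GAN-augmented transformer classification of fundus images: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Contour-guided, GAN-augmented transformer classification of fundus images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(fundusvit)
```

## The problem

Glaucoma grading from colour fundus photographs is a five-way
classification task — glaucoma, normal, POAG/NTG (primary open-angle /
normal-tension glaucoma), referable, and suspect — on data with severe
class imbalance: the public SMDG-19 inventory this package's ledgers mirror
holds 6,732 normal but only 40 POAG/NTG and 25 suspect images among 11,665
in total. The anatomical signal is subtle: the optic cup (a brighter
depression inside the bright optic disc) enlarges as glaucoma progresses,
so the cup-to-disc ratio (CDR) carries most of the diagnostic information,
and the rest of the image is largely repeated anatomy.

`fundusvit` implements a three-phase workflow around that problem:

1. **Data generation.** Classical augmentation grows each class to an
   explicit target count, and a conditional GAN with a reconstruction path
   synthesises additional class-conditioned images, rebalancing the
   training pool (24,127 images under the package's published-ledger
   defaults, 4,035 of them GAN-generated).
2. **Training.** A transformer classifier processes each training image
   *and* a binary contour map of it (Canny-style edge extraction focused on
   disc/cup structure) through one shared backbone; the two pre-softmax
   score vectors are summed (feature alignment) and a class-weighted
   cross-entropy is minimised.
3. **Inference.** Only the image branch runs; no contour is computed. The
   package exposes a call counter (`contour_call_count()`) so this contract
   is machine-checkable.

Everything is exercisable on synthetic fundus *phantoms*, so no clinical
data or GPU is required to validate the mechanics.

## The phantom generator: what it emulates, and what it does not

`render_phantom()` draws a bright disc (filled circle, default intensity
150) containing a concentric brighter cup (220) on a darker background
(40), plus darker random-walk vessel polylines, a linear illumination
gradient across columns, and i.i.d. Gaussian sensor noise, quantised to
8-bit. Class is encoded geometrically through the default cup-to-disc
ratios {normal 0.30, suspect 0.45, referable 0.55, POAG/NTG 0.60, glaucoma
0.70} — a clinically plausible ordering of cupping severity, stored as
documented constants and overridable per spec. Defaults chosen once:
`noise_sigma = 5` (8-bit units, a realistic sensor-noise level),
`illumination_slope = 0.2`, three vessels, 64 px frames at desk scale
(512 px mirrors full-scale preprocessing).

Per-image seeds derive from `(master seed, class code, index)` via an exact
integer hash (`derive_seed()`), so datasets are bit-reproducible and
distinct across master seeds.

What the phantoms deliberately do *not* model: photorealistic texture,
colour channel asymmetries, pathology other than cupping, macula/fovea
anatomy, acquisition artefacts, mislabelling. Consequently, passing tests
demonstrate that the pipeline's machinery (geometry recovery, conditioning,
optimisation, bookkeeping) works — not that the classifier reaches clinical
performance on real photographs; the published full-scale results are out
of scope here precisely because they require the external dataset and
GPU-scale training.

## Contour extraction

The chain is grayscale (luma weights 0.299/0.587/0.114) → Gaussian
smoothing (normalised kernel, odd size, default 5×5 with the common
σ = 0.3·((k−1)/2 − 1) + 0.8 heuristic) → 3×3 Sobel derivatives, magnitude
`sqrt(gx² + gy²)` and direction `atan2(gy, gx)` folded to [0°, 180°) →
non-maximum suppression with the direction quantised to four bins (ties
kept: `>=` both neighbours) → double thresholding at `low`/`high` fractions
of the maximum suppressed magnitude (defaults 0.10/0.30, common Canny
practice; the upstream description fixes kernel sizes but no thresholds) →
hysteresis keeping weak pixels 8-connected to strong ones.

Numerical conventions are pinned down so that an independent nested-loop
implementation reproduces the chain *bit for bit* (the acceptance suite
does exactly this on 100 random images): borders reflect with edge
duplication; convolution sums accumulate kernel offsets in (dy, dx) order;
the high threshold is inclusive; and images whose maximum gradient is at
rounding-noise level (≤ 1e-9 in 8-bit units) yield empty contours rather
than thresholded noise.

Optic-disc localisation uses a circular Hough transform over a radius
range, voting each edge pixel onto candidate centres. When the source image
is available, votes are weighted by local gradient magnitude, so the
high-contrast disc rim out-scores the weaker cup rim — with unweighted
votes both rims are complete circles and the accumulator cannot prefer the
anatomically correct outer one. Scores are normalised per sampled perimeter
position to be comparable across radii; ties break towards the smallest
(row, col, radius). Cup segmentation thresholds the disc interior at a
percentile position (default 70) within the ROI's robust intensity range
(1st–99th pixel quantiles); the vertical CDR is approximated as
`sqrt(cup area / disc area)`. A *rank* percentile of the ROI pixels was
considered and rejected: on the near-bimodal disc/cup histogram a fixed
rank cut degenerates (for a large cup the 70th percentile falls inside the
cup cluster and truncates it), whereas a range-position threshold lands in
the gap between the two intensity modes for any cup size. A uniform disc
interior yields an empty cup and CDR 0, documented. Disc/cup localisation
is a diagnostic/QC output; it does not feed the classifier.

## Classical augmentation

Nine operations: transposition, horizontal/vertical flips, rotation (right
angles exactly by index permutation, plus a small-angle bilinear range),
brightness shifts, Gaussian blur, elastic distortion (Gaussian-smoothed
random displacement field, amplitude α = 4 px, smoothness σ = 3 px),
contrast scaling about the image mean, and CLAHE (via EBImage, 8×8 tiles,
clip limit 2). Budgets are per-class *totals* after augmentation — the
published rebalancing table implies non-uniform multipliers (glaucoma ×3,
referable ×2, normal ×≈1.27), so budgets are explicit counts, not a global
multiplier. Augmented records keep their source record's class and are
train-only.

## The conditional GAN

Encoder `E` maps an image to a class estimate and a latent code; generator
`G` decodes (latent, class one-hot) back to an image (tanh output in
[−1, 1], rescaled to 8-bit on export); critic `D` outputs an unbounded
realness score and auxiliary class logits. The objectives are

- critic:  `LDc = E[Ds(fake) − Ds(real)] + LGP − λ2·LCEL`, minimised;
- encoder/generator:
  `LEd = E[Ds(fake)] + λ4·log p(Dd(fake) = d) − λ5·L1(x, fake) − LCEL`,
  maximised (implemented as minimising its negation); the critic's
  auxiliary cross-entropy is minimised during its updates (see the design
  notes below);
- `LGP = λ1·E[(‖∇x̂ Ds(x̂)‖₂ − 1)²]` on per-sample interpolates
  `x̂ = ε·x + (1−ε)·fake`, ε drawn fresh per sample, the WGAN-GP penalty.

Loss weights are the published constants λ1 = 10, λ2 = λ4 = λ5 = 1; λ3 is
declared but enters no printed objective and is stored unused. The
auxiliary class term is a standard categorical cross-entropy against the
conditioning class (AC-GAN convention): the self-entropy form that a
literal transcription would give has no label dependence and cannot train a
conditional model; it is retained as the diagnostic `entropy_monitor()`.
The reconstruction term is the literal L1 *norm* ‖x − fake‖₁ per sample
(batch mean). This matters: with a per-pixel mean instead, the
reconstruction gradient is smaller than the critic's by a factor of the
pixel count and the adversarial term swamps it — with the norm, the two
compete at the same scale under the published unit weight.

Design choices: no normalisation layers in the critic (the gradient
penalty is per-sample; batch coupling would corrupt it — the WGAN-GP
convention), batch norm in `E` and `G`; Adam(1e-4, β 0.5/0.9) with
`n_critic = 5` critic updates per encoder/generator update (the WGAN-GP
defaults; the published hyperparameter table covers only the classifier);
expectations are batch means (the GAN batch size is unstated upstream;
default 16, 8 in the desk-scale tests). Within one training step the
encoder and generator do not move during the critic loop, so the fake batch
is reconstructed once per step and only ε is redrawn per critic iteration.
The critic's `LCEL` is computed on the real batch (the critic learns
classification from labelled data); the encoder/generator step uses the
encoder's own class estimate for its `LCEL`. The encoder is deterministic —
no KL term or latent sampling appears in the upstream description, so no
variational machinery is invented; free sampling draws latents from
N(0, I), which the encoder's code distribution is not constrained to
match, a known limitation documented here.

The gradient penalty is *trained*, not just reported: the package's
autodiff engine expresses every vector-Jacobian product through the same
tape operations, so the critic's input gradient is itself differentiable
and the penalty's parameter gradient is exact double backpropagation
(verified against finite differences in the test suite).

## The classifier

A patch-embedding convolution (kernel = stride = patch size) tokenises the
image; learned positional embeddings are added; a pre-norm transformer
encoder contextualises the tokens; a transformer decoder attends from
learned query embeddings over the encoder output (detection-transformer
style); the mean over query outputs feeds a linear presence head of length
5. Desk-scale defaults: 64×64 input, 8×8 patches, hidden 64, 2 heads, 2+2
layers, 8 queries, dropout 0.1, Adam with learning rate 1e-3 and decoupled
weight decay 1e-6. The full-scale configuration (`vit_config(full_scale =
TRUE)`) mirrors the published setting: 512×512, 6+6 layers, learning rate
1e-5, weight decay 1e-6, dropout 0.1. The desk learning rate is larger than
the published 1e-5 because the desk model is three orders of magnitude
smaller and trains from scratch rather than from detection-pretrained
weights.

During training one *shared* backbone processes both the image and its
contour map (replicated to three channels so the same stem accepts both);
the pre-softmax scores are summed. Sharing is the interpretation that makes
the inference contract well-defined: a single symbol denotes the backbone
in the alignment equation, and inference discards the contour branch, which
only leaves a meaningful image-only path if the trunk is common. The
alignment sums logits, not probabilities — the loss then takes
`log softmax` of the sum, whereas summing probabilities would break
normalisation. Class weights are inverse-frequency, `w_j = N/(C·n_j)`, so
balanced data gives unit weights and `Σ_j w_j n_j = N`; probabilities at
the true class are clamped at 1e-12 with a warning. Ties in the final
argmax resolve to the smallest class code.

## Numerical and engineering choices

- Coordinates are (row, col), 1-based, throughout.
- The autodiff engine uses two structural primitives — `gather` (with
  zero-padding) and its scatter-add dual — for convolution (im2col),
  upsampling, head splitting, broadcasts and reductions; their index
  vectors and scatter plans are cached per shape. Layer norm and the
  attention softmax are fused single nodes with hand-derived first-order
  backward passes; they never sit on the double-backprop path (the critic
  contains neither).
- Batch norm running moments use momentum 0.1; evaluation mode is
  deterministic.
- Adam: β = (0.9, 0.999) for the classifier, (0.5, 0.9) for the GAN,
  ε = 1e-8; weight decay is decoupled.
- Checkpoints are single RDS files with explicit format/version fields.

## Study sizes used by the test and acceptance runs

Chosen once as the package's desk-scale study conditions: the classifier
check trains on three separable classes (normal/referable/glaucoma — the
three dominant classes of the inventory) with 200 phantoms per class at
64×64, split 70/15/15, 10 epochs, batch 25, across 3 seeds (majority
criterion, evaluated until decided); the GAN check trains on 40 two-class
noiseless phantoms at 16×16 for 500 steps (batch 8, `n_critic` 5) per seed
and compares the reconstruction L1 at steps 10 and 500. The contour oracle
sweep uses 100 random 32×32 images. The ledger checks run in dry-run
manifest mode (no image files).

## Known limitations

- Free-form sampling quality at desk scale is modest: 500 tiny-scale steps
  produce blurry discs, and because the encoder's latent distribution is
  unconstrained, latents drawn from N(0, I) can sit off-manifold. The
  class-conditional geometry of *reconstructions* is the better-posed probe.
- The critic loss *as composed for reporting* carries a `−λ2·LCEL` term;
  taken literally as an optimisation objective that term is unbounded below
  (the critic is paid to drive its class head's cross-entropy to infinity),
  and desk-scale runs diverge: the shared trunk inflates, the penalised
  gradient norm grows without bound and reconstruction quality collapses.
  The critic is therefore *trained* with the auxiliary cross-entropy
  minimised — the AC-GAN convention this design descends from — while
  `discriminator_loss()` keeps the printed composition for monitoring.
- Phantom separability means desk-scale accuracies are near-perfect and say
  nothing about real-data difficulty.
- The two published bookkeeping tables disagree slightly (25 vs 27 suspect
  originals); both are implemented as printed and the discrepancy is
  surfaced in the documentation, not resolved.
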