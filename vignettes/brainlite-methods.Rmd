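---
title: "Models and methods behind brainlite"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind brainlite}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

brainlite implements a complete two-dimensional brain-MR diagnosis
stack: skull-stripping, geometric augmentation, a lightweight
convolutional network for normal/abnormal classification, and a
fast-linking modified spiking cortical model (FL-MSCM) for tumor
segmentation, together with the metrics and a synthetic phantom
generator that makes the whole chain testable without clinical data.
This vignette explains the models, their parameters, and the design
decisions taken where the method left choices open.

## Skull-stripping

T2-weighted head slices contain bright non-brain structure (scalp fat,
skin) that disturbs intensity-driven segmentation. `skull_strip()`
removes it in two phases.

**Thresholding.** The histogram is split at a point `t` into a dark
region $R_1$ (pixels `< t`) and a bright region $R_2$; the split point
is Otsu's threshold over 256 bins, which makes the split deterministic
and reuses machinery the segmenter needs anyway. From the region means
$m_1, m_2$ and population variances $s_1^2, s_2^2$ the separability
value and threshold are

$$H = \frac{(m_1 - m_2)^2}{s_1^2 + s_2^2 + \varepsilon},\qquad
  T = \frac{H + \min(I)}{2},\qquad T_{opt} = T / 255,$$

with `eps = 1e-6` guarding the zero-variance case (two constant
regions make $H$ blow up; $T_{opt}$ is clamped to $[0,1]$). The
binary head mask is `1` where `pixel/255 > Topt`. On head images the
separability value is small relative to 255, so the binarization
keeps everything except background — by design: the morphology does
the actual skull removal.

**Morphology.** In order: area opening (8-connected components smaller
than `min_area` are dropped — noise specks), hole filling, erosion by
a disk of radius `se_radius`, and retention of the largest remaining
component. The erosion peels the bright peripheral ring off the head
mask; keeping the largest component afterwards makes the "eliminate
small objects" step deterministic. Defaults (`se_radius = 5`,
`min_area = 300` for 256×256, scaled with image area) assume the
bright ring is thinner than the erosion radius, which holds for the
thin scalp-fat line typical of T2 slices; a thick bright annulus
requires a larger radius. Erosion order (before component selection)
and the radius are configuration-exposed because the procedure itself
does not fix them. Whether the region variances are population or
sample is equally unspecified; population variances are used.

## Geometric augmentation

`augment_dataset()` expands each image to `per_image` outputs (the
original plus `per_image - 1` random transforms). The operator ranges
are the study settings: rotation U(−30°, 30°), translation
U(−10, 10) px per axis, per-axis reflection with probability 0.5,
uniform scale U(0.5, 4), shear U(0°, 30°) per axis. `per_image = 9` is
the only multiplicity consistent with the published expansion
60 → 540 and 125 → 1125. Operators are composed (reflect → rotate →
shear → scale → translate, about the image center) and drawn jointly;
`single_op = TRUE` applies exactly one operator per output instead,
preserving the alternative reading of "five operators". Warping is
bilinear with zero fill; the scale range's upper end (4×) is extreme
but retained as configured. Augmentation is applied inside training
folds only (see the harness below), so augmented variants of one
original can never straddle a fold boundary.

## The lightweight CNN

The classifier is a four-block network whose repeating cell
("ConvNet") is convolution → batch normalization → softplus
($y = \log(1+e^x)$). Block 1 is a single 5×5/32 stride-2 ConvNet;
blocks 2–4 hold three ConvNets each (3×3, 3×3, 1×1 with 48, 64, 128
filters; only the first 3×3 of block 2 has stride 2), a point-to-point
add junction, and 2×2 stride-2 average pooling; a global average pool,
a 2-unit dense layer and softmax close the network. All convolutions
use valid padding with the floor rule
$H' = \lfloor (H - k)/s \rfloor + 1$ — derived rather than assumed:
it is the only convention that reproduces every published activation
shape (e.g. 224 → 110 under k = 5, s = 2). At the default 224×224×3
input the accounting is exact: 347,954 trainable plus 1,504
non-trainable (batch-norm running statistics) = 349,458 parameters.
`count_params()` reproduces this per layer; grayscale slices are
replicated to three channels at the CNN boundary.

The add junction sums the outputs of the second and third ConvNets of
each block — the only shape-compatible pair, since the first ConvNet
of block 2 changes resolution; a projection-based inclusion of the
first ConvNet would be a different architecture and is not claimed.
`use_add = FALSE` disables the junctions.

**Training.** Mini-batch softmax cross-entropy, batch 64, with the
optimizer family and hyperparameters as configured: learning rate
0.001 for all; SGDM momentum 0.9; Adam/AdaMax/Nadam β₁ = 0.9,
β₂ = 0.999; Adadelta ρ = 0.95; RMSProp ρ = 0.9; ε = 10×10⁻⁷ = 1e-6
for the adaptive rules. The forward/backward passes and the seven
update rules are implemented in the package (R with C++ kernels for
convolution, batch norm, and softplus); correctness is pinned by
finite-difference gradient checks in the test suite. Batch-norm
inference uses running statistics (momentum 0.99), warm-started from
the first batch and recalibrated after training by a forward sweep
over the training set ("precise BN"): with short training runs,
momentum-tracked statistics lag the weights badly enough to destroy
held-out predictions, while recalibrated statistics make inference
consistent with the final weights at any training length. Class
imbalance is left unweighted.

**Cross-validation harness.** `train_and_evaluate()` runs stratified
k-fold (default 5) over the *original* images; each fold's training
split is optionally augmented, fitted, and the held-out originals
scored. Stratification keeps per-fold class ratios within one sample.

## FL-MSCM segmentation

Each pixel is a spiking neuron with feeding input $S_{ij}$ (the
normalized intensity), linking input $L$, internal activity $U$,
dynamic threshold $E$, and pulse output $Y$:

$$L_{ij}(n) = m_L \sum_{k,l} W_{k,l}\, Y_{i+k,j+l}(n-1), \qquad
  U_{ij}(n) = f\,U_{ij}(n-1) + S_{ij}\,(1 + \beta_{ij} L_{ij}(n)),$$
$$Y_{ij}(n) = [\,U_{ij}(n) > E_{ij}(n)\,], \qquad
  E_{ij}(n) = E_{ij}(n-1) - \Delta + h_{ij}\,Y_{ij}(n).$$

The linear threshold decay (−Δ per outer iteration) is the defining
modification over the classical exponential decay: every neuron's
threshold falls at the same rate, so brighter pixels — higher $U$ —
fire in earlier, well-ordered waves. Constants follow the automatic
settings: $f = 0.2$, $m_L = 1$, $\Delta = 0.02$, $E_0 = 1$, $W$ a 7×7
Gaussian (σ = 1) normalized to sum 1 with the central self-term
retained (harmless, since a fired neuron's boosted threshold cannot be
re-crossed). The linking strength is a sigmoid of the
central-difference gradient magnitude, $\beta = 1/(1+e^{-G})$,
computed per pixel; because β is per-pixel, the threshold magnitude

$$h = \frac{\max S - \min S}{1 - f} + \max S\,(1 + \beta \textstyle\sum W)$$

is per-pixel too (`beta_reduce` offers scalar `mean`/`max` readings).
$h$ guarantees single firing: the property suite verifies on random
lattices that no pixel pulses twice. The iteration budget is
$N = \lceil (\max S - T_S)/\Delta + 1 \rceil$ with
$T_S = T_G/(1-f)$ and $T_G$ the Otsu level of $S$, so the threshold
decays exactly past the scaled Otsu level: pixels brighter than $T_G$
fire within the budget, dimmer ones never do. Ceiling rounding is
chosen because the quotient is non-integral in general and rounding
down could stop one step short of the level. Inputs are min-max
normalized to $[0,1]$ first, which is what makes $E_0 = 1$ consistent
with the $\max S$ term of the budget.

**Fast-linking.** Within one outer iteration (one threshold decay),
the linking/activity/firing triple is re-updated until the firing map
stops changing, so neurons with similar stimuli join a single
synchronized wave instead of firing over several iterations. The decay
is applied once per outer iteration, not per inner pass — only L, U, Y
iterate internally — and the $h$ reinforcement lands immediately when
a pixel first fires. The fired set is non-decreasing within an inner
loop, so it terminates; `inner_cap = 64` is a safety net that warns
rather than fails.

**Mask extraction.** The displayed output of the model is a pulse
sequence, not a mask; the extraction rule is this package's choice.
`first-wave` (default) keeps the pixels of the earliest wave — on a
stripped T2 slice the hyperintense tumor is the brightest structure
and fires first; `k-waves` unions the k earliest waves for lower
contrast material. The first-fire map itself is returned for
inspection.

## Metrics

Accuracy, TPR, TNR, PPV, F-score on the percent scale, plus the
balanced AUC = (TPR + TNR)/2 — the published tables use this form, not
a ROC sweep (their fold rows confirm it, e.g. (100 + 99.13)/2 =
99.56; one printed fold AUC, 99.4 against a computed 99.275, is
inconsistent with its own TPR/TNR and the formula is followed). DSC is
$2|S\cap G|/(|S|+|G|)$; for binary masks it equals the F-score of the
pixel confusion, which the tests assert numerically. Zero-denominator
metrics propagate as `NA` markers, never silent zeros; fold summaries
report means and sample SD (n−1), dropping `NA`s with a message.
Segmentation tables are macro-averaged (per image, then mean).

## The phantom generator

`make_phantom()` paints an axial T2-like head at desk scale:
background 0, elliptical brain disc 110, thin bright skull/scalp ring
230 (thickness 4 px at 256×256), and for abnormal samples a
hyperintense tumor ellipse 200 strictly interior to the brain — the
T2 convention in which fluid and most tumors are bright. Geometry
jitters by ±10% per sample; additive Gaussian noise (default σ = 3 on
the 0–255 scale) is clipped to range; masks are exact by construction
because they are recorded before noise. The defaults keep the
threshold and Otsu formulas in their stable regime while remaining
non-trivial (the ring survives naive thresholding and must be eroded
away; σ = 3 produces multiple spurious firing waves that fast-linking
must ride out).

What the phantom does **not** emulate: Rician noise statistics,
partial-volume boundaries, bias fields, anatomical texture, or tumor
heterogeneity. Passing the recovery suite therefore shows the
implementation is faithful and stable under the stated conditions —
it does not certify clinical performance on real MR data, where the
published results were obtained on a collection that is not publicly
deposited.

## Problem sizes and numerical choices

The test suite and the acceptance script run at sizes chosen for a
single CPU: property checks on 16×16 lattices (50 random seeds),
phantom recovery on 256×256 images (noiseless plus 20 noisy seeds),
and a 5-fold CNN smoke on the 185-sample phantom dataset at the full
224×224 input with 2 epochs — the phantom task is linearly separable
in practice and reaches perfect or near-perfect folds, so the reduced
epoch count demonstrates the harness without the full 30-epoch
protocol. Other numerical choices collected in one place: strict
inequality in the firing rule (ties do not fire); zero padding for the
linking correlation (no neurons beyond the lattice); 8-connectivity
for components and hole filling; Otsu ties broken toward the lower
threshold; bilinear resampling center-aligned with zero fill for
warps and border clamping for resizes; display rounding half-up to two
decimals.

## Limitations

Single 2-D slices only (no volumes, no DICOM); two classes; the
conventional spiking cortical model with exponential threshold decay
is deliberately out of scope (no decay constant is ever specified for
it); training at 30 epochs × 7 optimizers at full resolution is
compute-heavy on one CPU — the harness exposes every knob, but the
shipped defaults target the desk-scale phantom study.
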