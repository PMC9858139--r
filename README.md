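# brainlite

Tools for two-dimensional brain-MR diagnosis: remove the skull from a
T2-weighted slice, expand a small dataset by seeded geometric
augmentation, classify slices as normal/abnormal with a lightweight
convolutional network (~0.35 M parameters, exact per-layer
accounting), and delineate the tumor in abnormal slices with a
fast-linking modified spiking cortical model (FL-MSCM). A synthetic
phantom generator with exact ground-truth masks makes every stage
testable end to end without clinical data, which matters because the
MR collection behind the published benchmarks is not publicly
deposited.

The package is aimed at researchers in medical image analysis who
want a reproducible, fully inspectable reference implementation of
this diagnosis stack — every formula, parameter rule, and iteration
schedule is ordinary R code with tests.

## The methods in brief

**Skull-stripping.** Split the intensity histogram at Otsu's point
into regions with means `m1, m2` and population variances `s1², s2²`;
binarize at `Topt = clamp((H + min I)/2 / 255)` where
`H = (m1 − m2)²/(s1² + s2²)`; then area-open, fill holes, erode by a
disk, and keep the largest component. The erosion peels the bright
scalp ring off the head mask.

**Lightweight CNN.** Four blocks of convolution → batch norm →
softplus cells with add junctions and average pooling, global average
pooling and a 2-unit softmax head; valid padding throughout. At the
224×224×3 input: 347,954 trainable + 1,504 non-trainable = 349,458
parameters, reproduced exactly by `count_params()`. Training:
cross-entropy, batch 64, stratified 5-fold CV, with SGDM, Adam,
AdaMax, Nadam, Adagrad, Adadelta and RMSProp update rules built in.

**FL-MSCM.** Each pixel is a spiking neuron: internal activity
`U ← f·U + S·(1 + β·L)` with linking `L` from a 7×7 Gaussian over
neighboring pulses and per-pixel linking strength
`β = sigmoid(|∇S|)`; a pixel fires when `U > E`, and the threshold
decays linearly (`E ← E − Δ`) so brighter structures fire in earlier
synchronized waves (fast-linking iterates the firing map to a fixed
point within each decay step). The firing magnitude `h` and iteration
budget `N` are set automatically from the image; the tumor mask is
the first firing wave.

## Worked example

```r
library(brainlite)

# a noiseless abnormal phantom with ground truth
ph <- make_phantom(phantom_config(noise_sigma = 0, seed = 3))
ph
#> phantom_sample: 256x256, label abnormal, tumor 907 px

ss <- skull_strip(ph$image)
ss$report
#> separability threshold: t_split=0.9961 m1=0 m2=124.1 s1sq=0
#>   s2sq=1395 H=11.05 T=5.525 Topt=0.02166
dice_coefficient(ss$brain_mask, ph$brain_mask)
#> [1] 0.9848583

seg <- fl_mscm(ss$stripped)
seg
#> fl_mscm: 256x256 lattice, N=51 outer iterations, 3 firing waves, mask 907 px
dice_coefficient(seg$tumor_mask, ph$tumor_mask)
#> [1] 1
```

The threshold report shows why the morphology matters: the
separability value `H` is small, so the binarization keeps the whole
head (`Topt ≈ 0.02`) and the disk erosion removes the ring. The
segmenter then needs `N = 51` threshold-decay iterations; the tumor —
the brightest structure on the stripped slice — fires alone in the
first wave, so the extracted mask matches the painted tumor exactly
(DSC = 1).

Architecture accounting is exact and instantaneous:

```r
pb <- count_params(build_lightweight_cnn())
pb$total
#> [1] 349458
```

A classification run on phantoms (reduced epochs; the phantom task is
cleanly separable):

```r
ds <- make_phantom_dataset(60, 125, phantom_config(seed = 11))
cv <- train_and_evaluate(ds, config = cnn_train_config(
  optimizer = "adam", epochs = 2, folds = 5, seed = 1))
summary(cv)["mean", "accuracy"]
```

A thin command-line front end with the same stages lives at
`inst/cli/brainmr` (subcommands `phantom`, `skullstrip`, `augment`,
`segment`, `train`, `run-all`).

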