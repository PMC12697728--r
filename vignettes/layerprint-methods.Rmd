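---
title: "Methods: layer-orthogonalized stimulus synthesis and searchlight mapping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: layer-orthogonalized stimulus synthesis and searchlight mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(layerprint)
```

## The problem and the model

RSA summarizes a representation by its representational similarity matrix
(RSM): for a set of $n$ images, the $n \times n$ matrix of Pearson
correlations between the activation patterns the images evoke — across the
units of a CNN layer, or across the voxels of a searchlight. Two
representations can then be compared at second order, by correlating the
vectorized strict upper triangles of their RSMs.

In a feedforward CNN viewing natural images, adjacent layers produce RSMs
whose triangles correlate highly, so a brain region whose searchlight RSM
matches one layer matches its neighbors almost as well. The synthesis
procedure removes this confound at the stimulus level. With $R_\ell$ the RSM
of layer $\ell$, $v_\ell$ its upper triangle, and
$S_{k\ell} = \mathrm{cor}(v_k, v_\ell)$ the second-order matrix, the
objective

$$ C \;=\; \sum_{k \neq \ell} S_{k\ell}^2 $$

is minimized by joint gradient descent on the pixels of all images. The
diagonal of $S$ is constant (1) with zero gradient, so it is excluded from
the reported cost: $C = 0$ then means perfect orthogonalization, and the
optimization is unchanged.

### Gradients

The chain pixels $\to$ activations $\to$ $R_\ell$ $\to$ $v_\ell$ $\to$ $S$
$\to$ $C$ is differentiated analytically. For $r = \mathrm{cor}(x, y)$ with
centered $x_c, y_c$,

$$ \frac{\partial r}{\partial x} \;=\;
   \frac{y_c - (S_{xy}/S_{xx})\, x_c}{\sqrt{S_{xx} S_{yy}}}, $$

which is applied twice: once from second-order entries onto triangle
vectors, once from RSM entries onto activation rows. The network itself
enters only through the adapter's vector–Jacobian product (below); the
implementation is verified against central finite differences of the whole
chain to $10^{-4}$ relative error in the test suite.

## The model-adapter contract

All network access goes through a `ModelAdapter`: an ordered list of layer
ids, an activation function returning one flattened pattern per (layer,
image), and a gradient function mapping per-layer activation gradients to a
pixel gradient. Activations are flattened channel-major and no spatial
pooling is applied before correlation.

The built-in `randomCNNAdapter()` is a seeded, randomly initialized
(He-scaled) stack of valid 3×3 convolutions with stride 2 and leaky-ReLU
(slope 0.1) nonlinearities, with forward and backward passes implemented in
plain R. The leaky slope keeps gradients alive everywhere, so pixel
optimization cannot stall on dead units; random features are sufficient for
the package's purposes because the synthesis objective only needs layers
with distinct, differentiable geometries. Adapters for pretrained networks
(e.g. an Inception-V1 exposed from an external deep-learning runtime, using
its first three convolutional layers and the mixed-pooling block outputs)
plug into the same contract via `registerAdapter()`; the default unit for a
block is its concatenated output, and any internal tensor can be exposed
instead by the adapter author.

## Synthesis: two phases and their parameters

* **Phase 1, diversification** (`diversifyPhase`): per-image loss
  $-\overline{a}_{c(i)} + w \cdot p_{\mathrm{RGB}}$, where
  $\overline{a}_{c(i)}$ is the mean activation of image $i$'s target feature
  channel and $p_{\mathrm{RGB}}$ is the RGB-breadth penalty. The channel
  objective uses the channel **mean** (a spatial max or subset would be
  equally valid; the mean is the documented default). Target channels are
  sampled distinctly per image, seeded, from a configured layer (default:
  the last).
* **RGB-breadth penalty**: $p_{\mathrm{RGB}} = -\frac{1}{3}\sum_c
  \mathrm{sd}(\text{pixels}_c)$, the simplest differentiable surrogate for
  "a broad distribution of RGB values"; weight `rgbBreadthWeight`
  (default 0.1), isolated so other penalties can replace it.
* **Phase 2, orthogonalization** (`orthogonalizePhase`): plain gradient
  descent on $C$, fixed step size. No momentum or adaptive scheme is used by
  default — fidelity to the simplest procedure over speed.
* **Step size and normalization**: gradients are max-normalized before each
  step (per image in phase 1, globally in phase 2), so `stepSize`
  (default 0.02) is the largest per-pixel change per iteration in the
  declared range. This makes one step size serve networks of very different
  gradient scales; no schedule is applied.
* **Pixel parameterization**: direct pixel space with post-step clamping to
  the declared range — no Fourier or decorrelated parameterization, since
  the update target is the pixels themselves.
* **Iteration counts**: the default profile is 16 images with 28,800
  diversification and 1,800 orthogonalization steps, the full-scale regime
  for a pretrained network at 224×224. The `"test"` profile (8 images at
  64×64, 200 + 200 iterations on the random CNN) is the desk-scale regime
  used throughout the tests; at that scale the final mean off-diagonal
  second-order correlation falls below every one of 100 random-image
  baseline sets.
* **Degenerate states**: a zero-variance activation pattern (which would
  make a Pearson correlation undefined) raises an error rather than a
  silent `NaN`; mid-run, synthesis restarts from fresh seeded noise and
  logs the restart, giving up after 10 restarts.

The per-iteration cost trace records the cost *after* each update, so its
last entry equals the cost of the final second-order matrix exactly. With a
fixed step the trace can wiggle locally; smoothed over 20-iteration windows
it descends monotonically up to a small slack, and tests assert exactly
that.

## Trial sequences, HRF, and GLM

`generateSequence()` emits one run: each of `nImages` (16) images exactly
`nReps` (5) times — 80 trials — with no back-to-back repetition, 1.5 s
stimulus duration, inter-stimulus intervals drawn with equal probability
from {1.5, 3, 4.5} s, and `ceiling(0.1 × trials)` attention-target trials.
Orders are drawn sequentially (each trial sampled from the images with
remaining presentations, excluding the previous image, weighted by remaining
count) with bounded whole-sequence retries; this construction reaches high
repetition regimes (e.g. 4 images × 20 reps) where rejection sampling of
full permutations is hopeless, and fails constructively on infeasible
specifications. Target trials are modeled as ordinary presentations of their
image — no separate regressor.

`doubleGammaHRF()` is the canonical difference of two gamma densities:
response delay 6 s, undershoot delay 16 s, unit dispersions, undershoot
ratio 1/6, peak-normalized to 1. All five parameters are overridable. With
this parameterization the empirical argmax sits near 5 s, which the tests
pin against a brute-force fine-grid evaluation rather than a nominal value.
`buildDesign()` convolves per-image boxcars with the HRF on a 0.05 s grid
and samples at $t = \text{volume} \times \mathrm{TR}$ (TR 1.5 s, no
slice-timing offsets). `fitGLM()` is ordinary least squares per voxel with
an intercept nuisance column; rank deficiency fails loudly, naming the
collinear regressors. High-pass filtering, prewhitening and motion
regressors are deliberately out of scope — the synthetic pipeline generates
data without drift by default, with an optional AR(1) noise switch for
robustness checks.

## The synthetic brain

`embedRSM()` draws voxel columns i.i.d. from $\mathcal{N}(0, R)$ with $R$
the target RSM, so the expected image-by-image correlation matrix equals the
target exactly and without bias. `simulateBetaMaps()` assembles a 3D grid
in which each region carries `signalScale ×` an embedded layer pattern —
shared across runs within participant, jittered across participants by
additive Gaussian noise on the *patterns* (not the RSMs), mimicking shared
geometry with idiosyncratic codes — plus i.i.d. run noise; non-region voxels
are pure noise. `orthogonalLayerRSMs()` supplies ground-truth geometries
whose triangles are made exactly mutually orthogonal by Gram–Schmidt and
shrunk toward the identity until positive semidefinite, emulating a
successfully synthesized image set.

What the generator emulates: regional representational geometry, its
between-participant variability, run-level noise, and (via `simulateBOLD()`)
the HRF-convolved path from betas to time series. What it does not:
anatomical geometry, hemodynamic nonlinearity, spatially correlated or
physiological noise, motion. Passing tests therefore certify the statistical
machinery — recovery, calibration, specificity — under the stated noise
model, not performance on real scanner data.

## Searchlight analyses

Searchlights are 7×7×7 voxel cubes (half-width 3) around every in-mask
voxel, clipped at volume borders and intersected with the mask; centers
whose searchlight retains fewer than 2 voxels are undefined (`NA`), never
zero-filled.

**Stability.** Within-image similarity is the mean correlation of same-image
patterns over all unordered run pairs — $\binom{8}{2} \times 16 = 448$
values at 8 runs. Between-image similarity pools ordered image pairs over
unordered run pairs — $\binom{8}{2} \times 16 \times 15 = 6{,}720$ values
(both $A_{r_1}B_{r_2}$ and $B_{r_1}A_{r_2}$ count, which is what makes the
arithmetic come out at $16 \times 15$ rather than $\binom{16}{2}$). The null
subsamples, without replacement, as many between values as there are within
values, 5,000 times, and the stability z is the within mean located in that
null. Participants with fewer runs use their own $\binom{R}{2}$-scaled
counts, keeping the subsample size matched to the within count. The between
pool is held in sorted order so the statistic is exactly invariant to image
relabeling and run order. One caveat, measured and asserted in the tests:
because within-pool values share runs and images, the subsampled null is
slightly narrow, so the stability z on pure noise has SD ≈ 1.07 and ~8%
of |z| values exceed 1.96 rather than 5%; at the decision thresholds used
(z ≫ 3) this is immaterial.

**Layer mapping.** Per searchlight and layer: participants' run-averaged
RSM triangles are averaged over all but one participant; a slope+intercept
regression predicts that average from the layer triangle; the fitted weights
predict the held-out participant's triangle, scored with out-of-sample
$R^2 = 1 - SS_{res}/SS_{tot}$ (negative values are *not* clipped — clipping
would bias the null; the z-normalization absorbs location and scale). The
slope+intercept form is the plainest reading of learned linear weights; a
correlation-weight variant would be absorbed by the same normalization. The
permutation null shuffles every participant's triangle independently, afresh
in each of 500 permutations — independent shuffles maximize exchangeability
of the null — and stores the across-fold mean $R^2$. Per-participant z
scores locate each fold's $R^2$ in that null; the across-fold `mean_z` is
the calibrated per-center statistic (approximately standard normal under a
true null, verified over 200 simulations).

**Residual method.** All triangles are z-scored; within each training fold
the average searchlight triangle is residualized on the 11 other layers'
triangles (multiple regression with intercept), the target layer is fit to
the residuals, and the held-out triangle is residualized with the
*training-fold* coefficients before scoring. Estimating residual
coefficients inside the training fold prevents leakage; with no other
layers the procedure reduces exactly to the plain LOPO fit on z-scored
vectors (asserted to $10^{-10}$).

**Group inference.** One-sample t across participants per center with
family-wise correction by sign-flip max-statistic permutation (one-sided,
positive). This is a deliberate, self-contained substitute for
cluster-based corrections such as TFCE, which require external tooling; it
is statistically valid but lacks TFCE's cluster sensitivity, and
per-participant z maps can be exported as NIfTI for external tools.
Zero-variance centers with positive mean are treated as significant
(infinite evidence); consolidated maps label each significant center by the
layer with the largest group t, ties broken toward the lowest layer index.

**Overlap.** The directed overlap of base layer $M$ with $N$ is
$|M \cap N| / |M|$ over corrected significant-voxel sets — asymmetric by
construction. Layers with empty maps yield undefined rows, excluded from
the off-diagonal and adjacent-band means. Bootstrap comparison resamples
per-image-set means with replacement (5,000 draws) and locates the observed
mean one-sidedly toward *lower* overlap, with the add-one estimator
$p = (1 + \#\{\bar{x}^* \le x_{obs}\})/(1 + B)$ so p is never exactly zero;
a two-sided option exists.

## Seeds and reproducibility

Every stochastic operation takes a seed and restores the caller's RNG
state. Map-level operations derive per-center (and per-participant) seeds
from the master seed with a counter-based mix kept inside 32-bit range, so
results are identical regardless of evaluation order or parallel
scheduling. `(seed, config, adapter)` determine synthesized images
bit-for-bit on one platform.

## Problem sizes used in tests

Unit tests run the smallest instances that exercise each property: 16×16 to
64×64 inputs on the random CNN, grids up to 16×16×8, 4–8 runs, 6–8
participants, and reduced resample counts; the end-to-end checks use 200
noise calibrations, 100 baseline image sets, 10,000 sequence seeds, and 20
simulated brains for layer recovery. These sizes were chosen as the point
where the asserted statistics stabilize; the same code paths scale to
whole-brain grids and full resample counts through the same arguments.

## Known limitations

* The built-in network is randomly initialized; conclusions about *which*
  visual features drive a region require a pretrained adapter supplied by
  the user.
* The stability null's slight narrowness (above) is inherent to subsampling
  correlated pools; a crossnobis-style or analytically corrected null is
  out of scope.
* Group correction is voxelwise max-statistic, not cluster-enhanced.
* The synthetic brain's noise model is white; spatially structured noise
  would lower searchlight specificity relative to the tests' figures.
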