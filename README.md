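# layerprint

Tools for mapping individual layers of a convolutional neural network (CNN)
onto the human brain with representational similarity analysis (RSA).

Natural images evoke highly correlated representational geometries across the
layers of a CNN: the image-by-image representational similarity matrix (RSM)
of one layer looks much like that of the next, so fMRI searchlight analyses
cannot attribute a cortical region to any single processing stage.
`layerprint` addresses this in two complementary ways:

1. **Stimulus synthesis.** Starting from random noise, the pixels of an image
   set are optimized jointly by gradient descent so that the RSMs of all
   model layers become mutually decorrelated. Writing `R_l` for layer *l*'s
   `n x n` RSM (Pearson correlations between unit-activation patterns),
   `v_l = vec(triu(R_l))` for its vectorized strict upper triangle, and
   `S_{kl} = cor(v_k, v_l)` for the second-order layer-by-layer similarity,
   the synthesis objective is the off-diagonal sum of squares

   `C = sum_{k != l} S_{kl}^2`,

   backpropagated analytically through the Pearson correlations and through
   the network to the pixels. A preceding diversification phase maximizes one
   learned feature channel per image (plus an RGB-breadth penalty) so the
   images stay visually rich.

2. **Residual method.** For existing natural-image datasets, each searchlight
   RSM is residualized on the upper triangles of all model layers except one,
   and the held-out layer is fit to the residuals, isolating the variance
   that layer uniquely explains.

Around this core the package provides the full analysis chain: constrained
pseudo-random trial sequences, double-gamma HRF design matrices and
mass-univariate GLM betas; 7x7x7 cubic searchlights; representational
stability z-scores against subsampled between-image nulls (448 within /
6,720 between pairings at 16 images and 8 runs); leave-one-participant-out
(LOPO) layer-to-brain regression with permutation-null z-scoring; sign-flip
max-statistic group inference; asymmetric layer-overlap matrices with
bootstrap comparisons; and a seeded synthetic-fMRI generator that embeds
known layer geometries into voxel regions so every analysis can be tested
against ground truth.

Any network can drive the pipeline through the `ModelAdapter` contract
(layer activations plus a vector-Jacobian product onto the pixels); a seeded
random CNN adapter with analytic forward/backward passes is built in and
runs everything offline on CPU.

## Worked example

Synthesize a small decorrelated image set on the built-in random CNN and
compare it against random-image baselines:

```r
library(layerprint)

adapter <- randomCNNAdapter(inputSize = c(32, 32), channels = c(6, 8, 8),
                            seed = 7)
config  <- synthesisConfig(nImages = 6, phase1Iters = 30, phase2Iters = 60,
                           stepSize = 0.02, seed = 5)
stimuli <- diversifyPhase(initNoise(config, adapter), adapter, config)
trace   <- orthogonalizePhase(stimuli, adapter, config)
trace
#> SynthesisTrace: 60 iterations, cost 3.654 -> 0.01382

round(meanOffDiagonal(trace@initialSom), 3)   # before optimization
#> [1] 0.778
round(meanOffDiagonal(trace@finalSom), 3)     # after optimization
#> [1] 0.035
```

The diversified images start with a mean off-diagonal second-order
correlation of 0.78 — the layer geometries are nearly interchangeable — and
60 gradient steps push it to 0.035. Fifty random noise-image sets pushed
through the same network span mean correlations of about −0.11 to 0.68, so
the synthesized set sits below that whole distribution:

```r
library <- initNoise(synthesisConfig(nImages = 50, seed = 99), adapter)
baseline <- naturalBaseline(adapter, library, setSize = 6, nSets = 50,
                            seed = 11)
round(range(baseline$mean_offdiag), 3)
#> [1] -0.108  0.681
```

The fMRI side of the pipeline:

```r
countPairings(16, 8)      # within/between pairings at 16 images, 8 runs
#>  within between
#>     448    6720

sq <- generateSequence(seed = 1)
sq
#> TrialSequence: 80 trials (8 targets), 357.0 s
buildDesign(sq)
#> DesignMatrix: 254 volumes x 16 regressors, TR 1.50 s
```

A full demonstration chain (synthesis, synthetic brain, stability map, layer
mapping, overlap matrix) runs from one config:

```r
runWorkflow(list(workflow = "demo", seed = 21), "demo_out")
```

or from the shell via the thin CLI front-end:

```sh
Rscript inst/cli/layerprint.R demo --out demo_out --seed 21
```

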