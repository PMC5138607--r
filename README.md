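# camix

Convex analysis of mixtures (CAM): blind source separation for
non-negative, well-grounded sources.

## What problem this solves

Composite biomedical signals often follow a linear latent variable model
`X = A S`: an observed `M × N` matrix `X` mixes `K` unknown non-negative
source signals `S` (`K × N`) through an unknown mixing matrix `A`
(`M × K`). Typical instances are time-course gene expression from a mixed
cell population (sources = expression programs of cell subpopulations,
mixing weights = their proportions over time) and dynamic
contrast-enhanced MRI pixel time courses (sources = vascular compartments
with distinct pharmacokinetics). camix is for analysts who need both `A`
and `S` from `X` alone, when sources are non-negative and *well-grounded*
— for every source there are samples carried (almost) entirely by it.

## The method in brief

Every sample is a non-negative combination of the columns of `A`, so the
data scatter lies in the convex cone generated by those columns, and
well-grounded points sit on its lateral edges. If `A` is *simplicial* (no
column is a non-negative or non-positive combination of the others), the
lateral edges of the data cone **are** the columns of `A`, up to positive
scaling and permutation — in the exact-, over-, and even under-determined
(`M < K`) cases. The practical pipeline:

1. scale mixture rows to unit sums, drop a fraction of the smallest-norm
   samples (lowest local SNR), collapse duplicate directions;
2. cluster the rest into `J` sectors, each summarized by a unit central
   ray (principal eigenvector of the sector autocorrelation), best of
   `n_restarts` Lloyd-style runs;
3. detect lateral edges among the rays (a ray is kept when its projection
   onto the cone of the others deviates by more than `τ = 0.001°`), then
   pick the `K` edges minimizing the sector-population-weighted angular
   model fitting error by an exact branch-and-bound search;
4. recover sources by column-wise non-negative least squares, and — when
   `K` is unknown — select it by stability analysis: the normalized model
   instability (NMI), the cross-validated inter-fold disagreement angle of
   the fitted mixing matrices normalized by a random-ray baseline, is
   minimized at the true source number.

## Worked example

```r
library(camix)

cfg <- cam_sim_config(M = 3, K = 3, N = 1600, snr_db = 12.4, seed = 7)
sim <- cam_simulate(cfg)
fit <- cam_run(sim$X, K = 3, J = 30, n_restarts = 20,
               remove_fraction = 0.5, seed = 11)
print(fit)
acc <- mixing_recovery_accuracy(fit$A_hat_raw, sim$A_true)
cat("mixing recovery accuracy:", round(acc$accuracy, 4), "\n")
cat("source recovery accuracy:",
    round(source_recovery_accuracy(fit$S_hat, sim$S_true,
                                   acc$permutation), 4), "\n")
round(fit$A_hat, 3)
```

prints

```
Convex analysis of mixtures fit
  mixtures M = 3 ; sources K = 3
  detected edges: 9 ; selected sector rays: 19, 24, 26
  model fitting error: 828.6668
mixing recovery accuracy: 0.9142
source recovery accuracy: 0.9066
   source1 source2 source3
m1  -0.020   0.873   0.147
m2   0.709   0.103   0.187
m3   0.247   0.117   0.636
```

Reading the output: 1600 noisy samples (SNR 12.4 dB) were simulated from 3
sources; the 800 largest-norm samples were clustered into 30 sectors, 9
sector rays survived edge detection, and the 3 of them minimizing the
weighted angular fitting error became the mixing-matrix estimate. The
recovery accuracies compare that estimate (and the NNLS-recovered sources)
against the simulation ground truth: 1 means perfect, and both land around
0.91 here. `fit$A_hat` holds the mixing proportions (rows sum to 1);
columns are identified up to order and positive scale, and a slightly
negative entry simply reflects noise pushing an estimated edge outside the
orthant. Leaving `K = NULL` additionally runs the stability analysis
(`fit$stability`) and uses the NMI-minimizing source number.

A thin command-line wrapper is installed with the package
(`system.file("cli", "cam.R", package = "camix")`) with subcommands
`simulate`, `run`, `select-k`, `evaluate`, and `markers`, reading and
writing labelled TSV matrices.

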