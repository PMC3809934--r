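---
title: "Fractal texture tensors, multilinear subspaces and ant-colony-tuned DAG-SVMs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fractal texture tensors, multilinear subspaces and ant-colony-tuned DAG-SVMs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`fractensor` classifies 3-D gray-level volumes — the motivating application
is CT texture of diseased liver tissue — by combining three ingredients:
per-voxel fractal roughness features, a shared multilinear (Tucker) subspace
model of the resulting feature tensors, and a multiclass support vector
machine whose hyperparameters are tuned by an ant colony. This vignette
explains each stage, the tunable parameters and their defaults, the
synthetic data the package tests itself on, and the numerical choices and
limitations a user should know about.

## Fractal dimension of an intensity surface

A gray image `g(i, j)` is read as a height surface. A perfectly flat or
smooth surface has fractal dimension 2; increasingly space-filling roughness
pushes the dimension towards 3. Two classical estimators are implemented.

**Blanket (covering) method.** Upper and lower envelopes start at the
surface (`u_0 = b_0 = g`) and grow per scale step: the upper surface becomes
the maximum of itself plus one and its 8-connected neighbourhood, the lower
the minimum of itself minus one and its neighbourhood. The blanket volume
`v_eps = sum(u_eps - b_eps)` yields the area estimate
`A(eps) = (v_eps - v_(eps-1)) / 2`, which for a fractal surface follows
`A(eps) = F * eps^(2 - D)`. `blanket_dimension()` estimates `D` by ordinary
least squares of `log A(eps)` on `log eps` over `eps = 1..max_epsilon`
(default 8); the point `eps = 1` enters at abscissa 0 and anchors the
intercept `log F`. A closed-form single-scale variant (the slope read off
one scale) is available via `method = "single"`, but the regression is the
estimator of record because a single scale confounds `D` with `F`.

**Differential box counting.** The image plane is cut into
`cells_per_side^2` grid cells of side `S = R / cells_per_side`; the gray
axis is cut into boxes of height `h = G * S / R`, so the vertical box count
matches the horizontal one. Each cell contributes
`n = l - k + 1` boxes, where `k` and `l` index the boxes holding the cell's
minimum and maximum gray value (values at `G - 1` clamp into the top box);
the single-scale dimension is `D_B = log(sum n) / log(1/delta)` with
`delta = S/R`. Grids of 4, 8 and 16 cells per side give the features
`d2`, `d3`, `d4`; the blanket estimate is `d1`.

Two properties are worth keeping in mind (both are exercised by the test
suite). First, flat images give exactly 2 under both estimators, and all
four features decrease monotonically with the Hurst exponent of a
fractional Brownian surface. Second, the *single-scale* box dimension is
upward-biased at coarse grids: with only 4 cells per side, `log N / log 4`
saturates towards 3 for any rough texture, so `d2` discriminates roughness
but should not be read as an absolute dimension. The finest default grid
(16) and the blanket estimator track the theoretical value `D = 3 - H`
closely at image sides around 257.

Per-voxel maps (`local_fractal_map()`) evaluate the chosen estimator on a
sliding window centred at each voxel of each slice (symmetric reflection
padding at the edges). Windows default to 33 pixels for `d1` (the blanket
needs interior room; must be odd) and 32 for the box features (divisible
by all three grids; being even, the patch extends one pixel less on the
trailing side). Maps are 2-D per slice because both estimators are defined
on 2-D gray functions; volumetric generalizations are out of scope.

## Feature tensors and the multilinear model

`build_feature_tensor()` stacks five channels per volume — gray intensity
rescaled to `[0, 1]` and the four fractal maps divided by 3 so that a
dimension in `[2, 3]` lands in `[2/3, 1]` — into an order-4 tensor
(rows × cols × slices × channels). Voxels outside the region-of-interest
mask are zeroed in every channel, and the per-voxel maps are only computed
inside the mask.

`fit_gnd_pca()` learns one orthonormal basis per tensor mode, shared across
the sample, by maximizing the total projected energy
`C' = sum_i ||A_i ×_1 U1' ×_2 ... ×_N UN'||^2` of the centred samples —
the maximization form of minimizing the Tucker reconstruction error. The
algorithm is alternating eigen-updates: bases start from the leading
eigenvectors of each mode's scatter matrix (a truncated higher-order SVD)
and each pass replaces basis `n` by the leading eigenvectors of the scatter
of the samples projected on all other modes. `C'` is recorded after every
mode update and is non-decreasing by construction (each update solves that
mode's subproblem exactly). Two full cycles are the default: the cost trace
flattens after the second cycle on the synthetic datasets the suite runs
(the relative change from cycle two to three is below 1e-3), matching the
known fast convergence of multilinear PCA; a tolerance-based stop (`tol`)
is available. Fits are deterministic given the sample order.

Conventions and edge cases:

* Bases are stored as `I_n × J_n` matrices with orthonormal columns;
  projection contracts with `t(U)`, reconstruction with `U`. Mode
  unfoldings order the remaining modes cyclically; `mode_fold()` inverts
  exactly.
* The voxelwise sample mean is subtracted before fitting and stored. With a
  single sample centring would annihilate the data, so `center` defaults to
  off for one sample — in which case the model at its initialization
  (`iterations = 0`) *is* the truncated higher-order SVD of that tensor, a
  correspondence the tests check via principal angles against an
  independent SVD oracle. The alternating refinement that follows moves the
  bases towards the optimal single-tensor Tucker approximation, which
  differs from the plain HOSVD subspaces while only increasing the
  projected energy.
* Eigenvector sign and rotation within tied eigenspaces are not unique;
  comparisons should therefore be made between subspaces (principal
  angles), never between raw basis matrices.
* Reconstruction quality is measured by normalized correlation
  `NC = sum(I * I*) / sqrt(sum(I^2) * sum(I*^2))`, i.e. cosine similarity,
  which is 1 exactly when the mode subspaces have full dimension.
* `compression_rate()` is the percentage `100 * prod(J) / prod(I)`; when
  the channel mode is kept full (the default `J_4 = I_4 = 5`) it
  contributes a factor of one, so order-3 spatial rates are reproduced
  unchanged.
* `fit_eigenface_pca()` supplies the classical flattening baseline (PCA on
  vectorized samples via the M × M Gram eigenproblem) with the same
  `project()`/`reconstruct()` interface, so the multilinear and linear
  models can be compared at matched coefficient budgets.

## From core tensors to a tuned multiclass SVM

Projected core tensors are flattened in column-major order and each entry
is tagged `gray` or `fractal` by its channel index (`vectorize_core()`).
Because there are four fractal channels to one gray channel yet the gray
channel is the least specific, fractal entries are up-weighted: after
per-dimension standardization on training statistics, fractal entries are
multiplied by 0.6 and gray entries by 0.4 (`apply_weights()`; both weights
are configurable and need not sum to one).

The binary classifier is an RBF SVM with kernel
`exp(-||x - y||^2 / (2 sigma^2))` — `sigma` is a length scale, and the
penalty `C` the usual box constraint. Multiclass decisions use a decision
DAG: one binary SVM per unordered label pair (`k(k-1)/2` of them, six for
four classes), labels sorted lexicographically, the root comparing the
first against the last label, each node eliminating one candidate until a
single label survives after `k - 1` decisions.

`aco_optimize()` tunes `(C, sigma)` over a decimal-digit grid: five digits
for `C` (hundreds place first, so `C` ranges over 0–999.99 in steps of
0.01) and five for `sigma` (ones place first, 0–9.9999 in steps of
0.0001). Ants build a 10-digit path, one digit per column. The first cycle
places ants uniformly at random; later cycles follow the Ant Colony System
pseudo-random-proportional rule — with probability `q0` (default 0.9) the
highest-pheromone digit, otherwise sampling proportional to pheromone; the
heuristic term is identically 1, so pheromone alone drives the search.
After every move the chosen cell evaporates towards `tau0`
(`tau <- (1 - rho) tau + rho tau0`, `rho = 0.1`); after each cycle the best
ant's path gains `Q * Acc`, with `Acc` the cycle's best fitness. Fitness is
stratified cross-validated accuracy of the (DAG-)SVM on the training set
(5 folds by default, reduced to the smallest class count when classes are
tiny; folds are drawn once so all candidates face the same partition). The
search stops when the fitness reaches `target_acc` (default 1) or the cycle
budget runs out; ties for cycle best go to the earliest ant. Decoded zeros
are clamped to the smallest positive grid values (0.01 for `C`, 1e-4 for
`sigma`) since an SVM is undefined at zero. Given a seed the whole search
is exactly reproducible.

One design point deserves emphasis: the sigma grid tops out at 9.9999, so
the feature vector handed to the kernel must live at a commensurate scale.
Standardized features have typical inter-sample distances of about
`sqrt(2 d)` for `d` dimensions, which exceeds the grid's reach once `d` is
a few hundred. The end-to-end pipeline therefore defaults to a compact core
(2 × 2 × 2 spatial, channel mode full: 40 coefficients), which retains the
low-frequency class signal — mean level and coarse gradients per channel —
while keeping the kernel width grid effective. Larger cores are available
through `core_dims` when more training data justify them.

## Synthetic phantoms

No clinical volumes ship with the package; `generate_dataset()` builds
surrogates whose ground truth is known. Textures are fractional Brownian
surfaces synthesized spectrally (white Gaussian noise filtered so power
falls as `f^-(2H+2)`, inverse FFT, linear rescale to `[0, 255]`); a surface
with Hurst exponent `H` has theoretical fractal dimension `3 - H`, which is
what makes the estimators testable. Volumes stack per-slice textures
blended with a shared smooth base field (weight 0.3) so slices correlate as
in real stacks, are mapped to a class's intensity mean and spread (clamped
to `[0, 255]`), and masked by a centred ellipsoid (semi-axes 0.42 of each
dimension, covering roughly a third of the volume) standing in for a
segmented organ.

The four default class templates place classes on two Hurst levels and two
intensity levels: `normal` (H = 0.7, mean 100), `cirrhosis` (H = 0.5, mean
100), `cancer` (H = 0.3, mean 150), `hydatoncus` (H = 0.5, mean 150), five
volumes each at 64 × 64 × 10, intensity spread 20. This makes one pair
separable only by roughness and another only by intensity, so a classifier
must use both channels to succeed. The default shape is a desk-scale
stand-in for clinical 512 × 512 × 50 stacks: every property the suite
asserts (monotone cost, NC growth, full-rank exactness, estimator
consistency) is size-independent, and the generator accepts full-size
shapes when wanted. Everything is deterministic given the master seed
(per-volume seeds are derived as `seed + index`).

What the phantoms do *not* emulate: anatomical shape, CT physics (beam
hardening, reconstruction kernels, noise spectra), inter-slice thickness
effects, or intra-class heterogeneity beyond fBm. Passing tests on
phantoms therefore validate the machinery — estimator correctness, model
geometry, search reproducibility, end-to-end separability — not clinical
accuracy.

## Study harnesses and problem sizes

`run_reconstruction_study()` performs leave-one-out reconstruction over a
ladder of core sizes (each held-out volume is projected with the training
mean only, so no information leaks), alongside training-set NC, compression
rates and the eigenface baseline at a matched coefficient budget capped by
the training rank. `run_classification_study()` performs a stratified
half/half split and compares three classifiers on the held-out half: the
weighted-fractal ACO-tuned DAG-SVM, the unweighted ACO-tuned variant, and a
fixed default (`C = 1`, `sigma = 1`). The study's desk-scale defaults are
10 ants × 10 cycles (the standalone `aco_optimize()` keeps the fuller
20 × 50); with separable data the termination rule usually stops the search
within a cycle or two. Test-suite studies run at 24–32 pixel slices with
correspondingly smaller windows; the acceptance checks run the default
64 × 64 × 10 conditions.

## Known limitations

* Fractal maps are 2-D per slice; no volumetric estimator, multifractal
  spectrum or lacunarity.
* Single-scale box dimensions at coarse grids are biased estimators, used
  as discriminative features rather than absolute measurements.
* The ACO fitness is training-set cross-validation; with very few samples
  many parameter settings tie at perfect fitness and the termination rule
  returns the first one found, which need not generalize best.
* Shared `(C, sigma)` across all DAG nodes is the default; per-node tuning
  can be had by running `aco_optimize()` per label pair.
* The flattening step from core tensor to feature vector is plain
  column-major vectorization; `vectorize_core()` is the hook point if a
  nonlinear embedding is ever wanted.
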