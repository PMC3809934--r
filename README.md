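# fractensor

Statistical fractal texture models for volumetric image classification.

`fractensor` addresses a recurring problem in computer-aided diagnosis:
telling apart tissue classes in 3-D gray-level volumes (the motivating case
is CT texture of normal, cirrhotic, cancerous and hydatoncus liver tissue)
when the discriminating signal is surface *roughness* as much as intensity,
and when training samples are far fewer than voxels. It is aimed at
researchers in biomedical image analysis who want the full pipeline —
roughness features, tensor subspace model, tuned multiclass classifier —
as composable, tested R functions.

The pipeline:

1. **Fractal features.** Each slice is treated as a height surface and its
   fractal dimension estimated two ways: the blanket (covering) method,
   fitting the area–scale law `A(ε) = F·ε^(2−D)` by least squares on
   `log A(ε)` vs `log ε`, and differential box counting,
   `D_B = log N_δ / log(1/δ)` on grids of 4, 8 and 16 cells per side.
   Per-voxel sliding-window maps (`local_fractal_map()`) turn these into
   roughness images.
2. **Feature tensors and GND-PCA.** Gray intensity plus the four fractal
   maps form an order-4 tensor per volume
   (rows × cols × slices × 5 channels). Generalized N-dimensional PCA
   (`fit_gnd_pca()`) learns one shared orthonormal basis per mode by
   alternating eigen-updates that maximize the projected energy
   `C′ = Σᵢ ‖Aᵢ ×₁ U⁽¹⁾ᵀ ×₂ ⋯ ×_N U⁽ᴺ⁾ᵀ‖²`, giving a Tucker model
   `Aᵢ* = Bᵢ ×₁ U⁽¹⁾ ⋯ ×_N U⁽ᴺ⁾` whose small core tensors `Bᵢ` represent
   the samples. Reconstruction quality is measured by normalized
   correlation (cosine similarity); an eigenface PCA baseline is included.
3. **ACO-tuned DAG-SVM.** Cores are flattened, standardized, and weighted
   (fractal entries × 0.6, gray × 0.4). A decision DAG of pairwise RBF
   SVMs (`k(k−1)/2` nodes) classifies `k` classes; the shared penalty `C`
   (0–999.99) and kernel width `σ` (0–9.9999) are discretized to five
   decimal digits each and tuned by an ant colony with `η ≡ 1`, local
   evaporation `τ ← (1−ρ)τ + ρτ₀`, and global reinforcement `Δτ = Q·Acc`.
4. **Phantoms.** Fractional Brownian surfaces (spectral synthesis; a
   surface with Hurst exponent `H` has dimension `3 − H`) provide
   multi-class volumes with known ground truth, so every stage is testable
   without clinical data.

See `vignettes/fractal-tensor-models.Rmd` for the full methods account.

## Worked example

```r
library(fractensor)

# a rough and a smooth texture of known dimension (D = 3 - H)
img <- generate_fbm_image(hurst = 0.3, size = 257, seed = 1)
blanket_dimension(img)
#> Blanket fractal fit: D1 = 2.6809 over eps = 1.. 8
box_count(img, cells_per_side = 16)$dimension
#> [1] 2.641989

# compression of the published core ladder for a 512 x 512 x 50 volume
round(compression_rate(c(100, 100, 10), c(512, 512, 50)), 4)
#> [1] 0.7629

# full pipeline on synthetic 4-class phantoms (64 x 64 x 10, 5 per class;
# a few minutes on one CPU)
ds <- generate_dataset(phantom_spec(seed = 1))
report <- run_classification_study(ds, validate_config())
report$methods
#> # A tibble: 3 x 2
#>   method      accuracy
#>   <chr>          <dbl>
#> 1 wf_aco_svm     0.875
#> 2 aco_svm        1
#> 3 default_svm    0.25
```

The first two numbers are roughness estimates of a fractional Brownian
surface with theoretical dimension 2.7 — both estimators land close to it.
The study table compares held-out accuracy (8 test volumes) of the
weighted-fractal ACO-tuned DAG-SVM against the unweighted variant and a
fixed-parameter SVM on the same split: ant-colony tuning of (C, sigma) is
what lifts accuracy from chance-like to high on these phantoms.

A thin command-line front end over these functions ships in
`inst/cli/fractensor.R` (subcommands `simulate`, `features`, `fit`,
`reconstruct`, `train`, `classify`).

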