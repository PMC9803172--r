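# gliastate

Microglia — the immune cells of the central nervous system — signal their
activation state twice over: their morphology collapses from a ramified,
branched silhouette to a compact amoeboid blob, and their NADH metabolism
shifts in a way that fluorescence lifetime imaging (FLIM/TCSPC) can read out
label-free as a change in the per-pixel photon decay curve. `gliastate` is an
R package for researchers who have segmented single-cell masks and per-cell
TCSPC decay stacks and want to classify cells as resting or activated using
both signals at once, quantify what each modality contributes, and examine
how strongly shape and metabolism co-vary.

## What it computes

**Morphology.** Each mask is summarised by a fixed 67-dimensional descriptor:
10 Zernike moment magnitudes |Z_nm| on the centroid-centred unit disk, 10
general geometric features (area, perimeter, eccentricity, axis lengths,
bounding box, equivalent diameter), a 10-bin normal-chord-length histogram,
and 37 normalised Kuhl–Giardina elliptic Fourier coefficients (N = 10
harmonics).

**Classifier.** The descriptor is mean-centred, expanded by a
feature-convolution layer (φ_ij = α_i x_i + β_j x_j over all C(67, 2) feature
pairs), and passed through a 50-unit fully connected + batch-norm + ReLU
branch. The decay stack is reduced to a p × h histogram time series (per
lifetime component, the distribution of masked per-pixel counts) and fed to a
bidirectional LSTM (hidden 32 per direction, inverted dropout 0.5). The
concatenated branches feed a 2-unit softmax head trained with minibatch SGD
(50 epochs, learning rate 1e-4, momentum 0.9), with analytic gradients
throughout. `shape_only` and `shape_plus_tau` (morphology plus the
amplitude-weighted mean lifetime τ = mean(a₁τ₁ + a₂τ₂) from bi-exponential
fits) are available as ablation modalities.

**Evaluation.** Stratified k-fold cross-validation with accuracy, precision,
recall, Jaccard index, ROC and trapezoid AUC; a 15-row feature-family subset
grid; learning curves over training fractions.

**Shape–lifetime correlation.** Regularised kernel CCA between a Gaussian
kernel on the shape features and a lifetime kernel
K^L_ij = exp(−t · d_ij), where d_ij sums 1-D Wasserstein distances between
per-component count histograms.

**Synthetic data.** Because no public dataset pairs single-cell microglia
masks with decay stacks, a generator produces labelled 64 × 64 masks
(soma + drifted lattice-walk processes vs perturbed blobs) and Poisson
bi-exponential decay stacks convolved with a Gaussian instrument response,
with switches that selectively remove the morphological or the lifetime
class contrast. All outputs are deterministic functions of one seed.

## Worked example

```r
library(gliastate)

out <- file.path(tempdir(), "demo")
manifest <- generate_dataset(60, activated_fraction = 0.5, p = 64, seed = 42,
                             out_dir = out)
bundle   <- load_dataset(manifest)
features <- extract_feature_table(bundle)
features[1:3, 1:4]
#> # A tibble: 3 × 4
#>   cell_id   zernike_0 zernike_1 zernike_2
#>   <chr>         <dbl>     <dbl>     <dbl>
#> 1 cell_0001     0.615  1.44e-16     0.501
#> 2 cell_0002     0.569  2.23e-16     0.540
#> 3 cell_0003     0.553  3.14e-16     0.547

cv <- cross_validate(bundle, glia_config(modality = "joint", epochs = 20, seed = 42))
cv
#> <glia_cv> joint, 5 folds; mean test accuracy 0.9167 (AUC 0.9889)
glance(cv)
#> # A tibble: 1 × 12
#>   modality k_folds accuracy precision recall jaccard   auc train_accuracy ...
#> 1 joint          5    0.917     0.871      1   0.871 0.989          0.938

kc <- kcca_analysis(bundle)
kc
#> <glia_kcca> canonical correlations: 0.982, 0.967 (kappa = 6)
```

`zernike_0` is |Z_00|, essentially the filled fraction of the enclosing
disk — lower for the branched resting cells; `zernike_1` (|Z_11|) vanishes to
rounding because the unit disk is centred on the shape centroid. The 60-cell
demo reaches 0.917 held-out accuracy after 20 epochs; the default 400-cell
benchmark at the full 50-epoch schedule reaches ≈ 0.97 (joint) vs ≈ 0.97
(shape-only, slightly lower) — run the acceptance script below for the exact
numbers on your seed. `autoplot(cv)` draws the pooled ROC; `tidy(cv)` gives
per-fold metrics; `autoplot(kc)` shows the per-class KCCA projection.

A command-line interface wrapping the same functions ships at
`inst/cli/gliastate.R` with subcommands `synth`, `extract`, `train`, `cv` and
`kcca`; every stage rerun with the same configuration and seed is
byte-identical.

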