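# thalparc

Segmentation of thalamic nuclei groups from single-shell diffusion MRI,
using the complete orientation distribution function (ODF) of each voxel
rather than a scalar or directional summary.

The thalamus is a mosaic of small nuclei that conventional MRI contrast
cannot separate. Their fiber populations differ in orientation, so the
angular diffusion profile can: `thalparc` reconstructs per-voxel ODFs
with the constant-solid-angle (CSA) q-ball estimator in a real symmetric
spherical-harmonic (SH) basis and clusters thalamic voxels on combined
spatial + ODF features. It is aimed at neuroimaging researchers who need
a reproducible, atlas-free parcellation from a clinical-grade diffusion
acquisition (64 directions, b = 1000 s/mm², ~2 mm voxels).

## Method in brief

Per voxel, the signal is expanded in the order-6 SH basis
(R = (l+1)(l+2)/2 = 28 coefficients):

    ln(−ln S(u)/S(0)) = Σⱼ cⱼ Yⱼ(u),   j = 1..28

and mapped to the ODF analytically (Funk–Radon and Laplace–Beltrami
operators are diagonal in SH):

    ODF(u) = 1/(4π) + (1/16π²) · FRT{ Δᵦ ln(−ln S/S(0)) }(u)

with 50 residual-bootstrap replicates averaged per voxel. Voxels are then
clustered by a modified k-means with decision metric

    d²(v, C) = α·d²_pos + (1−α)·d²_ODF,   α = 0.5,  S_ODF = 55

initialized data-driven from the average of many position-only k-means
runs. A binary thalamus mask is refined beforehand with the published
rules (remove CSF probability ≥ 0.05; remove FA > 0.55 within 2 mm of the
border). An angular-difference baseline (tensor principal eigenvectors,
scale factor 6), the standard evaluation metrics (Dice, centroid
distance, modified Hausdorff, majority-vote consensus, Wilcoxon symmetry
tests) and a multi-tensor phantom generator with Rician noise complete
the package. See the vignette (`vignettes/thalamic-parcellation.Rmd`) for
the full model and design rationale.

## Worked example

```r
library(thalparc)

# synthetic 7-region thalamus phantom: DWI + mask + CSF map + truth
ph  <- generate_phantom(phantom_spec(), seed = 1)
cfg <- cluster_config(n_init_runs = 200)   # production default is 5000
lab <- parcellate_dwi(ph$dwi, ph$mask, cfg, seed = 2)
lab
#> Labeling: 7 clusters over 1712 voxels; sizes 309, 282, 279, 231, 229, 191, 191

round(normalized_volumes(lab, ph$mask), 3)
#> [1] 0.180 0.165 0.163 0.135 0.134 0.112 0.112
```

Each cluster's volume fraction of the whole thalamus is printed above —
the seven regions occupy between 11% and 18% of the mask. Scan–rescan
reproducibility on two independent noise realizations of the same
phantom:

```r
pair <- simulate_scan_rescan(phantom_spec(), seed_a = 11, seed_b = 12)
res  <- scan_rescan_metrics(pair, cfg, feature = "odf", seed = 2)
print(res$metrics, digits = 3)
#>   label1 label2  dice centroid_distance modified_hausdorff
#> 1      1      1 0.994            0.0609             0.0317
#> 2      2      2 0.996            0.0513             0.0112
#> 3      3      3 0.996            0.0456             0.0112
#> 4      4      4 0.991            0.1149             0.0252
#> 5      5      5 0.993            0.0300             0.0377
#> 6      6      6 0.992            0.0993             0.0308
#> 7      7      7 0.995            0.0720             0.0157
res$mean_dice
#> [1] 0.994
```

Matched clusters overlap at Dice ≈ 0.99 with centroid displacements far
below the 2 mm voxel size — the two independently noised and
independently segmented scans give essentially the same parcellation.

Command-line wrappers over the same functions live in `inst/scripts/`
(`phantom.R`, `parcellate.R`, `evaluate.R`).

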