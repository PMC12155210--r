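# avcscore

Automated quantification of **aortic valve calcification (AVC)** in
non-contrast CT calcium-score (CTCS) exams. Calcific aortic stenosis is the
most common valvular disease, and AV-Agatston scores from routine
calcium-score CTs can flag patients who need echocardiographic evaluation —
but the valve itself is nearly invisible at non-contrast soft-tissue
contrast, so the calcium must be measured inside a *localized region*,
not detected free-form.

`avcscore` implements that region as an idealized 8-parameter cylinder
— unit axis $(\mu_x,\mu_y,\mu_z)$, origin $(x_0,y_0,z_0)$, radius $r$,
height $h$ — and provides the full pipeline around it:

* **Geometry** — fit a local PCA frame to a disk-like expert annotation and
  expand it to the valve cylinder via the strict membership rules
  $x'^2+y'^2 < (r_\text{valve}+\Delta r)^2$ and $-d_B < z' < d_A$
  (defaults $\Delta r = 2$, $d_A = 10$, $d_B = 30$ mm, a 40 mm cylinder);
  rasterize, parameterize and map cylinders between acquisition and
  isotropic crop space losslessly.
* **Scoring** — Agatston, volume and mass scores and valid-lesion counts
  inside the ROI (per-slice 8-connected components ≥ 130 HU and ≥ 1 mm²,
  26-connected 3D lesions, density weights 1–4), with the sex-specific
  severity thresholds (likely severe > 2000 Ag men / > 1200 Ag women) and
  clinical bins 0, 1–800, 800–1200, 1200–2000, 2000+.
* **Sub-ROIs** — exact partition of the cylinder into 3 concentric shells ×
  3 height slabs × 3 anchor-defined sectors (27 regions, labels `A-D-G` …)
  with regional score tables and heatmaps.
* **Noise QC** — descending-aorta noise statistic (sd of sub-130 HU voxels)
  with the 36 HU denoise / 45 HU exclude rules and slice-wise 3×3 median
  filtering.
* **Multi-task deep learning** — a three-branch network (3D U-Net-style
  segmentation; latent-space regression of 7 cylinder parameters;
  differentiable soft-cylinder reconstruction loss) with center-of-mass
  origin linkage at inference. The 3D convolution engine and all backward
  passes are implemented in the package (RcppArmadillo) and verified
  against finite differences.
* **Synthetic phantoms** — CTCS-like volumes with exact cylinder/calcium
  truth, cohort generation across severity bins, and calibrated streak
  artifacts, so every stage is testable without clinical data.

## Worked example

```r
library(avcscore)

# a synthetic case with known truth: oblique valve cylinder + calcifications
ph <- generate_phantom(phantom_spec(seed = 7, blobs = data.frame(
  radius_mm = c(2.5, 3), peak_hu = c(450, 800), inside = TRUE)))

# annotate path: QC -> disk-to-cylinder expansion -> Agatston -> sub-ROIs
rec <- run_pipeline(ph$volume, case_id = "demo", sex = "female",
                    disk = ph$disk, aorta_mask = ph$aorta_mask)
rec
#> <case_record> demo: annotated cylinder, Ag 154.2, bin 1-800
rec$scores[, c("agatston", "volume_mm3", "n_valid_lesions", "severity_bin", "severe")]
#>   agatston volume_mm3 n_valid_lesions severity_bin severe
#> 1   154.25    106.875               2        1-800  FALSE
```

The two rendered blobs yield an Agatston score of 154 — calcium is present
(two valid lesions, each > 10 Ag) but far below the female likely-severe
threshold of 1200 Ag, so the case lands in the 1–800 bin with
`severe = FALSE`. The marginal sub-ROI table localizes the calcium (here
the mid shell and the top slab, toward the aortic root):

```r
rec$regional$marginal[, c("code", "axis", "agatston")]
#>   code   axis agatston
#> 1    A  shell    29.00
#> 2    B  shell   125.25
#> 3    C  shell     0.00
#> 4    D   slab   103.75
#> 5    E   slab    48.00
#> 6    F   slab     0.00
#> 7    G sector    26.00
#> 8    H sector    54.75
#> 9    I sector    73.50
plot_regional_heatmap(rec$regional)
```

Training and predicting with the multi-task model at desk scale:

```r
phantoms <- lapply(1:40, function(i)
  generate_phantom(phantom_spec(seed = 5000 + i, blobs = NULL),
                   expected = FALSE))
ds   <- phantom_dataset(phantoms, out_shape = c(64, 64, 64))
pre  <- desk_preset(seed = 11)
net  <- build_network(pre$input_shape, pre$base_channels, seed = 11)
res  <- split_and_train(ds, net, pre$train)   # ~8 min on one CPU
tail(res$log, 1)
#>   epoch train_loss val_dice_seg val_dice_recon val_origin_err_mm ...
#> 1    30     0.0705        0.884          0.842             0.27
```

A validation reconstructed-cylinder Dice of ~0.84 with sub-millimetre
center-of-mass origin error shows the three branches and the CoM linkage
working together; `predict_cylinder()` then maps the predicted parameters
back to acquisition space for scoring.

A thin command-line front end (`inst/cli/avcscore.R`) exposes `simulate`,
`qc`, `score`, `train`, `predict` and `report` subcommands over the same
functions.

## Testing

```sh
Rscript -e 'testthat::test_dir("tests/testthat", package = "avcscore",
                               load_package = "installed")'
```

The suite covers unit behaviour per module, property-style invariants
(orthonormal PCA frames, exact sub-ROI partitions, score monotonicity and
additivity, oracle equivalence, finite-difference gradient checks) and the
end-to-end checks above. The methods vignette
(`vignettes/valve-roi-methods.Rmd`) documents the model, its assumptions,
parameter defaults, and what the synthetic phantoms do and do not
demonstrate.
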