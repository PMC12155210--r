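---
title: "Methods: cylindrical valve ROIs and Agatston scoring in avcscore"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cylindrical valve ROIs and Agatston scoring in avcscore}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(avcscore)
```

## The problem

Aortic valve calcification (AVC) on non-contrast CT calcium-score exams is a
guideline-supported marker of aortic stenosis, but the valve itself is
nearly invisible at soft-tissue contrast. `avcscore` quantifies AVC by first
localizing an idealized cylindrical region of interest (ROI) around the
valve and then applying the standard Agatston criteria inside it. The
cylinder is an 8-parameter model — a unit axis direction
$(\mu_x,\mu_y,\mu_z)$, an origin $(x_0,y_0,z_0)$ at the cylinder's centre of
mass, a radius $r$ and a height $h$ — which makes the region easy to edit,
to map between coordinate spaces, and to decompose into anatomically
meaningful sub-regions.

## From disk annotation to cylinder

An expert annotates the valve as a disk in one reformatted slice, plus the
valve centre and three anchor points (PALA, LARA, RAPA) between the
pulmonary artery, left atrium and right atrium. `fit_local_frame()` applies
principal component analysis to the millimetre-rescaled disk voxels; the
two leading components span the disk plane and the least-variance component
is the valve normal. The valve radius is the largest in-plane distance from
the annotated centre to any disk voxel. `expand_disk_to_cylinder()` then
includes every voxel whose centre satisfies the two strict rules

$$x'^2 + y'^2 < (r_\text{valve} + \Delta r)^2, \qquad -d_B < z' < d_A,$$

in the local frame about the disk centroid. The defaults
$\Delta r = 2\,$mm, $d_A = 10\,$mm (above the disk, toward the aortic
root), $d_B = 30\,$mm (below, toward the cusps) give a 40 mm cylinder that
covers the valve apparatus while excluding proximal coronary calcium.
Membership is evaluated with strict inequalities at voxel centres, exactly
as the rules are written; half-voxel effects are absorbed by the stated
tolerances.

Two conventions are deliberate choices where the geometry is ambiguous:

* **Normal sign.** The height rule is asymmetric, so the sign of the normal
  matters. The normal is oriented toward the scanner superior (+z) axis and
  "above" means superior. A config flag is unnecessary in practice because
  every downstream quantity is reported with this convention stated.
* **Radius centre.** The radius is measured from the annotated valve
  centre, not the PCA centroid; for an asymmetric disk these differ, and the
  annotated centre is what the annotator intended as "the centre of the
  valve". The expansion itself is anchored at the PCA centroid.

`parameterize_mask()` inverts the rasterization: the axis is the principal
direction whose eigenvalue is most separated from the other two (a
cylinder's two radial variances are equal), the origin is the unweighted
centre of mass, and radius/height are refined by minimizing voxel-wise
disagreement with the re-rasterized model. On 1 mm grids this recovers
cohort-range cylinders ($r \in [16, 22]$ mm, $h = 40$ mm) to within half a
voxel diagonal in origin, one in-plane spacing in radius, and
$|\cos| \ge 0.999$ in axis direction.

## Agatston scoring inside the ROI

`find_lesions()` implements the clinical calcium-scoring convention:
voxels $\ge 130$ HU inside the ROI are grouped per slice into 8-connected
2D components; components smaller than 1 mm$^2$ (e.g. 7 voxels at
0.4 × 0.4 mm) are discarded; surviving components are merged across
adjacent slices by 26-connectivity into 3D lesions. The Agatston score is
$\sum_\text{components} \text{area} \times w$, with $w \in \{1,2,3,4\}$ for
a component maximum HU in $[130,200)$, $[200,300)$, $[300,400)$, $\ge 400$,
computed on native slices without slice-increment rescaling. The volume
score counts qualifying-lesion voxels; the mass score is
$c \sum_\text{lesions} \overline{HU} \times V$. The calibration factor $c$
is scanner specific and not derivable from first principles here; the
default 0.001 is a placeholder that should be replaced by a phantom-derived
value when absolute milligrams are needed. Volume and mass are restricted
to qualifying lesions (not every voxel above 130 HU) so that all four
metrics describe the same objects. A *valid* lesion for the lesion count
must exceed 10 Ag (strict), guarding the count against noise specks.

Severity uses the European guideline thresholds: severe stenosis likely
above 2000 Ag (men) / 1200 Ag (women), unlikely below 1600 / 800, with
clinical bins 0, 1–800, 800–1200, 1200–2000, 2000+. Scores exactly on an
edge fall in the lower bin, consistent with the strict "greater than" used
for the flags. With unknown sex the bin is reported and the flags are `NA`.

Scoring is always performed on the acquisition-space volume; the isotropic
resample exists only as network input.

## Sub-ROI decomposition

`partition_cylinder()` splits the ROI three ways: concentric shells at 1/3
and 2/3 of the radius (A inner to C outer — equal radius fractions, not
equal areas, so the shells map onto centre / mid-leaflet / wall anatomy),
height slabs in thirds (D top toward the aortic root, E, F bottom toward
the cusps), and angular sectors bounded by rays from the axis through the
projected anchors (G flanked by RAPA and PALA, H by PALA and LARA, I by
LARA and RAPA). Boundary handling is half-open everywhere, so every ROI
voxel belongs to exactly one of the 27 crossed regions and the 9 marginal
regions are exact unions of their children. Rays *through* the anchors were
chosen over bisectors between them because the anchors mark boundaries
between anatomical structures, which is what a sector boundary should
follow; `sub_roi_scheme(sector_mode = "bisector")` provides the
alternative. Without anchors (a purely predicted cylinder) sectors are
undefined and the 9 shell × slab decomposition is emitted.

Regional Agatston scores re-run lesion detection inside each region, so a
lesion straddling a boundary is re-evaluated per side and regional Agatston
need not sum to the ROI total (the gap is reported). Regional *volume*
scores intersect the whole-ROI lesions with each region and are therefore
exactly additive.

## Noise QC

Image noise is measured as the standard deviation of descending-aorta
voxels below 130 HU (excluding calcium candidates) inside an externally
supplied aorta mask. Cases above 36 HU are denoised with a slice-wise
3 × 3 median filter — well matched to the streak artifacts of photon
starvation — before calcification detection; cases above 45 HU are
excluded from automated analysis. Both thresholds are configurable but the
defaults are part of the method. Organ segmentation itself (descending
aorta, heart sac) is treated as an external input throughout; for phantoms
the generator supplies both.

## The multi-task network

`build_network()` constructs a 3D U-Net-style encoder–decoder with three
strided 3 × 3 × 3 convolution levels, skip connections, and a pointwise
segmentation head (branch 1). The bottleneck is globally average-pooled
into a descriptor whose length equals the encoder output channel count
(256 at the default width of 64 base channels) and passed through a
regularized MLP — fully connected, LeakyReLU, LayerNorm, dropout, fully
connected, tanh — regressing 7 values (branch 2): the axis direction, the
origin normalized to $[-1,1]$ over the crop extent, and the radius
rescaled by $r_\text{rescaled} = 2(r/40) - 1$. The height is fixed at
40 mm. Branch 3 reconstructs a cylinder from the decoded parameters as a
differentiable soft mask
$\sigma\!\big(k(r-\rho)\big)\,\sigma\!\big(k(h/2-|z'|)\big)$ with sharpness
$k = 50\,\text{mm}^{-1}$ (thresholded at 0.5 it agrees with the exact
rasterization at Dice ≥ 0.995 on 1 mm grids) and compares it with the
label mask by soft Dice. The trained loss is

$$\alpha\,\text{Dice}_{seg} + \beta\,\text{MSE}_{origin} +
  \Delta\,\text{MSE}_{normal,radius} + \gamma\,\text{Dice}_{recon},
  \qquad \alpha=\beta=\Delta=\gamma=\tfrac14 .$$

The MSE terms are evaluated on the encoded $[-1,1]$ parameters so all
seven targets share one scale. At inference the origin is *not* taken from
the regression: the branch-1 segmentation is thresholded at 0.5 and its
unweighted centre of mass becomes the origin (CoM linkage), with the
regressed origin as a flagged fallback if the segmentation is empty.
Normal and radius come from branch 2, and the parameters are mapped back
to acquisition space through the recorded crop geometry.

The whole network, including the im2col-based 3D convolutions and every
backward pass, is implemented in this package (RcppArmadillo + R) and
verified against finite differences in the test suite. Unstated
engineering choices — Adam ($10^{-3}$ at the desk scale), He-style
initialization, a segmentation bias initialized near the foreground prior
logit, dropout 0.1 — were made for optimization stability and are all
overridable. Displacement augmentation is omitted; only Gaussian intensity
noise (sd 0.1 on the $[0,1]$-windowed input) is applied on the fly.

Preprocessing for the network: trilinear resampling to 1 mm isotropic
voxels, a fixed window cropped about the heart-sac bounding box (176 × 176
× 128 at full scale; the window is padded with the volume minimum when the
box under-fills), HU windowing to $[-300, 100]$ and rescaling to $[0,1]$.
Crop offsets are recorded so cylinder parameters round-trip between
acquisition and crop space to machine precision. The 65/15/20
train/validation/test split uses floor rounding for the first two buckets
with the remainder to test; exact counts (e.g. 200/49/61 for a 310-case
cohort) can be forced via `split_counts`.

## Synthetic phantoms: what they emulate and what they do not

`phantom_spec()` / `generate_phantom()` produce CTCS-like volumes with
exact ground truth. The geometry follows the clinical ranges: 0.42–0.59 mm
in-plane spacing, 2.5/3 mm slices, valve radii drawn from $[16, 22]$ mm, a
fixed 40 mm height, axis tilts of 10–30° from the scanner axis. The scene
is a mediastinal abstraction: lung-density background (−700 HU), a
soft-tissue cardiac ellipsoid (45 HU) whose **long axis follows the valve
normal** and whose **width scales with the valve radius**, a
descending-aorta tube for noise QC, and the valve cylinder itself with
only mild (+18 HU) intrinsic contrast. This encoding of the cylinder in
the surrounding anatomy is intentional: in real non-contrast CT the valve
is almost invisible and a network must infer the ROI from cardiac
landmarks, so the phantom makes exactly that information available rather
than painting an artificially conspicuous valve. An earlier renderer that
offered only the faint valve contrast on a featureless background produced
a network that regressed to the cohort-prior mask — a useful reminder that
these phantoms validate the *machinery* (geometry, losses, CoM linkage,
coordinate mapping), not clinical performance. Real images differ in every
texture: no organ boundaries are this clean, orientation cues are not this
regular, and passing the phantom suite says nothing about cohort Dice on
patient data.

Calcifications are rendered as clipped Gaussian bumps whose 130 HU contour
sits at the nominal blob radius, so partial-volume effects exercise the
area threshold nontrivially. Inside blobs keep a 4 mm clearance from the
cylinder wall; distractor blobs are placed outside with clearance so they
can never leak into the ROI. Expected score reports are computed by
`score_reference()` — a deliberately scalar, independently coded
implementation of the full scoring chain — so phantom truth never shares
code with the path under test. Streak artifacts are alternating-sign
1-voxel lines through the aorta neighbourhood; with 120 lines, amplitudes
of 20 HU and 40 HU were calibrated (once, by sweep) to land the aorta
statistic in the denoise band and above the exclusion threshold
respectively on top of a 20 HU noise floor.

## Problem sizes and numerical choices

The package's own experiments run at a desk scale chosen to keep a full
training cycle within minutes on one CPU: 64³ isotropic crops, an
8-channel encoder (32-channel latent), 40 phantoms split 26/6/8, 30 epochs
of single-case Adam steps at $10^{-3}$, and a stride-2 reconstruction grid
for branch 3. Validation at this scale reaches reconstructed-cylinder Dice
above 0.8 with sub-millimetre CoM origin error; the acceptance thresholds
(Dice ≥ 0.6, origin < 3 mm) are deliberately looser because stochastic
training on 40 cases has run-to-run spread. Oracle-equivalence checks use
200 random grids up to 64³ so the scalar reference implementations stay
affordable. Degenerate inputs are handled explicitly: collinear disks and
empty masks raise errors, radii below half the in-plane spacing produce an
empty mask with a warning, non-unit normals are normalized only within a
$10^{-3}$ tolerance, and voxels exactly on partition boundaries go to the
lower region.

## Known limitations

* The mass calibration factor is a placeholder; absolute mass requires a
  scanner calibration.
* DICOM support covers single-frame uncompressed little-endian series
  only; NIfTI is the primary format.
* Sectors give anatomical context (PALA/LARA/RAPA-flanked), not true
  leaflet segmentation; whether boundaries should pass through anchors or
  bisect between them is exposed as `sector_mode`.
* Phantom realism is statistical/geometric, not photometric; no projection
  physics is simulated, and streaks are an emulation sufficient to drive
  the QC statistic.
* The desk-scale network shares its architecture family with the
  full-scale configuration but not its capacity; cohort-level clinical
  metrics are out of reach of synthetic data by design.
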