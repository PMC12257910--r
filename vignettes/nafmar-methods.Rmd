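---
title: "Neural attenuation fields for CT metal artifact reduction: model, simulator and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Neural attenuation fields for CT metal artifact reduction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(nafmar)
```

## The problem

Metal implants make parts of a CT sinogram unusable. Photons that cross a
gold filling are attenuated by orders of magnitude more than the
surrounding anatomy; with a polychromatic source the surviving photons are
strongly hardened, and detected counts can fall to single digits (photon
starvation). After the logarithm and water beam-hardening correction these
line integrals are inconsistent with the rest of the scan, and filtered
backprojection (FBP) spreads the inconsistency across the image as streaks
and shadows. Sinogram-inpainting MAR methods treat the affected detector
pixels — the *metal trace* — as missing data and replace them. The
decisive question is what prior information guides the replacement.
`nafmar` answers it with a scan-specific implicit model: a neural
attenuation field optimized on the reliable (off-trace) rays of the same
acquisition, so no external training data are involved.

## The model

The field $f_\theta(\mathbf{x}) \mapsto \mu$ is a multi-resolution hash
encoding followed by a 4-layer, 64-channel ReLU MLP, with a softplus
output so attenuation is non-negative. Per level $\ell$ the encoding
bilinearly (trilinearly in 3D) interpolates 4 feature values from a table
indexed either densely (when the level grid fits) or by spatial hashing
into $2^{16}$ entries; level resolutions grow geometrically from 16 to the
finest resolution (512 at full scale). The full-scale configuration holds
about 4.2 million trainable parameters.

A detector ray contributes through the discrete Beer–Lambert model
$I_\text{pred}/I_0 = \exp(-\sum_i \mu_i \delta_i)$ with $N$ uniform
mid-point samples between the ray's entry and exit of the volume bounding
box ($N = 576$ at full scale). The fitting target is the *normalized
intensity* $I/I_0 = e^{-p}$ rather than the raw line integral: this
matches the attenuation equations literally and bounds the target in
$(0, 1]$. A log-domain option was considered and rejected as the default
because squared error on $p$ would overweight exactly the
photon-starved, least-trustworthy measurements near the trace.

### Masked sampling and the metal-aware loss

The metal volume (ground-truth mask in simulation mode; a 2000 HU
threshold on the uncorrected FBP in the clinical-style path) is
forward-projected; detector pixels with strictly positive metal path
length form the trace $T_\text{metal}$. Rays in the trace are never
sampled — an instrumented counter in the optimizer records how many trace
rays entered any batch, and the test suite asserts the count is exactly
zero over full runs.

Off-trace rays within $d_{th} = 20$ detector pixels (Euclidean distance
transform, computed exactly per view) of the trace form the metal-aware
set $R_m$ with weights $w(r) = \exp(-\lambda\, d(r))$, $\lambda = 0.01$,
normalized once per run by the global maximum so that
$\max \hat w = 1$ and the loss scale is stationary across batches.
Distances are in detector pixels, which keeps the parameters
geometry-independent. The total objective is
$L = L_\text{RECON}(\theta, R_r) + \lambda_M L_\text{MA}(\theta, R_m)$
with $\lambda_M = 1$. Because $R_m \subseteq R_r$, a metal-aware ray
appears in both terms; the batch estimator therefore gives a ray drawn
from $R_m$ the coefficient $1 + \lambda_M \hat w(r)$ — this keeps the
estimator unbiased for the objective and realizes the intended behavior
of *raising* attention near metal rather than down-weighting it. Batches
(256 rays) are split between $R_r \setminus R_m$ and $R_m$ in proportion
to the sets' sizes and drawn uniformly without replacement, so a batch
never contains duplicates and the two terms are computed on disjoint
draws.

### Optimization

Adam (standard $\beta$'s) with learning rate $10^{-3}$ halved every 50
epochs. Two numerical choices matter and are deliberate:

* **Output-bias initialization.** With a zero-initialized output layer,
  softplus puts the field at $\mu \approx 0.69\,\text{mm}^{-1}$
  everywhere; every ray then saturates ($e^{-\mu L} \approx 0$) and all
  gradients vanish through the exponential. The output bias is
  initialized to $-4$, starting the field near water-scale attenuation
  ($\approx 0.018\,\text{mm}^{-1}$), where gradients are healthy. Hash
  tables start at $\mathcal{U}(-10^{-4}, 10^{-4})$, MLP weights with
  He-uniform fan-in scaling.
* **Sparse Adam on the tables.** Only table rows touched by the current
  batch are stepped (with bias correction from the global step count);
  the MLP uses dense Adam. This is the usual optimizer treatment for
  hash-grid parameters and is what makes single-CPU training practical.

Training is bit-reproducible for a given seed: one Mersenne-Twister
drives initialization and every batch draw, and all arithmetic is double
precision through sequential BLAS.

### Rendering, prior and inpainting

The fitted field is evaluated at voxel centers (the *NAF image*) and
converted to HU with $\mu = \mu_w (1 + \text{HU}/1000)$,
$\mu_w = 0.0206\,\text{mm}^{-1}$ (water near the 60–70 keV effective
energy; the same constant anchors the simulator's ground-truth HU scale).
`stats::kmeans` (3 centers, 5 seeded starts) clusters the intensities;
classes ordered by centroid become air / soft tissue / bone; air is set
to −1000 HU and soft tissue to 0 HU exactly, bone keeps its rendered
values. A volume with fewer than three distinct intensities falls back to
fixed thresholds (−500 / 376 HU) with a message.

The prior is forward-projected monochromatically at $\mu_w$'s reference
energy; the measured sinogram is normalized by the prior sinogram with a
$10^{-7}$ floor applied identically in the normalize and denormalize
steps, so the round trip is exact off the floor. Each maximal run of
trace pixels in each (view, row) is bridged by 1D linear interpolation
between its nearest off-trace neighbors along the detector columns; runs
touching a row edge extend the nearest valid value; a row entirely inside
the trace borrows the mean of its nearest valid rows (neighboring views
in single-row geometries), with a message. After denormalization the
off-trace pixels are *copied* from the measurements rather than
recomputed, making sinogram consistency exact to floating-point equality
— `(p/m)·m` would not round-trip bitwise. FBP of the corrected sinogram
plus reinsertion of the uncorrected reconstruction's values at the metal
mask yields the final volume.

## The reconstruction substrate

The projector marches each ray at a uniform step of half the smallest
voxel edge with trilinear in-volume interpolation; it is exactly linear
in the volume, and its chords through an anti-aliased uniform disk match
$2\mu\sqrt{R^2 - s^2}$ within 1% away from grazing incidence.
Reconstruction is flat-panel fan-beam FBP (cone-beam FDK in 3D): cosine
pre-weighting on iso-plane detector coordinates, a discrete
Ramachandran–Lakshminarayanan ramp applied per detector row by FFT
(Hann/cosine apodization available), and $1/U^2$-weighted backprojection
for a full 360° turn; short-scan weighting is out of scope. The
forward–inverse round trip on a smooth 256² phantom with 360 views stays
within ~0.5% RMSE of the dynamic range.

## The simulator

The synthetic test bed emulates a dental CBCT acquisition with gold
implants:

* **Phantom.** A soft-tissue head ellipse, a U-shaped jaw arch of bone
  carrying a row of teeth, and 2–5 gold inserts (disks or squares,
  1.2–2.2 mm) placed in randomly chosen teeth. Structures are rasterized
  with 3×3 sub-voxel supersampling so voxels carry partial-volume
  fractions — a real scanner's ground truth is band-limited, and sharp
  binary masks would add Gibbs ringing that no reconstruction could
  fairly be scored against. Soft tissue carries a seeded texture field
  (sum of oriented cosines, ±18 HU, periods ≳ 5.5 mm): detail of the
  kind a coordinate network blurs but FBP preserves. HU values are tied
  to the material table at 60 keV (soft ≈ +43, jaw ≈ +880, teeth ≈
  +1350, gold ≫ 3000), so the ground truth and the physics chain agree
  by construction. The metal-free ground truth keeps tooth material
  where the implant sits.
* **Spectrum and materials.** 12 energy bins from 10 to 120 keV with
  relative weights of an aluminum-filtered 120 kVp tungsten beam (zero
  at 10 keV, peak near 60 keV), $10^6$ incident photons per ray.
  Attenuation columns for water, soft tissue, cortical bone and gold are
  NIST-derived values interpolated to the 10 keV grid; the gold column
  is smoothed across the Au K-edge at 80.7 keV so every material is
  monotone non-increasing over the grid — a documented simplification
  that preserves the artifact physics (gold dominates bone at every
  energy) without tabulating the edge. Jaw and teeth project at 0.65 and
  0.80 of cortical bone density.
* **Acquisition.** Material path lengths come from the same projector as
  everything else; detected intensity is the spectral sum; Poisson noise
  is drawn per pixel after spectral summation; the log transform clamps
  at 1 count (photon starvation guard); water beam-hardening correction
  maps the polychromatic log projections through a cubic fitted so pure
  water paths of 0–400 mm return $\mu_w L$ exactly. A water cylinder
  reconstructs flat to within a few HU. Paths through gold leave the
  water calibration range — that residual is the artifact source the
  pipeline corrects.

What the simulator does **not** emulate: scatter, detector blur and
afterglow, tube-current modulation, anatomical variability beyond the
dental-like layout, and the K-edge structure of gold. Passing tests
therefore demonstrate correctness of the algorithms under controlled
polychromatic + Poisson physics, not clinical performance.

## Problem sizes and presets

Full-scale 3D training is a GPU workload; the package keeps the
full-scale preset (`naf_config("paper")`) but runs its experiments on 2D
fan-beam configurations chosen so every study completes in minutes on one
CPU core:

* `geom_preset("desk")`: 300/500 mm, 180 views, 192 detector columns at
  1.2 mm, 128² volume at 1 mm. Used for the clean-recovery experiment
  (field trained on uncorrupted projections reaches ≥ 28 dB against the
  phantom; the loss plateaus by epoch ~8, hence the preset's 10 epochs —
  30 were tried and bought nothing).
* The seeded method-comparison cases use 120 views × 144 columns on a
  128² grid with the `"desk-fast"` preset (96 samples/ray, 5 epochs,
  $2^{14}$ tables, finest level 128). Five epochs are enough because the
  prior needs only a stable 3-class segmentation, not a polished field.

On these cases the package reproduces the method ranking expected of a
prior-based MAR pipeline: NAFMAR > LI > uncorrected in masked SSIM, with
a PSNR gain of several dB over no correction. Two scale effects are worth
stating plainly. First, the metal-aware loss modulates ~12% of rays by at
most a factor ~2; across repeated desk-scale runs its effect on final
SSIM (±0.0005) is comparable to training-sampling noise, so while the
full pipeline does not fall below its ablation on the bundled cases, the
clear separation the full-scale setting shows should not be expected
here. Second, the rendered NAF image can score *above* the final
inpainted result on SSIM at desk scale: the field denoises while the
final volume keeps the measured (noisy) off-trace sinogram — at full
resolution the balance tips the other way because the field's texture
loss dominates. The final result still improves on the uncorrected FBP
and the LI baseline, which is the comparison that matters.

## Evaluation

Masked PSNR and SSIM: both metrics exclude the metal voxels, are computed
on a declared display window (default [−1000, 1500] HU, clipped), PSNR
uses the reference's unmasked maximum, and SSIM uses the global-statistics
form with $C_1 = (0.01 L)^2$, $C_2 = (0.03 L)^2$ for window width $L$ (a
sliding-window variant is available behind a flag). For 3D volumes both
per-slice and whole-volume aggregates are reported, since either
convention appears in the literature.

## Known limitations

* The projector assumes a circular trajectory, centered flat detector and
  full angular coverage; no helical or offset-detector support.
* Water-only beam-hardening correction leaves a bone residual of a few
  tens of HU — visible as the gap between the clean chain's ~27 dB and
  the monochromatic round trip's ~33 dB at 256².
* The field is fit per scan; there is no amortization across scans.
* k-means determinism relies on seeded multiple random starts rather than
  a k-means++ construction.
* Very large metal objects (hip-prosthesis scale) leave traces too wide
  for any interpolation-based completion; the method targets dental-scale
  implants.
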