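# nafmar: metal artifact reduction for CT with neural attenuation fields

Metal implants corrupt the X-ray projections that pass through them: beam
hardening and photon starvation make those sinogram entries inconsistent
with the rest of the scan, and filtered backprojection (FBP) turns the
inconsistency into the familiar bright/dark streaks around dental fillings
and prostheses. `nafmar` implements a self-supervised sinogram-inpainting
approach to metal artifact reduction (MAR): instead of learning a prior
from a training corpus, it optimizes a **neural attenuation field** (NAF)
on the reliable rays of the *one* scan at hand and uses the rendered field
as the prior image for normalized sinogram interpolation.

The package is aimed at researchers working on CT reconstruction and
artifact-correction methods who want a complete, CPU-scale, fully
synthetic test bed: it ships the physics substrate (ray-driven projector,
fan-beam FBP and cone-beam FDK), a polychromatic dental-phantom simulator
that manufactures paired clean/corrupted data, the field optimizer, the
inpainting engine, a linear-interpolation (LI) baseline and masked
PSNR/SSIM evaluation.

## The method

A coordinate network `f_θ : (x, y, z) → μ` (multi-resolution hash encoding
followed by a 4-layer, 64-channel ReLU MLP) represents the attenuation
volume. For a detector ray `r(t) = o + t·d` the predicted normalized
intensity follows the discrete Beer–Lambert law

    I_pred(r) / I0 = exp( − Σ_i μ(r(t_i)) · δ_i ),

with `N` uniform samples between the ray's volume entry and exit. Fitting
minimizes squared error between predicted and measured normalized
intensities — but only on **reliable rays**: the metal volume (thresholded
at 2000 HU from the uncorrected FBP, or a known mask) is forward-projected,
and every detector pixel with positive metal path length forms the *metal
trace* `T_metal`, which is excluded from sampling entirely
(`R_r = { r : r ∉ T_metal }`). Rays within `d_th = 20` detector pixels of
the trace form the *metal-aware* set `R_m`; they carry an additional
squared-error term weighted by `ŵ(r) = exp(−λ·d(r)) / max ŵ` (λ = 0.01),
focusing the fit on the region the artifacts degrade most:

    L = L_RECON(θ, R_r) + λ_M · L_MA(θ, R_m),   λ_M = 1.

Batches of 256 rays are drawn without replacement, split between
`R_r \ R_m` and `R_m` in proportion to their sizes, and optimized with
Adam (lr 1e-3, halved every 50 epochs).

The optimized field is rendered on the voxel grid (the *NAF image*),
reduced to a 3-class prior by k-means on intensity — air voxels set to
−1000 HU, soft tissue to 0 HU, bone kept at its rendered values — and
forward-projected. The measured sinogram is divided pixel-wise by the
prior sinogram (floor 1e-7), the trace is bridged by per-row linear
interpolation in this normalized domain, the result is denormalized
(off-trace pixels are copied from the measurements bit-for-bit), FBP
reconstructs the corrected sinogram, and the original metal voxels are
reinserted.

## A worked example

```r
library(nafmar)

geom <- scan_geometry("fanbeam2d", source_to_iso_mm = 300,
                      source_to_detector_mm = 500, n_views = 120,
                      detector_cols = 144, pixel_pitch_mm = 1.5,
                      volume_shape = c(128, 128, 1), voxel_size_mm = 1)
case <- simulate_case(phantom_spec(n_metal = 3, seed = 101), geom, seed = 101)

mar <- mar_correct(case$proj_corrupted, geom,
                   config = naf_config("desk-fast", seed = 101),
                   metal_mask = case$metal_mask)
li  <- li_baseline(case$proj_corrupted, mar$trace, geom,
                   metal_mask = case$metal_mask,
                   uncorrected_hu = case$fbp_uncorrected)

evaluate_mar(case$fbp_uncorrected, case$gt_hu, case$metal_mask)
#> PSNR 17.47 dB, SSIM 0.9486 (window [-1000, 1500] HU, 16355 voxels)
evaluate_mar(li$volume, case$gt_hu, case$metal_mask)
#> PSNR 21.78 dB, SSIM 0.9816 (window [-1000, 1500] HU, 16355 voxels)
evaluate_mar(mar$volume, case$gt_hu, case$metal_mask)
#> PSNR 22.63 dB, SSIM 0.9848 (window [-1000, 1500] HU, 16355 voxels)
```

The three reports read as: the uncorrected FBP of the corrupted scan is
heavily streaked (PSNR ≈ 17 dB against the ground-truth phantom, metal
voxels excluded); plain linear interpolation of the trace removes most of
the streak energy (≈ +4.3 dB); normalizing by the NAF prior before
interpolating recovers a further ≈ 0.9 dB and the highest SSIM, because
the prior carries the anatomy that raw interpolation smears. `mar$volume`
holds the corrected HU volume, `mar$naf_image` the rendered field, and
`mar$corrected_projections` the inpainted sinogram, which equals the
measured one exactly outside the metal trace.

A thin command-line front-end wraps the same functions:

```sh
Rscript exec/nafmar simulate --out sim_out --seed 7 --metals 3
Rscript exec/nafmar run --out run_out --seed 7
Rscript exec/nafmar evaluate --x run_out/nafmar.nii.gz --y run_out/ground_truth.nii.gz
```

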