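# dwdc

Extraction of filament-like cytoskeletal structures — microtubule networks
are the motivating case — from noisy confocal fluorescence z-stacks.

Confocal images of thin filaments are blurred by the system point spread
function and buried in out-of-focus and detector noise; deconvolution alone
amplifies the noise, and wavelet denoising alone does not sharpen. This
package implements a composite restoration pipeline that improves SNR and
apparent structural resolution together, for sparse curvilinear structures:

1. **Gaussian-interpolation grid refinement** of the stack (250 nm → 62.5 nm
   pixel pitch by default), with lateral/axial weight radii
   r⊥ = 0.61 λe/NA and r∥ = 4 n λe/(2 NA²);
2. **discrete-wavelet scale-band extraction** (Coiflet-3, six levels;
   detail levels 4–6 retained, i.e. structures 16–64 px wide on the fine
   grid), discarding the illumination background and pixel-scale noise;
3. **probability-density binarization** — threshold at the value retaining
   the top 15% of the positive scale-band intensities — giving the
   structure outline as a logical matrix;
4. **accelerated, damped Richardson–Lucy deconvolution of the outline**
   (PSF radius Δr = ξ·r⊥, ξ = 2.5, 10 iterations, damping 0.01) followed by
   re-binarization at the fixed threshold 1, which shrinks the outline to a
   skeleton mask;
5. **masking**: the final image is the refined intensity image times the
   skeleton mask — extraction, never re-scaling.

A first-class synthetic phantom module (ground-truth filament bundles plus
a blur/noise degradation model) makes every stage testable without
microscope data, and the metrics module provides PSNR, SSIM and
line-profile FWHM.

## Worked example

```r
library(dwdc)

model <- optical_model(numerical_aperture = 1.4, excitation_wavelength_nm = 640)
model
#> Optical model: NA 1.4  lambda_e 640 nm  n 1.515  xi 2.5
#>   r_lateral  278.8571 nm;  r_axial  989.3878 nm;  delta_r  697.1429 nm

# synthetic ground truth: 8 filament strokes, 63 nm wide, on a 512^2 field
spec  <- phantom_spec(image_size_px = 512, n_filaments = 8, seed = 1)
truth <- generate_ground_truth(spec)

# forward degradation: 270 nm Gaussian blur + N(40, 10) noise, clipped to [0, 255]
degraded <- degrade(truth, degradation_spec(blur_radius_nm = 270,
                                            noise_mean = 40, noise_std = 10,
                                            seed = 1))

# the phantom is already at the fine 63 nm pitch: bypass grid refinement
cfg <- dwdc_config(expansion_xy = 1, expansion_z = 1)
res <- run_dwdc(degraded, cfg)
res$mf
#> Image stack: 512 x 512 pixels, 1 slice(s); pitch 63 nm (xy), 63 nm (z)
#>   intensity range [0, 122.1]
signif(res$chi, 4)      # data-derived outline threshold for this slice
#> [1] 13.63
```

Quality against the known truth, with each compared image exposure-normalized
to peak 255 (the convention of the verification study):

```r
norm <- function(m) m * 255 / max(m)
ti <- truth$data[, , 1]
psnr(ti, norm(degraded$data[, , 1]));  psnr(ti, norm(res$mf$data[, , 1]))
#> [1] 8.66   # degraded
#> [1] 18.44  # restored: ~10 dB gained
ssim(ti, norm(degraded$data[, , 1]));  ssim(ti, norm(res$mf$data[, , 1]))
#> [1] 0.0028 # degraded: noise destroys structural similarity
#> [1] 0.7802 # restored
```

The strong noise floor (mean 40, STD 10) is removed entirely — the restored
background is exactly zero — and the recovered skeleton follows the true
filaments at 1–2 px width. `run_ground_truth_experiment()` repeats this over
the four-condition noise grid ((0,2), (20,4), (40,6), (40,10)) and replicate
seeds, and also measures the before/after FWHM of a line profile through an
isolated filament; `summarize_ground_truth()` collapses it to a per-condition
table. See `vignette("filament-extraction")` for the method account, the
measurement conventions, and the design decisions.

## Command line

A thin CLI over the package functions lives at `inst/cli/dwdc.R`:

```sh
Rscript inst/cli/dwdc.R phantom --size 1024 --noise-mean 40 --noise-std 10 \
    --seed 1 --out-truth truth.tif --out-degraded degraded.tif
Rscript inst/cli/dwdc.R run --input stack.tif --pitch-xy-nm 250 --pitch-z-nm 1000 \
    --expand-xy 4 --expand-z 4 --keep 4:6 --out mf.tif
Rscript inst/cli/dwdc.R metrics --ref truth.tif --test mf.tif
Rscript inst/cli/dwdc.R benchmark --seeds 1,2,3,4,5 --out report.tsv
```

Stacks are exchanged as multi-page 32-bit float TIFF with a key=value
sidecar recording pitch metadata.

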