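# petdec

Validation tooling for **deconvolution (convolution–subtraction) scatter
correction** of 2D-rebinned brain PET sinograms, with a **hybrid
dual-energy-window (HDE)** reference correction, a synthetic-data
simulator with known scatter ground truth, filtered-back-projection
reconstruction, oxygen-15 quantification (CBF, CBV, OEF, CMRO₂), and the
agreement statistics of a method-comparison study.

## Who this is for

3D-mode PET accepts a large fraction of Compton-scattered coincidences,
and for quantitative ¹⁵O brain imaging the scatter correction directly
moves the physiological numbers. Validating a correction on patients is
hard because the scatter-free truth is never observed. `petdec` is for
physicists and methods researchers who want to exercise a simplified,
calculation-based correction against a reference method on data where the
truth *is* known, using the same comparison machinery (slice-difference
profiles, ROI tables, ICC, geometric mean regression) a clinical
validation would use.

## The method

The deconvolution correction (DEC) estimates scatter by convolving each
view's radial × axial sinogram plane with an empirical low-pass kernel
and subtracting it. The kernel is defined in spatial frequency
(cycles/cm):

$$S(\vec f) = \frac{1}{1 + \alpha\, e^{\beta |\vec f|^2}}$$

`alpha` sets the amplitude (DC scatter gain `1/(1+alpha)`), `beta` (cm²)
the breadth of the scatter tails. `(alpha, beta)` are calibrated per
phantom by matching the calculated scatter to the sinogram *tail* (the
bins outside the object's projected support, where only scatter is
measured) and tabulated against object volume — the volume of
transmission-image voxels with μ > 0.06 cm⁻¹ — with linear
interpolation between table rows.

The reference HDE correction recovers the (nearly scatter-free) upper
energy window's trues by a DEC-style correction with a UEW-specific
kernel, scales them to standard-window trues with a measured window
ratio `R`, and subtracts from the standard-window prompts, leaving the
scatter estimate.

The simulator provides two ground-truth modes: `broad_gaussian`
(wide-Gaussian scatter that deliberately violates the kernel family —
realistic model mismatch) and `dec_self_consistent` (prompts solve
`P(f) = T(f)/(1 - S(f))`, so DEC with the generating parameters is exact
to machine precision — the algebraic anchor for every test).

## Worked example

Simulate a brain acquisition with 35% broad-Gaussian scatter, calibrate
the kernel tables on two uniform phantoms, correct with both methods, and
compare:

```r
library(petdec)

geom <- scanner_geometry(n_views = 24, n_radial = 48, radial_bin_cm = 0.55,
                         n_slices = 10, slice_thickness_cm = 1.2,
                         fov_radius_cm = 12.8)
ex <- run_experiment(n_subjects = 10, geometry = geom,
                     scatter_mode = "broad_gaussian",
                     noise = TRUE, counts_per_scan = 2e6, seed = 5)
ex
#> <pet_experiment> 10 subjects, scatter mode broad_gaussian, Poisson noise
#> ICC(2,1), absolute values:  cbf=0.9870  cbv=0.9897  oef=0.9370  cmro2=0.9892
#> ICC(2,1), left-right ratios: cbf=0.7318  cbv=0.8809  oef=0.8251  cmro2=0.8591
#> Total |DEC-HDE|/HDE (%):    cbf=4.29  cbv=2.60  oef=2.64  cmro2=4.23
```

Reading the output: each of the four ¹⁵O parameters is quantified
voxel-wise from both corrections; `ICC(2,1)` is the absolute-agreement
intraclass correlation across 10 subjects × 6 ROIs, and the last line is
the subject-averaged `|DEC − HDE|/HDE × 100%` over all ROIs. Under
realistic mismatch and noise the two corrections agree to a few percent
with ICC ≈ 0.94–0.99 — and the per-ROI CBF table (`ex$diff_tables$cbf`:
frontal 4.2, occipital 3.2, parietal 2.2, temporal 2.6,
centrum_semiovale 6.6, pons_analogue 6.9, Total 4.3%) shows the largest
discrepancies in the white-matter core and the deep midline region,
where relative scatter contamination is highest. In the exact self-consistent, noiseless limit
(`scatter_mode = "dec_self_consistent", noise = FALSE`) every ICC is
1.000 and every difference cell collapses to zero.

Single steps are available as plain functions, e.g.:

```r
ph    <- build_phantom("uniform_cylinder", geom, diameter_cm = 15)
trues <- forward_project(ph$activity, geom, mu = ph$mu)
mask  <- tail_mask(ph$mu, geom, margin_bins = 1)
cfg   <- scatter_config(mode = "dec_self_consistent",
                        params = kernel_params(0.35, 30))
pr    <- compose_prompts(trues, simulate_scatter(trues, ph$mu, cfg),
                         window_config(1, 1), cfg)
fit_kernel_params(pr$sew, mask, mode = "circular")
#> <kernel_fit> alpha = 0.35, beta = 30 cm^2 | objective 3.617e-11 over 4080 tail bins
```

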