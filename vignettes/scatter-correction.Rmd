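---
title: "Validating deconvolution scatter correction for 3D brain PET"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating deconvolution scatter correction for 3D brain PET}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(petdec)
```

## The problem

A 3D-acquisition PET scanner accepts far more Compton-scattered
coincidences than a septa-collimated 2D scanner, so scatter correction is
a first-order accuracy requirement for quantitative work — in particular
for oxygen-15 brain studies, where cerebral blood flow (CBF), cerebral
blood volume (CBV), oxygen extraction fraction (OEF) and the metabolic
rate of oxygen (CMRO~2~) are all computed from absolute tissue activity.
Validating a scatter correction on human data is hard because the
scatter-free ground truth is never observed. `petdec` approaches the
problem the way a physics validation study would, but in silico: a
simulator produces brain-like and phantom sinograms with *known* scatter,
two independent corrections are run on the same data, and the package
quantifies their agreement with the statistics used in method-comparison
studies (slice-wise percent differences, region-of-interest tables,
ICC(2,1), geometric mean regression).

Two corrections are implemented:

* **DEC** (deconvolution, convolution–subtraction): scatter in the
  standard energy window (SEW) is estimated by convolving the measured
  sinogram itself with an empirical scatter kernel and subtracting the
  result.
* **HDE** (hybrid dual-energy window), the reference: the upper energy
  window (UEW) contains relatively little scatter, so its trues are
  recovered by a DEC-style correction with a UEW-specific kernel, scaled
  to SEW trues by a measured window ratio `R`, and subtracted from the
  SEW prompts, leaving the SEW scatter.

## The scatter kernel

The DEC kernel acts per view angle on the radial × axial plane of the
2D-rebinned sinogram, as a low-pass filter in spatial frequency:

$$S(\vec f) = \frac{1}{1 + \alpha\, e^{\beta |\vec f|^2}}$$

`alpha` (dimensionless) sets the amplitude — the DC gain is
$1/(1+\alpha)$, which is the fraction of total counts attributed to
scatter under cyclic convolution — and `beta` (cm²) sets the roll-off,
i.e. how broad the scatter tails are in image space. Frequencies are
physical (cycles/cm), computed from the radial bin width and slice
thickness, so a fitted `(alpha, beta)` transfers across sinogram
samplings and the anisotropy of radial (0.2 cm) versus axial (0.26 cm)
sampling is respected. The frequency magnitude is Euclidean; nothing in
the functional form suggests axis weighting, and with physical units the
choice is at least self-consistent. Convolution is implemented by FFT
with two modes: `zeropad` (the default; each axis padded to at least
twice its length, approximating linear convolution so tails do not wrap
around the FOV edge) and `circular` (cyclic; used where the exact count
identity `sum(out) = dc_gain * sum(in)` matters, e.g. in tests and in the
self-consistent simulation mode described below).

The kernel parameters depend on object size. Following the tabulated
design, `(alpha, beta)` pairs are fitted per calibration phantom, stored
against the phantom's object volume — the volume of transmission-image
voxels with $\mu > 0.06\,\mathrm{cm}^{-1}$ — and looked up for a new
object by independent linear interpolation of `alpha` and `beta`, with
clamping outside the tabulated range.

## The simulator and its two ground-truth modes

`build_phantom()` voxelizes three shapes on the scanner grid: the 15 cm
uniform water cylinder (the well-counter calibration object), a
body-sized ellipse, and a brain made of nested ellipsoids — a
gray-matter shell (activity 4) around a white-matter core (activity 1),
a cold CSF rim, and a thin bony shell with $\mu = 0.151$/cm; soft tissue
gets water attenuation, $\mu = 0.096$/cm. An optional in-plane
`supersample` factor anti-aliases the activity and $\mu$ boundaries;
labels always follow voxel centers so label-based contrasts (the exact
4:1 GM:WM ratio) are preserved at `supersample = 1`.

`forward_project()` is a parallel-beam, slice-by-slice line-integral
projector (bilinear image interpolation at a fixed step along each LOR,
half an in-plane voxel by default). Attenuation multiplies the whole LOR
integral by $e^{-\int \mu\, dl}$, as coincidence physics requires, and
`acf_sinogram()` inverts exactly the same quadrature, so attenuation and
its correction cancel bin-wise in noiseless tests.

Ground-truth scatter comes in two deliberately different flavors:

* `broad_gaussian`: scatter is a wide 2D Gaussian blur (default 8 cm
  radial, 6 cm axial FWHM) of the attenuation-weighted trues,
  renormalized so that scattered/total counts equal the configured
  scatter fraction (default 0.35 in the SEW, 0.10 in the UEW — typical
  3D-brain values, with the narrower window always cleaner). This shape
  does *not* follow the DEC kernel family, so corrections face genuine
  model mismatch, and the hybrid reference is measurably better than DEC
  here — the property that justifies calling it the reference.
* `dec_self_consistent`: prompts solve the convolution model exactly,
  per view, $P(f) = T(f)/(1-S(f))$ under cyclic convolution. DEC with
  the generating `(alpha, beta)` then recovers the trues to machine
  precision, which pins down the algebra of every downstream stage. The
  sharp edge of an analytic phantom makes $p = t/(1-S)$ ring slightly
  negative just outside the support; those side lobes are retained
  (the sinogram is flagged) because clamping them would break the very
  identity this mode exists to provide. With the broad default kernel
  (below) the ringing is O(10^-5^) of the maximum.

Poisson noise is sampled reproducibly from a caller-supplied seed (the
caller's RNG state is saved and restored), with negative self-consistent
ringing clamped to zero mean. An additive axial ramp with configurable
amplitude (default 0) stands in for out-of-FOV background, concentrated
in low slices as a neck source would be.

## Tail-matching calibration

In the sinogram tail — bins whose attenuation line integral is below
`eps_support`, at least `margin_bins` radial bins away from the
projected support — the trues vanish and the measurement is scatter
only. `fit_kernel_params()` exploits this: for candidate
`(alpha, beta)` it computes the calculated scatter as the
self-consistent solution of

$$\hat s = \mathrm{conv}\!\left(p \cdot 1_{\neg\mathrm{tail}} +
  \hat s \cdot 1_{\mathrm{tail}};\ \alpha, \beta\right)$$

(a linear, contractive fixed point solved per view with Aitken
acceleration) and scores it against the measured tail counts. Feeding
the *estimated* rather than the measured tail into the convolution
matters twice over: the construction is exact at the true parameters on
self-consistent data, and it removes a degenerate solution in which a
near-identity kernel (tiny `alpha`, `conv(p) ~ p`) reproduces the
measured tail — Poisson noise included — with near-zero residual. Two
objectives are available: unweighted least squares (the default, fine
for high-count calibration scans) and the Poisson negative
log-likelihood, which weighs the orders-of-magnitude range of tail
expectations correctly; with sparse tails (10^6^-count acquisitions) the
likelihood recovers parameters near the information bound while least
squares does not.

The `(alpha, beta)` landscape is a narrow curved valley — a broader
kernel trades against a larger amplitude — and on some data carries a
second, shallower dip. A plain 2D grid search with one local refinement
reliably lands in the wrong dip; the optimizer therefore profiles
`alpha` out with a bounded 1D scan-plus-golden-section search at each of
a log-spaced series of `beta` nodes, then refines every local minimum of
the resulting profile and keeps the best. The procedure contains no
randomness and is bit-stable.

Study conditions for the calibration experiments: the noiseless
round-trip uses an injected `(0.35, 3.0 cm^2)` kernel; the noisy
recovery experiment (20 Poisson seeds at 10^6^ total counts) uses
`(0.35, 30 cm^2)`, i.e. scatter tails a few centimeters wide, with a
1-bin tail margin and the likelihood objective. The broad kernel is the
physically plausible regime — scatter tails in brain PET extend over
centimeters, which is what makes tail fitting informative; with the
narrow 3 cm² kernel almost no scattered counts survive past the margin
(about 3 × 10³ of 10^6^), and the Fisher information bound alone puts
`alpha` recovery at the several-percent level, so no estimator could
meet a 5% median there. A Cramér–Rao computation supporting this choice
is sketched in the repository notes; the package exposes every one of
these knobs (`margin_bins`, `objective`, bounds, grid density).

## Reconstruction and quantification

`fbp_reconstruct()` multiplies the scatter-corrected sinogram by the
ACF — attenuation correction after scatter correction, matching the
processing order of the scanner pipeline — ramp-filters each view in
frequency space and back-projects per slice. The ramp is the DFT of the
band-limited (Ram–Lak) spatial kernel rather than a plain $|f|$
sampling, which would zero the DC bin and bias the reconstructed mean
(about −4% on a 15 cm cylinder); with the correct ramp the inner-disc
bias of a noiseless cylinder is below 0.1%. A Hann window at the full
Nyquist cutoff apodizes by default; the resolution-dominant filter is
the separate 6 mm FWHM 3D Gaussian post-filter (`gaussian_filter_3d()`,
separable, reflective boundaries with column-normalized kernels so
volume totals are preserved to machine precision). A global
cross-calibration factor (`cross_calibrate()`) reproduces the
well-counter step: reconstruct a known uniform cylinder and scale; for
this projector/FBP pair the factor is 1 within a percent.

Quantification implements the standard ^15^O chain with forward models
and estimators drawn from the same equations, so each estimator is the
exact inverse of its own forward model:

* **CBF** — one-compartment Kety kinetics for freely diffusible water,
  $dC/dt = (f\rho/6000)\,C_a(t) - (f/(6000\,p))\,C$ with $f$ in
  ml/(100 g·min), integrated over the scan to the autoradiographic
  accumulated count $A(f)$; inversion by monotone lookup table with
  linear interpolation (grid 0–150 ml/100 g/min, 1-unit steps;
  out-of-range voxels clamped and flagged).
* **CBV** — intravascular ratio method,
  $CBV = 100\,C_{pet}/(\rho\,R_{sl}\,C_{blood})$.
* **OEF / CMRO~2~** — a simplified oxygen model: extracted O~2~-water
  follows the same one-compartment kinetics scaled by OEF, plus a purely
  intravascular term from CBV; OEF solves the model linearly per voxel
  (clipped to [0, 1.5] with flags) and $CMRO_2 = OEF \cdot f \cdot
  C_aO_2$. Recirculating water of metabolism is deliberately omitted:
  the artifact's purpose is scatter-correction validation, and because
  simulator and estimator share the forward model, round-trip testing
  remains exact. Constants default to standard literature values
  ($p = 0.8$ ml/g, $\rho = 1.04$ g/ml, $R_{sl} = 0.85$,
  $C_aO_2 = 0.19$ ml O~2~/ml) and are configurable. Curves are
  decay-corrected; integration uses an exact exponential-update
  recursion at 0.5 s steps. Arterial input functions are analytic gamma
  variates (delay- and dispersion-free by construction).

## The comparison machinery and the cohort harness

`evalstats` reproduces the comparison procedure of a method-agreement
study: GM/WM masks by strict `> 0.5` probability thresholding;
slice-wise $(A - B)/B \times 100\%$ profiles over a mask (undefined
slices are `NA`, never an error); elliptical (16 × 32 mm) and circular
(16 mm) ROIs placed at voxel centers in 3 adjacent slices, mirrored
across the mid-sagittal plane for bilateral regions, with left-to-right
ratios; ICC(2,1) from two-way mean squares; geometric-mean (reduced
major axis) regression; and patient-averaged
$|A - B|/B \times 100\%$ tables with an unweighted Total row.

`run_experiment()` chains everything: phantom calibration of SEW and UEW
kernel tables and the window ratio, then per synthetic subject three
scans (CO, O~2~, H~2~O) on the brain phantom with physiology jittered
around normal gray/white values (GM CBF 55 ± 5, WM 22 ± 2.5
ml/100 g/min; CBV 4/2 ml/100 g; OEF ≈ 0.4), both corrections,
reconstruction, voxel-wise quantification, and the full statistics. All
subjects share one grid, so no spatial normalization step is needed —
masks and ROIs are defined once by construction, and the synthetic ROI
centers are package choices, not anatomical coordinates. In the
`dec_self_consistent`/noiseless limit both corrections are exact, so
ICCs reach 1 and all difference cells collapse to zero — the harness's
self-validation; under `broad_gaussian` scatter and Poisson noise the
outcome is simulation-dependent and is reported, not asserted.

## Numerical choices and problem sizes

Defaults chosen once and used throughout: ray step = half an in-plane
voxel; support threshold `eps_support` $= 10^{-3}$ on the $\mu$ line
integral; tail margin 2 bins for correction-side masks (1 in the
calibration studies, where the edge bins carry most of the amplitude
information and the broad kernel leaves them ring-free); HDE smoothing
2 cm FWHM (off in exactness tests); fit bounds $\alpha \in [0.01, 10]$,
$\beta \in [0.01, 50]$ cm². Tests and the acceptance script run on
scaled-down geometries (e.g. 48–64 radial bins, 8–24 slices, 16–48
views instead of 128 × 59 × 96) — every identity, invariant and
recovery property checked is resolution-independent, and the compact
grids keep the full suite within minutes; `experiment_geometry()` is
the package's standard compact cohort grid. The cohort harness in the
acceptance script uses 10 subjects, mirroring the size of a typical
retrospective validation series.

## Known limitations

* The scatter kernel is spatially invariant within a plane; real
  scatter varies with position and object, which is exactly the
  simplification whose consequences the DEC-vs-HDE comparison measures.
* The simulator is not a Monte Carlo: broad-Gaussian scatter emulates
  the width and smoothness of true scatter but not its energy- and
  geometry-dependent shape, randoms and dead time are out of scope, and
  detector effects reduce to an optional Gaussian blur. Passing tests
  therefore demonstrate correctness of the algorithms and of the
  comparison machinery under controlled conditions, not clinical
  accuracy on real data.
* The out-of-FOV background model is a one-parameter axial ramp —
  enough to probe robustness, far from a physical thorax model.
* The HDE combination implemented here (DEC-corrected UEW scaled by a
  global trues ratio, optional smoothing) is a minimal reconstruction of
  the hybrid idea; per-LOR or per-slice scaling would be extensions.
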