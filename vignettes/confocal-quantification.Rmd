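---
title: "Quantifying colocalization, synaptic boutons and fluorescence dynamics in confocal stacks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying colocalization, synaptic boutons and fluorescence dynamics in confocal stacks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cdaq)
```

## Scope

`cdaq` quantifies three things in two-channel confocal imaging of
presynaptic structures, plus the statistics used to compare experimental
groups:

1. **Effective colocalization** of two fluorescent signals inside a
   confined region (e.g. photoreceptor-axon cartridges in the fly
   lamina), via the confined displacement algorithm (CDA);
2. **Synaptic bouton counts** from z-projected stacks after activity
   dependent dye labeling (FM4-64), via gradient segmentation and a size
   filter in physical units;
3. **ROI fluorescence dynamics**: baseline-normalized responses of
   Ca²⁺ indicators (ΔF/F₀), dye-unloading decay, and correction against a
   photobleaching control.

Because this class of experiment rarely ships raw image data, the package
pairs every analysis stage with a seeded synthetic generator whose ground
truth is known exactly. All validation claims in this vignette are claims
the test suite and `scripts/acceptance.R` actually compute.

## Colocalization: Manders M1 and the confined displacement null

For a channel-1 intensity image $I_1$, segmented signal masks $S_1, S_2$
and a confinement mask $C$ (all $S_i \subseteq C$), the intensity-weighted
Manders coefficient restricted to the confinement is

$$
M_1 = \frac{\sum_{x \in S_1 \cap S_2 \cap C} I_1(x)}
           {\sum_{x \in S_1 \cap C} I_1(x)} \in [0, 1].
$$

Dense punctate signals overlap substantially by chance, so $M_1$ alone
overstates association. The CDA estimates that chance level by rigidly
shifting channel 1 (intensity and mask together) by every integer
displacement $d = (d_y, d_x)$ with $0 < \lVert d \rVert \le r_{\max}$
(default $r_{\max} = 20$ px) for which at least a fraction $\rho$ (default
0.9) of the displaced mask stays inside the confinement — pixels leaving
the frame or the confinement are dropped. Each valid displacement yields a
null coefficient $M_1(d)$; the null mean is the random-colocalization
estimate and

$$
M_1^{\mathrm{eff}} = M_1(d{=}0) - \overline{M_1(d)},
\qquad
\text{Eff-Colocalization}(\%) = 100 \, M_1^{\mathrm{eff}}.
$$

`cda_effective_colocalization()` returns these together with the full null
distribution and an add-one-corrected empirical exceedance p-value
$(1 + \#\{M_1(d) \ge M_1(0)\}) / (1 + n)$, so the mean-subtraction
convention and the significance use of the null can both be audited.
Whether the original algorithm family averaged the null or integrated a
probability distribution over displacements is a convention choice;
emitting the whole null makes either reading checkable.

Design choices worth knowing:

- **Displacements are integer-valued, x/y only, no interpolation.**
  Sub-pixel shifts would interpolate intensity and blur the null.
- **Retention threshold.** Dropping displaced pixels outside the
  confinement shrinks the numerator and denominator together; without a
  retention floor the null would be dominated by displacements that leave
  almost no mask behind. 0.9 keeps the null comparable to the original
  mask; it is configurable, and the enumeration errors out when no
  displacement qualifies rather than silently returning an empty null.
- **Intensity weighting** is the default (the coefficient's original
  definition); `weighted = FALSE` gives pure binary overlap.
- **Segmentation for CDA.** When only raw stacks are available,
  `segment_coloc_channels()` max-projects each channel and applies an
  Otsu threshold computed over confinement pixels only. Any external
  segmentation can be supplied instead through `coloc_input()`.

The implementation shifts sparse mask pixels in compiled code with exact
integer arithmetic; on small instances it agrees with a naive
enumerate-and-shift oracle to numerical identity (the test tolerance,
1e-12, is far above the observed ~1e-16 error). An FFT cross-correlation
formulation was deliberately rejected because its rounding error would sit
near that tolerance.

## Bouton segmentation and counting

The counting pipeline mirrors a standard unbiased bouton quantification:

1. maximum-intensity projection of `n_slices = 10` optical sections
   (Δz = 0.3 µm) — projection method configurable (`mean`, `sum`);
2. optional Gaussian pre-smoothing (σ = 1 px);
3. Sobel gradient magnitude (replicate-edge padding, so borders and
   constant regions respond zero);
4. Otsu threshold on the gradient image (the package's own 256-bin
   exhaustive between-class-variance scan, ties to the lowest threshold,
   threshold recorded on the image's intensity scale);
5. 3×3 morphological closing and hole filling;
6. connected-component labeling (8-connectivity by default; labels in
   deterministic raster order);
7. **half-amplitude (FWHM) refinement**: each filled component is
   re-thresholded at `background + (peak − background)/2`, with the
   background the median outside the mask and the peak the 0.95 quantile
   of the raw projection inside the component;
8. size filter keeping objects with area in **[0.5, 1.1] µm²** (bounds
   inclusive; the window is stated without openness in the source
   convention, and inclusivity is the permissive reading), then
   per-object quantification (area, intensity-weighted centroid, mean
   intensity) and an area histogram.

Step 7 is the one genuinely open design point. A filled gradient ring
overestimates an object by roughly one rim width, which would bias every
area against a fixed physical window; the half-maximum area is the
standard, well-defined object size for resolved structures and makes the
measured area agree exactly with the generator's ground-truth definition
on noise-free fields. The 0.95 peak quantile (rather than the maximum) is
robust to single-pixel noise maxima while still evaluating to the exact
plateau value on clean plateaued objects. Whether the original "gradient
filter" was edge detection or a background-flattening high-pass is not
derivable from the source; the gradient-magnitude reading is implemented,
every threshold and option is recorded in the result's `settings` (and in
a JSON sidecar when run through `run_pipeline()`), and a manual threshold
mode is available.

The default calibration, 0.07 µm/px, maps a ~36 µm quantification field
onto 512 px, which keeps the 0.5–1.1 µm² window meaningful in pixels
(102–225 px at 0.0049 µm²/px). Counts are reported per projected field;
the experimental unit for the statistics layer is one field per animal.

## Fluorescence dynamics

Traces are per-ROI means over time (`roi_mean_timeseries()`), normalized
by a baseline-window mean (`normalize_trace()`, idempotent), optionally
divided pointwise by a normalized photobleaching control measured in a
light-insensitive region (`bleach_correct()`; a trace decaying identically
to the control becomes constant 1), and summarized by:

- `delta_f()`: ΔF/F₀ = (mean post − mean pre)/mean pre. The evoked "mean
  increase" is interpreted as baseline-normalized by default, since the
  source convention plots normalized fluorescence; a raw-difference mode
  exists. Default windows: everything before the event, and 10 samples
  from the event on — the post-event span is not derivable from the
  source, and 10 samples at 1 Hz brackets the sustained phase of a step
  response without diluting it.
- `unloading_decay()`: $1 - F(t_m)/F(t_e^-)$ with nearest-sample lookup
  (no interpolation — sub-frame kinetics are not invented).

## The synthetic generator

The generator emulates the statistical structure of the study's data,
not its optics:

- **Confinement**: parallel elongated bands (cartridge-like), placed by
  sampling a uniform composition of the free columns, so placement always
  succeeds when the layout is feasible and fails loudly otherwise.
- **Colocalization scenes**: isotropic 2-D Gaussian puncta (σ = 2 px,
  evaluated on a 4σ support patch) at uniform positions inside the
  confinement; a controlled fraction of channel-1 puncta sits within
  1 px jitter of a channel-2 punctum (perfect coincidence would make the
  CDA's job unrealistically easy). Amplitudes uniform in 120–220 over a
  background of 20, Poisson noise on the clean signal plus Gaussian read
  noise (σ = 3), clipped at zero — the standard confocal approximation.
  At these levels SNR ≈ 10.
- **Bouton fields**: plateaued discs with a raised-cosine rim (half-width
  1.5 px) rather than Gaussians: boutons are resolved extended objects of
  0.5–1.1 µm², and a plateau makes the half-amplitude area well defined
  for generator and pipeline alike, whereas a Gaussian's FWHM area hinges
  on estimating a one-pixel apex. Target areas are drawn from the window
  shrunk by 5% of its width per side so discretized areas stay strictly
  inside it; placement is on a jittered grid that guarantees the minimum
  separation; per-object z-envelopes peak at exactly 1 so
  maximum-intensity projection preserves amplitudes.
- **Time courses**: baseline × exp(−bleach·t) × response, with the
  response a sustained step (1 + ΔF/F₀), an exponential unloading, or
  their product; additive Gaussian noise specified as a fraction of
  baseline. The default step amplitude (0.68) and the tested set
  (0.1, 0.38, 0.68) mirror the scale of the reported indicator responses;
  they are scale references for simulation, not reproducible targets.

Everything is bit-reproducible from the spec seed, and with all noise
disabled every voxel is an exact evaluation of the stated analytic model
(tested to machine precision). What the generator does **not** emulate:
realistic point-spread functions, depth-dependent attenuation, motion,
staining chemistry, or spatially correlated background. Passing tests on
this generator therefore demonstrate the correctness and calibration of
the computations, not robustness to every artifact of real microscopy.

## Statistics layer

`group_summary()` reports mean ± SEM (sample s.d., n − 1). One- and
two-way fixed-effects ANOVA use the standard machinery (balanced two-way
designs via textbook sums of squares; unbalanced via type II
model-comparison sums of squares, flagged in the output — the source
convention does not state its handling). Post-tests at α = 0.05:

- **Dunnett** many-to-one: statistics on the pooled within-group mean
  square; family-wise adjusted p-values from a seeded Monte-Carlo
  simulation of the max-|t| null with the design's exact correlation
  structure (group means and a shared pooled variance simulated
  directly). This handles arbitrary unbalanced designs without critical
  value tables, is reproducible given a seed, and with one treatment
  group collapses to the ordinary two-sided t test (verified within
  Monte-Carlo error; 200,000 draws give p-value noise ≈ 5·10⁻⁴ near
  p = 0.05).
- **Bonferroni** pairwise: pooled-t tests with `min(1, m·p)`.

All tests are two-sided; under a simulated 3-group null the one-way ANOVA
rejects at 5.2% over 10,000 runs (the acceptance script recomputes this).

## Numerical conventions and edge cases

- Coordinates are 1-based `(row, col) = (y, x)`; areas always in µm² from
  the calibration. Area-histogram bins are left-closed, right-open,
  starting at 0.
- Otsu on a constant image, ANOVA on zero-variance data, displacement
  sets that come up empty, empty ROIs, zero baselines and mismatched time
  grids all raise informative errors rather than returning NaN.
- Stacks are written as 32-bit TIFF with a power-of-two intensity scale
  in a JSON sidecar; integer-valued stacks (photon counts) round-trip
  bit-exactly, general reals to one part in 2³².
- Pipeline runs (`run_pipeline()`) write their resolved configuration and
  a manifest with output checksums and no timestamps; reruns under the
  same seed and configuration are byte-identical.

## Problem sizes used in validation

The shipped validation uses: 60–200 random small instances for the CDA
brute-force equivalence; 20 seeds per colocalized fraction at 512×512 px
and displacement radius 20 for null calibration and monotone recovery;
bouton fields of 10–200 objects (clean) and 10 noisy seeds of 50 objects;
100 seeds per ΔF/F₀ amplitude; 10,000 simulations for the type-I error
rate; and 2·10⁵–4·10⁵ Monte-Carlo draws for Dunnett p-values. These sizes
give comfortable statistical resolution for every tolerance tested while
keeping a full validation run in the low minutes on one CPU.

## Known limitations

- CDA displacements are 2-D; axial (z) randomization is out of scope.
- No deconvolution and no 3-D volumetric bouton segmentation; counting
  operates on projections, so axially overlapping boutons merge.
- No kinetic model fitting (τ is checked against closed forms, not
  estimated), no motion correction, no ratiometric arithmetic.
- The Dunnett adjustment is Monte-Carlo: p-values carry simulation noise
  of order `sqrt(p(1-p)/n_mc)`; increase `n_mc` where decisions sit on
  the α boundary.
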