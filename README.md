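# cdaq — confined-displacement colocalization and synaptic bouton quantification

`cdaq` is an R package for quantifying two-channel confocal imaging of
presynaptic structures — the kind of data produced when studying
activity-dependent vesicle release and protein localization in axonal
neuropiles (e.g. the *Drosophila* lamina). It is aimed at imaging labs
that need auditable, reproducible versions of three everyday
computations, plus the statistics used to compare genotypes or
treatments:

1. **Effective colocalization (CDA).** The Manders coefficient of
   channel 1 over channel 2 inside a confined region *C* (segmented
   axon cartridges),

   M1 = Σ I₁ over (S₁ ∩ S₂ ∩ C) / Σ I₁ over (S₁ ∩ C),

   corrected for chance overlap with the confined displacement
   algorithm: channel 1 and its mask are rigidly shifted by every
   integer displacement with radius ≤ 20 px that keeps ≥ 90 % of the
   mask inside *C*; the mean of the resulting null M1 values is the
   random-colocalization estimate, and

   Eff-Colocalization (%) = 100 × (M1(d = 0) − M1(random)).

2. **Bouton counting.** Maximum-intensity projection of 10 optical
   sections (Δz = 0.3 µm), Sobel gradient magnitude, Otsu threshold,
   closing + hole fill, connected components, half-amplitude (FWHM) area
   refinement, and a size filter keeping objects of 0.5–1.1 µm².

3. **Fluorescence dynamics.** Per-ROI traces, baseline normalization,
   photobleaching-control correction, ΔF/F₀ of evoked responses, and
   dye-unloading decay fractions.

4. **Statistics.** Mean ± SEM, one-/two-way ANOVA, Monte-Carlo Dunnett
   many-to-one and Bonferroni pairwise post-tests at α = 0.05.

Because raw confocal data of this kind is rarely deposited, the package
includes a seeded synthetic generator (punctate two-channel scenes inside
cartridge-like confinement bands, bouton fields with calibrated areas,
fluorescence time courses with step/unloading/bleaching components under
Poisson–Gaussian noise) whose exact ground truth drives the entire test
suite. See the methods vignette
(`vignettes/confocal-quantification.Rmd`) for the model details and
design decisions.

## Worked example

```r
library(cdaq)

## --- effective colocalization on a synthetic scene (truth: 50 % of
##     channel-1 puncta colocalized) ---------------------------------
scene <- generate_coloc_scene(coloc_scene_spec(
  shape = c(1, 512, 512), n_puncta_ch1 = 80, n_puncta_ch2 = 80,
  coloc_fraction = 0.5,
  confinement_params = list(n_regions = 4, region_width_px = 60),
  seed = 7))
inp <- segment_coloc_channels(scene$ch1, scene$ch2, scene$confinement)
cda_effective_colocalization(inp, max_radius = 20)
#> <cda_result> M1(d=0) = 0.4456, M1(random) = 0.0557 over 480 displacements
#>   effective colocalization = 0.3899 (39.0%), p_null = 0.002079
```

About 45 % of channel-1 intensity sits on channel-2 signal, but shifting
channel 1 inside the cartridges shows ~6 % would overlap by chance; the
difference (39 percentage points, null exceedance p ≈ 0.002) is the
colocalization beyond random.

```r
## --- bouton counting on a synthetic field (truth: 50 boutons) ------
field <- generate_bouton_field(bouton_field_spec(n_boutons = 50, seed = 7))
seg <- segment_boutons(field$stack)
seg$count
#> [1] 50
head(seg$table, 3)
#>   label area_um2 centroid_y centroid_x mean_intensity
#> 1     1   1.0290   25.08397   283.0614       191.7381
#> 2     2   0.6860   23.26103   441.3031       152.7214
#> 3     3   0.6517   26.19895   154.3250       217.0075

## --- evoked dF/F0 (truth: step of 0.68, 5 % noise) -----------------
sim <- generate_timeseries(timeseries_spec(step_amplitude = 0.68,
                                           noise_sd = 0.05, seed = 7))
delta_f(sim$traces[[1]])
#> <delta_f_result> roi 1: f_pre = 102, f_post = 167.5, delta (ratio) = 0.6423

## --- group comparison of bouton counts (one field per animal) ------
counts <- c(201, 188, 224, 196, 35, 42, 28, 31, 118, 105, 131, 122)
geno   <- rep(c("wt", "mutant", "blocked"), each = 4)
group_summary(counts, geno)
#>     group n   mean      sem
#> 1 blocked 4 119.00 5.400617
#> 2  mutant 4  34.00 3.027650
#> 3      wt 4 202.25 7.728465
one_way_anova(counts, geno)
#> <anova_result> F(2, 9) = 216.5, p = 2.452e-08
dunnett_posthoc(counts, geno, control = "wt", seed = 1)
#>     comparison estimate statistic adjusted_p significant
#> 1 blocked - wt   -83.25 -10.29623      1e-05        TRUE
#> 2  mutant - wt  -168.25 -20.80890      0e+00        TRUE
```

Both reductions relative to the wild-type control are significant after
family-wise (Dunnett) adjustment.

The `analysis/` directory holds numbered driver scripts
(`01_simulate.R` … `05_stats.R`) that run these stages over generated
data and write their tables under `results/`.

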