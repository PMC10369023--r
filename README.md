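# distsig

Distance-dependent **detectability** and **boldness** of animal colour
patterns under receptor-noise-limited (RNL) vision.

Aposematic animals advertise chemical defences with conspicuous patterns,
but "conspicuous" conflates two different perceptual properties: how much
an animal's edge statistics stand out from its background (*detectability*,
the inverse of background matching) and how internally contrasty its own
pattern is once detected (*boldness*). Both depend on viewing distance: an
observer with finite spatial acuity (e.g. a triggerfish at ~3 cycles per
degree) loses fine pattern detail as distance grows, so a pattern can be
bold at 2 cm and camouflaged at 30 cm. `distsig` is for visual ecologists
who want to quantify that distance dependence from calibrated cone-catch
imagery — or to study the behaviour of the metrics themselves on fully
controlled synthetic scenes.

## What it computes

Starting from a linear cone-catch stack (one channel per receptor class
plus luminance) with a pixels-per-cm calibration, for each viewing distance
in a grid (default 2, 5, 10, 30 cm):

1. **Gaussian acuity modelling** — isotropic blur with
   σ = d·θ·ppcm / k, where θ = (1/acuity)·π/180 is the angle of one
   resolvable cycle;
2. **RNL ranked filtering** — edge-preserving smoothing that replaces each
   pixel by the mean of its perceptually nearest kernel neighbours, ranked
   by ΔS = √(ΔS²_chrom + ΔS²_achrom);
3. **LEIA** (local edge intensity analysis) — per-location chromatic and
   achromatic edge contrast (ΔS, in just-noticeable differences) over
   horizontal, vertical and diagonal axes, within an animal mask and a
   background annulus;
4. the two statistics, per channel type:
   * boldness = abundance-weighted CoV of the animal's local edge contrast
     (`Lum.CoV`, `Col.CoV`),
   * detectability = |CoV_animal − CoV_background|;
5. downstream statistics: Kruskal–Wallis + Dunn/Bonferroni species
   comparisons, random-intercept mixed models (Satterthwaite df) of
   defence class × distance, and per-distance Pearson correlations between
   species-median statistics and an unpalatability score u = normalized
   1 − ED₅₀, with an OLS regression of R on distance.

Chromatic ΔS uses the log-linear n-receptor RNL model
(ΔS² = Δfᵀ A Δf on log catches, equivalent to the classical pairwise
formula); achromatic ΔS = |ln(l_a/l_b)|/ω.

A synthetic-scene generator (`scene_spec()`/`generate_scene()`,
`cohort_spec()`/`generate_cohort()`) produces cone-catch scenes with exact,
analytically inverted ΔS phase contrasts, two-scale blob textures, and a
13-species cohort design whose pattern parameters couple monotonically to
unpalatability — the harness on which every pipeline stage is tested.

## Worked example

```r
library(distsig)

obs <- observer()   # triggerfish-like: e = (.05,.05,.05), w = .05, 3 cpd
achromatic_delta_s(2, 1, obs)
#> [1] 13.86294     # a 2:1 luminance step is ~14 jnd

# a defended-looking animal: sparse (15% coverage), fine (3 px),
# high-contrast markings on a textured background
scene <- generate_scene(scene_spec(seed = 1,
  animal = list(element_size_px = 3, phase_fraction = 0.15,
                achromatic_contrast = 8, chromatic_contrast = 5)))

distance_profile(scene$image, scene$masks, obs,
                 individual_id = "demo", species = "sp01")
#>   distance_cm lum_boldness col_boldness lum_detectability col_detectability
#> 1           2        1.433        1.420             0.443             0.508
#> 2           5        1.356        1.338             0.380             0.426
#> 3          10        1.132        1.133             0.177             0.216
#> 4          30        0.503        0.486             0.138             0.165
```

Read: at 2 cm the sparse bold pattern gives a high within-animal edge CoV
(boldness ≈ 1.4) and a clear mismatch with the background (detectability
≈ 0.4–0.5 CoV units). As viewing distance grows the acuity blur removes
the fine markings; by 30 cm detectability has fallen ~3-fold towards
background matching while boldness decays more slowly — the
distance-dependent signalling structure the cohort-level statistics test
for.

Cohort-level analysis:

```r
cohort  <- generate_cohort(cohort_spec(individuals_per_species = 8, seed = 1))
records <- process_cohort(cohort)             # one row per individual x distance
res     <- distance_correlation_regression(records)
res$regressions[, c("metric", "slope", "r_squared", "p_value")]
```

gives the per-metric slope of the unpalatability correlation R against
distance (negative and steepest for detectability on the default effect
cohort). `run_stats()` adds the Kruskal–Wallis/Dunn and mixed-model
tables; `run_pipeline(config, out_dir)` orchestrates everything from a
YAML/JSON config (see `inst/extdata/example_config.yaml`) and writes tidy
CSVs plus a JSON run log.

A command-line front end with `simulate` / `process` / `stats` / `run`
subcommands is in `inst/cli/distsig.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/distsig.R", package = "distsig"))')" \
  run --config inst/extdata/example_config.yaml --out results/demo
```

## Documentation

Function-level documentation is in the roxygen comments under `R/`; the
methods vignette (`vignettes/distance-dependent-signals.Rmd`) explains the
perceptual model, every tunable parameter with units and defaults, what
the synthetic generator does and does not emulate, and the package's
numerical conventions.
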