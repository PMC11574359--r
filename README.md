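# lipotrack

Single-particle hydrodynamic sizing of liposomes, with two membrane-biology
assays built on top: **curvature-preference classification** for
lipid-binding proteins and a **vesiculation dose-response** readout for
membrane-remodelling domains.

## The problem and the method

Nanoparticle-tracking instruments film sub-micron particles diffusing in
solution, track each particle for a few dozen frames, and size it from its
Brownian motion. For a particle tracked in 2D, the mean squared displacement
over one frame interval is

```
MSD(Δt) = 4 D Δt
```

so the per-track diffusion coefficient is estimated as
`D̂ = MSD(1 frame) / (4 Δt)` (lag-1 estimator), and the Stokes–Einstein
relation converts it to a hydrodynamic diameter

```
d = k_B T / (3 π η D)
```

with `k_B` the Boltzmann constant, `T` the temperature and `η` the medium
viscosity (defaults: water at 25 °C). Diameters are binned in 5-nm
half-open intervals `[5k, 5(k+1))` into a concentration distribution
(particles/ml per bin), the representation all downstream analysis works on.

Two channels are measured: **diffraction** (every particle, but small
liposomes diffract weakly and a "hidden fraction" goes undetected) and
**fluorescence** (only labelled particles, detected independently of size).
This asymmetry enables two assays:

* **Curvature preference** — incubate non-fluorescent liposomes of mixed
  sizes with a fluorescent protein; compare the size distribution of the
  protein-bound (fluorescent) subpopulation with the total population.
  Distributions are summarised by their mode and mode-centred boundaries
  enclosing 50% of the concentration mass on each side; replicate modes are
  compared by one-way ANOVA with Bonferroni correction, and the bound
  population is classified as preferring `smaller`, `larger`, or `none`.
* **Vesiculation** — membrane-inserting domains fragment liposomes into
  smaller vesicles. This appears as a dose-dependent drop in mean size, a
  rise in particle concentration, and growth of the bin centred at 82.5 nm,
  which serves as the vesiculation-efficiency metric.

A bin-wise correction factor `CF = (Fluo − Diff) / Diff`, estimated from a
fully fluorescent calibration sample, repairs the hidden fraction in
diffraction measurements of small-liposome preparations
(`compute_cf()` / `apply_cf()`, opt-in).

Because the package ships a seeded physics simulator (extruded lognormal
populations, curvature-dependent labelling, size-dependent diffraction
detectability, Brownian 2D tracks, area-conserving vesiculation), the whole
pipeline runs and is tested end-to-end without an instrument.

## Worked example

```r
library(lipotrack)

# a fluorescent protein with a strong preference for small (highly curved)
# liposomes, assayed on an 800-nm-extruded polydisperse population
pop <- population_spec(220, 1.4, extrusion_cutoff = 800)
res <- curvature_assay(pop, binding_model("high_curvature", midpoint = 150),
                       seed = 42)
tidy(res)
#> # A tibble: 1 × 7
#>   n_replicates total_mode bound_mode shift_nm   p_adj significance class
#>          <dbl>      <dbl>      <dbl>    <dbl>   <dbl> <chr>        <chr>
#> 1            3       186.       131.      -55 0.00430 **           smaller
```

Three simulated replicates put the total-population mode at ~186 nm and the
protein-bound mode at ~131 nm; the −55 nm shift is significant at the 0.05
level after correction, so the protein is classified as preferring smaller
liposomes.

```r
# dose-response of an efficient vesiculator on fluorescent liposomes
ves <- vesiculation_assay(population_spec(140, 1.35, extrusion_cutoff = 400),
                          vesiculation_model(max_fraction = 0.8),
                          n_particles = 1000, seed = 42)
tidy(ves)
#> # A tibble: 5 × 4
#>    dose   metric mean_size total_concentration
#>   <dbl>    <dbl>     <dbl>               <dbl>
#> 1   0    2000000     147.             79800000
#> 2   0.5  6800000     105.            140700000
#> 3   1   12300000      87.3           210400000
#> 4   2   15000000      79.7           257800000
#> 5   4   18000000      75.6           297100000
```

With rising dose the 82.5-nm marker bin grows 9-fold, mean liposome size
falls from 147 to 76 nm and total particle concentration almost quadruples —
the joint signature of vesiculation. `autoplot()` draws the distribution,
box-plot and dose-response displays for each result type.

## Command line

A thin wrapper (`inst/cli/lipotrack.R`) exposes the pipeline as
subcommands, all driven by one YAML config and one master seed:

```sh
Rscript inst/cli/lipotrack.R simulate  --config run.yaml --out-dir out   # tracks + truth CSVs
Rscript inst/cli/lipotrack.R size      --tracks out/tracks.csv --out-dir out
Rscript inst/cli/lipotrack.R dist      --diff out/distribution_diffraction.csv \
                                       --fluo out/distribution_fluorescence.csv --apply-cf
Rscript inst/cli/lipotrack.R curvature --config run.yaml --out-dir out
Rscript inst/cli/lipotrack.R vesiculation --config run.yaml --out-dir out
Rscript inst/cli/lipotrack.R stats     --modes modes.csv --out-dir out
```

Every output embeds the config hash and seed; identical config + seed gives
byte-identical files.

## Package tour

| Area | Functions |
| --- | --- |
| Physics | `stokes_einstein_diameter()`, `diameter_to_diffusion()`, `lag1_diffusion()`, `estimate_diffusion()`, `drift_correct()`, `size_tracks()` |
| Simulator | `population_spec()`, `sample_population()`, `binding_model()`, `label_by_binding()`, `detection_model()`, `apply_detection()`, `simulate_tracks()`, `vesiculate()`, `simulate_experiment()` |
| Distributions | `bin_sizes()`, `smooth_distribution()`, `compute_cf()`, `apply_cf()`, `regrid_cf()`, `box_stats()`, `mean_size()`, `total_concentration()`, `bin_concentration_at()` |
| Assays | `anova_oneway()`, `pairwise_bonferroni()`, `classify_preference()`, `curvature_preference()`, `curvature_assay()`, `vesiculation_dose_response()`, `vesiculation_assay()`, `compare_efficiency()` |
| I/O + CLI | `read_tracks()`, `write_tracks()`, `read_distribution()`, `write_distribution()`, `read_run_config()`, `lipo_cli()` |

The methods vignette (`vignettes/liposome-sizing.Rmd`) documents the model
assumptions, parameter choices and known limitations.
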