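---
title: "Hydrodynamic liposome sizing and curvature assays: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hydrodynamic liposome sizing and curvature assays: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lipotrack)
```

This vignette is the package's account of the science it implements: the
sizing model and its assumptions, what the simulator does and does not
emulate, the parameters that matter, and the choices made where the design
was genuinely open.

## 1. Sizing from Brownian motion

A sphere of hydrodynamic diameter $d$ suspended in a medium of viscosity
$\eta$ at temperature $T$ diffuses with coefficient

$$D = \frac{k_B T}{3 \pi \eta d},$$

the diameter form of the Stokes–Einstein relation ($r = k_B T / 6\pi\eta D$
in radius form). `lipotrack` treats the *diameter* as the canonical public
unit because size distributions, filter pore sizes and calibration-bead
specifications are all quoted as diameters; the radius appears only inside
the formula. $k_B = 1.380649\times10^{-23}$ J/K (SI exact). The default
medium is water at 25 °C ($T = 298.15$ K, $\eta = 0.89$ mPa·s); both values
are configurable, and no temperature–viscosity model is applied — the
caller states the medium they used.

For a particle tracked in 2D at frame interval $\Delta t$, pure Brownian
motion gives $\mathrm{MSD}(\tau) = 4D\tau$. The per-track estimator is the
**lag-1 MSD**:

$$\hat D = \frac{\overline{(\Delta x)^2 + (\Delta y)^2}}{4 \Delta t}.$$

*Why lag 1 and not a multi-lag MSD fit:* for pure Brownian motion without
localisation noise, the lag-1 estimator is unbiased and uses every
displacement exactly once; multi-lag fits must weight correlated MSD points
and buy variance reduction only when a noise floor or drift must be
separated out. Localisation noise is out of scope here (no noise model is
part of the pipeline), which removes the main reason to prefer multi-lag
fitting. With $n$ steps the relative standard error of $\hat D$ is
$\approx\sqrt{2/n}$ — 14% at 100 steps — which the test-suite properties
(unbiasedness within 2% over 1000 tracks; $1/\sqrt{n}$ spread scaling)
verify directly.

Tracks shorter than `min_steps` displacement steps are discarded before
sizing (default 10). Commercial tracking software applies a proprietary,
unpublished track-length filter; 10 steps is our stand-in, chosen as the
point where single-track relative error (~45%) is still usable inside a
population histogram while discarding the shortest, essentially
uninformative tracks. No finite-track-length deconvolution is applied: the
package analyses raw per-track sizes throughout, so distributions carry the
full track-length broadening visibly rather than through an opaque
correction.

Drift correction (`drift_correct()`) subtracts the per-frame ensemble-mean
displacement, cancelling any flow shared by all particles while leaving
each particle's Brownian component intact (the subtraction of the ensemble
Brownian mean is $O(1/\sqrt{N_\text{tracks}})$). It is **off by default**:
instruments handle pump flow in their own software, and blind correction of
an already-corrected recording would add noise.

## 2. What the simulator emulates

The simulator exists so every downstream stage can be exercised and tested
against known ground truth. Its stages, and the real features they stand
for:

* **Extruded populations** (`population_spec()`, `sample_population()`):
  lognormal mixture with a hard upper truncation at the filter pore size,
  implemented by rejection resampling. Extrusion imposes an upper size
  limit while passing a broad range of smaller vesicles; a hard cutoff on a
  lognormal is the simplest shape with exactly those two properties. The
  reference scenarios used in the tests are median 220 nm, geometric SD
  1.4, cutoff 800 nm (an 800-nm-extruded preparation) and median 140 nm,
  GSD 1.35, cutoff 400 nm (the fluorescent preparation used for
  vesiculation runs).
* **Curvature-dependent binding** (`binding_model()`): a Bernoulli label
  per liposome with probability logistic in log-diameter, decreasing
  (high-curvature preference), constant (insensitive) or increasing
  (low-curvature preference) between `baseline_prob` and `max_prob` with
  inflection at `midpoint` (nm). A logistic in diameter rather than in
  curvature $1/d$ keeps the midpoint interpretable on the same axis as the
  distributions. Protein concentration is not modelled kinetically:
  the assay operates at a fixed nanomolar concentration, and `max_prob` is
  its proxy. The default steepness (10) encodes a *near-exclusive*
  preference — the regime the assay's reference behaviours exhibit (strong
  binders found almost only on their preferred sizes). Gentler binders are
  modelled by lowering steepness or raising `baseline_prob`; the package's
  property tests show the bound-vs-total mode gap erodes continuously as
  `baseline_prob` rises toward `max_prob`, the simulator's analogue of
  curvature specificity drowning in indiscriminate electrostatic binding
  as membrane charge increases.
* **Detection** (`detection_model()`): the diffraction channel sees a
  particle with probability logistic in log-diameter (Rayleigh scattering
  intensity scales as $d^6$, so log-domain steepness is natural; defaults:
  midpoint 90 nm, steepness 6), producing the *hidden fraction* of small
  liposomes; the fluorescence channel sees labelled particles with a
  size-independent probability (default 0.95). No published
  detection-efficiency-versus-size curve exists for the instrument; these
  are stand-ins, exposed in the config, chosen so that a 50-nm-extruded
  preparation shows a clearly visible hidden fraction while particles above
  ~150 nm are essentially always detected.
* **Tracks** (`simulate_tracks()`): per-axis i.i.d. Gaussian steps of
  variance $2D\Delta t$ at 25 fps. Track lengths are geometric with mean 50
  frames, capped at the movie length (120 s): a constant per-frame hazard
  of leaving the illuminated volume is the simplest exit model and produces
  the realistic preponderance of short tracks. The default observed volume
  ($10^{-5}$ ml) places a 3000–8000-particle run at a few $10^8$
  particles/ml, the instrument's working range, and the default particle
  count per simulated run (6000) puts the number of *measured* particles in
  that same 3000–8000 window.
* **Vesiculation** (`vesiculate()`): each liposome is processed with a
  Hill-curve probability of the dose
  ($p = p_\max \cdot \text{dose}^h/(\text{dose}^h + \text{dose}_{50}^h)$),
  and a processed parent is replaced by daughters drawn lognormal (default
  median 70 nm, GSD 1.25) until its membrane area is used up. Conservation
  of $\sum d^2$ is enforced *exactly*: the last daughter takes the area
  remainder, or folds into the previous daughter if it would fall below
  `min_daughter` (20 nm, about the smallest stable vesicle). Lipid is
  neither created nor destroyed, which the tests assert to machine
  precision for every seed. Parents not larger than the daughter scale pass
  through with a logged count rather than erroring, so heterogeneous
  populations survive aggressive models.

All randomness flows from one master seed, split deterministically into
per-stage substreams (`derive_seed()`), so any stage can be reproduced in
isolation and identical config + seed yields byte-identical outputs.

**What the simulator does not emulate** — and hence what passing tests do
*not* demonstrate about real data: localisation noise and its MSD offset,
photobleaching, 3D-to-2D projection effects near the depth-of-field edges,
polydisperse refractive-index effects on detectability, tubulation (only
fission into closed daughters is modelled), and the proprietary
finite-track-length adjustment. Real recordings also exhibit
camera-setting-dependent detection thresholds that our two-parameter
logistic cannot capture.

## 3. Distributions and their statistics

Diameters are binned into half-open intervals $[5k, 5(k+1))$ nm, centres
$5k + 2.5$ — the convention is forced by the vesiculation marker bin being
*centred* at 82.5 nm. Counts divide by the observed volume to give
particles/ml. Leading/trailing empty bins are trimmed, interior zeros kept.

`smooth_distribution()` applies the conventional 7-point centred moving
average, truncated at the edges. Smoothing is **display-only**: the mode
and box statistics are always computed on raw binned data, because
smoothing shifts and flattens maxima, and published modes are extracted
from raw exports. (Whether historic figures quoted raw or smoothed modes is
not always stated; this package chose raw and says so.)

`box_stats()` summarises a distribution as its **mode** (centre of the
maximum-concentration bin; ties break to the smallest centre — a
deterministic rule for a measure-zero event) plus boundaries enclosing 50%
of the concentration mass on each side of the mode bin. Boundaries are
located by linear interpolation on the outward cumulative concentration
from the mode bin's edge: with 5-nm bins, boundary positions would
otherwise jump in 5-nm steps, and interpolation makes them continuous,
deterministic and testable. A side with no mass collapses its boundary onto
the mode.

The **correction factor** for the hidden fraction is, per bin,
$\mathrm{CF} = (\mathrm{Fluo} - \mathrm{Diff})/\mathrm{Diff}$, estimated
from a fully fluorescent calibration sample measured in both channels, and
applied as $\mathrm{Diff} \cdot (1 + \mathrm{CF})$. Bins where the
diffraction concentration is zero carry no information about the deficit
and are flagged invalid; they pass through `apply_cf()` unchanged with a
logged count. The CF is meant for strongly affected preparations
(50-nm-extruded liposomes) and is applied only on explicit request — the
CLI exposes it as a flag rather than auto-applying, since applying a
calibration measured on one preparation to a dissimilar one is a scientific
decision, not a default.

## 4. The assays

**Replicate unit.** A single run sizes thousands of particles, so
per-particle tests would declare trivially small differences significant.
The statistical unit is therefore the **mode of one experimental
replicate**; conditions are compared by one-way ANOVA on replicate modes
with Bonferroni-corrected pooled-variance pairwise t-tests (the classical
post-hoc chain). `anova_oneway()` wraps `stats::aov()`;
`pairwise_bonferroni()` wraps `stats::pairwise.t.test(pool.sd = TRUE)` and
applies $p_\text{adj} = \min(1, m \cdot p)$ with $m$ the number of
comparisons actually made. Degenerate inputs (identical constant groups,
zero pooled variance) are mapped to the limits a statistician would assign:
$F = 0, p = 1$ for no between-group signal over no within-group noise with
equal means; $p = 0$ for distinct means with zero variance.

**Curvature preference.** `classify_preference()` compares replicate modes
of the bound subpopulation against the total population. The call is
`smaller` / `larger` only when both (a) the mean mode shift exceeds
`min_shift` in magnitude and (b) the Bonferroni-adjusted p-value is below
`alpha`; otherwise `none`. Defaults: `alpha = 0.05`; `min_shift = 5` nm,
one bin width — no established effect-size floor exists for this readout,
and one bin is the resolution of the mode, so a sub-bin shift cannot be
distinguished from binning jitter regardless of significance. Both
thresholds are arguments, not constants.

**Vesiculation.** `vesiculation_dose_response()` reports, per dose, the
concentration in the 82.5-nm marker bin (the efficiency metric), the
concentration-weighted mean size and the total particle concentration,
requiring a dose-0 baseline. No EC50 is fitted: the readout is the curve
itself, and fitting a Hill function to five doses would project simulator
assumptions onto the output. `compare_efficiency()` compares two proteins'
replicate metrics at one dose with a two-sided pooled t-test.

## 5. Numerical choices and degenerate inputs

* Stokes–Einstein forward/inverse compose to identity at machine precision;
  both reject non-positive inputs as domain errors.
* A track whose positions never move has $\hat D = 0$ and no finite
  diameter; such tracks are dropped with a logged count rather than
  propagating infinities.
* `bin_sizes()` of zero estimates returns an *empty distribution* (0
  particles), not an error — an empty channel is a legitimate measurement
  outcome; `box_stats()` of an empty distribution *is* an error, because a
  mode of nothing is meaningless.
* CF round trip `apply_cf(diff, compute_cf(fluo, diff)) = fluo` holds on
  valid bins to floating-point round-off (asserted at $10^{-12}$ relative
  tolerance).
* Area conservation in `vesiculate()` is exact by construction (the last
  daughter is defined as the square root of the remaining area), not
  approximate.
* Off-grid bin centres (e.g. 84 nm on a 5-nm grid) are errors everywhere —
  silently snapping them would corrupt the marker-bin lookup.

## 6. Test problem sizes

The verification suite simulates at sizes chosen to make the statistical
assertions sharp while keeping the suite quick to run routinely: 3000
tracks × 100 steps per calibration bead (mode recovery within one bin),
1000 × 100-step tracks for estimator bias (±2%), five seed-triplets per
binder scenario at 6000 particles per replicate for the classification
properties, and five seeds × five doses at 800 particles for the
vesiculation ordering. These ns match the scale of real runs (a typical
measurement sizes 3000–8000 particles) rather than asymptotic limits, so
the demonstrated stability is the stability a user should expect at
realistic particle counts.

## 7. Known limitations

* Lag-1 MSD is optimal only in the no-noise regime the simulator inhabits;
  on real data with localisation error it underestimates diameters of the
  smallest, fastest particles unless a noise offset is modelled (out of
  scope by design).
* The mode of a raw 5-nm-binned histogram is an inherently jumpy statistic
  on broad distributions; the assays inherit that jitter honestly (it is
  what the replicate-level ANOVA sees). Narrow, well-peaked preparations
  classify far more reliably than nearly flat ones — as in the laboratory.
* The binding and detection logistics are phenomenological stand-ins, not
  fitted to any instrument; conclusions about a *specific* protein or
  instrument require measured curves.
* Concentrations are only as accurate as the observed-volume calibration,
  which is instrument-specific and entered by the user.
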