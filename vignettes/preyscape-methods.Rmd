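---
title: "Methods: from echograms and tags to prey-field habitat models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from echograms and tags to prey-field habitat models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(preyscape)
```

## The problem

Whale sharks aggregating over a narrow forereef shelf are tracked with
towed satellite tags that record depth and temperature at 1 Hz and
transmit a position fix whenever the animal surfaces. A ship-based
120 kHz echosounder simultaneously surveys the surrounding water column,
producing volume backscattering strength (Sv) that can be scaled to
volumetric zooplankton density. `preyscape` implements the full chain
that links the two data streams: echogram cleaning and echo integration,
target-strength modelling, tag filtering and time-at-depth accounting,
2D/3D kernel utilisation distributions, variogram-scaled spatial
matching, and mixed-effects habitat models — plus a synthetic-data
module that generates all inputs with known ground truth so every stage
is testable without access to field data.

## Acoustic processing

**Echo integration.** Raw per-ping Sv samples are averaged into
along-track (30 s ≈ 150 m) × 1-m depth cells. Averaging always happens
in the linear domain: MVBS $= 10\log_{10}\overline{10^{S_v/10}}$.
Averaging dB directly is wrong by Jensen's inequality; the test suite
pins this with the worked two-sample example
($-70$ and $-80$ dB → $-72.60$ dB, not $-75$).

**Cleaning.** The seabed is found per ping as the deepest sample whose
echo exceeds a $-35$ dB threshold below 10 m, then median-smoothed
across pings; samples below the bottom and within a 0.5-m backstep above
it are excluded, as is everything above 5 m (transducer draft plus
bubble entrainment) and any pings inside user-supplied trawl windows.
The threshold-plus-smoothing detector is a deliberate simplification —
production echosounder software uses more elaborate bottom pickers — but
it is exact on the forward model used here and is exercised against
injected bottom echoes in the tests.

**NASC.** The nautical area scattering coefficient per 500-m interval is
$\mathrm{NASC} = 4\pi \cdot 1852^2 \sum_z \overline{s_v}\,\Delta z$
(m² nmi⁻²), additive over disjoint depth layers, which the tests verify
to < 0.1%.

**Below detection.** Cells whose forward Sv falls under the detection
floor (default $-100$ dB) are kept as explicit zeros, not dropped:
depth layers with measured zero density must enter downstream means,
otherwise buffer averages are biased upward. Unsampled cells, by
contrast, stay missing.

## Target strength: DWBA bent fluid cylinder

Density is obtained from MVBS as
$n = 10^{\mathrm{MVBS}/10} / 10^{\mathrm{TS}/10}$, so everything hinges
on the population target strength. We model a euphausiid as a weakly
scattering uniformly bent fluid cylinder and integrate the
distorted-wave Born approximation along the discretised body:

$$f_{bs} = \frac{k_1}{4}\int (\gamma_\kappa - \gamma_\rho)\,
  e^{2 i \mathbf{k}_2\cdot\mathbf{r}}\, a\,
  \frac{J_1(2 k_2 a \cos\beta)}{\cos\beta}\,|d\mathbf{r}|,$$

with $\gamma_\kappa = (1-gh^2)/(gh^2)$, $\gamma_\rho = (g-1)/g$,
interior wavenumber $k_2 = k_1/h$, and $\beta$ the angle between the
incident direction and the local cross-section. $\sigma_{bs} = |f_{bs}|^2$
is averaged over a Normal tilt distribution (Gauss-weighted quadrature
over ±3 sd) and then over the animal length distribution;
$\mathrm{TS} = 10\log_{10}\overline{\sigma_{bs}}$ uses the arithmetic
mean of cross-sections (energy-consistent), never the mean of dB values.

Defaults are standard small-euphausiid material properties
($g = 1.0357$, $h = 1.0279$), slenderness $L/a = 16$, bend radius $3L$,
50 body segments, and 100 lengths uniform on 8–13 mm. The orientation
distribution is the one parameter with real leverage and no published
value for this system. We default to tilt ~ Normal(0°, 10°) — a
near-horizontal swimming posture with modest spread, appropriate for
small euphausiids insonified dorsally — which yields $-90.5$ dB at
120 kHz, within the ±3 dB band around the field estimate of $-88.53$ dB
that the uncertainty in material and orientation parameters warrants.
Wider or strongly pitched distributions (e.g. mean −20°, sd 20°) shed
3–4 dB through phase decorrelation along the body and fall outside that
band, so they are available but not the default. Model physicality is
pinned by two scale-free checks: zero material contrast scatters
nothing, and in the Rayleigh regime ($k a < 0.1$) halving the frequency
lowers TS by $10\log_{10} 16 \approx 12$ dB.

## Tag processing

**Detachment.** A released tag floats and acquires fixes exactly on its
programmed 30-min schedule; an attached tag transmits opportunistically.
The filter flags the trailing maximal run of ≥ 3 fixes whose gaps equal
30 min ± 2 min and drops everything from the run's start. Three regular
gaps was chosen as the minimum run giving negligible false-positive
probability for opportunistic surfacing (two gaps can align by chance
within the tolerance; three in a row essentially cannot).

**TAD/TAT.** Dwell-time histograms use half-open 1-m / 1-°C bins
$[b, b+1)$; seconds per bin sum exactly to the record length, and
day/night splits use solar elevation ≥ 0° at a reference position (the
low-precision NOAA ephemeris implemented in `solar_elevation()`).
Depths in $(-1, 0)$ m are surface-sensor noise and are clipped to 0;
anything below $-1$ m is refused as data corruption rather than noise.

**Pseudo-tracks.** Easting and northing are interpolated against time
with a natural cubic spline through the attached fixes, evaluated at
every 1-Hz timestamp inside the fix span, and paired with measured
depth. No extrapolation: cubic splines diverge outside their support,
so record samples beyond the first/last fix are dropped rather than
invented.

## Utilisation distributions

2D and 3D UDs are Gaussian product-kernel densities evaluated on a
metric grid (500-m cells in 2D, bandwidth/4 voxels in 3D), renormalised
so the discrete cell sum × cell measure is exactly 1. Isopleths use
descending-density accumulation — sort cells by density, accumulate mass
to the target level, ties broken by cell index — the standard
home-range construction; 50% is the core, 95% the range. Bandwidths
default to the per-axis normal-reference rule ($h_j = s_j n^{-1/6}$ in
2D, $s_j n^{-1/7}$ in 3D) because the source analyses name their
packages but not their selectors; the argument is pluggable and
recorded in the returned object.

Two analytic fixtures calibrate the machinery: a single point with
isotropic bandwidth has HPD areas $\pi r_p^2$ with
$r_p^2 = -2h^2\ln(1-p)$, hence area(95%)/area(50%) $= \ln 20 / \ln 2
\approx 4.322$; in 3D, volumes follow $\tfrac{4}{3}\pi h_xh_yh_z r^3$
with $r^2 = \chi^2_3(p)$. The default voxel edge (bandwidth/4) keeps
single-point volumes within ~0.1% of these closed forms; the voxel
halving test bounds refinement drift at < 5%. The gridded KDE is also
checked against a brute-force double-loop oracle to 10⁻⁸.

3D UDs are computed on the full 1-Hz pseudo-track (optionally thinned),
and density below the local seabed can be zeroed and renormalised —
physically an animal cannot occupy rock; this masking is this package's
addition and is off unless a seabed function is supplied. Day/night
volume comparisons use the exact two-sided Wilcoxon rank-sum test when
ties permit.

## Variogram matching scale and buffer extraction

The spatial scale for predator–prey matching comes from the empirical
Matheron semivariogram of backscatter between survey points
($\gamma(h) = \frac{1}{2N(h)}\sum(z_i-z_j)^2$; MVBS in dB, lag width
100 m, max lag 3 km) with a Gaussian model
$\gamma(h) = c_0 + c\,(1 - e^{-h^2/a^2})$ fitted by weighted least
squares (weights = pair counts, Levenberg–Marquardt); the effective
range is $a\sqrt{3}$, where the model reaches ~95% of its sill. A fit
whose structured component is under 5% of the sill or explains under
20% of the weighted variation around a flat model is flagged
unidentifiable — pure-nugget data carry no spatial scale, and reporting
one anyway would be meaningless.

Around each (time-matched) shark location, density cells whose
centroids lie strictly within the buffer radius (default 1 km, a
vertical cylinder — buffers are horizontal distances through the whole
column) and within ±6 h are averaged per 1-m depth bin, zeros included.
The ±6 h window is a package default: the source analyses matched
tracks and transects "temporally" without stating a tolerance, and
same-survey-day matching at ±6 h keeps day-scale prey-field coherence
while excluding overnight vertical-migration turnover. It is an
argument, not an assumption baked in.

## Mixed models

Two analyses share a `habitat_fit` container:

- **Horizontal:** per-cell UD value against $10\log_{10}(\mathrm{NASC}+1)$
  on the 500-m grid, by ordinary least squares (the pooled UD has no
  grouping structure).
- **Vertical:** `TAD ~ density + (1 | shark)` fitted by maximum
  likelihood with lme4. ML (not REML) is deliberate: AIC comparisons
  against the null `TAD ~ 1 + (1 | shark)` are only valid under a
  common likelihood definition. The default response is
  $\log(\mathrm{TAD} + 1\,\mathrm{s})$ — TAD is a nonnegative,
  long-tailed duration — with the raw scale retained as an option, and
  the reported $r^2$ is the marginal (fixed-effects) share
  $\mathrm{var}(X\beta)/(\mathrm{var}(X\beta)+\sigma_b^2+\sigma_e^2)$,
  so it is comparable to published fixed-effect $r^2$ values. The
  random-intercept variance share $\sigma_b^2/(\sigma_b^2+\sigma_e^2)$
  is reported alongside. Akaike weights are
  $w_m = e^{-\Delta_m/2}/\sum_k e^{-\Delta_k/2}$.

Simulation-based checks (10 sharks × 50 depth bins, slope 0.5,
unit-variance intercepts and residuals, 100 replicates) show ~93% Wald
CI coverage of the slope and a mean variance-share estimate within 0.06
of truth; with a zero slope the null wins the Akaike weights in the
large majority of replicates, and with no between-shark variance the
estimated share collapses to zero.

## The synthetic study system

`sim_config()` fixes the study conditions the generator emulates:

- **Bathymetry** — a 4 × 4 km metric domain at 50-m resolution, shelf
  sloping 10 → 70 m, with four gutters/pinnacles (±12 m relief) seeded
  on the 50-m contour, which also defines the reef-edge polyline.
- **Prey** — a 0.05 ind m⁻³ background plus five Gaussian patches
  (300 m horizontal, 6 m vertical scale, peak 2000 ind m⁻³) anchored to
  the bathymetric features and pulled toward the seabed
  (`seabed_weight = 0.8`), reproducing the observed association of
  dense prey with near-bottom structure and a density range spanning
  ~0.01 to > 10⁴ ind m⁻³ across noise realisations. A configurable
  night offset shifts patch centres upward to emulate diel vertical
  migration.
- **Survey** — cross-shelf 3.5-km lines spaced 1 km, 10 kn, 0.5-s
  pings, 1-m samples from 5 m to the seabed, additive Gaussian noise of
  3 dB in the dB domain (standard single-ping variability), a strong
  bottom echo, and a −100 dB detection floor.
- **Sharks** — a two-state vertical renewal process (surface phases
  alternating with constant-0.5 m s⁻¹ dives to targets drawn from a
  mixture favouring < 10 m and 40–60 m, matching the observed bimodal
  depth use) over a correlated random walk whose candidate headings are
  weighted by $\exp(\beta_{pref} z)$, $z$ the standardised column
  density smoothed over 600 m. The smoothing scale deserves a note: raw
  patch fields are nearly flat almost everywhere, so an unsmoothed
  preference cannot express itself at realistic swim speeds; smoothing
  over roughly twice the patch radius represents sensory/memory
  integration at the scale of the cue field and makes β_pref a
  recoverable parameter. Fixes are emitted only at seconds with depth
  < 1 m, thinned to ~2 × 10⁻⁴ per surface-second so a day-scale
  deployment yields the handful of fixes real tags produced.

What the generator does **not** emulate: hydrodynamics (eddies,
dense-water outflows), multi-frequency acoustics, mixed scatterer
assemblages, tide- or light-driven behaviour, and any real movement
model of the animal — the biased walk is a testing stand-in with a
known preference parameter, not an inference of behaviour. Tests passing
on these scenes therefore demonstrate correctness of the *pipeline*
(forward–inverse consistency, estimator calibration), not ecological
realism of any fitted value.

## Numerical choices and degenerate inputs

- Depth bin $k$ covers $[k, k+1)$ m; a bin is water if its centre is
  above the local seabed; density is zero below.
- With zero forward noise and the floor disabled, the acoustic chain
  inverts the generator to ~10⁻¹⁵ relative error; the shipped check
  requires < 10⁻⁶.
- `-Inf` dB is the below-detection sentinel throughout; `10^(-Inf/10)`
  is exactly 0, so sentinels flow through linear averages correctly.
- Zero-variance predictors, single-shark inputs, empty periods, < 2
  fixes, disjoint transects and all-masked densities all have explicit
  error or warning paths (see the tests).
- Problem sizes in the shipped tests and acceptance script (2–4 km
  scenes, 4–6 simulated deployments, 100 mixed-model replicates,
  20 variogram replicates at 300 points) were chosen as the smallest
  sizes at which the Monte-Carlo assertions are stable across seeds.

## Known limitations

- The seabed detector assumes a single strong bottom echo; side-lobe
  and dead-zone effects are not modelled.
- TS is single-frequency, single-species; no dB-differencing.
- UDs are plain KDEs: no autocorrelation correction (tracks are 1 Hz,
  so effective sample sizes are far below nominal) and no
  movement-model bridges.
- The Gaussian variogram model is the only implemented family, as it is
  the one the matching scale is defined on; fields with non-Gaussian
  covariance will fit it only approximately.
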