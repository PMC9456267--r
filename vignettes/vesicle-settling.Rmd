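---
title: "Brownian settling, cap geometry and log-normal statistics: the methods behind vesicledrop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Brownian settling, cap geometry and log-normal statistics: the methods behind vesicledrop}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`vesicledrop` studies a sampling artifact of AFM-based sizing of
extracellular vesicles: the vesicles an AFM sees on the substrate are the
ones that have already diffused down through the sample drop, and because
the Einstein–Stokes diffusion constant scales as `1/d`, small vesicles
arrive first. This vignette is the package's own account of the models it
implements, the parameters that matter, the numerical choices made where the
design was open, and what the synthetic-data tests do and do not show about
real data.

```{r setup}
library(vesicledrop)
```

## The settling model

A vesicle with hydrodynamic diameter $d$ in a liquid of viscosity $\eta$ at
temperature $T$ diffuses with

$$D = \frac{k_B T}{3 \pi \eta d},$$

so over a time step $\Delta t$ its vertical displacement is Gaussian with
standard deviation $\sigma = \sqrt{2 D \Delta t}$. The simulation
(`simulate_settling()`) tracks only the height coordinate: lateral motion
neither changes the arrival time at the substrate nor the boundary
interactions in a laterally uniform drop.

The sessile drop — a spherical cap of height $h_{drop}$ on a substrate disc
of radius $r_{base}$ — is replaced by a cylinder whose height is the mean
height of the cap surface over the base,

$$h_{cyl} = \frac{h_{drop}}{2} + \frac{h_{drop}^3}{6\, r_{base}^2},$$

implemented in `effective_drop_height()`. For the default 1 mm drop on a
5 mm disc this is 0.5067 mm: vesicles near the drop rim sit under much less
liquid than the apex value suggests, and the cylinder approximation captures
the average column a vesicle must traverse.

Walk rules, in order, per step: add the Gaussian displacement; if the new
height exceeds $h_{cyl}$, reflect it as $z \mapsto 2 h_{cyl} - z$ (a single
mirror fold — the kernel stops with an error if a step ever exceeds the
whole column, which cannot happen at sane step sizes); if the new height is
at or below zero, the vesicle attaches permanently and leaves the
simulation. Initial heights are uniform on $(0, h_{cyl})$, the well-mixed
condition immediately after pipetting.

### Parameters and defaults

| parameter | default | unit | why |
|---|---|---|---|
| `temperature` | 295 | K | room-temperature imaging |
| `viscosity` | 0.95e-3 | Pa s | water at ~22 °C |
| `drop_height` | 1 | mm | typical 150 µL drop on a 1 cm mica disc |
| `base_radius` | 5 | mm | mica disc radius |
| `dt` | 10 | s | see the discretisation note below |
| `duration` | 72000 | s | 20 h, spanning overnight incubation |
| `n_vesicles` | 2e5 | — | desk-scale population (see below) |

Temperature and viscosity are not independently constrained by attachment
data — the observable kinetics depend on them only through $D$ — so they are
fixed once at the values above and echoed in every scenario manifest.

The population default, a log-normal with median 149.2 nm and
multiplicative shape 1.461, is the NTA-style hydrodynamic population used
throughout; the generator (`gen_lognormal_sample()`) treats that fitted
distribution as the canonical population because binned raw NTA exports
carry no extra information the fit does not.

`n_vesicles = 2e5` is a deliberate desk-scale choice: attachment fractions
and attached-population means are unbiased in the population size, and at
2×10⁵ their Monte Carlo noise (±0.1 percentage points on a fraction, ±0.15
nm on a mean) is far below every tolerance of interest, at ~13 s per 20 h
run on one CPU. Scenarios accept larger N when tighter error is wanted.

### Discretisation

Absorption is checked only at step ends. A vesicle can dip below the
substrate and return within one step without being registered, so discrete
first-passage times are biased late by $O(\sqrt{\Delta t})$ — equivalently,
the absorbing boundary appears shifted by $\approx 0.58\,\sigma$. At the
default step ($\sigma \approx 7.8\ \mu m$ for a 150 nm vesicle against a
507 µm column) this costs under one percentage point of attached fraction,
which the monodisperse oracle test bounds explicitly (see below).
`simulate_settling()` warns whenever the median step exceeds $h_{cyl}/5$,
the regime where this bias stops being negligible.

### The analytic oracle

For a monodisperse population the model has a closed form: 1D diffusion on
$(0, L)$ with an absorbing bottom, reflecting top and uniform initial
condition has survival probability

$$S(t) = \sum_{n \ge 1} \frac{8}{(2n-1)^2 \pi^2}
  \exp\!\left(-D \left(\tfrac{(n - 1/2)\pi}{L}\right)^2 t\right).$$

The test suite evaluates this series independently of the simulator and
requires agreement of the attached fraction within 2 percentage points at
$N = 10^5$ — which also pins down the discretisation bias just discussed.

## Cap geometry and the image pipeline

A vesicle adsorbed on mica deforms into a spherical cap of sphere radius
$R_c$ and height $H$. If the membrane area is conserved (inextensible lipid
bilayer), the free-floating sphere had diameter

$$d_{geom} = \sqrt{4 R_c H - H^2},$$

which `geometric_diameter()` evaluates, refusing (with a diagnostic, never a
clamp) the out-of-domain case $4 R_c H < H^2$. An undeformed sphere
($H = 2 R_c$) gives $d_{geom} = H$ exactly.

`analyze_image()` recovers $(R_c, H)$ per vesicle from a height image:

1. **Flattening** (`flatten()`): per-scanline median subtraction (robust to
   sparse tall vesicles), global least-squares plane removal, zero level at
   the image mean. With vesicles covering less than ~10% of the image the
   mean-zeroing shifts the baseline by well under 1 nm.
2. **Detection** (`detect_blobs()`): local maxima above the height filter on
   a lightly smoothed copy seed windowed 2D elliptical Gaussian fits
   (window = 3× the seed's rough FWHM); the fits give sub-pixel centres.
   Candidates must have fitted height > 10 nm — features thinner than a
   collapsed double bilayer are not vesicles — and fitted FWHM < 200 nm.
3. **Profiles** (`extract_profiles()`): four directions (0°, 45°, 90°,
   135°), total length 2× the FWHM cutoff, sampled by clamped bicubic
   interpolation (below). Per profile, $H_p$ is the maximum and the FWHM is
   measured between linearly interpolated half-maximum crossings; truncated
   profiles exclude the blob.
4. **Asymmetry filter**: $(\max_p \mathrm{FWHM}_p - \min_p \mathrm{FWHM}_p)
   / \overline{\mathrm{FWHM}}_p > 0.6$ rejects elongated objects (probe-drag
   smears). The cutoff is a fixed, configurable parameter applied uniformly;
   the filter is monotone by construction — lowering it never admits more
   blobs — and the suite checks this.
5. **Circle fits**: to each profile's points above $H_p/2$, a Kåsa algebraic
   fit refined by geometric least squares (`fit_circle()`). The cap
   cross-section through the centre *is* the circle of radius $R_c$, so
   noiseless recovery is exact up to interpolation. $R_c$ is the mean of the
   per-profile radii (failed fits are dropped from the average), $H$ the
   mean of the four $H_p$ — the same symmetric reduction for both, since
   nothing distinguishes the four directions a priori. The Gaussian-fit
   height is also recorded (`height_fit_nm`) for comparison, but the
   profile-based $H$ enters the cap relation.

### Numerical choices

*Interpolation.* Bilinear interpolation of a convex surface sits below the
true surface by the chord error, which biased recovered $R_c$ low by 2–3%
for 20 nm caps at ~4 nm pixels. Profiles therefore use Catmull–Rom bicubic
interpolation clamped to the enclosing 2×2 pixel range; the clamp suppresses
cubic ringing at the steep rim of past-hemisphere caps while keeping the
smooth-region accuracy.

*Resolution.* Recovery to within 2% requires roughly 12 pixels per cap
radius. The property tests render each cap at a pitch of
`max(1.5, min(3.9, Rc/12))` nm — the instrument-typical 3.9 nm for caps of
$R_c \ge 47$ nm, finer zoomed scans for smaller ones. At a 3 µm / 512 px
scan (5.9 nm pitch), sub-50 nm caps are under-resolved and show
percent-level bias; this is a genuine resolution limit, not an algorithmic
one.

*Coordinates.* Pixel centres sit at $(i - 0.5) \cdot$ `pixel_size`; all
thresholds and outputs are in physical nm, so none of the parameters depend
on scan resolution.

## Log-normal statistics

Particle size distributions are natural log-normals, parameterised here by
the median $\mu^*$ and multiplicative shape $\sigma^*$: 68.3% of the mass
lies in $[\mu^*/\sigma^*, \mu^*\sigma^*]$. `fit_lognormal()` uses the
closed-form log-moment estimator — $\mu^* = \exp(\overline{\ln x})$,
$\sigma^* = \exp(s_{\ln x})$ — which is exact for the model and
scale-equivariant: scaling every diameter by $k$ scales $\mu^*$ by $k$ and
leaves $\sigma^*$ untouched. That equivariance is what makes the
**median-ratio statistic** meaningful: if the hydrodynamic and geometric
populations share $\sigma^*$ within their confidence intervals, the
hydrodynamic distribution is a linearly scaled copy of the geometric one and
`nta_afm_ratio()` returns the scaling constant
$\mu^*_{NTA} / \mu^*_{AFM}$ — about 2.1 for the populations used here — as a
candidate physical characteristic of a vesicle type.

Uncertainty is quantified by a seeded percentile bootstrap (default 10,000
resamples; asymmetric intervals are reported as offsets, e.g.
`149.2 [-2.3, +2.3]`). Two means are called significantly different when
their 95% intervals are disjoint; intervals touching at a point count as
overlapping, the conservative reading. For binned histogram input the fit
weights bin centres by counts — documented as an approximation, adequate
when bins are narrow relative to $\sigma^*$.

A coverage property test (400 Monte Carlo replicates of $n = 200$ samples,
1000 bootstrap resamples each) checks that the nominal 95% interval for
$\mu^*$ covers the truth between 92% and 98% of the time.

## What the synthetic generator does and does not emulate

`gen_height_map()` renders exact spherical caps at pixel centres — no
anti-aliasing — so the ground truth obeys the cap relation to machine
precision and pipeline errors are attributable to the pipeline alone.
Opt-in artifacts emulate the common AFM nuisances: i.i.d. Gaussian pixel
noise, per-scanline offsets, a background tilt plane, and elongated Gaussian
"smear" ridges that stand in for probe-dragged objects. Each artifact is
separately switchable so the flattening and asymmetry stages can be
exercised in isolation.

Deliberately **not** modelled: AFM tip convolution (the rendered cap is the
true surface, not a dilated one), PeakForce mechanics, vesicle–substrate
electrostatics, gravity/sedimentation, hydrodynamic wall corrections, and
vesicle–vesicle interactions. Passing tests therefore demonstrate that the
*analysis chain* is correct and that Brownian settling alone produces the
time-dependent size bias — they do not validate tip-shape corrections or
adhesion kinetics on real instruments. The membrane-stretch factor
(`apply_stretch()`, 1.08 for an 8% linear stretch) is likewise applied post
hoc to sampled diameters of late timepoints: it models slow osmotic
swelling of already-attached vesicles and intentionally does not alter
diffusion during the run.

Overlapping vesicle footprints are combined by pointwise maximum and
flagged with a warning; the layout helper `place_vesicles()` avoids
overlaps by rejection sampling, with a border margin that keeps every
profile inside the image.

## Reproducibility and problem sizes

Every stochastic function takes a `seed`; workflows derive per-stage child
seeds deterministically from one root seed, so a `study_config` (optionally
a YAML file — chosen over ad-hoc key-value formats because YAML is the
R-ecosystem standard with a mature parser) regenerates every artifact
byte-for-byte. Scenario manifests record all parameters including the
defaulted physical constants.

The shipped test suite uses desk-scale sizes chosen so the whole suite runs
in a few minutes: settling oracles at $N = 2\times10^4$–$10^5$, the
timepoint comparison at $N = 2\times10^5$, 50 resampling repeats for the
significance-emergence check, and 400 replicates for bootstrap coverage.
These sizes put Monte Carlo noise comfortably below each assertion's
tolerance; none of the conclusions change at larger N.

## Known limitations

- Discrete-time absorption biases attachment slightly late; bounded and
  warned about, not corrected (no Brownian-bridge crossing test).
- The cylinder drop ignores the true cap geometry's lateral variation in
  column height; vesicles do not migrate laterally.
- Sub-50 nm caps need finer-than-default scan pitch for 2% geometry
  recovery (see the resolution note).
- The histogram-weighted fit ignores within-bin spread.
- The image pipeline assumes a flat, clean substrate; real mica steps and
  contamination are out of scope.
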