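---
title: "Methods: automated aortic stiffness indices from CMR-derived inputs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: automated aortic stiffness indices from CMR-derived inputs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aortastiff)
```

## The problem and the model

Aortic stiffening raises pulse pressure and cardiac afterload and predicts
cardiovascular mortality, so non-invasive stiffness indices are of direct
clinical interest. Two families of indices are in routine use:

* **Distensibility** `D = strain / ΔP` — the relative change in lumen
  cross-sectional area per unit pulse pressure, a *local* index measured at
  one aortic level (here the ascending aorta, `AA_Strain = (Ss - Sd)/Sd`
  with `Ss`/`Sd` the systolic/diastolic areas).
* **Pulse wave velocity (PWV)** — the propagation speed of the flow/pressure
  wave, a *regional* index measured over a segment: here the aortic arch,
  `Arch_PWV = arch length / transit time`.

The Bramwell-Hill model for a compliant vessel carrying an incompressible,
non-viscous fluid links the two:

$$\mathrm{PWV} = \sqrt{\frac{1}{\rho \, D}},$$

with blood density `ρ = 1059 kg·m⁻³` by default and `D` in SI units
(`1 mmHg = 133.322 Pa`, fixed in one constants location). This package
implements both measurements from CMR-derived inputs plus the cohort-level
consistency analysis between them, and ships a synthetic-cohort generator
whose subjects obey the model exactly before noise, so every stage can be
validated against known ground truth.

## Transit-time estimation

The regional measurement needs the delay between the ascending and
descending aorta mean-velocity waveforms, extracted from one
velocity-encoded phase-contrast slice that cuts both limbs. Velocity
waveforms sampled every ~18 ms are too coarse for foot-to-foot timing, so
the estimator works on the whole systolic up-slope:

1. both waveforms are resampled to 1 ms by piecewise-cubic interpolation
   (`resample_to_1ms()`; an interpolation, not a smoother — original samples
   are reproduced exactly and cubic polynomials are resampled exactly);
2. both are min-max normalized to `[0, 1]` (`normalize_waveform()`), which
   makes the comparison invariant to any positive affine change of gain or
   offset — velocity amplitudes differ genuinely between the two sites;
3. the systolic up-slope `EA*` of the ascending curve is extracted as the
   window from the onset of flow to the first global maximum
   (`extract_systolic_upslope()`);
4. the up-slope is slid across the normalized descending curve `E_D` in
   unitary 1 ms steps `k = 0..100`, scoring each shift by the mean quadratic
   error

   $$Er(k) = \frac{1}{N}\sum_{i=1}^{N}\left(EA^*(i) - E_D(i+k)\right)^2,$$

   and the transit time is the minimizing shift
   `Δt = k⁺, Er(k⁺) = min Er(k)` (`estimate_transit_time()`).

Design choices the data did not fix, and how they were resolved:

* **Onset of flow** is the last pre-peak sample at or below 5% of the
  normalized amplitude (`onset_fraction`, configurable). A small positive
  threshold is standard in the foot-to-foot literature because it is robust
  to baseline noise; 0% would latch onto noise, large values eat the
  up-slope.
* **Indexing past the cycle end** (`i + k` beyond the last sample) wraps
  periodically with period `rr_interval`: retrospective gating covers the
  full RR interval, so the curve is periodic by construction. The short gap
  between the last 1 ms grid point and the RR length is bridged linearly
  back to the first sample.
* **Ties** in the minimum resolve to the smallest `k` — deterministic, with
  the bias toward the physically smaller delay made explicit.
* The search range is `k ∈ [0, 100]` ms inclusive; an argmin at either end
  sets a `boundary_flag`, which downstream turns into a warning rather than
  an error so cohort code can decide to exclude such subjects.

Because `Δt` is returned on the integer-ms grid, a noiseless pair with a
continuous-time delay `s` is recovered within ±1 ms (in practice at the
nearest integer), and the estimate is invariant to amplitude scaling of
either waveform.

## Arch length from 3D markers

Arch length comes from lumen-center markers picked on axial slices (six to
eight per limb) and coronal slices (three on the arch top), in a common 3D
mm frame. `fit_centerline()` interpolates them with a composite cubic
Bezier curve: markers are parameterized by cumulative chord length, marker
tangents are taken from the C² cubic spline of each coordinate in that
parameter, and each span is expressed in Bezier form from the Hermite data
(so each Bezier segment *is* the spline segment). The curve passes through
every marker, has linear precision (collinear markers give an exact straight
line) and is C² at joins.

The obvious alternative — local Catmull-Rom tangents — was measured and
rejected: on an arch top sampled by only three markers (45° spacing on a
25 mm semicircle) Catmull-Rom tangents are systematically too short and
bias the arc length low by about 0.6%, while the spline tangents keep the
bias near 0.13%. At the 1.6 mm pixel scale of the source data both are
sub-pixel, but the length bias propagates quadratically into the
`1/Arch_PWV²` regression, so the more accurate tangent was preferred.

`clip_to_plane()` intersects the curve with the phase-contrast slice plane
(origin + unit normal): the signed distance is scanned on a fine parameter
grid and each bracketing interval is refined by bisection until the point
is within `1e-6 mm` of the plane; the first and last crossings are the
ascending and descending intersections. `arc_length()` integrates the
parametric speed with adaptive 15-point Gauss-Legendre panels split at the
segment knots, to an absolute tolerance of `1e-3 mm`. Both tolerances are
far below marker-picking noise; the quadrature is exact to machine
precision on straight segments and rigid-motion invariant because chord
lengths and speeds are.

## Local indices and pressure calibration

`compute_strain()` takes the global maximum and minimum of the lumen-area
curve as `Ss` and `Sd`. Distensibility uses either the brachial pulse
pressure (cuff, measured in the magnet) or the carotid pulse pressure from
applanation tonometry. Tonometry records pressure only in arbitrary units;
`calibrate_carotid_pressure()` rescales it by the unique positive affine
map that sends the waveform mean to the brachial mean pressure and the
waveform minimum to the brachial diastolic pressure — the standard
assumption that the mean-minus-diastolic difference is conserved along the
large-artery tree determines exactly this two-constraint fit. The carotid
pulse pressure is then the range of the rescaled waveform, and is invariant
to the recording gain. When the device reports no mean pressure,
`mean_arterial_pressure()` falls back to the one-third rule
`MAP = diastolic + PP/3`; a measured mean always takes precedence.

`pwv_from_distensibility()` and `distensibility_from_pwv()` implement the
Bramwell-Hill transform and its inverse; they are mutual inverses to
`1e-12` relative and the associativity of
`strain → distensibility → PWV` is tested explicitly.

## The synthetic cohort

`generate_cohort()` stands in for a volunteer study; its defaults are the
package's statement of realistic study conditions and are deliberately not
tuned per analysis:

| parameter | default | why |
|---|---|---|
| n_subjects | 46 | healthy-volunteer cohort size the analysis targets |
| true distensibility | log-normal, marginal mean 5.86e-3, SD 3.23e-3 mmHg⁻¹ | matches the reported cohort mean ± SD of the carotid-calibrated index |
| age | uniform 20-70 y; log-D declines 0.025/y | stiffening with age; keeps both sides of the 50 y split populated |
| velocity sampling | 18 ms | view-shared breath-hold phase contrast |
| area sampling | 33 ms | SSFP cine inter-phase duration |
| velocity noise | 1 cm/s | calibrated so transit-time and PWV reproducibility land at the reported ~4-7% CoV regime |
| area noise | 2 mm² | segmentation jitter on a ~600 mm² lumen |
| marker jitter | 1 mm | sub-pixel manual picking error (1.6 mm pixels) |
| brachial−carotid PP offset | 9.5 mmHg (noise SD 3) | peripheral pulse-pressure amplification |
| arch geometry | limbs 25 mm, top radius 20-30 mm, tilt ±15° | total length ~12.5 cm, matching adult arch dimensions |
| CF_PWV | `1.71·PWV − 0.35` + N(0, 2.3²) m/s | reproduces the reported CF_PWV mean/SD and its ~0.7 correlation with arch PWV |

Every subject is internally consistent before noise: `true_pwv` is the
Bramwell-Hill transform of `true_distensibility`; `true_transit_time`
equals the clipped arch length divided by `true_pwv`; `true_strain` equals
`true_distensibility ×` carotid PP; the raw tonometric waveform is shaped
(by solving a one-parameter exponent) so that the mean/diastolic
calibration returns the generating carotid PP exactly; the descending
velocity waveform is the ascending template delayed by the true transit
time *in continuous time, before sampling*, so the truth is never quantized
to the acquisition grid; and the area curve's systolic peak is placed on a
sample instant so its discrete extrema equal the continuous ones.

What the generator does **not** emulate: image formation and segmentation
(inputs are already curves and markers), pressure-wave propagation physics
(the descending waveform is a delayed, scaled copy — real reflections
change its morphology), beat-to-beat physiological variability, and any
pathology. Passing tests on synthetic cohorts therefore validate the
*estimators and their composition*, not the upstream segmentation.

## Numerical behaviour and known limitations

* **Transit-time quantization is the accuracy floor.** With transit times
  around 24 ms (the consequence of a ~12.5 cm arch and Bramwell-Hill PWV of
  ~5.5 m/s at the cohort's distensibility), the integer-ms `Δt` carries a
  uniform ±0.5 ms quantization error, i.e. ~1.2% per subject, doubled in
  `1/Arch_PWV²`. On zero-noise cohorts of 46 this leaves the
  distensibility-vs-`1/Arch_PWV²` regression at r ≈ 0.999 and a slope
  within ~1-2% of `1/ρ`, fluctuating seed to seed; substituting the exact
  transit times gives r = 1 to machine precision, which pins the residual
  entirely on quantization. The remaining −0.27% slope offset is twice the
  −0.135% centerline length bias.
* **Interpolation through noisy markers inflates length.** The centerline
  passes through every marker by construction, so i.i.d. picking jitter
  makes the curve wiggle between closely spaced limb markers and biases the
  arc length *upward* (about +8% at the default 1 mm jitter on ~4 mm marker
  spacing) while leaving its reproducibility CoV at ~2-3%. Real operators
  correlate their errors and real analyses inherit the same effect; a
  smoothing (approximating) fit would trade this bias for a curvature
  underestimate and is deliberately not applied, since the method is an
  interpolation by contract.
* **Boundary shifts.** True delays beyond 100 ms clamp to the search edge
  and are flagged, not silently returned.
* **Degenerate inputs** are rejected with stage-named errors: constant
  waveforms (no amplitude to normalize), peaks at the first sample (no
  up-slope), planes that miss a limb (fewer than two crossings), fewer than
  4 markers, non-positive areas or pressures.
* **Problem sizes in the shipped tests** were chosen to keep the full suite
  in the tens of seconds: cohorts of 46 for the identity and noise-regime
  checks (the size the analysis is designed around), 100 random geometries
  for invariance properties, 100 replicates for Monte-Carlo recovery bands.

## Reproducing the cohort analysis

`scripts/acceptance.R` (repository root) regenerates everything from
scratch for a given `--seed`: the theoretical slope, transit-time recovery,
semicircle length error, the zero-noise identity regression, the
default-noise consistency correlations and CoVs, the marker-jitter length
reproducibility, and the worked micro-examples, writing one JSON object of
named numbers.
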