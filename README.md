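# aortastiff

Automated aortic stiffness indices from CMR-derived inputs, with a
ground-truth synthetic cohort generator and the cohort-level consistency
statistics that tie the regional and local measurements together.

## The problem

Aortic stiffness is an independent predictor of cardiovascular risk. Two
complementary non-invasive indices are in clinical use:

* **Regional aortic arch pulse wave velocity** —
  `Arch_PWV = L / Δt`, where `L` is the 3D centerline length of the arch
  between the phase-contrast slice intersections and `Δt` is the transit
  time of the flow wave between the ascending and descending aorta. `Δt` is
  estimated by least-squares matching of the systolic up-slope `EA*` of the
  normalized ascending velocity waveform against the normalized descending
  waveform `E_D`, both cubically resampled to 1 ms:
  `Er(k) = (1/N) Σᵢ (EA*(i) − E_D(i+k))²`, `Δt = argmin_{k ∈ [0,100]} Er(k)`.
* **Local ascending-aorta distensibility and theoretical PWV** —
  `AA_Strain = (Ss − Sd)/Sd` from the lumen-area curve,
  `D = AA_Strain / ΔP` using carotid (tonometric, calibrated by the
  brachial mean/diastolic pressures) or brachial pulse pressure, and the
  Bramwell-Hill theoretical velocity `PWV = √(1/(ρ·D))` with
  `ρ = 1059 kg·m⁻³`.

Consistency between the two is assessed cohort-wide by regressing the
distensibility indices (in Pa⁻¹) on `1/Arch_PWV²` — the Bramwell-Hill model
predicts a slope of `1/ρ ≈ 9×10⁻⁴` — plus regressions of the theoretical
local PWV on `Arch_PWV`, comparison with tonometric carotid-femoral PWV,
inter-observer coefficients of variation, and age-group summaries.

Because no patient data ship with the package, a synthetic cohort generator
(`generate_cohort()`) produces per-subject velocity waveform pairs with a
known continuous-time delay, area curves with known strain, 3D arch markers
with analytic arc length, and pressures — all mutually Bramwell-Hill
consistent before configurable noise — so every stage is testable against
ground truth.

## Worked example

```r
library(aortastiff)

dir <- tempfile("demo")
co <- generate_cohort(noise_free(synth_params(n_subjects = 8, seed = 42)))
write_cohort(co, dir)           # per-subject CSVs + truth.csv + config.json

rec <- run_subject(file.path(dir, "subj_001"))
sprintf("transit %d ms | length %.1f mm | Arch_PWV %.2f m/s",
        rec$transit_time_ms, rec$arch_length_mm, rec$arch_pwv)
#> "transit 20 ms | length 117.1 mm | Arch_PWV 5.85 m/s"
sprintf("strain %.3f | carotid PP %.1f mmHg | AA_Distc %.3g mmHg^-1 | AA_PWVc %.2f m/s",
        rec$strain, rec$carotid_pp, rec$aa_distc, rec$aa_pwvc)
#> "strain 0.184 | carotid PP 51.9 mmHg | AA_Distc 0.00355 mmHg^-1 | AA_PWVc 5.96 m/s"
```

The ground truth for that subject is a 19.7 ms transit time, 117.2 mm arch
length, 5.96 m/s true PWV and distensibility 0.00355 mmHg⁻¹: the strain,
pressure calibration and distensibility are recovered exactly at zero
noise, while the transit time (and hence `Arch_PWV`) is correct up to the
estimator's 1 ms grid.

```r
res <- run_cohort(dir)
res$report
#> Bramwell-Hill consistency report (n = 8)
#>   theoretical slope 1/rho = 0.000944 Pa^-1 (m/s)^2
#>   measured/theoretical distensibility slope ratio = 1.018
#>   aa_distc_vs_inv_arch_pwv2    r = 0.995 (p = 2.7e-07), slope = 0.0009613, n = 8
#>   aa_distb_vs_inv_arch_pwv2    r = 0.979 (p = 2.2e-05), slope = 0.0007688, n = 8
#>   aa_pwvc_vs_arch_pwv          r = 0.997 (p = 8.4e-08), slope = 1.038, n = 8
#>   aa_pwvb_vs_arch_pwv          r = 0.988 (p = 4.3e-06), slope = 1.1, n = 8
#>   arch_pwv_vs_cf_pwv           r = 0.997 (p = 8.4e-08), slope = 0.56, n = 8
#>   CoV (%): arch_length 0.00, transit_time 0.00, arch_pwv 0.00
```

The carotid-calibrated distensibility regression lands on the theoretical
Bramwell-Hill slope within ~2% (the residual is 1 ms transit-time
quantization), the brachial variant falls below it because the brachial
pulse pressure overestimates the central one, and the zero-noise CoVs are
exactly zero. With the default noise model the correlations drop into the
0.65–0.98 range and the CoVs rise to the few-percent regime typical of
inter-observer reproducibility — see the methods vignette
(`vignettes/aortastiff-methods.Rmd`).

A thin CLI wraps the same functions:

```sh
Rscript "$(Rscript -e 'cat(system.file("scripts/aortastiff.R", package="aortastiff"))')" \
    simulate --out cohort_dir --n 46 --seed 1
Rscript .../aortastiff.R subject cohort_dir/subj_001 --report report.json
Rscript .../aortastiff.R cohort cohort_dir --out results --plots
```

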