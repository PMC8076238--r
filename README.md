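# skindrs

Diffuse reflectance spectroscopy (DRS) analysis of skin water bonding.

Psoriatic skin has a compromised epidermal barrier: free water escapes, and
the near-infrared water absorption bands of the remaining (macromolecule-bound)
water are shifted and broadened relative to pure water. A simple fiber-probe
DRS system — one source fiber and two collection fibers at 1 and 2 mm — can
detect this: measured two-separation reflectance is inverted to absorption
and reduced-scattering spectra, and the deviation of the absorption spectrum
from a scaled pure-water spectrum quantifies the bound-water signature.

`skindrs` implements that entire chain for researchers in tissue optics and
quantitative dermatology:

* **Forward model** — Monte Carlo photon transport in a homogeneous
  semi-infinite medium under the probe (Henyey–Greenstein scattering,
  g = 0.8, index-matched boundary, NA-cone detection), with
  white-Monte-Carlo path recording so one scatter-only run serves every
  absorption value by Beer–Lambert reweighting
  `w · exp(−µa·L)`.
* **Inverse model** — a reflectance database over the optical-property grid
  µa ∈ [0.001, 1] mm⁻¹, µs′ ∈ [0.1, 3] mm⁻¹, and a small tanh MLP mapping
  (log R₁, log R₂) → (log µa, log µs′) per wavelength.
* **Water-band analysis** — the fitting residual
  `ρ = 100 · Σᵢ(µa(λᵢ) − c·µa_water(λᵢ))² / N`
  (amplitude `c ≥ 0` fitted by least squares) over the 940–1000 nm second
  overtone and 1230–1380 nm first overtone bands, and the scattering power
  law `µs′ = a·λ⁻ᵇ`.
* **Cohort statistics** — one-way ANOVA across the four site groups
  (psoriatic lesion, adjacent uninvolved, psoriasis arm, normal arm),
  Scheffé pairwise tests, Pearson correlation with PASI subscores,
  box-and-whisker summaries.
* **Synthetic study** — a generator for a 21 + 21 subject cohort (three
  sites per psoriasis subject, five replicates per site) with
  group-dependent bound-water fraction, absorption offset and scattering,
  pushed through the forward model with multiplicative noise, for
  end-to-end validation of the pipeline.

## Worked example

Simulate the probe on skin-like optics, then quantify a bound-water
perturbation:

```r
library(skindrs)

m <- medium_optics(mu_a = 0.05, mu_s_prime = 1.2, g = 0.8)
simulate_reflectance(m, probe_geometry(), mc_config(n_photons = 2e5, seed = 7))
#> Monte Carlo reflectance (200000 photons, seed 7)
#>   SDS 1.00 mm: R = 9.725e-05 (SE 4.7e-06, n = 487)
#>   SDS 2.00 mm: R = 2.514e-05 (SE 1.6e-06, n = 310)
```

About 1 photon in 10⁴ launched is collected at 1 mm, a quarter of that at
2 mm — the raw signal the inverse model consumes.

```r
ref <- water_reference()
bd  <- band("first")          # 1230-1380 nm

# lesion-like skin: 70% water, bound fraction 0.55, blue-shifted + broadened
mua_lesion <- compose_absorption(0.7, 0.55, -8, 1.15, 0.0035, bd, ref)
fit_pure_water(mua_lesion, bd, ref)
#> Pure-water fit (first_overtone): amplitude c = 0.8094, rho = 0.001642 (n = 151)

# arm-like skin: bound fraction 0.25
mua_arm <- compose_absorption(0.7, 0.25, -8, 1.15, 0.0028, bd, ref)
fit_pure_water(mua_arm, bd, ref)
#> Pure-water fit (first_overtone): amplitude c = 0.7548, rho = 0.0004073 (n = 151)
```

The lesion-like spectrum deviates four times more from pure water
(ρ = 1.6×10⁻³ vs 4.1×10⁻⁴) — the statistic that separates lesions from
uninvolved skin at the first overtone. The scattering power law
round-trips exactly on noiseless data:

```r
wl <- seq(940, 1000, by = 1)
fit_power_law(spectrum(wl, 315.565 * wl^(-0.808), kind = "scattering"),
              band("second"))
#> Power law mu_s' = a * lambda^-b: a = 315.565, b = 0.808 (rms 3.48e-16 mm^-1, n = 61)
```

The full pipeline — database build, inverse-model training, cohort
generation, inversion and statistics — is:

```r
db     <- build_reflectance_database(grid_spec(), probe_geometry(),
                                     mc_config(n_photons = 1e5, seed = 100))
model  <- train_inverse_model(db, seed = 1)
cohort <- generate_cohort(cohort_config(seed = 42), db)
run_pipeline(cohort, model)
```

which prints ANOVA p-values per metric and the PASI correlations. See
`vignettes/skindrs-methods.Rmd` for the model details, parameter choices
and limitations.

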