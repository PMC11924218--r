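# marinp

Classical-nucleation-theory modelling of marine polysaccharide
ice-nucleating macromolecules (INMs), and of the ice-nucleating particle
(INP) populations they imply over remote oceans.

## What this package is for

Clouds over the Southern Ocean and Arctic are poorly represented in climate
models partly because the sources of the ice-nucleating particles that
glaciate them are uncertain. Sea spray aerosol carries biogenic INMs; for
several marine eukaryotic microorganisms these are heat-stable
polysaccharides, and their ice activity collapses onto a common curve when
normalised to carbohydrate carbon mass (C-TCCHO) instead of sample volume.
`marinp` is for researchers who run droplet freezing assays on such
material and want to (a) reduce them to quantitative INM spectra, (b) fit a
physically bounded CNT parametrization, and (c) see what that
parametrization implies for INP concentrations on gridded aerosol fields,
compared against dust- and sea-spray-surface schemes and against
observations.

The model at the core: each INM carries a nucleation site with contact
angle θ drawn from a truncated normal N(μ<sub>θ</sub>, σ<sub>θ</sub>) on
(0, π]. A site nucleates within the effective exposure Δt at rate

> j(T, θ) = A<sub>kin</sub>(T) · exp(−[ΔF<sub>diff</sub>(T) + f(θ)·ΔG<sub>hom</sub>(T)] / k<sub>B</sub>T),
> &nbsp;&nbsp; f(θ) = (2 + cos θ)(1 − cos θ)² / 4

so the site density active at temperature T is
n<sub>m</sub>(T) = n<sub>max</sub> · ∫ p(θ)·[1 − e^(−j·a<sub>site</sub>·Δt)] dθ
— monotone with cooling and saturating at n<sub>max</sub>, unlike
log-linear fits, which extrapolate without bound. A droplet of volume V
from a sample with basis concentration c freezes with probability
f(T) = 1 − exp(−n<sub>m</sub>(T)·c·V/dilution); `cnt_fit()` maximises the
exact interval-censored binomial likelihood of the observed freeze counts
under this forward model.

## Worked example

Fit the CNT model to a bundled synthetic assay (two dilutions of one
cultured sample, 60 droplets each; the file is generated data, not a real
measurement):

```r
library(marinp)
assays <- read_assay_csv(system.file("extdata", "synthetic_assay.csv",
                                     package = "marinp"))
chem <- read_chemistry_csv(system.file("extdata", "synthetic_chemistry.csv",
                                       package = "marinp"))
fit <- cnt_fit(assays, chem, basis = "c_tccho", seed = 1)
fit
#> CNT contact-angle fit to freezing spectra
#>   sample: T-striatum-like  (2 assays, 120 droplets, 120 frozen in grid)
#>   basis: c_tccho   logLik: -405.12   converged: TRUE
#> CNT contact-angle parametrization
#>   mu_theta    = 1.6848 rad
#>   sigma_theta = 0.2912 rad
#>   n_max       = 6.535e+10 per g c_tccho
#>   a_site = 1e-14 m^2, delta_t = 60 s
```

The fitted mean contact angle (1.68 rad) and spread (0.29 rad) place the
freezing onset near −10 °C, and n<sub>max</sub> ≈ 6.5 × 10¹⁰ sites per
gram carbohydrate carbon is the ceiling the sample's INM population cannot
exceed however deep the supercooling. Predicted site densities:

```r
predict(fit, celsius_to_kelvin(c(-15, -20, -25)))
#>   temp_K temp_C      p_site         n_m
#> 1 258.15    -15 0.006140953   401335973
#> 2 253.15    -20 0.038096011  2489727355
#> 3 248.15    -25 0.165075226 10788329170
```

At −15 °C about 0.6 % of sites are active, giving
n<sub>m,C-TCCHO</sub> ≈ 4 × 10⁸ per g C. Applying the fit to an airborne
polysaccharide loading of 5 × 10⁻¹² kg m⁻³ (0.5 % of a typical
accumulation-mode sea salt mass):

```r
hsz25_inp(celsius_to_kelvin(-15), 5e-12, fit$params)
#> [1] 0.000803   # INP per litre of air
```

`run_demo_pipeline(seed = 1)` chains everything — simulated assays,
spectra, fit, a synthetic 24 × 12 aerosol globe, the three INP
parametrizations (polysaccharide, dust surface, sea-spray surface),
synthetic observations and FAC2/FAC10 evaluation — in under a minute.

## Layout

| path | contents |
| --- | --- |
| `R/spectra.R` | assay records, Vali spectra, normalisation, treatments |
| `R/thermo.R`, `R/cnt-model.R` | thermodynamic profile and CNT forward model |
| `R/fit.R` | `cnt_fit()` and its S3 methods, ensemble spread |
| `R/parametrizations.R` | mode geometry, dust/sea-spray/polysaccharide schemes |
| `R/fields.R` | gridded application, share maps, plain-text gridded I/O |
| `R/evaluation.R` | observation matching, FAC2/FAC10, improvement fraction |
| `R/synthetic.R` | seeded generators for every input, demo pipeline |
| `vignettes/cnt-inm-modelling.Rmd` | the methods vignette |

See the vignette for the model assumptions, numerical choices, and what
passing the synthetic-data tests does and does not demonstrate.
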