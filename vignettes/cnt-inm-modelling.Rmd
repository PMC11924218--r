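---
title: "Modelling marine polysaccharide ice-nucleating macromolecules with classical nucleation theory"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling marine polysaccharide ice-nucleating macromolecules with classical nucleation theory}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(marinp)
```

## The scientific problem

Primary ice formation in remote marine clouds is controlled by
ice-nucleating particles (INPs), whose concentrations over the Southern
Ocean and Arctic are low and poorly represented in models. Two INP sources
dominate the marine atmosphere: long-range-transported mineral dust and sea
spray aerosol (SSA) carrying organic material from the ocean's biosphere.
The biological ice activity of SSA is carried by ice-nucleating
macromolecules (INMs); for several marine eukaryotic microorganisms the
responsible INMs are heat-stable, filterable, hydrolysable polysaccharides,
and the ice nucleation activity of very different organisms collapses onto
a common curve once it is normalised to the carbohydrate carbon mass
(C-TCCHO) rather than to sample volume.

`marinp` implements that analysis chain end to end:

1. reduce droplet freezing assays to cumulative INM concentration spectra
   (Vali spectra) with exact binomial uncertainty;
2. normalise the spectra to a chemical basis to obtain site densities
   `n_m(T)` per gram of carbohydrate carbon;
3. fit a classical nucleation theory (CNT) model with a distribution of
   contact angles to those spectra by maximum likelihood (`cnt_fit()`, the
   package's central object);
4. apply the fitted polysaccharide parametrization, together with a dust
   surface scheme and a sea-spray surface scheme, to gridded aerosol
   fields;
5. evaluate modelled INP concentrations against observation records with
   factor-of-2/factor-of-10 agreement metrics and an improvement fraction.

A seeded synthetic-data module generates every input with known ground
truth, so the whole pipeline runs and is tested without any external data.

## Assay reduction

A cooling-ramp droplet assay dispenses `n` droplets of volume `V` from a
(possibly diluted) sample and records the temperature at which each
freezes. The frozen fraction at grid temperature `T` counts droplets
frozen *by* `T`; assuming INMs are Poisson-distributed over droplets, the
cumulative INM concentration per litre of undiluted sample is the Vali
transform

    n(T) = -ln(1 - f(T)) / V * dilution.

Design choices:

* **Confidence bounds** are Clopper-Pearson intervals on `f`, pushed
  through the same transform. Assays have on the order of 100 droplets;
  exact small-sample intervals matter there, and the transform is
  monotone, so endpoint transformation is exact.
* **Censoring.** `f = 1` bins have no finite cumulative value. They are
  flagged and reported at `f = (k - 0.5)/k` as an explicit lower bound;
  this keeps curves plottable without inventing information.
* **Units.** Kelvin everywhere internally; Celsius only in CSV columns
  with `_C` suffixes. One internal unit avoids sign errors in supercooling
  arithmetic.
* **Background.** A paired pure-water spectrum can be subtracted in
  n-space (floored at zero) via `subtract_background()`, but this is off
  by default: reported assay signals are usually *compared against*
  background rather than background-corrected, and subtraction is a
  decision the analyst should make explicitly.
* **Grid.** 0.5 K bins from 272.15 K down to 238.15 K, resolving the -8 to
  -25 degC onset window of marine biogenic INMs with room below for the
  dust-dominated regime.

## The CNT forward model

Each INM carries one nucleation site whose quality is described by a
contact angle `theta`. The heterogeneous nucleation rate per site is

    j(T, theta) = A_kin(T) exp(-[dF_diff(T) + f(theta) dG_hom(T)] / kB T)

with the spherical-cap compatibility factor
`f(theta) = (2 + cos theta)(1 - cos theta)^2 / 4` and the homogeneous
barrier `dG_hom = (16 pi / 3) sigma_iw^3 v_ice^2 / delta_mu^2`. The
thermodynamic ingredients are bundled in a named, versioned
`thermo_profile()`:

* `delta_mu(T)` from the Murphy & Koop (2005) saturation vapour pressures
  over supercooled water and ice (`kB T ln(p_liq/p_ice)`),
* `dF_diff(T)` as the Vogel-Fulcher-Tammann activation energy of water
  self-diffusion (E = 892 K, T0 = 118 K),
* `sigma_iw(T) = 0.0289 + 2.5e-4 (T - 273.15)` J m^-2,
* `A_kin(T) = (kB T / h) * 1e19` m^-2 s^-1.

Any internally consistent thermodynamic set supports fitting, because the
fitted parameters absorb overall scale; what matters is that the set is
pinned, named, and reported with every fit. The profile's validity range
(233.15-272.15 K) is enforced: evaluation outside it is an error, never an
extrapolation.

Sites differ: `theta` is drawn from a normal distribution with mean
`mu_theta` and spread `sigma_theta`, truncated to `(0, pi]` and
renormalised (a proper density keeps the activation probability at or
below 1 exactly; clipping would not). The per-site activation probability
by temperature `T` is

    P_site(T) = Int p(theta) [1 - exp(-j(T, theta) a_site delta_t)] dtheta

and the site density curve is `n_m(T) = n_max P_site(T)`: monotone with
cooling and saturating at `n_max`. This built-in plateau is the model
family's key advantage over log-linear fits, which extrapolate without
bound outside the measured range.

`a_site` (default 1e-14 m^2) and `delta_t` (default 60 s, one 1-K bin at a
1 K/min cooling ramp) trade off exactly against `mu_theta` and `n_max`;
they are therefore fixed, stored in every `cnt_params` object, and printed
with every fit.

### Numerics of the activation integral

The integrand switches from ~1 to ~0 across a narrow activation front at
the angle `theta*(T)` where `j a_site delta_t = 1`. Two properties make an
accurate fixed-cost rule possible: the compatibility factor has the closed
form `f(theta) = (cos^3 theta - 3 cos theta + 2)/4`, so `theta*` is
available analytically by inverting a depressed cubic, and the front width
is `w = kB T / (dG_hom f'(theta*))`, also analytic. The integral is
evaluated by composite Gauss-Legendre quadrature (64 nodes per panel) with
panel breaks at `theta* +- 6w`, `theta* +- 30w` and `mu +- 8 sigma` over
the full `(0, pi]` support. The tests validate this rule against a
100,001-node Simpson brute force to better than 1e-8 relative (observed:
~1e-15) for polysaccharide-like, dust-like and narrow-spread parameter
sets. A flat 200-node rule over `mu +- 6 sigma` - the obvious first choice
- resolves the ~0.01 rad front only to ~1e-3 and was rejected for that
reason.

Degenerate inputs: `sigma_theta -> 0` recovers the single-angle model
`1 - exp(-j(T, mu_theta) a delta_t)` (tested at 1e-6); temperatures with
no supercooling give `j = 0` and `P = 0`; probabilities are clamped to
`[0, 1]` against roundoff.

## Fitting: `cnt_fit()`

The data enter as per-bin freeze counts on the grid. The objective is the
exact interval-censored likelihood: a droplet freezing in bin
`(T_s, T_{s-1}]` contributes `F(T_s) - F(T_{s-1})` with
`F(T) = 1 - exp(-n_m(T) c V / dilution)`, and droplets still liquid at the
cold end contribute the survival probability. This is the correct
factorisation of the binomial likelihood of frozen counts (cumulative bins
are nested, so treating them as independent binomials would double-count
droplets) and it handles `f -> 0` and fully-frozen `f -> 1` bins without
ad hoc weighting. Dilution series of one sample are fitted jointly.

Optimisation is over `(mu_theta, log sigma_theta, log10 n_max)` -
unconstrained transforms enforce positivity and condition the problem. The
likelihood is multi-modal in `(mu, sigma)`, so eight starts are used:
`mu_theta` in {1.2, 1.6, 2.0, 2.4} rad crossed with two `log10 n_max`
guesses read off the empirical spectrum's most informative bins, each with
seed-controlled jitter. A cheap exploration stage (Nelder-Mead, reduced
quadrature accuracy) ranks the starts and the best candidate is polished
at full accuracy. On synthetic data with known truth (300 droplets x 3
dilutions) the recovered `mu_theta` is within 0.1 rad and `log10 n_max`
within 0.3 in over 90 % of seeded replicates; typical errors are an order
of magnitude smaller.

Uncertainties come from a seeded parametric bootstrap (resimulate the
fitted design from the fitted parameters, refit): droplet counts are too
small for asymptotic covariances. The production recommendation is
`n_boot = 200`; the default is 0 so that exploratory fits stay fast, and
`summary()` says explicitly when no bootstrap has been run.

`ensemble_spread()` quantifies the normalisation argument: organisms
sharing a C-TCCHO-basis truth but spanning three orders of magnitude in
carbohydrate concentration show a per-volume spread of ~3 orders at -15
degC that collapses below one order on the C-TCCHO basis. This collapse -
and not any absolute activity level - is the evidence that the chemical
measure carries the activity.

## From parametrization to gridded INP fields

Three parametrizations are applied to aerosol fields:

* **Polysaccharide (HSZ25-style).** Airborne polysaccharide mass is a
  fixed fraction of sea salt mass per mode (0.5 % soluble accumulation,
  0.1 % coarse; bounds 0.05 % and 0.5 % in both modes), converted to
  carbohydrate carbon with `carbon_fraction = 0.40` (glucan-like CH2O
  stoichiometry ~0.44, rounded conservatively - an explicit assumption
  surfaced in the scenario object), then multiplied by the fitted
  `n_m,C-TCCHO(T)`. Co-emission with sea salt is implicit in the mass
  fraction.
* **Dust (N15-style).** Surface-area based, using the same CNT machinery
  on an area basis. The shipped profile is named `n15.synthetic.v1`:
  representative values reproducing published desert-dust site-density
  magnitudes, not a transcription of the original coefficients, and fully
  configurable.
* **Sea spray (M18).** The published exponential surface site density
  `n_s(T) = exp(-0.545 Tc + 1.0125)` m^-2, validity -26 to -5 degC. The
  scheme is unbounded in its raw form, so out-of-range evaluation errors
  unless `extrapolation = "clamp"` is requested explicitly.

Mode surface areas come from lognormal mode geometry
(`d_g = (6M / pi rho N)^{1/3} exp(-1.5 ln^2 sigma_g)`,
`S = N pi d_g^2 exp(2 ln^2 sigma_g)`), with declared defaults
`sigma_g = 1.59/2.0` (accumulation/coarse) and densities 2200/2650 kg m^-3
(sea salt/dust).

Only the lowermost model layer is represented. INP fields are computed per
time step and averaged over the record; since each scheme is linear in its
aerosol proxy at fixed temperature, this equals applying the scheme to the
time-mean proxy, which the implementation exploits. Sea-salt-derived INPs
are zero over land; dust INPs are kept everywhere. The polysaccharide
share map `100 poly / (poly + dust)` is masked where both schemes are
zero.

Gridded I/O uses a documented long-format CSV dialect
(`write_aerosol_csv()` / `read_aerosol_csv()`), which keeps the whole
artifact plain-text and round-trips exactly.

## Evaluation

Observations are paired with the great-circle-nearest grid cell and the
nearest evaluated activation temperature within 0.5 K (activation
temperatures are continuous, model temperatures discrete; beyond 0.5 K the
record is skipped and counted). Time-mean model values are compared with
instantaneous observations deliberately: over remote oceans the proxies
show no strong seasonal cycle and short-term variability averages out.
FAC2/FAC10 are the fractions of pairs within a factor of 2/10
(symmetric ratio; a ratio exactly at the factor counts as within; pairs
with zeros are excluded and reported, because the ratio metric is
undefined at zero). The improvement fraction

    F = (FAC10_dust+poly - FAC10_dust) / (FAC10_dust+seaspray - FAC10_dust)

asks how much of the agreement gained by a generic sea-spray surface
scheme is explained when the added marine INPs are attributed to
polysaccharides alone; it can exceed 1 and is flagged undefined when the
sea-spray scheme added nothing.

## The synthetic-data module

`sim_config()` fixes a seed and the generating truth; all generators are
exactly reproducible and each derives an independent stream from the
configured seed (assays, fields and observations use distinct offsets, so
regenerating one input does not perturb another).

* **Assays** (`simulate_assay()`): site counts are Poisson with mean
  `n_max c V / dilution`; angles are drawn from the truncated normal; each
  site's freezing temperature is sampled by inverse transform from the
  forward model's activation CDF along the cooling ramp - per grid step,
  the site nucleates with the increment of the cumulative hazard
  `j(T) a_site delta_t`. Simulator and analytic model therefore agree
  exactly in distribution by construction; a cooling-rate-resolved hazard
  integral would differ from the single-exposure model only by a
  reinterpretation of `delta_t`, which is pinned anyway. A 10,000-droplet
  run reproduces the analytic curve within pointwise 95 % binomial bands
  at well over 95 % of bins.
* **Fields** (`generate_fields()`): synthetic continents from seeded
  circular land masses (biased to the northern hemisphere); sea salt over
  ocean with a storm-belt latitude profile near 2e-9 kg m^-3; dust as
  plumes decaying with a 2000 km scale from land sources, ~30x stronger in
  the north; smooth lognormal AR(1) time variability; mode numbers derived
  from the masses through the mode geometry, so surface-area inversion is
  exact. The default globe is 24 x 12 cells at 6-hourly resolution over 30
  days - small enough that the full pipeline runs in well under a minute
  of field arithmetic, while the hourly/annual pathway is the same code on
  bigger arrays.
* **Observations** (`generate_observations()`): ocean cells and evaluated
  activation temperatures inside the window are sampled uniformly, truth
  is read from a chosen model variant, and lognormal noise
  `exp(N(0, sigma))` with `sigma = ln 3` is applied. Temperatures are
  drawn from the *evaluated* levels (not continuously) so that noise-free
  observations reproduce the model truth exactly - the closure property
  the evaluation tests rely on.

What the generators do *not* emulate: real meteorology or seasonality,
emission physics, campaign-specific sampling biases, instrument detection
limits, or the spatial correlation structure of real aerosol fields.
Passing tests on synthetic data therefore demonstrate the correctness of
the statistical machinery and the internal consistency of the pipeline -
not the field validity of any particular parametrization value.

## Reference parameter values

The shipped polysaccharide reference `hsz25_params()` (`mu_theta = 1.75`
rad, `sigma_theta = 0.30` rad, `n_max = 1e11` per g C) is a synthetic
reference set, chosen once so that freezing onset falls in the -10 to -18
degC window characteristic of marine microbial INMs and the implied INP
concentrations track the sea-spray surface scheme within about an order of
magnitude between -15 and -25 degC. It is the default the application
layer uses when no fit is supplied; the intended workflow is to fit your
own assay data and pass `fit$params` onward, which is exactly what
`run_demo_pipeline()` does.

## Problem sizes and limitations

The test suite and the acceptance script use desk-scale sizes chosen as
the package's own defaults: 10,000 droplets for Monte-Carlo/analytic
agreement, 20 replicates of 300 droplets x 3 dilutions for parameter
recovery, 4 organisms for the spread-collapse construction, and the
24 x 12 synthetic globe for the application and evaluation stages.

Known limitations: no isothermal (time-resolved) freezing analysis beyond
the fixed effective exposure; no immersion-vs-deposition mode distinction;
no dynamic polysaccharide emission modelling (the mass-fraction scenario
is deliberately static); single-model-family fitting (no selection against
e.g. log-linear proteinaceous alternatives); and the N15-style dust
coefficients are representative stand-ins, so absolute dust INP levels -
and with them absolute share maps - carry that uncertainty even though
every structural property (saturation, monotonicity, linearity) holds.
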