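---
title: "Modelling hypoxia effects on estuarine macrobenthos: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling hypoxia effects on estuarine macrobenthos: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(benthox)
```

## The problem and the modelling stance

Seasonal hypoxia (dissolved oxygen, DO, at or below 2 mg O~2~ l^-1^)
develops in many stratified estuaries in late spring and persists into
early autumn. Sediment macrofauna are sessile: when bottom-water
oxygen collapses they cannot leave, and community biomass falls
sharply below fairly well-defined oxygen concentrations. `benthox`
takes the deliberately minimal route to quantifying that loss: oxygen
is *forced* (read from data or synthesized), not simulated by a
hydrodynamic–biogeochemical model, and the ecosystem is reduced to
the three biomass pools that matter for benthic–pelagic energy
transfer — phytoplankton `P`, zooplankton `M` (both g C m^-3^) and
macrobenthos `B` (g C m^-2^). The benefit of this minimalism is that
the oxygen dose–response, the part that carries the scientific claim,
can be constrained directly by field data and examined in isolation.

## Governing equations

With daily forward-Euler steps (`run_year()`, 365 steps of
$\Delta t = 1$ d):

$$\frac{dP}{dt} = (G - R - W_a)\,P - PR, \qquad
G = P^b_m\,\theta_P^{T-T_{ref}}\,
\frac{\mathrm{PAR}}{K_I + \mathrm{PAR}}\,
\frac{\mathrm{DIN}}{K_N + \mathrm{DIN}},\quad PR = \mathrm{Phtl}\cdot M P$$

$$\frac{dM}{dt} = (G_z - BM_z - M_z)\,M - PR_z, \qquad
G_z = G_z^{max}\,\theta_Z^{T-T_{ref}}\frac{P}{K_{gz}+P},\quad
PR_z = \mathrm{PHTlz}\cdot M^2$$

$$\frac{dB}{dt} = \alpha I - r\,Z(\mathrm{DO})\,\theta_B^{T-T_{ref}} B
- \beta B^2 - m B$$

with benthic ingestion
$I = I_0\,\theta_B^{T-T_{ref}}\,Z(\mathrm{DO})\,B\,F/(K_1 m_2 + F)$ on
the total available food $F = \mathrm{POC} + (P + M)\,h$ (a single
sediment organic-carbon pool plus water-column plankton mapped through
the coupling depth $h$), predation closure
$\beta = \hat\beta\,\theta_\beta^{T-T_{ref}}\,
\mathrm{DO}/(K_{DO}+\mathrm{DO})$, and hypoxia-induced mortality
$m = m_0\,(1 - Z'(\mathrm{DO}))$.

Oxygen acts through three channels:

1. **Zooplankton mortality** $M_z = MZERO_z\,(1 - DOREF/DOCRIT_z)$
   with $DOREF = \min(\mathrm{DO}, DOCRIT_z)$ and
   $DOCRIT_z = 2$ mg O~2~ l^-1^: zero at and above the threshold,
   maximal ($MZERO_z$) at anoxia, linear and continuous in between
   (`zoo_hypoxic_mortality()`).
2. **Macrobenthic function** (ingestion and respiration) is scaled by
   the logistic $Z(\mathrm{DO})$ anchored at the oxygen levels of
   50 % (`do_gx`) and 25 % (`do_qx`) function (`z_function()`); the
   implied steepness is $k = \ln 3/(do_{gx} - do_{qx})$.
3. **Macrobenthic mortality** is governed by the empirically fitted,
   normalized sigmoid
   $Z'(\mathrm{DO}) = 1/(1 + a e^{-b\,\mathrm{DO}})$ (`z_prime()`):
   $m$ vanishes under normoxia and approaches $m_0$ at anoxia. $Z'$
   — not $Z$ — carries the mortality response because it is the
   quantity that can be estimated directly from paired
   oxygen–biomass field observations.

Nutrient recycling, sediment carbon diagenesis, a separate
suspension-feeder pool, and any feedback of the benthos on the
plankton are deliberately out of scope; the plankton feed the benthos
but not conversely.

## Estimating the dose–response

`fit_sigmoid()` estimates $(a, b, c)$ of the biomass-scale curve
$c/(1 + a e^{-b\,\mathrm{DO}})$ by bounded Levenberg–Marquardt
(through **minpack.lm**), and `normalize_sigmoid()` replaces the
amplitude with 1 to produce the modifier applied in the model.
Two estimator choices deserve explanation:

* **Loss scale.** Biomass observation error is multiplicative to a
  good approximation — replicate grabs scatter with a roughly
  constant coefficient of variation. The default loss is therefore
  squared error on $\log(\mathrm{biomass})$, which weights the
  curve's low-biomass rise (where $a$ and $b$ live) correctly. In
  simulation at the reference design (60 observations, CV 20 %),
  log-scale fitting recovers $a$, $b$, $c$ with median relative
  errors of about 7 %, 3 % and 4 % over 50 replicates, whereas
  absolute-scale least squares lets the plateau dominate and inflates
  the median error on $a$ to ~24 %. `log_residuals = FALSE` remains
  available for data containing zero-biomass (defaunated) records,
  which the log scale cannot accept.
* **Identifiability guards.** The curve is unidentifiable from
  one-sided designs, so the fitter refuses (with an explicit
  identifiability error, not a silent bad fit) data sets with fewer
  than 6 records, no hypoxic record (DO < 2), or no normoxic record
  (DO > 4). Starting values use crude logistic moment matching
  ($c \leftarrow \max$ biomass, $b \leftarrow 4/\mathrm{range(DO)}$,
  $a \leftarrow e^{b\,\mathrm{median(DO)}}$); bounds
  $a \le 10^{12}$, $b \le 100$ keep the optimizer in
  floating-point-safe territory.

## Default calibration and what each number means

Parent-model parameter values were not available, so the package
ships its own documented calibration (`model_parameters()`), chosen
once to produce a realistic lower-estuary annual cycle and the
qualitative hypoxia responses that field and laboratory work report:
bounded seasonal plankton dynamics with phytoplankton roughly an
order of magnitude above zooplankton biomass, macrobenthos averaging
a few g C m^-2^, collapse under sustained severe hypoxia, recovery
within weeks of reoxygenation, and near-equivalent outcomes at
0.5–1.0 mg O~2~ l^-1^. The notable choices:

* `mzero_b = 0.40` d^-1^: community biomass e-folds in ~2.5 days at
  anoxia, consistent with laboratory LT~50~ values of roughly 1–13
  days for the dominant opportunistic taxa of muddy estuarine
  bottoms.
* `default_zprime()` ($a = 38500$, $b = 8$): midpoint near
  1.3 mg O~2~ l^-1^ with the steep rise between ~1 and ~1.7 mg O~2~
  l^-1^. The shape expresses the field observation that biomass
  loss sets in below rather sharply defined oxygen levels; it also
  makes responses at 1.0 mg O~2~ l^-1^ and at anoxia nearly
  indistinguishable, as severity experiments show. `do_gx = 1.27`,
  `do_qx = 1.18` place the function response $Z$ in the same oxygen
  range.
* `kdo = 0.5` mg O~2~ l^-1^: predation saturates quickly with oxygen,
  so mild hypoxia (2 mg O~2~ l^-1^) barely relieves predation
  pressure while anoxia shuts it off entirely.
* `theta_beta = 1.13` versus `theta_b = 1.08`: predation is more
  temperature-sensitive than benthic metabolism. This produces the
  autumn predation release that lets macrobenthic biomass rebound
  *above* its pre-hypoxia level after reoxygenation — predators'
  metabolic demand falls with cooling water faster than the benthos'
  ingestion does.
* `biomass_floor = c(P = 0.001, M = 0.001, B = 0.2)`: a purely
  multiplicative model that reaches exactly zero can never recover,
  but defaunated estuarine sediments are recolonised within weeks by
  planktonic larvae settling from the water column. The benthic
  floor of 0.2 g C m^-2^ (roughly 5 % of the annual mean) is a proxy
  for that recruitment stock plus juveniles below the sampling sieve;
  the plankton floors stand for immigration with water exchange. An
  infinitesimal floor (say 10^-6^) would be equivalent to requiring
  net regrowth above 0.5 d^-1^ for the observed weeks-scale recovery,
  which is biologically implausible; the floor, not the growth rate,
  is the honest place to put recolonisation.
* `phtlz` enters a *quadratic* closure $PR_z = \mathrm{PHTlz}\,M^2$,
  representing a planktivore field that tracks zooplankton biomass.
  A linear closure leaves the phytoplankton–zooplankton pair
  neutrally stable, and under daily Euler stepping its oscillations
  grow without bound once hypoxia perturbs the grazers; the
  quadratic term is the standard stabilising choice in NPZ-type
  models.

All values are overridable programmatically or through flat YAML
config files (`read_params_config()`), so none of these choices is
load-bearing for users with their own calibration data.

## Forcing, scenarios, and conventions

`synthetic_climatology()` builds single-harmonic sinusoidal drivers
(temperature 16 ± 10 °C peaking on day 212; PAR 32 ± 22 mol photons
m^-2^ d^-1^ peaking near the solstice; DO drawn down from 7 to a
5 mg O~2~ l^-1^ summer minimum; late-winter DIN maximum). These are
synthetic stand-ins for a lower-Chesapeake-style climatology, not
transcriptions of any monitoring product. Optional multiplicative
noise (relative SD) is seed-controlled; the default is the smooth
deterministic cycle, matching the role of interpolated multi-year
mean forcing.

Scenario conventions (`do_scenario()`, `apply_do_scenario()`):
Julian-day windows with *inclusive* endpoints are held exactly at the
target DO; 3-day linear ramps sit *outside* the window on both sides
so that "60 days of hypoxia" means 60 days at target. Ramps
interpolate from the last unmodified day's value to the target, which
makes the operation idempotent. Years are always 365 days; leap days
are ignored. Where printed duration labels and day ranges disagree,
the day ranges are authoritative.

The integrator is fixed at one forward-Euler step per day to match
the daily-calculation design of the class of models this package
belongs to; state recorded for day $d$ is the value *before* that
day's step (day 1 is the initial condition). Initial conditions
default to modest mid-winter stocks (`default_init()`). After each
step states are clamped at the biomass floor; a non-finite derivative
aborts with the offending day and state.

## Verification metrics and sensitivity protocol

* `mpe()` — mean percent error — is implemented as the normalized
  mean absolute error $100\cdot\overline{|o-p|}/\bar o$, which is
  robust to near-zero individual observations; a per-point variant
  ($100\cdot\overline{|o-p|/o}$) is available. MPE has no single
  canonical definition, so the choice is stated here prominently.
* `rmsd()` is the plain root-mean-square deviation.
* `sensitivity_analysis()` implements the one-at-a-time ±20 %
  protocol: for each (state variable, parameter) pair it reruns the
  year and reports the RMS deviation of the perturbed from the base
  trajectory over all 365 days, the percent difference
  $100\cdot\mathrm{rms}/\overline{\mathrm{base}}$, and a sensitivity
  flag at the 10 % threshold. Under the default calibration,
  assimilation efficiency $\alpha$ is strongly sensitive (~24 %)
  while the ingestion limitation $K_1$ is insensitive (~1 %), because
  the default food supply saturates the Michaelis–Menten term — the
  benthos is energy-assimilation-limited, not food-limited.

## What the synthetic generators do and do not show

`gen_biomass_do_pairs()` draws oxygen values with deliberate
oversampling of the hypoxic range (half the points below 2 mg O~2~
l^-1^ by default — uniform sampling under-covers the sigmoid's rise)
and multiplies the truth curve by unit-mean lognormal noise.
`gen_observation_series()` emulates a biweekly May–October monitoring
program with additive Gaussian error clipped at zero. Passing tests
on these generators demonstrates *estimator correctness under the
stated error model* and *internal consistency of the pipeline*; it
does not demonstrate that real monitoring data satisfy the error
model, that a single-year climatology captures interannual
variability, or that the community-aggregated dose–response transfers
across systems with different species pools. Absolute verification
statistics obtained against any particular monitoring data set
travel with that data set and calibration, not with the package.

## Problem sizes

The shipped test-suite and acceptance runs use the year-long daily
model (365 steps; a full severity experiment is five runs plus
baseline), 50-replicate fit-recovery simulations at 60 observations
each, and property sweeps of a few hundred random configurations —
all sized so a complete check runs in well under a minute on one CPU.

## Known limitations

* Oxygen is forced, so feedbacks of the biota on oxygen are absent by
  design.
* The plankton do not lose biomass to benthic suspension feeding;
  energy flows to the benthos without a corresponding pelagic sink.
* A single aggregated macrobenthic pool cannot express
  taxon-specific hypoxia tolerance or succession during recovery;
  the floor-based recolonisation is a coarse proxy for larval supply
  dynamics.
* Forward Euler at $\Delta t = 1$ d slightly overestimates decay
  relative to the continuous solution (about 5 % after ten days at a
  loss rate of 0.1 d^-1^); this is an accepted property of the
  daily-step design, and a user needing the continuous limit can
  verify any run against a finer integrator since all rate functions
  are exported.
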