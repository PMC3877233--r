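# benthox

Seasonal hypoxia — dissolved oxygen (DO) at or below 2 mg O₂ l⁻¹ —
strips estuarine sediments of their macrofauna and interrupts the
energy flow from primary producers to demersal fish and epibenthic
predators. `benthox` is a biomass-based, continuous-time ecosystem
model of this process for a seasonally hypoxic estuary. It is aimed
at coastal ecosystem modellers and benthic ecologists who want to ask
*how much macrobenthic biomass is lost for a given duration, severity,
or rhythm of hypoxia*, with an empirically constrained dose–response
at the core instead of a hypothetical one.

## The model

Three state variables are advanced with daily forward-Euler steps over
a 365-day year under forced drivers (temperature *T*, irradiance PAR,
dissolved oxygen DO, sediment organic carbon POC, inorganic nitrogen
DIN):

```
dP/dt = (G − R − Wa)·P − PR                     phytoplankton, g C m⁻³
dM/dt = (Gz − BMz − Mz)·M − PRz                 zooplankton,    g C m⁻³
dB/dt = α·I − r·Z·B − β·B² − m·B                macrobenthos,   g C m⁻²
```

Growth terms are Monod-limited and temperature-scaled by Arrhenius
multipliers θ^(T−Tref). Oxygen enters three ways:

* **Zooplankton hypoxic mortality** `Mz = MZEROz·(1 − DOREF/DOCRITz)`,
  active only below the threshold DOCRITz = 2 mg O₂ l⁻¹
  (`DOREF = min(DO, DOCRITz)`).
* **Macrobenthic function** (ingestion *I*, respiration *r*) is
  throttled by the logistic `Z(DO)`, parameterized by the oxygen
  levels at 50 % (`DOgx`) and 25 % (`DOqx`) of maximum function.
* **Macrobenthic hypoxia-induced mortality** `m = m₀·(1 − Z′(DO))`
  is controlled by the package's centrepiece, the *normalized sigmoid
  dose–response*

  `Z′(DO) = 1 / (1 + a·e^(−b·DO))`,

  estimated from paired (DO, biomass) field observations by bounded
  nonlinear least squares (`fit_sigmoid()`), then normalized to a 0–1
  modifier (`normalize_sigmoid()`). Mortality is maximal at anoxia
  and vanishes under normoxia.

Predation on the benthos closes the system with
`β = β̂·θ^(T−Tref)·DO/(K_DO + DO)` — predators feed less in cold water
and abandon anoxic bottoms.

Scenario machinery reproduces a standard experimental design
(`scenario_table()`): S1–S3 vary sustained hypoxic duration (120, 60,
30 days at 0.5 mg O₂ l⁻¹), S4 applies intermittent hypoxia on a
14-day neap–spring rhythm, and S5–S9 vary severity (2.0 → 0.0 mg O₂
l⁻¹) over a fixed 60-day window (days 178–237), each window flanked
by 3-day linear DO ramps. Skill metrics (`mpe()`, `rmsd()`), a ±20 %
one-at-a-time sensitivity protocol (`sensitivity_analysis()`), and
synthetic-data generators (`synthetic_climatology()`,
`gen_biomass_do_pairs()`, `gen_observation_series()`) make the whole
pipeline runnable with no external data.

## Worked example

Fit the oxygen dose–response from synthetic field pairs, normalize it,
and compare a 60-day hypoxic summer against the normoxic baseline:

```r
library(benthox)

obs <- gen_biomass_do_pairs(sigmoid_params(a = 50, b = 2, c = 4),
                            n_obs = 60, noise_cv = 0.2, seed = 42)
fit <- fit_sigmoid(obs)
fit
#> Sigmoid biomass-oxygen fit (nonlinear least squares)
#>   a = 56.74, b = 2.005, c = 4.151  (midpoint 2.01 mg O2/l)
#>   n = 60, RSS = 1.879, converged: TRUE

zp <- normalize_sigmoid(fit)       # the 0-1 modifier Z'
fc <- synthetic_climatology()      # smooth lower-estuary annual cycle
p  <- model_parameters()

s2 <- run_scenario("S2", p, fc, sigmoid = zp)   # 60 d at 0.5 mg/l
summary(s2)
#> Scenario: S2
#> Annual state summaries (mean, sample SD, n):
#>  variable       mean        sd   n
#>         P 1.12376615 1.0905304 365
#>         M 0.07406679 0.0473022 365
#>         B 3.84113003 2.0574392 365
#> Hypoxic days (DO <= 2): 62; minimum DO 0.50 mg O2/l
#> Final state: P = 0.269, M = 0.016, B = 6.079

summarize_window(s2, 178, 237)     # inside the hypoxic window
#>   variable      mean         sd  n
#> 1        P 2.9909839 1.51375093 60
#> 2        M 0.1347862 0.02116636 60
#> 3        B 0.2715118 0.33898339 60
```

The fitted curve recovers the generating parameters (b within 0.3 %,
c within 4 %; a, the hardest to identify, within 14 %). During the
hypoxic window macrobenthic biomass collapses to a mean of
0.27 g C m⁻² — fifteen-fold below the annual mean — while
phytoplankton *rise* to ~3 g C m⁻³ (released from grazing as
zooplankton die) before the system recovers to its baseline path:
the final state on day 365 is identical to the baseline run's.
`plot(s2)` draws both panels with DO overlaid.

A thin CLI over the same functions ships in `inst/scripts/benthox`
(`scenarios`, `simulate`, `verify`, `sensitivity`, `make-fixtures`).

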