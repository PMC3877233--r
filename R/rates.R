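#' Arrhenius temperature multiplier
#'
#' `theta ^ (temp - t_ref)`: the standard exponential temperature
#' dependence of biological rates, equal to 1 at the reference
#' temperature and increasing with temperature for `theta > 1`.
#'
#' @param temp water temperature, deg C (vectorized).
#' @param theta Arrhenius coefficient, > 0 (typically 1.02-1.10).
#' @param t_ref reference temperature, deg C.
#' @return Dimensionless multipliers.
#' @examples
#' arrhenius(30, 1.07, 20)  # 1.07^10
#' @export
arrhenius <- function(temp, theta, t_ref = 20) {
  if (!is_number(theta) || theta <= 0) stop_config("theta must be positive")
  theta^(temp - t_ref)
}

#' Zooplankton hypoxic mortality
#'
#' Oxygen-induced zooplankton mortality, zero at and above the
#' threshold `docrit_z` (2 mg O2 l^-1 by default) and rising linearly
#' to `mzero_z` at anoxia:
#' `Mz = mzero_z * (1 - DOREF / docrit_z)` with
#' `DOREF = min(DO, docrit_z)`.  Continuous at the threshold.
#'
#' @param do_conc dissolved oxygen, mg O2 l^-1 (vectorized, >= 0).
#' @param params a [model_parameters()] object (uses `mzero_z`,
#'   `docrit_z`).
#' @return A list with components `mz` (mortality rate, d^-1) and
#'   `doref` (the clamped oxygen concentration, mg O2 l^-1).
#' @examples
#' zoo_hypoxic_mortality(1, model_parameters(mzero_z = 0.2))$mz  # 0.1
#' @export
zoo_hypoxic_mortality <- function(do_conc, params) {
  if (any(!is.finite(do_conc)) || any(do_conc < 0))
    stop_domain("dissolved oxygen must be finite and nonnegative")
  doref <- pmin(do_conc, params$docrit_z)
  mz <- params$mzero_z * (1 - doref / params$docrit_z)
  list(mz = mz, doref = doref)
}

#' Predation rate on macrobenthos
#'
#' Temperature- and oxygen-dependent quadratic closure rate
#' `beta = beta_hat * theta_beta^(T - t_ref) * DO / (kdo + DO)`
#' (m^2 (g C)^-1 d^-1).  Predation shuts off at anoxia (predators
#' leave) and saturates at the temperature-adjusted reference rate
#' under high oxygen.
#'
#' @param temp water temperature, deg C.
#' @param do_conc dissolved oxygen, mg O2 l^-1, >= 0 (vectorized).
#' @param params a [model_parameters()] object (uses `beta_hat`,
#'   `theta_beta`, `t_ref`, `kdo`).
#' @return Predation rate(s), m^2 (g C)^-1 d^-1.
#' @export
predation_rate <- function(temp, do_conc, params) {
  if (any(!is.finite(do_conc)) || any(do_conc < 0))
    stop_domain("dissolved oxygen must be finite and nonnegative")
  params$beta_hat * arrhenius(temp, params$theta_beta, params$t_ref) *
    do_conc / (params$kdo + do_conc)
}

# saturating limitation x / (k + x), defined as 0 when both are 0
monod <- function(x, k) {
  d <- k + x
  ifelse(d > 0, x / d, 0)
}

#' Phytoplankton derivative
#'
#' Daily rate of change of phytoplankton biomass:
#' `dP/dt = (G - R - Wa) * P - PR`, with growth
#' `G = pbm * theta_p^(T - t_ref) * PAR/(light_k + PAR) *
#' DIN/(kdin + DIN)` and grazing `PR = phtl * M * P`.
#'
#' @param state list with components `P`, `M`, `B`.
#' @param forcing_record one-row forcing (list or data.frame row) with
#'   `temperature`, `par`, `din` (and the other forcing fields).
#' @param params a [model_parameters()] object.
#' @return List with `deriv` (g C m^-3 d^-1) and `diagnostics`
#'   (list with `G`, `PR`).
#' @export
phytoplankton_derivative <- function(state, forcing_record, params) {
  tmul <- arrhenius(forcing_record$temperature, params$theta_p, params$t_ref)
  g <- params$pbm * tmul *
    monod(forcing_record$par, params$light_k) *
    monod(forcing_record$din, params$kdin)
  pr <- params$phtl * state$M * state$P
  dP <- (g - params$resp_p - params$wa) * state$P - pr
  list(deriv = dP, diagnostics = list(G = g, PR = pr))
}

#' Zooplankton derivative
#'
#' Daily rate of change of zooplankton biomass:
#' `dM/dt = (Gz - BMz - Mz) * M - PRz`, with saturating growth on
#' phytoplankton `Gz = gz_max * theta_z^(T - t_ref) * P/(kgz + P)`,
#' temperature-scaled basal metabolism, oxygen-induced mortality `Mz`
#' from [zoo_hypoxic_mortality()] and a quadratic closure
#' `PRz = phtlz * M^2` (an implicit planktivore field that tracks
#' zooplankton biomass).
#'
#' @inheritParams phytoplankton_derivative
#' @return List with `deriv` (g C m^-3 d^-1) and `diagnostics`
#'   (`Gz`, `BMz`, `Mz`, `doref`, `PRz`).
#' @export
zooplankton_derivative <- function(state, forcing_record, params) {
  tmul <- arrhenius(forcing_record$temperature, params$theta_z, params$t_ref)
  gz <- params$gz_max * tmul * monod(state$P, params$kgz)
  bmz <- params$bmz * tmul
  hyp <- zoo_hypoxic_mortality(forcing_record$do_conc, params)
  prz <- params$phtlz * state$M^2
  dM <- (gz - bmz - hyp$mz) * state$M - prz
  list(deriv = dM,
       diagnostics = list(Gz = gz, BMz = bmz, Mz = hyp$mz,
                          doref = hyp$doref, PRz = prz))
}

#' Macrobenthos derivative
#'
#' Daily rate of change of macrobenthic biomass:
#' `dB/dt = alpha * I - r * Z * B - beta * B^2 - m * B`, where
#' \itemize{
#'   \item assimilated ingestion
#'     `I = i0 * theta_b^(T - t_ref) * Z(DO) * B * F / (kmn1 * m2 + F)`
#'     feeds on the total available food
#'     `F = POC + (P + M) * depth_h` (a single sediment organic-carbon
#'     pool plus water-column plankton mapped through the coupling
#'     depth);
#'   \item respiration `r` and ingestion are both throttled by the
#'     oxygen function [z_function()] (Z);
#'   \item predation uses the quadratic closure [predation_rate()];
#'   \item hypoxia-induced mortality `m = mzero_b * (1 - Z'(DO))` is
#'     controlled solely by the empirically fitted, normalized sigmoid
#'     [z_prime()] (Z'), vanishing under normoxia and maximal at
#'     anoxia.
#' }
#'
#' @inheritParams phytoplankton_derivative
#' @param sigmoid a [sigmoid_params()] object: the normalized Z' curve.
#' @return List with `deriv` (g C m^-2 d^-1) and `diagnostics`
#'   (`Z`, `Zprime`, `beta`, `m`, `PM`, `ration`).
#' @export
macrobenthos_derivative <- function(state, forcing_record, params, sigmoid) {
  do_conc <- forcing_record$do_conc
  z <- z_function(do_conc, params$do_gx, params$do_qx)
  zp <- z_prime(do_conc, sigmoid)
  tmul <- arrhenius(forcing_record$temperature, params$theta_b, params$t_ref)

  pm <- state$P + state$M
  food <- forcing_record$poc + pm * params$depth_h
  ration <- params$i0 * tmul * z * monod(food, params$kmn1 * params$m2)

  gain <- params$alpha * ration * state$B
  resp <- params$resp_b * tmul * z * state$B
  beta <- predation_rate(forcing_record$temperature, do_conc, params)
  pred <- beta * state$B^2
  m <- params$mzero_b * (1 - zp)
  mort <- m * state$B

  dB <- gain - resp - pred - mort
  list(deriv = dB,
       diagnostics = list(Z = z, Zprime = zp, beta = beta, m = m,
                          PM = pm, ration = ration))
}
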