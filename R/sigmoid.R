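#' Sigmoid oxygen dose-response parameters
#'
#' Parameters of the logistic curve `c / (1 + a * exp(-b * DO))`
#' relating dissolved oxygen to macrobenthic biomass (unnormalized
#' form) or to the dimensionless 0-1 modifier Z' (normalized form,
#' `c = 1`).
#'
#' @param a dimensionless shape offset, > 0.  The curve's midpoint sits
#'   at `DO = log(a) / b`.
#' @param b steepness, l (mg O2)^-1, > 0.
#' @param c amplitude (asymptotic biomass, g C m^-2) for the
#'   unnormalized curve; 1 for the normalized modifier.
#' @return A list of class `"sigmoid_params"`.
#' @seealso [z_prime()], [unnormalized_sigmoid()], [fit_sigmoid()]
#' @examples
#' sp <- sigmoid_params(a = 100, b = 3)
#' z_prime(2, sp)
#' @export
sigmoid_params <- function(a, b, c = 1) {
  if (!is_number(a) || a <= 0) stop_config("sigmoid 'a' must be positive")
  if (!is_number(b) || b <= 0) stop_config("sigmoid 'b' must be positive")
  if (!is_number(c) || c <= 0) stop_config("sigmoid 'c' must be positive")
  structure(list(a = a, b = b, c = c), class = "sigmoid_params")
}

#' @export
print.sigmoid_params <- function(x, ...) {
  cat(sprintf("Sigmoid DO response: %s / (1 + %.6g * exp(-%.6g * DO))\n",
              format(x$c), x$a, x$b))
  cat(sprintf("  midpoint (50%% of maximum) at DO = %.3f mg O2/l\n",
              log(x$a) / x$b))
  invisible(x)
}

#' Default normalized oxygen dose-response Z'
#'
#' The package's default calibration of the normalized sigmoid modifier
#' used for hypoxia-induced macrobenthic mortality: midpoint near
#' 1.3 mg O2 l^-1 with a steep rise between roughly 1 and 1.7 mg O2
#' l^-1, reflecting field evidence that macrobenthic mortality sets in
#' below rather sharply defined oxygen concentrations.  Override by
#' fitting your own curve with [fit_sigmoid()] and
#' [normalize_sigmoid()].
#'
#' @return A `"sigmoid_params"` object with `c = 1`.
#' @export
default_zprime <- function() sigmoid_params(a = 38500, b = 8, c = 1)

#' Macrobenthic function response to oxygen (Z)
#'
#' Logistic response of macrobenthic physiological function
#' (respiration and ingestion) to dissolved oxygen, parameterized by
#' the oxygen concentrations at which function is 50% (`do_gx`) and
#' 25% (`do_qx`) of maximum:
#' `Z(DO) = 1 / (1 + exp(-k * (DO - do_gx)))` with
#' `k = log(3) / (do_gx - do_qx)`, so that `Z(do_gx) = 1/2` and
#' `Z(do_qx) = 1/4` exactly.
#'
#' @param do_conc dissolved oxygen, mg O2 l^-1 (vectorized).
#' @param do_gx DO at 50% of maximum function.
#' @param do_qx DO at 25% of maximum function; must be `< do_gx`.
#' @return Values in (0, 1).
#' @examples
#' z_function(c(1, 1.5, 2), do_gx = 2, do_qx = 1.5)
#' @export
z_function <- function(do_conc, do_gx, do_qx) {
  if (!is_number(do_gx) || !is_number(do_qx) || do_qx >= do_gx)
    stop_config("do_qx must be smaller than do_gx")
  k <- log(3) / (do_gx - do_qx)
  1 / (1 + exp(-k * (do_conc - do_gx)))
}

#' Normalized oxygen dose-response (Z')
#'
#' The dimensionless 0-1 sigmoid modifier
#' `Z'(DO) = 1 / (1 + a * exp(-b * DO))` that controls hypoxia-induced
#' macrobenthic mortality: mortality is maximal where Z' is near 0
#' (anoxia) and vanishes where Z' saturates at 1 (normoxia).
#'
#' @param do_conc dissolved oxygen, mg O2 l^-1 (vectorized, >= 0).
#' @param params a [sigmoid_params()] object (its `c` is ignored here).
#' @return Values in (0, 1), nondecreasing in `do_conc`.
#' @examples
#' z_prime(2, sigmoid_params(a = 100, b = 3))  # ~0.8014
#' @export
z_prime <- function(do_conc, params) {
  stopifnot(inherits(params, "sigmoid_params"))
  if (any(!is.finite(do_conc)) || any(do_conc < 0))
    stop_domain("dissolved oxygen must be finite and nonnegative")
  1 / (1 + params$a * exp(-params$b * do_conc))
}

#' Unnormalized sigmoid biomass-oxygen curve
#'
#' The fitted biomass-scale curve `c / (1 + a * exp(-b * DO))`
#' (g C m^-2); equal to `c * z_prime(DO)` at every oxygen value.
#'
#' @inheritParams z_prime
#' @return Biomass values in (0, c).
#' @export
unnormalized_sigmoid <- function(do_conc, params) {
  params$c * z_prime(do_conc, params)
}
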