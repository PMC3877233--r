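#' Fit the sigmoid oxygen dose-response to field observations
#'
#' Estimates the parameters (a, b, c) of the biomass-oxygen curve
#' `biomass = c / (1 + a * exp(-b * DO))` from paired observations by
#' bounded nonlinear least squares (Levenberg-Marquardt via
#' \pkg{minpack.lm}).  Because biomass observation error is typically
#' multiplicative (a roughly constant coefficient of variation), the
#' default loss is squared error on the log scale, which weights the
#' curve's low-biomass rise -- where the shape parameters live --
#' properly; it requires strictly positive biomass.  Set
#' `log_residuals = FALSE` for unweighted least squares on the
#' absolute biomass scale (use this when the data contain zero-biomass
#' records, e.g. defaunated samples).
#'
#' The fit refuses data that cannot identify the curve: fewer than 6
#' records, or observations that do not span both the hypoxic
#' (DO < 2 mg O2 l^-1) and normoxic (DO > 4) regimes, raise an
#' identifiability error rather than returning a silently bad fit.
#'
#' Starting values follow crude logistic moment matching unless
#' supplied: `c` from the maximum observed biomass, `b = 4 / range(DO)`
#' and `a = exp(b * median(DO))`.  Bounds keep the optimizer in
#' floating-point-safe territory: `a <= 1e12`, `b <= 100`.
#'
#' @param obs a data frame with columns `do_conc` (mg O2 l^-1, >= 0)
#'   and `biomass` (>= 0), e.g. from [read_biomass_do_csv()] or
#'   [gen_biomass_do_pairs()]; extra columns are ignored.
#' @param init optional [sigmoid_params()] starting values.
#' @param seed accepted for interface symmetry with the stochastic
#'   generators; the fit itself is deterministic given `obs` and
#'   `init`.
#' @param log_residuals minimize squared residuals of `log(biomass)`
#'   (the default) rather than of biomass itself.
#' @return An object of class `"zprime_fit"` with components `params`
#'   (a [sigmoid_params()]), `rss` (residual sum of squares on the
#'   fitting scale), `converged`, `n_obs`, `vcov` (parameter
#'   covariance, or `NULL` if unavailable) and the data used.
#'   Methods: `print`, `summary`, `coef`, `predict`, `plot`,
#'   `residuals`.
#' @examples
#' obs <- gen_biomass_do_pairs(truth = sigmoid_params(50, 2, 4),
#'                             n_obs = 40, noise_cv = 0.1, seed = 1)
#' fit <- fit_sigmoid(obs)
#' coef(fit)
#' @export
fit_sigmoid <- function(obs, init = NULL, seed = NULL,
                        log_residuals = TRUE) {
  obs <- as.data.frame(obs)
  if (!all(c("do_conc", "biomass") %in% names(obs)))
    stop_format("observations need columns 'do_conc' and 'biomass'")
  keep <- is.finite(obs$do_conc) & is.finite(obs$biomass)
  obs <- obs[keep, , drop = FALSE]
  if (any(obs$do_conc < 0) || any(obs$biomass < 0))
    stop_domain("do_conc and biomass must be nonnegative")
  if (nrow(obs) < 6L)
    stop_identifiability("need at least 6 observations to attempt a fit")
  if (min(obs$do_conc) >= 2)
    stop_identifiability(
      "no hypoxic observations (DO < 2 mg/l): sigmoid rise unidentifiable")
  if (max(obs$do_conc) <= 4)
    stop_identifiability(
      "no normoxic observations (DO > 4 mg/l): plateau unidentifiable")
  if (log_residuals && any(obs$biomass <= 0))
    stop_domain(paste0("log-scale fitting requires strictly positive ",
                       "biomass; use log_residuals = FALSE for data ",
                       "with zero-biomass records"))

  if (is.null(init)) {
    b0 <- 4 / diff(range(obs$do_conc))
    start <- list(a = exp(b0 * stats::median(obs$do_conc)), b = b0,
                  cc = max(obs$biomass))
  } else {
    stopifnot(inherits(init, "sigmoid_params"))
    start <- list(a = init$a, b = init$b, cc = init$c)
  }
  lower <- c(a = 1e-12, b = 1e-12, cc = 1e-12)
  upper <- c(a = 1e12, b = 100, cc = Inf)

  form <- if (log_residuals)
    log(biomass) ~ log(cc) - log1p(a * exp(-b * do_conc))
  else
    biomass ~ cc / (1 + a * exp(-b * do_conc))

  fit <- tryCatch(
    minpack.lm::nlsLM(form, data = obs, start = start,
                      lower = lower, upper = upper,
                      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) e)
  if (inherits(fit, "error"))
    stop_numerical(paste0("sigmoid fit failed: ", conditionMessage(fit)))

  est <- stats::coef(fit)
  converged <- isTRUE(fit$convInfo$isConv)
  vc <- tryCatch(stats::vcov(fit), error = function(e) NULL)
  structure(list(
    params = sigmoid_params(est[["a"]], est[["b"]], est[["cc"]]),
    rss = stats::deviance(fit),
    converged = converged,
    n_obs = nrow(obs),
    vcov = vc,
    log_residuals = log_residuals,
    data = obs
  ), class = "zprime_fit")
}

#' Normalize a fitted sigmoid to the 0-1 modifier Z'
#'
#' Replaces the fitted amplitude with 1 (leaving `a` and `b`
#' untouched), turning the biomass-scale curve into the dimensionless
#' oxygen modifier whose supremum is 1.  Idempotent; accepts either a
#' converged `"zprime_fit"` or a bare [sigmoid_params()].
#'
#' @param fit a `"zprime_fit"` (must have converged) or
#'   [sigmoid_params()].
#' @return A [sigmoid_params()] with `c = 1`.
#' @export
normalize_sigmoid <- function(fit) {
  if (inherits(fit, "sigmoid_params"))
    return(sigmoid_params(fit$a, fit$b, 1))
  stopifnot(inherits(fit, "zprime_fit"))
  if (!isTRUE(fit$converged))
    stop_numerical("cannot normalize an unconverged fit")
  sigmoid_params(fit$params$a, fit$params$b, 1)
}

#' @export
coef.zprime_fit <- function(object, ...) {
  c(a = object$params$a, b = object$params$b, c = object$params$c)
}

#' @export
predict.zprime_fit <- function(object, newdata = NULL, ...) {
  do_conc <- if (is.null(newdata)) object$data$do_conc
             else if (is.data.frame(newdata)) newdata$do_conc
             else newdata
  unnormalized_sigmoid(do_conc, object$params)
}

#' @export
residuals.zprime_fit <- function(object, ...) {
  object$data$biomass - predict(object)
}

#' @export
print.zprime_fit <- function(x, ...) {
  cat("Sigmoid biomass-oxygen fit (nonlinear least squares)\n")
  cat(sprintf("  a = %.4g, b = %.4g, c = %.4g  (midpoint %.2f mg O2/l)\n",
              x$params$a, x$params$b, x$params$c,
              log(x$params$a) / x$params$b))
  cat(sprintf("  n = %d, RSS = %.4g, converged: %s\n",
              x$n_obs, x$rss, x$converged))
  invisible(x)
}

#' @export
summary.zprime_fit <- function(object, ...) {
  se <- if (!is.null(object$vcov)) sqrt(diag(object$vcov)) else
    rep(NA_real_, 3)
  tab <- data.frame(estimate = unname(coef(object)), std_error = unname(se),
                    row.names = c("a", "b", "c"))
  structure(list(coefficients = tab, rss = object$rss,
                 n_obs = object$n_obs, converged = object$converged,
                 sigma = sqrt(object$rss / max(object$n_obs - 3, 1))),
            class = "summary.zprime_fit")
}

#' @export
print.summary.zprime_fit <- function(x, ...) {
  cat("Sigmoid biomass-oxygen fit\n\nCoefficients:\n")
  print(x$coefficients)
  cat(sprintf("\nRSS %.4g on %d observations (residual SE %.4g); converged: %s\n",
              x$rss, x$n_obs, x$sigma, x$converged))
  invisible(x)
}

#' @export
plot.zprime_fit <- function(x, ...) {
  graphics::plot(x$data$do_conc, x$data$biomass,
                 xlab = "DO (mg O2/l)", ylab = "biomass (g C m-2)",
                 main = "Sigmoid biomass-oxygen fit", ...)
  grid_do <- seq(0, max(x$data$do_conc), length.out = 200)
  graphics::lines(grid_do, unnormalized_sigmoid(grid_do, x$params),
                  col = "firebrick", lwd = 2)
  invisible(x)
}

#' Read paired oxygen-biomass observations from CSV
#'
#' Columns `do_conc` and `biomass` are required; `site` and `date` are
#' carried through when present.
#'
#' @param path file path.
#' @return A data frame of class `"biomass_do_obs"`.
#' @export
read_biomass_do_csv <- function(path) {
  if (!file.exists(path)) stop_format(paste0("no such file: ", path))
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("do_conc", "biomass") %in% names(x)))
    stop_format("CSV needs columns 'do_conc' and 'biomass'")
  if (!is.numeric(x$do_conc) || !is.numeric(x$biomass))
    stop_format("'do_conc' and 'biomass' must be numeric")
  if (any(x$do_conc < 0, na.rm = TRUE) || any(x$biomass < 0, na.rm = TRUE))
    stop_format("'do_conc' and 'biomass' must be nonnegative")
  class(x) <- c("biomass_do_obs", "data.frame")
  x
}

#' Write a fit report as a key-value text file
#'
#' @param fit a `"zprime_fit"`.
#' @param path file path (YAML key-value format).
#' @return `path`, invisibly.
#' @export
write_fit_report <- function(fit, path) {
  stopifnot(inherits(fit, "zprime_fit"))
  yaml::write_yaml(list(a = fit$params$a, b = fit$params$b,
                        c = fit$params$c, rss = fit$rss,
                        n_obs = fit$n_obs, converged = fit$converged),
                   path)
  invisible(path)
}
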