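#' Mean percent error
#'
#' Normalized mean absolute error,
#' `MPE = 100 * mean(|obs - pred|) / mean(obs)` (percent), robust to
#' individual near-zero observations.  Set `per_point = TRUE` for the
#' per-observation variant `100 * mean(|obs - pred| / obs)` (requires
#' strictly positive observations).
#'
#' @param observed,predicted numeric vectors of equal length >= 1.
#' @param per_point use the per-point relative error variant.
#' @return A percentage (>= 0; 0 iff the series are identical).
#' @examples
#' mpe(c(2, 4), c(1, 5))  # 33.33
#' @export
mpe <- function(observed, predicted, per_point = FALSE) {
  check_paired(observed, predicted)
  if (per_point) {
    if (any(observed <= 0))
      stop_domain("per-point MPE requires strictly positive observations")
    return(100 * mean(abs(observed - predicted) / observed))
  }
  mo <- mean(observed)
  if (mo <= 0) stop_domain("mean of observed values must be positive")
  100 * mean(abs(observed - predicted)) / mo
}

#' Root mean square deviation
#'
#' `RMSD = sqrt(mean((obs - pred)^2))`, in the units of the inputs.
#'
#' @inheritParams mpe
#' @return A nonnegative deviation; 0 iff the series are identical.
#' @examples
#' rmsd(c(2, 4), c(1, 5))  # 1
#' @export
rmsd <- function(observed, predicted) {
  check_paired(observed, predicted)
  sqrt(mean((observed - predicted)^2))
}

check_paired <- function(observed, predicted) {
  if (length(observed) != length(predicted))
    stop_domain(sprintf("length mismatch: %d observed vs %d predicted",
                        length(observed), length(predicted)))
  if (length(observed) < 1L)
    stop_domain("need at least one observation")
  if (any(!is.finite(observed)) || any(!is.finite(predicted)))
    stop_domain("observed and predicted values must be finite")
  invisible(TRUE)
}

#' Pair a simulation with an observation series
#'
#' Inner join of an observation series on day-of-year against the
#' daily trajectory of one state variable.  Observation days outside
#' 1..365 are dropped with a warning reporting how many were excluded.
#'
#' @param result a `"hypoxia_sim"` object.
#' @param obs a data frame with columns `day` and `value` (e.g. from
#'   [gen_observation_series()]); if it has a `variable` column, only
#'   rows matching `variable` are used.
#' @param variable one of `"P"`, `"M"`, `"B"`.
#' @return A data frame with columns `day`, `observed`, `predicted`.
#' @export
match_observations <- function(result, obs, variable = c("B", "P", "M")) {
  stopifnot(inherits(result, "hypoxia_sim"))
  variable <- match.arg(variable)
  obs <- as.data.frame(obs)
  if (!all(c("day", "value") %in% names(obs)))
    stop_format("observations need columns 'day' and 'value'")
  if ("variable" %in% names(obs))
    obs <- obs[obs$variable == variable, , drop = FALSE]
  out_of_range <- obs$day < 1 | obs$day > 365
  if (any(out_of_range)) {
    warning(sprintf("%d observation(s) outside days 1..365 excluded",
                    sum(out_of_range)))
    obs <- obs[!out_of_range, , drop = FALSE]
  }
  if (nrow(obs) == 0L)
    stop_domain("no observations remain to match against the simulation")
  pred <- result$trajectory[[variable]][match(obs$day,
                                              result$trajectory$day)]
  data.frame(day = obs$day, observed = obs$value, predicted = pred)
}

#' Default sensitivity targets
#'
#' The (state variable, parameter) pairs examined by the one-at-a-time
#' protocol: growth and loss parameters that directly drive each state
#' variable -- maximum photosynthesis, settling and grazing for
#' phytoplankton; the predation closure for zooplankton; assimilation
#' efficiency and ingestion limitation for the macrobenthos.
#'
#' @return A data frame with columns `variable` and `parameter`.
#' @export
default_sensitivity_targets <- function() {
  data.frame(
    variable = c("P", "P", "P", "M", "B", "B"),
    parameter = c("pbm", "wa", "phtl", "phtlz", "alpha", "kmn1"))
}

#' One-at-a-time parameter sensitivity analysis
#'
#' Perturbs each target parameter by `+/- perturbation` (default 20%),
#' reruns the year, and reports for the paired state variable the RMS
#' deviation of the perturbed from the base trajectory over all 365
#' days, `rms = sqrt(mean((perturbed - base)^2))`, its percent
#' difference `100 * rms / mean(base)` relative to the base annual
#' mean, and whether the variable is deemed sensitive (percent
#' difference > 10).
#'
#' @param params a [model_parameters()] object (the base calibration).
#' @param forcing a [forcing_series()].
#' @param sigmoid a [sigmoid_params()] Z' curve.
#' @param init initial state.
#' @param targets data frame with columns `variable`, `parameter`;
#'   defaults to [default_sensitivity_targets()].
#' @param perturbation fractional perturbation (0.2 = +/-20%).
#' @return A data frame of class `"sensitivity_report"` with columns
#'   `variable`, `parameter`, `direction` (-1/+1), `rms`, `avg_rms`
#'   (mean of the two directions), `pct_diff`, `sensitive`.
#' @export
sensitivity_analysis <- function(params, forcing,
                                 sigmoid = default_zprime(),
                                 init = default_init(),
                                 targets = default_sensitivity_targets(),
                                 perturbation = 0.2) {
  stopifnot(inherits(params, "model_parameters"))
  targets <- as.data.frame(targets)
  if (!all(c("variable", "parameter") %in% names(targets)))
    stop_config("targets need columns 'variable' and 'parameter'")
  bad <- setdiff(targets$parameter, names(params))
  if (length(bad))
    stop_config(paste0("unknown parameter(s) in targets: ",
                       paste(bad, collapse = ", ")))
  if (!all(targets$variable %in% c("P", "M", "B")))
    stop_config("target variables must be P, M or B")

  base <- run_year(params, forcing, sigmoid, init)
  base_mean <- vapply(c(P = "P", M = "M", B = "B"),
                      function(v) mean(base$trajectory[[v]]), numeric(1))

  rows <- list()
  for (i in seq_len(nrow(targets))) {
    v <- targets$variable[i]; pname <- targets$parameter[i]
    rms_both <- numeric(2)
    for (j in 1:2) {
      dir <- c(-1, 1)[j]
      pp <- unclass(params)
      pp[[pname]] <- pp[[pname]] * (1 + dir * perturbation)
      pert <- run_year(validate_parameters(pp), forcing, sigmoid, init)
      rms_both[j] <- sqrt(mean((pert$trajectory[[v]] -
                                  base$trajectory[[v]])^2))
    }
    for (j in 1:2) {
      pct <- 100 * rms_both[j] / base_mean[[v]]
      rows[[length(rows) + 1L]] <- data.frame(
        variable = v, parameter = pname, direction = c(-1L, 1L)[j],
        rms = rms_both[j], avg_rms = mean(rms_both), pct_diff = pct,
        sensitive = pct > 10)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("sensitivity_report", "data.frame")
  out
}

#' @export
print.sensitivity_report <- function(x, ...) {
  cat("One-at-a-time sensitivity (RMS deviation from base run, n = 365)\n")
  y <- as.data.frame(x)
  y$rms <- signif(y$rms, 4)
  y$avg_rms <- signif(y$avg_rms, 4)
  y$pct_diff <- round(y$pct_diff, 1)
  print(y, row.names = FALSE)
  invisible(x)
}
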