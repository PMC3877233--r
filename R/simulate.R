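#' Run the ecosystem model for one year
#'
#' Advances phytoplankton (P), zooplankton (M) and macrobenthos (B)
#' through 365 daily forward-Euler steps under the supplied forcing.
#' The state recorded for day *t* is the value *before* that day's
#' step, so day 1 equals the initial condition; rate diagnostics for
#' day *t* are evaluated at that state and that day's forcing.  After
#' each step the state is clamped at `params$biomass_floor`, a proxy
#' for recolonisation from planktonic larvae that lets biomass recover
#' after local extirpation.
#'
#' @param params a [model_parameters()] object.
#' @param forcing a [forcing_series()].
#' @param sigmoid a [sigmoid_params()] object: the normalized Z'
#'   oxygen dose-response controlling macrobenthic hypoxic mortality.
#' @param init initial state, a list with `P`, `M` (g C m^-3) and `B`
#'   (g C m^-2); defaults to [default_init()].
#' @param scenario_id label stored on the result.
#' @return An object of class `"hypoxia_sim"`: a list with
#'   `trajectory` (365-row data frame of day, drivers, states and
#'   diagnostics `G`, `PR`, `Gz`, `Mz`, `doref`, `PRz`, `Z`, `Zprime`,
#'   `beta`, `m`, `PM`), plus the `params`, `sigmoid`, `init`,
#'   `scenario_id` and a forcing fingerprint.
#' @examples
#' sim <- run_year(model_parameters(), synthetic_climatology())
#' summary(sim)
#' @export
run_year <- function(params, forcing, sigmoid = default_zprime(),
                     init = default_init(), scenario_id = "baseline") {
  stopifnot(inherits(params, "model_parameters"),
            inherits(sigmoid, "sigmoid_params"))
  forcing <- validate_forcing(forcing)
  for (nm in c("P", "M", "B")) {
    if (!is_number(init[[nm]]) || init[[nm]] < 0)
      stop_config(paste0("initial state '", nm,
                         "' must be a nonnegative number"))
  }

  n <- 365L
  fl <- params$biomass_floor
  if (length(fl) == 1L) fl <- c(P = fl, M = fl, B = unname(fl))
  P <- M <- B <- numeric(n)
  G <- PR <- Gz <- Mz <- doref <- PRz <- numeric(n)
  Z <- Zprime <- beta <- m <- PM <- numeric(n)

  state <- list(P = max(init$P, fl[["P"]]), M = max(init$M, fl[["M"]]),
                B = max(init$B, fl[["B"]]))
  for (t in seq_len(n)) {
    fr <- list(temperature = forcing$temperature[t], par = forcing$par[t],
               do_conc = forcing$do_conc[t], poc = forcing$poc[t],
               din = forcing$din[t])
    dp <- phytoplankton_derivative(state, fr, params)
    dm <- zooplankton_derivative(state, fr, params)
    db <- macrobenthos_derivative(state, fr, params, sigmoid)

    P[t] <- state$P; M[t] <- state$M; B[t] <- state$B
    G[t] <- dp$diagnostics$G; PR[t] <- dp$diagnostics$PR
    Gz[t] <- dm$diagnostics$Gz; Mz[t] <- dm$diagnostics$Mz
    doref[t] <- dm$diagnostics$doref; PRz[t] <- dm$diagnostics$PRz
    Z[t] <- db$diagnostics$Z; Zprime[t] <- db$diagnostics$Zprime
    beta[t] <- db$diagnostics$beta; m[t] <- db$diagnostics$m
    PM[t] <- db$diagnostics$PM

    dd <- c(dp$deriv, dm$deriv, db$deriv)
    if (any(!is.finite(dd)))
      stop_numerical(sprintf(
        "non-finite derivative on day %d (P=%.4g, M=%.4g, B=%.4g)",
        t, state$P, state$M, state$B))
    state <- list(P = max(state$P + dp$deriv, fl[["P"]]),
                  M = max(state$M + dm$deriv, fl[["M"]]),
                  B = max(state$B + db$deriv, fl[["B"]]))
  }

  traj <- data.frame(day = forcing$day, temperature = forcing$temperature,
                     par = forcing$par, do_conc = forcing$do_conc,
                     poc = forcing$poc, din = forcing$din,
                     P = P, M = M, B = B, G = G, PR = PR, Gz = Gz,
                     Mz = Mz, doref = doref, PRz = PRz, Z = Z,
                     Zprime = Zprime, beta = beta, m = m, PM = PM)
  structure(list(trajectory = traj, params = params, sigmoid = sigmoid,
                 init = init, scenario_id = scenario_id,
                 forcing_fingerprint = forcing_fingerprint(forcing)),
            class = "hypoxia_sim")
}

forcing_fingerprint <- function(forcing) {
  sums <- vapply(forcing[FORCING_COLUMNS], sum, numeric(1))
  paste(formatC(sums, digits = 10, format = "g"), collapse = "|")
}

#' Run a named hypoxia scenario
#'
#' Composes [scenario_table()], [apply_do_scenario()] and [run_year()].
#' `"baseline"` runs the unmodified forcing, the normoxic reference
#' against which the hypoxia scenarios are compared.
#'
#' @param scenario_id one of `"baseline"`, `"S1"` ... `"S9"`.
#' @param params a [model_parameters()] object.
#' @param base_forcing a [forcing_series()].
#' @inheritParams run_year
#' @return A `"hypoxia_sim"` object.
#' @export
run_scenario <- function(scenario_id, params, base_forcing,
                         sigmoid = default_zprime(), init = default_init()) {
  if (identical(scenario_id, "baseline"))
    return(run_year(params, base_forcing, sigmoid, init, "baseline"))
  tab <- scenario_table()
  if (!scenario_id %in% names(tab))
    stop_scenario(paste0("unknown scenario id: ", scenario_id))
  forced <- apply_do_scenario(base_forcing, tab[[scenario_id]])
  run_year(params, forced, sigmoid, init, scenario_id)
}

#' Summarize state variables over a day window
#'
#' Arithmetic mean and sample (n-1) standard deviation of each state
#' variable over an inclusive Julian-day window.
#'
#' @param result a `"hypoxia_sim"` object.
#' @param start_day,end_day window endpoints, `1 <= start <= end <= 365`.
#' @return A data frame with one row per state variable (`P`, `M`,
#'   `B`) and columns `variable`, `mean`, `sd`, `n`.
#' @examples
#' sim <- run_year(model_parameters(), synthetic_climatology())
#' summarize_window(sim, 178, 237)
#' @export
summarize_window <- function(result, start_day, end_day) {
  stopifnot(inherits(result, "hypoxia_sim"))
  if (!is_number(start_day) || !is_number(end_day) ||
      start_day < 1 || end_day > 365 || start_day > end_day)
    stop_domain("window must satisfy 1 <= start_day <= end_day <= 365")
  idx <- result$trajectory$day >= start_day & result$trajectory$day <= end_day
  vars <- c("P", "M", "B")
  out <- data.frame(
    variable = vars,
    mean = vapply(vars, function(v) mean(result$trajectory[[v]][idx]),
                  numeric(1)),
    sd = vapply(vars, function(v) stats::sd(result$trajectory[[v]][idx]),
                numeric(1)),
    n = sum(idx))
  rownames(out) <- NULL
  out
}

#' @export
print.hypoxia_sim <- function(x, ...) {
  tr <- x$trajectory
  cat("Ecosystem simulation (365 daily Euler steps), scenario: ",
      x$scenario_id, "\n", sep = "")
  cat(sprintf("  annual mean P = %.3f g C m-3, M = %.3f g C m-3, B = %.3f g C m-2\n",
              mean(tr$P), mean(tr$M), mean(tr$B)))
  cat(sprintf("  hypoxic days (DO <= 2 mg/l): %d; min DO = %.2f mg/l\n",
              sum(tr$do_conc <= 2), min(tr$do_conc)))
  invisible(x)
}

#' @export
summary.hypoxia_sim <- function(object, ...) {
  tr <- object$trajectory
  ann <- summarize_window(object, 1, 365)
  structure(list(scenario_id = object$scenario_id, annual = ann,
                 hypoxic_days = sum(tr$do_conc <= 2),
                 min_do = min(tr$do_conc),
                 final = tr[365, c("P", "M", "B")]),
            class = "summary.hypoxia_sim")
}

#' @export
print.summary.hypoxia_sim <- function(x, ...) {
  cat("Scenario:", x$scenario_id, "\n")
  cat("Annual state summaries (mean, sample SD, n):\n")
  print(x$annual, row.names = FALSE)
  cat(sprintf("Hypoxic days (DO <= 2): %d; minimum DO %.2f mg O2/l\n",
              x$hypoxic_days, x$min_do))
  cat(sprintf("Final state: P = %.3f, M = %.3f, B = %.3f\n",
              x$final$P, x$final$M, x$final$B))
  invisible(x)
}

#' Plot a simulation
#'
#' Two stacked panels: plankton (P, M; g C m^-3) and macrobenthos
#' (B; g C m^-2) with dissolved oxygen overlaid on a secondary axis.
#'
#' @param x a `"hypoxia_sim"` object.
#' @param ... passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.hypoxia_sim <- function(x, ...) {
  tr <- x$trajectory
  op <- graphics::par(mfrow = c(2, 1), mar = c(2.5, 4, 2, 4))
  on.exit(graphics::par(op))
  graphics::plot(tr$day, tr$P, type = "l", xlab = "", col = "darkgreen",
                 ylab = "plankton (g C m-3)",
                 main = paste("scenario", x$scenario_id), ...)
  graphics::lines(tr$day, tr$M, col = "steelblue")
  graphics::legend("topleft", c("P", "M"), lty = 1, bty = "n",
                   col = c("darkgreen", "steelblue"))
  graphics::plot(tr$day, tr$B, type = "l", xlab = "Julian day",
                 ylab = "macrobenthos (g C m-2)", ...)
  graphics::par(new = TRUE)
  graphics::plot(tr$day, tr$do_conc, type = "l", lty = 2, col = "grey50",
                 axes = FALSE, xlab = "", ylab = "")
  graphics::axis(4)
  graphics::mtext("DO (mg O2/l)", side = 4, line = 2.5, cex = 0.8)
  invisible(x)
}

#' Write a daily simulation CSV
#'
#' Writes `day, P, M, B, DO, Z, Zprime, Mz, beta, m` for downstream
#' analysis.
#'
#' @param result a `"hypoxia_sim"` object.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_sim_csv <- function(result, path) {
  stopifnot(inherits(result, "hypoxia_sim"))
  tr <- result$trajectory
  out <- data.frame(day = tr$day, P = tr$P, M = tr$M, B = tr$B,
                    DO = tr$do_conc, Z = tr$Z, Zprime = tr$Zprime,
                    Mz = tr$Mz, beta = tr$beta, m = tr$m)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
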