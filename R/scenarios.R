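#' Dissolved-oxygen forcing scenario
#'
#' Define a hypoxia scenario as one or more Julian-day windows during
#' which dissolved oxygen is forced to a target concentration, with
#' linear entry/exit ramps (default 3 days) sitting *outside* the
#' windows so that every window day is fully at the target.
#'
#' @param scenario_id label, e.g. `"S1"`.
#' @param windows a data frame (or list coercible to one) with columns
#'   `start_day`, `end_day`, `target_do`; endpoints inclusive, windows
#'   sorted and non-overlapping.
#' @param ramp_days integer >= 0, days of linear adjustment before and
#'   after each window.
#' @return A list of class `"do_scenario"`.
#' @seealso [scenario_table()], [apply_do_scenario()]
#' @export
do_scenario <- function(scenario_id, windows, ramp_days = 3L) {
  w <- as.data.frame(windows)
  need <- c("start_day", "end_day", "target_do")
  if (!all(need %in% names(w)))
    stop_scenario("windows need columns start_day, end_day, target_do")
  w <- w[need]
  if (!is_number(ramp_days) || ramp_days < 0 || ramp_days != round(ramp_days))
    stop_scenario("ramp_days must be a nonnegative integer")
  if (any(w$start_day < 1 | w$end_day > 365 | w$start_day > w$end_day))
    stop_scenario("each window needs 1 <= start_day <= end_day <= 365")
  if (any(w$target_do < 0))
    stop_scenario("target_do must be nonnegative")
  if (nrow(w) > 1L) {
    if (is.unsorted(w$start_day, strictly = TRUE))
      stop_scenario("windows must be sorted by start_day")
    if (any(w$start_day[-1L] <= w$end_day[-nrow(w)]))
      stop_scenario("windows must not overlap")
  }
  structure(list(scenario_id = scenario_id, windows = w,
                 ramp_days = as.integer(ramp_days)),
            class = "do_scenario")
}

#' @export
print.do_scenario <- function(x, ...) {
  cat("DO scenario ", x$scenario_id, " (ramp ", x$ramp_days, " d)\n",
      sep = "")
  print(x$windows, row.names = FALSE)
  invisible(x)
}

#' The nine standard hypoxia scenarios
#'
#' The scenario set used in the simulation experiments: S1-S3 vary
#' sustained hypoxic duration (120, 60, 30 days) at 0.5 mg O2 l^-1,
#' S4 is intermittent hypoxia on a 14-day neap-spring tidal rhythm,
#' and S5-S9 vary severity (2.0 down to 0.0 mg O2 l^-1) over a fixed
#' 60-day window (days 178-237).
#'
#' @param ramp_days days of linear DO adjustment flanking each window.
#' @return A named list of [do_scenario()] objects (`S1` ... `S9`).
#' @export
scenario_table <- function(ramp_days = 3L) {
  win <- function(s, e, t) data.frame(start_day = s, end_day = e,
                                      target_do = t)
  list(
    S1 = do_scenario("S1", win(148, 267, 0.5), ramp_days),
    S2 = do_scenario("S2", win(178, 237, 0.5), ramp_days),
    S3 = do_scenario("S3", win(191, 222, 0.5), ramp_days),
    S4 = do_scenario("S4", win(c(162, 190, 218, 246),
                               c(176, 204, 232, 260), 0.5), ramp_days),
    S5 = do_scenario("S5", win(178, 237, 2.0), ramp_days),
    S6 = do_scenario("S6", win(178, 237, 1.5), ramp_days),
    S7 = do_scenario("S7", win(178, 237, 1.0), ramp_days),
    S8 = do_scenario("S8", win(178, 237, 0.5), ramp_days),
    S9 = do_scenario("S9", win(178, 237, 0.0), ramp_days)
  )
}

#' Force a DO scenario onto a base series
#'
#' Inside each window (inclusive endpoints) dissolved oxygen equals the
#' target concentration.  In the `ramp_days` immediately before and
#' after a window, oxygen is linearly interpolated between the series
#' value just outside the ramp and the target, avoiding artificial
#' step changes.  All other days, and every non-oxygen driver, are
#' left untouched.  The operation is idempotent.
#'
#' @param base a [forcing_series()].
#' @param scenario a [do_scenario()].
#' @return A modified [forcing_series()].
#' @examples
#' fc <- synthetic_climatology()
#' s8 <- apply_do_scenario(fc, scenario_table()$S8)
#' s8$do_conc[200]  # 0.5
#' @export
apply_do_scenario <- function(base, scenario) {
  base <- validate_forcing(base)
  stopifnot(inherits(scenario, "do_scenario"))
  w <- scenario$windows
  ramp <- scenario$ramp_days
  if (any(w$start_day - ramp < 1 | w$end_day + ramp > 365))
    stop_scenario("scenario windows (with ramps) must fit within 1..365")
  if (nrow(w) > 1L) {
    lo <- w$start_day - ramp
    hi <- w$end_day + ramp
    if (any(lo[-1L] <= hi[-nrow(w)]))
      stop_scenario("windows overlap after ramp expansion")
  }

  out <- base
  for (i in seq_len(nrow(w))) {
    s <- w$start_day[i]; e <- w$end_day[i]; target <- w$target_do[i]
    out$do_conc[s:e] <- target
    if (ramp > 0L) {
      # entry ramp: from the last unmodified day toward the target
      v0 <- out$do_conc[max(s - ramp - 1L, 1L)]
      k <- seq_len(ramp)
      out$do_conc[s - ramp - 1L + k] <-
        (1 - k / (ramp + 1)) * v0 + (k / (ramp + 1)) * target
      # exit ramp: from the target back to the first unmodified day
      v1 <- out$do_conc[min(e + ramp + 1L, 365L)]
      out$do_conc[e + k] <-
        (1 - k / (ramp + 1)) * target + (k / (ramp + 1)) * v1
    }
  }
  validate_forcing(out)
}

#' Read a scenario definition from a YAML config
#'
#' Expects keys `scenario_id`, `ramp_days` and `windows` (a list of
#' mappings with `start_day`, `end_day`, `target_do`).
#'
#' @param path file path.
#' @return A [do_scenario()].
#' @export
read_scenario_config <- function(path) {
  if (!file.exists(path)) stop_format(paste0("no such file: ", path))
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$scenario_id) || is.null(cfg$windows))
    stop_format("scenario config needs 'scenario_id' and 'windows'")
  w <- do.call(rbind, lapply(cfg$windows, function(x)
    data.frame(start_day = x$start_day, end_day = x$end_day,
               target_do = x$target_do)))
  do_scenario(cfg$scenario_id, w,
              if (is.null(cfg$ramp_days)) 3L else cfg$ramp_days)
}
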