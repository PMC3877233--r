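FORCING_COLUMNS <- c("day", "temperature", "par", "do_conc", "poc", "din")

#' Daily forcing series
#'
#' Construct and validate a 365-day forcing series: Julian day,
#' water temperature (deg C), photosynthetically active radiation
#' (mol photons m^-2 d^-1), dissolved oxygen (mg O2 l^-1), sediment
#' particulate organic carbon (g C m^-3) and dissolved inorganic
#' nitrogen (g N m^-3).
#'
#' @param day integer Julian days, exactly `1:365`.
#' @param temperature,par,do_conc,poc,din numeric vectors of length
#'   365; `par`, `do_conc`, `poc` and `din` must be nonnegative.
#' @return A data frame of class `"forcing_series"`.
#' @export
forcing_series <- function(day, temperature, par, do_conc, poc, din) {
  x <- data.frame(day = as.integer(day), temperature = temperature,
                  par = par, do_conc = do_conc, poc = poc, din = din)
  validate_forcing(x)
}

validate_forcing <- function(x) {
  missing_cols <- setdiff(FORCING_COLUMNS, names(x))
  if (length(missing_cols))
    stop_format(paste0("forcing is missing column(s): ",
                       paste(missing_cols, collapse = ", ")))
  x <- x[FORCING_COLUMNS]
  if (nrow(x) != 365L)
    stop_format(paste0("forcing must have exactly 365 rows, got ", nrow(x)))
  for (nm in FORCING_COLUMNS) {
    if (!is.numeric(x[[nm]]))
      stop_format(paste0("forcing column '", nm, "' is not numeric"))
    bad <- which(!is.finite(x[[nm]]))
    if (length(bad))
      stop_format(paste0("forcing column '", nm,
                         "' has a non-finite value at row ", bad[1L]))
  }
  if (!identical(as.integer(x$day), 1:365))
    stop_format("forcing days must be strictly increasing 1..365")
  for (nm in c("par", "do_conc", "poc", "din")) {
    bad <- which(x[[nm]] < 0)
    if (length(bad))
      stop_format(paste0("forcing column '", nm, "' is negative on day ",
                         x$day[bad[1L]]))
  }
  class(x) <- c("forcing_series", "data.frame")
  x
}

#' Synthetic annual forcing climatology
#'
#' Build a smooth, single-harmonic annual climatology of the daily
#' drivers, emulating a lower-Chesapeake seasonal cycle: sinusoidal
#' temperature and light peaking in summer, a seasonal dissolved-oxygen
#' drawdown reaching its minimum in late July, and (optionally
#' seasonal) organic-carbon and nutrient levels.  Each driver follows
#' `mean + amplitude * cos(2 * pi * (day - peak_day) / 365)`, except
#' oxygen which is drawn *down*:
#' `do_base - do_amplitude * cos(2 * pi * (day - do_min_day) / 365)`,
#' so its annual minimum equals `do_base - do_amplitude` on
#' `do_min_day`.  Optional multiplicative Gaussian noise perturbs every
#' driver; outputs are clipped at zero where negativity is physically
#' meaningless.
#'
#' Defaults are synthetic stand-ins for a lower-Chesapeake climatology,
#' not values transcribed from any monitoring product; see the methods
#' vignette.
#'
#' @param temp_mean,temp_amplitude,temp_peak_day temperature annual
#'   mean (deg C), amplitude and day of maximum.
#' @param par_mean,par_amplitude,par_peak_day irradiance annual mean
#'   (mol photons m^-2 d^-1), amplitude and day of maximum.
#' @param do_base,do_amplitude,do_min_day oxygen baseline (mg O2
#'   l^-1), seasonal drawdown amplitude and day of minimum.
#' @param poc_mean,poc_amplitude,poc_peak_day sediment organic carbon
#'   (g C m^-3).
#' @param din_mean,din_amplitude,din_peak_day dissolved inorganic
#'   nitrogen (g N m^-3); peaks in late winter by default.
#' @param noise_sd relative (fractional) standard deviation of
#'   multiplicative Gaussian noise applied to every driver; 0 (the
#'   default) gives the deterministic climatology.
#' @param seed integer seed used when `noise_sd > 0`.
#' @return A [forcing_series()].
#' @examples
#' fc <- synthetic_climatology()
#' fc$temperature[212]  # summer maximum, 26 degrees C
#' @export
synthetic_climatology <- function(temp_mean = 16, temp_amplitude = 10,
                                  temp_peak_day = 212,
                                  par_mean = 32, par_amplitude = 22,
                                  par_peak_day = 172,
                                  do_base = 7, do_amplitude = 2,
                                  do_min_day = 212,
                                  poc_mean = 2.5, poc_amplitude = 0,
                                  poc_peak_day = 120,
                                  din_mean = 0.15, din_amplitude = 0.10,
                                  din_peak_day = 46,
                                  noise_sd = 0, seed = NULL) {
  amps <- c(temp_amplitude = temp_amplitude, par_amplitude = par_amplitude,
            do_amplitude = do_amplitude, poc_amplitude = poc_amplitude,
            din_amplitude = din_amplitude)
  bad <- names(amps)[amps < 0]
  if (length(bad))
    stop_config(paste0("negative amplitude: ", paste(bad, collapse = ", ")))
  peaks <- c(temp_peak_day = temp_peak_day, par_peak_day = par_peak_day,
             do_min_day = do_min_day, poc_peak_day = poc_peak_day,
             din_peak_day = din_peak_day)
  bad <- names(peaks)[peaks < 1 | peaks > 365]
  if (length(bad))
    stop_config(paste0("peak day outside 1..365: ",
                       paste(bad, collapse = ", ")))
  if (!is_number(noise_sd) || noise_sd < 0)
    stop_config("noise_sd must be a nonnegative number")

  day <- 1:365
  harmonic <- function(mean, amp, peak)
    mean + amp * cos(2 * pi * (day - peak) / 365)

  temperature <- harmonic(temp_mean, temp_amplitude, temp_peak_day)
  par <- pmax(harmonic(par_mean, par_amplitude, par_peak_day), 0)
  do_conc <- pmax(do_base - do_amplitude *
                    cos(2 * pi * (day - do_min_day) / 365), 0)
  poc <- pmax(harmonic(poc_mean, poc_amplitude, poc_peak_day), 0)
  din <- pmax(harmonic(din_mean, din_amplitude, din_peak_day), 0)

  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    jitter <- function(x, clip0 = TRUE) {
      y <- x * (1 + stats::rnorm(365L, 0, noise_sd))
      if (clip0) pmax(y, 0) else y
    }
    temperature <- jitter(temperature, clip0 = FALSE)
    par <- jitter(par)
    do_conc <- jitter(do_conc)
    poc <- jitter(poc)
    din <- jitter(din)
  }

  forcing_series(day, temperature, par, do_conc, poc, din)
}

#' Read or write a forcing series as CSV
#'
#' The CSV carries the header `day,temperature,par,do_conc,poc,din`;
#' the reader enforces every forcing invariant (365 strictly increasing
#' days, nonnegative par/oxygen/carbon/nitrogen) and names the
#' offending row or column on failure.
#'
#' @param path file path.
#' @return `read_forcing_csv()` returns a [forcing_series()];
#'   `write_forcing_csv()` returns `path` invisibly.
#' @export
read_forcing_csv <- function(path) {
  if (!file.exists(path)) stop_format(paste0("no such file: ", path))
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_forcing(x)
}

#' @rdname read_forcing_csv
#' @param series a [forcing_series()].
#' @export
write_forcing_csv <- function(series, path) {
  series <- validate_forcing(series)
  utils::write.csv(series, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
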