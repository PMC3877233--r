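#' Generate sigmoid-structured oxygen-biomass observation pairs
#'
#' Draws dissolved-oxygen values over `do_range` and computes biomass
#' on the truth curve [unnormalized_sigmoid()] perturbed by
#' multiplicative lognormal noise with unit mean and coefficient of
#' variation `noise_cv`.  Because uniform sampling under-covers the
#' sigmoid's rise, a fraction `low_do_frac` of the points (default
#' half) is drawn from the hypoxic range below 2 mg O2 l^-1 so fits
#' stay identifiable; set it to 0 for plain uniform sampling.
#'
#' @param truth a [sigmoid_params()] object: the generating curve.
#' @param n_obs number of observation pairs (>= 1).
#' @param noise_cv coefficient of variation of the multiplicative
#'   lognormal noise (>= 0; 0 puts every point exactly on the curve).
#' @param do_range length-2 oxygen range (mg O2 l^-1), min < max.
#' @param low_do_frac fraction of points oversampled below 2 mg O2
#'   l^-1 (used only when `do_range` straddles 2).
#' @param seed integer seed; generation is reproducible given the seed.
#' @return A data frame of class `"biomass_do_obs"` with columns
#'   `do_conc`, `biomass`, `site`, `date`.
#' @examples
#' obs <- gen_biomass_do_pairs(sigmoid_params(50, 2, 4), n_obs = 20,
#'                             noise_cv = 0, seed = 1)
#' all.equal(obs$biomass, unnormalized_sigmoid(obs$do_conc,
#'                                             sigmoid_params(50, 2, 4)))
#' @export
gen_biomass_do_pairs <- function(truth, n_obs = 60, noise_cv = 0.2,
                                 do_range = c(0, 8), low_do_frac = 0.5,
                                 seed = NULL) {
  stopifnot(inherits(truth, "sigmoid_params"))
  if (!is_number(n_obs) || n_obs < 1) stop_config("n_obs must be >= 1")
  if (!is_number(noise_cv) || noise_cv < 0)
    stop_config("noise_cv must be nonnegative")
  if (length(do_range) != 2L || do_range[1] >= do_range[2])
    stop_config("do_range must be (min, max) with min < max")
  if (!is.null(seed)) set.seed(seed)

  n_obs <- as.integer(n_obs)
  if (low_do_frac > 0 && do_range[1] < 2 && do_range[2] > 2) {
    n_low <- round(low_do_frac * n_obs)
    do_conc <- c(stats::runif(n_low, do_range[1], 2),
                 stats::runif(n_obs - n_low, 2, do_range[2]))
  } else {
    do_conc <- stats::runif(n_obs, do_range[1], do_range[2])
  }

  curve <- unnormalized_sigmoid(do_conc, truth)
  if (noise_cv > 0) {
    sdlog <- sqrt(log(1 + noise_cv^2))
    noise <- stats::rlnorm(n_obs, meanlog = -sdlog^2 / 2, sdlog = sdlog)
  } else {
    noise <- rep(1, n_obs)
  }
  structure(data.frame(do_conc = do_conc, biomass = curve * noise,
                       site = "synthetic",
                       date = sprintf("sample-%03d", seq_len(n_obs))),
            class = c("biomass_do_obs", "data.frame"))
}

#' Sample pseudo-observations from a simulated trajectory
#'
#' Emulates a monitoring program: samples one state variable of a
#' simulation at the given days (default, biweekly May-October),
#' adds independent Gaussian noise, and clips at zero.
#'
#' @param truth_run a `"hypoxia_sim"` object.
#' @param sampling_days Julian days to sample (within 1..365).
#' @param obs_noise_sd additive Gaussian noise SD, in the variable's
#'   units (0 reproduces the trajectory exactly).
#' @param variable one of `"P"`, `"M"`, `"B"`.
#' @param site site label carried on the records.
#' @param seed integer seed.
#' @return A data frame of class `"observation_series"` with columns
#'   `day`, `value`, `variable`, `site`.
#' @export
gen_observation_series <- function(truth_run,
                                   sampling_days = seq(121, 304, by = 14),
                                   obs_noise_sd = 0,
                                   variable = c("B", "P", "M"),
                                   site = "synthetic", seed = NULL) {
  stopifnot(inherits(truth_run, "hypoxia_sim"))
  variable <- match.arg(variable)
  if (any(sampling_days < 1 | sampling_days > 365))
    stop_domain("sampling days must lie within 1..365")
  if (!is_number(obs_noise_sd) || obs_noise_sd < 0)
    stop_config("obs_noise_sd must be nonnegative")
  if (!is.null(seed)) set.seed(seed)

  truth <- truth_run$trajectory[[variable]][match(sampling_days,
                                                  truth_run$trajectory$day)]
  value <- truth
  if (obs_noise_sd > 0)
    value <- value + stats::rnorm(length(value), 0, obs_noise_sd)
  value <- pmax(value, 0)
  structure(data.frame(day = as.integer(sampling_days), value = value,
                       variable = variable, site = site),
            class = c("observation_series", "data.frame"))
}

#' Write a complete synthetic fixture set
#'
#' Writes `forcing.csv` (default climatology), `pairs.csv`
#' (oxygen-biomass pairs from the default truth curve) and `obs.csv`
#' (biweekly macrobenthos pseudo-observations of the baseline run)
#' into a directory, so the full pipeline can be exercised without any
#' external data.
#'
#' @param dir output directory (created if absent).
#' @param seed integer seed controlling all randomness.
#' @return Character vector of the three file paths, invisibly.
#' @export
make_fixtures <- function(dir, seed = 1) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  fc <- synthetic_climatology()
  write_forcing_csv(fc, file.path(dir, "forcing.csv"))
  pairs <- gen_biomass_do_pairs(sigmoid_params(50, 2, 4), n_obs = 60,
                                noise_cv = 0.2, seed = seed)
  utils::write.csv(pairs, file.path(dir, "pairs.csv"), row.names = FALSE)
  sim <- run_year(model_parameters(), fc)
  obs <- gen_observation_series(sim, obs_noise_sd = 0.3, seed = seed + 1)
  utils::write.csv(obs, file.path(dir, "obs.csv"), row.names = FALSE)
  invisible(file.path(dir, c("forcing.csv", "pairs.csv", "obs.csv")))
}
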