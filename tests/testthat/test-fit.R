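test_that("noiseless data identify the generating parameters", {
  obs <- gen_biomass_do_pairs(default_truth(), n_obs = 30, noise_cv = 0,
                              do_range = c(0, 8), seed = 7)
  fit <- fit_sigmoid(obs)
  expect_true(fit$converged)
  expect_equal(unname(coef(fit)), c(50, 2, 4), tolerance = 1e-6)
  expect_lt(fit$rss, 1e-12)
  expect_equal(fit$n_obs, 30)
})

test_that("noisy recovery at the reference design stays within 15%", {
  obs <- gen_biomass_do_pairs(default_truth(), n_obs = 60, noise_cv = 0.2,
                              seed = 42)
  fit <- fit_sigmoid(obs)
  expect_true(fit$converged)
  rel <- abs(coef(fit) - c(50, 2, 4)) / c(50, 2, 4)
  expect_true(all(rel < 0.15))
})

test_that("degenerate designs raise identifiability errors", {
  truth <- default_truth()
  # too few records
  few <- gen_biomass_do_pairs(truth, n_obs = 5, noise_cv = 0, seed = 1)
  expect_error(fit_sigmoid(few), class = "benthox_identifiability_error")
  # all normoxic: flat-region degeneracy
  hi <- gen_biomass_do_pairs(truth, n_obs = 30, noise_cv = 0.1,
                             do_range = c(5, 9), low_do_frac = 0, seed = 1)
  expect_error(fit_sigmoid(hi), class = "benthox_identifiability_error")
  # all hypoxic
  lo <- gen_biomass_do_pairs(truth, n_obs = 30, noise_cv = 0.1,
                             do_range = c(0, 1.8), low_do_frac = 0, seed = 1)
  expect_error(fit_sigmoid(lo), class = "benthox_identifiability_error")
})

test_that("the fit is invariant to observation order", {
  obs <- gen_biomass_do_pairs(default_truth(), n_obs = 40, noise_cv = 0.15,
                              seed = 3)
  fit1 <- fit_sigmoid(obs)
  set.seed(99)
  fit2 <- fit_sigmoid(obs[sample(nrow(obs)), ])
  expect_equal(coef(fit1), coef(fit2), tolerance = 1e-8)
})

test_that("the optimum is a local minimum of the fitting loss", {
  obs <- gen_biomass_do_pairs(default_truth(), n_obs = 60, noise_cv = 0.2,
                              seed = 8)
  fit <- fit_sigmoid(obs)
  loss <- function(a, b, cc)
    sum((log(obs$biomass) -
           (log(cc) - log1p(a * exp(-b * obs$do_conc))))^2)
  est <- coef(fit)
  rss0 <- loss(est["a"], est["b"], est["c"])
  expect_equal(rss0, fit$rss, tolerance = 1e-8)
  set.seed(31)
  for (i in 1:100) {
    f <- 1 + stats::runif(3, -0.02, 0.02)
    expect_gte(loss(est["a"] * f[1], est["b"] * f[2], est["c"] * f[3]),
               rss0 - 1e-10)
  }
})

test_that("normalization sets c to 1 and preserves the shape exactly", {
  obs <- gen_biomass_do_pairs(default_truth(), n_obs = 40, noise_cv = 0.1,
                              seed = 12)
  fit <- fit_sigmoid(obs)
  norm <- normalize_sigmoid(fit)
  expect_equal(norm$c, 1)
  expect_identical(norm$a, fit$params$a)
  expect_identical(norm$b, fit$params$b)
  # algebraic identity at random oxygen values
  set.seed(4)
  do_vals <- runif(100, 0, 10)
  expect_equal(z_prime(do_vals, norm) * fit$params$c,
               unnormalized_sigmoid(do_vals, fit$params))
  # idempotence
  expect_identical(normalize_sigmoid(norm), norm)
})

test_that("fit methods work and the report round-trips", {
  obs <- gen_biomass_do_pairs(default_truth(), n_obs = 30, noise_cv = 0.1,
                              seed = 2)
  fit <- fit_sigmoid(obs)
  expect_named(coef(fit), c("a", "b", "c"))
  expect_length(residuals(fit), 30)
  expect_equal(predict(fit, newdata = 100), fit$params$c)
  s <- summary(fit)
  expect_s3_class(s, "summary.zprime_fit")
  expect_output(print(fit), "converged")

  path <- withr::local_tempfile(fileext = ".yml")
  write_fit_report(fit, path)
  rep <- yaml::read_yaml(path)
  expect_equal(rep$a, fit$params$a, tolerance = 1e-8)
  expect_equal(rep$n_obs, 30)
})

test_that("observation CSV reader validates columns and signs", {
  obs <- gen_biomass_do_pairs(default_truth(), n_obs = 10, noise_cv = 0,
                              seed = 1)
  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(obs, path, row.names = FALSE)
  back <- read_biomass_do_csv(path)
  expect_equal(back$biomass, obs$biomass, tolerance = 1e-12)
  bad <- obs; bad$do_conc[1] <- -2
  utils::write.csv(bad, path, row.names = FALSE)
  expect_error(read_biomass_do_csv(path), class = "benthox_format_error")
})
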