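test_that("null dynamics conserve the initial state exactly", {
  sim <- run_year(null_params(), constant_forcing(),
                  init = list(P = 0.3, M = 0.1, B = 2.5))
  tr <- sim$trajectory
  expect_equal(nrow(tr), 365L)
  expect_true(all(tr$P == 0.3) && all(tr$M == 0.1) && all(tr$B == 2.5))
})

test_that("pure benthic decay reproduces the discrete geometric solution", {
  # constant per-capita loss 0.1/d via mzero_b with a Z' that is ~0
  p <- null_params(mzero_b = 0.1)
  sim <- run_year(p, constant_forcing(), sigmoid = dead_zprime(),
                  init = list(P = 0.1, M = 0.1, B = 4))
  tr <- sim$trajectory
  # day d records the state after d - 1 Euler steps
  expect_equal(tr$B[1:20], 4 * 0.9^(0:19), tolerance = 1e-12)
  # deviation from the continuous exponential after 10 steps is 5.22%
  expect_equal(abs(4 * 0.9^10 - 4 * exp(-1)) / (4 * exp(-1)),
               0.0522, tolerance = 1e-3)
  expect_lt(abs(tr$B[11] - 4 * exp(-1)) / (4 * exp(-1)), 0.06)
})

test_that("simulation is bitwise deterministic", {
  p <- model_parameters()
  fc <- synthetic_climatology()
  a <- run_year(p, fc)
  b <- run_year(p, fc)
  expect_identical(a$trajectory, b$trajectory)
})

test_that("the biomass floor clamps every state", {
  p <- null_params(mzero_b = 0.5,
                   biomass_floor = c(P = 0.001, M = 0.001, B = 0.2))
  sim <- run_year(p, constant_forcing(), sigmoid = dead_zprime(),
                  init = list(P = 0.3, M = 0.1, B = 4))
  expect_equal(min(sim$trajectory$B), 0.2)
  expect_true(all(sim$trajectory$B >= 0.2))
})

test_that("non-finite derivatives are reported with the day", {
  p <- model_parameters(pbm = 1e308, light_k = 0, kdin = 0)
  fc <- constant_forcing(temperature = 300)
  expect_error(run_year(p, fc, init = list(P = 1e300, M = 0.1, B = 1)),
               "day", class = "benthox_numerical_error")
})

test_that("run_scenario composes table, forcing and integration", {
  p <- model_parameters()
  fc <- synthetic_climatology()
  s8 <- run_scenario("S8", p, fc)
  expect_equal(s8$scenario_id, "S8")
  # forced oxygen shows up in the trajectory and diagnostics:
  # Z' is constant at z_prime(0.5) through the window interior
  expect_true(all(s8$trajectory$do_conc[181:234] == 0.5))
  expect_equal(s8$trajectory$Zprime[181:234],
               rep(z_prime(0.5, default_zprime()), 54))
  # baseline runs the unmodified forcing
  base <- run_scenario("baseline", p, fc)
  expect_identical(base$trajectory$do_conc, fc$do_conc)
  # normoxic baseline: zooplankton oxygen mortality identically zero and
  # benthic hypoxic mortality at its normoxic minimum all year
  expect_true(all(base$trajectory$Mz == 0))
  expect_true(all(base$trajectory$m < 1e-6))
  expect_error(run_scenario("S10", p, fc),
               class = "benthox_scenario_error")
})

test_that("window summaries use inclusive endpoints and sample SD", {
  p <- null_params()
  sim <- run_year(p, constant_forcing(), init = list(P = 1, M = 1, B = 3))
  s <- summarize_window(sim, 178, 237)
  expect_equal(unique(s$n), 60L)
  expect_equal(s$mean[s$variable == "B"], 3)
  expect_equal(s$sd[s$variable == "B"], 0)
  # hand calculation on a 2-day window of a varying series
  sim2 <- run_year(null_params(mzero_b = 0.5), constant_forcing(),
                   sigmoid = dead_zprime(),
                   init = list(P = 1, M = 1, B = 4))
  # B on days 1, 2 is 4, 2 -> mean 3, sd sqrt(2)
  s2 <- summarize_window(sim2, 1, 2)
  expect_equal(s2$mean[s2$variable == "B"], 3)
  expect_equal(s2$sd[s2$variable == "B"], sqrt(2))
  expect_error(summarize_window(sim, 200, 100),
               class = "benthox_domain_error")
})

test_that("simulation object methods print, summarize, and export", {
  p <- model_parameters()
  sim <- run_year(p, synthetic_climatology())
  expect_output(print(sim), "scenario: baseline")
  s <- summary(sim)
  expect_s3_class(s, "summary.hypoxia_sim")
  expect_output(print(s), "Hypoxic days")
  path <- withr::local_tempfile(fileext = ".csv")
  write_sim_csv(sim, path)
  out <- utils::read.csv(path)
  expect_equal(nrow(out), 365L)
  expect_named(out, c("day", "P", "M", "B", "DO", "Z", "Zprime",
                      "Mz", "beta", "m"))
  pdf(NULL)
  expect_invisible(plot(sim))
  dev.off()
})
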