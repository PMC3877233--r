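test_that("Z passes through its defining quantiles", {
  expect_equal(z_function(2, do_gx = 2, do_qx = 1.5), 0.5)
  expect_equal(z_function(1.5, do_gx = 2, do_qx = 1.5), 0.25)
  # logistic symmetry: the point reflected about do_gx gives 0.75
  expect_equal(z_function(2 * 2 - 1.5, do_gx = 2, do_qx = 1.5), 0.75)
  expect_error(z_function(1, do_gx = 1.5, do_qx = 1.5),
               class = "benthox_config_error")
})

test_that("Z' matches hand-evaluated values and its limits", {
  sp <- sigmoid_params(a = 100, b = 3)
  # midpoint at DO = ln(a)/b
  expect_equal(z_prime(log(100) / 3, sp), 0.5)
  # hand evaluation: 1 / (1 + 100 exp(-6))
  expect_equal(z_prime(2, sp), 1 / (1 + 100 * exp(-6)))
  expect_equal(z_prime(2, sp), 0.8014, tolerance = 1e-4)
  # saturation
  expect_equal(z_prime(20, sp), 1, tolerance = 1e-8)
  expect_error(z_prime(-1, sp), class = "benthox_domain_error")
})

test_that("Z and Z' are bounded in [0,1] and Z' is monotone", {
  set.seed(7)
  for (i in 1:100) {
    sp <- sigmoid_params(a = 10^runif(1, -2, 8), b = runif(1, 0.1, 30))
    do_grid <- sort(runif(50, 0, 15))
    zp <- z_prime(do_grid, sp)
    expect_true(all(zp >= 0 & zp <= 1))
    expect_true(all(diff(zp) >= 0))
    qx <- runif(1, 0.1, 5); gx <- qx + runif(1, 0.05, 3)
    z <- z_function(do_grid, gx, qx)
    expect_true(all(z >= 0 & z <= 1))
  }
})

test_that("the unnormalized curve is exactly c times the modifier", {
  sp <- sigmoid_params(a = 100, b = 3, c = 5)
  expect_equal(unnormalized_sigmoid(2, sp), 4.007, tolerance = 1e-3)
  expect_equal(unnormalized_sigmoid(0, sp), 5 / (1 + 100))
  set.seed(11)
  do_vals <- runif(1000, 0, 12)
  expect_equal(unnormalized_sigmoid(do_vals, sp) / z_prime(do_vals, sp),
               rep(5, 1000))
})

test_that("zooplankton hypoxic mortality is clamped, linear, continuous", {
  p <- model_parameters(mzero_z = 0.2, docrit_z = 2)
  expect_equal(zoo_hypoxic_mortality(2, p)$mz, 0)
  expect_equal(zoo_hypoxic_mortality(5, p)$mz, 0)
  expect_equal(zoo_hypoxic_mortality(0, p)$mz, 0.2)
  expect_equal(zoo_hypoxic_mortality(1, p)$mz, 0.1)
  # DOREF clamp
  expect_equal(zoo_hypoxic_mortality(c(0.5, 3), p)$doref, c(0.5, 2))
  # monotone decreasing on [0, docrit], continuous at the threshold
  do_grid <- seq(0, 2, by = 0.01)
  mz <- zoo_hypoxic_mortality(do_grid, p)$mz
  expect_true(all(diff(mz) <= 0))
  expect_equal(zoo_hypoxic_mortality(2 - 1e-9, p)$mz, 0, tolerance = 1e-8)
})

test_that("Arrhenius multiplier behaves", {
  expect_equal(arrhenius(20, 1.07, 20), 1)
  expect_equal(arrhenius(30, 1.07, 20), 1.07^10)
  expect_equal(arrhenius(30, 1.07, 20), 1.9672, tolerance = 1e-4)
  expect_equal(arrhenius(35, 1, 20), 1)
  expect_true(all(diff(arrhenius(0:30, 1.05, 20)) > 0))
})

test_that("predation rate is a temperature-scaled Monod in oxygen", {
  p <- model_parameters(beta_hat = 0.01, kdo = 1, theta_beta = 2, t_ref = 20)
  # half-saturation
  expect_equal(predation_rate(20, 1, p), 0.01 / 2)
  # anoxia shuts predation off
  expect_equal(predation_rate(20, 0, p), 0)
  # hand value: theta multiplier 2 at T = t_ref + 1, DO = 3
  expect_equal(predation_rate(21, 3, p), 0.01 * 2 * 0.75)
  # monotone in both arguments
  expect_true(all(diff(predation_rate(seq(10, 30, 1), 3, p)) > 0))
  expect_true(all(diff(predation_rate(20, seq(0, 10, 0.5), p)) > 0))
})

test_that("phytoplankton derivative reproduces the balance structure", {
  # G = 0.5 (saturating light and nutrients, theta 1), R = 0.1, Wa = 0.1,
  # PR = 0.05 at P = M = 1 -> dP/dt = 0.25
  p <- model_parameters(pbm = 0.5, light_k = 0, kdin = 0, theta_p = 1,
                        resp_p = 0.1, wa = 0.1, phtl = 0.05)
  fr <- list(temperature = 20, par = 30, do_conc = 6, poc = 2, din = 0.2)
  out <- phytoplankton_derivative(list(P = 1, M = 1, B = 1), fr, p)
  expect_equal(out$deriv, 0.25)
  expect_equal(out$diagnostics$G, 0.5)
  expect_equal(out$diagnostics$PR, 0.05)
  # extinction is absorbing
  out0 <- phytoplankton_derivative(list(P = 0, M = 1, B = 1), fr, p)
  expect_equal(out0$deriv, 0)
  # balance point G = R + Wa with no grazing
  p2 <- model_parameters(pbm = 0.2, light_k = 0, kdin = 0, theta_p = 1,
                         resp_p = 0.1, wa = 0.1, phtl = 0)
  expect_equal(phytoplankton_derivative(list(P = 2, M = 1, B = 1),
                                        fr, p2)$deriv, 0)
})

test_that("zooplankton derivative reproduces the balance structure", {
  # Gz = 0.3, BMz = 0.1, Mz = 0.2 (DO = 1 with mzero_z = 0.4), PRz = 0
  p <- model_parameters(gz_max = 0.3, kgz = 1e-12, theta_z = 1, bmz = 0.1,
                        mzero_z = 0.4, docrit_z = 2, phtlz = 0)
  fr <- list(temperature = 20, par = 30, do_conc = 1, poc = 2, din = 0.2)
  out <- zooplankton_derivative(list(P = 1, M = 1, B = 1), fr, p)
  expect_equal(out$diagnostics$Mz, 0.2)
  expect_equal(out$deriv, 0)
  # extinction absorbing
  expect_equal(zooplankton_derivative(list(P = 1, M = 0, B = 1),
                                      fr, p)$deriv, 0)
  # normoxia: no oxygen-induced mortality term
  fr2 <- fr; fr2$do_conc <- 2
  expect_equal(zooplankton_derivative(list(P = 1, M = 1, B = 1),
                                      fr2, p)$diagnostics$Mz, 0)
})

test_that("macrobenthos derivative sums its loss terms", {
  # gains off; r*Z = 0.05, beta*B = 0.01, m = 0.04 at B = 2 -> -0.2
  zp <- sigmoid_params(a = (2 / 3) * exp(2), b = 1)  # Z'(2) = 0.6
  p <- model_parameters(i0 = 0, resp_b = 0.1, do_gx = 2, do_qx = 1.5,
                        theta_b = 1, theta_beta = 1, beta_hat = 0.01,
                        kdo = 2, mzero_b = 0.1)
  fr <- list(temperature = 20, par = 30, do_conc = 2, poc = 2, din = 0.2)
  out <- macrobenthos_derivative(list(P = 0.5, M = 0.1, B = 2), fr, p, zp)
  expect_equal(out$diagnostics$Z, 0.5)
  expect_equal(out$diagnostics$Zprime, 0.6)
  expect_equal(out$diagnostics$m, 0.04)
  expect_equal(out$diagnostics$beta, 0.005)
  expect_equal(out$deriv, -(0.05 + 0.01 + 0.04) * 2)
  # extinction absorbing
  out0 <- macrobenthos_derivative(list(P = 0.5, M = 0.1, B = 0), fr, p, zp)
  expect_equal(out0$deriv, 0)
  # saturated oxygen: hypoxic mortality vanishes
  fr2 <- fr; fr2$do_conc <- 50
  out2 <- macrobenthos_derivative(list(P = 0.5, M = 0.1, B = 2), fr2, p,
                                  sigmoid_params(100, 3))
  expect_equal(out2$diagnostics$m, 0, tolerance = 1e-8)
})

test_that("no state generates spontaneously from zero", {
  p <- model_parameters()
  zp <- default_zprime()
  fr <- list(temperature = 25, par = 40, do_conc = 4, poc = 3, din = 0.1)
  expect_equal(phytoplankton_derivative(list(P = 0, M = 0.2, B = 2),
                                        fr, p)$deriv, 0)
  expect_equal(zooplankton_derivative(list(P = 0.5, M = 0, B = 2),
                                      fr, p)$deriv, 0)
  expect_equal(macrobenthos_derivative(list(P = 0.5, M = 0.2, B = 0),
                                       fr, p, zp)$deriv, 0)
})
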