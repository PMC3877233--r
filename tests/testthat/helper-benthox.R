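# shared fixtures, all built in code

# a forcing series with every driver constant
constant_forcing <- function(temperature = 20, par = 30, do_conc = 6,
                             poc = 2.5, din = 0.2) {
  forcing_series(1:365, rep(temperature, 365), rep(par, 365),
                 rep(do_conc, 365), rep(poc, 365), rep(din, 365))
}

# parameters with every biological rate switched off: null dynamics
null_params <- function(...) {
  base <- list(pbm = 0, resp_p = 0, wa = 0, phtl = 0,
               gz_max = 0, bmz = 0, mzero_z = 0, phtlz = 0,
               i0 = 0, resp_b = 0, beta_hat = 0, mzero_b = 0,
               biomass_floor = 1e-9)
  do.call(model_parameters, utils::modifyList(base, list(...)))
}

# a Z' curve that is ~0 at any oxygen level (so the hypoxic mortality
# rate equals mzero_b everywhere): a at its upper bound, b tiny
dead_zprime <- function() sigmoid_params(a = 1e12, b = 1e-9, c = 1)

default_truth <- function() sigmoid_params(a = 50, b = 2, c = 4)
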