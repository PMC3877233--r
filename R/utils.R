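# Condition helpers: every benthox error carries a subclass so callers
# (and tests) can distinguish configuration, format, scenario, domain,
# identifiability and numerical failures.

benthox_stop <- function(msg, class, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "benthox_error"),
                      call = call))
}

stop_config <- function(msg) benthox_stop(msg, "benthox_config_error")
stop_format <- function(msg) benthox_stop(msg, "benthox_format_error")
stop_scenario <- function(msg) benthox_stop(msg, "benthox_scenario_error")
stop_domain <- function(msg) benthox_stop(msg, "benthox_domain_error")
stop_identifiability <- function(msg)
  benthox_stop(msg, "benthox_identifiability_error")
stop_numerical <- function(msg) benthox_stop(msg, "benthox_numerical_error")

# scalar numeric check
is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
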