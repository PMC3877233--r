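#' Read or write a parameter configuration file
#'
#' Parameter sets are serialized as flat YAML key-value files using
#' the parameter names of [model_parameters()].  The reader merges the
#' file over the package defaults and validates the result, so partial
#' files work.
#'
#' @param path file path.
#' @return `read_params_config()` returns a [model_parameters()]
#'   object; the writers return `path` invisibly.
#' @export
read_params_config <- function(path) {
  if (!file.exists(path)) stop_format(paste0("no such file: ", path))
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg) || is.null(names(cfg)))
    stop_format("parameter config must be a flat key-value mapping")
  do.call(model_parameters, cfg)
}

#' @rdname read_params_config
#' @param params a [model_parameters()] object.
#' @export
write_params_config <- function(params, path) {
  stopifnot(inherits(params, "model_parameters"))
  out <- unclass(params)
  # keep the names of the per-state floor through YAML
  out$biomass_floor <- as.list(out$biomass_floor)
  yaml::write_yaml(out, path)
  invisible(path)
}

#' Read or write a sigmoid (Z') configuration file
#'
#' Flat YAML with keys `a`, `b` and optional `c` (default 1).
#'
#' @param path file path.
#' @return `read_sigmoid_config()` returns a [sigmoid_params()]
#'   object; the writer returns `path` invisibly.
#' @export
read_sigmoid_config <- function(path) {
  if (!file.exists(path)) stop_format(paste0("no such file: ", path))
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$a) || is.null(cfg$b))
    stop_format("sigmoid config needs keys 'a' and 'b'")
  sigmoid_params(cfg$a, cfg$b, if (is.null(cfg$c)) 1 else cfg$c)
}

#' @rdname read_sigmoid_config
#' @param params a [sigmoid_params()] object.
#' @export
write_sigmoid_config <- function(params, path) {
  stopifnot(inherits(params, "sigmoid_params"))
  yaml::write_yaml(list(a = params$a, b = params$b, c = params$c), path)
  invisible(path)
}
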