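#' Model parameters
#'
#' Construct the full parameter set of the three-state ecosystem model.
#' Any subset of parameters may be overridden; the remainder take the
#' package's documented default calibration (see the methods vignette
#' for the rationale behind each value).  All rates are per day and
#' refer to the reference temperature `t_ref` unless noted.
#'
#' @param ... named parameter overrides.  Valid names and meanings:
#' \describe{
#'   \item{pbm}{maximum photosynthetic rate of phytoplankton (d^-1)}
#'   \item{resp_p}{phytoplankton respiration rate R (d^-1)}
#'   \item{wa}{phytoplankton settling loss Wa (d^-1)}
#'   \item{phtl}{zooplankton grazing (predation-on-algae) rate
#'     (m^3 (g C)^-1 d^-1); predation on phytoplankton is
#'     `PR = phtl * M * P`}
#'   \item{light_k}{light half-saturation (mol photons m^-2 d^-1)}
#'   \item{kdin}{DIN half-saturation for phytoplankton growth (g N m^-3)}
#'   \item{theta_p}{Arrhenius coefficient for phytoplankton rates}
#'   \item{gz_max}{maximum zooplankton growth rate (d^-1)}
#'   \item{kgz}{phytoplankton half-saturation for zooplankton grazing
#'     (g C m^-3)}
#'   \item{bmz}{zooplankton basal metabolic rate BMz (d^-1)}
#'   \item{mzero_z}{zooplankton mortality at zero dissolved oxygen
#'     MZEROz (d^-1)}
#'   \item{docrit_z}{DO threshold below which zooplankton
#'     oxygen-induced mortality occurs, DOCRITz (mg O2 l^-1)}
#'   \item{phtlz}{predator biomass times clearance rate on zooplankton
#'     PHTlz (m^3 (g C)^-1 d^-1) for an implicit planktivore field
#'     proportional to zooplankton biomass; predation on zooplankton
#'     is the quadratic closure `PRz = phtlz * M^2`}
#'   \item{theta_z}{Arrhenius coefficient for zooplankton rates}
#'   \item{alpha}{macrobenthic assimilation efficiency for carbon
#'     (dimensionless, 0-1)}
#'   \item{i0}{maximum carbon-specific ingestion (ration) of
#'     macrobenthos I0 (d^-1 at food saturation)}
#'   \item{m2}{sediment solids concentration (kg l^-1); scales the
#'     food half-saturation, see `kmn1`}
#'   \item{kmn1}{Michaelis-Menten carbon limitation constant K1 for
#'     macrobenthic ingestion, expressed per unit sediment solids
#'     (g C m^-3 per kg l^-1); the volumetric half-saturation used in
#'     the food response is `kmn1 * m2` (g C m^-3)}
#'   \item{resp_b}{macrobenthic respiration rate r (d^-1)}
#'   \item{beta_hat}{reference predation rate on macrobenthos before
#'     temperature and oxygen effects (m^2 (g C)^-1 d^-1)}
#'   \item{kdo}{predation DO half-saturation K_DO (mg O2 l^-1)}
#'   \item{mzero_b}{macrobenthic mortality rate at zero dissolved
#'     oxygen (d^-1)}
#'   \item{do_gx}{DO at which macrobenthic function (respiration,
#'     ingestion) is 50% of maximum (mg O2 l^-1)}
#'   \item{do_qx}{DO at which macrobenthic function is 25% of maximum
#'     (mg O2 l^-1)}
#'   \item{theta_b}{Arrhenius coefficient for macrobenthic rates}
#'   \item{theta_beta}{Arrhenius coefficient for the predation rate}
#'   \item{t_ref}{reference temperature for all Arrhenius terms (deg C)}
#'   \item{depth_h}{water-column coupling depth converting volumetric
#'     plankton biomass to benthic food availability (m)}
#'   \item{biomass_floor}{minimum permitted state values, a proxy for
#'     recolonisation (planktonic larvae settling from the water
#'     column for the benthos; immigration from adjacent waters for
#'     the plankton).  Either a single number applied to all states or
#'     a named vector `c(P = , M = , B = )` in each state's native
#'     units}
#' }
#'
#' @return A named list of class `"model_parameters"`.
#' @seealso [read_params_config()], [write_params_config()]
#' @examples
#' p <- model_parameters(mzero_b = 0.1)
#' p$mzero_b
#' @export
model_parameters <- function(...) {
  params <- default_parameters_list()
  over <- list(...)
  if (length(over) == 1L && is.list(over[[1L]]) && is.null(names(over)[1L]))
    over <- over[[1L]]
  if (length(over)) {
    bad <- setdiff(names(over), names(params))
    if (length(bad))
      stop_config(paste0("unknown parameter(s): ",
                         paste(bad, collapse = ", ")))
    for (nm in names(over)) params[[nm]] <- over[[nm]]
  }
  validate_parameters(params)
}

default_parameters_list <- function() {
  list(
    # phytoplankton
    pbm       = 1.5,
    resp_p    = 0.10,
    wa        = 0.10,
    phtl      = 8.0,
    light_k   = 8,
    kdin      = 0.025,
    theta_p   = 1.068,
    # zooplankton
    gz_max    = 1.0,
    kgz       = 1.0,
    bmz       = 0.08,
    mzero_z   = 0.60,
    docrit_z  = 2.0,
    phtlz     = 4.0,
    theta_z   = 1.08,
    # macrobenthos
    alpha     = 0.615,
    i0        = 0.33,
    m2        = 0.50,
    kmn1      = 1.0,
    resp_b    = 0.02,
    beta_hat  = 0.048,
    kdo       = 0.5,
    mzero_b   = 0.40,
    do_gx     = 1.27,
    do_qx     = 1.18,
    theta_b   = 1.08,
    theta_beta = 1.13,
    # shared
    t_ref     = 20,
    depth_h   = 10,
    biomass_floor = c(P = 0.001, M = 0.001, B = 0.2)
  )
}

validate_parameters <- function(p) {
  rates <- c("pbm", "resp_p", "wa", "phtl", "gz_max", "bmz", "mzero_z",
             "phtlz", "i0", "resp_b", "beta_hat", "mzero_b",
             "light_k", "kdin", "kgz", "m2", "kmn1")
  for (nm in rates) {
    if (!is_number(p[[nm]]) || p[[nm]] < 0)
      stop_config(paste0("parameter '", nm, "' must be a nonnegative number"))
  }
  for (nm in c("theta_p", "theta_z", "theta_b", "theta_beta")) {
    if (!is_number(p[[nm]]) || p[[nm]] <= 0)
      stop_config(paste0("parameter '", nm, "' must be positive"))
  }
  if (!is_number(p$alpha) || p$alpha <= 0 || p$alpha > 1)
    stop_config("alpha must lie in (0, 1]")
  if (!is_number(p$docrit_z) || p$docrit_z <= 0)
    stop_config("docrit_z must be positive")
  if (!is_number(p$kdo) || p$kdo <= 0)
    stop_config("kdo must be positive")
  if (!is_number(p$do_gx) || !is_number(p$do_qx) || p$do_qx >= p$do_gx)
    stop_config("do_qx must be smaller than do_gx")
  if (!is_number(p$depth_h) || p$depth_h <= 0)
    stop_config("depth_h must be positive")
  fl <- p$biomass_floor
  if (is.list(fl)) fl <- unlist(fl)  # e.g. read back from YAML
  if (!is.numeric(fl) || !length(fl) %in% c(1L, 3L) ||
      any(!is.finite(fl)) || any(fl < 0))
    stop_config("biomass_floor must be a nonnegative scalar or length-3 vector")
  if (length(fl) == 1L) fl <- c(P = fl, M = fl, B = unname(fl))
  if (is.null(names(fl))) names(fl) <- c("P", "M", "B")
  if (!all(c("P", "M", "B") %in% names(fl)))
    stop_config("a length-3 biomass_floor needs names P, M, B")
  p$biomass_floor <- fl[c("P", "M", "B")]
  if (!is_number(p$t_ref)) stop_config("t_ref must be a number")
  structure(p, class = "model_parameters")
}

#' Default initial state
#'
#' Day-1 (mid-winter) climatological biomass values used when no initial
#' condition is supplied: phytoplankton and zooplankton near their
#' winter minima, macrobenthos at a modest overwintering stock.
#'
#' @return A list with components `P`, `M` (g C m^-3) and `B`
#'   (g C m^-2).
#' @export
default_init <- function() {
  list(P = 0.15, M = 0.03, B = 2.0)
}

#' @export
print.model_parameters <- function(x, ...) {
  cat("Ecosystem model parameters (", length(x), " values)\n", sep = "")
  df <- data.frame(value = unlist(x))
  print(df, ...)
  invisible(x)
}
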