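# Seasonal mixed-layer forcing: single-harmonic stand-in for circulation
# model output, plus the named scenario library.

#' Construct a seasonal mixed-layer forcing
#'
#' The physical/chemical environment of the 0-D model: mixed-layer depth
#' (MLD), sea-surface temperature and surface irradiance each follow a single
#' annual cosine harmonic, and the water below the layer carries fixed
#' nutrient concentrations. When the layer deepens, mixed-layer concentrations
#' relax toward the deep values at rate (dh/dt)/h (entrainment); when it
#' shoals, concentrations are unchanged. Particulate pools are assumed absent
#' below the layer, so deepening dilutes them. A weak background exchange
#' operates year-round.
#'
#' @param mld_mean,mld_amplitude,mld_phase Mean (m), annual amplitude (m) and
#'   day-of-year of maximum (deepest) mixed layer. `mld_amplitude` must be
#'   smaller than `mld_mean - 5` so the layer never shoals above 5 m.
#' @param sst_mean,sst_amplitude,sst_phase Sea-surface temperature harmonic
#'   (degrees C; phase = day of maximum).
#' @param surface_par_mean,surface_par_amplitude,surface_par_phase Surface
#'   photosynthetically available radiation harmonic (W m-2; phase = day of
#'   maximum, default the solstice, day 172). Light leads temperature: SST
#'   lags the irradiance maximum by roughly two months, and the deepest
#'   mixing sits at the end of winter.
#' @param attenuation_k Light attenuation coefficient (m-1).
#' @param deep_conc Named numeric vector of concentrations below the layer:
#'   `NH4`, `NO2`, `NO3` (uM N), `PO4` (uM P), `Fe` (nM).
#' @param background_exchange Weak mixing across the layer base (day-1),
#'   active even when the layer is not deepening.
#' @param nutricline_depth,nutricline_width Depth (m) and width (m) of the
#'   sub-layer nutrient gradient: the NO3, NO2 and PO4 concentrations seen by
#'   entrainment are the deep values scaled by a sigmoid
#'   `1/(1 + exp(-(mld - nutricline_depth)/nutricline_width))`, so shallow
#'   autumn deepening taps nutrient-poor water and only deep winter mixing
#'   reaches the full reservoir. `nutricline_depth = 0` (default) disables
#'   the profile (uniform reservoir). Ammonium and iron are uniform.
#' @return An object of class `mixed_layer_forcing`.
#' @seealso [build_scenario()], [evaluate_forcing()]
#' @export
mixed_layer_forcing <- function(mld_mean, mld_amplitude = 0, mld_phase = 60,
                                sst_mean, sst_amplitude = 0,
                                sst_phase = mld_phase + 182.5,
                                surface_par_mean,
                                surface_par_amplitude = 0,
                                surface_par_phase = 172,
                                attenuation_k = 0.04,
                                deep_conc = nutrient_vector(),
                                background_exchange = 0.02,
                                nutricline_depth = 0,
                                nutricline_width = 25) {
  deep_conc <- nutrient_vector(NH4 = deep_conc[["NH4"]],
                               NO2 = deep_conc[["NO2"]],
                               NO3 = deep_conc[["NO3"]],
                               PO4 = deep_conc[["PO4"]],
                               Fe = deep_conc[["Fe"]])
  f <- structure(list(mld_mean = mld_mean, mld_amplitude = mld_amplitude,
                      mld_phase = mld_phase, sst_mean = sst_mean,
                      sst_amplitude = sst_amplitude, sst_phase = sst_phase,
                      surface_par_mean = surface_par_mean,
                      surface_par_amplitude = surface_par_amplitude,
                      surface_par_phase = surface_par_phase,
                      attenuation_k = attenuation_k, deep_conc = deep_conc,
                      background_exchange = background_exchange,
                      nutricline_depth = nutricline_depth,
                      nutricline_width = nutricline_width),
                 class = "mixed_layer_forcing")
  validate_forcing(f)
}

validate_forcing <- function(f) {
  stopifnot(inherits(f, "mixed_layer_forcing"))
  if (f$mld_amplitude < 0 || f$mld_mean - f$mld_amplitude < 5)
    stop("mixed layer must stay deeper than 5 m: require 0 <= amplitude < mean - 5")
  if (any(f$deep_conc < 0)) stop("deep concentrations must be >= 0")
  if (f$attenuation_k <= 0) stop("attenuation_k must be > 0")
  if (f$background_exchange < 0) stop("background_exchange must be >= 0")
  if (f$nutricline_depth < 0 || f$nutricline_width <= 0)
    stop("nutricline_depth must be >= 0 and nutricline_width > 0")
  if (f$surface_par_mean < f$surface_par_amplitude)
    stop("surface PAR must stay >= 0: require amplitude <= mean")
  f
}

#' Construct a dissolved-nutrient vector
#'
#' @param NH4,NO2,NO3 Dissolved inorganic nitrogen species (uM N).
#' @param PO4 Phosphate (uM P).
#' @param Fe Dissolved iron (nM).
#' @return Named numeric vector with the five concentrations.
#' @export
nutrient_vector <- function(NH4 = 0, NO2 = 0, NO3 = 0, PO4 = 0, Fe = 0) {
  v <- c(NH4 = NH4, NO2 = NO2, NO3 = NO3, PO4 = PO4, Fe = Fe)
  if (any(!is.finite(v)) || any(v < 0))
    stop("nutrient concentrations must be finite and >= 0")
  v
}

#' Evaluate the forcing at given times
#'
#' Returns the sinusoidal mixed-layer depth, its analytic time derivative,
#' sea-surface temperature and surface irradiance. All outputs are exactly
#' 365-day periodic.
#'
#' @param forcing A [mixed_layer_forcing()].
#' @param t Time in days since the start of year 1 (vectorized, `t >= 0`).
#' @return A data.frame with columns `t`, `mld` (m), `dmld_dt` (m day-1),
#'   `sst` (degrees C), `surface_par` (W m-2).
#' @export
evaluate_forcing <- function(forcing, t) {
  validate_forcing(forcing)
  if (any(t < 0)) stop("t must be >= 0")
  w <- 2 * pi / 365
  am <- w * (t - forcing$mld_phase)
  data.frame(
    t = t,
    mld = forcing$mld_mean + forcing$mld_amplitude * cos(am),
    dmld_dt = -forcing$mld_amplitude * w * sin(am),
    sst = forcing$sst_mean +
      forcing$sst_amplitude * cos(w * (t - forcing$sst_phase)),
    surface_par = pmax(0, forcing$surface_par_mean +
      forcing$surface_par_amplitude *
        cos(w * (t - forcing$surface_par_phase)))
  )
}

#' Depth-averaged irradiance over the mixed layer
#'
#' Mean of exponentially attenuated light over a layer of thickness `mld`:
#' `I0 * (1 - exp(-k*h)) / (k*h)`. Strictly less than the surface value and
#' monotonically decreasing in both `mld` and `attenuation_k`.
#'
#' @param surface_par Surface irradiance I0 (W m-2, `>= 0`).
#' @param attenuation_k Attenuation coefficient (m-1, `> 0`).
#' @param mld Mixed-layer depth (m, `> 0`).
#' @return Mean irradiance (W m-2).
#' @export
mean_mixed_layer_irradiance <- function(surface_par, attenuation_k, mld) {
  if (any(mld <= 0)) stop("mld must be > 0")
  if (any(attenuation_k <= 0)) stop("attenuation_k must be > 0")
  if (any(surface_par < 0)) stop("surface_par must be >= 0")
  kh <- attenuation_k * mld
  surface_par * (-expm1(-kh)) / kh
}

#' Named forcing scenarios
#'
#' The scenario library stands in for the range of environmental regimes a
#' global circulation model exposes:
#' \describe{
#'   \item{tropical_oligotrophic}{permanently stratified, recycled-ammonium
#'     gyre; shallow MLD with small seasonal range, low deep nitrate.}
#'   \item{subtropical_seasonal}{deep winter mixing (MLD 20-300 m) over a
#'     nitrate-rich reservoir; the seasonal-succession site.}
#'   \item{temperate}{high-latitude regime: deeper mixing still, cold, high
#'     deep nitrate.}
#'   \item{hnlc_iron_limited}{identical to `tropical_oligotrophic` except
#'     deep iron is reduced to a strongly limiting level and deep nitrate is
#'     elevated (high-nutrient low-chlorophyll analog).}
#'   \item{closed_box}{constant MLD, no exchange: the mass-conservation
#'     diagnostic (run it with export disabled).}
#'   \item{nh4_only}{like the tropical gyre but with zero deep nitrate and
#'     nitrite; with nitrification disabled, ammonium is the only nitrogen
#'     source and nitrogen-use gene loss is exactly neutral.}
#' }
#'
#' @param name Scenario name, one of [scenario_names()].
#' @return A [mixed_layer_forcing()].
#' @export
build_scenario <- function(name) {
  tab <- .scenario_table()
  if (!is.character(name) || length(name) != 1 || !name %in% names(tab))
    stop("unknown scenario '", paste(name, collapse = ","),
         "'; valid scenarios: ", paste(names(tab), collapse = ", "))
  .forcing_from_list(tab[[name]])
}

#' @rdname build_scenario
#' @export
scenario_names <- function() names(.scenario_table())

.scenario_table <- function() {
  if (is.null(.pico_env$scenarios))
    .pico_env$scenarios <- jsonlite::read_json(.extdata("scenarios.json"),
                                               simplifyVector = TRUE)$scenarios
  .pico_env$scenarios
}

.forcing_from_list <- function(x) {
  dc <- unlist(x$deep_conc)
  mixed_layer_forcing(
    mld_mean = x$mld_mean, mld_amplitude = x$mld_amplitude,
    mld_phase = x$mld_phase, sst_mean = x$sst_mean,
    sst_amplitude = x$sst_amplitude, sst_phase = x$sst_phase,
    surface_par_mean = x$surface_par_mean,
    surface_par_amplitude = x$surface_par_amplitude,
    surface_par_phase = x$surface_par_phase,
    attenuation_k = x$attenuation_k,
    deep_conc = nutrient_vector(NH4 = dc[["NH4"]], NO2 = dc[["NO2"]],
                                NO3 = dc[["NO3"]], PO4 = dc[["PO4"]],
                                Fe = dc[["Fe"]]),
    background_exchange = x$background_exchange,
    nutricline_depth = x$nutricline_depth %||% 0,
    nutricline_width = x$nutricline_width %||% 25)
}

#' Read or write a forcing scenario as JSON
#'
#' One JSON document per scenario, keys exactly matching the
#' [mixed_layer_forcing()] field names.
#'
#' @param forcing A `mixed_layer_forcing`.
#' @param path File path.
#' @return `read_scenario` returns a `mixed_layer_forcing`;
#'   `write_scenario` returns `path` invisibly.
#' @export
write_scenario <- function(forcing, path) {
  validate_forcing(forcing)
  x <- unclass(forcing)
  x$deep_conc <- as.list(x$deep_conc)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_scenario
#' @export
read_scenario <- function(path) {
  .forcing_from_list(jsonlite::read_json(path, simplifyVector = TRUE))
}
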