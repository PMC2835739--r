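# The individual rate laws of the ecosystem model, exposed as pure,
# vectorized functions. The compiled system derivative uses the same
# formulas; test-derivative.R asserts the two routes agree.

#' Gaussian temperature response
#'
#' `gamma_T = exp(-((sst - T_opt)/T_width)^2)`: 1 at the optimum, `exp(-1)`
#' one width away, symmetric.
#'
#' @param sst Temperature (degrees C).
#' @param traits A one-row trait set (or list) with `T_opt`, `T_width`.
#' @return Dimensionless modifier in (0, 1].
#' @export
temperature_modifier <- function(sst, traits) {
  if (any(traits$T_width <= 0)) stop("T_width must be > 0")
  exp(-((sst - traits$T_opt) / traits$T_width)^2)
}

#' Saturating light response with photoinhibition
#'
#' `gamma_I = c * (1 - exp(-I/I_opt)) * exp(-k_inhib * I)` with `c` the
#' normalization making the maximum over `I` equal 1. With `k_inhib = 0` the
#' response saturates to 1; with `k_inhib > 0` the maximum sits at the finite
#' irradiance `I_opt * log(1 + 1/(k_inhib * I_opt))`.
#'
#' @param I Irradiance (W m-2, `>= 0`).
#' @param traits Trait set with `I_opt` and `k_inhib`.
#' @return Dimensionless modifier in \[0, 1\].
#' @export
light_modifier <- function(I, traits) {
  if (any(traits$I_opt <= 0)) stop("I_opt must be > 0")
  if (any(I < 0)) stop("irradiance must be >= 0")
  peak <- 1
  if (traits$k_inhib > 0) {
    istar <- traits$I_opt * log(1 + 1 / (traits$k_inhib * traits$I_opt))
    peak <- (1 - exp(-istar / traits$I_opt)) * exp(-traits$k_inhib * istar)
  }
  (1 - exp(-I / traits$I_opt)) * exp(-traits$k_inhib * I) / peak
}

#' Ammonium repression of nitrate/nitrite use
#'
#' `exp(-psi * NH4)`: 1 with no ammonium (or with repression disabled),
#' strictly decreasing as ammonium accumulates.
#'
#' @param NH4 Ammonium concentration (uM N, `>= 0`).
#' @param psi Inhibition coefficient (uM-1, `>= 0`).
#' @return Dimensionless factor in (0, 1].
#' @export
ammonium_inhibition <- function(NH4, psi) {
  if (any(NH4 < 0)) stop("NH4 must be >= 0")
  if (any(psi < 0)) stop("psi must be >= 0")
  exp(-psi * NH4)
}

#' Nitrogen limitation and source partitioning
#'
#' Monod uptake affinities per source, with ammonium repression of the
#' oxidized sources and capability gating:
#' `u_NH4 = NH4/(K_NH4+NH4)`;
#' `u_NO2 = can_NO2 * NO2/(K_NO2+NO2) * exp(-psi*NH4)`;
#' `u_NO3 = can_NO3 * NO3/(K_NO3+NO3) * exp(-psi*NH4)`.
#' Total nitrogen limitation is `gamma_N = min(1, u_NH4+u_NO2+u_NO3)` and the
#' uptake fractions are proportional to the `u` terms.
#'
#' @param nut Named nutrient vector (see [nutrient_vector()]).
#' @param traits Trait set (uses the K's and `psi`).
#' @param can_NO3,can_NO2 Effective capability; defaults come from `traits`.
#' @return List with `gamma_N`, `fractions` (named NH4/NO2/NO3, summing to 1
#'   when `gamma_N > 0`), and `defined` (FALSE when no source is usable, in
#'   which case the fractions are `NA`).
#' @export
nitrogen_uptake_partition <- function(nut, traits,
                                      can_NO3 = traits$can_NO3,
                                      can_NO2 = traits$can_NO2) {
  if (any(nut[c("NH4", "NO2", "NO3")] < 0))
    stop("nitrogen concentrations must be >= 0")
  inh <- ammonium_inhibition(nut[["NH4"]], traits$psi)
  u <- c(NH4 = nut[["NH4"]] / (traits$K_NH4 + nut[["NH4"]]),
         NO2 = if (isTRUE(as.logical(can_NO2)))
           nut[["NO2"]] / (traits$K_NO2 + nut[["NO2"]]) * inh else 0,
         NO3 = if (isTRUE(as.logical(can_NO3)))
           nut[["NO3"]] / (traits$K_NO3 + nut[["NO3"]]) * inh else 0)
  s <- sum(u)
  if (s > 0)
    list(gamma_N = min(1, s), fractions = u / s, defined = TRUE)
  else
    list(gamma_N = 0, fractions = c(NH4 = NA_real_, NO2 = NA_real_,
                                    NO3 = NA_real_), defined = FALSE)
}

#' Liebig minimum across elements
#'
#' `gamma_nut = min(gamma_N, PO4/(K_PO4+PO4), Fe/(K_Fe+Fe))`: growth is set
#' by the single most limiting element, so under strong iron limitation the
#' nitrogen term (and with it any nitrogen-use capability difference) becomes
#' irrelevant.
#'
#' @param nut Named nutrient vector.
#' @param traits Trait set (uses `K_PO4`, `K_Fe`).
#' @param gamma_N Nitrogen limitation from [nitrogen_uptake_partition()].
#' @return Dimensionless modifier in \[0, 1\].
#' @export
elemental_limitation <- function(nut, traits, gamma_N) {
  if (any(nut[c("PO4", "Fe")] < 0)) stop("concentrations must be >= 0")
  pmin(gamma_N,
       nut[["PO4"]] / (traits$K_PO4 + nut[["PO4"]]),
       nut[["Fe"]] / (traits$K_Fe + nut[["Fe"]]))
}

#' Realized specific growth rate
#'
#' Multiplicative composition `mu = mu_max * gamma_T * gamma_I * gamma_nut`.
#'
#' @param traits Trait set (uses `mu_max`).
#' @param gamma_T,gamma_I,gamma_nut Modifiers in \[0, 1\].
#' @return Specific growth rate (day-1), between 0 and `mu_max`.
#' @export
realized_growth <- function(traits, gamma_T, gamma_I, gamma_nut) {
  stopifnot(all(c(gamma_T, gamma_I, gamma_nut) >= 0),
            all(c(gamma_T, gamma_I, gamma_nut) <= 1))
  traits$mu_max * gamma_T * gamma_I * gamma_nut
}

#' Holling type-II grazing losses
#'
#' A grazer feeds on the palatability-weighted total biomass of its size
#' class, `B = sum(pal_i * B_i)`; total ingestion is
#' `g_max * B^n/(K_graze^n + B^n) * Z`, apportioned to each prey in
#' proportion to its weighted biomass. Mutant pools share the parent's
#' palatability. The saturation exponent `n` is 1 for a Holling type-II
#' response and 2 (the package default) for the type-III form, whose
#' low-abundance prey refuge keeps rare populations from being ground to
#' unphysical depths; ingestion is half-saturated at `B = K_graze` for any
#' `n`.
#'
#' @param prey_biomass Numeric vector of prey pool biomasses (uM P).
#' @param palatability Matching palatability vector (0, 1].
#' @param grazer List with `g_max` (day-1), `K_graze` (uM P), `biomass`
#'   (uM P) and optionally `exponent` (default 1).
#' @return Numeric vector of per-prey loss rates (uM P day-1).
#' @export
grazing_loss <- function(prey_biomass, palatability, grazer) {
  stopifnot(length(prey_biomass) == length(palatability))
  n <- grazer$exponent %||% 1
  w <- palatability * pmax(prey_biomass, 0)
  btot <- sum(w)
  if (btot <= 0) return(rep(0, length(prey_biomass)))
  ing <- grazer$g_max * btot^n / (grazer$K_graze^n + btot^n) *
    grazer$biomass
  ing * w / btot
}

#' First-order nitrification fluxes
#'
#' `NH4 -> NO2` at `k1 * NH4` and `NO2 -> NO3` at `k2 * NO2`; total fixed
#' nitrogen is unchanged.
#'
#' @param nut Named nutrient vector.
#' @param k_nitrif1,k_nitrif2 Rate constants (day-1, `>= 0`).
#' @return Named vector `c(NH4_to_NO2, NO2_to_NO3)` (uM N day-1).
#' @export
nitrification_fluxes <- function(nut, k_nitrif1, k_nitrif2) {
  stopifnot(k_nitrif1 >= 0, k_nitrif2 >= 0)
  c(NH4_to_NO2 = k_nitrif1 * nut[["NH4"]],
    NO2_to_NO3 = k_nitrif2 * nut[["NO2"]])
}

#' Detritus remineralization and export
#'
#' Detrital phosphorus returns to phosphate, detrital nitrogen to ammonium
#' (the recycling loop that keeps stratified regimes ammonium-rich), and
#' detrital iron to dissolved iron, each at `remin_rate * pool`; an
#' additional `export_rate * pool` sinks out of the system.
#'
#' @param det List/vector with `det_P`, `det_N`, `det_Fe`, `remin_rate`,
#'   `export_rate`.
#' @return List with nutrient `sources` (named `PO4`, `NH4`, `Fe`) and
#'   `export` (named losses from each detritus pool).
#' @export
remineralization_fluxes <- function(det) {
  stopifnot(det$remin_rate >= 0, det$export_rate >= 0)
  list(sources = c(PO4 = det$remin_rate * det$det_P,
                   NH4 = det$remin_rate * det$det_N,
                   Fe = det$remin_rate * det$det_Fe),
       export = c(det_P = det$export_rate * det$det_P,
                  det_N = det$export_rate * det$det_N,
                  det_Fe = det$export_rate * det$det_Fe))
}
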