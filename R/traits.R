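# Physiological trait sets for individual phytoplankton types.

#' Construct a phytoplankton trait set
#'
#' One row of the community table: the full physiology of a single
#' phytoplankton type. Growth is `mu_max` times a Gaussian temperature
#' response, a normalized saturating/photoinhibited light response, and a
#' Liebig minimum over nitrogen, phosphorus and iron limitation. Nitrogen can
#' be taken up as ammonium, nitrite or nitrate (Monod kinetics per source),
#' with nitrate and nitrite uptake repressed by ambient ammonium through
#' `exp(-psi * NH4)`.
#'
#' @param id Label (unique within a community).
#' @param size_class `"small"` (picophytoplankton; may receive mutants) or
#'   `"large"`.
#' @param mu_max Maximum specific growth rate (day-1).
#' @param T_opt,T_width Optimum temperature and Gaussian width (degrees C).
#' @param I_opt Light response scale (W m-2).
#' @param k_inhib Photoinhibition coefficient ((W m-2)-1, `>= 0`).
#' @param K_NH4,K_NO2,K_NO3 Nitrogen half-saturations (uM N).
#' @param K_PO4 Phosphate half-saturation (uM P).
#' @param K_Fe Iron half-saturation (nM).
#' @param psi Ammonium inhibition coefficient for NO3/NO2 use (uM-1).
#' @param R_FeP Iron quota (nM Fe per uM P biomass).
#' @param mortality Linear mortality rate (day-1).
#' @param palatability Relative grazing vulnerability, in (0, 1].
#' @param can_NO3,can_NO2 Capability flags; ammonium use is always possible.
#' @return A one-row data.frame of class `phyto_community`.
#' @export
phyto_traits <- function(id, size_class = c("small", "large"),
                         mu_max, T_opt, T_width = 8, I_opt = 60,
                         k_inhib = 0.001, K_NH4, K_NO2 = K_NH4,
                         K_NO3 = K_NH4, K_PO4 = K_NH4 / 16, K_Fe = 0.2,
                         psi = 1.5, R_FeP = 1.5, mortality = 0.05,
                         palatability = 1, can_NO3 = TRUE, can_NO2 = TRUE) {
  size_class <- match.arg(size_class)
  com <- data.frame(id = as.character(id), size_class = size_class,
                    mu_max = mu_max, T_opt = T_opt, T_width = T_width,
                    I_opt = I_opt, k_inhib = k_inhib, K_NH4 = K_NH4,
                    K_NO2 = K_NO2, K_NO3 = K_NO3, K_PO4 = K_PO4,
                    K_Fe = K_Fe, psi = psi, R_FeP = R_FeP,
                    mortality = mortality, palatability = palatability,
                    can_NO3 = can_NO3, can_NO2 = can_NO2,
                    stringsAsFactors = FALSE)
  class(com) <- c("phyto_community", "data.frame")
  validate_community(com)
}

#' Validate a community table
#'
#' Checks every per-type trait invariant, and the across-class ordering
#' contract when both size classes are present: picophytoplankton ("small")
#' have lower maximum growth rates and lower N/P half-saturations than
#' "large" types (gleaners versus opportunists).
#'
#' @param com A `phyto_community` data.frame.
#' @return `com`, invisibly classed, or an error naming the offending field.
#' @export
validate_community <- function(com) {
  stopifnot(is.data.frame(com))
  need <- c("id", "size_class", .TRAIT_COLS, "can_NO3", "can_NO2")
  miss <- setdiff(need, names(com))
  if (length(miss)) stop("community table missing columns: ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(com$id)) stop("duplicated type ids")
  if (!all(com$size_class %in% c("small", "large")))
    stop("size_class must be 'small' or 'large'")
  chk <- function(ok, what) if (!all(ok)) stop("invalid trait '", what,
    "' for type(s): ", paste(com$id[!ok], collapse = ", "))
  chk(com$mu_max > 0, "mu_max")
  chk(com$T_width > 0, "T_width")
  chk(com$I_opt > 0, "I_opt")
  chk(com$k_inhib >= 0, "k_inhib")
  for (kk in c("K_NH4", "K_NO2", "K_NO3", "K_PO4", "K_Fe"))
    chk(com[[kk]] > 0, kk)
  chk(com$psi >= 0, "psi")
  chk(com$R_FeP > 0, "R_FeP")
  chk(com$mortality >= 0, "mortality")
  chk(com$palatability > 0 & com$palatability <= 1, "palatability")
  sm <- com$size_class == "small"
  if (any(sm) && any(!sm)) {
    ord <- function(col) max(com[[col]][sm]) < min(com[[col]][!sm])
    for (col in c("mu_max", "K_NH4", "K_NO2", "K_NO3", "K_PO4"))
      if (!ord(col)) stop("size-class ordering violated for ", col,
        ": every small value must be below every large value")
  }
  if (!inherits(com, "phyto_community"))
    class(com) <- c("phyto_community", "data.frame")
  com
}

# numeric trait matrix in the column order the C++ side expects
.traits_matrix <- function(com) {
  m <- as.matrix(com[, .TRAIT_COLS])
  m <- cbind(m, small = as.numeric(com$size_class == "small"),
             can_NO3 = as.numeric(com$can_NO3),
             can_NO2 = as.numeric(com$can_NO2))
  storage.mode(m) <- "double"
  m
}
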