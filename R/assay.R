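# Mutant bookkeeping and the selective-disadvantage statistics.

#' Mutation parameters
#'
#' Each division of a picophytoplankton parent produces, with probability
#' `rate_lambda` per mutant class, one of three mutants: a null mutant
#' (identical to the parent), a nitrate-loss mutant (`can_NO3 = FALSE`), and
#' a nitrate/nitrite-loss mutant (neither oxidized source usable). Mutation
#' begins at `onset` (default: after three years of community spin-up);
#' mutant pools start at exactly zero biomass and are filled only by the
#' mutation flux. Because each class arises at the same rate, relative mutant
#' abundances read out selection alone.
#'
#' @param rate_lambda Mutations per division per class (default `1e-8`).
#' @param onset Days since simulation start (default `3 * 365`).
#' @return List of class `mutation_params`.
#' @export
mutation_params <- function(rate_lambda = 1e-8, onset = 3 * 365) {
  stopifnot(rate_lambda >= 0, rate_lambda < 0.01, onset >= 0)
  structure(list(rate_lambda = rate_lambda, onset = onset),
            class = "mutation_params")
}

#' Mutation inflows to the three mutant pools
#'
#' Before `onset` all inflows are zero; after it, each class receives
#' `rate_lambda * gross_growth`, where gross growth `mu * B` (uM P day-1)
#' counts divisions. The parent is debited the sum, so mutation conserves
#' mass.
#'
#' @param gross_growth Parent gross production (uM P day-1, `>= 0`).
#' @param params A [mutation_params()].
#' @param t Time (days).
#' @return Named vector of inflows for `NULL`, `NO3_LOSS`, `NO3NO2_LOSS`
#'   with attribute `parent_debit`.
#' @export
mutation_fluxes <- function(gross_growth, params, t) {
  if (gross_growth < 0) stop("gross_growth must be >= 0")
  stopifnot(inherits(params, "mutation_params"))
  f <- if (t < params$onset) c(0, 0, 0)
       else rep(params$rate_lambda * gross_growth, 3)
  names(f) <- c("NULL", "NO3_LOSS", "NO3NO2_LOSS")
  attr(f, "parent_debit") <- sum(f)
  f
}

#' Disadvantage of losing nitrate use
#'
#' `D_NO3 = log10(null / NO3-loss)`: 0 means the loss is neutral, positive
#' means it is selected against. Non-positive inputs yield `NA` (flagged,
#' not an error) so batch computation over masked series keeps going.
#'
#' @param null_biomass,no3_loss_biomass Abundances (uM P), vectorized.
#' @return Dimensionless log10 ratio (NA where undefined).
#' @export
disadvantage_no3 <- function(null_biomass, no3_loss_biomass) {
  out <- rep(NA_real_, length(null_biomass))
  ok <- is.finite(null_biomass) & is.finite(no3_loss_biomass) &
    null_biomass > 0 & no3_loss_biomass > 0
  out[ok] <- log10(null_biomass[ok] / no3_loss_biomass[ok])
  out
}

#' Disadvantage of losing nitrite use
#'
#' `D_NO2 = log10(NO3-loss / NO3+NO2-loss)`: the further penalty of losing
#' nitrite use on top of nitrate use.
#'
#' @param no3_loss_biomass,no3no2_loss_biomass Abundances (uM P), vectorized.
#' @return Dimensionless log10 ratio (NA where undefined).
#' @export
disadvantage_no2 <- function(no3_loss_biomass, no3no2_loss_biomass) {
  disadvantage_no3(no3_loss_biomass, no3no2_loss_biomass)
}

#' Mask by parent abundance
#'
#' Disadvantage indices are only reported where the parent is abundant:
#' strictly greater than `threshold_frac` times its maximum over the analysis
#' domain (here the time axis; default threshold 1e-3).
#'
#' @param parent_series Parent biomass over the analysis domain.
#' @param threshold_frac Fraction of the maximum, in (0, 1).
#' @return Logical vector: TRUE where the index may be reported.
#' @export
mask_by_parent_abundance <- function(parent_series, threshold_frac = 1e-3) {
  if (length(parent_series) == 0) stop("empty parent series")
  stopifnot(threshold_frac > 0, threshold_frac < 1)
  parent_series > threshold_frac * max(parent_series)
}

#' Mean over the final whole years of a daily series
#'
#' @param series Daily values.
#' @param window Number of final whole years to average (default 1).
#' @param per_year Samples per year (default 365).
#' @return Arithmetic mean over the final `window * per_year` values.
#' @export
annual_average <- function(series, window = 1, per_year = 365) {
  n <- window * per_year
  if (length(series) < n)
    stop("series (", length(series), ") shorter than averaging window (",
         n, ")")
  mean(series[(length(series) - n + 1):length(series)])
}

#' Convert phosphorus biomass to cell density
#'
#' `cells ml-1 = biomass [uM P] * 1e-6 mol/L * 30.974 g/mol * 1e15 fg/g /
#' (1e3 ml/L) / fg_P_per_cell`. The default 1 fg P per cell is a typical
#' picocyanobacterial quota.
#'
#' @param biomass Phosphorus biomass (uM P, `> 0`).
#' @param fg_P_per_cell Cell phosphorus quota (fg, `> 0`, default 1).
#' @return Cells per millilitre.
#' @export
biomass_to_cells <- function(biomass, fg_P_per_cell = 1) {
  if (any(fg_P_per_cell <= 0)) stop("fg_P_per_cell must be > 0")
  if (any(biomass <= 0)) stop("biomass must be > 0")
  biomass * 1e-6 * 30.974 * 1e15 / 1e3 / fg_P_per_cell
}

#' Selective-disadvantage assay of a simulation
#'
#' For every picophytoplankton parent, averages the parent and mutant pools
#' over the analysis window (by default the final whole year, the paper-style
#' reporting year), restricted to times where the parent passes the abundance
#' mask, and forms the two disadvantage indices. With
#' `average = "biomass"` (default) biomasses are averaged first and the
#' log-ratio taken of the means; `average = "ratio"` averages the
#' instantaneous log-ratios instead.
#'
#' @param sim A `pico_sim` object from [simulate_ecosystem()] or
#'   [run_experiment()].
#' @param window Final whole years to analyse (default 1).
#' @param threshold_frac Parent-abundance mask threshold (default 1e-3).
#' @param average `"biomass"` or `"ratio"`.
#' @return data.frame of class `assay_result`: one row per small parent with
#'   mean pool biomasses, `D_NO3`, `D_NO2`, `masked` (TRUE when the parent
#'   never passes the mask, in which case indices are NA) and the window.
#' @export
compute_assay <- function(sim, window = 1, threshold_frac = 1e-3,
                          average = c("biomass", "ratio")) {
  average <- match.arg(average)
  stopifnot(inherits(sim, "pico_sim"))
  pt <- sim$pool_table
  nidx <- .window_index(sim, window)
  small_parents <- pt$parent_id[pt$class == "PARENT" & pt$small &
                                  pt$has_mutants]
  rows <- lapply(small_parents, function(pid) {
    pcol <- function(cls) sim$pools[nidx, pt$class == cls &
                                      pt$parent_id == pid]
    par <- pcol("PARENT"); nul <- pcol("NULL")
    l3 <- pcol("NO3_LOSS"); l32 <- pcol("NO3NO2_LOSS")
    msk <- mask_by_parent_abundance(par, threshold_frac)
    masked <- !any(msk)
    if (masked) {
      d3 <- d2 <- NA_real_
      mn <- c(NA_real_, NA_real_, NA_real_, NA_real_)
    } else {
      mn <- c(mean(par[msk]), mean(nul[msk]), mean(l3[msk]),
              mean(l32[msk]))
      if (average == "biomass") {
        d3 <- disadvantage_no3(mn[2], mn[3])
        d2 <- disadvantage_no2(mn[3], mn[4])
      } else {
        d3 <- mean(disadvantage_no3(nul[msk], l3[msk]))
        d2 <- mean(disadvantage_no2(l3[msk], l32[msk]))
      }
    }
    data.frame(parent_id = pid, mean_parent = mn[1], mean_null = mn[2],
               mean_no3_loss = mn[3], mean_no3no2_loss = mn[4],
               D_NO3 = d3, D_NO2 = d2, masked = masked,
               window_days = length(nidx), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("assay_result", "data.frame")
  out
}

#' Community-aggregate disadvantage indices
#'
#' The whole-picophytoplankton view: mutant pools are summed over all small
#' parents at each time, averaged over the analysis window, and the log10
#' ratios taken of the summed means (no per-parent masking; the sums are
#' dominated by abundant parents).
#'
#' @inheritParams compute_assay
#' @return Named vector `c(D_NO3, D_NO2)`.
#' @export
aggregate_disadvantage <- function(sim, window = 1) {
  stopifnot(inherits(sim, "pico_sim"))
  pt <- sim$pool_table
  nidx <- .window_index(sim, window)
  tot <- function(cls) {
    cols <- which(pt$class == cls & pt$small)
    mean(rowSums(sim$pools[nidx, cols, drop = FALSE]))
  }
  c(D_NO3 = unname(disadvantage_no3(tot("NULL"), tot("NO3_LOSS"))),
    D_NO2 = unname(disadvantage_no2(tot("NO3_LOSS"), tot("NO3NO2_LOSS"))))
}

.window_index <- function(sim, window) {
  tend <- max(sim$time)
  idx <- which(sim$time > tend - window * 365 + 1e-9)
  if (length(idx) < 2)
    stop("simulation does not cover the requested analysis window")
  idx
}
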