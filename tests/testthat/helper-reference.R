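# Shared fixtures and an independent R assembly of the state derivative.
# The reference implementation composes the exported rate-law operations in
# plain R; test-derivative.R checks the compiled derivative against it at
# randomly sampled state points (dual-route check).

tiny_community <- function() {
  com <- rbind(
    phyto_traits("picoA", "small", mu_max = 0.6, T_opt = 24, T_width = 6,
                 I_opt = 40, k_inhib = 0.002, K_NH4 = 0.08, K_NO2 = 0.1,
                 K_NO3 = 0.1, K_PO4 = 0.006, K_Fe = 0.15, psi = 1.5,
                 R_FeP = 1.2, mortality = 0.05, palatability = 0.9),
    phyto_traits("picoB", "small", mu_max = 0.9, T_opt = 18, T_width = 9,
                 I_opt = 30, k_inhib = 0.001, K_NH4 = 0.12, K_NO2 = 0.15,
                 K_NO3 = 0.15, K_PO4 = 0.01, K_Fe = 0.25, psi = 1.5,
                 R_FeP = 2.0, mortality = 0.06, palatability = 1),
    phyto_traits("diatom", "large", mu_max = 2.0, T_opt = 14, T_width = 8,
                 I_opt = 90, k_inhib = 0.001, K_NH4 = 0.5, K_NO2 = 0.6,
                 K_NO3 = 0.6, K_PO4 = 0.03, K_Fe = 0.6, psi = 1.5,
                 R_FeP = 1.8, mortality = 0.08, palatability = 0.85))
  class(com) <- c("phyto_community", "data.frame")
  validate_community(com)
}

# random non-negative state with the model's layout, biased toward
# ecologically plausible magnitudes
random_state <- function(model) {
  n <- length(model$y0)
  y <- stats::runif(n, 0, 1) * 10^stats::runif(n, -4, 0)
  names(y) <- model$state_names
  y[1:5] <- c(stats::runif(1, 0, 2), stats::runif(1, 0, 1),
              stats::runif(1, 0, 10), stats::runif(1, 0, 1.5),
              stats::runif(1, 0, 2))
  y
}

# full right-hand side assembled in R from the exported operations
ref_derivative <- function(model, t, y) {
  com <- model$community
  f <- model$forcing
  params <- model$params
  pt <- model$pool_table
  np <- model$n_pools; ng <- model$n_grazers
  nm <- model$state_names
  yp <- pmax(y, 0)
  nut <- nutrient_vector(NH4 = yp[[1]], NO2 = yp[[2]], NO3 = yp[[3]],
                         PO4 = yp[[4]], Fe = yp[[5]])
  pools <- yp[5 + seq_len(np)]
  graz <- if (ng) yp[5 + np + seq_len(ng)] else numeric(0)
  det <- yp[5 + np + ng + 1:3]

  env <- evaluate_forcing(f, t)
  ibar <- mean_mixed_layer_irradiance(env$surface_par, f$attenuation_k,
                                      env$mld)
  exch <- max(env$dmld_dt, 0) / env$mld + f$background_exchange
  ncl <- if (f$nutricline_depth > 0)
    1 / (1 + exp(-(env$mld - f$nutricline_depth) / f$nutricline_width))
  else 1
  deep_eff <- f$deep_conc * c(1, ncl, ncl, ncl, 1)

  dnut <- exch * (deep_eff - nut)
  nf <- nitrification_fluxes(nut, model$pars$biogeo[1], model$pars$biogeo[2])
  dnut["NH4"] <- dnut["NH4"] - nf[["NH4_to_NO2"]]
  dnut["NO2"] <- dnut["NO2"] + nf[["NH4_to_NO2"]] - nf[["NO2_to_NO3"]]
  dnut["NO3"] <- dnut["NO3"] + nf[["NO2_to_NO3"]]

  remin <- params$detritus$remin_rate
  export <- model$pars$biogeo[4]
  rf <- remineralization_fluxes(list(det_P = det[[1]], det_N = det[[2]],
                                     det_Fe = det[[3]], remin_rate = remin,
                                     export_rate = export))
  dnut["PO4"] <- dnut["PO4"] + rf$sources[["PO4"]]
  dnut["NH4"] <- dnut["NH4"] + rf$sources[["NH4"]]
  dnut["Fe"] <- dnut["Fe"] + rf$sources[["Fe"]]
  ddet <- -(remin + export) * det - exch * det

  RNP <- params$R_NP
  dpools <- numeric(np)
  mut <- model$mutation
  for (i in seq_len(np)) {
    k <- match(pt$parent_id[i], com$id)
    tr <- com[k, ]
    cls <- pt$class[i]
    gT <- temperature_modifier(env$sst, tr)
    gI <- light_modifier(ibar, tr)
    can3 <- tr$can_NO3 && cls %in% c("PARENT", "NULL")
    can2 <- tr$can_NO2 && cls %in% c("PARENT", "NULL", "NO3_LOSS")
    up <- nitrogen_uptake_partition(nut, tr, can_NO3 = can3, can_NO2 = can2)
    gnut <- elemental_limitation(nut, tr, up$gamma_N)
    mu <- realized_growth(tr, gT, gI, gnut)
    gross <- mu * pools[i]
    if (up$defined && gross > 0) {
      nup <- RNP * gross * up$fractions
      dnut["NH4"] <- dnut["NH4"] - nup[["NH4"]]
      dnut["NO2"] <- dnut["NO2"] - nup[["NO2"]]
      dnut["NO3"] <- dnut["NO3"] - nup[["NO3"]]
    }
    dnut["PO4"] <- dnut["PO4"] - gross
    dnut["Fe"] <- dnut["Fe"] - tr$R_FeP * gross
    mrt <- tr$mortality * pools[i]
    dpools[i] <- dpools[i] + gross - mrt - exch * pools[i]
    ddet <- ddet + c(mrt, RNP * mrt, tr$R_FeP * mrt)
    if (!is.null(mut) && cls == "PARENT" && tr$size_class == "small" &&
        pt$has_mutants[i]) {
      mf <- mutation_fluxes(gross, mut, t)
      dpools[i] <- dpools[i] - attr(mf, "parent_debit")
      for (mc in names(mf)) {
        j <- which(pt$parent_id == pt$parent_id[i] & pt$class ==
                     c("NULL" = "NULL", "NO3_LOSS" = "NO3_LOSS",
                       "NO3NO2_LOSS" = "NO3NO2_LOSS")[mc])
        dpools[j] <- dpools[j] + mf[[mc]]
      }
    }
  }

  dgraz <- numeric(ng)
  if (ng) {
    gcls <- if (ng == 2) c("small", "large")
            else unique(com$size_class)
    for (g in seq_len(ng)) {
      gp <- params$grazers[[gcls[g]]]
      prey <- which(pt$small == (gcls[g] == "small"))
      pal <- com$palatability[match(pt$parent_id[prey], com$id)]
      losses <- grazing_loss(pools[prey], pal,
                             list(g_max = gp$g_max, K_graze = gp$K_graze,
                                  biomass = graz[g],
                                  exponent = gp$exponent))
      ing <- sum(losses)
      dpools[prey] <- dpools[prey] - losses
      rfe <- com$R_FeP[match(pt$parent_id[prey], com$id)]
      zm <- gp$mortality * graz[g]
      dgraz[g] <- gp$assimilation * ing - zm - exch * graz[g]
      spill <- (1 - gp$assimilation) * ing + zm
      ddet <- ddet + c(spill, RNP * spill, sum(rfe * losses))
    }
  }

  out <- c(dnut, dpools, dgraz, ddet)
  names(out) <- nm
  out
}
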