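tr <- tiny_community()[1, ]   # picoA

test_that("temperature response is a normalized Gaussian", {
  expect_equal(temperature_modifier(tr$T_opt, tr), 1)
  expect_equal(temperature_modifier(tr$T_opt + tr$T_width, tr), exp(-1))
  expect_equal(temperature_modifier(tr$T_opt - tr$T_width, tr), exp(-1))
  # warm-adapted type beats cold-adapted type in warm water
  warm <- tr; warm$T_opt <- 24
  cold <- tr; cold$T_opt <- 18
  expect_gt(temperature_modifier(24, warm), temperature_modifier(24, cold))
  # strictly decreasing away from the optimum
  d <- temperature_modifier(tr$T_opt + c(0, 1, 3, 7, 12), tr)
  expect_true(all(diff(d) < 0))
  bad <- tr; bad$T_width <- 0
  expect_error(temperature_modifier(20, bad), "T_width")
})

test_that("light response: origin, saturation, photoinhibition peak", {
  expect_equal(light_modifier(0, tr), 0)
  sat <- tr; sat$k_inhib <- 0
  expect_equal(light_modifier(1e6, sat), 1, tolerance = 1e-10)
  # with photoinhibition the argmax is I_opt*log(1 + 1/(k*I_opt)) and the
  # response is normalized to 1 there
  istar <- tr$I_opt * log(1 + 1 / (tr$k_inhib * tr$I_opt))
  grid <- seq(1, 20 * istar, length.out = 4000)
  vals <- vapply(grid, light_modifier, numeric(1), traits = tr)
  expect_equal(grid[which.max(vals)], istar, tolerance = istar * 0.01)
  expect_equal(max(vals), 1, tolerance = 1e-4)
  expect_lt(light_modifier(10 * istar, tr), light_modifier(istar, tr))
  bad <- tr; bad$I_opt <- 0
  expect_error(light_modifier(10, bad), "I_opt")
  expect_error(light_modifier(-1, tr), ">= 0")
})

test_that("ammonium repression is the exponential inhibition factor", {
  expect_equal(ammonium_inhibition(0, 1.5), 1)
  expect_equal(ammonium_inhibition(3, 0), 1)
  expect_equal(ammonium_inhibition(log(2) / 1.5, 1.5), 0.5)
  expect_true(all(diff(ammonium_inhibition(c(0, 0.1, 0.5, 2), 1.5)) < 0))
  expect_error(ammonium_inhibition(-0.1, 1.5), ">= 0")
  expect_error(ammonium_inhibition(0.1, -1), ">= 0")
})

test_that("nitrogen partition: single-source, capability gating, repression", {
  # single source at its half-saturation
  nut <- nutrient_vector(NO3 = tr$K_NO3)
  u <- nitrogen_uptake_partition(nut, tr)
  expect_equal(u$gamma_N, 0.5)
  expect_equal(u$fractions[["NO3"]], 1)
  # the double-loss mutant starves without ammonium
  u2 <- nitrogen_uptake_partition(nutrient_vector(NO2 = 5, NO3 = 5), tr,
                                  can_NO3 = FALSE, can_NO2 = FALSE)
  expect_equal(u2$gamma_N, 0)
  expect_false(u2$defined)
  expect_true(all(is.na(u2$fractions)))
  # ammonium-rich regime: all capability classes equivalent within 1e-3
  rich <- nutrient_vector(NH4 = 100 * tr$K_NH4, NO2 = 1, NO3 = 1)
  gs <- c(nitrogen_uptake_partition(rich, tr)$gamma_N,
          nitrogen_uptake_partition(rich, tr, can_NO3 = FALSE)$gamma_N,
          nitrogen_uptake_partition(rich, tr, can_NO3 = FALSE,
                                    can_NO2 = FALSE)$gamma_N)
  expect_lt(max(gs) - min(gs), 1e-3)
  expect_gt(nitrogen_uptake_partition(rich, tr)$fractions[["NH4"]], 0.99)
  expect_error(nitrogen_uptake_partition(
    c(NH4 = -1, NO2 = 0, NO3 = 0, PO4 = 0, Fe = 0), tr), ">= 0")
})

test_that("Liebig minimum and multiplicative growth", {
  nut <- nutrient_vector(NH4 = 10, NO2 = 1, NO3 = 1, PO4 = 10,
                         Fe = tr$K_Fe / 100)
  g <- elemental_limitation(nut, tr, gamma_N = 1)
  expect_equal(g, (1 / 100) / (1 + 1 / 100), tolerance = 1e-12)
  replete <- nutrient_vector(NH4 = 1e4, NO2 = 0, NO3 = 0, PO4 = 1e4,
                             Fe = 1e4)
  expect_equal(elemental_limitation(replete, tr, 1), 1, tolerance = 1e-3)
  expect_equal(elemental_limitation(replete, tr, 0), 0)

  expect_equal(realized_growth(list(mu_max = 0.6), 0.9, 0.5, 0.4), 0.108)
  expect_equal(realized_growth(tr, 1, 1, 1), tr$mu_max)
  expect_equal(realized_growth(tr, 0, 1, 1), 0)
  expect_error(realized_growth(tr, 1.2, 1, 1))
})

test_that("grazing: symmetry, half-saturation, zero prey, refuge", {
  gz <- list(g_max = 1, K_graze = 0.2, biomass = 0.1, exponent = 2)
  expect_equal(grazing_loss(c(0, 0), c(1, 1), gz), c(0, 0))
  # equal prey, equal palatability: equal losses
  l <- grazing_loss(c(0.3, 0.3), c(0.9, 0.9), gz)
  expect_equal(l[1], l[2])
  # half-saturation at weighted biomass == K_graze, for either exponent
  for (n in c(1, 2)) {
    gzn <- list(g_max = 1, K_graze = 0.2, biomass = 0.1, exponent = n)
    expect_equal(sum(grazing_loss(0.2, 1, gzn)), 1 * 0.1 / 2)  # g_max*Z/2
  }
  # apportionment proportional to weighted biomass
  l2 <- grazing_loss(c(0.2, 0.1), c(1, 0.5), gz)
  expect_equal(l2[1] / l2[2], (0.2 * 1) / (0.1 * 0.5))
  # type-III refuge: specific loss vanishes as prey gets rare
  spec1 <- sum(grazing_loss(1e-4, 1, gz)) / 1e-4
  spec2 <- sum(grazing_loss(1e-2, 1, gz)) / 1e-2
  expect_lt(spec1, spec2 / 10)
})

test_that("nitrification and remineralization bookkeeping", {
  nut <- nutrient_vector(NH4 = 1, NO2 = 0.4)
  expect_equal(unname(nitrification_fluxes(nut, 0.05, 0.1)), c(0.05, 0.04))
  expect_equal(unname(nitrification_fluxes(nut, 0, 0)), c(0, 0))
  # conservation: the three dN terms from nitrification alone sum to zero
  fl <- nitrification_fluxes(nut, 0.07, 0.02)
  dn <- c(-fl[["NH4_to_NO2"]], fl[["NH4_to_NO2"]] - fl[["NO2_to_NO3"]],
          fl[["NO2_to_NO3"]])
  expect_equal(sum(dn), 0)

  det <- list(det_P = 0.5, det_N = 2, det_Fe = 1, remin_rate = 0.1,
              export_rate = 0.05)
  rf <- remineralization_fluxes(det)
  expect_equal(rf$sources[["NH4"]], 0.2)
  expect_equal(rf$sources[["PO4"]], 0.05)
  expect_equal(unname(rf$export), c(0.025, 0.1, 0.05))
  det$remin_rate <- 0
  expect_equal(unname(remineralization_fluxes(det)$sources), c(0, 0, 0))
})
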