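test_that("run_config validates the spin-up/onset/analysis schedule", {
  expect_error(run_config(t_end = 3 * 365 + 100), "730")
  cfg <- run_config()
  expect_equal(cfg$t_end, 1825)
  expect_true(cfg$nitrification)
  # scenario-resolved process switches
  expect_false(run_config(scenario = "nh4_only")$nitrification)
  expect_false(run_config(scenario = "closed_box")$export)
  expect_true(run_config(scenario = "closed_box", export = TRUE)$export)
})

test_that("mutant pools are exactly zero before onset and fill after", {
  m <- build_model(tiny_community(), "closed_box",
                   mutation = mutation_params(onset = 200))
  sim <- simulate_ecosystem(m, 400)
  mut_cols <- sim$pool_table$class != "PARENT"
  pre <- sim$time < 200
  expect_true(all(sim$pools[pre, mut_cols] == 0))
  expect_true(all(sim$pools[sim$time > 250, mut_cols] > 0))
})

test_that("simulation is deterministic and positivity-preserving", {
  cfg <- run_config(scenario = "tropical_oligotrophic",
                    community = list(type = "random", n_small = 3,
                                     n_large = 3), seed = 21)
  r1 <- run_experiment(cfg)
  r2 <- run_experiment(cfg)
  expect_identical(r1$sim$pools, r2$sim$pools)
  expect_identical(r1$assay, r2$assay)
  expect_true(all(r1$sim$pools >= 0))
  expect_true(all(r1$sim$nutrients >= 0))
  expect_lt(r1$sim$diagnostics$max_clip, 1e-9)
})

test_that("run outputs: tidy CSV trajectory, assay CSV, manifest", {
  outdir <- withr::local_tempdir()
  cfg <- run_config(community = list(type = "pair"), seed = 4,
                    t_end = 1825)
  run <- run_experiment(cfg, outdir = outdir)
  traj <- read.csv(file.path(outdir, "trajectory.csv"))
  expect_named(traj, c("time", "variable", "value"))
  expect_true(all(c("NH4", "E2", "E3.NO3_LOSS", "det_P") %in%
                    traj$variable))
  expect_equal(nrow(traj), length(run$sim$time) *
                 (5 + ncol(run$sim$pools) + ncol(run$sim$grazers) + 3))
  assay <- read.csv(file.path(outdir, "assay.csv"))
  expect_setequal(assay$mutant_class, c("NULL", "NO3_LOSS", "NO3NO2_LOSS"))
  man <- jsonlite::read_json(file.path(outdir, "manifest.json"),
                             simplifyVector = TRUE)
  expect_equal(man$scenario, "subtropical_seasonal")
  expect_equal(man$mutation$rate_lambda, 1e-8)
  # manifest + config reproduce the files bit-identically
  outdir2 <- withr::local_tempdir()
  run2 <- run_experiment(cfg, outdir = outdir2)
  expect_identical(unname(tools::md5sum(file.path(outdir, "trajectory.csv"))),
                   unname(tools::md5sum(file.path(outdir2, "trajectory.csv"))))
  # the embedded community is itself a valid input
  com <- validate_community(as.data.frame(man$community))
  expect_s3_class(com, "phyto_community")
})

test_that("ensembles: member independence and summary shape", {
  cfg <- run_config(community = list(type = "random", n_small = 2,
                                     n_large = 2), seed = 33)
  ens <- run_ensemble(cfg, n = 2)
  expect_length(ens$members, 2)
  expect_equal(nrow(ens$summary), 2)
  expect_true(is.na(ens$consistent_ordering))   # no E2/E3 in random runs
  # member 1 must equal a standalone run with the same member seed
  cfg1 <- cfg
  cfg1$seed <- ens$seeds[1]
  cfg1$community$seed <- ens$seeds[1]
  solo <- run_experiment(cfg1)
  expect_identical(solo$assay, ens$members[[1]]$assay)
  expect_error(run_ensemble(run_config(community = list(type = "pair"))),
               "seeded-random")
})

test_that("sweep axes modify exactly one knob", {
  cfg <- run_config(community = list(type = "random", n_small = 2,
                                     n_large = 2), seed = 12)
  sw <- sweep_experiment(cfg, axis = "deep_Fe", values = c(0.05, 1.2))
  expect_equal(nrow(sw$table), 2)
  expect_equal(sw$table$value, c(0.05, 1.2))
  f1 <- sw$runs[[1]]$sim$model$forcing
  f2 <- sw$runs[[2]]$sim$model$forcing
  expect_equal(f1$deep_conc[["Fe"]], 0.05)
  f1$deep_conc["Fe"] <- f2$deep_conc[["Fe"]]
  expect_identical(f1, f2)
  expect_error(sweep_experiment(cfg, axis = "lambda", values = 1e-8),
               "length")
})
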