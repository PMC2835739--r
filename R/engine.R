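# Model assembly, integration, and experiment orchestration.

#' Default ecosystem parameters
#'
#' Grazing, nitrification, detritus and integration settings, loaded from the
#' versioned table shipped with the package. Override individual entries by
#' modifying the returned list.
#'
#' @return Nested parameter list (see `inst/extdata/default_params.json`).
#' @export
default_params <- function() {
  jsonlite::read_json(.extdata("default_params.json"), simplifyVector = TRUE)
}

#' Assemble an integrable model
#'
#' Binds a community, a forcing, ecosystem parameters and a mutation scheme
#' into the flat structure the compiled derivative consumes. One pool is
#' created per parent type; every picophytoplankton parent additionally owns
#' three mutant pools (null, NO3 loss, NO3/NO2 loss) which start at zero
#' biomass and are filled only by the mutation flux after onset. One
#' Holling-II grazer per size class closes the food web.
#'
#' @param community A `phyto_community` (see [generate_community()],
#'   [make_ecotype_pair()], [phyto_traits()]).
#' @param forcing A [mixed_layer_forcing()] or scenario name.
#' @param params Ecosystem parameters, see [default_params()].
#' @param mutation A [mutation_params()], or `NULL` to disable mutation.
#' @param with_mutants Allocate mutant pools (default TRUE).
#' @param grazing Include grazers (default TRUE).
#' @param nitrification Enable NH4 -> NO2 -> NO3 oxidation (default TRUE).
#' @param export Enable detritus export out of the system (default TRUE).
#' @param fixed_nutrients Hold nutrient concentrations constant (diagnostic
#'   chemostat mode; default FALSE).
#' @return A `pico_model` list with elements `pars` (for the compiled code),
#'   `pool_table`, `y0`, `state_names`, `community`, `forcing`.
#' @export
build_model <- function(community, forcing, params = default_params(),
                        mutation = mutation_params(), with_mutants = TRUE,
                        grazing = TRUE, nitrification = TRUE, export = TRUE,
                        fixed_nutrients = FALSE) {
  if (is.character(forcing)) forcing <- build_scenario(forcing)
  validate_forcing(forcing)
  community <- validate_community(community)
  n <- nrow(community)
  small <- community$size_class == "small"

  pool_type <- seq_len(n)
  pool_class <- rep(0L, n)
  parent_id <- community$id
  mut_index <- matrix(-1L, n, 3)
  if (with_mutants && any(small)) {
    for (k in which(small)) {
      base <- length(pool_type)
      pool_type <- c(pool_type, rep(k, 3))
      pool_class <- c(pool_class, 1L, 2L, 3L)
      parent_id <- c(parent_id, rep(community$id[k], 3))
      mut_index[k, ] <- base + 0:2           # 0-based for C++
    }
  }
  np <- length(pool_type)
  pool_table <- data.frame(
    parent_id = parent_id,
    class = .MUTANT_CLASSES[pool_class + 1L],
    small = small[pool_type],
    has_mutants = (mut_index[, 1][pool_type] >= 0),
    stringsAsFactors = FALSE)
  pool_table$pool <- ifelse(pool_table$class == "PARENT", pool_table$parent_id,
    paste(pool_table$parent_id, pool_table$class, sep = "."))

  gz <- NULL
  if (grazing) {
    for (cls in c("small", "large")) {
      if (!any((community$size_class == cls))) next
      g <- params$grazers[[cls]]
      gz <- rbind(gz, c(as.numeric(cls == "small"), g$g_max, g$K_graze,
                        g$assimilation, g$mortality, g$exponent %||% 1))
    }
  }
  if (is.null(gz)) gz <- matrix(0, 0, 6)
  ng <- nrow(gz)

  mut <- if (is.null(mutation)) c(0, 0, 0)
         else c(mutation$rate_lambda, mutation$onset, 1)

  pars <- list(
    traits = .traits_matrix(community),
    pool_type = as.integer(pool_type - 1L),
    pool_class = as.integer(pool_class),
    mut_index = matrix(as.integer(mut_index), n, 3),
    grazers = gz,
    biogeo = c(if (nitrification) params$nitrification$k_nh4_no2 else 0,
               if (nitrification) params$nitrification$k_no2_no3 else 0,
               params$detritus$remin_rate,
               if (export) params$detritus$export_rate else 0,
               params$R_NP),
    mutation = mut,
    forcing = c(forcing$mld_mean, forcing$mld_amplitude, forcing$mld_phase,
                forcing$sst_mean, forcing$sst_amplitude, forcing$sst_phase,
                forcing$surface_par_mean, forcing$surface_par_amplitude,
                forcing$surface_par_phase, forcing$attenuation_k,
                forcing$background_exchange, forcing$nutricline_depth,
                forcing$nutricline_width),
    deep = unname(forcing$deep_conc[.NUTRIENTS]),
    flags = as.numeric(fixed_nutrients))

  y0 <- c(forcing$deep_conc[.NUTRIENTS],
          setNames(ifelse(pool_class == 0L, params$initial$phyto_biomass, 0),
                   pool_table$pool),
          if (ng) setNames(rep(params$grazer_init %||%
                                 params$initial$grazer_biomass, ng),
                           paste0("grazer_", seq_len(ng))),
          det_P = 0, det_N = 0, det_Fe = 0)

  structure(list(pars = pars, pool_table = pool_table, y0 = y0,
                 state_names = names(y0), community = community,
                 forcing = forcing, params = params, mutation = mutation,
                 n_pools = np, n_grazers = ng),
            class = "pico_model")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Full state derivative
#'
#' Evaluates d(state)/dt of the assembled ecosystem at one state point:
#' growth, nitrogen-source partitioning with ammonium repression, grazing,
#' mortality, mutation, nitrification, remineralization, export and
#' mixed-layer exchange. Mainly a diagnostic/testing surface; integration
#' happens in compiled code.
#'
#' @param model A [build_model()] result.
#' @param t Time (days).
#' @param y State vector (defaults to the model's initial state).
#' @return Named derivative vector (same layout as `model$y0`).
#' @export
system_derivative <- function(model, t, y = model$y0) {
  stopifnot(inherits(model, "pico_model"))
  if (length(y) != length(model$y0))
    stop("state length ", length(y), " does not match model (",
         length(model$y0), ")")
  bad <- which(!is.finite(y) | y < 0)
  if (length(bad))
    stop("state invariant violated (negative or non-finite) at: ",
         paste(model$state_names[bad], collapse = ", "))
  setNames(cpp_derivative(t, as.numeric(y), model$pars), model$state_names)
}

#' Integrate the ecosystem model
#'
#' Adaptive Dormand-Prince 5(4) integration with a positivity floor (tiny
#' negative undershoots are clipped to zero) and output at fixed cadence. The
#' defaults (`rtol 1e-8`, `atol 1e-12` uM) are deliberately tight: mutant
#' pools sit up to eight orders of magnitude below their parents and must not
#' drown in integrator noise.
#'
#' @param model A [build_model()] result.
#' @param t_end End time (days).
#' @param cadence Output interval (days, default 1).
#' @param rtol,atol Integration tolerances (defaults from
#'   [default_params()]).
#' @param t0 Start time (default 0).
#' @return A `pico_sim` list: `time`, matrices `nutrients`, `pools`,
#'   `grazers`, `detritus`, the `pool_table`, the originating `model`, and
#'   integrator `diagnostics`.
#' @export
simulate_ecosystem <- function(model, t_end, cadence = 1,
                               rtol = model$params$integration$rtol,
                               atol = model$params$integration$atol,
                               t0 = 0) {
  stopifnot(inherits(model, "pico_model"), t_end > t0)
  times <- seq(t0, t_end, by = cadence)
  if (times[length(times)] < t_end) times <- c(times, t_end)
  res <- cpp_integrate(as.numeric(model$y0), times, model$pars, rtol, atol,
                       model$params$integration$max_step,
                       model$params$integration$initial_step)
  y <- res$y
  colnames(y) <- model$state_names
  np <- model$n_pools; ng <- model$n_grazers
  structure(list(
    time = times,
    nutrients = y[, 1:5, drop = FALSE],
    pools = y[, 5 + seq_len(np), drop = FALSE],
    grazers = if (ng) y[, 5 + np + seq_len(ng), drop = FALSE]
              else matrix(0, length(times), 0),
    detritus = y[, 5 + np + ng + 1:3, drop = FALSE],
    pool_table = model$pool_table,
    model = model,
    diagnostics = res[c("n_accept", "n_reject", "n_clip", "max_clip")]),
    class = "pico_sim")
}

#' @export
print.pico_sim <- function(x, ...) {
  cat("<pico_sim> ", nrow(x$pools), " outputs, ", ncol(x$pools), " pools, ",
      ncol(x$grazers), " grazers; t in [", min(x$time), ", ", max(x$time),
      "] d\n", sep = "")
  cat("  integrator: ", x$diagnostics$n_accept, " accepted / ",
      x$diagnostics$n_reject, " rejected steps; max clip ",
      format(x$diagnostics$max_clip, digits = 3), "\n", sep = "")
  invisible(x)
}

#' Experiment configuration
#'
#' Everything needed to reproduce a run: forcing scenario, community source,
#' mutation scheme and integration schedule. The schedule follows the
#' reporting convention years 1-3 spin-up, year 4 mutant accumulation,
#' year 5 analysis, so `t_end` must be at least `onset + 730` days.
#'
#' @param scenario Scenario name (see [scenario_names()]) or a
#'   [mixed_layer_forcing()].
#' @param community Community source: `list(type = "random", seed, n_small,
#'   n_large)`, `list(type = "pair", style)`, `list(type = "pair_plus_large",
#'   seed, n_large)` (the prescribed pair over a randomized
#'   large-phytoplankton background), or `list(type = "explicit", traits)`.
#' @param mutation A [mutation_params()].
#' @param t_end Simulation length (days, default 5 years).
#' @param cadence Output cadence (days, default 1).
#' @param window Analysis window (final whole years, default 1).
#' @param seed Base seed for seeded community sources.
#' @param nitrification,export Process switches; `NULL` resolves by scenario
#'   (`nh4_only` disables nitrification, `closed_box` disables export).
#' @param rtol,atol Integrator tolerances (`NULL`: package defaults).
#' @return List of class `run_config`.
#' @export
run_config <- function(scenario = "subtropical_seasonal",
                       community = list(type = "random"),
                       mutation = mutation_params(),
                       t_end = 5 * 365, cadence = 1, window = 1, seed = 1,
                       nitrification = NULL, export = NULL,
                       rtol = NULL, atol = NULL) {
  scen_name <- if (is.character(scenario)) scenario else "custom"
  if (is.null(nitrification)) nitrification <- scen_name != "nh4_only"
  if (is.null(export)) export <- scen_name != "closed_box"
  stopifnot(inherits(mutation, "mutation_params"))
  if (t_end < mutation$onset + 730)
    stop("t_end must be >= onset + 730 days ",
         "(one accumulation year plus one analysis year)")
  community$type <- community$type %||% "random"
  structure(list(scenario = scenario, scenario_name = scen_name,
                 community = community, mutation = mutation, t_end = t_end,
                 cadence = cadence, window = window, seed = seed,
                 nitrification = nitrification, export = export,
                 rtol = rtol, atol = atol),
            class = "run_config")
}

.resolve_community <- function(spec, seed) {
  seed <- spec$seed %||% seed
  switch(spec$type,
    random = generate_community(spec$ranges %||% default_trait_ranges(),
                                n_small = spec$n_small %||% 15,
                                n_large = spec$n_large %||% 18, seed = seed),
    pair = make_ecotype_pair(spec$style %||% "E2_E3"),
    pair_plus_large = {
      bg <- generate_community(spec$ranges %||% default_trait_ranges(),
                               n_small = 1, n_large = spec$n_large %||% 18,
                               seed = seed)
      com <- rbind(make_ecotype_pair(spec$style %||% "E2_E3"),
                   bg[bg$size_class == "large", ])
      class(com) <- c("phyto_community", "data.frame")
      validate_community(com)
    },
    explicit = {
      tr <- spec$traits
      if (is.character(tr)) tr <- read_community(tr)
      validate_community(tr)
    },
    stop("unknown community source type '", spec$type, "'"))
}

#' Run a single experiment
#'
#' Resolves the configuration, integrates the ecosystem (mutation switches on
#' automatically at onset), computes the per-parent selective-disadvantage
#' assay and the community aggregate over the analysis window, and assembles
#' a manifest sufficient to reproduce the run. Optionally writes trajectory
#' CSV, assay CSV and manifest JSON to `outdir`.
#'
#' @param config A [run_config()].
#' @param outdir Output directory, or `NULL` (default) for no files.
#' @return List of class `pico_run`: `sim`, `assay`, `aggregate`,
#'   `manifest`, `config`.
#' @export
run_experiment <- function(config, outdir = NULL) {
  stopifnot(inherits(config, "run_config"))
  community <- .resolve_community(config$community, config$seed)
  model <- build_model(community, config$scenario,
                       mutation = config$mutation,
                       nitrification = config$nitrification,
                       export = config$export)
  params <- model$params
  sim <- simulate_ecosystem(model, t_end = config$t_end,
                            cadence = config$cadence,
                            rtol = config$rtol %||% params$integration$rtol,
                            atol = config$atol %||% params$integration$atol)
  assay <- compute_assay(sim, window = config$window)
  agg <- aggregate_disadvantage(sim, window = config$window)
  manifest <- list(
    package = "picosel",
    version = as.character(utils::packageVersion("picosel")),
    scenario = config$scenario_name,
    scenario_def = if (is.character(config$scenario))
      NULL else unclass(config$scenario),
    community = as.data.frame(community),
    mutation = unclass(config$mutation),
    seed = config$seed, t_end = config$t_end, cadence = config$cadence,
    window = config$window, nitrification = config$nitrification,
    export = config$export,
    rtol = config$rtol %||% params$integration$rtol,
    atol = config$atol %||% params$integration$atol,
    diagnostics = sim$diagnostics)
  run <- structure(list(sim = sim, assay = assay, aggregate = agg,
                        manifest = manifest, config = config),
                   class = "pico_run")
  if (!is.null(outdir)) write_run(run, outdir)
  run
}

#' Run an ensemble of experiments
#'
#' `n` members share the forcing but draw independent communities from
#' member seeds expanded deterministically from `config$seed`. The summary
#' reports, per member, the aggregate indices and (when the prescribed E2/E3
#' pair is present) the per-ecotype indices, plus the cross-member sign
#' consistency of the E3-minus-E2 disadvantage ordering.
#'
#' @param config A [run_config()] with a seeded community source.
#' @param n Number of members (default 10).
#' @return List of class `pico_ensemble`: `members` (list of `pico_run`),
#'   `summary` (data.frame), `consistent_ordering` (logical or NA).
#' @export
run_ensemble <- function(config, n = 10) {
  stopifnot(inherits(config, "run_config"))
  if (!config$community$type %in% c("random", "pair_plus_large"))
    stop("ensembles need a seeded-random community source")
  seeds <- ensemble_seeds(config$seed, n)
  members <- lapply(seq_len(n), function(i) {
    cfg <- config
    cfg$seed <- seeds[i]
    cfg$community$seed <- seeds[i]
    tryCatch(run_experiment(cfg),
             error = function(e) stop("ensemble member ", i, " (seed ",
                                      seeds[i], ") failed: ",
                                      conditionMessage(e)))
  })
  summary <- do.call(rbind, lapply(seq_len(n), function(i) {
    r <- members[[i]]
    a <- r$assay
    d_e2 <- if ("E2" %in% a$parent_id) a$D_NO3[a$parent_id == "E2"] else NA
    d_e3 <- if ("E3" %in% a$parent_id) a$D_NO3[a$parent_id == "E3"] else NA
    data.frame(member = i, seed = seeds[i],
               D_NO3_agg = unname(r$aggregate["D_NO3"]),
               D_NO2_agg = unname(r$aggregate["D_NO2"]),
               D_NO3_E2 = d_e2, D_NO3_E3 = d_e3)
  }))
  ord <- sign(summary$D_NO3_E3 - summary$D_NO3_E2)
  consistent <- if (all(is.na(ord))) NA else all(ord == ord[1])
  structure(list(members = members, summary = summary,
                 consistent_ordering = consistent, seeds = seeds),
            class = "pico_ensemble")
}

#' Parameter sweep
#'
#' Repeats one experiment along a single axis, all else fixed: the mutation
#' rate `lambda`, the deep nitrate reservoir `deep_NO3`, or the deep iron
#' reservoir `deep_Fe` (uM / nM).
#'
#' @param config A [run_config()].
#' @param axis `"lambda"`, `"deep_NO3"` or `"deep_Fe"`.
#' @param values Sorted numeric vector (length >= 2).
#' @return List of class `pico_sweep`: `table` (value + aggregate indices),
#'   `runs` (list of `pico_run`), `axis`.
#' @export
sweep_experiment <- function(config, axis = c("lambda", "deep_NO3",
                                              "deep_Fe"), values) {
  axis <- match.arg(axis)
  stopifnot(inherits(config, "run_config"), length(values) >= 2,
            !is.unsorted(values))
  forcing0 <- if (is.character(config$scenario))
    build_scenario(config$scenario) else config$scenario
  runs <- lapply(values, function(v) {
    cfg <- config
    if (axis == "lambda") {
      cfg$mutation <- mutation_params(rate_lambda = v,
                                      onset = config$mutation$onset)
    } else {
      f <- forcing0
      f$deep_conc[[sub("deep_", "", axis)]] <- v
      cfg$scenario <- validate_forcing(f)
      cfg$scenario_name <- paste0(config$scenario_name, "+", axis, "=", v)
    }
    run_experiment(cfg)
  })
  tab <- do.call(rbind, lapply(seq_along(values), function(i)
    data.frame(value = values[i],
               D_NO3_agg = unname(runs[[i]]$aggregate["D_NO3"]),
               D_NO2_agg = unname(runs[[i]]$aggregate["D_NO2"]))))
  structure(list(table = tab, runs = runs, axis = axis),
            class = "pico_sweep")
}
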