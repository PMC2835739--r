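# Output writers: tidy CSV trajectories, assay tables, JSON manifests.

#' Write a trajectory as tidy CSV
#'
#' Long format with columns `time`, `variable`, `value`; variables are the
#' five nutrients, every population pool (mutant pools named
#' `<parent>.<class>`), the grazers and the detritus pools.
#'
#' @param sim A `pico_sim`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(sim, path) {
  stopifnot(inherits(sim, "pico_sim"))
  m <- cbind(sim$nutrients, sim$pools, sim$grazers, sim$detritus)
  long <- data.frame(
    time = rep(sim$time, ncol(m)),
    variable = rep(colnames(m), each = length(sim$time)),
    value = as.vector(m))
  write.csv(long, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write an assay table as CSV
#'
#' One row per (parent, mutant class) with the scenario label, mean biomass
#' over the analysis window, the disadvantage indices and the mask flag.
#'
#' @param assay An `assay_result` from [compute_assay()].
#' @param path Output file.
#' @param scenario Scenario label column (default `"custom"`).
#' @return `path`, invisibly.
#' @export
write_assay_csv <- function(assay, path, scenario = "custom") {
  stopifnot(inherits(assay, "data.frame"))
  long <- do.call(rbind, lapply(seq_len(nrow(assay)), function(i) {
    r <- assay[i, ]
    data.frame(scenario = scenario, parent_id = r$parent_id,
               mutant_class = c("NULL", "NO3_LOSS", "NO3NO2_LOSS"),
               mean_biomass = c(r$mean_null, r$mean_no3_loss,
                                r$mean_no3no2_loss),
               D_NO3 = r$D_NO3, D_NO2 = r$D_NO2, masked = r$masked)
  }))
  write.csv(long, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write all outputs of a run
#'
#' Emits `trajectory.csv`, `assay.csv` and `manifest.json` (the manifest
#' embeds the resolved community, so a run can be reproduced bit-identically
#' from the manifest alone at fixed tolerances).
#'
#' @param run A `pico_run` from [run_experiment()].
#' @param outdir Output directory (created if missing).
#' @return Named vector of file paths, invisibly.
#' @export
write_run <- function(run, outdir) {
  stopifnot(inherits(run, "pico_run"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(trajectory = file.path(outdir, "trajectory.csv"),
             assay = file.path(outdir, "assay.csv"),
             manifest = file.path(outdir, "manifest.json"))
  write_trajectory_csv(run$sim, paths[["trajectory"]])
  write_assay_csv(run$assay, paths[["assay"]],
                  scenario = run$manifest$scenario)
  manifest <- run$manifest
  manifest$files <- lapply(
    list(trajectory = paths[["trajectory"]], assay = paths[["assay"]]),
    function(p) unname(tools::md5sum(p)))
  jsonlite::write_json(manifest, paths[["manifest"]], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, dataframe = "rows")
  invisible(paths)
}
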