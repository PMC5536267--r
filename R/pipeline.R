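# End-to-end orchestration: simulate -> extract -> fit -> select -> stats,
# each stage writing a plain-text artifact, plus a JSON run manifest that
# makes a run reproducible and auditable.

#' Simulate stage: synthetic cohort to disk
#'
#' @param config A [cohort_config()].
#' @param spec An [edq_design()].
#' @param out_dir Output directory (created if needed).
#' @return Paths of `agents.csv` and `choices.csv`, invisibly.
#' @export
pipeline_simulate <- function(config, spec = edq_design(), out_dir = ".") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cohort <- generate_cohort(config, spec)
  agents_path <- file.path(out_dir, "agents.csv")
  choices_path <- file.path(out_dir, "choices.csv")
  utils::write.csv(cohort$agents, agents_path, row.names = FALSE, quote = FALSE)
  write_choices(cohort$choices, choices_path)
  invisible(c(agents = agents_path, choices = choices_path))
}

#' Extract stage: choices to indifference points
#'
#' Extracts indifference points, drops the excluded zero-effort rows, and
#' writes both the individual table and the group medians.
#'
#' @param choices Path to a choices CSV, or a choices data.frame.
#' @param spec An [edq_design()].
#' @param out_dir Output directory.
#' @return Paths of `ips.csv` and `median_ips.csv`, invisibly.
#' @export
pipeline_extract <- function(choices, spec = edq_design(), out_dir = ".") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.character(choices)) choices <- read_choices(choices)
  ips <- apply_exclusions(extract_ips(choices, spec))
  med <- group_median_ips(ips, spec)
  ips_path <- file.path(out_dir, "ips.csv")
  med_path <- file.path(out_dir, "median_ips.csv")
  write_ip_table(ips, ips_path)
  write_ip_table(med, med_path)
  invisible(c(ips = ips_path, median_ips = med_path))
}

#' Fit stage: joint model fits for every unit and domain
#'
#' @param ips Path to an indifference-point CSV, or the data.frame itself.
#' @param models Character vector of model names.
#' @param spec An [edq_design()].
#' @param units `"individual"`, `"median"` or `"both"`.
#' @param out_dir Output directory.
#' @return The `disc_fitset`, invisibly; writes `fits.csv`.
#' @export
pipeline_fit <- function(ips, models = disc_models()$model,
                         spec = edq_design(), units = "both", out_dir = ".") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.character(ips)) ips <- read_ip_table(ips)
  fits <- disc_fit_all(ips, models, spec, units)
  utils::write.csv(as.data.frame(fits), file.path(out_dir, "fits.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(fits)
}

#' Select stage: information criteria and best-model tables
#'
#' @param fits A `disc_fitset`.
#' @param out_dir Output directory.
#' @return The `disc_selection`, invisibly; writes `selection.csv` and
#'   `selection_summary.json`.
#' @export
pipeline_select <- function(fits, out_dir = ".") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sel <- model_selection(fits)
  utils::write.csv(sel$table, file.path(out_dir, "selection.csv"),
                   row.names = FALSE, quote = FALSE)
  summary_obj <- list(
    summed = lapply(sel$summed, function(d) lapply(d, function(ic) {
      list(sums = as.list(ic$sums), deltas = as.list(ic$deltas),
           n_subjects = ic$n_subjects,
           n_dropped = length(attr(ic, "dropped")))
    })),
    frequencies = lapply(sel$frequencies, function(d) lapply(d, function(fr) {
      list(counts = as.list(fr$counts), ratios = as.list(fr$ratios),
           n_subjects = fr$n_subjects, n_ties = fr$n_ties)
    })))
  jsonlite::write_json(summary_obj,
                       file.path(out_dir, "selection_summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(sel)
}

#' Stats stage: nonparametric comparison suite
#'
#' @param fits A `disc_fitset` of individual-level fits.
#' @param spec An [edq_design()].
#' @param reference_model Model whose parameters are compared across
#'   magnitudes and domains.
#' @param out_dir Output directory.
#' @return The `disc_stats` report, invisibly; writes `stats_report.json`.
#' @export
pipeline_stats <- function(fits, spec = edq_design(),
                           reference_model = "power", out_dir = ".") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  report <- run_stats_suite(fits, spec, reference_model)
  jsonlite::write_json(unclass(report),
                       file.path(out_dir, "stats_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(report)
}

#' Run the full pipeline
#'
#' Composes the five stages on a synthetic cohort and writes a run manifest
#' (`manifest.json`) recording the configuration, seed, package version,
#' output files with MD5 checksums, and warnings (skipped fits, dropped
#' subjects, ties). Identical configuration and seed reproduce identical
#' artifacts.
#'
#' @param config A [cohort_config()].
#' @param spec An [edq_design()].
#' @param models Character vector of model names.
#' @param out_dir Output directory.
#' @param reference_model Reference model for the statistics stage.
#' @return List with the in-memory stage results and the manifest, invisibly.
#' @export
run_pipeline <- function(config, spec = edq_design(),
                         models = disc_models()$model, out_dir = ".",
                         reference_model = "power") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sim_paths <- pipeline_simulate(config, spec, out_dir)
  ip_paths <- pipeline_extract(sim_paths[["choices"]], spec, out_dir)
  fits <- pipeline_fit(ip_paths[["ips"]], models, spec, "both", out_dir)
  sel <- pipeline_select(fits, out_dir)
  stats_rep <- pipeline_stats(fits, spec, reference_model, out_dir)

  files <- file.path(out_dir, c("agents.csv", "choices.csv", "ips.csv",
                                "median_ips.csv", "fits.csv", "selection.csv",
                                "selection_summary.json", "stats_report.json"))
  checksums <- as.list(tools::md5sum(files))
  names(checksums) <- basename(files)
  failures <- attr(fits, "failures")
  manifest <- list(
    config = unclass(config),
    design = unclass(spec),
    models = models,
    seed = config$seed,
    package_version = as.character(utils::packageVersion("effdisc")),
    files = checksums,
    warnings = list(
      n_failed_fits = if (is.null(failures)) 0L else nrow(failures),
      n_clamped = sum(vapply(unclass(fits), `[[`, TRUE, "clamped")),
      n_nonconverged = sum(!vapply(unclass(fits), `[[`, TRUE, "converged"))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(fits = fits, selection = sel, stats = stats_rep,
                 manifest = manifest))
}
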