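# Config-driven pipeline chaining simulate -> quantify -> calibrate ->
# compare -> report.  All artifacts are written with a ".partial" suffix
# and renamed atomically only when the whole run succeeds, so an aborted
# run leaves only .partial files behind.

#' Build and validate a pipeline run configuration
#'
#' @param mode `"full"` (simulate then analyse), `"simulate"` (evidence
#'   only) or `"analyze"` (start from an evidence file on disk).
#' @param out_dir Output directory (created if missing).
#' @param scenario A [scenario_config()]; used by `simulate`/`full`.
#' @param evidence_path Evidence TSV to analyse (required for `analyze`).
#' @param annotation_path Optional annotation TSV; defaults to
#'   [default_annotation()].
#' @param markers_path Optional marker TSV; when absent, calibration is
#'   fitted from the reference condition's marker complexes
#'   ([self_calibration()]).
#' @param swap_map Replicate-to-heavy-condition map for `analyze` mode
#'   (defaults to the scenario's map otherwise).
#' @param conditions Condition pair for `analyze` mode.
#' @param n_slices Number of gel slices for `analyze` mode (defaults to the
#'   scenario gel's slice count).
#' @param seed Integer seed governing all stochastic stages.
#' @param min_rel_height Peak-height threshold.
#' @param match_tol Peak-matching tolerance in slices.
#' @param comigration_proteins Protein set for the co-migration table.
#' @param log_level `"info"` or `"quiet"`.
#' @return Object of class `run_config`.
#' @export
run_config <- function(mode = c("full", "simulate", "analyze"),
                       out_dir,
                       scenario = default_scenario(),
                       evidence_path = NULL, annotation_path = NULL,
                       markers_path = NULL, swap_map = NULL,
                       conditions = NULL, n_slices = NULL, seed = NULL,
                       min_rel_height = 0.2, match_tol = 1.5,
                       comigration_proteins = c("MT-CO1", "COA3", "HIGD1A",
                                                "HIGD2A", "COX5B", "NDUFA4"),
                       log_level = "info") {
  mode <- match.arg(mode)
  if (missing(out_dir) || !is.character(out_dir) || !nzchar(out_dir))
    stopf("config error: out_dir is required")
  if (mode == "analyze") {
    if (is.null(evidence_path))
      stopf("config error: analyze mode requires evidence_path")
    if (is.null(swap_map))
      stopf("config error: analyze mode requires a swap_map")
  }
  structure(
    list(mode = mode, out_dir = out_dir, scenario = scenario,
         evidence_path = evidence_path, annotation_path = annotation_path,
         markers_path = markers_path, swap_map = swap_map,
         conditions = conditions,
         n_slices = as.integer(n_slices %||% scenario$gel$n_slices),
         seed = as.integer(seed %||% scenario$seed),
         min_rel_height = min_rel_height, match_tol = match_tol,
         comigration_proteins = comigration_proteins,
         log_level = log_level),
    class = "run_config")
}

#' Run the complexome-profiling pipeline
#'
#' `"full"` mode writes `evidence.tsv`, `profiles_wide.tsv`,
#' `profiles_long.csv`, `report.tsv`, `complexes.tsv`, `shifts.tsv`,
#' `comigration.tsv` and `run_manifest.yaml` into the configured output
#' directory.  Two runs with an identical configuration and seed produce
#' byte-identical numeric outputs.  Any stage failure aborts with a
#' stage-named error; files already written keep the `.partial` suffix.
#'
#' @param config A [run_config()].
#' @return Invisibly, a named list of the artifact paths.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "run_config")) stopf("run_config required")
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(config$out_dir, "run.log")
  log_con <- file(log_path, open = "wt")
  on.exit(close(log_con), add = TRUE)
  say <- function(...) {
    msg <- sprintf(...)
    writeLines(msg, log_con)
    if (!identical(config$log_level, "quiet")) message(msg)
  }
  stage <- function(name, code) {
    tryCatch(code, error = function(e)
      stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
  }
  partial <- function(name) file.path(config$out_dir, paste0(name, ".partial"))
  written <- character()
  emit <- function(name, writer) {
    writer(partial(name))
    written[[length(written) + 1L]] <<- name
  }

  inputs <- c(config$evidence_path, config$annotation_path, config$markers_path)
  annotation <- stage("annotation", {
    if (is.null(config$annotation_path)) default_annotation()
    else read_complex_annotation(config$annotation_path)
  })

  if (config$mode %in% c("full", "simulate")) {
    scenario <- config$scenario
    say("simulate: scenario with %d forms, %d slices, seed %d",
        length(scenario$forms), scenario$gel$n_slices, config$seed)
    evidence <- stage("simulate",
                      simulate_evidence(scenario, seed = config$seed))
    say("simulate: %d evidence rows for %d proteins", nrow(evidence),
        length(unique(evidence$protein_id)))
    emit("evidence.tsv", function(p) write_evidence(evidence, p))
    swap_map <- scenario_swap_map(scenario)
    conditions <- scenario$conditions
    n_slices <- scenario$gel$n_slices
    gel <- scenario$gel
    mixing_ratio <- scenario$mixing_ratio
  } else {
    evidence <- stage("read-evidence", read_evidence(config$evidence_path))
    swap_map <- config$swap_map
    conditions <- config$conditions %||% attr(swap_map, "conditions")
    if (is.null(conditions))
      stopf("pipeline stage 'read-evidence' failed: conditions unknown")
    n_slices <- config$n_slices
    gel <- config$scenario$gel
    mixing_ratio <- config$scenario$mixing_ratio
  }

  if (config$mode != "simulate") {
    mapped <- stage("map-conditions",
                    map_channels_to_conditions(evidence, swap_map, conditions))
    say("quantify: building profiles for %d proteins",
        length(unique(mapped$protein_id)))
    profiles <- stage("quantify", build_profiles(mapped, n_slices, conditions))
    ratios <- stage("quantify",
                    protein_ratios(mapped, conditions, mixing_ratio))
    emit("profiles_wide.tsv", function(p)
      write_profile_matrix(profiles, annotation, p,
                           long_path = partial("profiles_long.csv")))
    written[[length(written) + 1L]] <- "profiles_long.csv"
    calibration <- stage("calibrate", {
      if (!is.null(config$markers_path))
        fit_mass_calibration(read_marker_table(config$markers_path),
                             n_slices = n_slices)
      else
        self_calibration(profiles, gel, conditions[[1L]])
    })
    say("calibrate: slope %.5f log10(kDa)/slice from %d markers",
        calibration$slope, calibration$n_markers)
    report <- stage("compare", comparison_report(
      profiles, ratios, annotation, calibration, conditions,
      min_rel_height = config$min_rel_height, match_tol = config$match_tol,
      comigration_proteins = config$comigration_proteins))
    tsv <- function(df) function(p)
      utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    emit("report.tsv", tsv(report$proteins))
    emit("complexes.tsv", tsv(report$complexes))
    emit("shifts.tsv", tsv(report$shifts))
    emit("comigration.tsv", tsv(report$comigration %||%
                                  data.frame(protein_a = character(),
                                             protein_b = character(),
                                             condition = character(),
                                             r = numeric())))
    say("compare: %d shift calls, %d complexes summarised",
        nrow(report$shifts), nrow(report$complexes))
  }

  manifest <- list(
    mode = config$mode, seed = config$seed,
    conditions = as.list(unname(conditions)),
    package = "comprof",
    package_version = as.character(utils::packageVersion("comprof")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    thresholds = list(min_rel_height = config$min_rel_height,
                      match_tol = config$match_tol),
    input_checksums = if (length(inputs))
      as.list(tools::md5sum(inputs)) else list(),
    artifacts = as.list(unlist(written)))
  if (config$mode %in% c("full", "simulate"))
    manifest$scenario <- yaml::yaml.load(yaml::as.yaml(
      list(n_forms = length(config$scenario$forms),
           gel = unclass(config$scenario$gel),
           replicates = as.list(config$scenario$replicates),
           mixing_ratio = config$scenario$mixing_ratio,
           noise = config$scenario$noise)))
  yaml::write_yaml(manifest, partial("run_manifest.yaml"))
  written[[length(written) + 1L]] <- "run_manifest.yaml"

  paths <- vapply(unlist(written), function(name) {
    final <- file.path(config$out_dir, name)
    file.rename(partial(name), final)
    final
  }, "")
  say("done: %d artifacts in %s", length(paths), config$out_dir)
  invisible(paths)
}
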