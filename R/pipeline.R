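#' Default pipeline configuration
#'
#' The full configuration tree with every field at its default. The cohort
#' section encodes the reference stage-conditional distributions (see
#' [cohort_design()]); the fitting, ROI and statistics sections mirror the
#' corresponding module defaults. The same structure is shipped as
#' `inst/extdata/default_config.yaml`.
#'
#' @return Nested list: sections `seed`, `output_dir`, `cohort`, `fitting`,
#'   `roi`, `statistics`.
#' @export
default_pipeline_config <- function() {
  tab <- default_stage_table()
  stage_tbl <- lapply(seq_len(5L), function(i) {
    list(n = tab$n[i],
         ADC = c(tab$ADC_mean[i], tab$ADC_sd[i]),
         D_app = c(tab$D_app_mean[i], tab$D_app_sd[i]),
         K_app = c(tab$K_app_mean[i], tab$K_app_sd[i]),
         DDC = c(tab$DDC_mean[i], tab$DDC_sd[i]),
         alpha = c(tab$alpha_mean[i], tab$alpha_sd[i]))
  })
  names(stage_tbl) <- tab$stage
  list(seed = 1L,
       output_dir = "fibrostage-out",
       cohort = list(stage_table = stage_tbl,
                     sigma = 0.02,
                     S0 = 100,
                     generator_model = "sem",
                     grid_size = 32L,
                     pixel_size_mm = 50 / 64,
                     jitter_sd = 0,
                     collagen_mean = c(2, 6, 12, 20, 30),
                     collagen_sd = 5,
                     b_values_mono = c(0, 800),
                     averages_mono = c(1L, 3L),
                     b_values_multib = c(0, 700, 1400, 2100),
                     averages_multib = 1:4),
       fitting = list(models = c("mono", "dki", "sem")),
       roi = list(n_rois = 5L, area_range_mm2 = c(3, 4)),
       statistics = list(roc_parameters = c("ADC", "D_app", "DDC"),
                         splits = roc_splits(),
                         replicates = 200L))
}

# recursive merge of user config onto defaults; unknown keys rejected
merge_config <- function(defaults, user, path = "") {
  if (is.null(user)) return(defaults)
  if (!is.list(defaults) || !is.list(user)) return(user)
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown)) {
    stop("unknown config key(s): ",
         paste0(path, unknown, collapse = ", "), call. = FALSE)
  }
  for (nm in names(user)) {
    defaults[[nm]] <- merge_config(defaults[[nm]], user[[nm]],
                                   paste0(path, nm, "."))
  }
  defaults
}

#' Read a pipeline configuration
#'
#' Reads a YAML (or JSON) configuration file, fills every absent field from
#' [default_pipeline_config()], and rejects unknown keys. `overrides` are
#' applied last (CLI flags override the file).
#'
#' @param path Path to a YAML/JSON config, or NULL for pure defaults.
#' @param overrides Named nested list applied on top.
#' @return The resolved configuration list.
#' @export
read_pipeline_config <- function(path = NULL, overrides = list()) {
  config <- default_pipeline_config()
  if (!is.null(path)) {
    user <- if (grepl("\\.json$", path)) {
      jsonlite::read_json(path, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(path)
    }
    config <- merge_config(config, user)
  }
  merge_config(config, overrides)
}

#' Build a cohort design from the config's cohort section
#'
#' @param config A resolved pipeline configuration.
#' @return A [cohort_design()].
#' @export
config_to_design <- function(config) {
  ch <- config$cohort
  stage_tbl <- ch$stage_table
  grab <- function(param, which) {
    vapply(stage_tbl, function(s) as.numeric(s[[param]][which]), 0)
  }
  tab <- data.frame(stage = metavir_stages(),
                    n = vapply(stage_tbl, function(s) as.integer(s$n), 0L),
                    stringsAsFactors = FALSE)
  for (p in dwi_parameters()) {
    tab[[paste0(p, "_mean")]] <- grab(p, 1L)
    tab[[paste0(p, "_sd")]] <- grab(p, 2L)
  }
  cohort_design(stage_table = tab,
                collagen_mean = ch$collagen_mean,
                collagen_sd = ch$collagen_sd,
                sigma = ch$sigma, S0 = ch$S0,
                scheme_mono = bvalue_scheme(ch$b_values_mono,
                                            ch$averages_mono),
                scheme_multib = bvalue_scheme(ch$b_values_multib,
                                              ch$averages_multib),
                generator_model = ch$generator_model,
                grid_size = ch$grid_size,
                pixel_size_mm = ch$pixel_size_mm,
                jitter_sd = ch$jitter_sd)
}

write_provenance <- function(out_dir, config, seed) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  config$seed <- seed
  yaml::write_yaml(config, file.path(out_dir, "resolved_config.yaml"))
  invisible(NULL)
}

#' Simulate a cohort to disk
#'
#' Draws the cohort truth, synthesizes per-subject DWI volumes, and writes
#' everything under `out_dir`: one `<subject>_mono` and `<subject>_multib`
#' NIfTI + b-value/averages file set per subject, `truth.csv` (stage and
#' true parameters, coefficients in 1e-3 mm^2/s), and the resolved config
#' with the seed for provenance.
#'
#' @param config Resolved pipeline configuration (default: package
#'   defaults).
#' @param seed Integer seed (overrides the config's).
#' @param out_dir Output directory (overrides the config's).
#' @return Invisibly, a list with the truth data frame and the directory.
#' @export
cmd_simulate <- function(config = read_pipeline_config(), seed = NULL,
                         out_dir = NULL) {
  if (is.null(seed)) seed <- config$seed
  if (is.null(out_dir)) out_dir <- config$output_dir
  design <- config_to_design(config)
  truth <- sample_cohort(design, seed = seed)
  write_provenance(out_dir, config, seed)
  for (i in seq_len(nrow(truth))) {
    vols <- synthesize_subject(truth[i, ], design, seed = seed + 1000L + i)
    write_dwi_volume(vols$mono,
                     file.path(out_dir, paste0(truth$subject_id[i], "_mono")))
    write_dwi_volume(vols$multib,
                     file.path(out_dir, paste0(truth$subject_id[i], "_multib")))
  }
  write_subjects_csv(truth, file.path(out_dir, "truth.csv"))
  message(sprintf("simulated %d subjects (stages %s) into %s",
                  nrow(truth),
                  paste(design$stage_table$n, collapse = "/"), out_dir))
  invisible(list(truth = truth, out_dir = out_dir))
}

#' Fit parametric maps for a volume on disk
#'
#' @param prefix Path prefix of the volume (see [read_dwi_volume()]).
#' @param model One of `"mono"`, `"dki"`, `"sem"`.
#' @param out_dir Output directory for the maps.
#' @param bval_path,nsa_path,mask_path Optional explicit input paths.
#' @return Invisibly, the `parameter_maps`.
#' @export
cmd_fit <- function(prefix, model, out_dir,
                    bval_path = NULL, nsa_path = NULL, mask_path = NULL) {
  volume <- read_dwi_volume(prefix, bval_path, nsa_path, mask_path)
  maps <- fit_volume(volume, model)
  write_parameter_maps(maps, out_dir)
  message(sprintf("%s fit: %d pixels, %.1f%% converged", model,
                  sum(!is.na(maps$converged)),
                  100 * maps$convergence_fraction))
  invisible(maps)
}

#' Run the staging statistics on a subjects CSV
#'
#' @param subjects_csv Path to a subjects CSV (see [write_subjects_csv()]).
#' @param out_dir Output directory for the report tables.
#' @param config Resolved pipeline configuration (statistics section).
#' @return Invisibly, the `staging_report`.
#' @export
cmd_analyze <- function(subjects_csv, out_dir,
                        config = read_pipeline_config()) {
  subjects <- read_subjects_csv(subjects_csv)
  report <- build_report(subjects,
                         roc_parameters = config$statistics$roc_parameters,
                         splits = config$statistics$splits)
  write_report_tables(report, out_dir)
  message("report tables written to ", out_dir)
  invisible(report)
}

#' Run the full simulate-fit-summarize-analyze pipeline
#'
#' Simulates the cohort in memory, fits every subject's volumes
#' (monoexponential on the two-b-value volume; kurtosis and stretched
#' exponential on the four-b-value volume), summarizes each subject over
#' seeded ROIs, and builds the staging report. Deterministic for a fixed
#' seed. With `out_dir` set, subject summaries, report tables and the
#' resolved config are written to disk.
#'
#' @param config Resolved pipeline configuration.
#' @param seed Integer seed (overrides the config's).
#' @param out_dir Output directory, or NULL to keep everything in memory.
#' @return List with `subjects` (per-subject summaries, mm^2/s) and
#'   `report` (a `staging_report`).
#' @export
run_pipeline <- function(config = read_pipeline_config(), seed = NULL,
                         out_dir = NULL) {
  if (is.null(seed)) seed <- config$seed
  design <- config_to_design(config)
  truth <- sample_cohort(design, seed = seed)
  models <- config$fitting$models
  rows <- vector("list", nrow(truth))
  for (i in seq_len(nrow(truth))) {
    vols <- synthesize_subject(truth[i, ], design, seed = seed + 1000L + i)
    maps <- list()
    if ("mono" %in% models) maps <- c(maps, list(fit_volume(vols$mono, "mono")))
    if ("dki" %in% models) maps <- c(maps, list(fit_volume(vols$multib, "dki")))
    if ("sem" %in% models) maps <- c(maps, list(fit_volume(vols$multib, "sem")))
    rois <- place_rois(vols$mono$liver_mask, design$pixel_size_mm,
                       n_rois = config$roi$n_rois,
                       area_range_mm2 = config$roi$area_range_mm2,
                       seed = seed + 500000L + i)
    meta <- list(subject_id = truth$subject_id[i], stage = truth$stage[i])
    if (!is.null(truth$collagen)) meta$collagen <- truth$collagen[i]
    rows[[i]] <- summarize_subject(maps, rois, meta)
  }
  subjects <- do.call(rbind, rows)
  report <- build_report(subjects,
                         roc_parameters = config$statistics$roc_parameters,
                         splits = config$statistics$splits)
  if (!is.null(out_dir)) {
    write_provenance(out_dir, config, seed)
    write_subjects_csv(subjects, file.path(out_dir, "subjects.csv"))
    write_report_tables(report, file.path(out_dir, "tables"))
  }
  list(subjects = subjects, report = report)
}
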