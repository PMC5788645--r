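#' Write and read DWI volumes as NIfTI plus b-value text files
#'
#' A volume is stored as `<prefix>.nii.gz` (rows x cols x b-value index,
#' last axis = b-value), `<prefix>.bval` and `<prefix>.nsa`
#' (whitespace-separated b-values and signal averages), and
#' `<prefix>_mask.nii.gz` (liver mask, 0/1). The in-plane pixel size is
#' carried in the NIfTI pixdim.
#'
#' @param volume A [dwi_volume()].
#' @param prefix Path prefix (directories are created as needed).
#' @return `write_dwi_volume()` returns the prefix invisibly;
#'   `read_dwi_volume()` returns a [dwi_volume()].
#' @export
write_dwi_volume <- function(volume, prefix) {
  stopifnot(inherits(volume, "dwi_volume"))
  dir.create(dirname(prefix), recursive = TRUE, showWarnings = FALSE)
  img <- RNifti::asNifti(volume$signals)
  RNifti::pixdim(img) <- c(volume$pixel_size_mm, volume$pixel_size_mm, 1)
  RNifti::writeNifti(img, paste0(prefix, ".nii.gz"))
  msk <- RNifti::asNifti(array(as.integer(volume$liver_mask),
                               dim = dim(volume$liver_mask)))
  RNifti::pixdim(msk) <- c(volume$pixel_size_mm, volume$pixel_size_mm)
  RNifti::writeNifti(msk, paste0(prefix, "_mask.nii.gz"))
  writeLines(paste(volume$scheme$b_values, collapse = " "),
             paste0(prefix, ".bval"))
  writeLines(paste(volume$scheme$averages, collapse = " "),
             paste0(prefix, ".nsa"))
  invisible(prefix)
}

#' @rdname write_dwi_volume
#' @param bval_path,nsa_path,mask_path Optional explicit paths; default to
#'   the `<prefix>.bval` / `<prefix>.nsa` / `<prefix>_mask.nii.gz`
#'   convention. Without an averages file, all averages default to 1;
#'   without a mask file, pixels with positive b = 0 signal are used.
#' @export
read_dwi_volume <- function(prefix, bval_path = NULL, nsa_path = NULL,
                            mask_path = NULL) {
  nii_path <- if (file.exists(paste0(prefix, ".nii.gz"))) {
    paste0(prefix, ".nii.gz")
  } else prefix
  img <- RNifti::readNifti(nii_path)
  arr <- as.array(img)
  if (length(dim(arr)) == 4L && dim(arr)[3] == 1L) {
    arr <- arr[, , 1L, , drop = TRUE]  # single-slice 4-D file
    dim(arr) <- dim(arr)
  }
  if (length(dim(arr)) != 3L) {
    stop("expected a rows x cols x n_b volume, got dimensions ",
         paste(dim(arr), collapse = " x "), call. = FALSE)
  }
  if (is.null(bval_path)) bval_path <- paste0(prefix, ".bval")
  b_values <- scan(bval_path, quiet = TRUE)
  if (length(b_values) != dim(arr)[3]) {
    stop(sprintf("b-value file has %d entries but the volume has %d frames",
                 length(b_values), dim(arr)[3]), call. = FALSE)
  }
  if (is.null(nsa_path)) nsa_path <- paste0(prefix, ".nsa")
  averages <- if (file.exists(nsa_path)) {
    scan(nsa_path, quiet = TRUE)
  } else rep(1L, length(b_values))
  if (length(averages) != length(b_values)) {
    stop(sprintf("averages file has %d entries but there are %d b-values",
                 length(averages), length(b_values)), call. = FALSE)
  }
  if (is.null(mask_path)) mask_path <- paste0(prefix, "_mask.nii.gz")
  mask <- if (file.exists(mask_path)) {
    m <- as.array(RNifti::readNifti(mask_path))
    if (length(dim(m)) > 2L) m <- m[, , 1L]
    m > 0
  } else arr[, , 1L] > 0
  px <- RNifti::pixdim(img)[1]
  if (!is.finite(px) || px <= 0) px <- 1
  dwi_volume(arr, bvalue_scheme(b_values, averages), mask, px)
}

#' Write parametric maps as NIfTI with a JSON fit report
#'
#' One float32 NIfTI per parameter (masked-out or non-converged pixels are
#' NaN) plus `<prefix>_fit.json` describing the model, the fit settings and
#' the convergence summary.
#'
#' @param maps A `parameter_maps` object from [fit_volume()].
#' @param out_dir Output directory (created if needed).
#' @param prefix File-name prefix, default the model name.
#' @return Invisibly, the vector of files written.
#' @export
write_parameter_maps <- function(maps, out_dir, prefix = maps$model) {
  stopifnot(inherits(maps, "parameter_maps"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  par_names <- intersect(c("S0", dwi_parameters()), names(maps))
  files <- character(0)
  for (p in par_names) {
    img <- RNifti::asNifti(maps[[p]])
    RNifti::pixdim(img) <- c(maps$pixel_size_mm, maps$pixel_size_mm)
    f <- file.path(out_dir, paste0(prefix, "_", tolower(p), ".nii.gz"))
    RNifti::writeNifti(img, f, datatype = "float")
    files <- c(files, f)
  }
  sidecar <- file.path(out_dir, paste0(prefix, "_fit.json"))
  jsonlite::write_json(
    list(model = maps$model,
         parameters = par_names,
         fit_settings = fit_settings(maps$model),
         n_fitted = sum(!is.na(maps$converged)),
         n_converged = sum(maps$converged, na.rm = TRUE),
         convergence_fraction = maps$convergence_fraction),
    sidecar, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(files, sidecar))
}

fit_settings <- function(model) {
  base <- list(domain = "log-signal", weighting = "signal averages",
               algorithm = "Levenberg-Marquardt", max_iterations = 200,
               tolerance = 1e-12, S0 = "free parameter")
  switch(model,
         mono = c(base, list(closed_form_two_points = TRUE)),
         dki = c(base, list(D_app_bounds = c(1e-5, 5e-3),
                            K_app_bounds = c(0, 3),
                            multistart_K_app = c(0.5, 1, 2))),
         sem = c(base, list(DDC_bounds = c(1e-5, 5e-3),
                            alpha_bounds = c(0.01, 1),
                            multistart_alpha = c(0.5, 0.7, 0.9))))
}

#' Subject-summary CSV round trip
#'
#' The subjects CSV stores one row per subject with the stage and the five
#' ROI-mean parameters, diffusion coefficients in the conventional
#' 1e-3 mm^2/s units; in-memory objects keep mm^2/s.
#'
#' @param subjects Data frame of subject summaries (mm^2/s).
#' @param path CSV path.
#' @return `read_subjects_csv()` returns the data frame in mm^2/s.
#' @export
write_subjects_csv <- function(subjects, path) {
  out <- subjects
  for (p in intersect(c("ADC", "D_app", "DDC"), names(out))) {
    out[[p]] <- out[[p]] * 1000
  }
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_subjects_csv
#' @export
read_subjects_csv <- function(path) {
  subjects <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (p in intersect(c("ADC", "D_app", "DDC"), names(subjects))) {
    subjects[[p]] <- subjects[[p]] / 1000
  }
  if ("stage" %in% names(subjects)) {
    subjects$stage <- factor(subjects$stage, levels = metavir_stages())
  }
  subjects
}

#' Write the report tables to disk
#'
#' CSVs (floats rounded to 3 decimals) named `table1_means.csv`,
#' `table2_stage_corr.csv`, `table3_collagen_corr.csv` (when collagen is
#' present) and `table4_roc.csv`, plus `report.json` at full precision.
#'
#' @param report A `staging_report` from [build_report()].
#' @param out_dir Output directory.
#' @return Invisibly, the files written.
#' @export
write_report_tables <- function(report, out_dir) {
  stopifnot(inherits(report, "staging_report"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  round3 <- function(df) {
    num <- vapply(df, is.numeric, TRUE)
    df[num] <- lapply(df[num], round, 3)
    df
  }
  tables <- list(table1_means = report$table1_means,
                 table2_stage_corr = report$table2_stage_corr,
                 table3_collagen_corr = report$table3_collagen_corr,
                 table4_roc = report$table4_roc)
  files <- character(0)
  for (nm in names(tables)) {
    if (is.null(tables[[nm]])) next
    f <- file.path(out_dir, paste0(nm, ".csv"))
    utils::write.csv(round3(tables[[nm]]), f, row.names = FALSE)
    files <- c(files, f)
  }
  jf <- file.path(out_dir, "report.json")
  jsonlite::write_json(
    list(tables = Filter(Negate(is.null), tables),
         normality = report$normality,
         meta = report$meta),
    jf, auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null")
  invisible(c(files, jf))
}
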