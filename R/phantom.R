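#' METAVIR stage labels
#'
#' @return Character vector of the five METAVIR fibrosis stages, F0 (no
#'   fibrosis) through F4 (cirrhosis).
#' @export
metavir_stages <- function() c("F0", "F1", "F2", "F3", "F4")

#' Reference stage-conditional parameter distributions
#'
#' The per-stage mean and SD of each diffusion parameter in the emulated
#' 80-rat cohort, together with the per-stage subject counts. Diffusion
#' coefficients are tabulated in the conventional 1e-3 mm^2/s units and
#' converted to mm^2/s when subjects are drawn.
#'
#' @return Data frame with columns `stage`, `n`, and `<param>_mean` /
#'   `<param>_sd` for ADC, D_app, K_app, DDC and alpha.
#' @export
default_stage_table <- function() {
  data.frame(
    stage      = metavir_stages(),
    n          = c(16L, 16L, 16L, 17L, 15L),
    ADC_mean   = c(1.283, 1.056, 0.915, 0.863, 0.884),
    ADC_sd     = c(0.138, 0.151, 0.131, 0.109, 0.088),
    D_app_mean = c(1.581, 1.343, 1.090, 1.072, 0.992),
    D_app_sd   = c(0.192, 0.183, 0.171, 0.160, 0.095),
    K_app_mean = c(0.930, 0.956, 1.025, 1.065, 1.070),
    K_app_sd   = c(0.083, 0.080, 0.093, 0.085, 0.083),
    DDC_mean   = c(1.353, 1.101, 0.761, 0.697, 0.679),
    DDC_sd     = c(0.268, 0.173, 0.147, 0.129, 0.146),
    alpha_mean = c(0.569, 0.600, 0.687, 0.674, 0.642),
    alpha_sd   = c(0.073, 0.071, 0.075, 0.067, 0.066),
    stringsAsFactors = FALSE)
}

#' Design of a synthetic liver-fibrosis cohort
#'
#' Describes everything needed to simulate a METAVIR-staged cohort: per-stage
#' subject counts, stage-conditional normal distributions of the five
#' diffusion parameters, an optional stage-conditional collagen-area
#' fraction, the two acquisition schemes, the Rician noise level, and the
#' slice geometry. The defaults emulate an 80-subject rat cohort (stage
#' counts 16/16/16/17/15) with the package's reference stage-conditional
#' distributions, imaged at b = 0, 800 (1 and 3 averages) for the
#' monoexponential protocol and b = 0, 700, 1400, 2100 (1, 2, 3, 4 averages)
#' for the kurtosis/stretched-exponential protocol, with noise sigma = 2%
#' of S0 (SNR 50 at b = 0) on a 32 x 32 pixel liver disc at 50/64 mm pixels.
#'
#' @param stage_counts Integer vector of length 5: subjects per stage F0-F4.
#' @param stage_table Data frame with columns `stage`, `n`, and
#'   `<param>_mean` / `<param>_sd` for ADC, D_app, K_app, DDC, alpha
#'   (coefficients in 1e-3 mm^2/s). Defaults to the package's reference
#'   cohort table. `stage_counts`, when given, overrides its `n`.
#' @param collagen_mean,collagen_sd Per-stage mean (length 5) and common SD
#'   of the collagen-area percentage, clipped to \[0, 60\]. Set
#'   `collagen_mean = NULL` to disable the collagen covariate.
#' @param sigma Rician noise SD as a fraction of S0.
#' @param S0 Baseline signal at b = 0, arbitrary units.
#' @param scheme_mono,scheme_multib The two [bvalue_scheme()]s.
#' @param generator_model Model generating the multi-b volume: `"sem"`
#'   (default, uses the subject's DDC/alpha) or `"dki"` (D_app/K_app).
#' @param grid_size Side of the square pixel grid.
#' @param pixel_size_mm In-plane pixel size, mm.
#' @param jitter_sd Within-subject pixel-to-pixel jitter, as a fraction of
#'   the subject's parameter value (0 = subject-constant truth).
#' @return An object of class `cohort_design`.
#' @export
cohort_design <- function(stage_counts = NULL,
                          stage_table = default_stage_table(),
                          collagen_mean = c(2, 6, 12, 20, 30),
                          collagen_sd = 5,
                          sigma = 0.02,
                          S0 = 100,
                          scheme_mono = mono_scheme(),
                          scheme_multib = multib_scheme(),
                          generator_model = c("sem", "dki"),
                          grid_size = 32L,
                          pixel_size_mm = 50 / 64,
                          jitter_sd = 0) {
  generator_model <- match.arg(generator_model)
  needed <- c("stage", "n",
              paste0(rep(c("ADC", "D_app", "K_app", "DDC", "alpha"), each = 2),
                     c("_mean", "_sd")))
  if (!all(needed %in% names(stage_table))) {
    stop("stage_table is missing columns: ",
         paste(setdiff(needed, names(stage_table)), collapse = ", "),
         call. = FALSE)
  }
  if (!identical(stage_table$stage, metavir_stages())) {
    stop("stage_table must have one row per stage F0-F4, in order",
         call. = FALSE)
  }
  if (!is.null(stage_counts)) {
    stopifnot(length(stage_counts) == 5L, all(stage_counts >= 0))
    stage_table$n <- as.integer(stage_counts)
  }
  sd_cols <- grep("_sd$", needed, value = TRUE)
  if (any(stage_table[sd_cols] < 0)) stop("SDs must be >= 0", call. = FALSE)
  if (!is.null(collagen_mean)) stopifnot(length(collagen_mean) == 5L)
  stopifnot(sigma >= 0, S0 > 0, grid_size >= 8L, pixel_size_mm > 0,
            jitter_sd >= 0)
  structure(list(stage_table = stage_table,
                 collagen_mean = collagen_mean, collagen_sd = collagen_sd,
                 sigma = sigma, S0 = S0,
                 scheme_mono = scheme_mono, scheme_multib = scheme_multib,
                 generator_model = generator_model,
                 grid_size = as.integer(grid_size),
                 pixel_size_mm = pixel_size_mm,
                 jitter_sd = jitter_sd),
            class = "cohort_design")
}

#' @export
print.cohort_design <- function(x, ...) {
  cat("<cohort_design>", sum(x$stage_table$n), "subjects (",
      paste(x$stage_table$n, collapse = "/"),
      "), sigma =", x$sigma, ", generator =", x$generator_model, "\n")
  invisible(x)
}

#' Draw the per-subject ground truth of a cohort
#'
#' Each subject receives a stage and one draw per diffusion parameter from
#' that stage's normal distribution (parameters are drawn independently:
#' only marginal distributions are specified by the design). Draws are
#' clipped to the parameter bounds used by the fitters (coefficients to
#' \[1e-5, 5e-3\] mm^2/s, K_app to \[0, 3\], alpha to \[0.01, 1\]).
#'
#' @param design A [cohort_design()].
#' @param seed Integer seed; the cohort is reproducible from it.
#' @return Data frame with one row per subject: `subject_id`, `stage`
#'   (factor F0-F4), `ADC`, `D_app`, `DDC` (mm^2/s), `K_app`, `alpha`, and
#'   `collagen` (percent) when the design includes it.
#' @export
sample_cohort <- function(design, seed = NULL) {
  stopifnot(inherits(design, "cohort_design"))
  if (!is.null(seed)) set.seed(seed)
  tab <- design$stage_table
  n_total <- sum(tab$n)
  stage_idx <- rep(seq_len(5L), tab$n)
  draw <- function(param, lo, hi) {
    m <- tab[[paste0(param, "_mean")]][stage_idx]
    s <- tab[[paste0(param, "_sd")]][stage_idx]
    clip(stats::rnorm(n_total, m, s), lo, hi)
  }
  out <- data.frame(
    subject_id = sprintf("S%03d", seq_len(n_total)),
    stage = factor(metavir_stages()[stage_idx], levels = metavir_stages()),
    ADC   = draw("ADC", 1e-2, 5) * 1e-3,
    D_app = draw("D_app", 1e-2, 5) * 1e-3,
    K_app = draw("K_app", 0, 3),
    DDC   = draw("DDC", 1e-2, 5) * 1e-3,
    alpha = draw("alpha", 0.01, 1),
    stringsAsFactors = FALSE)
  if (!is.null(design$collagen_mean)) {
    out$collagen <- clip(
      stats::rnorm(n_total, design$collagen_mean[stage_idx],
                   design$collagen_sd), 0, 60)
  }
  out
}

#' Corrupt magnitude signals with averaged Rician noise
#'
#' Each acquisition adds independent complex Gaussian noise to the true
#' signal; the recorded magnitude is sqrt((S + g1)^2 + g2^2) with
#' g1, g2 ~ N(0, sigma). With `n_averages` acquisitions, the recorded value
#' is the mean of the independent magnitudes, so its variance shrinks by
#' roughly 1/n_averages while the Rician floor bias remains. No bias
#' correction is applied anywhere downstream; the phantom exists partly to
#' quantify that bias.
#'
#' @param signal Numeric vector of true magnitudes (>= 0).
#' @param sigma Noise SD, same units as `signal`.
#' @param n_averages Number of signal averages (>= 1).
#' @return Numeric vector of noisy magnitudes, same length as `signal`.
#'   Uses the current RNG state; seed via `set.seed()` upstream.
#' @export
add_rician_noise <- function(signal, sigma, n_averages = 1L) {
  stopifnot(sigma >= 0, n_averages >= 1L)
  if (sigma == 0) return(signal)
  n <- length(signal)
  g1 <- matrix(stats::rnorm(n * n_averages, 0, sigma), nrow = n)
  g2 <- matrix(stats::rnorm(n * n_averages, 0, sigma), nrow = n)
  rowMeans(sqrt((signal + g1)^2 + g2^2))
}

# circular liver mask centred in the grid
disc_mask <- function(grid_size, radius = grid_size / 2 - 1.5) {
  ctr <- (grid_size + 1) / 2
  outer(seq_len(grid_size), seq_len(grid_size),
        function(i, j) (i - ctr)^2 + (j - ctr)^2 <= radius^2)
}

#' Synthesize the DWI volumes of one subject
#'
#' Produces the pair of acquisitions of the imaging protocol: a two-b-value
#' volume generated by the monoexponential model with the subject's true
#' ADC, and a four-b-value volume generated by the design's
#' `generator_model` (stretched exponential by default, using the subject's
#' DDC and alpha). Noiseless signals are computed per masked pixel and then
#' corrupted by [add_rician_noise()] with each b-value's number of signal
#' averages. With `jitter_sd = 0` (default) the truth is constant over the
#' liver, so ROI means are unbiased estimates of the subject truth.
#'
#' @param truth One row of the data frame returned by [sample_cohort()].
#' @param design The [cohort_design()].
#' @param seed Integer seed; volumes are reproducible from it.
#' @return List with `mono` and `multib` [dwi_volume()] objects.
#' @export
synthesize_subject <- function(truth, design, seed = NULL) {
  stopifnot(inherits(design, "cohort_design"))
  if (!is.null(seed)) set.seed(seed)
  mask <- disc_mask(design$grid_size)
  sig <- design$sigma * design$S0

  pixel_truth <- function(value, lo, hi) {
    v <- rep(value, sum(mask))
    if (design$jitter_sd > 0) {
      v <- clip(v * (1 + stats::rnorm(length(v), 0, design$jitter_sd)), lo, hi)
    }
    v
  }

  make_volume <- function(scheme, predict_pixel, par_list) {
    nb <- length(scheme$b_values)
    arr <- array(0, dim = c(design$grid_size, design$grid_size, nb))
    idx <- which(mask)
    n_px <- length(idx)
    clean <- matrix(0, n_px, nb)
    for (p in seq_len(n_px)) {
      clean[p, ] <- predict_pixel(lapply(par_list, `[`, p), scheme$b_values)
    }
    for (k in seq_len(nb)) {
      plane <- matrix(0, design$grid_size, design$grid_size)
      plane[idx] <- add_rician_noise(clean[, k], sig, scheme$averages[k])
      arr[, , k] <- plane
    }
    dwi_volume(arr, scheme, mask, design$pixel_size_mm)
  }

  adc <- pixel_truth(truth$ADC, 1e-5, 5e-3)
  mono_vol <- make_volume(
    design$scheme_mono,
    function(p, b) predict_mono(mono_params(design$S0, p$ADC), b),
    list(ADC = adc))

  if (design$generator_model == "sem") {
    ddc <- pixel_truth(truth$DDC, 1e-5, 5e-3)
    al <- pixel_truth(truth$alpha, 0.01, 1)
    multib_vol <- make_volume(
      design$scheme_multib,
      function(p, b) predict_sem(sem_params(design$S0, p$DDC, p$alpha), b),
      list(DDC = ddc, alpha = al))
  } else {
    dap <- pixel_truth(truth$D_app, 1e-5, 5e-3)
    kap <- pixel_truth(truth$K_app, 0, 3)
    multib_vol <- make_volume(
      design$scheme_multib,
      function(p, b) predict_dki(dki_params(design$S0, p$D_app, p$K_app), b),
      list(D_app = dap, K_app = kap))
  }
  list(mono = mono_vol, multib = multib_vol)
}
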