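# shared fixtures: noiseless series and a desk-scale cohort design

noiseless_series <- function(model, ..., scheme = multib_scheme()) {
  p <- list(...)
  signals <- switch(model,
    mono = predict_mono(mono_params(p$S0, p$ADC), scheme$b_values),
    dki = predict_dki(dki_params(p$S0, p$D_app, p$K_app), scheme$b_values),
    sem = predict_sem(sem_params(p$S0, p$DDC, p$alpha), scheme$b_values))
  dwi_series(scheme, signals)
}

# uniform volume: every masked pixel carries the same signals
uniform_volume <- function(signals, scheme, n = 8L, pixel_size_mm = 50 / 64) {
  arr <- array(rep(signals, each = n * n), dim = c(n, n, length(signals)))
  mask <- matrix(TRUE, n, n)
  dwi_volume(arr, scheme, mask, pixel_size_mm)
}

# small cohort design for pipeline-level tests
tiny_design <- function(...) {
  cohort_design(stage_counts = c(2L, 2L, 2L, 2L, 2L), grid_size = 16L, ...)
}

tiny_config <- function(n_per_stage = 2L, grid_size = 16L, ...) {
  cfg <- read_pipeline_config()
  cfg$cohort$stage_table <- lapply(cfg$cohort$stage_table, function(s) {
    s$n <- n_per_stage
    s
  })
  cfg$cohort$grid_size <- grid_size
  extra <- list(...)
  for (nm in names(extra)) cfg$cohort[[nm]] <- extra[[nm]]
  cfg
}

rel_err <- function(est, truth) abs(est - truth) / abs(truth)
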