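#' A multi-b-value signal series for one voxel
#'
#' @param scheme A [bvalue_scheme()].
#' @param signals Numeric vector of non-negative magnitude signals, one per
#'   b-value of the scheme.
#' @return An object of class `dwi_series`.
#' @export
dwi_series <- function(scheme, signals) {
  stopifnot(inherits(scheme, "bvalue_scheme"))
  signals <- as.numeric(signals)
  if (length(signals) != length(scheme$b_values)) {
    stop("signals must have one value per b-value", call. = FALSE)
  }
  if (anyNA(signals) || any(signals < 0)) {
    stop("signals must be non-negative", call. = FALSE)
  }
  structure(list(scheme = scheme, signals = signals), class = "dwi_series")
}

#' A 2-D diffusion-weighted volume (slice)
#'
#' Carries the per-pixel signal stack for one acquisition scheme together
#' with the liver mask and the in-plane pixel size.
#'
#' @param signals 3-D array `rows x cols x n_b` of magnitude signals.
#' @param scheme A [bvalue_scheme()] whose length matches the third axis.
#' @param liver_mask Logical matrix `rows x cols`; `TRUE` marks liver pixels.
#' @param pixel_size_mm In-plane pixel dimension in mm, > 0.
#' @return An object of class `dwi_volume`.
#' @export
dwi_volume <- function(signals, scheme, liver_mask, pixel_size_mm) {
  stopifnot(inherits(scheme, "bvalue_scheme"))
  if (length(dim(signals)) != 3L ||
      dim(signals)[3] != length(scheme$b_values)) {
    stop("signals must be rows x cols x n_b with n_b matching the scheme",
         call. = FALSE)
  }
  if (!is.logical(liver_mask) ||
      !identical(dim(liver_mask), dim(signals)[1:2])) {
    stop("liver_mask must be a logical matrix matching the grid", call. = FALSE)
  }
  if (!is.numeric(pixel_size_mm) || pixel_size_mm <= 0) {
    stop("pixel_size_mm must be > 0", call. = FALSE)
  }
  structure(list(signals = signals, scheme = scheme, liver_mask = liver_mask,
                 pixel_size_mm = pixel_size_mm),
            class = "dwi_volume")
}

fit_result <- function(params, residual_norm, converged) {
  structure(list(params = params, residual_norm = residual_norm,
                 converged = converged),
            class = "dwi_fit")
}

#' @export
print.dwi_fit <- function(x, ...) {
  cat("<dwi_fit>", if (x$converged) "converged" else "NOT converged",
      "| residual_norm =", format(x$residual_norm), "\n")
  if (x$converged) utils::str(x$params, give.attr = FALSE)
  invisible(x)
}

# weighted least squares of log-signal on b; weights = signal averages
log_linear_fit <- function(b, log_s, w) {
  sw <- sum(w)
  mb <- sum(w * b) / sw
  my <- sum(w * log_s) / sw
  slope <- sum(w * (b - mb) * (log_s - my)) / sum(w * (b - mb)^2)
  intercept <- my - slope * mb
  c(intercept = intercept, slope = slope)
}

#' Fit the monoexponential model to one voxel
#'
#' Averages-weighted least squares of ln(S) against b. With exactly two
#' b-values this reduces to the closed form
#' ADC = ln(S_b0 / S_b1) / (b1 - b0). Any non-positive signal flags the voxel
#' as non-converged (the log-domain fit is undefined there).
#'
#' @param series A [dwi_series()] with at least two distinct b-values.
#' @return A `dwi_fit` with `params` ([mono_params()]), `residual_norm` (sum
#'   of averages-weighted squared log-domain residuals) and `converged`.
#' @export
fit_mono <- function(series) {
  stopifnot(inherits(series, "dwi_series"))
  b <- series$scheme$b_values
  if (length(unique(b)) < 2L) {
    stop("fit_mono needs at least 2 distinct b-values", call. = FALSE)
  }
  if (any(series$signals <= 0)) {
    return(fit_result(NULL, NA_real_, FALSE))
  }
  w <- series$scheme$averages
  log_s <- log(series$signals)
  co <- log_linear_fit(b, log_s, w)
  adc <- max(-co[["slope"]], 0)
  s0 <- exp(co[["intercept"]])
  resid <- log_s - (co[["intercept"]] + co[["slope"]] * b)
  fit_result(mono_params(S0 = s0, ADC = adc), sum(w * resid^2), TRUE)
}

# shared Levenberg-Marquardt driver in the log domain.
# starts: list of numeric start vectors; residual_fn(theta, b, log_s, sqrt_w)
# returns weighted residual vector. Ties across starts broken by lowest
# residual, then by tie_value(theta) ascending.
lm_multistart <- function(starts, residual_fn, b, log_s, sqrt_w,
                          lower, upper, tie_value) {
  best <- NULL
  for (i in seq_along(starts)) {
    fit <- tryCatch(
      minpack.lm::nls.lm(
        par = starts[[i]], lower = lower, upper = upper,
        fn = residual_fn, b = b, log_s = log_s, sqrt_w = sqrt_w,
        control = minpack.lm::nls.lm.control(
          maxiter = 200, ptol = 1e-12, ftol = 1e-12, gtol = 0)),
      error = function(e) NULL)
    if (is.null(fit)) next
    # info 1-3: tolerance met. info 4 (with gtol = 0) and 6-7: gradient or
    # residual already at machine limits, which arises for exactly-solvable
    # noiseless data - equally a solution. info 5 (maxiter) / 0 are failures.
    cand <- list(par = fit$par,
                 rss = sum(fit$fvec^2),
                 converged = fit$info %in% c(1:4, 6:7))
    if (i == 1L && cand$converged) return(cand)
    if (is.null(best) ||
        cand$rss < best$rss - 1e-14 ||
        (abs(cand$rss - best$rss) <= 1e-14 &&
         tie_value(cand$par) < tie_value(best$par))) {
      best <- cand
    }
  }
  best
}

#' Fit the diffusion kurtosis model to one voxel
#'
#' Levenberg-Marquardt minimization of the averages-weighted squared
#' residuals of ln(S) under
#' ln S(b) = ln S0 - b D_app + (1/6) (b D_app)^2 K_app,
#' with D_app constrained to \[1e-5, 5e-3\] mm^2/s and K_app to \[0, 3\].
#' The fit is initialized from the monoexponential fit (D_app from the ADC,
#' K_app = 1); if that start does not converge, additional starts at
#' K_app = 0.5, 1 and 2 are tried and the lowest-residual solution kept
#' (ties resolved toward the smaller K_app).
#'
#' @param series A [dwi_series()] with at least three distinct b-values.
#' @return A `dwi_fit` with [dki_params()].
#' @export
fit_dki <- function(series) {
  stopifnot(inherits(series, "dwi_series"))
  b <- series$scheme$b_values
  if (length(unique(b)) < 3L) {
    stop("fit_dki needs at least 3 distinct b-values", call. = FALSE)
  }
  if (any(series$signals <= 0)) {
    return(fit_result(NULL, NA_real_, FALSE))
  }
  log_s <- log(series$signals)
  sqrt_w <- sqrt(series$scheme$averages)
  mono <- fit_mono(series)
  d0 <- clip(mono$params$ADC, 1e-5, 5e-3)
  s0 <- log(mono$params$S0)
  resid_fn <- function(theta, b, log_s, sqrt_w) {
    bd <- b * theta[2]
    sqrt_w * (log_s - (theta[1] - bd + bd^2 * theta[3] / 6))
  }
  starts <- lapply(c(1, 0.5, 2), function(k) c(s0, d0, k))
  best <- lm_multistart(starts, resid_fn, b, log_s, sqrt_w,
                        lower = c(-Inf, 1e-5, 0), upper = c(Inf, 5e-3, 3),
                        tie_value = function(p) p[3])
  if (is.null(best)) return(fit_result(NULL, NA_real_, FALSE))
  fit_result(dki_params(S0 = exp(best$par[1]), D_app = best$par[2],
                        K_app = best$par[3]),
             best$rss, best$converged)
}

#' Fit the stretched exponential model to one voxel
#'
#' Levenberg-Marquardt minimization of the averages-weighted squared
#' residuals of ln(S) under ln S(b) = ln S0 - (b DDC)^alpha, with DDC
#' constrained to \[1e-5, 5e-3\] mm^2/s and alpha to \[0.01, 1\]. Initialized
#' from the monoexponential fit (DDC from the ADC, alpha = 0.8); on
#' non-convergence, additional starts at alpha = 0.5, 0.7 and 0.9 are tried
#' and the lowest-residual solution kept (ties resolved toward the larger
#' alpha).
#'
#' @param series A [dwi_series()] with at least three distinct b-values.
#' @return A `dwi_fit` with [sem_params()].
#' @export
fit_sem <- function(series) {
  stopifnot(inherits(series, "dwi_series"))
  b <- series$scheme$b_values
  if (length(unique(b)) < 3L) {
    stop("fit_sem needs at least 3 distinct b-values", call. = FALSE)
  }
  if (any(series$signals <= 0)) {
    return(fit_result(NULL, NA_real_, FALSE))
  }
  log_s <- log(series$signals)
  sqrt_w <- sqrt(series$scheme$averages)
  mono <- fit_mono(series)
  d0 <- clip(mono$params$ADC, 1e-5, 5e-3)
  s0 <- log(mono$params$S0)
  resid_fn <- function(theta, b, log_s, sqrt_w) {
    sqrt_w * (log_s - (theta[1] - (b * theta[2])^theta[3]))
  }
  starts <- lapply(c(0.8, 0.5, 0.7, 0.9), function(a) c(s0, d0, a))
  best <- lm_multistart(starts, resid_fn, b, log_s, sqrt_w,
                        lower = c(-Inf, 1e-5, 0.01), upper = c(Inf, 5e-3, 1),
                        tie_value = function(p) -p[3])
  if (is.null(best)) return(fit_result(NULL, NA_real_, FALSE))
  fit_result(sem_params(S0 = exp(best$par[1]), DDC = best$par[2],
                        alpha = best$par[3]),
             best$rss, best$converged)
}

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Fit a whole volume pixel-by-pixel
#'
#' Applies [fit_mono()], [fit_dki()] or [fit_sem()] independently to every
#' masked pixel of a [dwi_volume()] and assembles parametric maps. Pixels
#' whose fit fails (for example all-zero signal) are flagged and left `NA`
#' in the maps; all other pixels are unaffected.
#'
#' @param volume A [dwi_volume()].
#' @param model One of `"mono"`, `"dki"`, `"sem"`.
#' @return An object of class `parameter_maps`: a list with one matrix per
#'   model parameter (`ADC`; or `D_app`, `K_app`; or `DDC`, `alpha`; plus
#'   `S0`), a `residual_norm` map, a logical `converged` map, the model
#'   name, the convergence fraction, and the pixel size.
#' @export
fit_volume <- function(volume, model = c("mono", "dki", "sem")) {
  stopifnot(inherits(volume, "dwi_volume"))
  model <- match.arg(model)
  if (!any(volume$liver_mask)) stop("empty liver mask", call. = FALSE)
  fitter <- switch(model, mono = fit_mono, dki = fit_dki, sem = fit_sem)
  par_names <- switch(model,
                      mono = c("S0", "ADC"),
                      dki = c("S0", "D_app", "K_app"),
                      sem = c("S0", "DDC", "alpha"))
  dm <- dim(volume$liver_mask)
  maps <- stats::setNames(
    rep(list(matrix(NA_real_, dm[1], dm[2])), length(par_names)), par_names)
  resid_map <- matrix(NA_real_, dm[1], dm[2])
  conv_map <- matrix(NA, dm[1], dm[2])
  idx <- which(volume$liver_mask, arr.ind = TRUE)
  for (k in seq_len(nrow(idx))) {
    i <- idx[k, 1]; j <- idx[k, 2]
    fit <- fitter(dwi_series(volume$scheme, volume$signals[i, j, ]))
    conv_map[i, j] <- fit$converged
    if (fit$converged) {
      resid_map[i, j] <- fit$residual_norm
      for (p in par_names) maps[[p]][i, j] <- fit$params[[p]]
    }
  }
  structure(c(maps,
              list(residual_norm = resid_map, converged = conv_map,
                   model = model,
                   convergence_fraction = mean(conv_map[volume$liver_mask]),
                   pixel_size_mm = volume$pixel_size_mm)),
            class = "parameter_maps")
}

#' @export
print.parameter_maps <- function(x, ...) {
  cat("<parameter_maps>", x$model, "model,",
      sum(!is.na(x$converged)), "fitted pixels,",
      sprintf("%.1f%% converged", 100 * x$convergence_fraction), "\n")
  invisible(x)
}
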