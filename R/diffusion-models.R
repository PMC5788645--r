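#' Diffusion acquisition scheme
#'
#' A b-value scheme describes the diffusion weightings of an acquisition and
#' the number of signal averages (NSA) collected at each weighting. Averaging
#' reduces the noise variance of the magnitude signal roughly in proportion to
#' the number of averages, so the fitters weight each b-value's residual by
#' its NSA.
#'
#' @param b_values Numeric vector of diffusion weightings in s/mm^2. Must be
#'   non-negative, strictly increasing, and start at 0.
#' @param averages Integer vector of signal averages per b-value (each >= 1),
#'   same length as `b_values`.
#' @return An object of class `bvalue_scheme`.
#' @examples
#' bvalue_scheme(c(0, 800), c(1, 3))
#' @export
bvalue_scheme <- function(b_values, averages = rep(1L, length(b_values))) {
  b_values <- as.numeric(b_values)
  averages <- as.integer(averages)
  if (length(b_values) < 1L || anyNA(b_values)) {
    stop("b_values must be a non-empty numeric vector", call. = FALSE)
  }
  if (any(b_values < 0)) stop("b_values must be non-negative", call. = FALSE)
  if (b_values[1] != 0) stop("the first b-value must be 0", call. = FALSE)
  if (is.unsorted(b_values, strictly = TRUE)) {
    stop("b_values must be strictly increasing", call. = FALSE)
  }
  if (length(averages) != length(b_values) || anyNA(averages) ||
      any(averages < 1L)) {
    stop("averages must be positive integers, one per b-value", call. = FALSE)
  }
  structure(list(b_values = b_values, averages = averages),
            class = "bvalue_scheme")
}

#' @export
print.bvalue_scheme <- function(x, ...) {
  cat("<bvalue_scheme> b =", paste(x$b_values, collapse = ", "),
      "s/mm^2; NSA =", paste(x$averages, collapse = ", "), "\n")
  invisible(x)
}

#' Acquisition schemes used for liver DWI staging
#'
#' `mono_scheme()` is the two-point monoexponential protocol (b = 0, 800
#' s/mm^2 with 1 and 3 averages); `multib_scheme()` is the four-point
#' protocol shared by the kurtosis and stretched-exponential models
#' (b = 0, 700, 1400, 2100 s/mm^2 with 1, 2, 3, 4 averages).
#'
#' @return A [bvalue_scheme()].
#' @export
mono_scheme <- function() bvalue_scheme(c(0, 800), c(1L, 3L))

#' @rdname mono_scheme
#' @export
multib_scheme <- function() bvalue_scheme(c(0, 700, 1400, 2100), 1:4)

#' Per-voxel diffusion parameter sets
#'
#' Constructors for the parameter sets of the three signal models. All
#' diffusion coefficients are stored in mm^2/s (so a typical liver ADC is
#' about 1e-3); reporting layers rescale to the conventional 1e-3 mm^2/s
#' units. `alpha` is the dimensionless heterogeneity index of the stretched
#' exponential: values near 1 mean nearly monoexponential (low heterogeneity)
#' decay, values near 0 mean highly multi-compartment decay.
#'
#' @param S0 Signal at b = 0, arbitrary units, > 0.
#' @param ADC Apparent diffusion coefficient, mm^2/s, >= 0.
#' @param D_app Kurtosis-corrected diffusion coefficient, mm^2/s, > 0.
#' @param K_app Dimensionless apparent kurtosis, >= 0.
#' @param DDC Distributed diffusion coefficient, mm^2/s, > 0.
#' @param alpha Heterogeneity index in (0, 1].
#' @return A parameter object (`mono_params`, `dki_params` or `sem_params`).
#' @export
mono_params <- function(S0, ADC) {
  stopifnot(is.numeric(S0), is.numeric(ADC))
  if (S0 <= 0) stop("S0 must be > 0", call. = FALSE)
  if (ADC < 0) stop("ADC must be >= 0", call. = FALSE)
  structure(list(S0 = S0, ADC = ADC), class = c("mono_params", "dwi_params"))
}

#' @rdname mono_params
#' @export
dki_params <- function(S0, D_app, K_app) {
  stopifnot(is.numeric(S0), is.numeric(D_app), is.numeric(K_app))
  if (S0 <= 0) stop("S0 must be > 0", call. = FALSE)
  if (D_app <= 0) stop("D_app must be > 0", call. = FALSE)
  if (K_app < 0) stop("K_app must be >= 0", call. = FALSE)
  structure(list(S0 = S0, D_app = D_app, K_app = K_app),
            class = c("dki_params", "dwi_params"))
}

#' @rdname mono_params
#' @export
sem_params <- function(S0, DDC, alpha) {
  stopifnot(is.numeric(S0), is.numeric(DDC), is.numeric(alpha))
  if (S0 <= 0) stop("S0 must be > 0", call. = FALSE)
  if (DDC <= 0) stop("DDC must be > 0", call. = FALSE)
  if (alpha <= 0 || alpha > 1) stop("alpha must be in (0, 1]", call. = FALSE)
  structure(list(S0 = S0, DDC = DDC, alpha = alpha),
            class = c("sem_params", "dwi_params"))
}

#' Forward signal models
#'
#' Closed-form magnitude signals for the three diffusion representations:
#' \describe{
#'   \item{monoexponential}{S(b) = S0 exp(-b ADC)}
#'   \item{diffusion kurtosis}{ln S(b) = ln S0 - b D_app + (1/6) (b D_app)^2 K_app}
#'   \item{stretched exponential}{ln S(b) = ln S0 - (b DDC)^alpha}
#' }
#' The kurtosis expansion is only monotone decreasing for
#' b < 3 / (D_app K_app); beyond that the quadratic term dominates and the
#' predicted signal turns upward. `predict_dki()` warns when evaluated there
#' but still returns the closed-form value (the fitters' parameter bounds keep
#' estimates inside the valid range).
#'
#' @param params A `mono_params`, `dki_params` or `sem_params` object.
#' @param b_values Numeric vector of non-negative b-values, s/mm^2.
#' @return Numeric vector of predicted signals, one per b-value.
#' @examples
#' predict_mono(mono_params(100, 0.92e-3), c(0, 800))
#' predict_sem(sem_params(100, 0.76e-3, 0.68), c(0, 700, 1400, 2100))
#' @export
predict_mono <- function(params, b_values) {
  stopifnot(inherits(params, "mono_params"))
  b_values <- check_b(b_values)
  params$S0 * exp(-b_values * params$ADC)
}

#' @rdname predict_mono
#' @export
predict_dki <- function(params, b_values) {
  stopifnot(inherits(params, "dki_params"))
  b_values <- check_b(b_values)
  if (params$K_app > 0) {
    b_max <- 3 / (params$D_app * params$K_app)
    if (any(b_values > b_max)) {
      warning(sprintf(
        "b-values beyond the monotone range of the kurtosis expansion (b > %.0f s/mm^2)",
        b_max), call. = FALSE)
    }
  }
  bd <- b_values * params$D_app
  exp(log(params$S0) - bd + bd^2 * params$K_app / 6)
}

#' @rdname predict_mono
#' @export
predict_sem <- function(params, b_values) {
  stopifnot(inherits(params, "sem_params"))
  b_values <- check_b(b_values)
  exp(log(params$S0) - (b_values * params$DDC)^params$alpha)
}

check_b <- function(b_values) {
  b_values <- as.numeric(b_values)
  if (anyNA(b_values) || any(b_values < 0)) {
    stop("b_values must be non-negative", call. = FALSE)
  }
  b_values
}
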