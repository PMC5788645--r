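#' One-way ANOVA with Fisher's LSD post hoc tests
#'
#' Classical between/within decomposition across fibrosis stages (fitted via
#' [stats::lm()]), followed by Fisher's least-significant-difference
#' pairwise comparisons: unadjusted pairwise t tests that share the pooled
#' within-group mean square and its degrees of freedom. The LSD p values
#' are deliberately not corrected for multiplicity - that is what LSD means
#' - and the result is tagged accordingly.
#'
#' @param values_by_group List of numeric vectors, one per group (>= 2
#'   groups, each with >= 2 values). Names are used as group labels.
#' @return An object of class `anova_result`: `F`, `p_value`, `df`
#'   (between, within), `group_means`, `group_sds`, `group_n`, and `lsd_p`,
#'   a symmetric pairwise p-value matrix with unit diagonal
#'   (attribute `adjusted` = "none").
#' @export
one_way_anova <- function(values_by_group) {
  if (!is.list(values_by_group) || length(values_by_group) < 2L) {
    stop("need at least 2 groups", call. = FALSE)
  }
  sizes <- lengths(values_by_group)
  if (any(sizes < 2L)) {
    stop("every group needs at least 2 values", call. = FALSE)
  }
  labels <- names(values_by_group)
  if (is.null(labels)) labels <- paste0("g", seq_along(values_by_group))
  y <- unlist(values_by_group, use.names = FALSE)
  g <- factor(rep(labels, sizes), levels = labels)
  # degenerate zero-variance layouts are handled explicitly below, so the
  # "essentially perfect fit" warning from anova() carries no information
  aov_tab <- suppressWarnings(stats::anova(stats::lm(y ~ g)))
  k <- length(sizes)
  msw <- aov_tab["Residuals", "Mean Sq"]
  df_w <- aov_tab["Residuals", "Df"]
  means <- vapply(values_by_group, mean, 0)
  lsd <- matrix(1, k, k, dimnames = list(labels, labels))
  for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
    if (msw == 0) {  # degenerate: no within-group variance at all
      pij <- if (means[i] == means[j]) 1 else 0
    } else {
      tij <- (means[i] - means[j]) / sqrt(msw * (1 / sizes[i] + 1 / sizes[j]))
      pij <- 2 * stats::pt(-abs(tij), df_w)
    }
    lsd[i, j] <- lsd[j, i] <- pij
  }
  attr(lsd, "adjusted") <- "none"
  f_val <- aov_tab["g", "F value"]
  p_val <- aov_tab["g", "Pr(>F)"]
  if (all(means == means[1])) {
    f_val <- 0; p_val <- 1       # no between-group signal at all
  } else if (msw == 0) {
    f_val <- Inf; p_val <- 0     # separation with zero within-group noise
  }
  structure(list(F = f_val,
                 p_value = p_val,
                 df = c(between = k - 1L, within = df_w),
                 group_means = means,
                 group_sds = vapply(values_by_group, stats::sd, 0),
                 group_n = sizes,
                 lsd_p = lsd),
            class = "anova_result")
}

correlation_result <- function(coefficient, ci, p_value, method, n) {
  structure(list(coefficient = coefficient, ci = ci, p_value = p_value,
                 method = method, n = n),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("<%s> r = %.3f (95%% CI %.3f, %.3f), p = %.3g, n = %d\n",
              x$method, x$coefficient, x$ci[1], x$ci[2], x$p_value, x$n))
  invisible(x)
}

fisher_z_ci <- function(r, n, conf = 0.95) {
  if (abs(r) >= 1) return(c(r, r))
  z <- atanh(r)
  half <- stats::qnorm(1 - (1 - conf) / 2) / sqrt(n - 3)
  tanh(c(z - half, z + half))
}

#' Rank and product-moment correlations with Fisher-z intervals
#'
#' `spearman_with_ci()` computes Spearman's rho as the Pearson correlation
#' of mid-ranks (ties averaged) with a two-sided p value from the
#' large-sample approximation; `pearson_with_ci()` computes the standard
#' product-moment coefficient. Both report a 95% confidence interval from
#' the Fisher z transform with standard error 1/sqrt(n - 3).
#'
#' @param x,y Numeric vectors of equal length, n >= 4. For stage
#'   correlations, pass the stage as its numeric score (0-4).
#' @return A `correlation_result`: `coefficient`, `ci`, `p_value`,
#'   `method`, `n`.
#' @export
spearman_with_ci <- function(x, y) {
  check_corr_input(x, y)
  rho <- stats::cor(rank(x), rank(y))
  p <- stats::cor.test(x, y, method = "spearman", exact = FALSE)$p.value
  correlation_result(rho, fisher_z_ci(rho, length(x)), p, "spearman",
                     length(x))
}

#' @rdname spearman_with_ci
#' @export
pearson_with_ci <- function(x, y) {
  check_corr_input(x, y)
  ct <- stats::cor.test(x, y, method = "pearson")
  correlation_result(unname(ct$estimate),
                     fisher_z_ci(unname(ct$estimate), length(x)),
                     ct$p.value, "pearson", length(x))
}

check_corr_input <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length",
                                   call. = FALSE)
  if (length(x) < 4L) stop("need n >= 4", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined for constant input", call. = FALSE)
  }
  invisible(NULL)
}

#' Dichotomize METAVIR stages for ROC analysis
#'
#' The four diagnostic questions of fibrosis staging, each splitting the
#' five stages into a negative (lower) and positive (higher) side:
#' \describe{
#'   \item{any_fibrosis}{F0 versus F1-F4}
#'   \item{significant}{F0-F1 versus F2-F4}
#'   \item{advanced}{F0-F2 versus F3-F4}
#'   \item{cirrhosis}{F0-F3 versus F4}
#' }
#'
#' @param stages Vector (factor or character) of stage labels F0-F4.
#' @param split One of `"any_fibrosis"`, `"significant"`, `"advanced"`,
#'   `"cirrhosis"`.
#' @return Logical vector: `TRUE` for the positive (higher-stage) class.
#' @export
dichotomize_stages <- function(stages,
                               split = c("any_fibrosis", "significant",
                                         "advanced", "cirrhosis")) {
  split <- match.arg(split)
  stages <- as.character(stages)
  if (length(stages) == 0L) return(logical(0))
  if (!all(stages %in% metavir_stages())) {
    stop("unknown stage labels: ",
         paste(unique(setdiff(stages, metavir_stages())), collapse = ", "),
         call. = FALSE)
  }
  cut_at <- switch(split, any_fibrosis = 1L, significant = 2L,
                   advanced = 3L, cirrhosis = 4L)
  match(stages, metavir_stages()) - 1L >= cut_at
}

#' ROC analysis with Youden-index cutoff and DeLong interval
#'
#' The AUC is the empirical pairwise concordance (tied pairs count 1/2),
#' identical to the Mann-Whitney U statistic divided by n1*n0. With
#' `direction = "auto"` the orientation is chosen so that AUC >= 0.5:
#' diffusion coefficients, which fall with fibrosis, come out as
#' "positive when <= cutoff". The 95% CI uses DeLong's placement-value
#' variance. The cutoff maximizes the Youden index
#' (sensitivity + specificity - 100) over the midpoints between consecutive
#' sorted unique values; ties are broken toward higher specificity, then
#' the smaller cutoff.
#'
#' @param values Numeric marker values.
#' @param labels Logical (or 0/1) vector; `TRUE` = positive class.
#' @param direction `"auto"`, `"le"` (positive test when value <= cutoff)
#'   or `"ge"`.
#' @return An object of class `roc_result`: `auc`, `ci`, `cutoff`,
#'   `direction`, `sensitivity` and `specificity` (percent), `n_pos`,
#'   `n_neg`.
#' @export
roc_analysis <- function(values, labels, direction = c("auto", "le", "ge")) {
  direction <- match.arg(direction)
  labels <- as.logical(labels)
  stopifnot(length(values) == length(labels), !anyNA(values), !anyNA(labels))
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0L || n_neg == 0L) {
    stop("both classes must be non-empty", call. = FALSE)
  }
  r <- rank(values)
  auc_ge <- (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  if (direction == "auto") direction <- if (auc_ge >= 0.5) "ge" else "le"
  auc <- if (direction == "ge") auc_ge else 1 - auc_ge

  # DeLong placement values on orientation-adjusted scores
  s <- if (direction == "ge") values else -values
  x <- s[labels]; y <- s[!labels]
  psi <- outer(x, y, function(a, b) (a > b) + 0.5 * (a == b))
  v_pos <- rowMeans(psi)
  v_neg <- colMeans(psi)
  se <- sqrt(stats::var(v_pos) / n_pos + stats::var(v_neg) / n_neg)
  ci <- clip(auc + c(-1, 1) * stats::qnorm(0.975) * se, 0, 1)

  cuts <- sort(unique(values))
  cand <- if (length(cuts) > 1L) (cuts[-1] + cuts[-length(cuts)]) / 2
          else cuts
  best <- NULL
  for (cc in cand) {
    if (direction == "le") {
      sens <- 100 * mean(values[labels] <= cc)
      spec <- 100 * mean(values[!labels] > cc)
    } else {
      sens <- 100 * mean(values[labels] >= cc)
      spec <- 100 * mean(values[!labels] < cc)
    }
    j <- sens + spec - 100
    if (is.null(best) || j > best$j + 1e-12 ||
        (abs(j - best$j) <= 1e-12 &&
         (spec > best$spec + 1e-12 ||
          (abs(spec - best$spec) <= 1e-12 && cc < best$cutoff)))) {
      best <- list(j = j, cutoff = cc, sens = sens, spec = spec)
    }
  }
  structure(list(auc = auc, ci = ci, cutoff = best$cutoff,
                 direction = direction,
                 sensitivity = best$sens, specificity = best$spec,
                 n_pos = n_pos, n_neg = n_neg),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf(
    "<roc_result> AUC %.3f (%.3f, %.3f); %s %.4g: sens %.1f%%, spec %.1f%%\n",
    x$auc, x$ci[1], x$ci[2],
    if (x$direction == "le") "<=" else ">=", x$cutoff,
    x$sensitivity, x$specificity))
  invisible(x)
}

#' Closed-form AUC of a stage-mixture of normal classes
#'
#' Semi-analytic oracle for the expected pairwise-concordance AUC when both
#' classes are mixtures of the stage-conditional normal distributions of a
#' [cohort_design()]: the class-size-weighted average over (negative stage,
#' positive stage) pairs of Phi(dmu / sqrt(sd_neg^2 + sd_pos^2)), with dmu
#' oriented by the marker's direction.
#'
#' @param design A [cohort_design()].
#' @param parameter One of `"ADC"`, `"D_app"`, `"K_app"`, `"DDC"`,
#'   `"alpha"`.
#' @param split A split name accepted by [dichotomize_stages()].
#' @param direction `"le"` (marker falls with fibrosis), `"ge"`, or
#'   `"auto"` (chosen from the design's stage means).
#' @return The closed-form expected AUC.
#' @export
auc_binormal_mixture <- function(design, parameter, split,
                                 direction = c("auto", "le", "ge")) {
  stopifnot(inherits(design, "cohort_design"))
  direction <- match.arg(direction)
  tab <- design$stage_table
  mu <- tab[[paste0(parameter, "_mean")]]
  sd <- tab[[paste0(parameter, "_sd")]]
  n <- tab$n
  pos <- dichotomize_stages(tab$stage, split)
  if (direction == "auto") {
    wm <- function(sel) sum(mu[sel] * n[sel]) / sum(n[sel])
    direction <- if (wm(pos) < wm(!pos)) "le" else "ge"
  }
  total <- 0
  for (i in which(!pos)) for (j in which(pos)) {
    dmu <- if (direction == "le") mu[i] - mu[j] else mu[j] - mu[i]
    total <- total + n[i] * n[j] * stats::pnorm(dmu / sqrt(sd[i]^2 + sd[j]^2))
  }
  total / (sum(n[!pos]) * sum(n[pos]))
}
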