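#' Names of the five diffusion parameters and the four stage splits
#'
#' @return `dwi_parameters()`: the parameter names in table order;
#'   `roc_splits()`: the split identifiers accepted by
#'   [dichotomize_stages()].
#' @export
dwi_parameters <- function() c("ADC", "D_app", "K_app", "DDC", "alpha")

#' @rdname dwi_parameters
#' @export
roc_splits <- function() c("any_fibrosis", "significant", "advanced",
                           "cirrhosis")

split_label <- function(split) {
  switch(split,
         any_fibrosis = "F0 versus F1-2-3-4",
         significant = "F0-1 versus F2-3-4",
         advanced = "F0-1-2 versus F3-4",
         cirrhosis = "F0-1-2-3 versus F4")
}

#' Build the staging report tables from per-subject summaries
#'
#' Reproduces the shape of the study's result tables from a cohort of
#' subject summaries: per-stage means and SDs with one-way ANOVA per
#' parameter (with LSD post hoc matrices), Spearman correlations of every
#' parameter with stage, Pearson correlations with the collagen-area
#' fraction when present, and ROC analyses of the diffusion coefficients
#' across the four stage splits. K_app and alpha ROC rows can be added with
#' `roc_parameters`; by default only the three diffusion coefficients are
#' analysed.
#'
#' @param subjects Data frame with columns `stage` (F0-F4) and the five
#'   parameters `ADC`, `D_app`, `K_app`, `DDC`, `alpha`; optionally
#'   `collagen`. Diffusion coefficients are expected in mm^2/s and are
#'   rescaled by `coefficient_scale` for display.
#' @param roc_parameters Parameters given ROC rows.
#' @param splits Stage splits to analyse; see [dichotomize_stages()].
#' @param coefficient_scale Display rescaling of the diffusion coefficients
#'   (default 1000: mm^2/s to the conventional 1e-3 mm^2/s).
#' @return A list of class `staging_report`: `table1_means`,
#'   `table2_stage_corr`, `table3_collagen_corr` (NULL without collagen),
#'   `table4_roc`, plus `anova` (per-parameter `anova_result`s, including
#'   the LSD matrices), `normality` (advisory Kolmogorov-Smirnov screen of
#'   the pooled within-stage z-scores), and `meta`.
#' @export
build_report <- function(subjects,
                         roc_parameters = c("ADC", "D_app", "DDC"),
                         splits = roc_splits(),
                         coefficient_scale = 1000) {
  params <- dwi_parameters()
  missing_cols <- setdiff(c("stage", params), names(subjects))
  if (length(missing_cols)) {
    stop("subjects is missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  stage <- factor(as.character(subjects$stage), levels = metavir_stages())
  present <- levels(droplevels(stage))
  if (length(present) < 2L) {
    stop("need subjects from at least 2 stages", call. = FALSE)
  }
  stopifnot(all(roc_parameters %in% params),
            all(splits %in% roc_splits()))
  coef_params <- c("ADC", "D_app", "DDC")
  scale_of <- function(p) if (p %in% coef_params) coefficient_scale else 1
  stage_num <- as.integer(stage) - 1L

  # Table 1: per-stage mean +/- SD and ANOVA per parameter
  anovas <- list()
  t1 <- data.frame(parameter = params, stringsAsFactors = FALSE)
  for (s in present) {
    t1[[paste0(s, "_mean")]] <- NA_real_
    t1[[paste0(s, "_sd")]] <- NA_real_
  }
  t1$anova_F <- NA_real_; t1$anova_p <- NA_real_
  normality <- data.frame(parameter = params, ks_p = NA_real_,
                          stringsAsFactors = FALSE)
  for (pi in seq_along(params)) {
    p <- params[pi]
    v <- subjects[[p]] * scale_of(p)
    groups <- split(v, droplevels(stage))
    an <- one_way_anova(groups)
    anovas[[p]] <- an
    for (s in present) {
      t1[pi, paste0(s, "_mean")] <- an$group_means[[s]]
      t1[pi, paste0(s, "_sd")] <- an$group_sds[[s]]
    }
    t1$anova_F[pi] <- an$F
    t1$anova_p[pi] <- an$p_value
    # advisory normality screen on pooled within-stage z-scores
    z <- unlist(lapply(groups, function(g) {
      if (stats::sd(g) > 0) (g - mean(g)) / stats::sd(g) else NULL
    }), use.names = FALSE)
    normality$ks_p[pi] <- if (length(z) >= 4L) {
      suppressWarnings(stats::ks.test(z, "pnorm")$p.value)
    } else NA_real_  # degenerate groups: screen not informative
  }

  corr_table <- function(y, y_scale_free = FALSE, method = "spearman") {
    rows <- lapply(params, function(p) {
      fn <- if (method == "spearman") spearman_with_ci else pearson_with_ci
      cr <- fn(y, subjects[[p]])
      data.frame(parameter = p, coefficient = cr$coefficient,
                 ci_low = cr$ci[1], ci_high = cr$ci[2],
                 p_value = cr$p_value, n = cr$n, stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  }
  t2 <- corr_table(stage_num, method = "spearman")
  t3 <- if ("collagen" %in% names(subjects)) {
    corr_table(subjects$collagen, method = "pearson")
  } else NULL

  t4 <- do.call(rbind, lapply(splits, function(sp) {
    labels <- dichotomize_stages(stage, sp)
    do.call(rbind, lapply(roc_parameters, function(p) {
      roc <- roc_analysis(subjects[[p]], labels, direction = "auto")
      data.frame(split = split_label(sp), parameter = p,
                 auc = roc$auc, ci_low = roc$ci[1], ci_high = roc$ci[2],
                 cutoff = roc$cutoff * scale_of(p),
                 direction = if (roc$direction == "le") "<=" else ">=",
                 sensitivity = roc$sensitivity,
                 specificity = roc$specificity,
                 stringsAsFactors = FALSE)
    }))
  }))

  structure(list(table1_means = t1, table2_stage_corr = t2,
                 table3_collagen_corr = t3, table4_roc = t4,
                 anova = anovas, normality = normality,
                 meta = list(n_subjects = nrow(subjects),
                             stages_present = present,
                             lsd_adjusted = "none",
                             coefficient_scale = coefficient_scale)),
            class = "staging_report")
}

#' @export
print.staging_report <- function(x, ...) {
  cat("<staging_report>", x$meta$n_subjects, "subjects, stages",
      paste(x$meta$stages_present, collapse = "/"), "\n\n")
  cat("Stage correlations (Spearman):\n")
  print(x$table2_stage_corr, digits = 3, row.names = FALSE)
  cat("\nROC (Youden cutoffs):\n")
  print(x$table4_roc, digits = 3, row.names = FALSE)
  invisible(x)
}

#' Replicate-averaged subject-level staging statistics
#'
#' Draws many independent cohorts from a design and averages the
#' subject-level statistics across replicates: the Spearman correlation of
#' each parameter with stage, and the empirical AUC of each requested
#' (parameter, split) pair. This Monte-Carlo average is the package's
#' estimate of the statistics implied by the design's stage-conditional
#' distributions alone (no imaging noise, no fitting), and is cross-checked
#' against the closed-form [auc_binormal_mixture()] oracle in the test
#' suite. Only per-subject draws are needed, so hundreds of replicates run
#' in seconds.
#'
#' @param design A [cohort_design()].
#' @param n_replicates Number of replicate cohorts.
#' @param seed Base seed; replicate r uses `seed + r - 1`.
#' @param parameters Parameters to correlate with stage.
#' @param roc_parameters,splits ROC rows to average.
#' @return List with `correlations` (parameter, mean_rho, se_rho),
#'   `aucs` (parameter, split, mean_auc, se_auc) and `n_replicates`.
#' @export
replicate_cohort_stats <- function(design, n_replicates = 200, seed = 1,
                                   parameters = dwi_parameters(),
                                   roc_parameters = c("ADC", "D_app", "DDC"),
                                   splits = roc_splits()) {
  stopifnot(inherits(design, "cohort_design"), n_replicates >= 2)
  rho <- matrix(NA_real_, n_replicates, length(parameters),
                dimnames = list(NULL, parameters))
  auc_grid <- expand.grid(parameter = roc_parameters, split = splits,
                          stringsAsFactors = FALSE)
  aucs <- matrix(NA_real_, n_replicates, nrow(auc_grid))
  for (r in seq_len(n_replicates)) {
    cohort <- sample_cohort(design, seed = seed + r - 1)
    stage_num <- as.integer(cohort$stage) - 1L
    for (p in parameters) {
      rho[r, p] <- stats::cor(stage_num, cohort[[p]], method = "spearman")
    }
    for (g in seq_len(nrow(auc_grid))) {
      labels <- dichotomize_stages(cohort$stage, auc_grid$split[g])
      aucs[r, g] <- roc_analysis(cohort[[auc_grid$parameter[g]]], labels,
                                 direction = "auto")$auc
    }
  }
  list(correlations = data.frame(
         parameter = parameters,
         mean_rho = colMeans(rho),
         se_rho = apply(rho, 2, stats::sd) / sqrt(n_replicates),
         row.names = NULL, stringsAsFactors = FALSE),
       aucs = data.frame(
         auc_grid,
         mean_auc = colMeans(aucs),
         se_auc = apply(aucs, 2, stats::sd) / sqrt(n_replicates),
         stringsAsFactors = FALSE),
       n_replicates = n_replicates)
}
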