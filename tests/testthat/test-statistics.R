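# brute-force sums-of-squares ANOVA used as the oracle
anova_brute <- function(groups) {
  y <- unlist(groups)
  gm <- mean(y)
  ssb <- sum(lengths(groups) * (vapply(groups, mean, 0) - gm)^2)
  ssw <- sum(unlist(lapply(groups, function(g) (g - mean(g))^2)))
  k <- length(groups)
  (ssb / (k - 1)) / (ssw / (length(y) - k))
}

test_that("one-way ANOVA matches hand and brute-force computations", {
  res <- one_way_anova(list(c(1, 2, 3), c(2, 3, 4), c(4, 5, 6)))
  expect_equal(res$F, 7)  # SSB = 14, SSW = 6 by hand
  expect_equal(unname(res$df), c(2L, 6L))
  expect_equal(res$p_value, pf(7, 2, 6, lower.tail = FALSE))
  expect_true(isSymmetric(res$lsd_p))
  expect_equal(unname(diag(res$lsd_p)), rep(1, 3))

  set.seed(17)
  for (rep in 1:20) {
    groups <- lapply(sample(2:6, sample(2:5, 1), replace = TRUE) + 1,
                     rnorm)
    expect_equal(one_way_anova(groups)$F, anova_brute(groups),
                 tolerance = 1e-10)
  }
})

test_that("identical groups give F = 0 and unit LSD p-values", {
  res <- one_way_anova(list(c(5, 5), c(5, 5), c(5, 5)))
  expect_equal(res$F, 0)
  expect_equal(res$p_value, 1)
  expect_true(all(res$lsd_p == 1))
})

test_that("two-group F equals the squared pooled t statistic", {
  set.seed(23)
  x <- rnorm(8); y <- rnorm(10, 0.5)
  res <- one_way_anova(list(x, y))
  tt <- t.test(x, y, var.equal = TRUE)
  expect_equal(res$F, unname(tt$statistic)^2, tolerance = 1e-12)
  expect_equal(res$lsd_p[1, 2], tt$p.value, tolerance = 1e-12)
})

test_that("ANOVA rejects undersized input", {
  expect_error(one_way_anova(list(c(1, 2))), "2 groups")
  expect_error(one_way_anova(list(c(1, 2), 3)), "at least 2 values")
})

test_that("Spearman handles perfect monotone and tied inputs", {
  expect_equal(spearman_with_ci(0:4, c(5, 4, 3, 2, 1))$coefficient, -1)
  # mid-rank ties by hand: ranks x = 1.5,1.5,3.5,3.5 vs 1:4 -> 4/sqrt(20)
  expect_equal(spearman_with_ci(c(1, 1, 2, 2), 1:4)$coefficient,
               2 / sqrt(5), tolerance = 1e-10)
  expect_error(spearman_with_ci(rep(1, 5), 1:5), "constant")
  expect_error(spearman_with_ci(1:3, 1:3), "n >= 4")
})

test_that("Spearman equals Pearson on mid-ranks on random tied data", {
  set.seed(29)
  for (rep in 1:25) {
    x <- sample(0:4, 30, replace = TRUE)
    y <- rnorm(30) + x
    res <- spearman_with_ci(x, y)
    expect_equal(res$coefficient, cor(rank(x), rank(y)), tolerance = 1e-12)
    expect_equal(res$coefficient, cor(x, y, method = "spearman"),
                 tolerance = 1e-12)
    expect_true(res$ci[1] <= res$coefficient && res$coefficient <= res$ci[2])
  }
})

test_that("Pearson correlation and Fisher-z interval match the references", {
  expect_equal(pearson_with_ci(1:10, 2 * (1:10) + 1)$coefficient, 1)
  expect_equal(pearson_with_ci(c(1, 2, 3, 4), c(2, 1, 3, 4))$coefficient,
               cor(c(1, 2, 3, 4), c(2, 1, 3, 4)))
  set.seed(37)
  x <- rnorm(50); y <- x + rnorm(50)
  res <- pearson_with_ci(x, y)
  ct <- cor.test(x, y)
  expect_equal(res$coefficient, unname(ct$estimate))
  expect_equal(res$ci, as.numeric(ct$conf.int), tolerance = 1e-10)
  expect_equal(res$p_value, ct$p.value)
  # independence: coefficient near 0 at large n
  set.seed(41)
  expect_lt(abs(pearson_with_ci(rnorm(5000), rnorm(5000))$coefficient), 0.05)
})

test_that("stage dichotomization assigns the higher-stage side positive", {
  stages <- metavir_stages()
  expect_equal(dichotomize_stages(stages, "any_fibrosis"),
               c(FALSE, TRUE, TRUE, TRUE, TRUE))
  expect_equal(dichotomize_stages(stages, "significant"),
               c(FALSE, FALSE, TRUE, TRUE, TRUE))
  expect_equal(dichotomize_stages(stages, "advanced"),
               c(FALSE, FALSE, FALSE, TRUE, TRUE))
  expect_equal(dichotomize_stages(stages, "cirrhosis"),
               c(FALSE, FALSE, FALSE, FALSE, TRUE))
  expect_identical(dichotomize_stages(character(0), "cirrhosis"), logical(0))
  expect_error(dichotomize_stages(stages, "nonsense"))
  expect_error(dichotomize_stages(c("F0", "F9"), "cirrhosis"), "F9")
})

test_that("ROC handles perfect separation and tied pairs as specified", {
  perfect <- roc_analysis(c(1.2, 1.1, 0.8, 0.7),
                          c(FALSE, FALSE, TRUE, TRUE), direction = "le")
  expect_equal(perfect$auc, 1)
  expect_equal(perfect$sensitivity, 100)
  expect_equal(perfect$specificity, 100)
  expect_equal(perfect$ci, c(1, 1))
  # one tied pair: 7.5 concordant half-pairs out of 9
  tied <- roc_analysis(c(1.2, 1.0, 0.9, 1.0, 0.8, 0.7),
                       c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE),
                       direction = "le")
  expect_equal(tied$auc, 7.5 / 9)
  expect_error(roc_analysis(1:4, rep(TRUE, 4)), "non-empty")
})

test_that("empirical AUC equals the Mann-Whitney statistic on random data", {
  set.seed(43)
  for (rep in 1:25) {
    n1 <- sample(5:30, 1); n0 <- sample(5:30, 1)
    v <- c(rnorm(n0, 1), rnorm(n1, 0.4))
    if (rep %% 3 == 0) v <- round(v, 1)  # force ties
    labels <- c(rep(FALSE, n0), rep(TRUE, n1))
    res <- roc_analysis(v, labels, direction = "le")
    u <- unname(suppressWarnings(
      wilcox.test(v[!labels], v[labels])$statistic))
    expect_equal(res$auc, u / (n1 * n0), tolerance = 1e-12)
  }
})

test_that("reported cutoff attains the maximal Youden index (exhaustive scan)", {
  set.seed(47)
  for (rep in 1:20) {
    v <- round(c(rnorm(15, 1, 0.3), rnorm(20, 0.7, 0.3)), 2)
    labels <- c(rep(FALSE, 15), rep(TRUE, 20))
    res <- roc_analysis(v, labels, direction = "le")
    # scan every possible threshold, including the observed values
    thr <- sort(unique(c(v, v - 1e-6, v + 1e-6)))
    j_all <- vapply(thr, function(cc) {
      100 * mean(v[labels] <= cc) + 100 * mean(v[!labels] > cc) - 100
    }, 0)
    expect_equal(res$sensitivity + res$specificity - 100, max(j_all),
                 tolerance = 1e-9)
  }
})

test_that("auto direction orients diffusion-like markers as lower-positive", {
  set.seed(53)
  v <- c(rnorm(20, 1.2, 0.1), rnorm(20, 0.9, 0.1))
  labels <- c(rep(FALSE, 20), rep(TRUE, 20))
  res <- roc_analysis(v, labels, direction = "auto")
  expect_equal(res$direction, "le")
  expect_gte(res$auc, 0.5)
  res_ge <- roc_analysis(-v, labels, direction = "auto")
  expect_equal(res_ge$direction, "ge")
  expect_equal(res_ge$auc, res$auc)
})

test_that("DeLong interval matches the independent pROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(59)
  for (rep in 1:10) {
    v <- rnorm(60, rep(c(1, 0.7), each = 30), 0.25)
    labels <- rep(c(FALSE, TRUE), each = 30)
    res <- roc_analysis(v, labels, direction = "le")
    pr <- suppressMessages(pROC::roc(labels, v, direction = ">"))
    ci <- suppressWarnings(as.numeric(pROC::ci.auc(pr, method = "delong")))
    expect_equal(res$auc, as.numeric(pr$auc), tolerance = 1e-12)
    expect_equal(res$ci, ci[c(1, 3)], tolerance = 1e-9)
  }
})

test_that("replicate-averaged AUCs converge to the binormal-mixture closed form", {
  design <- cohort_design()
  stats <- replicate_cohort_stats(design, n_replicates = 120, seed = 71,
                                  parameters = "ADC",
                                  roc_parameters = "ADC")
  for (sp in roc_splits()) {
    emp <- stats$aucs$mean_auc[stats$aucs$split == sp]
    closed <- auc_binormal_mixture(design, "ADC", sp)
    expect_lt(abs(emp - closed), 0.015)
  }
})
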