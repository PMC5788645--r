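# weighted RSS in the log domain, used as an implementation-independent
# objective for grid oracles and local-optimality checks
weighted_rss <- function(series, log_pred) {
  sum(series$scheme$averages * (log(series$signals) - log_pred)^2)
}

dki_log_pred <- function(ln_s0, d, k, b) ln_s0 - b * d + (b * d)^2 * k / 6
sem_log_pred <- function(ln_s0, d, a, b) ln_s0 - (b * d)^a

# profile out ln S0 (weighted mean of residual offsets) and return the RSS
# minimized over S0 for fixed shape parameters
profiled_rss <- function(series, shape_pred) {
  w <- series$scheme$averages
  off <- log(series$signals) - shape_pred
  ln_s0 <- sum(w * off) / sum(w)
  sum(w * (off - ln_s0)^2)
}

test_that("two-point mono fit equals the closed form and recovers exactly", {
  s <- noiseless_series("mono", S0 = 100, ADC = 0.92e-3,
                        scheme = mono_scheme())
  fit <- fit_mono(s)
  expect_true(fit$converged)
  expect_equal(fit$params$ADC,
               log(s$signals[1] / s$signals[2]) / 800)  # closed form
  expect_equal(fit$params$ADC, 0.92e-3)
  expect_equal(fit$params$S0, 100)
  expect_equal(fit$residual_norm, 0)
})

test_that("multi-point mono fit solves the weighted log-linear normal equations", {
  scheme <- bvalue_scheme(c(0, 400, 800), c(1L, 2L, 3L))
  # noiseless: exact recovery
  s <- noiseless_series("mono", S0 = 90, ADC = 1.5e-3, scheme = scheme)
  expect_equal(fit_mono(s)$params$ADC, 1.5e-3, tolerance = 1e-12)
  # noisy: cross-check against an independent weighted LS solve
  set.seed(7)
  noisy <- dwi_series(scheme, s$signals * exp(rnorm(3, 0, 0.02)))
  fit <- fit_mono(noisy)
  X <- cbind(1, scheme$b_values)
  W <- diag(as.numeric(scheme$averages))
  beta <- solve(t(X) %*% W %*% X, t(X) %*% W %*% log(noisy$signals))
  expect_equal(fit$params$ADC, -beta[2], tolerance = 1e-10)
  expect_equal(log(fit$params$S0), beta[1], tolerance = 1e-10)
})

test_that("constant signal across b gives ADC = 0", {
  s <- dwi_series(mono_scheme(), c(80, 80))
  expect_equal(fit_mono(s)$params$ADC, 0)
})

test_that("nonlinear fits recover noiseless generating parameters to 1e-6", {
  fk <- fit_dki(noiseless_series("dki", S0 = 100, D_app = 0.99e-3,
                                 K_app = 1.07))
  expect_true(fk$converged)
  expect_lt(rel_err(fk$params$D_app, 0.99e-3), 1e-6)
  expect_lt(rel_err(fk$params$K_app, 1.07), 1e-6)

  fs <- fit_sem(noiseless_series("sem", S0 = 100, DDC = 0.68e-3,
                                 alpha = 0.64))
  expect_true(fs$converged)
  expect_lt(rel_err(fs$params$DDC, 0.68e-3), 1e-6)
  expect_lt(rel_err(fs$params$alpha, 0.64), 1e-6)
})

test_that("kurtosis-free signals reduce the DKI fit to the mono fit", {
  s <- noiseless_series("dki", S0 = 100, D_app = 1.1e-3, K_app = 0)
  fit <- fit_dki(s)
  expect_lt(fit$params$K_app, 1e-6)
  expect_equal(fit$params$D_app, fit_mono(s)$params$ADC, tolerance = 1e-6)
  s1 <- noiseless_series("sem", S0 = 100, DDC = 1.1e-3, alpha = 1)
  expect_equal(fit_sem(s1)$params$DDC, fit_mono(s1)$params$ADC,
               tolerance = 1e-6)
})

test_that("DKI fit agrees with an exhaustive profiled grid search", {
  truth <- c(d = 1.2e-3, k = 0.8)
  s <- noiseless_series("dki", S0 = 100, D_app = truth["d"],
                        K_app = truth["k"])
  b <- s$scheme$b_values
  d_grid <- seq(0.8e-3, 1.6e-3, by = 2e-6)
  k_grid <- seq(0.4, 1.2, by = 2e-3)
  rss <- outer(d_grid, k_grid, Vectorize(function(d, k) {
    profiled_rss(s, -b * d + (b * d)^2 * k / 6)
  }))
  arg <- which(rss == min(rss), arr.ind = TRUE)[1, ]
  fit <- fit_dki(s)
  expect_lt(abs(d_grid[arg[1]] - fit$params$D_app), 2e-6)
  expect_lt(abs(k_grid[arg[2]] - fit$params$K_app), 2e-3)
  expect_lte(fit$residual_norm, min(rss) + 1e-12)
})

test_that("SEM fit agrees with an exhaustive profiled grid search", {
  s <- noiseless_series("sem", S0 = 100, DDC = 1.0e-3, alpha = 0.75)
  b <- s$scheme$b_values
  d_grid <- seq(0.7e-3, 1.3e-3, by = 2e-6)
  a_grid <- seq(0.5, 1, by = 1e-3)
  rss <- outer(d_grid, a_grid, Vectorize(function(d, a) {
    profiled_rss(s, -(b * d)^a)
  }))
  arg <- which(rss == min(rss), arr.ind = TRUE)[1, ]
  fit <- fit_sem(s)
  expect_lt(abs(d_grid[arg[1]] - fit$params$DDC), 2e-6)
  expect_lt(abs(a_grid[arg[2]] - fit$params$alpha), 1e-3)
  expect_lte(fit$residual_norm, min(rss) + 1e-12)
})

test_that("fitted parameters sit at a local minimum of the weighted residual", {
  set.seed(11)
  scheme <- multib_scheme()
  for (rep in 1:5) {
    clean <- predict_sem(sem_params(100, runif(1, 0.6e-3, 1.4e-3),
                                    runif(1, 0.55, 0.9)),
                         scheme$b_values)
    s <- dwi_series(scheme, add_rician_noise(clean, 2, scheme$averages[1]))
    fit <- fit_sem(s)
    p <- fit$params
    base <- fit$residual_norm
    for (f in c(0.99, 1.01)) {
      expect_gte(weighted_rss(s, sem_log_pred(log(p$S0), p$DDC * f, p$alpha,
                                              scheme$b_values)), base - 1e-10)
      expect_gte(weighted_rss(s, sem_log_pred(log(p$S0), p$DDC,
                                              min(p$alpha * f, 1),
                                              scheme$b_values)), base - 1e-10)
    }
    fitk <- fit_dki(s)
    pk <- fitk$params
    for (f in c(0.99, 1.01)) {
      expect_gte(weighted_rss(s, dki_log_pred(log(pk$S0), pk$D_app * f,
                                              pk$K_app, scheme$b_values)),
                 fitk$residual_norm - 1e-10)
    }
  }
})

test_that("fit error decreases monotonically with Rician noise level", {
  sigmas <- c(0.05, 0.02, 0.01, 0.001)  # fractions of S0
  n_vox <- 500
  scheme <- multib_scheme()
  set.seed(101)
  truths <- data.frame(adc = runif(n_vox, 0.7e-3, 1.3e-3),
                       d = runif(n_vox, 0.8e-3, 1.6e-3),
                       k = runif(n_vox, 0.7, 1.3),
                       ddc = runif(n_vox, 0.6e-3, 1.4e-3),
                       a = runif(n_vox, 0.55, 0.9))
  mae <- matrix(NA_real_, length(sigmas), 3,
                dimnames = list(NULL, c("ADC", "D_app", "DDC")))
  for (si in seq_along(sigmas)) {
    sg <- sigmas[si] * 100
    err <- matrix(NA_real_, n_vox, 3)
    for (v in seq_len(n_vox)) {
      sm <- dwi_series(mono_scheme(), vapply(1:2, function(i) {
        add_rician_noise(predict_mono(mono_params(100, truths$adc[v]),
                                      mono_scheme()$b_values[i]),
                         sg, mono_scheme()$averages[i])
      }, 0))
      err[v, 1] <- abs(fit_mono(sm)$params$ADC - truths$adc[v])
      sk <- dwi_series(scheme, vapply(1:4, function(i) {
        # some draws put b = 2100 just past the monotone range; the
        # out-of-range warning is exercised in the forward-model tests
        add_rician_noise(suppressWarnings(
          predict_dki(dki_params(100, truths$d[v], truths$k[v]),
                      scheme$b_values[i])),
                         sg, scheme$averages[i])
      }, 0))
      err[v, 2] <- abs(fit_dki(sk)$params$D_app - truths$d[v])
      ss <- dwi_series(scheme, vapply(1:4, function(i) {
        add_rician_noise(predict_sem(sem_params(100, truths$ddc[v],
                                                truths$a[v]),
                                     scheme$b_values[i]),
                         sg, scheme$averages[i])
      }, 0))
      err[v, 3] <- abs(fit_sem(ss)$params$DDC - truths$ddc[v])
    }
    mae[si, ] <- colMeans(err)
  }
  for (j in 1:3) expect_true(all(diff(mae[, j]) < 0))
})

test_that("degenerate inputs are rejected or flagged per contract", {
  expect_error(fit_mono(dwi_series(bvalue_scheme(0), 100)), "2 distinct")
  expect_error(fit_dki(dwi_series(mono_scheme(), c(100, 50))), "3 distinct")
  expect_error(fit_sem(dwi_series(mono_scheme(), c(100, 50))), "3 distinct")
  flagged <- fit_mono(dwi_series(mono_scheme(), c(100, 0)))
  expect_false(flagged$converged)
  expect_null(flagged$params)
  expect_false(fit_sem(dwi_series(multib_scheme(), c(100, 50, 0, 10)))$converged)
})

test_that("volume fitting maps every masked pixel and isolates failures", {
  scheme <- multib_scheme()
  sig <- predict_dki(dki_params(100, 1.05e-3, 0.95), scheme$b_values)
  vol <- uniform_volume(sig, scheme, n = 8L)
  maps <- fit_volume(vol, "dki")
  expect_equal(unname(maps$D_app), matrix(1.05e-3, 8, 8), tolerance = 1e-6)
  expect_equal(unname(maps$K_app), matrix(0.95, 8, 8), tolerance = 1e-6)
  expect_equal(maps$convergence_fraction, 1)

  # one all-zero pixel is flagged; all others are unaffected
  vol$signals[3, 4, ] <- 0
  maps2 <- fit_volume(vol, "dki")
  expect_false(maps2$converged[3, 4])
  expect_true(is.na(maps2$D_app[3, 4]))
  zero_px <- 3 + (4 - 1) * 8  # linear index of pixel (3, 4)
  expect_equal(maps2$D_app[-zero_px], maps$D_app[-zero_px], tolerance = 1e-9)

  # two-pixel volume with distinct SEM truths: per-pixel recovery
  arr <- array(NA_real_, c(1, 2, 4))
  arr[1, 1, ] <- predict_sem(sem_params(100, 0.8e-3, 0.7), scheme$b_values)
  arr[1, 2, ] <- predict_sem(sem_params(100, 1.2e-3, 0.9), scheme$b_values)
  v2 <- dwi_volume(arr, scheme, matrix(TRUE, 1, 2), 1)
  m2 <- fit_volume(v2, "sem")
  expect_equal(as.numeric(m2$DDC), c(0.8e-3, 1.2e-3), tolerance = 1e-6)
  expect_equal(as.numeric(m2$alpha), c(0.7, 0.9), tolerance = 1e-6)

  expect_error(fit_volume(dwi_volume(vol$signals, scheme,
                                     matrix(FALSE, 8, 8), 1), "dki"),
               "empty")
})

test_that("repeated fits of the same volume are bit-identical", {
  set.seed(5)
  scheme <- multib_scheme()
  arr <- array(runif(4 * 4 * 4, 10, 100), c(4, 4, 4))
  arr <- aperm(apply(arr, c(1, 2), sort, decreasing = TRUE), c(2, 3, 1))
  vol <- dwi_volume(arr, scheme, matrix(TRUE, 4, 4), 1)
  m1 <- fit_volume(vol, "sem")
  m2 <- fit_volume(vol, "sem")
  expect_identical(m1$DDC, m2$DDC)
  expect_identical(m1$alpha, m2$alpha)
})
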