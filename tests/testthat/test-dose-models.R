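noise_free_net_signal <- function(seed = 42) {
  em <- generate_array_study(zero_noise_array_cfg(seed = seed))
  net_signal_array(em, attr(em, "signature_truth"))
}

test_that("noise-free data refit the generating coefficients exactly, robust and OLS alike", {
  ns <- noise_free_net_signal()
  truth <- c(k1 = 0.906, k2 = 0.274, k3 = 0.549)
  f_rob <- fit_eq1(ns)
  f_ols <- fit_eq1(ns, loss = "ols")
  expect_equal(f_rob$coefficients, truth, tolerance = 1e-8)
  expect_equal(f_ols$coefficients, truth, tolerance = 1e-8)
  expect_equal(f_rob$coefficients, f_ols$coefficients, tolerance = 1e-12)
  expect_true(f_rob$converged)
  expect_true(all(f_rob$weights == 1)) # exact fit: nothing down-weighted
})

test_that("OLS loss equals the closed-form least-squares solution", {
  withr::with_seed(17, {
    n <- rnorm(40, 2, 1)
    t <- sample(c(0.25, 1, 3), 40, replace = TRUE)
    d <- 0.9 * n + 0.27 * n^2 + 0.5 * sqrt(t) + rnorm(40, 0, 0.4)
  })
  X <- cbind(n, n^2, sqrt(t))
  beta_oracle <- solve(t(X) %*% X, t(X) %*% d)[, 1]
  f <- fit_eq1(n, t, d, loss = "ols")
  expect_equal(unname(f$coefficients), unname(beta_oracle), tolerance = 1e-10)
  # and agrees with lm on the same no-intercept design
  lm_fit <- lm(d ~ 0 + X)
  expect_equal(unname(f$coefficients), unname(coef(lm_fit)), tolerance = 1e-10)
  expect_equal(unname(f$se), unname(summary(lm_fit)$coefficients[, 2]),
    tolerance = 1e-10
  )
})

test_that("robust and OLS estimates agree on clean homoscedastic data", {
  withr::with_seed(23, {
    n <- runif(120, 0, 5)
    t <- sample(c(0.25, 1, 2), 120, replace = TRUE)
    d <- 0.906 * n + 0.274 * n^2 + 0.549 * sqrt(t) + rnorm(120, 0, 0.3)
  })
  f_rob <- fit_eq1(n, t, d)
  f_ols <- fit_eq1(n, t, d, loss = "ols")
  expect_true(all(
    abs(f_rob$coefficients - f_ols$coefficients) < f_ols$se
  ))
})

test_that("the M-estimator matches an independent bisquare implementation", {
  skip_if_not_installed("MASS")
  withr::with_seed(29, {
    n <- runif(100, 0, 5)
    t <- sample(c(0.25, 1, 2, 7), 100, replace = TRUE)
    d <- 0.906 * n + 0.274 * n^2 + 0.549 * sqrt(t) + rnorm(100, 0, 0.5)
    d[1:5] <- d[1:5] + 8 # gross outliers the bisquare should shrug off
  })
  f <- fit_eq1(n, t, d)
  X <- cbind(n, n^2, sqrt(t))
  ref <- MASS::rlm(X, d,
    psi = MASS::psi.bisquare, c = 4.685,
    scale.est = "MAD", maxit = 100
  )
  expect_equal(unname(f$coefficients), unname(coef(ref)), tolerance = 1e-3)
  # outliers visibly down-weighted relative to the bulk
  expect_lt(mean(f$weights[1:5]), mean(f$weights[-(1:5)]))
})

test_that("degenerate all-zero input yields a zero time coefficient and zero residuals", {
  f <- suppressWarnings(
    fit_eq1(rep(0, 8), rep(c(1, 4), 4), rep(0, 8), loss = "ols")
  )
  expect_equal(unname(f$coefficients[["k3"]]), 0)
  expect_equal(f$residuals, rep(0, 8))
})

test_that("dose prediction evaluates the model and floors for reporting", {
  ns <- noise_free_net_signal()
  f <- fit_eq1(ns)
  k <- c(0.906, 0.274, 0.549)
  pred <- predict_dose_eq1(f, 2, 1)
  expect_equal(pred$dose_raw, sum(k * c(2, 4, 1)), tolerance = 1e-6)
  # linear special case
  f_lin <- f
  f_lin$coefficients <- c(k1 = 1, k2 = 0, k3 = 0)
  expect_equal(predict_dose_eq1(f_lin, 2.5, 1)$dose_raw, 2.5)
  expect_equal(predict_dose_eq1(f_lin, 0, 0)$dose_raw, 0)
  expect_equal(predict_dose_eq1(f_lin, -3, 0)$dose_floored, 0)
  expect_error(predict_dose_eq1(f, 1, -1), "time")
})

test_that("the generating sqrt-time additive structure wins the variant comparison", {
  withr::with_seed(37, {
    n <- runif(120, 0.5, 5)
    t <- sample(c(0.25, 1, 3, 7), 120, replace = TRUE)
    d <- 0.906 * n + 0.274 * n^2 + 0.549 * sqrt(t) + rnorm(120, 0, 0.25)
  })
  tab <- compare_time_structures(n, t, d, n_splits = 25, base_seed = 7)
  expect_equal(nrow(tab), 12) # 6 structures x 2 losses
  best <- tab[tab$rank == 1, ]
  expect_true(all(
    best$form == "additive" & best$time_term == "sqrt"
  ))
  # single time point: every structure absorbs the time term; declared tied
  tied <- compare_time_structures(n[t == 1], rep(1, sum(t == 1)), d[t == 1],
    n_splits = 5, base_seed = 7
  )
  expect_true(all(tied$tied))
  expect_true(all(is.na(tied$rank)))
})

test_that("sex terms vanish exactly on sex-balanced mirrored data", {
  withr::with_seed(41, {
    nv <- runif(30, -5, 5)
    dose <- 2.6 - 0.8 * nv + 0.05 * nv^2 + rnorm(30, 0, 0.5)
  })
  n2 <- c(nv, nv)
  d2 <- c(dose, dose)
  sex <- rep(c("F", "M"), each = 30)
  full <- fit_quadratic_sex_model(n2, d2, sex)
  expect_equal(unname(full$coefficients[c("b_sex", "b_sexn", "b_sexn2")]),
    c(0, 0, 0),
    tolerance = 1e-10
  )
  red <- reduce_model(full)
  expect_false(red$includes_sex_terms)
  # dropping null sex terms never changes predictions
  expect_equal(
    predict_dose_quadratic(red, n2)$dose_raw,
    predict_dose_quadratic(full, n2, sex)$dose_raw,
    tolerance = 1e-8
  )
  expect_error(fit_quadratic_sex_model(nv, dose, rep("F", 30)), "one sex")
  expect_error(fit_quadratic_sex_model(nv, dose, rep("X", 30)), "sex code")
})

test_that("model reduction branches on sex-term significance", {
  # hand-built model with all sex p-values > alpha reduces; any <= alpha kept
  withr::with_seed(43, {
    nv <- runif(70, -5, 5)
    sexm <- rep(0:1, 35)
    dose <- 2.6 - 0.8 * nv + 0.05 * nv^2 + rnorm(70, 0, 0.6)
  })
  full <- fit_quadratic_sex_model(nv, dose, sexm)
  red <- reduce_model(full)
  if (all(full$p_value[c("b_sex", "b_sexn", "b_sexn2")] > 0.05)) {
    expect_false(red$includes_sex_terms)
    expect_equal(names(red$coefficients), c("b0", "b_n", "b_n2"))
  }
  strong <- dose + 2.5 * sexm # blatant sex effect
  full2 <- fit_quadratic_sex_model(nv, strong, sexm)
  red2 <- reduce_model(full2)
  expect_true(red2$includes_sex_terms)
  expect_identical(red2$flag, "sex_terms_significant")
})

test_that("the zero-noise qPCR path recovers the generating quadratic coefficients", {
  cfg <- zero_noise_qpcr_cfg()
  ct <- generate_qpcr_cohort(cfg)
  red <- qpcr_reduced_fit(ct, cfg)
  expect_equal(
    unname(red$coefficients),
    c(2.592, -0.785, 0.048),
    tolerance = 1e-7
  )
  # quadratic prediction arithmetic
  expect_equal(predict_dose_quadratic(red, 0)$dose_raw, 2.592,
    tolerance = 1e-7
  )
  expect_equal(predict_dose_quadratic(red, -2)$dose_raw,
    2.592 + 1.570 + 0.192,
    tolerance = 1e-6
  )
})

test_that("fit metrics follow their closed forms", {
  d <- c(0, 1, 2, 4, 8)
  expect_equal(fit_metrics(d, d)$rmse, 0)
  expect_equal(fit_metrics(d, d)$r2, 1)
  m <- fit_metrics(d + 1, d)
  expect_equal(m$rmse, 1)
  expect_equal(m$r2, 1 - length(d) / sum((d - mean(d))^2))
  expect_equal(fit_metrics(rep(mean(d), 5), d)$r2, 0)
  expect_warning(flat <- fit_metrics(c(1, 2), c(3, 3)), "variance")
  expect_true(is.na(flat$r2))
})
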