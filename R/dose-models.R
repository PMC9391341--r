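# Weighted least squares on an explicit design matrix, tolerating rank
# deficiency (aliased columns get NA coefficients, as lm does).
fit_wls <- function(X, y, w = NULL) {
  sw <- if (is.null(w)) rep(1, length(y)) else sqrt(w)
  fit <- stats::lm.fit(X * sw, y * sw)
  b <- fit$coefficients
  b0 <- ifelse(is.na(b), 0, b)
  fitted <- drop(X %*% b0)
  res <- y - fitted
  rank <- fit$rank
  rdf <- length(y) - rank
  se <- rep(NA_real_, ncol(X))
  names(se) <- colnames(X)
  sigma2 <- NA_real_
  if (rdf > 0) {
    p1 <- seq_len(rank)
    covu <- chol2inv(fit$qr$qr[p1, p1, drop = FALSE])
    sigma2 <- sum((res * sw)^2) / rdf
    se[fit$qr$pivot[p1]] <- sqrt(diag(covu) * sigma2)
  }
  tval <- b / se
  p <- 2 * pt(-abs(tval), df = max(rdf, 1))
  list(
    coefficients = b, se = se, p_value = p, fitted = fitted,
    residuals = res, df_residual = rdf, sigma2 = sigma2, rank = rank
  )
}

tukey_bisquare_weights <- function(u, c_tune = 4.685) {
  w <- (1 - (u / c_tune)^2)^2
  w[abs(u) > c_tune] <- 0
  w
}

# M-estimation by iteratively reweighted least squares with Tukey bisquare
# weights; scale = median(|r|)/0.6745 (MAD about zero), rescaled every
# iteration. On an exact fit (scale ~ 0) all weights are 1 and the solution
# is the OLS solution.
fit_mest <- function(X, y, c_tune = 4.685, max_iter = 50, tol = 1e-8) {
  ols <- fit_wls(X, y)
  beta <- ifelse(is.na(ols$coefficients), 0, ols$coefficients)
  n <- length(y)
  w <- rep(1, n)
  iter <- 0L
  converged <- FALSE
  fit <- ols
  scale_floor <- 1e-10 * max(1, max(abs(y)))
  repeat {
    iter <- iter + 1L
    r <- y - drop(X %*% beta)
    s <- median(abs(r)) / 0.6745
    if (s < scale_floor) {
      w <- rep(1, n)
      fit <- fit_wls(X, y, w)
      beta <- ifelse(is.na(fit$coefficients), 0, fit$coefficients)
      converged <- TRUE
      break
    }
    w <- tukey_bisquare_weights(r / s, c_tune)
    if (all(w == 0)) {
      stop("robust fit degenerate: all observations down-weighted to 0",
        call. = FALSE
      )
    }
    fit <- fit_wls(X, y, w)
    beta_new <- ifelse(is.na(fit$coefficients), 0, fit$coefficients)
    delta <- max(abs(beta_new - beta))
    beta <- beta_new
    if (delta < tol) {
      converged <- TRUE
      break
    }
    if (iter >= max_iter) break
  }
  if (!converged) {
    stop(
      "robust fit did not converge in ", max_iter,
      " iterations (last coefficient change ",
      signif(delta, 3), ", scale ", signif(s, 3), ")",
      call. = FALSE
    )
  }
  c(fit, list(weights = w, n_iterations = iter, converged = TRUE))
}

fit_design <- function(X, y, loss = c("robust", "ols"), ...) {
  loss <- match.arg(loss)
  if (loss == "robust") {
    fit_mest(X, y, ...)
  } else {
    c(fit_wls(X, y), list(
      weights = rep(1, length(y)),
      n_iterations = 0L, converged = TRUE
    ))
  }
}

resolve_nv <- function(n) {
  if (inherits(n, "net_signal")) n$n_value else as.numeric(n)
}

#' Fit the microarray dose-reconstruction model
#'
#' Fits `D = k1*N + k2*N^2 + k3*sqrt(T)` (no intercept; D dose in Gy, N net
#' signal, T days after exposure). The model is linear in k1..k3 given the
#' regressors (N, N^2, sqrt(T)), so the OLS loss is solved in closed form;
#' the default robust loss is Tukey bisquare M-estimation (tuning constant
#' 4.685, MAD scale rescaled each iteration) solved by iteratively
#' reweighted least squares starting from OLS. Standard errors and two-sided
#' t-based p-values come from the final (weighted) linear system.
#'
#' @param n Net signal per sample: a `net_signal` object (dose/time taken
#'   from its metadata if present) or numeric vector.
#' @param time_days,dose_gy Per-sample time (days, > 0) and dose (Gy).
#' @param loss "robust" (default) or "ols".
#' @param c_tune Bisquare tuning constant (default 4.685, 95\% Gaussian
#'   efficiency).
#' @param max_iter,tol IRLS iteration cap (default 50) and convergence
#'   tolerance on the max coefficient change (default 1e-8). Non-convergence
#'   is an error.
#' @return Object of class `eq1_fit`: coefficients `k1`, `k2`, `k3` with
#'   `se` and `p_value`, plus `loss`, `converged`, `n_iterations`,
#'   `weights`, `residuals`, `fitted`, `df_residual`, `kappa` (design
#'   condition number), `n_samples`.
#' @export
fit_eq1 <- function(n, time_days = NULL, dose_gy = NULL,
                    loss = c("robust", "ols"),
                    c_tune = 4.685, max_iter = 50, tol = 1e-8) {
  loss <- match.arg(loss)
  nv <- resolve_nv(n)
  if (inherits(n, "net_signal")) {
    if (is.null(time_days) && "time_days" %in% names(n)) time_days <- n$time_days
    if (is.null(dose_gy) && "dose_gy" %in% names(n)) dose_gy <- n$dose_gy
  }
  stopifnot(
    length(nv) == length(time_days), length(nv) == length(dose_gy),
    length(nv) >= 4, all(time_days > 0)
  )
  if (length(unique(dose_gy)) < 2) {
    warning("fewer than 2 distinct dose levels: model poorly identified",
      call. = FALSE
    )
  }
  X <- cbind(k1 = nv, k2 = nv^2, k3 = sqrt(time_days))
  kap <- kappa(X)
  if (is.finite(kap) && kap > 1e8) {
    warning("ill-conditioned design (condition number ", signif(kap, 3), ")",
      call. = FALSE
    )
  }
  fit <- if (loss == "robust") {
    fit_mest(X, dose_gy, c_tune = c_tune, max_iter = max_iter, tol = tol)
  } else {
    fit_design(X, dose_gy, "ols")
  }
  structure(
    list(
      coefficients = fit$coefficients, se = fit$se, p_value = fit$p_value,
      loss = loss, converged = fit$converged,
      n_iterations = fit$n_iterations, weights = fit$weights,
      residuals = fit$residuals, fitted = fit$fitted,
      df_residual = fit$df_residual, kappa = kap, n_samples = length(nv)
    ),
    class = "eq1_fit"
  )
}

#' @export
print.eq1_fit <- function(x, ...) {
  cat("<eq1_fit> D = k1*N + k2*N^2 + k3*sqrt(T)   [", x$loss, " loss]\n",
    sep = ""
  )
  tab <- data.frame(
    estimate = x$coefficients, se = x$se, p_value = x$p_value
  )
  print(signif(tab, 4))
  cat(
    "n =", x$n_samples, "; converged in", x$n_iterations, "iteration(s)\n"
  )
  invisible(x)
}

#' Reconstruct dose from a fitted microarray model
#'
#' @param fit A converged [fit_eq1()] object.
#' @param n Net signal values (numeric or `net_signal`).
#' @param time_days Days after exposure (>= 0).
#' @return Tibble with `dose_raw` (Gy, used for fit metrics) and
#'   `dose_floored` (negative reconstructions clipped to 0, for reporting).
#' @export
predict_dose_eq1 <- function(fit, n, time_days) {
  stopifnot(inherits(fit, "eq1_fit"))
  if (!isTRUE(fit$converged)) stop("fit did not converge", call. = FALSE)
  if (any(time_days < 0)) stop("time must be >= 0 days", call. = FALSE)
  nv <- resolve_nv(n)
  k <- ifelse(is.na(fit$coefficients), 0, fit$coefficients)
  raw <- k[["k1"]] * nv + k[["k2"]] * nv^2 + k[["k3"]] * sqrt(time_days)
  tibble::tibble(dose_raw = raw, dose_floored = pmax(raw, 0))
}

time_structures <- function() {
  tidyr::crossing(
    form = c("additive", "multiplicative"),
    time_term = c("sqrt", "linear", "quadratic")
  )
}

time_structure_design <- function(nv, time_days, form, time_term) {
  g <- switch(time_term,
    sqrt = sqrt(time_days),
    linear = time_days,
    quadratic = time_days^2
  )
  if (form == "additive") {
    cbind(k1 = nv, k2 = nv^2, k3 = g)
  } else {
    cbind(k1 = nv * g, k2 = nv^2 * g)
  }
}

#' Compare alternative time-term structures of the dose model
#'
#' Fits every combination of time term (`sqrt(T)`, `T`, `T^2`), form
#' (additive `k1*N + k2*N^2 + k3*g(T)` vs multiplicative
#' `(k1*N + k2*N^2)*g(T)`) and loss (robust, OLS) — 12 variants — and ranks
#' them by mean test RMSE over repeated random half splits. With a single
#' time point all structures are reparameterizations of each other and the
#' ranking is declared tied.
#'
#' @inheritParams fit_eq1
#' @param n_splits Half splits per variant (default 50).
#' @param base_seed Seed from which the per-split seeds are derived.
#' @return Tibble with one row per variant: `form`, `time_term`, `loss`,
#'   `rmse_train_mean`, `rmse_test_mean`, `rank` (NA when `tied`), `tied`,
#'   `n_failed` (split fits that errored).
#' @export
compare_time_structures <- function(n, time_days = NULL, dose_gy = NULL,
                                    n_splits = 50, base_seed = 1L) {
  nv <- resolve_nv(n)
  if (inherits(n, "net_signal")) {
    if (is.null(time_days) && "time_days" %in% names(n)) time_days <- n$time_days
    if (is.null(dose_gy) && "dose_gy" %in% names(n)) dose_gy <- n$dose_gy
  }
  stopifnot(length(nv) == length(time_days), length(nv) == length(dose_gy))
  tied <- length(unique(time_days)) == 1
  grid <- tidyr::crossing(time_structures(), loss = c("robust", "ols"))
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    X <- time_structure_design(
      nv, time_days, grid$form[i], grid$time_term[i]
    )
    ev <- split_eval_core(X, dose_gy,
      loss = grid$loss[i],
      n_splits = n_splits, base_seed = base_seed
    )
    tibble::tibble(
      form = grid$form[i], time_term = grid$time_term[i],
      loss = grid$loss[i],
      rmse_train_mean = ev$summary$mean[ev$summary$metric == "rmse_train"],
      rmse_test_mean = ev$summary$mean[ev$summary$metric == "rmse_test"],
      n_failed = ev$n_failed
    )
  })
  out <- dplyr::bind_rows(rows)
  out$tied <- tied
  out$rank <- if (tied) {
    NA_integer_
  } else {
    rank(out$rmse_test_mean, ties.method = "min")
  }
  dplyr::arrange(out, .data$rank)
}

sex_to_binary <- function(sex) {
  if (is.numeric(sex)) {
    if (!all(sex %in% c(0, 1))) stop("numeric sex must be 0/1", call. = FALSE)
    return(as.numeric(sex))
  }
  s <- toupper(substr(as.character(sex), 1, 1))
  if (!all(s %in% c("M", "F"))) {
    stop("unknown sex code(s): ", paste(unique(sex[!s %in% c("M", "F")]),
      collapse = ", "
    ), call. = FALSE)
  }
  as.numeric(s == "M") # male = 1, female = 0
}

new_quad_model <- function(fit, terms, includes_sex, data, flag = NULL) {
  structure(
    list(
      coefficients = setNames(fit$coefficients, terms),
      se = setNames(fit$se, terms),
      p_value = setNames(fit$p_value, terms),
      includes_sex_terms = includes_sex,
      df_residual = fit$df_residual,
      fitted = fit$fitted, residuals = fit$residuals,
      data = data, flag = flag
    ),
    class = "quad_dose_model"
  )
}

#' Fit the quadratic qPCR dose model with sex-interaction screening
#'
#' Ordinary least squares of dose on `{1, N, N^2, Sex, Sex*N, Sex*N^2}` with
#' sex coded male = 1, female = 0. Used to test whether dose reconstruction
#' from the delta-Ct net signal differs between sexes before settling on the
#' reduced calibration (see [reduce_model()]).
#'
#' @param n Net signal per animal (`net_signal` or numeric).
#' @param dose_gy Delivered dose (Gy).
#' @param sex Per-animal sex: "M"/"F" (or 0/1, male = 1). Both sexes must be
#'   present; single-sex data should use the reduced model directly.
#' @return Object of class `quad_dose_model` with coefficient terms `b0`,
#'   `b_n`, `b_n2`, `b_sex`, `b_sexn`, `b_sexn2` (estimates, SEs, two-sided
#'   t p-values) and `includes_sex_terms = TRUE`.
#' @export
fit_quadratic_sex_model <- function(n, dose_gy = NULL, sex = NULL) {
  nv <- resolve_nv(n)
  if (inherits(n, "net_signal")) {
    if (is.null(dose_gy) && "dose_gy" %in% names(n)) dose_gy <- n$dose_gy
    if (is.null(sex) && "sex" %in% names(n)) sex <- n$sex
  }
  stopifnot(length(nv) == length(dose_gy), length(nv) >= 7)
  sexm <- sex_to_binary(sex)
  stopifnot(length(sexm) == length(nv))
  if (length(unique(sexm)) < 2) {
    stop("only one sex present; fit the reduced N + N^2 model instead",
      call. = FALSE
    )
  }
  X <- cbind(
    b0 = 1, b_n = nv, b_n2 = nv^2,
    b_sex = sexm, b_sexn = sexm * nv, b_sexn2 = sexm * nv^2
  )
  fit <- fit_wls(X, dose_gy)
  new_quad_model(fit, colnames(X),
    includes_sex = TRUE,
    data = list(n = nv, dose_gy = dose_gy, sexm = sexm)
  )
}

#' Drop non-significant sex terms from the quadratic dose model
#'
#' If every sex-containing coefficient of the full model has p > `alpha`,
#' refits the reduced calibration `D = b0 + b_n*N + b_n2*N^2` on the stored
#' data; otherwise the full model is returned unchanged with a flag.
#'
#' @param full A [fit_quadratic_sex_model()] result.
#' @param alpha Significance level for the sex terms (default 0.05).
#' @return A `quad_dose_model`: reduced (terms `b0`, `b_n`, `b_n2`) or the
#'   flagged full model (`flag = "sex_terms_significant"`).
#' @export
reduce_model <- function(full, alpha = 0.05) {
  stopifnot(inherits(full, "quad_dose_model"))
  if (!full$includes_sex_terms) {
    return(full)
  }
  sex_p <- full$p_value[c("b_sex", "b_sexn", "b_sexn2")]
  if (any(sex_p <= alpha, na.rm = TRUE)) {
    full$flag <- "sex_terms_significant"
    return(full)
  }
  fit_quadratic_model(full$data$n, full$data$dose_gy)
}

#' Fit the reduced quadratic qPCR dose model
#'
#' `D = b0 + b_n*N + b_n2*N^2` by ordinary least squares.
#'
#' @inheritParams fit_quadratic_sex_model
#' @return A `quad_dose_model` with `includes_sex_terms = FALSE`.
#' @export
fit_quadratic_model <- function(n, dose_gy = NULL) {
  nv <- resolve_nv(n)
  if (inherits(n, "net_signal") && is.null(dose_gy) &&
    "dose_gy" %in% names(n)) {
    dose_gy <- n$dose_gy
  }
  stopifnot(length(nv) == length(dose_gy), length(nv) >= 4)
  X <- cbind(b0 = 1, b_n = nv, b_n2 = nv^2)
  fit <- fit_wls(X, dose_gy)
  new_quad_model(fit, colnames(X),
    includes_sex = FALSE,
    data = list(n = nv, dose_gy = dose_gy)
  )
}

#' @export
print.quad_dose_model <- function(x, ...) {
  cat("<quad_dose_model> D = b0 + b_n*N + b_n2*N^2",
    if (x$includes_sex_terms) " + sex terms", "\n",
    sep = ""
  )
  tab <- data.frame(estimate = x$coefficients, se = x$se, p_value = x$p_value)
  print(signif(tab, 4))
  if (!is.null(x$flag)) cat("flag:", x$flag, "\n")
  invisible(x)
}

#' Reconstruct dose from a quadratic qPCR model
#'
#' @param model A `quad_dose_model`.
#' @param n Net signal values.
#' @param sex Required iff the model includes sex terms.
#' @return Tibble with `dose_raw` and `dose_floored` (Gy).
#' @export
predict_dose_quadratic <- function(model, n, sex = NULL) {
  stopifnot(inherits(model, "quad_dose_model"))
  nv <- resolve_nv(n)
  b <- model$coefficients
  raw <- b[["b0"]] + b[["b_n"]] * nv + b[["b_n2"]] * nv^2
  if (model$includes_sex_terms) {
    if (is.null(sex)) {
      stop("model includes sex terms: supply `sex`", call. = FALSE)
    }
    sexm <- sex_to_binary(sex)
    raw <- raw + b[["b_sex"]] * sexm + b[["b_sexn"]] * sexm * nv +
      b[["b_sexn2"]] * sexm * nv^2
  }
  tibble::tibble(dose_raw = unname(raw), dose_floored = pmax(raw, 0))
}

#' Goodness of dose reconstruction
#'
#' RMSE and coefficient of determination of reconstructed versus actual
#' dose, computed on raw (unfloored) predictions:
#' `rmse = sqrt(mean((d_hat - d_true)^2))`,
#' `r2 = 1 - SS_res / SS_tot` about the mean of `d_true`.
#'
#' @param d_hat Reconstructed doses (Gy).
#' @param d_true Delivered doses (Gy).
#' @return One-row tibble `r2`, `rmse`, `n_samples`. `r2` is `NA` (with a
#'   warning) when `d_true` has zero variance.
#' @export
fit_metrics <- function(d_hat, d_true) {
  stopifnot(length(d_hat) == length(d_true), length(d_true) >= 2)
  rmse <- sqrt(mean((d_hat - d_true)^2))
  ss_tot <- sum((d_true - mean(d_true))^2)
  if (ss_tot == 0) {
    warning("zero variance in true dose: R^2 undefined", call. = FALSE)
    r2 <- NA_real_
  } else {
    r2 <- 1 - sum((d_hat - d_true)^2) / ss_tot
  }
  tibble::tibble(r2 = r2, rmse = rmse, n_samples = length(d_true))
}
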