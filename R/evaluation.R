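#' Random half split of sample IDs
#'
#' Partitions samples into disjoint, exhaustive training and testing halves
#' (sizes differ by at most 1), deterministically for a given seed. An
#' optional stratification vector splits within strata, so small dose groups
#' appear in both halves.
#'
#' @param sample_ids Vector of >= 4 unique sample identifiers.
#' @param seed Integer seed.
#' @param stratify Optional per-sample grouping (e.g. dose); split is
#'   performed within each stratum.
#' @return List with elements `train` and `test`.
#' @export
random_half_split <- function(sample_ids, seed, stratify = NULL) {
  n <- length(sample_ids)
  stopifnot(n >= 4, !anyDuplicated(sample_ids))
  withr::with_seed(as.integer(seed), {
    if (is.null(stratify)) {
      perm <- sample(sample_ids)
      train <- perm[seq_len(n %/% 2)]
    } else {
      stopifnot(length(stratify) == n)
      perm <- sample.int(n)
      strata <- split(sample_ids[perm], stratify[perm])
      train <- sample_ids[0]
      extra <- 0L # odd-stratum leftovers alternate halves to keep sizes even
      for (ids in strata) {
        k <- length(ids) %/% 2L
        if (length(ids) %% 2L == 1L) {
          k <- k + extra
          extra <- 1L - extra
        }
        train <- c(train, ids[seq_len(k)])
      }
    }
  })
  list(train = train, test = setdiff(sample_ids, train))
}

# Shared engine: repeated half-split refits of a linear design (rows of X
# are samples). Used by repeated_split_evaluation and
# compare_time_structures.
split_eval_core <- function(X, dose_gy, loss = "robust",
                            n_splits = 1000, base_seed = 1L,
                            stratify = NULL) {
  idx <- seq_len(nrow(X))
  recs <- vector("list", n_splits)
  n_failed <- 0L
  for (i in seq_len(n_splits)) {
    seed_i <- as.integer(base_seed) + i
    sp <- random_half_split(idx, seed_i, stratify = stratify)
    rec <- tryCatch(
      {
        fit <- fit_design(X[sp$train, , drop = FALSE], dose_gy[sp$train],
          loss = loss
        )
        b <- ifelse(is.na(fit$coefficients), 0, fit$coefficients)
        pred_tr <- drop(X[sp$train, , drop = FALSE] %*% b)
        pred_te <- drop(X[sp$test, , drop = FALSE] %*% b)
        mtr <- fit_metrics(pred_tr, dose_gy[sp$train])
        tibble::tibble(
          split = i, seed = seed_i,
          r2_train = mtr$r2, rmse_train = mtr$rmse,
          rmse_test = sqrt(mean((pred_te - dose_gy[sp$test])^2))
        )
      },
      error = function(e) NULL
    )
    if (is.null(rec)) n_failed <- n_failed + 1L else recs[[i]] <- rec
  }
  per_split <- dplyr::bind_rows(recs)
  summ <- tidyr::pivot_longer(
    per_split[, c("r2_train", "rmse_train", "rmse_test")],
    dplyr::everything(),
    names_to = "metric", values_to = "value"
  )
  summ <- dplyr::summarise(
    dplyr::group_by(summ, .data$metric),
    mean = mean(.data$value), sd = sd(.data$value), .groups = "drop"
  )
  list(
    per_split = per_split, summary = summ,
    n_splits = n_splits, n_failed = n_failed
  )
}

#' Repeated random half-split validation of a dose model
#'
#' Repeats: split the samples randomly into halves, fit the model on the
#' training half, record training R^2 and RMSE and testing RMSE (raw
#' predictions). Per-split seeds are `base_seed + split index`, so the full
#' run is reproducible from one integer. Split fits that fail are recorded
#' and excluded.
#'
#' @inheritParams fit_eq1
#' @param model_spec One of `"eq1_robust"` (default), `"eq1_ols"`,
#'   `"quadratic"` (the reduced `b0 + b_n*N + b_n2*N^2` calibration).
#' @param n_splits Number of half splits (default 1000).
#' @param base_seed Integer from which per-split seeds are derived.
#' @param stratify_by_dose Split within dose groups instead of uniformly
#'   (default FALSE, a plain random halving).
#' @return Object of class `split_evaluation`: `per_split` tibble
#'   (`split`, `seed`, `r2_train`, `rmse_train`, `rmse_test`), `summary`
#'   tibble (mean and SD per metric), `n_splits`, `n_failed`.
#' @export
repeated_split_evaluation <- function(n, time_days = NULL, dose_gy = NULL,
                                      model_spec = c(
                                        "eq1_robust", "eq1_ols", "quadratic"
                                      ),
                                      n_splits = 1000, base_seed = 1L,
                                      stratify_by_dose = FALSE) {
  model_spec <- match.arg(model_spec)
  nv <- resolve_nv(n)
  if (inherits(n, "net_signal")) {
    if (is.null(time_days) && "time_days" %in% names(n)) time_days <- n$time_days
    if (is.null(dose_gy) && "dose_gy" %in% names(n)) dose_gy <- n$dose_gy
  }
  stopifnot(length(nv) == length(dose_gy), length(nv) >= 4)
  X <- switch(model_spec,
    eq1_robust = ,
    eq1_ols = {
      stopifnot(length(time_days) == length(nv))
      cbind(k1 = nv, k2 = nv^2, k3 = sqrt(time_days))
    },
    quadratic = cbind(b0 = 1, b_n = nv, b_n2 = nv^2)
  )
  loss <- if (model_spec == "eq1_robust") "robust" else "ols"
  out <- split_eval_core(X, dose_gy,
    loss = loss, n_splits = n_splits,
    base_seed = base_seed,
    stratify = if (stratify_by_dose) dose_gy
  )
  out$model_spec <- model_spec
  class(out) <- "split_evaluation"
  out
}

#' @export
print.split_evaluation <- function(x, ...) {
  cat("<split_evaluation> ", x$model_spec, ", ", x$n_splits,
    " random half splits (", x$n_failed, " failed)\n",
    sep = ""
  )
  print(as.data.frame(x$summary))
  invisible(x)
}

#' Sensitivity of the net signal to signature group sizes
#'
#' Rebuilds the signature at several (n_up, n_down) size pairs, recomputes
#' the net signal and its Spearman correlation with dose. Size pairs
#' exceeding the available ranked genes yield a flagged row rather than an
#' error.
#'
#' @param expr An [expression_matrix()].
#' @param correlations Ranked (and typically Bonferroni-filtered)
#'   correlation table.
#' @param size_pairs List of `c(n_up, n_down)` pairs (default
#'   `(10,10), (20,10), (30,30)`).
#' @return Tibble with one row per pair: `n_up`, `n_down`, `rho`
#'   (Spearman correlation of N with dose), `flagged`.
#' @export
group_size_sensitivity <- function(expr, correlations,
                                   size_pairs = list(
                                     c(10, 10), c(20, 10), c(30, 30)
                                   )) {
  rows <- lapply(size_pairs, function(pair) {
    res <- tryCatch(
      {
        sig <- select_signature(correlations,
          n_up = pair[1], n_down = pair[2]
        )
        ns <- net_signal_array(expr, sig)
        cors <- correlate_net_signal_with_dose(ns)
        tibble::tibble(
          n_up = pair[1], n_down = pair[2],
          rho = cors$estimate[cors$method == "spearman"], flagged = FALSE
        )
      },
      error = function(e) {
        tibble::tibble(
          n_up = pair[1], n_down = pair[2],
          rho = NA_real_, flagged = TRUE
        )
      }
    )
    res
  })
  dplyr::bind_rows(rows)
}
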