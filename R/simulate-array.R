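#' Ground-truth net signal implied by the microarray dose model
#'
#' Inverts `D = k1*N + k2*N^2 + k3*sqrt(T)` for N at given dose and time.
#' Where the time term alone already accounts for the dose
#' (`D < k3*sqrt(T)`), the net signal is floored at 0: dose 0 defines the
#' baseline and N cannot go negative in the generative model.
#'
#' @param dose_gy Dose(s) in Gy, >= 0.
#' @param time_days Time(s) after exposure in days, > 0.
#' @param k1,k2,k3 Model coefficients; `k2` must be > 0 for invertibility.
#' @return Numeric vector of net-signal values (log2-signal units).
#' @export
net_signal_truth <- function(dose_gy, time_days, k1, k2, k3) {
  if (k2 <= 0) stop("k2 must be > 0 for an invertible dose model", call. = FALSE)
  len <- max(length(dose_gy), length(time_days))
  dose_gy <- rep_len(dose_gy, len)
  time_days <- rep_len(time_days, len)
  z <- dose_gy - k3 * sqrt(time_days)
  out <- numeric(len)
  active <- z > 0
  disc <- k1^2 + 4 * k2 * z[active]
  if (any(disc < 0)) {
    stop("dose model not invertible at some condition (negative discriminant)",
      call. = FALSE
    )
  }
  out[active] <- (-k1 + sqrt(disc)) / (2 * k2)
  out
}

#' Configuration for the synthetic multi-study microarray generator
#'
#' Defines the study conditions emulated by [generate_array_study()]: a merge
#' of several normalized microarray studies of irradiated mouse blood, with
#' doses 0--10 Gy and sampling 0.25--7 days after exposure. Up-regulated
#' signature genes gain, and down-regulated genes lose, half the ground-truth
#' net signal each (weight 1 by default, so the difference of group medians
#' reproduces the generative net signal); background genes carry no dose term.
#'
#' @param n_up_genes,n_down_genes,n_background_genes Gene counts (>= 1).
#' @param doses Dose levels in Gy (>= 0).
#' @param times Sampling times in days (> 0).
#' @param samples_per_condition Replicates per dose x time x study cell.
#' @param k1,k2,k3 Generating coefficients of `D = k1*N + k2*N^2 + k3*sqrt(T)`
#'   (defaults: the fitted microarray values 0.906 Gy^-1, 0.274 Gy^-2,
#'   0.549 days^-1/2).
#' @param gene_effect_weights Positive per-gene loadings for the signature
#'   genes (length `n_up_genes + n_down_genes`, or scalar, recycled).
#' @param baseline_mean,baseline_sd Per-gene baseline log2 signal: drawn once
#'   per study from `N(baseline_mean, baseline_sd)`.
#' @param noise_sd Per-observation Gaussian noise, log2-signal units.
#' @param study_effects Named numeric vector of additive per-study offsets
#'   (log2 units); samples are assigned to studies cyclically.
#' @param seed Integer seed; the generator is deterministic given the config.
#' @return A validated list of class `array_sim_config`.
#' @export
array_sim_config <- function(n_up_genes = 20,
                             n_down_genes = 10,
                             n_background_genes = 470,
                             doses = c(0, 1, 2, 4, 6, 8, 10),
                             times = c(0.25, 1, 2, 3, 7),
                             samples_per_condition = 3,
                             k1 = 0.906, k2 = 0.274, k3 = 0.549,
                             gene_effect_weights = 1,
                             baseline_mean = 8, baseline_sd = 1.5,
                             noise_sd = 0.5,
                             study_effects = c(
                               GS1 = 0, GS2 = 0.3, GS3 = -0.2, GS4 = 0.5
                             ),
                             seed = 1L) {
  cfg <- list(
    n_up_genes = as.integer(n_up_genes),
    n_down_genes = as.integer(n_down_genes),
    n_background_genes = as.integer(n_background_genes),
    doses = as.numeric(doses), times = as.numeric(times),
    samples_per_condition = as.integer(samples_per_condition),
    k1 = k1, k2 = k2, k3 = k3,
    gene_effect_weights = as.numeric(gene_effect_weights),
    baseline_mean = baseline_mean, baseline_sd = baseline_sd,
    noise_sd = noise_sd, study_effects = study_effects,
    seed = as.integer(seed)
  )
  n_sig <- cfg$n_up_genes + cfg$n_down_genes
  if (length(cfg$gene_effect_weights) == 1) {
    cfg$gene_effect_weights <- rep(cfg$gene_effect_weights, n_sig)
  }
  stopifnot(
    cfg$n_up_genes >= 1, cfg$n_down_genes >= 1, cfg$n_background_genes >= 0,
    cfg$samples_per_condition >= 1,
    all(cfg$doses >= 0), all(cfg$times > 0),
    cfg$k2 > 0,
    length(cfg$gene_effect_weights) == n_sig,
    all(cfg$gene_effect_weights > 0),
    cfg$baseline_sd >= 0, cfg$noise_sd >= 0
  )
  if (is.null(names(cfg$study_effects))) {
    names(cfg$study_effects) <- paste0("GS", seq_along(cfg$study_effects))
  }
  # defensive: on the unfloored region (D > k3*sqrt(T)) the discriminant of
  # the inverse model must be non-negative; guaranteed for k2 > 0
  grid <- expand.grid(dose = cfg$doses, time = cfg$times)
  z <- grid$dose - cfg$k3 * sqrt(grid$time)
  if (any(z > 0 & cfg$k1^2 + 4 * cfg$k2 * z < 0)) {
    stop("config not invertible: negative discriminant at a dosed condition",
      call. = FALSE
    )
  }
  structure(cfg, class = "array_sim_config")
}

#' Simulate a merged multi-study microarray experiment
#'
#' Generates a genes x samples matrix of normalized log2 signals with known
#' ground-truth structure. For a sample at dose D and time T the generative
#' net signal is `N* = net_signal_truth(D, T, k1, k2, k3)`; each up-regulated
#' gene g reads `baseline_g + w_g * N*/2 + study offset + noise`, each
#' down-regulated gene `baseline_g - w_g * N*/2 + ...`, and background genes
#' have no dose term. Deterministic given the config (including its seed).
#'
#' @param config An [array_sim_config()].
#' @return An [expression_matrix()] whose `samples` tibble additionally
#'   carries the generative net signal in column `n_true`. Signature gene IDs
#'   are `UP01..`/`DN01..`; background genes `BG0001..`.
#' @examples
#' em <- generate_array_study(array_sim_config(
#'   n_background_genes = 5,
#'   samples_per_condition = 1, seed = 7
#' ))
#' em
#' @export
generate_array_study <- function(config) {
  stopifnot(inherits(config, "array_sim_config"))
  cfg <- config
  grid <- expand.grid(
    rep = seq_len(cfg$samples_per_condition),
    dose_gy = cfg$doses, time_days = cfg$times,
    KEEP.OUT.ATTRS = FALSE
  )
  n_samp <- nrow(grid)
  studies <- names(cfg$study_effects)
  grid$study <- studies[(seq_len(n_samp) - 1L) %% length(studies) + 1L]
  grid$sample_id <- sprintf("S%04d", seq_len(n_samp))
  grid$n_true <- net_signal_truth(
    grid$dose_gy, grid$time_days,
    cfg$k1, cfg$k2, cfg$k3
  )

  up_ids <- sprintf("UP%02d", seq_len(cfg$n_up_genes))
  dn_ids <- sprintf("DN%02d", seq_len(cfg$n_down_genes))
  bg_ids <- if (cfg$n_background_genes > 0) {
    sprintf("BG%04d", seq_len(cfg$n_background_genes))
  } else {
    character()
  }
  gene_ids <- c(up_ids, dn_ids, bg_ids)
  n_genes <- length(gene_ids)
  dir <- c(
    rep(1, cfg$n_up_genes), rep(-1, cfg$n_down_genes),
    rep(0, cfg$n_background_genes)
  )
  w <- c(cfg$gene_effect_weights, rep(0, cfg$n_background_genes))

  withr::with_seed(cfg$seed, {
    baseline <- rnorm(n_genes, cfg$baseline_mean, cfg$baseline_sd)
    noise <- matrix(rnorm(n_genes * n_samp, 0, cfg$noise_sd), n_genes, n_samp)
  })
  dose_term <- outer(dir * w / 2, grid$n_true)
  study_term <- matrix(cfg$study_effects[grid$study],
    n_genes, n_samp,
    byrow = TRUE
  )
  signal <- baseline + dose_term + study_term + noise
  dimnames(signal) <- list(gene_ids, grid$sample_id)

  meta <- tibble::tibble(
    sample_id = grid$sample_id, dose_gy = grid$dose_gy,
    time_days = grid$time_days, study = grid$study, n_true = grid$n_true
  )
  out <- expression_matrix(signal, meta)
  attr(out, "signature_truth") <- gene_signature(up_ids, dn_ids)
  out
}
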