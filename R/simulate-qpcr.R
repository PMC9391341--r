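#' Ground-truth net signal implied by the quadratic qPCR dose model
#'
#' Inverts `D = b0 + b1*N + b2*N^2` for N at given dose, on the branch where
#' N decreases with dose (the sign convention of delta-Ct net signals: up
#' genes' dCt falls and down genes' dCt rises with dose, so their difference
#' falls).
#'
#' @param dose_gy Dose(s) in Gy.
#' @param b0,b1,b2 Model coefficients (Gy, Gy per dCt unit, Gy per dCt
#'   unit^2).
#' @return Numeric vector of net-signal values (dCt units).
#' @export
qpcr_net_signal_truth <- function(dose_gy, b0, b1, b2) {
  if (b2 == 0) {
    if (b1 == 0) stop("b1 and b2 cannot both be 0", call. = FALSE)
    return((dose_gy - b0) / b1)
  }
  disc <- b1^2 - 4 * b2 * (b0 - dose_gy)
  if (any(disc < 0)) {
    stop("quadratic dose model has complex roots at some configured dose",
      call. = FALSE
    )
  }
  # the minus root always has dD/dN = -sqrt(disc) < 0: the decreasing branch
  (-b1 - sqrt(disc)) / (2 * b2)
}

#' Configuration for the synthetic qRT-PCR cohort generator
#'
#' Emulates an independently irradiated validation cohort: equal numbers of
#' male and female adult mice at each dose, blood sampled 24 h after
#' exposure, a 7-gene signature (3 up-, 4 down-regulated) plus two reference
#' genes, assays run in duplicate wells. The generative inverse is the
#' quadratic calibration `D = b0 + b1*N + b2*N^2` on the delta-Ct net signal.
#'
#' @param up_genes,down_genes Signature gene names. Defaults: up =
#'   Phlda3, Rhoc, Lrg1; down = Cd19, Cxcr5, Ly6D, Ccr7.
#' @param reference_genes Housekeeping genes (default Actb, Gapdh).
#' @param doses Dose levels in Gy (default 0--8 Gy, seven levels).
#' @param mice_per_sex_per_dose Animals per sex per dose (default 5).
#' @param b0,b1,b2 Generating coefficients of the inverse quadratic model
#'   (defaults: the fitted qPCR calibration 2.592, -0.785, 0.048).
#' @param per_gene_offsets Named numeric vector of per-gene baseline dCt
#'   values. The up- and down-group means must be equal so that the group
#'   mean difference of dCt reproduces the generative net signal exactly.
#' @param well_replicates Wells per (sample, gene) (default 2).
#' @param ct_noise_sd Gaussian noise per well, Ct units (default 0.2, a
#'   typical TaqMan duplicate spread).
#' @param sex_effect Additive shift of the male net signal, dCt units
#'   (default 0: no sex difference, as observed).
#' @param sample_shift_sd SD of a per-mouse loading offset added to every Ct
#'   of that sample (default 0.3); cancelled by reference-gene normalization.
#' @param ref_ct Named baseline Ct of the reference genes.
#' @param seed Integer seed.
#' @return A validated list of class `qpcr_sim_config`.
#' @export
qpcr_sim_config <- function(up_genes = c("Phlda3", "Rhoc", "Lrg1"),
                            down_genes = c("Cd19", "Cxcr5", "Ly6D", "Ccr7"),
                            reference_genes = c("Actb", "Gapdh"),
                            doses = c(0, 1, 2, 3, 4, 6, 8),
                            mice_per_sex_per_dose = 5,
                            b0 = 2.592, b1 = -0.785, b2 = 0.048,
                            per_gene_offsets = c(
                              Phlda3 = 5.5, Rhoc = 4, Lrg1 = 6.5,
                              Cd19 = 4, Cxcr5 = 6, Ly6D = 5, Ccr7 = 19 / 3
                            ),
                            well_replicates = 2,
                            ct_noise_sd = 0.2,
                            sex_effect = 0,
                            sample_shift_sd = 0.3,
                            ref_ct = c(Actb = 19, Gapdh = 21),
                            seed = 1L) {
  cfg <- list(
    up_genes = up_genes, down_genes = down_genes,
    reference_genes = reference_genes,
    doses = as.numeric(doses),
    mice_per_sex_per_dose = as.integer(mice_per_sex_per_dose),
    b0 = b0, b1 = b1, b2 = b2,
    per_gene_offsets = per_gene_offsets,
    well_replicates = as.integer(well_replicates),
    ct_noise_sd = ct_noise_sd, sex_effect = sex_effect,
    sample_shift_sd = sample_shift_sd, ref_ct = ref_ct,
    seed = as.integer(seed)
  )
  targets <- c(cfg$up_genes, cfg$down_genes)
  stopifnot(
    length(cfg$up_genes) >= 1, length(cfg$down_genes) >= 1,
    !anyDuplicated(c(targets, cfg$reference_genes)),
    length(cfg$reference_genes) >= 1,
    cfg$mice_per_sex_per_dose >= 1, cfg$well_replicates >= 1,
    cfg$ct_noise_sd >= 0, cfg$sample_shift_sd >= 0,
    setequal(names(cfg$per_gene_offsets), targets),
    setequal(names(cfg$ref_ct), cfg$reference_genes)
  )
  # real roots at every configured dose (errors if complex)
  qpcr_net_signal_truth(cfg$doses, cfg$b0, cfg$b1, cfg$b2)
  up_mean <- mean(cfg$per_gene_offsets[cfg$up_genes])
  dn_mean <- mean(cfg$per_gene_offsets[cfg$down_genes])
  if (abs(up_mean - dn_mean) > 1e-8) {
    warning(
      "up- and down-group offset means differ by ",
      signif(up_mean - dn_mean, 3),
      " dCt; the net signal will be shifted by that constant",
      call. = FALSE
    )
  }
  structure(cfg, class = "qpcr_sim_config")
}

#' Simulate a qRT-PCR validation cohort
#'
#' Generates a long-format Ct table for a cohort of mice irradiated at the
#' configured doses. For each mouse the generative net signal is
#' `N* = qpcr_net_signal_truth(D, b0, b1, b2)` (plus `sex_effect` for males);
#' each up-regulated gene's target dCt is `offset_g + N*/2`, each
#' down-regulated gene's `offset_g - N*/2`, so the difference of group-mean
#' dCt equals `N*` by construction. Raw Ct adds the reference baseline, a
#' per-mouse loading shift and well-level Gaussian noise; reference genes
#' carry baseline + shift + noise only. Deterministic given the config.
#'
#' @param config A [qpcr_sim_config()].
#' @return Tibble with columns `sample_id`, `mouse_id`, `sex` ("F"/"M"),
#'   `dose_gy`, `gene`, `well`, `ct`, plus the generative net signal
#'   `n_true` (repeated per row).
#' @examples
#' ct <- generate_qpcr_cohort(qpcr_sim_config(
#'   mice_per_sex_per_dose = 1,
#'   doses = c(0, 4, 8), seed = 3
#' ))
#' head(ct)
#' @export
generate_qpcr_cohort <- function(config) {
  stopifnot(inherits(config, "qpcr_sim_config"))
  cfg <- config
  mice <- expand.grid(
    rep = seq_len(cfg$mice_per_sex_per_dose),
    sex = c("F", "M"), dose_gy = cfg$doses,
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  n_mice <- nrow(mice)
  mice$mouse_id <- sprintf("M%03d", seq_len(n_mice))
  mice$sample_id <- mice$mouse_id
  n_base <- qpcr_net_signal_truth(mice$dose_gy, cfg$b0, cfg$b1, cfg$b2)
  mice$n_true <- n_base + cfg$sex_effect * (mice$sex == "M")

  targets <- c(cfg$up_genes, cfg$down_genes)
  dir <- c(rep(1, length(cfg$up_genes)), rep(-1, length(cfg$down_genes)))
  names(dir) <- targets
  genes <- c(targets, cfg$reference_genes)
  ref_base <- mean(cfg$ref_ct)

  rows <- tidyr::crossing(
    mouse_id = mice$mouse_id,
    gene = factor(genes, levels = genes),
    well = seq_len(cfg$well_replicates)
  )
  rows <- dplyr::left_join(
    rows,
    mice[, c("mouse_id", "sample_id", "sex", "dose_gy", "n_true")],
    by = "mouse_id"
  )
  rows$gene <- as.character(rows$gene)

  withr::with_seed(cfg$seed, {
    shift <- setNames(rnorm(n_mice, 0, cfg$sample_shift_sd), mice$mouse_id)
    noise <- rnorm(nrow(rows), 0, cfg$ct_noise_sd)
  })
  is_ref <- rows$gene %in% cfg$reference_genes
  ct <- numeric(nrow(rows))
  ct[is_ref] <- cfg$ref_ct[rows$gene[is_ref]]
  tg <- rows$gene[!is_ref]
  dct_target <- cfg$per_gene_offsets[tg] + dir[tg] * rows$n_true[!is_ref] / 2
  ct[!is_ref] <- ref_base + dct_target
  ct <- ct + shift[rows$mouse_id] + noise

  tibble::tibble(
    sample_id = rows$sample_id, mouse_id = rows$mouse_id,
    sex = rows$sex, dose_gy = rows$dose_gy,
    gene = rows$gene, well = as.integer(rows$well), ct = unname(ct),
    n_true = rows$n_true
  )
}
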