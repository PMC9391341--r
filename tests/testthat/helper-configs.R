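# Shared synthetic study configurations.

# Noise-free array study on the invertible dose region (every condition has
# D > k3*sqrt(T), so the generative net signal is never floored and the
# dose model holds exactly for every sample).
zero_noise_array_cfg <- function(seed = 42, ...) {
  array_sim_config(
    noise_sd = 0, baseline_sd = 0,
    doses = c(1, 2, 4, 6, 8, 10), times = c(0.25, 1),
    study_effects = c(S1 = 0), samples_per_condition = 2,
    n_background_genes = 5, seed = seed, ...
  )
}

zero_noise_qpcr_cfg <- function(seed = 5, ...) {
  qpcr_sim_config(ct_noise_sd = 0, sample_shift_sd = 0, seed = seed, ...)
}

truth_signature <- function(em) attr(em, "signature_truth")

default_qpcr_signature <- function(cfg = qpcr_sim_config()) {
  gene_signature(cfg$up_genes, cfg$down_genes)
}

# qPCR table -> reduced quadratic model, the full delta-Ct path
qpcr_reduced_fit <- function(ct, cfg = qpcr_sim_config()) {
  dct <- delta_ct(ct, reference_genes = cfg$reference_genes)
  ns <- net_signal_qpcr(dct, gene_signature(cfg$up_genes, cfg$down_genes))
  reduce_model(fit_quadratic_sex_model(ns))
}
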