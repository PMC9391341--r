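new_net_signal <- function(sample_id, n_value, aggregator, platform,
                           signature, extra = NULL) {
  out <- tibble::tibble(sample_id = sample_id, n_value = n_value)
  if (!is.null(extra)) out <- dplyr::bind_cols(out, extra)
  structure(out,
    class = c("net_signal", class(out)),
    aggregator = aggregator, platform = platform, signature = signature
  )
}

#' Net signal from a microarray expression matrix
#'
#' The net signal N of a sample is the median log2 signal of the
#' up-regulated signature genes minus the median of the down-regulated
#' group. Any additive constant applied to all genes of a sample (array
#' scaling, batch shift) cancels exactly.
#'
#' @param expr An [expression_matrix()].
#' @param sig A [gene_signature()]; all its genes must be present.
#' @return A `net_signal` tibble with columns `sample_id`, `n_value` and the
#'   sample metadata (`dose_gy`, `time_days`, `study`); attributes record
#'   the aggregator ("median"), platform ("array") and signature.
#' @export
net_signal_array <- function(expr, sig) {
  stopifnot(inherits(expr, "expr_matrix"), inherits(sig, "gene_signature"))
  missing <- setdiff(c(sig$up_genes, sig$down_genes), rownames(expr$signal))
  if (length(missing)) {
    stop("signature gene(s) absent from matrix: ",
      paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  up <- apply(expr$signal[sig$up_genes, , drop = FALSE], 2, median)
  dn <- apply(expr$signal[sig$down_genes, , drop = FALSE], 2, median)
  extra <- expr$samples[, setdiff(names(expr$samples), "sample_id")]
  new_net_signal(expr$samples$sample_id, unname(up - dn),
    aggregator = "median", platform = "array", signature = sig,
    extra = extra
  )
}

#' Net signal from qPCR delta-Ct values
#'
#' Group aggregation is done on the dCt (log2) scale: the arithmetic mean of
#' dCt is exactly the geometric mean of linear-scale relative expression,
#' the default aggregator. N = aggregate(up) - aggregate(down). Because
#' up-regulated genes' dCt falls with dose and down-regulated genes' dCt
#' rises, the qPCR net signal decreases with dose.
#'
#' @param dct Delta-Ct table from [delta_ct()].
#' @param sig A [gene_signature()].
#' @param aggregator "geometric_mean" (default; mean on the dCt scale) or
#'   "median".
#' @return A `net_signal` tibble with sample metadata carried through.
#' @export
net_signal_qpcr <- function(dct, sig,
                            aggregator = c("geometric_mean", "median")) {
  stopifnot(is.data.frame(dct), inherits(sig, "gene_signature"))
  aggregator <- match.arg(aggregator)
  agg_fun <- if (aggregator == "median") median else mean
  missing <- setdiff(c(sig$up_genes, sig$down_genes), unique(dct$gene))
  if (length(missing)) {
    stop("signature gene(s) absent from dCt table: ",
      paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  grp <- dplyr::mutate(
    dplyr::filter(dct, .data$gene %in% c(sig$up_genes, sig$down_genes)),
    group = ifelse(.data$gene %in% sig$up_genes, "up", "down")
  )
  agg <- dplyr::summarise(
    dplyr::group_by(
      grp, dplyr::across(dplyr::any_of(c(ct_meta_cols, "group")))
    ),
    value = agg_fun(.data$dct), .groups = "drop"
  )
  wide <- tidyr::pivot_wider(agg,
    names_from = "group", values_from = "value"
  )
  extra <- wide[, setdiff(names(wide), c("sample_id", "up", "down"))]
  new_net_signal(wide$sample_id, wide$up - wide$down,
    aggregator = aggregator, platform = "qpcr", signature = sig,
    extra = extra
  )
}

#' Correlate the net signal with dose
#'
#' Reports both Spearman and Pearson correlation of N with dose, with
#' two-sided p-values (Spearman p by the package-wide policy, Pearson by the
#' usual t test).
#'
#' @param ns A `net_signal` object, or a numeric vector of N values.
#' @param dose_gy Dose per sample; taken from `ns` metadata when omitted.
#' @return Tibble with columns `method`, `estimate`, `p_value`; a constant
#'   net signal yields `NA` estimates with a warning.
#' @export
correlate_net_signal_with_dose <- function(ns, dose_gy = NULL) {
  n_value <- if (inherits(ns, "net_signal")) ns$n_value else as.numeric(ns)
  if (is.null(dose_gy)) {
    stopifnot(inherits(ns, "net_signal"), "dose_gy" %in% names(ns))
    dose_gy <- ns$dose_gy
  }
  stopifnot(length(n_value) == length(dose_gy))
  if (length(n_value) < 3) stop("need >= 3 samples", call. = FALSE)
  if (sd(n_value) == 0) {
    warning("constant net signal: correlation undefined", call. = FALSE)
    return(tibble::tibble(
      method = c("spearman", "pearson"),
      estimate = NA_real_, p_value = NA_real_
    ))
  }
  n <- length(n_value)
  rho <- cor(rank(n_value), rank(dose_gy))
  p_s <- spearman_p(rho, n, x = n_value, y = dose_gy)
  pear <- stats::cor.test(n_value, dose_gy, method = "pearson")
  tibble::tibble(
    method = c("spearman", "pearson"),
    estimate = c(rho, unname(pear$estimate)),
    p_value = c(p_s, pear$p.value)
  )
}
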