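# Spearman correlation with dose, with the p-value policy used throughout:
# large-sample t approximation for n >= 10; exact permutation-null p (via the
# exact distribution in cor.test) for smaller untied vectors.
spearman_p <- function(rho, n, x = NULL, y = NULL) {
  if (is.na(rho)) {
    return(NA_real_)
  }
  no_ties <- !is.null(x) && !is.null(y) &&
    !anyDuplicated(x) && !anyDuplicated(y)
  if (n < 10 && no_ties) {
    return(stats::cor.test(x, y, method = "spearman", exact = TRUE)$p.value)
  }
  if (abs(rho) >= 1) {
    return(0)
  }
  tstat <- rho * sqrt((n - 2) / (1 - rho^2))
  2 * pt(-abs(tstat), df = n - 2)
}

#' Rank genes by Spearman correlation of expression with dose
#'
#' Computes, for every gene, the Spearman correlation of its log-scale
#' signal with dose across all samples (all time points combined), a
#' two-sided p-value, and the Bonferroni-adjusted p-value with multiplier
#' equal to the number of genes tested. Genes with zero variance have no
#' defined correlation; they are flagged (`excluded = TRUE`) and do not
#' count towards the Bonferroni multiplier.
#'
#' @param expr An [expression_matrix()] with at least 3 distinct dose levels.
#' @return Tibble with columns `gene_id`, `rho`, `p_value`, `p_bonferroni`,
#'   `direction` ("up" iff rho > 0), `excluded`; ordered by decreasing rho,
#'   flagged genes last.
#' @export
rank_genes_by_dose_correlation <- function(expr) {
  stopifnot(inherits(expr, "expr_matrix"))
  dose <- expr$samples$dose_gy
  if (length(unique(dose)) < 3) {
    stop("need >= 3 distinct dose levels to rank genes", call. = FALSE)
  }
  sig <- expr$signal
  n <- ncol(sig)
  rd <- rank(dose)
  rx <- t(apply(sig, 1, rank))
  sds <- apply(sig, 1, sd)
  constant <- sds == 0
  rho <- rep(NA_real_, nrow(sig))
  rho[!constant] <- as.numeric(cor(t(rx[!constant, , drop = FALSE]), rd))

  exact_ok <- n < 10 && !anyDuplicated(dose)
  p <- vapply(seq_len(nrow(sig)), function(i) {
    if (constant[i]) {
      return(NA_real_)
    }
    spearman_p(
      rho[i], n,
      x = if (exact_ok && !anyDuplicated(sig[i, ])) sig[i, ],
      y = dose
    )
  }, numeric(1))

  m <- sum(!constant)
  out <- tibble::tibble(
    gene_id = rownames(sig),
    rho = rho,
    p_value = p,
    p_bonferroni = pmin(1, p * m),
    direction = ifelse(rho > 0, "up", "down"),
    excluded = constant
  )
  if (any(constant)) {
    warning(
      sum(constant), " constant gene(s) flagged and excluded from ranking",
      call. = FALSE
    )
  }
  dplyr::arrange(out, .data$excluded, dplyr::desc(.data$rho))
}

#' Retain genes significant after Bonferroni correction
#'
#' @param correlations Output of [rank_genes_by_dose_correlation()].
#' @param alpha Family-wise significance level (default 0.05).
#' @return The input rows with `p_bonferroni < alpha` (flagged genes
#'   dropped), original order preserved. May be empty.
#' @export
bonferroni_filter <- function(correlations, alpha = 0.05) {
  stopifnot(is.data.frame(correlations), nrow(correlations) >= 1)
  dplyr::filter(
    correlations,
    !.data$excluded, !is.na(.data$p_bonferroni), .data$p_bonferroni < alpha
  )
}

#' Select the up/down dose-response gene signature
#'
#' Takes the `n_up` most positively and `n_down` most negatively
#' dose-correlated genes from a (typically Bonferroni-filtered) correlation
#' table. Ties in rho are broken by smaller raw p-value, then lexicographic
#' gene ID.
#'
#' @param correlations Correlation table (see
#'   [rank_genes_by_dose_correlation()]).
#' @param n_up,n_down Group sizes (defaults 20 and 10).
#' @return A [gene_signature()]: `up_genes` ordered by descending rho,
#'   `down_genes` by ascending rho.
#' @export
select_signature <- function(correlations, n_up = 20, n_down = 10) {
  stopifnot(is.data.frame(correlations))
  usable <- dplyr::filter(correlations, !.data$excluded, !is.na(.data$rho))
  pos <- dplyr::arrange(
    dplyr::filter(usable, .data$rho > 0),
    dplyr::desc(.data$rho), .data$p_value, .data$gene_id
  )
  neg <- dplyr::arrange(
    dplyr::filter(usable, .data$rho < 0),
    .data$rho, .data$p_value, .data$gene_id
  )
  if (nrow(pos) < n_up || nrow(neg) < n_down) {
    stop(
      "insufficient surviving genes for the requested signature: need ",
      n_up, " up (have ", nrow(pos), ") and ",
      n_down, " down (have ", nrow(neg), ")",
      call. = FALSE
    )
  }
  gene_signature(pos$gene_id[seq_len(n_up)], neg$gene_id[seq_len(n_down)])
}

#' Pairwise gene-gene correlation matrix
#'
#' Correlations between the expression profiles of a set of genes across all
#' samples, Spearman by default (matching the dose ranking) with a Pearson
#' option.
#'
#' @param expr An [expression_matrix()].
#' @param genes Character vector of >= 2 gene IDs present in `expr`.
#' @param method "spearman" (default) or "pearson".
#' @return Symmetric numeric matrix with unit diagonal and entries in
#'   \[-1, 1\]. Entries involving a constant gene are `NA`; such genes are
#'   listed in the `constant_genes` attribute and a warning is raised.
#' @export
pairwise_correlation_matrix <- function(expr, genes,
                                        method = c("spearman", "pearson")) {
  stopifnot(inherits(expr, "expr_matrix"))
  method <- match.arg(method)
  if (length(genes) < 2) stop("need >= 2 genes", call. = FALSE)
  missing <- setdiff(genes, rownames(expr$signal))
  if (length(missing)) {
    stop("genes absent from matrix: ", paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  x <- t(expr$signal[genes, , drop = FALSE])
  constant <- genes[apply(x, 2, sd) == 0]
  m <- suppressWarnings(cor(x, method = method))
  diag(m) <- 1
  if (length(constant)) {
    warning("constant gene(s) with undefined correlations: ",
      paste(constant, collapse = ", "),
      call. = FALSE
    )
  }
  attr(m, "constant_genes") <- constant
  m
}
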