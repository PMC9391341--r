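#' Construct an expression matrix with sample metadata
#'
#' Container for normalized, log-scale expression signals (genes x samples)
#' together with per-sample dose, time and study annotation. All downstream
#' signature and net-signal operations consume this object.
#'
#' @param signal Numeric matrix, genes in rows (rownames = gene IDs), samples
#'   in columns (colnames = sample IDs). Values are normalized log2-scale
#'   intensities.
#' @param samples Data frame with one row per column of `signal`: columns
#'   `sample_id`, `dose_gy` (numeric, >= 0), `time_days` (numeric, > 0),
#'   `study` and optionally `sex`.
#' @return An object of class `expr_matrix`: a list with elements `signal`
#'   (the matrix) and `samples` (a tibble, ordered to match the columns).
#' @examples
#' sig <- matrix(rnorm(12), 3, 4,
#'   dimnames = list(paste0("g", 1:3), paste0("s", 1:4))
#' )
#' meta <- data.frame(
#'   sample_id = paste0("s", 1:4), dose_gy = c(0, 1, 2, 4),
#'   time_days = 1, study = "A"
#' )
#' em <- expression_matrix(sig, meta)
#' em
#' @export
expression_matrix <- function(signal, samples) {
  if (!is.matrix(signal) || !is.numeric(signal)) {
    stop("`signal` must be a numeric matrix (genes x samples)", call. = FALSE)
  }
  if (is.null(rownames(signal)) || is.null(colnames(signal))) {
    stop("`signal` must carry gene IDs as rownames and sample IDs as colnames",
      call. = FALSE
    )
  }
  if (anyDuplicated(rownames(signal))) {
    dup <- unique(rownames(signal)[duplicated(rownames(signal))])
    stop("duplicated gene IDs: ", paste(head(dup, 5), collapse = ", "),
      call. = FALSE
    )
  }
  samples <- tibble::as_tibble(samples)
  req <- c("sample_id", "dose_gy", "time_days", "study")
  miss <- setdiff(req, names(samples))
  if (length(miss)) {
    stop("sample metadata lacks column(s): ", paste(miss, collapse = ", "),
      call. = FALSE
    )
  }
  if (!setequal(samples$sample_id, colnames(signal)) ||
    anyDuplicated(samples$sample_id)) {
    only_meta <- setdiff(samples$sample_id, colnames(signal))
    only_mat <- setdiff(colnames(signal), samples$sample_id)
    stop(
      "sample IDs disagree between matrix and metadata",
      if (length(only_mat)) {
        paste0("; missing from metadata: ", paste(head(only_mat, 5), collapse = ", "))
      },
      if (length(only_meta)) {
        paste0("; missing from matrix: ", paste(head(only_meta, 5), collapse = ", "))
      },
      call. = FALSE
    )
  }
  if (!is.numeric(samples$dose_gy) || any(samples$dose_gy < 0)) {
    stop("`dose_gy` must be numeric and >= 0", call. = FALSE)
  }
  if (!is.numeric(samples$time_days) || any(samples$time_days <= 0)) {
    stop("`time_days` must be numeric and > 0", call. = FALSE)
  }
  samples <- samples[match(colnames(signal), samples$sample_id), ]
  structure(list(signal = signal, samples = samples), class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(
    "<expr_matrix> ", nrow(x$signal), " genes x ", ncol(x$signal),
    " samples\n",
    sep = ""
  )
  cat(
    "  doses (Gy): ", paste(sort(unique(x$samples$dose_gy)), collapse = ", "),
    "\n  times (days): ",
    paste(sort(unique(x$samples$time_days)), collapse = ", "),
    "\n  studies: ", paste(unique(x$samples$study), collapse = ", "), "\n",
    sep = ""
  )
  invisible(x)
}

#' Construct a gene signature
#'
#' An ordered pair of gene lists: genes whose expression rises with dose and
#' genes whose expression falls with dose. The net signal contrasts the two
#' groups.
#'
#' @param up_genes Character vector, ordered by descending dose correlation.
#' @param down_genes Character vector, ordered by ascending dose correlation.
#' @return Object of class `gene_signature` with elements `up_genes`,
#'   `down_genes`, `n_up`, `n_down`.
#' @export
gene_signature <- function(up_genes, down_genes) {
  up_genes <- as.character(up_genes)
  down_genes <- as.character(down_genes)
  if (!length(up_genes) || !length(down_genes)) {
    stop("both gene groups must be non-empty", call. = FALSE)
  }
  both <- intersect(up_genes, down_genes)
  if (length(both)) {
    stop("up and down groups overlap: ", paste(both, collapse = ", "),
      call. = FALSE
    )
  }
  structure(
    list(
      up_genes = up_genes, down_genes = down_genes,
      n_up = length(up_genes), n_down = length(down_genes)
    ),
    class = "gene_signature"
  )
}

#' @export
print.gene_signature <- function(x, ...) {
  cat("<gene_signature> ", x$n_up, " up / ", x$n_down, " down\n", sep = "")
  cat("  up:   ", paste(head(x$up_genes, 8), collapse = ", "),
    if (x$n_up > 8) ", ..." else "", "\n",
    sep = ""
  )
  cat("  down: ", paste(head(x$down_genes, 8), collapse = ", "),
    if (x$n_down > 8) ", ..." else "", "\n",
    sep = ""
  )
  invisible(x)
}
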