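ct_meta_cols <- c("sample_id", "mouse_id", "sex", "dose_gy")

assert_ct_table <- function(table, need_well = FALSE) {
  req <- c(ct_meta_cols, "gene", "ct", if (need_well) "well")
  miss <- setdiff(req, names(table))
  if (length(miss)) {
    stop("Ct table lacks column(s): ", paste(miss, collapse = ", "),
      call. = FALSE
    )
  }
  if (any(table$ct <= 0, na.rm = TRUE)) {
    stop("Ct values must be > 0 cycles", call. = FALSE)
  }
  invisible(table)
}

#' Collapse replicate wells to one Ct per sample and gene
#'
#' Averages well-replicate Ct values (arithmetic mean) for each
#' (sample, gene) pair and flags pairs whose well spread exceeds a quality
#' threshold. Flagged pairs are warned about but never dropped; well-level
#' QC policy is left to the caller.
#'
#' @param table Long-format Ct table with columns `sample_id`, `mouse_id`,
#'   `sex`, `dose_gy`, `gene`, `well`, `ct` (e.g. from
#'   [generate_qpcr_cohort()] or [read_ct_table()]).
#' @param spread_threshold Max acceptable well range in cycles (default 0.5).
#' @return Tibble with one row per (sample, gene): metadata, `ct` (mean),
#'   `n_wells`, `well_range`, `flagged`.
#' @export
collapse_wells <- function(table, spread_threshold = 0.5) {
  assert_ct_table(table, need_well = TRUE)
  out <- dplyr::summarise(
    dplyr::group_by(
      table, dplyr::across(dplyr::all_of(c(ct_meta_cols, "gene")))
    ),
    n_wells = dplyr::n(),
    well_range = max(.data$ct) - min(.data$ct),
    ct = mean(.data$ct),
    .groups = "drop"
  )
  out$flagged <- out$well_range > spread_threshold
  if (any(out$flagged)) {
    warning(
      sum(out$flagged), " (sample, gene) pair(s) exceed the ",
      spread_threshold, "-cycle well-spread threshold",
      call. = FALSE
    )
  }
  out
}

#' Delta-Ct normalization against reference genes
#'
#' `dct(sample, gene) = Ct(sample, gene) - mean over reference genes of
#' Ct(sample, ref)`. Since Ct is a log2 quantity, the arithmetic mean of
#' reference Cts is exactly the geometric mean of their linear-scale
#' expression, the standard multi-reference normalizer. Wells are collapsed
#' first if replicates are present. Samples missing any reference gene are
#' excluded with a warning naming them.
#'
#' @param table Ct table (well-level or already collapsed).
#' @param reference_genes Character vector of housekeeping gene names
#'   (default `c("Actb", "Gapdh")`).
#' @return Tibble with one row per (sample, gene) — reference genes
#'   included, whose dct values average to 0 per sample by construction —
#'   with columns `sample_id`, `mouse_id`, `sex`, `dose_gy`, `gene`, `dct`.
#' @export
delta_ct <- function(table, reference_genes = c("Actb", "Gapdh")) {
  if ("well" %in% names(table) &&
    anyDuplicated(table[, c("sample_id", "gene")])) {
    table <- suppressWarnings(collapse_wells(table))
  }
  assert_ct_table(table)
  ref <- dplyr::filter(table, .data$gene %in% reference_genes)
  ref_norm <- dplyr::summarise(
    dplyr::group_by(ref, .data$sample_id),
    n_ref = dplyr::n(), ref_ct = mean(.data$ct), .groups = "drop"
  )
  ok <- ref_norm$sample_id[ref_norm$n_ref == length(reference_genes)]
  bad <- setdiff(unique(table$sample_id), ok)
  if (length(bad)) {
    warning(
      "sample(s) excluded for missing reference gene(s): ",
      paste(bad, collapse = ", "),
      call. = FALSE
    )
  }
  out <- dplyr::inner_join(
    dplyr::filter(table, .data$sample_id %in% ok),
    ref_norm[, c("sample_id", "ref_ct")],
    by = "sample_id"
  )
  out$dct <- out$ct - out$ref_ct
  out[, c(ct_meta_cols, "gene", "dct")]
}

#' Fold change by the 2^-ddCt method
#'
#' ddCt is each sample's dct minus the mean dct of the control group
#' (dose 0, both sexes pooled) for the same gene; fold change is
#' `2^-ddCt`, so a control sample at the control mean has fold change 1.
#'
#' @param dct Delta-Ct table from [delta_ct()].
#' @param control Logical vector or predicate selecting control rows;
#'   default selects `dose_gy == 0`.
#' @return The input with added columns `ddct` and `fold_change`.
#' @export
fold_change_ddct <- function(dct, control = NULL) {
  stopifnot(is.data.frame(dct), "dct" %in% names(dct))
  if (is.null(control)) control <- dct$dose_gy == 0
  stopifnot(is.logical(control), length(control) == nrow(dct))
  if (!any(control)) stop("control group is empty", call. = FALSE)
  ctrl_mean <- dplyr::summarise(
    dplyr::group_by(dct[control, ], .data$gene),
    ctrl_dct = mean(.data$dct), .groups = "drop"
  )
  missing <- setdiff(unique(dct$gene), ctrl_mean$gene)
  if (length(missing)) {
    stop("gene(s) absent from the control group: ",
      paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  out <- dplyr::left_join(dct, ctrl_mean, by = "gene")
  out$ddct <- out$dct - out$ctrl_dct
  out$fold_change <- 2^(-out$ddct)
  out$ctrl_dct <- NULL
  out
}
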