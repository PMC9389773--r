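#' QC thresholds for plate-based scRNA-seq
#'
#' Defaults are the canonical SORT-seq gates: a cell is discarded when it
#' has fewer than 500 detected genes, more than 12,000 UMIs, more than 30%
#' mitochondrial UMIs or more than 20% ERCC reads. Rules are strict
#' inequalities, so a cell sitting exactly on a boundary passes.
#'
#' @param min_genes minimum detected genes (features with >= 1 UMI,
#'   excluding ERCC spike-ins).
#' @param max_umi maximum total non-ERCC UMIs.
#' @param max_mito_frac maximum mitochondrial fraction of non-ERCC UMIs.
#' @param max_ercc_frac maximum ERCC fraction of all UMIs (ERCC included in
#'   the denominator).
#' @return a `qc_thresholds` list.
#' @export
qc_thresholds <- function(min_genes = 500, max_umi = 12000,
                          max_mito_frac = 0.30, max_ercc_frac = 0.20) {
  check_count(min_genes, "min_genes", positive = FALSE)
  if (!is.numeric(max_umi) || max_umi <= 0) stopf("'max_umi' must be > 0")
  check_fraction(max_mito_frac, "max_mito_frac")
  check_fraction(max_ercc_frac, "max_ercc_frac")
  structure(list(min_genes = min_genes, max_umi = max_umi,
                 max_mito_frac = max_mito_frac, max_ercc_frac = max_ercc_frac),
            class = "qc_thresholds")
}

#' Per-cell QC metrics
#'
#' Spike-ins are identified by the `ERCC-` prefix (or rowData `type`) and
#' are excluded from the detected-gene and UMI totals; the ERCC fraction
#' uses the full library (ERCC included) as denominator, the mitochondrial
#' fraction the non-ERCC total.
#'
#' @param x count matrix or SingleCellExperiment with a `counts` assay.
#' @param thresholds a [qc_thresholds()].
#' @return data.frame with one row per cell: `cell`, `n_genes_detected`,
#'   `n_umi`, `mito_frac`, `ercc_frac`, the four per-rule failure flags and
#'   `pass`.
#' @export
compute_qc_metrics <- function(x, thresholds = qc_thresholds()) {
  counts <- get_counts(x)
  if (nrow(counts) == 0 || ncol(counts) == 0) {
    stopf("count matrix has %d features and %d cells; nothing to QC",
          nrow(counts), ncol(counts))
  }
  type <- feature_types(x)
  is_ercc <- type == "ercc"
  is_mito <- type == "mito"

  tot_all <- Matrix::colSums(counts)
  ercc_tot <- Matrix::colSums(counts[is_ercc, , drop = FALSE])
  mito_tot <- Matrix::colSums(counts[is_mito, , drop = FALSE])
  n_umi <- tot_all - ercc_tot
  n_genes <- Matrix::colSums(counts[!is_ercc, , drop = FALSE] > 0)
  mito_frac <- ifelse(n_umi > 0, mito_tot / n_umi, 0)
  ercc_frac <- ifelse(tot_all > 0, ercc_tot / tot_all, 0)

  fail_min_genes <- n_genes < thresholds$min_genes
  fail_max_umi <- n_umi > thresholds$max_umi
  fail_mito <- mito_frac > thresholds$max_mito_frac
  fail_ercc <- ercc_frac > thresholds$max_ercc_frac

  data.frame(
    cell = colnames(counts),
    n_genes_detected = as.integer(n_genes),
    n_umi = as.numeric(n_umi),
    mito_frac = as.numeric(mito_frac),
    ercc_frac = as.numeric(ercc_frac),
    fail_min_genes = fail_min_genes,
    fail_max_umi = fail_max_umi,
    fail_mito = fail_mito,
    fail_ercc = fail_ercc,
    pass = !(fail_min_genes | fail_max_umi | fail_mito | fail_ercc),
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Filter cells by QC metrics
#'
#' @inheritParams compute_qc_metrics
#' @return list with `sce` (or matrix) restricted to passing cells,
#'   the per-cell `metrics`, and a `report` with per-rule failure counts.
#'   Errors rather than returning silently when no cell survives.
#' @export
qc_filter <- function(x, thresholds = qc_thresholds()) {
  metrics <- compute_qc_metrics(x, thresholds)
  if (!any(metrics$pass)) {
    stopf("no cell passes QC (of %d); check thresholds and input",
          nrow(metrics))
  }
  report <- list(
    n_in = nrow(metrics),
    n_pass = sum(metrics$pass),
    n_fail = sum(!metrics$pass),
    fail_min_genes = sum(metrics$fail_min_genes),
    fail_max_umi = sum(metrics$fail_max_umi),
    fail_mito = sum(metrics$fail_mito),
    fail_ercc = sum(metrics$fail_ercc),
    thresholds = unclass(thresholds))
  list(sce = x[, metrics$pass], metrics = metrics, report = report)
}

#' Library-size log-normalization
#'
#' Computes `log1p(count / cell_total * scale_factor)` per cell (natural
#' log, scale factor 10,000 by default). ERCC spike-ins are excluded from
#' the cell totals and dropped from the output; mitochondrial genes are
#' kept.
#'
#' @param x count matrix or SingleCellExperiment (QC-filtered).
#' @param scale_factor pseudo-library size after rescaling.
#' @return for a SingleCellExperiment input, the object minus ERCC rows with
#'   a dense `logcounts` assay added; for a matrix, the normalized matrix.
#' @export
normalize_counts <- function(x, scale_factor = 1e4) {
  type <- feature_types(x)
  x <- x[type != "ercc", , drop = FALSE]
  counts <- get_counts(x)
  totals <- Matrix::colSums(counts)
  if (any(totals == 0)) {
    stopf("%d cell(s) have zero non-spike-in counts; filter before normalizing",
          sum(totals == 0))
  }
  norm <- log1p(sweep(as.matrix(counts), 2, totals, `/`) * scale_factor)
  if (methods::is(x, "SingleCellExperiment")) {
    logcounts(x) <- norm
    x
  } else {
    norm
  }
}
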