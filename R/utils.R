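stopf <- function(...) stop(sprintf(...), call. = FALSE)

warnf <- function(...) warning(sprintf(...), call. = FALSE)

check_fraction <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    stopf("'%s' must be a single number in [0, 1] (got %s)", name,
          paste(format(x), collapse = ", "))
  }
  invisible(x)
}

check_count <- function(x, name, positive = TRUE) {
  ok <- is.numeric(x) && length(x) == 1L && !is.na(x) && x == floor(x) &&
    (if (positive) x > 0 else x >= 0)
  if (!ok) {
    stopf("'%s' must be a %s integer (got %s)", name,
          if (positive) "positive" else "non-negative", paste(format(x), collapse = ", "))
  }
  invisible(as.integer(x))
}

#' Centered moving average with shrinking edge windows
#'
#' Used to smooth per-cell tile signal along a chromosome; windows are
#' truncated (never wrapped) at chromosome ends.
#'
#' @param x numeric vector.
#' @param w window width in elements; even values are rounded up to the next
#'   odd width. `w <= 1` returns `x` unchanged.
#' @return numeric vector of the same length.
#' @keywords internal
smooth_ma <- function(x, w) {
  n <- length(x)
  if (w <= 1 || n <= 1) return(x)
  h <- floor(w / 2)
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

# Half-sample mode (Robertson & Cryer): repeatedly keeps the densest half
# of the sorted sample. Used as the per-cell normalizer of the tile signal:
# it tracks the dominant (diploid) tile population and, unlike the median,
# is not dragged by a sizeable aberrant region.
half_sample_mode <- function(x) {
  x <- sort(x)
  while (length(x) > 3) {
    n <- length(x)
    h <- ceiling(n / 2)
    w <- x[h:n] - x[seq_len(n - h + 1)]
    i <- which.min(w)
    x <- x[i:(i + h - 1)]
  }
  mean(x)
}

# Row grouping by sparse indicator product; keeps sparse counts sparse.
rowsum_sparse <- function(x, group, n_groups) {
  ind <- Matrix::sparseMatrix(i = group, j = seq_along(group),
                              x = 1, dims = c(n_groups, length(group)))
  as.matrix(ind %*% x)
}

# Mito/spike-in feature identification by community-convention prefixes,
# with rowData 'type' (gene/mito/ercc) taking precedence when present.
feature_types <- function(x) {
  ids <- rownames(x)
  if (is.null(ids)) stopf("matrix must carry feature names")
  type <- rep("gene", length(ids))
  rd <- if (methods::is(x, "SummarizedExperiment")) rowData(x) else NULL
  if (!is.null(rd) && "type" %in% colnames(rd)) {
    type <- as.character(rd$type)
  } else {
    type[grepl("^MT-", ids)] <- "mito"
    type[grepl("^ERCC-", ids)] <- "ercc"
  }
  type
}

#' Extract gene annotation as a 0-based data.frame
#'
#' Returns the per-feature annotation (`feature_id`, `chrom`, `start`,
#' `end`, `strand`, `type`) in 0-based, half-open coordinates, from either
#' a SummarizedExperiment with `rowRanges` (the package convention:
#' spike-ins sit on the placeholder seqname `"spikein"` and are reported
#' with `NA` coordinates) or a data.frame already in that layout.
#'
#' @param x SingleCellExperiment/SummarizedExperiment or data.frame.
#' @return data.frame with one row per feature.
#' @export
gene_annotation <- function(x) {
  if (is.data.frame(x) || methods::is(x, "DataFrame")) {
    ann <- as.data.frame(x)
    need <- c("feature_id", "chrom", "start", "end")
    miss <- setdiff(need, colnames(ann))
    if (length(miss)) stopf("annotation lacks column(s): %s",
                            paste(miss, collapse = ", "))
    return(ann)
  }
  if (!methods::is(x, "SummarizedExperiment")) {
    stopf("cannot extract gene annotation from a '%s'", class(x)[1])
  }
  gr <- SummarizedExperiment::rowRanges(x)
  chrom <- as.character(seqnames(gr))
  placeholder <- chrom == "spikein"
  data.frame(
    feature_id = rownames(x),
    chrom = ifelse(placeholder, NA_character_, chrom),
    start = ifelse(placeholder, NA_real_, start(gr) - 1),
    end = ifelse(placeholder, NA_real_, as.numeric(end(gr))),
    strand = as.character(GenomicRanges::strand(gr)),
    type = if ("type" %in% colnames(rowData(x))) as.character(rowData(x)$type)
      else NA_character_,
    stringsAsFactors = FALSE, row.names = NULL)
}

get_counts <- function(x) {
  if (methods::is(x, "SummarizedExperiment")) assay(x, "counts") else x
}

get_logcounts <- function(x) {
  if (methods::is(x, "SingleCellExperiment")) {
    if (!"logcounts" %in% assayNames(x)) {
      stopf("no 'logcounts' assay; run normalize_counts() first")
    }
    logcounts(x)
  } else {
    x
  }
}
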