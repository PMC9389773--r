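#' Wilcoxon rank-sum test (two-sided)
#'
#' Exact enumeration for small untied samples (`n_a + n_b <= 12`), normal
#' approximation with tie correction and continuity correction otherwise —
#' the per-gene test conventionally used for single-cell marker detection.
#'
#' @param a,b numeric value vectors for the two groups.
#' @return two-sided p-value in (0, 1]; 1 when all pooled values are tied.
#' @export
rank_sum_test <- function(a, b) {
  if (length(a) == 0 || length(b) == 0) stopf("both groups must be non-empty")
  pooled <- c(a, b)
  if (length(unique(pooled)) == 1) return(1)
  if (length(pooled) <= 12 && !anyDuplicated(pooled)) {
    return(wilcox.test(a, b, exact = TRUE)$p.value)
  }
  .rank_sum_approx(rank(pooled), seq_along(a), length(a), length(b))
}

# Normal approximation on precomputed pooled ranks, with tie and
# continuity corrections; shared by rank_sum_test and find_markers.
.rank_sum_approx <- function(r, idx_a, na, nb) {
  n <- na + nb
  U <- sum(r[idx_a]) - na * (na + 1) / 2
  mu <- na * nb / 2
  ties <- table(r)
  tie_term <- sum(ties^3 - ties)
  sigma2 <- na * nb / 12 * ((n + 1) - tie_term / (n * (n - 1)))
  if (sigma2 <= 0) return(1)
  z <- (abs(U - mu) - 0.5) / sqrt(sigma2)
  min(1, 2 * pnorm(-max(z, 0)))
}

#' Marker gene / differential expression detection
#'
#' For each group (one-vs-rest when `group = NULL`, or a single group vs
#' the rest / a chosen reference), genes are pre-filtered on detection
#' fraction and fold change, tested with the Wilcoxon rank-sum test on
#' log-normalized expression, and BH-adjusted over the tested genes of
#' that contrast. Fold changes are computed on de-logged normalized means
#' with a fixed pseudocount of 1.
#'
#' @param x normalized matrix or SingleCellExperiment with `logcounts`
#'   and a `counts` assay (detection fractions use raw counts when
#'   available, normalized values otherwise).
#' @param labels group label per cell, or the name of a `colData` column.
#' @param group optional single group to test (against `reference`, or the
#'   rest); default tests every group one-vs-rest.
#' @param reference optional reference group label.
#' @param min_pct minimum detection fraction in either group (default 0.1).
#' @param min_abs_log2fc minimum |log2 fold change| to test (default 0.25).
#' @param alpha significance level on q (default 0.05).
#' @return data.frame of [MarkerResult rows]: `gene`, `group`, `log2fc`,
#'   `pct_in`, `pct_out`, `p`, `q`, `significant`, `rank` — ranked by q,
#'   then |log2fc|, then gene id. Groups with fewer than 3 cells are
#'   skipped with a warning.
#' @export
find_markers <- function(x, labels, group = NULL, reference = NULL,
                         min_pct = 0.1, min_abs_log2fc = 0.25,
                         alpha = 0.05) {
  norm <- get_logcounts(x)
  if (length(labels) == 1 && methods::is(x, "SingleCellExperiment") &&
      labels %in% colnames(colData(x))) {
    labels <- colData(x)[[labels]]
  }
  labels <- as.character(labels)
  if (length(labels) != ncol(norm)) {
    stopf("'labels' must cover all %d cells", ncol(norm))
  }
  detect <- if (methods::is(x, "SingleCellExperiment") &&
                "counts" %in% assayNames(x)) {
    as.matrix(counts(x)[rownames(norm), , drop = FALSE]) > 0
  } else {
    norm > 0
  }
  expr <- expm1(norm)

  groups <- if (is.null(group)) sort(unique(labels)) else group
  res <- list()
  for (g in groups) {
    in_cells <- which(labels == g)
    out_cells <- if (is.null(reference)) which(labels != g)
      else which(labels == reference)
    if (length(in_cells) < 3 || length(out_cells) < 3) {
      warnf("group '%s': fewer than 3 cells on one side; skipped", g)
      next
    }
    mean_in <- rowMeans(expr[, in_cells, drop = FALSE])
    mean_out <- rowMeans(expr[, out_cells, drop = FALSE])
    pct_in <- rowMeans(detect[, in_cells, drop = FALSE])
    pct_out <- rowMeans(detect[, out_cells, drop = FALSE])
    log2fc <- log2((mean_in + 1) / (mean_out + 1))
    keep <- which(pmax(pct_in, pct_out) >= min_pct &
                    abs(log2fc) >= min_abs_log2fc)
    if (length(keep) == 0) next

    cells <- c(in_cells, out_cells)
    na <- length(in_cells)
    p <- vapply(keep, function(i) {
      v <- norm[i, cells]
      if (length(unique(v)) == 1) return(1)
      .rank_sum_approx(rank(v), seq_len(na), na, length(out_cells))
    }, numeric(1))
    q <- bh_adjust(p)
    tab <- data.frame(gene = rownames(norm)[keep], group = g,
                      log2fc = log2fc[keep], pct_in = pct_in[keep],
                      pct_out = pct_out[keep], p = p, q = q,
                      significant = q < alpha, stringsAsFactors = FALSE)
    tab <- tab[order(tab$q, -abs(tab$log2fc), tab$gene), , drop = FALSE]
    tab$rank <- seq_len(nrow(tab))
    res[[g]] <- tab
  }
  if (length(res) == 0) {
    return(data.frame(gene = character(), group = character(),
                      log2fc = numeric(), pct_in = numeric(),
                      pct_out = numeric(), p = numeric(), q = numeric(),
                      significant = logical(), rank = integer(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Fold change and rank-sum test for a named gene set
#'
#' Per-gene fold change (de-logged normalized means, pseudocount 1) and
#' Wilcoxon p between two sample groups for a curated gene set (e.g. known
#' NPM1 target genes or HOX-cluster genes), with a set-level summary
#' counting genes that pass the fold-change and significance thresholds.
#'
#' @param x normalized matrix or SingleCellExperiment with `logcounts`.
#' @param gene_set character vector of genes; absent genes are reported as
#'   missing and excluded from the summary.
#' @param group_a,group_b cell id or index vectors for the two groups.
#' @param fc_threshold fold-change threshold for the summary (default 1.5).
#' @param alpha p-value threshold for the summary (default 0.05).
#' @return list with `genes` (per-gene `fc`, `log2fc`, `p`), `missing`
#'   (genes absent from the matrix) and `summary` (`n_tested`, `n_pass`).
#' @export
signature_contrast <- function(x, gene_set, group_a, group_b,
                               fc_threshold = 1.5, alpha = 0.05) {
  norm <- get_logcounts(x)
  if (is.character(group_a)) group_a <- match(group_a, colnames(norm))
  if (is.character(group_b)) group_b <- match(group_b, colnames(norm))
  if (anyNA(group_a) || anyNA(group_b) ||
      length(group_a) == 0 || length(group_b) == 0) {
    stopf("both groups must name cells present in the matrix")
  }
  present <- intersect(gene_set, rownames(norm))
  missing <- setdiff(gene_set, present)
  if (length(present) == 0) stopf("no gene of the set is present in the matrix")

  expr <- expm1(norm[present, , drop = FALSE])
  mean_a <- rowMeans(expr[, group_a, drop = FALSE])
  mean_b <- rowMeans(expr[, group_b, drop = FALSE])
  fc <- (mean_a + 1) / (mean_b + 1)
  na <- length(group_a)
  cells <- c(group_a, group_b)
  p <- vapply(present, function(g) {
    v <- norm[g, cells]
    if (length(unique(v)) == 1) return(1)
    .rank_sum_approx(rank(v), seq_len(na), na, length(group_b))
  }, numeric(1))

  genes <- data.frame(gene = present, fc = fc, log2fc = log2(fc), p = p,
                      stringsAsFactors = FALSE, row.names = NULL)
  list(genes = genes, missing = missing,
       summary = list(n_tested = nrow(genes),
                      n_pass = sum(genes$fc > fc_threshold & genes$p < alpha)))
}

#' Inclusion-exclusion partition of DEG sets
#'
#' Input for Venn-style comparison of per-patient DEG lists: for every
#' non-empty combination of the input sets, the number of genes belonging
#' to exactly that combination.
#'
#' @param sets named list (>= 2) of character vectors.
#' @return data.frame with `subset` (member names joined by `&`), `degree`
#'   and `count`, covering all non-empty combinations.
#' @export
compare_deg_sets <- function(sets) {
  if (!is.list(sets) || length(sets) < 2) stopf("need at least two sets")
  if (is.null(names(sets)) || any(names(sets) == "")) {
    names(sets) <- paste0("set", seq_along(sets))
  }
  universe <- unique(unlist(sets, use.names = FALSE))
  membership <- vapply(sets, function(s) universe %in% s,
                       logical(length(universe)))
  if (length(universe) == 1) membership <- matrix(membership, nrow = 1)
  key <- apply(membership, 1, function(m) paste(names(sets)[m], collapse = "&"))

  combos <- unlist(lapply(seq_along(sets), function(k) {
    apply(combn(names(sets), k), 2, paste, collapse = "&")
  }))
  counts <- table(factor(key, levels = combos))
  data.frame(subset = combos,
             degree = lengths(strsplit(combos, "&", fixed = TRUE)),
             count = as.integer(counts),
             stringsAsFactors = FALSE, row.names = NULL)
}
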