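#' The LSC17 leukemic stem cell signature
#'
#' The 17-gene weighted signature of Ng et al. (2016), shipped as an
#' editable two-column TSV. The per-cell score is the weighted sum of
#' normalized expression over the 17 genes; higher scores indicate a more
#' stem-like, therapy-resistant leukemic state.
#'
#' @param file path to a two-column TSV (`gene`, `weight`); defaults to the
#'   bundled Ng et al. weights.
#' @return named numeric vector of signed weights.
#' @references Ng SW et al. (2016) A 17-gene stemness score for rapid
#'   determination of risk in acute leukaemia. Nature 540:433-437.
#' @export
lsc17_signature <- function(file = system.file("extdata", "lsc17_weights.tsv",
                                               package = "relapseScope")) {
  tab <- read.delim(file, stringsAsFactors = FALSE)
  if (!all(c("gene", "weight") %in% colnames(tab))) {
    stopf("signature file must have columns 'gene' and 'weight'")
  }
  if (anyDuplicated(tab$gene)) stopf("duplicate gene in signature file")
  setNames(tab$weight, tab$gene)
}

#' Cell-cycle phase gene sets
#'
#' The S-phase and G2/M gene lists of Tirosh et al. (2016), as bundled with
#' Seurat, shipped as editable one-column text files.
#'
#' @param s_file,g2m_file paths to one-gene-per-line text files.
#' @return list with character vectors `s` and `g2m`; overlapping genes are
#'   warned about but allowed.
#' @references Tirosh I et al. (2016) Dissecting the multicellular
#'   ecosystem of metastatic melanoma by single-cell RNA-seq. Science
#'   352:189-196.
#' @export
cell_cycle_genes <- function(
    s_file = system.file("extdata", "cell_cycle_s_genes.txt",
                         package = "relapseScope"),
    g2m_file = system.file("extdata", "cell_cycle_g2m_genes.txt",
                           package = "relapseScope")) {
  s <- readLines(s_file)
  g2m <- readLines(g2m_file)
  common <- intersect(s, g2m)
  if (length(common)) warnf("%d gene(s) appear in both cycle sets: %s",
                            length(common), paste(common, collapse = ", "))
  list(s = s, g2m = g2m)
}

#' Score a weighted gene signature per cell
#'
#' The score of cell j is `sum_i w_i * x_ij` over the signature genes on
#' log-normalized expression — the linear form used by the LSC17 score.
#' Signature genes absent from the matrix are imputed as zero expression
#' (with a loud warning) rather than renormalizing the weights, preserving
#' comparability across datasets.
#'
#' @param x normalized matrix or SingleCellExperiment with `logcounts`.
#' @param signature named numeric vector of weights, e.g.
#'   [lsc17_signature()].
#' @return named numeric vector of per-cell scores.
#' @export
score_weighted_signature <- function(x, signature = lsc17_signature()) {
  norm <- get_logcounts(x)
  if (is.null(names(signature)) || length(signature) == 0) {
    stopf("'signature' must be a non-empty named weight vector")
  }
  present <- intersect(names(signature), rownames(norm))
  if (length(present) == 0) {
    stopf("none of the %d signature genes is present in the matrix",
          length(signature))
  }
  if (length(present) < length(signature)) {
    warnf("%d of %d signature genes absent from the matrix and scored as zero expression: %s",
          length(signature) - length(present), length(signature),
          paste(setdiff(names(signature), present), collapse = ", "))
  }
  w <- signature[present]
  scores <- as.numeric(w %*% norm[present, , drop = FALSE])
  setNames(scores, colnames(norm))
}

.p_stars <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "")))
}

#' Pairwise per-group comparison of per-cell scores
#'
#' Two-sample t-tests (Student by default) between every pair of groups,
#' with the conventional star annotation (* p < 0.05, ** p < 0.01,
#' *** p < 0.001). Used to compare e.g. the LSC17 score distribution across
#' clusters.
#'
#' @param scores numeric per-cell scores.
#' @param groups group label per cell (cluster, timepoint, ...).
#' @param var_equal use the pooled-variance Student test (default); set
#'   `FALSE` for Welch.
#' @return data.frame with one row per pair: group means, t statistic,
#'   degrees of freedom, `p` and `stars`.
#' @export
compare_scores_by_group <- function(scores, groups, var_equal = TRUE) {
  if (length(scores) != length(groups)) {
    stopf("'scores' and 'groups' must have equal length")
  }
  groups <- as.character(groups)
  lv <- unique(groups)
  if (length(lv) < 2) stopf("need at least two groups")
  sizes <- table(groups)
  if (any(sizes < 2)) {
    stopf("group(s) with fewer than 2 cells: %s",
          paste(names(sizes)[sizes < 2], collapse = ", "))
  }
  pairs <- combn(lv, 2)
  res <- lapply(seq_len(ncol(pairs)), function(k) {
    a <- scores[groups == pairs[1, k]]
    b <- scores[groups == pairs[2, k]]
    if (sd(a) == 0 && sd(b) == 0) {
      stopf("groups '%s' and '%s' are both constant; t-test undefined",
            pairs[1, k], pairs[2, k])
    }
    tt <- t.test(a, b, var.equal = var_equal)
    data.frame(group1 = pairs[1, k], group2 = pairs[2, k],
               mean1 = mean(a), mean2 = mean(b),
               t = unname(tt$statistic), df = unname(tt$parameter),
               p = tt$p.value, stars = .p_stars(tt$p.value),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Cell-cycle scoring and phase assignment
#'
#' Tirosh-style module scores: genes are binned into `n_bins` bins of
#' dataset-average expression; for each phase set the score of a cell is
#' the mean expression of the set genes minus the mean of `n_ctrl` control
#' genes drawn (seeded) from the same bins. A cell is assigned G1 when both
#' scores are negative, otherwise the phase of the larger score (ties go to
#' S).
#'
#' @param x normalized matrix or SingleCellExperiment with `logcounts`.
#' @param gene_sets list with character vectors `s` and `g2m`
#'   (default the bundled Tirosh sets).
#' @param n_bins expression bins for control matching (default 24).
#' @param n_ctrl control genes per signature gene (default 100).
#' @param seed seed for the control draw, making scores reproducible.
#' @return data.frame with `cell`, `s_score`, `g2m_score` and `phase`
#'   (`G1`/`S`/`G2M`).
#' @export
cell_cycle_score <- function(x, gene_sets = cell_cycle_genes(),
                             n_bins = 24, n_ctrl = 100, seed = 1) {
  norm <- get_logcounts(x)
  sets <- list(s = intersect(gene_sets$s, rownames(norm)),
               g2m = intersect(gene_sets$g2m, rownames(norm)))
  for (nm in names(sets)) {
    if (length(sets[[nm]]) == 0) {
      stopf("no gene of the '%s' set is present in the matrix", nm)
    }
  }
  avg <- rowMeans(norm)
  n_bins <- min(n_bins, nrow(norm))
  bin <- ceiling(rank(avg, ties.method = "first") / (nrow(norm) / n_bins))
  by_bin <- split(rownames(norm), bin)

  score_set <- function(genes, sub_seed) {
    ctrl <- withr::with_seed(sub_seed, {
      unlist(lapply(genes, function(g) {
        pool <- by_bin[[as.character(bin[g])]]
        sample(pool, min(n_ctrl, length(pool)))
      }), use.names = FALSE)
    })
    colMeans(norm[genes, , drop = FALSE]) -
      colMeans(norm[ctrl, , drop = FALSE])
  }
  s_score <- score_set(sets$s, seed)
  g2m_score <- score_set(sets$g2m, seed + 1L)

  phase <- ifelse(s_score < 0 & g2m_score < 0, "G1",
                  ifelse(g2m_score > s_score, "G2M", "S"))
  data.frame(cell = colnames(norm), s_score = s_score,
             g2m_score = g2m_score, phase = phase,
             stringsAsFactors = FALSE, row.names = NULL)
}
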