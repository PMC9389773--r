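#' Variant allele frequency
#'
#' `alt / (alt + ref)`; zero-depth entries are returned as `NA` (missing),
#' never as 0.
#'
#' @param alt,ref non-negative read counts (vectorized).
#' @return numeric vector of VAFs in \[0, 1\] with `NA` at zero depth.
#' @export
compute_vaf <- function(alt, ref) {
  if (any(alt < 0, na.rm = TRUE) || any(ref < 0, na.rm = TRUE)) {
    stopf("read counts must be non-negative")
  }
  depth <- alt + ref
  ifelse(depth > 0, alt / depth, NA_real_)
}

#' Mutation detection rule
#'
#' A variant is called detected at a timepoint when it has at least
#' `min_alt` ALT reads and a VAF of at least `min_vaf` (both boundaries
#' inclusive).
#'
#' @param alt,ref read counts (vectorized).
#' @param min_alt minimum ALT reads (default 5).
#' @param min_vaf minimum VAF (default 0.05).
#' @return logical vector; `FALSE` at zero depth.
#' @export
detect_variant <- function(alt, ref, min_alt = 5, min_vaf = 0.05) {
  vaf <- compute_vaf(alt, ref)
  alt >= min_alt & !is.na(vaf) & vaf >= min_vaf
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Probability-ordering definition: the p-value is the sum of the
#' hypergeometric probabilities of all tables with the observed margins
#' whose probability does not exceed that of the observed table (up to the
#' customary 1e-7 relative slack against floating-point ties).
#'
#' @param tab 2x2 matrix of non-negative integers, rows = timepoints,
#'   columns = (ALT, REF).
#' @return p-value in (0, 1]. An all-zero table returns 1 with a warning.
#' @export
#' @examples
#' fisher_exact_2x2(matrix(c(1, 1, 9, 9), 2))   # identical rows -> 1
fisher_exact_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2, 2))) stopf("'tab' must be a 2x2 table")
  if (any(is.na(tab)) || any(tab < 0) || any(tab != floor(tab))) {
    stopf("'tab' must contain non-negative integers")
  }
  if (sum(tab) == 0) {
    warnf("all-zero 2x2 table; returning p = 1")
    return(1)
  }
  m <- sum(tab[1, ])          # row-1 total
  n2 <- sum(tab[2, ])         # row-2 total
  k <- sum(tab[, 1])          # column-1 total
  x <- tab[1, 1]
  support <- max(0, k - n2):min(k, m)
  d <- dhyper(support, m, n2, k)
  p <- sum(d[d <= d[support == x] * (1 + 1e-7)])
  min(1, p)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p p-values in \[0, 1\] (`NA` allowed and propagated).
#' @return q-values in input order, `q >= p` elementwise and monotone in p.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stopf("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Test variant-allele-frequency shifts between diagnosis and relapse
#'
#' Per variant, a two-sided Fisher's exact test on the 2x2 ALT/REF table of
#' the two timepoints, BH-adjusted across all tested variants of the pair
#' (the per-patient unit). Variants undetected at both timepoints carry no
#' information and are excluded from testing (kept in the output with
#' `tested = FALSE`). A variant is `reportable` when its larger VAF reaches
#' `report_vaf` and the raw Fisher p-value is below `alpha`.
#'
#' @param variants data.frame with columns `variant_id`, `ref_dx`,
#'   `alt_dx`, `ref_re`, `alt_re` (e.g. from [simulate_variants()] or
#'   [read_variants_tsv()]).
#' @param min_alt,min_vaf detection rule passed to [detect_variant()].
#' @param report_vaf minimum max(VAF Dx, VAF Re) for a reportable shift
#'   (default 0.2).
#' @param alpha significance level on the raw p-value (default 0.05).
#' @return data.frame with per-variant `vaf_dx`, `vaf_re`, detection flags,
#'   `tested`, `p`, `q`, `direction` (`Dx-enriched`/`Re-enriched`/`none`)
#'   and `reportable`.
#' @export
test_vaf_shifts <- function(variants, min_alt = 5, min_vaf = 0.05,
                            report_vaf = 0.2, alpha = 0.05) {
  need <- c("variant_id", "ref_dx", "alt_dx", "ref_re", "alt_re")
  miss <- setdiff(need, colnames(variants))
  if (length(miss)) stopf("'variants' lacks column(s): %s",
                          paste(miss, collapse = ", "))
  if (nrow(variants) == 0) stopf("'variants' must contain at least one variant")
  if (anyDuplicated(variants$variant_id)) {
    stopf("duplicate variant_id: '%s'",
          variants$variant_id[duplicated(variants$variant_id)][1])
  }
  depth <- with(variants, ref_dx + alt_dx + ref_re + alt_re)
  if (any(depth == 0)) {
    stopf("variant '%s' has zero depth at both timepoints",
          variants$variant_id[depth == 0][1])
  }

  out <- variants
  out$vaf_dx <- compute_vaf(variants$alt_dx, variants$ref_dx)
  out$vaf_re <- compute_vaf(variants$alt_re, variants$ref_re)
  out$detected_dx <- detect_variant(variants$alt_dx, variants$ref_dx,
                                    min_alt, min_vaf)
  out$detected_re <- detect_variant(variants$alt_re, variants$ref_re,
                                    min_alt, min_vaf)
  out$tested <- out$detected_dx | out$detected_re

  out$p <- NA_real_
  for (i in which(out$tested)) {
    out$p[i] <- fisher_exact_2x2(matrix(
      c(variants$alt_dx[i], variants$alt_re[i],
        variants$ref_dx[i], variants$ref_re[i]), 2, 2))
  }
  out$q <- NA_real_
  out$q[out$tested] <- bh_adjust(out$p[out$tested])

  max_vaf <- pmax(out$vaf_dx, out$vaf_re, na.rm = TRUE)
  out$reportable <- out$tested & !is.na(out$p) & out$p < alpha &
    max_vaf >= report_vaf
  out$direction <- ifelse(
    out$reportable,
    ifelse(ifelse(is.na(out$vaf_dx), 0, out$vaf_dx) >
             ifelse(is.na(out$vaf_re), 0, out$vaf_re),
           "Dx-enriched", "Re-enriched"),
    "none")
  out
}
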