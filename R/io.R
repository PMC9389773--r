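# Plain-text artifact I/O: MatrixMarket counts + TSV sidecars, in the
# 10x-like directory convention (matrix.mtx, genes.tsv, barcodes.tsv,
# cell_metadata.tsv). All writers are deterministic: fixed column order,
# no timestamps, tab separation, no quoting.

write_tsv <- function(df, path) {
  df <- as.data.frame(df)
  listcols <- vapply(df, is.list, logical(1))
  df <- df[, !listcols, drop = FALSE]
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a count experiment to a directory of plain-text files
#'
#' @param sce SingleCellExperiment with a `counts` assay.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_counts_dir <- function(sce, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Matrix::writeMM(methods::as(counts(sce), "generalMatrix"),
                  file.path(dir, "matrix.mtx"))
  write_tsv(gene_annotation(sce), file.path(dir, "genes.tsv"))
  writeLines(colnames(sce), file.path(dir, "barcodes.tsv"))
  write_tsv(as.data.frame(colData(sce)), file.path(dir, "cell_metadata.tsv"))
  invisible(dir)
}

#' Read a count experiment written by [write_counts_dir()]
#'
#' @param dir directory with `matrix.mtx`, `genes.tsv`, `barcodes.tsv` and
#'   optionally `cell_metadata.tsv`.
#' @return a SingleCellExperiment.
#' @export
read_counts_dir <- function(dir) {
  for (f in c("matrix.mtx", "genes.tsv", "barcodes.tsv")) {
    if (!file.exists(file.path(dir, f))) stopf("missing '%s' in %s", f, dir)
  }
  m <- methods::as(Matrix::readMM(file.path(dir, "matrix.mtx")), "CsparseMatrix")
  genes <- read.delim(file.path(dir, "genes.tsv"), stringsAsFactors = FALSE)
  barcodes <- readLines(file.path(dir, "barcodes.tsv"))
  if (nrow(genes) != nrow(m) || length(barcodes) != ncol(m)) {
    stopf("matrix dimensions (%d x %d) disagree with sidecar files",
          nrow(m), ncol(m))
  }
  rownames(m) <- genes$feature_id
  colnames(m) <- barcodes
  cd <- if (file.exists(file.path(dir, "cell_metadata.tsv"))) {
    DataFrame(read.delim(file.path(dir, "cell_metadata.tsv"),
                         stringsAsFactors = FALSE), row.names = barcodes)
  } else {
    DataFrame(cell_id = barcodes, row.names = barcodes)
  }
  placeholder <- is.na(genes$chrom)
  gr <- GRanges(
    seqnames = ifelse(placeholder, "spikein", genes$chrom),
    ranges = IRanges(start = ifelse(placeholder, 1, genes$start + 1),
                     end = ifelse(placeholder, 0, genes$end)),
    strand = if ("strand" %in% colnames(genes)) genes$strand else "*")
  names(gr) <- genes$feature_id
  gr$feature_id <- genes$feature_id
  if ("type" %in% colnames(genes)) gr$type <- genes$type
  SingleCellExperiment(assays = list(counts = m), rowRanges = gr,
                       colData = cd)
}

#' Read a Dx/Re variant table from TSV
#'
#' @param path TSV with columns `variant_id`, `ref_dx`, `alt_dx`,
#'   `ref_re`, `alt_re` (plus optional annotation columns).
#' @return data.frame suitable for [test_vaf_shifts()].
#' @export
read_variants_tsv <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("variant_id", "ref_dx", "alt_dx", "ref_re", "alt_re")
  miss <- setdiff(need, colnames(tab))
  if (length(miss)) stopf("variant TSV lacks column(s): %s",
                          paste(miss, collapse = ", "))
  tab
}

#' Read paired Dx/Re VCFs into a variant table
#'
#' Uses the AD FORMAT field of the first sample of each VCF (first value
#' REF depth, second the ALT depth) and matches variants by
#' chrom/pos/ref/alt. Requires the VariantAnnotation package.
#'
#' @param dx_vcf,re_vcf VCF paths (may be bgzipped).
#' @return data.frame suitable for [test_vaf_shifts()]; variants present
#'   in only one file get zero counts at the other timepoint.
#' @export
read_variants_vcf <- function(dx_vcf, re_vcf) {
  if (!requireNamespace("VariantAnnotation", quietly = TRUE)) {
    stopf("reading VCFs requires the VariantAnnotation package")
  }
  read_one <- function(path) {
    vcf <- VariantAnnotation::readVcf(path)
    ad <- VariantAnnotation::geno(vcf)$AD
    if (is.null(ad)) stopf("VCF '%s' has no AD FORMAT field", path)
    ad1 <- ad[, 1]
    rr <- SummarizedExperiment::rowRanges(vcf)
    data.frame(
      variant_id = names(rr),
      chrom = as.character(seqnames(rr)),
      pos = start(rr) - 1L,
      ref = vapply(ad1, function(v) as.numeric(v[1]), numeric(1)),
      alt = vapply(ad1, function(v) as.numeric(v[2]), numeric(1)),
      stringsAsFactors = FALSE, row.names = NULL)
  }
  dx <- read_one(dx_vcf)
  re <- read_one(re_vcf)
  merged <- merge(dx, re, by = c("variant_id", "chrom", "pos"),
                  all = TRUE, suffixes = c("_dx", "_re"))
  merged$ref_dx[is.na(merged$ref_dx)] <- 0
  merged$alt_dx[is.na(merged$alt_dx)] <- 0
  merged$ref_re[is.na(merged$ref_re)] <- 0
  merged$alt_re[is.na(merged$alt_re)] <- 0
  merged
}

#' Read per-cell allele counts from TSV
#'
#' @param path TSV with columns `cell`, `snp_id`, `chrom`, `pos`,
#'   `ref_count`, `alt_count`.
#' @return data.frame suitable for [baf_confirm()].
#' @export
read_allele_counts_tsv <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("cell", "snp_id", "chrom", "pos", "ref_count", "alt_count")
  miss <- setdiff(need, colnames(tab))
  if (length(miss)) stopf("allele-count TSV lacks column(s): %s",
                          paste(miss, collapse = ", "))
  tab
}

#' Write segment calls as BED
#'
#' Six-column BED (0-based, half-open): name is `<state>_<n>`; score is the
#' mean segment signal; strand is ".".
#'
#' @param segments data.frame from [call_segments()].
#' @param path output path.
#' @export
write_segments_bed <- function(segments, path) {
  bed <- data.frame(
    chrom = segments$chrom,
    start = format(segments$start, scientific = FALSE, trim = TRUE),
    end = format(segments$end, scientific = FALSE, trim = TRUE),
    name = paste0(segments$state, "_", seq_len(max(1, nrow(segments)))[seq_len(nrow(segments))]),
    score = round(segments$mean_signal, 4),
    strand = rep(".", nrow(segments)),
    stringsAsFactors = FALSE)
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
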