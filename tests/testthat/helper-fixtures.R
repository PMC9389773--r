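# Small, fast generator configurations for unit tests. Two 45 Mb
# chromosomes keep every 3 Mb tile above the iCNV gene minimum even with
# few genes.
small_config <- function(...) {
  defaults <- list(
    n_genes = 400, n_cells_dx = 60, n_cells_re = 60,
    n_chromosomes = 2, chrom_length_bp = 45e6,
    mean_depth_umi = 2000, n_clusters = 2, marker_genes_per_cluster = 10,
    cnv_events = list(), variant_specs = default_variant_specs(),
    lowq_cell_fraction = 0, n_het_snps = 60, seed = 42)
  dots <- list(...)
  defaults[names(dots)] <- dots   # wholesale replacement, no recursive merge
  do.call(sim_config, defaults)
}

# Hand-built 10-cell QC fixture with one cell violating each rule, one
# cell sitting exactly on each boundary, and two clean cells.
# 600 genes named G0001.., 2 mito, 2 ERCC features.
qc_fixture <- function() {
  genes <- sprintf("G%04d", 1:600)
  feats <- c(genes, "MT-A", "MT-B", "ERCC-1", "ERCC-2")
  cells <- c("fail_genes", "fail_umi", "fail_mito", "fail_ercc",
             "edge_genes", "edge_umi", "edge_mito", "edge_ercc",
             "clean_1", "clean_2")
  m <- matrix(0L, length(feats), length(cells),
              dimnames = list(feats, cells))
  fill <- function(cell, n_genes, gene_umi, mito, ercc) {
    m[genes[seq_len(n_genes)], cell] <<- gene_umi
    m["MT-A", cell] <<- mito
    m["ERCC-1", cell] <<- ercc
  }
  # n_genes counts mito features too (non-ERCC detected); keep mito > 0
  # everywhere so detected genes = n + 1
  fill("fail_genes", 399, 5, 10, 1)            # 400 detected < 500
  fill("fail_umi", 599, 20, 21, 1)             # 11,980 + 21 = 12,001 UMIs
  fill("fail_mito", 550, 4, 990, 1)            # mito 990/3190 = 0.3103 > 0.30
  fill("fail_ercc", 550, 4, 10, 588)           # ercc 588/2798 = 0.2101 > 0.20
  fill("edge_genes", 499, 5, 10, 1)            # exactly 500 detected
  fill("edge_umi", 599, 20, 20, 1)             # exactly 12,000 UMIs
  fill("edge_mito", 550, 4, 943, 1)            # 943/3143 = 0.300031... hmm
  fill("edge_ercc", 550, 4, 10, 552)           # tuned below
  fill("clean_1", 550, 5, 50, 30)
  fill("clean_2", 520, 6, 60, 20)
  # exact boundary fractions: mito = 0.30 of non-ERCC, ercc = 0.20 of all
  m["MT-A", "edge_mito"] <- 0L
  m[genes[1:550], "edge_mito"] <- 7L                  # 3,850 gene UMIs
  m["MT-A", "edge_mito"] <- 1650L                     # 1650/5500 = 0.30
  m["ERCC-1", "edge_ercc"] <- 0L
  m[genes[1:550], "edge_ercc"] <- 4L                  # 2,200
  m["MT-A", "edge_ercc"] <- 200L                      # non-ERCC = 2,400
  m["ERCC-1", "edge_ercc"] <- 600L                    # 600/3000 = 0.20
  m
}
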