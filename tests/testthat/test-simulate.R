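test_that("identical configs give bit-identical output across all simulators", {
  cfg <- small_config(lowq_cell_fraction = 0.1, seed = 7,
                      cnv_events = list(cnv_event("chr2", 10e6, 25e6, 1.5)))
  a <- simulate_counts(cfg)
  b <- simulate_counts(cfg)
  expect_identical(as.matrix(counts(a)), as.matrix(counts(b)))
  expect_identical(as.data.frame(colData(a)), as.data.frame(colData(b)))
  expect_identical(simulate_variants(cfg), simulate_variants(cfg))
  expect_identical(simulate_allele_counts(cfg, a),
                   simulate_allele_counts(cfg, b))
  # different seed changes the draw
  c2 <- simulate_counts(small_config(lowq_cell_fraction = 0.1, seed = 8))
  expect_false(identical(as.matrix(counts(a)), as.matrix(counts(c2))))
})

test_that("per-cell totals decompose into gene, mito and spike-in counts", {
  sce <- simulate_counts(small_config())
  type <- SummarizedExperiment::rowData(sce)$type
  cnt <- counts(sce)
  expect_equal(
    Matrix::colSums(cnt),
    Matrix::colSums(cnt[type == "gene", ]) +
      Matrix::colSums(cnt[type == "mito", ]) +
      Matrix::colSums(cnt[type == "ercc", ]))
  expect_setequal(unique(type), c("gene", "mito", "ercc"))
  expect_true(all(grepl("^MT-", rownames(sce)[type == "mito"])))
  expect_true(all(grepl("^ERCC-", rownames(sce)[type == "ercc"])))
})

test_that("config invariants are enforced with the offending field named", {
  expect_error(sim_config(lowq_cell_fraction = 1.2), "lowq_cell_fraction")
  expect_error(sim_config(n_genes = -5), "n_genes")
  expect_error(sim_config(nb_dispersion = 0), "nb_dispersion")
  expect_error(cnv_event("chr1", 5e6, 4e6), "end")
  expect_error(cnv_event("chr1", 0, 1e6, copy_ratio = -1), "copy_ratio")
  expect_error(cnv_event("chr1", 0, 1e6, copy_ratio = 1.5, loh = TRUE), "LOH")
  expect_error(variant_spec("v", 1.2, 0.5), "vaf_dx")
  # overlapping events on one chromosome at a shared timepoint
  expect_error(sim_config(cnv_events = list(
    cnv_event("chr2", 10e6, 40e6, 1.5, "Re"),
    cnv_event("chr2", 30e6, 60e6, 0.5, "Re"))), "overlap")
  # same interval at disjoint timepoints is legal
  expect_s3_class(sim_config(cnv_events = list(
    cnv_event("chr2", 10e6, 40e6, 1.5, "Re"),
    cnv_event("chr2", 10e6, 40e6, 0.5, "Dx"))), "sim_config")
  expect_error(sim_config(variant_specs = list(
    variant_spec("v1", 0.5, 0.5), variant_spec("v1", 0.2, 0.2))),
    "duplicate")
  expect_error(sim_config(cnv_events = list(
    cnv_event("chr9", 0, 1e6, 1.5))), "chromosome")
})

test_that("a clonal relapse gain multiplies event-gene UMIs by its copy ratio", {
  cfg <- sim_config(n_cells_dx = 200, n_cells_re = 200,
                    lowq_cell_fraction = 0,
                    cnv_events = list(cnv_event("chr2", 30e6, 60e6,
                                                copy_ratio = 1.5,
                                                timepoint = "Re",
                                                cell_fraction = 1)),
                    seed = 31)
  sce <- simulate_counts(cfg)
  ann <- gene_annotation(sce)
  mid <- (ann$start + ann$end) / 2
  ev <- !is.na(ann$chrom) & ann$chrom == "chr2" & mid >= 30e6 & mid < 60e6
  u <- Matrix::colSums(counts(sce)[ann$feature_id[ev], ])
  re <- sce$timepoint == "Re"
  ratio <- mean(u[re]) / mean(u[!re])
  # delta-method SEM of the ratio of two Monte-Carlo means
  sem <- ratio * sqrt(sd(u[re])^2 / sum(re) / mean(u[re])^2 +
                        sd(u[!re])^2 / sum(!re) / mean(u[!re])^2)
  expect_lt(abs(ratio - 1.5), 3 * sem)
  # carriers recorded for every Re cell
  expect_true(all(colData(sce)[[metadata(sce)$ground_truth$cnv_events$carrier_col]][re]))
})

test_that("every cell passes the default QC filter when no failures are planted", {
  sce <- simulate_counts(sim_config(n_cells_dx = 100, n_cells_re = 100,
                                    lowq_cell_fraction = 0, seed = 5))
  expect_true(all(compute_qc_metrics(sce)$pass))
})

test_that("WES variant depths follow the planted allele fractions", {
  cfg <- small_config(
    variant_specs = list(variant_spec("stable", 0.5, 0.5),
                         variant_spec("lost", 0.35, 0)),
    wes_depth_mean = 10000, seed = 12)
  v <- simulate_variants(cfg)
  # binomial SE at depth 10,000 is 0.005; 0.02 is a 4-sigma band
  expect_lt(abs(compute_vaf(v$alt_dx[1], v$ref_dx[1]) - 0.5), 0.02)
  expect_lt(abs(compute_vaf(v$alt_re[1], v$ref_re[1]) - 0.5), 0.02)
  expect_identical(v$alt_re[2], 0L)
  expect_error(simulate_variants(small_config(variant_specs = list())),
               "non-empty")
})

test_that("allele fractions at heterozygous SNPs reflect planted copy states", {
  cfg <- small_config(
    n_cells_dx = 150, n_cells_re = 150, n_het_snps = 120,
    snp_read_rate = 1,
    cnv_events = list(cnv_event("chr1", 5e6, 20e6, 0.5, "Re"),
                      cnv_event("chr2", 5e6, 20e6, 1.5, "Re")),
    seed = 9)
  sce <- simulate_counts(cfg)
  ac <- simulate_allele_counts(cfg, sce)
  re <- colnames(sce)[sce$timepoint == "Re"]
  dx <- colnames(sce)[sce$timepoint == "Dx"]

  pool_f <- function(chrom, lo, hi, cells) {
    sub <- ac[ac$chrom == chrom & ac$pos >= lo & ac$pos < hi &
                ac$cell %in% cells, ]
    agg <- rowsum(cbind(sub$alt_count, sub$ref_count), sub$snp_id)
    agg <- agg[rowSums(agg) >= 50, , drop = FALSE]
    agg[, 1] / rowSums(agg)
  }
  # diploid region: pooled alt fraction ~ 0.5 per SNP
  f_dip <- pool_f("chr1", 25e6, 45e6, c(dx, re))
  expect_true(all(abs(f_dip - 0.5) < 0.15))
  # loss carriers: one haplotype gone, f -> 0 or 1
  f_loss <- pool_f("chr1", 5e6, 20e6, re)
  expect_true(all(pmin(f_loss, 1 - f_loss) < 0.05))
  # gain carriers: f -> 1/3 or 2/3 within pooled binomial error
  f_gain <- pool_f("chr2", 5e6, 20e6, re)
  expect_true(all(abs(abs(f_gain - 0.5) - 1 / 6) < 0.1))
  expect_gt(length(f_gain), 2)
})
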