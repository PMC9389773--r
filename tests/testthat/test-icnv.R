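toy_annotation <- function() {
  data.frame(
    feature_id = c("g1", "g2", "g3", "g4"),
    chrom = "chr1",
    start = c(2999000, 2999500, 5e6, 9.4e6),
    end = c(3000998, 3001500, 5.01e6, 9.42e6),
    stringsAsFactors = FALSE)
}

test_that("genes map to 3 Mb tiles by midpoint with half-open bounds", {
  ann <- toy_annotation()
  # midpoints: 2,999,999 | 3,000,500 | 5,005,000 | 9,410,000
  ti <- build_tiles(ann, chrom_lengths = c(chr1 = 10e6))
  expect_equal(width(ti$tiles), c(3e6, 3e6, 3e6, 1e6))
  expect_equal(unname(ti$gene_tile), c(1L, 2L, 2L, 4L))
  expect_error(build_tiles(ann, chrom_lengths = c(chr1 = 9e6)), "beyond")
  expect_error(build_tiles(ann[, 1:2]), "lacks column")
})

test_that("reference cells center at zero and the signal is depth invariant", {
  cfg <- small_config(n_cells_dx = 80, n_cells_re = 80, seed = 3)
  sce <- normalize_counts(simulate_counts(cfg))
  tiles <- build_tiles(gene_annotation(sce),
                       chrom_lengths = metadata(sce)$ground_truth$chrom_lengths)
  dx <- colnames(sce)[sce$timepoint == "Dx"]
  tm <- icnv_signal(sce, tiles, reference_cells = dx)
  # per-tile reference means scatter around zero with SE ~ sd/sqrt(cells)
  ref_means <- rowMeans(tm$raw[, dx])
  ref_se <- apply(tm$raw[, dx], 1, sd) / sqrt(length(dx))
  expect_lt(mean(abs(ref_means)), 0.03)
  expect_true(all(abs(ref_means) < 5 * ref_se))
  expect_true(all(abs(tm$signal) <= tm$params$clip + 1e-12))

  # rescaling a cell's library leaves its per-tile fractions, and hence its
  # signal, unchanged up to the pseudocount (log-space shift invariance)
  m <- as.matrix(counts(sce))
  m[, 1] <- m[, 1] * 5
  tm2 <- icnv_signal(m, tiles, reference_cells = dx)
  expect_lt(max(abs(tm2$raw[, 1] - tm$raw[, 1])), 0.05)
  expect_equal(icnv_signal(m, tiles, dx, pseudocount = 1e-6)$raw[, 1],
               icnv_signal(as.matrix(counts(sce)), tiles, dx,
                           pseudocount = 1e-6)$raw[, 1],
               tolerance = 1e-4)
  expect_error(icnv_signal(sce, tiles, reference_cells = character(0)),
               "reference_cells")
})

test_that("swapping target and reference mirrors the planted segment signal", {
  # the event spans ~10% of the toy genome: per-cell median centering
  # assumes CNVs affect a genomic minority
  cfg <- small_config(n_cells_dx = 100, n_cells_re = 100,
                      cnv_events = list(cnv_event("chr2", 9e6, 18e6, 1.5, "Re")),
                      seed = 21)
  sce <- normalize_counts(simulate_counts(cfg))
  tiles <- build_tiles(gene_annotation(sce),
                       chrom_lengths = metadata(sce)$ground_truth$chrom_lengths)
  dx <- colnames(sce)[sce$timepoint == "Dx"]
  re <- colnames(sce)[sce$timepoint == "Re"]
  fwd <- call_segments(icnv_signal(sce, tiles, dx), re)
  rev <- call_segments(icnv_signal(sce, tiles, re), dx)
  expect_equal(fwd$state, "gain")
  expect_equal(rev$state, "loss")   # Dx scanned against Re looks like a loss
  expect_equal(fwd$chrom, rev$chrom)
  expect_lt(abs(fwd$mean_signal + rev$mean_signal), 0.1)
})

test_that("segment calling needs real signal and valid thresholds", {
  cfg <- small_config(n_cells_dx = 80, n_cells_re = 80, seed = 13)
  sce <- normalize_counts(simulate_counts(cfg))
  tiles <- build_tiles(gene_annotation(sce),
                       chrom_lengths = metadata(sce)$ground_truth$chrom_lengths)
  dx <- colnames(sce)[sce$timepoint == "Dx"]
  re <- colnames(sce)[sce$timepoint == "Re"]
  tm <- icnv_signal(sce, tiles, dx)
  expect_equal(nrow(call_segments(tm, re)), 0L)   # no planted event
  expect_error(call_segments(tm, re, gain_thr = -0.2, loss_thr = 0.2),
               "gain_thr")
})

test_that("folded BAF deviation separates planted LOH from diploid noise", {
  # hand-built allele counts: 5 SNPs inside a segment, 50 cells per group
  withr::with_seed(8, {
    cells <- c(paste0("t", 1:50), paste0("r", 1:50))
    snps <- data.frame(snp_id = paste0("s", 1:5), chrom = "chr1",
                       pos = seq(1e6, 5e6, by = 1e6))
    rows <- expand.grid(cell = cells, snp_id = snps$snp_id,
                        stringsAsFactors = FALSE)
    rows <- merge(rows, snps, by = "snp_id")
    reads <- rpois(nrow(rows), 2)
    hap <- setNames(sample(0:1, 5, replace = TRUE), snps$snp_id)
    f <- ifelse(grepl("^t", rows$cell), hap[rows$snp_id], 0.5)
    alt <- rbinom(nrow(rows), reads, f)
    ac <- data.frame(rows, ref_count = reads - alt, alt_count = alt)

    seg <- data.frame(chrom = "chr1", start = 0, end = 6e6)
    b <- baf_confirm(ac, seg, target_cells = paste0("t", 1:50),
                     reference_cells = paste0("r", 1:50))
    expect_equal(b$status, "confirmed")
    expect_gt(b$target_deviation, 0.45)
    expect_lt(b$reference_deviation, 0.15)

    # folding makes the statistic invariant to haplotype phase
    flipped <- ac
    flipped$ref_count <- ac$alt_count
    flipped$alt_count <- ac$ref_count
    b2 <- baf_confirm(flipped, seg, paste0("t", 1:50), paste0("r", 1:50))
    expect_equal(b2$target_deviation, b$target_deviation)

    # too few covered SNPs: unconfirmable, not "not confirmed"
    b3 <- baf_confirm(ac[ac$snp_id %in% c("s1", "s2"), ], seg,
                      paste0("t", 1:50), paste0("r", 1:50))
    expect_equal(b3$status, "unconfirmable")
    expect_true(is.na(b3$confirmed))
  })
})

test_that("DEGs are attributed to segments by midpoint with direction checks", {
  ann <- data.frame(
    feature_id = c("up_in", "down_in", "up_out", "lost"),
    chrom = c("chr1", "chr1", "chr2", "chr1"),
    start = c(1e6, 2e6, 1e6, 8e6),
    end = c(1.01e6, 2.01e6, 1.01e6, 8.01e6), stringsAsFactors = FALSE)
  markers <- data.frame(
    gene = c("up_in", "down_in", "up_out", "missing_gene"),
    group = "Re", log2fc = c(1, -1, 1, 2), q = rep(0.001, 4),
    significant = TRUE, stringsAsFactors = FALSE)
  segs <- data.frame(chrom = "chr1", start = 0, end = 3e6, state = "gain",
                     stringsAsFactors = FALSE)
  expect_warning(res <- degs_in_segments(markers, segs, ann), "coordinates")
  expect_equal(res$n_degs, 2L)
  expect_equal(res$n_consistent, 1L)        # only the up-regulated DEG
  expect_setequal(res$genes[[1]], c("up_in", "down_in"))
  expect_equal(nrow(degs_in_segments(markers, segs[0, ], ann)), 0L)
})
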