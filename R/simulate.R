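# Canonical plate-based QC envelope the generator respects for clean cells.
# Clean cells are constructed to satisfy the default filter of qc_filter();
# deliberately failing cells are pushed well past one gate each.
.qc_envelope <- list(min_genes = 500, max_umi = 12000,
                     max_mito = 0.30, max_ercc = 0.20)

.mito_gene_names <- c("MT-ND1", "MT-ND2", "MT-CO1", "MT-CO2", "MT-ATP8",
                      "MT-ATP6", "MT-CO3", "MT-ND3", "MT-ND4L", "MT-ND4",
                      "MT-ND5", "MT-ND6", "MT-CYB")

# Quasi-uniform placement: stratified midpoints give every 3 Mb tile an
# approximately equal gene count, so no tile drops below the iCNV minimum.
.stratified_positions <- function(n, len) {
  if (n == 0) return(numeric(0))
  (seq_len(n) - runif(n)) / n * len
}

#' Simulate a paired Dx/Re UMI count experiment with planted ground truth
#'
#' Draws gene-wise negative-binomial UMI counts whose per-cell expected total
#' is `mean_depth_umi`, then plants the structures every downstream stage
#' must recover: expression clusters with exclusive marker genes
#' (up-shifted by `2^marker_logfc`), multi-megabase CNVs acting
#' multiplicatively on expected expression (copy-neutral LOH leaves
#' expression untouched), an LSC-like subpopulation with a 2x up-shift of
#' the positively weighted LSC17 genes, cell-cycle phases with a 4x up-shift
#' of the Tirosh S or G2M sets, and a configurable fraction of cells built
#' to fail exactly one QC gate. Mitochondrial genes (`MT-` prefix) and ERCC
#' spike-ins (`ERCC-` prefix) are included at the configured fractions.
#'
#' @param config a [sim_config()].
#' @return a [SingleCellExperiment::SingleCellExperiment] with a sparse
#'   `counts` assay; `rowData` carries `chrom`, `start`, `end` (0-based,
#'   half-open), `strand` and `type` (gene/mito/ercc); `colData` carries
#'   `sample`, `timepoint`, `cluster`, `lsc`, `phase`, `lowq_mode`,
#'   `qc_clean` and one logical carrier column per CNV event;
#'   `metadata(sce)$ground_truth` holds the planted marker table, CNV event
#'   table and the config.
#' @seealso [simulate_variants()], [simulate_allele_counts()]
#' @export
simulate_counts <- function(config) {
  if (!inherits(config, "sim_config")) stopf("'config' must be a sim_config")
  withr::with_seed(config$seed, .simulate_counts_impl(config))
}

.simulate_counts_impl <- function(cfg) {
  n_genes <- cfg$n_genes
  n_cells <- cfg$n_cells_dx + cfg$n_cells_re

  ## ---- gene annotation -------------------------------------------------
  lsc <- lsc17_signature()
  cc <- cell_cycle_genes()
  named_genes <- unique(c(names(lsc), cc$s, cc$g2m))
  gene_ids <- c(named_genes,
                sprintf("GENE%05d", seq_len(n_genes - length(named_genes))))
  # shuffle so signature genes land anywhere on the genome
  gene_ids <- sample(gene_ids)

  n_per_chrom <- diff(round(c(0, cumsum(cfg$chrom_length_bp)) /
                              sum(cfg$chrom_length_bp) * n_genes))
  gene_chrom <- rep(cfg$chroms, n_per_chrom)
  mids <- unlist(lapply(seq_len(cfg$n_chromosomes), function(i) {
    .stratified_positions(n_per_chrom[i], cfg$chrom_length_bp[i])
  }), use.names = FALSE)
  gene_start <- pmax(0, round(mids) - 5000)
  gene_end <- pmin(rep(cfg$chrom_length_bp, n_per_chrom), gene_start + 10000)
  gene_strand <- sample(c("+", "-"), n_genes, replace = TRUE)

  ## ---- relative abundance ----------------------------------------------
  abund <- rlnorm(n_genes, 0, 1)
  # curated signature genes and planted markers are reliably expressed
  # transcripts in this cell type; draw them from the upper abundance half
  special <- gene_ids %in% named_genes
  abund[special] <- exp(abs(rnorm(sum(special), 0, 1)))

  generic_idx <- which(!special)
  marker_idx <- sample(generic_idx, cfg$n_clusters * cfg$marker_genes_per_cluster)
  abund[marker_idx] <- exp(abs(rnorm(length(marker_idx), 0, 1)))
  marker_cluster <- rep(seq_len(cfg$n_clusters),
                        each = cfg$marker_genes_per_cluster)

  gene_rel <- abund / sum(abund)
  mito_rel <- rlnorm(length(.mito_gene_names), 0, 0.5)
  mito_rel <- mito_rel / sum(mito_rel)
  n_ercc <- 92
  ercc_ids <- sprintf("ERCC-%05d", seq_len(n_ercc))
  ercc_rel <- rlnorm(n_ercc, 0, 1)
  ercc_rel <- ercc_rel / sum(ercc_rel)

  ## ---- cell-level structure --------------------------------------------
  timepoint <- rep(c("Dx", "Re"), c(cfg$n_cells_dx, cfg$n_cells_re))
  cell_ids <- sprintf("%s_cell%04d", timepoint,
                      c(seq_len(cfg$n_cells_dx), seq_len(cfg$n_cells_re)))
  # cluster/LSC/phase labels are stratified within each timepoint so the
  # planted subpopulation mix is identical at Dx and Re; this keeps the
  # planted structures orthogonal to the Dx/Re contrast (a timepoint-pure
  # contrast should only see the planted CNVs)
  cluster <- integer(n_cells)
  lsc_flag <- logical(n_cells)
  phase <- character(n_cells)
  for (tp in c("Dx", "Re")) {
    i <- which(timepoint == tp)
    cluster[i] <- sample(rep_len(seq_len(cfg$n_clusters), length(i)))
    lsc_flag[i][sample(length(i), round(cfg$lsc_fraction * length(i)))] <- TRUE
    n_phase <- round(cfg$phase_props * length(i))
    n_phase["G1"] <- length(i) - sum(n_phase[c("S", "G2M")])
    phase[i] <- sample(rep(names(n_phase), n_phase))
  }

  lowq_mode <- rep("none", n_cells)
  n_lowq <- round(cfg$lowq_cell_fraction * n_cells)
  if (n_lowq > 0) {
    modes <- rep_len(c("low_genes", "high_umi", "high_mito", "high_ercc"), n_lowq)
    lowq_mode[sample(n_cells, n_lowq)] <- modes
  }

  # depth and contamination fractions; clean cells are clipped inside the
  # canonical QC envelope so the planted clean set passes the filter exactly
  depth <- cfg$mean_depth_umi * rlnorm(n_cells, -0.02, 0.2)
  mito_frac <- pmin(cfg$mito_fraction_mean * rlnorm(n_cells, -0.031, 0.25),
                    0.8 * .qc_envelope$max_mito)
  ercc_frac <- pmin(cfg$ercc_fraction_mean * rlnorm(n_cells, -0.031, 0.25),
                    0.8 * .qc_envelope$max_ercc)
  depth <- pmin(depth, 0.8 * .qc_envelope$max_umi)

  depth[lowq_mode == "low_genes"] <- pmin(depth[lowq_mode == "low_genes"],
                                          0.3 * .qc_envelope$min_genes)
  depth[lowq_mode == "high_umi"] <- 1.8 * .qc_envelope$max_umi
  # contamination set 2x past its gate: the realized fraction of a
  # negative-binomial draw over few mito genes has sd ~ 0.05-0.09, so the
  # planted failure must clear the gate by several sigma
  mito_frac[lowq_mode == "high_mito"] <- 2 * .qc_envelope$max_mito
  ercc_frac[lowq_mode == "high_ercc"] <- 2 * .qc_envelope$max_ercc

  ## ---- expected expression ----------------------------------------------
  # multipliers act on expected expression and are NOT renormalized, so a
  # copy-number gain increases the carrying cell's expected library size
  mult <- matrix(1, n_genes, n_cells)
  for (k in seq_len(cfg$n_clusters)) {
    rows <- marker_idx[marker_cluster == k]
    mult[rows, cluster == k] <- mult[rows, cluster == k] * 2^cfg$marker_logfc
  }
  lsc_pos <- which(gene_ids %in% names(lsc)[lsc > 0])
  mult[lsc_pos, lsc_flag] <- mult[lsc_pos, lsc_flag] * 2
  s_rows <- which(gene_ids %in% cc$s)
  g2m_rows <- which(gene_ids %in% cc$g2m)
  mult[s_rows, phase == "S"] <- mult[s_rows, phase == "S"] * 4
  mult[g2m_rows, phase == "G2M"] <- mult[g2m_rows, phase == "G2M"] * 4

  carrier <- matrix(FALSE, n_cells, length(cfg$cnv_events))
  ev_rows <- list()
  for (i in seq_along(cfg$cnv_events)) {
    ev <- cfg$cnv_events[[i]]
    tp_cells <- if (ev$timepoint == "both") seq_len(n_cells)
      else which(timepoint == ev$timepoint)
    n_carry <- round(ev$cell_fraction * length(tp_cells))
    carry <- if (n_carry >= length(tp_cells)) tp_cells
      else sort(sample(tp_cells, n_carry))
    carrier[carry, i] <- TRUE
    rows <- which(gene_chrom == ev$chrom & mids >= ev$start & mids < ev$end)
    ev_rows[[i]] <- rows
    if (!ev$loh && ev$copy_ratio != 1 && length(rows) && length(carry)) {
      mult[rows, carry] <- mult[rows, carry] * ev$copy_ratio
    }
  }

  mu_gene <- sweep(gene_rel * mult, 2, depth * (1 - mito_frac), `*`)
  mu_mito <- outer(mito_rel, depth * mito_frac)
  mu_ercc <- outer(ercc_rel, depth * ercc_frac / (1 - ercc_frac))

  size <- 1 / cfg$nb_dispersion
  draw <- function(mu) {
    matrix(rnbinom(length(mu), mu = mu, size = size), nrow = nrow(mu))
  }
  counts <- rbind(draw(mu_gene), draw(mu_mito), draw(mu_ercc))
  rownames(counts) <- c(gene_ids, .mito_gene_names, ercc_ids)
  colnames(counts) <- cell_ids

  ## ---- assemble ----------------------------------------------------------
  # genomic coordinates are carried as rowRanges (1-based internally,
  # 0-based half-open via gene_annotation()); spike-ins sit zero-width on
  # the placeholder seqname "spikein"
  mito_start <- round(seq(0, 15000, length.out = length(.mito_gene_names)))
  row_gr <- GRanges(
    seqnames = c(gene_chrom, rep("chrM", length(.mito_gene_names)),
                 rep("spikein", n_ercc)),
    ranges = IRanges(
      start = c(gene_start + 1, mito_start + 1, rep(1, n_ercc)),
      end = c(gene_end, mito_start + 1000, rep(0, n_ercc))),
    strand = c(gene_strand, rep("+", length(.mito_gene_names)),
               rep("*", n_ercc)))
  names(row_gr) <- rownames(counts)
  row_gr$feature_id <- rownames(counts)
  row_gr$type <- rep(c("gene", "mito", "ercc"),
                     c(n_genes, length(.mito_gene_names), n_ercc))

  coldat <- DataFrame(
    cell_id = cell_ids,
    sample = paste0("P1_", timepoint),
    timepoint = timepoint,
    cluster = factor(cluster),
    lsc = lsc_flag,
    phase = phase,
    lowq_mode = lowq_mode,
    qc_clean = lowq_mode == "none",
    row.names = cell_ids)
  ev_ids <- vapply(cfg$cnv_events, `[[`, character(1), "id")
  for (i in seq_along(cfg$cnv_events)) {
    coldat[[paste0("carrier_", ev_ids[i])]] <- carrier[, i]
  }

  truth <- list(
    markers = data.frame(gene = gene_ids[marker_idx],
                         cluster = marker_cluster,
                         log2fc = rep(cfg$marker_logfc, length(marker_idx)),
                         stringsAsFactors = FALSE),
    cnv_events = if (length(cfg$cnv_events) == 0) {
      data.frame(id = character(), chrom = character(), start = numeric(),
                 end = numeric(), copy_ratio = numeric(),
                 timepoint = character(), cell_fraction = numeric(),
                 loh = logical(), n_genes = integer(),
                 carrier_col = character(), stringsAsFactors = FALSE)
    } else data.frame(
      id = ev_ids,
      chrom = vapply(cfg$cnv_events, `[[`, character(1), "chrom"),
      start = vapply(cfg$cnv_events, `[[`, numeric(1), "start"),
      end = vapply(cfg$cnv_events, `[[`, numeric(1), "end"),
      copy_ratio = vapply(cfg$cnv_events, `[[`, numeric(1), "copy_ratio"),
      timepoint = vapply(cfg$cnv_events, `[[`, character(1), "timepoint"),
      cell_fraction = vapply(cfg$cnv_events, `[[`, numeric(1), "cell_fraction"),
      loh = vapply(cfg$cnv_events, `[[`, logical(1), "loh"),
      n_genes = lengths(ev_rows),
      carrier_col = paste0("carrier_", ev_ids),
      stringsAsFactors = FALSE),
    chrom_lengths = setNames(cfg$chrom_length_bp, cfg$chroms))

  sce <- SingleCellExperiment(
    assays = list(counts = methods::as(counts, "CsparseMatrix")),
    rowRanges = row_gr, colData = coldat)
  metadata(sce)$ground_truth <- truth
  metadata(sce)$config <- cfg
  sce
}

#' Simulate WES-like allelic depths for the planted variant panel
#'
#' Per variant and timepoint, total depth is Poisson(`wes_depth_mean`) and
#' the ALT count binomial with the planted true VAF.
#'
#' @param config a [sim_config()] with non-empty `variant_specs`.
#' @return data.frame with one row per variant: `variant_id`, `chrom`,
#'   `pos`, `gene`, `ref_dx`, `alt_dx`, `ref_re`, `alt_re` and the planted
#'   `true_vaf_dx`, `true_vaf_re`.
#' @export
simulate_variants <- function(config) {
  if (!inherits(config, "sim_config")) stopf("'config' must be a sim_config")
  specs <- config$variant_specs
  if (length(specs) == 0) stopf("'variant_specs' must be non-empty")
  withr::with_seed(config$seed + 1L, {
    n <- length(specs)
    depth_dx <- rpois(n, config$wes_depth_mean)
    depth_re <- rpois(n, config$wes_depth_mean)
    vaf_dx <- vapply(specs, `[[`, numeric(1), "vaf_dx")
    vaf_re <- vapply(specs, `[[`, numeric(1), "vaf_re")
    alt_dx <- rbinom(n, depth_dx, vaf_dx)
    alt_re <- rbinom(n, depth_re, vaf_re)
    data.frame(
      variant_id = vapply(specs, `[[`, character(1), "id"),
      chrom = vapply(specs, `[[`, character(1), "chrom"),
      pos = vapply(specs, `[[`, numeric(1), "pos"),
      gene = vapply(specs, `[[`, character(1), "gene"),
      ref_dx = depth_dx - alt_dx, alt_dx = alt_dx,
      ref_re = depth_re - alt_re, alt_re = alt_re,
      true_vaf_dx = vaf_dx, true_vaf_re = vaf_re,
      stringsAsFactors = FALSE)
  })
}

#' Simulate per-cell allele counts at heterozygous germline SNPs
#'
#' SNPs are placed quasi-uniformly across the synthetic genome. Per cell and
#' SNP, total reads are Poisson with mean `snp_read_rate` (scaled by the
#' local copy ratio in CNV carriers) and ALT reads binomial with allele
#' fraction f: 0.5 in diploid cells; 0 or 1 (haplotype fixed per SNP per
#' event) in single-copy-loss or copy-neutral-LOH carriers; 1/3 or 2/3 in
#' single-copy-gain carriers. Haplotype phase is random per SNP, so
#' downstream summaries fold the deviation as |f - 0.5|.
#'
#' @param config a [sim_config()].
#' @param sce the matching output of [simulate_counts()] (provides carrier
#'   cells and the genome).
#' @return data.frame in long format (`cell`, `snp_id`, `chrom`, `pos`,
#'   `ref_count`, `alt_count`), one row per cell/SNP with at least one read,
#'   plus an `snps` attribute with the full SNP table.
#' @export
simulate_allele_counts <- function(config, sce) {
  if (!inherits(config, "sim_config")) stopf("'config' must be a sim_config")
  if (!methods::is(sce, "SingleCellExperiment")) {
    stopf("'sce' must be the SingleCellExperiment from simulate_counts()")
  }
  withr::with_seed(config$seed + 2L, {
    n_per_chrom <- diff(round(c(0, cumsum(config$chrom_length_bp)) /
                                sum(config$chrom_length_bp) * config$n_het_snps))
    snp_chrom <- rep(config$chroms, n_per_chrom)
    snp_pos <- round(unlist(lapply(seq_len(config$n_chromosomes), function(i) {
      .stratified_positions(n_per_chrom[i], config$chrom_length_bp[i])
    }), use.names = FALSE))
    n_snps <- length(snp_pos)
    snp_id <- sprintf("snp%04d", seq_len(n_snps))

    cells <- colnames(sce)
    n_cells <- length(cells)
    f <- matrix(0.5, n_snps, n_cells)
    rate <- matrix(config$snp_read_rate, n_snps, n_cells)
    truth <- metadata(sce)$ground_truth$cnv_events
    for (i in seq_len(nrow(truth))) {
      ev <- truth[i, ]
      rows <- which(snp_chrom == ev$chrom & snp_pos >= ev$start & snp_pos < ev$end)
      if (!length(rows)) next
      carry <- which(colData(sce)[[ev$carrier_col]])
      if (!length(carry)) next
      hap <- sample(0:1, length(rows), replace = TRUE)
      if (ev$copy_ratio < 1 || ev$loh) {
        f[rows, carry] <- hap             # allele fully lost or duplicated
      } else if (ev$copy_ratio > 1) {
        f[rows, carry] <- (1 + hap) / 3   # one of two haplotypes amplified
      }
      rate[rows, carry] <- rate[rows, carry] * ev$copy_ratio
    }

    reads <- matrix(rpois(n_snps * n_cells, rate), n_snps, n_cells)
    alt <- matrix(rbinom(n_snps * n_cells, reads, f), n_snps, n_cells)
    keep <- which(reads > 0, arr.ind = TRUE)
    out <- data.frame(
      cell = cells[keep[, 2]],
      snp_id = snp_id[keep[, 1]],
      chrom = snp_chrom[keep[, 1]],
      pos = snp_pos[keep[, 1]],
      ref_count = reads[keep] - alt[keep],
      alt_count = alt[keep],
      stringsAsFactors = FALSE)
    out <- out[order(keep[, 1], keep[, 2]), , drop = FALSE]
    rownames(out) <- NULL
    attr(out, "snps") <- data.frame(snp_id = snp_id, chrom = snp_chrom,
                                    pos = snp_pos, stringsAsFactors = FALSE)
    out
  })
}
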