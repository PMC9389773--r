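#' Describe a planted copy-number event
#'
#' Coordinates are 0-based, half-open, on the synthetic genome declared by
#' [sim_config()]. `copy_ratio` acts multiplicatively on expected expression
#' of genes whose midpoint falls inside the event: 1.5 models a single-copy
#' gain of a diploid locus, 0.5 a single-copy loss. Copy-neutral loss of
#' heterozygosity (`loh = TRUE`, `copy_ratio = 1`) leaves expression
#' untouched and only skews allele fractions at heterozygous SNPs, so it is
#' visible to [baf_confirm()] but invisible to [icnv_signal()].
#'
#' @param chrom chromosome name, e.g. `"chr2"`.
#' @param start,end event interval in bp (0-based, half-open).
#' @param copy_ratio multiplicative factor on expected expression (> 0).
#' @param timepoint which timepoint carries the event: `"Dx"`, `"Re"` or
#'   `"both"`.
#' @param cell_fraction fraction of that timepoint's cells carrying the
#'   event, in (0, 1].
#' @param loh flag for copy-neutral loss of heterozygosity; requires
#'   `copy_ratio = 1`.
#' @param id optional label; derived from the coordinates when missing.
#' @return a `cnv_event` list.
#' @export
#' @examples
#' cnv_event("chr2", 30e6, 60e6, copy_ratio = 1.5, timepoint = "Re")
cnv_event <- function(chrom, start, end, copy_ratio = 1.5,
                      timepoint = c("Re", "Dx", "both"),
                      cell_fraction = 1, loh = FALSE, id = NULL) {
  timepoint <- match.arg(timepoint)
  if (!is.numeric(start) || !is.numeric(end) || end <= start) {
    stopf("cnv_event: 'end' must exceed 'start' (got [%s, %s))",
          format(start), format(end))
  }
  if (!is.numeric(copy_ratio) || copy_ratio <= 0) {
    stopf("cnv_event: 'copy_ratio' must be > 0")
  }
  if (!is.numeric(cell_fraction) || cell_fraction <= 0 || cell_fraction > 1) {
    stopf("cnv_event: 'cell_fraction' must be in (0, 1]")
  }
  if (loh && copy_ratio != 1) {
    stopf("cnv_event: copy-neutral LOH requires copy_ratio = 1")
  }
  if (is.null(id)) {
    kind <- if (loh) "loh" else if (copy_ratio > 1) "gain"
      else if (copy_ratio < 1) "loss" else "cnv"
    id <- sprintf("%s_%s_%d_%d", kind, chrom, as.integer(start / 1e6),
                  as.integer(end / 1e6))
  }
  structure(list(id = id, chrom = chrom, start = as.numeric(start),
                 end = as.numeric(end), copy_ratio = copy_ratio,
                 timepoint = timepoint, cell_fraction = cell_fraction,
                 loh = isTRUE(loh)),
            class = "cnv_event")
}

#' Describe a planted somatic variant
#'
#' @param id variant label (unique within a config).
#' @param vaf_dx,vaf_re true variant allele fractions at diagnosis and
#'   relapse, in \[0, 1\].
#' @param chrom,pos optional genomic placement (0-based position).
#' @param gene optional gene label carried through to output tables.
#' @return a `variant_spec` list.
#' @export
variant_spec <- function(id, vaf_dx, vaf_re, chrom = "chr1", pos = NA_real_,
                         gene = NA_character_) {
  check_fraction(vaf_dx, "vaf_dx")
  check_fraction(vaf_re, "vaf_re")
  structure(list(id = as.character(id), vaf_dx = vaf_dx, vaf_re = vaf_re,
                 chrom = chrom, pos = pos, gene = gene),
            class = "variant_spec")
}

#' Default planted CNV landscape
#'
#' One relapse-specific 30 Mb gain, one 30 Mb loss and one 30 Mb copy-neutral
#' LOH on separate chromosomes, each clonal in the relapse sample — the kind
#' of large relapse-specific events seen in CNV-driven Dx/Re pairs.
#'
#' @return list of [cnv_event()] objects.
#' @export
default_cnv_events <- function() {
  list(
    cnv_event("chr2", 30e6, 60e6, copy_ratio = 1.5, timepoint = "Re"),
    cnv_event("chr3", 30e6, 60e6, copy_ratio = 0.5, timepoint = "Re"),
    cnv_event("chr4", 30e6, 60e6, copy_ratio = 1.0, timepoint = "Re", loh = TRUE)
  )
}

#' Default planted variant panel
#'
#' A small panel spanning the archetypes of clonal dynamics between Dx and
#' Re: a clone shrinking at relapse, a low-VAF clone lost entirely, a stable
#' founding mutation, a relapse-gained mutation, and a strongly reduced
#' clone.
#'
#' @return list of [variant_spec()] objects.
#' @export
default_variant_specs <- function() {
  list(
    variant_spec("NPM1_like",   0.40, 0.10, pos = 10e6),
    variant_spec("NRAS_like",   0.087, 0.0, pos = 30e6),
    variant_spec("DNMT3A_like", 0.30, 0.30, pos = 50e6),
    variant_spec("FAT3_like",   0.0, 0.238, pos = 70e6),
    variant_spec("KIT_like",    0.325, 0.05, pos = 90e6)
  )
}

#' Configuration of the synthetic Dx/Re generator
#'
#' Defines the study conditions emulated by [simulate_counts()],
#' [simulate_variants()] and [simulate_allele_counts()]: a plate-based
#' (SORT-seq/CEL-Seq2-like) UMI count experiment on CD33/CD34+ blasts at two
#' timepoints from one patient, with ERCC spike-ins, mitochondrial genes,
#' planted expression clusters, planted multi-megabase CNVs, an LSC-like
#' subpopulation, planted cell-cycle phases and WES-like variant depths.
#'
#' Defaults follow the sequencing scale of plate-based AML profiling
#' (roughly 4,000 UMIs per cell over a 2,000-gene panel, negative-binomial
#' overdispersion 0.3) and plant one clonal relapse-specific gain, loss and
#' copy-neutral LOH of 30 Mb each (see [default_cnv_events()]).
#'
#' @param n_genes number of nuclear genes (excluding mitochondrial genes and
#'   ERCC spike-ins). Must accommodate the bundled LSC17 and cell-cycle
#'   signature genes plus the planted cluster markers.
#' @param n_cells_dx,n_cells_re cells per timepoint.
#' @param n_chromosomes,chrom_length_bp synthetic autosomes and their common
#'   length in bp.
#' @param mean_depth_umi expected non-spike-in UMIs per cell.
#' @param nb_dispersion negative-binomial dispersion phi (variance
#'   mu + phi * mu^2), shared across genes.
#' @param n_clusters,marker_genes_per_cluster,marker_logfc planted expression
#'   clusters, exclusive marker genes per cluster, and their log2
#'   fold change.
#' @param cnv_events list of [cnv_event()] objects; must not overlap on the
#'   same chromosome for overlapping timepoints.
#' @param lsc_fraction fraction of cells flagged LSC-like; these cells carry
#'   a 2x up-shift of the positively weighted LSC17 genes.
#' @param phase_props named proportions for planted G1/S/G2M phase labels;
#'   S and G2M cells carry a 4x up-shift of the respective phase gene set.
#' @param variant_specs list of [variant_spec()] objects.
#' @param n_het_snps heterozygous germline SNPs placed quasi-uniformly on
#'   the genome.
#' @param snp_read_rate expected scRNA-seq reads per cell per SNP in diploid
#'   cells.
#' @param wes_depth_mean expected WES depth per variant and timepoint.
#' @param mito_fraction_mean,ercc_fraction_mean expected mitochondrial
#'   fraction (of non-spike-in UMIs) and ERCC fraction (of all UMIs) in
#'   clean cells.
#' @param lowq_cell_fraction fraction of cells deliberately constructed to
#'   violate one of the four QC rules of [qc_filter()].
#' @param seed RNG seed; identical configs give bit-identical output.
#' @return a validated `sim_config` list.
#' @export
#' @examples
#' cfg <- sim_config(n_cells_dx = 50, n_cells_re = 50, seed = 7)
#' sce <- simulate_counts(cfg)
sim_config <- function(n_genes = 2000,
                       n_cells_dx = 300,
                       n_cells_re = 300,
                       n_chromosomes = 4,
                       chrom_length_bp = 120e6,
                       mean_depth_umi = 4000,
                       nb_dispersion = 0.3,
                       n_clusters = 3,
                       marker_genes_per_cluster = 25,
                       marker_logfc = 2,
                       cnv_events = default_cnv_events(),
                       lsc_fraction = 0.2,
                       phase_props = c(G1 = 0.6, S = 0.2, G2M = 0.2),
                       variant_specs = default_variant_specs(),
                       n_het_snps = 200,
                       snp_read_rate = 0.5,
                       wes_depth_mean = 100,
                       mito_fraction_mean = 0.08,
                       ercc_fraction_mean = 0.05,
                       lowq_cell_fraction = 0.1,
                       seed = 1) {
  check_count(n_genes, "n_genes")
  check_count(n_cells_dx, "n_cells_dx")
  check_count(n_cells_re, "n_cells_re")
  check_count(n_chromosomes, "n_chromosomes")
  check_count(n_het_snps, "n_het_snps")
  if (!is.numeric(chrom_length_bp) || any(chrom_length_bp <= 0)) {
    stopf("'chrom_length_bp' must be positive")
  }
  if (!is.numeric(mean_depth_umi) || mean_depth_umi <= 0) {
    stopf("'mean_depth_umi' must be positive")
  }
  if (!is.numeric(nb_dispersion) || nb_dispersion <= 0) {
    stopf("'nb_dispersion' must be positive")
  }
  check_count(n_clusters, "n_clusters")
  check_count(marker_genes_per_cluster, "marker_genes_per_cluster", positive = FALSE)
  if (!is.numeric(wes_depth_mean) || wes_depth_mean <= 0) {
    stopf("'wes_depth_mean' must be positive")
  }
  if (!is.numeric(snp_read_rate) || snp_read_rate <= 0) {
    stopf("'snp_read_rate' must be positive")
  }
  check_fraction(lsc_fraction, "lsc_fraction")
  check_fraction(mito_fraction_mean, "mito_fraction_mean")
  check_fraction(ercc_fraction_mean, "ercc_fraction_mean")
  check_fraction(lowq_cell_fraction, "lowq_cell_fraction")
  if (is.null(names(phase_props)) ||
      !setequal(names(phase_props), c("G1", "S", "G2M")) ||
      any(phase_props < 0) || abs(sum(phase_props) - 1) > 1e-8) {
    stopf("'phase_props' must be named proportions for G1, S, G2M summing to 1")
  }
  if (!is.list(cnv_events) ||
      !all(vapply(cnv_events, inherits, logical(1), "cnv_event"))) {
    stopf("'cnv_events' must be a list of cnv_event objects")
  }
  if (!is.list(variant_specs) ||
      !all(vapply(variant_specs, inherits, logical(1), "variant_spec"))) {
    stopf("'variant_specs' must be a list of variant_spec objects")
  }
  vids <- vapply(variant_specs, `[[`, character(1), "id")
  if (anyDuplicated(vids)) stopf("duplicate variant_spec id: '%s'",
                                 vids[duplicated(vids)][1])

  chrom_length_bp <- rep_len(as.numeric(chrom_length_bp), n_chromosomes)
  chroms <- paste0("chr", seq_len(n_chromosomes))

  # events must sit on the declared genome and not overlap per timepoint
  for (ev in cnv_events) {
    ci <- match(ev$chrom, chroms)
    if (is.na(ci)) stopf("cnv_event '%s': unknown chromosome '%s'", ev$id, ev$chrom)
    if (ev$end > chrom_length_bp[ci]) {
      stopf("cnv_event '%s': end %s exceeds length of %s (%s bp)",
            ev$id, format(ev$end), ev$chrom, format(chrom_length_bp[ci]))
    }
  }
  if (length(cnv_events) > 1) {
    for (i in seq_len(length(cnv_events) - 1)) {
      for (j in seq(i + 1, length(cnv_events))) {
        a <- cnv_events[[i]]; b <- cnv_events[[j]]
        shared_tp <- a$timepoint == b$timepoint ||
          a$timepoint == "both" || b$timepoint == "both"
        if (a$chrom == b$chrom && shared_tp &&
            a$start < b$end && b$start < a$end) {
          stopf("cnv_events '%s' and '%s' overlap on %s for a shared timepoint",
                a$id, b$id, a$chrom)
        }
      }
    }
  }

  named <- length(unique(c(names(lsc17_signature()),
                           unlist(cell_cycle_genes(), use.names = FALSE))))
  needed <- named + n_clusters * marker_genes_per_cluster
  if (n_genes < needed + 50) {
    stopf("'n_genes' (%d) too small: need at least %d for signature genes, cluster markers and background",
          n_genes, needed + 50)
  }

  structure(list(
    n_genes = n_genes, n_cells_dx = n_cells_dx, n_cells_re = n_cells_re,
    n_chromosomes = n_chromosomes, chrom_length_bp = chrom_length_bp,
    chroms = chroms, mean_depth_umi = mean_depth_umi,
    nb_dispersion = nb_dispersion, n_clusters = n_clusters,
    marker_genes_per_cluster = marker_genes_per_cluster,
    marker_logfc = marker_logfc, cnv_events = cnv_events,
    lsc_fraction = lsc_fraction, phase_props = phase_props,
    variant_specs = variant_specs, n_het_snps = n_het_snps,
    snp_read_rate = snp_read_rate, wes_depth_mean = wes_depth_mean,
    mito_fraction_mean = mito_fraction_mean,
    ercc_fraction_mean = ercc_fraction_mean,
    lowq_cell_fraction = lowq_cell_fraction, seed = as.integer(seed)),
    class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("sim_config: %d genes, %d Dx + %d Re cells, %d chromosomes\n",
              x$n_genes, x$n_cells_dx, x$n_cells_re, x$n_chromosomes))
  cat(sprintf("  depth %s UMI/cell, dispersion %.2f, %d clusters, %d CNV events, %d variants, seed %d\n",
              format(x$mean_depth_umi), x$nb_dispersion, x$n_clusters,
              length(x$cnv_events), length(x$variant_specs), x$seed))
  invisible(x)
}
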