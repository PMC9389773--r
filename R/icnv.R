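#' Partition a genome into fixed-width expression tiles
#'
#' Tiles of `tile_size` bp (default 3 Mb) are laid from position 0 of every
#' chromosome; the last tile of a chromosome may be shorter. Each gene is
#' assigned to exactly one tile by its midpoint `floor((start + end) / 2)`
#' (0-based, half-open coordinates), so no gene is double-counted.
#'
#' @param annotation a SingleCellExperiment (its `rowRanges` are used via
#'   [gene_annotation()]) or a data.frame with `feature_id`, `chrom`,
#'   `start`, `end` (0-based, half-open); features with missing
#'   coordinates are ignored.
#' @param tile_size tile width in bp.
#' @param chrom_lengths named vector of chromosome lengths; inferred from
#'   the annotation (maximum gene end) when missing.
#' @param exclude_chroms chromosomes never tiled (mitochondrial genome by
#'   default).
#' @return a `tile_index`: list with `tiles` (a
#'   [GenomicRanges::GRanges] with `tile_id`), `gene_tile` (named integer
#'   vector mapping gene id to tile row) and `tile_size`.
#' @export
build_tiles <- function(annotation, tile_size = 3e6, chrom_lengths = NULL,
                        exclude_chroms = c("chrM", "MT")) {
  ann <- gene_annotation(annotation)
  ann <- ann[!is.na(ann$chrom) & !is.na(ann$start) & !is.na(ann$end) &
               !(ann$chrom %in% exclude_chroms), , drop = FALSE]
  if (nrow(ann) == 0) stopf("no annotated genes to tile")

  if (is.null(chrom_lengths)) {
    chrom_lengths <- vapply(split(ann$end, ann$chrom), max, numeric(1))
  } else {
    chrom_lengths <- chrom_lengths[!(names(chrom_lengths) %in% exclude_chroms)]
    bad <- setdiff(unique(ann$chrom), names(chrom_lengths))
    if (length(bad)) stopf("no length declared for chromosome(s): %s",
                           paste(bad, collapse = ", "))
  }
  mid <- floor((ann$start + ann$end) / 2)
  over <- mid >= chrom_lengths[ann$chrom]
  if (any(over)) {
    stopf("gene '%s' lies beyond the declared length of %s",
          ann$feature_id[which(over)[1]], ann$chrom[which(over)[1]])
  }

  si <- GenomeInfoDb::Seqinfo(seqnames = names(chrom_lengths),
                              seqlengths = as.integer(chrom_lengths))
  tiles <- GenomicRanges::tileGenome(si, tilewidth = tile_size,
                                     cut.last.tile.in.chrom = TRUE)
  tiles$tile_id <- sprintf("tile_%s_%06d", as.character(seqnames(tiles)),
                           start(tiles) - 1L)

  # midpoints are 0-based; GRanges is 1-based
  gpos <- GRanges(ann$chrom, IRanges(mid + 1, mid + 1))
  hit <- findOverlaps(gpos, tiles)
  gene_tile <- setNames(rep(NA_integer_, nrow(ann)), ann$feature_id)
  gene_tile[queryHits(hit)] <- subjectHits(hit)
  if (anyNA(gene_tile)) {
    stopf("gene '%s' could not be assigned to a tile",
          names(gene_tile)[which(is.na(gene_tile))[1]])
  }
  structure(list(tiles = tiles, gene_tile = gene_tile, tile_size = tile_size),
            class = "tile_index")
}

#' @export
print.tile_index <- function(x, ...) {
  cat(sprintf("tile_index: %d tiles of %s bp on %d chromosome(s), %d genes assigned\n",
              length(x$tiles), format(x$tile_size),
              length(unique(as.character(seqnames(x$tiles)))),
              length(x$gene_tile)))
  invisible(x)
}

#' Inferred-CNV signal in genomic tiles
#'
#' Per cell, counts of the tiled genes are pooled per tile and converted to
#' library fractions (with a pseudocount); the log2 fraction is centered on
#' the reference-cell mean per tile and then re-centered per cell on the
#' mode of the cell's own tile signal ("cell normalized"), so the dominant
#' diploid tile population sits at 0 and a clonal single-copy gain at
#' ~log2(1.5). Pooling at tile level before the log keeps the signal on the
#' copy-ratio scale, which per-gene averaging of log-normalized UMI counts
#' would shrink towards zero. Signals are smoothed with a centered moving
#' average within chromosomes and clipped. The method assumes aberrant
#' regions cover a minority of the tiled genome.
#'
#' @param x count matrix or SingleCellExperiment (`counts` assay).
#' @param tiles a [build_tiles()] index.
#' @param reference_cells character or integer index of the baseline cell
#'   group (e.g. the Dx cells when scanning Re).
#' @param min_genes_per_tile tiles with fewer assigned genes are excluded
#'   (with a warning).
#' @param smooth moving-average window in tiles (1 = no smoothing).
#' @param clip symmetric clip bound in log2 units for the smoothed signal.
#' @param pseudocount added to tile counts before forming fractions.
#' @return a `tile_matrix`: list with `signal` (smoothed, clipped tiles x
#'   cells matrix), `raw` (unsmoothed, unclipped), `tiles` (GRanges of used
#'   tiles), `reference_cells` and the parameters.
#' @export
icnv_signal <- function(x, tiles, reference_cells, min_genes_per_tile = 5,
                        smooth = 3, clip = 1.5, pseudocount = 1) {
  if (!inherits(tiles, "tile_index")) stopf("'tiles' must come from build_tiles()")
  counts <- get_counts(x)
  if (is.character(reference_cells)) {
    reference_cells <- match(reference_cells, colnames(counts))
  }
  if (length(reference_cells) == 0 || anyNA(reference_cells)) {
    stopf("'reference_cells' must name cells present in the matrix")
  }

  genes <- intersect(names(tiles$gene_tile), rownames(counts))
  if (length(genes) == 0) stopf("no tiled gene found in the count matrix")
  assign <- tiles$gene_tile[genes]
  n_tiles <- length(tiles$tiles)
  tile_counts <- rowsum_sparse(counts[genes, , drop = FALSE], assign, n_tiles)

  genes_per_tile <- tabulate(assign, n_tiles)
  used <- genes_per_tile >= min_genes_per_tile
  if (!any(used)) stopf("no tile reaches min_genes_per_tile = %d", min_genes_per_tile)
  if (any(genes_per_tile > 0 & !used)) {
    warnf("excluding %d tile(s) with fewer than %d genes",
          sum(genes_per_tile > 0 & !used), min_genes_per_tile)
  }
  tile_counts <- tile_counts[used, , drop = FALSE]
  used_tiles <- tiles$tiles[used]

  totals <- colSums(tile_counts)
  if (any(totals == 0)) stopf("%d cell(s) have no counts on tiled genes",
                              sum(totals == 0))
  frac <- sweep(tile_counts + pseudocount, 2, totals + pseudocount * sum(used), `/`)
  logf <- log2(frac)
  baseline <- rowMeans(logf[, reference_cells, drop = FALSE])
  centered <- logf - baseline
  # "cell normalized": each cell is re-centered on the mode of its own
  # tile signal, so the dominant diploid tile population sits at zero even
  # when a large aberrant region would drag a median
  cell_center <- apply(centered, 2, half_sample_mode)
  centered <- sweep(centered, 2, cell_center)

  chrom <- as.character(seqnames(used_tiles))
  smoothed <- centered
  if (smooth > 1) {
    for (ch in unique(chrom)) {
      i <- which(chrom == ch)
      smoothed[i, ] <- apply(centered[i, , drop = FALSE], 2, smooth_ma, w = smooth)
    }
  }
  smoothed <- pmin(pmax(smoothed, -clip), clip)
  rownames(smoothed) <- rownames(centered) <- used_tiles$tile_id

  rownames(tile_counts) <- used_tiles$tile_id
  structure(list(signal = smoothed, raw = centered, tiles = used_tiles,
                 tile_counts = tile_counts, totals = totals,
                 cell_center = cell_center,
                 reference_cells = colnames(counts)[reference_cells],
                 params = list(min_genes_per_tile = min_genes_per_tile,
                               smooth = smooth, clip = clip,
                               pseudocount = pseudocount)),
            class = "tile_matrix")
}

#' @export
print.tile_matrix <- function(x, ...) {
  cat(sprintf("tile_matrix: %d tiles x %d cells (%d reference cells), clip +/-%.2f, smooth %d\n",
              nrow(x$signal), ncol(x$signal), length(x$reference_cells),
              x$params$clip, x$params$smooth))
  invisible(x)
}

#' Call gained and lost segments from tile signal
#'
#' Per cell, tiles whose smoothed signal exceeds `gain_thr` (or falls below
#' `loss_thr`) are marked; maximal runs of at least `min_tiles` consecutive
#' tiles marked in at least `min_cell_frac` of the target cells become
#' candidate segments. Candidate boundaries are then trimmed on the
#' unsmoothed signal (edge tiles whose cross-cell mean does not clear the
#' threshold are dropped), which undoes the one-tile bleed of the moving
#' average. A cell's segment-level signal then pools the raw counts of the
#' whole segment into a single super-tile (log2 pooled fraction against
#' the pooled reference baseline, with the same per-cell median
#' normalization), which keeps the reported magnitude on the copy-ratio
#' scale without the per-tile log shrinkage of weakly expressed tiles. A
#' cell counts as affected when its pooled segment signal clears the
#' threshold; `mean_signal` averages the pooled signal over affected
#' cells.
#'
#' @param tm a [icnv_signal()] result.
#' @param target_cells cells to scan (character or integer index).
#' @param gain_thr,loss_thr per-tile thresholds in log2 units
#'   (`gain_thr > loss_thr` required).
#' @param min_tiles minimum run length in tiles.
#' @param min_cell_frac minimum fraction of target cells marking a tile.
#' @return data.frame of segment calls: `chrom`, `start`, `end` (0-based,
#'   half-open), `state`, `n_tiles`, `mean_signal`, `sd_signal` (across
#'   affected cells), `frac_cells`, `n_affected`, plus a list column
#'   `cells` of affected cell ids.
#' @export
call_segments <- function(tm, target_cells, gain_thr = 0.15,
                          loss_thr = -0.15, min_tiles = 2,
                          min_cell_frac = 0.5) {
  if (!inherits(tm, "tile_matrix")) stopf("'tm' must come from icnv_signal()")
  if (gain_thr <= loss_thr) stopf("'gain_thr' must exceed 'loss_thr'")
  if (is.character(target_cells)) {
    target_cells <- match(target_cells, colnames(tm$signal))
  }
  if (length(target_cells) == 0 || anyNA(target_cells)) {
    stopf("'target_cells' must name cells present in the tile matrix")
  }
  S <- tm$signal[, target_cells, drop = FALSE]
  R <- tm$raw[, target_cells, drop = FALSE]
  chrom <- as.character(seqnames(tm$tiles))
  start0 <- start(tm$tiles) - 1L
  end0 <- end(tm$tiles)

  ref_idx <- match(tm$reference_cells, colnames(tm$signal))
  pc <- tm$params$pseudocount

  # candidate tiles per state: marked in enough target cells on the
  # smoothed signal
  cand <- list(gain = rowMeans(S > gain_thr) >= min_cell_frac,
               loss = rowMeans(S < loss_thr) >= min_cell_frac)
  # the diploid backdrop excludes every candidate-aberrant tile, whatever
  # its state, so one event does not contaminate the baseline of another
  diploid <- !(cand$gain | cand$loss)
  if (!any(diploid)) diploid <- rep(TRUE, nrow(S))

  # Pooled per-cell signal of a tile run: log2 odds of the run's counts
  # against the diploid backdrop, centered on the reference mean. The
  # backdrop absorbs the library-size change caused by the events
  # themselves, so a clonal gain sits at log2(copy_ratio).
  pooled_signal <- function(idx, cells) {
    back <- setdiff(which(diploid), idx)
    if (length(back) == 0) back <- setdiff(seq_len(nrow(S)), idx)
    seg <- colSums(tm$tile_counts[idx, cells, drop = FALSE])
    bk <- colSums(tm$tile_counts[back, cells, drop = FALSE])
    lodds <- log2((seg + pc) / (bk + pc))
    seg_r <- colSums(tm$tile_counts[idx, ref_idx, drop = FALSE])
    bk_r <- colSums(tm$tile_counts[back, ref_idx, drop = FALSE])
    base <- mean(log2((seg_r + pc) / (bk_r + pc)))
    lodds - base
  }

  segs <- list()
  for (state in c("gain", "loss")) {
    clears <- if (state == "gain") function(v) v > gain_thr
      else function(v) v < loss_thr
    for (ch in unique(chrom)) {
      idx_ch <- which(chrom == ch)
      r <- rle(cand[[state]][idx_ch])
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1
      for (j in which(r$values & r$lengths >= min_tiles)) {
        idx <- idx_ch[starts[j]:ends[j]]
        # trim moving-average bleed at the run edges
        while (length(idx) && !clears(mean(R[idx[1], ]))) idx <- idx[-1]
        while (length(idx) && !clears(mean(R[idx[length(idx)], ]))) {
          idx <- idx[-length(idx)]
        }
        if (length(idx) < min_tiles) next
        cell_signal <- pooled_signal(idx, target_cells)
        affected <- clears(cell_signal)
        use <- if (any(affected)) affected else rep(TRUE, length(cell_signal))
        segs[[length(segs) + 1]] <- data.frame(
          chrom = ch, start = start0[idx[1]], end = end0[idx[length(idx)]],
          state = state, n_tiles = length(idx),
          mean_signal = mean(cell_signal[use]),
          sd_signal = sd(cell_signal[use]),
          frac_cells = mean(affected), n_affected = sum(affected),
          stringsAsFactors = FALSE)
        segs[[length(segs)]]$cells <-
          list(colnames(S)[affected])
      }
    }
  }
  if (length(segs) == 0) {
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), state = character(),
                      n_tiles = integer(), mean_signal = numeric(),
                      sd_signal = numeric(), frac_cells = numeric(),
                      n_affected = integer(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, segs)
  rownames(out) <- NULL
  out[order(out$chrom, out$start), , drop = FALSE]
}

#' Confirm a segment with B-allele fractions at heterozygous SNPs
#'
#' Reads at heterozygous SNPs inside the segment are pooled (cell-summed)
#' per SNP within the target and reference cell groups; the per-SNP pooled
#' ALT fraction f is folded to |f - 0.5| so the statistic is invariant to
#' haplotype phase. The segment-level statistic is the mean folded
#' deviation per group; the segment is confirmed when the target deviation
#' exceeds the reference deviation by more than `dev_threshold`. With fewer
#' than `min_snps` adequately covered SNPs the segment is reported
#' "unconfirmable", never "not confirmed".
#'
#' @param allele_counts long data.frame from [simulate_allele_counts()] or
#'   [read_allele_counts_tsv()] (`cell`, `snp_id`, `chrom`, `pos`,
#'   `ref_count`, `alt_count`).
#' @param segment one segment: a single-row data.frame (or list) with
#'   `chrom`, `start`, `end` (0-based, half-open).
#' @param target_cells,reference_cells cell id vectors.
#' @param min_snps minimum SNPs covered in both groups.
#' @param min_reads minimum pooled reads per SNP per group.
#' @param dev_threshold minimum excess folded deviation for confirmation.
#' @return a `baf_summary`: list with the per-SNP table (`f` and folded
#'   deviation per group), per-group mean deviations, `status`
#'   (`confirmed` / `not_confirmed` / `unconfirmable`) and `confirmed`
#'   (logical, `NA` when unconfirmable).
#' @export
baf_confirm <- function(allele_counts, segment, target_cells,
                        reference_cells, min_snps = 3, min_reads = 20,
                        dev_threshold = 0.1) {
  segment <- as.list(as.data.frame(segment)[1, , drop = FALSE])
  need <- c("cell", "snp_id", "chrom", "pos", "ref_count", "alt_count")
  miss <- setdiff(need, colnames(allele_counts))
  if (length(miss)) stopf("'allele_counts' lacks column(s): %s",
                          paste(miss, collapse = ", "))

  inseg <- allele_counts$chrom == segment$chrom &
    allele_counts$pos >= segment$start & allele_counts$pos < segment$end
  ac <- allele_counts[inseg, , drop = FALSE]

  pool <- function(cells) {
    sub <- ac[ac$cell %in% cells, , drop = FALSE]
    if (nrow(sub) == 0) {
      return(data.frame(snp_id = character(), ref = numeric(),
                        alt = numeric(), stringsAsFactors = FALSE))
    }
    agg <- rowsum(cbind(ref = sub$ref_count, alt = sub$alt_count), sub$snp_id)
    data.frame(snp_id = rownames(agg), ref = agg[, "ref"], alt = agg[, "alt"],
               stringsAsFactors = FALSE, row.names = NULL)
  }
  tgt <- pool(target_cells)
  ref <- pool(reference_cells)
  merged <- merge(tgt, ref, by = "snp_id", suffixes = c("_target", "_reference"))
  merged$depth_target <- merged$ref_target + merged$alt_target
  merged$depth_reference <- merged$ref_reference + merged$alt_reference
  ok <- merged$depth_target >= min_reads & merged$depth_reference >= min_reads
  merged <- merged[ok, , drop = FALSE]

  if (nrow(merged) < min_snps) {
    return(structure(list(snps = merged, segment = segment,
                          n_snps = nrow(merged),
                          target_deviation = NA_real_,
                          reference_deviation = NA_real_,
                          status = "unconfirmable", confirmed = NA),
                     class = "baf_summary"))
  }
  merged$f_target <- merged$alt_target / merged$depth_target
  merged$f_reference <- merged$alt_reference / merged$depth_reference
  merged$dev_target <- abs(merged$f_target - 0.5)
  merged$dev_reference <- abs(merged$f_reference - 0.5)

  dev_t <- mean(merged$dev_target)
  dev_r <- mean(merged$dev_reference)
  confirmed <- (dev_t - dev_r) > dev_threshold
  structure(list(snps = merged, segment = segment, n_snps = nrow(merged),
                 target_deviation = dev_t, reference_deviation = dev_r,
                 status = if (confirmed) "confirmed" else "not_confirmed",
                 confirmed = confirmed),
            class = "baf_summary")
}

#' @export
print.baf_summary <- function(x, ...) {
  cat(sprintf("baf_summary [%s]: %d SNPs, folded deviation %.3f (target) vs %.3f (reference)\n",
              x$status, x$n_snps,
              x$target_deviation, x$reference_deviation))
  invisible(x)
}

#' Count differentially expressed genes inside CNV segments
#'
#' DEGs whose gene midpoint lies inside a called segment, with a direction
#' consistency check: a gain is expected to carry up-regulated DEGs, a loss
#' down-regulated ones (in the contrast target vs reference).
#'
#' @param markers marker/DEG table from [find_markers()], restricted to the
#'   relevant group (e.g. Re); only rows with `significant = TRUE` (or
#'   `q < 0.05` when the column is missing) are counted.
#' @param segments segment calls from [call_segments()].
#' @param annotation gene annotation (`feature_id`, `chrom`, `start`,
#'   `end`); DEGs missing from it are skipped with a warning.
#' @return data.frame with one row per segment: `n_degs`, `n_consistent`
#'   and a list column `genes`.
#' @export
degs_in_segments <- function(markers, segments, annotation) {
  ann <- gene_annotation(annotation)
  if (nrow(segments) == 0) {
    return(data.frame(chrom = character(), start = numeric(), end = numeric(),
                      state = character(), n_degs = integer(),
                      n_consistent = integer(), stringsAsFactors = FALSE))
  }
  sig <- if ("significant" %in% colnames(markers)) markers$significant
    else markers$q < 0.05
  degs <- markers[sig, , drop = FALSE]
  pos <- match(degs$gene, ann$feature_id)
  if (anyNA(pos)) {
    warnf("skipping %d DEG(s) without gene coordinates", sum(is.na(pos)))
    degs <- degs[!is.na(pos), , drop = FALSE]
    pos <- pos[!is.na(pos)]
  }
  mid <- floor((ann$start[pos] + ann$end[pos]) / 2)
  chrom <- ann$chrom[pos]

  out <- segments[, c("chrom", "start", "end", "state")]
  out$n_degs <- 0L
  out$n_consistent <- 0L
  out$genes <- vector("list", nrow(out))
  for (i in seq_len(nrow(segments))) {
    inseg <- !is.na(chrom) & chrom == segments$chrom[i] &
      mid >= segments$start[i] & mid < segments$end[i]
    g <- degs[inseg, , drop = FALSE]
    expected <- if (segments$state[i] == "gain") 1 else -1
    out$n_degs[i] <- nrow(g)
    out$n_consistent[i] <- sum(sign(g$log2fc) == expected)
    out$genes[[i]] <- g$gene
  }
  rownames(out) <- NULL
  out
}
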