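#' Default end-to-end pipeline configuration
#'
#' A plain nested list (YAML-serializable) describing one full synthetic
#' run: generator settings (see [sim_config()]), QC thresholds, VAF-shift
#' test settings, iCNV settings (target/reference timepoints, tiling,
#' thresholds, BAF confirmation), signature scoring and marker detection
#' settings, plus the global seed propagated to every stochastic stage.
#'
#' @param seed global RNG seed.
#' @return nested configuration list.
#' @export
default_pipeline_config <- function(seed = 1) {
  list(
    seed = as.integer(seed),
    sim = list(
      cnv_events = lapply(default_cnv_events(), unclass),
      variant_specs = lapply(default_variant_specs(), unclass)),
    qc = list(min_genes = 500, max_umi = 12000,
              max_mito_frac = 0.30, max_ercc_frac = 0.20),
    clonal = list(min_alt = 5, min_vaf = 0.05, report_vaf = 0.2,
                  alpha = 0.05),
    icnv = list(target = "Re", reference = "Dx", tile_size = 3e6,
                min_genes_per_tile = 5, smooth = 3, clip = 1.5,
                gain_thr = 0.15, loss_thr = -0.15, min_tiles = 2,
                min_cell_frac = 0.5,
                baf = list(min_snps = 3, min_reads = 20,
                           dev_threshold = 0.1)),
    signatures = list(n_bins = 24, n_ctrl = 100),
    markers = list(min_pct = 0.1, min_abs_log2fc = 0.25, alpha = 0.05))
}

#' Read a pipeline configuration from YAML
#'
#' Missing blocks are filled from [default_pipeline_config()]; an explicit
#' empty `clonal:` or empty `sim$variant_specs` skips the clonal stage.
#'
#' @param path YAML file.
#' @return configuration list.
#' @export
read_pipeline_config <- function(path) {
  user <- yaml::read_yaml(path)
  def <- default_pipeline_config(seed = user$seed %||% 1)
  merge_lists <- function(d, u) {
    for (nm in names(u)) {
      d[[nm]] <- if (is.list(u[[nm]]) && is.list(d[[nm]]) &&
                     !is.null(names(u[[nm]]))) {
        merge_lists(d[[nm]], u[[nm]])
      } else {
        u[[nm]]
      }
    }
    d
  }
  cfg <- merge_lists(def, user)
  if ("clonal" %in% names(user) && is.null(user$clonal)) cfg["clonal"] <- list(NULL)
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.build_sim_config <- function(sim, seed) {
  sim <- sim %||% list()
  # YAML scalars like "9.0e6" arrive as strings; coerce numeric fields
  renum <- function(x, fields) {
    for (f in intersect(fields, names(x))) x[[f]] <- as.numeric(x[[f]])
    x
  }
  sim <- renum(sim, c("n_genes", "n_cells_dx", "n_cells_re",
                      "n_chromosomes", "chrom_length_bp", "mean_depth_umi",
                      "nb_dispersion", "n_clusters",
                      "marker_genes_per_cluster", "marker_logfc",
                      "lsc_fraction", "n_het_snps", "snp_read_rate",
                      "wes_depth_mean", "mito_fraction_mean",
                      "ercc_fraction_mean", "lowq_cell_fraction"))
  if (!is.null(sim$cnv_events)) {
    sim$cnv_events <- lapply(sim$cnv_events, function(ev) {
      if (inherits(ev, "cnv_event")) return(ev)
      ev <- renum(ev, c("start", "end", "copy_ratio", "cell_fraction"))
      if (!is.null(ev$loh)) ev$loh <- as.logical(ev$loh)
      do.call(cnv_event, ev[intersect(names(ev), names(formals(cnv_event)))])
    })
  }
  if (!is.null(sim$variant_specs)) {
    sim$variant_specs <- lapply(sim$variant_specs, function(vs) {
      if (inherits(vs, "variant_spec")) return(vs)
      vs <- renum(vs, c("vaf_dx", "vaf_re", "pos"))
      do.call(variant_spec,
              vs[intersect(names(vs), names(formals(variant_spec)))])
    })
  }
  do.call(sim_config, c(sim, list(seed = seed)))
}

.run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stopf("stage '%s' failed: %s", name, conditionMessage(e))
  })
}

#' Run the full synthetic Dx/Re pipeline
#'
#' Executes simulate, qc, normalize, clonal (optional), icnv (signal,
#' segment calls, BAF confirmation), signatures and markers in dependency
#' order, writing deterministic plain-text artifacts (MTX/TSV/BED/JSON)
#' under `out_dir` plus a `manifest.json` echoing parameters, package
#' version, seed and per-stage summaries. Re-running with an identical
#' configuration and seed reproduces byte-identical artifacts.
#'
#' @param config configuration list (see [default_pipeline_config()]) or
#'   path to a YAML file.
#' @param out_dir output directory.
#' @param seed optional override of `config$seed`.
#' @return the run report (manifest content), invisibly.
#' @export
run_pipeline <- function(config = default_pipeline_config(), out_dir,
                         seed = NULL) {
  if (is.character(config)) config <- read_pipeline_config(config)
  if (!is.null(seed)) config$seed <- as.integer(seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  report <- list(package = "relapseScope",
                 version = as.character(packageVersion("relapseScope")),
                 seed = config$seed, parameters = config, stages = list())

  ## simulate -------------------------------------------------------------
  sce <- .run_stage("simulate", {
    cfg <- .build_sim_config(config$sim, config$seed)
    sce <- simulate_counts(cfg)
    write_counts_dir(sce, file.path(out_dir, "sim"))
    sce
  })
  cfg <- metadata(sce)$config
  truth <- metadata(sce)$ground_truth
  report$stages$simulate <- list(
    n_cells = ncol(sce), n_features = nrow(sce),
    n_clean_cells = sum(sce$qc_clean),
    n_cnv_events = nrow(truth$cnv_events),
    n_variants = length(cfg$variant_specs))

  ## qc -------------------------------------------------------------------
  qcres <- .run_stage("qc", {
    thr <- do.call(qc_thresholds, config$qc %||% list())
    res <- qc_filter(sce, thr)
    dir.create(file.path(out_dir, "qc"), showWarnings = FALSE)
    write_tsv(res$metrics, file.path(out_dir, "qc", "cell_metrics.tsv"))
    jsonlite::write_json(res$report, file.path(out_dir, "qc", "summary.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    res
  })
  sce_f <- qcres$sce
  report$stages$qc <- qcres$report[c("n_in", "n_pass", "n_fail",
                                     "fail_min_genes", "fail_max_umi",
                                     "fail_mito", "fail_ercc")]

  ## normalize ------------------------------------------------------------
  sce_f <- .run_stage("normalize", normalize_counts(sce_f))
  report$stages$normalize <- list(n_cells = ncol(sce_f),
                                  n_features = nrow(sce_f))

  ## clonal ---------------------------------------------------------------
  if (!is.null(config$clonal) && length(cfg$variant_specs) > 0) {
    vaf <- .run_stage("clonal", {
      variants <- simulate_variants(cfg)
      res <- do.call(test_vaf_shifts, c(list(variants = variants),
                                        config$clonal))
      dir.create(file.path(out_dir, "clonal"), showWarnings = FALSE)
      write_tsv(variants, file.path(out_dir, "clonal", "variants.tsv"))
      write_tsv(res, file.path(out_dir, "clonal", "vaf_tests.tsv"))
      res
    })
    report$stages$clonal <- list(n_variants = nrow(vaf),
                                 n_tested = sum(vaf$tested),
                                 n_reportable = sum(vaf$reportable))
  } else {
    report$stages$clonal <- list(skipped = TRUE,
                                 reason = "no variant panel configured")
  }

  ## icnv -----------------------------------------------------------------
  icnv_cfg <- config$icnv %||% list()
  icnv_out <- .run_stage("icnv", {
    target_cells <- colnames(sce_f)[sce_f$timepoint == (icnv_cfg$target %||% "Re")]
    ref_cells <- colnames(sce_f)[sce_f$timepoint == (icnv_cfg$reference %||% "Dx")]
    tiles <- build_tiles(gene_annotation(sce_f),
                         tile_size = icnv_cfg$tile_size %||% 3e6,
                         chrom_lengths = truth$chrom_lengths)
    tm <- icnv_signal(sce_f, tiles, reference_cells = ref_cells,
                      min_genes_per_tile = icnv_cfg$min_genes_per_tile %||% 5,
                      smooth = icnv_cfg$smooth %||% 3,
                      clip = icnv_cfg$clip %||% 1.5)
    segs <- call_segments(tm, target_cells,
                          gain_thr = icnv_cfg$gain_thr %||% 0.15,
                          loss_thr = icnv_cfg$loss_thr %||% -0.15,
                          min_tiles = icnv_cfg$min_tiles %||% 2,
                          min_cell_frac = icnv_cfg$min_cell_frac %||% 0.5)
    dir.create(file.path(out_dir, "icnv"), showWarnings = FALSE)
    write_segments_bed(segs, file.path(out_dir, "icnv", "segments.bed"))

    ac <- simulate_allele_counts(cfg, sce)
    write_tsv(ac, file.path(out_dir, "icnv", "allele_counts.tsv"))
    baf_cfg <- icnv_cfg$baf %||% list()
    baf <- lapply(seq_len(nrow(segs)), function(i) {
      baf_confirm(ac, segs[i, ], target_cells, ref_cells,
                  min_snps = baf_cfg$min_snps %||% 3,
                  min_reads = baf_cfg$min_reads %||% 20,
                  dev_threshold = baf_cfg$dev_threshold %||% 0.1)
    })
    if (nrow(segs)) {
      baf_tab <- data.frame(
        chrom = segs$chrom, start = segs$start, end = segs$end,
        state = segs$state,
        n_snps = vapply(baf, `[[`, numeric(1), "n_snps"),
        target_deviation = vapply(baf, `[[`, numeric(1), "target_deviation"),
        reference_deviation = vapply(baf, `[[`, numeric(1), "reference_deviation"),
        status = vapply(baf, `[[`, character(1), "status"),
        stringsAsFactors = FALSE)
      write_tsv(baf_tab, file.path(out_dir, "icnv", "baf_confirmation.tsv"))
    }
    list(segments = segs, baf = baf, tiles = tiles,
         target_cells = target_cells, ref_cells = ref_cells)
  })
  report$stages$icnv <- list(
    n_tiles = length(icnv_out$tiles$tiles),
    n_segments = nrow(icnv_out$segments),
    n_confirmed = sum(vapply(icnv_out$baf, function(b)
      isTRUE(b$confirmed), logical(1))))

  ## signatures -----------------------------------------------------------
  sig_cfg <- config$signatures %||% list()
  scores <- .run_stage("signatures", {
    lsc <- score_weighted_signature(sce_f, lsc17_signature())
    cc <- cell_cycle_score(sce_f, n_bins = sig_cfg$n_bins %||% 24,
                           n_ctrl = sig_cfg$n_ctrl %||% 100,
                           seed = config$seed)
    out <- data.frame(cell = colnames(sce_f), lsc17 = lsc,
                      s_score = cc$s_score, g2m_score = cc$g2m_score,
                      phase = cc$phase,
                      timepoint = sce_f$timepoint,
                      stringsAsFactors = FALSE, row.names = NULL)
    dir.create(file.path(out_dir, "signatures"), showWarnings = FALSE)
    write_tsv(out, file.path(out_dir, "signatures", "scores.tsv"))
    out
  })
  report$stages$signatures <- list(
    n_cells = nrow(scores),
    mean_lsc17 = mean(scores$lsc17),
    phase_counts = as.list(table(scores$phase)))

  ## markers --------------------------------------------------------------
  mk_cfg <- config$markers %||% list()
  markers <- .run_stage("markers", {
    res <- find_markers(sce_f, labels = sce_f$timepoint,
                        min_pct = mk_cfg$min_pct %||% 0.1,
                        min_abs_log2fc = mk_cfg$min_abs_log2fc %||% 0.25,
                        alpha = mk_cfg$alpha %||% 0.05)
    dir.create(file.path(out_dir, "markers"), showWarnings = FALSE)
    write_tsv(res, file.path(out_dir, "markers", "markers.tsv"))
    if (nrow(icnv_out$segments)) {
      target <- icnv_cfg$target %||% "Re"
      degs <- degs_in_segments(res[res$group == target, , drop = FALSE],
                               icnv_out$segments, gene_annotation(sce_f))
      write_tsv(degs[, setdiff(colnames(degs), "genes")],
                file.path(out_dir, "markers", "degs_in_segments.tsv"))
    }
    res
  })
  report$stages$markers <- list(
    n_tested = nrow(markers),
    n_significant = sum(markers$significant))

  jsonlite::write_json(report, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(report)
}
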