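#' Run the full synthetic differential-methylation pipeline
#'
#' Drives every stage end to end on data from the synthetic generator:
#' tiling simulation, median-centring quantile normalisation, running
#' mean smoothing, the M-prime track, DEP calling and two-stage
#' filtering, the top-fraction shortlist, the per-sample PeakScore
#' matrix with UPGMA clustering, miRNA/gene differential expression,
#' inverse-pair filtering, promoter concordance, imprinted-region
#' mapping with a permutation enrichment test, and delta-delta-Ct
#' quantitation of a simulated validation assay. Every source of
#' randomness derives from `config$seed`, so a given config yields a
#' byte-identical report.
#'
#' @param config A [sim_config()].
#' @param params A [peak_params()].
#' @param filter A [dep_filter_params()].
#' @param smooth_bp Running-mean window in bp (0 disables smoothing).
#' @param fc_min,alpha Differential-expression stringency.
#' @param n_perm Permutations for the region-enrichment test.
#' @param qpcr_true_fc True fold change of the simulated qPCR target.
#' @param outdir Optional directory; when given, writes the probe
#'   track, DEP BED, matrices and the JSON report there.
#' @return A list of class `medip_report` with per-stage results and a
#'   `summary` tibble of the headline counts and fractions.
#' @export
run_pipeline <- function(config = sim_config(),
                         params = peak_params(),
                         filter = dep_filter_params(),
                         smooth_bp = 300,
                         fc_min = 1.2, alpha = 0.05,
                         n_perm = 999,
                         qpcr_true_fc = 1.45,
                         outdir = NULL) {
  cfg <- validate_sim_config(config)

  # --- methylation arm -------------------------------------------------
  sim <- simulate_tiling(cfg)
  track <- quantile_normalize(sim$track)
  if (smooth_bp > 0) track <- linear_smooth(track, smooth_bp)
  mtrack <- compute_mprime(track)
  deps <- call_deps(mtrack, params, filter)
  accepted <- deps[deps$accepted, , drop = FALSE]
  shortlist <- top_peak_filter(accepted, filter$top_fraction)
  recovery <- dmr_recovery(accepted, sim$truth)

  cluster_res <- NULL
  purity <- NA_real_
  if (nrow(accepted) >= 1L) {
    psm <- peak_score_matrix(track, accepted, params)
    if (nrow(psm) >= 1L) {
      hc <- hcluster(psm, axis = "columns")
      labels <- sample_info(track)$group
      names(labels) <- sample_info(track)$sample
      purity <- cluster_purity(hc, labels)
      cluster_res <- list(matrix = psm, dendrogram = hc)
    }
  }

  # --- expression arm --------------------------------------------------
  expr <- simulate_expression(cfg)
  mirna_de <- differential_expression(expr$mirna, fc_min, alpha)
  gene_de <- differential_expression(expr$gene, fc_min, alpha)
  pairs_kept <- inverse_pair_filter(mirna_de, gene_de, expr$pairs)

  # --- integration -----------------------------------------------------
  catalogs <- make_catalogs(cfg)
  concordance <- promoter_concordance(accepted, gene_de, catalogs$promoters)
  de_mirna_ids <- mirna_de$feature_id[mirna_de$passes_filter]
  de_anno <- expr$mirna_anno[expr$mirna_anno$feature_id %in% de_mirna_ids, ,
                             drop = FALSE]
  mapping <- map_to_regions(de_anno, catalogs$imprinted)
  enrichment <- if (length(de_mirna_ids) >= 1L) {
    region_enrichment(de_mirna_ids, catalogs$imprinted, expr$mirna_anno,
                      n_perm = n_perm, seed = sub_seed(cfg$seed, 4L))
  } else {
    tibble(observed = 0L, expected = NA_real_, p_value = NA_real_,
           n_features = 0L, n_perm = n_perm)
  }

  # --- qPCR validation arm ---------------------------------------------
  qpcr_tab <- simulate_qpcr(true_fc = qpcr_true_fc,
                            seed = sub_seed(cfg$seed, 5L))
  qpcr <- ddct_fold_change(qpcr_tab)

  summary <- tibble(
    n_probes = nrow(track),
    n_dep_called = nrow(deps),
    n_dep_accepted = nrow(accepted),
    n_dep_shortlist = nrow(shortlist),
    n_planted_dmr = nrow(sim$truth),
    dmr_recall = recovery$recall,
    dmr_false_discovery = recovery$false_discovery,
    cluster_purity = purity,
    n_de_mirna = sum(mirna_de$passes_filter),
    n_de_gene = sum(gene_de$passes_filter),
    n_inverse_pairs_kept = nrow(pairs_kept),
    n_target_genes = dplyr::n_distinct(pairs_kept$gene_id),
    fraction_promoter_concordant = concordance$fraction_concordant,
    fraction_mirna_imprinted = mapping$fraction_mapped,
    imprinted_enrichment_p = enrichment$p_value,
    qpcr_fold_change = qpcr$fold_change,
    qpcr_p_value = qpcr$p_value
  )

  report <- list(
    config = cfg, truth = sim$truth, track = track, mtrack = mtrack,
    deps = deps, shortlist = shortlist, cluster = cluster_res,
    mirna_de = mirna_de, gene_de = gene_de, pairs = pairs_kept,
    concordance = concordance, mapping = mapping, enrichment = enrichment,
    qpcr = qpcr, summary = summary
  )
  class(report) <- "medip_report"

  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    write_tsv_table(track, file.path(outdir, "probes_normalized.tsv"))
    write_deps_bed(deps, file.path(outdir, "deps.bed"))
    write_tsv_table(mirna_de, file.path(outdir, "mirna_de.tsv"))
    write_tsv_table(gene_de, file.path(outdir, "gene_de.tsv"))
    write_bed(catalogs$imprinted, file.path(outdir, "imprinted.bed"))
    jsonlite::write_json(as.list(summary), file.path(outdir, "report.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  report
}

#' Planted-DMR recovery of a set of DEP calls
#'
#' Recall is the fraction of planted DMRs overlapped (>= 1 bp) by at
#' least one peak; the false-discovery proportion is the fraction of
#' peaks overlapping no planted DMR.
#'
#' @param peaks A peak tibble (`chrom`, `start`, `end`).
#' @param truth Planted-DMR tibble from [simulate_tiling()].
#' @return A one-row tibble: `recall`, `false_discovery`, `n_truth`,
#'   `n_peaks`.
#' @export
dmr_recovery <- function(peaks, truth) {
  if (nrow(truth) == 0L || nrow(peaks) == 0L) {
    return(tibble(
      recall = if (nrow(truth) == 0L) NA_real_ else 0,
      false_discovery = if (nrow(peaks) == 0L) NA_real_ else 1,
      n_truth = nrow(truth), n_peaks = nrow(peaks)
    ))
  }
  hits <- overlap_pairs(truth, peaks)
  tibble(
    recall = length(unique(S4Vectors::queryHits(hits))) / nrow(truth),
    false_discovery = 1 - length(unique(S4Vectors::subjectHits(hits))) / nrow(peaks),
    n_truth = nrow(truth),
    n_peaks = nrow(peaks)
  )
}

#' @export
print.medip_report <- function(x, ...) {
  cat("<medip_report>\n")
  s <- x$summary
  cat(sprintf("  probes: %d | DEPs called/accepted/shortlisted: %d/%d/%d\n",
              s$n_probes, s$n_dep_called, s$n_dep_accepted, s$n_dep_shortlist))
  cat(sprintf("  planted DMRs: %d | recall %.3f | false discovery %.3f\n",
              s$n_planted_dmr, s$dmr_recall, s$dmr_false_discovery))
  cat(sprintf("  cluster purity: %.3f\n", s$cluster_purity))
  cat(sprintf("  DE miRNA/gene: %d/%d | inverse pairs kept: %d (%d genes)\n",
              s$n_de_mirna, s$n_de_gene, s$n_inverse_pairs_kept, s$n_target_genes))
  cat(sprintf("  promoter concordance: %.3f | miRNA imprinted fraction: %.3f (p=%.3g)\n",
              s$fraction_promoter_concordant, s$fraction_mirna_imprinted,
              s$imprinted_enrichment_p))
  cat(sprintf("  qPCR fold change: %.3f (p=%.3g)\n",
              s$qpcr_fold_change, s$qpcr_p_value))
  invisible(x)
}
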