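# 0-based half-open tibble -> GRanges (1-based closed) for overlap work.
as_granges0 <- function(x, seqlevels = unique(x$chrom)) {
  GenomicRanges::GRanges(
    seqnames = factor(x$chrom, levels = seqlevels),
    ranges = IRanges::IRanges(start = x$start + 1, end = x$end)
  )
}

# findOverlaps on two interval tibbles with a shared seqlevel set.
overlap_pairs <- function(a, b) {
  lv <- union(unique(a$chrom), unique(b$chrom))
  GenomicRanges::findOverlaps(as_granges0(a, lv), as_granges0(b, lv))
}

confidence_levels <- c("predicted", "low", "moderate", "high")

#' Filter miRNA-target pairs to inverse, confident, tissue-matched hits
#'
#' Retains predicted miRNA-to-gene interactions where (1) both the miRNA
#' and the gene pass their differential-expression filters, (2) their
#' fold changes have opposite signs (the inverse-relationship criterion),
#' (3) the interaction confidence is at least `min_confidence` on the
#' scale predicted < low < moderate < high, and (4) the tissue label
#' matches. Pairs referencing features absent from the DE tables are
#' dropped with a warning. The result carries, per retained gene, the
#' number of distinct miRNAs targeting it.
#'
#' @param mirna_de,gene_de [differential_expression()] results.
#' @param pairs Target table: `mirna_id`, `gene_id`, `confidence`,
#'   `tissue`.
#' @param min_confidence Minimum confidence label (default
#'   `"moderate"`).
#' @param tissue Required tissue label (default `"brain"`; `NULL` skips
#'   the tissue filter).
#' @return A tibble of retained pairs with `mirna_fc`, `gene_fc` and
#'   `n_mirnas_targeting_gene` columns.
#' @export
inverse_pair_filter <- function(mirna_de, gene_de, pairs,
                                min_confidence = "moderate",
                                tissue = "brain") {
  need <- c("mirna_id", "gene_id", "confidence", "tissue")
  if (!all(need %in% names(pairs))) {
    abort("pairs must have mirna_id, gene_id, confidence, tissue")
  }
  if (anyDuplicated(pairs[c("mirna_id", "gene_id")]) > 0L) {
    abort("duplicate (mirna_id, gene_id) rows in pair table")
  }
  if (!min_confidence %in% confidence_levels) {
    abort(paste("min_confidence must be one of:",
                paste(confidence_levels, collapse = ", ")))
  }
  unknown <- !(pairs$mirna_id %in% mirna_de$feature_id) |
    !(pairs$gene_id %in% gene_de$feature_id)
  if (any(unknown)) {
    warn(sprintf("skipping %d pair(s) referencing unknown features", sum(unknown)))
    pairs <- pairs[!unknown, , drop = FALSE]
  }
  conf_rank <- match(pairs$confidence, confidence_levels)
  if (anyNA(conf_rank)) abort("unknown confidence label in pair table")

  m_idx <- match(pairs$mirna_id, mirna_de$feature_id)
  g_idx <- match(pairs$gene_id, gene_de$feature_id)
  keep <- conf_rank >= match(min_confidence, confidence_levels) &
    mirna_de$passes_filter[m_idx] & gene_de$passes_filter[g_idx] &
    sign(mirna_de$fold_change[m_idx]) != sign(gene_de$fold_change[g_idx])
  if (!is.null(tissue)) keep <- keep & pairs$tissue == tissue
  out <- pairs[which(keep), , drop = FALSE]
  out$mirna_fc <- mirna_de$fold_change[m_idx[which(keep)]]
  out$gene_fc <- gene_de$fold_change[g_idx[which(keep)]]
  out |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::mutate(n_mirnas_targeting_gene = dplyr::n_distinct(.data$mirna_id)) |>
    dplyr::ungroup()
}

#' Concordance between promoter methylation peaks and expression changes
#'
#' Computes the fraction of differentially expressed features whose
#' promoter interval overlaps (by at least 1 bp, half-open convention)
#' at least one accepted differential enrichment peak, together with the
#' inverse fraction (accepted DEPs falling in the promoter of at least
#' one DE feature). Features with no promoter annotation are excluded
#' from the denominator and reported separately.
#'
#' @param deps A [call_deps()] result (only rows with `accepted = TRUE`
#'   are used; a plain peak tibble without `accepted` is used as is).
#' @param de_results A [differential_expression()] result; rows with
#'   `passes_filter = TRUE` define the DE set.
#' @param promoters Promoter catalog: `chrom`, `start`, `end`, `name`,
#'   where `name` is the feature id the promoter belongs to.
#' @return A one-row tibble: `n_de`, `n_annotated`, `n_unannotated`,
#'   `n_concordant`, `fraction_concordant`, `n_deps`,
#'   `n_deps_in_de_promoters`, `fraction_deps_in_de_promoters`.
#' @export
promoter_concordance <- function(deps, de_results, promoters) {
  if ("accepted" %in% names(deps)) {
    deps <- deps[deps$accepted, , drop = FALSE]
  }
  de <- de_results[de_results$passes_filter, , drop = FALSE]
  ann <- de$feature_id %in% promoters$name
  de_prom <- promoters[promoters$name %in% de$feature_id, , drop = FALSE]

  zero <- tibble(
    n_de = nrow(de), n_annotated = sum(ann), n_unannotated = sum(!ann),
    n_concordant = 0L, fraction_concordant = 0,
    n_deps = nrow(deps), n_deps_in_de_promoters = 0L,
    fraction_deps_in_de_promoters = 0
  )
  if (nrow(deps) == 0L || nrow(de_prom) == 0L) return(zero)

  hits <- overlap_pairs(de_prom, deps)
  feat_hit <- unique(de_prom$name[S4Vectors::queryHits(hits)])
  dep_hit <- unique(S4Vectors::subjectHits(hits))
  tibble(
    n_de = nrow(de),
    n_annotated = sum(ann),
    n_unannotated = sum(!ann),
    n_concordant = length(feat_hit),
    fraction_concordant = if (sum(ann) > 0) length(feat_hit) / sum(ann) else 0,
    n_deps = nrow(deps),
    n_deps_in_de_promoters = length(dep_hit),
    fraction_deps_in_de_promoters = length(dep_hit) / nrow(deps)
  )
}

#' Map genomic features to catalog regions
#'
#' Labels each feature with every catalog region it overlaps (any
#' overlap of at least 1 bp; abutting half-open intervals do not touch)
#' and summarises per-region counts plus the overall fraction of
#' features mapped to at least one region. Features on chromosomes
#' absent from the catalog are simply unmapped.
#'
#' @param features Tibble: `feature_id`, `chrom`, `start`, `end`.
#' @param catalog Region set: `chrom`, `start`, `end`, `name`.
#' @return A list: `membership` (one row per feature-region hit),
#'   `per_region` (region, n), `n_features`, `n_mapped`,
#'   `fraction_mapped`.
#' @export
map_to_regions <- function(features, catalog) {
  need <- c("feature_id", "chrom", "start", "end")
  if (!all(need %in% names(features))) {
    abort("features need feature_id, chrom, start, end")
  }
  if (nrow(features) == 0L) {
    return(list(
      membership = tibble(feature_id = character(), region = character()),
      per_region = tibble(region = catalog$name, n = 0L),
      n_features = 0L, n_mapped = 0L, fraction_mapped = NaN
    ))
  }
  hits <- overlap_pairs(features, catalog)
  membership <- tibble(
    feature_id = features$feature_id[S4Vectors::queryHits(hits)],
    region = catalog$name[S4Vectors::subjectHits(hits)]
  )
  per_region <- membership |>
    dplyr::count(.data$region) |>
    dplyr::right_join(tibble(region = catalog$name), by = "region") |>
    dplyr::mutate(n = dplyr::coalesce(.data$n, 0L))
  n_mapped <- dplyr::n_distinct(membership$feature_id)
  list(
    membership = membership,
    per_region = per_region,
    n_features = nrow(features),
    n_mapped = n_mapped,
    fraction_mapped = n_mapped / nrow(features)
  )
}

#' Permutation test for region enrichment of a feature set
#'
#' Tests whether more of the selected features map into the catalog
#' regions than expected for a random draw of the same size from the
#' universe. The p-value is `(1 + b) / (n_perm + 1)` where `b` counts
#' permuted draws whose mapped count reaches the observed one.
#'
#' @param features Character vector of selected feature ids (must be a
#'   subset of the universe), or a tibble with a `feature_id` column.
#' @param catalog Region set as in [map_to_regions()].
#' @param universe Tibble of all candidate features with coordinates
#'   (`feature_id`, `chrom`, `start`, `end`).
#' @param n_perm Number of permutations.
#' @param seed Integer seed (mandatory for reproducibility).
#' @return A one-row tibble: `observed`, `expected`, `p_value`,
#'   `n_features`, `n_perm`.
#' @export
region_enrichment <- function(features, catalog, universe, n_perm = 999, seed) {
  if (missing(seed)) abort("seed is required")
  if (is.data.frame(features)) features <- features$feature_id
  if (!all(features %in% universe$feature_id)) {
    abort("features must be a subset of the universe")
  }
  if (length(features) > nrow(universe)) abort("more features than universe rows")
  mapped <- map_to_regions(universe, catalog)
  is_mapped <- universe$feature_id %in% mapped$membership$feature_id
  obs <- sum(is_mapped[universe$feature_id %in% features])
  k <- length(unique(features))
  perm <- with_local_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      sum(sample(is_mapped, k))
    }, numeric(1))
  })
  tibble(
    observed = obs,
    expected = k * mean(is_mapped),
    p_value = (1 + sum(perm >= obs)) / (n_perm + 1),
    n_features = k,
    n_perm = n_perm
  )
}
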