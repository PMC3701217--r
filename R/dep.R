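#' DEP filter parameters
#'
#' Defaults follow the published two-stage differential-enrichment-peak
#' (DEP) filter: (i) at least one group's median log2(MeDIP/Input)
#' within the peak must reach `median_ratio_min` and the peak-median
#' M-prime must agree in sign with the called direction; (ii) at least
#' `cv_probe_fraction` of member probes must have a replicate
#' coefficient of variability (CV) at or below `cv_max` in both groups.
#' `top_fraction` drives the final shortlist of peaks that are in both
#' the top PeakScore and top |PeakDMValue| fractions.
#'
#' @param median_ratio_min Minimum within-peak median log2(MeDIP/Input)
#'   for at least one group (log2 units).
#' @param cv_max Maximum per-probe CV.
#' @param cv_probe_fraction Minimum fraction of member probes passing the
#'   CV bound in both groups.
#' @param top_fraction Fraction kept by [top_peak_filter()].
#' @return A list of class `dep_filter_params`.
#' @export
dep_filter_params <- function(median_ratio_min = 0.3, cv_max = 0.8,
                              cv_probe_fraction = 0.5, top_fraction = 0.2) {
  p <- list(
    median_ratio_min = as.numeric(median_ratio_min),
    cv_max = as.numeric(cv_max),
    cv_probe_fraction = as.numeric(cv_probe_fraction),
    top_fraction = as.numeric(top_fraction)
  )
  if (p$cv_probe_fraction <= 0 || p$cv_probe_fraction > 1 ||
      p$top_fraction <= 0 || p$top_fraction > 1) {
    abort("fractions must be in (0, 1]")
  }
  class(p) <- "dep_filter_params"
  p
}

#' Per-probe M-prime differential-enrichment track
#'
#' Computes, per probe, M-prime = mean log2(MeDIP/Input) over treated
#' replicates minus the mean over control replicates, together with each
#' group's mean and its replicate coefficient of variability
#' (CV = sd / |mean|; a group mean within 1e-8 of zero gives CV = Inf,
#' which always fails the CV criterion).
#'
#' @param track A probe track with `treated_*` and `control_*` sample
#'   columns.
#' @param treated,control Group labels in the sample column names.
#' @return A tibble: `probe_id`, `chrom`, `start`, `end`, `mprime`,
#'   `mean_treated`, `mean_control`, `cv_treated`, `cv_control`.
#' @examples
#' tr <- tibble::tibble(
#'   probe_id = "p1", chrom = "chr1", start = 0, end = 50,
#'   treated_1 = 1.1, treated_2 = 0.9, control_1 = 0.5, control_2 = 0.3
#' )
#' compute_mprime(tr)
#' @export
compute_mprime <- function(track, treated = "treated", control = "control") {
  check_track(track)
  info <- sample_info(track)
  t_cols <- info$sample[info$group == treated]
  c_cols <- info$sample[info$group == control]
  if (length(t_cols) == 0L || length(c_cols) == 0L) {
    abort("both groups must have at least one replicate")
  }
  tmat <- as.matrix(track[t_cols])
  cmat <- as.matrix(track[c_cols])
  grp_cv <- function(m) {
    mu <- rowMeans(m)
    s <- if (ncol(m) > 1L) apply(m, 1, sd) else rep(0, nrow(m))
    ifelse(abs(mu) < 1e-8, Inf, s / abs(mu))
  }
  tibble(
    probe_id = track$probe_id, chrom = track$chrom,
    start = track$start, end = track$end,
    mprime = rowMeans(tmat) - rowMeans(cmat),
    mean_treated = rowMeans(tmat),
    mean_control = rowMeans(cmat),
    cv_treated = grp_cv(tmat),
    cv_control = grp_cv(cmat)
  )
}

#' Call and filter differential enrichment peaks (DEPs)
#'
#' Runs the sliding-window peak finder on the M-prime track twice --
#' once on M-prime (methylation gains) and once on its negation
#' (losses) -- then applies the two-stage DEP filter to every peak:
#' criterion (i), at least one group's within-peak median
#' log2(MeDIP/Input) at or above `median_ratio_min` AND a peak-median
#' M-prime whose sign matches the direction; criterion (ii), at least
#' half (by default) of member probes with CV at or below `cv_max` in
#' both groups. Peaks failing a criterion are kept in the output with
#' `accepted = FALSE` and a `reason` code (`"median_ratio"`, `"cv"`, or
#' both, semicolon-separated).
#'
#' @param mtrack Output of [compute_mprime()].
#' @param params A [peak_params()].
#' @param filter A [dep_filter_params()].
#' @return A tibble of class `dep_calls`: peak columns from
#'   [find_peaks()] plus `direction` (`"gain"`/`"loss"`),
#'   `peak_dm_value` (median member M-prime, signed), `median_treated`,
#'   `median_control`, `cv_pass_fraction`, `accepted`, `reason`.
#' @export
call_deps <- function(mtrack, params = peak_params(),
                      filter = dep_filter_params()) {
  stopifnot(inherits(filter, "dep_filter_params"))
  need <- c("probe_id", "chrom", "start", "end", "mprime",
            "mean_treated", "mean_control", "cv_treated", "cv_control")
  if (!all(need %in% names(mtrack))) abort("mtrack must come from compute_mprime()")

  scan_one <- function(direction) {
    m <- mtrack
    m$.score <- if (direction == "gain") m$mprime else -m$mprime
    pv <- probe_pvalues(m, ".score", params)
    pk <- find_peaks(pv, params)
    if (nrow(pk) > 0L) pk$direction <- direction
    pk
  }
  peaks <- dplyr::bind_rows(scan_one("gain"), scan_one("loss"))
  if (nrow(peaks) == 0L) {
    out <- tibble(
      chrom = character(), start = numeric(), end = numeric(),
      name = character(), n_probes = integer(), peak_score = numeric(),
      mean_p = numeric(), probe_ids = list(), direction = character(),
      peak_dm_value = numeric(), median_treated = numeric(),
      median_control = numeric(), cv_pass_fraction = numeric(),
      accepted = logical(), reason = character()
    )
    class(out) <- c("dep_calls", class(out))
    return(out)
  }

  idx_of <- setNames(seq_len(nrow(mtrack)), mtrack$probe_id)
  stats_per_peak <- purrr::map_dfr(peaks$probe_ids, function(ids) {
    i <- idx_of[ids]
    cv_ok <- mtrack$cv_treated[i] <= filter$cv_max &
      mtrack$cv_control[i] <= filter$cv_max
    tibble(
      peak_dm_value = median(mtrack$mprime[i]),
      median_treated = median(mtrack$mean_treated[i]),
      median_control = median(mtrack$mean_control[i]),
      cv_pass_fraction = mean(cv_ok)
    )
  })
  out <- dplyr::bind_cols(peaks, stats_per_peak) |>
    dplyr::mutate(
      crit_median = (.data$median_treated >= filter$median_ratio_min |
                       .data$median_control >= filter$median_ratio_min) &
        ifelse(.data$direction == "gain",
               .data$peak_dm_value > 0, .data$peak_dm_value < 0),
      crit_cv = .data$cv_pass_fraction >= filter$cv_probe_fraction,
      accepted = .data$crit_median & .data$crit_cv,
      reason = dplyr::case_when(
        .data$accepted ~ "",
        !.data$crit_median & !.data$crit_cv ~ "median_ratio;cv",
        !.data$crit_median ~ "median_ratio",
        TRUE ~ "cv"
      )
    ) |>
    dplyr::select(-"crit_median", -"crit_cv") |>
    dplyr::arrange(.data$chrom, .data$start, .data$direction) |>
    dplyr::mutate(name = sprintf("dep_%04d", dplyr::row_number()))
  class(out) <- c("dep_calls", class(out))
  out
}

#' Shortlist peaks in both top PeakScore and top PeakDMValue fractions
#'
#' Returns the intersection of the top `ceiling(f * n)` peaks ranked by
#' `peak_score` and the top `ceiling(f * n)` ranked by
#' `abs(peak_dm_value)`. Rank ties are broken by genomic order
#' (chrom, start) so the shortlist is deterministic.
#'
#' @param peaks A peak tibble carrying `peak_score` and `peak_dm_value`
#'   (e.g. accepted rows of [call_deps()]).
#' @param top_fraction Fraction kept by each ranking (default 0.2).
#' @return The shortlisted peaks in genomic order.
#' @export
top_peak_filter <- function(peaks, top_fraction = 0.2) {
  if (top_fraction <= 0 || top_fraction > 1) abort("top_fraction must be in (0, 1]")
  if (nrow(peaks) == 0L) return(peaks)
  if (!all(c("peak_score", "peak_dm_value") %in% names(peaks))) {
    abort("peaks must carry peak_score and peak_dm_value")
  }
  k <- ceiling(top_fraction * nrow(peaks))
  by_score <- order(-peaks$peak_score, peaks$chrom, peaks$start)[seq_len(k)]
  by_dm <- order(-abs(peaks$peak_dm_value), peaks$chrom, peaks$start)[seq_len(k)]
  keep <- sort(intersect(by_score, by_dm))
  peaks[keep, , drop = FALSE]
}

#' Per-sample PeakScore matrix over DEP regions
#'
#' Recomputes, for every sample column of the (normalised) probe track,
#' the sliding-window per-probe p-values and summarises each DEP region
#' as its PeakScore (-log10 of the mean member p-value) in that sample.
#' A region with no member probes in the track scores 0. The result is
#' the regions-by-samples matrix fed to hierarchical clustering.
#'
#' @param track The probe track the peaks were called from.
#' @param peaks A peak tibble with a `probe_ids` list column.
#' @param params A [peak_params()].
#' @return A tibble: `name` (peak) plus one numeric column per sample.
#' @export
peak_score_matrix <- function(track, peaks, params = peak_params()) {
  check_track(track)
  if (!"probe_ids" %in% names(peaks)) abort("peaks must carry probe_ids")
  smp <- sample_cols(track)
  if (length(smp) < 2L) abort("need >= 2 sample columns")
  out <- tibble(name = peaks$name)
  for (s in smp) {
    pv <- probe_pvalues(track, s, params)
    p_of <- setNames(pv$p_value, pv$probe_id)
    out[[s]] <- vapply(peaks$probe_ids, function(ids) {
      p <- p_of[ids]
      p <- p[!is.na(p)]
      if (length(p) == 0L) 0 else -log10(mean(p))
    }, numeric(1))
  }
  out
}
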