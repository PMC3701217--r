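#' Sliding-window peak-finder parameters
#'
#' The defaults reproduce the vendor sliding-window settings standard for
#' promoter tiling arrays: a 750 bp sliding window, a per-probe score
#' cutoff of 2 on the -log10(p) scale, at least 2 probes per peak, and a
#' maximum spacing of 500 bp between neighbouring probes within a peak.
#'
#' @param window_bp Full sliding-window width in bp.
#' @param min_probes Minimum member probes for a peak to be reported.
#' @param probe_score_cutoff Per-probe qualification threshold on
#'   -log10(p).
#' @param max_gap_bp Maximum midpoint spacing between consecutive member
#'   probes.
#' @return A list of class `peak_params`.
#' @export
peak_params <- function(window_bp = 750, min_probes = 2,
                        probe_score_cutoff = 2, max_gap_bp = 500) {
  p <- list(
    window_bp = as.numeric(window_bp),
    min_probes = as.integer(min_probes),
    probe_score_cutoff = as.numeric(probe_score_cutoff),
    max_gap_bp = as.numeric(max_gap_bp)
  )
  if (any(unlist(p) <= 0)) abort("all peak parameters must be positive")
  class(p) <- "peak_params"
  p
}

#' Per-probe sliding-window enrichment p-values
#'
#' For each probe, tests whether the score values of the probes inside
#' the centred `window_bp` window are shifted upward relative to the
#' track-wide score distribution, by a one-sided Wilcoxon rank-sum test
#' of the window members against all remaining probes. Ties take
#' midranks; the p-value uses the tie-corrected, continuity-corrected
#' normal approximation and is never exactly zero. Windows never cross
#' chromosomes. A probe whose comparison set is empty (single-probe
#' track, or window spanning the whole track) gets p = 1.
#'
#' @param track A sorted probe track tibble.
#' @param score_col Name of the numeric column holding the per-probe
#'   statistic to scan (e.g. `"mprime"` or a sample column).
#' @param params A [peak_params()].
#' @return The track's probes as a tibble with columns `probe_id`,
#'   `chrom`, `start`, `end`, `score`, `p_value`.
#' @export
probe_pvalues <- function(track, score_col, params = peak_params()) {
  stopifnot(inherits(params, "peak_params"))
  if (!score_col %in% names(track)) {
    abort(paste0("no column '", score_col, "' in track"))
  }
  check_track(track, require_finite = FALSE)
  score <- track[[score_col]]
  if (!all(is.finite(score))) abort("non-finite scores")
  n <- length(score)
  r <- rank(score, ties.method = "average")
  # tie correction term shared by all windows
  tt <- table(score)
  tie_term <- sum(tt^3 - tt)

  half <- params$window_bp / 2
  mids <- probe_mid(track$start, track$end)
  p <- rep(1, n)
  for (ch in unique(track$chrom)) {
    idx <- which(track$chrom == ch)
    m_mid <- mids[idx]
    lo <- findInterval(m_mid - half, m_mid, left.open = TRUE) + 1L
    hi <- findInterval(m_mid + half, m_mid)
    csr <- c(0, cumsum(r[idx]))
    w_sum <- csr[hi + 1L] - csr[lo]
    m <- hi - lo + 1L
    n_rest <- n - m
    u <- w_sum - m * (m + 1) / 2
    mu <- m * n_rest / 2
    v <- m * n_rest / 12 * ((n + 1) - tie_term / (n * (n - 1)))
    ok <- n_rest > 0L & v > 0
    z <- rep(-Inf, length(m))
    z[ok] <- (u[ok] - 0.5 - mu[ok]) / sqrt(v[ok])
    p[idx] <- ifelse(ok, pnorm(z, lower.tail = FALSE), 1)
  }
  tibble(
    probe_id = track$probe_id, chrom = track$chrom,
    start = track$start, end = track$end,
    score = score, p_value = pmin(p, 1)
  )
}

#' Call peaks from per-probe p-values
#'
#' A peak is a maximal run of qualifying probes (-log10 p at or above
#' `probe_score_cutoff`), split wherever the midpoint spacing between
#' consecutive qualifying probes exceeds `max_gap_bp`, and retained only
#' when it holds at least `min_probes` probes. The PeakScore is the
#' -log10 of the mean member p-value, so a PeakScore of 2 means the
#' average p-value was 0.01.
#'
#' @param pvalues Output of [probe_pvalues()].
#' @param params A [peak_params()].
#' @return A tibble of peaks: `chrom`, `start`, `end`, `name`,
#'   `n_probes`, `peak_score`, `mean_p`, `probe_ids` (list column),
#'   sorted and disjoint.
#' @export
find_peaks <- function(pvalues, params = peak_params()) {
  stopifnot(inherits(params, "peak_params"))
  need <- c("probe_id", "chrom", "start", "end", "p_value")
  if (!all(need %in% names(pvalues))) {
    abort("pvalues must come from probe_pvalues()")
  }
  q <- pvalues[-log10(pvalues$p_value) >= params$probe_score_cutoff, , drop = FALSE]
  empty <- tibble(
    chrom = character(), start = numeric(), end = numeric(),
    name = character(), n_probes = integer(), peak_score = numeric(),
    mean_p = numeric(), probe_ids = list()
  )
  if (nrow(q) == 0L) return(empty)

  mids <- probe_mid(q$start, q$end)
  new_run <- c(TRUE, q$chrom[-1] != q$chrom[-nrow(q)] |
                 diff(mids) > params$max_gap_bp)
  run_id <- cumsum(new_run)
  peaks <- q |>
    dplyr::mutate(.run = run_id) |>
    dplyr::group_by(.data$.run) |>
    dplyr::summarise(
      chrom = dplyr::first(.data$chrom),
      start = min(.data$start),
      end = max(.data$end),
      n_probes = dplyr::n(),
      mean_p = mean(.data$p_value),
      probe_ids = list(.data$probe_id),
      .groups = "drop"
    ) |>
    dplyr::filter(.data$n_probes >= params$min_probes) |>
    dplyr::mutate(peak_score = -log10(.data$mean_p)) |>
    dplyr::arrange(.data$chrom, .data$start)
  if (nrow(peaks) == 0L) return(empty)
  peaks |>
    dplyr::mutate(name = sprintf("peak_%04d", dplyr::row_number())) |>
    dplyr::select("chrom", "start", "end", "name", "n_probes",
                  "peak_score", "mean_p", "probe_ids")
}
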