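#' Median-centring quantile normalisation of a probe track
#'
#' Forces every sample column onto the identical value distribution (the
#' per-rank mean across samples, with tied ranks receiving the mean of
#' their rank range), then median-centres each column at zero. This is
#' the standard two-colour tiling-array normalisation applied to
#' log2(MeDIP/Input) ratios before peak finding.
#'
#' @param track A probe track tibble (`probe_id`, `chrom`, `start`,
#'   `end` + one column per sample).
#' @return The track with normalised sample columns.
#' @examples
#' tr <- tibble::tibble(
#'   probe_id = c("a", "b", "c"), chrom = "chr1",
#'   start = c(0, 100, 200), end = c(50, 150, 250),
#'   treated_1 = c(1, 2, 3), control_1 = c(4, 5, 6)
#' )
#' quantile_normalize(tr)
#' @export
quantile_normalize <- function(track) {
  check_track(track)
  smp <- sample_cols(track)
  if (length(smp) < 2L) abort("quantile normalisation needs >= 2 sample columns")
  x <- as.matrix(track[smp])
  if (!all(is.finite(x))) abort("non-finite values in probe track")
  sorted_mean <- rowMeans(apply(x, 2, sort))
  out <- apply(x, 2, function(col) {
    # midranks so ties map to the mean of their target quantiles
    r <- rank(col, ties.method = "average")
    stats::approx(seq_along(sorted_mean), sorted_mean, xout = r)$y
  })
  out <- sweep(out, 2, apply(out, 2, median))
  track[smp] <- as_tibble(out)
  track
}

#' Running-mean (linear) smoothing of a probe track
#'
#' Replaces each probe's value with the mean over all probes on the same
#' chromosome whose midpoints lie within `window_bp / 2` of its midpoint,
#' independently per sample. Windows never cross chromosomes; a probe
#' with no neighbours keeps its own value (it is its own window member).
#'
#' @param track A sorted probe track tibble.
#' @param window_bp Full window width in bp (default 300).
#' @return The track with smoothed sample columns.
#' @export
linear_smooth <- function(track, window_bp = 300) {
  check_track(track)
  if (window_bp <= 0) abort("window_bp must be > 0")
  smp <- sample_cols(track)
  half <- window_bp / 2
  mids <- probe_mid(track$start, track$end)
  x <- as.matrix(track[smp])
  out <- x
  for (ch in unique(track$chrom)) {
    idx <- which(track$chrom == ch)
    m <- mids[idx]
    lo <- findInterval(m - half, m, left.open = TRUE) + 1L
    hi <- findInterval(m + half, m)
    cs <- rbind(0, apply(x[idx, , drop = FALSE], 2, cumsum))
    out[idx, ] <- (cs[hi + 1L, , drop = FALSE] - cs[lo, , drop = FALSE]) / (hi - lo + 1L)
  }
  track[smp] <- as_tibble(out)
  track
}
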