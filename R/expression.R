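#' Per-feature differential expression (one-way ANOVA, fold-change filter)
#'
#' For every feature of a log2-scale expression matrix, computes a
#' one-way ANOVA p-value between the two groups and a signed linear
#' fold change: `2^(mean_treated - mean_control)` when at or above 1,
#' and the negative reciprocal otherwise (a ratio of 1/1.24 is reported
#' as -1.24, the convention of the array literature). A feature passes
#' the stringency filter when `|fold_change| >= fc_min` and
#' `p <= alpha`; defaults reproduce the 1.2-fold / P = 0.05 criterion.
#' Features in a group with fewer than 2 samples get `p = NA` and are
#' flagged untestable.
#'
#' @param mat Expression tibble: `feature_id` plus `treated_*` /
#'   `control_*` sample columns of log2 intensities.
#' @param fc_min Minimum absolute linear fold change.
#' @param alpha Significance threshold on the (optionally adjusted)
#'   p-value.
#' @param adjust `"none"` (default, per-feature testing as published) or
#'   `"BH"` for Benjamini-Hochberg adjustment before filtering.
#' @param treated,control Group labels.
#' @return A tibble of class `de_result`: `feature_id`, `log2_fc`,
#'   `fold_change`, `p_value`, `testable`, `passes_filter`.
#' @examples
#' m <- tibble::tibble(
#'   feature_id = c("f1", "f2"),
#'   treated_1 = c(8.3, 8), treated_2 = c(8.25, 8.1), treated_3 = c(8.35, 7.9),
#'   control_1 = c(8.0, 8.1), control_2 = c(8.05, 8.0), control_3 = c(7.95, 8.0)
#' )
#' differential_expression(m)
#' @export
differential_expression <- function(mat, fc_min = 1.2, alpha = 0.05,
                                    adjust = c("none", "BH"),
                                    treated = "treated", control = "control") {
  adjust <- match.arg(adjust)
  if (!"feature_id" %in% names(mat)) abort("expression matrix needs feature_id")
  info <- sample_info(mat)
  t_cols <- info$sample[info$group == treated]
  c_cols <- info$sample[info$group == control]
  if (length(t_cols) == 0L || length(c_cols) == 0L) abort("two groups required")
  tmat <- as.matrix(mat[t_cols])
  cmat <- as.matrix(mat[c_cols])
  if (!all(is.finite(tmat)) || !all(is.finite(cmat))) {
    abort("non-finite expression values")
  }
  testable <- length(t_cols) >= 2L && length(c_cols) >= 2L
  lfc <- rowMeans(tmat) - rowMeans(cmat)
  grp <- factor(rep(c("t", "c"), c(length(t_cols), length(c_cols))))
  pv <- if (testable) {
    vapply(seq_len(nrow(mat)), function(i) {
      y <- c(tmat[i, ], cmat[i, ])
      if (sd(y) == 0) return(1)
      oneway.test(y ~ grp, var.equal = TRUE)$p.value
    }, numeric(1))
  } else rep(NA_real_, nrow(mat))
  p_used <- if (adjust == "BH" && testable) p.adjust(pv, "BH") else pv
  ratio <- 2^lfc
  out <- tibble(
    feature_id = mat$feature_id,
    log2_fc = lfc,
    fold_change = ifelse(ratio >= 1, ratio, -1 / ratio),
    p_value = pv,
    p_adjusted = if (adjust == "BH") p_used else NA_real_,
    testable = testable,
    passes_filter = testable & abs(ifelse(ratio >= 1, ratio, -1 / ratio)) >= fc_min &
      !is.na(p_used) & p_used <= alpha
  )
  class(out) <- c("de_result", class(out))
  attr(out, "fc_min") <- fc_min
  attr(out, "alpha") <- alpha
  out
}

#' Relative quantitation by the delta-delta-Ct method
#'
#' Technical replicates are averaged per sample and assay; per sample,
#' delta-Ct = mean target Ct minus mean endogenous-control Ct; the
#' delta-delta-Ct is the treated-group mean delta-Ct minus the
#' control-group mean, and the fold change is `2^(-ddct)`. Group
#' difference is assessed by an unpaired two-sided Student's t-test on
#' the per-sample delta-Ct values.
#'
#' @param table A qPCR tibble: `sample`, `group`, `target_ct`,
#'   `control_ct`, one row per technical replicate (see
#'   [simulate_qpcr()]).
#' @param treated,control Group labels.
#' @return A one-row tibble: `ddct`, `fold_change`, `p_value`,
#'   `n_treated`, `n_control`.
#' @export
ddct_fold_change <- function(table, treated = "treated", control = "control") {
  need <- c("sample", "group", "target_ct", "control_ct")
  if (!all(need %in% names(table))) {
    abort("qPCR table needs sample, group, target_ct, control_ct")
  }
  if (any(!is.finite(table$target_ct)) || any(!is.finite(table$control_ct))) {
    abort("missing Ct value (every sample needs target and endogenous control)")
  }
  if (any(table$target_ct <= 0) || any(table$control_ct <= 0)) {
    abort("Ct values must be positive")
  }
  per_sample <- table |>
    dplyr::group_by(.data$sample, .data$group) |>
    dplyr::summarise(
      dct = mean(.data$target_ct) - mean(.data$control_ct),
      .groups = "drop"
    )
  dt <- per_sample$dct[per_sample$group == treated]
  dc <- per_sample$dct[per_sample$group == control]
  if (length(dt) == 0L || length(dc) == 0L) abort("both groups must be present")
  ddct <- mean(dt) - mean(dc)
  p <- if (length(dt) >= 2L && length(dc) >= 2L) {
    # constant delta-Ct in both groups leaves the t statistic undefined
    tryCatch(t.test(dt, dc, var.equal = TRUE)$p.value,
             error = function(e) NA_real_)
  } else NA_real_
  tibble(
    ddct = ddct,
    fold_change = 2^(-ddct),
    p_value = p,
    n_treated = length(dt),
    n_control = length(dc)
  )
}
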