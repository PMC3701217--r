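#' Tidy and glance methods
#'
#' broom-style accessors: `tidy()` returns a plain per-observation
#' tibble, `glance()` a one-row summary.
#'
#' @param x A `de_result`, `dep_calls` or `medip_report` object.
#' @param ... Unused.
#' @return A tibble.
#' @name medipdmr-tidiers
NULL

#' @rdname medipdmr-tidiers
#' @export
tidy.de_result <- function(x, ...) {
  out <- x
  class(out) <- class(tibble())
  out
}

#' @rdname medipdmr-tidiers
#' @export
glance.de_result <- function(x, ...) {
  tibble(
    n_features = nrow(x),
    n_testable = sum(x$testable),
    n_pass = sum(x$passes_filter),
    fc_min = attr(x, "fc_min") %||% NA_real_,
    alpha = attr(x, "alpha") %||% NA_real_
  )
}

#' @rdname medipdmr-tidiers
#' @export
tidy.dep_calls <- function(x, ...) {
  out <- x
  out$probe_ids <- NULL
  class(out) <- class(tibble())
  out
}

#' @rdname medipdmr-tidiers
#' @export
glance.dep_calls <- function(x, ...) {
  tibble(
    n_peaks = nrow(x),
    n_accepted = sum(x$accepted),
    n_gain = sum(x$direction == "gain" & x$accepted),
    n_loss = sum(x$direction == "loss" & x$accepted),
    n_rejected_median_ratio = sum(grepl("median_ratio", x$reason)),
    n_rejected_cv = sum(grepl("cv", x$reason))
  )
}

#' @rdname medipdmr-tidiers
#' @export
tidy.medip_report <- function(x, ...) {
  tidyr::pivot_longer(x$summary, dplyr::everything(),
                      names_to = "metric", values_to = "value")
}

#' @rdname medipdmr-tidiers
#' @export
glance.medip_report <- function(x, ...) {
  x$summary
}

`%||%` <- function(a, b) if (is.null(a)) b else a
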