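#' Read a BED file into an interval tibble
#'
#' Parses BED3+ lines into a tibble of 0-based half-open intervals,
#' preserved exactly as written. `track`/`browser` lines and `#`
#' comments are skipped. Malformed lines (fewer than 3 fields,
#' non-integer or negative coordinates, `start >= end`) raise an error
#' naming the offending line number.
#'
#' @param path Path to a BED file.
#' @return A tibble: `chrom`, `start`, `end`, plus `name`, `score`,
#'   `strand` when present.
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^(#|track\\b|browser\\b)", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  if (length(idx) == 0L) {
    return(tibble(chrom = character(), start = numeric(), end = numeric()))
  }
  fields <- strsplit(lines[idx], "[ \t]+")
  nf <- vapply(fields, length, integer(1))
  if (any(nf < 3L)) {
    abort(sprintf("BED line %d: fewer than 3 fields", idx[which(nf < 3L)[1]]))
  }
  get <- function(k) vapply(fields, function(f) if (length(f) >= k) f[k] else NA_character_,
                            character(1))
  s_chr <- get(1); s_start <- get(2); s_end <- get(3)
  start <- suppressWarnings(as.numeric(s_start))
  end <- suppressWarnings(as.numeric(s_end))
  bad_int <- is.na(start) | is.na(end) | start != floor(start) | end != floor(end)
  if (any(bad_int)) {
    abort(sprintf("BED line %d: non-integer coordinates", idx[which(bad_int)[1]]))
  }
  if (any(start < 0)) {
    abort(sprintf("BED line %d: negative coordinate", idx[which(start < 0)[1]]))
  }
  if (any(start >= end)) {
    abort(sprintf("BED line %d: start >= end (empty interval)",
                  idx[which(start >= end)[1]]))
  }
  out <- tibble(chrom = s_chr, start = start, end = end)
  if (max(nf) >= 4L) out$name <- get(4)
  if (max(nf) >= 5L) out$score <- suppressWarnings(as.numeric(get(5)))
  if (max(nf) >= 6L) out$strand <- get(6)
  out
}

#' Write an interval tibble as BED
#'
#' Writes `chrom`, `start`, `end` and, when present, `name`, `score`,
#' `strand` as tab-separated BED (0-based half-open coordinates,
#' unchanged).
#'
#' @param x Interval tibble.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  cols <- intersect(c("chrom", "start", "end", "name", "score", "strand"), names(x))
  if (!all(c("chrom", "start", "end") %in% cols)) {
    abort("need chrom, start, end columns")
  }
  df <- as.data.frame(x[cols])
  df$start <- format(df$start, scientific = FALSE, trim = TRUE)
  df$end <- format(df$end, scientific = FALSE, trim = TRUE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write DEP calls as BED6+ intervals
#'
#' Emits one BED line per peak with name, PeakScore as the score field,
#' `"."` strand, and extra columns: direction, number of probes,
#' PeakDMValue, mean member p-value, accepted flag and rejection reason.
#'
#' @param deps A [call_deps()] result.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_deps_bed <- function(deps, path) {
  df <- data.frame(
    chrom = deps$chrom,
    start = format(deps$start, scientific = FALSE, trim = TRUE),
    end = format(deps$end, scientific = FALSE, trim = TRUE),
    name = deps$name,
    score = signif(deps$peak_score, 6),
    strand = ".",
    direction = deps$direction,
    n_probes = deps$n_probes,
    peak_dm_value = signif(deps$peak_dm_value, 6),
    mean_p = signif(deps$mean_p, 6),
    accepted = deps$accepted,
    reason = ifelse(deps$reason == "", ".", deps$reason)
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read / write the probe-track and matrix TSV dialect
#'
#' Tab-separated with a header row; sample columns encode group and
#' replicate as `<group>_<replicate>`.
#'
#' @param x Tibble to write.
#' @param path File path.
#' @return `read_tsv_table()` returns a tibble; `write_tsv_table()`
#'   returns `path` invisibly.
#' @export
write_tsv_table <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' @rdname write_tsv_table
#' @export
read_tsv_table <- function(path) {
  as_tibble(utils::read.delim(path, check.names = FALSE,
                              stringsAsFactors = FALSE))
}
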