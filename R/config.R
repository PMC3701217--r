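#' Simulation configuration
#'
#' Bundles every tunable parameter of the synthetic-data generator. The
#' defaults emulate the design of a two-colour promoter tiling array
#' experiment: each promoter is tiled from 8.2 kb upstream to 3 kb
#' downstream of its transcription start site, probes are laid every
#' 100 bp, and three biological replicates are hybridised per group.
#' A fraction of promoters receives one planted differentially methylated
#' region (DMR) whose treated-group probes are shifted by `dmr_effect`
#' log2 units; planted DMRs sit on a baseline enrichment of
#' `dmr_baseline` log2 units in both groups so that loss-of-methylation
#' DMRs remain enriched in the control group.
#'
#' Coordinates are 0-based half-open throughout; each promoter occupies
#' its own synthetic chromosome so windows never bleed across promoters.
#'
#' @param n_promoters Number of tiled promoters (one chromosome each).
#' @param promoter_span Length-2 numeric, bp upstream and downstream of the
#'   TSS covered by probes. Default `c(8200, 3000)`.
#' @param probe_spacing Centre-to-centre probe spacing in bp.
#' @param probe_length Probe length in bp (must be <= spacing).
#' @param n_replicates_per_group Biological replicates per group for the
#'   methylation arrays.
#' @param dmr_fraction Fraction of promoters carrying one planted DMR.
#' @param dmr_effect Mean M-prime shift of a planted DMR, log2 units.
#'   Sign is drawn at random per DMR (gain or loss of methylation).
#' @param dmr_width Width of each planted DMR in bp; must be at least
#'   `2 * probe_spacing` so a DMR always contains >= 2 probes.
#' @param dmr_baseline Baseline log2(MeDIP/Input) enrichment inside
#'   planted DMRs (both groups), log2 units.
#' @param noise_sd Standard deviation of iid Gaussian noise added to each
#'   replicate's log2 ratio, log2 units.
#' @param n_mirna,n_gene Feature counts for the expression matrices.
#' @param expr_replicates_per_group Arrays per group for expression
#'   (3 emulates the continuous-preference-drinking design).
#' @param de_fraction Fraction of expression features with a planted
#'   log2 fold change.
#' @param de_effect Absolute planted log2 fold change for DE features.
#' @param expr_noise_sd Gaussian noise sd on expression log2 values.
#' @param n_inverse_pairs Planted inverse miRNA-target pairs.
#' @param imprinted_fraction Fraction of planted-DE miRNAs whose gene
#'   coordinates fall inside a catalog imprinted region (the study-design
#'   analogue of the ~25 percent observed on real arrays).
#' @param seed Integer seed; identical seeds give bit-identical output.
#'
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_promoters = 40,
                       promoter_span = c(8200, 3000),
                       probe_spacing = 100,
                       probe_length = 50,
                       n_replicates_per_group = 3,
                       dmr_fraction = 0.2,
                       dmr_effect = 1.0,
                       dmr_width = 750,
                       dmr_baseline = 0.5,
                       noise_sd = 0.3,
                       n_mirna = 32,
                       n_gene = 120,
                       expr_replicates_per_group = 3,
                       de_fraction = 0.25,
                       de_effect = 0.5,
                       expr_noise_sd = 0.15,
                       n_inverse_pairs = 8,
                       imprinted_fraction = 0.25,
                       seed = 1L) {
  cfg <- list(
    n_promoters = as.integer(n_promoters),
    promoter_span = as.numeric(promoter_span),
    probe_spacing = as.numeric(probe_spacing),
    probe_length = as.numeric(probe_length),
    n_replicates_per_group = as.integer(n_replicates_per_group),
    dmr_fraction = as.numeric(dmr_fraction),
    dmr_effect = as.numeric(dmr_effect),
    dmr_width = as.numeric(dmr_width),
    dmr_baseline = as.numeric(dmr_baseline),
    noise_sd = as.numeric(noise_sd),
    n_mirna = as.integer(n_mirna),
    n_gene = as.integer(n_gene),
    expr_replicates_per_group = as.integer(expr_replicates_per_group),
    de_fraction = as.numeric(de_fraction),
    de_effect = as.numeric(de_effect),
    expr_noise_sd = as.numeric(expr_noise_sd),
    n_inverse_pairs = as.integer(n_inverse_pairs),
    imprinted_fraction = as.numeric(imprinted_fraction),
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$n_promoters < 1L) abort("n_promoters must be >= 1")
  if (length(cfg$promoter_span) != 2L || any(cfg$promoter_span < 0)) {
    abort("promoter_span must be two non-negative lengths (upstream, downstream)")
  }
  if (cfg$probe_spacing <= 0) abort("probe_spacing must be > 0")
  if (cfg$probe_length <= 0 || cfg$probe_length > cfg$probe_spacing) {
    abort("probe_length must be in (0, probe_spacing]")
  }
  if (cfg$dmr_fraction < 0 || cfg$dmr_fraction > 1) {
    abort("dmr_fraction must be in [0, 1]")
  }
  if (cfg$noise_sd < 0 || cfg$expr_noise_sd < 0) abort("noise sd must be >= 0")
  if (cfg$dmr_width < 2 * cfg$probe_spacing) {
    abort("dmr_width must be >= 2 * probe_spacing so a planted DMR holds >= 2 probes")
  }
  if (cfg$n_replicates_per_group < 1L || cfg$expr_replicates_per_group < 2L) {
    abort("need >= 1 methylation replicate and >= 2 expression replicates per group")
  }
  if (cfg$de_fraction < 0 || cfg$de_fraction > 1) abort("de_fraction must be in [0, 1]")
  if (cfg$imprinted_fraction < 0 || cfg$imprinted_fraction > 1) {
    abort("imprinted_fraction must be in [0, 1]")
  }
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  for (nm in names(x)) {
    cat(sprintf("  %-26s %s\n", nm, paste(format(x[[nm]]), collapse = ", ")))
  }
  invisible(x)
}
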