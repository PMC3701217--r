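# Run code under a temporary RNG state so generators are deterministic in
# their seed without clobbering the caller's stream.
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Derived sub-seeds keep the tiling, expression and catalog streams
# independent while remaining functions of the single config seed.
sub_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 1009 + k * 9176) %% 2147483629 + 1)
}

# Promoters that carry a planted DMR; shared between the tiling and
# expression generators so methylation and expression truth agree.
planted_dmr_promoters <- function(cfg) {
  n_dmr <- round(cfg$dmr_fraction * cfg$n_promoters)
  if (n_dmr == 0L) return(integer(0))
  with_local_seed(sub_seed(cfg$seed, 1L), {
    sort(sample.int(cfg$n_promoters, n_dmr))
  })
}

promoter_chrom <- function(i) sprintf("prom%03d", i)
gene_id_of_promoter <- function(i) sprintf("gene_%03d", i)

#' Simulate a MeDIP-chip promoter tiling-array experiment
#'
#' Generates a probe-level log2(MeDIP/Input) track for a treated and a
#' control group with a known set of planted differentially methylated
#' regions (DMRs). Each promoter occupies its own synthetic chromosome
#' tiled with probes of `probe_length` bp every `probe_spacing` bp. A
#' planted DMR sits on a baseline enrichment of `dmr_baseline` log2 units
#' in both groups; the treated group is additionally shifted by a signed
#' `dmr_effect` inside the DMR (positive = methylation gain, negative =
#' loss). Replicate noise is iid Gaussian on the log2 scale.
#'
#' @param config A [sim_config()].
#' @return A list with components:
#' \describe{
#'   \item{track}{tibble: `probe_id`, `chrom`, `start`, `end` plus one
#'     column per sample (`treated_1`, ..., `control_1`, ...), sorted by
#'     (chrom, start), 0-based half-open coordinates.}
#'   \item{truth}{tibble of planted DMRs: `chrom`, `start`, `end`,
#'     `effect` (signed log2 shift), `promoter` (index).}
#' }
#' @examples
#' sim <- simulate_tiling(sim_config(n_promoters = 4, seed = 7))
#' head(sim$track)
#' sim$truth
#' @export
simulate_tiling <- function(config) {
  cfg <- validate_sim_config(config)
  span <- sum(cfg$promoter_span)
  starts <- seq(0, span - cfg$probe_length, by = cfg$probe_spacing)
  n_probe <- length(starts)
  if (n_probe < 2L) abort("promoter span too short for two probes")

  dmr_prom <- planted_dmr_promoters(cfg)
  groups <- c("treated", "control")
  smp <- as.vector(t(outer(groups, seq_len(cfg$n_replicates_per_group),
                           paste, sep = "_")))

  with_local_seed(sub_seed(cfg$seed, 2L), {
    # one planted DMR per selected promoter, uniformly placed
    truth <- tibble(
      chrom = promoter_chrom(dmr_prom),
      start = floor(stats::runif(length(dmr_prom), 0, span - cfg$dmr_width)),
      effect = cfg$dmr_effect * sample(c(-1, 1), length(dmr_prom), replace = TRUE),
      promoter = dmr_prom
    )
    truth$end <- truth$start + cfg$dmr_width
    truth <- truth[, c("chrom", "start", "end", "effect", "promoter")]

    tracks <- vector("list", cfg$n_promoters)
    for (i in seq_len(cfg$n_promoters)) {
      chrom <- promoter_chrom(i)
      base <- numeric(n_probe)
      eff <- numeric(n_probe)
      hit <- which(truth$chrom == chrom)
      if (length(hit) == 1L) {
        # probes overlapping the planted interval (half-open, >=1 bp)
        inside <- starts < truth$end[hit] & (starts + cfg$probe_length) > truth$start[hit]
        base[inside] <- cfg$dmr_baseline
        eff[inside] <- truth$effect[hit]
      }
      vals <- matrix(0, n_probe, length(smp), dimnames = list(NULL, smp))
      for (s in smp) {
        mu <- base + if (startsWith(s, "treated")) eff else 0
        vals[, s] <- mu + rnorm(n_probe, sd = cfg$noise_sd)
      }
      tracks[[i]] <- tibble(
        probe_id = sprintf("%s_p%05d", chrom, seq_len(n_probe)),
        chrom = chrom,
        start = starts,
        end = starts + cfg$probe_length
      ) |> dplyr::bind_cols(as_tibble(vals))
    }
    track <- dplyr::bind_rows(tracks) |>
      dplyr::arrange(.data$chrom, .data$start)
    list(track = track, truth = dplyr::arrange(truth, .data$chrom, .data$start))
  })
}

#' Simulate miRNA and gene expression matrices with planted inverse pairs
#'
#' Generates log2-scale expression matrices for miRNAs and genes in two
#' groups, a miRNA-to-gene target-prediction table, and the planted truth.
#' A fraction of features receives a signed log2 fold change; planted
#' inverse miRNA-target pairs (opposite-signed fold changes) enter the
#' target table with confidence `"high"` and tissue `"brain"`, alongside
#' decoy pairs (same-direction, null, low-confidence and non-brain) that
#' downstream filters must reject. Planted differentially expressed genes
#' are preferentially those whose promoters carry a planted DMR under the
#' same `config`, so methylation and expression truth cohere.
#'
#' Each miRNA is also assigned a genomic locus; a fraction
#' `imprinted_fraction` of the differentially expressed miRNAs falls
#' inside the imprinted-region catalog of [make_catalogs()].
#'
#' @param config A [sim_config()].
#' @return A list with `mirna`, `gene` (tibbles: `feature_id` + sample
#'   columns), `pairs` (tibble: `mirna_id`, `gene_id`, `confidence`,
#'   `tissue`), `mirna_anno` (tibble: `feature_id`, `chrom`, `start`,
#'   `end`), and `truth` (list: `de_features`, `inverse_pairs`).
#' @export
simulate_expression <- function(config) {
  cfg <- validate_sim_config(config)
  mirna_ids <- sprintf("mirna_%03d", seq_len(cfg$n_mirna))
  gene_ids <- sprintf("gene_%03d", seq_len(cfg$n_gene))

  n_de_mirna <- max(round(cfg$de_fraction * cfg$n_mirna), cfg$n_inverse_pairs)
  n_de_gene <- max(round(cfg$de_fraction * cfg$n_gene), cfg$n_inverse_pairs)
  if (n_de_mirna > cfg$n_mirna || n_de_gene > cfg$n_gene) {
    abort("n_inverse_pairs exceeds the number of available DE features")
  }

  dmr_prom <- planted_dmr_promoters(cfg)

  with_local_seed(sub_seed(cfg$seed, 3L), {
    de_mirna <- sort(sample.int(cfg$n_mirna, n_de_mirna))
    # DE genes: first those whose promoter carries a planted DMR, then others
    dmr_genes <- dmr_prom[dmr_prom <= cfg$n_gene]
    extra <- setdiff(seq_len(cfg$n_gene), dmr_genes)
    if (n_de_gene <= length(dmr_genes)) {
      de_gene <- sort(sample(dmr_genes, n_de_gene))
    } else {
      de_gene <- sort(c(dmr_genes, sample(extra, n_de_gene - length(dmr_genes))))
    }

    mirna_lfc <- setNames(numeric(cfg$n_mirna), mirna_ids)
    gene_lfc <- setNames(numeric(cfg$n_gene), gene_ids)
    mirna_lfc[de_mirna] <- cfg$de_effect * sample(c(-1, 1), n_de_mirna, replace = TRUE)
    gene_lfc[de_gene] <- cfg$de_effect * sample(c(-1, 1), n_de_gene, replace = TRUE)

    # planted inverse pairs: force opposite signs
    pair_mirna <- sample(de_mirna, cfg$n_inverse_pairs)
    pair_gene <- sample(de_gene, cfg$n_inverse_pairs)
    gene_lfc[pair_gene] <- -abs(gene_lfc[pair_gene]) * sign(mirna_lfc[pair_mirna])
    inverse_pairs <- tibble(
      mirna_id = mirna_ids[pair_mirna],
      gene_id = gene_ids[pair_gene]
    )

    make_matrix <- function(ids, lfc) {
      n <- length(ids)
      base <- rnorm(n, mean = 8, sd = 1)
      smp <- as.vector(t(outer(c("treated", "control"),
                               seq_len(cfg$expr_replicates_per_group),
                               paste, sep = "_")))
      vals <- matrix(0, n, length(smp), dimnames = list(NULL, smp))
      for (s in smp) {
        mu <- base + if (startsWith(s, "treated")) lfc else 0
        vals[, s] <- mu + rnorm(n, sd = cfg$expr_noise_sd)
      }
      dplyr::bind_cols(tibble(feature_id = ids), as_tibble(vals))
    }
    mirna <- make_matrix(mirna_ids, mirna_lfc)
    gene <- make_matrix(gene_ids, gene_lfc)

    # decoy pairs for the target table
    same_dir <- de_mirna[!(de_mirna %in% pair_mirna)]
    decoys <- list()
    if (length(same_dir) >= 1L && length(de_gene) >= 1L) {
      dm <- same_dir[1L]
      dg <- de_gene[which(sign(gene_lfc[de_gene]) == sign(mirna_lfc[dm]))[1L]]
      if (!is.na(dg)) {
        decoys$same_direction <- tibble(
          mirna_id = mirna_ids[dm], gene_id = gene_ids[dg],
          confidence = "high", tissue = "brain"
        )
      }
    }
    null_mirna <- setdiff(seq_len(cfg$n_mirna), de_mirna)
    null_gene <- setdiff(seq_len(cfg$n_gene), de_gene)
    if (length(null_mirna) >= 1L && length(null_gene) >= 1L) {
      decoys$null_pair <- tibble(
        mirna_id = mirna_ids[null_mirna[1L]], gene_id = gene_ids[null_gene[1L]],
        confidence = "moderate", tissue = "brain"
      )
    }
    # low-confidence and non-brain versions of otherwise-passing pairs
    decoys$low_conf <- tibble(
      mirna_id = inverse_pairs$mirna_id[1L],
      gene_id = if (length(null_gene) >= 2L) gene_ids[null_gene[2L]] else gene_ids[1L],
      confidence = "low", tissue = "brain"
    )
    decoys$non_brain <- tibble(
      mirna_id = inverse_pairs$mirna_id[min(2L, nrow(inverse_pairs))],
      gene_id = if (length(null_gene) >= 3L) gene_ids[null_gene[3L]] else gene_ids[2L],
      confidence = "high", tissue = "liver"
    )
    pairs <- dplyr::bind_rows(
      dplyr::mutate(inverse_pairs, confidence = "high", tissue = "brain"),
      dplyr::bind_rows(decoys)
    ) |>
      dplyr::distinct(.data$mirna_id, .data$gene_id, .keep_all = TRUE)

    # miRNA genomic loci: a fraction of DE miRNAs inside imprinted regions
    imp <- imprinted_region_catalog()
    n_imp <- round(cfg$imprinted_fraction * n_de_mirna)
    in_imp <- de_mirna[seq_len(n_imp)]
    anno <- tibble(
      feature_id = mirna_ids,
      chrom = "chrU",
      start = 10000 * seq_len(cfg$n_mirna),
      end = 10000 * seq_len(cfg$n_mirna) + 100
    )
    if (n_imp > 0L) {
      slot <- ((seq_along(in_imp) - 1L) %% nrow(imp)) + 1L
      anno$chrom[in_imp] <- imp$chrom[slot]
      anno$start[in_imp] <- imp$start[slot] + 500 * seq_along(in_imp)
      anno$end[in_imp] <- anno$start[in_imp] + 100
    }

    de_features <- dplyr::bind_rows(
      tibble(feature_id = mirna_ids, type = "mirna", true_lfc = unname(mirna_lfc)),
      tibble(feature_id = gene_ids, type = "gene", true_lfc = unname(gene_lfc))
    ) |> dplyr::filter(.data$true_lfc != 0)

    list(
      mirna = mirna, gene = gene, pairs = pairs, mirna_anno = anno,
      truth = list(de_features = de_features, inverse_pairs = inverse_pairs)
    )
  })
}

# Fixed synthetic analogues of the three imprinted ncRNA clusters, each on
# its own chromosome (Sfmbt2-like on chr2, Snrpn-Ube3a-like on chr7,
# Dlk1-Dio3-like on chr12).
imprinted_region_catalog <- function() {
  tibble(
    chrom = c("chr2", "chr7", "chr12"),
    start = c(1000000, 2000000, 3000000),
    end = c(1500000, 2600000, 3800000),
    name = c("Sfmbt2_region", "Snrpn_Ube3a_region", "Dlk1_Dio3_region")
  )
}

#' Build the interval catalogs for a simulated experiment
#'
#' Emits the three BED-style region sets consumed downstream: one promoter
#' window per simulated promoter chromosome (named after the gene whose
#' promoter it is), three imprinted regions on distinct chromosomes, and
#' point CTCF-binding-site intervals near each simulated TSS. All
#' intervals are 0-based half-open.
#'
#' @param config A [sim_config()].
#' @return A list of tibbles `promoters`, `imprinted`, `ctcf`, each with
#'   columns `chrom`, `start`, `end`, `name`.
#' @export
make_catalogs <- function(config) {
  cfg <- validate_sim_config(config)
  span <- sum(cfg$promoter_span)
  tss <- cfg$promoter_span[1]
  promoters <- tibble(
    chrom = promoter_chrom(seq_len(cfg$n_promoters)),
    start = 0,
    end = span,
    name = gene_id_of_promoter(seq_len(cfg$n_promoters))
  )
  ctcf <- tibble(
    chrom = promoters$chrom,
    start = tss - 250,
    end = tss - 230,
    name = sprintf("ctcf_%03d", seq_len(cfg$n_promoters))
  )
  list(promoters = promoters, imprinted = imprinted_region_catalog(), ctcf = ctcf)
}

#' Simulate a qPCR Ct table for relative quantitation
#'
#' Emulates a TaqMan validation run: per sample, technical replicates of
#' the target assay and of an endogenous-control assay (the snoRNA-202
#' role). The treated group's delta-Ct is shifted by `-log2(true_fc)` so
#' the delta-delta-Ct estimator recovers `true_fc` in expectation.
#'
#' @param true_fc True linear fold change of the target in treated vs
#'   control (default 1.45, the study-scale effect used throughout).
#' @param n_per_group Biological samples per group.
#' @param n_tech Technical replicates per assay.
#' @param ct_sd Technical-replicate Ct standard deviation (cycles).
#' @param bio_sd Between-sample biological Ct standard deviation (cycles).
#' @param seed Integer seed.
#' @return A tibble: `sample`, `group`, `tech_rep`, `target_ct`,
#'   `control_ct`.
#' @export
simulate_qpcr <- function(true_fc = 1.45, n_per_group = 6, n_tech = 3,
                          ct_sd = 0.12, bio_sd = 0.35, seed = 1L) {
  stopifnot(true_fc > 0, n_per_group >= 2, n_tech >= 1, ct_sd >= 0, bio_sd >= 0)
  with_local_seed(seed, {
    groups <- rep(c("treated", "control"), each = n_per_group)
    samples <- paste(groups, rep(seq_len(n_per_group), 2), sep = "_")
    # lower target Ct = more template; shift treated by -log2(fc)
    dct_mu <- ifelse(groups == "treated", 5 - log2(true_fc), 5)
    dct <- dct_mu + rnorm(length(samples), sd = bio_sd)
    control_base <- 20 + rnorm(length(samples), sd = 0.5)
    purrr::map_dfr(seq_along(samples), function(i) {
      tibble(
        sample = samples[i],
        group = groups[i],
        tech_rep = seq_len(n_tech),
        target_ct = control_base[i] + dct[i] + rnorm(n_tech, sd = ct_sd),
        control_ct = control_base[i] + rnorm(n_tech, sd = ct_sd)
      )
    })
  })
}
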