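fake_de <- function(ids, fc, pass = NULL) {
  tibble::tibble(
    feature_id = ids,
    fold_change = fc,
    p_value = 0.01,
    passes_filter = pass %||% (abs(fc) >= 1.2)
  )
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("inverse_pair_filter keeps confident inverse brain pairs only", {
  mirna_de <- fake_de(c("m1", "m2", "m3"), c(1.3, 1.3, 1.3))
  gene_de <- fake_de(c("g1", "g2", "g3", "g4"), c(-1.25, 1.25, -1.25, -1.25))
  pairs <- tibble::tibble(
    mirna_id = c("m1", "m2", "m1", "m2", "m3"),
    gene_id = c("g1", "g2", "g3", "g4", "g1"),
    confidence = c("high", "high", "low", "high", "moderate"),
    tissue = c("brain", "brain", "brain", "liver", "brain")
  )
  kept <- inverse_pair_filter(mirna_de, gene_de, pairs)
  # m1-g1: inverse, high, brain -> kept; m2-g2: same sign -> out;
  # m1-g3: low confidence -> out; m2-g4: liver -> out; m3-g1: moderate ok
  expect_setequal(paste(kept$mirna_id, kept$gene_id), c("m1 g1", "m3 g1"))
  expect_true(all(kept$n_mirnas_targeting_gene == 2))
  expect_true(all(sign(kept$mirna_fc) != sign(kept$gene_fc)))
})

test_that("pairs failing the DE filter or unknown to the DE tables are dropped", {
  mirna_de <- fake_de(c("m1", "m2"), c(1.3, 1.1))
  gene_de <- fake_de("g1", -1.3)
  pairs <- tibble::tibble(
    mirna_id = c("m1", "m2", "mX"),
    gene_id = c("g1", "g1", "g1"),
    confidence = "high", tissue = "brain"
  )
  expect_warning(kept <- inverse_pair_filter(mirna_de, gene_de, pairs),
                 "unknown")
  # m2 fails its own DE filter (|fc| < 1.2); mX is unknown
  expect_identical(paste(kept$mirna_id, kept$gene_id), "m1 g1")
  expect_error(
    inverse_pair_filter(mirna_de, gene_de, pairs[c(1, 1), ]),
    "duplicate"
  )
})

test_that("tightening min_confidence never grows the retained set", {
  set.seed(31)
  mirna_de <- fake_de(sprintf("m%d", 1:20), sample(c(-1.5, 1.5), 20, TRUE))
  gene_de <- fake_de(sprintf("g%d", 1:20), sample(c(-1.5, 1.5), 20, TRUE))
  pairs <- tibble::tibble(
    mirna_id = sample(mirna_de$feature_id, 40, TRUE),
    gene_id = sample(gene_de$feature_id, 40, TRUE),
    confidence = sample(c("predicted", "low", "moderate", "high"), 40, TRUE),
    tissue = "brain"
  ) |> dplyr::distinct(mirna_id, gene_id, .keep_all = TRUE)
  prev <- Inf
  for (conf in c("predicted", "low", "moderate", "high")) {
    kept <- inverse_pair_filter(mirna_de, gene_de, pairs, min_confidence = conf)
    expect_lte(nrow(kept), prev)
    expect_true(all(paste(kept$mirna_id, kept$gene_id) %in%
                      paste(pairs$mirna_id, pairs$gene_id)))
    prev <- nrow(kept)
  }
})

test_that("promoter concordance counts DE features with a DEP in the promoter", {
  promoters <- tibble::tibble(
    chrom = sprintf("c%03d", 1:129), start = 0, end = 10000,
    name = sprintf("g%03d", 1:129)
  )
  de <- fake_de(sprintf("g%03d", 1:129), rep(1.5, 129))
  deps <- tibble::tibble(
    chrom = sprintf("c%03d", 1:21), start = 4000, end = 4750,
    accepted = TRUE
  )
  res <- promoter_concordance(deps, de, promoters)
  expect_identical(res$n_concordant, 21L)
  expect_equal(round(res$fraction_concordant, 4), 0.1628)
  expect_equal(res$fraction_deps_in_de_promoters, 1.0)
  # no DEPs -> zero fraction
  none <- promoter_concordance(deps[0, ], de, promoters)
  expect_equal(none$fraction_concordant, 0)
  # unannotated features leave the denominator
  de2 <- fake_de(c(sprintf("g%03d", 1:129), "orphan"), rep(1.5, 130))
  res2 <- promoter_concordance(deps, de2, promoters)
  expect_identical(res2$n_unannotated, 1L)
  expect_equal(res2$fraction_concordant, 21 / 129)
})

test_that("noise-free end-to-end run gives full promoter concordance for DMR genes", {
  cfg <- sim_config(n_promoters = 8, dmr_fraction = 0.5, noise_sd = 0, seed = 17)
  sim <- simulate_tiling(cfg)
  deps <- call_deps(compute_mprime(sim$track))
  cats <- make_catalogs(cfg)
  # declare exactly the planted promoters' genes differentially expressed
  de <- fake_de(sprintf("gene_%03d", sim$truth$promoter), rep(1.5, nrow(sim$truth)))
  res <- promoter_concordance(deps, de, cats$promoters)
  expect_equal(res$fraction_concordant, 1.0)
})

test_that("region mapping respects the half-open convention and reports fractions", {
  catalog <- tibble::tibble(chrom = "chr1", start = 100, end = 200, name = "r1")
  feats <- tibble::tibble(
    feature_id = c("inside", "abut_end", "abut_start", "off_chrom"),
    chrom = c("chr1", "chr1", "chr1", "chr9"),
    start = c(120, 200, 50, 120),
    end = c(180, 260, 100, 180)
  )
  res <- map_to_regions(feats, catalog)
  expect_identical(res$membership$feature_id, "inside")
  expect_equal(res$fraction_mapped, 0.25)
  expect_identical(res$per_region$n, 1L)
})

test_that("8 of 32 features inside regions gives fraction 0.25", {
  catalog <- tibble::tibble(chrom = "chr1", start = 0, end = 1000, name = "imp")
  feats <- tibble::tibble(
    feature_id = sprintf("f%02d", 1:32),
    chrom = c(rep("chr1", 8), rep("chr2", 24)),
    start = 100, end = 200
  )
  expect_equal(map_to_regions(feats, catalog)$fraction_mapped, 0.25)
})

test_that("region enrichment has the trivial p = 1 cases and flags planted signal", {
  catalog <- tibble::tibble(chrom = "chr1", start = 0, end = 1000, name = "imp")
  universe <- tibble::tibble(
    feature_id = sprintf("f%03d", 1:100),
    chrom = c(rep("chr1", 10), rep("chr2", 90)),
    start = 10, end = 20
  )
  all_p <- region_enrichment(universe$feature_id, catalog, universe,
                             n_perm = 99, seed = 1)
  expect_equal(all_p$p_value, 1)
  none <- region_enrichment(sprintf("f%03d", 51:60), catalog, universe,
                            n_perm = 99, seed = 1)
  expect_equal(none$observed, 0L)
  expect_equal(none$p_value, 1)
  # 10x enrichment: all 10 selected features are in-region
  ps <- vapply(1:20, function(s) {
    region_enrichment(sprintf("f%03d", 1:10), catalog, universe,
                      n_perm = 999, seed = s)$p_value
  }, numeric(1))
  expect_true(all(ps <= 0.01))
  expect_error(region_enrichment("f001", catalog, universe, n_perm = 9),
               "seed")
  expect_error(region_enrichment("nope", catalog, universe, n_perm = 9, seed = 1),
               "subset")
})
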