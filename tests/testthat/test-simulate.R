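test_that("zero-effect, zero-noise simulation gives identical groups and M' == 0", {
  cfg <- sim_config(n_promoters = 5, dmr_fraction = 0, noise_sd = 0, seed = 11)
  sim <- simulate_tiling(cfg)
  info <- sample_info(sim$track)
  tre <- as.matrix(sim$track[info$sample[info$group == "treated"]])
  ctl <- as.matrix(sim$track[info$sample[info$group == "control"]])
  expect_identical(unname(tre), unname(ctl))
  m <- compute_mprime(sim$track)
  expect_true(all(m$mprime == 0))
  expect_identical(nrow(sim$truth), 0L)
})

test_that("noise-free planted DMR reproduces its effect exactly over member probes", {
  cfg <- sim_config(n_promoters = 5, dmr_fraction = 0.2, noise_sd = 0,
                    dmr_effect = 1.0, seed = 4)
  sim <- simulate_tiling(cfg)
  expect_identical(nrow(sim$truth), 1L)
  m <- compute_mprime(sim$track)
  member <- m$chrom == sim$truth$chrom &
    m$start < sim$truth$end & m$end > sim$truth$start
  expect_true(sum(member) >= 2)
  expect_equal(mean(m$mprime[member]), sim$truth$effect, tolerance = 1e-12)
  expect_true(all(m$mprime[!member] == 0))
})

test_that("generators are deterministic in the seed and leave the RNG alone", {
  cfg <- sim_config(n_promoters = 4, seed = 1)
  a <- simulate_tiling(cfg)
  set.seed(999)
  before <- .Random.seed
  b <- simulate_tiling(cfg)
  expect_identical(before, .Random.seed)
  expect_identical(a, b)
  expect_identical(simulate_expression(cfg), simulate_expression(cfg))
  expect_identical(simulate_qpcr(seed = 7), simulate_qpcr(seed = 7))
  expect_false(identical(a, simulate_tiling(sim_config(n_promoters = 4, seed = 2))))
})

test_that("config validation rejects degenerate designs", {
  expect_error(sim_config(dmr_width = 150, probe_spacing = 100), "dmr_width")
  expect_error(sim_config(dmr_fraction = 1.5), "dmr_fraction")
  expect_error(sim_config(noise_sd = -1), "noise")
  expect_error(sim_config(probe_spacing = 0), "probe_spacing")
})

test_that("probe tracks are sorted, half-open and duplicate-free", {
  sim <- simulate_tiling(sim_config(n_promoters = 6, seed = 3))
  tr <- sim$track
  expect_identical(anyDuplicated(tr$probe_id), 0L)
  expect_true(all(tr$start < tr$end))
  expect_identical(order(tr$chrom, tr$start), seq_len(nrow(tr)))
  # every planted DMR lies within its promoter window
  span <- sum(sim_config()$promoter_span)
  expect_true(all(sim$truth$start >= 0 & sim$truth$end <= span))
})

test_that("noise-free expression matrices realise planted fold changes exactly", {
  cfg <- sim_config(n_promoters = 10, expr_noise_sd = 0, seed = 5)
  ex <- simulate_expression(cfg)
  info <- sample_info(ex$gene)
  diff <- rowMeans(as.matrix(ex$gene[info$sample[info$group == "treated"]])) -
    rowMeans(as.matrix(ex$gene[info$sample[info$group == "control"]]))
  truth <- ex$truth$de_features
  gene_truth <- truth[truth$type == "gene", ]
  idx <- match(gene_truth$feature_id, ex$gene$feature_id)
  expect_equal(unname(diff[idx]), gene_truth$true_lfc, tolerance = 1e-12)
  # non-DE genes have zero realised difference
  expect_true(all(abs(diff[-idx]) < 1e-12))
})

test_that("planted inverse pairs have opposite-signed truth and survive the filter; decoys do not", {
  cfg <- sim_config(n_promoters = 10, expr_noise_sd = 0.02, seed = 6)
  ex <- simulate_expression(cfg)
  truth <- ex$truth$de_features
  lfc <- setNames(truth$true_lfc, truth$feature_id)
  ip <- ex$truth$inverse_pairs
  expect_true(all(sign(lfc[ip$mirna_id]) * sign(lfc[ip$gene_id]) == -1))

  mirna_de <- differential_expression(ex$mirna)
  gene_de <- differential_expression(ex$gene)
  kept <- inverse_pair_filter(mirna_de, gene_de, ex$pairs)
  # every planted inverse pair is recovered at low noise
  expect_true(all(paste(ip$mirna_id, ip$gene_id) %in%
                    paste(kept$mirna_id, kept$gene_id)))
  # decoys (same-direction, low-confidence, non-brain) are rejected
  decoys <- dplyr::anti_join(ex$pairs, ip, by = c("mirna_id", "gene_id"))
  expect_false(any(paste(decoys$mirna_id, decoys$gene_id) %in%
                     paste(kept$mirna_id, kept$gene_id)))
})

test_that("catalogs are valid half-open BED-style sets and round-trip through BED", {
  cfg <- sim_config(n_promoters = 5, seed = 2)
  cats <- make_catalogs(cfg)
  for (cat in cats) {
    expect_true(all(cat$start >= 0 & cat$start < cat$end))
    expect_identical(anyDuplicated(cat$name), 0L)
  }
  path <- withr::local_tempfile(fileext = ".bed")
  write_bed(cats$imprinted, path)
  back <- read_bed(path)
  expect_equal(back[c("chrom", "start", "end", "name")],
               cats$imprinted[c("chrom", "start", "end", "name")])
  expect_identical(make_catalogs(cfg), cats)
})

test_that("a DE miRNA placed in an imprinted region is mapped by map_to_regions", {
  cfg <- sim_config(n_promoters = 10, seed = 8)
  ex <- simulate_expression(cfg)
  cats <- make_catalogs(cfg)
  res <- map_to_regions(ex$mirna_anno, cats$imprinted)
  de_mirna <- ex$truth$de_features$feature_id[ex$truth$de_features$type == "mirna"]
  n_expected <- round(cfg$imprinted_fraction * length(de_mirna))
  expect_identical(res$n_mapped, as.integer(n_expected))
  expect_true(all(res$membership$feature_id %in% de_mirna))
})
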