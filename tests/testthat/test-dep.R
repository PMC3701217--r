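test_that("M' is the treated-minus-control mean and is antisymmetric", {
  tr <- tibble::tibble(
    probe_id = "p1", chrom = "chr1", start = 0, end = 50,
    treated_1 = 1.2, treated_2 = 0.8, control_1 = 0.5, control_2 = 0.3
  )
  m <- compute_mprime(tr)
  expect_equal(m$mprime, 1.0 - 0.4, tolerance = 1e-12)
  swapped <- dplyr::rename(
    tr, control_1 = "treated_1", control_2 = "treated_2",
    treated_1 = "control_1", treated_2 = "control_2"
  )
  expect_equal(compute_mprime(swapped)$mprime, -m$mprime, tolerance = 1e-12)
})

test_that("within-group CV is sd over |mean|, zero for identical replicates, Inf near zero mean", {
  tr <- tibble::tibble(
    probe_id = c("p1", "p2", "p3"), chrom = "chr1",
    start = c(0, 100, 200), end = c(50, 150, 250),
    treated_1 = c(2, 1, 1e-9), treated_2 = c(2, 3, -1e-9),
    control_1 = c(1, 1, 1), control_2 = c(3, 1, 1)
  )
  m <- compute_mprime(tr)
  expect_equal(m$cv_treated[1], 0)
  expect_equal(m$cv_treated[2], sd(c(1, 3)) / 2)
  expect_identical(m$cv_treated[3], Inf)
  expect_equal(m$cv_control[2], 0)
  expect_error(compute_mprime(dplyr::select(tr, -dplyr::starts_with("control"))),
               "group")
})

test_that("DEP filter criterion (i) applies the 0.3 median-ratio bound sharply", {
  for (med in c(0.29, 0.30)) {
    mt <- toy_mtrack(mean_treated = med, mean_control = med)
    deps <- call_deps(mt)
    peak <- deps[deps$direction == "gain" & deps$start <= 5100 & deps$end >= 5300, ]
    expect_identical(nrow(peak), 1L)
    if (med < 0.3) {
      expect_false(peak$accepted)
      expect_identical(peak$reason, "median_ratio")
    } else {
      expect_true(peak$accepted)
      expect_identical(peak$reason, "")
    }
  }
})

test_that("DEP filter criterion (ii) needs half the probes below the CV bound in both groups", {
  for (n_ok in c(1L, 2L)) {
    mt <- toy_mtrack(mean_treated = 1)
    mt$cv_treated[] <- 2
    mt$cv_control[] <- 2
    ok <- (21:24)[seq_len(n_ok)]
    mt$cv_treated[ok] <- 0.8
    mt$cv_control[ok] <- 0.8
    deps <- call_deps(mt)
    peak <- deps[deps$direction == "gain" & deps$start <= 5100 & deps$end >= 5300, ]
    expect_identical(nrow(peak), 1L)
    expect_identical(peak$n_probes, 4L)
    if (n_ok == 1L) {
      expect_false(peak$accepted)
      expect_identical(peak$reason, "cv")
    } else {
      expect_true(peak$accepted)
    }
  }
})

test_that("a probe above the CV bound in one group only fails that probe", {
  mt <- toy_mtrack(mean_treated = 1)
  mt$cv_treated[21:24] <- c(0.5, 0.5, 0.9, 0.5)
  mt$cv_control[21:24] <- c(0.5, 0.9, 0.5, 0.5)
  deps <- call_deps(mt)
  peak <- deps[deps$direction == "gain" & deps$start <= 5100 & deps$end >= 5300, ]
  expect_equal(peak$cv_pass_fraction, 0.5)
  expect_true(peak$accepted)
})

test_that("swapping group labels maps gain DEPs onto loss DEPs bit-identically", {
  sim <- simulate_tiling(sim_config(n_promoters = 12, seed = 21))
  m1 <- compute_mprime(sim$track)
  info <- sample_info(sim$track)
  renames <- setNames(
    info$sample,
    ifelse(info$group == "treated", paste0("control_", info$replicate),
           paste0("treated_", info$replicate))
  )
  m2 <- compute_mprime(dplyr::rename(sim$track, !!!renames))
  expect_equal(m2$mprime, -m1$mprime, tolerance = 1e-15)
  d1 <- call_deps(m1)
  d2 <- call_deps(m2)
  flip <- function(x) ifelse(x == "gain", "loss", "gain")
  key <- function(d) paste(d$chrom, d$start, d$end, d$direction)
  expect_setequal(key(d1), paste(d2$chrom, d2$start, d2$end, flip(d2$direction)))
  g1 <- d1[d1$direction == "gain", ]
  l2 <- d2[d2$direction == "loss", ]
  expect_equal(g1$peak_score, l2$peak_score, tolerance = 1e-12)
  expect_equal(g1$peak_dm_value, -l2$peak_dm_value, tolerance = 1e-12)
  expect_identical(g1$accepted, l2$accepted)
})

test_that("a noise-free planted DMR yields an accepted DEP over the planted interval", {
  cfg <- sim_config(n_promoters = 6, dmr_fraction = 0.35, noise_sd = 0, seed = 9)
  sim <- simulate_tiling(cfg)
  deps <- call_deps(compute_mprime(sim$track))
  acc <- deps[deps$accepted, ]
  rec <- dmr_recovery(acc, sim$truth)
  expect_equal(rec$recall, 1.0)
  expect_equal(rec$false_discovery, 0.0)
  dir_expected <- ifelse(sim$truth$effect > 0, "gain", "loss")
  for (i in seq_len(nrow(sim$truth))) {
    hit <- acc$chrom == sim$truth$chrom[i] &
      acc$start < sim$truth$end[i] & acc$end > sim$truth$start[i]
    expect_true(all(acc$direction[hit] == dir_expected[i]))
  }
})

test_that("top_peak_filter returns the intersection of the two top-20% rankings", {
  mk <- function(score, dm) tibble::tibble(
    chrom = "chr1", start = seq_along(score) * 1000,
    end = seq_along(score) * 1000 + 500,
    name = sprintf("pk%02d", seq_along(score)),
    peak_score = score, peak_dm_value = dm
  )
  # disjoint top-2 sets: scores favour peaks 1,2; |dm| favours peaks 9,10
  disjoint <- mk(c(10, 9, 1:8), c(1:8, 20, 21))
  expect_identical(nrow(top_peak_filter(disjoint, 0.2)), 0L)
  # the same two peaks lead both rankings
  agree <- mk(c(10, 9, 1:8), c(-30, 25, 1:8))
  expect_identical(top_peak_filter(agree, 0.2)$name, c("pk01", "pk02"))
  expect_identical(nrow(top_peak_filter(agree[0, ], 0.2)), 0L)

  set.seed(5)
  rnd <- mk(runif(100), rnorm(100))
  got <- top_peak_filter(rnd, 0.2)
  by_score <- rnd$name[order(-rnd$peak_score)][1:20]
  by_dm <- rnd$name[order(-abs(rnd$peak_dm_value))][1:20]
  expect_lte(nrow(got), 20L)
  expect_setequal(got$name, intersect(by_score, by_dm))
})

test_that("the PeakScore matrix has one row per region, one column per sample", {
  sim <- simulate_tiling(sim_config(n_promoters = 8, dmr_fraction = 0.25,
                                    noise_sd = 0.2, seed = 13))
  deps <- call_deps(compute_mprime(sim$track))
  acc <- deps[deps$accepted, ]
  expect_gt(nrow(acc), 0)
  psm <- peak_score_matrix(sim$track, acc)
  expect_identical(dim(psm), c(nrow(acc), ncol(sim$track) - 4L + 1L))
  # duplicated sample columns give identical matrix columns
  dup <- sim$track
  dup$treated_9 <- dup$treated_1
  psm2 <- peak_score_matrix(dup, acc)
  expect_identical(psm2$treated_9, psm2$treated_1)
})
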