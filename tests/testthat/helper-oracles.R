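# Independent reference implementations used only to check the package.

# Brute-force maximal-run peak enumeration: walk probes one by one,
# opening a run at each qualifying probe and closing it on a gap or a
# non-qualifying probe. Deliberately imperative and unshared with the
# package's vectorised path.
brute_force_peaks <- function(pvalues, params) {
  qualifies <- -log10(pvalues$p_value) >= params$probe_score_cutoff
  mids <- (pvalues$start + pvalues$end) / 2
  runs <- list()
  cur <- integer(0)
  for (i in seq_len(nrow(pvalues))) {
    if (!qualifies[i]) next
    if (length(cur) > 0) {
      prev <- cur[length(cur)]
      same <- pvalues$chrom[i] == pvalues$chrom[prev]
      close_enough <- same && (mids[i] - mids[prev]) <= params$max_gap_bp
      if (!close_enough) {
        runs[[length(runs) + 1]] <- cur
        cur <- integer(0)
      }
    }
    cur <- c(cur, i)
  }
  if (length(cur) > 0) runs[[length(runs) + 1]] <- cur
  runs <- Filter(function(r) length(r) >= params$min_probes, runs)
  if (length(runs) == 0) {
    return(data.frame(chrom = character(), start = numeric(), end = numeric(),
                      n_probes = integer(), peak_score = numeric()))
  }
  do.call(rbind, lapply(runs, function(r) {
    data.frame(
      chrom = pvalues$chrom[r[1]],
      start = min(pvalues$start[r]),
      end = max(pvalues$end[r]),
      n_probes = length(r),
      peak_score = -log10(mean(pvalues$p_value[r]))
    )
  }))
}

# Exhaustive UPGMA: clusters as index sets, inter-cluster distance as the
# mean of all pairwise Euclidean distances, merging the closest pair
# (ties by lowest indices). Returns the n-1 merge heights in order.
upgma_oracle_heights <- function(x) {
  d <- as.matrix(dist(x))
  clusters <- as.list(seq_len(nrow(x)))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- c(NA, NA)
    best_d <- Inf
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (j <= i) next
        dd <- mean(d[clusters[[i]], clusters[[j]]])
        if (dd < best_d - 1e-12) {
          best_d <- dd
          best <- c(i, j)
        }
      }
    }
    heights <- c(heights, best_d)
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  heights
}

# Random probe track on a handful of chromosomes for property tests.
random_toy_track <- function(n = 50, seed = 1, n_chrom = 1, spacing = 100) {
  set.seed(seed)
  per <- ceiling(n / n_chrom)
  chrom <- rep(sprintf("chr%d", seq_len(n_chrom)), each = per)[seq_len(n)]
  start <- unlist(lapply(table(chrom), function(k) seq(0, by = spacing, length.out = k)))
  tibble::tibble(
    probe_id = sprintf("p%03d", seq_len(n)),
    chrom = chrom,
    start = as.numeric(start),
    end = as.numeric(start) + 50,
    treated_1 = rnorm(n), treated_2 = rnorm(n),
    control_1 = rnorm(n), control_2 = rnorm(n)
  )
}

# Hand-built M-prime track (bypasses compute_mprime) for filter tests.
# Four elevated probes sit alone at 5000-5350 bp, > window/2 and > max_gap
# away from the flanking null probes, so the gain peak holds exactly the
# probes 21:24 and every flag can be engineered per member.
toy_mtrack <- function(block_m = 3, mean_treated = 1, mean_control = 0,
                       cv_treated = 0.1, cv_control = 0.1, seed = 1) {
  set.seed(seed)
  start <- c(seq(0, by = 100, length.out = 20),
             seq(5000, by = 100, length.out = 4),
             seq(9000, by = 100, length.out = 20))
  n <- length(start)
  m <- rnorm(n, sd = 0.05)
  m[21:24] <- block_m
  tibble::tibble(
    probe_id = sprintf("p%03d", seq_len(n)),
    chrom = "chr1",
    start = as.numeric(start),
    end = as.numeric(start) + 50,
    mprime = m,
    mean_treated = rep_len(mean_treated, n),
    mean_control = rep_len(mean_control, n),
    cv_treated = rep_len(cv_treated, n),
    cv_control = rep_len(cv_control, n)
  )
}
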