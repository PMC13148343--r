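const_track <- function(value, chrom = "chr1", len = 100000) {
  tibble::tibble(chrom = chrom, start = 0, end = len, value = value)
}

test_that("signal matrices average per bin and flag edges", {
  centers <- tibble::tibble(chrom = "chr1", start = 50000, end = 50001)
  sm <- build_signal_matrix(centers, list(X = const_track(3)),
                            span = 2000, bin_width = 50)
  expect_equal(dim(sm$tracks$X), c(1, 80))
  expect_true(all(sm$tracks$X == 3))

  # delta peak at the center maximises the central bins
  delta <- tibble::tibble(chrom = "chr1", start = 49990, end = 50010,
                          value = 100)
  sm2 <- build_signal_matrix(centers, list(X = delta), span = 2000,
                             bin_width = 50)
  expect_true(which.max(sm2$tracks$X[1, ]) %in% c(40, 41))

  # center close to the chromosome start is zero-padded and flagged
  near <- tibble::tibble(chrom = "chr1", start = 100, end = 101)
  sm3 <- build_signal_matrix(near, list(X = const_track(3)), span = 2000,
                             bin_width = 50)
  expect_true(sm3$regions$edge)
  expect_equal(sm3$tracks$X[1, 1], 0)
})

test_that("per-bin values equal a per-base averaging oracle", {
  withr::local_seed(41)
  track <- tibble::tibble(chrom = "chr1",
                          start = seq(0, 99000, by = 1000))
  track$end <- track$start + 1000
  track$value <- round(runif(100, 0, 5), 3)
  centers <- tibble::tibble(chrom = "chr1",
                            start = sample(5000:95000, 20), end = 0)
  centers$end <- centers$start + 1
  sm <- build_signal_matrix(centers, list(X = track), span = 400,
                            bin_width = 100)
  base_val <- rep(track$value, each = 1000)  # per-base expansion
  for (i in seq_len(20)) {
    mid <- centers$start[i]
    for (b in 1:8) {
      a0 <- mid - 400 + (b - 1) * 100
      expect_equal(sm$tracks$X[i, b], mean(base_val[(a0 + 1):(a0 + 100)]),
                   tolerance = 1e-9)
    }
  }
})

test_that("minus-strand rows are flipped to the 5'->3' convention", {
  ramp <- tibble::tibble(chrom = "chr1", start = seq(0, 99950, by = 50))
  ramp$end <- ramp$start + 50
  ramp$value <- seq_len(nrow(ramp))
  centers <- tibble::tibble(chrom = "chr1", start = 50000, end = 50001,
                            strand = c("+"))
  centers2 <- centers
  centers2$strand <- "-"
  p <- build_signal_matrix(centers, list(X = ramp), span = 1000)$tracks$X[1, ]
  m <- build_signal_matrix(centers2, list(X = ramp), span = 1000)$tracks$X[1, ]
  expect_equal(m, rev(p))
})

test_that("top-fraction selection keeps the right count with the tie rule", {
  withr::local_seed(43)
  centers <- tibble::tibble(chrom = "chr1",
                            start = seq(10000, by = 10000, length.out = 100))
  centers$end <- centers$start + 1
  track <- tibble::tibble(chrom = "chr1", start = centers$start - 2000,
                          end = centers$start + 2000,
                          value = runif(100, 0, 10))
  sm <- build_signal_matrix(centers, list(TCF3HLF = track), span = 2000)
  top <- select_top_enriched(sm, "TCF3HLF", 0.75)
  expect_equal(nrow(top$regions), 75)
  rs <- rowSums(sm$tracks$TCF3HLF)
  expect_true(min(rowSums(top$tracks$TCF3HLF)) >= sort(rs, decreasing = TRUE)[75] - 1e-9)

  # all-equal rows: first 75 by coordinate
  sm$tracks$TCF3HLF[] <- 1
  top2 <- select_top_enriched(sm, "TCF3HLF", 0.75)
  expect_equal(top2$regions$start, centers$start[1:75])

  expect_error(select_top_enriched(sm, "nope"), "not present")
})

test_that("clustering recovers planted archetypes and orders by activity", {
  sim <- simulate_archetype_matrix(n_regions = 300, noise_sd = 0.1, seed = 2)
  cl <- cluster_regions(sim$matrix, k = 3, seed = 2)
  expect_equal(sum(cl$sizes), 300)
  ari <- mclust::adjustedRandIndex(cl$cluster, sim$labels)
  expect_gte(ari, 0.9)
  # archetype 1 has the highest H3K27ac -> relabelled cluster 1
  expect_equal(unname(which.max(cl$track_means[, "H3K27ac"])), 1L)

  # duplicated regions get identical assignments
  dup <- sim$matrix
  dup$regions <- rbind(dup$regions, dup$regions[1:10, ])
  dup$tracks <- lapply(dup$tracks, function(m) rbind(m, m[1:10, ]))
  cl2 <- cluster_regions(dup, k = 3, seed = 2)
  expect_equal(cl2$cluster[301:310], cl2$cluster[1:10])

  # k = 1 puts everything in cluster 1; k > n errors
  expect_true(all(cluster_regions(sim$matrix, k = 1, seed = 1)$cluster == 1))
  small <- epregulome:::subset_signal_matrix(sim$matrix, 1:2)
  expect_error(cluster_regions(small, k = 3), "k >")
})

test_that("density statistics detect planted shifts and adjust with BH", {
  sim <- simulate_archetype_matrix(n_regions = 200, noise_sd = 0.1, seed = 5)
  cl <- cluster_regions(sim$matrix, k = 3, seed = 5)
  ds <- density_stats(sim$matrix, cl)
  # archetype 1 vs 3 differ strongly in H3K27ac by construction
  row <- ds[ds$track == "H3K27ac" & ds$cluster_a == 1 & ds$cluster_b == 3, ]
  expect_lt(row$q_value, 0.05)
  # q values are the BH step-up of the p values (hand-computed step-up)
  p <- ds$p_value
  n <- length(p)
  o <- order(p)
  stepup <- rev(cummin(rev(p[o] * n / seq_len(n))))
  expect_equal(ds$q_value[o], pmin(1, stepup), tolerance = 1e-12)

  # rescaling one track leaves its densities (and tests) unchanged
  sim2 <- sim$matrix
  sim2$tracks$H3K27ac <- sim2$tracks$H3K27ac * 7
  ds2 <- density_stats(sim2, cl)
  expect_equal(ds2$p_value, ds$p_value, tolerance = 1e-9)
  expect_equal(ds2$mean_a, ds$mean_a, tolerance = 1e-9)
})

test_that("identical clusters yield null density comparisons", {
  sim <- simulate_archetype_matrix(n_regions = 100, noise_sd = 0.1, seed = 6,
                                   archetype_fractions = c(1, 0, 0))
  fake <- structure(list(cluster = rep(1:2, 50), sizes = c(50L, 50L), k = 2,
                         active_track = "H3K27ac",
                         regions = sim$matrix$regions),
                    class = "chromatin_clusters")
  ds <- density_stats(sim$matrix, fake)
  expect_gt(min(ds$q_value), 0.2)
})

test_that("per-cluster correlations recover exact linear relations", {
  sim <- simulate_archetype_matrix(n_regions = 60, noise_sd = 0.1, seed = 7)
  x <- sim$matrix
  x$tracks$ATAC <- x$tracks$TCF3HLF * 2
  cl <- structure(list(cluster = rep(1L, 60), sizes = 60L, k = 1,
                       active_track = "H3K27ac", regions = x$regions),
                  class = "chromatin_clusters")
  expect_equal(cluster_signal_correlation(x, cl)$r, 1)

  x$tracks$ATAC <- -x$tracks$TCF3HLF + 5
  expect_equal(cluster_signal_correlation(x, cl)$r, -1)

  # naive formula oracle on random data
  withr::local_seed(47)
  x$tracks$ATAC <- matrix(runif(60 * 80), 60)
  a <- rowSums(x$tracks$ATAC)
  b <- rowSums(x$tracks$TCF3HLF)
  r_naive <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(cluster_signal_correlation(x, cl)$r, r_naive,
               tolerance = 1e-12)

  # clusters below n = 3 are skipped
  tiny <- epregulome:::subset_signal_matrix(x, 1:2)
  cl2 <- structure(list(cluster = c(1L, 1L), sizes = 2L, k = 1,
                        active_track = "H3K27ac", regions = tiny$regions),
                   class = "chromatin_clusters")
  expect_true(is.na(cluster_signal_correlation(tiny, cl2)$r))
})

test_that("tidy and glance summarise signal matrices coherently", {
  sim <- simulate_archetype_matrix(n_regions = 10, seed = 8)
  td <- tidy(sim$matrix)
  expect_equal(nrow(td), 10 * 80 * 6)
  g <- glance(sim$matrix)
  expect_equal(g$n_regions, 10)
  expect_equal(g$n_tracks, 6)
})
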