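test_that("two-cluster partition separates the two characteristic synapse populations", {
  agree <- vapply(1:20, function(s) {
    pop <- simulate_synapse_population(seed = s)
    cl <- cluster_psd_metrics(pop)
    mean(cl$labels == pop$true_label)
  }, numeric(1))
  expect_gt(mean(agree), 0.95)
  # thick centre has the larger d2 by construction
  pop <- simulate_synapse_population(seed = 1)
  cl <- cluster_psd_metrics(pop)
  expect_gt(cl$centers["thick", "d2"], cl$centers["thin", "d2"])
})

test_that("clustering is invariant to record order, duplication, and joint rescaling", {
  # the deterministic 2-means variant carries the invariance guarantees
  pop <- simulate_synapse_population(seed = 3)
  base <- cluster_psd_metrics(pop, method = "kmeans")$labels
  set.seed(1)
  perm <- sample(nrow(pop))
  shuffled <- cluster_psd_metrics(pop[perm, ], method = "kmeans")$labels
  expect_identical(shuffled, base[perm])
  dup <- cluster_psd_metrics(rbind(pop, pop), method = "kmeans")$labels
  expect_identical(dup, c(base, base))
  scaled <- pop
  scaled$d1 <- scaled$d1 * 3 + 2
  scaled$d2 <- scaled$d2 * 3 + 2
  expect_identical(cluster_psd_metrics(scaled, method = "kmeans")$labels,
                   base)
})

test_that("gmm and kmeans clustering agree on well-separated data", {
  pop <- simulate_synapse_population(
    n_thick = 40, n_thin = 20,
    thick_mean = c(15, 33), thick_sd = c(1.5, 3),
    thin_mean = c(9, 12), thin_sd = c(0.8, 1.2), seed = 5)
  a <- cluster_psd_metrics(pop, method = "kmeans")$labels
  b <- cluster_psd_metrics(pop, method = "gmm")$labels
  expect_gt(mean(a == b), 0.98)
})

test_that("no_psd records are excluded from clustering but kept in the labels", {
  pop <- simulate_synapse_population(n_thick = 10, n_thin = 10, seed = 2)
  pop$d1[c(3, 15)] <- NA
  cl <- cluster_psd_metrics(pop)
  expect_identical(cl$labels[c(3, 15)], c("no_psd", "no_psd"))
  expect_true(all(cl$labels[-c(3, 15)] %in% c("thick", "thin")))
  expect_error(cluster_psd_metrics(data.frame(d1 = c(1, 1), d2 = c(2, 2))),
               "identical")
})

test_that("population summary gives per-group mean and sample SD", {
  rec <- data.frame(d1 = c(10, 14, 9), d2 = c(30, 34, 12),
                    cleft_width = c(26, 25, 27),
                    cluster_label = c("thick", "thick", "thin"))
  s <- summarize_population(rec)
  thick_d1 <- s[s$group == "thick" & s$metric == "d1", ]
  expect_equal(thick_d1$n, 2)
  expect_equal(thick_d1$mean, 12)
  expect_equal(thick_d1$sd, sd(c(10, 14)))
  thin_d2 <- s[s$group == "thin" & s$metric == "d2", ]
  expect_equal(thin_d2$sd, 0)   # single record
  expect_match(attr(s, "sd_convention"), "n-1")
  # simulated populations recover generative means within 2 SE
  pop <- simulate_synapse_population(seed = 9)
  pop$cluster_label <- pop$true_label
  s2 <- summarize_population(pop)
  m <- s2[s2$group == "thick" & s2$metric == "d1", ]
  expect_lt(abs(m$mean - 14.7), 2 * 3.0 / sqrt(85))
})

test_that("KS statistic handles identical, disjoint, and monotone-transformed samples", {
  x <- c(1.2, 3.4, 2.2, 5.0)
  same <- ks_two_sample(x, x)
  expect_equal(same$D, 0)
  expect_equal(same$p, 1)
  disj <- ks_two_sample(c(1, 2, 3), c(4, 5, 6))
  expect_equal(disj$D, 1)
  set.seed(4)
  a <- rnorm(12); b <- rnorm(15, 0.8)
  d0 <- ks_two_sample(a, b)$D
  d1 <- ks_two_sample(exp(a), exp(b))$D   # strictly monotone transform
  expect_equal(d0, d1, tolerance = 1e-12)
})

test_that("exact KS p-value equals the full enumeration oracle", {
  set.seed(7)
  for (nm in list(c(5, 5), c(4, 6), c(3, 8))) {
    x <- runif(nm[1]); y <- runif(nm[2], 0.2, 1.2)
    ours <- ks_two_sample(x, y)
    expect_true(ours$exact)
    expect_equal(ours$p, ks_enumeration_oracle(x, y), tolerance = 1e-12)
  }
  # ties: enumeration over the pooled multiset must still match
  xt <- c(1, 2, 2, 3); yt <- c(2, 3, 3, 4)
  expect_equal(ks_two_sample(xt, yt)$p, ks_enumeration_oracle(xt, yt),
               tolerance = 1e-12)
})

test_that("exact KS p-value matches stats::ks.test for continuous samples", {
  set.seed(12)
  x <- rnorm(8); y <- rnorm(7, 0.5)
  ours <- ks_two_sample(x, y)
  ref <- suppressWarnings(stats::ks.test(x, y, exact = TRUE))
  expect_equal(ours$D, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(ours$p, ref$p.value, tolerance = 1e-9)
  # large-sample asymptotic branch against stats::ks.test
  x2 <- rnorm(60); y2 <- rnorm(55, 0.3)
  ours2 <- ks_two_sample(x2, y2)
  ref2 <- suppressWarnings(stats::ks.test(x2, y2, exact = FALSE))
  expect_false(ours2$exact)
  expect_equal(ours2$D, unname(ref2$statistic), tolerance = 1e-12)
  expect_equal(ours2$p, ref2$p.value, tolerance = 1e-7)
})
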