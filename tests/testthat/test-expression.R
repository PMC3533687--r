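test_that("zero-noise genes reproduce their cluster trajectories exactly", {
  spec <- default_cluster_spec()
  es <- simulate_expression(cluster_spec = spec, n_background = 0,
                            noise_sd = 0, seed = 1)
  pluri <- es$expr[es$labels == "pluripotency", ]
  for (i in seq_len(nrow(pluri))) {
    expect_equal(unname(pluri[i, ]), unname(2^spec$pluripotency$trajectory))
    expect_equal(names(which.max(pluri[i, ])), "E11.5")
  }
  meio <- es$expr[es$labels == "meiosis", ]
  peak <- apply(meio, 1, function(v) names(which.max(v)))
  expect_true(all(peak %in% c("E13.5_female", "E16.5_female")))
})

test_that("the simulated matrix bookkeeping adds up", {
  es <- simulate_expression(cluster_spec = default_cluster_spec(),
                            n_background = 940, seed = 2)
  expect_equal(dim(es$expr), c(1000, 8))
  expect_equal(sum(es$labels == "background"), 940)
  expect_true(all(es$expr >= 0))
  bad_spec <- default_cluster_spec()
  bad_spec$pluripotency$trajectory <- 1:3
  expect_error(simulate_expression(cluster_spec = bad_spec), "length")
})

test_that("complexity bands tally silent and expressed genes", {
  expr <- matrix(0, 5, 2, dimnames = list(paste0("g", 1:5), c("a", "b")))
  cx <- complexity_profile(expr)
  expect_equal(cx$silent, c(5, 5))
  expect_true(all(cx[, -(1:2)] == 0))
  expr2 <- matrix(c(0, 2, 20, 200, 5, 0, 2, 20, 200, 5), 5, 2,
                  dimnames = list(paste0("g", 1:5), c("a", "b")))
  cx2 <- complexity_profile(expr2)
  expect_identical(cx2[1, -1], cx2[2, -1], ignore_attr = TRUE)
})

test_that("transcriptome complexity is stable across simulated stages", {
  es <- simulate_expression(seed = 3)
  cx <- complexity_profile(es)
  counts <- as.matrix(cx[, -1])
  for (b in seq_len(ncol(counts))) {
    if (max(counts[, b]) == 0) next
    rel <- (max(counts[, b]) - min(counts[, b])) / max(counts[, b])
    expect_lt(rel, 0.10)
  }
})

test_that("planted clusters are recovered perfectly without noise", {
  es <- simulate_expression(n_background = 0, noise_sd = 0, seed = 4)
  cl <- cluster_profiles(es, min_size = 5)
  expect_length(cl$clusters, 2)
  truth <- split(names(es$labels), es$labels)
  got <- split(names(cl$assignment)[cl$assignment > 0],
               cl$assignment[cl$assignment > 0])
  for (m in truth) {
    expect_true(any(vapply(got, function(g) setequal(g, m), TRUE)))
  }
  # a min size beyond the gene count returns no clusters
  expect_length(cluster_profiles(es, min_size = 1000)$clusters, 0)
})

test_that("clustering is invariant to gene order and excludes constant genes", {
  es <- simulate_expression(n_background = 100, seed = 5)
  expr <- es$expr
  cl1 <- cluster_profiles(expr)
  perm <- sample(nrow(expr))
  cl2 <- cluster_profiles(expr[perm, ])
  expect_identical(cl1$assignment[sort(names(cl1$assignment))],
                   cl2$assignment[sort(names(cl2$assignment))])
  silent <- names(es$labels)[rowSums(expr) == 0]
  expect_true(all(silent %in% cl1$excluded_constant))
})

test_that("planted clusters survive moderate noise with high agreement", {
  for (seed in 1:2) {
    es <- simulate_expression(noise_sd = 0.5, seed = seed)
    cl <- cluster_profiles(es)
    planted <- names(es$labels)[es$labels != "background"]
    ari <- mclust::adjustedRandIndex(es$labels[planted],
                                     cl$assignment[planted])
    expect_gte(ari, 0.9)
  }
})

test_that("cluster trajectory summaries find the documented peaks", {
  es <- simulate_expression(noise_sd = 0.3, seed = 6)
  pluri <- names(es$labels)[es$labels == "pluripotency"]
  meio <- names(es$labels)[es$labels == "meiosis"]
  expect_equal(cluster_trajectory_summary(pluri, es)$peak, "E11.5")
  expect_true(cluster_trajectory_summary(meio, es)$peak %in%
                c("E13.5_female", "E16.5_female"))
  single <- cluster_trajectory_summary(pluri[1], es)
  expect_true(all(single$summary$sd == 0))
})

test_that("repeat read fractions are percentages of the sample totals", {
  rc <- simulate_repeat_counts(seed = 7)
  pct <- repeat_expression_fraction(rc$counts, rc$totals)
  expect_true(all(pct >= 0))
  expect_true(all(colSums(pct) <= 100))
  line1 <- colSums(pct[rc$targets, ])
  expect_equal(names(which.max(line1)), "E16.5_female")
  zero <- rc$counts; zero["LINE1Tf", ] <- 0
  expect_true(all(repeat_expression_fraction(zero,
                                             rc$totals)["LINE1Tf", ] == 0))
  expect_error(repeat_expression_fraction(rc$counts,
                                          setNames(rep(0, 8),
                                                   colnames(rc$counts))),
               "positive")
})

test_that("methylation-expression rank correlation reports sign and magnitude", {
  x <- 1:20
  expect_equal(methylation_expression_correlation(x, exp(x))$rho, 1)
  expect_equal(methylation_expression_correlation(x, -x)$rho, -1)
  cc <- methylation_expression_correlation(rep(5, 10), 1:10)
  expect_false(cc$defined)
  expect_error(methylation_expression_correlation(1:2, 1:2), "three")
  # independent vectors stay inside the permutation null band
  set.seed(11)
  m <- runif(200); e <- runif(200)
  rho <- methylation_expression_correlation(m, e)$rho
  perm <- replicate(1000, cor(m, sample(e), method = "spearman"))
  expect_lt(abs(rho), quantile(abs(perm), 0.999))
})

test_that("equal de novo gain in up and down genes is not called different", {
  set.seed(12)
  n <- 200
  m13 <- runif(n, 0, 5)
  gain <- rnorm(n, 40, 5)               # same gain regardless of direction
  m16 <- pmin(m13 + gain, 100)
  e13 <- runif(n, 1, 100)
  e16 <- e13 * runif(n, 0.2, 5)         # mixed up/down
  res <- denovo_vs_expression_change(m13, m16, e13, e16, seed = 1)
  expect_true(res$tested)
  expect_gt(res$p_perm, 0.01)
  # zero gain everywhere -> both group means 0
  res0 <- denovo_vs_expression_change(m13, m13, e13, e16, seed = 1)
  expect_equal(res0$mean_gain_up, 0)
  expect_equal(res0$mean_gain_down, 0)
  # all genes moving one way leaves a group empty and flags it
  res1 <- denovo_vs_expression_change(m13, m16, e13, e13 + 1, seed = 1)
  expect_false(res1$tested)
  expect_equal(res1$n_down, 0)
})
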