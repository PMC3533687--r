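test_that("genome tiling partitions each chromosome", {
  expect_equal(nrow(tile_genome(c(a = 10000), 5000)), 2)
  t3 <- tile_genome(c(a = 10001), 5000)
  expect_equal(nrow(t3), 3)
  expect_equal(t3$end[3] - t3$start[3], 1)
  lens <- c(chr1 = 12345, chr2 = 4999)
  tl <- tile_genome(lens, 1000)
  expect_equal(sum(tl$end - tl$start), sum(lens))
  expect_true(all(tl$start[-1] >= tl$start[-nrow(tl)] |
                    tl$chrom[-1] != tl$chrom[-nrow(tl)]))
})

test_that("probe methylation is the weighted percentage over contained CpGs", {
  calls <- list(s1 = make_calls("chr1", c(10, 20, 30), c(2, 1, 0),
                                c(0, 1, 0)))
  probes <- data.frame(chrom = "chr1", start = 0, end = 100, id = "p1")
  mm <- probe_methylation(calls, probes, min_total_count = 1)
  expect_equal(unname(mm$pct[1, 1]), 75)  # 3 meth / 4 total
  # bottom-strand calls count toward the dyad's probe
  calls2 <- list(s1 = make_calls("chr1", c(99, 100), c(1, 1), c(0, 1),
                                 strand = c("+", "-")))
  probes2 <- data.frame(chrom = "chr1", start = c(0, 100),
                        end = c(100, 200), id = c("p1", "p2"))
  mm2 <- probe_methylation(calls2, probes2, min_total_count = 1)
  expect_equal(unname(mm2$pct[1, 1]), 100 * 2 / 3)
  expect_true(is.na(mm2$pct[2, 1]))
})

test_that("probes below the coverage minimum are missing, never zero", {
  calls <- list(s1 = make_calls("chr1", c(10, 510), c(3, 0), c(2, 4)))
  probes <- tile_genome(c(chr1 = 1000), 500)
  mm <- probe_methylation(calls, probes, min_total_count = 10)
  expect_true(all(is.na(mm$pct[, 1])))
  expect_error(probe_methylation(calls, probes[0, ]), "empty")
})

test_that("probe and feature methylation match a per-CpG summation oracle", {
  set.seed(31)
  for (rep in 1:5) {
    n <- 200
    calls <- make_calls(
      chrom = sample(c("chr1", "chr2"), n, replace = TRUE),
      pos = sample(1:999, n, replace = TRUE),
      meth = rpois(n, 2), unmeth = rpois(n, 3),
      strand = sample(c("+", "-"), n, replace = TRUE))
    probes <- tile_genome(c(chr1 = 1000, chr2 = 800),
                          sample(c(100, 250, 333), 1))
    mm <- probe_methylation(list(s = calls), probes, min_total_count = 5)
    expect_equal(unname(mm$pct[, 1]),
                 oracle_interval_pct(calls, probes, 5))
    feats <- data.frame(chrom = c("chr1", "chr1", "chr2"),
                        start = c(0, 400, 100), end = c(450, 900, 700),
                        id = c("f1", "f2", "f3"),
                        class = "CGI", stringsAsFactors = FALSE)
    fm <- feature_methylation(list(s = calls), feats, min_total_count = 5)
    expect_equal(unname(fm$pct[, 1]),
                 oracle_interval_pct(calls, feats, 5))
  }
})

test_that("merging adjacent probes gives the count-weighted combination", {
  set.seed(8)
  calls <- make_calls("chr1", sample(0:999, 150), rpois(150, 3),
                      rpois(150, 3))
  two <- tile_genome(c(chr1 = 1000), 500)
  one <- tile_genome(c(chr1 = 1000), 1000)
  m2 <- probe_methylation(list(s = calls), two, min_total_count = 1)
  m1 <- probe_methylation(list(s = calls), one, min_total_count = 1)
  w <- m2$total[, 1]
  expect_equal(unname(m1$pct[1, 1]),
               sum(m2$pct[, 1] * w) / sum(w))
})

test_that("global summaries average probes and take replicate medians", {
  pct <- matrix(c(40, 60, 28, 28, 40, 60, 32, 32), nrow = 2,
                dimnames = list(c("p1", "p2"),
                                c("E9.5_r1", "E9.5_r2", "x", "y")))
  pct <- pct[, 1:2]
  mm <- make_stage_matrix(pct)
  mm$samples <- data.frame(sample = colnames(pct), stage = "E9.5",
                           sex = "mixed", replicate = 1:2)
  mm$pct[, 2] <- c(28, 32)
  gs <- global_summary(mm)
  expect_equal(gs$per_sample$value, c(50, 30))
  expect_equal(gs$per_stage$value, 40)  # median of 50 and 30
  # all-zero matrix floors at 0
  mm$pct[] <- 0
  expect_equal(global_summary(mm)$per_sample$value, c(0, 0))
  # all-missing sample errors with its name
  mm$pct[, 1] <- NA
  expect_error(global_summary(mm), "E9.5_r1")
})

test_that("methylation percentiles are monotone and match a sorted oracle", {
  pct <- matrix(50, nrow = 10, ncol = 1,
                dimnames = list(paste0("p", 1:10), "s1"))
  mm <- make_stage_matrix(pct)
  d <- methylation_distribution(mm, percentiles = c(5, 50, 95))
  expect_true(all(d == 50))
  set.seed(2)
  v <- runif(5000, 0, 100)
  mm2 <- make_stage_matrix(matrix(v, ncol = 1,
                                  dimnames = list(paste0("p", 1:5000),
                                                  "s1")))
  grid <- seq(10, 90, 10)
  d2 <- methylation_distribution(mm2, percentiles = grid)
  expect_true(all(diff(d2[1, ]) >= 0))
  sorted <- sort(v)
  oracle <- sorted[ceiling(grid / 100 * length(v))]
  expect_true(all(abs(d2[1, ] - oracle) < 2))
  expect_true(all(abs(d2[1, ] - grid) < 3))  # uniform: percentile p ~ p
})

test_that("conversion efficiency counts fully converted probes", {
  # 60 probes, every CHH site unmethylated -> fraction 1
  pos <- as.numeric(outer(seq(10, 990, 49), (0:59) * 1000, "+"))
  calls <- list(s1 = make_calls("chr1", pos, 0, 20, context = "CHH"))
  ce <- conversion_efficiency(calls, chrom_lengths = c(chr1 = 60000),
                              window_bp = 1000, min_total_count = 20)
  expect_equal(unname(ce$fraction), 1)
  # one methylated CHH in the only qualifying probe -> fraction 0
  calls2 <- list(s1 = make_calls("chr1", seq(10, 990, 10), c(1, rep(0, 98)),
                                 10, context = "CHH"))
  ce2 <- conversion_efficiency(calls2, chrom_lengths = c(chr1 = 1000),
                               window_bp = 1000, min_total_count = 20)
  expect_equal(unname(ce2$fraction), 0)
  expect_error(conversion_efficiency(calls2,
                                     chrom_lengths = c(chr1 = 1000),
                                     window_bp = 1000,
                                     min_total_count = 1e6),
               "qualifying|observations")
})

test_that("conversion fraction matches the Poisson-thinning expectation", {
  # 200 CHH observations per probe at failure rate 0.002:
  # P(zero failures) = (1 - 0.002)^200 ~ e^-0.4
  set.seed(77)
  n_probe <- 800
  sites_per_probe <- 10
  pos <- as.numeric(outer(seq(10, 910, 100),
                          (seq_len(n_probe) - 1) * 1000, "+"))
  meth <- rbinom(length(pos), 20, 0.002)
  calls <- list(s1 = make_calls("chr1", pos, meth, 20 - meth,
                                context = "CHH"))
  ce <- conversion_efficiency(calls,
                              chrom_lengths = c(chr1 = n_probe * 1000),
                              window_bp = 1000, min_total_count = 20)
  expected <- (1 - 0.002)^200
  tol <- 4 * sqrt(expected * (1 - expected) / n_probe)
  expect_lt(abs(unname(ce$fraction) - expected), tol)
})

test_that("CpG-density correlation handles degenerate inputs", {
  pct <- matrix(c(10, 20, 30, 40), ncol = 1,
                dimnames = list(paste0("p", 1:4), "s1"))
  mm <- make_stage_matrix(pct)
  mm$n_cpg <- setNames(c(1, 2, 3, 4), rownames(pct))
  cc <- cg_density_correlation(mm)
  expect_equal(cc$r, 1)
  mm$pct[] <- 50
  cc2 <- cg_density_correlation(mm)
  expect_false(cc2$defined)
  expect_true(is.na(cc2$r))
})

test_that("an imprinted DMR with balanced allelic coverage reads exactly 50%", {
  # one methylated and one unmethylated allele, error-free equal depth
  pos <- seq(110, 190, 10)
  calls <- list(s1 = make_calls("chr1", pos, 5, 5))
  dmr <- data.frame(chrom = "chr1", start = 100, end = 200, id = "dmr1",
                    class = "DMR_maternal", stringsAsFactors = FALSE)
  fm <- feature_methylation(list(s1 = calls$s1), dmr, min_total_count = 10)
  expect_identical(unname(fm$pct[1, 1]), 50)
  # fully methylated feature reads 100
  calls2 <- list(s1 = make_calls("chr1", pos, 7, 0))
  fm2 <- feature_methylation(calls2, dmr, min_total_count = 10)
  expect_identical(unname(fm2$pct[1, 1]), 100)
})

test_that("percentages stay within [0, 100] and IAPs stay above bulk", {
  sim <- small_sim()
  sm <- small_feature_stage_medians()
  expect_true(all(sm$pct >= 0 & sm$pct <= 100, na.rm = TRUE))
  probes <- tile_genome(sim$annotation$chrom_lengths, 5000)
  pm <- probe_methylation(sim, probes)
  stage_pm <- stage_medians(pm)
  iap <- sm$rows$id[sm$rows$class == "IAP"]
  for (k in colnames(sm$pct)) {
    bulk_med <- median(stage_pm$pct[, k], na.rm = TRUE)
    iap_med <- median(sm$pct[iap, k], na.rm = TRUE)
    expect_gt(iap_med, bulk_med)
  }
})

test_that("global demethylation shifts the whole percentile distribution down", {
  sim <- small_sim()
  probes <- tile_genome(sim$annotation$chrom_lengths, 5000)
  pm <- probe_methylation(sim, probes)
  d <- methylation_distribution(pm, percentiles = seq(10, 90, 20))
  expect_true(all(d["E13.5_female_r1", ] <= d["E6.5_r1", ]))
  # CG-density correlation weakens as methylation is erased
  cc <- cg_density_correlation(pm)
  r_e65 <- abs(cc$r[cc$sample == "E6.5_r1"])
  r_e135 <- abs(cc$r[cc$sample == "E13.5_female_r1"])
  expect_gt(r_e65, r_e135)
})
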