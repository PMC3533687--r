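stage_cols <- c("E6.5", "E9.5", "E10.5", "E11.5", "E13.5_male",
                "E13.5_female")

demo_matrix <- function() {
  pct <- rbind(
    dmr1 = c(50, 50, 48, 51, 1, 1),      # late demethylater
    cgi1 = c(60, 10, 5, 2, 0, 0),        # early erasure
    cgi2 = c(26, 26, 25.5, 26, 0, 0),    # just above threshold early
    cgi3 = c(25, 25, 25, 25, 25, 25),    # exactly at threshold
    iap1 = c(90, 88, 90, 91, 89, 90),    # resistant both sexes
    vec1 = c(40, 35, 30, 28, 40, 10),    # male-biased resistance
    gone = c(5, 3, 2, 1, 0.5, 0.2)       # fully erased
  )
  colnames(pct) <- stage_cols
  make_stage_matrix(pct)
}

test_that("late demethylaters must exceed the threshold at every early stage", {
  mm <- demo_matrix()
  sel <- select_late_demethylaters(mm)
  expect_setequal(sel$selected, c("dmr1", "cgi2", "iap1", "vec1"))
  expect_false("cgi3" %in% sel$selected)  # strict inequality at 25
  expect_false("cgi1" %in% sel$selected)  # fails from E9.5 on
  # threshold 100 selects nothing
  expect_length(select_late_demethylaters(mm, threshold = 100)$selected, 0)
  # absent stage errors with its name
  expect_error(select_late_demethylaters(mm, stages = c("E6.5", "E12")),
               "E12")
})

test_that("features missing at a rule stage are excluded and reported", {
  mm <- demo_matrix()
  mm$pct["dmr1", "E10.5"] <- NA
  sel <- select_late_demethylaters(mm)
  expect_false("dmr1" %in% sel$selected)
  expect_true("dmr1" %in% sel$excluded_missing)
})

test_that("resistance at E13.5 is assessed per sex on the single value", {
  mm <- demo_matrix()
  rm_ <- select_resistant(mm, "male")
  rf_ <- select_resistant(mm, "female")
  expect_setequal(rm_$selected, c("iap1", "vec1"))
  expect_setequal(rf_$selected, "iap1")
  expect_false("cgi3" %in% rm_$selected)  # exactly 25 fails
  # agrees with the general rule restricted to the single stage
  expect_identical(rm_$selected,
                   select_late_demethylaters(mm,
                                             stages = "E13.5_male")$selected)
})

test_that("raising thresholds or adding stages never enlarges selections", {
  set.seed(19)
  for (rep in 1:5) {
    pct <- matrix(runif(60, 0, 100), nrow = 10,
                  dimnames = list(paste0("f", 1:10), stage_cols))
    mm <- make_stage_matrix(pct)
    s25 <- select_late_demethylaters(mm, threshold = 25)$selected
    s50 <- select_late_demethylaters(mm, threshold = 50)$selected
    expect_true(all(s50 %in% s25))
    two <- select_late_demethylaters(mm, stages = c("E6.5", "E9.5"))$selected
    three <- select_late_demethylaters(mm, stages = c("E6.5", "E9.5",
                                                      "E10.5"))$selected
    expect_true(all(three %in% two))
  }
})

test_that("IAP proximity uses strict edge-to-edge distances", {
  feats <- data.frame(
    chrom = "chr1",
    start = c(1000, 5000, 10100, 20000),
    end = c(2000, 6000, 11000, 21000),
    id = c("overlap", "near", "at_cutoff", "far"),
    class = "CGI", stringsAsFactors = FALSE)
  iaps <- data.frame(chrom = "chr1",
                     start = c(1500, 7999, 13000, 50000),
                     end = c(1600, 8100, 13100, 50100),
                     id = "iap", class = "IAP", stringsAsFactors = FALSE)
  prox <- annotate_iap_proximity(feats, iaps, cutoff = 2000)
  expect_equal(prox$iap_dist, c(0, 1999, 2000, 6900))
  expect_equal(prox$proximal, c(TRUE, TRUE, FALSE, FALSE))
})

test_that("resistant fraction decays with IAP distance as the generator protects", {
  sim <- small_sim()
  sm <- small_feature_stage_medians()
  prom <- sm$rows[sm$rows$class == "promoter_nonCGI", ]
  sub <- sm
  sub$pct <- sm$pct[prom$id, , drop = FALSE]
  prox <- annotate_iap_proximity(sim$annotation, cutoff = 2000)
  prox <- prox[prox$id %in% prom$id, ]
  rvd <- resistance_vs_distance(sub, prox, breaks = c(0, 1000, 2500, 4000),
                                sex = "male")
  expect_true(all(diff(rvd$resistant_fraction) <= 0))
  # the generator's protection function predicts the same calls
  prof <- sim$profile
  pred <- vapply(prox$iap_dist, function(d) {
    100 * expected_class_level(prof, "promoter_nonCGI", "E13.5", "male",
                               divisions = 8, iap_dist = d) > 25
  }, TRUE)
  got <- prox$id %in% select_resistant(sub, "male")$selected
  expect_gt(mean(pred == got), 0.95)
})

test_that("VECs are resistant outside IAP context with a sex-bias tally", {
  mm <- demo_matrix()
  prox <- data.frame(id = rownames(mm$pct),
                     iap_dist = c(Inf, Inf, Inf, Inf, 0, 5000, Inf),
                     proximal = c(FALSE, FALSE, FALSE, FALSE, TRUE, FALSE,
                                  FALSE), stringsAsFactors = FALSE)
  vec <- identify_vecs(select_resistant(mm, "male"),
                       select_resistant(mm, "female"), prox, mm)
  expect_equal(vec$id, "vec1")           # iap1 excluded by proximity
  expect_equal(vec$sex_bias, 1L)         # male-only resistance
  expect_equal(vec$meth_range, 30)       # 40 - 10 across columns
  expect_length(intersect(vec$id, prox$id[prox$proximal]), 0)
})

test_that("protected CGI cores stand out against their flanks mid-course", {
  sim <- small_sim()
  gp <- sim$annotation$features
  gp <- gp[gp$class == "germline_promoter", ][1, ]
  cvf <- core_vs_flank_profile(sim, gp)
  e105 <- cvf[grepl("^E10.5", cvf$sample), ]
  expect_true(all(e105$difference > 0))
})

test_that("core equals flank under uniform methylation and at baseline", {
  pos <- seq(500, 3500, 10)
  calls <- list(s1 = make_calls("chr1", pos, 3, 1))
  cgi <- data.frame(chrom = "chr1", start = 1500, end = 2500, id = "c",
                    class = "CGI", stringsAsFactors = FALSE)
  cvf <- core_vs_flank_profile(list(s1 = calls$s1), cgi, flank_bp = 1000,
                               chrom_lengths = c(chr1 = 10000))
  expect_equal(cvf$difference, 0)
  # binomial sampling around a common rate keeps the difference small
  set.seed(4)
  meth <- rbinom(length(pos), 20, 0.5)
  calls2 <- list(s1 = make_calls("chr1", pos, meth, 20 - meth))
  cvf2 <- core_vs_flank_profile(calls2, cgi, flank_bp = 1000,
                                chrom_lengths = c(chr1 = 10000))
  n_core <- 20 * sum(pos >= 1500 & pos < 2500)
  tol <- 100 * 4 * sqrt(0.25 / n_core + 0.25 / (20 * length(pos) - n_core))
  expect_lt(abs(cvf2$difference), tol)
  # a flank without CpGs is missing
  cgi2 <- data.frame(chrom = "chr1", start = 400, end = 3600, id = "c",
                     class = "CGI", stringsAsFactors = FALSE)
  cvf3 <- core_vs_flank_profile(calls2, cgi2, flank_bp = 100,
                                chrom_lengths = c(chr1 = 10000))
  expect_true(is.na(cvf3$flank))
})

test_that("overlap enrichment matches an exact enumeration oracle", {
  bg <- paste0("f", 1:12)
  sel <- paste0("f", 1:4)
  hits <- paste0("f", c(1, 2, 3))
  res <- overlap_enrichment(sel, bg, hits)
  expect_equal(res$ratio, (3 / 4) / (3 / 12))
  # enumerate all selections of size 4 from 12 and count >= 3 hits
  combos <- utils::combn(12, 4)
  n_hit <- colSums(matrix(combos %in% 1:3, nrow = 4))
  expect_equal(res$p_value, mean(n_hit >= 3))
  # selected = background -> ratio 1
  expect_equal(overlap_enrichment(bg, bg, hits)$ratio, 1)
  # no hits anywhere -> undefined flag
  none <- overlap_enrichment(sel, bg, character())
  expect_false(none$defined)
  expect_error(overlap_enrichment(c(sel, "zz"), bg, hits), "subset")
})
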