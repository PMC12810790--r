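test_that("quantile normalization reproduces rank-wise means on complete data", {
  vals <- cbind(s1 = c(2, 4, 6), s2 = c(3, 5, 7))
  pqm <- make_pqm(vals, conditions = c("T", "C"))
  qn <- quantileNormalizeByOrganism(pqm)
  expect_equal(unname(log2Abundance(qn)),
               cbind(c(2.5, 4.5, 6.5), c(2.5, 4.5, 6.5)))
  ## already-identical samples are a fixed point
  vals2 <- cbind(s1 = c(1, 5, 9), s2 = c(1, 5, 9), s3 = c(1, 5, 9))
  pqm2 <- make_pqm(vals2, conditions = c("T", "T", "C"))
  expect_equal(unname(log2Abundance(quantileNormalizeByOrganism(pqm2))),
               unname(vals2))
})

test_that("quantile normalization agrees with the reference implementation", {
  ## complete matrices, no ties: limma's implementation is the oracle
  for (s in 1:10) {
    set.seed(s)
    m <- matrix(rnorm(8 * 6, 20, 3), 8, 6)
    pqm <- make_pqm(m, conditions = rep(c("T", "C"), each = 3))
    ours <- unname(log2Abundance(quantileNormalizeByOrganism(pqm)))
    ref <- unname(limma::normalizeQuantiles(m))
    expect_equal(ours, ref, tolerance = 1e-9)
  }
})

test_that("quantile normalization handles missingness by rank", {
  set.seed(42)
  m <- matrix(rnorm(30, 20, 2), 10, 3)
  m[sample(30, 8)] <- NA
  pqm <- make_pqm(m, conditions = c("T", "T", "C"))
  qn <- log2Abundance(quantileNormalizeByOrganism(pqm))
  ## missing stays missing
  expect_identical(unname(is.na(qn)), is.na(unname(m)))
  ## within-sample order preserved exactly (Spearman rho = 1)
  for (j in 1:3) {
    obs <- !is.na(m[, j])
    expect_equal(cor(m[obs, j], qn[obs, j], method = "spearman"), 1)
  }
  ## two organisms never normalized together: the bacterial block of a
  ## mixed matrix equals the same block normalized alone
  org <- rep(c("alga", "bacterium"), each = 5)
  pqm_mixed <- proteinQuantMatrix(m, organism = org,
                                  colData = data.frame(sample_id = paste0("s", 1:3),
                                                       condition = c("T", "T", "C")))
  qn_mixed <- log2Abundance(quantileNormalizeByOrganism(pqm_mixed))
  pqm_bact <- make_pqm(m[6:10, , drop = FALSE], conditions = c("T", "T", "C"))
  expect_equal(unname(qn_mixed[6:10, ]),
               unname(log2Abundance(quantileNormalizeByOrganism(pqm_bact))))
  ## a single usable sample is an error
  one <- matrix(c(1, 2, NA, NA), 2, 2)
  expect_error(quantileNormalizeByOrganism(
    make_pqm(one, conditions = c("T", "C"))), "at least 2 samples")
})

test_that("the limit of quantitation is mean minus two standard deviations", {
  expect_equal(unname(computeLoq(c(18, 20, 22))), 16)
  expect_equal(unname(computeLoq(c(5, 5, 5, 5))), 5)
  set.seed(1)
  v <- rnorm(200, 20, 3)
  expect_equal(unname(computeLoq(v)), mean(v) - 2 * sd(v))
  expect_error(computeLoq(c(3)), "at least 2")
  ## per-organism scope
  vals <- rbind(a = c(10, 12), b = c(11, 13), c = c(30, 34), d = c(31, 35))
  pqm <- proteinQuantMatrix(vals, organism = c("alga", "alga", "bacterium",
                                               "bacterium"))
  loq <- computeLoq(pqm, scope = "organism")
  expect_equal(unname(loq["alga"]),
               mean(c(10, 12, 11, 13)) - 2 * sd(c(10, 12, 11, 13)))
  loq_e <- computeLoq(pqm, scope = "experiment")
  expect_equal(unname(loq_e), mean(vals) - 2 * sd(vals))
})

test_that("differential expression implements LOQ-gated Welch testing", {
  ## identical arms: fold change 0, never significant
  vals <- matrix(rep(c(10, 11, 12), 2), 1, byrow = TRUE)
  pqm <- make_pqm(rbind(g1 = c(10, 11, 12, 10, 11, 12)))
  de0 <- differentialExpression(pqm, c("T", "C"), loq = c(alga = -Inf))
  expect_equal(de0$log2_fc, 0)
  expect_false(de0$significant)
  ## textbook Welch case: B - A = +3, t = 3.674, df = 4
  pqm2 <- make_pqm(rbind(g1 = c(13, 14, 15, 10, 11, 12)))
  de2 <- differentialExpression(pqm2, c("T", "C"), loq = c(alga = -Inf))
  o <- oracle_welch(c(13, 14, 15), c(10, 11, 12))
  expect_equal(de2$log2_fc, 3)
  expect_equal(de2$t_stat, o$t, tolerance = 1e-10)
  expect_equal(de2$df, 4)
  expect_equal(de2$p_value, o$p, tolerance = 1e-10)
  ## one replicate in one arm: excluded from testing
  pqm3 <- make_pqm(rbind(g1 = c(13, NA, NA, 10, 11, 12)))
  de3 <- differentialExpression(pqm3, c("T", "C"), loq = c(alga = -Inf))
  expect_false(de3$tested)
  expect_true(is.na(de3$p_value))
  ## the LOQ gate blocks significance below the limit
  pqm4 <- make_pqm(rbind(g1 = c(13, 14, 15, 10, 11, 12)))
  de4 <- differentialExpression(pqm4, c("T", "C"), loq = c(alga = 50))
  expect_false(de4$significant)
  expect_false(de4$above_loq_treat)
})

test_that("swapping the contrast negates the fold change, p unchanged", {
  set.seed(7)
  vals <- matrix(rnorm(60, 20, 2), 10, 6)
  vals[1, 1:3] <- vals[1, 1:3] + 3
  pqm <- make_pqm(vals)
  d1 <- differentialExpression(pqm, c("T", "C"), loq = c(alga = -Inf))
  d2 <- differentialExpression(pqm, c("C", "T"), loq = c(alga = -Inf))
  expect_equal(d1$log2_fc, -d2$log2_fc)
  expect_identical(d1$p_value, d2$p_value)
  expect_identical(d1$p_adj, d2$p_adj)
})

test_that("degenerate zero-variance genes never auto-pass", {
  pqm <- make_pqm(rbind(g1 = c(5, 5, 5, 9, 9, 9),
                        g2 = c(5, 5, 5, 5, 5, 5)))
  expect_warning(de <- differentialExpression(pqm, c("T", "C"),
                                              loq = c(alga = -Inf)),
                 "degenerate")
  expect_true(de$degenerate[1])
  expect_false(de$significant[1])
  expect_true(is.na(de$p_value[1]))
  ## equal means with zero variance: p = 1 by convention
  expect_equal(de$p_value[2], 1)
  expect_false(de$significant[2])
})

test_that("Z-scores standardize condition means per protein", {
  vals <- rbind(g1 = c(10, 10, 12, 12, 14, 14),
                g2 = c(8, 8, 8, 8, 8, 8))
  cd <- data.frame(sample_id = paste0("s", 1:6),
                   condition = rep(c("c1", "c2", "c3"), each = 2))
  pqm <- proteinQuantMatrix(vals, organism = "alga", colData = cd)
  z <- computeZScores(pqm)
  expect_equal(unname(z["g1", ]), c(-1, 0, 1))
  ## constant profile: flagged, all zero
  expect_equal(unname(z["g2", ]), c(0, 0, 0))
  expect_true(attr(z, "flat")["g2"])
  ## two conditions: +/- 1/sqrt(2)
  cd2 <- data.frame(sample_id = paste0("s", 1:4),
                    condition = rep(c("c1", "c2"), each = 2))
  pqm2 <- proteinQuantMatrix(rbind(g1 = c(4, 4, 6, 6)), organism = "alga",
                             colData = cd2)
  z2 <- computeZScores(pqm2)
  expect_equal(unname(z2["g1", ]), c(-1, 1) / sqrt(2), tolerance = 1e-12)
})

test_that("detection-count comparison is a two-tailed Student t-test", {
  r <- compareDetectionCounts(c(100, 101, 99), c(100, 99, 101))
  expect_equal(r$p_value, 1)
  r2 <- compareDetectionCounts(c(100, 101, 99), c(50, 51, 49))
  expect_lt(r2$p_value, 0.05)
  expect_equal(r2$statistic,
               unname(t.test(c(100, 101, 99), c(50, 51, 49),
                             var.equal = TRUE)$statistic))
  expect_error(compareDetectionCounts(c(100), c(50, 51)), "at least 2")
})

test_that("distribution comparison is a rank-sum test on protein means", {
  set.seed(3)
  base <- rnorm(50, 20, 2)
  vals <- cbind(base, base, base, base - 5, base - 5, base - 5) +
    matrix(rnorm(300, 0, 0.01), 50, 6)
  pqm <- make_pqm(vals)
  r <- compareDistributions(pqm, "T", "C")
  expect_lt(r$p_value, 0.001)
  expect_equal(r$n_proteins, 50L)
  ## medians equal direct computation on the replicate means
  ma <- rowMeans(vals[, 1:3]); mb <- rowMeans(vals[, 4:6])
  expect_equal(r$median_a, median(ma))
  expect_equal(r$median_b, median(mb))
  ## identical sets: no distributional difference
  vals2 <- cbind(base, base, base, base, base, base)
  r2 <- compareDistributions(make_pqm(vals2), "T", "C")
  expect_gte(r2$p_value, 0.99)
})
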