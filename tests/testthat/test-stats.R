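test_that("exact JT p-values match full enumeration", {
  groups <- list(c(1, 2), c(3, 4), c(5, 6))
  oracle <- jtEnumOracle(groups)
  expect_equal(oracle$nArrangements, 90)
  res <- jonckheereTerpstra(groups, alternative = "increasing",
                           method = "exact")
  expect_equal(res$statistic, 12)
  expect_equal(res$p.value, oracle$p, tolerance = 1e-12)
  expect_equal(res$p.value, 1 / 90, tolerance = 1e-12)

  # a scrambled arrangement agrees with the oracle too
  g2 <- list(c(3, 6), c(1, 5), c(2, 4))
  expect_equal(jonckheereTerpstra(g2, alternative = "increasing",
                                  method = "exact")$p.value,
               jtEnumOracle(g2)$p, tolerance = 1e-12)
})

test_that("complete ties sit at the null mean with two-sided p of 1", {
  res <- jonckheereTerpstra(list(rep(2, 3), rep(2, 4), rep(2, 3)),
                            method = "exact")
  expect_equal(res$statistic, res$mean)
  expect_equal(res$p.value, 1)
  expect_true(res$tieCorrected)
})

test_that("normal approximation agrees with Monte-Carlo permutation", {
  set.seed(21)
  x <- rnorm(30)
  g <- rep(1:5, each = 6)
  pn <- jonckheereTerpstra(x, g, method = "normal")$p.value
  pm <- jonckheereTerpstra(x, g, method = "monte_carlo", nperm = 1e5,
                           seed = 5)$p.value
  expect_lt(abs(pn - pm), 0.02)
})

test_that("JT alternatives and input validation behave", {
  inc <- list(c(1, 2), c(3, 4), c(5, 6))
  dec <- lapply(inc, function(v) -v)
  expect_equal(jonckheereTerpstra(dec, alternative = "decreasing",
                                  method = "exact")$p.value, 1 / 90,
               tolerance = 1e-12)
  expect_equal(jonckheereTerpstra(inc, alternative = "two.sided",
                                  method = "exact")$p.value, 2 / 90,
               tolerance = 1e-12)
  expect_error(jonckheereTerpstra(list(c(1, 2))), "2 non-empty")
  expect_error(jonckheereTerpstra(1:6, rep(1, 6)), "2 non-empty")
})

test_that("AUROC equals brute-force pair counting and is rank invariant", {
  perfect <- rocAuc(c(1, 2, 3, 10, 11, 12), rep(c(FALSE, TRUE), each = 3))
  expect_equal(perfect$auroc, 1)
  expect_equal(perfect$sensitivity, 1)
  expect_equal(perfect$specificity, 1)

  tied <- rocAuc(rep(5, 10), rep(c(TRUE, FALSE), 5))
  expect_equal(tied$auroc, 0.5)

  set.seed(31)
  for (k in 1:20) {
    v <- sample(round(rnorm(200), 1))  # ties included
    l <- runif(200) < 0.4
    r <- rocAuc(v, l, orientation = "high_positive")
    expect_equal(r$auroc, bruteAUC(v, l), tolerance = 1e-12)
    expect_equal(rocAuc(exp(v), l, orientation = "high_positive")$auroc,
                 r$auroc, tolerance = 1e-12)
  }
  expect_error(rocAuc(1:5, rep(TRUE, 5)), "both classes")
})

test_that("auto orientation flips features where lower values mean disease", {
  set.seed(32)
  minor <- c(rnorm(25, 120, 8), rnorm(10, 85, 8))
  labels <- rep(c(FALSE, TRUE), c(25, 10))
  r <- rocAuc(minor, labels)
  expect_identical(r$orientation, "low_positive")
  expect_gt(r$auroc, 0.9)
  expect_equal(r$auroc, 1 - bruteAUC(minor, labels), tolerance = 1e-12)
})

test_that("rocAuc cross-checks against pROC on a shared example", {
  set.seed(33)
  v <- rnorm(80); l <- runif(80) < 0.5
  ours <- rocAuc(v, l, orientation = "high_positive")$auroc
  theirs <- as.numeric(pROC::auc(pROC::roc(l, v, direction = "<",
                                           quiet = TRUE)))
  expect_equal(ours, theirs, tolerance = 1e-12)
})

test_that("confusion reconstruction reproduces printed diagnostic rows", {
  c1 <- confusionFromRates(0.571, 0.862, 14, 29)
  expect_equal(c1[c("TP", "FN", "TN", "FP")],
               list(TP = 8, FN = 6, TN = 25, FP = 4))
  expect_equal(round(f1FromConfusion(c1), 3), 0.615)

  c2 <- confusionFromRates(1, 0.600, 3, 40)
  expect_equal(c2[c("TP", "FN", "TN", "FP")],
               list(TP = 3, FN = 0, TN = 24, FP = 16))
  expect_equal(round(f1FromConfusion(c2), 3), 0.273)

  perf <- confusionFromRates(1, 1, 7, 9)
  expect_equal(perf$FP, 0)
  expect_equal(perf$FN, 0)
  expect_equal(f1FromConfusion(perf), 1)

  expect_warning(confusionFromRates(0.3, 0.9, 7, 10), "integer-consistent")
  expect_error(f1FromConfusion(list(TP = 0, FP = 0, FN = 0)), "undefined")
})

test_that("rates -> counts -> rates is the identity on consistent inputs", {
  set.seed(34)
  for (k in 1:20) {
    nPos <- sample(3:40, 1); nNeg <- sample(3:40, 1)
    tp <- sample(0:nPos, 1); tn <- sample(0:nNeg, 1)
    cc <- confusionFromRates(tp / nPos, tn / nNeg, nPos, nNeg)
    expect_equal(cc$TP, tp)
    expect_equal(cc$TN, tn)
  }
})

test_that("stageFeatureTable tests all 16 features in report order", {
  cohort <- generateCohort(cohortConfig(seed = 11), render = "mask")
  feats <- shapeFeatureTable(cohort)
  stages <- vapply(cohort, stage, integer(1))
  tab <- stageFeatureTable(feats, stages)
  expect_equal(nrow(tab), 16)
  expect_identical(tab$feature, featureNames())
  expect_true(all(tab$p >= 0 & tab$p <= 1))
  # injected thinning is detected on the measured Minor
  expect_lt(tab$p[tab$feature == "Minor"], 0.05)
  # Roundness = Minor/Major under the equal-area fit: its two-sided trend
  # p-value duplicates AspectRatio's
  expect_equal(tab$p[tab$feature == "Roundness"],
               tab$p[tab$feature == "AspectRatio"], tolerance = 1e-12)

  dt <- diagnosticTable(feats, stages, endpoints = c(3, 4))
  expect_equal(nrow(dt), 32)
  expect_identical(unique(dt$endpoint), c(">=F3", ">=F4"))
  expect_identical(dt$orientation[dt$feature == "Minor" &
                                    dt$endpoint == ">=F3"], "low_positive")
})
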