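test_that("splitFrontRear cuts at lateral extremes and orders by depth", {
  th <- seq(0, 2 * pi, length.out = 145)[-145]
  ell <- cbind(100 + 80 * cos(th), 60 + 25 * sin(th))
  sides <- splitFrontRear(ell)
  expect_gt(mean(sides$rear[, 2]), mean(sides$front[, 2]))
  expect_identical(attr(sides$rear, "side"), "rear")
  # shared endpoints at the leftmost and rightmost vertices
  expect_equal(sides$front[1, ], sides$rear[1, ], ignore_attr = TRUE)
  expect_equal(sides$front[nrow(sides$front), ],
               sides$rear[nrow(sides$rear), ], ignore_attr = TRUE)

  # concatenating front and reversed rear reconstructs the vertex set
  joined <- rbind(sides$front,
                  sides$rear[rev(seq_len(nrow(sides$rear))), ])
  expect_setequal(paste(round(joined[, 1], 9), round(joined[, 2], 9)),
                  paste(round(ell[, 1], 9), round(ell[, 2], 9)))

  tall <- cbind(c(5, 5, 5.5), c(0, 30, 15))
  expect_error(splitFrontRear(tall), "lateral extent")
})

test_that("rear perturbation only affects the rear roughness score", {
  sh <- makeLiverShape(shapeParams(150, 60, roughAmplitude = 6,
                                   roughNWaves = 9), seed = 4)
  sides <- splitFrontRear(traceContour(sh$mask))
  expect_gt(roughnessScore(sides$rear)$rmsResidual,
            2 * roughnessScore(sides$front)$rmsResidual)
})

test_that("renderContourImage draws recoverable 1-px curves", {
  th <- seq(0, 2 * pi, length.out = 181)[-181]
  ell <- cbind(100 + 70 * cos(th), 80 + 40 * sin(th))
  sides <- splitFrontRear(ell)
  img <- renderContourImage(sides$front, sides$rear, c(160, 200))
  expect_identical(renderContourImage(sides$front, sides$rear, c(160, 200)),
                   img)
  expect_setequal(unique(as.vector(img)), c(0, 255))

  # every vertex lies within 1 px of a drawn pixel
  px <- which(img == 255, arr.ind = TRUE)
  px <- cbind(px[, 2] - 1, px[, 1] - 1)
  verts <- rbind(sides$front, sides$rear)
  dmin <- vapply(seq_len(nrow(verts)), function(i)
    sqrt(min((px[, 1] - verts[i, 1])^2 + (px[, 2] - verts[i, 2])^2)),
    numeric(1))
  expect_lt(max(dmin), 1)

  # drawn pixel count tracks the total arc length
  arc <- sum(sqrt(rowSums(diff(sides$front)^2))) +
    sum(sqrt(rowSums(diff(sides$rear)^2)))
  expect_equal(sum(img == 255), arc, tolerance = 0.2)

  expect_error(renderContourImage(sides$front, sides$rear, c(100, 100)),
               "outside the canvas")
})

test_that("affine augmentation respects bounds and exact translations", {
  img <- matrix(0, 50, 50); img[20:30, 18:32] <- 255
  expect_identical(affineAugment(img, affineParams(0, 0, 0)), img)

  big <- matrix(0, 500, 500); big[201:300, 201:300] <- 255
  shifted <- affineAugment(big, affineParams(0, 0.10, 0))
  expect_identical(shifted[, 51:500], big[, 1:450])
  expect_true(all(shifted[, 1:50] == 0))

  disc <- ifelse(discMask(80, pad = 60), 255, 0)
  rot <- affineAugment(disc, affineParams(10, 0, 0))
  expect_equal(sum(rot > 0), sum(disc > 0), tolerance = 0.03)
  expect_identical(dim(rot), dim(disc))

  expect_error(affineParams(11, 0, 0), "rotationDeg")
  expect_error(affineParams(0, 0.2, 0), "shiftXFrac")
  r1 <- affineAugment(img, seed = 3)
  expect_identical(affineAugment(img, seed = 3), r1)
})

test_that("focal loss matches its closed forms and is bounded by cross-entropy", {
  expect_equal(focalLoss(1, 2), 0)
  p <- c(0.05, 0.2, 0.5, 0.9, 1)
  expect_equal(focalLoss(p, 0), -log(p))
  expect_equal(focalLoss(0.5, 2), 0.25 * log(2), tolerance = 1e-12)
  for (g in c(0, 0.5, 1, 2, 5))
    expect_true(all(focalLoss(p, g) <= -log(p) + 1e-15))
  expect_error(focalLoss(0), "pT")
  expect_error(focalLoss(-0.1), "pT")
})

test_that("roughness score: zero for lines, A/sqrt(2) for fast sinusoids, monotone in amplitude", {
  x <- seq(0, 300, by = 1)
  expect_equal(roughnessScore(cbind(x, 0.5 * x))$rmsResidual, 0,
               tolerance = 1e-9)

  for (A in c(0.5, 1)) {
    xx <- seq(0, 400, by = 0.25)
    r <- roughnessScore(cbind(xx, A * sin(2 * pi * xx / 8)), 31)$rmsResidual
    expect_equal(r, A / sqrt(2), tolerance = 0.1)
  }

  rms <- vapply(c(0, 2, 4, 6, 8), function(A) {
    sh <- makeLiverShape(shapeParams(150, 60, roughAmplitude = A,
                                     roughNWaves = 9), seed = 3)
    sides <- splitFrontRear(traceContour(sh$mask))
    roughnessScore(sides$rear)$rmsResidual
  }, numeric(1))
  expect_true(all(diff(rms) > 0))

  expect_error(roughnessScore(cbind(0:20, 0), smoothWindow = 31), "too short")
})

test_that("threshold calibration separates generated smooth and rough shapes", {
  cohort <- generateCohort(cohortConfig(countsPerStage = rep(6L, 5),
                                        roughProbPerStage = rep(0.5, 5),
                                        seed = 9), render = "mask")
  scores <- vapply(cohort, function(r) {
    sides <- splitFrontRear(traceContour(subjectMask(r)))
    roughnessScore(sides$rear)$rmsResidual
  }, numeric(1))
  labels <- vapply(cohort, roughLabel, character(1))
  th <- calibrateRoughnessThreshold(scores, labels)
  calls <- ifelse(scores >= th, "rough", "smooth")
  ev <- evaluateClassifier(calls, labels)
  expect_gte(ev$overallAccPct, 90)
})

test_that("classifier evaluation reports per-class percentages", {
  calls <- rep("smooth", 32)
  labels <- rep(c("rough", "smooth"), c(9, 23))
  ev <- evaluateClassifier(calls, labels)
  expect_equal(ev$smoothAccPct, 100)
  expect_equal(ev$roughAccPct, 0)
  expect_equal(round(ev$overallAccPct, 1), 71.9)

  perm <- sample(32)
  expect_equal(evaluateClassifier(calls[perm], labels[perm]), ev)

  expect_equal(evaluateClassifier(labels, labels),
               list(smoothAccPct = 100, roughAccPct = 100,
                    overallAccPct = 100, nSmooth = 23, nRough = 9))
  expect_error(evaluateClassifier(calls[1:5], labels), "equal length")
  expect_error(evaluateClassifier(rep("smooth", 3), rep("smooth", 3)),
               "both classes")
})
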