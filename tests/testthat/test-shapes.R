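test_that("areaPerimeter follows the pixel-center polygon convention", {
  sq <- cbind(c(0, 9, 9, 0), c(0, 0, 9, 9))
  ap <- areaPerimeter(sq)
  expect_equal(ap$area, 81)
  expect_equal(ap$perimeter, 36)

  mirrored <- cbind(-sq[, 1], sq[, 2])
  expect_equal(areaPerimeter(mirrored), ap)

  ct <- traceContour(discMask(50))
  apd <- areaPerimeter(ct, checkSimple = FALSE)
  expect_equal(apd$area, pi * 2500, tolerance = 0.02)
  expect_equal(apd$perimeter, 2 * pi * 50, tolerance = 0.05)

  bowtie <- cbind(c(0, 4, 4, 0), c(0, 4, 0, 4))
  expect_error(areaPerimeter(bowtie), "self-intersecting")
})

test_that("solidity is 1 for convex shapes and matches the analytic plus-sign value", {
  sq <- cbind(c(0, 9, 9, 0), c(0, 0, 9, 9))
  expect_equal(convexHullSolidity(sq)$solidity, 1)

  # plus sign, arms 20 wide x 60 long: area 2000, hull (octagon) area 2800
  plus <- cbind(
    c(-30, -10, -10, 10, 10, 30, 30, 10, 10, -10, -10, -30),
    c(-10, -10, -30, -30, -10, -10, 10, 10, 30, 30, 10, 10))
  expect_equal(convexHullSolidity(plus)$solidity, 2000 / 2800, tolerance = 1e-12)

  set.seed(11)
  for (k in 1:20) {
    pts <- matrix(runif(40), ncol = 2)
    hull <- pts[chull(pts), ]
    expect_equal(convexHullSolidity(hull)$solidity, 1, tolerance = 1e-9)
  }

  expect_error(convexHullSolidity(cbind(0:4, 0:4)), "collinear")
})

test_that("a rough rear surface lowers solidity relative to the smooth shape", {
  smooth <- makeLiverShape(shapeParams(150, 60), seed = 5)
  rough <- makeLiverShape(shapeParams(150, 60, roughAmplitude = 6,
                                      roughNWaves = 9), seed = 5)
  sSm <- convexHullSolidity(traceContour(smooth$mask))$solidity
  sRg <- convexHullSolidity(traceContour(rough$mask))$solidity
  expect_lt(sRg, sSm)
})

test_that("Feret diameters of canonical shapes", {
  f <- feretDiameters(cbind(c(0, 4, 4, 0), c(0, 0, 4, 4)))
  expect_equal(f$feret, 4 * sqrt(2))
  expect_equal(f$minFeret, 4)
  expect_equal(f$feretAngle, 45)

  seg <- feretDiameters(cbind(c(0, 6), c(0, 0)))
  expect_equal(seg$feret, 6)
  expect_equal(seg$minFeret, 0)
  expect_equal(seg$feretAngle, 0)
  expect_equal(c(seg$feretX, seg$feretY), c(0, 0))

  expect_error(feretDiameters(cbind(c(2, 2), c(3, 3))), "degenerate")
})

test_that("Feret and MinFeret match brute-force oracles on random point sets", {
  set.seed(42)
  for (k in 1:100) {
    pts <- matrix(runif(2 * sample(10:40, 1)), ncol = 2)
    f <- feretDiameters(pts)
    expect_equal(f$feret, bruteFeret(pts), tolerance = 1e-12)
    expect_lt(abs(f$minFeret - bruteMinWidthGrid(pts)), 1e-6)
    expect_lte(f$minFeret, f$feret)
  }
})

test_that("equal-area moment ellipse recovers known geometry", {
  fd <- fitEllipse(discMask(30))
  expect_equal(fd$major, 60, tolerance = 0.02)
  expect_equal(fd$minor, 60, tolerance = 0.02)
  expect_equal(fd$major / fd$minor, 1, tolerance = 0.02)

  fe <- fitEllipse(ellipseMask(60, 30))
  expect_equal(fe$major, 120, tolerance = 0.02)
  expect_equal(fe$minor, 60, tolerance = 0.02)
  expect_true(fe$angle < 2 || fe$angle > 178)

  fr <- fitEllipse(ellipseMask(60, 30, angleDeg = 30))
  expect_equal(fr$angle, 30, tolerance = 2 / 30)
  expect_equal(fr$major, fe$major, tolerance = 0.02)
  expect_equal(fr$minor, fe$minor, tolerance = 0.02)

  single <- matrix(FALSE, 9, 9); single[5, 5] <- TRUE
  expect_error(fitEllipse(single, minSize = 1), "zero-variance")
})

test_that("bounding box counts pixel extents", {
  m <- matrix(FALSE, 15, 25); m[3:12, 2:21] <- TRUE
  bb <- boundingBox(m)
  expect_equal(bb$width, 20)
  expect_equal(bb$height, 10)

  row1 <- matrix(FALSE, 5, 10); row1[3, 2:8] <- TRUE
  expect_equal(boundingBox(row1), list(width = 7L, height = 1L))

  expect_equal(boundingBox(discMask(30)), list(width = 61L, height = 61L))
  expect_error(boundingBox(matrix(FALSE, 3, 3)), "empty")
})

test_that("shapeFeatures assembles the 16 descriptors with stated conventions", {
  feats <- shapeFeatures(discMask(50))
  expect_identical(names(feats), featureNames())
  # under the pixel-center polygon convention the staircase perimeter of a
  # raster disc runs ~5% long, putting circularity near 4pi A / (1.05 P)^2
  expect_gte(feats$Circularity, 0.85)
  expect_lte(feats$Circularity, 1)
  expect_equal(feats$Roundness, 1, tolerance = 0.05)
  expect_equal(feats$AspectRatio, 1, tolerance = 0.02)
  expect_lte(feats$MinFeret, feats$Feret)
  expect_lte(feats$Minor, feats$Major)
  expect_lte(feats$Area, feats$Width * feats$Height)

  m <- matrix(FALSE, 60, 60); m[6:55, 6:55] <- TRUE
  fsq <- shapeFeatures(m)
  expect_equal(fsq$Circularity, pi / 4, tolerance = 1e-6)
})

test_that("features are translation invariant and rotation tolerant", {
  base <- ellipseMask(40, 22, pad = 30)
  shifted <- matrix(FALSE, nrow(base) + 15, ncol(base) + 9)
  shifted[15 + seq_len(nrow(base)), 9 + seq_len(ncol(base))] <- base
  fb <- shapeFeatures(base); fs <- shapeFeatures(shifted)
  inv <- setdiff(featureNames(), c("FeretX", "FeretY"))
  expect_equal(fs[inv], fb[inv], tolerance = 1e-9)

  rot90 <- base[, rev(seq_len(ncol(base)))]
  rot90 <- t(rot90)  # 90-degree rotation of the raster
  f9 <- shapeFeatures(rot90)
  for (f in c("Area", "Perimeter", "Feret", "MinFeret", "Major", "Minor",
              "Solidity"))
    expect_equal(f9[[f]], fb[[f]], tolerance = 1e-9)

  f30 <- shapeFeatures(ellipseMask(40, 22, angleDeg = 37, pad = 30))
  for (f in c("Area", "Perimeter", "Feret", "MinFeret", "Major", "Minor"))
    expect_equal(f30[[f]], fb[[f]], tolerance = 0.03)
})

test_that("stage-dependent thinning shows up in the measured Minor", {
  thick <- makeLiverShape(shapeParams(150, 85), seed = 8)   # F1-like
  thin <- makeLiverShape(shapeParams(150, 59.5), seed = 8)  # F4-like, -30%
  mThick <- shapeFeatures(largestParticle(thick$mask))$Minor
  mThin <- shapeFeatures(largestParticle(thin$mask))$Minor
  expect_lt(mThin, mThick)
  expect_equal(mThin / mThick, 0.7, tolerance = 0.05)
})
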