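# Synthetic liver-lobe phantoms. The base silhouette is a superellipse
# |x/a|^p + |y/b|^p = 1 whose minor axis tapers linearly toward the caudal
# (x > 0) end, giving the wedge profile of a sagittal left-lobe section;
# surface roughness is a band-limited random-phase perturbation applied to
# the rear (y-down) half only, where fibrotic irregularity is assessed.

#' Generate a liver-lobe-like phantom contour and mask
#'
#' Builds the analytic closed polygon of a superellipse-based lobe profile
#' (optionally with a rough rear surface), then rasterizes it. The rear
#' perturbation is a sum of `roughNWaves` random-phase sinusoids in the
#' boundary parameter, scaled to RMS amplitude `roughAmplitude` and windowed
#' so the front surface is untouched; it displaces the boundary along the
#' outward radial direction. Deterministic given `seed`.
#'
#' @param params a [ShapeParams-class] object.
#' @param canvas length-2 integer, (H, W) in pixels.
#' @param seed integer seed for the roughness phases.
#' @param nVertices number of polygon vertices (default 720).
#' @return A list with `contour` (analytic polygon, 0-based (x, y)) and
#'   `mask` (logical `H x W` matrix).
#' @export
#' @examples
#' sh <- makeLiverShape(shapeParams(60, 25, center = c(63.5, 63.5)),
#'                      canvas = c(128, 128), seed = 1)
#' sum(sh$mask)
makeLiverShape <- function(params, canvas = c(512L, 512L), seed = 1L,
                           nVertices = 720L) {
  stopifnot(is(params, "ShapeParams"))
  validObject(params)
  H <- as.integer(canvas[1]); W <- as.integer(canvas[2])
  a <- params@semiMajor; b <- params@semiMinor; p <- params@bluntness
  theta <- seq(0, 2 * pi, length.out = nVertices + 1L)[-(nVertices + 1L)]
  # superellipse parameterization; y > 0 is the rear (dorsal) side (y-down)
  bx <- a * sign(cos(theta)) * abs(cos(theta))^(2 / p)
  by <- b * sign(sin(theta)) * abs(sin(theta))^(2 / p)
  by <- by * (1 - params@taper * (bx / a + 1) / 2)  # caudal thinning
  if (params@roughAmplitude > 0 && params@roughNWaves > 0L) {
    m <- params@roughNWaves
    d <- withSeed(seed, {
      phases <- runif(m, 0, 2 * pi)
      # 15-50 cycles around the boundary: nodular irregularity at a scale
      # (roughly 15-45 px along the rear arc) well below the smoothing
      # window used by the roughness score
      freq <- 12L + 3L * seq_len(m)
      rowSums(vapply(seq_len(m),
                     function(k) sin(freq[k] * theta + phases[k]),
                     numeric(nVertices))) / sqrt(m / 2)
    })
    # smooth half-cosine window over the rear half keeps the cut continuous
    wnd <- ifelse(sin(theta) > 0, sin(theta)^2, 0)
    r <- sqrt(bx^2 + by^2)
    scale <- 1 + params@roughAmplitude * d * wnd / r
    bx <- bx * scale; by <- by * scale
  }
  phi <- params@rotationDeg * pi / 180
  x <- params@center[1] + bx * cos(phi) - by * sin(phi)
  y <- params@center[2] + bx * sin(phi) + by * cos(phi)
  if (min(x) < 1 || min(y) < 1 || max(x) > W - 2 || max(y) > H - 2)
    stop("shape exceeds the canvas after rotation", call. = FALSE)
  contour <- orientCCW(cbind(x = x, y = y))
  list(contour = contour, mask = rasterizeContour(contour, c(H, W)))
}

#' Render a B-mode-like image from a phantom mask
#'
#' Paints the liver region in mid gray with multiplicative Rayleigh-like
#' speckle (lightly correlated by a 3 x 3 mean filter), a darker speckled
#' background, and a bright 2-px capsule line along the region boundary —
#' the texture cues a classical segmenter relies on. Deterministic given
#' `seed`.
#'
#' @param mask logical matrix, non-empty with a visible boundary.
#' @param seed integer seed.
#' @param fgLevel,bgLevel mean foreground/background intensities (0--255).
#' @return A numeric matrix in `[0, 255]`.
#' @export
#' @examples
#' m <- outer(1:64, 1:64, function(y, x) (x - 32)^2 + (y - 32)^2 < 20^2)
#' img <- renderBmode(m, seed = 2)
#' mean(img[m]) > mean(img[!m])
renderBmode <- function(mask, seed = 1L, fgLevel = 140, bgLevel = 38) {
  mask <- assertBinaryMask(mask)
  if (!any(mask)) stop("cannot render an empty mask", call. = FALSE)
  if (all(mask))
    stop("mask covers the whole canvas: no capsule line can be drawn",
         call. = FALSE)
  edge <- maskBoundary(mask)
  if (!any(edge))
    stop("mask has no boundary inside the canvas; cannot draw a capsule line",
         call. = FALSE)
  H <- nrow(mask); W <- ncol(mask)
  img <- withSeed(seed, {
    u <- matrix(runif(H * W), H, W)
    speckle <- sqrt(-2 * log(u)) / sqrt(pi / 2)  # Rayleigh, mean 1
    base <- ifelse(mask, fgLevel, bgLevel) * speckle
    kern <- matrix(1 / 9, 3, 3)
    sm <- EBImage::imageData(EBImage::filter2(base, kern))
    cap <- edge | EBImage::imageData(EBImage::dilate(
      edge + 0, EBImage::makeBrush(3, "box"))) > 0 & mask
    sm[cap] <- 235 * (0.9 + 0.1 * runif(sum(cap)))
    sm
  })
  pmin(pmax(img, 0), 255)
}

# Foreground pixels 4-adjacent to background or the canvas border.
maskBoundary <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  up <- rbind(FALSE, mask[-H, , drop = FALSE])
  dn <- rbind(mask[-1, , drop = FALSE], FALSE)
  lf <- cbind(FALSE, mask[, -W, drop = FALSE])
  rt <- cbind(mask[, -1, drop = FALSE], FALSE)
  mask & !(up & dn & lf & rt)
}

#' Generate a synthetic fibrosis-staged cohort
#'
#' Draws one [CohortRecord-class] per subject under the study conditions of
#' a [CohortConfig-class]: stage counts are fixed, the truth semi-minor
#' axis is a baseline Gaussian draw multiplied by
#' `1 - minorShrinkPerStage * stage`, and the rough-surface label is
#' Bernoulli with the stage's prevalence. Fully reproducible: the cohort is
#' a pure function of the config, and truth parameters do not depend on the
#' `render` level.
#'
#' @param config a [CohortConfig-class].
#' @param render `"full"` (masks and B-mode images), `"mask"` (masks only)
#'   or `"none"` (truth parameters only, for large sampling studies).
#' @return A list of [CohortRecord-class] objects.
#' @export
#' @examples
#' cohort <- generateCohort(cohortConfig(seed = 3), render = "none")
#' table(vapply(cohort, stage, integer(1)))
generateCohort <- function(config = cohortConfig(),
                           render = c("full", "mask", "none")) {
  stopifnot(is(config, "CohortConfig"))
  validObject(config)
  render <- match.arg(render)
  n <- sum(config@countsPerStage)
  stages <- rep(0:4, times = config@countsPerStage)
  H <- config@canvas[1]; W <- config@canvas[2]
  scale <- min(H, W) / 512  # axes stated for a 512-px canvas
  draws <- withSeed(config@seed, {
    list(
      major = rnorm(n, config@baselineMajor, config@axisSD) * scale,
      minorBase = rnorm(n, config@baselineMinor, config@axisSD) * scale,
      rough = runif(n) < config@roughProbPerStage[stages + 1L],
      amp = runif(n, 4, 8) * scale,
      nWaves = sample(7:12, n, replace = TRUE),
      rot = runif(n, -8, 8),
      cx = (W - 1) / 2 + runif(n, -8, 8) * scale,
      cy = (H - 1) / 2 + runif(n, -8, 8) * scale,
      childSeeds = sample.int(2147483646L, 2L * n))
  })
  minor <- draws$minorBase * (1 - config@minorShrinkPerStage * stages)
  # keep draws inside validity bounds (tail guards, not the main effect)
  minor <- pmax(minor, 12 * scale)
  major <- pmax(draws$major, minor)
  empty <- matrix(numeric(0), 0, 0)
  lapply(seq_len(n), function(i) {
    pars <- shapeParams(
      semiMajor = major[i], semiMinor = minor[i],
      roughAmplitude = if (draws$rough[i]) min(draws$amp[i], minor[i] / 2 - 1e-6) else 0,
      roughNWaves = if (draws$rough[i]) draws$nWaves[i] else 0L,
      rotationDeg = draws$rot[i], center = c(draws$cx[i], draws$cy[i]))
    mask <- empty > 0; image <- empty
    if (render != "none") {
      sh <- makeLiverShape(pars, canvas = c(H, W),
                           seed = draws$childSeeds[2L * i - 1L])
      mask <- sh$mask
      if (render == "full")
        image <- renderBmode(mask, seed = draws$childSeeds[2L * i])
    }
    new("CohortRecord", subjectId = sprintf("subj%03d", i),
        stage = as.integer(stages[i]),
        roughLabel = if (draws$rough[i]) "rough" else "smooth",
        mask = mask, image = image, truth = pars)
  })
}

#' Manifest table of a synthetic cohort
#'
#' @param cohort a list of [CohortRecord-class] objects.
#' @return A `data.frame` with one row per subject: id, stage, roughness
#'   label and the ground-truth shape parameters.
#' @export
cohortManifest <- function(cohort) {
  do.call(rbind, lapply(cohort, function(rec) {
    tr <- truthParams(rec)
    data.frame(subjectId = rec@subjectId, stage = stage(rec),
               roughLabel = roughLabel(rec), semiMajor = tr@semiMajor,
               semiMinor = tr@semiMinor, bluntness = tr@bluntness,
               taper = tr@taper, roughAmplitude = tr@roughAmplitude,
               roughNWaves = tr@roughNWaves, rotationDeg = tr@rotationDeg,
               centerX = tr@center[1], centerY = tr@center[2],
               stringsAsFactors = FALSE)
  }))
}
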