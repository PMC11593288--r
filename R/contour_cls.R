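# Surface-roughness stage: split a lobe contour into front and rear sides,
# render contour-only images, augment them, and score/evaluate the
# smooth-vs-rough call. The classifier shipped here is a deterministic
# residual-roughness statistic with a calibrated threshold; any external
# scorer returning a numeric score per polyline can be plugged into the
# same evaluation path.

#' Split a closed contour into front and rear side polylines
#'
#' The contour is cut at its leftmost and rightmost vertices (ties broken
#' by the topmost, i.e. smallest y). In the y-down image frame the deeper
#' polyline — the one with greater mean y — is the rear (dorsal) surface,
#' where fibrotic irregularity appears; the other is the front. Both
#' polylines share the two cut vertices and are oriented left to right.
#'
#' @param contour `n x 2` matrix of (x, y) vertices, simple and closed.
#' @return A list with `front` and `rear`, each an open polyline matrix
#'   carrying a `side` attribute.
#' @export
#' @examples
#' th <- seq(0, 2 * pi, length.out = 73)[-73]
#' sides <- splitFrontRear(cbind(50 + 40 * cos(th), 30 + 15 * sin(th)))
#' mean(sides$rear[, 2]) > mean(sides$front[, 2])
splitFrontRear <- function(contour) {
  contour <- assertContour(contour)
  x <- contour[, 1]; y <- contour[, 2]
  if (diff(range(x)) + 1 < 3)
    stop("no lateral extent: contour narrower than 3 px", call. = FALSE)
  iL <- which(x == min(x)); iL <- iL[which.min(y[iL])]
  iR <- which(x == max(x)); iR <- iR[which.min(y[iR])]
  n <- nrow(contour)
  walk <- function(from, to) {
    if (from <= to) from:to else c(from:n, 1:to)
  }
  pathA <- contour[walk(iL, iR), , drop = FALSE]
  pathB <- contour[walk(iR, iL), , drop = FALSE]
  pathB <- pathB[rev(seq_len(nrow(pathB))), , drop = FALSE]  # left to right
  if (mean(pathA[, 2]) >= mean(pathB[, 2])) {
    rear <- pathA; front <- pathB
  } else {
    rear <- pathB; front <- pathA
  }
  attr(front, "side") <- "front"; attr(rear, "side") <- "rear"
  list(front = front, rear = rear)
}

#' Render front and rear polylines as a contour-only image
#'
#' Draws both polylines as 1-px white (255) curves on a black canvas — the
#' input representation for surface-roughness classification, stripped of
#' everything unrelated to the boundary.
#'
#' @param front,rear polyline matrices (see [splitFrontRear()]).
#' @param dims length-2 integer (H, W).
#' @return A numeric `H x W` matrix with values 0/255.
#' @export
renderContourImage <- function(front, rear, dims) {
  H <- as.integer(dims[1]); W <- as.integer(dims[2])
  canvas <- matrix(0, H, W)
  for (pl in list(front, rear)) {
    if (!is.matrix(pl) || ncol(pl) != 2L)
      stop("polylines must be n x 2 matrices", call. = FALSE)
    if (min(pl) < 0 || max(pl[, 1]) > W - 1 || max(pl[, 2]) > H - 1)
      stop("polyline vertex outside the canvas", call. = FALSE)
    px <- drawPolyline(pl)
    canvas[cbind(px[, 2] + 1L, px[, 1] + 1L)] <- 255
  }
  canvas
}

# Pixels along a polyline: segments sampled at half-pixel steps, rounded.
drawPolyline <- function(pl) {
  n <- nrow(pl)
  if (n == 1L) return(cbind(round(pl[, 1]), round(pl[, 2])))
  seg <- lapply(seq_len(n - 1L), function(i) {
    d <- sqrt(sum((pl[i + 1L, ] - pl[i, ])^2))
    t <- seq(0, 1, length.out = max(2L, ceiling(d * 2) + 1L))
    cbind(pl[i, 1] + t * (pl[i + 1L, 1] - pl[i, 1]),
          pl[i, 2] + t * (pl[i + 1L, 2] - pl[i, 2]))
  })
  pts <- do.call(rbind, seg)
  unique(cbind(round(pts[, 1]), round(pts[, 2])))
}

#' Bounded affine parameters for contour-image augmentation
#'
#' Rotations are limited to +/-10 degrees and translations to 10% of each
#' canvas dimension — augmentation that perturbs pose without changing
#' scale, as appropriate for shape cues.
#'
#' @param rotationDeg degrees in `[-10, 10]`.
#' @param shiftXFrac,shiftYFrac fractions in `[-0.10, 0.10]`.
#' @return A list of class `affineParams`.
#' @export
affineParams <- function(rotationDeg = 0, shiftXFrac = 0, shiftYFrac = 0) {
  stopifnotScalarNumber(rotationDeg, "rotationDeg", -10, 10)
  stopifnotScalarNumber(shiftXFrac, "shiftXFrac", -0.10, 0.10)
  stopifnotScalarNumber(shiftYFrac, "shiftYFrac", -0.10, 0.10)
  structure(list(rotationDeg = rotationDeg, shiftXFrac = shiftXFrac,
                 shiftYFrac = shiftYFrac), class = "affineParams")
}

#' Affine augmentation of an image (rotation + translation, no scaling)
#'
#' Rotates about the image center by `rotationDeg` and translates by
#' `(shiftXFrac * W, shiftYFrac * H)` pixels, with nearest-neighbor
#' resampling; content leaving the canvas is dropped and entering pixels
#' are black. Dimensions never change. When `params` is `NULL` the
#' parameters are drawn uniformly within their bounds from `seed`.
#'
#' @param image numeric matrix.
#' @param params an [affineParams()] list, or `NULL` to randomize.
#' @param seed integer seed used when `params` is `NULL`.
#' @return The transformed image, same dimensions.
#' @export
#' @examples
#' img <- matrix(0, 50, 50); img[20:30, 20:30] <- 255
#' identical(affineAugment(img, affineParams(0, 0, 0)), img)
affineAugment <- function(image, params = NULL, seed = 1L) {
  assertGrayImage(image)
  if (is.null(params)) {
    params <- withSeed(seed, affineParams(runif(1, -10, 10),
                                          runif(1, -0.10, 0.10),
                                          runif(1, -0.10, 0.10)))
  }
  if (!inherits(params, "affineParams"))
    params <- do.call(affineParams, as.list(params))  # re-validates bounds
  H <- nrow(image); W <- ncol(image)
  tx <- params$shiftXFrac * W; ty <- params$shiftYFrac * H
  phi <- params$rotationDeg * pi / 180
  cx <- (W - 1) / 2; cy <- (H - 1) / 2
  gx <- matrix(rep(0:(W - 1), each = H), H, W)
  gy <- matrix(rep(0:(H - 1), W), H, W)
  rx <- gx - cx - tx; ry <- gy - cy - ty
  sx <- round(cos(phi) * rx + sin(phi) * ry + cx)
  sy <- round(-sin(phi) * rx + cos(phi) * ry + cy)
  out <- matrix(0, H, W)
  ok <- sx >= 0 & sx < W & sy >= 0 & sy < H
  out[ok] <- image[cbind(sy[ok] + 1L, sx[ok] + 1L)]
  out
}

#' Focal loss for a predicted true-class probability
#'
#' `FL(p_t) = -(1 - p_t)^gamma * log(p_t)` with the natural logarithm:
#' cross-entropy down-weighted for well-classified examples, which keeps
#' rare rough-surface cases from being drowned out by the smooth majority.
#' `gamma = 0` recovers plain cross-entropy.
#'
#' @param pT probability of the true class, in `(0, 1]` (vectorized).
#' @param gamma focusing exponent, >= 0 (default 2).
#' @return Nonnegative loss value(s).
#' @export
#' @examples
#' focalLoss(0.5, 2)  # 0.25 * log(2)
focalLoss <- function(pT, gamma = 2) {
  stopifnotScalarNumber(gamma, "gamma", 0, Inf)
  if (!is.numeric(pT) || any(!is.finite(pT)) || any(pT <= 0) || any(pT > 1))
    stop("pT must lie in (0, 1]", call. = FALSE)
  -(1 - pT)^gamma * log(pT)
}

#' Residual roughness score of a side polyline
#'
#' The polyline is resampled to unit arc-length spacing and smoothed with a
#' moving average of `smoothWindow` px; the score is the root-mean-square
#' deviation of the resampled curve from its smoothed version (a
#' point-to-point residual, which for wiggles much shorter than the window
#' approximates the perpendicular deviation). Half a window at each end is
#' excluded, where the truncated average tracks the curve too closely. A
#' straight segment scores 0; a sinusoid of amplitude A and wavelength well
#' below the window scores close to A / sqrt(2).
#'
#' @param polyline `n x 2` matrix (see [splitFrontRear()]).
#' @param smoothWindow moving-average window, arc-length px (default 31).
#' @param threshold optional calibrated threshold; when given, a
#'   smooth/rough call is made (`rough` iff score >= threshold).
#' @return A list of class `roughnessScore` with `rmsResidual`, `call`
#'   (`NA` without a threshold) and `threshold`.
#' @seealso [calibrateRoughnessThreshold()]
#' @export
#' @examples
#' x <- seq(0, 200, by = 1)
#' roughnessScore(cbind(x, 3 * sin(x)), smoothWindow = 31)$rmsResidual
roughnessScore <- function(polyline, smoothWindow = 31, threshold = NULL) {
  if (!is.matrix(polyline) || ncol(polyline) != 2L || nrow(polyline) < 2L)
    stop("polyline must be an n x 2 matrix", call. = FALSE)
  stopifnotScalarNumber(smoothWindow, "smoothWindow", 3, Inf)
  seg <- sqrt(rowSums(diff(polyline)^2))
  arc <- c(0, cumsum(seg))
  if (arc[length(arc)] < 3 * smoothWindow)
    stop("polyline too short: need arc length >= 3 * smoothWindow",
         call. = FALSE)
  t <- seq(0, arc[length(arc)], by = 1)
  xr <- approx(arc, polyline[, 1], t)$y
  yr <- approx(arc, polyline[, 2], t)$y
  k <- as.integer(smoothWindow); if (k %% 2L == 0L) k <- k + 1L
  xs <- runningMean(xr, k); ys <- runningMean(yr, k)
  resid <- sqrt((xr - xs)^2 + (yr - ys)^2)
  half <- k %/% 2L
  core <- resid[(half + 1L):(length(resid) - half)]
  rms <- sqrt(mean(core^2))
  call <- NA_character_
  if (!is.null(threshold)) call <- if (rms >= threshold) "rough" else "smooth"
  structure(list(rmsResidual = rms, call = call,
                 threshold = if (is.null(threshold)) NA_real_ else threshold),
            class = "roughnessScore")
}

# Truncated-window running mean via cumulative sums.
runningMean <- function(v, k) {
  half <- k %/% 2L
  n <- length(v)
  cs <- cumsum(c(0, v))
  lo <- pmax(0L, seq_len(n) - 1L - half)
  hi <- pmin(n, seq_len(n) + half)
  (cs[hi + 1L] - cs[lo + 1L]) / (hi - lo)
}

#' @export
print.roughnessScore <- function(x, ...) {
  cat(sprintf("roughness rms residual: %.3f px%s\n", x$rmsResidual,
              if (!is.na(x$call)) sprintf(" -> %s (threshold %.3f)",
                                          x$call, x$threshold) else ""))
  invisible(x)
}

#' Calibrate the smooth/rough threshold on a labeled set
#'
#' Chooses the score threshold maximizing balanced accuracy
#' (mean of smooth- and rough-class accuracy), scanning midpoints between
#' consecutive sorted scores. Ties resolve to the smallest threshold.
#'
#' @param scores numeric roughness scores.
#' @param labels matching `"smooth"`/`"rough"` labels.
#' @return The calibrated threshold (numeric scalar).
#' @export
calibrateRoughnessThreshold <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  labels <- as.character(labels)
  if (!all(c("smooth", "rough") %in% labels))
    stop("calibration needs both smooth and rough examples", call. = FALSE)
  s <- sort(unique(scores))
  cand <- c(s[1] - 1e-6, (head(s, -1) + tail(s, -1)) / 2, s[length(s)] + 1e-6)
  bal <- vapply(cand, function(th) {
    calls <- ifelse(scores >= th, "rough", "smooth")
    mean(c(mean(calls[labels == "smooth"] == "smooth"),
           mean(calls[labels == "rough"] == "rough")))
  }, numeric(1))
  cand[which.max(bal)]
}

#' Per-class and overall accuracy of smooth/rough calls
#'
#' @param calls,labels equal-length vectors with values `"smooth"`/`"rough"`;
#'   `labels` must contain both classes.
#' @return A list with `smoothAccPct`, `roughAccPct`, `overallAccPct`
#'   (percentages), and the class counts `nSmooth`, `nRough`.
#' @export
#' @examples
#' evaluateClassifier(rep("smooth", 32),
#'                    rep(c("smooth", "rough"), c(23, 9)))
evaluateClassifier <- function(calls, labels) {
  if (length(calls) != length(labels))
    stop("calls and labels must have equal length", call. = FALSE)
  calls <- as.character(calls); labels <- as.character(labels)
  if (!all(calls %in% c("smooth", "rough")) ||
      !all(labels %in% c("smooth", "rough")))
    stop("calls and labels must be 'smooth' or 'rough'", call. = FALSE)
  if (!all(c("smooth", "rough") %in% labels))
    stop("labels must contain both classes", call. = FALSE)
  sm <- labels == "smooth"
  list(smoothAccPct = 100 * mean(calls[sm] == "smooth"),
       roughAccPct = 100 * mean(calls[!sm] == "rough"),
       overallAccPct = 100 * mean(calls == labels),
       nSmooth = sum(sm), nRough = sum(!sm))
}
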