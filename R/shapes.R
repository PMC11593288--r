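# Particle-analysis shape descriptors. All quantities are in pixels and
# follow the traced pixel-center polygon convention of traceContour():
# Area by the shoelace formula on that polygon, Perimeter as its arc length
# (axial steps 1, diagonal steps sqrt(2)). This convention determines the
# scale of Circularity and is stated here because it differs by O(boundary)
# from pixel-count area.

#' Polygon area and perimeter of a contour
#'
#' @param contour `n x 2` matrix of (x, y) vertices.
#' @param checkSimple if `TRUE`, reject self-intersecting polygons
#'   (O(n^2) test; default `TRUE`, disabled internally on traced contours
#'   which are simple by construction).
#' @return A list with elements `area` and `perimeter`.
#' @export
#' @examples
#' sq <- cbind(c(0, 9, 9, 0), c(0, 0, 9, 9))
#' areaPerimeter(sq)  # area 81, perimeter 36
areaPerimeter <- function(contour, checkSimple = TRUE) {
  contour <- assertContour(contour)
  if (checkSimple && !isSimplePolygon(contour))
    stop("polygon is self-intersecting", call. = FALSE)
  n <- nrow(contour)
  j <- c(2:n, 1L)
  seglen <- sqrt(rowSums((contour[j, , drop = FALSE] - contour)^2))
  list(area = abs(shoelace(contour)), perimeter = sum(seglen))
}

# Segment-intersection test over all non-adjacent edge pairs (vectorized).
isSimplePolygon <- function(contour) {
  n <- nrow(contour)
  if (n > 4000L) return(TRUE)  # traced contours are simple by construction
  x <- contour[, 1]; y <- contour[, 2]
  j <- c(2:n, 1L)
  idx <- which(outer(seq_len(n), seq_len(n), function(a, b)
    b > a + 1L & !(a == 1L & b == n)), arr.ind = TRUE)
  if (!nrow(idx)) return(TRUE)
  a <- idx[, 1]; b <- idx[, 2]
  d <- function(px, py, qx, qy, rx, ry) (qx - px) * (ry - py) - (qy - py) * (rx - px)
  d1 <- d(x[a], y[a], x[j[a]], y[j[a]], x[b], y[b])
  d2 <- d(x[a], y[a], x[j[a]], y[j[a]], x[j[b]], y[j[b]])
  d3 <- d(x[b], y[b], x[j[b]], y[j[b]], x[a], y[a])
  d4 <- d(x[b], y[b], x[j[b]], y[j[b]], x[j[a]], y[j[a]])
  !any(d1 * d2 < 0 & d3 * d4 < 0)
}

#' Convex hull and solidity of a contour
#'
#' Solidity is the polygon area divided by the area of its convex hull;
#' irregular (rough) outlines score lower.
#'
#' @inheritParams areaPerimeter
#' @return A list with `hull` (an `h x 2` matrix of hull vertices, CCW in
#'   the y-down frame) and `solidity`.
#' @export
#' @examples
#' convexHullSolidity(cbind(c(0, 9, 9, 0), c(0, 0, 9, 9)))$solidity
convexHullSolidity <- function(contour) {
  contour <- assertContour(contour)
  hi <- grDevices::chull(contour[, 1], contour[, 2])
  if (length(hi) < 3L)
    stop("contour vertices are collinear: convex hull is degenerate",
         call. = FALSE)
  hull <- orientCCW(contour[hi, , drop = FALSE])
  hullArea <- abs(shoelace(hull))
  list(hull = hull, solidity = abs(shoelace(contour)) / hullArea)
}

#' Feret (caliper) diameters of a contour
#'
#' `feret` is the longest distance between any two boundary points;
#' `minFeret` the minimum caliper width, found by rotating calipers over
#' convex-hull edge directions. `feretAngle` is measured counter-clockwise
#' from the +x axis in the standard (y-up) orientation, in `[0, 180)`;
#' image-frame (y-down) angles are negated to match. When several point
#' pairs attain the maximum the pair with the smallest angle, then the
#' smallest x of its first endpoint, is reported; the first endpoint of the
#' pair is the one with smaller x (ties: smaller y), and its coordinates
#' are returned as `feretX`, `feretY`.
#'
#' @param contour matrix of (x, y) vertices (>= 2 points).
#' @return A list with `feret`, `feretAngle`, `feretX`, `feretY`, `minFeret`.
#' @export
#' @examples
#' feretDiameters(cbind(c(0, 4, 4, 0), c(0, 0, 4, 4)))
feretDiameters <- function(contour) {
  if (!is.matrix(contour) || ncol(contour) != 2L || nrow(contour) < 2L)
    stop("contour must be an n x 2 matrix with n >= 2", call. = FALSE)
  pts <- unique(contour)
  if (nrow(pts) < 2L)
    stop("degenerate contour: a single distinct point has no diameter",
         call. = FALSE)
  hi <- grDevices::chull(pts[, 1], pts[, 2])
  hull <- pts[hi, , drop = FALSE]
  collinear <- nrow(hull) < 3L || abs(shoelace(hull)) < 1e-12
  if (collinear) hull <- pts

  # max Feret: exhaustive over hull vertices
  dx <- outer(hull[, 1], hull[, 1], "-")
  dy <- outer(hull[, 2], hull[, 2], "-")
  dd <- sqrt(dx^2 + dy^2)
  feret <- max(dd)
  cand <- which(dd >= feret - 1e-12 * max(1, feret), arr.ind = TRUE)
  cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
  best <- NULL
  for (k in seq_len(nrow(cand))) {
    p <- hull[cand[k, 1], ]; q <- hull[cand[k, 2], ]
    if (p[1] > q[1] || (p[1] == q[1] && p[2] > q[2])) { tmp <- p; p <- q; q <- tmp }
    ang <- (atan2(-(q[2] - p[2]), q[1] - p[1]) * 180 / pi) %% 180
    key <- c(ang, p[1])
    if (is.null(best) || key[1] < best$key[1] - 1e-9 ||
        (abs(key[1] - best$key[1]) <= 1e-9 && key[2] < best$key[2]))
      best <- list(p = p, ang = ang, key = key)
  }

  if (collinear) {
    minFeret <- 0
  } else {
    h <- nrow(hull)
    j <- c(2:h, 1L)
    ex <- hull[j, 1] - hull[, 1]; ey <- hull[j, 2] - hull[, 2]
    el <- sqrt(ex^2 + ey^2)
    nx <- -ey / el; ny <- ex / el  # unit normals of hull edges
    proj <- outer(nx, hull[, 1]) + outer(ny, hull[, 2])
    widths <- apply(proj, 1, function(v) diff(range(v)))
    minFeret <- min(widths)
  }
  list(feret = feret, feretAngle = best$ang, feretX = unname(best$p[1]),
       feretY = unname(best$p[2]), minFeret = minFeret)
}

#' Equal-area moment ellipse of a particle
#'
#' Orientation and axis ratio come from the second-order central moments of
#' the foreground pixel centers; the axes are then rescaled so the fitted
#' ellipse's area equals the particle's pixel count (the equal-area
#' convention of classical particle analysis). `angle` is in degrees,
#' `[0, 180)`, measured y-up.
#'
#' @param mask logical matrix with a single particle.
#' @param minSize minimum pixel count (default 8).
#' @return A list with `major`, `minor` (full axis lengths, px) and `angle`.
#' @export
#' @examples
#' m <- outer(0:60, 0:60, function(y, x) ((x - 30) / 30)^2 + ((y - 30) / 15)^2 <= 1)
#' fitEllipse(m)
fitEllipse <- function(mask, minSize = 8) {
  mask <- assertBinaryMask(mask)
  idx <- which(mask, arr.ind = TRUE)
  n <- nrow(idx)
  if (n < minSize)
    stop(sprintf("particle has %d px, need at least %d", n, as.integer(minSize)),
         call. = FALSE)
  x <- idx[, 2] - 1; y <- idx[, 1] - 1
  mxx <- mean(x^2) - mean(x)^2
  myy <- mean(y^2) - mean(y)^2
  mxy <- mean(x * y) - mean(x) * mean(y)
  if (mxx + myy < 1e-12)
    stop("zero-variance region: cannot fit an ellipse", call. = FALSE)
  e <- eigen(matrix(c(mxx, mxy, mxy, myy), 2), symmetric = TRUE)
  if (e$values[2] < 1e-9 * e$values[1])
    stop("degenerate (one-dimensional) region: cannot fit an ellipse",
         call. = FALSE)
  ratio <- sqrt(e$values[1] / e$values[2])
  major <- 2 * sqrt(n * ratio / pi)
  minor <- 2 * sqrt(n / (pi * ratio))
  v <- e$vectors[, 1]
  angle <- (atan2(-v[2], v[1]) * 180 / pi) %% 180
  list(major = major, minor = minor, angle = angle)
}

#' Axis-aligned bounding box of a particle
#'
#' @param mask logical matrix, non-empty.
#' @return A list with `width` and `height` in pixel counts.
#' @export
#' @examples
#' m <- matrix(FALSE, 15, 25); m[3:12, 2:21] <- TRUE
#' boundingBox(m)  # width 20, height 10
boundingBox <- function(mask) {
  mask <- assertBinaryMask(mask)
  idx <- which(mask, arr.ind = TRUE)
  if (!nrow(idx)) stop("empty mask has no bounding box", call. = FALSE)
  list(width = diff(range(idx[, 2])) + 1L,
       height = diff(range(idx[, 1])) + 1L)
}

#' The 16 shape descriptors used for analysis
#'
#' Names of the morphometric features computed by [shapeFeatures()], in
#' report order.
#' @export
featureNames <- function() {
  c("Angle", "AspectRatio", "Area", "Circularity", "Feret", "FeretAngle",
    "FeretX", "FeretY", "Height", "Major", "MinFeret", "Minor", "Perimeter",
    "Roundness", "Solidity", "Width")
}

#' Compute the full morphometric feature record of a particle
#'
#' Assembles the 16-descriptor record from a single solid particle mask:
#' polygon `Area` and `Perimeter` (traced pixel-center contour),
#' `Circularity = min(1, 4 pi Area / Perimeter^2)` (capped at 1 because
#' raster perimeters can underestimate), `Solidity`, the Feret caliper
#' family, the equal-area moment ellipse (`Major`, `Minor`, `Angle`),
#' `AspectRatio = Major / Minor`, `Roundness = 4 Area / (pi Major^2)`, and
#' the bounding-box `Width`/`Height`.
#'
#' @param mask logical matrix holding one solid particle (see
#'   [largestParticle()]).
#' @return A one-row `data.frame` with the columns of [featureNames()].
#' @export
#' @examples
#' m <- outer(0:80, 0:80, function(y, x) (x - 40)^2 + (y - 40)^2 <= 30^2)
#' shapeFeatures(m)$Circularity
shapeFeatures <- function(mask) {
  mask <- assertBinaryMask(mask)
  contour <- traceContour(mask)
  ap <- areaPerimeter(contour, checkSimple = FALSE)
  sol <- convexHullSolidity(contour)
  fer <- feretDiameters(contour)
  ell <- fitEllipse(mask)
  bb <- boundingBox(mask)
  data.frame(
    Angle = ell$angle,
    AspectRatio = ell$major / ell$minor,
    Area = ap$area,
    Circularity = min(1, 4 * pi * ap$area / ap$perimeter^2),
    Feret = fer$feret,
    FeretAngle = fer$feretAngle,
    FeretX = fer$feretX,
    FeretY = fer$feretY,
    Height = as.numeric(bb$height),
    Major = ell$major,
    MinFeret = fer$minFeret,
    Minor = ell$minor,
    Perimeter = ap$perimeter,
    Roundness = 4 * ap$area / (pi * ell$major^2),
    Solidity = sol$solidity,
    Width = as.numeric(bb$width))
}

#' Feature table for a list of masks or cohort records
#'
#' @param masks a list of logical matrices, or of [CohortRecord-class]
#'   objects (their masks are used).
#' @param ids optional character subject ids.
#' @return A `data.frame` with a `subjectId` column followed by the 16
#'   features.
#' @export
shapeFeatureTable <- function(masks, ids = NULL) {
  rows <- lapply(seq_along(masks), function(i) {
    m <- masks[[i]]
    if (is(m, "CohortRecord")) m <- subjectMask(m)
    shapeFeatures(m)
  })
  out <- do.call(rbind, rows)
  if (is.null(ids)) {
    ids <- vapply(seq_along(masks), function(i) {
      m <- masks[[i]]
      if (is(m, "CohortRecord")) m@subjectId else sprintf("subj%03d", i)
    }, character(1))
  }
  cbind(data.frame(subjectId = ids, stringsAsFactors = FALSE), out)
}
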