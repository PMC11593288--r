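# Raster mask utilities: binarization, particle selection, contour tracing,
# square padding, and PNG I/O. Images are matrices [y + 1, x + 1] with
# intensities in [0, 255]; masks are logical matrices of the same layout.

#' Threshold a grayscale image into a binary mask
#'
#' A pixel is foreground iff its intensity is greater than or equal to the
#' threshold.
#'
#' @param image numeric matrix with intensities in `[0, 255]`.
#' @param threshold scalar in `[0, 255]`.
#' @return A logical matrix of the same dimensions.
#' @export
#' @examples
#' binarize(matrix(c(10, 200), 1), 128)
binarize <- function(image, threshold) {
  assertGrayImage(image)
  stopifnotScalarNumber(threshold, "threshold", 0, 255)
  image >= threshold
}

# 8-connected labeling: EBImage::bwlabel is 4-connected, so labels touching
# diagonally are merged with a small union-find pass.
label8 <- function(mask) {
  lab <- EBImage::imageData(EBImage::bwlabel(mask + 0))
  lab <- matrix(as.integer(lab), nrow(mask), ncol(mask))
  nl <- max(lab)
  if (nl <= 1L) return(lab)
  nr <- nrow(lab); nc <- ncol(lab)
  a1 <- lab[-nr, -nc]; b1 <- lab[-1, -1]     # \ diagonal
  a2 <- lab[-nr, -1];  b2 <- lab[-1, -nc]    # / diagonal
  keep1 <- a1 > 0L & b1 > 0L & a1 != b1
  keep2 <- a2 > 0L & b2 > 0L & a2 != b2
  pairs <- unique(rbind(cbind(a1[keep1], b1[keep1]),
                        cbind(a2[keep2], b2[keep2])))
  if (!nrow(pairs)) return(lab)
  parent <- seq_len(nl)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  for (k in seq_len(nrow(pairs))) {
    ra <- find(pairs[k, 1]); rb <- find(pairs[k, 2])
    if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
  }
  root <- vapply(seq_len(nl), find, integer(1))
  lab[lab > 0L] <- root[lab[lab > 0L]]
  lab
}

#' Keep the largest particle of a mask and fill its holes
#'
#' Retains the largest 8-connected foreground component, fills interior
#' holes (4-connected background), and rejects particles smaller than
#' `minSize` pixels.
#'
#' @param mask logical matrix.
#' @param minSize minimum particle size in pixels (default 64).
#' @return A logical matrix containing a single solid particle.
#' @export
#' @examples
#' m <- matrix(FALSE, 20, 20); m[4:16, 4:16] <- TRUE; m[8:10, 8:10] <- FALSE
#' sum(largestParticle(m)) - sum(m)  # holes filled
largestParticle <- function(mask, minSize = 64) {
  mask <- assertBinaryMask(mask)
  if (!any(mask)) stop("no particle: mask is empty", call. = FALSE)
  lab <- label8(mask)
  sizes <- tabulate(lab[lab > 0L])
  best <- which.max(sizes)
  if (sizes[best] < minSize)
    stop(sprintf("largest particle (%d px) is below minSize (%d px)",
                 sizes[best], as.integer(minSize)), call. = FALSE)
  out <- lab == best
  filled <- EBImage::imageData(EBImage::fillHull(out + 0)) > 0
  matrix(filled, nrow(mask), ncol(mask))
}

#' Trace the boundary of a single filled particle
#'
#' Returns the closed polygon through the particle's boundary pixel centers
#' (Moore-neighbor boundary order), in 0-based (x, y) coordinates, oriented
#' counter-clockwise in the y-down frame. Consecutive vertices step by 1
#' (axial) or sqrt(2) (diagonal), which fixes the perimeter convention used
#' throughout the package.
#'
#' @param mask logical matrix containing one filled particle
#'   (see [largestParticle()]).
#' @return An `n x 2` matrix with columns `x`, `y`.
#' @export
#' @examples
#' m <- matrix(FALSE, 14, 14); m[3:12, 3:12] <- TRUE
#' nrow(traceContour(m))  # 36 boundary pixels of a 10 x 10 square
traceContour <- function(mask) {
  mask <- assertBinaryMask(mask)
  if (!any(mask)) stop("no particle: mask is empty", call. = FALSE)
  lab <- label8(mask)
  if (max(lab) != 1L)
    stop("mask must contain exactly one particle; run largestParticle() first",
         call. = FALSE)
  oc <- EBImage::ocontour(mask + 0)[[1]]
  # EBImage indexes the first matrix dimension as x; with our [y, x] layout
  # its output columns are (y, x), both already 0-based.
  contour <- cbind(x = oc[, 2], y = oc[, 1])
  dup <- c(FALSE, rowSums(abs(diff(contour))) == 0)
  contour <- contour[!dup, , drop = FALSE]
  n <- nrow(contour)
  if (n >= 2 && all(contour[n, ] == contour[1, ]))
    contour <- contour[-n, , drop = FALSE]
  if (nrow(contour) < 3 || abs(shoelace(contour)) < .Machine$double.eps)
    stop("degenerate particle: no 2-D extent to trace", call. = FALSE)
  orientCCW(contour)
}

#' Rasterize a closed polygon into a mask
#'
#' Fills all pixels whose centers fall inside the polygon (even-odd scanline
#' rule). Vertices that sit exactly on pixel centers are included, so
#' rasterizing a traced contour reproduces the particle's boundary pixels.
#'
#' @param contour `n x 2` matrix, 0-based (x, y) vertices.
#' @param dims length-2 integer, (H, W) of the output mask.
#' @return A logical `H x W` matrix.
#' @export
#' @examples
#' tri <- cbind(c(2, 12, 7), c(2, 2, 12))
#' sum(rasterizeContour(tri, c(16, 16)))
rasterizeContour <- function(contour, dims) {
  contour <- assertContour(contour)
  H <- as.integer(dims[1]); W <- as.integer(dims[2])
  xs <- contour[, 1]; ys <- contour[, 2]
  n <- length(xs)
  j <- c(2:n, 1L)
  x2 <- xs[j]; y2 <- ys[j]
  keep <- ys != y2
  ex1 <- xs[keep]; ey1 <- ys[keep]; ex2 <- x2[keep]; ey2 <- y2[keep]
  lo <- pmin(ey1, ey2); hi <- pmax(ey1, ey2)
  mask <- matrix(FALSE, H, W)
  yr <- max(0L, floor(min(ys))):min(H - 1L, ceiling(max(ys)))
  for (y in yr) {
    sel <- lo <= y & y < hi  # half-open rule handles vertex crossings
    if (!any(sel)) next
    cx <- sort(ex1[sel] + (y - ey1[sel]) * (ex2[sel] - ex1[sel]) /
                 (ey2[sel] - ey1[sel]))
    for (k in seq(1L, length(cx) - 1L, by = 2L)) {
      a <- max(0L, ceiling(cx[k] - 1e-9))
      b <- min(W - 1L, floor(cx[k + 1] + 1e-9))
      if (b >= a) mask[y + 1L, (a:b) + 1L] <- TRUE
    }
  }
  # integer vertices are boundary pixel centers; mark them explicitly
  iv <- abs(xs - round(xs)) < 1e-9 & abs(ys - round(ys)) < 1e-9
  if (any(iv)) {
    vx <- round(xs[iv]); vy <- round(ys[iv])
    ok <- vx >= 0 & vx < W & vy >= 0 & vy < H
    mask[cbind(vy[ok] + 1L, vx[ok] + 1L)] <- TRUE
  }
  mask
}

#' Pad an image to a square with black pixels
#'
#' Extends the shorter dimension with zero-valued pixels so the output is
#' `max(H, W)` square. The original content stays anchored at the top-left,
#' keeping any annotation coordinates valid.
#'
#' @param image numeric matrix.
#' @return A square numeric matrix.
#' @export
#' @examples
#' dim(padToSquare(matrix(0, 600, 800)))
padToSquare <- function(image) {
  assertGrayImage(image)
  side <- max(dim(image))
  if (all(dim(image) == side)) return(image)
  out <- matrix(0, side, side)
  out[seq_len(nrow(image)), seq_len(ncol(image))] <- image
  out
}

#' Read and write 8-bit grayscale PNG images and masks
#'
#' Images are stored as 8-bit grayscale PNG; masks use 0/255 encoding.
#' Multi-channel files are averaged to gray on read.
#'
#' @param path file path.
#' @param image numeric matrix in `[0, 255]`.
#' @param mask logical matrix.
#' @param threshold intensity above which a pixel read from disk counts as
#'   foreground (default 128).
#' @return `readGrayPNG` a numeric matrix in `[0, 255]`; `readMaskPNG` a
#'   logical matrix; the writers return the path invisibly.
#' @name png-io
NULL

#' @rdname png-io
#' @export
readGrayPNG <- function(path) {
  px <- png::readPNG(path)
  if (length(dim(px)) == 3L) px <- apply(px[, , 1:min(3, dim(px)[3]), drop = FALSE], c(1, 2), mean)
  px * 255
}

#' @rdname png-io
#' @export
writeGrayPNG <- function(image, path) {
  assertGrayImage(image)
  png::writePNG(image / 255, path)
  invisible(path)
}

#' @rdname png-io
#' @export
readMaskPNG <- function(path, threshold = 128) {
  readGrayPNG(path) >= threshold
}

#' @rdname png-io
#' @export
writeMaskPNG <- function(mask, path) {
  mask <- assertBinaryMask(mask)
  png::writePNG(mask * 1, path)
  invisible(path)
}
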