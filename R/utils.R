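# Internal helpers shared across modules.

# Run `expr` with the RNG seeded to `seed`, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

#' Derive a reproducible child seed from a master seed and a stage label
#'
#' The pipeline fans a single master seed out to its stages so any stage can
#' be rerun in isolation with the same stream. The child seed is a stable
#' 31-bit hash of the label mixed with the master seed.
#'
#' @param seed integer master seed.
#' @param label character stage label.
#' @return A single integer in `[1, 2^31 - 2]`.
#' @export
#' @examples
#' childSeed(1, "cohort")
childSeed <- function(seed, label) {
  stopifnot(length(seed) == 1L, is.finite(seed), is.character(label))
  h <- 0
  for (ch in utf8ToInt(label)) h <- (h * 131 + ch) %% 2147483647
  as.integer((h + as.numeric(seed) * 7919) %% 2147483646 + 1)
}

stopifnotScalarNumber <- function(x, name, lo = -Inf, hi = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lo || x > hi)
    stop(sprintf("'%s' must be a single finite number in [%s, %s]",
                 name, format(lo), format(hi)), call. = FALSE)
  invisible(x)
}

assertGrayImage <- function(image, name = "image") {
  if (!is.matrix(image) || !is.numeric(image) || any(!is.finite(image)))
    stop(sprintf("'%s' must be a finite numeric matrix", name), call. = FALSE)
  if (min(image) < 0 || max(image) > 255)
    stop(sprintf("'%s' intensities must lie in [0, 255]", name),
         call. = FALSE)
  invisible(image)
}

assertBinaryMask <- function(mask, name = "mask") {
  if (is.matrix(mask) && is.numeric(mask) && all(mask %in% c(0, 1)))
    mask <- mask > 0
  if (!is.matrix(mask) || !is.logical(mask))
    stop(sprintf("'%s' must be a logical matrix", name), call. = FALSE)
  mask
}

assertContour <- function(contour, minVertices = 3L) {
  if (!is.matrix(contour) || ncol(contour) != 2L || !is.numeric(contour))
    stop("a contour must be an n x 2 numeric matrix (columns x, y)",
         call. = FALSE)
  if (nrow(contour) < minVertices)
    stop(sprintf("contour needs at least %d vertices", minVertices),
         call. = FALSE)
  dup <- rowSums(abs(contour - contour[c(nrow(contour), 1:(nrow(contour) - 1L)), , drop = FALSE])) == 0
  dup[1] <- FALSE
  if (any(dup))
    stop("contour has identical consecutive vertices", call. = FALSE)
  contour
}

# Raw shoelace sum (signed, y treated as a plain coordinate). Negative for a
# polygon that is counter-clockwise in the y-down image frame.
shoelace <- function(contour) {
  x <- contour[, 1]; y <- contour[, 2]
  n <- length(x)
  j <- c(2:n, 1L)
  sum(x * y[j] - x[j] * y) / 2
}

# Enforce the package contour orientation (CCW in the y-down frame).
orientCCW <- function(contour) {
  if (shoelace(contour) > 0) contour[rev(seq_len(nrow(contour))), , drop = FALSE]
  else contour
}
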