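# Segmentation-quality metrics and a classical baseline segmenter, so the
# pipeline runs end to end on synthetic B-mode-like images. Metrics are
# computed from raw pixel counts, exactly as their formulas state, never
# batch-averaged.

#' Overlap metrics between a predicted and a reference mask
#'
#' Pixelwise true positives, false positives and false negatives, and the
#' derived overlap scores: `IoU = TP / (TP + FP + FN)`,
#' `F = TP / (TP + (FP + FN) / 2)` and `DiceLoss = 1 - F`. The identity
#' `F = 2 IoU / (1 + IoU)` holds exactly.
#'
#' @param pred,truth logical matrices of identical dimensions; `truth`
#'   must be non-empty.
#' @return A list with `TP`, `FP`, `FN`, `IoU`, `F`, `DiceLoss`.
#' @export
#' @examples
#' a <- matrix(c(TRUE, TRUE, FALSE, FALSE), 2)
#' segMetrics(a, a)$IoU
segMetrics <- function(pred, truth) {
  pred <- assertBinaryMask(pred, "pred")
  truth <- assertBinaryMask(truth, "truth")
  if (!identical(dim(pred), dim(truth)))
    stop("pred and truth dimensions differ", call. = FALSE)
  if (!any(truth)) stop("reference mask is empty", call. = FALSE)
  tp <- sum(pred & truth)
  fp <- sum(pred & !truth)
  fn <- sum(!pred & truth)
  f <- tp / (tp + (fp + fn) / 2)
  list(TP = tp, FP = fp, FN = fn,
       IoU = tp / (tp + fp + fn), F = f, DiceLoss = 1 - f)
}

#' Classical baseline liver segmenter
#'
#' A deterministic stand-in for a learned segmenter on speckle images: a
#' global Otsu threshold is estimated on a box-smoothed copy (stabilizing
#' it against speckle) and applied to the raw image, followed by
#' morphological closing and largest-filled-particle selection, which
#' absorb the pixelwise speckle misclassifications. Noise-free two-level
#' images are recovered exactly. Accepts any grayscale image in `[0, 255]`.
#'
#' @param image numeric matrix.
#' @param blur side of the pre-smoothing box kernel (odd, default 5).
#' @param brushSize diameter of the closing disc (default 5).
#' @param minSize passed to [largestParticle()].
#' @return A logical mask.
#' @export
#' @examples
#' img <- matrix(20, 64, 64); img[20:44, 16:48] <- 200
#' sum(baselineSegmenter(img) != (img >= 128))
baselineSegmenter <- function(image, blur = 5, brushSize = 5, minSize = 64) {
  assertGrayImage(image)
  kern <- matrix(1 / blur^2, blur, blur)
  sm <- EBImage::imageData(EBImage::filter2(image / 255, kern))
  rng <- range(sm)
  if (diff(rng) < 1e-6)
    stop("no foreground found: image is uniform", call. = FALSE)
  th <- EBImage::otsu(EBImage::Image(pmin(pmax(sm, 0), 1)))
  bin <- image / 255 >= th
  if (!any(bin) || all(bin))
    stop("no foreground found: thresholding produced a trivial mask",
         call. = FALSE)
  closed <- EBImage::imageData(EBImage::closing(
    bin + 0, EBImage::makeBrush(brushSize, "disc"))) > 0
  largestParticle(matrix(closed, nrow(image), ncol(image)), minSize = minSize)
}

#' Per-image and aggregate segmentation report
#'
#' @param preds,truths lists of masks of equal length.
#' @param ids optional subject ids.
#' @return A list with `perImage` (data.frame of counts and metrics per
#'   image) and `aggregate` (means of IoU, F and Dice loss, plus pooled
#'   metrics recomputed from summed counts).
#' @export
segReport <- function(preds, truths, ids = NULL) {
  stopifnot(length(preds) == length(truths))
  if (is.null(ids)) ids <- sprintf("subj%03d", seq_along(preds))
  rows <- lapply(seq_along(preds), function(i) {
    m <- segMetrics(preds[[i]], truths[[i]])
    data.frame(subjectId = ids[i], TP = m$TP, FP = m$FP, FN = m$FN,
               IoU = m$IoU, F = m$F, DiceLoss = m$DiceLoss,
               stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, rows)
  tp <- sum(per$TP); fp <- sum(per$FP); fn <- sum(per$FN)
  fPooled <- tp / (tp + (fp + fn) / 2)
  list(perImage = per,
       aggregate = list(meanIoU = mean(per$IoU), meanF = mean(per$F),
                        meanDiceLoss = mean(per$DiceLoss),
                        pooledIoU = tp / (tp + fp + fn), pooledF = fPooled,
                        pooledDiceLoss = 1 - fPooled))
}
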