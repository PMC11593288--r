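#' Ground-truth shape parameters for a synthetic liver-lobe phantom
#'
#' A superellipse-based description of a sagittal left-lobe-like cross
#' section: semi-axes, a bluntness exponent controlling how sharp the margin
#' is, an optional rear-surface roughness perturbation, rotation, and
#' placement on the canvas.
#'
#' @slot semiMajor,semiMinor semi-axes in pixels; `semiMajor >= semiMinor > 0`.
#' @slot bluntness superellipse exponent `p` in `|x/a|^p + |y/b|^p = 1`;
#'   `p = 2` is an ellipse, larger values give blunter margins. Must be >= 1.
#' @slot taper linear thinning of the minor axis toward the caudal (x > 0)
#'   end, mimicking the wedge profile of the lobe; fraction in `[0, 0.9]`.
#' @slot roughAmplitude amplitude (px, >= 0) of the rear-surface
#'   perturbation; must stay below `semiMinor / 2`.
#' @slot roughNWaves integer number of random-phase sinusoids (>= 0).
#' @slot rotationDeg rotation of the phantom, degrees.
#' @slot center length-2 numeric, (x, y) center in 0-based pixel coordinates.
#' @seealso [makeLiverShape()], [generateCohort()]
#' @export
setClass("ShapeParams",
  representation(semiMajor = "numeric", semiMinor = "numeric",
                 bluntness = "numeric", taper = "numeric",
                 roughAmplitude = "numeric", roughNWaves = "integer",
                 rotationDeg = "numeric", center = "numeric"),
  prototype(bluntness = 2.5, taper = 0.10, roughAmplitude = 0,
            roughNWaves = 0L, rotationDeg = 0, center = c(255.5, 255.5)))

setValidity("ShapeParams", function(object) {
  msg <- character()
  if (length(object@semiMajor) != 1L || length(object@semiMinor) != 1L ||
      !is.finite(object@semiMajor) || !is.finite(object@semiMinor))
    msg <- c(msg, "semiMajor and semiMinor must be single finite numbers")
  else {
    if (object@semiMinor <= 0) msg <- c(msg, "semiMinor must be > 0")
    if (object@semiMajor < object@semiMinor)
      msg <- c(msg, "semiMajor must be >= semiMinor")
    if (object@roughAmplitude >= object@semiMinor / 2)
      msg <- c(msg, "roughAmplitude must be < semiMinor / 2")
  }
  if (object@bluntness < 1) msg <- c(msg, "bluntness must be >= 1")
  if (object@taper < 0 || object@taper > 0.9)
    msg <- c(msg, "taper must lie in [0, 0.9]")
  if (object@roughAmplitude < 0) msg <- c(msg, "roughAmplitude must be >= 0")
  if (object@roughNWaves < 0L) msg <- c(msg, "roughNWaves must be >= 0")
  if (length(object@center) != 2L || any(!is.finite(object@center)))
    msg <- c(msg, "center must be a length-2 finite numeric")
  if (length(msg)) msg else TRUE
})

#' @describeIn ShapeParams-class Constructor.
#' @param semiMajor,semiMinor,bluntness,taper,roughAmplitude,roughNWaves,rotationDeg,center
#'   see the slot descriptions.
#' @return A validated `ShapeParams` object.
#' @export
#' @examples
#' shapeParams(150, 60)
shapeParams <- function(semiMajor, semiMinor, bluntness = 2.5, taper = 0.10,
                        roughAmplitude = 0, roughNWaves = 0L,
                        rotationDeg = 0, center = c(255.5, 255.5)) {
  new("ShapeParams", semiMajor = as.numeric(semiMajor),
      semiMinor = as.numeric(semiMinor), bluntness = as.numeric(bluntness),
      taper = as.numeric(taper), roughAmplitude = as.numeric(roughAmplitude),
      roughNWaves = as.integer(roughNWaves),
      rotationDeg = as.numeric(rotationDeg), center = as.numeric(center))
}

#' Configuration of a synthetic fibrosis-staged cohort
#'
#' Describes the study conditions a generated cohort emulates: how many
#' subjects carry each fibrosis stage F0--F4, how strongly the lobe's minor
#' axis thins per stage step, how the prevalence of a rough rear surface
#' rises with stage, and the canvas size. Defaults reproduce a 43-subject
#' biopsy cohort with stage counts 5/11/13/11/3 and an overall rough
#' prevalence near 27%.
#'
#' @slot countsPerStage integer vector of length 5, subjects at F0..F4.
#' @slot minorShrinkPerStage fraction of the baseline semi-minor axis lost
#'   per stage step; the truth semi-minor is
#'   `baseline * (1 - minorShrinkPerStage * stage)`.
#' @slot roughProbPerStage probability of a rough rear surface at each stage.
#' @slot canvas length-2 integer, (height, width) of the raster canvas, px.
#' @slot baselineMajor,baselineMinor mean baseline semi-axes, px.
#' @slot axisSD standard deviation of both baseline semi-axes, px.
#' @slot seed integer RNG seed; the cohort is a pure function of the config.
#' @seealso [generateCohort()]
#' @export
setClass("CohortConfig",
  representation(countsPerStage = "integer", minorShrinkPerStage = "numeric",
                 roughProbPerStage = "numeric", canvas = "integer",
                 baselineMajor = "numeric", baselineMinor = "numeric",
                 axisSD = "numeric", seed = "integer"),
  prototype(countsPerStage = c(5L, 11L, 13L, 11L, 3L),
            minorShrinkPerStage = 0.10,
            roughProbPerStage = c(0.05, 0.15, 0.25, 0.40, 0.60),
            canvas = c(512L, 512L), baselineMajor = 155, baselineMinor = 90,
            axisSD = 9, seed = 1L))

setValidity("CohortConfig", function(object) {
  msg <- character()
  if (length(object@countsPerStage) != 5L || any(object@countsPerStage < 0L))
    msg <- c(msg, "countsPerStage must be 5 nonnegative integers")
  if (sum(object@countsPerStage) < 1L)
    msg <- c(msg, "cohort must contain at least one subject")
  if (length(object@roughProbPerStage) != 5L ||
      any(object@roughProbPerStage < 0 | object@roughProbPerStage > 1))
    msg <- c(msg, "roughProbPerStage must be 5 probabilities in [0, 1]")
  if (object@minorShrinkPerStage < 0 || object@minorShrinkPerStage > 0.24)
    msg <- c(msg, "minorShrinkPerStage must lie in [0, 0.24]")
  if (length(object@canvas) != 2L || any(object@canvas < 32L))
    msg <- c(msg, "canvas must be (H, W) with both >= 32")
  if (object@baselineMajor <= 0 || object@baselineMinor <= 0 ||
      object@axisSD < 0)
    msg <- c(msg, "baseline axes must be positive and axisSD >= 0")
  if (object@baselineMinor > object@baselineMajor)
    msg <- c(msg, "baselineMinor must not exceed baselineMajor")
  if (length(msg)) msg else TRUE
})

#' @describeIn CohortConfig-class Constructor.
#' @param countsPerStage,minorShrinkPerStage,roughProbPerStage,canvas,baselineMajor,baselineMinor,axisSD,seed
#'   see the slot descriptions.
#' @return A validated `CohortConfig` object.
#' @export
#' @examples
#' cohortConfig(seed = 7)
cohortConfig <- function(countsPerStage = c(5L, 11L, 13L, 11L, 3L),
                         minorShrinkPerStage = 0.10,
                         roughProbPerStage = c(0.05, 0.15, 0.25, 0.40, 0.60),
                         canvas = c(512L, 512L), baselineMajor = 155,
                         baselineMinor = 90, axisSD = 9, seed = 1L) {
  new("CohortConfig", countsPerStage = as.integer(countsPerStage),
      minorShrinkPerStage = as.numeric(minorShrinkPerStage),
      roughProbPerStage = as.numeric(roughProbPerStage),
      canvas = as.integer(canvas), baselineMajor = as.numeric(baselineMajor),
      baselineMinor = as.numeric(baselineMinor), axisSD = as.numeric(axisSD),
      seed = as.integer(seed))
}

#' One synthetic subject of a staged cohort
#'
#' Couples a subject's fibrosis stage and roughness label with its phantom
#' mask, B-mode-like image, and the ground-truth [ShapeParams-class] it was
#' generated from. Mask and image slots may be 0 x 0 matrices when the
#' cohort was generated without rendering.
#'
#' @slot subjectId character identifier.
#' @slot stage integer fibrosis stage in 0..4.
#' @slot roughLabel `"smooth"` or `"rough"`.
#' @slot mask logical matrix (may be empty).
#' @slot image numeric matrix in `[0, 255]` (may be empty).
#' @slot truth the generating [ShapeParams-class].
#' @seealso [generateCohort()], [cohortManifest()]
#' @export
setClass("CohortRecord",
  representation(subjectId = "character", stage = "integer",
                 roughLabel = "character", mask = "matrix",
                 image = "matrix", truth = "ShapeParams"))

setValidity("CohortRecord", function(object) {
  msg <- character()
  if (!object@stage %in% 0:4) msg <- c(msg, "stage must be in 0..4")
  if (!object@roughLabel %in% c("smooth", "rough"))
    msg <- c(msg, "roughLabel must be 'smooth' or 'rough'")
  if (length(object@mask) && length(object@image) &&
      !identical(dim(object@mask), dim(object@image)))
    msg <- c(msg, "mask and image dimensions must agree")
  if (length(msg)) msg else TRUE
})

#' @rdname CohortRecord-class
#' @param object,x a `CohortRecord`.
#' @export
setGeneric("stage", function(x) standardGeneric("stage"))
#' @rdname CohortRecord-class
#' @export
setGeneric("roughLabel", function(x) standardGeneric("roughLabel"))
#' @rdname CohortRecord-class
#' @export
setGeneric("subjectMask", function(x) standardGeneric("subjectMask"))
#' @rdname CohortRecord-class
#' @export
setGeneric("subjectImage", function(x) standardGeneric("subjectImage"))
#' @rdname CohortRecord-class
#' @export
setGeneric("truthParams", function(x) standardGeneric("truthParams"))

#' @rdname CohortRecord-class
#' @export
setMethod("stage", "CohortRecord", function(x) x@stage)
#' @rdname CohortRecord-class
#' @export
setMethod("roughLabel", "CohortRecord", function(x) x@roughLabel)
#' @rdname CohortRecord-class
#' @export
setMethod("subjectMask", "CohortRecord", function(x) x@mask)
#' @rdname CohortRecord-class
#' @export
setMethod("subjectImage", "CohortRecord", function(x) x@image)
#' @rdname CohortRecord-class
#' @export
setMethod("truthParams", "CohortRecord", function(x) x@truth)

setMethod("show", "ShapeParams", function(object) {
  cat(sprintf(
    "ShapeParams: a=%.1f b=%.1f px, bluntness=%.2f, taper=%.2f\n",
    object@semiMajor, object@semiMinor, object@bluntness, object@taper))
  cat(sprintf("  roughness: amplitude=%.1f px, %d waves; rotation=%.1f deg, center=(%.1f, %.1f)\n",
              object@roughAmplitude, object@roughNWaves, object@rotationDeg,
              object@center[1], object@center[2]))
  invisible(object)
})

setMethod("show", "CohortConfig", function(object) {
  cat("CohortConfig:", sum(object@countsPerStage), "subjects, stages F0..F4 =",
      paste(object@countsPerStage, collapse = "/"), "\n")
  cat(sprintf("  minor shrink/stage = %.2f; rough prob = %s\n",
              object@minorShrinkPerStage,
              paste(format(object@roughProbPerStage), collapse = ", ")))
  cat(sprintf("  canvas %d x %d px, baseline axes %.0f/%.0f (sd %.0f), seed %d\n",
              object@canvas[1], object@canvas[2], object@baselineMajor,
              object@baselineMinor, object@axisSD, object@seed))
  invisible(object)
})

setMethod("show", "CohortRecord", function(object) {
  cat(sprintf("CohortRecord %s: stage F%d, %s surface%s\n",
              object@subjectId, object@stage, object@roughLabel,
              if (length(object@mask)) sprintf(", %d x %d raster",
                                               nrow(object@mask),
                                               ncol(object@mask))
              else " (not rendered)"))
  invisible(object)
})
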