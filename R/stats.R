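# Statistical layer: Jonckheere-Terpstra trend tests across ordered
# fibrosis stages, ROC/AUROC diagnostics with Youden operating points, and
# confusion-matrix reconstruction from printed sensitivity/specificity
# pairs. Raw p-values are reported; no multiplicity correction is applied
# by default (an adjusted column can be added by the caller).

# Pairwise comparison matrix C[i, j] = 1(x_i < x_j) + 0.5 * 1(x_i == x_j).
pairwiseLess <- function(x) {
  outer(x, x, "<") + 0.5 * outer(x, x, "==")
}

jtStatistic <- function(C, g) {
  sum(C[outer(g, g, "<")])
}

# Null mean and tie-corrected variance of the JT statistic
# (Hollander & Wolfe form).
jtNullMoments <- function(x, g) {
  ni <- as.numeric(table(g))
  N <- length(x)
  tj <- as.numeric(table(x))
  mu <- (N^2 - sum(ni^2)) / 4
  A <- N * (N - 1) * (2 * N + 5) - sum(ni * (ni - 1) * (2 * ni + 5)) -
    sum(tj * (tj - 1) * (2 * tj + 5))
  B <- sum(ni * (ni - 1) * (ni - 2)) * sum(tj * (tj - 1) * (tj - 2))
  C2 <- sum(ni * (ni - 1)) * sum(tj * (tj - 1))
  v <- A / 72 + B / (36 * N * (N - 1) * (N - 2)) + C2 / (8 * N * (N - 1))
  list(mean = mu, var = v, tied = any(tj > 1))
}

# All distinct permutations of a multiset label vector (lexicographic).
multisetPermutations <- function(labels) {
  labels <- sort(labels)
  out <- list()
  recur <- function(prefix, remaining) {
    if (!length(remaining)) {
      out[[length(out) + 1L]] <<- prefix
      return(invisible())
    }
    for (v in unique(remaining)) {
      i <- match(v, remaining)
      recur(c(prefix, v), remaining[-i])
    }
  }
  recur(integer(0), labels)
  out
}

nArrangements <- function(g) {
  ni <- table(g)
  exp(lgamma(length(g) + 1) - sum(lgamma(ni + 1)))
}

#' Jonckheere-Terpstra test for an ordered trend across groups
#'
#' Tests whether values shift monotonically across ordered groups (here,
#' fibrosis stages). The statistic is the sum over ordered group pairs of
#' Mann-Whitney counts, ties counting 1/2. P-values come from full
#' permutation enumeration when the number of distinct label arrangements
#' is small, from seeded Monte-Carlo permutation on request, or from a
#' normal approximation with tie-corrected variance. Two-sided p-values
#' are twice the smaller tail, capped at 1.
#'
#' @param values numeric vector, or a list of per-group value vectors (in
#'   group order) with `groups` omitted.
#' @param groups ordered group membership (coerced to an ordered factor;
#'   numeric stages are ordered numerically).
#' @param alternative `"two.sided"` (default), `"increasing"` or
#'   `"decreasing"`.
#' @param method `"auto"` (exact when the arrangement count is at most
#'   `exactLimit`, else normal), `"exact"`, `"monte_carlo"`, or `"normal"`.
#' @param nperm Monte-Carlo permutation count (default 1e5).
#' @param seed seed for Monte-Carlo permutations.
#' @param exactLimit arrangement-count cap for full enumeration.
#' @return A list of class `jtTest`: `statistic`, `mean`, `variance`, `z`,
#'   `p.value`, `method`, `alternative`, `tieCorrected`.
#' @export
#' @examples
#' jonckheereTerpstra(list(c(1, 2), c(3, 4), c(5, 6)),
#'                    alternative = "increasing")$p.value  # 1/90
jonckheereTerpstra <- function(values, groups = NULL,
                               alternative = c("two.sided", "increasing",
                                               "decreasing"),
                               method = c("auto", "exact", "monte_carlo",
                                          "normal"),
                               nperm = 1e5, seed = 1L, exactLimit = 20000) {
  alternative <- match.arg(alternative)
  method <- match.arg(method)
  if (is.list(values)) {
    if (!is.null(groups))
      stop("give either a list of groups or values + groups, not both",
           call. = FALSE)
    groups <- rep(seq_along(values), lengths(values))
    values <- unlist(values, use.names = FALSE)
  }
  if (length(values) != length(groups))
    stop("values and groups must have equal length", call. = FALSE)
  g <- as.integer(factor(groups, levels = sort(unique(groups))))
  if (length(unique(g)) < 2L)
    stop("need at least 2 non-empty ordered groups", call. = FALSE)
  if (any(!is.finite(values))) stop("values must be finite", call. = FALSE)

  C <- pairwiseLess(values)
  jt <- jtStatistic(C, g)
  mom <- jtNullMoments(values, g)

  if (method == "auto")
    method <- if (nArrangements(g) <= exactLimit) "exact" else "normal"

  if (method == "exact") {
    nArr <- nArrangements(g)
    if (nArr > exactLimit)
      stop(sprintf("exact enumeration needs %.0f arrangements (limit %d); use monte_carlo or normal",
                   nArr, as.integer(exactLimit)), call. = FALSE)
    perms <- multisetPermutations(g)
    stats <- vapply(perms, function(p) jtStatistic(C, p), numeric(1))
    pUp <- mean(stats >= jt - 1e-9)
    pDn <- mean(stats <= jt + 1e-9)
    z <- (jt - mom$mean) / sqrt(mom$var)
    methodUsed <- "exact_permutation"
  } else if (method == "monte_carlo") {
    n <- length(values)
    mask <- outer(g, g, "<")
    stats <- withSeed(seed, vapply(seq_len(nperm), function(i) {
      ord <- sample.int(n)
      sum(C[ord, ord][mask])
    }, numeric(1)))
    pUp <- (1 + sum(stats >= jt - 1e-9)) / (nperm + 1)
    pDn <- (1 + sum(stats <= jt + 1e-9)) / (nperm + 1)
    z <- (jt - mom$mean) / sqrt(mom$var)
    methodUsed <- "monte_carlo_permutation"
  } else {
    z <- (jt - mom$mean) / sqrt(mom$var)
    pUp <- pnorm(z, lower.tail = FALSE)
    pDn <- pnorm(z)
    methodUsed <- "normal_approx"
  }

  p <- switch(alternative,
              increasing = pUp,
              decreasing = pDn,
              two.sided = min(1, 2 * min(pUp, pDn)))
  structure(list(statistic = jt, mean = mom$mean, variance = mom$var,
                 z = z, p.value = p, method = methodUsed,
                 alternative = alternative, tieCorrected = mom$tied),
            class = "jtTest")
}

#' @export
print.jtTest <- function(x, ...) {
  cat("Jonckheere-Terpstra trend test\n")
  cat(sprintf("  JT = %.1f (null mean %.1f, sd %.2f), z = %.3f\n",
              x$statistic, x$mean, sqrt(x$variance), x$z))
  cat(sprintf("  p = %.4g (%s, %s%s)\n", x$p.value, x$alternative, x$method,
              if (x$tieCorrected) ", tie-corrected" else ""))
  invisible(x)
}

#' ROC analysis with a Youden operating point
#'
#' AUROC is computed by pairwise concordance (ties count 1/2), the
#' probability that a positive case outranks a negative one. With
#' `orientation = "auto"` the feature direction is flipped when needed so
#' AUROC >= 0.5 (`low_positive` marks features where lower values indicate
#' disease, as left-lobe thickness does for advanced fibrosis). The cutoff
#' maximizes the Youden index J = sensitivity + specificity - 1; ties
#' resolve to the higher sensitivity, then the cutoff closest to the data
#' center.
#'
#' @param values numeric feature values.
#' @param labels logical (or 0/1) vector, `TRUE` = positive class.
#' @param orientation `"auto"`, `"high_positive"`, or `"low_positive"`.
#' @return A list of class `diagnosticResult`: `sensitivity`,
#'   `specificity`, `f1`, `auroc`, `cutoff`, `orientation`.
#' @export
#' @examples
#' rocAuc(c(1, 2, 3, 10, 11), c(FALSE, FALSE, FALSE, TRUE, TRUE))$auroc
rocAuc <- function(values, labels,
                   orientation = c("auto", "high_positive", "low_positive")) {
  orientation <- match.arg(orientation)
  if (is.numeric(labels)) labels <- labels > 0
  stopifnot(length(values) == length(labels), is.logical(labels))
  if (!any(labels) || all(labels))
    stop("both classes must be present in labels", call. = FALSE)
  if (any(!is.finite(values))) stop("values must be finite", call. = FALSE)

  aucOf <- function(v) {
    r <- rank(v)
    nPos <- sum(labels); nNeg <- sum(!labels)
    (sum(r[labels]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)
  }
  auc <- aucOf(values)
  if (orientation == "auto")
    orientation <- if (auc >= 0.5) "high_positive" else "low_positive"
  v <- if (orientation == "high_positive") values else -values
  auc <- aucOf(v)

  s <- sort(unique(v))
  cuts <- c(s[1] - 1, (head(s, -1) + tail(s, -1)) / 2, s[length(s)] + 1)
  nPos <- sum(labels); nNeg <- sum(!labels)
  sens <- vapply(cuts, function(ct) sum(v >= ct & labels) / nPos, numeric(1))
  spec <- vapply(cuts, function(ct) sum(v < ct & !labels) / nNeg, numeric(1))
  J <- sens + spec - 1
  best <- which(J >= max(J) - 1e-12)
  best <- best[order(-sens[best], abs(cuts[best] - stats::median(v)))][1]
  tp <- sens[best] * nPos; fp <- (1 - spec[best]) * nNeg
  fn <- nPos - tp
  cutoff <- cuts[best]
  if (orientation == "low_positive") cutoff <- -cutoff  # back to data scale
  structure(list(sensitivity = sens[best], specificity = spec[best],
                 f1 = 2 * tp / (2 * tp + fp + fn), auroc = auc,
                 cutoff = cutoff, orientation = orientation),
            class = "diagnosticResult")
}

#' @export
print.diagnosticResult <- function(x, ...) {
  cat(sprintf("AUROC %.3f (%s); at cutoff %.3g: sens %.3f, spec %.3f, F1 %.3f\n",
              x$auroc, x$orientation, x$cutoff, x$sensitivity,
              x$specificity, x$f1))
  invisible(x)
}

#' Rebuild a confusion matrix from printed sensitivity and specificity
#'
#' `TP = round(sensitivity * nPos)`, `TN = round(specificity * nNeg)`,
#' with `FN`/`FP` as complements. Warns when a printed rate is not
#' integer-consistent with the class sizes (rounding error above 0.01
#' counts).
#'
#' @param sensitivity,specificity rates in `[0, 1]`.
#' @param nPos,nNeg positive/negative class sizes (>= 1).
#' @return A list of class `confusionCounts`: `TP`, `FP`, `TN`, `FN`,
#'   `nPos`, `nNeg`.
#' @export
#' @examples
#' confusionFromRates(0.571, 0.862, 14, 29)
confusionFromRates <- function(sensitivity, specificity, nPos, nNeg) {
  stopifnotScalarNumber(sensitivity, "sensitivity", 0, 1)
  stopifnotScalarNumber(specificity, "specificity", 0, 1)
  stopifnotScalarNumber(nPos, "nPos", 1, Inf)
  stopifnotScalarNumber(nNeg, "nNeg", 1, Inf)
  tp <- round(sensitivity * nPos); tn <- round(specificity * nNeg)
  if (abs(sensitivity * nPos - tp) > 0.01)
    warning(sprintf("sensitivity %.3f is not integer-consistent with %d positives",
                    sensitivity, as.integer(nPos)))
  if (abs(specificity * nNeg - tn) > 0.01)
    warning(sprintf("specificity %.3f is not integer-consistent with %d negatives",
                    specificity, as.integer(nNeg)))
  structure(list(TP = as.integer(tp), FP = as.integer(nNeg - tn),
                 TN = as.integer(tn), FN = as.integer(nPos - tp),
                 nPos = as.integer(nPos), nNeg = as.integer(nNeg)),
            class = "confusionCounts")
}

#' @export
print.confusionCounts <- function(x, ...) {
  cat(sprintf("confusion: TP %d  FP %d  TN %d  FN %d (%d pos / %d neg)\n",
              x$TP, x$FP, x$TN, x$FN, x$nPos, x$nNeg))
  invisible(x)
}

#' F1 score from confusion counts
#'
#' `F1 = 2 TP / (2 TP + FP + FN)`; undefined (error) when all three are 0.
#'
#' @param counts a `confusionCounts` list (see [confusionFromRates()]) or
#'   any list with `TP`, `FP`, `FN`.
#' @return The F1 score in `[0, 1]`.
#' @export
#' @examples
#' f1FromConfusion(list(TP = 8, FP = 4, FN = 6))  # 0.615
f1FromConfusion <- function(counts) {
  tp <- counts$TP; fp <- counts$FP; fn <- counts$FN
  if (tp + fp + fn < 1) stop("undefined F1: TP, FP and FN are all zero",
                             call. = FALSE)
  2 * tp / (2 * tp + fp + fn)
}

#' Trend-test table of all shape features against fibrosis stage
#'
#' Runs one two-sided Jonckheere-Terpstra test per feature across
#' stage-ordered groups and returns one row per feature in report order
#' ([featureNames()]). All 16 descriptors are tested, including Roundness
#' (which, under the equal-area ellipse fit, is exactly the reciprocal of
#' AspectRatio and therefore shares its two-sided p-value).
#'
#' @param features data.frame containing the [featureNames()] columns.
#' @param stages integer vector of fibrosis stages, one per row.
#' @param method,nperm,seed passed to [jonckheereTerpstra()].
#' @return A data.frame with columns `feature` and `p`.
#' @export
stageFeatureTable <- function(features, stages, method = "auto",
                              nperm = 1e5, seed = 1L) {
  if (nrow(features) != length(stages))
    stop("features and stages must have matching length", call. = FALSE)
  if (length(unique(stages)) < 2L)
    stop("need at least 2 stages present", call. = FALSE)
  miss <- setdiff(featureNames(), names(features))
  if (length(miss))
    stop("missing feature columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  p <- vapply(featureNames(), function(f) {
    jonckheereTerpstra(features[[f]], stages, alternative = "two.sided",
                       method = method, nperm = nperm, seed = seed)$p.value
  }, numeric(1))
  data.frame(feature = featureNames(), p = unname(p),
             stringsAsFactors = FALSE)
}

#' Diagnostic operating points for staging endpoints
#'
#' For each endpoint (positive class = stage >= cutpoint) and each feature,
#' computes AUROC and the Youden-index operating point with its
#' sensitivity, specificity and F1.
#'
#' @param features data.frame with the [featureNames()] columns.
#' @param stages integer stages per row.
#' @param endpoints integer cutpoints; `c(3, 4)` means ">= F3" and ">= F4".
#' @return A data.frame with one row per endpoint x feature.
#' @export
diagnosticTable <- function(features, stages, endpoints = c(3, 4)) {
  rows <- lapply(endpoints, function(ep) {
    pos <- stages >= ep
    if (!any(pos) || all(pos))
      stop(sprintf("endpoint >=F%d leaves a single class", ep), call. = FALSE)
    do.call(rbind, lapply(featureNames(), function(f) {
      d <- rocAuc(features[[f]], pos, orientation = "auto")
      data.frame(endpoint = sprintf(">=F%d", ep), feature = f,
                 sensitivity = d$sensitivity, specificity = d$specificity,
                 f1 = d$f1, auroc = d$auroc, cutoff = d$cutoff,
                 orientation = d$orientation, stringsAsFactors = FALSE)
    }))
  })
  do.call(rbind, rows)
}
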