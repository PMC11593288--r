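# Fixtures built in code and independent brute-force oracles used across
# the suite. Oracles deliberately avoid the package's own code paths.

discMask <- function(r, pad = 10) {
  n <- 2 * (r + pad)
  outer(0:n, 0:n, function(y, x) (x - r - pad)^2 + (y - r - pad)^2 <= r^2)
}

ellipseMask <- function(a, b, angleDeg = 0, pad = 10) {
  n <- 2 * (a + pad)
  c0 <- a + pad
  phi <- angleDeg * pi / 180
  outer(0:n, 0:n, function(y, x) {
    # rotate into the ellipse frame; image y-down, angle given y-up
    u <- (x - c0) * cos(phi) - (y - c0) * sin(phi)
    v <- (x - c0) * sin(phi) + (y - c0) * cos(phi)
    (u / a)^2 + (v / b)^2 <= 1
  })
}

# Exhaustive maximum pairwise distance over all points.
bruteFeret <- function(pts) {
  d <- as.matrix(dist(pts))
  max(d)
}

# Minimum projected width over an angle grid (0.01-degree steps), refined
# by a second fine grid around the coarse minimum: the width function has
# kinks, so a single coarse pass is only O(diameter * step) accurate.
bruteMinWidthGrid <- function(pts, stepDeg = 0.01) {
  widthAt <- function(angDeg) {
    ang <- angDeg * pi / 180
    P <- cbind(-sin(ang), cos(ang))  # caliper normal directions
    M <- P %*% t(pts)
    cols <- lapply(seq_len(ncol(M)), function(j) M[, j])
    do.call(pmax, cols) - do.call(pmin, cols)
  }
  coarse <- seq(0, 180 - stepDeg, by = stepDeg)
  w <- widthAt(coarse)
  # refine every near-minimal coarse angle: the global kink can sit in a
  # bin whose sampled value is slightly above the coarse minimum
  slack <- 4 * max(dist(pts)) * stepDeg * pi / 180
  cand <- coarse[w <= min(w) + slack]
  best <- min(w)
  for (a0 in cand)
    best <- min(best, widthAt(seq(a0 - stepDeg, a0 + stepDeg,
                                  length.out = 2001)))
  best
}

# AUROC by explicit positive-negative pair counting.
bruteAUC <- function(values, labels) {
  vp <- values[labels]; vn <- values[!labels]
  cmp <- outer(vp, vn, ">") + 0.5 * outer(vp, vn, "==")
  mean(cmp)
}

# Exact one-sided (increasing) Jonckheere-Terpstra p-value by full
# enumeration of group-label assignments, with the statistic computed by
# plain nested loops. Tiny inputs only.
jtEnumOracle <- function(groups) {
  x <- unlist(groups)
  g0 <- rep(seq_along(groups), lengths(groups))
  jtOf <- function(vals, g) {
    s <- 0
    for (i in seq_along(vals)) for (j in seq_along(vals)) {
      if (g[i] < g[j])
        s <- s + (vals[i] < vals[j]) + 0.5 * (vals[i] == vals[j])
    }
    s
  }
  obs <- jtOf(x, g0)
  perms <- list()
  recur <- function(prefix, remaining) {
    if (!length(remaining)) { perms[[length(perms) + 1L]] <<- prefix; return() }
    for (v in unique(remaining))
      recur(c(prefix, v), remaining[-match(v, remaining)])
  }
  recur(integer(0), sort(g0))
  stats <- vapply(perms, function(g) jtOf(x, g), numeric(1))
  list(p = mean(stats >= obs - 1e-9), nArrangements = length(stats))
}

# Star-shaped simple polygon around the origin (radial graph, so always
# non-self-intersecting).
randomStarPolygon <- function(n = 24, rMin = 0.4, rMax = 1) {
  th <- sort(runif(n, 0, 2 * pi))
  r <- runif(n, rMin, rMax)
  cbind(r * cos(th), r * sin(th))
}

# Small random blob mask: a filled disc with a few rectangular bites.
randomBlobMask <- function(seed, side = 60) {
  set.seed(seed)
  r <- side %/% 3
  m <- outer(0:side, 0:side, function(y, x)
    (x - side / 2)^2 + (y - side / 2)^2 <= r^2)
  for (k in 1:3) {
    x0 <- sample(0:(side - 8), 1); y0 <- sample(0:(side - 8), 1)
    m[(y0:(y0 + 5)) + 1, (x0:(x0 + 5)) + 1] <- FALSE
  }
  m
}
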