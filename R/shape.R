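# Shape descriptors (feature ids 1-9): boundary regularity measures from the
# resampled contour, the convex-hull difference area, and moment statistics of
# the angular Feret-extent ("variation") profile. Round/oval masses score low
# on all of them; irregular and spiculated masses score high.

#' Resample a contour at arc-length-uniform positions
#'
#' @param contour a [Contour-class] (or n x 2 point matrix).
#' @param nPoints number of resampled points.
#' @param closed treat the point sequence as a closed loop (default) or an
#'   open polyline (used by the boundary-geometry degenerate tests).
#' @return `nPoints` x 2 numeric matrix.
#' @export
resampleContour <- function(contour, nPoints = 128L, closed = TRUE) {
  p <- if (is(contour, "Contour")) contourPoints(contour) else as.matrix(contour)
  p <- matrix(as.numeric(p), nrow(p), 2L)
  if (closed) p <- rbind(p, p[1L, ])
  seg <- sqrt(rowSums(diff(p)^2))
  s <- c(0, cumsum(seg))
  total <- s[length(s)]
  if (total <= 0) return(matrix(rep(p[1L, ], nPoints), nPoints, 2L, byrow = TRUE))
  target <- if (closed) seq(0, total, length.out = nPoints + 1L)[-(nPoints + 1L)]
            else seq(0, total, length.out = nPoints)
  cbind(approx(s, p[, 1], xout = target, ties = "ordered")$y,
        approx(s, p[, 2], xout = target, ties = "ordered")$y)
}

#' Boundary regularity: continuity, curvature and irregularity
#'
#' The contour is resampled to `nPoints` arc-length-uniform points.
#' *Continuity* is the mean squared deviation of consecutive point spacings
#' from their mean (0 for a perfectly even boundary). *Curvature* is the mean
#' squared norm of the discrete second difference of the resampled boundary.
#' *Irregularity* counts the resampled points where the edge path changes
#' direction — where the turning angle between successive segments exceeds the
#' angular tolerance `tau` (default pi/12).
#'
#' @param contour a [Contour-class] or point matrix.
#' @param nPoints resampling density, `>= 8` (default 128).
#' @param tau turning-angle tolerance in radians (default `pi / 12`).
#' @param closed closed loop (default) or open polyline.
#' @return named numeric: `continuity`, `curvature`, `irregularity`.
#' @export
boundaryGeometry <- function(contour, nPoints = 128L, tau = pi / 12, closed = TRUE) {
  p <- if (is(contour, "Contour")) contourPoints(contour) else as.matrix(contour)
  if (nrow(p) < 3L) stop("degenerate contour: fewer than 3 points")
  if (nPoints < 8L) stop("nPoints must be >= 8")
  q <- resampleContour(p, nPoints, closed = closed)
  d1 <- if (closed) rbind(diff(q), q[1L, ] - q[nPoints, ]) else diff(q)
  spacing <- sqrt(rowSums(d1^2))
  continuity <- mean((spacing - mean(spacing))^2)
  d2 <- if (closed) rbind(diff(d1), d1[1L, ] - d1[nrow(d1), ]) else diff(d1)
  curvature <- mean(rowSums(d2^2))
  # turning angle between successive direction vectors
  a <- d1
  b <- if (closed) rbind(a[-1L, , drop = FALSE], a[1L, , drop = FALSE])
       else a[-1L, , drop = FALSE]
  if (!closed) a <- a[-nrow(a), , drop = FALSE]
  na <- sqrt(rowSums(a^2)); nb <- sqrt(rowSums(b^2))
  ok <- na > 0 & nb > 0
  cosang <- pmin(1, pmax(-1, rowSums(a * b)[ok] / (na[ok] * nb[ok])))
  irregularity <- sum(acos(cosang) > tau)
  c(continuity = continuity, curvature = curvature, irregularity = irregularity)
}

#' Difference area: convex hull pixel count minus mass pixel count
#'
#' The convex hull is the smallest convex polygon containing the mass; both
#' areas are actual pixel counts, so the difference is 0 exactly when the
#' mass region is convex and grows with concavities and spiculation.
#'
#' @param mask a [MassMask-class] or logical matrix.
#' @return non-negative pixel count.
#' @export
differenceArea <- function(mask) {
  m <- if (is(mask, "MassMask")) maskMatrix(mask) else mask
  idx <- which(m, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("empty mask")
  if (nrow(idx) <= 2L) return(0)
  h <- grDevices::chull(idx[, 2], idx[, 1])  # (x = col, y = row)
  hx <- idx[h, 2]; hy <- idx[h, 1]
  if (length(h) <= 2L) return(0)
  rows <- min(idx[, 1]):max(idx[, 1])
  cols <- min(idx[, 2]):max(idx[, 2])
  grid <- expand.grid(row = rows, col = cols)
  inside <- pracma::inpolygon(grid$col, grid$row, hx, hy, boundary = TRUE)
  sum(inside) - nrow(idx)
}

#' Angular extent (variation) profile of a mass
#'
#' For each direction `phi` on an even grid over `[0, pi)`, the extent is the
#' maximal projection distance between any two mass pixels along `phi` — the
#' Feret diameter at that angle. The maximum over pixel pairs is attained on
#' the boundary, so only contour points are projected.
#'
#' @param mask a [MassMask-class] or logical matrix with `>= 2` pixels (a
#'   single-pixel mask yields an all-zero profile with a warning).
#' @param nAngles angle-grid size (default 180, i.e. 1 degree steps).
#' @return list with `angles` (radians) and `extent` (pixels).
#' @export
variationProfile <- function(mask, nAngles = 180L) {
  m <- if (is(mask, "MassMask")) maskMatrix(mask) else mask
  angles <- seq(0, pi, length.out = nAngles + 1L)[seq_len(nAngles)]
  idx <- which(m, arr.ind = TRUE)
  if (nrow(idx) < 2L) {
    warning("single-pixel mask: variation profile is all zero")
    return(list(angles = angles, extent = numeric(nAngles)))
  }
  pts <- if (nrow(idx) > 8L) {
    mm <- if (is(mask, "MassMask")) mask else MassMask(m, idx[1L, ])
    contourPoints(extractContour(mm))
  } else idx
  pts <- matrix(as.numeric(pts), nrow(pts), 2L)
  # projection of (row, col) onto direction phi = (cos phi, sin phi) in (x, y)
  # with x = col, y = -row (orientation does not matter for extents)
  proj <- outer(pts[, 2], cos(angles)) + outer(-pts[, 1], sin(angles))
  extent <- apply(proj, 2, max) - apply(proj, 2, min)
  list(angles = angles, extent = extent)
}

#' Moment statistics of the variation profile
#'
#' Mean, population variance, skewness and non-excess kurtosis of the extent
#' sequence, plus the Shannon entropy (bits) of the sequence normalized to a
#' probability vector. A zero-variance profile reports skewness and kurtosis
#' 0 by convention.
#'
#' @param profile the list returned by [variationProfile()] (or a numeric
#'   extent vector).
#' @return named numeric: `mean`, `variance`, `skewness`, `kurtosis`,
#'   `entropy`.
#' @export
variationStats <- function(profile) {
  x <- if (is.list(profile)) profile$extent else profile
  if (length(x) == 0L) stop("empty profile")
  ms <- .momentStats(x)
  c(mean = unname(ms["mean"]), variance = unname(ms["variance"]),
    skewness = unname(ms["skewness"]), kurtosis = unname(ms["kurtosis"]),
    entropy = .shannonBits(x))
}

#' The nine BI-RADS shape features
#'
#' Assembles feature ids 1-9 in reporting order: continuity, curvature,
#' irregularity, difference area, and the mean / variance / skewness /
#' kurtosis / entropy of the variation profile.
#'
#' @param mask a [MassMask-class].
#' @param contour the matching [Contour-class]; traced from `mask` when
#'   missing.
#' @param nPoints,tau,nAngles tuning parameters forwarded to
#'   [boundaryGeometry()] and [variationProfile()].
#' @return named numeric vector of length 9.
#' @export
shapeFeatures <- function(mask, contour = NULL, nPoints = 128L, tau = pi / 12,
                          nAngles = 180L) {
  stopifnot(is(mask, "MassMask"))
  if (is.null(contour)) contour <- extractContour(mask)
  bg <- if (nrow(contourPoints(contour)) < 3L)
    c(continuity = 0, curvature = 0, irregularity = 0)
  else boundaryGeometry(contour, nPoints = nPoints, tau = tau)
  vs <- variationStats(suppressWarnings(variationProfile(mask, nAngles)))
  c(continuity = unname(bg["continuity"]),
    curvature = unname(bg["curvature"]),
    irregularity = unname(bg["irregularity"]),
    difference_area = differenceArea(mask),
    mean_variation = unname(vs["mean"]),
    variance_variation = unname(vs["variance"]),
    skewness_variation = unname(vs["skewness"]),
    kurtosis_variation = unname(vs["kurtosis"]),
    entropy_variation = unname(vs["entropy"]))
}
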