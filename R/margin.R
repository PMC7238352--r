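# Margin descriptors (feature ids 12-32). The mass margin is probed by 32
# intensity waveforms of length 64 sampled perpendicular to the boundary
# (radially from the mass centroid, one anchor every pi/16). Each waveform is
# turned into an edge-probability vector whose kurtosis, entropy and
# index-of-maximum localize and characterize the edge; seven summary
# statistics across the 32 waveforms give 3 x 7 = 21 features. Circumscribed
# margins yield peaked, low-entropy edge probabilities; obscured or
# spiculated margins yield flat, high-entropy ones.

.N_WAVEFORMS <- 32L
.WAVEFORM_LEN <- 64L

#' Sample perpendicular intensity waveforms along the mass margin
#'
#' 32 anchors are chosen as the contour points nearest to rays cast from the
#' mass centroid every `pi/16`. Along each centroid-to-anchor direction, 64
#' grey values are sampled by bilinear interpolation at 1-pixel spacing,
#' centered so that sample 33 (0-based index 32) coincides with the anchor:
#' 32 samples inside the mass, 32 at/outside. Samples falling outside the ROI
#' take the nearest-border value.
#'
#' @param roi an [ROIImage-class].
#' @param contour the mass [Contour-class]; must provide at least 32 points.
#' @param centroid optional `(row, col)` mass centroid; defaults to the mean
#'   of the contour points.
#' @return list with `profiles` (32 x 64 matrix), `centers` (32 x 2 anchor
#'   coordinates), `normals` (32 x 2 outward unit directions) and `thetaStep`
#'   (`pi/16`).
#' @export
sampleWaveforms <- function(roi, contour, centroid = NULL) {
  stopifnot(is(roi, "ROIImage"), is(contour, "Contour"))
  cp <- contourPoints(contour)
  pts <- matrix(as.numeric(cp), nrow(cp), 2L)
  if (nrow(pts) < .N_WAVEFORMS)
    stop("contour has fewer than 32 points; mass too small for margin waveforms")
  if (is.null(centroid)) centroid <- colMeans(pts)
  # angle of each contour point around the centroid, in (x, y) = (col, -row)
  ang <- atan2(-(pts[, 1] - centroid[1]), pts[, 2] - centroid[2]) %% (2 * pi)
  rays <- (seq_len(.N_WAVEFORMS) - 1L) * pi / 16
  px <- roiPixels(roi)
  profiles <- matrix(0, .N_WAVEFORMS, .WAVEFORM_LEN)
  centers <- matrix(0, .N_WAVEFORMS, 2L)
  normals <- matrix(0, .N_WAVEFORMS, 2L)
  offs <- seq_len(.WAVEFORM_LEN) - 33  # sample 33 sits on the anchor
  for (k in seq_len(.N_WAVEFORMS)) {
    dist <- abs((ang - rays[k] + pi) %% (2 * pi) - pi)
    i <- which.min(dist)
    anchor <- pts[i, ]
    dir <- anchor - centroid
    nrm <- sqrt(sum(dir^2))
    if (nrm == 0) dir <- c(-sin(rays[k]), cos(rays[k])) else dir <- dir / nrm
    centers[k, ] <- anchor
    normals[k, ] <- dir
    profiles[k, ] <- .bilinear(px, anchor[1] + offs * dir[1], anchor[2] + offs * dir[2])
  }
  list(profiles = profiles, centers = centers, normals = normals,
       thetaStep = pi / 16)
}

#' Edge-probability vector of a waveform
#'
#' The waveform is smoothed with a 3-sample moving average and the absolute
#' first difference is taken as edge evidence, padded (at the inner end) back
#' to length 64 and normalized to sum 1. The offset of the maximum is
#' reported relative to the margin: 0 on the margin, positive outside,
#' negative inside; ties are broken towards the margin (then outward).
#' A constant waveform carries no edge evidence and yields the uniform
#' vector with offset 0.
#'
#' @param profile numeric vector of length 64.
#' @return list with `ep` (length-64 probability vector) and `offsetIndex`.
#' @export
edgeProbability <- function(profile) {
  n <- length(profile)
  if (n != .WAVEFORM_LEN) stop("waveform must have length 64")
  idx <- seq_len(n)
  smoothed <- vapply(idx, function(i)
    mean(profile[max(1L, i - 1L):min(n, i + 1L)]), numeric(1))
  ep <- c(0, abs(diff(smoothed)))
  s <- sum(ep)
  if (s <= 0) {
    message("constant waveform: uniform edge probability assumed")
    ep <- rep(1 / n, n)
  } else {
    ep <- ep / s
  }
  offsets <- idx - 1L - 32L
  maxv <- max(ep)
  cand <- which(ep >= maxv * (1 - 1e-12))
  pick <- cand[order(abs(offsets[cand]), -sign(offsets[cand]))[1L]]
  list(ep = ep, offsetIndex = offsets[pick])
}

#' Kurtosis, entropy and index-of-maximum of an edge-probability vector
#'
#' Treats `ep` as a probability distribution over signed margin offsets:
#' kurtosis is the fourth central moment over the squared variance of that
#' positional distribution (0 by convention when the variance vanishes),
#' entropy is the Shannon entropy in bits, and the index of maximum is the
#' signed offset of the most probable edge location.
#'
#' @param ep the list returned by [edgeProbability()], or a probability
#'   vector (offsets then default to a zero-centered grid).
#' @param offsets optional signed positions matching `ep`.
#' @return named numeric: `kurtosis`, `entropy`, `indexOfMax`.
#' @export
waveformDescriptors <- function(ep, offsets = NULL) {
  if (is.list(ep)) {
    v <- ep$ep
    if (is.null(offsets)) offsets <- seq_along(v) - 1L - length(v) %/% 2L
    idxMax <- ep$offsetIndex
  } else {
    v <- ep
    if (is.null(offsets)) offsets <- seq_along(v) - 1L - length(v) %/% 2L
    cand <- which(v >= max(v) * (1 - 1e-12))
    idxMax <- offsets[cand[order(abs(offsets[cand]), -sign(offsets[cand]))[1L]]]
  }
  if (abs(sum(v) - 1) > 1e-9) stop("edge-probability vector must sum to 1")
  mu <- sum(v * offsets)
  m2 <- sum(v * (offsets - mu)^2)
  kurt <- if (m2 <= .Machine$double.eps) 0 else sum(v * (offsets - mu)^4) / m2^2
  c(kurtosis = kurt, entropy = .shannonBits(v), indexOfMax = as.numeric(idxMax))
}

#' The 21 BI-RADS margin features
#'
#' For each of the three waveform descriptors (kurtosis, entropy, index of
#' the maximum probability), the seven statistics mean / maximum / minimum /
#' standard deviation / variance / skewness / kurtosis are taken across the
#' 32 waveforms, descriptor-major (feature ids 12-32).
#'
#' @param roi an [ROIImage-class].
#' @param contour the mass [Contour-class].
#' @param centroid optional mass centroid forwarded to [sampleWaveforms()].
#' @return named numeric vector of length 21.
#' @export
marginFeatures <- function(roi, contour, centroid = NULL) {
  ws <- sampleWaveforms(roi, contour, centroid)
  desc <- t(apply(ws$profiles, 1, function(p)
    waveformDescriptors(suppressMessages(edgeProbability(p)))))
  out <- c(.sevenStats(desc[, "kurtosis"]),
           .sevenStats(desc[, "entropy"]),
           .sevenStats(desc[, "indexOfMax"]))
  names(out) <- as.vector(t(outer(c("kurtosis", "entropy", "index_of_max"),
                                  .statNames, paste, sep = "_")))
  out
}
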