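# Density/texture descriptors (feature ids 33-130): grey-level co-occurrence
# analysis. The 14 classical Haralick descriptors are computed per
# (distance, angle), averaged over the 8 angles at each distance, and the
# seven summary statistics over the distance axis give 14 x 7 = 98 features.

.GLCM_ANGLES <- c(0, pi / 8, pi / 4, 3 * pi / 8, pi / 2, 5 * pi / 8,
                  3 * pi / 4, 7 * pi / 8)

.HARALICK_NAMES <- c("asm", "contrast", "correlation", "variance", "idm",
                     "sum_average", "sum_variance", "sum_entropy", "entropy",
                     "difference_variance", "difference_entropy", "imc1",
                     "imc2", "mcc")

#' GLCM configuration
#'
#' The angle set is fixed to the eight directions `0, pi/8, ..., 7pi/8`;
#' distances default to all integers `1..floor(L/2)` for a square ROI of side
#' `L` (supplied by [textureFeatures()] when left `NULL`).
#'
#' @param distances integer distances in pixels, or `NULL` for the default.
#' @param levels grey quantization count (default 64).
#' @param symmetric accumulate both displacement directions (default TRUE).
#' @return a list of class `GLCMConfig`.
#' @export
glcmConfig <- function(distances = NULL, levels = 64L, symmetric = TRUE) {
  if (!is.null(distances)) {
    distances <- as.integer(distances)
    if (length(distances) == 0L || any(distances < 1L))
      stop("distances must be a non-empty set of integers >= 1")
  }
  structure(list(angles = .GLCM_ANGLES, distances = distances,
                 levels = as.integer(levels), symmetric = isTRUE(symmetric)),
            class = "GLCMConfig")
}

#' Quantize grey levels for co-occurrence analysis
#'
#' Min-max quantization of an image into `levels` equal-width bins
#' (values `1..levels`); a constant image maps to bin 1.
#'
#' @param px numeric matrix or [ROIImage-class].
#' @param levels number of bins.
#' @return integer matrix with values in `1..levels`.
#' @export
quantizeGrey <- function(px, levels = 64L) {
  if (is(px, "ROIImage")) px <- roiPixels(px)
  lo <- min(px); hi <- max(px)
  if (hi == lo) {
    q <- matrix(1L, nrow(px), ncol(px))
  } else {
    q <- pmin(floor((px - lo) / (hi - lo) * levels) + 1L, levels)
    q <- matrix(as.integer(q), nrow(px), ncol(px))
  }
  q
}

#' Normalized grey-level co-occurrence matrix
#'
#' Counts pairs of quantized grey levels separated by the integer pixel
#' displacement `(round(d sin a), round(d cos a))` in `(row, col)`
#' coordinates. With `symmetric = TRUE` (the default) each pair is counted
#' in both directions, making the matrix equal to its transpose; entries are
#' normalized to sum 1.
#'
#' @param q integer matrix of quantized levels `1..levels` (see
#'   [quantizeGrey()]).
#' @param d displacement distance in pixels, `>= 1`.
#' @param alpha displacement angle, one of the eight canonical values.
#' @param levels number of grey levels.
#' @param symmetric symmetrize the matrix.
#' @return `levels` x `levels` numeric matrix summing to 1.
#' @export
glcm <- function(q, d, alpha, levels = max(q), symmetric = TRUE) {
  stopifnot(d >= 1)
  dr <- as.integer(round(d * sin(alpha)))
  dc <- as.integer(round(d * cos(alpha)))
  nr <- nrow(q); nc <- ncol(q)
  rows <- seq_len(nr); cols <- seq_len(nc)
  r1 <- rows[rows + dr >= 1L & rows + dr <= nr]
  c1 <- cols[cols + dc >= 1L & cols + dc <= nc]
  if (length(r1) == 0L || length(c1) == 0L)
    stop("displacement larger than the image: no co-occurring pairs")
  a <- q[r1, c1, drop = FALSE]
  b <- q[r1 + dr, c1 + dc, drop = FALSE]
  counts <- tabulate((a - 1L) * levels + b, nbins = levels * levels)
  P <- matrix(counts, levels, levels, byrow = TRUE)
  if (symmetric) P <- P + t(P)
  P / sum(P)
}

#' The 14 Haralick descriptors of a normalized GLCM
#'
#' Angular second moment, contrast, correlation, variance (sum of squares),
#' inverse difference moment, sum average, sum variance, sum entropy,
#' entropy, difference variance, difference entropy, the two information
#' measures of correlation, and the maximal correlation coefficient (square
#' root of the second-largest eigenvalue of the Q matrix). Entropies are in
#' bits; the exponential in the second information measure uses natural-log
#' entropies, as is conventional. Degenerate marginals (zero variance)
#' report correlation 0 and MCC 0.
#'
#' @param P square normalized co-occurrence matrix (entries sum to 1).
#' @return named numeric vector of length 14.
#' @export
haralick14 <- function(P) {
  stopifnot(is.matrix(P), nrow(P) == ncol(P))
  if (abs(sum(P) - 1) > 1e-8) stop("P must be normalized to sum 1")
  N <- nrow(P)
  i <- seq_len(N)
  px <- rowSums(P); py <- colSums(P)
  mux <- sum(i * px); muy <- sum(i * py)
  sdx <- sqrt(sum((i - mux)^2 * px)); sdy <- sqrt(sum((i - muy)^2 * py))
  I <- matrix(i, N, N); J <- t(I)
  psum <- rowsum(as.vector(P), group = as.vector(I + J))          # k = 2..2N
  ksum <- as.numeric(rownames(psum)); psum <- as.vector(psum)
  pdiff <- rowsum(as.vector(P), group = as.vector(abs(I - J)))    # k = 0..N-1
  kdiff <- as.numeric(rownames(pdiff)); pdiff <- as.vector(pdiff)

  asm <- sum(P^2)
  contrast <- sum(kdiff^2 * pdiff)
  correlation <- if (sdx <= 0 || sdy <= 0) 0 else
    (sum(I * J * P) - mux * muy) / (sdx * sdy)
  variance <- sum((I - mux)^2 * P)
  idm <- sum(P / (1 + (I - J)^2))
  sumAverage <- sum(ksum * psum)
  sumVariance <- sum((ksum - sumAverage)^2 * psum)
  sumEntropy <- .entropyBits(psum)
  entropy <- .entropyBits(P)
  muD <- sum(kdiff * pdiff)
  diffVariance <- sum((kdiff - muD)^2 * pdiff)
  diffEntropy <- .entropyBits(pdiff)

  hx <- .entropyBits(px); hy <- .entropyBits(py)
  pxpy <- outer(px, py)
  pos <- P > 0
  hxy1 <- -sum(P[pos] * log2(pxpy[pos]))
  hxy2 <- .entropyBits(pxpy)
  imc1 <- if (max(hx, hy) <= 0) 0 else (entropy - hxy1) / max(hx, hy)
  imc2 <- sqrt(max(0, 1 - exp(-2 * log(2) * (hxy2 - entropy))))

  valid <- px > 0
  mcc <- if (sum(valid) < 2L) 0 else {
    Pv <- P[valid, valid, drop = FALSE]
    B <- Pv / px[valid]
    D <- Pv / rep(py[valid], each = nrow(Pv))
    ev <- Re(eigen(B %*% t(D), only.values = TRUE)$values)
    sqrt(max(0, min(1, sort(ev, decreasing = TRUE)[2L])))
  }

  c(asm = asm, contrast = contrast, correlation = correlation,
    variance = variance, idm = idm, sum_average = sumAverage,
    sum_variance = sumVariance, sum_entropy = sumEntropy, entropy = entropy,
    difference_variance = diffVariance, difference_entropy = diffEntropy,
    imc1 = imc1, imc2 = imc2, mcc = mcc)
}

# entropy in bits of a (possibly matrix-shaped) probability mass
.entropyBits <- function(p) {
  p <- p[p > 0]
  if (length(p) == 0L) return(0)
  -sum(p * log2(p))
}

#' The 98 BI-RADS texture features
#'
#' The ROI (its full square; pixels outside the mass are retained, since
#' density is judged against the surrounding tissue) is quantized and, for
#' every distance `d` in `1..floor(L/2)`, each of the 14 Haralick descriptors
#' is averaged over the 8 canonical angles. The seven summary statistics over
#' the distance axis then give `14 x 7 = 98` features, descriptor-major.
#'
#' @param roi an [ROIImage-class] (square; for a non-square ROI the leading
#'   square of side `min(nrow, ncol)` is used).
#' @param mask accepted for interface symmetry with the other feature
#'   families; the co-occurrence analysis deliberately covers the full ROI
#'   square and ignores it.
#' @param cfg a [glcmConfig()].
#' @return named numeric vector of length 98.
#' @export
textureFeatures <- function(roi, mask = NULL, cfg = glcmConfig()) {
  stopifnot(is(roi, "ROIImage"))
  px <- roiPixels(roi)
  L <- min(dim(px))
  if (L < 4L) stop("ROI side < 4: no usable co-occurrence distances")
  px <- px[seq_len(L), seq_len(L), drop = FALSE]
  distances <- if (is.null(cfg$distances)) seq_len(L %/% 2L) else cfg$distances
  q <- quantizeGrey(px, cfg$levels)
  perDistance <- vapply(distances, function(d) {
    rowMeans(vapply(cfg$angles, function(a)
      haralick14(glcm(q, d, a, levels = cfg$levels, symmetric = cfg$symmetric)),
      numeric(14L)))
  }, numeric(14L))  # 14 x n_distances
  # apply() returns stats x descriptors; column-major flattening gives the
  # descriptor-major layout (7 statistics contiguous per descriptor)
  out <- as.vector(apply(perDistance, 1, .sevenStats))
  names(out) <- as.vector(t(outer(.HARALICK_NAMES, .statNames, paste, sep = "_")))
  out
}
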