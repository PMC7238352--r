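# Deterministic lesion phantoms and synthetic feature tables. The phantoms
# emulate the three BI-RADS descriptor axes with controllable ground truth:
# boundary irregularity (low-order harmonic perturbation of a disc), margin
# sharpness (Gaussian edge blur) and interior density contrast, plus
# additive noise. The four category archetypes map monotonically onto the
# irregularity/blur axes: B-2 phantoms are round and circumscribed, B-5
# phantoms irregular and ill-defined.

.PHANTOM_DEFAULTS <- data.frame(
  category = c("B2", "B3", "B4", "B5"),
  amplitude = c(0.5, 1.5, 3.0, 5.0),   # px, boundary harmonic amplitude
  blur = c(0.5, 1.0, 1.6, 2.2),        # px, edge Gaussian sigma
  contrast = c(80, 95, 110, 125),      # grey levels above background
  ageBase = c(44, 52, 60, 66),         # years, synthetic age centre
  stringsAsFactors = FALSE)

#' Lesion phantom specification
#'
#' Unset parameters default to the archetype of `category`: amplitude and
#' blur (and interior contrast) increase monotonically from B2 to B5.
#'
#' @param category BI-RADS class, one of `B2 B3 B4 B5`.
#' @param radiusPx base disc radius in pixels (`>= 5`, default 16).
#' @param amplitude total boundary-harmonic amplitude in pixels.
#' @param harmonics integer harmonic orders of the boundary perturbation
#'   (default `c(2, 3, 5)`).
#' @param blurSigma edge blur sigma in pixels.
#' @param interiorContrast interior grey level above the background (60).
#' @param noiseSigma additive Gaussian noise sigma (default 4).
#' @param seed RNG seed; the phantom is fully determined by the spec.
#' @return list of class `PhantomSpec`.
#' @export
phantomSpec <- function(category = "B2", radiusPx = 16, amplitude = NULL,
                        harmonics = c(2L, 3L, 5L), blurSigma = NULL,
                        interiorContrast = NULL, noiseSigma = 4, seed = 1L) {
  category <- match.arg(category, .BIRADS_CLASSES)
  if (radiusPx < 5) stop("radiusPx must be >= 5")
  d <- .PHANTOM_DEFAULTS[.PHANTOM_DEFAULTS$category == category, ]
  structure(list(
    category = category, radiusPx = radiusPx,
    amplitude = if (is.null(amplitude)) d$amplitude else amplitude,
    harmonics = as.integer(harmonics),
    blurSigma = if (is.null(blurSigma)) d$blur else blurSigma,
    interiorContrast = if (is.null(interiorContrast)) d$contrast else interiorContrast,
    noiseSigma = noiseSigma, ageBase = d$ageBase, seed = as.integer(seed)),
    class = "PhantomSpec")
}

#' Generate a lesion phantom with known ground truth
#'
#' The boundary radius is `radiusPx + sum_k a_k cos(k phi + phase_k)` over
#' the spec's harmonics (amplitudes summing to `amplitude`, phases random
#' under the seed); the truth mask contains all pixels within that radius.
#' The image is background 60 plus `interiorContrast` inside the mass,
#' Gaussian-blurred at the edge, with additive Gaussian noise, clamped to
#' 0..255. A parameter set whose perturbation exceeds the base radius would
#' self-intersect and is rejected.
#'
#' @param spec a [phantomSpec()].
#' @return list with `roi` ([ROIImage-class]), `mask` (truth
#'   [MassMask-class]), `category`, `ageYears` and `radiusPx`.
#' @export
makePhantom <- function(spec) {
  stopifnot(inherits(spec, "PhantomSpec"))
  .withSeed(spec$seed, {
    nh <- length(spec$harmonics)
    w <- abs(stats::rnorm(nh)) + 0.2
    amps <- spec$amplitude * w / sum(w)
    phases <- stats::runif(nh, 0, 2 * pi)
    pad <- ceiling(spec$amplitude + 3 * spec$blurSigma + 6)
    half <- ceiling(spec$radiusPx) + pad
    side <- 2L * as.integer(half) + 1L
    ctr <- half + 1
    rows <- matrix(seq_len(side), side, side)
    cols <- t(rows)
    dy <- rows - ctr; dx <- cols - ctr
    phi <- atan2(dy, dx)
    rphi <- spec$radiusPx + Reduce(`+`, lapply(seq_len(nh), function(j)
      amps[j] * cos(spec$harmonics[j] * phi + phases[j])))
    if (min(rphi) < 2) stop("self-intersecting boundary: amplitude too large for radius")
    mask <- sqrt(dy^2 + dx^2) <= rphi
    img <- 60 + spec$interiorContrast * mask
    if (spec$blurSigma > 0) img <- EBImage::gblur(img, sigma = spec$blurSigma)
    if (spec$noiseSigma > 0) img <- img + stats::rnorm(length(img), 0, spec$noiseSigma)
    img <- pmin(pmax(round(img), 0), 255)
    age <- round(min(90, max(25, spec$ageBase + stats::rnorm(1, 0, 5))))
    list(roi = ROIImage(matrix(img, side, side),
                        sourceId = sprintf("phantom-%s-seed%d", spec$category, spec$seed)),
         mask = MassMask(mask, c(as.integer(ctr), as.integer(ctr))),
         category = spec$category, ageYears = age, radiusPx = spec$radiusPx)
  })
}

#' Synthetic labeled feature table
#'
#' Balanced four-class table of 130 features: the informative columns are
#' drawn from class-shifted unit Gaussians, every other column is
#' class-independent standard noise. The `i`-th informative feature shifts
#' the mean of one class (cycling over B3, B4, B5, B2) by `classEffectSize`
#' standard deviations in a one-vs-rest pattern, so each informative feature
#' carries complementary signal: with three informative features no strict
#' subset of them separates all four classes, making the informative set an
#' identifiable ground truth for selection experiments. Deterministic under
#' `seed`.
#'
#' @param nCases total cases (allocated as evenly as possible over the four
#'   classes).
#' @param informativeIds feature ids in `1..130` carrying class signal.
#' @param classEffectSize standardized adjacent-class mean separation
#'   (default 2).
#' @param seed RNG seed.
#' @return data.frame with columns `case_id`, `label`, `f001..f130`.
#' @export
makeFeatureTable <- function(nCases, informativeIds = integer(0),
                             classEffectSize = 2, seed = 1L) {
  informativeIds <- as.integer(informativeIds)
  if (length(informativeIds) && (min(informativeIds) < 1L || max(informativeIds) > 130L))
    stop("informativeIds must lie in 1..130")
  .withSeed(seed, {
    per <- rep(nCases %/% 4L, 4L) + c(rep(1L, nCases %% 4L), rep(0L, 4L - nCases %% 4L))
    label <- rep(.BIRADS_CLASSES, times = per)
    classIdx <- match(label, .BIRADS_CLASSES) - 1L
    x <- matrix(stats::rnorm(nCases * 130L), nCases, 130L)
    shiftClass <- rep(c(1L, 2L, 3L, 0L), length.out = length(informativeIds))
    for (j in seq_along(informativeIds))
      x[, informativeIds[j]] <- x[, informativeIds[j]] +
        (classIdx == shiftClass[j]) * classEffectSize
    colnames(x) <- .featureIds()
    data.frame(case_id = sprintf("case%04d", seq_len(nCases)), label = label,
               x, stringsAsFactors = FALSE)
  })
}
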