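#' Crop a square region of interest around a lesion center
#'
#' Extracts the square window of side `2 * radius + 1` centered on the
#' reported abnormality center, clamped at the image borders. This is the
#' first pipeline stage: the lesion center and approximate radius shipped
#' with a screening dataset define the ROI that all later stages operate on.
#'
#' @param image numeric matrix of grey levels (0..255), or an
#'   [ROIImage-class].
#' @param center integer `(row, col)`, 1-based, inside the image.
#' @param radius window half-side in pixels, `>= 1`.
#' @param spacingMm pixel spacing forwarded to the result (ignored when
#'   `image` is an `ROIImage`).
#' @param sourceId provenance tag for the result.
#' @return an [ROIImage-class] holding the cropped window.
#' @examples
#' img <- matrix(rep(0:99, 10), 100, 10)
#' roi <- cropROI(img, center = c(50, 5), radius = 4)
#' dim(roiPixels(roi))  # 9 x 9
#' @export
cropROI <- function(image, center, radius, spacingMm = 0.05, sourceId = "") {
  if (is(image, "ROIImage")) {
    spacingMm <- spacingMm(image)
    if (!nzchar(sourceId)) sourceId <- sourceId(image)
    image <- roiPixels(image)
  }
  image <- as.matrix(image)
  center <- as.integer(center)
  radius <- as.integer(radius)
  if (radius < 1L) stop("radius must be >= 1")
  if (center[1] < 1L || center[1] > nrow(image) ||
      center[2] < 1L || center[2] > ncol(image))
    stop("center lies outside the image")
  rows <- max(1L, center[1] - radius):min(nrow(image), center[1] + radius)
  cols <- max(1L, center[2] - radius):min(ncol(image), center[2] + radius)
  ROIImage(image[rows, cols, drop = FALSE], spacingMm = spacingMm, sourceId = sourceId)
}

#' Histogram equalization of an ROI
#'
#' Classical cumulative-distribution histogram equalization over the 8-bit
#' grey range: each level `v` maps to `round(255 * CDF(v))` where `CDF` is the
#' empirical cumulative distribution of the ROI's pixels. The mapping is
#' monotone non-decreasing in the input grey level, so the rank order of
#' pixel intensities is preserved while the histogram is spread across the
#' full dynamic range — raising the contrast between a mass and the
#' surrounding fibroglandular tissue before segmentation.
#'
#' @param roi an [ROIImage-class].
#' @return an [ROIImage-class] with equalized pixels.
#' @examples
#' roi <- ROIImage(matrix(c(rep(10, 5), rep(20, 3), 30), 3, 3))
#' roiPixels(equalizeHistogram(roi))
#' @export
equalizeHistogram <- function(roi) {
  stopifnot(is(roi, "ROIImage"))
  px <- roiPixels(roi)
  counts <- tabulate(as.vector(px) + 1L, nbins = 256L)
  cdf <- cumsum(counts) / length(px)
  lut <- as.integer(round(255 * cdf))
  ROIImage(matrix(lut[px + 1L], nrow(px), ncol(px)),
           spacingMm = spacingMm(roi), sourceId = sourceId(roi))
}

#' Seeded region growing at a fixed grey-level threshold
#'
#' Grows the mass region from the ROI center pixel: the mask is the
#' 8-connected component, containing the seed, of all pixels with grey level
#' `>= threshold` (masses are hyperintense relative to background). If the
#' seed itself fails the threshold the mask degenerates to the seed alone.
#'
#' @param roi an [ROIImage-class].
#' @param threshold grey level within the ROI's 0..255 range.
#' @return a [MassMask-class] seeded at the ROI center.
#' @examples
#' px <- matrix(50L, 8, 8); px[3:5, 3:5] <- 200L
#' m <- regionGrow(ROIImage(px), threshold = 100)
#' maskArea(m)
#' @export
regionGrow <- function(roi, threshold) {
  stopifnot(is(roi, "ROIImage"))
  px <- roiPixels(roi)
  if (threshold < 0 || threshold > 255) stop("threshold outside the grey range")
  seed <- c((nrow(px) + 1L) %/% 2L, (ncol(px) + 1L) %/% 2L)
  binary <- px >= threshold
  if (!binary[seed[1], seed[2]]) {
    mask <- matrix(FALSE, nrow(px), ncol(px))
    mask[seed[1], seed[2]] <- TRUE
  } else {
    mask <- .connectedComponent8(binary, seed)
  }
  MassMask(mask, seed)
}

#' Generate candidate masks over an evenly spaced threshold sweep
#'
#' An optimal stopping threshold for region growing differs per image, so a
#' range of candidates is produced instead: `nThresholds` values evenly
#' spaced over `[min grey, max grey]` of the ROI, one grown mask per value.
#' Masks for increasing thresholds are nested (each a subset of the previous),
#' which the candidate-selection step exploits.
#'
#' @param roi an [ROIImage-class].
#' @param nThresholds number of thresholds, `>= 1` (default 16).
#' @return list with elements `masks` (list of [MassMask-class]) and
#'   `thresholds` (numeric vector).
#' @export
generateCandidates <- function(roi, nThresholds = 16L) {
  stopifnot(is(roi, "ROIImage"), nThresholds >= 1L)
  px <- roiPixels(roi)
  lo <- min(px); hi <- max(px)
  if (lo == hi) {
    warning("constant ROI: a single region-growing candidate is produced")
    thresholds <- as.numeric(lo)
  } else if (nThresholds == 1L) {
    thresholds <- (lo + hi) / 2
  } else {
    thresholds <- seq(lo, hi, length.out = nThresholds)
  }
  list(masks = lapply(thresholds, function(t) regionGrow(roi, t)),
       thresholds = thresholds)
}

#' Select the most plausible candidate mask
#'
#' The interactive refinement a radiologist would perform is proxied by an
#' automatic rule: return the candidate whose equivalent-circle radius
#' `sqrt(area / pi)` is closest to the dataset-provided approximate lesion
#' radius, breaking ties towards the larger mask. `strategy = "interactive"`
#' lists the candidates and delegates the choice to `chooser` (by default a
#' console prompt), providing the hook for expert review.
#'
#' @param candidates list of [MassMask-class] objects (or the list returned
#'   by [generateCandidates()]).
#' @param targetRadius approximate lesion radius in pixels.
#' @param strategy `"auto"` (default) or `"interactive"`.
#' @param chooser for the interactive strategy, a function taking the number
#'   of candidates and returning the chosen index.
#' @return the selected [MassMask-class].
#' @export
selectCandidate <- function(candidates, targetRadius,
                            strategy = c("auto", "interactive"),
                            chooser = NULL) {
  if (is.list(candidates) && !is.null(candidates$masks)) candidates <- candidates$masks
  if (length(candidates) == 0L) stop("empty candidate list")
  strategy <- match.arg(strategy)
  areas <- vapply(candidates, maskArea, numeric(1))
  if (strategy == "interactive") {
    if (is.null(chooser)) {
      chooser <- function(n) {
        cat(sprintf("%d candidate masks; areas: %s\n", n,
                    paste(areas, collapse = ", ")))
        as.integer(readline("candidate index: "))
      }
    }
    idx <- chooser(length(candidates))
    if (is.na(idx) || idx < 1L || idx > length(candidates))
      stop("invalid interactive candidate index")
    return(candidates[[idx]])
  }
  eqRadius <- sqrt(areas / pi)
  dev <- abs(eqRadius - targetRadius)
  best <- which(dev == min(dev))
  candidates[[best[which.max(areas[best])]]]
}

#' Fill interior holes of a mask
#'
#' Region growing over bright tissue can leave dark interior holes; a single
#' closed boundary requires a simply-connected region, so holes are filled
#' before contour tracing.
#'
#' @param mask a [MassMask-class].
#' @return a [MassMask-class] without interior holes.
#' @export
fillMaskHoles <- function(mask) {
  stopifnot(is(mask, "MassMask"))
  m <- maskMatrix(mask)
  filled <- EBImage::fillHull(matrix(as.integer(m), nrow(m), ncol(m))) > 0
  MassMask(filled, maskSeed(mask))
}

# clockwise Moore neighbourhood, starting north, in image coordinates
# (rows grow downwards): N, NE, E, SE, S, SW, W, NW
.mooreOffsets <- matrix(c(-1L, 0L, -1L, 1L, 0L, 1L, 1L, 1L,
                          1L, 0L, 1L, -1L, 0L, -1L, -1L, -1L),
                        ncol = 2L, byrow = TRUE)

#' Trace the closed boundary of a mask
#'
#' Moore neighbour tracing with Jacob's stopping criterion, clockwise in
#' image coordinates, starting from the topmost-leftmost mask pixel. The
#' result is a closed pixel sequence (closure implicit between last and
#' first point); a pixel is revisited only where the region is one pixel
#' wide, so the sequence always stays 8-connected. Shape and margin
#' descriptors are computed from it.
#'
#' @param mask a [MassMask-class]; must be non-empty and connected (enforced
#'   by the class validity).
#' @return a [Contour-class].
#' @export
extractContour <- function(mask) {
  stopifnot(is(mask, "MassMask"))
  m <- maskMatrix(mask)
  if (!any(m)) stop("empty mask")
  idx <- which(m, arr.ind = TRUE)
  start <- idx[order(idx[, 1], idx[, 2])[1L], ]
  if (nrow(idx) == 1L) return(Contour(matrix(start, 1L, 2L)))
  inMask <- function(p) p[1] >= 1L && p[1] <= nrow(m) && p[2] >= 1L &&
    p[2] <= ncol(m) && m[p[1], p[2]]
  pts <- matrix(0L, nrow(idx) * 4L, 2L)
  n <- 0L
  cur <- start
  # entered the start pixel "from the north" (row above is background since
  # start is topmost-leftmost), so begin scanning at the backtrack direction
  back <- 1L  # index into .mooreOffsets pointing at the previous (bg) pixel
  firstMove <- NA_integer_
  maxSteps <- 4L * nrow(idx) + 16L
  repeat {
    n <- n + 1L
    if (n > maxSteps) stop("contour tracing did not close; is the mask connected?")
    if (n > nrow(pts)) pts <- rbind(pts, pts * 0L)
    pts[n, ] <- cur
    found <- FALSE
    for (k in 0:7) {
      j <- ((back - 1L + k) %% 8L) + 1L
      cand <- cur + .mooreOffsets[j, ]
      if (inMask(cand)) {
        # next backtrack: the neighbour scanned just before the hit,
        # relative to the new current pixel
        prevDir <- ((j - 2L) %% 8L) + 1L
        bgPix <- cur + .mooreOffsets[prevDir, ]
        rel <- bgPix - cand
        back <- which(.mooreOffsets[, 1] == rel[1] & .mooreOffsets[, 2] == rel[2])
        if (n == 1L) firstMove <- j
        cur <- cand
        found <- TRUE
        break
      }
    }
    if (!found) break  # isolated pixel (handled above) — defensive
    if (all(cur == start)) {
      # Jacob's criterion: stop when re-entering the start via the same move
      nxt <- NA_integer_
      for (k in 0:7) {
        j <- ((back - 1L + k) %% 8L) + 1L
        if (inMask(start + .mooreOffsets[j, ])) { nxt <- j; break }
      }
      if (is.na(nxt) || nxt == firstMove) break
    }
  }
  pts <- pts[seq_len(n), , drop = FALSE]
  # drop the closing repeat of the start; revisited pixels along
  # one-pixel-wide spurs are retained so the sequence stays 8-connected
  if (n > 1L && all(pts[n, ] == pts[1L, ]))
    pts <- pts[-n, , drop = FALSE]
  Contour(pts)
}

#' Rasterize a closed contour back into a filled mask
#'
#' Inverse of [extractContour()] for simply-connected regions: the boundary
#' pixels are stamped into an empty image and the enclosed hole is filled.
#'
#' @param contour a [Contour-class].
#' @param dim `(rows, cols)` of the target mask.
#' @return a [MassMask-class] seeded at the first contour point.
#' @export
fillContour <- function(contour, dim) {
  stopifnot(is(contour, "Contour"))
  m <- matrix(0L, dim[1], dim[2])
  m[contourPoints(contour)] <- 1L
  filled <- EBImage::fillHull(m) > 0
  MassMask(filled, contourPoints(contour)[1L, ])
}

## ---- image I/O -------------------------------------------------------------

#' Read a greyscale image file as an ROI
#'
#' Reads 8-bit greyscale PNG/TIFF/JPEG via EBImage and rescales to the 0..255
#' integer range. Multichannel images are averaged to grey.
#'
#' @param path image file path.
#' @param spacingMm pixel spacing in mm per pixel.
#' @param sourceId provenance tag; defaults to the file name.
#' @return an [ROIImage-class].
#' @export
readROIImage <- function(path, spacingMm = 0.05, sourceId = basename(path)) {
  img <- EBImage::readImage(path)
  d <- EBImage::imageData(img)
  if (length(dim(d)) > 2L) d <- apply(d, c(1, 2), mean)
  # EBImage stores (x, y); transpose to (row, col)
  ROIImage(t(round(d * 255)), spacingMm = spacingMm, sourceId = sourceId)
}

#' Write a binary mask as a 0/255 PNG
#'
#' @param mask a [MassMask-class] or logical matrix.
#' @param path output PNG path.
#' @return `path`, invisibly.
#' @export
writeMaskPNG <- function(mask, path) {
  if (is(mask, "MassMask")) mask <- maskMatrix(mask)
  EBImage::writeImage(t(matrix(as.numeric(mask), nrow(mask), ncol(mask))), path)
  invisible(path)
}
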