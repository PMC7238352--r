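#' @import methods
NULL

#' Region-of-interest image
#'
#' An 8-bit grey-level region of interest cropped around a mass lesion,
#' together with its pixel spacing and a free-text provenance identifier.
#' Pixel values live in `0..255`; coordinates throughout the package are
#' 1-based `(row, col)` with rows increasing downwards.
#'
#' @slot pixels integer matrix of grey levels in `0..255`.
#' @slot spacingMm pixel spacing in mm per pixel (default 0.05, i.e. 50 micron
#'   scan resolution).
#' @slot sourceId free-text provenance tag.
#'
#' @seealso [ROIImage()], [cropROI()], [equalizeHistogram()]
#' @exportClass ROIImage
setClass("ROIImage",
  representation(pixels = "matrix", spacingMm = "numeric", sourceId = "character"),
  prototype(spacingMm = 0.05, sourceId = "")
)

setValidity("ROIImage", function(object) {
  p <- object@pixels
  if (length(p) == 0L) return("pixels must be a non-empty matrix")
  if (!is.numeric(p)) return("pixels must be numeric")
  if (anyNA(p) || any(!is.finite(p))) return("pixels must be finite")
  if (any(p < 0) || any(p > 255)) return("pixels must lie in 0..255")
  if (length(object@spacingMm) != 1L || object@spacingMm <= 0)
    return("spacingMm must be a single positive number")
  TRUE
})

#' Binary mass mask
#'
#' The segmented mass region: a boolean matrix congruent with its ROI plus the
#' seed pixel the region was grown from. A valid mask is 8-connected and
#' contains its seed.
#'
#' @slot mask logical matrix.
#' @slot seed integer `(row, col)` of the growth seed.
#'
#' @seealso [MassMask()], [regionGrow()]
#' @exportClass MassMask
setClass("MassMask", representation(mask = "matrix", seed = "integer"))

setValidity("MassMask", function(object) {
  m <- object@mask
  if (!is.logical(m) || length(m) == 0L) return("mask must be a non-empty logical matrix")
  if (length(object@seed) != 2L) return("seed must be (row, col)")
  s <- object@seed
  if (s[1] < 1L || s[1] > nrow(m) || s[2] < 1L || s[2] > ncol(m))
    return("seed outside mask matrix")
  if (!m[s[1], s[2]]) return("seed pixel must belong to the mask")
  if (!.isConnected8(m)) return("mask region must be 8-connected")
  TRUE
})

#' Closed mass contour
#'
#' The ordered boundary of a mass mask as traced by Moore neighbour tracing:
#' a closed sequence of `(row, col)` pixels, clockwise in image coordinates
#' (rows increasing downwards), starting at the topmost-leftmost boundary
#' pixel. Closure is implicit: the last point is 8-adjacent to the first.
#'
#' @slot points integer matrix with columns `row`, `col`.
#' @slot clockwise logical orientation flag.
#'
#' @seealso [Contour()], [extractContour()]
#' @exportClass Contour
setClass("Contour", representation(points = "matrix", clockwise = "logical"),
  prototype(clockwise = TRUE))

setValidity("Contour", function(object) {
  p <- object@points
  if (!is.numeric(p) || ncol(p) != 2L || nrow(p) < 1L)
    return("points must be an n x 2 matrix")
  if (nrow(p) > 1L) {
    nxt <- rbind(p[-1L, , drop = FALSE], p[1L, , drop = FALSE])
    gaps <- pmax(abs(nxt[, 1] - p[, 1]), abs(nxt[, 2] - p[, 2]))
    if (any(gaps > 1)) return("consecutive contour points (incl. closure) must be 8-adjacent")
  }
  TRUE
})

## ---- constructors ----------------------------------------------------------

#' @rdname ROIImage-class
#' @param pixels numeric matrix of grey levels in 0..255 (rounded to integer).
#' @param spacingMm pixel spacing, mm per pixel.
#' @param sourceId provenance string.
#' @return `ROIImage()` returns a validated [ROIImage-class] object.
#' @examples
#' roi <- ROIImage(matrix(0:255, 16, 16))
#' dim(roiPixels(roi))
#' @export
ROIImage <- function(pixels, spacingMm = 0.05, sourceId = "") {
  px <- round(as.matrix(pixels))
  storage.mode(px) <- "integer"
  new("ROIImage", pixels = px, spacingMm = spacingMm, sourceId = as.character(sourceId))
}

#' @rdname MassMask-class
#' @param mask logical matrix.
#' @param seed integer `(row, col)` seed coordinate.
#' @return `MassMask()` returns a validated [MassMask-class] object.
#' @export
MassMask <- function(mask, seed) {
  new("MassMask", mask = matrix(as.logical(mask), nrow(mask), ncol(mask)),
      seed = as.integer(seed))
}

#' @rdname Contour-class
#' @param points n x 2 matrix of `(row, col)` boundary pixels.
#' @param clockwise orientation flag.
#' @return `Contour()` returns a validated [Contour-class] object.
#' @export
Contour <- function(points, clockwise = TRUE) {
  p <- as.matrix(points)
  storage.mode(p) <- "integer"
  colnames(p) <- c("row", "col")
  new("Contour", points = p, clockwise = clockwise)
}

## ---- accessors -------------------------------------------------------------

#' @describeIn ROIImage-class grey-level matrix.
#' @param object,x an object of the documented class.
#' @export
roiPixels <- function(object) object@pixels

#' @describeIn ROIImage-class pixel spacing in mm per pixel.
#' @export
spacingMm <- function(object) object@spacingMm

#' @describeIn ROIImage-class provenance identifier.
#' @export
sourceId <- function(object) object@sourceId

#' @describeIn MassMask-class logical mask matrix.
#' @export
maskMatrix <- function(object) object@mask

#' @describeIn MassMask-class seed `(row, col)`.
#' @export
maskSeed <- function(object) object@seed

#' @describeIn MassMask-class mask area in pixels.
#' @export
maskArea <- function(object) sum(object@mask)

#' @describeIn Contour-class boundary points, n x 2 `(row, col)`.
#' @export
contourPoints <- function(object) object@points

## ---- show ------------------------------------------------------------------

setMethod("show", "ROIImage", function(object) {
  cat(sprintf("ROIImage %dx%d px, %.3f mm/px, grey range [%d, %d]%s\n",
              nrow(object@pixels), ncol(object@pixels), object@spacingMm,
              min(object@pixels), max(object@pixels),
              if (nzchar(object@sourceId)) paste0(", source '", object@sourceId, "'") else ""))
})

setMethod("show", "MassMask", function(object) {
  cat(sprintf("MassMask %dx%d px, area %d px, seed (%d, %d)\n",
              nrow(object@mask), ncol(object@mask), sum(object@mask),
              object@seed[1], object@seed[2]))
})

setMethod("show", "Contour", function(object) {
  cat(sprintf("Contour of %d boundary points (%s)\n", nrow(object@points),
              if (object@clockwise) "clockwise" else "counter-clockwise"))
})
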