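# The 130-feature BI-RADS vector: fixed id ordering (shape 1-9, mass size 10,
# patient age 11, margin 12-32, density 33-130), min-max normalization, and
# the CSV table format used by the selection and classification stages.

.BIRADS_CLASSES <- c("B2", "B3", "B4", "B5")

#' Registry of the 130 BI-RADS features
#'
#' A data frame mapping feature id `1..130` to its category and name:
#' ids 1-9 shape, 10 mass size (mm^2), 11 patient age (years), 12-32 margin
#' (3 descriptors x 7 statistics), 33-130 density (14 Haralick descriptors x
#' 7 statistics). The id-to-name mapping is a bijection.
#'
#' @return data.frame with columns `id`, `category`, `name`.
#' @export
biradsFeatureRegistry <- function() {
  shape <- c("continuity", "curvature", "irregularity", "difference_area",
             "mean_variation", "variance_variation", "skewness_variation",
             "kurtosis_variation", "entropy_variation")
  margin <- as.vector(t(outer(c("kurtosis", "entropy", "index_of_max"),
                              .statNames, paste, sep = "_")))
  density <- as.vector(t(outer(.HARALICK_NAMES, .statNames, paste, sep = "_")))
  data.frame(
    id = 1:130,
    category = c(rep("shape", 9L), rep("additional", 2L),
                 rep("margin", 21L), rep("density", 98L)),
    name = c(shape, "mass_size", "patient_age",
             paste0("margin_", margin), paste0("density_", density)),
    stringsAsFactors = FALSE)
}

#' Assemble the full 130-feature vector
#'
#' Places the four feature families at their fixed ids. Mass size (id 10) is
#' the mask pixel count scaled by the squared pixel spacing, in mm^2.
#'
#' @param shape numeric vector of length 9 (see [shapeFeatures()]).
#' @param sizeMm2 mass size in mm^2.
#' @param ageYears patient age in years.
#' @param margin numeric vector of length 21 (see [marginFeatures()]).
#' @param texture numeric vector of length 98 (see [textureFeatures()]).
#' @return named numeric vector of length 130 in registry order.
#' @export
assembleFeatures <- function(shape, sizeMm2, ageYears, margin, texture) {
  for (fam in list(c("shape", 9L), c("margin", 21L), c("texture", 98L))) {
    x <- get(fam[1])
    if (length(x) != as.integer(fam[2]))
      stop(sprintf("%s features must have length %s, got %d",
                   fam[1], fam[2], length(x)))
  }
  if (length(sizeMm2) != 1L || length(ageYears) != 1L)
    stop("sizeMm2 and ageYears must be scalars")
  v <- c(as.numeric(shape), as.numeric(sizeMm2), as.numeric(ageYears),
         as.numeric(margin), as.numeric(texture))
  names(v) <- biradsFeatureRegistry()$name
  v
}

#' Mass size in mm^2
#'
#' @param mask a [MassMask-class] or logical matrix.
#' @param spacingMm pixel spacing in mm per pixel.
#' @return area in mm^2 (pixel count times squared spacing).
#' @export
massSizeMm2 <- function(mask, spacingMm = 0.05) {
  n <- if (is(mask, "MassMask")) maskArea(mask) else sum(mask)
  n * spacingMm^2
}

#' Extract all 130 features from a segmented ROI
#'
#' Convenience wrapper running the three descriptor families plus mass size
#' on one ROI/mask pair.
#'
#' @param roi an [ROIImage-class].
#' @param mask the segmented [MassMask-class].
#' @param ageYears patient age in years.
#' @param contour optional precomputed [Contour-class].
#' @param glcmCfg a [glcmConfig()] for the texture family.
#' @return named numeric vector of length 130.
#' @export
extractFeatures <- function(roi, mask, ageYears, contour = NULL,
                            glcmCfg = glcmConfig()) {
  if (is.null(contour)) contour <- extractContour(mask)
  assembleFeatures(
    shape = shapeFeatures(mask, contour),
    sizeMm2 = massSizeMm2(mask, spacingMm(roi)),
    ageYears = ageYears,
    margin = marginFeatures(roi, contour),
    texture = textureFeatures(roi, mask, glcmCfg))
}

## ---- min-max scaling -------------------------------------------------------

#' Fit a per-feature min-max scaler
#'
#' Learns each feature's minimum and maximum from a training table. Applying
#' the scaler maps a value `d` to `(d - dmin) / (dmax - dmin)`: the training
#' minimum to 0, the training maximum to 1. Values outside the training range
#' (as occur on held-out data) are clamped to `[0, 1]`, and a constant
#' feature maps to 0 — conventions that keep test-set normalization free of
#' information leaking from the evaluation split.
#'
#' @param table data.frame or matrix of training feature values (non-feature
#'   columns `case_id` / `label` are ignored).
#' @return an object of class `FeatureScaler` with fields `dmin`, `dmax`.
#' @export
fitScaler <- function(table) {
  x <- .featureColumns(table)
  if (nrow(x) == 0L) stop("empty training table")
  structure(list(dmin = apply(x, 2, min), dmax = apply(x, 2, max),
                 features = colnames(x)),
            class = "FeatureScaler")
}

#' @rdname fitScaler
#' @param scaler a fitted `FeatureScaler`.
#' @param x numeric vector, matrix or data.frame of feature values to map
#'   into `[0, 1]`.
#' @return `applyScaler()` returns the normalized object with the same shape
#'   as `x` (non-feature columns passed through).
#' @export
applyScaler <- function(scaler, x) {
  stopifnot(inherits(scaler, "FeatureScaler"))
  if (is.data.frame(x) && any(c("case_id", "label") %in% names(x))) {
    feats <- .featureColumns(x)
    norm <- applyScaler(scaler, feats)
    x[, colnames(feats)] <- norm
    return(x)
  }
  vec <- is.null(dim(x))
  m <- if (vec) matrix(as.numeric(x), 1L) else as.matrix(x)
  rng <- scaler$dmax - scaler$dmin
  out <- sweep(m, 2, scaler$dmin)
  out <- sweep(out, 2, ifelse(rng > 0, rng, 1), "/")
  out[, rng <= 0] <- 0
  out <- pmin(pmax(out, 0), 1)
  if (vec) { out <- as.vector(out); names(out) <- names(x) }
  out
}

.featureColumns <- function(table) {
  m <- as.data.frame(table)
  m <- m[, setdiff(colnames(m), c("case_id", "label")), drop = FALSE]
  as.matrix(m)
}

## ---- CSV table format ------------------------------------------------------

#' Write / read a labeled feature table as CSV
#'
#' One row per case with columns `case_id`, `label` (one of `B2 B3 B4 B5`)
#' and `f001..f130`; UTF-8, header row, `.` decimal separator.
#'
#' @param table data.frame with columns `case_id`, `label`, `f001..f130`.
#' @param path CSV file path.
#' @return `writeFeatureTable()` returns `path` invisibly;
#'   `readFeatureTable()` returns the data.frame.
#' @export
writeFeatureTable <- function(table, path) {
  stopifnot(all(c("case_id", "label") %in% names(table)))
  if (!all(table$label %in% .BIRADS_CLASSES))
    stop("labels must be one of ", paste(.BIRADS_CLASSES, collapse = ", "))
  utils::write.csv(table, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname writeFeatureTable
#' @export
readFeatureTable <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  if (!all(c("case_id", "label") %in% names(tab)))
    stop("not a feature table: case_id / label columns missing")
  if (!all(tab$label %in% .BIRADS_CLASSES))
    stop("unknown BI-RADS labels in table")
  tab
}

# canonical feature column names f001..f130
.featureIds <- function(ids = 1:130) sprintf("f%03d", ids)
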