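# Internal numeric helpers shared across feature families.

# Population moment statistics with the degenerate-input conventions used
# throughout the descriptor set: zero variance => skewness 0, kurtosis 0.
# Kurtosis is non-excess (m4 / m2^2).
.momentStats <- function(x) {
  m <- mean(x)
  d <- x - m
  m2 <- mean(d^2)
  if (m2 <= .Machine$double.eps * max(1, m^2)) {
    return(c(mean = m, variance = 0, sd = 0, skewness = 0, kurtosis = 0))
  }
  c(mean = m, variance = m2, sd = sqrt(m2),
    skewness = mean(d^3) / m2^1.5, kurtosis = mean(d^4) / m2^2)
}

# The seven summary statistics applied across waveforms / GLCM distances,
# in the fixed reporting order.
.sevenStats <- function(x) {
  ms <- .momentStats(x)
  c(mean = unname(ms["mean"]), maximum = max(x), minimum = min(x),
    sd = unname(ms["sd"]), variance = unname(ms["variance"]),
    skewness = unname(ms["skewness"]), kurtosis = unname(ms["kurtosis"]))
}

.statNames <- c("mean", "maximum", "minimum", "sd", "variance", "skewness", "kurtosis")

# Shannon entropy in bits of a non-negative vector normalized to sum 1.
# 0 * log 0 := 0. A zero-sum vector is treated as uniform.
.shannonBits <- function(p) {
  s <- sum(p)
  if (s <= 0) return(log2(length(p)))
  p <- p / s
  p <- p[p > 0]
  -sum(p * log2(p))
}

# Evaluate expr under a temporary RNG seed, restoring the caller's RNG state.
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# 8-connected component of `binary` containing `seed`, by iterative neighbour
# propagation (masks are small; the loop runs O(region diameter) times).
.connectedComponent8 <- function(binary, seed) {
  nr <- nrow(binary); nc <- ncol(binary)
  comp <- matrix(FALSE, nr, nc)
  if (!binary[seed[1], seed[2]]) return(comp)
  comp[seed[1], seed[2]] <- TRUE
  repeat {
    grown <- comp
    # dilate by one pixel in the 8 directions
    grown[-1, ]  <- grown[-1, ]  | comp[-nr, ]
    grown[-nr, ] <- grown[-nr, ] | comp[-1, ]
    grown[, -1]  <- grown[, -1]  | comp[, -nc]
    grown[, -nc] <- grown[, -nc] | comp[, -1]
    grown[-1, -1]   <- grown[-1, -1]   | comp[-nr, -nc]
    grown[-1, -nc]  <- grown[-1, -nc]  | comp[-nr, -1]
    grown[-nr, -1]  <- grown[-nr, -1]  | comp[-1, -nc]
    grown[-nr, -nc] <- grown[-nr, -nc] | comp[-1, -1]
    grown <- grown & binary
    if (identical(grown, comp)) break
    comp <- grown
  }
  comp
}

.isConnected8 <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(FALSE)
  comp <- .connectedComponent8(mask, idx[1L, ])
  sum(comp) == nrow(idx)
}

# Bilinear interpolation of matrix `img` at fractional (row, col) positions,
# clamping samples outside the matrix to the nearest border value.
.bilinear <- function(img, r, c) {
  nr <- nrow(img); nc <- ncol(img)
  r <- pmin(pmax(r, 1), nr)
  c <- pmin(pmax(c, 1), nc)
  r0 <- pmin(floor(r), nr - 1L); c0 <- pmin(floor(c), nc - 1L)
  if (nr == 1L) r0 <- rep(1L, length(r))
  if (nc == 1L) c0 <- rep(1L, length(c))
  fr <- r - r0; fc <- c - c0
  r1 <- pmin(r0 + 1L, nr); c1 <- pmin(c0 + 1L, nc)
  img[cbind(r0, c0)] * (1 - fr) * (1 - fc) +
    img[cbind(r1, c0)] * fr * (1 - fc) +
    img[cbind(r0, c1)] * (1 - fr) * fc +
    img[cbind(r1, c1)] * fr * fc
}

# Dice overlap between two logical masks.
#' Dice similarity coefficient between two binary masks
#'
#' `2|A ∩ B| / (|A| + |B|)`; 1 for identical non-empty masks.
#'
#' @param a,b logical matrices or [MassMask-class] objects of equal dimension.
#' @return numeric scalar in `[0, 1]`.
#' @export
diceCoefficient <- function(a, b) {
  if (is(a, "MassMask")) a <- maskMatrix(a)
  if (is(b, "MassMask")) b <- maskMatrix(b)
  stopifnot(identical(dim(a), dim(b)))
  denom <- sum(a) + sum(b)
  if (denom == 0) return(1)
  2 * sum(a & b) / denom
}
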