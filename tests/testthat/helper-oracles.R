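# Independent oracles and fixture builders, deliberately written as naive
# brute-force code paths distinct from the package implementation.

# filled disc mask of radius r centered in a side x side matrix
discMask <- function(side, r, ctr = (side + 1) / 2) {
  sqrt(outer((seq_len(side) - ctr)^2, (seq_len(side) - ctr)^2, "+")) <= r
}

# queue-based BFS flood fill (8-connected, >= threshold), independent of the
# package's iterative-dilation region grower
bfsFlood <- function(px, seed, threshold) {
  nr <- nrow(px); nc <- ncol(px)
  mask <- matrix(FALSE, nr, nc)
  if (px[seed[1], seed[2]] < threshold) {
    mask[seed[1], seed[2]] <- TRUE
    return(mask)
  }
  queue <- list(seed)
  mask[seed[1], seed[2]] <- TRUE
  while (length(queue)) {
    p <- queue[[1]]; queue <- queue[-1]
    for (dr in -1:1) for (dc in -1:1) {
      r <- p[1] + dr; c <- p[2] + dc
      if (r >= 1 && r <= nr && c >= 1 && c <= nc &&
          !mask[r, c] && px[r, c] >= threshold) {
        mask[r, c] <- TRUE
        queue[[length(queue) + 1L]] <- c(r, c)
      }
    }
  }
  mask
}

# exhaustive pair-count GLCM oracle: loop over every pixel pair
glcmOracle <- function(q, d, alpha, levels, symmetric = TRUE) {
  dr <- round(d * sin(alpha)); dc <- round(d * cos(alpha))
  P <- matrix(0, levels, levels)
  for (r in seq_len(nrow(q))) for (c in seq_len(ncol(q))) {
    r2 <- r + dr; c2 <- c + dc
    if (r2 >= 1 && r2 <= nrow(q) && c2 >= 1 && c2 <= ncol(q)) {
      P[q[r, c], q[r2, c2]] <- P[q[r, c], q[r2, c2]] + 1
      if (symmetric) P[q[r2, c2], q[r, c]] <- P[q[r2, c2], q[r, c]] + 1
    }
  }
  P / sum(P)
}

# literal double-sum Haralick oracle from the textbook definitions
haralickOracle <- function(P) {
  N <- nrow(P)
  lg <- function(x) ifelse(x > 0, log2(x), 0)
  px <- rowSums(P); py <- colSums(P)
  mux <- sum(seq_len(N) * px); muy <- sum(seq_len(N) * py)
  sdx <- sqrt(sum((seq_len(N) - mux)^2 * px))
  sdy <- sqrt(sum((seq_len(N) - muy)^2 * py))
  asm <- 0; contrast <- 0; corr <- 0; vari <- 0; idm <- 0; ent <- 0; hxy1 <- 0
  psum <- numeric(2 * N); pdiff <- numeric(N)
  for (i in seq_len(N)) for (j in seq_len(N)) {
    p <- P[i, j]
    asm <- asm + p^2
    contrast <- contrast + (i - j)^2 * p
    vari <- vari + (i - mux)^2 * p
    idm <- idm + p / (1 + (i - j)^2)
    ent <- ent - p * lg(p)
    corr <- corr + i * j * p
    psum[i + j] <- psum[i + j] + p
    pdiff[abs(i - j) + 1] <- pdiff[abs(i - j) + 1] + p
    hxy1 <- hxy1 - p * lg(px[i] * py[j])
  }
  corr <- if (sdx <= 0 || sdy <= 0) 0 else (corr - mux * muy) / (sdx * sdy)
  sa <- sum(seq_along(psum) * psum)
  sv <- sum((seq_along(psum) - sa)^2 * psum)
  se <- -sum(psum * lg(psum))
  mud <- sum((seq_along(pdiff) - 1) * pdiff)
  dv <- sum((seq_along(pdiff) - 1 - mud)^2 * pdiff)
  de <- -sum(pdiff * lg(pdiff))
  hx <- -sum(px * lg(px)); hy <- -sum(py * lg(py))
  hxy2 <- 0
  for (i in seq_len(N)) for (j in seq_len(N))
    hxy2 <- hxy2 - px[i] * py[j] * lg(px[i] * py[j])
  imc1 <- if (max(hx, hy) <= 0) 0 else (ent - hxy1) / max(hx, hy)
  imc2 <- sqrt(max(0, 1 - exp(-2 * log(2) * (hxy2 - ent))))
  valid <- which(px > 0)
  mcc <- if (length(valid) < 2) 0 else {
    Q <- matrix(0, length(valid), length(valid))
    for (a in seq_along(valid)) for (b in seq_along(valid)) {
      for (k in valid)
        Q[a, b] <- Q[a, b] + P[valid[a], k] * P[valid[b], k] / (px[valid[a]] * py[k])
    }
    ev <- sort(Re(eigen(Q, only.values = TRUE)$values), decreasing = TRUE)
    sqrt(max(0, min(1, ev[2])))
  }
  c(asm = asm, contrast = contrast, correlation = corr, variance = vari,
    idm = idm, sum_average = sa, sum_variance = sv, sum_entropy = se,
    entropy = ent, difference_variance = dv, difference_entropy = de,
    imc1 = imc1, imc2 = imc2, mcc = mcc)
}

# half-plane convex-hull pixel counter (independent of pracma::inpolygon)
hullPixelCountOracle <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  h <- grDevices::chull(idx[, 2], idx[, 1])
  hx <- idx[h, 2]; hy <- idx[h, 1]  # counter-clockwise in (x, y)
  n <- length(h)
  count <- 0
  for (r in min(idx[, 1]):max(idx[, 1])) for (c in min(idx[, 2]):max(idx[, 2])) {
    inside <- TRUE
    for (k in seq_len(n)) {
      k2 <- if (k == n) 1 else k + 1
      cross <- (hx[k2] - hx[k]) * (r - hy[k]) - (hy[k2] - hy[k]) * (c - hx[k])
      if (cross > 1e-9) { inside <- FALSE; break }  # chull returns clockwise in (x,y)
    }
    if (inside) count <- count + 1
  }
  count
}

# reference best-subset confusion matrix of a 200-case evaluation
referenceConfusion <- function() {
  matrix(c(47, 2, 1, 0,
           3, 41, 4, 2,
           2, 5, 36, 7,
           0, 3, 2, 45),
         4, 4, byrow = TRUE,
         dimnames = list(actual = c("B2", "B3", "B4", "B5"),
                         predicted = c("B2", "B3", "B4", "B5")))
}

# 4-class Gaussian blob table in the feature-table CSV layout
blobTable <- function(n, sep, nFeatures = 2, seed = 1) {
  set.seed(seed)
  classes <- c("B2", "B3", "B4", "B5")
  lab <- rep(classes, length.out = n)
  centers <- matrix(c(0, 0, sep, 0, 0, sep, sep, sep), 4, 2, byrow = TRUE)
  x <- matrix(rnorm(n * nFeatures), n, nFeatures)
  x[, 1] <- x[, 1] + centers[match(lab, classes), 1]
  x[, 2] <- x[, 2] + centers[match(lab, classes), 2]
  colnames(x) <- sprintf("f%03d", seq_len(nFeatures))
  data.frame(case_id = sprintf("case%04d", seq_len(n)), label = lab, x,
             stringsAsFactors = FALSE)
}
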