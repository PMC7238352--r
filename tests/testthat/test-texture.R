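test_that("the co-occurrence matrix is normalized, symmetric and exact", {
  # constant image: single diagonal entry
  P <- glcm(matrix(1L, 4, 4), 1, 0, levels = 2)
  expect_equal(P[1, 1], 1)
  expect_equal(sum(P), 1)

  # two-level checkerboard, d = 1, horizontal: all pairs differ
  cb <- outer(1:4, 1:4, function(r, c) ((r + c) %% 2) + 1L)
  P2 <- glcm(cb, 1, 0, levels = 2)
  expect_equal(P2[1, 2] + P2[2, 1], 1)
  expect_equal(P2[1, 1] + P2[2, 2], 0)

  # random images match the exhaustive pair-counting oracle at every
  # (distance, angle); always normalized and symmetric
  set.seed(9)
  q <- matrix(sample.int(8, 100, TRUE), 10, 10)
  for (d in c(1, 2, 4)) for (a in biradsCAD:::.GLCM_ANGLES) {
    got <- glcm(q, d, a, levels = 8)
    expect_equal(got, glcmOracle(q, d, a, 8), tolerance = 1e-12)
    expect_equal(sum(got), 1, tolerance = 1e-12)
    expect_equal(got, t(got))
  }

  expect_error(glcm(q, 50, 0, levels = 8), "larger than the image")
})

test_that("the 14 Haralick descriptors match hand values and the literal oracle", {
  # constant image's GLCM: point mass
  h <- haralick14(glcm(matrix(1L, 4, 4), 1, 0, levels = 2))
  expect_equal(unname(h["asm"]), 1)
  expect_equal(unname(h["contrast"]), 0)
  expect_equal(unname(h["entropy"]), 0)
  expect_equal(unname(h["correlation"]), 0)  # degenerate marginal convention

  # uniform 2x2 matrix: hand arithmetic
  h2 <- haralick14(matrix(0.25, 2, 2))
  expect_equal(unname(h2["asm"]), 0.25)
  expect_equal(unname(h2["entropy"]), 2)
  expect_equal(unname(h2["contrast"]), 0.5)
  expect_equal(unname(h2["correlation"]), 0)  # independent marginals

  # random toy matrices: all 14 within 1e-9 of the double-sum oracle
  set.seed(4)
  for (i in 1:6) {
    q <- matrix(sample.int(8, 144, TRUE), 12, 12)
    P <- glcm(q, sample(1:3, 1), sample(biradsCAD:::.GLCM_ANGLES, 1), levels = 8)
    expect_equal(haralick14(P), haralickOracle(P), tolerance = 1e-9)
  }
  expect_error(haralick14(matrix(0.5, 2, 2)), "normalized")
})

test_that("texture aggregation yields 98 features matching a full-path oracle", {
  set.seed(31)
  px <- matrix(sample(0:255, 256, TRUE), 16, 16)
  roi <- ROIImage(px)
  tf <- textureFeatures(roi, cfg = glcmConfig(levels = 8))
  expect_length(tf, 98)
  expect_true(all(is.finite(tf)))

  # independent aggregation: per (d, angle) oracle -> angle mean -> 7 stats
  q <- quantizeGrey(px, 8)
  perD <- sapply(1:8, function(d)
    rowMeans(sapply(biradsCAD:::.GLCM_ANGLES, function(a)
      haralickOracle(glcmOracle(q, d, a, 8)))))
  stats7 <- function(x) {
    m <- mean(x); v <- mean((x - m)^2)
    c(m, max(x), min(x), sqrt(v), v,
      if (v > 0) mean((x - m)^3) / v^1.5 else 0,
      if (v > 0) mean((x - m)^4) / v^2 else 0)
  }
  want <- numeric(0)
  for (i in 1:14) want <- c(want, stats7(perD[i, ]))
  expect_equal(unname(tf), want, tolerance = 1e-9)
  # spot-check the layout against directly computed quantities
  contrastPerD <- perD[2, ]
  expect_equal(unname(tf["contrast_mean"]), mean(contrastPerD), tolerance = 1e-9)
  expect_equal(unname(tf["contrast_maximum"]), max(contrastPerD), tolerance = 1e-9)
  expect_equal(unname(tf["entropy_minimum"]), min(perD[9, ]), tolerance = 1e-9)

  # constant ROI: zero contrast, unit ASM
  tfc <- textureFeatures(ROIImage(matrix(100L, 12, 12)), cfg = glcmConfig(levels = 8))
  expect_equal(unname(tfc["contrast_mean"]), 0)
  expect_equal(unname(tfc["asm_mean"]), 1)

  expect_error(textureFeatures(ROIImage(matrix(1L, 3, 3))), "side < 4")
})

test_that("contrast is shift-invariant on quantized input and tracks texture scale", {
  set.seed(12)
  q <- matrix(sample.int(16, 400, TRUE), 20, 20)
  P1 <- glcm(q, 1, 0, levels = 20)
  P2 <- glcm(q + 4L, 1, 0, levels = 20)
  expect_equal(unname(haralick14(P1)["contrast"]),
               unname(haralick14(P2)["contrast"]), tolerance = 1e-12)

  # coarser blotches -> lower contrast at d = 1
  blotch <- function(cell) {
    base <- outer(0:31, 0:31, function(r, c) ((r %/% cell + c %/% cell) %% 2))
    ROIImage(base * 200)
  }
  contrastAt <- function(cell) {
    tf <- textureFeatures(blotch(cell), cfg = glcmConfig(distances = 1L, levels = 8))
    unname(tf["contrast_mean"])
  }
  cs <- vapply(c(1, 4, 8), contrastAt, numeric(1))
  expect_true(all(diff(cs) <= 0))
})
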