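test_that("cropROI extracts the clamped square window around the center", {
  img <- matrix(seq_len(100), 10, 10)

  # identity: window covering the whole image
  whole <- cropROI(img %% 256, c(5, 5), 20)
  expect_identical(dim(roiPixels(whole)), c(10L, 10L))
  expect_equal(roiPixels(whole), matrix(as.integer(seq_len(100) %% 256), 10, 10))

  # interior window: center (6,6), radius 2 -> rows/cols 4..8
  roi <- cropROI(img, c(6, 6), 2)
  expect_equal(roiPixels(roi), matrix(as.integer(img[4:8, 4:8]), 5, 5))

  # clamped corner window: center (1,1), radius 2 -> 3x3
  corner <- cropROI(img, c(1, 1), 2)
  expect_equal(roiPixels(corner), matrix(as.integer(img[1:3, 1:3]), 3, 3))

  expect_error(cropROI(img, c(0, 5), 2), "outside")
  expect_error(cropROI(img, c(5, 5), 0), "radius")
})

test_that("histogram equalization follows the CDF mapping and is monotone", {
  # hand-computed CDF oracle: levels 10 (x5), 20 (x3), 30 (x1) on 9 pixels
  # map to round(255 * c(5, 8, 9) / 9) = 142, 227, 255
  toy <- ROIImage(matrix(c(rep(10, 5), rep(20, 3), 30), 3, 3))
  eq <- equalizeHistogram(toy)
  got <- roiPixels(eq)
  expect_setequal(unique(as.vector(got)), c(142L, 227L, 255L))
  expect_equal(sum(got == 142L), 5)
  expect_equal(sum(got == 227L), 3)

  # constant image stays constant
  flat <- equalizeHistogram(ROIImage(matrix(77L, 4, 4)))
  expect_true(all(roiPixels(flat) == roiPixels(flat)[1]))

  # uniform histogram is (nearly) a fixed point
  ramp <- ROIImage(matrix(0:255, 16, 16))
  expect_lte(max(abs(roiPixels(equalizeHistogram(ramp)) - roiPixels(ramp))), 1)

  # monotonicity of the grey-level mapping on random images
  set.seed(42)
  for (i in 1:5) {
    px <- matrix(sample(0:255, 400, TRUE), 20, 20)
    out <- roiPixels(equalizeHistogram(ROIImage(px)))
    ord <- order(px)
    expect_true(all(diff(out[ord]) >= 0))
  }
})

test_that("region growing equals brute-force flood fill and keeps its invariants", {
  # bright block phantom
  px <- matrix(50L, 8, 8); px[3:5, 3:5] <- 200L
  m <- regionGrow(ROIImage(px), 100)
  want <- matrix(FALSE, 8, 8); want[3:5, 3:5] <- TRUE
  expect_equal(maskMatrix(m), want)

  # uniform image: whole ROI
  u <- regionGrow(ROIImage(matrix(90L, 6, 6)), 50)
  expect_equal(maskArea(u), 36)

  # threshold above maximum: seed alone
  s <- regionGrow(ROIImage(px), 250)
  expect_equal(maskArea(s), 1)
  expect_true(maskMatrix(s)[maskSeed(s)[1], maskSeed(s)[2]])

  # random matrices vs the independent BFS oracle; masks stay connected
  set.seed(7)
  for (i in 1:10) {
    rnd <- matrix(sample(0:255, 15 * 15, TRUE), 15, 15)
    thr <- sample(40:220, 1)
    got <- regionGrow(ROIImage(rnd), thr)
    expect_equal(maskMatrix(got), bfsFlood(rnd, c(8, 8), thr))
    expect_true(maskMatrix(got)[8, 8])
  }
})

test_that("candidate masks are nested over the threshold sweep", {
  ph <- makePhantom(phantomSpec("B4", seed = 3))
  cand <- generateCandidates(ph$roi, 12L)
  expect_length(cand$masks, 12L)
  for (k in seq_len(11)) {
    lo <- maskMatrix(cand$masks[[k]])
    hi <- maskMatrix(cand$masks[[k + 1]])
    expect_true(all(lo | !hi))  # mask(t2) subset of mask(t1)
  }
  # single threshold sits at the grey midpoint
  one <- generateCandidates(ph$roi, 1L)
  px <- roiPixels(ph$roi)
  expect_equal(one$thresholds, (min(px) + max(px)) / 2)
  # constant ROI warns and returns one candidate
  expect_warning(cc <- generateCandidates(ROIImage(matrix(9L, 5, 5)), 4L),
                 "constant")
  expect_length(cc$masks, 1L)
})

test_that("candidate selection picks the closest equivalent radius", {
  stripe <- function(area, side = 30) {
    mm <- matrix(FALSE, side, side); mm[1, seq_len(area)] <- TRUE
    MassMask(mm, c(1L, 1L))
  }
  small <- stripe(10)   # eq radius 1.78
  big <- stripe(25)     # eq radius 2.82
  expect_identical(selectCandidate(list(small, big), targetRadius = 2.7), big)
  expect_identical(selectCandidate(list(small, big), targetRadius = 1.5), small)
  expect_identical(selectCandidate(list(small), targetRadius = 99), small)
  expect_error(selectCandidate(list(), 3), "empty")

  # area-100 vs area-400 candidates, target radius 11 -> the 400-px one
  a100 <- stripe(100, 500); a400 <- stripe(400, 500)
  expect_identical(selectCandidate(list(a100, a400), targetRadius = 11), a400)

  # interactive hook delegates to the chooser
  expect_identical(
    selectCandidate(list(small, big), 2, strategy = "interactive",
                    chooser = function(n) 1L), small)

  # disc phantom at the true radius: near-perfect overlap
  ph <- makePhantom(phantomSpec("B2", amplitude = 0, blurSigma = 0,
                                noiseSigma = 0, seed = 1))
  cand <- generateCandidates(ph$roi, 16L)
  sel <- selectCandidate(cand, targetRadius = ph$radiusPx)
  expect_gte(diceCoefficient(sel, ph$mask), 0.95)
})

test_that("Moore tracing yields a closed clockwise boundary that refills exactly", {
  # single pixel
  one <- matrix(FALSE, 3, 3); one[2, 2] <- TRUE
  expect_equal(contourPoints(extractContour(MassMask(one, c(2L, 2L)))),
               matrix(c(2L, 2L), 1, 2, dimnames = list(NULL, c("row", "col"))))

  # filled 3x3 square: the 8 boundary pixels, clockwise from top-left
  sq <- matrix(FALSE, 5, 5); sq[2:4, 2:4] <- TRUE
  pts <- contourPoints(extractContour(MassMask(sq, c(3L, 3L))))
  expect_equal(pts[, "row"], c(2L, 2L, 2L, 3L, 4L, 4L, 4L, 3L), ignore_attr = TRUE)
  expect_equal(pts[, "col"], c(2L, 3L, 4L, 4L, 4L, 3L, 2L, 2L), ignore_attr = TRUE)

  # disc: closed loop with length within 20% of the circumference
  d <- discMask(21, 7)
  ct <- extractContour(MassMask(d, c(11L, 11L)))
  len <- nrow(contourPoints(ct))
  expect_lt(abs(len - 2 * pi * 7) / (2 * pi * 7), 0.2)

  # round trip on simply-connected masks, including irregular phantoms
  shapes <- list(d, sq)
  for (s in c(2, 9)) {
    ph <- makePhantom(phantomSpec("B5", blurSigma = 0, noiseSigma = 0, seed = s))
    shapes[[length(shapes) + 1]] <- maskMatrix(ph$mask)
  }
  for (m in shapes) {
    seed <- which(m, arr.ind = TRUE)[1, ]
    mm <- MassMask(m, seed)
    rt <- fillContour(extractContour(mm), dim(m))
    expect_identical(maskMatrix(rt), m)
  }
})

test_that("mask PNG round trip preserves the segmentation", {
  ph <- makePhantom(phantomSpec("B3", seed = 4))
  tmp <- tempfile(fileext = ".png")
  writeMaskPNG(ph$mask, tmp)
  back <- readROIImage(tmp)
  expect_equal(roiPixels(back) > 127, maskMatrix(ph$mask))
  unlink(tmp)
})
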