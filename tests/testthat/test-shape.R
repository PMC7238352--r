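test_that("boundary geometry separates straight, cornered and ragged outlines", {
  # collinear open segment: no curvature, no direction changes
  seg <- boundaryGeometry(cbind(1:20, 5), nPoints = 8, closed = FALSE)
  expect_equal(unname(seg["curvature"]), 0, tolerance = 1e-12)
  expect_equal(unname(seg["irregularity"]), 0)

  # axis-aligned square resampled at its 4 corners + 4 edge midpoints:
  # exactly the 4 corners turn by pi/2 > pi/12
  square <- rbind(cbind(1, 1:9), cbind(2:9, 9), cbind(9, 8:1), cbind(8:2, 1))
  bg <- boundaryGeometry(square, nPoints = 8)
  expect_equal(unname(bg["irregularity"]), 4)
  expect_equal(unname(bg["continuity"]), 0, tolerance = 1e-12)

  expect_error(boundaryGeometry(cbind(1:2, 1:2)), "degenerate")
  expect_error(boundaryGeometry(square, nPoints = 4), ">= 8")

  # irregularity increases with the amplitude of high-frequency spiculation
  # (low-order undulation is below the digitization noise floor of the
  # turning-angle count; spiculation is the clinically meaningful axis)
  irr <- vapply(c(0, 2, 4), function(a) {
    ph <- makePhantom(phantomSpec("B2", amplitude = a, harmonics = c(8, 10, 12),
                                  blurSigma = 0, noiseSigma = 0, seed = 11))
    unname(shapeFeatures(ph$mask)["irregularity"])
  }, numeric(1))
  expect_true(all(diff(irr) > 0))
})

test_that("difference area is the hull pixel count minus the mask pixel count", {
  # convex regions: zero
  expect_equal(differenceArea(discMask(21, 8)), 0)
  sq <- matrix(FALSE, 7, 7); sq[2:6, 2:6] <- TRUE
  expect_equal(differenceArea(sq), 0)

  # thin 5x5 plus sign (9 px): hull is the 13-pixel diamond, difference 4
  plus <- matrix(FALSE, 5, 5)
  plus[3, ] <- TRUE; plus[, 3] <- TRUE
  expect_equal(sum(plus), 9)
  expect_equal(differenceArea(plus), hullPixelCountOracle(plus) - 9)
  expect_equal(differenceArea(plus), 4)

  # crescent: disc minus an offset disc is concave
  crescent <- discMask(31, 12) & !discMask(31, 9, ctr = 11)
  expect_gt(differenceArea(crescent), 0)

  # random blobs agree with the oracle
  set.seed(21)
  for (i in 1:5) {
    ph <- makePhantom(phantomSpec("B5", blurSigma = 0, noiseSigma = 0,
                                  seed = 100 + i))
    m <- maskMatrix(ph$mask)
    expect_equal(differenceArea(m), hullPixelCountOracle(m) - sum(m))
  }
})

test_that("the variation profile is the Feret extent at every angle", {
  # disc: extent ~ 2r at every angle
  vp <- variationProfile(discMask(41, 15), nAngles = 36)
  expect_true(all(abs(vp$extent - 30) <= 1.5))

  # two pixels 10 apart along the column axis
  two <- matrix(FALSE, 5, 15); two[3, 3] <- TRUE; two[3, 13] <- TRUE
  vp2 <- variationProfile(two, nAngles = 4)
  expect_equal(vp2$extent[1], 10)            # angle 0
  expect_equal(vp2$extent[3], 0, tolerance = 1e-9)  # angle pi/2

  # digital ellipse vs brute-force all-pixel pairwise projections
  ell <- outer((1:51 - 26)^2 / 10^2, (1:51 - 26)^2 / 20^2, "+") <= 1
  vp3 <- variationProfile(ell, nAngles = 12)
  idx <- which(ell, arr.ind = TRUE)
  for (k in seq_along(vp3$angles)) {
    a <- vp3$angles[k]
    proj <- idx[, 2] * cos(a) - idx[, 1] * sin(a)
    expect_equal(vp3$extent[k], max(proj) - min(proj), tolerance = 1e-9)
  }
  expect_equal(max(vp3$extent), 40, tolerance = 1)
  expect_equal(min(vp3$extent), 20, tolerance = 1)

  expect_warning(z <- variationProfile(matrix(c(TRUE, FALSE), 1, 2)), "single")
  expect_true(all(z$extent == 0))
})

test_that("variation statistics use population moments and bit entropy", {
  # constant profile: entropy log2(n), no spread
  vs <- variationStats(rep(3, 16))
  expect_equal(unname(vs["mean"]), 3)
  expect_equal(unname(vs["variance"]), 0)
  expect_equal(unname(vs["skewness"]), 0)
  expect_equal(unname(vs["kurtosis"]), 0)
  expect_equal(unname(vs["entropy"]), log2(16))

  # hand arithmetic on [1, 3]
  vs2 <- variationStats(c(1, 3))
  expect_equal(unname(vs2["mean"]), 2)
  expect_equal(unname(vs2["variance"]), 1)
  expect_equal(unname(vs2["entropy"]),
               -(0.25 * log2(0.25) + 0.75 * log2(0.75)))

  # disc vs ellipse: rotational symmetry means (near) zero variance
  vDisc <- variationStats(variationProfile(discMask(41, 15)))
  ell <- outer((1:51 - 26)^2 / 10^2, (1:51 - 26)^2 / 20^2, "+") <= 1
  vEll <- variationStats(variationProfile(ell))
  expect_lt(unname(vDisc["variance"]), 0.1)
  expect_gt(unname(vEll["variance"]), 1)
})

test_that("the nine shape features assemble with rotation robustness", {
  ph <- makePhantom(phantomSpec("B3", blurSigma = 0, noiseSigma = 0, seed = 5))
  sf <- shapeFeatures(ph$mask)
  expect_length(sf, 9)
  expect_true(all(is.finite(sf)))
  expect_named(sf, c("continuity", "curvature", "irregularity",
                     "difference_area", "mean_variation", "variance_variation",
                     "skewness_variation", "kurtosis_variation",
                     "entropy_variation"))

  # disc phantom: convex and rotationally symmetric
  disc <- makePhantom(phantomSpec("B2", amplitude = 0, blurSigma = 0,
                                  noiseSigma = 0, seed = 1))
  sfd <- shapeFeatures(disc$mask)
  expect_equal(unname(sfd["difference_area"]), 0)
  expect_lt(unname(sfd["variance_variation"]), 0.1)

  # spiculated phantom is strictly more irregular than the disc
  spic <- makePhantom(phantomSpec("B5", amplitude = 6, harmonics = c(7, 9, 11),
                                  blurSigma = 0, noiseSigma = 0, seed = 5))
  expect_gt(unname(shapeFeatures(spic$mask)["irregularity"]),
            unname(sfd["irregularity"]))

  # 90-degree rotation changes mean variation by < 2%
  m <- maskMatrix(ph$mask)
  mr <- t(m)[, nrow(m):1, drop = FALSE]
  v1 <- variationStats(variationProfile(m))["mean"]
  v2 <- variationStats(variationProfile(mr))["mean"]
  expect_lt(abs(v1 - v2) / v1, 0.02)
})
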