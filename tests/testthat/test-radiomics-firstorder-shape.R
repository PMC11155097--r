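# Discretization, first-order statistics and 2D shape descriptors.

test_that("fixed-bin-width discretization anchors at the in-mask minimum", {
  img <- matrix(c(0, 24.9, 25, 75, 100, 130), 2, 3)
  mk <- matrix(TRUE, 2, 3)
  gl <- discretize(img, mk, bin_width = 25)
  expect_equal(as.vector(gl$levels), c(1, 1, 2, 4, 5, 6))
  expect_equal(gl$n_levels, 6)
  # outside-mask pixels get level 0
  mk2 <- mk; mk2[1, 1] <- FALSE
  expect_equal(discretize(img, mk2, 25)$levels[1, 1], 0L)
  expect_error(discretize(img, matrix(FALSE, 2, 3), 25), "empty mask")
  expect_error(discretize(img, mk, 0), "positive")
})

test_that("discretized levels are invariant to an intensity shift", {
  set.seed(4)
  img <- matrix(runif(64, 0, 200), 8, 8)
  mk <- matrix(runif(64) > 0.3, 8, 8)
  expect_identical(discretize(img, mk, 25)$levels,
                   discretize(img + 500, mk, 25)$levels)
})

test_that("first-order statistics match hand-computed values", {
  img <- matrix(c(1, 2, 3, 99), 2, 2)
  mk <- matrix(c(TRUE, TRUE, TRUE, FALSE), 2, 2)
  fo <- first_order_features(img, mk, bin_width = 1, pixel_spacing = c(2, 3))
  expect_equal(unname(fo["Mean"]), 2)
  expect_equal(unname(fo["Variance"]), 2 / 3)       # population variance
  expect_equal(unname(fo["StandardDeviation"]), sqrt(2 / 3))
  expect_equal(unname(fo["Range"]), 2)
  expect_equal(unname(fo["Energy"]), 1 + 4 + 9)
  expect_equal(unname(fo["TotalEnergy"]), 6 * 14)
  expect_equal(unname(fo["RootMeanSquared"]), sqrt(14 / 3))
  expect_equal(unname(fo["Skewness"]), 0)           # symmetric sample
  expect_equal(unname(fo["Uniformity"]), 3 * (1 / 3)^2)
  expect_equal(unname(fo["Entropy"]), log2(3))
  expect_length(fo, 19)
})

test_that("a constant ROI has zero spread and zero higher moments", {
  fo <- first_order_features(matrix(7, 5, 5), matrix(TRUE, 5, 5))
  expect_equal(unname(fo["Variance"]), 0)
  expect_equal(unname(fo["Skewness"]), 0)
  expect_equal(unname(fo["Kurtosis"]), 0)
  expect_equal(unname(fo["Entropy"]), 0)
  expect_equal(unname(fo["Uniformity"]), 1)
  expect_equal(unname(fo["InterquartileRange"]), 0)
})

test_that("first-order values agree with a direct-formula oracle", {
  set.seed(10)
  img <- matrix(runif(144, 0, 300), 12, 12)
  mk <- matrix(runif(144) > 0.25, 12, 12)
  x <- img[mk]
  fo <- first_order_features(img, mk, bin_width = 25)
  expect_equal(unname(fo["Mean"]), mean(x))
  expect_equal(unname(fo["Median"]), median(x))
  expect_equal(unname(fo["Variance"]), mean((x - mean(x))^2))
  expect_equal(unname(fo["MeanAbsoluteDeviation"]), mean(abs(x - mean(x))))
  expect_equal(unname(fo["Skewness"]),
               mean((x - mean(x))^3) / mean((x - mean(x))^2)^1.5)
  expect_equal(unname(fo["Kurtosis"]),
               mean((x - mean(x))^4) / mean((x - mean(x))^2)^2)
  q <- quantile(x, c(0.1, 0.9))
  r <- x[x >= q[1] & x <= q[2]]
  expect_equal(unname(fo["RobustMeanAbsoluteDeviation"]),
               mean(abs(r - mean(r))))
  expect_equal(unname(fo["10Percentile"]), unname(q[1]))
  expect_equal(unname(fo["90Percentile"]), unname(q[2]))
})

test_that("shape features of simple geometries behave as expected", {
  # single pixel
  one <- matrix(FALSE, 9, 9); one[5, 5] <- TRUE
  s1 <- shape2d_features(one)
  expect_equal(unname(s1["PixelSurface"]), 1)
  expect_equal(unname(s1["MaximumDiameter"]), 0)
  expect_length(s1, 10)

  # axis-aligned square: isotropic second moments
  sq <- matrix(FALSE, 30, 30); sq[10:19, 8:17] <- TRUE
  ss <- shape2d_features(sq)
  expect_equal(unname(ss["Elongation"]), 1)
  expect_equal(unname(ss["PixelSurface"]), 100)
  expect_equal(unname(ss["MaximumDiameter"]), 9 * sqrt(2))

  # disc: near-unit sphericity, above any elongated shape
  d <- matrix(FALSE, 40, 40)
  rr <- row(d); cc <- col(d)
  d[(rr - 20)^2 + (cc - 20)^2 <= 144] <- TRUE
  sd_ <- shape2d_features(d)
  expect_gt(unname(sd_["Sphericity"]), 0.9)
  expect_lte(unname(sd_["Sphericity"]), 1.05)
  rect <- matrix(FALSE, 40, 40); rect[19:21, 5:35] <- TRUE
  expect_gt(unname(sd_["Sphericity"]),
            unname(shape2d_features(rect)["Sphericity"]))
  expect_equal(unname(sd_["SphericalDisproportion"]),
               1 / unname(sd_["Sphericity"]))
})

test_that("shape features honour anisotropic pixel spacing", {
  sq <- matrix(FALSE, 20, 20); sq[5:14, 5:14] <- TRUE
  iso <- shape2d_features(sq, c(1, 1))
  ani <- shape2d_features(sq, c(1, 2))
  expect_equal(unname(ani["PixelSurface"]), 2 * unname(iso["PixelSurface"]))
  expect_equal(unname(ani["MeshSurface"]), 2 * unname(iso["MeshSurface"]))
  expect_lt(unname(ani["Elongation"]), 1)
  expect_error(shape2d_features(matrix(FALSE, 5, 5)), "empty")
})

test_that("mesh surface and perimeter converge for a large disc", {
  d <- matrix(FALSE, 120, 120)
  rr <- row(d); cc <- col(d)
  d[(rr - 60)^2 + (cc - 60)^2 <= 50^2] <- TRUE
  s <- shape2d_features(d)
  expect_equal(unname(s["MeshSurface"]), pi * 50^2, tolerance = 0.02)
  # the marching-squares contour is a staircase of axis and 45-degree
  # facets, which systematically overestimates a smooth perimeter
  expect_equal(unname(s["Perimeter"]), 2 * pi * 50, tolerance = 0.08)
})
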