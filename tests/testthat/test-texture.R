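# Texture matrices and features cross-checked against explicit pixel-loop
# oracles plus hand-derived fixed examples.

oracle_glcm_feats <- function(lv) {
  ng <- max(lv)
  angles <- list(c(0L, 1L), c(-1L, 1L), c(-1L, 0L), c(-1L, -1L))
  rows <- list()
  for (a in angles) {
    M <- oracle_glcm(lv, ng, a[1], a[2])
    if (sum(M) == 0) next
    rows[[length(rows) + 1]] <- mipvasc:::.glcm_features_one(M / sum(M))
  }
  colMeans(do.call(rbind, rows))
}

oracle_glrlm_feats <- function(lv) {
  ng <- max(lv)
  np <- sum(lv > 0)
  angles <- list(c(0L, 1L), c(-1L, 1L), c(-1L, 0L), c(-1L, -1L))
  rows <- lapply(angles, function(a) {
    M <- oracle_glrlm(lv, ng, a[1], a[2])
    mipvasc:::.size_features(M, np, mipvasc:::.glrlm_names)
  })
  colMeans(do.call(rbind, rows))
}

test_that("GLCM features agree with the brute-force oracle", {
  set.seed(101)
  for (i in 1:10) {
    lv <- random_level_image()
    got <- glcm_features(as_gray_level(lv))
    want <- oracle_glcm_feats(lv)
    expect_equal(got, want, tolerance = 1e-12)
    expect_length(got, 24)
  }
})

test_that("GLCM fixed examples: checkerboard and constant images", {
  cb <- matrix(rep(c(1L, 2L), 8), 4, 4)  # rows alternate between 1 and 2
  f <- glcm_features(as_gray_level(cb))
  # vertical and both diagonals cross levels; horizontal stays equal
  expect_equal(unname(f["Contrast"]), mean(c(0, 1, 1, 1)))
  flat <- glcm_features(as_gray_level(matrix(1L, 4, 4)))
  expect_equal(unname(flat["Contrast"]), 0)
  expect_equal(unname(flat["JointEnergy"]), 1)
  expect_equal(unname(flat["Correlation"]), 1)
  expect_equal(unname(flat["MCC"]), 1)
  one <- matrix(0L, 5, 5); one[3, 3] <- 1L
  expect_error(glcm_features(as_gray_level(one)), "no co-occurring")
})

test_that("GLRLM features agree with the brute-force oracle", {
  set.seed(102)
  for (i in 1:10) {
    lv <- random_level_image()
    got <- glrlm_features(as_gray_level(lv))
    want <- oracle_glrlm_feats(lv)
    expect_equal(got, want, tolerance = 1e-12)
    expect_length(got, 16)
  }
})

test_that("GLRLM of a constant image is dominated by long runs", {
  f <- glrlm_features(as_gray_level(matrix(1L, 4, 4)))
  expect_equal(unname(f["GrayLevelNonUniformityNormalized"]), 1)
  expect_gt(unname(f["LongRunEmphasis"]), unname(f["ShortRunEmphasis"]))
  # horizontal/vertical: 4 runs of length 4; diagonals: 7 runs each
  expect_equal(unname(f["RunPercentage"]), mean(c(4, 4, 7, 7) / 16))
})

test_that("GLSZM features agree with the brute-force oracle", {
  set.seed(103)
  for (i in 1:10) {
    lv <- random_level_image()
    got <- glszm_features(as_gray_level(lv))
    M <- oracle_glszm(lv, max(lv))
    want <- mipvasc:::.size_features(M, sum(lv > 0), mipvasc:::.glszm_names)
    expect_equal(got, want, tolerance = 1e-12)
    expect_length(got, 16)
  }
})

test_that("GLSZM zones are 8-connected", {
  lv <- matrix(0L, 5, 5)
  lv[1, 1] <- 1L; lv[2, 2] <- 1L  # diagonal touch: one zone of size 2
  lv[5, 5] <- 2L
  f <- glszm_features(as_gray_level(lv))
  expect_equal(unname(f["ZonePercentage"]), 2 / 3)
  expect_equal(unname(f["LargeAreaEmphasis"]), (1 * 4 + 1 * 1) / 2)
})

test_that("GLDM matrices and features agree with the brute-force oracle", {
  set.seed(104)
  for (i in 1:10) {
    lv <- random_level_image()
    alpha <- sample(0:1, 1); delta <- sample(1:2, 1)
    m <- gldm_matrix(as_gray_level(lv), alpha, delta)
    want_M <- oracle_gldm(lv, max(lv), alpha, delta)
    w <- max(ncol(m$counts), ncol(want_M))
    expect_equal(pad_cols(m$counts, w), pad_cols(want_M, w),
                 ignore_attr = TRUE)
    want <- gldm_features(structure(list(counts = want_M, alpha = alpha,
                                         delta = delta),
                                    class = "gldm_matrix"))
    expect_equal(gldm_features(m), want, tolerance = 1e-12)
    expect_length(want, 14)
  }
})

test_that("GLDM of a uniform 3 x 3 patch matches the hand-derived values", {
  m <- gldm_matrix(as_gray_level(matrix(1L, 3, 3)))
  # 4 corners with 3 neighbours, 4 edges with 5, 1 center with 8
  expect_equal(sum(m$counts), 9)
  expect_equal(m$counts[1, c(4, 6, 9)], c(4, 4, 1), ignore_attr = TRUE)
  f <- gldm_features(m)
  expect_equal(unname(f["LargeDependenceEmphasis"]),
               (4 * 9 + 4 * 25 + 1 * 64) / 9)
  expect_equal(unname(f["DependenceNonUniformity"]), (16 + 16 + 1) / 9)
  expect_equal(unname(f["GrayLevelNonUniformity"]), 9)
})

test_that("isolated pixels carry no small-dependence evidence (base 0)", {
  lv <- matrix(0L, 5, 5); lv[1, 1] <- 1L; lv[5, 5] <- 1L
  f0 <- gldm_features(gldm_matrix(as_gray_level(lv)))
  expect_equal(unname(f0["SmallDependenceEmphasis"]), 0)
  f1 <- gldm_features(gldm_matrix(as_gray_level(lv)), dependence_base = 1)
  expect_equal(unname(f1["SmallDependenceEmphasis"]), 1)
})

test_that("texture features are invariant to level-preserving shifts", {
  set.seed(7)
  img <- matrix(runif(100, 0, 250), 10, 10)
  mk <- matrix(runif(100) > 0.2, 10, 10)
  gl1 <- discretize(img, mk, 25)
  gl2 <- discretize(img + 1000, mk, 25)   # same levels, shifted intensities
  expect_equal(glcm_features(gl1), glcm_features(gl2))
  expect_equal(glszm_features(gl1), glszm_features(gl2))
  expect_equal(glrlm_features(gl1), glrlm_features(gl2))
  expect_equal(gldm_features(gldm_matrix(gl1)),
               gldm_features(gldm_matrix(gl2)))
})

test_that("connected component labelling honours connectivity", {
  m <- matrix(FALSE, 4, 4)
  m[1, 1] <- TRUE; m[2, 2] <- TRUE
  expect_equal(max(label_components(m, 8L)), 1)
  expect_equal(max(label_components(m, 4L)), 2)
  expect_equal(max(label_components(matrix(FALSE, 3, 3))), 0)
})
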