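# Scaling, LASSO-configured RFE, k-NN scoring and score fusion.

test_that("min-max scaling maps the training range onto [0, 1]", {
  tr <- tibble::tibble(case_id = c("a", "b", "c"),
                       f1 = c(2, 4, 6), f2 = c(10, 10, 10))
  sc <- fit_minmax(tr)
  out <- apply_minmax(sc, tr)
  expect_equal(out$f1, c(0, 0.5, 1))
  expect_equal(out$f2, c(0, 0, 0))       # constant feature maps to 0
  te <- tibble::tibble(case_id = "d", f1 = 100, f2 = -5)
  expect_equal(apply_minmax(sc, te)$f1, 1)   # clipped above
  expect_equal(apply_minmax(sc, te)$f2, 0)
  expect_error(apply_minmax(sc, tibble::tibble(f1 = 1)), "names")
  expect_error(fit_minmax(tibble::tibble(case_id = "a")), "empty")
})

test_that("RFE keeps the informative feature among pure noise", {
  set.seed(21)
  n <- 80
  y <- rep(c(0, 1), each = n / 2)
  X <- tibble::as_tibble(matrix(rnorm(n * 11), n,
                                dimnames = list(NULL, sprintf("f%02d", 1:11))))
  X$f01 <- y + rnorm(n, sd = 0.2)
  sel <- select_features_lasso_rfe(X, y, n_target = 3, seed = 5)
  expect_s3_class(sel, "lasso_rfe")
  expect_true("f01" %in% sel$selected)
  expect_length(sel$selected, 3)
  td <- tidy(sel)
  expect_equal(sum(td$selected), 3)
  expect_setequal(td$feature, names(X))
  # deterministic given the same seed
  sel2 <- select_features_lasso_rfe(X, y, n_target = 3, seed = 5)
  expect_identical(sel$selected, sel2$selected)
})

test_that("RFE edge cases: identity when n_target = p, guards otherwise", {
  set.seed(22)
  X <- tibble::as_tibble(matrix(rnorm(40), 20,
                                dimnames = list(NULL, c("a", "b"))))
  y <- rep(c(0, 1), 10)
  sel <- select_features_lasso_rfe(X, y, n_target = 2)
  expect_setequal(sel$selected, c("a", "b"))
  expect_error(select_features_lasso_rfe(X, y, n_target = 5), "exceeds")
  expect_error(select_features_lasso_rfe(X[1:5, ], y[1:5], n_target = 1),
               "at least 10")
})

test_that("RFE on pure noise still returns the requested feature count", {
  set.seed(23)
  X <- tibble::as_tibble(matrix(rnorm(30 * 4), 30,
                                dimnames = list(NULL, sprintf("g%d", 1:4))))
  y <- sample(rep(c(0, 1), 15))
  # the penalty may shrink every coefficient to zero here; the univariate
  # fallback (with its warning) must still deliver n_target features
  sel <- suppressWarnings(select_features_lasso_rfe(X, y, n_target = 2))
  expect_length(sel$selected, 2)
  expect_true(all(sel$selected %in% names(X)))
})

test_that("k-NN scores are positive fractions among the k nearest", {
  # 1D lattice makes neighbourhoods exact
  X <- tibble::tibble(f = c(0, 1, 2, 3, 10, 11, 12, 13))
  y <- c(1, 1, 1, 0, 0, 0, 0, 1)
  model <- fit_knn(X, y, k = 3)
  sc <- predict_scores(model, tibble::tibble(f = c(0.4, 11.4)), "tumor")
  # query 0.4: neighbours {0,1,2} -> labels 1,1,1; query 11.4: {11,12,10}
  expect_equal(sc$score, c(1, 0))
  expect_true(all(sc$source == "tumor"))
  # scores live on the k-quantized lattice
  sc2 <- predict_scores(model, X, "tumor")
  lattice <- (0:3) / 3
  expect_true(all(sc2$score %in% lattice))
  expect_error(fit_knn(X, y, k = 9), "exceeds")
  g <- glance(model)
  expect_equal(g$k, 3L)
  expect_equal(g$n_train, 8L)
})

test_that("exact distance ties break by training-row order", {
  X <- tibble::tibble(f = c(1, 1, 1, 1))
  y <- c(1, 0, 0, 0)
  model <- fit_knn(X, y, k = 1)
  # all four rows are equidistant; the first training row wins
  expect_equal(predict_scores(model, tibble::tibble(f = 1))$score, 1)
})

test_that("fusion rules follow their defining arithmetic", {
  t_sc <- tibble::tibble(case_id = c("a", "b"), score = c(0.2, 0.8),
                         label = c(0L, 1L), source = "tumor")
  v_sc <- tibble::tibble(case_id = c("a", "b"), score = c(0.6, 0.4),
                         label = c(0L, 1L), source = "vessel")
  expect_equal(fuse_scores(t_sc, v_sc, "min")$score, c(0.2, 0.4))
  expect_equal(fuse_scores(t_sc, v_sc, "max")$score, c(0.6, 0.8))
  expect_equal(fuse_scores(t_sc, v_sc, "weighted", 0.25)$score,
               0.25 * c(0.2, 0.8) + 0.75 * c(0.6, 0.4))
  expect_equal(fuse_scores(t_sc, v_sc, "weighted", 1)$score, t_sc$score)
  expect_equal(fuse_scores(t_sc, v_sc, "weighted", 0)$score, v_sc$score)
  expect_error(fuse_scores(t_sc, v_sc, "weighted", 1.5), "w must be")
  bad <- v_sc; bad$case_id <- c("a", "z")
  expect_error(fuse_scores(t_sc, bad, "min"), "case ids")
})

test_that("weighted fusion always lies between the min and max rules", {
  set.seed(30)
  t_sc <- tibble::tibble(case_id = sprintf("c%02d", 1:25),
                         score = runif(25), label = rbinom(25, 1, 0.4),
                         source = "tumor")
  v_sc <- t_sc; v_sc$score <- runif(25); v_sc$source <- "vessel"
  lo <- fuse_scores(t_sc, v_sc, "min")$score
  hi <- fuse_scores(t_sc, v_sc, "max")$score
  for (w in seq(0, 1, by = 0.1)) {
    mid <- fuse_scores(t_sc, v_sc, "weighted", w)$score
    expect_true(all(mid >= lo - 1e-12 & mid <= hi + 1e-12))
  }
})
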