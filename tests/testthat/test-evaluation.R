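# ROC/AUC, DeLong variance and paired test, thresholded metrics, the
# fusion grid and cohort summaries.

test_that("AUC matches hand-computed values on small fixtures", {
  expect_equal(roc_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))$auc, 0.75)
  expect_equal(roc_auc(c(1, 2, 3, 4), c(0, 0, 1, 1))$auc, 1)
  expect_equal(roc_auc(c(4, 3, 2, 1), c(0, 0, 1, 1))$auc, 0)
  expect_equal(roc_auc(c(1, 1, 1, 1), c(0, 0, 1, 1))$auc, 0.5)  # all ties
  expect_error(roc_auc(c(1, 2), c(1, 1)), "both outcome classes")
})

test_that("the mid-rank AUC equals brute-force pair counting", {
  set.seed(41)
  for (i in 1:25) {
    n <- sample(5:30, 1)
    labels <- c(1, 0, rbinom(n - 2, 1, 0.5))
    scores <- round(rnorm(n), sample(0:1, 1))  # rounding induces ties
    expect_equal(roc_auc(scores, labels)$auc, oracle_auc(scores, labels))
  }
})

test_that("negating scores reflects the AUC around one half", {
  set.seed(42)
  labels <- rbinom(40, 1, 0.4); labels[1:2] <- c(0, 1)
  scores <- rnorm(40)
  expect_equal(roc_auc(-scores, labels)$auc, 1 - roc_auc(scores, labels)$auc)
})

test_that("the ROC curve starts at (0,0), ends at (1,1) and is monotone", {
  set.seed(43)
  r <- roc_auc(rnorm(30), c(1, 0, rbinom(28, 1, 0.5)))
  expect_equal(r$curve$tpr[1], 0)
  expect_equal(r$curve$fpr[1], 0)
  expect_equal(utils::tail(r$curve$tpr, 1), 1)
  expect_equal(utils::tail(r$curve$fpr, 1), 1)
  expect_true(all(diff(r$curve$tpr) >= 0) && all(diff(r$curve$fpr) >= 0))
  expect_s3_class(autoplot(r), "ggplot")
  expect_named(glance(r), c("auc", "n_pos", "n_neg"))
})

test_that("DeLong intervals cover the AUC and match pROC", {
  set.seed(44)
  labels <- rep(c(1, 0), c(15, 25))
  scores <- c(rnorm(15, 1), rnorm(25))
  ci <- delong_ci(scores, labels)
  pr <- pROC::roc(labels, scores, quiet = TRUE, direction = "<")
  pci <- as.numeric(pROC::ci.auc(pr, method = "delong"))
  expect_equal(ci$auc, as.numeric(pROC::auc(pr)))
  expect_equal(ci$ci_low, pci[1], tolerance = 1e-9)
  expect_equal(ci$ci_high, pci[3], tolerance = 1e-9)
  expect_true(ci$ci_low <= ci$auc && ci$auc <= ci$ci_high)
  wide <- delong_ci(scores, labels, level = 0.99)
  expect_lt(ci$ci_high - ci$ci_low, wide$ci_high - wide$ci_low)
})

test_that("perfect separation collapses the interval with a warning", {
  expect_warning(ci <- delong_ci(c(1, 2, 3, 10, 11, 12),
                                 c(0, 0, 0, 1, 1, 1)),
                 "degenerate")
  expect_equal(ci$auc, 1)
  expect_equal(ci$variance, 0)
  expect_equal(c(ci$ci_low, ci$ci_high), c(1, 1))
})

test_that("the paired DeLong test matches pROC and is symmetric", {
  set.seed(45)
  labels <- rep(c(1, 0), c(12, 18))
  a <- c(rnorm(12, 1), rnorm(18))
  b <- 0.5 * a + rnorm(30, sd = 0.8)
  res <- delong_test(a, b, labels)
  pr <- pROC::roc.test(pROC::roc(labels, a, quiet = TRUE, direction = "<"),
                       pROC::roc(labels, b, quiet = TRUE, direction = "<"),
                       method = "delong", paired = TRUE)
  expect_equal(res$p_value, pr$p.value, tolerance = 1e-9)
  flipped <- delong_test(b, a, labels)
  expect_equal(res$p_value, flipped$p_value)
  expect_equal(res$auc_diff, -flipped$auc_diff)
})

test_that("comparing identical score sets yields p = 1", {
  set.seed(46)
  labels <- rep(c(1, 0), c(5, 7))
  s <- rnorm(12)
  res <- delong_test(s, s, labels)
  expect_equal(res$p_value, 1)
  expect_equal(res$auc_diff, 0)
  expect_error(delong_test(s, s[1:5], labels), "different cases")
})

test_that("the Youden threshold maximizes sensitivity + specificity - 1", {
  set.seed(47)
  labels <- rbinom(50, 1, 0.4); labels[1:2] <- c(0, 1)
  scores <- rnorm(50) + labels
  thr <- youden_threshold(scores, labels)
  j_at <- function(t) mean(scores[labels == 1] >= t) +
    mean(scores[labels == 0] < t) - 1
  j_all <- vapply(sort(unique(scores)), j_at, numeric(1))
  expect_equal(j_at(thr), max(j_all))
})

test_that("classification metrics recover a designed confusion matrix", {
  labels <- rep(c(1, 1, 0, 0), c(30, 10, 10, 50))
  scores <- rep(c(1, 0, 1, 0), c(30, 10, 10, 50))
  m <- classification_metrics(scores, labels, threshold = 0.5)
  expect_equal(m$accuracy, 0.8)
  expect_equal(m$precision, 30 / 40)
  expect_equal(m$sensitivity, 0.75)
  expect_equal(m$recall, 0.75)
  expect_equal(m$specificity, 50 / 60)
})

test_that("the fusion grid has 11 rules and flags the best one", {
  set.seed(48)
  n <- 40
  lab <- rep(c(1L, 0L), c(15, 25))
  t_sc <- tibble::tibble(case_id = sprintf("c%02d", 1:n),
                         score = runif(n) + 0.3 * lab, label = lab,
                         source = "tumor")
  v_sc <- t_sc; v_sc$score <- runif(n) + 0.2 * lab; v_sc$source <- "vessel"
  grid <- fusion_weight_grid(t_sc, v_sc)
  expect_equal(nrow(grid), 11)
  expect_equal(grid$rule, c("min", "max", rep("weighted", 9)))
  expect_equal(grid$w[3:11], seq(0.1, 0.9, by = 0.1))
  expect_equal(sum(grid$best), 1)
  expect_equal(grid$auc[grid$best], max(grid$auc))
  # each rule's AUC matches a direct fuse + score computation
  direct <- roc_auc(fuse_scores(t_sc, v_sc, "weighted", 0.5))$auc
  expect_equal(grid$auc[grid$rule == "weighted" & grid$w == 0.5], direct)
})

test_that("cohort prevalence reproduces per-cohort and pooled rates", {
  tab <- tibble::tibble(
    label = c(rep(1, 4), rep(0, 6), rep(1, 3), rep(0, 2)),
    cohort = rep(c("train", "validation"), c(10, 5))
  )
  out <- cohort_prevalence(tab)
  expect_equal(out$percent[out$cohort == "train"], 40)
  expect_equal(out$percent[out$cohort == "validation"], 60)
  expect_equal(out$n[out$cohort == "pooled"], 15)
  expect_equal(out$percent[out$cohort == "pooled"], round(100 * 7 / 15, 1))
  expect_error(cohort_prevalence(tab[0, ]), "empty")
})
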