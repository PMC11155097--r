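# ROC/AUC with DeLong variance and paired comparison, thresholded
# classification metrics, the fusion-weight grid and cohort summaries.

.check_scores <- function(scores, labels) {
  stopifnot(length(scores) == length(labels), all(labels %in% c(0, 1)))
  if (length(unique(labels)) < 2) {
    stop("both outcome classes must be present", call. = FALSE)
  }
}

#' ROC curve and AUC
#'
#' AUC via the mid-rank (Mann-Whitney) statistic
#' `(R_pos - n_pos (n_pos + 1) / 2) / (n_pos n_neg)`, equivalent to
#' pair counting with half-credit for ties.
#'
#' @param scores Numeric prediction scores (higher = more positive), or a
#'   score tibble from [predict_scores()].
#' @param labels Binary labels (ignored when `scores` is a score tibble).
#' @return A `roc_result`: `auc`, `n_pos`, `n_neg` and a `curve` tibble of
#'   `(threshold, fpr, tpr)` pairs.
#' @export
roc_auc <- function(scores, labels = NULL) {
  if (is.data.frame(scores)) {
    labels <- scores$label
    scores <- scores$score
  }
  .check_scores(scores, labels)
  n_pos <- sum(labels == 1); n_neg <- sum(labels == 0)
  r <- rank(scores)  # mid-ranks for ties
  auc <- (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  curve <- tibble::tibble(
    threshold = thr,
    tpr = vapply(thr, function(t) mean(scores[labels == 1] >= t), numeric(1)),
    fpr = vapply(thr, function(t) mean(scores[labels == 0] >= t), numeric(1))
  )
  structure(list(auc = auc, n_pos = n_pos, n_neg = n_neg, curve = curve),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result: AUC %.3f (%d pos / %d neg)>\n",
              x$auc, x$n_pos, x$n_neg))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.roc_result <- function(x, ...) x$curve

#' @exportS3Method generics::glance
glance.roc_result <- function(x, ...) {
  tibble::tibble(auc = x$auc, n_pos = x$n_pos, n_neg = x$n_neg)
}

#' @exportS3Method ggplot2::autoplot
autoplot.roc_result <- function(object, ...) {
  ggplot2::ggplot(object$curve, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "False-positive rate", y = "True-positive rate",
                  title = sprintf("ROC curve (AUC = %.2f)", object$auc)) +
    ggplot2::theme_minimal()
}

# DeLong structural components: V10 (per positive) and V01 (per negative)
.delong_components <- function(scores, labels) {
  x <- scores[labels == 1]
  y <- scores[labels == 0]
  psi <- outer(x, y, function(a, b) (a > b) + 0.5 * (a == b))
  list(v10 = rowMeans(psi), v01 = colMeans(psi), auc = mean(psi))
}

#' DeLong AUC variance and confidence interval
#'
#' Nonparametric structural-component variance of the AUC with a normal
#' 95% (or `level`) interval truncated to `[0, 1]`.
#'
#' @inheritParams roc_auc
#' @param level Confidence level (default 0.95).
#' @return A one-row tibble: `auc`, `variance`, `ci_low`, `ci_high`.
#' @export
delong_ci <- function(scores, labels = NULL, level = 0.95) {
  if (is.data.frame(scores)) {
    labels <- scores$label
    scores <- scores$score
  }
  .check_scores(scores, labels)
  if (sum(labels == 1) < 2 || sum(labels == 0) < 2) {
    stop("delong_ci: need at least 2 cases per class", call. = FALSE)
  }
  comp <- .delong_components(scores, labels)
  v <- var(comp$v10) / length(comp$v10) + var(comp$v01) / length(comp$v01)
  if (v == 0 && comp$auc %in% c(0, 1)) {
    warning("delong_ci: degenerate separation; interval collapses to the point")
  }
  z <- qnorm(1 - (1 - level) / 2)
  tibble::tibble(
    auc = comp$auc, variance = v,
    ci_low = max(0, comp$auc - z * sqrt(v)),
    ci_high = min(1, comp$auc + z * sqrt(v))
  )
}

#' Paired DeLong test for two correlated AUCs
#'
#' Z-test on the AUC difference of two score sets over the same cases,
#' using the DeLong covariance of structural components; two-sided p-value.
#' A zero-variance difference with equal AUCs yields p = 1 by convention.
#'
#' @param scores_a,scores_b Numeric score vectors over the same cases, or
#'   score tibbles with matching `case_id` sequences.
#' @param labels Binary labels (taken from `scores_a` when tibbles given).
#' @return A one-row tibble: `auc_a`, `auc_b`, `auc_diff`, `variance`, `z`,
#'   `p_value`.
#' @export
delong_test <- function(scores_a, scores_b, labels = NULL) {
  if (is.data.frame(scores_a)) {
    if (is.data.frame(scores_b) &&
        !identical(scores_a$case_id, scores_b$case_id)) {
      stop("delong_test: score sets cover different cases", call. = FALSE)
    }
    labels <- scores_a$label
    scores_a <- scores_a$score
  }
  if (is.data.frame(scores_b)) scores_b <- scores_b$score
  if (length(scores_a) != length(scores_b)) {
    stop("delong_test: score sets cover different cases", call. = FALSE)
  }
  .check_scores(scores_a, labels)
  ca <- .delong_components(scores_a, labels)
  cb <- .delong_components(scores_b, labels)
  m <- length(ca$v10); n <- length(ca$v01)
  s10 <- stats::cov(cbind(ca$v10, cb$v10))
  s01 <- stats::cov(cbind(ca$v01, cb$v01))
  v <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / m +
       (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n
  d <- ca$auc - cb$auc
  if (v <= 0) {
    z <- if (d == 0) 0 else sign(d) * Inf
    p <- if (d == 0) 1 else 0
  } else {
    z <- d / sqrt(v)
    p <- 2 * pnorm(-abs(z))
  }
  tibble::tibble(auc_a = ca$auc, auc_b = cb$auc, auc_diff = d,
                 variance = max(v, 0), z = z, p_value = p)
}

#' Youden-index threshold of a score set
#'
#' The finite threshold maximizing sensitivity + specificity - 1, with
#' prediction positive at `score >= threshold`. Intended to be fitted on
#' the training score set and carried to validation sets.
#'
#' @inheritParams roc_auc
#' @return A single numeric threshold.
#' @export
youden_threshold <- function(scores, labels = NULL) {
  if (is.data.frame(scores)) {
    labels <- scores$label
    scores <- scores$score
  }
  .check_scores(scores, labels)
  cand <- sort(unique(scores))
  j <- vapply(cand, function(t) {
    mean(scores[labels == 1] >= t) + mean(scores[labels == 0] < t) - 1
  }, numeric(1))
  cand[which.max(j)]
}

#' Thresholded classification metrics
#'
#' Accuracy, precision, recall/sensitivity and specificity at a fixed
#' threshold (predict positive at `score >= threshold`). Fit the threshold
#' with [youden_threshold()] on the training set and pass it here for
#' validation sets.
#'
#' @inheritParams roc_auc
#' @param threshold Decision threshold; default fits the Youden threshold
#'   on the scores themselves.
#' @return A one-row tibble: `threshold`, `accuracy`, `precision`,
#'   `recall`, `sensitivity`, `specificity`.
#' @export
classification_metrics <- function(scores, labels = NULL, threshold = NULL) {
  if (is.data.frame(scores)) {
    labels <- scores$label
    scores <- scores$score
  }
  .check_scores(scores, labels)
  if (is.null(threshold)) threshold <- youden_threshold(scores, labels)
  if (!is.finite(threshold)) {
    stop("classification_metrics: no finite threshold", call. = FALSE)
  }
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1 & labels == 1); fp <- sum(pred == 1 & labels == 0)
  tn <- sum(pred == 0 & labels == 0); fn <- sum(pred == 0 & labels == 1)
  sens <- tp / (tp + fn)
  tibble::tibble(
    threshold = threshold,
    accuracy = (tp + tn) / length(labels),
    precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
    recall = sens,
    sensitivity = sens,
    specificity = tn / (tn + fp)
  )
}

#' AUC grid over score-fusion rules
#'
#' Evaluates minimum, maximum and the nine weighted-average rules
#' (`w` on the tumor score from 0.1 to 0.9) on aligned tumor and vessel
#' score sets, with DeLong 95% intervals, and flags the argmax row.
#'
#' @param tumor,vessel Aligned score tibbles (same `case_id` order, labels
#'   on `tumor`).
#' @return An 11-row tibble: `rule`, `w`, `auc`, `ci_low`, `ci_high`,
#'   `best`.
#' @export
fusion_weight_grid <- function(tumor, vessel) {
  rules <- c(list(list(rule = "min", w = NA_real_),
                  list(rule = "max", w = NA_real_)),
             lapply(seq(0.1, 0.9, by = 0.1),
                    function(w) list(rule = "weighted", w = w)))
  rows <- purrr::map(rules, function(r) {
    fused <- if (r$rule == "weighted") {
      fuse_scores(tumor, vessel, "weighted", r$w)
    } else {
      fuse_scores(tumor, vessel, r$rule)
    }
    ci <- delong_ci(fused)
    tibble::tibble(rule = r$rule, w = r$w, auc = ci$auc,
                   ci_low = ci$ci_low, ci_high = ci$ci_high)
  })
  out <- dplyr::bind_rows(rows)
  dplyr::mutate(out, best = seq_len(dplyr::n()) == which.max(.data$auc))
}

#' Cohort prevalence summary
#'
#' Positive counts and percentages per cohort and pooled, with percentages
#' rounded to one decimal.
#'
#' @param table Tibble with `label` (0/1) and `cohort` columns, e.g. from
#'   [generate_cohort()].
#' @return Tibble: `cohort`, `n`, `n_positive`, `percent`.
#' @export
cohort_prevalence <- function(table) {
  stopifnot(all(table$label %in% c(0, 1)))
  if (nrow(table) == 0) stop("cohort_prevalence: empty cohort", call. = FALSE)
  per <- table |>
    dplyr::group_by(cohort = .data$cohort) |>
    dplyr::summarise(n = dplyr::n(), n_positive = sum(.data$label),
                     .groups = "drop")
  pooled <- tibble::tibble(cohort = "pooled", n = nrow(table),
                           n_positive = sum(table$label))
  dplyr::bind_rows(per, pooled) |>
    dplyr::mutate(percent = round(100 * .data$n_positive / .data$n, 1))
}
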