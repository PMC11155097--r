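# Feature scaling, LASSO-configured recursive feature elimination, k-NN
# scoring and tumor/vessel score fusion. Feature tables are wide tibbles
# with a `case_id` column plus one numeric column per feature.

.feature_cols <- function(df) setdiff(names(df), c("case_id", "label", "cohort"))

#' Fit a min-max scaler on training features
#'
#' @param train Wide feature tibble (a `case_id` column is ignored).
#' @return A `minmax_scaler` with per-feature `min` and `max`.
#' @export
fit_minmax <- function(train) {
  cols <- .feature_cols(train)
  if (length(cols) == 0 || nrow(train) == 0) {
    stop("fit_minmax: empty training matrix", call. = FALSE)
  }
  X <- as.matrix(train[cols])
  structure(list(
    feature = cols,
    min = apply(X, 2, min),
    max = apply(X, 2, max)
  ), class = "minmax_scaler")
}

#' Apply a fitted min-max scaler
#'
#' `(x - min) / (max - min)` per feature; values outside the training range
#' are clipped to `[0, 1]` and constant training features map to 0.
#'
#' @param scaler A `minmax_scaler` from [fit_minmax()].
#' @param df Feature tibble containing all fitted features.
#' @return The tibble with feature columns scaled into `[0, 1]`.
#' @export
apply_minmax <- function(scaler, df) {
  stopifnot(inherits(scaler, "minmax_scaler"))
  if (!all(scaler$feature %in% names(df))) {
    stop("apply_minmax: feature names do not match the fitted scaler",
         call. = FALSE)
  }
  out <- df
  rng <- scaler$max - scaler$min
  for (j in seq_along(scaler$feature)) {
    f <- scaler$feature[j]
    v <- if (rng[j] > 0) (df[[f]] - scaler$min[j]) / rng[j] else rep(0, nrow(df))
    out[[f]] <- unname(pmin(pmax(v, 0), 1))
  }
  out
}

#' LASSO-configured recursive feature elimination
#'
#' Repeatedly fits an L1-penalized (LASSO) linear model to the binary
#' outcome, with the penalty chosen by 5-fold cross-validation on the
#' training rows only, and drops the feature with the smallest absolute
#' coefficient until `n_target` remain. If every coefficient shrinks to
#' zero at some step, the feature with the weakest univariate association
#' is dropped instead (with a warning). Deterministic for a fixed `seed`
#' (which fixes the CV fold assignment).
#'
#' @param X Wide feature tibble (training rows only; `case_id`/`label`/
#'   `cohort` columns are ignored as features).
#' @param y Binary labels, one per row of `X`.
#' @param n_target Number of features to retain (default 10).
#' @param step Features dropped per iteration (default 1).
#' @param seed Integer seed for the CV fold assignment.
#' @return A `lasso_rfe` object: `selected` (feature names, final model
#'   order), `ranking` (tibble of all features with elimination rank; rank
#'   1 = eliminated last or kept), `lasso_alpha` (penalty of the final CV
#'   fit), `n_selected`.
#' @export
select_features_lasso_rfe <- function(X, y, n_target = 10L, step = 1L,
                                      seed = 1L) {
  cols <- .feature_cols(X)
  if (n_target > length(cols)) {
    stop("select_features_lasso_rfe: n_target exceeds the number of features",
         call. = FALSE)
  }
  if (nrow(X) < 10) {
    stop("select_features_lasso_rfe: need at least 10 training rows",
         call. = FALSE)
  }
  y <- as.numeric(y)
  foldid <- withr::with_seed(seed, sample(rep_len(1:5, nrow(X))))
  active <- cols
  eliminated <- character(0)
  lambda_last <- NA_real_
  while (length(active) > n_target) {
    M <- as.matrix(X[active])
    cv <- glmnet::cv.glmnet(M, y, alpha = 1, family = "gaussian",
                            foldid = foldid, standardize = FALSE)
    lambda_last <- cv$lambda.min
    co <- as.numeric(stats::coef(cv, s = "lambda.min"))[-1]
    if (all(co == 0)) {
      warning("select_features_lasso_rfe: all coefficients zero; dropping by univariate association")
      assoc <- abs(apply(M, 2, function(v) {
        if (stats::sd(v) == 0) 0 else stats::cor(v, y)
      }))
      ord <- order(assoc)
    } else {
      ord <- order(abs(co))
    }
    n_drop <- min(step, length(active) - n_target)
    drop <- active[ord[seq_len(n_drop)]]
    eliminated <- c(eliminated, drop)
    active <- setdiff(active, drop)
  }
  ranking <- tibble::tibble(
    feature = c(active, rev(eliminated)),
    rank = c(rep(1L, length(active)), seq_len(length(eliminated)) + 1L)
  )
  structure(list(
    selected = active,
    ranking = ranking,
    lasso_alpha = lambda_last,
    n_selected = length(active)
  ), class = "lasso_rfe")
}

#' @export
print.lasso_rfe <- function(x, ...) {
  cat(sprintf("<lasso_rfe: %d features selected (lambda = %.4g)>\n",
              x$n_selected, x$lasso_alpha))
  cat(strwrap(paste(x$selected, collapse = ", "), indent = 2, exdent = 2),
      sep = "\n")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.lasso_rfe <- function(x, ...) {
  dplyr::mutate(x$ranking, selected = .data$rank == 1L)
}

#' Fit a k-nearest-neighbour scorer
#'
#' @param X Wide feature tibble of (scaled) training features.
#' @param y Binary training labels.
#' @param k Number of neighbours (default 5); must not exceed the number
#'   of training rows.
#' @param case_ids Optional training case ids.
#' @return A `knn_model`.
#' @export
fit_knn <- function(X, y, k = 5L, case_ids = NULL) {
  cols <- .feature_cols(X)
  M <- as.matrix(X[cols])
  if (k > nrow(M)) stop("fit_knn: k exceeds the number of training rows",
                        call. = FALSE)
  stopifnot(all(y %in% c(0, 1)))
  structure(list(X = M, y = as.integer(y), k = as.integer(k),
                 feature = cols, case_ids = case_ids,
                 metric = "euclidean"),
            class = "knn_model")
}

#' Predict k-NN scores
#'
#' The score of a query is the fraction of positive labels among its `k`
#' nearest training rows (Euclidean distance, uniform weights); exact
#' distance ties are broken by training-row order.
#'
#' @param model A `knn_model` from [fit_knn()].
#' @param newdata Feature tibble containing the fitted features; a
#'   `case_id` column is carried through, and a `label` column (if present)
#'   is attached to the output.
#' @param source Score provenance tag (`"tumor"`, `"vessel"` or `"fused"`).
#' @return A score tibble: `case_id`, `score`, `label` (NA if unknown),
#'   `source`.
#' @export
predict_scores <- function(model, newdata, source = "tumor") {
  stopifnot(inherits(model, "knn_model"))
  if (!all(model$feature %in% names(newdata))) {
    stop("predict_scores: newdata lacks fitted features", call. = FALSE)
  }
  Q <- as.matrix(newdata[model$feature])
  scores <- vapply(seq_len(nrow(Q)), function(i) {
    d <- sqrt(colSums((t(model$X) - Q[i, ])^2))
    nn <- order(d, seq_along(d))[seq_len(model$k)]
    mean(model$y[nn])
  }, numeric(1))
  tibble::tibble(
    case_id = if ("case_id" %in% names(newdata)) newdata$case_id
              else sprintf("case_%03d", seq_len(nrow(Q))),
    score = scores,
    label = if ("label" %in% names(newdata)) as.integer(newdata$label)
            else NA_integer_,
    source = source
  )
}

#' @exportS3Method generics::glance
glance.knn_model <- function(x, ...) {
  tibble::tibble(k = x$k, n_train = nrow(x$X), n_features = length(x$feature),
                 prevalence = mean(x$y), metric = x$metric)
}

#' Fuse tumor and vessel prediction scores
#'
#' Element-wise minimum, maximum, or weighted average
#' `w * tumor + (1 - w) * vessel` of two aligned score sets.
#'
#' @param tumor,vessel Score tibbles from [predict_scores()], with matching
#'   `case_id` sequences.
#' @param method `"min"`, `"max"` or `"weighted"`.
#' @param w Weight on the tumor score for `method = "weighted"`, in `[0,1]`.
#' @return A score tibble with `source = "fused"`.
#' @export
fuse_scores <- function(tumor, vessel, method = c("min", "max", "weighted"),
                        w = 0.5) {
  method <- match.arg(method)
  if (!identical(tumor$case_id, vessel$case_id)) {
    stop("fuse_scores: case ids do not match", call. = FALSE)
  }
  if (method == "weighted" && (w < 0 || w > 1)) {
    stop("fuse_scores: w must be in [0, 1]", call. = FALSE)
  }
  s <- switch(method,
    min = pmin(tumor$score, vessel$score),
    max = pmax(tumor$score, vessel$score),
    weighted = w * tumor$score + (1 - w) * vessel$score
  )
  tibble::tibble(case_id = tumor$case_id, score = s, label = tumor$label,
                 source = "fused")
}
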