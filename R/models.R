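#' F-beta score
#'
#' `(1 + beta^2) * P * R / (beta^2 * P + R)`: the weighted harmonic mean of
#' precision and recall. `beta = 1` is the balanced F1; `beta = 2` weighs
#' recall (sensitivity) four times as heavily as precision, penalizing
#' missed MAS diagnoses. Vectorized over precision/recall.
#'
#' @param precision,recall Values in `[0, 1]`.
#' @param beta Positive weight; default 1.
#' @return The F-beta score; 0 (with a warning) where precision and recall
#'   are both 0.
#' @export
#' @examples
#' f_beta(0.5, 1.0, beta = 2)  # 0.8333...
f_beta <- function(precision, recall, beta = 1) {
  stopifnot(beta > 0)
  if (any(precision < 0 | precision > 1 | recall < 0 | recall > 1, na.rm = TRUE)) {
    stop("precision and recall must lie in [0, 1]")
  }
  both_zero <- precision == 0 & recall == 0
  if (any(both_zero, na.rm = TRUE)) {
    warning("precision and recall both zero: F-beta defined as 0")
  }
  ifelse(both_zero, 0,
         (1 + beta^2) * precision * recall / (beta^2 * precision + recall))
}

#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) AUC: the probability that a random positive
#' outscores a random negative, ties counted one-half. Invariant under any
#' strictly monotone transform of the scores.
#'
#' @param scores Numeric classifier scores, higher = more positive.
#' @param labels Binary labels (0/1 or logical).
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  y <- as.integer(labels)
  stopifnot(length(scores) == length(y))
  if (any(is.na(scores)) || any(is.na(y))) stop("NA in scores or labels")
  n1 <- sum(y == 1)
  n0 <- sum(y == 0)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present")
  r <- rank(scores)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Confusion-based evaluation metrics
#'
#' @param scores Positive-class probabilities or scores.
#' @param labels Binary labels.
#' @param threshold Decision cutoff (predict positive when
#'   `score >= threshold`); default 0.5.
#' @return A one-row data frame: auc, f1, f2, tp, fp, tn, fn, threshold.
#' @export
eval_metrics <- function(scores, labels, threshold = 0.5) {
  y <- as.integer(labels)
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1 & y == 1)
  fp <- sum(pred == 1 & y == 0)
  tn <- sum(pred == 0 & y == 0)
  fn <- sum(pred == 0 & y == 1)
  precision <- if (tp + fp == 0) 0 else tp / (tp + fp)
  recall <- if (tp + fn == 0) 0 else tp / (tp + fn)
  f1 <- if (precision == 0 && recall == 0) 0 else
    f_beta(precision, recall, 1)
  f2 <- if (precision == 0 && recall == 0) 0 else
    f_beta(precision, recall, 2)
  data.frame(auc = roc_auc(scores, y), f1 = f1, f2 = f2,
             tp = tp, fp = fp, tn = tn, fn = fn, threshold = threshold)
}

default_grid <- function(family) {
  switch(family,
    l2_logistic = list(lambda = c(0.001, 0.01, 0.1, 1)),
    random_forest = list(num.trees = 300L, mtry = c(2L, 4L)),
    svm = list(cost = c(0.1, 1, 10)),
    gradient_boosting = list(eta = c(0.1, 0.3), max_depth = c(2L, 4L),
                             nrounds = 100L),
    stop(sprintf("unknown model family '%s'", family))
  )
}

#' Model family specification with a hyperparameter grid
#'
#' @param family One of `"l2_logistic"` (ridge-penalized logistic
#'   regression), `"random_forest"`, `"svm"` (RBF kernel, Platt-calibrated
#'   probabilities), `"gradient_boosting"` (xgboost).
#' @param grid Named list, one entry per tunable parameter with its
#'   candidate values; defaults per family are used when `NULL`.
#' @param seed Seed for stochastic fits and inner CV folds.
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(family = c("l2_logistic", "random_forest", "svm",
                                  "gradient_boosting"),
                       grid = NULL, seed = 1L) {
  family <- match.arg(family)
  grid <- grid %||% default_grid(family)
  if (!length(grid) || any(!vapply(grid, length, integer(1)))) {
    empty <- names(grid)[vapply(grid, length, integer(1)) == 0]
    stop("invalid grid: empty candidate set for ",
         paste(empty, collapse = ", "))
  }
  known <- names(default_grid(family))
  unknown <- setdiff(names(grid), known)
  if (length(unknown)) {
    stop(sprintf("invalid grid for family '%s': unknown parameter(s) %s",
                 family, paste(unknown, collapse = ", ")))
  }
  structure(list(family = family, grid = grid, seed = as.integer(seed)),
            class = "model_spec")
}

fit_one <- function(x, y, family, params, seed) {
  switch(family,
    l2_logistic = {
      fit <- glmnet::glmnet(x, y, family = "binomial", alpha = 0,
                            standardize = FALSE)
      list(fit = fit, lambda = params$lambda)
    },
    random_forest = {
      d <- as.data.frame(x)
      d$.y <- factor(y, levels = c(0, 1))
      ranger::ranger(.y ~ ., data = d, probability = TRUE,
                     num.trees = params$num.trees %||% 300L,
                     mtry = min(params$mtry %||% floor(sqrt(ncol(x))), ncol(x)),
                     seed = seed, num.threads = 1)
    },
    svm = {
      withr::with_seed(seed,
        e1071::svm(x, factor(y, levels = c(0, 1)), kernel = "radial",
                   cost = params$cost %||% 1, probability = TRUE))
    },
    gradient_boosting = {
      dtrain <- xgboost::xgb.DMatrix(x, label = y, nthread = 1)
      withr::with_seed(seed,
        xgboost::xgb.train(
          params = list(objective = "binary:logistic",
                        eta = params$eta %||% 0.3,
                        max_depth = params$max_depth %||% 4L,
                        nthread = 1),
          data = dtrain,
          nrounds = params$nrounds %||% 100L,
          verbose = 0))
    }
  )
}

predict_prob_one <- function(fit, family, x) {
  switch(family,
    l2_logistic = as.numeric(
      stats::predict(fit$fit, newx = x, s = fit$lambda, type = "response")),
    random_forest = {
      p <- stats::predict(fit, as.data.frame(x))$predictions
      as.numeric(p[, "1"])
    },
    svm = {
      p <- attr(stats::predict(fit, x, probability = TRUE), "probabilities")
      as.numeric(p[, "1"])
    },
    gradient_boosting = as.numeric(
      stats::predict(fit, xgboost::xgb.DMatrix(x, nthread = 1)))
  )
}

cohort_xy <- function(cohort) {
  x <- as.matrix(cohort$data)
  if (any(is.na(x))) stop("cohort contains missing values; impute first")
  list(x = x, y = cohort$label)
}

#' Grid search over hyperparameters with stratified inner CV
#'
#' Evaluates every grid configuration by stratified k-fold cross-validation
#' on the training cohort (mean pooled AUC), then refits the best
#' configuration on all training data. Ties keep the first configuration in
#' grid order. The L2 penalty is always active for the logistic family.
#'
#' @param train Training `mas_cohort` (complete, both classes).
#' @param spec A [model_spec()].
#' @param inner_folds Inner CV folds; default 5.
#' @return An object of class `mas_model`: `family`, `params` (chosen),
#'   `fit`, `cv_results` (grid with mean CV AUC), `features`.
#' @export
grid_search_fit <- function(train, spec, inner_folds = 5L) {
  xy <- cohort_xy(train)
  if (length(unique(xy$y)) < 2L) stop("training cohort must contain both classes")
  grid <- expand.grid(spec$grid, KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  foldid <- stratified_folds(xy$y, inner_folds, spec$seed)
  cv_auc <- vapply(seq_len(nrow(grid)), function(g) {
    params <- as.list(grid[g, , drop = FALSE])
    pooled <- numeric(length(xy$y))
    for (k in seq_len(inner_folds)) {
      tr <- foldid != k
      fit <- fit_one(xy$x[tr, , drop = FALSE], xy$y[tr], spec$family,
                     params, spec$seed + k)
      pooled[!tr] <- predict_prob_one(fit, spec$family,
                                      xy$x[!tr, , drop = FALSE])
    }
    roc_auc(pooled, xy$y)
  }, numeric(1))
  best <- which.max(cv_auc)
  params <- as.list(grid[best, , drop = FALSE])
  fit <- fit_one(xy$x, xy$y, spec$family, params, spec$seed)
  structure(
    list(family = spec$family, params = params, fit = fit, spec = spec,
         cv_results = cbind(grid, cv_auc = cv_auc),
         features = colnames(xy$x)),
    class = "mas_model"
  )
}

#' @export
print.mas_model <- function(x, ...) {
  p <- paste(sprintf("%s=%s", names(x$params), unlist(x$params)),
             collapse = ", ")
  cat(sprintf("<mas_model> %s (%s), %d features\n", x$family, p,
              length(x$features)))
  invisible(x)
}

#' Predict positive-class probabilities
#'
#' @param object A `mas_model`.
#' @param cohort A `mas_cohort` (or numeric matrix) with the model's
#'   features.
#' @param ... Unused.
#' @return Numeric vector of MAS probabilities.
#' @export
predict.mas_model <- function(object, cohort, ...) {
  x <- if (inherits(cohort, "mas_cohort")) {
    as.matrix(cohort$data[, object$features, drop = FALSE])
  } else {
    as.matrix(cohort)[, object$features, drop = FALSE]
  }
  predict_prob_one(object$fit, object$family, x)
}

#' Leave-one-out validation
#'
#' Refits the model family n times, each fold holding out one patient, and
#' pools the n out-of-fold predictions into one metric set. Hyperparameters
#' are fixed beforehand: either taken from a fitted `mas_model` or chosen
#' once by [grid_search_fit()] on the full training cohort. A fold whose
#' fit fails is recorded, dropped from the pool with a warning, and the
#' metrics are computed on the remaining folds.
#'
#' @param train Training `mas_cohort` with at least 10 patients.
#' @param spec A [model_spec()] or fitted `mas_model`.
#' @param threshold Decision cutoff for confusion metrics; default 0.5.
#' @return A list: `metrics` (one-row data frame), `predictions`
#'   (out-of-fold probabilities), `failed_folds`.
#' @export
loo_validate <- function(train, spec, threshold = 0.5) {
  xy <- cohort_xy(train)
  n <- length(xy$y)
  if (n < 10L) stop("leave-one-out validation needs n >= 10")
  if (inherits(spec, "mas_model")) {
    family <- spec$family; params <- spec$params; seed <- spec$spec$seed
  } else {
    fitted <- grid_search_fit(train, spec)
    family <- fitted$family; params <- fitted$params; seed <- spec$seed
  }
  preds <- rep(NA_real_, n)
  failed <- integer(0)
  for (i in seq_len(n)) {
    res <- tryCatch({
      fit <- fit_one(xy$x[-i, , drop = FALSE], xy$y[-i], family, params,
                     seed)
      predict_prob_one(fit, family, xy$x[i, , drop = FALSE])
    }, error = function(e) NA_real_)
    if (is.na(res)) failed <- c(failed, i) else preds[i] <- res
  }
  if (length(failed)) {
    warning(sprintf("%d leave-one-out fold(s) failed to fit; metrics use the remaining %d",
                    length(failed), n - length(failed)))
  }
  ok <- !is.na(preds)
  list(metrics = eval_metrics(preds[ok], xy$y[ok], threshold),
       predictions = preds, failed_folds = failed)
}

#' Evaluate fitted models across data splits
#'
#' @param models Named list of `mas_model` objects.
#' @param splits Named list of `mas_cohort`s sharing the training schema
#'   (already transformed with the training Z-score model).
#' @param threshold Decision cutoff; default 0.5.
#' @return A data frame with one row per (model, split): model, split, auc,
#'   f1, f2 and confusion counts.
#' @export
evaluate_suite <- function(models, splits, threshold = 0.5) {
  rows <- list()
  for (mn in names(models)) {
    need <- models[[mn]]$features
    for (sn in names(splits)) {
      have <- colnames(splits[[sn]]$data)
      if (length(setdiff(need, have))) {
        stop(sprintf("split '%s' lacks feature(s) required by model '%s': %s",
                     sn, mn, paste(setdiff(need, have), collapse = ", ")))
      }
      p <- predict(models[[mn]], splits[[sn]])
      m <- eval_metrics(p, splits[[sn]]$label, threshold)
      rows[[length(rows) + 1L]] <- cbind(
        data.frame(model = mn, split = sn), m)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
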