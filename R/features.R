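#' Pearson correlation filter
#'
#' Removes one member of every feature pair whose absolute Pearson
#' correlation reaches `r_threshold`, iterating from the most correlated
#' pair downwards. Within a pair, the member with the weaker absolute
#' point-biserial correlation to the diagnosis label is removed; exact ties
#' keep the alphabetically earlier name. Constant features (undefined
#' correlation) are dropped first with a warning.
#'
#' @param cohort A complete `mas_cohort`.
#' @param r_threshold Absolute-correlation cutoff; default 0.8.
#' @return A list: `cohort` (reduced), `report` (data frame of removals:
#'   `feature`, `r`, `kept_partner`; constant drops have `NA` partners).
#' @export
pearson_filter <- function(cohort, r_threshold = 0.8) {
  df <- cohort$data
  y <- cohort$label
  removed <- data.frame(feature = character(), r = numeric(),
                        kept_partner = character())
  sds <- vapply(df, stats::sd, numeric(1))
  const <- names(df)[sds == 0 | !is.finite(sds)]
  if (length(const)) {
    warning("dropping constant feature(s) with undefined correlation: ",
            paste(const, collapse = ", "))
    removed <- rbind(removed, data.frame(feature = const, r = NA_real_,
                                         kept_partner = NA_character_))
    df <- df[, setdiff(names(df), const), drop = FALSE]
  }
  repeat {
    if (ncol(df) < 2L) break
    cm <- abs(stats::cor(df))
    diag(cm) <- 0
    if (max(cm) < r_threshold) break
    idx <- which(cm == max(cm), arr.ind = TRUE)[1L, ]
    pair <- sort(colnames(cm)[idx])  # ascending-name order for determinism
    lab_cor <- abs(vapply(pair, function(nm) stats::cor(df[[nm]], y), numeric(1)))
    drop <- if (lab_cor[1] == lab_cor[2]) pair[2] else pair[which.min(lab_cor)]
    keep <- setdiff(pair, drop)
    removed <- rbind(removed, data.frame(feature = drop, r = max(cm),
                                         kept_partner = keep))
    df <- df[, setdiff(names(df), drop), drop = FALSE]
  }
  cohort <- select_features(cohort, names(df))
  list(cohort = cohort, report = removed)
}

vif_values <- function(df) {
  vapply(names(df), function(nm) {
    others <- setdiff(names(df), nm)
    fit <- stats::lm(stats::reformulate(sprintf("`%s`", others),
                                        response = sprintf("`%s`", nm)),
                     data = df)
    # exact dependence triggers a "perfect fit" warning; it is the case we
    # detect and report as an infinite VIF, so keep it quiet here
    r2 <- suppressWarnings(summary(fit)$r.squared)
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
}

#' Variance-inflation-factor filter
#'
#' Iteratively removes the feature with the largest VIF (computed from the
#' auxiliary regression of each feature on all others) until every VIF is
#' below `vif_threshold`. Exact linear dependence yields an infinite VIF and
#' is resolved deterministically (alphabetically earliest among the tied
#' maxima is removed).
#'
#' @param cohort A complete `mas_cohort` with at least two features.
#' @param vif_threshold Cutoff; default 10.
#' @return A list: `cohort` (reduced), `report` (removals with their VIF at
#'   removal), `vif` (final per-feature VIFs).
#' @export
vif_filter <- function(cohort, vif_threshold = 10) {
  df <- cohort$data
  if (ncol(df) < 2L) stop("vif_filter needs at least two features")
  removed <- data.frame(feature = character(), vif = numeric())
  repeat {
    v <- vif_values(df)
    if (max(v) < vif_threshold) break
    worst <- names(v)[v == max(v)]
    drop <- sort(worst)[1L]
    removed <- rbind(removed, data.frame(feature = drop, vif = max(v)))
    df <- df[, setdiff(names(df), drop), drop = FALSE]
    if (ncol(df) < 2L) break
  }
  cohort <- select_features(cohort, names(df))
  final_vif <- if (ncol(df) >= 2L) vif_values(df) else
    stats::setNames(rep(NA_real_, ncol(df)), names(df))
  list(cohort = cohort, report = removed, vif = final_vif)
}

#' Replace raw haematology/transaminase columns with composites
#'
#' Builds the two clinically defined composite predictors and drops their
#' five source analytes: `pancytopenia` is 1 iff haemoglobin, platelets and
#' white cells are all below their lower normal limits (three-lineage
#' conjunction); `liver_damage` is 1 iff ALT or AST exceeds its upper normal
#' limit (transaminase disjunction).
#'
#' @param cohort A `mas_cohort` containing `hb`, `plt`, `wbc`, `alt`, `ast`
#'   with normal ranges in its specs (raw-lineage generator mode).
#' @return The cohort with the composites added and sources removed.
#' @export
make_composites <- function(cohort) {
  sources <- c("hb", "plt", "wbc", "alt", "ast")
  for (nm in sources) {
    if (!nm %in% colnames(cohort$data)) {
      stop(sprintf("make_composites: source column '%s' is missing", nm))
    }
    sp <- spec_by_name(cohort$specs, nm)
    if (is.null(sp) || is.null(sp$normal_range)) {
      stop(sprintf("make_composites: no normal_range for '%s'", nm))
    }
  }
  lo <- function(nm) spec_by_name(cohort$specs, nm)$normal_range[1]
  hi <- function(nm) spec_by_name(cohort$specs, nm)$normal_range[2]
  d <- cohort$data
  pancytopenia <- as.numeric(d$hb < lo("hb") & d$plt < lo("plt") & d$wbc < lo("wbc"))
  liver_damage <- as.numeric(d$alt > hi("alt") | d$ast > hi("ast"))
  keep <- setdiff(colnames(d), sources)
  cohort$data <- cbind(d[, keep, drop = FALSE],
                       pancytopenia = pancytopenia,
                       liver_damage = liver_damage)
  cohort$specs <- Filter(function(sp) !sp$name %in% sources, cohort$specs)
  cohort$specs <- c(cohort$specs,
                    list(feature_spec("pancytopenia", "binary"),
                         feature_spec("liver_damage", "binary")))
  cohort
}

#' LASSO feature selection with stratified cross-validation
#'
#' Fits an L1-penalized logistic model over a penalty path and selects the
#' features with nonzero coefficients at the cross-validated penalty. The
#' cross-validation is repeated over `n_repeats` independent stratified
#' fold assignments and the deviance curves averaged — a single k-fold
#' curve at these sample sizes is noisy enough to visibly destabilize the
#' chosen penalty. The default `rule = "1se"` takes the largest penalty
#' whose averaged CV binomial deviance is within one (averaged) standard
#' error of the minimum; `rule = "min"` takes the deviance-minimizing
#' penalty itself. The minimum rule is known to drag in spurious predictors
#' when many uninformative candidates are present, so the
#' one-standard-error rule is the default here. Columns are ordered
#' alphabetically before fitting so selection is invariant to input column
#' order.
#'
#' @param cohort A complete, standardized `mas_cohort`.
#' @param lambda_grid Optional decreasing penalty grid; by default glmnet's
#'   data-driven path from the null-model penalty downwards over four orders
#'   of magnitude.
#' @param k_folds Number of CV folds (>= 2); default 5.
#' @param seed Seed controlling fold assignment.
#' @param rule `"1se"` (default) or `"min"`.
#' @param n_repeats CV repetitions to average; default 5.
#' @return An object of class `lasso_report`: `selected` (feature names),
#'   `best_lambda`, `coef` (named nonzero coefficients, intercept included),
#'   `lambda_path` (data frame: lambda, cv_deviance, nonzero).
#' @export
lasso_select <- function(cohort, lambda_grid = NULL, k_folds = 5L, seed = 1L,
                         rule = c("1se", "min"), n_repeats = 5L) {
  rule <- match.arg(rule)
  y <- cohort$label
  if (length(unique(y)) < 2L) stop("label is degenerate: both classes required")
  if (k_folds < 2L) stop("k_folds must be >= 2")
  if (n_repeats < 1L) stop("n_repeats must be >= 1")
  ord <- order(colnames(cohort$data))
  x <- as.matrix(cohort$data[, ord, drop = FALSE])
  path <- glmnet::glmnet(x, y, family = "binomial", alpha = 1,
                         lambda = lambda_grid, standardize = FALSE)
  lam <- path$lambda
  cvm_sum <- cvsd_sum <- cnt <- numeric(length(lam))
  for (r in seq_len(n_repeats)) {
    foldid <- stratified_folds(y, k_folds, seed + (r - 1L) * 1000L)
    cv <- glmnet::cv.glmnet(x, y, family = "binomial", alpha = 1,
                            lambda = lam, foldid = foldid,
                            standardize = FALSE, type.measure = "deviance")
    idx <- match(cv$lambda, lam)
    cvm_sum[idx] <- cvm_sum[idx] + cv$cvm
    cvsd_sum[idx] <- cvsd_sum[idx] + cv$cvsd
    cnt[idx] <- cnt[idx] + 1
  }
  ok <- cnt == n_repeats
  cvm <- ifelse(ok, cvm_sum / cnt, NA_real_)
  cvsd <- ifelse(ok, cvsd_sum / cnt, NA_real_)
  imin <- which(ok)[which.min(cvm[ok])]
  best <- if (rule == "min") {
    lam[imin]
  } else {
    cand <- which(ok & lam >= lam[imin] & cvm <= cvm[imin] + cvsd[imin])
    lam[cand[1]]
  }
  cf <- as.matrix(stats::coef(path, s = best, exact = FALSE))[, 1]
  nz <- cf[cf != 0]
  selected <- sort(setdiff(names(nz), "(Intercept)"))
  structure(
    list(selected = selected,
         best_lambda = best,
         rule = rule,
         coef = nz,
         lambda_path = data.frame(lambda = lam,
                                  cv_deviance = cvm,
                                  nonzero = path$df)),
    class = "lasso_report"
  )
}

#' @export
print.lasso_report <- function(x, ...) {
  cat(sprintf("<lasso_report> best lambda %.4g (log %.2f), %d features selected:\n",
              x$best_lambda, log(x$best_lambda), length(x$selected)))
  cat("  ", paste(x$selected, collapse = ", "), "\n")
  invisible(x)
}

#' Two-stage feature selection
#'
#' Convenience wrapper chaining [pearson_filter()], [vif_filter()] and
#' [lasso_select()], as used by the pipeline.
#'
#' @inheritParams pearson_filter
#' @inheritParams vif_filter
#' @inheritParams lasso_select
#' @return A list: `cohort` (restricted to the selected features),
#'   `pearson`, `vif`, `lasso` (the per-stage reports), `selected`.
#' @export
select_two_stage <- function(cohort, r_threshold = 0.8, vif_threshold = 10,
                             k_folds = 5L, seed = 1L, rule = "1se") {
  p1 <- pearson_filter(cohort, r_threshold)
  p2 <- vif_filter(p1$cohort, vif_threshold)
  las <- lasso_select(p2$cohort, k_folds = k_folds, seed = seed, rule = rule)
  list(cohort = select_features(cohort, las$selected),
       pearson = p1$report, vif = p2$report, lasso = las,
       selected = las$selected)
}
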