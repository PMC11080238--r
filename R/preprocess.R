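#' Tiered imputation policy
#'
#' Features missing less than `low_threshold` are filled with the mode
#' (binary) or mean (continuous); features missing between the thresholds
#' are filled by iterative random-forest imputation; features at or above
#' `high_threshold` are rejected and must be dropped by the caller.
#'
#' @param low_threshold Fraction below which simple mean/mode filling is
#'   used; default 0.05.
#' @param high_threshold Fraction at or above which imputation refuses;
#'   default 0.20.
#' @param audit_alpha Significance level for the Mann-Whitney shift audit;
#'   default 0.05.
#' @param rf_trees Trees per random forest in the iterative imputer;
#'   default 100.
#' @param rf_max_iter Maximum imputation sweeps; default 10.
#' @param rf_tol Relative-change convergence tolerance between sweeps;
#'   default 1e-3.
#' @param seed Seed for the tree-ensemble imputer.
#' @return An object of class `imputation_policy`.
#' @export
imputation_policy <- function(low_threshold = 0.05, high_threshold = 0.20,
                              audit_alpha = 0.05, rf_trees = 100L,
                              rf_max_iter = 10L, rf_tol = 1e-3, seed = 1L) {
  if (!(low_threshold > 0 && low_threshold < high_threshold && high_threshold < 1)) {
    stop("need 0 < low_threshold < high_threshold < 1")
  }
  structure(
    list(low_threshold = low_threshold, high_threshold = high_threshold,
         audit_alpha = audit_alpha, rf_trees = as.integer(rf_trees),
         rf_max_iter = as.integer(rf_max_iter), rf_tol = rf_tol,
         seed = as.integer(seed)),
    class = "imputation_policy"
  )
}

is_binary_feature <- function(cohort, name) {
  sp <- spec_by_name(cohort$specs, name)
  if (!is.null(sp)) return(sp$kind == "binary")
  v <- cohort$data[[name]]
  all(stats::na.omit(v) %in% c(0, 1))
}

mode_value <- function(v) {
  tab <- table(v)
  as.numeric(names(tab)[which.max(tab)])  # which.max: first (lowest) on ties
}

#' Impute missing cohort values under a tiered policy
#'
#' Observed entries are never altered. Lightly missing features
#' (< `low_threshold`) get plurality (binary) or mean (continuous) filling;
#' moderately missing features get iterative random-forest imputation: all
#' gaps start at mean/mode values, then each such feature is repeatedly
#' re-predicted from all other features with a `ranger` forest until the
#' filled values stabilise or `rf_max_iter` sweeps are reached.
#'
#' @param cohort A `mas_cohort`.
#' @param policy An [imputation_policy()].
#' @return A list: `cohort` (complete), `report` (data frame with
#'   per-feature missing fraction and method used).
#' @export
impute_cohort <- function(cohort, policy = imputation_policy()) {
  df <- cohort$data
  frac <- vapply(df, function(v) mean(is.na(v)), numeric(1))
  too_heavy <- names(frac)[frac >= policy$high_threshold]
  if (length(too_heavy)) {
    stop("missingness at or above high_threshold for: ",
         paste(sprintf("%s (%.0f%%)", too_heavy, 100 * frac[too_heavy]),
               collapse = ", "),
         "; drop these features before imputation")
  }
  method <- ifelse(frac == 0, "none",
                   ifelse(frac < policy$low_threshold, "simple", "forest"))
  binary <- vapply(names(df), function(nm) is_binary_feature(cohort, nm), logical(1))

  # initial fill: mean / mode for everything
  for (nm in names(df)[frac > 0]) {
    obs <- df[[nm]][!is.na(df[[nm]])]
    fill <- if (binary[[nm]]) mode_value(obs) else mean(obs)
    df[[nm]][is.na(df[[nm]])] <- fill
  }

  forest_feats <- names(df)[method == "forest"]
  if (length(forest_feats) && ncol(df) < 2L) {
    # no covariates to learn from: the mean/mode initialisation stands
    method[method == "forest"] <- "simple"
    forest_feats <- character(0)
  }
  if (length(forest_feats)) {
    na_idx <- lapply(cohort$data, function(v) which(is.na(v)))
    # sweep order: least missing first, so better-known features stabilise early
    forest_feats <- forest_feats[order(frac[forest_feats])]
    for (iter in seq_len(policy$rf_max_iter)) {
      delta <- 0
      for (nm in forest_feats) {
        idx <- na_idx[[nm]]
        y <- df[[nm]]
        dtrain <- df[-idx, , drop = FALSE]
        if (binary[[nm]]) dtrain[[nm]] <- factor(y[-idx], levels = c(0, 1))
        else dtrain[[nm]] <- y[-idx]
        fit <- ranger::ranger(
          stats::as.formula(paste0("`", nm, "` ~ .")), data = dtrain,
          num.trees = policy$rf_trees, seed = policy$seed + iter,
          num.threads = 1,
          probability = FALSE
        )
        pred <- stats::predict(fit, df[idx, , drop = FALSE])$predictions
        if (binary[[nm]]) pred <- as.numeric(as.character(pred))
        old <- df[[nm]][idx]
        df[[nm]][idx] <- pred
        scale <- stats::sd(df[[nm]])
        if (scale > 0) delta <- max(delta, max(abs(pred - old)) / scale)
      }
      if (delta < policy$rf_tol) break
    }
  }

  out <- cohort
  out$data <- df
  list(cohort = out,
       report = data.frame(feature = names(frac),
                           missing_frac = unname(frac),
                           method = unname(method),
                           row.names = NULL))
}

#' Audit distributional shift introduced by imputation
#'
#' Per imputed feature, a two-sample Mann-Whitney U test compares the
#' observed (pre-imputation) values against the full post-imputation vector.
#' The audit passes iff no feature shows a shift at level `alpha`.
#'
#' @param before Cohort before imputation (with `NA`s).
#' @param after Completed cohort with the same schema.
#' @param alpha Significance level; default 0.05.
#' @return A list: `table` (feature, n_missing, p_value, skipped), `pass`.
#' @export
audit_shift <- function(before, after, alpha = 0.05) {
  if (!identical(colnames(before$data), colnames(after$data))) {
    stop("before/after cohorts have different schemas")
  }
  rows <- lapply(colnames(before$data), function(nm) {
    v0 <- before$data[[nm]]
    n_miss <- sum(is.na(v0))
    if (n_miss == 0L) return(NULL)
    obs <- v0[!is.na(v0)]
    if (length(obs) < 2L) {
      return(data.frame(feature = nm, n_missing = n_miss,
                        p_value = NA_real_, skipped = TRUE))
    }
    p <- suppressWarnings(
      stats::wilcox.test(obs, after$data[[nm]], exact = FALSE)$p.value
    )
    data.frame(feature = nm, n_missing = n_miss, p_value = p, skipped = FALSE)
  })
  tab <- do.call(rbind, rows)
  if (is.null(tab)) {
    tab <- data.frame(feature = character(), n_missing = integer(),
                      p_value = numeric(), skipped = logical())
  }
  pass <- all(tab$p_value[!tab$skipped] >= alpha)
  list(table = tab, pass = pass)
}

#' Append clinical range-flag features
#'
#' For every continuous feature with a known clinical reference interval, a
#' ternary companion feature `<name>_flag` is added: 1 above the upper
#' limit, -1 below the lower limit, 0 inside the (inclusive) interval.
#' Flags depend only on the raw value and the interval, never on the cohort
#' composition. Original columns are retained; missing values yield missing
#' flags.
#'
#' @param cohort A `mas_cohort`.
#' @param specs Feature specifications; defaults to `cohort$specs`.
#' @return The cohort with flag columns appended.
#' @export
derive_range_flags <- function(cohort, specs = cohort$specs) {
  if (is.null(specs)) stop("no feature specifications available")
  for (sp in specs) {
    if (sp$kind != "continuous") next
    if (!sp$name %in% colnames(cohort$data)) next
    if (is.null(sp$normal_range)) {
      stop(sprintf("feature '%s' has no normal_range", sp$name))
    }
    v <- cohort$data[[sp$name]]
    flag <- ifelse(v > sp$normal_range[2], 1,
                   ifelse(v < sp$normal_range[1], -1, 0))
    fname <- paste0(sp$name, "_flag")
    cohort$data[[fname]] <- flag
    fs <- feature_spec(fname, "continuous", "",
                       normal_range = c(-1.5, 1.5))
    fs$derived_from <- sp$name
    cohort$specs <- c(cohort$specs, list(fs))
  }
  cohort
}

#' Flag and winsorize box-plot outliers
#'
#' Per feature, entries outside the Tukey fences
#' `[Q1 - k*IQR, Q3 + k*IQR]` are flagged; the winsorized copy clips them to
#' the fence values. Constant features have collapsed fences and yield no
#' flags. Missing entries are neither flagged nor altered.
#'
#' @param cohort A `mas_cohort`.
#' @param k Fence multiplier (> 0); default 1.5.
#' @return A list: `mask` (logical matrix of flags), `cohort` (winsorized),
#'   `fences` (per-feature lower/upper).
#' @export
flag_outliers_iqr <- function(cohort, k = 1.5) {
  stopifnot(k > 0)
  df <- cohort$data
  mask <- matrix(FALSE, nrow(df), ncol(df),
                 dimnames = list(NULL, colnames(df)))
  fences <- data.frame(feature = colnames(df), lower = NA_real_, upper = NA_real_)
  for (j in seq_along(df)) {
    v <- df[[j]]
    q <- stats::quantile(v, c(0.25, 0.75), na.rm = TRUE, names = FALSE)
    iqr <- q[2] - q[1]
    lo <- q[1] - k * iqr
    hi <- q[2] + k * iqr
    fences$lower[j] <- lo
    fences$upper[j] <- hi
    out <- !is.na(v) & (v < lo | v > hi)
    mask[, j] <- out
    df[[j]] <- ifelse(is.na(v), v, pmin(pmax(v, lo), hi))
  }
  cohort$data <- df
  list(mask = mask, cohort = cohort, fences = fences)
}

#' Fit a Z-score standardization model
#'
#' Estimates per-feature mean and population standard deviation (divisor
#' `n`, so that fit-and-apply yields unit population variance exactly; two
#' points `{2, 4}` map to `{-1, 1}`) on the training cohort. The fitted
#' model is reused unchanged on later cohorts (test, external) via
#' [zscore_apply()]; it is never re-estimated downstream.
#'
#' @param cohort Training `mas_cohort` (complete).
#' @return An object of class `zscaler` (data frame: feature, mean, sd).
#' @export
zscore_fit <- function(cohort) {
  m <- vapply(cohort$data, mean, numeric(1), na.rm = TRUE)
  s <- vapply(cohort$data, function(v) {
    v <- v[!is.na(v)]
    sqrt(mean((v - mean(v))^2))
  }, numeric(1))
  degenerate <- names(s)[!is.finite(s) | s <= 0]
  if (length(degenerate)) {
    stop("zero-variance feature(s) at Z-score fit: ",
         paste(degenerate, collapse = ", "))
  }
  structure(data.frame(feature = names(m), mean = unname(m), sd = unname(s)),
            class = c("zscaler", "data.frame"))
}

#' Apply (or invert) a fitted Z-score model
#'
#' @param cohort A `mas_cohort` whose features include all scaler features.
#' @param scaler A `zscaler` from [zscore_fit()].
#' @return The transformed cohort.
#' @export
zscore_apply <- function(cohort, scaler) {
  missing <- setdiff(scaler$feature, colnames(cohort$data))
  if (length(missing)) {
    stop("cohort lacks scaler feature(s): ", paste(missing, collapse = ", "))
  }
  for (i in seq_len(nrow(scaler))) {
    nm <- scaler$feature[i]
    cohort$data[[nm]] <- (cohort$data[[nm]] - scaler$mean[i]) / scaler$sd[i]
  }
  cohort
}

#' @rdname zscore_apply
#' @export
zscore_invert <- function(cohort, scaler) {
  for (i in seq_len(nrow(scaler))) {
    nm <- scaler$feature[i]
    if (!nm %in% colnames(cohort$data)) next
    cohort$data[[nm]] <- cohort$data[[nm]] * scaler$sd[i] + scaler$mean[i]
  }
  cohort
}
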