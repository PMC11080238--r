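#' Build the diagnostic scorecard from a training cohort
#'
#' End-to-end card construction on raw (unscaled, complete) feature values:
#' chi-square binning of each continuous feature (binary features keep
#' their two categories), weight-of-evidence encoding, a logistic model in
#' WOE space, points-to-double-the-odds scaling, per-bin integer points, a
#' Kolmogorov-Smirnov decision threshold on the training scores, and
#' kernel-density risk bands.
#'
#' Higher odds of MAS map to lower scores (`Score = A - B ln(odds)`), so
#' MAS patients concentrate in the low score range. For presentation and
#' banding, total scores are clamped to `[0, 100]`; the raw total is also
#' kept.
#'
#' @param cohort Complete training `mas_cohort` restricted to the card
#'   features, with raw clinical values.
#' @param odds0,P0,PD0 Score-scaling calibration; defaults `1/19`, 70,
#'   4.14.
#' @param alpha,n_prebins,min_bins,max_bins,prebin,merge Binning controls,
#'   see [chimerge_bin()].
#' @param smoothing WOE zero-cell smoothing; default 0.5.
#' @param levels Risk-band levels; default `c(0.95, 0.75, 0.25, 0.05)`.
#' @param ridge Ridge penalty of the WOE logistic fit; default 0.1.
#' @param bw KDE bandwidth; default Silverman's `"nrd0"`.
#' @return An object of class `mas_scorecard`.
#' @export
build_scorecard <- function(cohort,
                            odds0 = 1 / 19, P0 = 70, PD0 = 4.14,
                            alpha = 0.05, n_prebins = 20L,
                            min_bins = 3L, max_bins = 8L,
                            prebin = "quantile", merge = "most_similar",
                            smoothing = 0.5,
                            levels = c(0.95, 0.75, 0.25, 0.05),
                            ridge = 0.1, bw = "nrd0") {
  xy <- cohort_xy(cohort)
  y <- xy$y
  feats <- colnames(cohort$data)
  bins <- lapply(feats, function(nm) {
    v <- cohort$data[[nm]]
    edges <- if (is_binary_feature(cohort, nm)) {
      0.5
    } else {
      chimerge_bin(v, y, n_prebins = n_prebins, alpha = alpha,
                   min_bins = min_bins, max_bins = max_bins,
                   prebin = prebin, merge = merge)$edges
    }
    woe_table(v, y, edges, smoothing = smoothing)
  })
  names(bins) <- feats
  woe_df <- as.data.frame(lapply(feats, function(nm) {
    woe_lookup(cohort$data[[nm]], bins[[nm]])
  }), col.names = feats)
  lr <- fit_woe_lr(woe_df, y, ridge = ridge)
  scaling <- scaling_coeffs(odds0, P0, PD0)
  pts <- assemble_points(lr, bins, scaling)
  card <- structure(
    list(features = feats, bins = bins, points = pts$points,
         base_share = pts$base_share, scaling = scaling,
         intercept = lr$intercept, coefficients = lr$coefficients,
         specs = cohort$specs),
    class = "mas_scorecard"
  )
  train_scores <- predict(card, cohort)
  ks <- ks_threshold(train_scores$score, y)
  rk <- kde_risk(train_scores$score[y == 1], train_scores$score[y == 0],
                 bw = bw)
  bands <- band_thresholds(rk, levels = levels)
  card$threshold <- ks$threshold
  card$ks <- ks
  card$risk <- rk
  card$bands <- bands
  card$train_scores <- train_scores$score
  card$train_labels <- y
  card
}

#' @export
print.mas_scorecard <- function(x, ...) {
  cat(sprintf("<mas_scorecard> %d features, A = %.2f, B = %.2f",
              length(x$features), x$scaling$A, x$scaling$B))
  if (!is.null(x$threshold)) {
    cat(sprintf(", KS threshold %g (score <= %g => MAS)", x$threshold,
                x$threshold))
  }
  cat("\n")
  if (!is.null(x$bands)) print(x$bands)
  invisible(x)
}

#' Score a cohort (or data frame) with a fitted scorecard
#'
#' @param object A `mas_scorecard`.
#' @param cohort A `mas_cohort` or data frame holding raw values of all card
#'   features; values outside all bins fall into the nearest terminal bin.
#' @param ... Unused.
#' @return Data frame: `score` (integer total clamped to `[0, 100]`),
#'   `score_raw` (unclamped rounded total), `score_unrounded` (exact
#'   `A - B ln(odds)`), plus, when the card's threshold/bands are fitted,
#'   `predicted` (1 = MAS), `band`, `risk`.
#' @export
predict.mas_scorecard <- function(object, cohort, ...) {
  df <- if (inherits(cohort, "mas_cohort")) cohort$data else as.data.frame(cohort)
  missing <- setdiff(object$features, colnames(df))
  if (length(missing)) {
    stop("missing required feature(s): ", paste(missing, collapse = ", "))
  }
  n <- nrow(df)
  total <- numeric(n)
  total_unrounded <- numeric(n)
  for (nm in object$features) {
    p <- object$points[[nm]]
    idx <- cut(df[[nm]], breaks = c(-Inf, p$hi[-nrow(p)], Inf),
               labels = FALSE, right = TRUE)
    if (anyNA(idx)) stop(sprintf("missing value in feature '%s'", nm))
    total <- total + p$points[idx]
    total_unrounded <- total_unrounded + p$unrounded[idx]
  }
  out <- data.frame(score = pmin(pmax(total, 0), 100),
                    score_raw = total,
                    score_unrounded = total_unrounded)
  if (!is.null(object$threshold)) {
    out$predicted <- as.integer(out$score <= object$threshold)
  }
  if (!is.null(object$bands)) {
    out$band <- band_label(object$bands, out$score)
  }
  if (!is.null(object$risk)) {
    out$risk <- object$risk$risk(out$score)
  }
  out
}

#' Score a single patient and flag out-of-range indicators
#'
#' @param card A fitted `mas_scorecard`.
#' @param patient Named list or one-row data frame with raw values for every
#'   card feature.
#' @return A list: `score`, `score_raw`, `score_unrounded`, `predicted`
#'   (1 = MAS), `band`, `risk`, `flags` (per-feature -1/0/1 against the
#'   clinical normal range, where known), `per_feature` (points
#'   contribution table).
#' @export
score_patient <- function(card, patient) {
  df <- as.data.frame(as.list(patient))[, , drop = FALSE]
  missing <- setdiff(card$features, colnames(df))
  if (length(missing)) {
    stop("missing required feature(s): ", paste(missing, collapse = ", "))
  }
  res <- predict(card, df[, card$features, drop = FALSE])
  contrib <- vapply(card$features, function(nm) {
    p <- card$points[[nm]]
    idx <- cut(df[[nm]], breaks = c(-Inf, p$hi[-nrow(p)], Inf),
               labels = FALSE, right = TRUE)
    p$points[idx]
  }, numeric(1))
  flags <- vapply(card$features, function(nm) {
    sp <- spec_by_name(card$specs, nm)
    if (is.null(sp) || sp$kind != "continuous" || is.null(sp$normal_range)) {
      return(NA_real_)
    }
    v <- df[[nm]]
    if (v > sp$normal_range[2]) 1 else if (v < sp$normal_range[1]) -1 else 0
  }, numeric(1))
  list(score = res$score, score_raw = res$score_raw,
       score_unrounded = res$score_unrounded,
       predicted = res$predicted %||% NA_integer_,
       band = res$band %||% NA_character_,
       risk = res$risk %||% NA_real_,
       flags = flags,
       per_feature = data.frame(feature = card$features,
                                points = unname(contrib)))
}

#' Export a scorecard as CSV + JSON bundle
#'
#' Writes a human-readable card CSV (feature, bin interval, points) and a
#' JSON bundle (edges, WOE, coefficients, scaling, threshold, bands)
#' sufficient for exact re-scoring via [read_scorecard()].
#'
#' @param card A `mas_scorecard`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_scorecard <- function(card, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- do.call(rbind, lapply(card$features, function(nm) {
    p <- card$points[[nm]]
    data.frame(feature = nm, bin = p$bin, lo = p$lo, hi = p$hi,
               woe = p$woe, points = p$points)
  }))
  utils::write.csv(rows, file.path(dir, "card.csv"), row.names = FALSE)
  bundle <- list(
    features = card$features,
    scaling = unclass(card$scaling),
    intercept = card$intercept,
    coefficients = as.list(card$coefficients),
    base_share = card$base_share,
    threshold = card$threshold,
    ks = card$ks$ks,
    bands = card$bands$bands,
    band_thresholds = as.list(card$bands$thresholds),
    bins = lapply(card$points, function(p) {
      # interior edges only: terminal bins are unbounded and JSON lacks Inf
      list(edges = p$hi[-nrow(p)], points = p$points,
           unrounded = p$unrounded, woe = p$woe)
    })
  )
  jsonlite::write_json(bundle, file.path(dir, "scorecard.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(dir)
}

#' Re-load an exported scorecard for re-scoring
#'
#' Reconstructs the point tables, threshold and bands from the JSON bundle;
#' the returned card scores patients identically to the original (the KDE
#' risk function is not serialized, so `risk` is absent).
#'
#' @param dir Directory written by [write_scorecard()].
#' @return A `mas_scorecard` (without the fitted `risk` function).
#' @export
read_scorecard <- function(dir) {
  b <- jsonlite::read_json(file.path(dir, "scorecard.json"),
                           simplifyVector = TRUE)
  feats <- b$features
  points <- lapply(feats, function(nm) {
    p <- b$bins[[nm]]
    edges <- as.numeric(unlist(p$edges))
    data.frame(bin = NA_character_, lo = c(-Inf, edges),
               hi = c(edges, Inf), woe = p$woe, points = p$points,
               unrounded = p$unrounded)
  })
  names(points) <- feats
  bands <- structure(list(bands = as.data.frame(b$bands),
                          thresholds = unlist(b$band_thresholds)),
                     class = "score_bands")
  structure(
    list(features = feats, points = points,
         base_share = b$base_share,
         scaling = do.call(scaling_coeffs,
                           b$scaling[c("odds0", "P0", "PD0")]),
         intercept = b$intercept,
         coefficients = unlist(b$coefficients),
         specs = NULL, threshold = b$threshold, bands = bands),
    class = "mas_scorecard"
  )
}
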