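chi2_pair <- function(counts) {
  # Pearson chi-square of a 2 x 2 table (pair of adjacent bins x class)
  n <- sum(counts)
  if (n == 0) return(0)
  rs <- rowSums(counts)
  cs <- colSums(counts)
  if (any(rs == 0) || any(cs == 0)) return(0)
  e <- outer(rs, cs) / n
  sum((counts - e)^2 / e)
}

#' Supervised discretization by chi-square (ChiMerge) binning
#'
#' Pre-divides a continuous feature into `n_prebins` bins (quantile-based by
#' default), then repeatedly merges the adjacent pair of bins whose class
#' distributions are most alike: the pair with the smallest chi-square
#' statistic is merged while its p-value is at least `alpha` or the number
#' of bins still exceeds `max_bins`, stopping once every adjacent pair
#' differs at `p < alpha` or `min_bins` is reached. Empty bins are always
#' merged. With fewer distinct values than `min_bins`, each distinct value
#' becomes its own bin.
#'
#' `merge = "most_different"` instead merges, at each step, the pair with
#' the largest chi-square among those with `p < alpha` (the literal reading
#' of some scorecard write-ups); it is provided for comparison only, since
#' it removes exactly the cut points that separate the classes.
#'
#' @param x Numeric feature values (`NA` dropped).
#' @param y Binary labels aligned with `x`.
#' @param n_prebins Initial bin count; default 20.
#' @param alpha Chi-square significance level for merging; default 0.05.
#' @param min_bins,max_bins Bin-count bounds; defaults 3 and 8.
#' @param prebin `"quantile"` (default) or `"width"` pre-binning.
#' @param merge `"most_similar"` (standard ChiMerge, default) or
#'   `"most_different"`.
#' @return A list: `edges` (interior cut points, strictly increasing; bins
#'   are `(-Inf, e1], (e1, e2], ..., (ek, Inf)`), `n_bins`.
#' @export
chimerge_bin <- function(x, y, n_prebins = 20L, alpha = 0.05,
                         min_bins = 3L, max_bins = 8L,
                         prebin = c("quantile", "width"),
                         merge = c("most_similar", "most_different")) {
  prebin <- match.arg(prebin)
  merge <- match.arg(merge)
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- as.integer(y[ok])
  ux <- sort(unique(x))
  if (length(ux) < 2L) stop("chimerge_bin needs at least 2 distinct values")
  if (length(unique(y)) < 2L) stop("chimerge_bin needs both classes")
  if (length(ux) <= min_bins) {
    edges <- (ux[-1] + ux[-length(ux)]) / 2
    return(list(edges = edges, n_bins = length(edges) + 1L))
  }
  edges <- if (prebin == "quantile") {
    qs <- stats::quantile(x, probs = seq(0, 1, length.out = n_prebins + 1L),
                          names = FALSE, type = 7)
    sort(unique(qs[-c(1, length(qs))]))
  } else {
    seq(min(x), max(x), length.out = n_prebins + 1L)[-c(1, n_prebins + 1L)]
  }
  edges <- edges[edges > min(x) & edges < max(x)]
  repeat {
    bin <- cut(x, breaks = c(-Inf, edges, Inf), labels = FALSE, right = TRUE)
    counts <- matrix(0, length(edges) + 1L, 2L)
    tab <- table(factor(bin, levels = seq_len(length(edges) + 1L)), factor(y, levels = 0:1))
    counts[] <- as.numeric(tab)
    nb <- nrow(counts)
    if (nb <= min_bins || length(edges) == 0L) break
    empty <- which(rowSums(counts) == 0)
    if (length(empty)) {
      # merging an empty bin = deleting one of its edges
      drop <- min(empty[1], length(edges))
      edges <- edges[-drop]
      next
    }
    chis <- vapply(seq_len(nb - 1L), function(i) {
      chi2_pair(counts[i:(i + 1L), , drop = FALSE])
    }, numeric(1))
    pvals <- stats::pchisq(chis, df = 1, lower.tail = FALSE)
    if (merge == "most_similar") {
      j <- which.min(chis)  # leftmost on ties
      if (pvals[j] >= alpha || nb > max_bins) {
        edges <- edges[-j]
      } else break
    } else {
      cand <- which(pvals < alpha)
      if (!length(cand)) break
      j <- cand[which.max(chis[cand])]
      edges <- edges[-j]
    }
  }
  list(edges = edges, n_bins = length(edges) + 1L)
}

#' Weight-of-evidence table for binned values
#'
#' Per-bin WOE = `ln(SLE% / MAS%)` where SLE% is the share of all SLE
#' (negative-class) patients falling in the bin and MAS% the share of all
#' MAS patients. Zero cells receive additive smoothing of `smoothing`
#' counts, and the class shares are renormalized afterwards, so every WOE is
#' finite. Bins empty in both classes are merged into their lower neighbour
#' with a warning.
#'
#' @param x Feature values.
#' @param y Binary labels (0 = SLE, 1 = MAS).
#' @param edges Interior cut points from [chimerge_bin()] (may be empty for
#'   a single bin; for binary features use `edges = 0.5`).
#' @param smoothing Count added to zero cells; default 0.5.
#' @return A `bin_stats` data frame: bin label, `lo`, `hi`, `n_sle`,
#'   `n_mas`, `sle_pct`, `mas_pct`, `woe`.
#' @export
woe_table <- function(x, y, edges, smoothing = 0.5) {
  y <- as.integer(y)
  if (!all(y %in% 0:1)) stop("labels must be binary 0/1")
  edges <- sort(edges)
  repeat {
    breaks <- c(-Inf, edges, Inf)
    bin <- cut(x, breaks = breaks, labels = FALSE, right = TRUE)
    nb <- length(edges) + 1L
    n0 <- tabulate(bin[y == 0], nbins = nb)
    n1 <- tabulate(bin[y == 1], nbins = nb)
    dead <- which(n0 + n1 == 0)
    if (!length(dead) || !length(edges)) break
    warning("bin empty in both classes; merging into neighbour")
    edges <- edges[-min(dead[1], length(edges))]
  }
  s0 <- ifelse(n0 == 0, smoothing, n0)
  s1 <- ifelse(n1 == 0, smoothing, n1)
  sle_pct <- s0 / sum(s0)
  mas_pct <- s1 / sum(s1)
  lo <- c(-Inf, edges)
  hi <- c(edges, Inf)
  structure(
    data.frame(
      bin = sprintf("(%s, %s]", formatC(lo, format = "g"), formatC(hi, format = "g")),
      lo = lo, hi = hi, n_sle = n0, n_mas = n1,
      sle_pct = sle_pct, mas_pct = mas_pct,
      woe = log(sle_pct / mas_pct)
    ),
    class = c("bin_stats", "data.frame")
  )
}

# values fall in bin i iff lo_i < v <= hi_i; out-of-range values land in the
# nearest terminal bin because the terminal breaks are infinite
woe_lookup <- function(values, bins) {
  idx <- cut(values, breaks = c(-Inf, bins$hi[-nrow(bins)], Inf),
             labels = FALSE, right = TRUE)
  bins$woe[idx]
}

#' Logistic regression on WOE-encoded features
#'
#' Fits the scorecard's logistic model (MAS = positive class) on
#' WOE-transformed features. An L2 (ridge) penalty, 0.1 by default, keeps
#' the fit stable when the classes are nearly separable and keeps the
#' linear predictor within the range the 0-100 point scale can represent;
#' set `ridge = 0` for an unpenalized `glm` fit.
#'
#' @param woe_data Data frame/matrix of WOE-encoded features.
#' @param y Binary labels.
#' @param ridge L2 penalty (glmnet lambda); default 0.1.
#' @return A list: `intercept`, `coefficients` (named).
#' @export
fit_woe_lr <- function(woe_data, y, ridge = 0.1) {
  x <- as.matrix(woe_data)
  y <- as.integer(y)
  if (length(unique(y)) < 2L) stop("both classes required")
  if (ridge > 0) {
    # glmnet needs >= 2 columns; pad single-feature fits with a null column
    pad <- ncol(x) < 2L
    if (pad) x <- cbind(x, `.null.` = 0)
    fit <- glmnet::glmnet(x, y, family = "binomial", alpha = 0,
                          lambda = ridge, standardize = FALSE)
    cf <- as.matrix(stats::coef(fit))[, 1]
    if (pad) cf <- cf[names(cf) != ".null."]
  } else {
    d <- as.data.frame(x)
    d$.y <- y
    fit <- stats::glm(.y ~ ., family = stats::binomial(), data = d)
    if (!fit$converged) {
      stop(sprintf("WOE logistic regression did not converge in %d iterations",
                   fit$iter))
    }
    cf <- stats::coef(fit)
  }
  list(intercept = unname(cf[1]), coefficients = cf[-1])
}

#' Score-scaling coefficients from odds0 / P0 / PD0
#'
#' The scorecard maps log-odds to points as `Score = A - B * ln(odds)`,
#' where `B = PD0 / ln 2` (PD0 points change per doubling of the odds) and
#' `A = P0 + B * ln(odds0)` (score P0 at baseline odds odds0). With the
#' published calibration `odds0 = 1/19, P0 = 70, PD0 = 4.14` this gives
#' `A = 52.41, B = 5.97`.
#'
#' @param odds0 Baseline disease/non-disease odds (> 0).
#' @param P0 Baseline score at `odds0`.
#' @param PD0 Points to double the odds (> 0).
#' @return An object of class `score_scaling`: `odds0`, `P0`, `PD0`, `A`,
#'   `B`.
#' @export
#' @examples
#' s <- scaling_coeffs(1/19, 70, 4.14)
#' round(c(A = s$A, B = s$B), 2)  # 52.41, 5.97
scaling_coeffs <- function(odds0 = 1 / 19, P0 = 70, PD0 = 4.14) {
  if (!(odds0 > 0)) stop("odds0 must be positive")
  if (!(PD0 > 0)) stop("PD0 must be positive")
  B <- PD0 / log(2)
  A <- P0 + B * log(odds0)
  structure(list(odds0 = odds0, P0 = P0, PD0 = PD0, A = A, B = B),
            class = "score_scaling")
}

#' Assemble per-bin score points
#'
#' Converts the WOE-logistic model into an additive integer point card:
#' each feature's bin contributes
#' `round(base_share - B * coefficient * WOE)`, with the intercept-derived
#' base `A - B * intercept` distributed equally across the active features.
#' For any patient the unrounded total equals `A - B * ln(odds)` exactly;
#' the rounded total differs by at most half a point per feature.
#'
#' @param lr Fit from [fit_woe_lr()].
#' @param bins Named list of `bin_stats`, one per model feature.
#' @param scaling A [scaling_coeffs()] object.
#' @return A list: `points` (named list of data frames: bin, lo, hi, woe,
#'   points, unrounded), `base_share`, `scaling`, `lr`.
#' @export
assemble_points <- function(lr, bins, scaling) {
  feats <- names(lr$coefficients)
  absent <- setdiff(feats, names(bins))
  if (length(absent)) {
    stop("model feature(s) missing from bins: ", paste(absent, collapse = ", "))
  }
  p <- length(feats)
  base_share <- (scaling$A - scaling$B * lr$intercept) / p
  points <- lapply(feats, function(nm) {
    b <- bins[[nm]]
    unrounded <- base_share - scaling$B * lr$coefficients[[nm]] * b$woe
    data.frame(bin = b$bin, lo = b$lo, hi = b$hi, woe = b$woe,
               points = round(unrounded), unrounded = unrounded)
  })
  names(points) <- feats
  list(points = points, base_share = base_share, scaling = scaling, lr = lr)
}

#' Kolmogorov-Smirnov decision threshold for scorecard scores
#'
#' Computes the cumulative score distributions of the MAS and SLE groups
#' over ascending scores; the KS statistic is the maximum absolute gap and
#' the threshold is the (lowest, on ties) score attaining it. Since MAS
#' patients concentrate at low scores, the decision rule is
#' `score <= threshold => predict MAS`.
#'
#' @param scores Numeric scorecard scores.
#' @param labels Binary labels (1 = MAS).
#' @return A list: `ks`, `threshold`, `curve` (data frame: score, cdf_mas,
#'   cdf_sle, diff).
#' @export
ks_threshold <- function(scores, labels) {
  y <- as.integer(labels)
  if (length(unique(y)) < 2L) stop("both classes must be present")
  cand <- sort(unique(scores))
  cdf_mas <- vapply(cand, function(s) mean(scores[y == 1] <= s), numeric(1))
  cdf_sle <- vapply(cand, function(s) mean(scores[y == 0] <= s), numeric(1))
  gap <- abs(cdf_mas - cdf_sle)
  ks <- max(gap)
  # ties (within float noise of the max) resolve to the lowest score
  list(ks = ks,
       threshold = cand[which(gap >= ks - 1e-9)[1]],
       curve = data.frame(score = cand, cdf_mas = cdf_mas,
                          cdf_sle = cdf_sle, diff = gap))
}

#' Kernel-density disease-risk function over the score axis
#'
#' Fits Gaussian kernel densities to the positive (MAS) and negative (SLE)
#' score samples and returns the posterior disease risk over unit score
#' intervals: for an interval centred at `s`,
#' `risk(s) = prior * P_pos(I) / (prior * P_pos(I) + (1 - prior) * P_neg(I))`
#' with `I = [s - 0.5, s + 0.5]` and `P` the density integral over `I`.
#' With the balanced default prior 0.5 this is the probability that a
#' patient scoring in that interval is a MAS case.
#'
#' @param scores_pos,scores_neg At least 5 scores per class.
#' @param prior_pos Positive-class prior; default the empirical fraction.
#' @param bw Bandwidth passed to [stats::density()] (default `"nrd0"`,
#'   Silverman's rule).
#' @return An object of class `kde_risk`: `risk(s)` (vectorized), the two
#'   density objects, `prior_pos`, and the evaluation `range`.
#' @export
kde_risk <- function(scores_pos, scores_neg,
                     prior_pos = length(scores_pos) /
                       (length(scores_pos) + length(scores_neg)),
                     bw = "nrd0") {
  if (length(scores_pos) < 5L || length(scores_neg) < 5L) {
    stop("need at least 5 scores per class")
  }
  if (stats::sd(scores_pos) == 0 || stats::sd(scores_neg) == 0) {
    stop("degenerate (constant) score set; supply a numeric bandwidth override")
  }
  lo <- min(scores_pos, scores_neg)
  hi <- max(scores_pos, scores_neg)
  pad <- 0.15 * (hi - lo) + 2
  dp <- stats::density(scores_pos, bw = bw, kernel = "gaussian",
                       from = lo - pad, to = hi + pad, n = 2048L)
  dn <- stats::density(scores_neg, bw = bw, kernel = "gaussian",
                       from = lo - pad, to = hi + pad, n = 2048L)
  fp <- stats::approxfun(dp$x, dp$y, yleft = 0, yright = 0)
  fn <- stats::approxfun(dn$x, dn$y, yleft = 0, yright = 0)
  integrate_unit <- function(f, s) {
    g <- seq(s - 0.5, s + 0.5, length.out = 41L)
    v <- f(g)
    sum((v[-1] + v[-length(v)]) / 2) * (g[2] - g[1])
  }
  risk <- function(s) {
    vapply(s, function(si) {
      pp <- prior_pos * integrate_unit(fp, si)
      pn <- (1 - prior_pos) * integrate_unit(fn, si)
      if (pp + pn <= 0) return(NA_real_)
      pp / (pp + pn)
    }, numeric(1))
  }
  structure(list(risk = risk, density_pos = dp, density_neg = dn,
                 prior_pos = prior_pos, range = c(lo, hi)),
            class = "kde_risk")
}

#' Score bands from risk levels
#'
#' For each predefined risk level (defaults 95%, 75%, 25%, 5%) finds the
#' highest score whose unit-interval risk still reaches the level, then
#' assembles the five diagnostic bands: extremely high
#' `[min, t95]`, high `(t95, t75]`, normal `(t75, t25]`, low `(t25, t05]`,
#' extremely low `(t05, max]`. Requires the risk function to be
#' non-increasing over the score grid; violations or unattainable levels
#' raise an error naming the offending scores.
#'
#' Boundaries are located on a quarter-point grid: when the fitted risk
#' falls steeply, two levels can be crossed within a single integer score,
#' and sub-integer resolution keeps the bands strictly ordered (a steep
#' transition then shows up honestly as a narrow band rather than as a
#' failure).
#'
#' @param rk A [kde_risk()] object (or any function of score).
#' @param levels Decreasing risk levels; default `c(0.95, 0.75, 0.25, 0.05)`.
#' @param score_range Evaluation grid; default `seq(0, 100, by = 0.25)`.
#' @param tol Monotonicity tolerance; default 1e-8.
#' @return An object of class `score_bands`: data frame `bands` (label,
#'   lo, hi, risk_range) and `thresholds` (named vector).
#' @export
band_thresholds <- function(rk, levels = c(0.95, 0.75, 0.25, 0.05),
                            score_range = seq(0, 100, by = 0.25),
                            tol = 1e-8) {
  f <- if (inherits(rk, "kde_risk")) rk$risk else rk
  r <- f(score_range)
  ok <- !is.na(r)
  grid <- score_range[ok]
  r <- r[ok]
  viol <- which(diff(r) > tol)
  if (length(viol)) {
    stop(sprintf("risk is not non-increasing in score near score(s) %s",
                 paste(utils::head(grid[viol], 5), collapse = ", ")))
  }
  thresholds <- vapply(levels, function(lv) {
    at <- which(r >= lv)
    if (!length(at)) {
      stop(sprintf("risk level %.2f is never attained on the score grid", lv))
    }
    as.numeric(grid[max(at)])
  }, numeric(1))
  names(thresholds) <- sprintf("t%02d", round(100 * levels))
  if (any(diff(thresholds) <= 0)) {
    stop("band thresholds are not strictly increasing; risk function too flat")
  }
  lo <- c(min(grid), thresholds)
  hi <- c(thresholds, max(grid))
  bands <- data.frame(
    label = c("extremely high", "high", "normal", "low", "extremely low"),
    lo = unname(lo), hi = unname(hi)
  )
  pct <- round(100 * levels)
  bands$risk <- c(sprintf("above %d%%", pct[1]),
                  sprintf("%d-%d%%", pct[2], pct[1]),
                  sprintf("%d-%d%%", pct[3], pct[2]),
                  sprintf("%d-%d%%", pct[4], pct[3]),
                  sprintf("below %d%%", pct[4]))
  structure(list(bands = bands, thresholds = thresholds, levels = levels),
            class = "score_bands")
}

#' @export
print.score_bands <- function(x, ...) {
  cat("<score_bands>\n")
  b <- x$bands
  for (i in seq_len(nrow(b))) {
    cat(sprintf("  %-15s %s%g, %g] (risk %s)\n", b$label[i],
                if (i == 1) "[" else "(", b$lo[i], b$hi[i], b$risk[i]))
  }
  invisible(x)
}

band_label <- function(bands, score) {
  b <- bands$bands
  idx <- cut(score, breaks = c(-Inf, b$hi[-nrow(b)], Inf), labels = FALSE,
             right = TRUE)
  b$label[idx]
}
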