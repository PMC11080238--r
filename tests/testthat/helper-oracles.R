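# Independent brute-force oracles used to validate the fast implementations.

# AUC by exhaustive pair counting (ties count one half)
auc_paircount <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

# KS threshold by exhaustive enumeration of every observed cutoff
ks_bruteforce <- function(scores, labels) {
  cand <- sort(unique(scores))
  gaps <- vapply(cand, function(s) {
    abs(mean(scores[labels == 1] <= s) - mean(scores[labels == 0] <= s))
  }, numeric(1))
  best <- max(gaps)
  # lowest score among (float-tolerant) ties, matching the documented rule
  list(ks = best, threshold = cand[which(gaps >= best - 1e-9)[1]])
}

# greedy ChiMerge re-implemented from first principles with stats::chisq.test
chimerge_oracle <- function(x, y, n_prebins = 20, alpha = 0.05,
                            min_bins = 3, max_bins = 8) {
  qs <- stats::quantile(x, probs = seq(0, 1, length.out = n_prebins + 1),
                        names = FALSE, type = 7)
  edges <- sort(unique(qs[-c(1, length(qs))]))
  edges <- edges[edges > min(x) & edges < max(x)]
  repeat {
    bin <- cut(x, c(-Inf, edges, Inf), labels = FALSE)
    nb <- length(edges) + 1
    tab <- table(factor(bin, levels = 1:nb), factor(y, levels = 0:1))
    if (nb <= min_bins || length(edges) == 0) break
    if (any(rowSums(tab) == 0)) {
      e <- which(rowSums(tab) == 0)[1]
      edges <- edges[-min(e, length(edges))]
      next
    }
    stats_chi <- sapply(1:(nb - 1), function(i) {
      m <- tab[i:(i + 1), , drop = FALSE]
      if (any(colSums(m) == 0)) return(0)
      suppressWarnings(stats::chisq.test(m, correct = FALSE)$statistic)
    })
    j <- which.min(stats_chi)
    p <- stats::pchisq(stats_chi[j], 1, lower.tail = FALSE)
    if (p >= alpha || nb > max_bins) edges <- edges[-j] else break
  }
  edges
}

# cohort construction shortcut for hand-built fixtures
make_cohort <- function(df, label, specs = NULL) {
  structure(list(data = as.data.frame(df), label = as.integer(label),
                 specs = specs, meta = NULL, config = list(seed = NA)),
            class = "mas_cohort")
}

planted_features <- function() {
  sort(vapply(mascard::default_feature_specs(), function(s) s$name,
              character(1)))
}

# default-conditions cohort prepared the way the pipeline prepares it
prepared_default_cohort <- function(seed) {
  co <- mascard::generate_cohort(mascard::cohort_config(seed = seed))
  ic <- mascard::impute_cohort(co)$cohort
  mascard::flag_outliers_iqr(ic)$cohort
}
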