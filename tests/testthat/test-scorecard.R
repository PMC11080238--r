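test_that("chimerge collapses uninformative features and keeps a planted step cut", {
  withr::with_seed(1, {
    x <- runif(200)
    y <- sample(0:1, 200, replace = TRUE)
  })
  res <- chimerge_bin(x, y, min_bins = 3)
  expect_equal(res$n_bins, 3)

  # single step-change in class ratio at 0.5 on a 40-point instance
  x2 <- seq(0.025, 1, by = 0.025)
  y2 <- as.integer(x2 > 0.5)
  res2 <- chimerge_bin(x2, y2, n_prebins = 10, min_bins = 2)
  expect_true(any(abs(res2$edges - 0.5) < 0.05))

  # binary-valued input: two bins, cut between the categories
  res3 <- chimerge_bin(c(rep(0, 20), rep(1, 20)), rep(0:1, 20))
  expect_equal(res3$n_bins, 2)
  expect_equal(res3$edges, 0.5)
  expect_error(chimerge_bin(rep(1, 10), rep(0:1, 5)), "distinct")
})

test_that("chimerge agrees with an independent greedy oracle on small instances", {
  for (s in 1:12) {
    withr::with_seed(s, {
      n <- sample(25:40, 1)
      x <- round(runif(n), 2)
      prob <- stats::plogis(3 * (x - 0.5))
      y <- stats::rbinom(n, 1, prob)
    })
    if (length(unique(y)) < 2 || length(unique(x)) < 4) next
    ours <- chimerge_bin(x, y, n_prebins = 8, min_bins = 2, max_bins = 6)
    oracle <- chimerge_oracle(x, y, n_prebins = 8, min_bins = 2, max_bins = 6)
    expect_equal(ours$edges, unname(oracle), info = paste("seed", s))
  }
})

test_that("the strict merge mode deletes the separating cuts it targets", {
  x <- seq(0.025, 1, by = 0.025)
  y <- as.integer(x > 0.5)
  strict <- chimerge_bin(x, y, n_prebins = 10, min_bins = 2,
                         merge = "most_different")
  expect_false(any(abs(strict$edges - 0.5) < 0.05))
})

test_that("WOE values follow ln(SLE%/MAS%) with smoothing only on zero cells", {
  # bin shares 40% SLE / 10% MAS => WOE = ln 4
  x <- c(rep(0, 40), rep(1, 60), rep(0, 10), rep(1, 90))
  y <- c(rep(0, 100), rep(1, 100))
  tab <- woe_table(x, y, edges = 0.5)
  expect_equal(tab$woe[1], log(4))
  expect_equal(sum(tab$sle_pct), 1, tolerance = 1e-9)
  expect_equal(sum(tab$mas_pct), 1, tolerance = 1e-9)
  expect_equal(tab$woe[tab$n_sle == tab$n_mas], numeric(0))  # no equal bins here

  eq <- woe_table(c(rep(0, 50), rep(1, 50), rep(0, 50), rep(1, 50)),
                  c(rep(0, 100), rep(1, 100)), edges = 0.5)
  expect_equal(eq$woe, c(0, 0))

  # zero MAS count in the low bin: finite positive WOE under smoothing
  z <- woe_table(c(rep(0, 30), rep(1, 70), rep(1, 100)),
                 c(rep(0, 100), rep(1, 100)), edges = 0.5)
  expect_true(is.finite(z$woe[1]))
  expect_gt(z$woe[1], 0)
  expect_error(woe_table(1:10, rep(2, 10), edges = 5), "binary")
})

test_that("the WOE logistic fit recovers the null model and orients signs correctly", {
  withr::with_seed(11, {
    w <- as.data.frame(matrix(rnorm(600 * 3), 600))
    y <- rep(c(0, 1, 1), 200)  # class ratio 1:2
  })
  lr <- fit_woe_lr(w, y)
  expect_lt(max(abs(lr$coefficients)), 0.2)
  expect_equal(lr$intercept, log(2), tolerance = 0.15)

  # an informative WOE feature: higher WOE = more SLE-like => negative weight
  withr::with_seed(12, {
    y2 <- rep(0:1, 300)
    w2 <- data.frame(f = ifelse(y2 == 0, 1, -1) + rnorm(600, sd = 0.8))
  })
  lr2 <- fit_woe_lr(w2, y2)
  expect_lt(lr2$coefficients[["f"]], 0)

  # duplicated feature under L2: the ridge solution splits the weight evenly,
  # and the summed weight equals a single-feature fit at half the penalty
  # (splitting w into w/2 + w/2 halves the quadratic penalty on the total)
  lr3 <- fit_woe_lr(data.frame(a = w2$f, b = w2$f), y2, ridge = 0.1)
  expect_equal(lr3$coefficients[["a"]], lr3$coefficients[["b"]],
               tolerance = 1e-3)
  single <- fit_woe_lr(data.frame(a = w2$f), y2, ridge = 0.05)
  expect_equal(sum(lr3$coefficients), single$coefficients[["a"]],
               tolerance = 1e-3)
})

test_that("PDO scaling identities hold exactly and reproduce the published coefficients", {
  s <- scaling_coeffs(1 / 19, 70, 4.14)
  expect_equal(round(s$A, 2), 52.41)
  expect_equal(round(s$B, 2), 5.97)
  expect_equal(s$B * log(2), s$PD0, tolerance = 1e-12)
  expect_equal(s$A - s$B * log(s$odds0), s$P0, tolerance = 1e-12)
  expect_equal(scaling_coeffs(1, 55, 4)$A, 55)
  expect_equal(scaling_coeffs(0.2, 55, log(2))$B, 1)
  expect_error(scaling_coeffs(-1, 70, 4.14), "odds0")
  expect_error(scaling_coeffs(1 / 19, 70, 0), "PD0")
})

default_card_fixture <- function(seed = 1) {
  co <- prepared_default_cohort(seed)
  tr <- mascard:::select_features(co, planted_features())
  list(cohort = tr, card = build_scorecard(tr))
}

test_that("the assembled card reconstructs A - B ln(odds) exactly before rounding", {
  fx <- default_card_fixture()
  card <- fx$card
  tr <- fx$cohort
  sc <- predict(card, tr)
  woe <- vapply(card$features, function(nm) {
    mascard:::woe_lookup(tr$data[[nm]], card$bins[[nm]])
  }, numeric(nrow(tr$data)))
  lnodds <- card$intercept + as.vector(woe %*% card$coefficients)
  expect_lt(max(abs(sc$score_unrounded - (card$scaling$A - card$scaling$B * lnodds))),
            1e-9)
  # integer rounding error bounded by half a point per feature
  expect_lte(max(abs(sc$score_raw - sc$score_unrounded)),
             length(card$features) / 2)
  # doubling the odds costs exactly PD0 points (unrounded)
  expect_equal((card$scaling$A - card$scaling$B * (lnodds[1] + log(2))),
               sc$score_unrounded[1] - card$scaling$PD0, tolerance = 1e-9)
})

test_that("ferritin points fall as its bins climb into MAS territory", {
  fx <- default_card_fixture()
  pts <- fx$card$points$ferritin$points
  expect_true(all(diff(pts) <= 0))
  expect_gt(length(pts), 2)
})

test_that("KS threshold equals the brute-force maximizer, with the documented tie rule", {
  toy <- c(10, 20, 30, 40, 50, 60, 70, 80)
  lab <- c(1, 1, 1, 0, 1, 0, 0, 0)
  res <- ks_threshold(toy, lab)
  ora <- ks_bruteforce(toy, lab)
  expect_equal(res$ks, ora$ks)
  expect_equal(res$threshold, ora$threshold)

  sep <- ks_threshold(c(1:5, 11:15), c(rep(1, 5), rep(0, 5)))
  expect_equal(sep$ks, 1)
  expect_equal(sep$threshold, 5)
  same <- ks_threshold(rep(c(1, 2, 3), 4), rep(0:1, 6))
  expect_lt(same$ks, 0.35)
  expect_error(ks_threshold(1:5, rep(1, 5)), "both classes")
})

test_that("the KDE risk function integrates to unit mass and respects symmetry and separation", {
  withr::with_seed(21, {
    a <- rnorm(100, 30, 8)
    b <- rnorm(100, 70, 8)
  })
  rk <- kde_risk(a, a, prior_pos = 0.5)
  expect_equal(rk$risk(c(20, 30, 40)), rep(0.5, 3), tolerance = 1e-6)

  rk2 <- kde_risk(a, b, prior_pos = 0.5)
  expect_gt(rk2$risk(25), 0.98)
  expect_lt(rk2$risk(75), 0.02)
  for (d in list(rk2$density_pos, rk2$density_neg)) {
    mass <- sum(diff(d$x) * (head(d$y, -1) + tail(d$y, -1)) / 2)
    expect_equal(mass, 1, tolerance = 0.01)
  }
  expect_error(kde_risk(rep(5, 10), b), "bandwidth")
  expect_error(kde_risk(a[1:3], b), "at least 5")
})

test_that("band thresholds partition a monotone risk curve and flag flat or unattained levels", {
  smooth <- function(s) stats::plogis((50 - s) / 6)
  bands <- band_thresholds(smooth, score_range = 0:100)
  th <- bands$thresholds
  expect_true(all(diff(th) > 0))
  expect_equal(bands$bands$label,
               c("extremely high", "high", "normal", "low", "extremely low"))
  # bands tile the grid: each hi is the next band's lo
  expect_equal(bands$bands$lo[-1], bands$bands$hi[-5])

  expect_error(band_thresholds(function(s) rep(0.5, length(s))), "never attained")
  expect_error(band_thresholds(function(s) s / 100), "not non-increasing")
})

test_that("patient scoring is band-consistent, bin-invariant, and strict about inputs", {
  fx <- default_card_fixture()
  card <- fx$card
  tr <- fx$cohort
  med <- as.list(vapply(tr$data, stats::median, numeric(1)))
  res <- score_patient(card, med)
  expect_identical(res$band,
                   mascard:::band_label(card$bands, res$score))
  expect_equal(res$predicted, as.integer(res$score <= card$threshold))
  expect_true(res$risk >= 0 && res$risk <= 1)

  # moving inside the same bin cannot change the score
  p2 <- med
  bin <- card$points$ferritin
  idx <- cut(med$ferritin, c(-Inf, bin$hi[-nrow(bin)], Inf), labels = FALSE)
  lo <- if (idx == 1) med$ferritin - 1 else bin$lo[idx] + 1e-6
  p2$ferritin <- (lo + bin$hi[idx]) / 2
  if (is.finite(p2$ferritin)) {
    expect_equal(score_patient(card, p2)$score, res$score)
  }
  # out-of-range values land in terminal bins rather than failing
  p3 <- med
  p3$ferritin <- 1e7
  expect_no_error(score_patient(card, p3))
  expect_error(score_patient(card, med[-1]),
               names(med)[1])
})

test_that("an exported card re-scores patients identically after reloading", {
  fx <- default_card_fixture()
  dir <- withr::local_tempdir()
  write_scorecard(fx$card, dir)
  card2 <- read_scorecard(dir)
  sc1 <- predict(fx$card, fx$cohort)
  sc2 <- predict(card2, fx$cohort)
  expect_identical(sc1$score, sc2$score)
  expect_identical(sc1$predicted, sc2$predicted)
  expect_true(file.exists(file.path(dir, "card.csv")))
})
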