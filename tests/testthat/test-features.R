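test_that("pearson filter removes duplicates and the less label-correlated pair member", {
  withr::with_seed(1, {
    a <- rnorm(200)
    y <- as.integer(a + rnorm(200, sd = 0.5) > 0)
    co <- make_cohort(data.frame(a = a, a_copy = a, c = rnorm(200)), y)
  })
  out <- pearson_filter(co, 0.8)
  expect_equal(ncol(out$cohort$data), 2)
  expect_equal(nrow(out$report), 1)
  expect_true("a" %in% colnames(out$cohort$data) ||
              "a_copy" %in% colnames(out$cohort$data))

  # engineered pair: b = a + small noise, label driven by a => b removed
  withr::with_seed(2, {
    a <- rnorm(500)
    b <- a + rnorm(500, sd = 0.2)
    y <- as.integer(a > 0)
    co2 <- make_cohort(data.frame(a = a, b = b, z = rnorm(500)), y)
  })
  out2 <- pearson_filter(co2, 0.8)
  expect_identical(out2$report$feature, "b")
  expect_identical(out2$report$kept_partner, "a")
})

test_that("independent features survive the pearson filter", {
  removed <- vapply(1:10, function(s) {
    withr::with_seed(s, {
      co <- make_cohort(as.data.frame(matrix(rnorm(2000 * 6), 2000)),
                        rep(0:1, 1000))
    })
    nrow(pearson_filter(co, 0.8)$report)
  }, numeric(1))
  expect_true(all(removed == 0))
})

test_that("constant features are dropped with a warning", {
  co <- make_cohort(data.frame(flat = rep(1, 20), v = rnorm(20)), rep(0:1, 10))
  expect_warning(out <- pearson_filter(co), "flat")
  expect_identical(colnames(out$cohort$data), "v")
})

test_that("VIF filter matches the auxiliary-regression definition and prunes collinearity", {
  # orthogonal design: all VIF exactly 1, nothing removed
  q <- qr.Q(qr(matrix(rnorm(100 * 4), 100)))
  co <- make_cohort(as.data.frame(q), rep(0:1, 50))
  out <- vif_filter(co, 10)
  expect_equal(unname(out$vif), rep(1, 4), tolerance = 1e-3)
  expect_equal(nrow(out$report), 0)

  # two uncorrelated features: closed form VIF = 1/(1 - r^2) ~ 1
  withr::with_seed(3, {
    two <- make_cohort(data.frame(a = rnorm(300), b = rnorm(300)), rep(0:1, 150))
  })
  expect_equal(unname(vif_filter(two, 10)$vif), c(1, 1), tolerance = 0.05)

  # c = a + b + tiny noise: one member of the dependent triple goes first
  withr::with_seed(4, {
    a <- rnorm(200); b <- rnorm(200)
    co3 <- make_cohort(data.frame(a = a, b = b, c = a + b + rnorm(200, sd = 0.01),
                                  d = rnorm(200)), rep(0:1, 100))
  })
  out3 <- vif_filter(co3, 10)
  expect_true(out3$report$feature[1] %in% c("a", "b", "c"))
  expect_true(all(out3$vif < 10))

  # independent cross-check against car's VIF on the same design
  skip_if_not_installed("car")
  withr::with_seed(5, {
    d <- data.frame(x1 = rnorm(150), x2 = rnorm(150))
    d$x3 <- d$x1 * 0.7 + rnorm(150, sd = 0.5)
    resp <- rnorm(150)
  })
  ours <- mascard:::vif_values(d)
  theirs <- car::vif(lm(resp ~ ., data = d))
  expect_equal(unname(ours[names(theirs)]), unname(theirs), tolerance = 1e-6)
})

test_that("exact duplicates give infinite VIF and are removed deterministically", {
  withr::with_seed(6, a <- rnorm(50))
  co <- make_cohort(data.frame(a = a, a2 = a, b = rnorm(50)), rep(0:1, 25))
  out <- vif_filter(co, 10)
  expect_equal(out$report$feature[1], "a")   # alphabetically first of the tie
  expect_false("a" %in% colnames(out$cohort$data))
})

test_that("composites implement the three-lineage conjunction and transaminase disjunction", {
  co <- generate_cohort(cohort_config(seed = 21, raw_lineage = TRUE,
                                      n_neg = 10, n_pos = 10, n_noise = 0))
  co <- impute_cohort(co)$cohort
  lo <- function(nm) mascard:::spec_by_name(co$specs, nm)$normal_range[1]
  hi <- function(nm) mascard:::spec_by_name(co$specs, nm)$normal_range[2]
  # plant the three canonical cases
  co$data[1, c("hb", "plt", "wbc")] <- c(lo("hb"), lo("plt"), lo("wbc")) - 1  # all low
  co$data[1, c("alt", "ast")] <- c(hi("alt"), hi("ast")) - 1                  # normal
  co$data[2, c("hb", "plt")] <- c(lo("hb"), lo("plt")) - 1
  co$data[2, "wbc"] <- lo("wbc") + 0.5                                        # wbc normal
  co$data[2, c("alt", "ast")] <- c(hi("alt"), hi("ast")) - 1                  # normal
  co$data[3, c("hb", "plt", "wbc", "alt")] <-
    c(lo("hb") + 1, lo("plt") + 1, lo("wbc") + 0.1, hi("alt") - 1)
  co$data[3, "ast"] <- hi("ast") + 5                                          # AST high only
  out <- make_composites(co)
  expect_equal(out$data$pancytopenia[1:3], c(1, 0, 0))
  expect_equal(out$data$liver_damage[1:3], c(0, 0, 1))
  expect_false(any(c("hb", "plt", "wbc", "alt", "ast") %in% colnames(out$data)))

  broken <- co
  broken$data$ast <- NULL
  expect_error(make_composites(broken), "ast")
})

test_that("full shrinkage selects nothing and a lone strong signal is found first", {
  withr::with_seed(7, {
    x <- as.data.frame(matrix(rnorm(200 * 5), 200))
    names(x) <- paste0("f", 1:5)
    y <- rep(0:1, 100)
    x$f1 <- x$f1 + 2 * y
    x[] <- scale(x)
    co <- make_cohort(x, y)
  })
  big <- lasso_select(co, lambda_grid = c(5, 4, 3, 2), seed = 1)
  expect_length(big$selected, 0)

  full <- lasso_select(co, seed = 1)
  expect_true("f1" %in% full$selected)
  # path order: the first feature to enter the path is the strong one
  path_first <- full$lambda_path$nonzero[full$lambda_path$nonzero > 0][1]
  expect_equal(path_first, 1)
  expect_error(lasso_select(make_cohort(x, rep(1, 200)), seed = 1), "degenerate")
})

test_that("selection is invariant to feature column order", {
  co <- prepared_default_cohort(seed = 31)
  z <- zscore_apply(co, zscore_fit(co))
  sel1 <- lasso_select(z, seed = 2)$selected
  perm <- z
  perm$data <- perm$data[, rev(colnames(perm$data))]
  sel2 <- lasso_select(perm, seed = 2)$selected
  expect_identical(sel1, sel2)
})

test_that("the CV path grows the active set as the penalty shrinks", {
  co <- prepared_default_cohort(seed = 32)
  z <- zscore_apply(co, zscore_fit(co))
  rep_ <- lasso_select(z, seed = 3)
  path <- rep_$lambda_path[order(-rep_$lambda_path$lambda), ]
  expect_equal(path$nonzero[1], 0)
  expect_gt(path$nonzero[nrow(path)], path$nonzero[1])
  expect_true(rep_$best_lambda %in% rep_$lambda_path$lambda)
  expect_true(all(rep_$selected %in% colnames(z$data)))
})

test_that("default-seed end-to-end selection recovers the planted panel (regression lock)", {
  co <- prepared_default_cohort(seed = 1)
  z <- zscore_apply(co, zscore_fit(co))
  sel <- lasso_select(z, seed = 1)$selected
  expect_true(all(planted_features() %in% sel))
  expect_lte(sum(grepl("^noise_", sel)), 3)
  expect_identical(sel, sort(c(planted_features(), "noise_08", "noise_15")))
})
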