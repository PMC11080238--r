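test_that("F-beta matches its closed form and harmonic-mean identities", {
  expect_equal(f_beta(0.9, 0.9, 2), 0.9)
  expect_equal(f_beta(0.9, 0.9, 1), 0.9)
  expect_equal(f_beta(0.5, 1.0, 2), 5 * 0.5 / (4 * 0.5 + 1))  # 0.8333...
  grid <- expand.grid(p = seq(0.05, 1, 0.05), r = seq(0.05, 1, 0.05))
  expect_equal(f_beta(grid$p, grid$r, 1),
               2 * grid$p * grid$r / (grid$p + grid$r))
  # recall > precision favours F2 over F1 and vice versa
  f1 <- f_beta(grid$p, grid$r, 1)
  f2 <- f_beta(grid$p, grid$r, 2)
  expect_true(all(f2[grid$r > grid$p] >= f1[grid$r > grid$p]))
  expect_true(all(f2[grid$r < grid$p] <= f1[grid$r < grid$p]))
  expect_warning(z <- f_beta(0, 0, 2), "zero")
  expect_equal(z, 0)
  expect_error(f_beta(1.2, 0.5), "\\[0, 1\\]")
  expect_error(f_beta(0.5, 0.5, beta = 0))
})

test_that("rank-based AUC agrees with exhaustive pair counting and pROC", {
  expect_equal(roc_auc(c(1, 2, 3, 10), c(0, 0, 1, 1)), 1)
  expect_equal(roc_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)), 0.75)
  expect_equal(auc_paircount(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)), 0.75)
  for (s in 1:20) {
    withr::with_seed(s, {
      n <- sample(10:30, 1)
      sc <- sample(seq(0, 1, 0.1), n, replace = TRUE)  # plenty of ties
      y <- sample(0:1, n, replace = TRUE)
    })
    if (length(unique(y)) < 2) next
    expect_equal(roc_auc(sc, y), auc_paircount(sc, y), info = paste("seed", s))
  }
  skip_if_not_installed("pROC")
  withr::with_seed(99, {
    sc <- rnorm(200)
    y <- rep(0:1, 100)
  })
  expect_equal(roc_auc(sc, y),
               as.numeric(pROC::auc(pROC::roc(y, sc, quiet = TRUE,
                                              direction = "<"))))
})

test_that("AUC is invariant under monotone transforms and ~0.5 for uninformative scores", {
  withr::with_seed(17, {
    sc <- runif(2000)
    y <- rep(0:1, 1000)
  })
  a <- roc_auc(sc, y)
  expect_equal(a, 0.5, tolerance = 0.1)
  expect_equal(roc_auc(exp(5 * sc), y), a)
  expect_equal(roc_auc(rank(sc), y), a)
  expect_error(roc_auc(sc, rep(1, 2000)), "both classes")
})

test_that("confusion metrics at a threshold behave at the degenerate corners", {
  y <- c(rep(0, 15), rep(1, 5))
  m <- eval_metrics(rep(0.3, 20), y, threshold = 0.5)  # constant majority rule
  expect_equal(m$tp, 0)
  expect_equal(m$f2, 0)
  expect_equal(m$tp + m$fp + m$tn + m$fn, 20)
})

toy_cohort <- function(n = 40, sep = 3, seed = 5, p = 3) {
  withr::with_seed(seed, {
    y <- rep(0:1, n / 2)
    x <- as.data.frame(matrix(rnorm(n * p), n))
    names(x) <- paste0("f", seq_len(p))
    x$f1 <- x$f1 + sep * y
    x[] <- scale(x)
  })
  make_cohort(x, y)
}

test_that("grid search over a single point equals a direct fit and is seed-reproducible", {
  co <- toy_cohort()
  spec <- model_spec("l2_logistic", grid = list(lambda = 0.1), seed = 3)
  fit <- grid_search_fit(co, spec)
  direct <- mascard:::fit_one(as.matrix(co$data), co$label, "l2_logistic",
                              list(lambda = 0.1), 3)
  expect_equal(predict(fit, co),
               mascard:::predict_prob_one(direct, "l2_logistic",
                                          as.matrix(co$data)))
  fit2 <- grid_search_fit(co, spec)
  expect_identical(fit$params, fit2$params)

  rf <- grid_search_fit(co, model_spec("random_forest", seed = 4))
  rf2 <- grid_search_fit(co, model_spec("random_forest", seed = 4))
  expect_identical(rf$params, rf2$params)
  expect_equal(predict(rf, co), predict(rf2, co))
})

test_that("stronger L2 penalties shrink the logistic coefficient norm monotonically", {
  co <- toy_cohort(sep = 4)
  norms <- vapply(c(0.05, 0.5, 5), function(l) {
    f <- mascard:::fit_one(as.matrix(co$data), co$label, "l2_logistic",
                           list(lambda = l), 1)
    sum(as.matrix(stats::coef(f$fit, s = l))[-1, 1]^2)
  }, numeric(1))
  expect_true(all(diff(norms) < 1e-8))
  expect_gt(norms[1], norms[3] * 1.5)
})

test_that("invalid grids are rejected with the offending parameter named", {
  expect_error(model_spec("svm", grid = list(cost = numeric(0))), "cost")
  expect_error(model_spec("svm", grid = list(bogus = 1)), "bogus")
  expect_error(model_spec("nonsense"))
})

test_that("leave-one-out pools exactly n held-out predictions and nails separable data", {
  co <- toy_cohort(n = 20, sep = 5)
  spec <- model_spec("l2_logistic", grid = list(lambda = 0.01), seed = 1)
  res <- loo_validate(co, spec)
  expect_length(res$predictions, 20)
  expect_false(any(is.na(res$predictions)))
  expect_equal(res$metrics$auc, 1.0)
  expect_error(loo_validate(toy_cohort(n = 8), spec), "n >= 10")
})

test_that("the evaluation suite emits one reproducible row per model and split", {
  co <- toy_cohort(n = 60, seed = 6)
  test1 <- toy_cohort(n = 30, seed = 7)
  models <- list(
    lr = grid_search_fit(co, model_spec("l2_logistic",
                                        grid = list(lambda = 0.01), seed = 1)),
    gb = grid_search_fit(co, model_spec("gradient_boosting",
                                        grid = list(eta = 0.3, max_depth = 2,
                                                    nrounds = 30), seed = 1))
  )
  tab <- evaluate_suite(models, list(test = test1, test_again = test1))
  expect_equal(nrow(tab), 4)
  expect_equal(tab[tab$split == "test", -2], tab[tab$split == "test_again", -2],
               ignore_attr = TRUE)
  expect_true(all(tab$auc >= 0 & tab$auc <= 1))
  bad <- test1
  bad$data$f1 <- NULL
  expect_error(evaluate_suite(models, list(b = bad)), "f1")
})

test_that("all four model families fit, predict probabilities, and separate an easy cohort", {
  co <- toy_cohort(n = 60, sep = 3, seed = 8)
  holdout <- toy_cohort(n = 40, sep = 3, seed = 9)
  for (fam in c("l2_logistic", "random_forest", "svm", "gradient_boosting")) {
    fit <- grid_search_fit(co, model_spec(fam, seed = 2))
    p <- predict(fit, holdout)
    expect_true(all(p >= 0 & p <= 1), info = fam)
    expect_gt(roc_auc(p, holdout$label), 0.9)
  }
})
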