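#' Pipeline configuration
#'
#' One serializable object drives the whole study: simulation, tiered
#' imputation, outlier handling, standardization, two-stage feature
#' selection, the four classifier families, and the scorecard. All
#' randomness flows from `seed` via fixed per-stage offsets (simulation
#' `seed`, split `seed + 1`, external cohort `seed + 2`, LASSO folds
#' `seed + 3`, model fits `seed + 4`...).
#'
#' @param seed Master seed; default 101.
#' @param n_neg,n_pos,n_noise Cohort design; defaults 94/94/20.
#' @param external_shift_location,external_shift_scale Inter-hospital drift
#'   of the external cohort; defaults 0.25 and 1.1. Set
#'   `external_n = 0` to disable the external split.
#' @param external_n Patients per class in the external cohort; default 60.
#' @param test_fraction Held-out internal test fraction; default 0.2.
#' @param range_flags Add range-flag features to the selection candidate
#'   set; default `FALSE` (the thirteen raw predictors define the planted
#'   truth).
#' @param outlier_k Tukey fence multiplier; default 1.5. `winsorize = FALSE`
#'   only flags outliers without clipping.
#' @param winsorize Clip outliers to the fences; default `TRUE`.
#' @param r_threshold,vif_threshold Stage-one selection cutoffs; defaults
#'   0.8 and 10.
#' @param families Model families to fit; default all four.
#' @param validation `"loo"` (leave-one-out on the training split, default)
#'   or `"none"`.
#' @param threshold Probability cutoff for classifier confusion metrics;
#'   default 0.5.
#' @param scorecard Named list of [build_scorecard()] arguments to
#'   override.
#' @param policy An [imputation_policy()].
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 101L,
                            n_neg = 94L, n_pos = 94L, n_noise = 20L,
                            external_n = 60L,
                            external_shift_location = 0.25,
                            external_shift_scale = 1.1,
                            test_fraction = 0.2,
                            range_flags = FALSE,
                            outlier_k = 1.5, winsorize = TRUE,
                            r_threshold = 0.8, vif_threshold = 10,
                            families = c("l2_logistic", "random_forest",
                                         "svm", "gradient_boosting"),
                            validation = c("loo", "none"),
                            threshold = 0.5,
                            scorecard = list(),
                            policy = NULL) {
  validation <- match.arg(validation)
  structure(
    list(seed = as.integer(seed), n_neg = as.integer(n_neg),
         n_pos = as.integer(n_pos), n_noise = as.integer(n_noise),
         external_n = as.integer(external_n),
         external_shift_location = external_shift_location,
         external_shift_scale = external_shift_scale,
         test_fraction = test_fraction, range_flags = isTRUE(range_flags),
         outlier_k = outlier_k, winsorize = isTRUE(winsorize),
         r_threshold = r_threshold, vif_threshold = vif_threshold,
         families = families, validation = validation,
         threshold = threshold, scorecard = scorecard,
         policy = policy %||% imputation_policy(seed = as.integer(seed))),
    class = "pipeline_config"
  )
}

#' Run the full diagnostic-modelling pipeline
#'
#' Executes simulate -> preprocess -> select -> train -> evaluate ->
#' scorecard -> bands, and (optionally) writes every artifact to a run
#' directory: the metric table over the five models (four classifiers plus
#' the scorecard) across the validation/test/external splits, the selection
#' reports, the card CSV/JSON, the KS-curve and density/risk-curve series,
#' and a manifest with the configuration and seeds. The run is fully
#' reproducible from `config` alone.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Optional run directory; when `NULL` nothing is written.
#' @param quiet Suppress stage messages; default `FALSE`.
#' @return An object of class `mas_run` (invisibly when writing): cohorts,
#'   scaler, selection reports, fitted models, `metrics`, scorecard,
#'   `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL,
                         quiet = FALSE) {
  say <- function(...) if (!quiet) message(sprintf(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  say("stage simulate: %d + %d patients, %d noise features",
      config$n_neg, config$n_pos, config$n_noise)
  cohort <- stage("simulate", generate_cohort(cohort_config(
    n_neg = config$n_neg, n_pos = config$n_pos, n_noise = config$n_noise,
    seed = config$seed)))
  external <- NULL
  if (config$external_n > 0) {
    external <- stage("simulate", generate_external_cohort(
      cohort_config(n_neg = config$external_n, n_pos = config$external_n,
                    n_noise = config$n_noise, seed = config$seed + 2L),
      shift_location = config$external_shift_location,
      shift_scale = config$external_shift_scale))
  }

  say("stage preprocess: tiered imputation + outlier winsorization")
  imp <- stage("preprocess", impute_cohort(cohort, config$policy))
  audit <- stage("preprocess", audit_shift(cohort, imp$cohort,
                                           config$policy$audit_alpha))
  complete <- imp$cohort
  if (config$range_flags) complete <- derive_range_flags(complete)
  outl <- stage("preprocess", flag_outliers_iqr(complete, config$outlier_k))
  if (config$winsorize) complete <- outl$cohort

  split <- stratified_split(complete$label, config$test_fraction,
                            config$seed + 1L)
  train_raw <- subset_cohort(complete, split$train)
  test_raw <- subset_cohort(complete, split$test)
  scaler <- stage("preprocess", zscore_fit(train_raw))
  train <- zscore_apply(train_raw, scaler)
  test <- zscore_apply(test_raw, scaler)
  external_raw <- NULL
  if (!is.null(external)) {
    # external patients with any missing value are excluded, then the
    # previously fitted Z-score model is reused unchanged
    keep <- rowSums(cohort_mask(external)) == 0
    external_raw <- subset_cohort(external, keep)
    if (config$range_flags) external_raw <- derive_range_flags(external_raw)
    external <- zscore_apply(external_raw, scaler)
    say("stage preprocess: external cohort kept %d/%d complete patients",
        sum(keep), length(keep))
  }

  # feature screening precedes the train/test split (the study's order:
  # candidate panel -> selection -> models); only hyperparameters and model
  # weights see the split
  say("stage select: Pearson |r| >= %.2f, VIF >= %.0f, LASSO 5-fold CV",
      config$r_threshold, config$vif_threshold)
  sel <- stage("select", select_two_stage(
    zscore_apply(complete, zscore_fit(complete)),
    r_threshold = config$r_threshold,
    vif_threshold = config$vif_threshold, seed = config$seed + 3L))
  selected <- sel$selected
  say("stage select: %d features selected: %s", length(selected),
      paste(selected, collapse = ", "))

  say("stage train: %s", paste(config$families, collapse = ", "))
  train_sel <- select_features(train, selected)
  test_sel <- select_features(test, selected)
  splits <- list(test = test_sel)
  if (!is.null(external)) splits$external <- select_features(external, selected)
  models <- list()
  metrics <- list()
  for (i in seq_along(config$families)) {
    fam <- config$families[i]
    fit <- stage("train", {
      spec <- model_spec(fam, seed = config$seed + 4L + i)
      grid_search_fit(train_sel, spec)
    })
    models[[fam]] <- fit
    if (config$validation == "loo") {
      say("stage evaluate: leave-one-out for %s", fam)
      loo <- stage("evaluate", loo_validate(train_sel, fit,
                                            config$threshold))
      metrics[[length(metrics) + 1L]] <- cbind(
        data.frame(model = fam, split = "validation"), loo$metrics)
    }
  }
  ev <- stage("evaluate", evaluate_suite(models, splits, config$threshold))
  metrics <- rbind(do.call(rbind, metrics), ev)

  say("stage scorecard: ChiMerge + WOE + PDO scaling")
  card_args <- utils::modifyList(
    list(cohort = select_features(train_raw, selected)), config$scorecard)
  card <- stage("scorecard", do.call(build_scorecard, card_args))
  sc_rows <- list()
  card_splits <- list(validation = select_features(train_raw, selected),
                      test = select_features(test_raw, selected))
  if (!is.null(external_raw)) {
    card_splits$external <- select_features(external_raw, selected)
  }
  for (sn in names(card_splits)) {
    sc_rows[[sn]] <- predict(card, card_splits[[sn]])
  }
  sc_metrics <- do.call(rbind, lapply(names(card_splits), function(sn) {
    sc <- sc_rows[[sn]]
    y <- card_splits[[sn]]$label
    # MAS = low scores: AUC on negated score; confusion from the KS rule
    m <- eval_metrics(-sc$score, y, threshold = -card$threshold)
    m$threshold <- card$threshold
    cbind(data.frame(model = "scorecard", split = sn), m)
  }))
  metrics <- rbind(metrics, sc_metrics)
  rownames(metrics) <- NULL

  manifest <- list(
    package = "mascard",
    version = as.character(utils::packageVersion("mascard")),
    seed = config$seed,
    config = config[setdiff(names(config), "policy")],
    policy = unclass(config$policy),
    n_train = nrow(train$data), n_test = nrow(test$data),
    n_external = if (is.null(external)) 0L else nrow(external$data),
    selected = selected
  )

  run <- structure(
    list(config = config, cohort = cohort, train = train_sel,
         test = test_sel, external = splits$external,
         train_raw = train_raw, test_raw = test_raw,
         external_raw = external_raw,
         imputation = imp$report, audit = audit, outliers = outl$mask,
         scaler = scaler, selection = sel, selected = selected,
         models = models, metrics = metrics, scorecard = card,
         scorecard_scores = sc_rows, manifest = manifest),
    class = "mas_run"
  )
  if (!is.null(out_dir)) write_run(run, out_dir)
  run
}

write_run <- function(run, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(run$metrics, file.path(out_dir, "metrics.csv"),
                   row.names = FALSE)
  utils::write.csv(run$imputation, file.path(out_dir, "imputation_report.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(pearson_removed = run$selection$pearson,
         vif_removed = run$selection$vif,
         best_lambda = run$selection$lasso$best_lambda,
         lambda_path = run$selection$lasso$lambda_path,
         selected = run$selected),
    file.path(out_dir, "selection.json"), auto_unbox = TRUE, digits = NA,
    na = "null")
  jsonlite::write_json(
    data.frame(feature = run$scaler$feature, mean = run$scaler$mean,
               sd = run$scaler$sd),
    file.path(out_dir, "scaler.json"), digits = NA)
  write_scorecard(run$scorecard, file.path(out_dir, "scorecard"))
  utils::write.csv(run$scorecard$ks$curve,
                   file.path(out_dir, "scorecard", "ks_curve.csv"),
                   row.names = FALSE)
  rk <- run$scorecard$risk
  grid <- 0:100
  utils::write.csv(
    data.frame(score = grid,
               density_mas = stats::approx(rk$density_pos$x,
                                           rk$density_pos$y, grid)$y,
               density_sle = stats::approx(rk$density_neg$x,
                                           rk$density_neg$y, grid)$y,
               risk = rk$risk(grid)),
    file.path(out_dir, "scorecard", "risk_curve.csv"), row.names = FALSE)
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(run$manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, na = "null")
  run$manifest$config_hash <- unname(tools::md5sum(manifest_path))
  invisible(out_dir)
}

#' Summarize a completed run directory
#'
#' Assembles the run's artifacts into a single markdown document: the
#' model-by-split metric table, the selected features, the scorecard with
#' its decision threshold, and the risk bands. Regenerating the report from
#' the same run directory yields a byte-identical document.
#'
#' @param run_dir Directory written by [run_pipeline()].
#' @param out Optional output path for the document; default
#'   `file.path(run_dir, "report.md")`; `NULL` to skip writing.
#' @return The report text, invisibly.
#' @export
report_run <- function(run_dir, out = file.path(run_dir, "report.md")) {
  need <- c("metrics.csv", "selection.json",
            file.path("scorecard", "card.csv"),
            file.path("scorecard", "scorecard.json"))
  absent <- need[!file.exists(file.path(run_dir, need))]
  if (length(absent)) {
    stop("incomplete run; missing: ", paste(absent, collapse = ", "))
  }
  metrics <- utils::read.csv(file.path(run_dir, "metrics.csv"))
  selection <- jsonlite::read_json(file.path(run_dir, "selection.json"),
                                   simplifyVector = TRUE)
  card <- utils::read.csv(file.path(run_dir, "scorecard", "card.csv"))
  bundle <- jsonlite::read_json(file.path(run_dir, "scorecard",
                                          "scorecard.json"),
                                simplifyVector = TRUE)
  fmt_tab <- function(df) {
    hdr <- paste0("| ", paste(names(df), collapse = " | "), " |")
    sep <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
    rows <- apply(df, 1, function(r) paste0("| ", paste(trimws(r), collapse = " | "), " |"))
    paste(c(hdr, sep, rows), collapse = "\n")
  }
  m <- metrics
  num <- vapply(m, is.numeric, logical(1))
  m[num] <- lapply(m[num], function(v) round(v, 3))
  splits_present <- unique(metrics$split)
  absent_splits <- setdiff(c("validation", "test", "external"), splits_present)
  lines <- c(
    "# MAS-secondary-to-SLE diagnostic pipeline report", "",
    "## Model performance (AUC / F1 / F2 by split)", "",
    fmt_tab(m[, c("model", "split", "auc", "f1", "f2")]), "",
    if (length(absent_splits)) {
      c(sprintf("Splits not evaluated in this run: %s.",
                paste(absent_splits, collapse = ", ")), "")
    },
    "## Selected features", "",
    paste0("- ", selection$selected), "",
    sprintf("LASSO best lambda: %.4g (log %.2f).", selection$best_lambda,
            log(selection$best_lambda)), "",
    "## Scorecard", "",
    sprintf("Scaling: A = %.2f, B = %.2f (odds0 = %.4g, P0 = %g, PD0 = %g).",
            bundle$scaling$A, bundle$scaling$B, bundle$scaling$odds0,
            bundle$scaling$P0, bundle$scaling$PD0), "",
    sprintf("KS decision threshold: score <= %g predicts MAS (KS = %.3f).",
            bundle$threshold, bundle$ks), "",
    fmt_tab(data.frame(feature = card$feature, bin = card$bin,
                       points = card$points)), "",
    "## Risk bands", "",
    fmt_tab(as.data.frame(bundle$bands)), ""
  )
  txt <- paste(lines, collapse = "\n")
  if (!is.null(out)) writeLines(txt, out)
  invisible(txt)
}

#' @export
print.mas_run <- function(x, ...) {
  cat(sprintf("<mas_run> seed %d: %d train / %d test / %s external patients\n",
              x$config$seed, nrow(x$train$data), nrow(x$test$data),
              if (is.null(x$external)) "no" else nrow(x$external$data)))
  cat(sprintf("  selected (%d): %s\n", length(x$selected),
              paste(x$selected, collapse = ", ")))
  cat(sprintf("  scorecard threshold %g, KS %.3f\n",
              x$scorecard$threshold, x$scorecard$ks$ks))
  print(x$metrics[, c("model", "split", "auc", "f1", "f2")], digits = 3)
  invisible(x)
}
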