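#' Cohort simulation configuration
#'
#' @param n_neg Number of SLE (negative-class) patients; default 94.
#' @param n_pos Number of MAS-secondary-to-SLE (positive-class) patients;
#'   default 94, giving the balanced 188-patient design.
#' @param features List of [feature_spec()] objects for the informative
#'   features; defaults to [default_feature_specs()].
#' @param n_noise Number of uninformative nuisance features (standard normal
#'   in both classes); default 20.
#' @param seed Integer seed; fully determines the generated cohort.
#' @param raw_lineage If `TRUE`, the pancytopenia and liver-damage composites
#'   are replaced by their five source analytes ([raw_lineage_specs()]) so
#'   that [make_composites()] can be exercised.
#' @param mortality Length-2 numeric `(neg, pos)` in-hospital mortality
#'   rates recorded in the cohort metadata; defaults to `c(0, 15/94)`, the
#'   study's observed group mortality (0/94 SLE deaths, 15/94 MAS deaths).
#' @param severity_rho Within-class correlation in `[0, 1)` induced among
#'   the continuous informative features by a latent per-patient severity
#'   factor (real laboratory panels co-move with overall inflammatory
#'   severity); marginal distributions are unaffected and noise features
#'   stay independent. Default 0: the benchmark cohort keeps features
#'   conditionally independent so that planted-predictor recovery by the
#'   selection stage is well defined.
#'
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_neg = 94L, n_pos = 94L,
                          features = default_feature_specs(),
                          n_noise = 20L, seed = 1L,
                          raw_lineage = FALSE,
                          mortality = c(0, 15 / 94),
                          severity_rho = 0) {
  bad <- function(field, why) {
    stop(sprintf("invalid cohort_config: field '%s' %s", field, why))
  }
  if (!is.numeric(n_neg) || n_neg < 2) bad("n_neg", "must be >= 2")
  if (!is.numeric(n_pos) || n_pos < 2) bad("n_pos", "must be >= 2")
  if (!is.numeric(n_noise) || n_noise < 0) bad("n_noise", "must be >= 0")
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) bad("seed", "must be a single integer")
  if (!is.list(features) || !all(vapply(features, inherits, logical(1), "feature_spec"))) {
    bad("features", "must be a list of feature_spec objects")
  }
  if (length(mortality) != 2L || any(mortality < 0) || any(mortality > 1)) {
    bad("mortality", "must be two rates in [0, 1]")
  }
  if (!is.numeric(severity_rho) || severity_rho < 0 || severity_rho >= 1) {
    bad("severity_rho", "must lie in [0, 1)")
  }
  if (isTRUE(raw_lineage)) {
    keep <- !vapply(features, function(s) s$name %in% c("pancytopenia", "liver_damage"),
                    logical(1))
    features <- c(features[keep], raw_lineage_specs())
  }
  nm <- vapply(features, `[[`, character(1), "name")
  if (anyDuplicated(nm)) bad("features", "contains duplicated feature names")
  structure(
    list(n_neg = as.integer(n_neg), n_pos = as.integer(n_pos),
         features = features, n_noise = as.integer(n_noise),
         seed = as.integer(seed), raw_lineage = isTRUE(raw_lineage),
         mortality = as.numeric(mortality),
         severity_rho = severity_rho),
    class = "cohort_config"
  )
}

draw_dist <- function(dist, n) {
  switch(dist$family,
    normal    = stats::rnorm(n, dist$mean, dist$sd),
    lognormal = stats::rlnorm(n, dist$meanlog, dist$sdlog),
    bernoulli = stats::rbinom(n, 1L, dist$prob),
    stop(sprintf("unknown distribution family '%s'", dist$family))
  )
}

#' Generate a synthetic SLE / MAS-secondary-to-SLE cohort
#'
#' Draws a balanced (or user-sized) two-class cohort from the per-feature
#' class-conditional distributions of the configuration, appends `n_noise`
#' nuisance features drawn identically for both classes, injects
#' missing-completely-at-random entries per feature at its `missing_rate`,
#' and records a per-patient mortality indicator in the metadata. When
#' `severity_rho > 0`, a latent per-patient severity factor induces
#' within-class correlation among the continuous informative features
#' (marginals are untouched). The output is fully determined by the
#' configuration (including its seed).
#'
#' Continuous normal-family draws for analytes with a non-negative reference
#' range are floored at 0.01 to keep concentrations physical.
#'
#' @param config A [cohort_config()].
#' @return An object of class `mas_cohort`: a list with `data` (data frame
#'   of numeric features, `NA` = missing), `label` (integer vector, 0 = SLE,
#'   1 = MAS), `specs` (feature specifications, noise included), `meta`
#'   (data frame with `deceased`), and `config`.
#' @export
#' @examples
#' co <- generate_cohort(cohort_config(seed = 1))
#' nrow(co$data)  # 188
#' table(co$label)
generate_cohort <- function(config) {
  if (!inherits(config, "cohort_config")) {
    config <- do.call(cohort_config, config)
  }
  specs <- c(config$features, noise_specs(config$n_noise))
  n_neg <- config$n_neg
  n_pos <- config$n_pos
  n <- n_neg + n_pos
  rho <- config$severity_rho %||% 0
  informative <- vapply(config$features, `[[`, character(1), "name")
  withr::with_seed(config$seed, {
    z <- stats::rnorm(n)  # latent per-patient severity factor
    cols <- lapply(specs, function(sp) {
      correlated <- sp$kind == "continuous" && rho > 0 &&
        sp$name %in% informative &&
        sp$dist_neg$family %in% c("normal", "lognormal")
      if (correlated) {
        u <- sqrt(rho) * z + sqrt(1 - rho) * stats::rnorm(n)
        v <- if (sp$dist_neg$family == "normal") {
          mu <- c(rep(sp$dist_neg$mean, n_neg), rep(sp$dist_pos$mean, n_pos))
          sg <- c(rep(sp$dist_neg$sd, n_neg), rep(sp$dist_pos$sd, n_pos))
          mu + sg * u
        } else {
          mu <- c(rep(sp$dist_neg$meanlog, n_neg), rep(sp$dist_pos$meanlog, n_pos))
          sg <- c(rep(sp$dist_neg$sdlog, n_neg), rep(sp$dist_pos$sdlog, n_pos))
          exp(mu + sg * u)
        }
      } else {
        v <- c(draw_dist(sp$dist_neg, n_neg), draw_dist(sp$dist_pos, n_pos))
      }
      if (sp$kind == "continuous" &&
          sp$dist_neg$family == "normal" &&
          !is.null(sp$normal_range) && sp$normal_range[1] >= 0) {
        v <- pmax(v, 0.01)
      }
      v
    })
    names(cols) <- vapply(specs, `[[`, character(1), "name")
    df <- as.data.frame(cols, check.names = FALSE)
    for (sp in specs) {
      if (sp$missing_rate > 0) {
        miss <- stats::rbinom(n, 1L, sp$missing_rate) == 1L
        df[[sp$name]][miss] <- NA_real_
      }
    }
    # fixed group margins (round(rate * n) deaths), random positions: the
    # baseline table is emulated exactly, not just in expectation
    draw_deaths <- function(n_grp, rate) {
      k <- round(rate * n_grp)
      v <- integer(n_grp)
      if (k > 0) v[sample.int(n_grp, k)] <- 1L
      v
    }
    deceased <- c(draw_deaths(n_neg, config$mortality[1]),
                  draw_deaths(n_pos, config$mortality[2]))
  })
  structure(
    list(data = df,
         label = c(rep(0L, n_neg), rep(1L, n_pos)),
         specs = specs,
         meta = data.frame(deceased = deceased),
         config = config),
    class = "mas_cohort"
  )
}

#' Generate an external-validation cohort with inter-hospital drift
#'
#' Draws a cohort from mildly perturbed class-conditional distributions to
#' emulate a different hospital's patient mix and assays. The perturbation
#' moves each continuous feature's location parameter by
#' `shift_location` standard units (i.e. `location + shift_location * scale`
#' in the native parameter space: mean/sd for normal features,
#' meanlog/sdlog for log-normal features) and multiplies its scale parameter
#' by `shift_scale`. Binary prevalences are left unchanged. With
#' `shift_location = 0, shift_scale = 1` the output is identical to
#' [generate_cohort()] under the same configuration.
#'
#' @param config A [cohort_config()].
#' @param shift_location Location perturbation in per-feature scale units
#'   (finite); default 0.
#' @param shift_scale Multiplicative scale perturbation (> 0, finite);
#'   default 1.
#' @return A `mas_cohort` with the same schema (feature names, order) as the
#'   internal cohort.
#' @export
generate_external_cohort <- function(config, shift_location = 0,
                                     shift_scale = 1) {
  if (!is.finite(shift_location) || !is.finite(shift_scale) || shift_scale <= 0) {
    stop("shift_location must be finite and shift_scale finite and positive")
  }
  shift_one <- function(d) {
    if (is.null(d)) return(d)
    switch(d$family,
      normal = {
        d$mean <- d$mean + shift_location * d$sd
        d$sd <- d$sd * shift_scale
        d
      },
      lognormal = {
        d$meanlog <- d$meanlog + shift_location * d$sdlog
        d$sdlog <- d$sdlog * shift_scale
        d
      },
      bernoulli = d
    )
  }
  feats <- lapply(config$features, function(sp) {
    sp$dist_neg <- shift_one(sp$dist_neg)
    sp$dist_pos <- shift_one(sp$dist_pos)
    sp
  })
  cfg <- config
  cfg$features <- feats
  # noise features are identical in both classes and unshifted by design;
  # regenerate through the same path so seed policy matches generate_cohort
  generate_cohort(cfg)
}

#' @export
print.mas_cohort <- function(x, ...) {
  cat(sprintf("<mas_cohort> %d patients (%d SLE, %d MAS), %d features, %.1f%% missing\n",
              nrow(x$data), sum(x$label == 0L), sum(x$label == 1L),
              ncol(x$data), 100 * mean(is.na(as.matrix(x$data)))))
  invisible(x)
}

#' Missingness mask of a cohort
#'
#' @param cohort A `mas_cohort`.
#' @return Logical matrix, `TRUE` where the value is absent.
#' @export
cohort_mask <- function(cohort) is.na(as.matrix(cohort$data))

#' @export
as.data.frame.mas_cohort <- function(x, ...) {
  cbind(x$data, diagnosis = factor(ifelse(x$label == 1L, "MAS", "SLE"),
                                   levels = c("SLE", "MAS")))
}

subset_cohort <- function(cohort, idx) {
  cohort$data <- cohort$data[idx, , drop = FALSE]
  rownames(cohort$data) <- NULL
  cohort$label <- cohort$label[idx]
  if (!is.null(cohort$meta)) {
    cohort$meta <- cohort$meta[idx, , drop = FALSE]
    rownames(cohort$meta) <- NULL
  }
  cohort
}

select_features <- function(cohort, names) {
  missing <- setdiff(names, colnames(cohort$data))
  if (length(missing)) {
    stop("features absent from cohort: ", paste(missing, collapse = ", "))
  }
  cohort$data <- cohort$data[, names, drop = FALSE]
  cohort$specs <- Filter(function(sp) sp$name %in% names, cohort$specs)
  cohort
}

spec_by_name <- function(specs, name) {
  for (sp in specs) if (sp$name == name) return(sp)
  NULL
}

#' Write a cohort to CSV with a JSON sidecar
#'
#' One row per patient; a header of feature names; a `diagnosis` column with
#' `SLE`/`MAS`; missing values as empty cells. The sidecar records the
#' feature specifications, seed, and mortality metadata so the cohort can be
#' reconstructed exactly.
#'
#' @param cohort A `mas_cohort`.
#' @param path CSV output path.
#' @param sidecar JSON sidecar path; default `paste0(path, ".json")`.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path, sidecar = paste0(path, ".json")) {
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE, na = "")
  side <- list(
    specs = lapply(cohort$specs, unclass),
    seed = cohort$config$seed,
    deceased = cohort$meta$deceased
  )
  jsonlite::write_json(side, sidecar, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param path CSV path.
#' @param sidecar JSON sidecar path; default `paste0(path, ".json")`.
#' @return A `mas_cohort` (its `config` holds only the recorded seed).
#' @export
read_cohort <- function(path, sidecar = paste0(path, ".json")) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!"diagnosis" %in% names(df)) stop("cohort CSV lacks a 'diagnosis' column")
  label <- ifelse(df$diagnosis == "MAS", 1L, 0L)
  df$diagnosis <- NULL
  specs <- NULL
  meta <- NULL
  seed <- NA_integer_
  if (file.exists(sidecar)) {
    side <- jsonlite::read_json(sidecar, simplifyVector = FALSE)
    specs <- lapply(side$specs, function(s) {
      s$normal_range <- if (is.null(s$normal_range)) NULL else unlist(s$normal_range)
      do.call(feature_spec, s)
    })
    seed <- side$seed
    if (!is.null(side$deceased)) meta <- data.frame(deceased = unlist(side$deceased))
  }
  structure(
    list(data = df, label = label, specs = specs, meta = meta,
         config = list(seed = seed)),
    class = "mas_cohort"
  )
}

#' Baseline bookkeeping for a cohort
#'
#' Group sizes and the recorded in-hospital mortality per diagnosis group,
#' with the mortality percentage rounded to the nearest whole percent as
#' conventionally reported.
#'
#' @param cohort A `mas_cohort` with `deceased` metadata.
#' @return A data frame with one row per group: `group`, `n`, `deaths`,
#'   `mortality_pct`.
#' @export
cohort_baseline <- function(cohort) {
  if (is.null(cohort$meta) || is.null(cohort$meta$deceased)) {
    stop("cohort has no mortality metadata")
  }
  grp <- factor(ifelse(cohort$label == 1L, "MAS", "SLE"), levels = c("SLE", "MAS"))
  n <- as.vector(table(grp))
  deaths <- as.vector(tapply(cohort$meta$deceased, grp, sum))
  data.frame(group = levels(grp), n = n, deaths = deaths,
             mortality_pct = round(100 * deaths / n))
}
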