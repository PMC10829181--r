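# Orchestration: simulate or load a cohort, pre-adjust ROI volumes,
# correlation table, compositional regression models, moderation models,
# reallocation curves, descriptives and a reproducibility manifest.

#' Default analysis lists
#' @noRd
default_rois <- function() c("total_gm", "temporal", "hippocampus",
                             "lateral_ventricle", "frontal")
default_outcomes <- function() c("long_term_memory", "executive_function",
                                 "processing_speed")

#' Assemble a pipeline run configuration
#'
#' Exactly one input source: `simulate` (a [cohort_config()]), `cohort_csv`
#' (participant-level table), or `epochs_csv` + `sleeplog_csv`.
#'
#' @param simulate A [cohort_config()] for synthetic-cohort mode.
#' @param cohort_csv Path to a participant-level CSV.
#' @param epochs_csv,sleeplog_csv Paths to epoch-level inputs (single
#'   participant extraction demo).
#' @param rois ROI columns to analyse.
#' @param outcomes Cognitive outcome columns.
#' @param covariates Covariate columns.
#' @param deltas Reallocation grid in minutes.
#' @param seed Master seed; per-stage substreams are derived from it.
#' @param alpha FDR-adjusted significance threshold used to select which
#'   interactions get reallocation curves.
#' @return List of class `run_config`.
#' @export
run_config <- function(simulate = cohort_config(), cohort_csv = NULL,
                       epochs_csv = NULL, sleeplog_csv = NULL,
                       rois = default_rois(), outcomes = default_outcomes(),
                       covariates = c("age", "sex", "education"),
                       deltas = seq(-60, 60, by = 15),
                       seed = 20240130L, alpha = 0.05) {
  sources <- c(!is.null(simulate), !is.null(cohort_csv), !is.null(epochs_csv))
  if (sum(sources) != 1L) {
    stop("Exactly one input source: simulate, cohort_csv, or epochs_csv.",
         call. = FALSE)
  }
  structure(as.list(environment()), class = "run_config")
}

#' Load a run configuration from YAML
#'
#' Recognised keys mirror [run_config()]; a `simulate:` block holds
#' [cohort_config()] overrides (scalar fields only).
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
load_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  sim <- NULL
  if (!is.null(y$simulate)) {
    # YAML 1.1 reads a bare `n:` key as boolean FALSE; restore it
    names(y$simulate)[names(y$simulate) %in% c("FALSE", "n")] <- "n"
    sim <- do.call(cohort_config, y$simulate)
  } else if (is.null(y$cohort_csv) && is.null(y$epochs_csv)) {
    sim <- cohort_config()
  }
  args <- y[intersect(names(y), c("cohort_csv", "epochs_csv", "sleeplog_csv",
                                  "rois", "outcomes", "covariates", "deltas",
                                  "seed", "alpha"))]
  do.call(run_config, c(list(simulate = sim), args))
}

#' Table-1-style cohort descriptives
#'
#' Mean, SD, min and max for numeric variables; counts and percentages for
#' categorical ones; both arithmetic and compositional (geometric) means of
#' the time-use behaviours, with the share of the day each compositional
#' mean represents (`part / 1440 * 100`).
#'
#' @param cohort Cohort data frame.
#' @param kappa Closure constant.
#' @return List with data frames `numeric`, `categorical`, `timeuse`.
#' @export
describe_cohort <- function(cohort, kappa = timeuse_kappa()) {
  num <- names(cohort)[vapply(cohort, is.numeric, logical(1))]
  num_tab <- do.call(rbind, lapply(num, function(v) {
    x <- cohort[[v]]
    data.frame(variable = v, mean = mean(x, na.rm = TRUE),
               sd = stats::sd(x, na.rm = TRUE),
               min = suppressWarnings(min(x, na.rm = TRUE)),
               max = suppressWarnings(max(x, na.rm = TRUE)),
               n = sum(!is.na(x)))
  }))
  cats <- names(cohort)[vapply(cohort, is.factor, logical(1))]
  cat_tab <- do.call(rbind, lapply(cats, function(v) {
    tb <- table(cohort[[v]])
    data.frame(variable = v, level = names(tb), count = as.integer(tb),
               percent = 100 * as.integer(tb) / sum(tb))
  }))
  tu <- NULL
  if (all(timeuse_parts() %in% names(cohort))) {
    m <- as.matrix(cohort[timeuse_parts()])
    m <- m[stats::complete.cases(m), , drop = FALSE]
    cm <- compositional_mean(m, kappa)
    tu <- data.frame(
      behaviour = timeuse_parts(),
      arithmetic_mean = colMeans(m),
      sd = apply(m, 2, stats::sd),
      compositional_mean = as.numeric(cm),
      percent_of_day = as.numeric(cm) / kappa * 100
    )
    rownames(tu) <- NULL
  }
  list(numeric = num_tab, categorical = cat_tab, timeuse = tu)
}

#' Tabulate exclusions from participant summaries
#'
#' @param summaries Data frame with `included` and `exclusion_reason`
#'   columns (one row per screened participant; use reason
#'   `"missing_data"` for participants with no usable recording).
#' @return List: `n_input`, `n_excluded`, `n_analysed`, `by_reason`.
#' @export
exclusion_audit <- function(summaries) {
  n <- nrow(summaries)
  excl <- !summaries$included
  by_reason <- table(summaries$exclusion_reason[excl])
  list(n_input = n, n_excluded = sum(excl), n_analysed = sum(!excl),
       by_reason = as.list(by_reason))
}

#' Run the full analysis pipeline
#'
#' Stages: obtain the cohort (simulate or load), descriptives, ROI
#' adjustment, correlation table, per-ROI compositional models (covariates
#' only; + composition; quadratic check), per-outcome x ROI moderation
#' models with Type II tests and within-model FDR, and reallocation
#' response curves for every moderation whose interaction survives FDR at
#' `alpha`.  Writes CSV outputs plus a JSON manifest of seeds and row
#' counts; deterministic given the config seed.
#'
#' @param config A [run_config()] or path to a YAML file.
#' @param outdir Output directory (created if needed).
#' @return Invisibly, a list with all computed tables and the manifest.
#' @export
run_timeuse_pipeline <- function(config = run_config(), outdir = tempdir()) {
  if (is.character(config)) config <- load_run_config(config)
  stopifnot(inherits(config, "run_config"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  seeds <- list(master = config$seed,
                simulate = config$seed %% 2147483647L,
                bootstrap = (config$seed + 1L) %% 2147483647L)

  audit <- NULL
  if (!is.null(config$simulate)) {
    cfg <- config$simulate
    cfg$seed <- seeds$simulate
    cohort <- generate_cohort(cfg)
  } else if (!is.null(config$cohort_csv)) {
    cohort <- utils::read.csv(config$cohort_csv, stringsAsFactors = TRUE)
  } else {
    epochs <- read_epochs(config$epochs_csv)
    slog <- read_sleep_log(config$sleeplog_csv)
    summary <- extract_timeuse(epochs, slog)
    utils::write.csv(summary, file.path(outdir, "timeuse_summary.csv"),
                     row.names = FALSE)
    manifest <- list(mode = "extract", seeds = seeds,
                     included = summary$included,
                     exclusion_reason = summary$exclusion_reason)
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    return(invisible(list(summary = summary, manifest = manifest)))
  }
  if ("included" %in% names(cohort)) {
    audit <- exclusion_audit(cohort)
    cohort <- cohort[cohort$included, , drop = FALSE]
  }

  desc <- describe_cohort(cohort)

  # ROI adjustment (ventricles on the log scale, then modelled untransformed)
  rois_adj <- character(0)
  for (r in config$rois) {
    v <- cohort[[r]]
    if (r == "lateral_ventricle") v <- log(v)
    cohort[[paste0(r, "_adj")]] <- adjust_roi(v, cohort$tiv, cohort$site,
                                              cohort$distortion)
    rois_adj[r] <- paste0(r, "_adj")
  }

  corr_vars <- c("age", "sex", "education", timeuse_parts(),
                 intersect(config$rois, names(cohort)),
                 intersect(config$outcomes, names(cohort)))
  correlations <- correlation_table(cohort, variables = corr_vars,
                                    seed = seeds$bootstrap)

  # Models 1-3 per ROI outcome
  roi_rows <- list()
  for (r in config$rois) {
    m1 <- fit_timeuse_model(cohort, rois_adj[r], covariates = config$covariates,
                            include_composition = FALSE)
    m2 <- fit_timeuse_model(cohort, rois_adj[r], covariates = config$covariates)
    q <- compare_quadratic(m2)
    for (model in c(1, 2)) {
      tt <- type2_tests(if (model == 1) m1 else m2)
      tt <- cbind(roi = r, model = model, tt)
      roi_rows[[length(roi_rows) + 1L]] <- tt
    }
    roi_rows[[length(roi_rows) + 1L]] <- data.frame(
      roi = r, model = 3, term = "quadratic_ilr_vs_model2", F = q$F,
      df1 = q$df1, df2 = q$df2, p = q$p, p_adj = NA_real_
    )
  }
  roi_models <- do.call(rbind, roi_rows)

  # Moderation models per outcome x ROI
  int_rows <- list()
  curves <- list()
  ref <- compositional_mean(as.matrix(cohort[timeuse_parts()]))
  for (oc in config$outcomes) {
    for (r in setdiff(config$rois, "lateral_ventricle")) {
      im <- fit_interaction_model(cohort, oc, rois_adj[r],
                                  covariates = config$covariates)
      tt <- cbind(outcome = oc, roi = r, im$tests)
      int_rows[[length(int_rows) + 1L]] <- tt
      int_p <- tt$p_adj[tt$term == "ilr:roi_v"]
      if (length(int_p) == 1L && int_p < config$alpha) {
        strata <- stratum_means(im$fit$data$roi_v)
        cv <- response_curves(im$fit, ref, deltas = config$deltas,
                              strata = strata)
        curves[[length(curves) + 1L]] <- cbind(outcome = oc, roi = r, cv)
      }
    }
  }
  interaction_models <- do.call(rbind, int_rows)
  curve_tab <- if (length(curves)) do.call(rbind, curves) else NULL

  wcsv <- function(x, f) if (!is.null(x)) {
    utils::write.csv(x, file.path(outdir, f), row.names = FALSE)
  }
  wcsv(desc$numeric, "descriptives_numeric.csv")
  wcsv(desc$categorical, "descriptives_categorical.csv")
  wcsv(desc$timeuse, "descriptives_timeuse.csv")
  wcsv(correlations, "correlations.csv")
  wcsv(roi_models, "roi_models.csv")
  wcsv(interaction_models, "interaction_models.csv")
  wcsv(curve_tab, "reallocation_curves.csv")

  manifest <- list(
    mode = if (!is.null(config$simulate)) "simulate" else "cohort_csv",
    seeds = seeds,
    n_analysed = nrow(cohort),
    exclusions = audit,
    rois = config$rois, outcomes = config$outcomes,
    reference_composition = as.list(ref),
    curves_emitted = if (is.null(curve_tab)) character(0) else
      unique(paste(curve_tab$outcome, curve_tab$roi, sep = ":"))
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(cohort = cohort, descriptives = desc,
                 correlations = correlations, roi_models = roi_models,
                 interaction_models = interaction_models,
                 curves = curve_tab, manifest = manifest))
}
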