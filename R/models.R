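# Cohort-level statistics: cognitive composites, ROI pre-adjustment,
# correlation tables, compositional linear regression (Models 1-3), ilr x ROI
# moderation models, Type II F-tests and Benjamini-Hochberg FDR.

#' Build cognitive composite z-scores
#'
#' Each raw test is z-scored against its own non-missing mean and SD
#' (higher-is-better orientation is assumed to be applied upstream), and a
#' composite is the per-participant mean of the available test z-scores.
#'
#' @param scores Data frame of raw test scores.
#' @param grouping Named list mapping composite name -> character vector of
#'   test columns.
#' @return Data frame with one z-score column per composite; `NA` where a
#'   participant is missing every test of a composite.
#' @export
make_composite <- function(scores, grouping) {
  out <- list()
  for (comp in names(grouping)) {
    tests <- grouping[[comp]]
    if (!length(tests) || !all(tests %in% names(scores))) {
      stop(sprintf("Composite '%s' needs at least one existing test column.", comp),
           call. = FALSE)
    }
    z <- sapply(tests, function(t) {
      x <- scores[[t]]
      s <- stats::sd(x, na.rm = TRUE)
      if (is.na(s) || s == 0) {
        stop(sprintf("Test '%s' has zero variance; cannot z-score.", t),
             call. = FALSE)
      }
      (x - mean(x, na.rm = TRUE)) / s
    })
    z <- matrix(z, nrow = nrow(scores))
    m <- rowMeans(z, na.rm = TRUE)
    m[is.nan(m)] <- NA_real_
    out[[comp]] <- m
  }
  as.data.frame(out)
}

#' Adjust an ROI volume for head size and scanner nuisance
#'
#' Residualises the volume on total intracranial volume, scanner site and
#' the distortion-correction flag, then restores the sample mean so the
#' adjusted values stay on the ml scale.
#'
#' @param volume Numeric ROI volume vector.
#' @param tiv Total intracranial volume (ml).
#' @param site,distortion Factors (or vectors coercible to factors).
#' @return Adjusted volume vector (residual + mean of `volume`).
#' @export
adjust_roi <- function(volume, tiv, site, distortion) {
  d <- data.frame(volume = volume, tiv = tiv,
                  site = factor(site), distortion = factor(distortion))
  drop1 <- function(f) if (nlevels(f) < 2L) NULL else f
  terms <- c("tiv",
             if (!is.null(drop1(d$site))) "site",
             if (!is.null(drop1(d$distortion))) "distortion")
  fit <- stats::lm(stats::reformulate(terms, "volume"), data = d,
                   na.action = stats::na.exclude)
  if (anyNA(stats::coef(fit))) {
    stop(sprintf("Collinear ROI adjusters: %s.",
                 paste(names(which(is.na(stats::coef(fit)))), collapse = ", ")),
         call. = FALSE)
  }
  as.numeric(stats::residuals(fit)) + mean(volume, na.rm = TRUE)
}

#' Fisher-z confidence interval for a correlation
#' @noRd
fisher_z_ci <- function(r, n, conf = 0.95) {
  if (abs(r) >= 1) return(c(r, r))
  q <- stats::qnorm(1 - (1 - conf) / 2)
  tanh(atanh(r) + c(-1, 1) * q / sqrt(n - 3))
}

#' Pairwise correlation table
#'
#' Pearson correlations with Fisher-z confidence intervals for pairs outside
#' the time-use composition (point-biserial, i.e. Pearson on a 0/1 coding,
#' when one variable is binary), and symmetric-balance correlations
#' ([cor_coda()]) with seeded non-parametric percentile bootstrap intervals
#' for pairs of compositional parts.  Pairwise-complete deletion throughout.
#'
#' @param data Cohort data frame.
#' @param variables Character vector of columns to correlate (default: all
#'   compositional parts plus every numeric/binary column supplied).
#' @param comp_cols Compositional part columns, default [timeuse_parts()].
#' @param n_boot Bootstrap resamples for compositional pairs (1000).
#' @param seed Seed for the bootstrap.
#' @param conf Confidence level.
#' @return Data frame: `var1`, `var2`, `method`, `r`, `ci_low`, `ci_high`,
#'   `ci_method`, `n`.
#' @export
correlation_table <- function(data, variables = NULL,
                              comp_cols = timeuse_parts(),
                              n_boot = 1000, seed = 1L, conf = 0.95) {
  if (is.null(variables)) {
    num <- vapply(data, function(x) is.numeric(x) || is.factor(x), logical(1))
    variables <- names(data)[num]
  }
  val <- lapply(stats::setNames(variables, variables), function(v) {
    x <- data[[v]]
    if (is.factor(x)) {
      if (nlevels(x) != 2L) stop(sprintf("Factor '%s' must be binary.", v), call. = FALSE)
      x <- as.numeric(x) - 1
    }
    x
  })
  binary <- vapply(val, function(x) all(x %in% c(0, 1, NA)), logical(1))
  comp_m <- as.matrix(data[comp_cols])
  pairs <- utils::combn(variables, 2)
  rows <- vector("list", ncol(pairs))
  set.seed(seed)
  for (k in seq_len(ncol(pairs))) {
    v1 <- pairs[1, k]; v2 <- pairs[2, k]
    if (v1 %in% comp_cols && v2 %in% comp_cols) {
      ok <- stats::complete.cases(comp_m)
      X <- comp_m[ok, , drop = FALSE]
      r <- cor_coda(X, v1, v2)
      bs <- replicate(n_boot, {
        cor_coda(X[sample.int(nrow(X), replace = TRUE), , drop = FALSE], v1, v2)
      })
      ci <- stats::quantile(bs, c((1 - conf) / 2, 1 - (1 - conf) / 2), names = FALSE)
      rows[[k]] <- data.frame(var1 = v1, var2 = v2, method = "symmetric_balance",
                              r = r, ci_low = ci[1], ci_high = ci[2],
                              ci_method = "bootstrap", n = nrow(X))
    } else {
      x <- val[[v1]]; y <- val[[v2]]
      ok <- !is.na(x) & !is.na(y)
      n <- sum(ok)
      if (n < 4L) stop(sprintf("Too few complete pairs for %s-%s.", v1, v2), call. = FALSE)
      if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) {
        stop(sprintf("Correlation undefined for constant variable in %s-%s.", v1, v2),
             call. = FALSE)
      }
      r <- stats::cor(x[ok], y[ok])
      ci <- fisher_z_ci(r, n, conf)
      rows[[k]] <- data.frame(
        var1 = v1, var2 = v2,
        method = if (binary[[v1]] || binary[[v2]]) "point_biserial" else "pearson",
        r = r, ci_low = ci[1], ci_high = ci[2], ci_method = "fisher_z", n = n
      )
    }
  }
  do.call(rbind, rows)
}

# ---------------------------------------------------------------------------
# Compositional linear models

#' Fit a compositional linear regression model
#'
#' Builds the analysis design on listwise-complete rows: covariates, the
#' time-use composition as its D-1 pivot ilr coordinates entering the model
#' as a single multi-column term, and optionally an ROI moderator with its
#' ilr x ROI interaction.  Covariates-only corresponds to Model 1,
#' covariates + composition to Model 2 (see [compare_quadratic()] for the
#' Model 3 check).
#'
#' @param data Cohort data frame (one row per participant).
#' @param outcome Outcome column name.
#' @param covariates Covariate columns, default age, sex, education.
#' @param composition Compositional part columns, default [timeuse_parts()].
#' @param include_composition Include the ilr term (FALSE gives the
#'   covariates-only model).
#' @param pivot_order Pivot order for the ilr basis; whole-composition
#'   inference is invariant to this choice.
#' @param roi Optional ROI column (already adjusted) to enter as moderator.
#' @param roi_form `"continuous"`, `"mean_split"` (two levels split at the
#'   sample mean) or `"quartiles"`.
#' @param interaction Add the composition x ROI interaction term.
#' @param log_outcome Log-transform the outcome (used for lateral-ventricle
#'   volumes); requires a strictly positive outcome.
#' @return Object of class `timeuse_fit`: list with the underlying `lm` fit
#'   (`$fit`), the analysis frame (`$data`), and design metadata.
#' @export
fit_timeuse_model <- function(data, outcome,
                              covariates = c("age", "sex", "education"),
                              composition = timeuse_parts(),
                              include_composition = TRUE,
                              pivot_order = composition,
                              roi = NULL,
                              roi_form = c("continuous", "mean_split", "quartiles"),
                              interaction = FALSE,
                              log_outcome = FALSE) {
  roi_form <- match.arg(roi_form)
  need <- c(outcome, covariates, composition, roi)
  miss <- setdiff(need, names(data))
  if (length(miss)) {
    stop(sprintf("Columns not found in data: %s.", paste(miss, collapse = ", ")),
         call. = FALSE)
  }
  keep <- stats::complete.cases(data[need])
  d <- data[keep, , drop = FALSE]
  y <- d[[outcome]]
  if (log_outcome) {
    if (any(y <= 0)) stop("Log transform requires a strictly positive outcome.",
                          call. = FALSE)
    y <- log(y)
  }
  df <- data.frame(.y = y)
  for (v in covariates) df[[v]] <- d[[v]]
  terms <- covariates
  if (include_composition) {
    Z <- ilr_pivot(as.matrix(d[composition]), pivot_order = pivot_order)
    df$ilr <- Z
    terms <- c(terms, "ilr")
  }
  roi_split <- NULL
  if (!is.null(roi)) {
    rv <- d[[roi]]
    if (roi_form == "mean_split") {
      roi_split <- mean(rv)
      rv <- factor(ifelse(rv >= roi_split, "upper", "lower"),
                   levels = c("lower", "upper"))
    } else if (roi_form == "quartiles") {
      rv <- cut(rv, breaks = stats::quantile(rv, probs = seq(0, 1, 0.25)),
                include.lowest = TRUE, labels = paste0("Q", 1:4))
    }
    if (is.factor(rv) && any(table(rv) == 0)) {
      stop("Empty stratum under categorical ROI coding.", call. = FALSE)
    }
    df$roi_v <- rv
    terms <- c(terms, "roi_v")
    if (interaction) {
      if (!include_composition) {
        stop("An ilr x ROI interaction requires the composition term.", call. = FALSE)
      }
      terms <- c(terms, "ilr:roi_v")
    }
  }
  n <- nrow(df)
  p_max <- 1 + length(covariates) +
    3 * include_composition + (!is.null(roi)) * 3 + interaction * 9
  if (n < p_max + 2) stop("Too few complete rows to fit the design.", call. = FALSE)
  fit <- stats::lm(stats::reformulate(terms, ".y"), data = df)
  if (anyNA(stats::coef(fit))) {
    stop(sprintf("Rank-deficient design; aliased columns: %s.",
                 paste(names(which(is.na(stats::coef(fit)))), collapse = ", ")),
         call. = FALSE)
  }
  structure(
    list(fit = fit, data = df, outcome = outcome, covariates = covariates,
         composition = composition, pivot_order = pivot_order,
         include_composition = include_composition,
         roi = roi, roi_form = roi_form, roi_split = roi_split,
         interaction = interaction, log_outcome = log_outcome, n = n),
    class = "timeuse_fit"
  )
}

#' @export
print.timeuse_fit <- function(x, ...) {
  cat(sprintf("Compositional linear model: %s ~ %s (n = %d)\n",
              x$outcome,
              paste(attr(stats::terms(x$fit), "term.labels"), collapse = " + "),
              x$n))
  invisible(x)
}

term_contains <- function(tt) {
  fac <- attr(tt, "factors")
  labels <- attr(tt, "term.labels")
  vars_of <- lapply(labels, function(l) rownames(fac)[fac[, l] > 0])
  names(vars_of) <- labels
  function(T) {
    tv <- vars_of[[T]]
    labels[vapply(labels, function(o) {
      o != T && all(tv %in% vars_of[[o]]) && length(vars_of[[o]]) > length(tv)
    }, logical(1))]
  }
}

#' Type II F-tests for every model term
#'
#' For each term the comparison respects marginality: both models exclude
#' any interaction containing the tested term, the reduced model
#' additionally drops the term itself, and the F statistic compares the two
#' by residual sum of squares with the error taken from the
#' marginality-respecting model that includes the term.  Multi-column terms
#' (the composition's 3 ilr coordinates, the 3-column ilr x ROI
#' interaction) are tested jointly.  Benjamini-Hochberg adjustment is
#' applied across the terms of the one model -- the FDR family is a single
#' model's Type II table, never pooled across models.
#'
#' @param object A `timeuse_fit`.
#' @return Data frame: `term`, `F`, `df1`, `df2`, `p`, `p_adj`.
#' @export
type2_tests <- function(object) {
  stopifnot(inherits(object, "timeuse_fit"))
  tt <- stats::terms(object$fit)
  labels <- attr(tt, "term.labels")
  higher <- term_contains(tt)
  refit <- function(labs) {
    f <- if (length(labs)) stats::reformulate(labs, ".y") else .y ~ 1
    stats::lm(f, data = object$data)
  }
  rows <- lapply(labels, function(T) {
    with_T <- refit(setdiff(labels, higher(T)))
    without_T <- refit(setdiff(labels, c(T, higher(T))))
    rss1 <- sum(stats::residuals(without_T)^2)
    rss2 <- sum(stats::residuals(with_T)^2)
    df1 <- without_T$df.residual - with_T$df.residual
    df2 <- with_T$df.residual
    Fst <- ((rss1 - rss2) / df1) / (rss2 / df2)
    data.frame(term = T, F = Fst, df1 = df1, df2 = df2,
               p = stats::pf(Fst, df1, df2, lower.tail = FALSE))
  })
  out <- do.call(rbind, rows)
  out$p_adj <- bh_adjust(out$p)
  rownames(out) <- NULL
  out
}

#' Test whether quadratic ilr terms improve fit (Model 3 vs Model 2)
#'
#' Augments the fitted design with the squared pivot ilr coordinates (no
#' cross-products) and runs the nested F-test of the augmented model against
#' the original.
#'
#' @param object A `timeuse_fit` containing the composition term.
#' @param cross_products Also add the three pairwise ilr products.
#' @return List: `F`, `df1`, `df2`, `p`, `rss_linear`, `rss_quadratic`.
#' @export
compare_quadratic <- function(object, cross_products = FALSE) {
  stopifnot(inherits(object, "timeuse_fit"))
  if (!object$include_composition) {
    stop("Quadratic comparison needs a model containing the composition term.",
         call. = FALSE)
  }
  df <- object$data
  Z <- df$ilr
  Q <- Z^2
  colnames(Q) <- paste0(colnames(Z), "_sq")
  if (cross_products) {
    cp <- cbind(Z[, 1] * Z[, 2], Z[, 1] * Z[, 3], Z[, 2] * Z[, 3])
    colnames(cp) <- c("z1z2", "z1z3", "z2z3")
    Q <- cbind(Q, cp)
  }
  df$ilr_sq <- Q
  labels <- attr(stats::terms(object$fit), "term.labels")
  m3 <- stats::lm(stats::reformulate(c(labels, "ilr_sq"), ".y"), data = df)
  a <- stats::anova(object$fit, m3)
  list(F = a$F[2], df1 = a$Df[2], df2 = m3$df.residual, p = a$`Pr(>F)`[2],
       rss_linear = a$RSS[1], rss_quadratic = a$RSS[2])
}

#' Fit the composition x ROI moderation model
#'
#' Design: covariates + composition (3 ilr columns) + ROI + ilr x ROI
#' interaction, with the ROI entered continuously, as a two-level mean
#' split, or as quartiles.  Returns Type II tests alongside the fit.
#'
#' @inheritParams fit_timeuse_model
#' @return List with `fit` (a `timeuse_fit`) and `tests`
#'   (the [type2_tests()] table).
#' @export
fit_interaction_model <- function(data, outcome, roi,
                                  covariates = c("age", "sex", "education"),
                                  composition = timeuse_parts(),
                                  pivot_order = composition,
                                  roi_form = c("continuous", "mean_split", "quartiles"),
                                  log_outcome = FALSE) {
  fit <- fit_timeuse_model(
    data, outcome, covariates = covariates, composition = composition,
    pivot_order = pivot_order, roi = roi, roi_form = match.arg(roi_form),
    interaction = TRUE, log_outcome = log_outcome
  )
  list(fit = fit, tests = type2_tests(fit))
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjustment of the p-values of one model's term tests.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, elementwise at least `p`.
#' @export
bh_adjust <- function(p) {
  if (!is.numeric(p) || any(is.na(p)) || any(p < 0 | p > 1)) {
    stop("p-values must be numbers in [0, 1].", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}

#' Residual diagnostics report for a fitted model
#'
#' Summarises what a transformation decision would be based on: residual
#' skewness, a Shapiro-Wilk normality p-value, and a leverage summary.
#' The package encodes the ventricle log transform explicitly rather than
#' transforming automatically.
#'
#' @param object A `timeuse_fit`.
#' @return List: `skewness`, `shapiro_p`, `max_leverage`, `mean_leverage`.
#' @export
fit_diagnostics <- function(object) {
  stopifnot(inherits(object, "timeuse_fit"))
  r <- stats::residuals(object$fit)
  h <- stats::hatvalues(object$fit)
  list(
    skewness = mean((r - mean(r))^3) / stats::sd(r)^3,
    shapiro_p = if (length(r) >= 3 && length(r) <= 5000)
      stats::shapiro.test(r)$p.value else NA_real_,
    max_leverage = max(h),
    mean_leverage = mean(h)
  )
}
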