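# Model-based time-reallocation analysis: displace a reference composition
# by +/- delta minutes (pro-rata from the remaining behaviours, or directly
# from a named donor), and predict the implied difference in a cognitive
# z-score with a delta-method confidence interval, stratified by
# brain-volume group.

#' Reallocate time between behaviours of a composition
#'
#' `one_for_remaining`: adds `delta` minutes to the target behaviour and
#' rescales every remaining part by `(kappa - target_new) / (kappa -
#' target_old)`, removing the time pro-rata.  `one_for_one`: moves `delta`
#' minutes directly from the donor behaviour to the target.  The result
#' sums to `kappa` exactly.
#'
#' @param ref Named reference composition (minutes, summing to `kappa`).
#' @param target Behaviour receiving time.
#' @param delta Minutes to add to `target` (negative to remove).
#' @param mode `"one_for_remaining"` or `"one_for_one"`.
#' @param donor Donor behaviour (`one_for_one` only, distinct from target).
#' @param kappa Closure constant, default `sum(ref)`.
#' @return Reallocated composition (named vector summing to `kappa`).
#' @examples
#' ref <- c(mvpa = 90, lpa = 180, sb = 670, sleep = 500)
#' reallocate(ref, "mvpa", 30)                      # pro-rata
#' reallocate(ref, "mvpa", 30, "one_for_one", "sleep")
#' @export
reallocate <- function(ref, target, delta,
                       mode = c("one_for_remaining", "one_for_one"),
                       donor = NULL, kappa = sum(ref)) {
  mode <- match.arg(mode)
  if (!target %in% names(ref)) stop("Unknown target behaviour.", call. = FALSE)
  out <- ref
  if (mode == "one_for_remaining") {
    old_t <- ref[[target]]
    new_t <- old_t + delta
    rest <- setdiff(names(ref), target)
    out[[target]] <- new_t
    out[rest] <- ref[rest] * (kappa - new_t) / (kappa - old_t)
  } else {
    if (is.null(donor) || !donor %in% names(ref) || donor == target) {
      stop("`one_for_one` needs a donor behaviour distinct from the target.",
           call. = FALSE)
    }
    out[[target]] <- ref[[target]] + delta
    out[[donor]] <- ref[[donor]] - delta
  }
  bad <- names(out)[out <= 0]
  if (length(bad)) {
    stop(sprintf("Infeasible reallocation: part(s) %s would be non-positive.",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  out
}

# coefficient displacement vector for moving ref -> new in a timeuse_fit,
# at a given ROI value (continuous) or stratum level (categorical);
# covariate and ROI main-effect columns cancel in the difference.
prediction_contrast <- function(object, ref, new, roi_value = NULL) {
  cf <- stats::coef(object$fit)
  d <- stats::setNames(numeric(length(cf)), names(cf))
  dz <- ilr_pivot(new[object$composition], pivot_order = object$pivot_order) -
    ilr_pivot(ref[object$composition], pivot_order = object$pivot_order)
  ilr_cols <- paste0("ilr", names(dz))
  if (!all(ilr_cols %in% names(cf))) {
    stop("Fit does not contain the composition term.", call. = FALSE)
  }
  d[ilr_cols] <- dz
  if (object$interaction) {
    if (is.null(roi_value)) {
      stop("An interaction fit needs `roi_value` (continuous value or stratum level).",
           call. = FALSE)
    }
    if (object$roi_form == "continuous") {
      d[paste0(ilr_cols, ":roi_v")] <- dz * roi_value
    } else {
      lev <- as.character(roi_value)
      cols <- paste0(ilr_cols, ":roi_v", lev)
      present <- cols %in% names(cf)
      if (!all(present) && lev != levels(object$data$roi_v)[1]) {
        stop(sprintf("Unknown ROI stratum '%s'.", lev), call. = FALSE)
      }
      d[cols[present]] <- dz[present]
    }
  }
  d
}

#' Predict the cognitive difference of a reallocation
#'
#' Estimated mean difference in the outcome between a reallocated and a
#' reference composition at a fixed covariate profile and ROI value:
#' `d' beta_hat` where `d` is the design displacement (only the ilr and
#' ilr x ROI columns differ, so covariates cancel), with the confidence
#' interval `estimate +/- t(df_resid) * sqrt(d' V d)` from the coefficient
#' covariance -- a CI for the mean difference, not a prediction interval.
#'
#' @param object A `timeuse_fit` containing the composition term.
#' @param ref,new Reference and reallocated compositions (named vectors).
#' @param roi_value ROI value (continuous fits) or stratum level
#'   (categorical fits) at which to predict; required when the fit has an
#'   interaction term.
#' @param level Confidence level, default 0.95.
#' @return List: `estimate`, `se`, `ci_low`, `ci_high`.
#' @export
predict_difference <- function(object, ref, new, roi_value = NULL,
                               level = 0.95) {
  stopifnot(inherits(object, "timeuse_fit"))
  d <- prediction_contrast(object, ref, new, roi_value)
  est <- sum(d * stats::coef(object$fit))
  se <- sqrt(drop(t(d) %*% stats::vcov(object$fit) %*% d))
  tq <- stats::qt(1 - (1 - level) / 2, object$fit$df.residual)
  list(estimate = est, se = se, ci_low = est - tq * se, ci_high = est + tq * se)
}

#' Stratum means of an adjusted ROI volume
#'
#' Mean-split strata: means of the values below and above (>=) the overall
#' sample mean, the values at which stratified response curves are
#' predicted.
#'
#' @param roi Numeric adjusted ROI vector.
#' @return Named list `lower`, `upper`.
#' @export
stratum_means <- function(roi) {
  m <- mean(roi)
  list(lower = mean(roi[roi < m]), upper = mean(roi[roi >= m]))
}

#' Reallocation response curves
#'
#' Predicted outcome differences over a grid of reallocations from a
#' reference composition, per behaviour and volume stratum.  With a
#' continuous-ROI interaction fit, strata are evaluated at the supplied
#' ROI values (typically [stratum_means()] of the adjusted ROI); with a
#' categorical fit, at the stratum levels.  Grid points whose reallocation
#' is infeasible (a part would become non-positive) are dropped.
#'
#' @param object A `timeuse_fit` with the composition term.
#' @param ref Reference composition, typically the analysed sample's
#'   [compositional_mean()].
#' @param deltas Minute grid, default `seq(-60, 60, by = 15)` (must
#'   include 0).
#' @param behaviours Target behaviours, default all parts.
#' @param mode `"one_for_remaining"` or `"one_for_one"`.
#' @param donors Donor behaviours for `one_for_one` (default: all
#'   non-target parts in turn).
#' @param strata Named list of ROI values / levels per stratum; `NULL` for
#'   an unstratified curve (no-interaction fits).
#' @param level Confidence level.
#' @return Data frame of curve points: `behaviour`, `mode`, `donor`,
#'   `stratum`, `delta_min`, `estimate`, `ci_low`, `ci_high`.  At
#'   `delta = 0` the difference is exactly 0 with a zero-width interval.
#' @export
response_curves <- function(object, ref, deltas = seq(-60, 60, by = 15),
                            behaviours = names(ref),
                            mode = c("one_for_remaining", "one_for_one"),
                            donors = NULL, strata = NULL, level = 0.95) {
  mode <- match.arg(mode)
  if (!any(deltas == 0)) stop("The delta grid must include 0.", call. = FALSE)
  if (is.null(strata)) strata <- list(all = NULL)
  rows <- list()
  for (b in behaviours) {
    donor_set <- if (mode == "one_for_one") {
      donors %||% setdiff(names(ref), b)
    } else NA_character_
    for (dn in donor_set) {
      for (s in names(strata)) {
        for (dl in deltas) {
          new <- tryCatch(
            reallocate(ref, b, dl, mode = mode,
                       donor = if (mode == "one_for_one") dn else NULL),
            error = function(e) NULL
          )
          if (is.null(new)) next  # infeasible grid point dropped
          pr <- predict_difference(object, ref, new,
                                   roi_value = strata[[s]], level = level)
          rows[[length(rows) + 1L]] <- data.frame(
            behaviour = b, mode = mode,
            donor = if (mode == "one_for_one") dn else NA_character_,
            stratum = s, delta_min = dl,
            estimate = pr$estimate, ci_low = pr$ci_low, ci_high = pr$ci_high
          )
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Plot reallocation response curves
#'
#' One panel per target behaviour; lines per volume stratum with
#' confidence ribbons, minutes reallocated on the x-axis.
#'
#' @param curves Output of [response_curves()].
#' @param outcome_label y-axis label.
#' @return A ggplot object.
#' @export
plot_response_curves <- function(curves, outcome_label = "Predicted difference (z)") {
  ggplot2::ggplot(
    curves,
    ggplot2::aes(x = delta_min, y = estimate, colour = stratum, fill = stratum)
  ) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = ci_low, ymax = ci_high),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~behaviour) +
    ggplot2::labs(x = "Minutes reallocated", y = outcome_label,
                  colour = "Volume group", fill = "Volume group") +
    ggplot2::theme_minimal()
}
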