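# Synthetic cohort generator: participant-level records (covariates, ROI
# volumes, time-use compositions, cognitive composites) with the statistical
# structure the analysis assumes, plus epoch-level traces with known
# ground-truth labels for accelerometry testing.  All effects are plantable
# so parameter-recovery and type-I-error calibration tests have known truth.

#' Synthetic cohort configuration
#'
#' Defaults emulate the marginal structure of a healthy older-adult cohort
#' of 378 participants: age 65.6 +/- 3.0 y (range 60-71.2), 67% female,
#' 16.6 +/- 3.2 y of education, two scanner sites; time-use compositional
#' mean (90.7, 178.8, 668.2, 502.2) min/day with per-part coefficients of
#' variation matching the observed SDs; ROI volume means/SDs (TIV 1551 +/-
#' 141 ml, total GM 596 +/- 50.8 ml, ...) with age and sex loadings of the
#' observed sign and magnitude (e.g. age-GM correlation -0.28) and a partly
#' assumed joint correlation structure; lateral ventricles and white-matter
#' hyperintensities are generated log-normally.
#'
#' Compositions are logistic-normal: the log-part vector is Gaussian and is
#' projected to pivot ilr space, so the compositional mean equals
#' `closure(comp_mean)` exactly in expectation.  Cognitive composites follow
#' a linear model in covariates, the pivot ilr coordinates, a standardised
#' ROI volume, and the ilr x ROI interaction, with per-outcome residual SD
#' and missing-completely-at-random rates tuned to analysis sample sizes of
#' roughly 360/363/368 out of 378.
#'
#' @param n Cohort size.
#' @param seed Integer seed; generation is deterministic given the seed.
#' @param comp_mean Target compositional mean (min/day), closed internally.
#' @param comp_cv Per-part coefficient of variation of the log-normal parts.
#' @param comp_sex_loading Additive effect of female sex on log parts.
#' @param empirical_center Centre the realised ilr sample on the target
#'   compositional mean (analogous to `MASS::mvrnorm(empirical = TRUE)`), so
#'   the generated cohort's compositional mean equals `closure(comp_mean)`
#'   exactly; dispersion is untouched.
#' @param cognition Named list of outcome models; each a list with elements
#'   `intercept`, `age`, `sex`, `education` (per-unit effects; age and
#'   education enter centred), `ilr` (length-3 coefficient vector on the
#'   pivot ilr coordinates), `roi` (ROI column name), `roi_coef` (effect per
#'   config SD of the ROI), `interaction` (length-3 ilr x ROI coefficients),
#'   `resid_sd`, `missing_rate`.
#' @param roi_means,roi_sds,roi_cor,roi_age_r,roi_sex_r ROI distribution:
#'   means/SDs on the natural scale (`lateral_ventricle` and `wmh` handled
#'   log-normally), residual correlation matrix, and target correlations
#'   with age and female sex.
#' @param site_shift_sd,distortion_shift_sd Scanner-site and
#'   distortion-correction shifts on ROI volumes, in ROI SD units (nuisance
#'   structure removed by [adjust_roi()]).
#' @param age_mean,age_sd,age_range,edu_mean,edu_sd,edu_range,female_p
#'   Covariate marginals (truncated normals / Bernoulli).
#' @return Object of class `cohort_config`.
#' @export
cohort_config <- function(
  n = 378,
  seed = 1L,
  comp_mean = c(mvpa = 90.7, lpa = 178.8, sb = 668.2, sleep = 502.2),
  comp_cv = c(mvpa = 0.50, lpa = 0.30, sb = 0.22, sleep = 0.08),
  comp_sex_loading = c(mvpa = -0.25, lpa = 0, sb = 0, sleep = 0.035),
  empirical_center = TRUE,
  cognition = default_cognition_models(),
  roi_means = c(tiv = 1551.0, total_gm = 596.0, temporal = 95.3,
                hippocampus = 6.2, lateral_ventricle = 25.0, frontal = 168.0),
  roi_sds = c(tiv = 141.2, total_gm = 50.8, temporal = 9.2,
              hippocampus = 0.6, lateral_ventricle = 12.5, frontal = 16.9),
  roi_cor = default_roi_correlation(),
  roi_age_r = c(tiv = 0, total_gm = -0.28, temporal = -0.20,
                hippocampus = -0.16, lateral_ventricle = 0.21, frontal = -0.10),
  roi_sex_r = c(tiv = -0.40, total_gm = 0.02, temporal = -0.01,
                hippocampus = -0.08, lateral_ventricle = -0.01, frontal = 0.12),
  site_shift_sd = 0.20,
  distortion_shift_sd = 0.10,
  wmh_mean = 1.9, wmh_sd = 3.4,
  age_mean = 65.6, age_sd = 3.0, age_range = c(60, 71.2),
  edu_mean = 16.6, edu_sd = 3.2, edu_range = c(7, 30),
  female_p = 0.67,
  kappa = timeuse_kappa()
) {
  cfg <- as.list(environment())
  if (!isTRUE(all.equal(roi_cor, t(roi_cor))) ||
      inherits(try(chol(roi_cor), silent = TRUE), "try-error")) {
    stop("`roi_cor` must be a symmetric positive-definite correlation matrix.",
         call. = FALSE)
  }
  structure(cfg, class = "cohort_config")
}

#' @rdname cohort_config
#' @export
default_roi_correlation <- function() {
  nm <- c("tiv", "total_gm", "temporal", "hippocampus",
          "lateral_ventricle", "frontal")
  R <- diag(6)
  dimnames(R) <- list(nm, nm)
  set <- function(a, b, v) {
    R[a, b] <<- v
    R[b, a] <<- v
  }
  # observed sign/magnitude where available; modest assumed values for TIV
  set("tiv", "total_gm", 0.80); set("tiv", "temporal", 0.60)
  set("tiv", "hippocampus", 0.25); set("tiv", "lateral_ventricle", 0.10)
  set("tiv", "frontal", 0.60)
  set("total_gm", "temporal", 0.70); set("total_gm", "hippocampus", 0.19)
  set("total_gm", "lateral_ventricle", -0.24); set("total_gm", "frontal", 0.67)
  set("temporal", "hippocampus", 0.18); set("temporal", "lateral_ventricle", -0.32)
  set("temporal", "frontal", 0.46)
  set("hippocampus", "lateral_ventricle", -0.21); set("hippocampus", "frontal", 0.05)
  set("lateral_ventricle", "frontal", -0.15)
  R
}

#' @rdname cohort_config
#' @export
default_cognition_models <- function() {
  list(
    long_term_memory = list(
      intercept = 0, age = 0, sex = 0, education = 0.02,
      ilr = c(0.37, 0, 0), roi = "frontal", roi_coef = 0.05,
      interaction = c(-0.70, 0, 0), resid_sd = 1.0, missing_rate = 18 / 378
    ),
    executive_function = list(
      intercept = 0, age = -0.043, sex = -0.18, education = 0.02,
      ilr = c(0, 0, 0), roi = "total_gm", roi_coef = 0.11,
      interaction = c(0, 0, 0.51), resid_sd = 0.5, missing_rate = 15 / 378
    ),
    processing_speed = list(
      intercept = 0, age = -0.047, sex = 0, education = 0,
      ilr = c(0.20, 0, 0), roi = "frontal", roi_coef = 0,
      interaction = c(0, 0, 0), resid_sd = 1.0, missing_rate = 10 / 378
    )
  )
}

rtrunc_norm <- function(n, mean, sd, lo, hi) {
  u <- stats::runif(n, stats::pnorm(lo, mean, sd), stats::pnorm(hi, mean, sd))
  stats::qnorm(u, mean, sd)
}

#' Generate a synthetic cohort
#'
#' Deterministic given `cfg$seed`.  The returned data frame carries a
#' `"truth"` attribute with the planted cognition coefficients and the exact
#' standardisation used for the ROI moderator, so recovery tests can refit
#' the generating model.
#'
#' @param cfg A [cohort_config()].
#' @return Data frame with one row per participant: `id`, `age`, `sex`
#'   (factor male/female, so model dummies code female = 1), `education`,
#'   `site` (factor A/B), `distortion` (factor off/on), ROI volumes (ml),
#'   `wmh`, closed composition columns [timeuse_parts()], and cognitive
#'   z-scores `long_term_memory`, `executive_function`, `processing_speed`
#'   (with missing values).
#' @export
generate_cohort <- function(cfg = cohort_config()) {
  stopifnot(inherits(cfg, "cohort_config"))
  set.seed(cfg$seed)
  n <- cfg$n

  age <- rtrunc_norm(n, cfg$age_mean, cfg$age_sd, cfg$age_range[1], cfg$age_range[2])
  female <- stats::rbinom(n, 1, cfg$female_p)
  education <- rtrunc_norm(n, cfg$edu_mean, cfg$edu_sd, cfg$edu_range[1], cfg$edu_range[2])
  site <- factor(sample(c("A", "B"), n, replace = TRUE), levels = c("A", "B"))
  distortion <- factor(sample(c("off", "on"), n, replace = TRUE),
                       levels = c("off", "on"))

  # --- ROI volumes: Gaussian (log scale for ventricles/WMH) with age/sex
  # loadings reproducing target correlations, residual correlation roi_cor,
  # and site/distortion nuisance shifts.
  nm <- names(cfg$roi_means)
  sds <- cfg$roi_sds[nm]
  log_roi <- nm %in% "lateral_ventricle"
  scale_sd <- ifelse(log_roi, sqrt(log(1 + (sds / cfg$roi_means)^2)), sds)
  loc <- ifelse(log_roi, log(cfg$roi_means) - scale_sd^2 / 2, cfg$roi_means)
  sd_sex <- sqrt(cfg$female_p * (1 - cfg$female_p))
  b_age <- cfg$roi_age_r[nm] * scale_sd / cfg$age_sd
  b_sex <- cfg$roi_sex_r[nm] * scale_sd / sd_sex
  resid_frac <- pmax(1 - cfg$roi_age_r[nm]^2 - cfg$roi_sex_r[nm]^2, 0.1)
  D <- diag(scale_sd * sqrt(resid_frac))
  Sigma <- D %*% cfg$roi_cor[nm, nm] %*% D
  eps <- MASS::mvrnorm(n, mu = rep(0, length(nm)), Sigma = Sigma)
  vol <- matrix(loc, n, length(nm), byrow = TRUE) +
    outer(age - cfg$age_mean, b_age) +
    outer(female - cfg$female_p, b_sex) +
    outer(as.numeric(site == "B") - 0.5, cfg$site_shift_sd * scale_sd) +
    outer(as.numeric(distortion == "on") - 0.5, cfg$distortion_shift_sd * scale_sd) +
    eps
  colnames(vol) <- nm
  vol[, log_roi] <- exp(vol[, log_roi, drop = FALSE])
  if (any(vol <= 0)) vol[vol <= 0] <- min(vol[vol > 0]) / 2  # guard, ~never hit
  wmh_sdlog <- sqrt(log(1 + (cfg$wmh_sd / cfg$wmh_mean)^2))
  wmh <- stats::rlnorm(n, log(cfg$wmh_mean) - wmh_sdlog^2 / 2, wmh_sdlog)

  # --- time-use compositions: Gaussian log parts -> pivot ilr space.
  parts <- names(cfg$comp_mean)
  V <- pivot_basis(length(parts))
  s_log <- sqrt(log(1 + cfg$comp_cv[parts]^2))
  mu_log <- log(cfg$comp_mean[parts])
  lx <- matrix(mu_log, n, length(parts), byrow = TRUE) +
    matrix(stats::rnorm(n * length(parts)), n) %*% diag(s_log) +
    outer(female - cfg$female_p, cfg$comp_sex_loading[parts])
  Z <- lx %*% V
  if (cfg$empirical_center) {
    # calibrate the realised sample centre to the target compositional mean
    # (dispersion untouched), in the spirit of mvrnorm(empirical = TRUE)
    target_z <- drop(crossprod(V, mu_log))
    Z <- Z - rep(colMeans(Z) - target_z, each = n)
  }
  colnames(Z) <- paste0("z", seq_len(ncol(Z)))
  comp <- ilr_inverse(Z, kappa = cfg$kappa, parts = parts)

  cohort <- data.frame(
    id = sprintf("P%04d", seq_len(n)),
    age = age,
    sex = factor(ifelse(female == 1, "female", "male"),
                 levels = c("male", "female")),
    education = education,
    site = site,
    distortion = distortion,
    as.data.frame(vol),
    wmh = wmh,
    as.data.frame(comp)
  )

  # --- cognition: linear model with known coefficients.
  truth <- list(pivot_order = parts, roi_scaling = list())
  for (oc in names(cfg$cognition)) {
    m <- cfg$cognition[[oc]]
    roi_z <- (vol[, m$roi] - cfg$roi_means[[m$roi]]) / cfg$roi_sds[[m$roi]]
    y <- m$intercept +
      m$age * (age - cfg$age_mean) +
      m$sex * female +
      m$education * (education - cfg$edu_mean) +
      drop(Z %*% m$ilr) +
      m$roi_coef * roi_z +
      drop((Z * roi_z) %*% m$interaction) +
      stats::rnorm(n, 0, m$resid_sd)
    y[stats::runif(n) < m$missing_rate] <- NA_real_
    cohort[[oc]] <- y
    truth[[oc]] <- m
    truth$roi_scaling[[oc]] <- c(center = cfg$roi_means[[m$roi]],
                                 scale = cfg$roi_sds[[m$roi]])
  }
  attr(cohort, "truth") <- truth
  cohort
}

#' Generate a synthetic epoch trace with known labels
#'
#' Builds full calendar days of epoch-level ENMO with ground-truth behaviour
#' labels: night sleep split across midnight (wake at half the sleep total
#' past 00:00, bed symmetric before 24:00), waking epochs assigned a seeded
#' random permutation of the profiled behaviours, ENMO drawn strictly inside
#' each behaviour's cut-point band (never on a boundary), and any residual
#' minutes as flagged non-wear.
#'
#' @param profile Named minutes per behaviour (`mvpa`, `lpa`, `sb`,
#'   `sleep`); the sum must be at most 1440, the remainder is non-wear.
#' @param dates Calendar days to generate (default Mon 2024-01-15 through
#'   Sun 2024-01-21, i.e. 5 weekdays + 2 weekend days).
#' @param epoch_seconds Epoch length; all profile entries must be whole
#'   epochs.
#' @param seed Integer seed.
#' @return List with `epochs` (timestamp, enmo_mg, wear), `log` (a
#'   [sleep_log()]), and `truth` (the per-epoch generating labels).
#' @export
generate_trace <- function(profile = c(mvpa = 90, lpa = 180, sb = 670, sleep = 500),
                           dates = seq(as.Date("2024-01-15"), by = "day",
                                       length.out = 7),
                           epoch_seconds = 60, seed = 1L) {
  profile <- profile[timeuse_parts()]
  if (anyNA(profile) || any(profile < 0)) {
    stop("`profile` needs non-negative minutes for mvpa, lpa, sb, sleep.",
         call. = FALSE)
  }
  if (sum(profile) > 1440) {
    stop("`profile` exceeds one day (sum > 1440 min).", call. = FALSE)
  }
  per_min <- 60 / epoch_seconds
  if (any(abs(profile * per_min - round(profile * per_min)) > 1e-9)) {
    stop("Profile minutes must be whole epochs at this epoch length.",
         call. = FALSE)
  }
  set.seed(seed)
  n_day <- as.integer(86400 / epoch_seconds)
  sleep_ep <- as.integer(round(profile[["sleep"]] * per_min))
  morning <- sleep_ep %/% 2L
  evening <- sleep_ep - morning
  wake_min <- morning / per_min
  bed_min <- 1440 - evening / per_min
  waking_n <- n_day - sleep_ep
  nonwear_ep <- waking_n - as.integer(round(sum(profile[c("mvpa", "lpa", "sb")]) * per_min))

  all_ts <- list(); all_enmo <- list(); all_wear <- list(); all_lab <- list()
  for (d in seq_along(dates)) {
    waking <- sample(rep(c("mvpa", "lpa", "sb", "nonwear"),
                         times = c(profile[["mvpa"]] * per_min,
                                   profile[["lpa"]] * per_min,
                                   profile[["sb"]] * per_min,
                                   nonwear_ep)))
    lab <- c(rep("sleep", morning), waking, rep("sleep", evening))
    enmo <- numeric(n_day)
    enmo[lab == "sleep"] <- stats::runif(sum(lab == "sleep"), 0, 30)
    enmo[lab == "sb"] <- stats::runif(sum(lab == "sb"), 0, 47.5)
    enmo[lab == "lpa"] <- stats::runif(sum(lab == "lpa"), 48.5, 92.5)
    enmo[lab == "mvpa"] <- stats::runif(sum(lab == "mvpa"), 93.5, 300)
    enmo[lab == "nonwear"] <- 0
    all_ts[[d]] <- as.POSIXct(paste(dates[d], "00:00:00"), tz = "UTC") +
      (seq_len(n_day) - 1L) * epoch_seconds
    all_enmo[[d]] <- enmo
    all_wear[[d]] <- as.integer(lab != "nonwear")
    all_lab[[d]] <- lab
  }
  epochs <- data.frame(
    timestamp = do.call(c, all_ts),
    enmo_mg = unlist(all_enmo),
    wear = unlist(all_wear)
  )
  log <- sleep_log(data.frame(
    date = dates,
    bed_time = rep(bed_min, length(dates)),
    wake_time = rep(wake_min, length(dates))
  ))
  list(epochs = epochs, log = log,
       truth = factor(unlist(all_lab), levels = behaviour_levels()))
}
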