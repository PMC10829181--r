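# Epoch-level wrist-accelerometry processing: ENMO cut-point classification
# under sleep-log precedence, daily summaries, wear-validity screening, and
# per-participant averaged time-use compositions.
#
# The pipeline starts at epoch-level ENMO (mg); raw 100 Hz processing,
# auto-calibration and algorithmic non-wear detection are out of scope --
# non-wear comes from the device wear flag and logged removal intervals.

#' Default ENMO cut points (mg)
#'
#' Waking epochs with ENMO above the `mvpa` cut are moderate-vigorous
#' physical activity; above the `lpa` cut, light activity; otherwise
#' sedentary.  Both rules are strict inequalities, so an epoch exactly at a
#' cut falls in the lower class (93 mg -> LPA, 48 mg -> SB).
#'
#' @return Named numeric vector `c(mvpa = 93, lpa = 48)`.
#' @export
default_cut_points <- function() c(mvpa = 93, lpa = 48)

behaviour_levels <- function() c("sleep", "mvpa", "lpa", "sb", "nonwear")

#' Construct a sleep log
#'
#' Per calendar day the log records the time the participant went to bed and
#' got out of bed, plus optional nap and monitor-removal intervals.  Epochs
#' of day `d` before `wake_time` or from `bed_time` onward are night sleep;
#' nap intervals are sleep during the waking day; removal intervals are
#' non-wear.
#'
#' @param days Data frame with columns `date` (Date or yyyy-mm-dd string),
#'   `bed_time`, `wake_time` (HH:MM or HH:MM:SS clock times within the day).
#' @param naps,removals Optional data frames with columns `date`, `start`,
#'   `end` (clock times, `start < end`).
#' @return Object of class `sleep_log`.
#' @export
sleep_log <- function(days, naps = NULL, removals = NULL) {
  days$date <- as.Date(days$date)
  if (anyNA(days$date)) stop("Unparseable dates in sleep log.", call. = FALSE)
  if (anyDuplicated(days$date)) stop("One sleep-log row per date.", call. = FALSE)
  check_ivl <- function(d) {
    if (is.null(d) || nrow(d) == 0L) return(NULL)
    d$date <- as.Date(d$date)
    d$start_min <- clock_minutes(d$start)
    d$end_min <- clock_minutes(d$end)
    if (any(d$start_min >= d$end_min)) {
      stop("Sleep-log intervals must have start < end.", call. = FALSE)
    }
    d
  }
  structure(
    list(
      days = data.frame(
        date = days$date,
        bed_min = clock_minutes(days$bed_time),
        wake_min = clock_minutes(days$wake_time)
      ),
      naps = check_ivl(naps),
      removals = check_ivl(removals)
    ),
    class = "sleep_log"
  )
}

clock_minutes <- function(x) {
  if (is.numeric(x)) return(as.numeric(x))
  p <- strsplit(as.character(x), ":", fixed = TRUE)
  vapply(p, function(v) {
    v <- as.numeric(v)
    if (length(v) < 2L || anyNA(v)) stop("Clock times must be HH:MM[:SS].", call. = FALSE)
    v[1] * 60 + v[2] + if (length(v) >= 3L) v[3] / 60 else 0
  }, numeric(1))
}

#' Read epoch-level ENMO series / sleep-log CSVs
#'
#' Epoch CSV columns: `timestamp` (ISO-8601), `enmo_mg`, `wear` (0/1).
#' Sleep-log CSV columns: `date`, `bed_time`, `wake_time`, optional
#' `nap_start`/`nap_end` and `removal_start`/`removal_end` (leave blank when
#' absent; repeat a date's row to record several intervals).
#'
#' @param path File path.
#' @param tz Time zone for timestamps (default UTC).
#' @return `read_epochs()`: data frame with `timestamp`, `enmo_mg`, `wear`;
#'   `read_sleep_log()`: a [sleep_log()].
#' @export
read_epochs <- function(path, tz = "UTC") {
  d <- utils::read.csv(path)
  need <- c("timestamp", "enmo_mg", "wear")
  if (!all(need %in% names(d))) {
    stop("Epoch CSV needs columns timestamp, enmo_mg, wear.", call. = FALSE)
  }
  d$timestamp <- as.POSIXct(d$timestamp, tz = tz,
                            tryFormats = c("%Y-%m-%dT%H:%M:%OS",
                                           "%Y-%m-%d %H:%M:%OS",
                                           "%Y-%m-%d %H:%M"))
  d[need]
}

#' @rdname read_epochs
#' @export
read_sleep_log <- function(path) {
  d <- utils::read.csv(path)
  first <- d[!duplicated(d$date), c("date", "bed_time", "wake_time")]
  grab <- function(s, e) {
    if (!all(c(s, e) %in% names(d))) return(NULL)
    keep <- !is.na(d[[s]]) & nzchar(d[[s]])
    if (!any(keep)) return(NULL)
    data.frame(date = d$date[keep], start = d[[s]][keep], end = d[[e]][keep])
  }
  sleep_log(first, naps = grab("nap_start", "nap_end"),
            removals = grab("removal_start", "removal_end"))
}

in_intervals <- function(date, minute, ivl) {
  if (is.null(ivl)) return(rep(FALSE, length(minute)))
  hit <- rep(FALSE, length(minute))
  for (r in seq_len(nrow(ivl))) {
    hit <- hit | (date == ivl$date[r] & minute >= ivl$start_min[r] & minute < ivl$end_min[r])
  }
  hit
}

#' Classify epochs into time-use behaviours
#'
#' Applies, in order of precedence: (1) manual sleep windows from the log
#' (night sleep and naps) regardless of ENMO; (2) non-wear from the wear
#' flag or logged removal intervals; (3) ENMO cut points for the remaining
#' waking epochs.
#'
#' @param epochs Data frame with `timestamp` (POSIXct), `enmo_mg`, `wear`.
#' @param log A [sleep_log()] covering every day in `epochs`.
#' @param cuts Named cut points, see [default_cut_points()].
#' @return `epochs` with an added factor column `behaviour` with levels
#'   sleep, mvpa, lpa, sb, nonwear.
#' @export
classify_epochs <- function(epochs, log, cuts = default_cut_points()) {
  stopifnot(inherits(log, "sleep_log"))
  if (any(epochs$enmo_mg < 0)) stop("ENMO must be non-negative.", call. = FALSE)
  date <- as.Date(epochs$timestamp, tz = attr(epochs$timestamp, "tzone") %||% "UTC")
  minute <- as.numeric(epochs$timestamp - as.POSIXct(
    paste(date, "00:00:00"), tz = attr(epochs$timestamp, "tzone") %||% "UTC"
  ), units = "mins")
  missing_days <- setdiff(as.character(unique(date)), as.character(log$days$date))
  if (length(missing_days)) {
    stop(sprintf("Sleep log missing for day(s): %s.",
                 paste(missing_days, collapse = ", ")), call. = FALSE)
  }
  di <- match(date, log$days$date)
  night <- minute < log$days$wake_min[di] | minute >= log$days$bed_min[di]
  asleep <- night | in_intervals(date, minute, log$naps)
  nonwear <- !asleep & (epochs$wear == 0 | in_intervals(date, minute, log$removals))
  lab <- ifelse(asleep, "sleep",
         ifelse(nonwear, "nonwear",
         ifelse(epochs$enmo_mg > cuts[["mvpa"]], "mvpa",
         ifelse(epochs$enmo_mg > cuts[["lpa"]], "lpa", "sb"))))
  epochs$behaviour <- factor(lab, levels = behaviour_levels())
  epochs
}

#' Summarise classified epochs into daily minute totals
#'
#' @param classified Output of [classify_epochs()]; every represented
#'   calendar day must be complete (86400 s of epochs).
#' @return Data frame (one row per day): `date`, `is_weekend`, minutes in
#'   each behaviour, `waking_wear_min` (mvpa + lpa + sb), `nonwear_min`, and
#'   `valid` per [assess_validity()].  Behaviour plus non-wear minutes sum
#'   to 1440 on every row.
#' @export
summarize_days <- function(classified) {
  ts <- classified$timestamp
  if (length(ts) < 2L) stop("Need a full day of epochs.", call. = FALSE)
  step <- as.numeric(diff(ts), units = "secs")
  if (diff(range(step)) > 1e-6) {
    stop("Epoch timestamps must be uniformly spaced.", call. = FALSE)
  }
  epoch_seconds <- step[1]
  per_day <- 86400 / epoch_seconds
  date <- as.Date(ts, tz = attr(ts, "tzone") %||% "UTC")
  tab <- table(date, classified$behaviour)
  if (any(rowSums(tab) != per_day)) {
    bad <- rownames(tab)[rowSums(tab) != per_day]
    stop(sprintf("Partial day(s) in epoch series: %s.",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  mins <- tab * epoch_seconds / 60
  out <- data.frame(
    date = as.Date(rownames(tab)),
    is_weekend = format(as.Date(rownames(tab)), "%u") %in% c("6", "7"),
    mvpa_min = as.numeric(mins[, "mvpa"]),
    lpa_min = as.numeric(mins[, "lpa"]),
    sb_min = as.numeric(mins[, "sb"]),
    sleep_min = as.numeric(mins[, "sleep"]),
    nonwear_min = as.numeric(mins[, "nonwear"])
  )
  out$waking_wear_min <- out$mvpa_min + out$lpa_min + out$sb_min
  out$valid <- assess_validity(out)
  rownames(out) <- NULL
  out
}

#' Wear-day validity rule
#'
#' A day is a valid wear day when the monitor was worn for at least 10
#' waking hours and accrued less than 6 hours of non-wear (so a valid day
#' carries at least 18 hours of average wear over the 24-hour period).
#'
#' @param days Data frame with `waking_wear_min` and `nonwear_min`.
#' @param min_waking_wear_min Minimum waking wear, default 600.
#' @param max_nonwear_min Non-wear must be strictly below this, default 360.
#' @return Logical vector.
#' @export
assess_validity <- function(days, min_waking_wear_min = 600,
                            max_nonwear_min = 360) {
  days$waking_wear_min >= min_waking_wear_min & days$nonwear_min < max_nonwear_min
}

#' Average valid days into a participant time-use summary
#'
#' Averages behaviour minutes across valid wear days, applies the inclusion
#' rules (at least `min_weekdays` valid weekdays and `min_weekend_days`
#' valid weekend days; average recorded daily total at most
#' `max_daily_total_min`), replaces structural zeros by half the smallest
#' observable increment before closure, and closes to `kappa`.
#'
#' @param days Data frame as returned by [summarize_days()].
#' @param kappa Closure constant.
#' @param epoch_seconds Epoch length used (sets the zero-replacement value,
#'   `epoch_seconds / 60 / 2` minutes).
#' @param min_weekdays,min_weekend_days Minimum valid-day counts (3 and 1).
#' @param max_daily_total_min Exclusion threshold on the average daily total
#'   of recorded time use (1500 min).
#' @return One-row data frame: raw average minutes (`raw_*`), closed
#'   composition ([timeuse_parts()], summing to `kappa` when computable),
#'   valid-day counts, `included`, `exclusion_reason`, `zero_replaced`.
#' @export
summarize_participant <- function(days, kappa = timeuse_kappa(),
                                  epoch_seconds = 60,
                                  min_weekdays = 3, min_weekend_days = 1,
                                  max_daily_total_min = 1500) {
  if (is.null(days) || nrow(days) == 0L) {
    stop("Need at least one day summary (participants with no data are handled upstream).",
         call. = FALSE)
  }
  if (!"valid" %in% names(days)) days$valid <- assess_validity(days)
  v <- days[days$valid, , drop = FALSE]
  n_wd <- sum(!v$is_weekend)
  n_we <- sum(v$is_weekend)
  cols <- paste0(timeuse_parts(), "_min")
  raw <- if (nrow(v)) colMeans(v[cols]) else stats::setNames(rep(NA_real_, 4), cols)
  total <- sum(raw)
  reason <- NA_character_
  if (n_wd < min_weekdays) {
    reason <- "insufficient_weekdays"
  } else if (n_we < min_weekend_days) {
    reason <- "no_weekend_day"
  } else if (total > max_daily_total_min) {
    reason <- "overfull_day"
  }
  included <- is.na(reason)
  zero_replaced <- FALSE
  comp <- stats::setNames(rep(NA_real_, 4), timeuse_parts())
  if (nrow(v) > 0L) {
    parts <- stats::setNames(as.numeric(raw), timeuse_parts())
    zero <- parts == 0
    if (any(zero)) {
      parts[zero] <- epoch_seconds / 60 / 2
      zero_replaced <- TRUE
    }
    comp <- closure(parts, kappa)
  }
  out <- data.frame(
    raw_mvpa_min = raw[[1]], raw_lpa_min = raw[[2]],
    raw_sb_min = raw[[3]], raw_sleep_min = raw[[4]],
    mvpa = comp[["mvpa"]], lpa = comp[["lpa"]], sb = comp[["sb"]],
    sleep = comp[["sleep"]],
    n_valid_weekdays = n_wd, n_valid_weekend_days = n_we,
    avg_daily_total_min = total,
    included = included, exclusion_reason = reason,
    zero_replaced = zero_replaced
  )
  rownames(out) <- NULL
  out
}

#' Extract a participant's time-use composition from raw inputs
#'
#' Convenience wrapper: classify epochs, summarise days, apply validity and
#' inclusion screening.
#'
#' @inheritParams classify_epochs
#' @inheritParams summarize_participant
#' @return As [summarize_participant()].
#' @export
extract_timeuse <- function(epochs, log, cuts = default_cut_points(),
                            kappa = timeuse_kappa(), epoch_seconds = 60,
                            ...) {
  days <- summarize_days(classify_epochs(epochs, log, cuts))
  summarize_participant(days, kappa = kappa, epoch_seconds = epoch_seconds, ...)
}
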