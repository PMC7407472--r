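#' Growth-curve analysis configuration
#'
#' Thresholds for feature extraction from daily OD600 traces. Growth is
#' log-linear up to OD600 = 0.16 (`exp_upper_od`); above 0.3
#' (`sat_lower_od`) the trace decays toward its daily maximum. The lower
#' fit bound (`fit_lower_od`, default 0.03) excludes the very low ODs where
#' plate readers are too noisy for a good rate estimate.
#'
#' @param exp_upper_od OD600 bounding exponential phase from above.
#' @param fit_lower_od lower OD600 bound for the rate regression.
#' @param sat_lower_od OD600 above which the trace is saturating.
#' @param sat_window_min final window, in minutes, averaged for the
#'   saturating OD.
#' @return object of class `growth_config`.
#' @export
growth_config <- function(exp_upper_od = 0.16, fit_lower_od = 0.03,
                          sat_lower_od = 0.3, sat_window_min = 60) {
  if (!(0 < fit_lower_od && fit_lower_od < exp_upper_od &&
        exp_upper_od < sat_lower_od))
    stop("need 0 < fit_lower_od < exp_upper_od < sat_lower_od")
  if (sat_window_min <= 0) stop("'sat_window_min' must be positive")
  structure(list(exp_upper_od = exp_upper_od, fit_lower_od = fit_lower_od,
                 sat_lower_od = sat_lower_od,
                 sat_window_min = sat_window_min),
            class = "growth_config")
}

check_series <- function(times, od) {
  if (length(times) != length(od)) stop("'times' and 'od' differ in length")
  if (is.unsorted(times, strictly = TRUE))
    stop("'times' must be strictly ascending")
}

#' Blank-correct a plate of OD600 traces
#'
#' Subtracts, per day and time point, the mean reading of the blank wells
#' from every non-blank well. Wells whose corrected OD drops below -0.05
#' are flagged in the `blank_flag` column (a correction that deep is a sign
#' the blanks do not represent the medium).
#'
#' @param plate long-format data.frame with columns `well`, `day`,
#'   `time_min`, `od600`, and logical `is_blank`.
#' @return the plate with `od600` corrected (blank wells untouched) and a
#'   logical `blank_flag` column.
#' @export
blank_correct <- function(plate) {
  need <- c("well", "day", "time_min", "od600", "is_blank")
  if (!all(need %in% names(plate)))
    stop("plate must have columns: ", paste(need, collapse = ", "))
  blanks <- plate[plate$is_blank, ]
  if (nrow(blanks) == 0) stop("no blank wells on the plate")
  key <- function(d) paste(d$day, d$time_min)
  bm <- tapply(blanks$od600, key(blanks), mean)
  if (any(!key(plate) %in% names(bm)))
    stop("some (day, time) points have no blank reading")
  corr <- plate$od600 - as.numeric(bm[key(plate)])
  plate$od600 <- ifelse(plate$is_blank, plate$od600, corr)
  plate$blank_flag <- !plate$is_blank & corr < -0.05
  plate
}

#' Derivative of OD over time vs OD
#'
#' Centered finite differences of a (lightly smoothed) trace, paired with
#' the OD at the central point; the classic diagnostic in which exponential
#' phase is a straight line through the origin of slope equal to the growth
#' rate. Smoothing (3-point moving average) is for this visualization only;
#' rate fitting uses log-linear regression on the raw trace.
#'
#' @param times minutes from the start of the day, strictly ascending.
#' @param od OD600 readings.
#' @param smooth apply the 3-point moving average first?
#' @return data.frame with columns `od` and `dod_dt` (per hour).
#' @export
derivative_curve <- function(times, od, smooth = TRUE) {
  check_series(times, od)
  if (length(od) < 3) stop("need at least 3 points")
  if (smooth && length(od) >= 3) {
    sm <- od
    n <- length(od)
    sm[2:(n - 1)] <- (od[1:(n - 2)] + od[2:(n - 1)] + od[3:n]) / 3
    od <- sm
  }
  n <- length(od)
  i <- 2:(n - 1)
  dt_hr <- (times[i + 1] - times[i - 1]) / 60
  data.frame(od = od[i], dod_dt = (od[i + 1] - od[i - 1]) / dt_hr)
}

#' Early exponential growth rate
#'
#' Slope of the ordinary least-squares regression of `ln OD` on time,
#' restricted to readings with OD in `[fit_lower_od, exp_upper_od]`.
#'
#' @param times minutes; `od` OD600 readings.
#' @param od OD600 readings.
#' @param cfg a [growth_config()].
#' @return rate in 1/hr, or `NA` when fewer than 4 in-window points exist
#'   (the low-OD regime a plate reader cannot resolve).
#' @export
exponential_rate <- function(times, od, cfg = growth_config()) {
  check_series(times, od)
  sel <- is.finite(od) & od >= cfg$fit_lower_od & od <= cfg$exp_upper_od
  if (sum(sel) < 4) return(NA_real_)
  unname(coef(lm(log(od[sel]) ~ I(times[sel] / 60)))[2])
}

#' Time to leave exponential phase
#'
#' First time the trace crosses `exp_upper_od` (OD600 = 0.16 by default),
#' linearly interpolated between the bracketing samples, in hours.
#'
#' @inheritParams exponential_rate
#' @return hours; 0 if the series starts at or above the threshold; `NA`
#'   when the threshold is never reached.
#' @export
time_to_leave_exponential <- function(times, od, cfg = growth_config()) {
  check_series(times, od)
  thr <- cfg$exp_upper_od
  hit <- which(od >= thr)
  if (length(hit) == 0) return(NA_real_)
  i <- hit[1]
  if (i == 1) return(times[1] / 60 * 0)  # starts above threshold
  frac <- (thr - od[i - 1]) / (od[i] - od[i - 1])
  (times[i - 1] + frac * (times[i] - times[i - 1])) / 60
}

#' Saturating optical density
#'
#' Mean OD over the final `sat_window_min` minutes of the day; a windowed
#' mean rather than the daily maximum so a single spiky sample cannot set
#' the value.
#'
#' @inheritParams exponential_rate
#' @return the saturating OD600.
#' @export
saturating_od <- function(times, od, cfg = growth_config()) {
  check_series(times, od)
  if (diff(range(times)) < cfg$sat_window_min)
    stop("series shorter than the saturation window")
  mean(od[times > max(times) - cfg$sat_window_min])
}

#' Flag erratic traces
#'
#' Operational definition of the rare plate-reader artifacts: TRUE when the
#' trace has a one-step drop of more than `drop_frac` of the current OD
#' while above `od_gate`, or a negative excursion beyond `noise_mult` times
#' the local noise scale that later recovers. A handful of curves per
#' thousand behave this way and they typically do not repeat, so they are
#' excluded from condition summaries (and counted separately).
#'
#' @inheritParams exponential_rate
#' @param drop_frac single-step fractional drop that triggers the flag.
#' @param od_gate OD below which drops are ignored (noise regime).
#' @param noise_mult multiple of the local noise scale for the negative
#'   excursion rule.
#' @return logical.
#' @export
flag_erratic <- function(times, od, drop_frac = 0.3, od_gate = 0.05,
                         noise_mult = 5) {
  check_series(times, od)
  n <- length(od)
  if (n < 3) return(FALSE)
  drops <- od[-n] > od_gate & (od[-1] - od[-n]) < -drop_frac * od[-n]
  if (any(drops)) return(TRUE)
  noise <- mad(diff(od)) / sqrt(2)
  if (noise > 0) {
    neg <- which(od < -noise_mult * noise)
    if (length(neg) && any(od[seq(max(neg), n)] > 0)) return(TRUE)
  }
  FALSE
}

#' Extract growth features for every well-day trace
#'
#' @param plate long-format data.frame with columns `well`, `day`,
#'   `time_min`, `od600`, `condition`, and (optionally) logical `is_blank`
#'   (blank wells are skipped).
#' @param cfg a [growth_config()].
#' @return data.frame with one row per (well, day): `condition`, `rate`
#'   (1/hr), `t_exit` (hr), `od_sat`, and logical `erratic`.
#' @export
extract_growth_features <- function(plate, cfg = growth_config()) {
  need <- c("well", "day", "time_min", "od600", "condition")
  if (!all(need %in% names(plate)))
    stop("plate must have columns: ", paste(need, collapse = ", "))
  if ("is_blank" %in% names(plate)) plate <- plate[!plate$is_blank, ]
  split_keys <- interaction(plate$well, plate$day, drop = TRUE)
  rows <- lapply(split(plate, split_keys), function(d) {
    d <- d[order(d$time_min), ]
    data.frame(well = d$well[1], day = d$day[1], condition = d$condition[1],
               rate = exponential_rate(d$time_min, d$od600, cfg),
               t_exit = time_to_leave_exponential(d$time_min, d$od600, cfg),
               od_sat = saturating_od(d$time_min, d$od600, cfg),
               erratic = flag_erratic(d$time_min, d$od600),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-condition summary of growth features
#'
#' Mean and coefficient of variation (sample SD / mean) of each feature per
#' condition and day. Wells flagged erratic are excluded and counted in
#' `n_erratic`. The CV is the study's measure of between-replicate
#' divergence.
#'
#' @param features output of [extract_growth_features()].
#' @return long data.frame: `condition`, `day`, `feature`, `mean`, `cv`,
#'   `n_wells`, `n_erratic`. `cv` is `NA` when the mean is 0.
#' @export
condition_summary <- function(features) {
  feats <- c("rate", "t_exit", "od_sat")
  keys <- unique(features[c("condition", "day")])
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    sub <- features[features$condition == keys$condition[i] &
                    features$day == keys$day[i], ]
    ok <- sub[!sub$erratic, ]
    if (nrow(ok) < 1)
      stop("no unflagged wells for condition ", keys$condition[i],
           " day ", keys$day[i])
    do.call(rbind, lapply(feats, function(f) {
      v <- ok[[f]][is.finite(ok[[f]])]
      mu <- mean(v)
      data.frame(condition = keys$condition[i], day = keys$day[i],
                 feature = f, mean = mu,
                 cv = if (length(v) > 1 && mu != 0) sd(v) / mu else
                      if (mu == 0) NA_real_ else 0,
                 n_wells = length(v), n_erratic = sum(sub$erratic),
                 stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Population fold change implied by reaching threshold earlier
#'
#' At a fixed exponential rate, leaving exponential phase `delta_t` hours
#' earlier means the effective inoculum grew by `exp(rate * delta_t)`:
#' e.g. a half-hour shift at 0.85/hr is about 1.5-fold more population, and
#' a full hour is a little over an additional doubling.
#'
#' @param rate exponential growth rate, 1/hr.
#' @param delta_t advance of the threshold-crossing time, hours (>= 0).
#' @return the fold change.
#' @examples
#' population_fold_change(0.85, 0.5)
#' @export
population_fold_change <- function(rate, delta_t) {
  if (any(delta_t < 0)) stop("'delta_t' must be >= 0")
  exp(rate * delta_t)
}
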