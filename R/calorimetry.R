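#' Weir energy expenditure
#'
#' Abbreviated Weir equation without the urinary-nitrogen term:
#' EE (kcal) = 3.941 x VO2 (L) + 1.106 x VCO2 (L). Linear and homogeneous
#' in its inputs, so it applies equally to volumes per epoch, per phase or
#' per day.
#'
#' @param vo2_l,vco2_l oxygen consumed and carbon dioxide produced, in
#'   litres over the same period; vectors are combined elementwise.
#' @return energy expenditure in kcal over the period.
#' @examples
#' weir_ee(1, 1)    # 5.047
#' weir_ee(1, 0.7)  # 4.7152
#' @export
weir_ee <- function(vo2_l, vco2_l) {
  df_assert(all(vo2_l >= 0) && all(vco2_l >= 0), "negative_gas",
            "gas volumes must be >= 0")
  3.941 * vo2_l + 1.106 * vco2_l
}

# internal: check trace structure; returns epoch_s
validate_trace <- function(trace) {
  df_assert(inherits(trace, "data.frame") && nrow(trace) >= 2,
            "bad_trace", "trace needs at least two readings")
  need <- c("timestamp", "vo2_ml_h", "vco2_ml_h", "x_counts", "z_counts",
            "feeder_g", "spill_g")
  miss <- setdiff(need, names(trace))
  df_assert(length(miss) == 0, "bad_trace",
            "trace missing column(s): %s", paste(miss, collapse = ", "))
  dt <- diff(as.numeric(trace$timestamp))
  df_assert(all(dt > 0), "bad_trace", "timestamps must strictly increase")
  df_assert(diff(range(dt)) < 1e-6, "bad_trace",
            "timestamps must be uniformly spaced")
  epoch_s <- attr(trace, "epoch_s")
  if (is.null(epoch_s)) epoch_s <- dt[1]
  df_assert(abs(epoch_s - dt[1]) < 1e-6, "bad_trace",
            "epoch_s attribute disagrees with timestamp spacing")
  df_assert(all(trace$vo2_ml_h >= 0) && all(trace$vco2_ml_h >= 0),
            "negative_gas", "VO2/VCO2 must be >= 0")
  refill <- if ("refill" %in% names(trace)) trace$refill else 0
  jumps <- which(diff(trace$feeder_g) > 1e-9)
  bad <- jumps[refill[jumps + 1L] == 0]
  df_assert(length(bad) == 0, "unflagged_refill",
            "feeder mass increases without refill flag at %s",
            paste(format(trace$timestamp[bad + 1L]), collapse = ", "))
  epoch_s
}

# internal: resolve an analysis window to a row index vector.
# window = NULL uses the largest integer number of trailing 24-h days.
resolve_window <- function(trace, epoch_s, window = NULL) {
  n <- nrow(trace)
  per_day <- as.integer(86400 / epoch_s)
  if (is.null(window)) {
    n_days <- n %/% per_day
    df_assert(n_days >= 1, "bad_window", "trace shorter than 24 h")
    idx <- (n - n_days * per_day + 1L):n
  } else {
    df_assert(length(window) == 2, "bad_window",
              "window must be c(start, end)")
    idx <- which(trace$timestamp >= window[1] & trace$timestamp < window[2])
    df_assert(length(idx) > 0 &&
                idx[1] >= 1 && idx[length(idx)] <= n &&
                as.numeric(difftime(window[2], window[1], units = "secs")) <=
                  n * epoch_s + 1e-6,
              "bad_window", "window exceeds the trace")
    df_assert(length(idx) %% per_day == 0, "bad_window",
              "window must span an integer number of 24-h days")
  }
  idx
}

#' Resting energy expenditure from a trace
#'
#' Finds the two lowest-EE non-overlapping 90-s readings in the analysis
#' window (ties broken by earliest timestamp), averages them, and
#' extrapolates over 24 h (x 960 for 90-s epochs, generally x 86400 /
#' epoch). Optionally requires a preceding quiet period (no beam breaks)
#' before a reading qualifies; this filter is off by default.
#'
#' @param trace a gas-exchange trace (see [simulate_clams_trace()]).
#' @param window analysis interval `c(start, end)` or NULL for the
#'   trailing whole days.
#' @param quiet_epochs integer; number of immediately preceding epochs
#'   that must have zero activity counts for a reading to qualify
#'   (default 0 = no precondition).
#' @return resting energy expenditure in kcal/d.
#' @export
resting_ee <- function(trace, window = NULL, quiet_epochs = 0L) {
  epoch_s <- validate_trace(trace)
  idx <- resolve_window(trace, epoch_s, window)
  df_assert(length(idx) >= 2, "too_few_readings",
            "resting EE needs at least two readings")
  epoch_h <- epoch_s / 3600
  ee <- weir_ee(trace$vo2_ml_h[idx] * epoch_h / 1000,
                trace$vco2_ml_h[idx] * epoch_h / 1000)
  if (quiet_epochs > 0) {
    act <- trace$x_counts + trace$z_counts
    quiet <- vapply(idx, function(i) {
      prev <- (i - quiet_epochs):(i - 1)
      all(prev >= 1) && all(act[prev] == 0)
    }, logical(1))
    df_assert(sum(quiet) >= 2, "too_few_readings",
              "fewer than two readings satisfy the quiet precondition")
    ee[!quiet] <- Inf
  }
  two <- order(ee, seq_along(ee))[1:2]  # stable: earliest wins ties
  mean(ee[two]) * 86400 / epoch_s
}

#' Summarize spontaneous activity
#'
#' Sums X (ambulatory/horizontal) and Z (rearing/vertical) beam-break
#' counts per 12-h phase and per 24 h, normalized per day over the
#' analysis window.
#'
#' @inheritParams resting_ee
#' @return one-row data frame with `activity_total`, `activity_dark_x`,
#'   `activity_dark_z`, `activity_light_x`, `activity_light_z` (counts/d).
#' @export
summarize_activity <- function(trace, window = NULL) {
  epoch_s <- validate_trace(trace)
  df_assert(all(trace$x_counts >= 0) && all(trace$z_counts >= 0),
            "bad_trace", "activity counts must be >= 0")
  idx <- resolve_window(trace, epoch_s, window)
  n_days <- length(idx) * epoch_s / 86400
  dark <- trace_dark(trace, idx)
  data.frame(
    activity_total = sum(trace$x_counts[idx] + trace$z_counts[idx]) / n_days,
    activity_dark_x = sum(trace$x_counts[idx][dark]) / n_days,
    activity_dark_z = sum(trace$z_counts[idx][dark]) / n_days,
    activity_light_x = sum(trace$x_counts[idx][!dark]) / n_days,
    activity_light_z = sum(trace$z_counts[idx][!dark]) / n_days)
}

# internal: dark-phase indicator for selected rows
trace_dark <- function(trace, idx) {
  light_on <- attr(trace, "light_on")
  light_off <- attr(trace, "light_off")
  if (is.null(light_on)) light_on <- 6
  if (is.null(light_off)) light_off <- 18
  ts <- trace$timestamp[idx]
  hour <- as.numeric(format(ts, "%H", tz = "UTC")) +
    as.numeric(format(ts, "%M", tz = "UTC")) / 60 +
    as.numeric(format(ts, "%S", tz = "UTC")) / 3600
  hour >= light_off | hour < light_on
}

#' Energy budget for one animal-cage session
#'
#' Integrates per-epoch Weir energy expenditure over an integer-day
#' analysis window, splits it into dark and light phases by clock hour,
#' computes phase and 24-h respiratory quotients as the ratio of summed
#' gas volumes, corrects food intake for spillage, and forms the energy
#' balance per animal (balance = intake - EE, exactly, before any
#' covariate adjustment).
#'
#' @inheritParams resting_ee
#' @param diet_energy_density metabolizable energy density of the diet in
#'   kcal/g (default 3.64, i.e. 3640 kcal/kg).
#' @return one-row data frame of class `energy_budget` with fields
#'   `animal_id`, `ee_24h` (kcal/d), `ee_dark`, `ee_light` (kcal/12 h),
#'   `ee_resting` (kcal/d), `rq_24h`, `rq_dark`, `rq_light`,
#'   `intake_kcal_d`, `balance_kcal_d`, and activity summaries.
#' @examples
#' tr <- simulate_clams_trace(trace_spec(duration_h = 48, noise_cv = 0),
#'                            truth_ee_kcal_d = 10.5)
#' summarize_trace(tr)
#' @export
summarize_trace <- function(trace, window = NULL,
                            diet_energy_density = 3.64) {
  epoch_s <- validate_trace(trace)
  idx <- resolve_window(trace, epoch_s, window)
  epoch_h <- epoch_s / 3600
  n_days <- length(idx) * epoch_s / 86400

  vo2_l <- trace$vo2_ml_h[idx] * epoch_h / 1000
  vco2_l <- trace$vco2_ml_h[idx] * epoch_h / 1000
  ee <- weir_ee(vo2_l, vco2_l)
  dark <- trace_dark(trace, idx)

  rq_of <- function(sel) {
    df_assert(sum(vo2_l[sel]) > 0, "bad_trace", "zero VO2 in phase")
    sum(vco2_l[sel]) / sum(vo2_l[sel])
  }
  rq_24h <- rq_of(TRUE & seq_along(vo2_l) > 0)
  rq_guard <- function(rq) {
    if (rq < 0.6 || rq > 1.3)
      warning(sprintf("RQ %.2f outside physiological guard band", rq))
    rq
  }

  feeder <- trace$feeder_g[idx]
  spill <- trace$spill_g[idx]
  intake_g <- (feeder[1] - feeder[length(feeder)]) -
    (spill[length(spill)] - spill[1])
  intake <- intake_g * diet_energy_density / n_days

  ee_24h <- sum(ee) / n_days
  act <- summarize_activity(trace, window)
  out <- data.frame(
    animal_id = attr(trace, "animal_id") %||% NA_character_,
    ee_24h = ee_24h,
    ee_dark = sum(ee[dark]) / n_days,
    ee_light = sum(ee[!dark]) / n_days,
    ee_resting = resting_ee(trace, window),
    rq_24h = rq_guard(rq_24h),
    rq_dark = rq_guard(rq_of(dark)),
    rq_light = rq_guard(rq_of(!dark)),
    intake_kcal_d = intake,
    balance_kcal_d = intake - ee_24h)
  out <- cbind(out, act)
  class(out) <- c("energy_budget", "data.frame")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
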