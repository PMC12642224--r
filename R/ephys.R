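#' fEPSP amplitude of one sweep
#'
#' Absolute deflection of the negative peak from the pre-stimulus baseline
#' mean (5 ms before the stimulus). Samples within 1 ms after the stimulus
#' are excluded so the stimulus artifact and fiber volley are not measured.
#' Traces clipped at the recording limit are flagged.
#'
#' @param sweep list with `time` (ms), `voltage` (mV), `stimulus_time` (ms).
#' @param baseline_window pre-stimulus window used for the baseline mean, ms.
#' @param artifact_blank post-stimulus exclusion window, ms.
#' @param clip_limit absolute voltage (mV) at which the trace counts as
#'   saturated; the result then carries attribute `clipped = TRUE`.
#' @return Amplitude in mV (non-negative).
#' @export
fepsp_amplitude <- function(sweep, baseline_window = 5, artifact_blank = 1,
                            clip_limit = 10) {
  t <- sweep$time; v <- sweep$voltage; st <- sweep$stimulus_time
  pre <- t < st & t >= st - baseline_window
  post <- t > st + artifact_blank
  if (!any(post)) stop("post-stimulus window empty")
  base <- mean(v[pre])
  amp <- abs(min(v[post]) - base)
  if (max(abs(v[post])) >= clip_limit) attr(amp, "clipped") <- TRUE
  amp
}

# Indices of the rising (negative-going) phase between lo and hi fractions of
# the peak deflection, located on a 3-point median-smoothed trace; the fit
# itself uses the raw trace.
rising_window <- function(sweep, lo = 0.10, hi = 0.40, baseline_window = 5,
                          artifact_blank = 1) {
  t <- sweep$time; v <- sweep$voltage; st <- sweep$stimulus_time
  base <- mean(v[t < st & t >= st - baseline_window])
  post <- which(t > st + artifact_blank)
  sm <- stats::runmed(v, 3)
  defl <- base - sm[post]               # positive-going deflection
  pk <- post[which.max(defl)]
  peak_defl <- max(defl)
  in_win <- post[post <= pk & defl[seq_along(post)] >= lo * peak_defl &
                   defl[seq_along(post)] <= hi * peak_defl]
  in_win
}

#' fEPSP initial slope of one sweep
#'
#' Least-squares slope of the raw voltage over the samples whose deflection
#' lies between 10% and 40% of the peak amplitude on the rising phase. The
#' window is located on a 3-point median-smoothed copy of the trace (which
#' stabilizes the crossings under noise) but the fit uses raw samples.
#'
#' @param sweep list with `time` (ms), `voltage` (mV), `stimulus_time` (ms).
#' @param window deflection window as fractions of peak, default `c(0.1, 0.4)`.
#' @return Slope in mV/ms (negative for a negative-going fEPSP).
#' @export
fepsp_slope <- function(sweep, window = c(0.1, 0.4)) {
  idx <- rising_window(sweep, window[1], window[2])
  if (length(idx) < 3) stop("fewer than 3 samples in rising-phase window")
  stats::coef(stats::lm(sweep$voltage[idx] ~ sweep$time[idx]))[[2]]
}

#' Input-output curve metrics
#'
#' The plateau (maximal response) is the maximum observed amplitude across
#' intensities (with a warning when the curve is not monotone), and the
#' stimulation intensity achieving a requested fraction of the maximum is
#' found by linear interpolation between the bracketing intensities.
#'
#' @param sweeps list of sweeps at increasing stimulation intensities
#'   (each carrying `intensity`); at least 3.
#' @param fraction fraction(s) of the maximal response for which to report
#'   the interpolated intensity (e.g. 0.4 for baseline, 0.7 for induction).
#' @return List: `max_amplitude`, `max_slope`, `intensity_at` (named numeric,
#'   one per fraction), `amplitudes`, `intensities`.
#' @export
io_curve <- function(sweeps, fraction = c(0.4, 0.7)) {
  stopifnot(length(sweeps) >= 3)
  intens <- vapply(sweeps, `[[`, numeric(1), "intensity")
  stopifnot(!any(is.na(intens)))
  o <- order(intens)
  sweeps <- sweeps[o]; intens <- intens[o]
  amps <- vapply(sweeps, fepsp_amplitude, numeric(1))
  if (all(amps == 0)) stop("all responses zero")
  slopes <- vapply(sweeps, function(s) {
    tryCatch(fepsp_slope(s), error = function(e) NA_real_)
  }, numeric(1))
  if (any(diff(amps) < -1e-9)) warning("non-monotone I/O curve; plateau is the maximum response")
  mx <- max(amps)
  intensity_at <- vapply(fraction, function(f) {
    target <- f * mx
    i <- which(amps >= target)[1]
    if (i == 1) return(intens[1])
    # linear interpolation between the bracketing intensities
    intens[i - 1] + (target - amps[i - 1]) *
      (intens[i] - intens[i - 1]) / (amps[i] - amps[i - 1])
  }, numeric(1))
  names(intensity_at) <- paste0(round(100 * fraction), "%")
  list(max_amplitude = mx, max_slope = slopes[which.max(abs(slopes))],
       intensity_at = intensity_at, amplitudes = amps, intensities = intens)
}

#' Normalize an LTP time course to its pre-induction baseline
#'
#' Each post-induction sweep's slope is expressed as a percentage of the mean
#' baseline slope (baseline mean = 100%), and window means over the early and
#' late phases are reported.
#'
#' @param baseline_sweeps list of pre-induction sweeps.
#' @param post_sweeps list of post-induction sweeps, in recording order.
#' @param sweep_interval seconds between consecutive sweeps (default 20).
#' @param early_window,late_window post-induction windows, minutes.
#' @param metric per-sweep metric function (default [fepsp_slope()]).
#' @return List: `normalized` (percent per post sweep), `time_min`
#'   (post-induction sweep times), `early_mean`, `late_mean`,
#'   `baseline_mean` (raw units).
#' @export
ltp_normalize <- function(baseline_sweeps, post_sweeps, sweep_interval = 20,
                          early_window = c(0, 30), late_window = c(30, 60),
                          metric = fepsp_slope) {
  stopifnot(length(baseline_sweeps) >= 1, length(post_sweeps) >= 1)
  post_min <- (seq_along(post_sweeps) - 1) * sweep_interval / 60
  total_min <- length(post_sweeps) * sweep_interval / 60
  for (w in list(early_window, late_window)) {
    if (w[1] < 0 || w[1] >= total_min) {
      stop("analysis window outside the post-induction period")
    }
  }
  base <- mean(vapply(baseline_sweeps, metric, numeric(1)))
  if (abs(base) < .Machine$double.eps) stop("zero baseline mean")
  norm <- 100 * vapply(post_sweeps, metric, numeric(1)) / base
  in_win <- function(w) post_min >= w[1] & post_min < w[2]
  list(normalized = norm, time_min = post_min,
       early_mean = mean(norm[in_win(early_window)]),
       late_mean = mean(norm[in_win(late_window)]),
       baseline_mean = base)
}

#' Validate a theta-burst stimulation schedule
#'
#' A standard induction protocol: trains of bursts of pulses (defaults: 5
#' trains at 20 s intervals, 10 bursts per train at 10 Hz, 4 pulses per burst
#' at 100 Hz, i.e. 200 pulses in total).
#'
#' @param n_trains,n_bursts,n_pulses schedule counts.
#' @param train_interval_s,burst_rate_hz,pulse_rate_hz timing parameters.
#' @return List describing the schedule, including `total_pulses`.
#' @export
tbs_schedule <- function(n_trains = 5, n_bursts = 10, n_pulses = 4,
                         train_interval_s = 20, burst_rate_hz = 10,
                         pulse_rate_hz = 100) {
  stopifnot(n_trains >= 1, n_bursts >= 1, n_pulses >= 1,
            burst_rate_hz < pulse_rate_hz)
  if (n_bursts / burst_rate_hz > train_interval_s) {
    stop("bursts do not fit inside the train interval")
  }
  list(n_trains = n_trains, n_bursts = n_bursts, n_pulses = n_pulses,
       train_interval_s = train_interval_s, burst_rate_hz = burst_rate_hz,
       pulse_rate_hz = pulse_rate_hz,
       total_pulses = n_trains * n_bursts * n_pulses)
}
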