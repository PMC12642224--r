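#' Detect NREM sleep spindles
#'
#' Band-pass filters the EEG (Butterworth, order 4, zero-phase), takes the
#' rectified envelope smoothed over 0.1 s, and thresholds it at the NREM
#' envelope mean plus `amp_threshold_sd` standard deviations. Event
#' boundaries are then extended outward to where the envelope falls below
#' mean + `boundary_sd` SD (dual-threshold detection, which recovers the full
#' extent of tapered bursts), events separated by gaps shorter than 0.1 s are
#' merged, and only events within the duration bounds that lie wholly inside
#' NREM epochs are kept. Per-event oscillation frequency is the zero-crossing
#' count of the band-passed signal divided by twice the duration; amplitude
#' is the raw band-passed peak within the event.
#'
#' @param rec recording list (`eeg`, `sampling_rate`).
#' @param h a [hypnogram()] aligned to the recording.
#' @param band detection band, Hz (default 10-14, within (0, fs/2)).
#' @param amp_threshold_sd core detection threshold in NREM-envelope SD units.
#' @param boundary_sd boundary-extension threshold (SD units).
#' @param dur_bounds event duration bounds, s.
#' @param min_core_s minimum time the envelope must stay above the core
#'   threshold (rejects brief noise excursions whose boundary-extended span
#'   would otherwise satisfy `dur_bounds`).
#' @return Data frame of events: `onset` (s), `duration` (s),
#'   `peak_amplitude`, `oscillation_frequency` (Hz). Empty (with a warning)
#'   when the hypnogram contains no NREM.
#' @export
detect_spindles <- function(rec, h, band = c(10, 14), amp_threshold_sd = 2.5,
                            boundary_sd = 1, dur_bounds = c(0.5, 3),
                            min_core_s = 0.2) {
  fs <- rec$sampling_rate
  stopifnot(band[1] > 0, band[2] < fs / 2, band[1] < band[2])
  empty <- data.frame(onset = numeric(0), duration = numeric(0),
                      peak_amplitude = numeric(0),
                      oscillation_frequency = numeric(0))
  nrem_mask <- rep(h$states == "NREM", each = round(h$epoch_len * fs))
  length(nrem_mask) <- length(rec$eeg)          # pad with NA -> FALSE
  nrem_mask[is.na(nrem_mask)] <- FALSE
  if (!any(nrem_mask)) {
    warning("no NREM epochs; returning empty spindle list")
    return(empty)
  }
  bf <- signal::butter(4, band / (fs / 2), type = "pass")
  xf <- signal::filtfilt(bf, rec$eeg)
  env <- stats::filter(abs(xf), rep(1 / round(0.1 * fs), round(0.1 * fs)),
                       sides = 2)
  env[is.na(env)] <- 0
  env <- as.numeric(env)
  mu_env <- mean(env[nrem_mask])
  sd_env <- stats::sd(env[nrem_mask])
  core <- env > mu_env + amp_threshold_sd * sd_env
  low <- env > mu_env + boundary_sd * sd_env
  if (!any(core)) return(empty)
  # extend each core run to the enclosing low-threshold run
  low_r <- rle(low)
  low_end <- cumsum(low_r$lengths)
  low_start <- low_end - low_r$lengths + 1L
  keep_run <- low_r$values & vapply(seq_along(low_r$values), function(i) {
    low_r$values[i] && any(core[low_start[i]:low_end[i]])
  }, logical(1))
  ev <- cbind(low_start[keep_run], low_end[keep_run])
  if (nrow(ev) == 0) return(empty)
  # merge events separated by < 0.1 s
  merged <- ev[1, , drop = FALSE]
  if (nrow(ev) > 1) {
    for (i in 2:nrow(ev)) {
      if (ev[i, 1] - merged[nrow(merged), 2] < 0.1 * fs) {
        merged[nrow(merged), 2] <- ev[i, 2]
      } else {
        merged <- rbind(merged, ev[i, ])
      }
    }
  }
  res <- lapply(seq_len(nrow(merged)), function(i) {
    a <- merged[i, 1]; b <- merged[i, 2]
    dur <- (b - a + 1) / fs
    if (dur < dur_bounds[1] || dur > dur_bounds[2]) return(NULL)
    if (sum(core[a:b]) < min_core_s * fs) return(NULL)
    if (!all(nrem_mask[a:b])) return(NULL)      # wholly inside NREM
    seg <- xf[a:b]
    # frequency from zero crossings over the core (above-threshold) span,
    # between the first and last crossing so only whole half-periods count
    core_idx <- which(core[a:b])
    if (length(core_idx) < 2) core_idx <- seq_along(seg)
    cs <- seg[min(core_idx):max(core_idx)]
    zc <- which(diff(sign(cs)) != 0)
    freq <- if (length(zc) >= 2) {
      (length(zc) - 1) / (2 * (zc[length(zc)] - zc[1]) / fs)
    } else {
      length(zc) / (2 * dur)
    }
    data.frame(onset = (a - 1) / fs, duration = dur,
               peak_amplitude = max(abs(seg)),
               oscillation_frequency = freq)
  })
  res <- do.call(rbind, res)
  if (is.null(res)) empty else res
}

#' Summarize spindle events against NREM exposure
#'
#' Abundance is normalized to minutes of NREM sleep (not total recording
#' time); means are undefined (`NA`) when there are no events, and abundance
#' is undefined when there is no NREM time.
#'
#' @param events spindle event data frame ([detect_spindles()]).
#' @param h a [hypnogram()].
#' @return One-row data frame: `abundance_per_min`, `mean_duration`,
#'   `mean_amplitude`, `mean_frequency`, `n_events`, `nrem_minutes`.
#' @export
spindle_summary <- function(events, h) {
  nrem_min <- sum(h$states == "NREM") * h$epoch_len / 60
  n <- nrow(events)
  data.frame(
    abundance_per_min = if (nrem_min > 0) n / nrem_min else NA_real_,
    mean_duration = if (n > 0) mean(events$duration) else NA_real_,
    mean_amplitude = if (n > 0) mean(events$peak_amplitude) else NA_real_,
    mean_frequency = if (n > 0) mean(events$oscillation_frequency)
                     else NA_real_,
    n_events = n,
    nrem_minutes = nrem_min)
}

#' Detect epileptiform spikes
#'
#' Deflections are measured on a running-median-detrended copy of the EEG
#' (window `detrend_s`, default 1 s): the median over full periods of the
#' slow sleep oscillations removes them essentially exactly while leaving a
#' brief transient untouched, so a spike riding a delta trough is not
#' masked. The detection threshold is scaled to the robust standard
#' deviation (median absolute deviation, scaled) of the raw EEG, which keeps
#' ordinary sleep spindles, whose amplitude is far below that scale, from
#' triggering false detections. An event fires where the absolute detrended
#' deflection exceeds `threshold_sd` robust SDs. Deflections closer than
#' 200 ms are merged into one event; each event's width is its full width at
#' half the peak deflection and must lie within `width_bounds`.
#'
#' @param rec recording list (`eeg`, `sampling_rate`).
#' @param threshold_sd detection threshold in robust-SD units (> 0).
#' @param width_bounds event FWHM bounds, ms.
#' @param detrend_s running-median detrend window, s (0 disables).
#' @return Data frame of events: `time` (s, at peak), `amplitude` (detrended
#'   deflection), `width_ms`; attribute `n_events` carries the total count.
#' @export
detect_spikes <- function(rec, threshold_sd = 6, width_bounds = c(5, 100),
                          detrend_s = 1) {
  stopifnot(threshold_sd > 0)
  fs <- rec$sampling_rate
  x <- rec$eeg - stats::median(rec$eeg)
  rsd <- stats::mad(x)
  if (detrend_s > 0) {
    k <- round(detrend_s * fs)
    if (k %% 2 == 0) k <- k + 1
    x <- x - stats::runmed(x, k)
  }
  empty <- data.frame(time = numeric(0), amplitude = numeric(0),
                      width_ms = numeric(0))
  if (rsd == 0) {
    attr(empty, "n_events") <- 0L
    return(empty)
  }
  above <- which(abs(x) > threshold_sd * rsd)
  if (length(above) == 0) {
    attr(empty, "n_events") <- 0L
    return(empty)
  }
  gap <- which(diff(above) > 0.2 * fs)
  starts <- above[c(1, gap + 1)]
  ends <- above[c(gap, length(above))]
  res <- lapply(seq_along(starts), function(i) {
    a <- starts[i]; b <- ends[i]
    pk <- a - 1 + which.max(abs(x[a:b]))
    half <- abs(x[pk]) / 2
    lo <- pk
    while (lo > 1 && abs(x[lo - 1]) > half) lo <- lo - 1
    hi <- pk
    while (hi < length(x) && abs(x[hi + 1]) > half) hi <- hi + 1
    width_ms <- (hi - lo + 1) / fs * 1000
    if (width_ms < width_bounds[1] || width_ms > width_bounds[2]) return(NULL)
    data.frame(time = pk / fs, amplitude = x[pk], width_ms = width_ms)
  })
  res <- do.call(rbind, res)
  if (is.null(res)) res <- empty
  attr(res, "n_events") <- nrow(res)
  res
}
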