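#' Hypnogram container
#'
#' @param states character vector of per-epoch vigilance states
#'   (Wake/QW/NREM/REM).
#' @param epoch_len epoch length, seconds.
#' @return An object of class `hypnogram`.
#' @export
hypnogram <- function(states, epoch_len = 10) {
  states <- as.character(states)
  bad <- setdiff(unique(states), sleep_states())
  if (length(bad)) stop("unknown state(s): ", paste(bad, collapse = ", "))
  stopifnot(epoch_len > 0, length(states) >= 1)
  structure(list(states = states, epoch_len = epoch_len), class = "hypnogram")
}

#' @export
print.hypnogram <- function(x, ...) {
  tab <- table(factor(x$states, levels = sleep_states()))
  cat(sprintf("<hypnogram> %d epochs x %g s | %s\n", length(x$states),
              x$epoch_len,
              paste(sprintf("%s %d", names(tab), tab), collapse = ", ")))
  invisible(x)
}

# Hann-windowed periodogram band power (uV^2) of one epoch.
band_power <- function(x, fs, band) {
  n <- length(x)
  w <- 0.5 * (1 - cos(2 * pi * (seq_len(n) - 1) / (n - 1)))
  xw <- (x - mean(x)) * w
  sp <- Mod(stats::fft(xw))^2 / (fs * sum(w^2))
  freq <- (seq_len(n) - 1) * fs / n
  half <- freq <= fs / 2
  sel <- half & freq >= band[1] & freq <= band[2]
  2 * sum(sp[sel]) * fs / n
}

#' Per-epoch spectral and motor features of a recording
#'
#' Splits the recording into non-overlapping epochs and computes delta-band
#' and theta-band EEG power (Hann-windowed periodogram), EMG root mean
#' square, and mean movement per epoch.
#'
#' @param rec recording list with `eeg`, `emg`, `movement`, `sampling_rate`
#'   (e.g. a [simulate_eeg()] result).
#' @param epoch_len epoch length in seconds; must not exceed the recording.
#' @param delta_band,theta_band frequency bands, Hz (defaults 1-4 and 6-9).
#' @return Data frame: `epoch`, `delta_power`, `theta_power`, `emg_rms`,
#'   `movement_mean`.
#' @export
epoch_features <- function(rec, epoch_len = 10,
                           delta_band = c(1, 4), theta_band = c(6, 9)) {
  fs <- rec$sampling_rate
  spe <- round(epoch_len * fs)
  n_ep <- floor(length(rec$eeg) / spe)
  if (n_ep < 1) stop("epoch longer than recording")
  res <- lapply(seq_len(n_ep), function(i) {
    idx <- ((i - 1) * spe + 1):(i * spe)
    data.frame(
      epoch = i,
      delta_power = band_power(rec$eeg[idx], fs, delta_band),
      theta_power = band_power(rec$eeg[idx], fs, theta_band),
      emg_rms = sqrt(mean(rec$emg[idx]^2)),
      movement_mean = mean(rec$movement[idx]))
  })
  do.call(rbind, res)
}

#' Stage sleep from epoch features
#'
#' Rule-based staging: an epoch is Wake iff EMG or movement is high; among
#' low-EMG epochs, REM iff the theta/delta ratio is high and the preceding
#' epoch was not Wake (REM never follows Wake directly, and the first epoch
#' is never REM); otherwise NREM iff delta power is high, else quiet
#' wakefulness (QW).
#'
#' Thresholds are auto-derived per recording as feature percentiles unless
#' supplied: EMG RMS and movement at their 60th percentile, theta/delta ratio
#' at its 85th percentile, delta power at its median. Percentile
#' auto-calibration assumes the recording samples every vigilance state; for
#' degenerate recordings (e.g. continuous wakefulness), pass `thresholds`
#' taken from the attribute of a staged full recording of the same animal.
#'
#' @param features data frame from [epoch_features()].
#' @param thresholds optional named list with elements `emg`, `movement`,
#'   `ratio`, `delta` overriding the auto-derived values.
#' @param epoch_len epoch length (s) recorded in the returned hypnogram.
#' @return A [hypnogram()] with attribute `thresholds`.
#' @export
stage_sleep <- function(features, thresholds = NULL, epoch_len = 10) {
  f <- features
  ratio <- f$theta_power / (f$delta_power + .Machine$double.eps)
  if (all(apply(f[c("delta_power", "theta_power", "emg_rms",
                    "movement_mean")], 2,
                function(x) max(x) - min(x)) < 1e-12)) {
    warning("all epoch features identical; staging entire recording as one state")
  }
  thr <- list(
    emg = stats::quantile(f$emg_rms, 0.60, names = FALSE),
    movement = stats::quantile(f$movement_mean, 0.60, names = FALSE),
    ratio = stats::quantile(ratio, 0.85, names = FALSE),
    delta = stats::median(f$delta_power))
  thr[names(thresholds)] <- thresholds
  n <- nrow(f)
  states <- character(n)
  for (i in seq_len(n)) {
    if (f$emg_rms[i] > thr$emg || f$movement_mean[i] > thr$movement) {
      states[i] <- "Wake"
    } else if (ratio[i] > thr$ratio && i > 1 && states[i - 1] != "Wake") {
      states[i] <- "REM"
    } else if (f$delta_power[i] > thr$delta) {
      states[i] <- "NREM"
    } else {
      states[i] <- "QW"
    }
  }
  h <- hypnogram(states, epoch_len)
  attr(h, "thresholds") <- thr
  h
}

#' REM-sleep architecture metrics, split by light phase
#'
#' Computes percent REM time (REM epochs / total epochs), percent REM bouts
#' (maximal REM runs / all state bouts), and the number of NREM-to-REM
#' transitions, for the whole recording and per light/dark phase. A bout is
#' attributed to the phase of its first epoch and a transition to the phase
#' of its REM epoch, so the per-phase counts partition the totals exactly.
#'
#' @param h a [hypnogram()].
#' @param phase_labels optional per-epoch `"light"`/`"dark"` labels.
#' @return Data frame with rows `all` (plus one per phase) and columns
#'   `rem_time_pct`, `rem_bout_pct`, `n_rem_bouts`, `n_bouts`,
#'   `nrem_rem_transitions`, `n_epochs`.
#' @export
rem_metrics <- function(h, phase_labels = NULL) {
  s <- h$states
  n <- length(s)
  r <- rle(s)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  trans_idx <- which(s[-1] == "REM" & s[-n] == "NREM") + 1L
  one <- function(keep_epoch, keep_bout, keep_trans) {
    n_ep <- sum(keep_epoch)
    n_bouts <- sum(keep_bout)
    n_rem_bouts <- sum(keep_bout & r$values == "REM")
    data.frame(
      rem_time_pct = if (n_ep > 0) 100 * sum(s == "REM" & keep_epoch) / n_ep
                     else NA_real_,
      rem_bout_pct = if (n_bouts > 0) 100 * n_rem_bouts / n_bouts
                     else NA_real_,
      n_rem_bouts = n_rem_bouts,
      n_bouts = n_bouts,
      nrem_rem_transitions = sum(keep_trans),
      n_epochs = n_ep)
  }
  out <- cbind(phase = "all",
               one(rep(TRUE, n), rep(TRUE, length(r$values)),
                   rep(TRUE, length(trans_idx))))
  if (!is.null(phase_labels)) {
    stopifnot(length(phase_labels) == n)
    for (ph in unique(phase_labels)) {
      out <- rbind(out, cbind(phase = ph, one(
        phase_labels == ph,
        phase_labels[starts] == ph,
        phase_labels[trans_idx] == ph)))
    }
  }
  rownames(out) <- NULL
  out
}
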