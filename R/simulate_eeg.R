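#' Vigilance-state labels used throughout the sleep module
#' @return `c("Wake", "QW", "NREM", "REM")`.
#' @export
sleep_states <- function() c("Wake", "QW", "NREM", "REM")

#' Specify a synthetic EEG/EMG recording with planted sleep architecture
#'
#' Defines the hypnogram, band amplitudes, and event rates for
#' [simulate_eeg()]. The EEG is built as additive band-limited oscillators on
#' a pink-noise floor: NREM segments carry a strong delta (1-4 Hz)
#' oscillation, REM segments a theta (6-9 Hz) oscillation with near-silent
#' EMG, Wake segments broadband EEG with high EMG and positive movement.
#' Spindles are planted as Hann-windowed sinusoids inside NREM; epileptiform
#' spikes as Gaussian transients. Event counts are deterministic
#' (`round(rate * exposure)`); event placement is random under the seed.
#'
#' The default state sequence cycles Wake 80 s, QW 20 s, NREM 50 s, REM 10 s,
#' NREM 20 s, REM 20 s (fractions 0.40 / 0.10 / 0.35 / 0.15), so REM is always
#' entered from NREM, as in real hypnograms.
#'
#' @param sampling_rate sampling rate in Hz (>= 100).
#' @param state_sequence data frame with columns `state` (Wake/QW/NREM/REM)
#'   and `duration` (seconds); default `n_cycles` repeats of the cycle above.
#' @param n_cycles number of default cycles when `state_sequence` is NULL.
#' @param spindle_rate planted spindle events per NREM minute.
#' @param spindle_freq spindle oscillation frequency in Hz, within `[10, 14]`.
#' @param spindle_duration_range interval (s) for planted spindle durations.
#' @param spindle_snr planted spindle peak amplitude as a multiple of the SD
#'   of the surrounding NREM background signal.
#' @param spike_rate planted epileptiform spikes per hour.
#' @param spike_snr spike peak amplitude as a multiple of the robust SD
#'   (MAD-scaled) of the background EEG.
#' @param spike_width_ms spike full width at half maximum, ms.
#' @param band_amplitudes named list state -> c(delta, theta, emg) amplitude
#'   scale factors (units of the pink-noise SD).
#' @param movement_scale movement-trace amplitude during Wake.
#' @param epoch_len epoch length (s) of the returned ground-truth hypnogram;
#'   state durations must be multiples of it.
#' @return An object of class `planted_eeg_spec`.
#' @export
planted_eeg_spec <- function(sampling_rate = 200,
                             state_sequence = NULL,
                             n_cycles = 9,
                             spindle_rate = 0,
                             spindle_freq = 12,
                             spindle_duration_range = c(0.6, 1.4),
                             spindle_snr = 3,
                             spike_rate = 0,
                             spike_snr = 7,
                             spike_width_ms = 30,
                             band_amplitudes = NULL,
                             movement_scale = 1,
                             epoch_len = 10) {
  stopifnot(sampling_rate >= 100,
            spindle_freq >= 10, spindle_freq <= 14,
            spindle_rate >= 0, spike_rate >= 0,
            spindle_duration_range[1] > 0,
            spindle_duration_range[1] <= spindle_duration_range[2])
  if (is.null(state_sequence)) {
    cyc <- data.frame(
      state = c("Wake", "QW", "NREM", "REM", "NREM", "REM"),
      duration = c(80, 20, 50, 10, 20, 20))
    state_sequence <- do.call(rbind, replicate(n_cycles, cyc, simplify = FALSE))
  }
  bad <- setdiff(unique(state_sequence$state), sleep_states())
  if (length(bad)) stop("unknown state(s): ", paste(bad, collapse = ", "))
  if (any(state_sequence$duration <= 0)) stop("durations must be positive")
  if (any(abs(state_sequence$duration / epoch_len -
              round(state_sequence$duration / epoch_len)) > 1e-9)) {
    stop("state durations must be multiples of epoch_len")
  }
  if (sum(state_sequence$duration) < 10 * epoch_len) {
    stop("total duration must cover at least 10 epochs")
  }
  if (is.null(band_amplitudes)) {
    band_amplitudes <- list(
      Wake = c(delta = 0.8, theta = 0.8, emg = 3.0),
      QW   = c(delta = 0.4, theta = 0.4, emg = 0.5),
      NREM = c(delta = 3.0, theta = 0.5, emg = 0.3),
      REM  = c(delta = 0.3, theta = 2.5, emg = 0.1))
  }
  structure(
    list(sampling_rate = sampling_rate, state_sequence = state_sequence,
         spindle_rate = spindle_rate, spindle_freq = spindle_freq,
         spindle_duration_range = spindle_duration_range,
         spindle_snr = spindle_snr, spike_rate = spike_rate,
         spike_snr = spike_snr, spike_width_ms = spike_width_ms,
         band_amplitudes = band_amplitudes, movement_scale = movement_scale,
         epoch_len = epoch_len),
    class = "planted_eeg_spec"
  )
}

# 1/f ("pink") noise via spectral shaping of white Gaussian noise,
# normalized to unit SD.
pink_noise <- function(n) {
  nf <- stats::fft(stats::rnorm(n))
  f <- c(1, seq_len(n - 1))
  f <- pmin(f, n - f + 1)          # symmetric frequency index
  shaped <- nf / sqrt(f)
  x <- Re(stats::fft(shaped, inverse = TRUE)) / n
  x / stats::sd(x)
}

#' Simulate an EEG/EMG/movement recording with known ground truth
#'
#' @param spec a [planted_eeg_spec()].
#' @param seed integer RNG seed; identical (spec, seed) gives identical output.
#' @return A list of class `eeg_recording` with elements `eeg`, `emg`,
#'   `movement` (numeric traces), `sampling_rate`, `epoch_len`, `light_phase`
#'   (per-epoch "light"/"dark"; first half light), `hypnogram` (ground truth,
#'   see [hypnogram()]), `spindles` (data frame: onset, duration, amplitude,
#'   frequency), and `spikes` (numeric vector of spike times, s).
#' @export
simulate_eeg <- function(spec, seed = 1) {
  stopifnot(inherits(spec, "planted_eeg_spec"))
  set.seed(as.integer(seed))
  fs <- spec$sampling_rate
  seg <- spec$state_sequence
  n_seg <- nrow(seg)
  n <- round(sum(seg$duration) * fs)
  t_all <- seq_len(n) / fs

  eeg <- pink_noise(n)
  emg <- numeric(n)
  movement <- numeric(n)

  seg_end <- cumsum(seg$duration)
  seg_start <- c(0, seg_end[-n_seg])
  seg_idx <- lapply(seq_len(n_seg), function(i) {
    (round(seg_start[i] * fs) + 1L):round(seg_end[i] * fs)
  })

  for (i in seq_len(n_seg)) {
    st <- seg$state[i]
    amp <- spec$band_amplitudes[[st]]
    idx <- seg_idx[[i]]
    tt <- t_all[idx]
    # narrowband oscillators with random phase per segment; 0.25 s cosine
    # ramps at the segment edges avoid step discontinuities
    nramp <- min(round(0.25 * fs), floor(length(idx) / 2))
    taper <- rep(1, length(idx))
    ramp <- 0.5 * (1 - cos(pi * seq_len(nramp) / nramp))
    taper[seq_len(nramp)] <- ramp
    taper[length(idx) + 1 - seq_len(nramp)] <- ramp
    eeg[idx] <- eeg[idx] + taper *
      (amp[["delta"]] * sin(2 * pi * 2.0 * tt + stats::runif(1, 0, 2 * pi)) +
       amp[["theta"]] * sin(2 * pi * 7.5 * tt + stats::runif(1, 0, 2 * pi)))
    emg[idx] <- amp[["emg"]] * stats::rnorm(length(idx))
    if (st == "Wake") {
      movement[idx] <- spec$movement_scale * abs(stats::rnorm(length(idx)))
    }
  }

  # --- planted spindles (NREM only, deterministic count) ---
  nrem_segs <- which(seg$state == "NREM")
  nrem_minutes <- sum(seg$duration[nrem_segs]) / 60
  n_spindles <- round(spec$spindle_rate * nrem_minutes)
  spindles <- data.frame(onset = numeric(0), duration = numeric(0),
                         amplitude = numeric(0), frequency = numeric(0))
  if (n_spindles > 0 && length(nrem_segs) > 0) {
    # allocate events to NREM segments proportionally to duration
    alloc <- sample(rep(nrem_segs, times = seg$duration[nrem_segs]),
                    n_spindles, replace = TRUE)
    for (i in sort(unique(alloc))) {
      k <- sum(alloc == i)
      idx <- seg_idx[[i]]
      bg_sd <- stats::sd(eeg[idx])
      durs <- stats::runif(k, spec$spindle_duration_range[1],
                           spec$spindle_duration_range[2])
      # non-overlapping placement inside the segment with 0.3 s margins
      slots <- place_events(seg$duration[i], durs, margin = 0.3)
      for (j in seq_along(slots)) {
        if (is.na(slots[j])) next
        onset <- seg_start[i] + slots[j]
        dur <- durs[j]
        amp <- spec$spindle_snr * bg_sd
        ei <- (round(onset * fs) + 1L):round((onset + dur) * fs)
        tt <- (seq_along(ei) - 1) / fs
        hann <- 0.5 * (1 - cos(2 * pi * tt / dur))
        eeg[ei] <- eeg[ei] + amp * hann * sin(2 * pi * spec$spindle_freq * tt)
        spindles <- rbind(spindles, data.frame(
          onset = onset, duration = dur, amplitude = amp,
          frequency = spec$spindle_freq))
      }
    }
    spindles <- spindles[order(spindles$onset), , drop = FALSE]
    rownames(spindles) <- NULL
  }

  # --- planted epileptiform spikes (deterministic count) ---
  hours <- sum(seg$duration) / 3600
  n_spikes <- round(spec$spike_rate * hours)
  spikes <- numeric(0)
  if (n_spikes > 0) {
    robust_sd <- stats::mad(eeg)
    amp <- spec$spike_snr * robust_sd
    s_sd <- spec$spike_width_ms / 1000 / (2 * sqrt(2 * log(2)))  # FWHM -> SD
    total <- sum(seg$duration)
    slots <- place_events(total, rep(0.2, n_spikes), margin = 1)
    slots <- slots[!is.na(slots)] + 0.1
    for (tc in slots) {
      win <- 4 * s_sd
      ei <- max(1L, round((tc - win) * fs)):min(n, round((tc + win) * fs))
      # spike amplitude is defined against the local baseline (the 1 s
      # running median), the standard peak-to-baseline convention: scale the
      # transient so the net peak sits `amp` above that baseline
      c0 <- ei[which.min(abs(t_all[ei] - tc))]
      bi <- max(1L, c0 - round(fs / 2)):min(n, c0 + round(fs / 2))
      target <- amp + stats::median(eeg[bi])
      eeg[ei] <- eeg[ei] + (target - eeg[c0]) *
        exp(-((t_all[ei] - tc)^2) / (2 * s_sd^2))
    }
    spikes <- sort(slots)
  }

  n_epochs <- round(sum(seg$duration) / spec$epoch_len)
  states <- rep(seg$state, times = round(seg$duration / spec$epoch_len))
  light <- rep(c("light", "dark"),
               c(ceiling(n_epochs / 2), floor(n_epochs / 2)))

  structure(
    list(eeg = eeg, emg = emg, movement = movement,
         sampling_rate = fs, epoch_len = spec$epoch_len,
         light_phase = light,
         hypnogram = hypnogram(states, spec$epoch_len),
         spindles = spindles, spikes = spikes),
    class = "eeg_recording"
  )
}

# Place events of given durations without overlap inside [0, total], keeping
# `margin` seconds from the edges and between events. Returns onsets (NA when
# an event could not be placed after 50 attempts).
place_events <- function(total, durations, margin = 0.3) {
  onsets <- rep(NA_real_, length(durations))
  taken <- matrix(numeric(0), ncol = 2)
  for (j in order(durations, decreasing = TRUE)) {
    d <- durations[j]
    hi <- total - d - margin
    if (hi <= margin) next
    for (try in 1:50) {
      o <- stats::runif(1, margin, hi)
      if (nrow(taken) == 0 ||
          all(o + d + margin < taken[, 1] | o > taken[, 2] + margin)) {
        onsets[j] <- o
        taken <- rbind(taken, c(o, o + d))
        break
      }
    }
  }
  onsets
}
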