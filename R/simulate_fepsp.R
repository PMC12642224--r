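#' Simulate fEPSP sweeps with a known rising slope and peak
#'
#' Each sweep is flat at baseline, shows a brief stimulus artifact, then a
#' linear negative-going rise of slope `true_slope` down to `-peak_amplitude`,
#' followed by an exponential decay back to baseline, plus optional Gaussian
#' noise. With `noise_sd = 0` the slope and amplitude estimators recover the
#' planted values exactly.
#'
#' @param true_slope rising-phase slope in mV/ms; must be negative
#'   (field potentials are negative-going).
#' @param peak_amplitude peak deflection in mV (> 0).
#' @param noise_sd Gaussian noise SD in mV.
#' @param n_sweeps number of sweeps.
#' @param seed integer RNG seed.
#' @param dt sample interval, ms.
#' @param duration sweep length, ms.
#' @param stimulus_time stimulus onset, ms.
#' @param latency delay from stimulus to fEPSP onset, ms (> 1 so the
#'   post-stimulus artifact-exclusion window does not clip the rise).
#' @param decay_tau recovery time constant, ms.
#' @param intensity optional stimulation intensity (uV) stored per sweep;
#'   recycled to `n_sweeps`.
#' @return A list of sweeps; each sweep is a list with `time` (ms), `voltage`
#'   (mV), `stimulus_time`, and `intensity`.
#' @export
simulate_fepsp <- function(true_slope, peak_amplitude, noise_sd = 0,
                           n_sweeps = 1, seed = 1, dt = 0.05, duration = 50,
                           stimulus_time = 5, latency = 1.5, decay_tau = 8,
                           intensity = NA_real_) {
  stopifnot(peak_amplitude > 0, noise_sd >= 0, n_sweeps >= 1, latency > 1)
  if (true_slope >= 0) stop("true_slope must be negative (mV/ms)")
  set.seed(as.integer(seed))
  time <- seq(0, duration, by = dt)
  onset <- stimulus_time + latency
  t_peak <- onset + peak_amplitude / abs(true_slope)
  if (t_peak >= duration) stop("sweep too short for the requested rise")
  base <- numeric(length(time))
  rise <- time >= onset & time <= t_peak
  base[rise] <- true_slope * (time[rise] - onset)
  after <- time > t_peak
  base[after] <- -peak_amplitude * exp(-(time[after] - t_peak) / decay_tau)
  # biphasic stimulus artifact, 0.2 ms
  art <- time >= stimulus_time & time < stimulus_time + 0.2
  base[art] <- base[art] + 1.5 * sin(2 * pi * (time[art] - stimulus_time) / 0.2)
  intensity <- rep_len(intensity, n_sweeps)
  lapply(seq_len(n_sweeps), function(i) {
    list(time = time,
         voltage = base + stats::rnorm(length(time), sd = noise_sd),
         stimulus_time = stimulus_time,
         intensity = intensity[i])
  })
}
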