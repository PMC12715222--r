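# Shared fixtures: all built in code at test time.

sine_trace <- function(freq, dur = 10, fs = 1000, amp = 1, phase = 0) {
  t <- seq(1 / fs, dur, by = 1 / fs)
  lfp_trace(amp * sin(2 * pi * freq * t + phase), fs = fs)
}

rms <- function(x) sqrt(mean(x^2))

# A noiseless single-gamma configuration for envelope/variance checks.
pure_gamma_config <- function(m = 0, base_amp = 10, gain = NULL, fs = 1000,
                              seed = 1) {
  gg <- if (is.null(gain)) list() else list(default = c(low_gamma = gain))
  sim_config(sampling_rate_hz = fs, aperiodic_sd = 0, theta_amp = 0,
             line_noise_amp = 0, noise_sd = 0,
             gamma_bands = list(low_gamma = list(carrier_hz = 40,
                                                 base_amp = base_amp)),
             pac_depth = m, group_gain = gg, seed = seed)
}

short_schedule <- function(dur = 30) {
  event_schedule(data.frame(label = "tone_1", start_s = 0, end_s = dur),
                 session_kind = "tone_extinction")
}

# Independent freezing reference: enumerate immobile runs explicitly.
freezing_reference <- function(motion_index, threshold, min_frames) {
  immobile <- motion_index < threshold
  frozen <- logical(length(immobile))
  i <- 1L
  while (i <= length(immobile)) {
    if (immobile[i]) {
      j <- i
      while (j < length(immobile) && immobile[j + 1L]) j <- j + 1L
      if (j - i + 1L >= min_frames) frozen[i:j] <- TRUE
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  frozen
}
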