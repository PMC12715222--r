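# FFT analytic signal (discrete Hilbert transform).
hilbert_analytic <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0L) {
    h[c(1L, n / 2 + 1L)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1L] <- 1
    h[2:((n + 1L) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

# Windowed-sinc (Hamming, via signal::fir1) linear-phase band-pass taps.
# Transition bandwidth = 25% of the lower band edge; order rounded up to even
# so the filter is odd-length symmetric (type I) and exactly zero-phase after
# group-delay compensation.
fir_bandpass_taps <- function(band, fs) {
  trans <- 0.25 * band$low
  ord <- ceiling(3.3 * fs / trans)
  if (ord %% 2 == 1L) ord <- ord + 1L
  nyq <- fs / 2
  if (band$high >= nyq) {
    stop(sprintf("band %s upper edge %g Hz is above Nyquist (%g Hz)",
                 band$name, band$high, nyq), call. = FALSE)
  }
  as.numeric(signal::fir1(ord, c(band$low, band$high) / nyq, type = "pass"))
}

# Zero-phase FIR band-pass: reflective padding, FFT convolution, group-delay
# removal.
fir_filter_zero_phase <- function(x, taps) {
  n <- length(x)
  d <- (length(taps) - 1L) / 2L
  pad <- min(length(taps), n - 1L)
  head_ref <- 2 * x[1] - x[(pad + 1):2]
  tail_ref <- 2 * x[n] - x[(n - 1):(n - pad)]
  xp <- c(head_ref, x, tail_ref, numeric(length(taps)))
  y <- as.numeric(signal::fftfilt(taps, xp))
  y[(pad + d + 1L):(pad + d + n)]
}

# Internal: analytic series container.
analytic_series <- function(phase, amplitude, band, fs, t0) {
  stopifnot(length(phase) == length(amplitude), all(amplitude >= 0))
  structure(list(phase = phase, amplitude = amplitude, band = band,
                 fs = fs, t0 = t0), class = "analytic_series")
}

#' @export
print.analytic_series <- function(x, ...) {
  cat(sprintf("<analytic_series> band %s (%g-%g Hz), %d samples @ %g Hz\n",
              x$band$name, x$band$low, x$band$high, length(x$phase), x$fs))
  invisible(x)
}

# Shared implementation for phase/amplitude extraction.
extract_analytic <- function(trace, band) {
  stopifnot(inherits(trace, "lfp_trace"))
  band <- get_band(band)
  taps <- fir_bandpass_taps(band, trace$fs)
  y <- fir_filter_zero_phase(trace$samples, taps)
  z <- hilbert_analytic(y)
  analytic_series(phase = Arg(z), amplitude = Mod(z), band = band,
                  fs = trace$fs, t0 = trace$t0)
}

#' Instantaneous phase of a band-limited component
#'
#' Zero-phase FIR band-pass (windowed sinc, transition bandwidth 25% of the
#' lower edge) followed by the analytic-signal phase. Cosine convention:
#' phase 0 at the oscillation peak, values in `(-pi, pi]`.
#'
#' @param trace Preprocessed [lfp_trace()] (1 kHz analysis rate assumed).
#' @param band A [frequency_band()] or registry name (e.g. `"theta"`).
#' @return An `analytic_series` (`phase`, `amplitude`, `band`, `fs`, `t0`).
#' @export
extract_phase <- function(trace, band = "theta") extract_analytic(trace, band)

#' Instantaneous amplitude envelope of a band-limited component
#'
#' Same filter chain as [extract_phase()]; the analytic-signal magnitude is
#' the envelope.
#'
#' @inheritParams extract_phase
#' @return An `analytic_series`.
#' @export
extract_amplitude <- function(trace, band = "low_gamma") {
  extract_analytic(trace, band)
}

#' Phase-amplitude modulation index (Tort)
#'
#' Bins the fast-band amplitude by slow-band phase (default 18 bins of 20
#' degrees), normalizes the bin-mean amplitudes to a distribution and reports
#' its Kullback-Leibler divergence from uniform, normalized by `log(n_bins)`
#' so that MI lies in `[0, 1]`: 0 for phase-independent amplitude, 1 when all
#' amplitude concentrates in one bin. The preferred phase is the
#' amplitude-weighted circular mean of the phase series. MI is exactly
#' invariant to positive rescaling of the amplitude.
#'
#' @param phase An `analytic_series` (its `phase` is used) or numeric phase
#'   vector in radians.
#' @param amplitude An `analytic_series` (its `amplitude` is used) or numeric
#'   non-negative vector; same length as `phase`.
#' @param n_bins Number of phase bins (default 18).
#' @return A `pac_result`: `phase_band`, `amplitude_band`, `mi`,
#'   `preferred_phase` (rad, `(-pi, pi]`), `n_bins`, `phase_bin_profile`
#'   (mean amplitude per bin; `NA` for unoccupied bins).
#' @export
modulation_index <- function(phase, amplitude, n_bins = 18L) {
  phase_band <- if (inherits(phase, "analytic_series")) phase$band else NULL
  amp_band <- if (inherits(amplitude, "analytic_series")) amplitude$band
              else NULL
  ph <- if (inherits(phase, "analytic_series")) phase$phase else phase
  am <- if (inherits(amplitude, "analytic_series")) amplitude$amplitude
        else amplitude
  n_bins <- as.integer(n_bins)
  stopifnot(n_bins >= 2L, length(ph) == length(am))
  if (length(ph) == 0L) stop("empty phase/amplitude series", call. = FALSE)
  if (length(ph) < 10L * n_bins) {
    warning(sprintf("only %d samples for %d phase bins; MI will be noisy",
                    length(ph), n_bins), call. = FALSE)
  }
  if (any(am < 0)) stop("amplitudes must be non-negative", call. = FALSE)
  bin <- pmin(floor((ph + pi) / (2 * pi) * n_bins) + 1L, n_bins)
  profile <- rep(NA_real_, n_bins)
  means <- tapply(am, factor(bin, levels = seq_len(n_bins)), mean)
  profile[!is.na(means)] <- means[!is.na(means)]
  occ <- which(!is.na(profile))
  if (length(occ) == 0L) stop("all phase bins are empty", call. = FALSE)
  if (length(occ) < n_bins) {
    warning(sprintf("%d of %d phase bins empty; MI computed over %d bins",
                    n_bins - length(occ), n_bins, length(occ)),
            call. = FALSE)
  }
  mvals <- profile[occ]
  tot <- sum(mvals)
  mi <- if (tot <= 0 || length(occ) < 2L) {
    0
  } else {
    p <- mvals / tot
    h <- -sum(ifelse(p > 0, p * log(p), 0))
    (log(length(occ)) - h) / log(length(occ))
  }
  pref <- atan2(sum(am * sin(ph)), sum(am * cos(ph)))
  structure(list(phase_band = phase_band, amplitude_band = amp_band,
                 mi = mi, preferred_phase = pref, n_bins = n_bins,
                 phase_bin_profile = profile), class = "pac_result")
}

#' @export
print.pac_result <- function(x, ...) {
  pb <- if (is.null(x$phase_band)) "?" else x$phase_band$name
  ab <- if (is.null(x$amplitude_band)) "?" else x$amplitude_band$name
  cat(sprintf(
    "<pac_result> %s phase -> %s amplitude: MI = %.4g, preferred phase = %.1f deg (%d bins)\n",
    pb, ab, x$mi, x$preferred_phase * 180 / pi, x$n_bins))
  invisible(x)
}

#' Phase-amplitude coupling over selected schedule intervals
#'
#' Extracts the slow-band phase and fast-band envelope once on the whole
#' trace (so interval edges carry no filter transients), then pools the
#' samples of every interval matching `selector` into one modulation-index
#' estimate. Pooling across same-label intervals is essential for the 5 s
#' ITIs, which individually under-sample theta phase space.
#'
#' @param trace Preprocessed [lfp_trace()].
#' @param schedule An [event_schedule()].
#' @param selector Glob label pattern (e.g. `"tone_*"`, `"iti_*"`).
#' @param phase_band,amplitude_band Registry names or [frequency_band()]s.
#' @param n_bins Phase bins (default 18).
#' @return A `pac_result`.
#' @export
pac_by_label <- function(trace, schedule, selector, phase_band = "theta",
                         amplitude_band = "low_gamma", n_bins = 18L) {
  ph <- extract_phase(trace, phase_band)
  am <- extract_amplitude(trace, amplitude_band)
  idx <- schedule_sample_index(trace, schedule, selector)
  if (length(idx) == 0L) {
    stop(sprintf("no intervals match '%s'", selector), call. = FALSE)
  }
  out <- modulation_index(ph$phase[idx], am$amplitude[idx], n_bins = n_bins)
  out$phase_band <- ph$band
  out$amplitude_band <- am$band
  out
}

# Sample indices of a trace falling in intervals whose label matches the glob.
schedule_sample_index <- function(trace, schedule, selector) {
  rx <- utils::glob2rx(selector)
  hit <- schedule[grepl(rx, schedule$label), , drop = FALSE]
  n <- length(trace$samples)
  idx <- integer(0)
  for (i in seq_len(nrow(hit))) {
    i0 <- round((hit$start_s[i] - trace$t0) * trace$fs) + 1L
    len <- floor((hit$end_s[i] - hit$start_s[i]) * trace$fs + 1e-9)
    i1 <- min(i0 + len - 1L, n)
    if (i0 <= i1) idx <- c(idx, i0:i1)
  }
  idx
}

#' Tone/ITI coupling ratio
#'
#' `MI(tone) / MI(ITI)`; values above 1 indicate stronger theta-gamma
#' coupling during tone presentation than between trials. The two results
#' must come from the same band pair and bin count. The Tort MI is invariant
#' to rescaling the raw trace, so the ratio is too.
#'
#' @param pac_tone,pac_iti `pac_result`s for the tone and ITI conditions.
#' @return A single positive number.
#' @export
coupling_ratio <- function(pac_tone, pac_iti) {
  stopifnot(inherits(pac_tone, "pac_result"), inherits(pac_iti, "pac_result"))
  same_band <- function(a, b) {
    (is.null(a) && is.null(b)) ||
      (!is.null(a) && !is.null(b) && a$low == b$low && a$high == b$high)
  }
  if (!same_band(pac_tone$phase_band, pac_iti$phase_band) ||
      !same_band(pac_tone$amplitude_band, pac_iti$amplitude_band) ||
      pac_tone$n_bins != pac_iti$n_bins) {
    stop("coupling_ratio requires the same band pair and bin count",
         call. = FALSE)
  }
  if (pac_iti$mi == 0) {
    stop("ITI modulation index is zero; coupling ratio undefined",
         call. = FALSE)
  }
  pac_tone$mi / pac_iti$mi
}
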