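#' Welch estimation parameters
#'
#' Defaults follow the analysis convention for 1 kHz LFP: 2048-sample
#' segments (2.048 s, ~0.488 Hz resolution), Hann taper, 1024-point overlap
#' (50%).
#'
#' @param nperseg Segment length in samples.
#' @param window Taper name; only `"hann"` is provided.
#' @param noverlap Overlapping samples between consecutive segments;
#'   `0 <= noverlap < nperseg`.
#' @return A `welch_params` list.
#' @export
welch_params <- function(nperseg = 2048L, window = "hann", noverlap = 1024L) {
  nperseg <- as.integer(nperseg); noverlap <- as.integer(noverlap)
  if (nperseg < 2L) stop("nperseg must be >= 2", call. = FALSE)
  if (noverlap < 0L || noverlap >= nperseg) {
    stop("require 0 <= noverlap < nperseg", call. = FALSE)
  }
  window <- match.arg(window, "hann")
  structure(list(nperseg = nperseg, window = window, noverlap = noverlap),
            class = "welch_params")
}

# Periodic Hann taper (the spectral-analysis convention).
hann_window <- function(n) 0.5 * (1 - cos(2 * pi * (0:(n - 1)) / n))

# One-sided modified periodogram of a single segment, density scaling
# (power / Hz): |FFT(w*x)|^2 / (fs * sum(w^2)), doubled off DC/Nyquist.
segment_periodogram <- function(x, w, fs) {
  n <- length(x)
  x <- x - mean(x) # constant detrend per segment
  X <- stats::fft(w * x)
  nf <- n %/% 2 + 1L
  p <- (Mod(X[seq_len(nf)])^2) / (fs * sum(w^2))
  scale2 <- rep(2, nf)
  scale2[1L] <- 1
  if (n %% 2 == 0L) scale2[nf] <- 1
  p * scale2
}

#' Welch power spectral density
#'
#' Averages Hann-tapered, overlapping, mean-detrended segment periodograms
#' into a one-sided density estimate (uV^2/Hz) on the grid
#' `f = (0:(nperseg/2)) * fs / nperseg`.
#'
#' @param trace An [lfp_trace()] at least `nperseg` samples long.
#' @param params A [welch_params()].
#' @return A `psd_result` with fields `freqs`, `power`, `params`,
#'   `normalization` (`"none"`), `reference`.
#' @export
welch_psd <- function(trace, params = welch_params()) {
  stopifnot(inherits(trace, "lfp_trace"), inherits(params, "welch_params"))
  x <- trace$samples
  n <- params$nperseg
  if (length(x) < n) {
    stop(sprintf(
      "trace too short for Welch estimation: %d samples < nperseg = %d",
      length(x), n), call. = FALSE)
  }
  step <- n - params$noverlap
  starts <- seq(1L, length(x) - n + 1L, by = step)
  w <- hann_window(n)
  acc <- 0
  for (s in starts) acc <- acc + segment_periodogram(x[s:(s + n - 1L)], w,
                                                     trace$fs)
  psd_result(freqs = (0:(n %/% 2)) * trace$fs / n,
             power = acc / length(starts), params = params)
}

# PSDResult constructor (internal; users obtain these from welch_psd()).
psd_result <- function(freqs, power, params, normalization = "none",
                       reference = NULL) {
  stopifnot(length(freqs) == length(power), all(diff(freqs) > 0),
            all(power >= -1e-15))
  structure(list(freqs = freqs, power = pmax(power, 0), params = params,
                 normalization = normalization, reference = reference),
            class = "psd_result")
}

#' @export
print.psd_result <- function(x, ...) {
  cat(sprintf(
    "<psd_result> %d bins, %.3g-%.4g Hz (res %.4g Hz), normalization: %s\n",
    length(x$freqs), min(x$freqs), max(x$freqs), diff(x$freqs[1:2]),
    x$normalization))
  invisible(x)
}

#' Whole-spectrum normalization
#'
#' Divides the PSD by the mean raw power across all bins in `band`
#' (default 1-120 Hz), the scheme used for open-field recordings. By
#' construction the normalized power averages exactly 1 over that band, and
#' the result is invariant to any rescaling of the raw trace.
#'
#' @param psd An unnormalized `psd_result`.
#' @param band Two-element numeric, normalization band edges (Hz), inclusive.
#' @return A normalized `psd_result` (`normalization = "whole_spectrum"`).
#' @export
normalize_whole_spectrum <- function(psd, band = c(1, 120)) {
  stopifnot(inherits(psd, "psd_result"))
  if (psd$normalization != "none") {
    stop(sprintf("PSD is already normalized (%s)", psd$normalization),
         call. = FALSE)
  }
  sel <- psd$freqs >= band[1] & psd$freqs <= band[2]
  if (!any(sel)) stop("normalization band contains no bins", call. = FALSE)
  denom <- mean(psd$power[sel])
  if (denom <= 0) stop("zero power in normalization band", call. = FALSE)
  psd_result(psd$freqs, psd$power / denom, psd$params,
             normalization = "whole_spectrum",
             reference = list(band = band, mean_power = denom))
}

#' Baseline normalization
#'
#' Divides the PSD by the scalar mean of the same animal's baseline-period
#' PSD over `band` (default 0-120 Hz, DC bin included as in the session
#' convention; set `include_dc = FALSE` to exclude it, a documented deviation
#' that matters little after band-pass/notch conditioning). Both PSDs must
#' share the frequency grid and Welch parameters.
#'
#' @param psd An unnormalized `psd_result` from a session condition.
#' @param baseline_psd Unnormalized `psd_result` of the 180 s baseline.
#' @param band Normalization band edges (Hz), inclusive.
#' @param include_dc Keep the 0 Hz bin in the baseline mean (default TRUE).
#' @return A normalized `psd_result` (`normalization = "baseline"`).
#' @export
normalize_to_baseline <- function(psd, baseline_psd, band = c(0, 120),
                                  include_dc = TRUE) {
  stopifnot(inherits(psd, "psd_result"), inherits(baseline_psd, "psd_result"))
  if (psd$normalization != "none") {
    stop(sprintf("PSD is already normalized (%s)", psd$normalization),
         call. = FALSE)
  }
  if (length(psd$freqs) != length(baseline_psd$freqs) ||
      any(abs(psd$freqs - baseline_psd$freqs) > 1e-9)) {
    stop("PSD and baseline PSD have mismatched frequency grids",
         call. = FALSE)
  }
  sel <- baseline_psd$freqs >= band[1] & baseline_psd$freqs <= band[2]
  if (!include_dc) sel <- sel & baseline_psd$freqs > 0
  if (!any(sel)) stop("normalization band contains no bins", call. = FALSE)
  denom <- mean(baseline_psd$power[sel])
  if (denom <= 0) {
    stop("baseline power is zero over the normalization band", call. = FALSE)
  }
  psd_result(psd$freqs, psd$power / denom, psd$params,
             normalization = "baseline",
             reference = list(band = band, baseline_mean = denom,
                              include_dc = include_dc))
}

#' Relative band power
#'
#' Summarizes a (typically normalized) PSD over a frequency band. The default
#' reducer is the mean of the bins with `low <= f <= high` (band edges
#' inclusive), which makes bands of different widths comparable as relative
#' power; `method = "integral"` returns the trapezoidal integral instead.
#'
#' @param psd A `psd_result`.
#' @param band A [frequency_band()] or registry band name.
#' @param method `"mean"` (default) or `"integral"`.
#' @return A single numeric value.
#' @export
band_power <- function(psd, band, method = c("mean", "integral")) {
  stopifnot(inherits(psd, "psd_result"))
  method <- match.arg(method)
  band <- get_band(band)
  sel <- psd$freqs >= band$low & psd$freqs <= band$high
  if (!any(sel)) {
    stop(sprintf("band %s (%g-%g Hz) covers no PSD bins", band$name,
                 band$low, band$high), call. = FALSE)
  }
  if (method == "mean") return(mean(psd$power[sel]))
  f <- psd$freqs[sel]; p <- psd$power[sel]
  sum(diff(f) * (utils::head(p, -1) + utils::tail(p, -1)) / 2)
}

#' Sliding-window spectrogram
#'
#' Single-taper (Hann) periodogram of a `nperseg`-sample window slid along
#' the trace in steps of `step_s` seconds; column timestamps are the window
#' centers.
#'
#' @param trace An [lfp_trace()] at least `nperseg` samples long.
#' @param params A [welch_params()] (only `nperseg`/`window` used per column).
#' @param step_s Window step (s), > 0.
#' @return `lfp_spectrogram` list: `times` (s), `freqs` (Hz), `power`
#'   (frequency x time matrix, uV^2/Hz).
#' @export
lfp_spectrogram <- function(trace, params = welch_params(), step_s = 1) {
  stopifnot(inherits(trace, "lfp_trace"), inherits(params, "welch_params"))
  if (step_s <= 0) stop("step_s must be > 0", call. = FALSE)
  n <- params$nperseg
  x <- trace$samples
  if (length(x) < n) {
    stop("trace shorter than one spectrogram window", call. = FALSE)
  }
  step <- max(1L, round(step_s * trace$fs))
  starts <- seq(1L, length(x) - n + 1L, by = step)
  w <- hann_window(n)
  p <- vapply(starts,
              function(s) segment_periodogram(x[s:(s + n - 1L)], w, trace$fs),
              numeric(n %/% 2 + 1L))
  structure(list(times = trace$t0 + (starts - 1L + n / 2) / trace$fs,
                 freqs = (0:(n %/% 2)) * trace$fs / n,
                 power = p), class = "lfp_spectrogram")
}

#' Per-condition PSD across same-label intervals
#'
#' Computes one Welch PSD per schedule interval matching `selector` and
#' reduces them to a single estimate: per-interval PSDs averaged bin-wise
#' (default, avoids segment-boundary artifacts) or a single PSD of the
#' concatenated segments.
#'
#' @param trace Preprocessed [lfp_trace()].
#' @param schedule An [event_schedule()].
#' @param selector Glob label pattern (e.g. `"tone_*"`, `"baseline"`).
#' @param params A [welch_params()].
#' @param mode `"average"` or `"concatenate"`.
#' @return An unnormalized `psd_result`.
#' @export
psd_by_label <- function(trace, schedule, selector,
                         params = welch_params(),
                         mode = c("average", "concatenate")) {
  mode <- match.arg(mode)
  segs <- segment_trace(trace, schedule, selector)
  if (length(segs) == 0L) {
    stop(sprintf("no intervals match '%s'", selector), call. = FALSE)
  }
  if (mode == "concatenate") {
    cat_trace <- lfp_trace(unlist(lapply(segs, `[[`, "samples")),
                           fs = trace$fs, t0 = segs[[1]]$t0,
                           provenance = trace$provenance)
    return(welch_psd(cat_trace, params))
  }
  psds <- lapply(segs, welch_psd, params = params)
  acc <- Reduce(`+`, lapply(psds, `[[`, "power")) / length(psds)
  psd_result(psds[[1]]$freqs, acc, params)
}
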