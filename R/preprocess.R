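# Butterworth design as cascaded second-order sections (biquads).
# High-order narrow-band designs (e.g. a 1 Hz edge at 30 kHz) are numerically
# unstable as a single transfer function in double precision; factoring the
# filter into biquads keeps every stage well conditioned at any rate.
butter_sos <- function(order, cutoff_hz, fs, type = c("low", "high")) {
  type <- match.arg(type)
  n <- as.integer(order)
  p <- exp(1i * pi * (2 * (1:n) + n - 1) / (2 * n)) # analog prototype poles
  wc <- 2 * fs * tan(pi * cutoff_hz / fs)           # pre-warped cutoff
  ps <- if (type == "low") p * wc else wc / p
  zs <- if (type == "low") complex(0) else rep(0 + 0i, n)
  zp <- (2 * fs + ps) / (2 * fs - ps)               # bilinear transform
  zz <- c(if (length(zs)) (2 * fs + zs) / (2 * fs - zs) else complex(0),
          rep(-1 + 0i, n - length(zs)))             # zeros at infinity -> -1
  z0 <- if (type == "low") 1 + 0i else -1 + 0i      # unity-gain reference
  g <- Mod(prod(z0 - zp) / prod(z0 - zz))
  used <- rep(FALSE, n)
  sections <- list()
  zr <- Re(zz)
  si <- 1L
  for (i in seq_len(n)) {
    if (used[i]) next
    if (abs(Im(zp[i])) > 1e-10) {
      j <- which(!used & abs(zp - Conj(zp[i])) < 1e-8 &
                   seq_len(n) != i)[1]
      used[c(i, j)] <- TRUE
      a <- c(1, -2 * Re(zp[i]), Mod(zp[i])^2)
      b <- c(1, -(zr[si] + zr[si + 1L]), zr[si] * zr[si + 1L])
      si <- si + 2L
    } else {
      used[i] <- TRUE
      a <- c(1, -Re(zp[i]))
      b <- c(1, -zr[si])
      si <- si + 1L
    }
    sections[[length(sections) + 1L]] <- list(b = b, a = a)
  }
  structure(list(sections = sections, gain = g), class = "sos_filter")
}

# Run an sos cascade (or a plain b/a biquad) forward over x via the
# compiled direct-form-II-transposed kernel.
run_cascade <- function(x, designs) {
  pad3 <- function(v) c(v, numeric(3L - length(v)))
  rows_b <- list()
  rows_a <- list()
  gain <- 1
  for (d in designs) {
    if (inherits(d, "sos_filter")) {
      gain <- gain * d$gain
      for (s in d$sections) {
        rows_b[[length(rows_b) + 1L]] <- pad3(s$b)
        rows_a[[length(rows_a) + 1L]] <- pad3(s$a)
      }
    } else {
      rows_b[[length(rows_b) + 1L]] <- pad3(d$b)
      rows_a[[length(rows_a) + 1L]] <- pad3(d$a)
    }
  }
  sosfilt_cpp(do.call(rbind, rows_b), do.call(rbind, rows_a), gain * x)
}

# Zero-phase filtering of a filter cascade with reflective padding; pad is
# ~3x the slowest impulse-response time constant so startup transients never
# reach the retained samples. Even (mirror) reflection keeps the padding's
# local mean equal to the signal's — right for low-cutoff high-pass stages,
# which would ring on the mean step that odd reflection introduces. Odd
# (point-symmetric) reflection continues the waveform smoothly — right for
# very narrow notches, whose in-band ringing is excited by the slope kink of
# even reflection.
zero_phase_cascade <- function(x, designs, pad,
                               reflection = c("even", "odd")) {
  reflection <- match.arg(reflection)
  n <- length(x)
  pad <- min(pad, n - 1L)
  if (pad > 0L) {
    xp <- if (reflection == "even") {
      c(x[(pad + 1):2], x, x[(n - 1):(n - pad)])
    } else {
      c(2 * x[1] - x[(pad + 1):2], x, 2 * x[n] - x[(n - 1):(n - pad)])
    }
  } else {
    xp <- x
  }
  y <- run_cascade(xp, designs)
  y <- rev(run_cascade(rev(y), designs))
  if (pad > 0L) y <- y[(pad + 1):(pad + n)]
  y
}

#' Band-pass filter an LFP trace
#'
#' Fifth-order (default) IIR Butterworth band-pass, applied forward-backward
#' (zero phase) so that downstream phase estimates are undistorted. The
#' default 1-120 Hz passband is the standard LFP conditioning band.
#'
#' @param trace An [lfp_trace()].
#' @param low,high Passband edges (Hz); `0 < low < high < fs/2`.
#' @param order Butterworth order (default 5).
#' @return Filtered `lfp_trace` (same sampling rate), provenance appended.
#' @export
lfp_bandpass <- function(trace, low = 1, high = 120, order = 5L) {
  stopifnot(inherits(trace, "lfp_trace"))
  nyq <- trace$fs / 2
  if (!(low > 0 && low < high && high < nyq)) {
    stop("band edges must satisfy 0 < low < high < Nyquist", call. = FALSE)
  }
  hp <- butter_sos(order, low, trace$fs, "high")
  lp <- butter_sos(order, high, trace$fs, "low")
  pad <- min(3L * round(trace$fs / low), length(trace$samples) - 1L)
  y <- zero_phase_cascade(trace$samples, list(hp, lp), pad)
  out <- lfp_trace(y, fs = trace$fs, t0 = trace$t0,
                   provenance = trace$provenance)
  add_provenance(out, sprintf("bandpass(low=%g,high=%g,order=%d)",
                              low, high, order))
}

# Second-order IIR notch biquad with -3 dB bandwidth `width` Hz centred on
# `center` (constrained-pole design; quality factor Q = center/width).
notch_coefs <- function(center, width, fs) {
  w0 <- 2 * pi * center / fs
  q <- center / width
  alpha <- sin(w0) / (2 * q)
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1 + alpha, -2 * cos(w0), 1 - alpha)
  list(b = b / a[1], a = a / a[1])
}

#' Notch-filter an LFP trace
#'
#' Narrow second-order IIR notch (default 50 Hz, -3 dB width 0.1 Hz, i.e.
#' Q = 500) applied zero-phase to suppress mains contamination while leaving
#' neighbouring frequencies (e.g. 45 Hz low gamma) untouched.
#'
#' @param trace An [lfp_trace()].
#' @param center Notch center frequency (Hz), below Nyquist.
#' @param width -3 dB rejection bandwidth (Hz), > 0.
#' @return Filtered `lfp_trace`, provenance appended.
#' @export
lfp_notch <- function(trace, center = 50, width = 0.1) {
  stopifnot(inherits(trace, "lfp_trace"))
  if (width <= 0) stop("notch width must be > 0", call. = FALSE)
  if (center >= trace$fs / 2) {
    stop("notch center must be below Nyquist", call. = FALSE)
  }
  co <- notch_coefs(center, width, trace$fs)
  pad <- min(3L * round(trace$fs / width), length(trace$samples) - 1L)
  y <- zero_phase_cascade(trace$samples, list(co), pad, reflection = "odd")
  out <- lfp_trace(y, fs = trace$fs, t0 = trace$t0,
                   provenance = trace$provenance)
  add_provenance(out, sprintf("notch(center=%g,width=%g)", center, width))
}

# Does provenance record a low-pass action covering the new Nyquist?
has_antialias_cover <- function(trace, target_hz) {
  for (p in trace$provenance) {
    m <- regmatches(p, regexec("^bandpass\\(low=[^,]+,high=([0-9.eE+-]+)", p))[[1]]
    if (length(m) == 2L && as.numeric(m[2]) <= target_hz / 2) return(TRUE)
    m <- regmatches(p, regexec("^antialias\\(cutoff=([0-9.eE+-]+)", p))[[1]]
    if (length(m) == 2L && as.numeric(m[2]) <= target_hz / 2) return(TRUE)
  }
  FALSE
}

#' Downsample an LFP trace by integer decimation
#'
#' Decimates to `target_hz` (default 1 kHz, the analysis rate). The input
#' rate must be an integer multiple of the target. If no prior low-pass in
#' the trace's provenance already covers the new Nyquist (e.g. the 1-120 Hz
#' band-pass before decimation to 1 kHz), an explicit zero-phase Butterworth
#' anti-alias low-pass at `0.4 * target_hz` is applied first, so decimation
#' never aliases silently when stages are used a la carte.
#'
#' @param trace An [lfp_trace()].
#' @param target_hz Target sampling rate (Hz).
#' @return Decimated `lfp_trace` at `target_hz`.
#' @export
lfp_downsample <- function(trace, target_hz = 1000) {
  stopifnot(inherits(trace, "lfp_trace"))
  factor <- trace$fs / target_hz
  if (abs(factor - round(factor)) > 1e-9) {
    stop(sprintf("input rate %g Hz is not an integer multiple of %g Hz",
                 trace$fs, target_hz), call. = FALSE)
  }
  factor <- as.integer(round(factor))
  if (factor == 1L) {
    return(add_provenance(trace, sprintf("downsample(%g)", target_hz)))
  }
  x <- trace
  if (!has_antialias_cover(trace, target_hz)) {
    cutoff <- 0.4 * target_hz
    lp <- butter_sos(8, cutoff, trace$fs, "low")
    pad <- min(3L * round(trace$fs / cutoff), length(trace$samples) - 1L)
    y <- zero_phase_cascade(trace$samples, list(lp), pad)
    x <- lfp_trace(y, fs = trace$fs, t0 = trace$t0,
                   provenance = trace$provenance)
    x <- add_provenance(x, sprintf("antialias(cutoff=%g,order=8)", cutoff))
  }
  out <- lfp_trace(x$samples[seq(1L, length(x$samples), by = factor)],
                   fs = target_hz, t0 = x$t0, provenance = x$provenance)
  add_provenance(out, sprintf("downsample(%g)", target_hz))
}

#' Standard LFP conditioning chain
#'
#' Applies band-pass, notch and decimation in order with the canonical
#' defaults: 1-120 Hz fifth-order Butterworth, 50 Hz notch of 0.1 Hz width,
#' decimation to 1 kHz. Any stage can be skipped by passing `NULL`.
#'
#' @param trace An [lfp_trace()]; traces with non-finite samples are rejected
#'   at construction.
#' @param bandpass `list(low, high, order)` or `NULL` to skip.
#' @param notch `list(center, width)` or `NULL` to skip.
#' @param target_hz Decimation target (Hz) or `NULL` to skip.
#' @return Preprocessed `lfp_trace`; provenance records each applied stage.
#' @export
preprocess_pipeline <- function(trace,
                                bandpass = list(low = 1, high = 120,
                                                order = 5L),
                                notch = list(center = 50, width = 0.1),
                                target_hz = 1000) {
  stopifnot(inherits(trace, "lfp_trace"))
  out <- trace
  if (!is.null(bandpass)) {
    out <- lfp_bandpass(out, low = bandpass$low, high = bandpass$high,
                        order = if (is.null(bandpass$order)) 5L
                                else bandpass$order)
  }
  if (!is.null(notch)) {
    out <- lfp_notch(out, center = notch$center, width = notch$width)
  }
  if (!is.null(target_hz)) out <- lfp_downsample(out, target_hz)
  out
}
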