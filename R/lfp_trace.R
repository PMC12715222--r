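#' Uniformly sampled LFP trace
#'
#' The substrate of all signal processing in the package: a single-channel
#' voltage series (microvolts) with its sampling rate, start time and an
#' append-only provenance record of the transforms applied so far.
#'
#' @param samples Numeric vector of voltages (uV); all values must be finite.
#' @param fs Sampling rate in Hz (> 0).
#' @param t0 Time of the first sample in seconds (default 0).
#' @param provenance Character vector of transform descriptions.
#' @return An object of class `lfp_trace`.
#' @examples
#' tr <- lfp_trace(sin(2 * pi * 8 * seq(0, 1, by = 1e-3)), fs = 1000)
#' duration(tr)
#' @export
lfp_trace <- function(samples, fs, t0 = 0, provenance = character()) {
  if (!is.numeric(samples) || length(samples) == 0L) {
    stop("samples must be a non-empty numeric vector", call. = FALSE)
  }
  if (anyNA(samples) || !all(is.finite(samples))) {
    stop("samples contain NA or non-finite values", call. = FALSE)
  }
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0) {
    stop("fs must be a single positive number", call. = FALSE)
  }
  structure(list(samples = as.numeric(samples), fs = as.numeric(fs),
                 t0 = as.numeric(t0), provenance = as.character(provenance)),
            class = "lfp_trace")
}

#' @rdname lfp_trace
#' @param x An `lfp_trace`.
#' @export
sampling_rate <- function(x) {
  stopifnot(inherits(x, "lfp_trace"))
  x$fs
}

#' @rdname lfp_trace
#' @export
n_samples <- function(x) {
  stopifnot(inherits(x, "lfp_trace"))
  length(x$samples)
}

#' @rdname lfp_trace
#' @export
duration <- function(x) {
  stopifnot(inherits(x, "lfp_trace"))
  length(x$samples) / x$fs
}

#' Sample times of a trace
#' @param x An `lfp_trace`.
#' @return Numeric vector of times (s), `t0 + (0:(n-1))/fs`.
#' @export
trace_times <- function(x) {
  stopifnot(inherits(x, "lfp_trace"))
  x$t0 + (seq_along(x$samples) - 1) / x$fs
}

# Append a provenance entry, returning a new trace (provenance is append-only).
add_provenance <- function(x, entry) {
  x$provenance <- c(x$provenance, entry)
  x
}

#' @export
print.lfp_trace <- function(x, ...) {
  cat(sprintf("<lfp_trace> %d samples @ %g Hz (%.3f s), t0 = %g s\n",
              length(x$samples), x$fs, duration(x), x$t0))
  if (length(x$provenance)) {
    cat("  provenance:\n")
    for (p in x$provenance) cat("   -", p, "\n")
  }
  invisible(x)
}

#' Write / read an LFP trace
#'
#' Traces are stored as little-endian float32 flat binary plus a JSON sidecar
#' (`<path>.json`) carrying `sampling_rate_hz`, `units`, `t0` and provenance.
#' A CSV dialect (`t,value` columns) is supported for small fixtures.
#'
#' @param x An `lfp_trace`.
#' @param path Output path. Paths ending `.csv` use the CSV dialect.
#' @return `write_lfp()` returns `path` invisibly; `read_lfp()` an
#'   `lfp_trace`. Float32 storage quantizes values to ~7 significant digits.
#' @export
write_lfp <- function(x, path) {
  stopifnot(inherits(x, "lfp_trace"))
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    utils::write.csv(data.frame(t = trace_times(x), value = x$samples),
                     path, row.names = FALSE)
    return(invisible(path))
  }
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(x$samples, con, size = 4L, endian = "little")
  meta <- list(sampling_rate_hz = x$fs, units = "uV", t0 = x$t0,
               n_samples = length(x$samples), dtype = "float32_le",
               provenance = x$provenance)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_lfp
#' @export
read_lfp <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    df <- utils::read.csv(path)
    stopifnot(all(c("t", "value") %in% names(df)), nrow(df) >= 2L)
    dt <- diff(df$t)
    if (max(dt) - min(dt) > 1e-6 * stats::median(dt)) {
      stop("CSV trace is not uniformly sampled", call. = FALSE)
    }
    return(lfp_trace(df$value, fs = 1 / stats::median(dt), t0 = df$t[1]))
  }
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  con <- file(path, "rb")
  on.exit(close(con))
  smp <- readBin(con, "numeric", n = meta$n_samples, size = 4L,
                 endian = "little")
  lfp_trace(smp, fs = meta$sampling_rate_hz, t0 = meta$t0,
            provenance = as.character(meta$provenance))
}
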