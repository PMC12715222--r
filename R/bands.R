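#' Frequency band definition
#'
#' A named frequency interval used for band-power extraction and for the
#' phase/amplitude bands of the coupling analysis.
#'
#' @param name Band label (e.g. `"theta"`).
#' @param low,high Band edges in Hz; `low < high` required.
#' @return An object of class `frequency_band` with fields `name`, `low`,
#'   `high`.
#' @examples
#' frequency_band("theta", 4, 12)
#' @export
frequency_band <- function(name, low, high) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.numeric(low) || !is.numeric(high) || length(low) != 1L ||
      length(high) != 1L || !is.finite(low) || !is.finite(high)) {
    stop("band edges must be finite numbers", call. = FALSE)
  }
  if (low >= high) stop("band requires low < high", call. = FALSE)
  structure(list(name = name, low = low, high = high),
            class = "frequency_band")
}

#' Canonical band registry
#'
#' The oscillation bands used throughout the analysis: theta (4-12 Hz),
#' gamma (30-90 Hz), low gamma (30-45 Hz) and high gamma (55-90 Hz).
#' The 45-55 Hz gap between the gamma sub-bands keeps 50 Hz line noise out
#' of both by construction.
#'
#' @return Named list of [frequency_band()] objects.
#' @export
band_registry <- function() {
  list(
    theta      = frequency_band("theta", 4, 12),
    gamma      = frequency_band("gamma", 30, 90),
    low_gamma  = frequency_band("low_gamma", 30, 45),
    high_gamma = frequency_band("high_gamma", 55, 90)
  )
}

#' Look up a band by name or pass a band through
#'
#' @param band A `frequency_band`, or the name of a registry band.
#' @return A `frequency_band`.
#' @export
get_band <- function(band) {
  if (inherits(band, "frequency_band")) return(band)
  if (is.character(band) && length(band) == 1L) {
    reg <- band_registry()
    if (!band %in% names(reg)) {
      stop(sprintf("unknown band '%s'; registry bands: %s", band,
                   paste(names(reg), collapse = ", ")), call. = FALSE)
    }
    return(reg[[band]])
  }
  stop("band must be a frequency_band or a registry band name", call. = FALSE)
}

#' @export
print.frequency_band <- function(x, ...) {
  cat(sprintf("<frequency_band> %s: %g-%g Hz\n", x$name, x$low, x$high))
  invisible(x)
}
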