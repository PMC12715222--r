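#' Behavioral event schedule
#'
#' An ordered set of labeled, non-overlapping time intervals (baseline,
#' tone_k, iti_k, shock_k, center, periphery) defining the analysis windows
#' of a session.
#'
#' @param intervals `data.frame` with columns `label`, `start_s`, `end_s`.
#' @param session_kind One of `"conditioning"`, `"context_extinction"`,
#'   `"tone_extinction"`, `"retrieval"`, `"open_field"`.
#' @return An `event_schedule` (a `data.frame` subclass).
#' @export
event_schedule <- function(intervals,
                           session_kind = c("tone_extinction", "conditioning",
                                            "context_extinction", "retrieval",
                                            "open_field")) {
  session_kind <- match.arg(session_kind)
  stopifnot(is.data.frame(intervals),
            all(c("label", "start_s", "end_s") %in% names(intervals)))
  intervals <- intervals[order(intervals$start_s),
                         c("label", "start_s", "end_s")]
  rownames(intervals) <- NULL
  if (any(intervals$end_s <= intervals$start_s)) {
    stop("every interval requires start_s < end_s", call. = FALSE)
  }
  if (nrow(intervals) > 1L) {
    overlap <- intervals$start_s[-1L] <
      intervals$end_s[-nrow(intervals)] - 1e-9
    if (any(overlap)) stop("intervals overlap", call. = FALSE)
  }
  ok <- grepl("^(baseline|tone_[0-9]+|iti_[0-9]+|shock_[0-9]+|center|periphery)$",
              intervals$label)
  if (!all(ok)) {
    stop(sprintf("labels outside controlled vocabulary: %s",
                 paste(unique(intervals$label[!ok]), collapse = ", ")),
         call. = FALSE)
  }
  structure(intervals, session_kind = session_kind,
            class = c("event_schedule", "data.frame"))
}

#' @export
print.event_schedule <- function(x, ...) {
  cat(sprintf("<event_schedule> %s: %d intervals, %.1f s\n",
              attr(x, "session_kind"), nrow(x), schedule_duration(x)))
  print.data.frame(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat(sprintf("  ... %d more\n", nrow(x) - 6))
  invisible(x)
}

#' Total duration spanned by a schedule (s)
#' @param schedule An `event_schedule`.
#' @export
schedule_duration <- function(schedule) {
  stopifnot(inherits(schedule, "event_schedule"))
  max(schedule$end_s) - min(schedule$start_s)
}

#' Read / write an event schedule as CSV
#'
#' Dialect: UTF-8 CSV with header `label,start_s,end_s`, seconds as decimals;
#' round-trips exactly through [write_schedule()] / [read_schedule()].
#'
#' @param schedule An `event_schedule`.
#' @param path CSV path.
#' @param session_kind Stored on read (CSV carries intervals only).
#' @export
write_schedule <- function(schedule, path) {
  stopifnot(inherits(schedule, "event_schedule"))
  df <- as.data.frame(schedule)
  df$start_s <- format(df$start_s, digits = 17, scientific = FALSE, trim = TRUE)
  df$end_s <- format(df$end_s, digits = 17, scientific = FALSE, trim = TRUE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_schedule
#' @export
read_schedule <- function(path, session_kind = "tone_extinction") {
  df <- utils::read.csv(path, fileEncoding = "UTF-8",
                        colClasses = c("character", "numeric", "numeric"))
  event_schedule(df, session_kind = session_kind)
}

#' Cut a trace into per-interval segments
#'
#' Selects schedule intervals whose label matches a glob-style pattern and
#' returns one sub-trace per interval. Intervals are half-open `[start, end)`:
#' the start is mapped to the nearest sample and the length is
#' `floor((end - start) * fs)` samples, so adjacent tone/ITI segments never
#' share a sample.
#'
#' @param trace An `lfp_trace`.
#' @param schedule An `event_schedule` lying within the trace's time span.
#' @param selector Glob pattern on labels, e.g. `"tone_*"`; `*` matches any
#'   run of characters.
#' @return Named list of `lfp_trace` (names = interval labels); empty list if
#'   nothing matches.
#' @export
segment_trace <- function(trace, schedule, selector) {
  stopifnot(inherits(trace, "lfp_trace"), inherits(schedule, "event_schedule"))
  rx <- utils::glob2rx(selector)
  hit <- schedule[grepl(rx, schedule$label), , drop = FALSE]
  if (nrow(hit) == 0L) return(list())
  fs <- trace$fs
  t_end <- trace$t0 + length(trace$samples) / fs
  out <- vector("list", nrow(hit))
  for (i in seq_len(nrow(hit))) {
    s <- hit$start_s[i]; e <- hit$end_s[i]
    if (s < trace$t0 - 1e-9 || e > t_end + 1e-9) {
      stop(sprintf("interval '%s' [%g, %g) lies outside the trace span",
                   hit$label[i], s, e), call. = FALSE)
    }
    i0 <- round((s - trace$t0) * fs) + 1L
    len <- floor((e - s) * fs + 1e-9)
    i1 <- min(i0 + len - 1L, length(trace$samples))
    out[[i]] <- lfp_trace(trace$samples[i0:i1], fs = fs, t0 = s,
                          provenance = c(trace$provenance,
                                         sprintf("segment(%s)", hit$label[i])))
  }
  names(out) <- hit$label
  out
}

#' Extinction-stage assignment of a trial
#'
#' For the 40-tone extinction protocol, trials 1-13 are `early`, 14-26
#' `intermediate`, 27-39 `late`, and trial 40 (the last CS and its ITI) is
#' `excluded`. For other trial counts the session is split into three equal
#' thirds of `floor(n/3)` trials with the remainder excluded at the end, and
#' a warning flags the deviation from the canonical protocol.
#'
#' @param k 1-based trial index (vectorized).
#' @param n_trials Total trials in the session (default 40).
#' @return Character vector in `{"early","intermediate","late","excluded"}`.
#' @export
stage_of_trial <- function(k, n_trials = 40L) {
  stopifnot(is.numeric(k), length(k) >= 1L, is.numeric(n_trials))
  k <- as.integer(k)
  n_trials <- as.integer(n_trials)
  if (any(k < 1L | k > n_trials)) {
    stop("trial index out of 1..n_trials range", call. = FALSE)
  }
  third <- n_trials %/% 3L
  if (n_trials != 40L) {
    warning(sprintf(
      "n_trials = %d differs from the canonical 40-tone protocol; using thirds of %d trials with the remainder excluded",
      n_trials, third), call. = FALSE)
  }
  stage <- rep("excluded", length(k))
  stage[k <= third] <- "early"
  stage[k > third & k <= 2L * third] <- "intermediate"
  stage[k > 2L * third & k <= 3L * third] <- "late"
  stage
}

#' Aggregate per-segment measures by condition (and stage)
#'
#' Reduces per-trial values (band powers, modulation indices, freezing
#' percentages) to one row per condition, either over the whole session or by
#' extinction stage.
#'
#' @param values `data.frame` with columns `trial`, `label` (condition label,
#'   e.g. `"tone"`/`"iti"`), `value`; extra columns pass through grouping.
#' @param grouping `"whole_session"` or `"by_stage"`.
#' @param n_trials Trials in the session, for stage assignment (default 40).
#' @return `data.frame` with columns `label`, `stage`, `mean`, `sd`, `n`.
#'   Stage-`excluded` trials are dropped under `"by_stage"`.
#' @export
aggregate_condition <- function(values,
                                grouping = c("whole_session", "by_stage"),
                                n_trials = 40L) {
  grouping <- match.arg(grouping)
  stopifnot(is.data.frame(values),
            all(c("trial", "label", "value") %in% names(values)))
  expected <- if (grouping == "by_stage") seq_len(n_trials) else NULL
  if (!is.null(expected)) {
    miss <- setdiff(intersect(expected, seq_len(n_trials)),
                    unique(values$trial))
    # the final trial is excluded by design; only flag missing analysed trials
    if (length(miss)) {
      miss <- miss[suppressWarnings(stage_of_trial(miss, n_trials)) !=
                     "excluded"]
    }
    if (length(miss)) {
      warning(sprintf("missing trial indices: %s; aggregating the rest",
                      paste(miss, collapse = ",")), call. = FALSE)
    }
  }
  if (grouping == "whole_session") {
    values$stage <- "all"
  } else {
    values$stage <- stage_of_trial(values$trial, n_trials)
    values <- values[values$stage != "excluded", , drop = FALSE]
  }
  if (nrow(values) == 0L) {
    return(data.frame(label = character(), stage = character(),
                      mean = numeric(), sd = numeric(), n = integer(),
                      stringsAsFactors = FALSE))
  }
  agg <- function(f) stats::aggregate(value ~ label + stage, data = values,
                                      FUN = f)
  m <- agg(mean)
  s <- agg(stats::sd)
  n <- agg(length)
  out <- data.frame(label = m$label, stage = m$stage, mean = m$value,
                    sd = s$value, n = n$value, stringsAsFactors = FALSE)
  out[order(out$label, out$stage), , drop = FALSE]
}
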