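#' Freezing-scorer parameters
#'
#' VideoFreeze-style defaults: a frame is immobile when its motion index is
#' strictly below 18 arbitrary units, and an immobile run counts as freezing
#' only when it lasts at least 30 frames (1 s at 30 fps). The threshold
#' comparison is strict: a frame exactly at the threshold counts as motion.
#'
#' @param threshold Motion threshold (a.u.), > 0.
#' @param min_freeze_frames Minimum freezing run length (frames), >= 1.
#' @return A `freezing_params` list.
#' @export
freezing_params <- function(threshold = 18, min_freeze_frames = 30L) {
  if (threshold <= 0) stop("threshold must be > 0", call. = FALSE)
  min_freeze_frames <- as.integer(min_freeze_frames)
  if (min_freeze_frames < 1L) {
    stop("min_freeze_frames must be >= 1", call. = FALSE)
  }
  structure(list(threshold = threshold,
                 min_freeze_frames = min_freeze_frames),
            class = "freezing_params")
}

# Frame indices (1-based, half-open) covered by a schedule interval.
interval_frames <- function(start_s, end_s, t0, fps, n) {
  i0 <- floor((start_s - t0) * fps) + 1L
  i1 <- min(floor((end_s - t0) * fps), n)
  if (i0 > i1) integer(0) else i0:i1
}

#' Score freezing from a motion-index trace
#'
#' Marks frames with motion index strictly below the threshold as immobile,
#' keeps maximal immobile runs of at least `min_freeze_frames` frames as
#' freezing, and reports the percentage of frozen frames per schedule
#' interval. Runs are evaluated on the uncut trace, so a bout spanning an
#' interval boundary still qualifies by its full length and its frames are
#' attributed to their containing intervals.
#'
#' @param motion A [motion_trace()] covering the schedule span.
#' @param params A [freezing_params()].
#' @param schedule An [event_schedule()]; `NULL` scores the whole trace as a
#'   single interval.
#' @return A `data.frame` with columns `label`, `start_s`, `end_s`,
#'   `n_frames`, `freezing_pct`.
#' @export
score_freezing <- function(motion, params = freezing_params(),
                           schedule = NULL) {
  stopifnot(inherits(motion, "motion_trace"),
            inherits(params, "freezing_params"))
  fps <- motion$frame_rate
  n <- length(motion$motion_index)
  if (params$min_freeze_frames != round(fps)) {
    warning(sprintf(
      "min_freeze_frames = %d is a frame count; at %g fps it spans %.2f s",
      params$min_freeze_frames, fps, params$min_freeze_frames / fps),
      call. = FALSE)
  }
  frozen <- frozen_frames(motion$motion_index, params$threshold,
                          params$min_freeze_frames)
  if (is.null(schedule)) {
    return(data.frame(label = "all", start_s = 0, end_s = n / fps,
                      n_frames = n, freezing_pct = 100 * mean(frozen),
                      stringsAsFactors = FALSE))
  }
  t0 <- min(schedule$start_s)
  if (n < floor(schedule_duration(schedule) * fps)) {
    stop("motion trace does not cover the schedule span", call. = FALSE)
  }
  out <- schedule[, c("label", "start_s", "end_s")]
  out$n_frames <- NA_integer_
  out$freezing_pct <- NA_real_
  for (i in seq_len(nrow(out))) {
    idx <- interval_frames(out$start_s[i], out$end_s[i], t0, fps, n)
    out$n_frames[i] <- length(idx)
    out$freezing_pct[i] <- if (length(idx)) 100 * mean(frozen[idx]) else NA
  }
  as.data.frame(out)
}

# Logical mask of frames belonging to qualifying freezing runs.
frozen_frames <- function(motion_index, threshold, min_frames) {
  immobile <- motion_index < threshold
  r <- rle(immobile)
  keep <- r$values & r$lengths >= min_frames
  rep(keep, r$lengths)
}

#' Five-trial block means
#'
#' Averages per-trial freezing percentages (or any per-trial measure) in
#' consecutive blocks of `block_size` trials: 40 extinction trials yield 8
#' blocks. A trailing partial block is averaged over the trials present and
#' flagged with a warning.
#'
#' @param per_trial Numeric vector of per-trial values, in trial order.
#' @param block_size Trials per block (default 5).
#' @return Numeric vector of block means, named `block_1`, `block_2`, ...
#' @export
block_means <- function(per_trial, block_size = 5L) {
  block_size <- as.integer(block_size)
  stopifnot(block_size >= 1L, is.numeric(per_trial), length(per_trial) >= 1L)
  n <- length(per_trial)
  if (n %% block_size != 0L) {
    warning(sprintf(
      "%d trials not divisible by block size %d; trailing block has %d trials",
      n, block_size, n %% block_size), call. = FALSE)
  }
  blk <- ceiling(seq_len(n) / block_size)
  out <- as.numeric(tapply(per_trial, blk, mean))
  names(out) <- paste0("block_", seq_along(out))
  out
}

#' Open-field trajectory
#'
#' @param t Time stamps (s), strictly increasing.
#' @param x,y Positions (cm) within the square arena.
#' @param arena_side Arena side length (cm), default 50.
#' @return A `trajectory` data.frame with attribute `arena_side`.
#' @export
trajectory <- function(t, x, y, arena_side = 50) {
  stopifnot(length(t) == length(x), length(x) == length(y))
  if (any(diff(t) <= 0)) stop("t must be strictly increasing", call. = FALSE)
  if (any(x < 0 | x > arena_side | y < 0 | y > arena_side)) {
    stop("trajectory leaves the arena", call. = FALSE)
  }
  structure(data.frame(t = t, x = x, y = y),
            arena_side = arena_side, class = c("trajectory", "data.frame"))
}

#' Open-field locomotion and zone metrics
#'
#' The center is the concentric square of area `inner_area_cm2` (side
#' `sqrt(inner_area_cm2)`, 30 cm for the default 900 cm^2 in a 50 cm arena);
#' the periphery is the remainder of the arena. Reported: total distance
#' (cm), mean speed (cm/s), time fractions in center/periphery, number of
#' center entries, and immobility time (s) below `immobility_speed`.
#'
#' @param traj A [trajectory()].
#' @param inner_area_cm2 Area of the central square (cm^2), default 900.
#' @param immobility_speed Speed (cm/s) below which a step counts as
#'   immobile, default 1.
#' @return Named list of metrics.
#' @export
openfield_metrics <- function(traj, inner_area_cm2 = 900,
                              immobility_speed = 1) {
  stopifnot(inherits(traj, "trajectory"))
  side <- attr(traj, "arena_side")
  half <- sqrt(inner_area_cm2) / 2
  c0 <- side / 2
  in_center <- abs(traj$x - c0) <= half & abs(traj$y - c0) <= half
  dt <- diff(traj$t)
  step <- sqrt(diff(traj$x)^2 + diff(traj$y)^2)
  total_t <- sum(dt)
  # time attributed to the sample opening each step
  t_center <- sum(dt[in_center[-length(in_center)]])
  speeds <- step / dt
  list(distance_cm = sum(step),
       mean_speed_cm_s = sum(step) / total_t,
       time_in_center_frac = t_center / total_t,
       time_in_periphery_frac = 1 - t_center / total_t,
       center_crossings = sum(diff(in_center) == 1L),
       immobility_s = sum(dt[speeds < immobility_speed]))
}

#' Novel-object preference index
#'
#' `PI = t_novel / (t_novel + t_familiar)`: 0.5 marks no preference, 1 an
#' exclusive preference for the novel object.
#'
#' @param t_novel,t_familiar Exploration times (s), non-negative, not both 0.
#' @return PI in `[0, 1]`.
#' @export
preference_index <- function(t_novel, t_familiar) {
  if (t_novel < 0 || t_familiar < 0) {
    stop("exploration times must be non-negative", call. = FALSE)
  }
  if (t_novel + t_familiar == 0) {
    stop("preference index undefined: no exploration time", call. = FALSE)
  }
  t_novel / (t_novel + t_familiar)
}

#' Read / write a motion trace as CSV (`frame,motion_index`)
#'
#' @param motion A [motion_trace()].
#' @param path CSV path.
#' @param frame_rate Frame rate (fps) assumed on read.
#' @export
write_motion <- function(motion, path) {
  stopifnot(inherits(motion, "motion_trace"))
  utils::write.csv(data.frame(frame = seq_along(motion$motion_index),
                              motion_index = motion$motion_index),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_motion
#' @export
read_motion <- function(path, frame_rate = 30) {
  df <- utils::read.csv(path)
  stopifnot(all(c("frame", "motion_index") %in% names(df)))
  motion_trace(df$motion_index[order(df$frame)], frame_rate = frame_rate)
}
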