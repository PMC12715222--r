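#' Fear-extinction session design
#'
#' Describes the temporal structure of a session: a baseline period followed
#' by `n_tones` conditioned-stimulus presentations separated by inter-trial
#' intervals. The canonical tone-extinction session is 180 s baseline,
#' 40 tones of 30 s and 5 s ITIs; the session ends with a tone (39 separating
#' ITIs) unless `trailing_iti = TRUE`.
#'
#' @param baseline_s Baseline duration (s), default 180.
#' @param n_tones Number of tone presentations, default 40.
#' @param tone_s Tone duration (s), default 30.
#' @param iti_s Inter-trial interval duration (s), default 5.
#' @param conditioning If `TRUE`, a 2 s shock marker follows each tone
#'   (carved out of the head of the following ITI).
#' @param trailing_iti If `TRUE`, append an ITI after the final tone.
#' @return A `session_design` list.
#' @export
session_design <- function(baseline_s = 180, n_tones = 40L, tone_s = 30,
                           iti_s = 5, conditioning = FALSE,
                           trailing_iti = FALSE) {
  if (any(c(baseline_s, tone_s, iti_s) <= 0)) {
    stop("all durations must be positive", call. = FALSE)
  }
  n_tones <- as.integer(n_tones)
  if (is.na(n_tones) || n_tones < 1L) {
    stop("n_tones must be >= 1", call. = FALSE)
  }
  if (conditioning && iti_s <= 2) {
    stop("conditioning requires iti_s > 2 s (shock marker)", call. = FALSE)
  }
  structure(list(baseline_s = baseline_s, n_tones = n_tones, tone_s = tone_s,
                 iti_s = iti_s, conditioning = conditioning,
                 trailing_iti = trailing_iti),
            class = "session_design")
}

#' Build the event schedule of a session design
#'
#' @param design A [session_design()].
#' @return An [event_schedule()] with contiguous intervals `baseline`,
#'   `tone_1`, `iti_1`, ..., `tone_n` (and `iti_n` if `trailing_iti`).
#' @examples
#' sched <- generate_schedule(session_design())
#' max(sched$end_s) # 180 + 40*30 + 39*5 = 1575
#' @export
generate_schedule <- function(design) {
  stopifnot(inherits(design, "session_design"))
  lab <- "baseline"; st <- 0; en <- design$baseline_s
  t <- design$baseline_s
  for (k in seq_len(design$n_tones)) {
    lab <- c(lab, sprintf("tone_%d", k))
    st <- c(st, t); en <- c(en, t + design$tone_s)
    t <- t + design$tone_s
    last <- k == design$n_tones
    if (!last || design$trailing_iti) {
      if (design$conditioning) {
        lab <- c(lab, sprintf("shock_%d", k))
        st <- c(st, t); en <- c(en, t + 2)
        t <- t + 2
        lab <- c(lab, sprintf("iti_%d", k))
        st <- c(st, t); en <- c(en, t + design$iti_s - 2)
        t <- t + design$iti_s - 2
      } else {
        lab <- c(lab, sprintf("iti_%d", k))
        st <- c(st, t); en <- c(en, t + design$iti_s)
        t <- t + design$iti_s
      }
    }
  }
  kind <- if (design$conditioning) "conditioning" else "tone_extinction"
  event_schedule(data.frame(label = lab, start_s = st, end_s = en,
                            stringsAsFactors = FALSE),
                 session_kind = kind)
}

#' Synthetic-LFP simulation configuration
#'
#' Parameters of the generative model: a 1/f^alpha aperiodic background, a
#' theta sinusoid, gamma carriers whose envelope is modulated by theta phase,
#' 50 Hz line contamination and white sensor noise. Amplitudes are in uV and
#' loosely follow rodent mPFC LFP scales (theta tens of uV, gamma an order of
#' magnitude smaller).
#'
#' @param sampling_rate_hz Sampling rate (Hz); the acquisition rate of the
#'   emulated system is 30 kHz. All simulated components lie below 120 Hz, so
#'   generating directly at a lower rate (e.g. the 1 kHz analysis rate) is
#'   equivalent to generating at 30 kHz and decimating.
#' @param aperiodic_exponent Exponent alpha of the 1/f^alpha background.
#' @param aperiodic_sd Standard deviation (uV) of the aperiodic background.
#' @param theta_hz Theta frequency (Hz), within 4-12.
#' @param theta_amp Theta amplitude (uV).
#' @param gamma_bands Named list of gamma components,
#'   `list(band = list(carrier_hz =, base_amp =))`.
#' @param pac_depth Coupling depth m in `[0, 1]`: a scalar, or a named vector
#'   keyed by condition for condition-dependent coupling.
#' @param pac_preferred_phase Theta phase (rad, cosine convention: 0 = theta
#'   peak) at which gamma amplitude is maximal.
#' @param line_noise_hz,line_noise_amp Mains frequency (Hz) and amplitude (uV).
#' @param group_gain Named list keyed by condition; each element a named
#'   numeric vector of multiplicative amplitude factors per gamma band (and
#'   optionally `theta`), e.g. `list(task = c(low_gamma = 0.7))`.
#' @param noise_sd White-noise standard deviation (uV).
#' @param animal_cv Between-animal variability: coefficient of variation of
#'   the lognormal per-animal factors applied (by [generate_cohort()]) to the
#'   theta, gamma and aperiodic amplitudes. 0.15 emulates the
#'   inter-individual spread of absolute LFP power typical of chronic
#'   recordings; 0 makes all animals statistically identical.
#' @param seed Integer RNG seed; seeded runs are bit-reproducible.
#' @param max_samples Memory budget: refuse to simulate traces longer than
#'   this many samples.
#' @return A `sim_config` list.
#' @export
sim_config <- function(sampling_rate_hz = 30000,
                       aperiodic_exponent = 2,
                       aperiodic_sd = 30,
                       theta_hz = 8,
                       theta_amp = 50,
                       gamma_bands = list(
                         low_gamma = list(carrier_hz = 40, base_amp = 10),
                         high_gamma = list(carrier_hz = 70, base_amp = 8)),
                       pac_depth = 0.5,
                       pac_preferred_phase = 0,
                       line_noise_hz = 50,
                       line_noise_amp = 5,
                       group_gain = list(),
                       noise_sd = 10,
                       animal_cv = 0.15,
                       seed = NULL,
                       max_samples = 2e8) {
  if (any(pac_depth < 0) || any(pac_depth > 1)) {
    stop("pac_depth must lie in [0, 1]", call. = FALSE)
  }
  if (theta_hz < 4 || theta_hz > 12) {
    stop("theta_hz must lie within the theta band (4-12 Hz)", call. = FALSE)
  }
  carriers <- vapply(gamma_bands, function(g) g$carrier_hz, numeric(1))
  if (length(carriers) && sampling_rate_hz <= 2 * max(carriers)) {
    stop("sampling_rate_hz must exceed twice the highest carrier frequency",
         call. = FALSE)
  }
  for (g in group_gain) {
    if (any(g <= 0)) stop("group_gain factors must be > 0", call. = FALSE)
  }
  structure(list(sampling_rate_hz = sampling_rate_hz,
                 aperiodic_exponent = aperiodic_exponent,
                 aperiodic_sd = aperiodic_sd,
                 theta_hz = theta_hz, theta_amp = theta_amp,
                 gamma_bands = gamma_bands, pac_depth = pac_depth,
                 pac_preferred_phase = pac_preferred_phase,
                 line_noise_hz = line_noise_hz,
                 line_noise_amp = line_noise_amp,
                 group_gain = group_gain, noise_sd = noise_sd,
                 animal_cv = animal_cv, seed = seed,
                 max_samples = max_samples),
            class = "sim_config")
}

# Run expr with a private RNG stream (leaves the caller's .Random.seed intact).
with_local_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# 1/f^alpha noise by frequency-domain shaping of white Gaussian noise,
# rescaled to unit standard deviation. Exact target exponent by construction.
one_over_f_noise <- function(n, fs, exponent) {
  if (exponent == 0) return(stats::rnorm(n))
  w <- stats::rnorm(n)
  X <- stats::fft(w)
  k <- 0:(n - 1)
  f <- pmin(k, n - k) * fs / n # two-sided frequency magnitude
  scale <- ifelse(f > 0, f^(-exponent / 2), 0)
  x <- Re(stats::fft(X * scale, inverse = TRUE)) / n
  x / stats::sd(x)
}

# Resolve a per-condition scalar parameter (scalar, or named by condition).
per_condition <- function(par, condition, default) {
  if (length(par) == 1L && is.null(names(par))) return(unname(par))
  if (!is.null(names(par)) && condition %in% names(par)) {
    return(unname(par[[condition]]))
  }
  default
}

#' Generate a synthetic LFP trace for a session
#'
#' Simulates `1/f^alpha` background + theta sinusoid + gamma carriers with
#' theta-phase-modulated envelopes + 50 Hz line noise + white noise. The
#' gamma envelope in an interval of condition `c` is
#' `base_amp * gain(c, band) * (1 + m(c) * cos(phase - preferred)) / (1 + m(c))`;
#' the `(1 + m)` normalization keeps mean gamma amplitude independent of the
#' coupling depth, so coupling and band-power effects stay orthogonal.
#'
#' @param config A [sim_config()].
#' @param schedule An [event_schedule()].
#' @param condition_map Named character vector mapping interval labels to
#'   condition names (for `pac_depth` / `group_gain` lookup). Unmapped labels
#'   get condition `"default"`. A single unnamed string maps every label.
#' @return `list(trace = lfp_trace, truth = data.frame)`; `truth` has one row
#'   per interval with the true per-band amplitudes (after gains) and the
#'   true coupling depth.
#' @export
generate_lfp <- function(config, schedule, condition_map = NULL) {
  stopifnot(inherits(config, "sim_config"),
            inherits(schedule, "event_schedule"))
  fs <- config$sampling_rate_hz
  t0 <- min(schedule$start_s)
  n <- round(schedule_duration(schedule) * fs)
  if (n > config$max_samples) {
    stop(sprintf("trace of %d samples exceeds max_samples budget (%g)",
                 n, config$max_samples), call. = FALSE)
  }
  cond_of <- function(label) {
    if (is.null(condition_map)) return("default")
    if (is.null(names(condition_map)) && length(condition_map) == 1L) {
      return(condition_map)
    }
    if (label %in% names(condition_map)) return(condition_map[[label]])
    "default"
  }
  with_local_seed(config$seed, {
    t <- (seq_len(n) - 1) / fs
    theta_phase <- 2 * pi * config$theta_hz * t
    x <- config$theta_amp * cos(theta_phase)
    if (config$aperiodic_sd > 0) {
      x <- x + config$aperiodic_sd *
        one_over_f_noise(n, fs, config$aperiodic_exponent)
    }
    if (config$line_noise_amp > 0) {
      x <- x + config$line_noise_amp * sin(2 * pi * config$line_noise_hz * t)
    }
    if (config$noise_sd > 0) x <- x + stats::rnorm(n, sd = config$noise_sd)

    truth <- data.frame(label = schedule$label,
                        condition = vapply(schedule$label, cond_of, ""),
                        start_s = schedule$start_s, end_s = schedule$end_s,
                        theta_amp = config$theta_amp,
                        pac_depth = NA_real_, stringsAsFactors = FALSE)
    for (b in names(config$gamma_bands)) truth[[paste0(b, "_amp")]] <- NA_real_

    # per-interval envelopes
    for (i in seq_len(nrow(schedule))) {
      cond <- truth$condition[i]
      i0 <- round((schedule$start_s[i] - t0) * fs) + 1L
      i1 <- min(round((schedule$end_s[i] - t0) * fs), n)
      idx <- i0:i1
      m <- per_condition(config$pac_depth, cond, default = 0)
      truth$pac_depth[i] <- m
      gains <- config$group_gain[[cond]]
      for (b in names(config$gamma_bands)) {
        gb <- config$gamma_bands[[b]]
        gain <- if (!is.null(gains) && b %in% names(gains)) gains[[b]] else 1
        amp <- gb$base_amp * gain
        env <- amp * (1 + m * cos(theta_phase[idx] -
                                    config$pac_preferred_phase)) / (1 + m)
        x[idx] <- x[idx] + env * cos(2 * pi * gb$carrier_hz * t[idx])
        truth[[paste0(b, "_amp")]][i] <- amp
      }
      tg <- if (!is.null(gains) && "theta" %in% names(gains)) gains[["theta"]]
            else 1
      if (tg != 1) {
        # replace the global theta contribution in this interval
        x[idx] <- x[idx] + (tg - 1) * config$theta_amp * cos(theta_phase[idx])
        truth$theta_amp[i] <- config$theta_amp * tg
      }
    }
    list(trace = lfp_trace(x, fs = fs, t0 = t0,
                           provenance = "simulated"),
         truth = truth)
  })
}

#' Per-frame motion trace
#'
#' @param motion_index Non-negative per-frame motion values (a.u.).
#' @param frame_rate Frames per second (default 30).
#' @return A `motion_trace` list.
#' @export
motion_trace <- function(motion_index, frame_rate = 30) {
  if (frame_rate <= 0) stop("frame_rate must be > 0", call. = FALSE)
  if (anyNA(motion_index) || any(!is.finite(motion_index)) ||
      any(motion_index < 0)) {
    stop("motion_index must be finite and non-negative", call. = FALSE)
  }
  structure(list(motion_index = as.numeric(motion_index),
                 frame_rate = frame_rate), class = "motion_trace")
}

#' @export
print.motion_trace <- function(x, ...) {
  cat(sprintf("<motion_trace> %d frames @ %g fps (%.1f s)\n",
              length(x$motion_index), x$frame_rate,
              length(x$motion_index) / x$frame_rate))
  invisible(x)
}

#' Generate a motion-index trace with scripted freezing
#'
#' Constructs a per-frame motion index such that the freezing scorer, run
#' with the matching threshold and minimum-duration parameters, recovers a
#' target freezing fraction in each interval. Freezing is scripted as one
#' contiguous sub-threshold bout per interval of `round(target * n_frames)`
#' frames (dropped to zero frames when shorter than `min_freeze_frames`, which
#' cannot score as freezing); remaining frames are supra-threshold motion
#' noise.
#'
#' @param schedule An [event_schedule()].
#' @param freezing_profile Target freezing fraction(s) in `[0, 1]`: a single
#'   number for all intervals or a named vector keyed by interval label
#'   (unnamed labels default to 0).
#' @param frame_rate Frames per second (default 30).
#' @param threshold Motion threshold (a.u., default 18): frames strictly below
#'   it are immobile.
#' @param min_freeze_frames Minimum immobility run that counts as freezing
#'   (default 30 frames).
#' @param seed Integer RNG seed.
#' @return `list(motion = motion_trace, truth = data.frame)` where `truth`
#'   holds the achieved freezing fraction per interval.
#' @export
generate_motion_trace <- function(schedule, freezing_profile = 0,
                                  frame_rate = 30, threshold = 18,
                                  min_freeze_frames = 30L, seed = NULL) {
  stopifnot(inherits(schedule, "event_schedule"))
  if (frame_rate <= 0) stop("frame_rate must be > 0", call. = FALSE)
  if (any(freezing_profile < 0) || any(freezing_profile > 1)) {
    stop("freezing targets must lie in [0, 1]", call. = FALSE)
  }
  t0 <- min(schedule$start_s)
  n <- round(schedule_duration(schedule) * frame_rate)
  target_of <- function(label) {
    if (is.null(names(freezing_profile))) return(freezing_profile[[1]])
    if (label %in% names(freezing_profile)) return(freezing_profile[[label]])
    0
  }
  with_local_seed(seed, {
    # supra-threshold motion background (strictly above threshold)
    m <- threshold * (1.2 + stats::rexp(n, rate = 2))
    truth <- data.frame(label = schedule$label, start_s = schedule$start_s,
                        end_s = schedule$end_s, target = NA_real_,
                        achieved = NA_real_, stringsAsFactors = FALSE)
    for (i in seq_len(nrow(schedule))) {
      i0 <- floor((schedule$start_s[i] - t0) * frame_rate) + 1L
      i1 <- floor((schedule$end_s[i] - t0) * frame_rate)
      nf <- i1 - i0 + 1L
      tgt <- target_of(schedule$label[i])
      f <- round(tgt * nf)
      if (f < min_freeze_frames) f <- 0L
      if (f > nf) f <- nf
      if (f > 0L) {
        off <- if (nf > f) sample.int(nf - f + 1L, 1L) - 1L else 0L
        idx <- (i0 + off):(i0 + off + f - 1L)
        m[idx] <- stats::runif(f, 0, threshold * 0.5)
      }
      truth$target[i] <- tgt
      truth$achieved[i] <- f / nf
    }
    list(motion = motion_trace(m, frame_rate = frame_rate), truth = truth)
  })
}

# Deterministic per-animal seed stream (Lehmer-style mix, stays < 2^31).
derive_seed <- function(master_seed, index) {
  s <- (as.numeric(master_seed) %% 2147483647)
  as.integer((s * 48271 + as.numeric(index) * 104729) %% 2147483647)
}

#' Generate a synthetic cohort of animals
#'
#' Produces `n_per_group` animals per group, each with its own LFP trace,
#' motion trace and ground truth, under deterministic per-animal seeds
#' derived from `master_seed`. Group-specific configuration deltas (e.g. a
#' low-gamma amplitude gain) are applied on top of the base config.
#'
#' @param n_per_group Animals per group (>= 1).
#' @param group_specs Named list: group label -> list of [sim_config()] field
#'   overrides (a delta, not a full config).
#' @param design A [session_design()].
#' @param master_seed Integer master seed.
#' @param config Base [sim_config()] shared by all groups.
#' @param condition_map Passed to [generate_lfp()].
#' @param freezing_profile Passed to [generate_motion_trace()]; a named list
#'   keyed by group overrides per group.
#' @param frame_rate Motion-trace frame rate (fps).
#' @return A `cohort` list of animal records
#'   `list(animal_id, group, trace, motion, truth, motion_truth)`, with the
#'   schedule attached as attribute `"schedule"`.
#' @export
generate_cohort <- function(n_per_group, group_specs, design, master_seed,
                            config = sim_config(), condition_map = NULL,
                            freezing_profile = 0, frame_rate = 30) {
  n_per_group <- as.integer(n_per_group)
  if (is.na(n_per_group) || n_per_group < 1L) {
    stop("n_per_group must be >= 1", call. = FALSE)
  }
  if (is.null(names(group_specs)) || any(!nzchar(names(group_specs)))) {
    stop("group_specs must be a named list of groups", call. = FALSE)
  }
  known <- names(formals(sim_config))
  for (g in names(group_specs)) {
    bad <- setdiff(names(group_specs[[g]]), known)
    if (length(bad)) {
      stop(sprintf("unknown sim_config fields in group '%s': %s", g,
                   paste(bad, collapse = ", ")), call. = FALSE)
    }
  }
  schedule <- generate_schedule(design)
  animals <- list()
  idx <- 0L
  for (g in names(group_specs)) {
    cfg <- unclass(config)
    for (f in names(group_specs[[g]])) cfg[[f]] <- group_specs[[g]][[f]]
    for (i in seq_len(n_per_group)) {
      idx <- idx + 1L
      cfg_i <- cfg
      if (cfg_i$animal_cv > 0) {
        # lognormal mean-1 per-animal amplitude factors: individual animals
        # differ in absolute oscillation and background power
        sigma <- sqrt(log(1 + cfg_i$animal_cv^2))
        fac <- with_local_seed(derive_seed(master_seed, idx + 200000L),
                               exp(stats::rnorm(2 + length(cfg_i$gamma_bands),
                                                -sigma^2 / 2, sigma)))
        cfg_i$theta_amp <- cfg_i$theta_amp * fac[1]
        cfg_i$aperiodic_sd <- cfg_i$aperiodic_sd * fac[2]
        for (k in seq_along(cfg_i$gamma_bands)) {
          cfg_i$gamma_bands[[k]]$base_amp <-
            cfg_i$gamma_bands[[k]]$base_amp * fac[2 + k]
        }
      }
      cfg_i$seed <- derive_seed(master_seed, idx)
      acfg <- do.call(sim_config, cfg_i[setdiff(names(cfg_i), "seed")])
      acfg$seed <- cfg_i$seed
      lfp <- generate_lfp(acfg, schedule, condition_map = condition_map)
      fp <- if (is.list(freezing_profile) && g %in% names(freezing_profile)) {
        freezing_profile[[g]]
      } else if (is.list(freezing_profile)) 0 else freezing_profile
      mot <- generate_motion_trace(schedule, freezing_profile = fp,
                                   frame_rate = frame_rate,
                                   seed = derive_seed(master_seed,
                                                      idx + 100000L))
      animals[[idx]] <- list(animal_id = sprintf("%s_%02d", g, i), group = g,
                             trace = lfp$trace, truth = lfp$truth,
                             motion = mot$motion, motion_truth = mot$truth)
    }
  }
  structure(animals, schedule = schedule, class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  groups <- table(vapply(x, `[[`, "", "group"))
  cat(sprintf("<cohort> %d animals (%s)\n", length(x),
              paste(sprintf("%s: %d", names(groups), groups),
                    collapse = ", ")))
  invisible(x)
}
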