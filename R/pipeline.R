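# Trial index encoded in a tone_k / iti_k label (NA for baseline etc.).
label_trial <- function(label) {
  ifelse(grepl("^(tone|iti)_[0-9]+$", label),
         as.integer(sub("^[a-z]+_", "", label)), NA_integer_)
}

# Condition class of an interval label.
label_condition <- function(label) {
  ifelse(grepl("^tone_", label), "tone",
         ifelse(grepl("^iti_", label), "iti",
                ifelse(label == "baseline", "baseline", label)))
}

#' Spectral, coupling and freezing measures for a simulated cohort
#'
#' Runs the full analysis chain on every animal: preprocessing (1-120 Hz
#' band-pass, 50 Hz notch, decimation to the analysis rate when needed),
#' per-interval Welch PSDs normalized to the animal's baseline, relative
#' band powers per tone and ITI, optionally theta-gamma modulation indices
#' and the tone/ITI coupling ratio, and freezing percentages per tone.
#'
#' @param cohort A [generate_cohort()] result.
#' @param params [welch_params()] for all PSDs.
#' @param bands Character vector of registry band names to extract.
#' @param normalization `"baseline"`, `"whole_spectrum"` or `"none"`.
#' @param include_pac Compute PAC measures (slower; default FALSE).
#' @param pac_amplitude_band Amplitude band for PAC (default `"low_gamma"`).
#' @param include_freezing Score freezing from the motion traces.
#' @param target_hz Analysis sampling rate (Hz).
#' @param freezing Optional [freezing_params()].
#' @return Tidy `data.frame` (the cohort-result table): columns `animal_id`,
#'   `group`, `condition`, `trial`, `stage`, `measure`, `value`.
#' @export
analyze_cohort <- function(cohort, params = welch_params(),
                           bands = c("theta", "low_gamma", "high_gamma"),
                           normalization = c("baseline", "whole_spectrum",
                                             "none"),
                           include_pac = FALSE,
                           pac_amplitude_band = "low_gamma",
                           include_freezing = FALSE,
                           target_hz = 1000,
                           freezing = freezing_params()) {
  stopifnot(inherits(cohort, "cohort"))
  normalization <- match.arg(normalization)
  schedule <- attr(cohort, "schedule")
  n_trials <- sum(grepl("^tone_", schedule$label))
  rows <- list()
  add <- function(animal, condition, trial, measure, value) {
    stage <- if (is.na(trial)) "all" else
      suppressWarnings(stage_of_trial(trial, n_trials))
    rows[[length(rows) + 1L]] <<- data.frame(
      animal_id = animal$animal_id, group = animal$group,
      condition = condition, trial = trial, stage = stage,
      measure = measure, value = value, stringsAsFactors = FALSE)
  }
  for (animal in cohort) {
    tr <- animal$trace
    if (tr$fs > target_hz) {
      tr <- preprocess_pipeline(tr, target_hz = target_hz)
    } else {
      tr <- preprocess_pipeline(tr, target_hz = NULL)
    }
    base_psd <- psd_by_label(tr, schedule, "baseline", params)
    norm <- function(p) switch(normalization,
      baseline = normalize_to_baseline(p, base_psd),
      whole_spectrum = normalize_whole_spectrum(p),
      none = p)
    for (lab in schedule$label[grepl("^(tone|iti)_", schedule$label)]) {
      p <- norm(psd_by_label(tr, schedule, lab, params))
      trial <- label_trial(lab)
      cond <- label_condition(lab)
      for (b in bands) {
        add(animal, cond, trial, paste0(b, "_power"), band_power(p, b))
      }
    }
    if (include_pac) {
      pac_tone <- pac_by_label(tr, schedule, "tone_*",
                               amplitude_band = pac_amplitude_band)
      pac_iti <- pac_by_label(tr, schedule, "iti_*",
                              amplitude_band = pac_amplitude_band)
      add(animal, "tone", NA_integer_, "mi", pac_tone$mi)
      add(animal, "iti", NA_integer_, "mi", pac_iti$mi)
      add(animal, "tone_iti", NA_integer_, "coupling_ratio",
          coupling_ratio(pac_tone, pac_iti))
    }
    if (include_freezing && !is.null(animal$motion)) {
      fr <- score_freezing(animal$motion, freezing, schedule)
      tone_rows <- fr[grepl("^tone_", fr$label), ]
      for (i in seq_len(nrow(tone_rows))) {
        add(animal, "tone", label_trial(tone_rows$label[i]), "freezing_pct",
            tone_rows$freezing_pct[i])
      }
    }
  }
  do.call(rbind, rows)
}

# Average trial-level values to one value per animal x condition x measure.
animal_means <- function(cohort_result) {
  stats::aggregate(value ~ animal_id + group + condition + measure,
                   data = cohort_result, FUN = mean)
}

default_run_config <- function() {
  list(
    simulate = list(n_per_group = 3, master_seed = 42,
                    design = list(baseline_s = 20, n_tones = 8, tone_s = 30,
                                  iti_s = 5),
                    config = list(sampling_rate_hz = 1000, noise_sd = 5),
                    groups = list(control = list(),
                                  attenuated = list(
                                    group_gain = list(
                                      default = list(low_gamma = 0.7)))),
                    freezing_profile = list(control = 0.3, attenuated = 0.6)),
    welch = list(nperseg = 2048, noverlap = 1024),
    bands = c("theta", "low_gamma", "high_gamma"),
    normalization = "baseline",
    pac = list(enabled = TRUE, amplitude_band = "low_gamma", n_bins = 18),
    behavior = list(threshold = 18, min_freeze_frames = 30, block_size = 5),
    stats = list(alpha = 0.05)
  )
}

# Deep-merge user config over defaults.
merge_config <- function(base, user) {
  for (k in names(user)) {
    base[[k]] <- if (is.list(base[[k]]) && is.list(user[[k]])) {
      merge_config(base[[k]], user[[k]])
    } else {
      user[[k]]
    }
  }
  base
}

#' Run the full analysis pipeline
#'
#' Simulates a cohort, analyzes it (spectra, band powers, coupling,
#' freezing), runs the group statistics and writes tables, figures, a copy
#' of the effective configuration and a checksum manifest into `out_dir`.
#' Deterministic under a fixed seed: running twice with the same
#' configuration reproduces byte-identical numeric tables.
#'
#' @param out_dir Output directory (created if missing).
#' @param config `NULL` for the demo configuration, a nested list, or the
#'   path of a YAML file with the same structure; values override the
#'   defaults of [default_run_config()].
#' @param seed Overrides the configured master seed when non-NULL.
#' @return Invisibly, the manifest `data.frame` (path, md5).
#' @export
run_pipeline <- function(out_dir, config = NULL, seed = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- merge_config(default_run_config(), if (is.null(config)) list()
                      else config)
  if (!is.null(seed)) cfg$simulate$master_seed <- as.integer(seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character()
  say <- function(stage, msg) {
    log_lines <<- c(log_lines, sprintf("[%s] %s", stage, msg))
  }

  say("config", paste("master_seed =", cfg$simulate$master_seed))
  yaml::write_yaml(cfg, file.path(out_dir, "config.yaml"))

  sim <- cfg$simulate
  design <- do.call(session_design, sim$design)
  schedule <- generate_schedule(design)
  write_schedule(schedule, file.path(out_dir, "schedule.csv"))
  base_cfg <- do.call(sim_config, sim$config)
  groups <- lapply(sim$groups, function(g) {
    if (!is.null(g$group_gain)) {
      g$group_gain <- lapply(g$group_gain, unlist)
    }
    g
  })
  say("simulate", sprintf("%d animals/group x %d groups, %d tones",
                          sim$n_per_group, length(groups), design$n_tones))
  cohort <- generate_cohort(sim$n_per_group, groups, design,
                            master_seed = sim$master_seed, config = base_cfg,
                            freezing_profile = sim$freezing_profile)

  say("analyze", "per-interval PSDs, band powers, PAC, freezing")
  wp <- welch_params(nperseg = cfg$welch$nperseg,
                     noverlap = cfg$welch$noverlap)
  res <- analyze_cohort(cohort, params = wp, bands = cfg$bands,
                        normalization = cfg$normalization,
                        include_pac = isTRUE(cfg$pac$enabled),
                        pac_amplitude_band = cfg$pac$amplitude_band,
                        include_freezing = TRUE,
                        freezing = freezing_params(
                          cfg$behavior$threshold,
                          cfg$behavior$min_freeze_frames))
  num_fmt <- function(df) {
    df$value <- formatC(df$value, digits = 12, format = "g")
    df
  }
  utils::write.csv(num_fmt(res), file.path(out_dir, "cohort_results.csv"),
                   row.names = FALSE)
  pm <- animal_means(res)
  utils::write.csv(num_fmt(pm), file.path(out_dir, "animal_means.csv"),
                   row.names = FALSE)

  say("aggregate", "stage-wise condition summaries")
  power_rows <- res[grepl("_power$", res$measure) & !is.na(res$trial), ]
  stage_tabs <- lapply(split(power_rows,
                             power_rows[c("group", "measure")], drop = TRUE),
                       function(d) {
    agg <- aggregate_condition(
      data.frame(trial = d$trial, label = d$condition, value = d$value),
      grouping = "by_stage", n_trials = design$n_tones)
    if (nrow(agg) == 0L) return(NULL)
    cbind(group = d$group[1], measure = d$measure[1], agg)
  })
  stage_tab <- do.call(rbind, stage_tabs)
  if (is.null(stage_tab)) {
    stage_tab <- data.frame(group = character(), measure = character(),
                            label = character(), stage = character(),
                            mean = numeric(), sd = numeric(), n = integer())
  }
  rownames(stage_tab) <- NULL
  utils::write.csv(stage_tab, file.path(out_dir, "stage_summary.csv"),
                   row.names = FALSE)

  say("stats", "gated two-group tests per measure and condition")
  gl <- unique(pm$group)
  tests <- list()
  if (length(gl) == 2L) {
    for (ms in unique(pm$measure)) {
      for (cn in unique(pm$condition[pm$measure == ms])) {
        sub <- pm[pm$measure == ms & pm$condition == cn, ]
        a <- sub$value[sub$group == gl[1]]
        b <- sub$value[sub$group == gl[2]]
        if (length(a) < 3L || length(b) < 3L) next
        tr <- compare_two_groups(a, b, alpha = cfg$stats$alpha)
        tests[[length(tests) + 1L]] <- data.frame(
          measure = ms, condition = cn, test = tr$test_name,
          statistic = tr$statistic, p_value = tr$p_value,
          mean_1 = mean(a), mean_2 = mean(b),
          group_1 = gl[1], group_2 = gl[2], stringsAsFactors = FALSE)
      }
    }
  }
  tests <- if (length(tests)) do.call(rbind, tests) else
    data.frame(measure = character(), condition = character())
  utils::write.csv(tests, file.path(out_dir, "group_tests.csv"),
                   row.names = FALSE)
  jsonlite::write_json(tests, file.path(out_dir, "group_tests.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)

  say("behavior", "freezing by 5-trial block")
  fr <- res[res$measure == "freezing_pct", ]
  blocks <- lapply(split(fr, fr$animal_id), function(d) {
    d <- d[order(d$trial), ]
    bm <- block_means(d$value, cfg$behavior$block_size)
    data.frame(animal_id = d$animal_id[1], group = d$group[1],
               block = seq_along(bm), freezing_pct = unname(bm),
               stringsAsFactors = FALSE)
  })
  blocks <- do.call(rbind, blocks)
  rownames(blocks) <- NULL
  utils::write.csv(blocks, file.path(out_dir, "freezing_blocks.csv"),
                   row.names = FALSE)

  say("figures", "normalized spectra, band powers, stage summaries, freezing")
  plot_pipeline_figures(out_dir, cohort, schedule, wp, cfg, pm, stage_tab,
                        blocks)

  writeLines(log_lines, file.path(out_dir, "run.log"))
  files <- setdiff(list.files(out_dir, recursive = TRUE), "manifest.csv")
  manifest <- data.frame(
    path = files,
    md5 = unname(tools::md5sum(file.path(out_dir, files))),
    stringsAsFactors = FALSE)
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}

# The four figure families of a run (base graphics, one PDF each).
plot_pipeline_figures <- function(out_dir, cohort, schedule, wp, cfg, pm,
                                  stage_tab, blocks) {
  groups <- unique(vapply(cohort, `[[`, "", "group"))
  cols <- stats::setNames(grDevices::hcl.colors(max(2L, length(groups)),
                                                "Dark 2")[seq_along(groups)],
                          groups)
  grDevices::pdf(file.path(out_dir, "fig_psd_by_group.pdf"), width = 7,
                 height = 5)
  on.exit(grDevices::dev.off(), add = TRUE)
  first <- TRUE
  for (animal in cohort) {
    tr <- animal$trace
    if (tr$fs > 1000) tr <- preprocess_pipeline(tr)
    else tr <- preprocess_pipeline(tr, target_hz = NULL)
    p <- normalize_to_baseline(psd_by_label(tr, schedule, "tone_*", wp),
                               psd_by_label(tr, schedule, "baseline", wp))
    sel <- p$freqs >= 1 & p$freqs <= 120
    if (first) {
      plot(p$freqs[sel], p$power[sel], type = "l", log = "y",
           col = cols[animal$group], xlab = "Frequency (Hz)",
           ylab = "Normalized power", main = "Tone-period PSD (baseline-normalized)")
      first <- FALSE
    } else {
      graphics::lines(p$freqs[sel], p$power[sel], col = cols[animal$group])
    }
  }
  graphics::legend("topright", legend = groups, col = cols[groups], lty = 1)

  grDevices::pdf(file.path(out_dir, "fig_band_power.pdf"), width = 7,
                 height = 5)
  on.exit(grDevices::dev.off(), add = TRUE)
  bp <- pm[grepl("_power$", pm$measure) & pm$condition == "tone", ]
  bp$gi <- match(bp$group, groups)
  bp$mi_ <- match(bp$measure, unique(bp$measure))
  plot(bp$mi_ + (bp$gi - 1.5) * 0.2, bp$value, pch = 19,
       col = cols[bp$group], xaxt = "n", xlab = "", ylab = "Relative power",
       main = "Tone-period band power per animal")
  graphics::axis(1, at = seq_along(unique(bp$measure)),
                 labels = sub("_power$", "", unique(bp$measure)))
  graphics::legend("topright", legend = groups, col = cols[groups], pch = 19)

  grDevices::pdf(file.path(out_dir, "fig_stage_summary.pdf"), width = 7,
                 height = 5)
  on.exit(grDevices::dev.off(), add = TRUE)
  st <- if (is.null(stage_tab)) NULL else
    stage_tab[stage_tab$label == "tone", ]
  if (!is.null(st) && nrow(st)) {
    st$stage <- factor(st$stage, levels = c("early", "intermediate", "late"))
    measures <- unique(st$measure)
    plot(NULL, xlim = c(0.5, 3.5), ylim = range(st$mean) * c(0.9, 1.1),
         xaxt = "n", xlab = "Stage", ylab = "Mean relative power",
         main = "Stage-wise tone-period band power")
    graphics::axis(1, at = 1:3, labels = levels(st$stage))
    for (ms in measures) {
      for (g in groups) {
        d <- st[st$measure == ms & st$group == g, ]
        d <- d[order(d$stage), ]
        graphics::lines(as.integer(d$stage), d$mean, col = cols[g],
                        lty = match(ms, measures))
      }
    }
    graphics::legend("topright",
                     legend = c(groups, sub("_power$", "", measures)),
                     col = c(cols[groups], rep("black", length(measures))),
                     lty = c(rep(1, length(groups)), seq_along(measures)))
  } else {
    plot.new()
  }

  grDevices::pdf(file.path(out_dir, "fig_freezing_blocks.pdf"), width = 7,
                 height = 5)
  on.exit(grDevices::dev.off(), add = TRUE)
  if (nrow(blocks)) {
    agg <- stats::aggregate(freezing_pct ~ group + block, data = blocks,
                            FUN = mean)
    plot(NULL, xlim = range(agg$block), ylim = c(0, 100),
         xlab = "5-trial block", ylab = "Freezing (%)",
         main = "Freezing by trial block")
    for (g in groups) {
      d <- agg[agg$group == g, ]
      graphics::lines(d$block, d$freezing_pct, col = cols[g], type = "b",
                      pch = 19)
    }
    graphics::legend("topright", legend = groups, col = cols[groups], lty = 1)
  } else {
    plot.new()
  }
  invisible(NULL)
}
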