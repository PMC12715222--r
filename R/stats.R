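#' Shapiro-Wilk-gated two-group comparison
#'
#' Reproduces the field's standard test-selection logic for unpaired
#' two-group data: both groups are first subjected to a Shapiro-Wilk
#' normality test (alpha = 0.05). If both pass, an F test of variance
#' equality (alpha = 0.05) selects between Student's t test (equal
#' variances) and Welch's t test; otherwise the Mann-Whitney U test is used.
#' All tests are two-tailed. Paired data use the paired t test / Wilcoxon
#' signed-rank test along the same gate.
#'
#' @param a,b Numeric samples, each of length >= 3.
#' @param paired Paired design flag (default FALSE).
#' @param alpha Gate level for the normality and variance tests.
#' @return A `test_report` list: `test_name`, `statistic`, `p_value`, `n`
#'   (per group), `normality` (per-group Shapiro p values), `gate`
#'   (`"parametric"`/`"nonparametric"`), `variance_equal` (NA on the
#'   nonparametric path).
#' @export
compare_two_groups <- function(a, b, paired = FALSE, alpha = 0.05) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 3L || length(b) < 3L) {
    stop("each group needs at least 3 observations", call. = FALSE)
  }
  if (paired && length(a) != length(b)) {
    stop("paired comparison requires equal lengths", call. = FALSE)
  }
  sh <- function(x) {
    if (stats::sd(x) == 0) return(0) # degenerate: route nonparametric
    stats::shapiro.test(x)$p.value
  }
  norm_p <- c(a = sh(a), b = sh(b))
  normal <- all(norm_p > alpha)
  if (normal) {
    var_equal <- if (paired) NA else stats::var.test(a, b)$p.value > alpha
    ht <- if (paired) {
      stats::t.test(a, b, paired = TRUE)
    } else {
      stats::t.test(a, b, var.equal = isTRUE(var_equal))
    }
    name <- if (paired) "paired t test"
            else if (isTRUE(var_equal)) "Student's t test" else "Welch's t test"
    gate <- "parametric"
  } else {
    ht <- suppressWarnings(stats::wilcox.test(a, b, paired = paired,
                                              exact = FALSE, correct = TRUE))
    name <- if (paired) "Wilcoxon signed-rank test" else "Mann-Whitney U test"
    var_equal <- NA
    gate <- "nonparametric"
  }
  structure(list(test_name = name, statistic = unname(ht$statistic),
                 p_value = ht$p.value, n = c(length(a), length(b)),
                 normality = norm_p, gate = gate,
                 variance_equal = var_equal, adjustment = "none"),
            class = "test_report")
}

#' @export
print.test_report <- function(x, ...) {
  cat(sprintf("<test_report> %s: statistic = %.4g, p = %.4g (n = %s)\n",
              x$test_name, x$statistic, x$p_value,
              paste(x$n, collapse = "/")))
  invisible(x)
}

#' Sidak multiple-comparison adjustment
#'
#' Closed form `p_adj = 1 - (1 - p)^m` for `m` comparisons in a family.
#' Monotone in `m` and never below the raw p value.
#'
#' @param p Raw p value(s) in `[0, 1]`.
#' @param m Number of comparisons (>= 1).
#' @return Adjusted p value(s).
#' @export
sidak_adjust <- function(p, m) {
  if (any(p < 0 | p > 1)) stop("p values must lie in [0, 1]", call. = FALSE)
  if (m < 1) stop("m must be >= 1", call. = FALSE)
  1 - (1 - p)^m
}

#' Two-way factorial comparison with Sidak post-hoc contrasts
#'
#' Fits a two-way ANOVA `value ~ groupA * groupB` and reports main effects,
#' the interaction, and Sidak-adjusted pairwise contrasts of factor-A levels
#' within each level of factor B (pooled-MSE t statistics; the adjustment
#' family is the full set of reported contrasts).
#'
#' @param data `data.frame` holding the response and both factors.
#' @param response Name of the response column.
#' @param factor_a Name of the primary factor (e.g. group).
#' @param factor_b Name of the second factor (e.g. stage or condition).
#' @param posthoc Adjustment method; `"sidak"` (default) or `"none"`.
#' @return List with `anova` (data.frame of effects) and `contrasts`
#'   (data.frame with raw and adjusted p values).
#' @export
factorial_compare <- function(data, response = "value", factor_a = "group",
                              factor_b = "stage",
                              posthoc = c("sidak", "none")) {
  posthoc <- match.arg(posthoc)
  stopifnot(is.data.frame(data),
            all(c(response, factor_a, factor_b) %in% names(data)))
  d <- data.frame(value = data[[response]],
                  A = factor(data[[factor_a]]), B = factor(data[[factor_b]]))
  if (nlevels(d$A) < 2L || nlevels(d$B) < 2L) {
    stop("both factors need at least 2 levels", call. = FALSE)
  }
  fit <- stats::aov(value ~ A * B, data = d)
  tab <- summary(fit)[[1]]
  eff <- data.frame(effect = c(factor_a, factor_b,
                               paste0(factor_a, ":", factor_b), "residuals"),
                    df = tab$Df, sum_sq = tab$`Sum Sq`,
                    f_value = tab$`F value`, p_value = tab$`Pr(>F)`,
                    stringsAsFactors = FALSE)
  mse <- tab$`Mean Sq`[4]
  df_res <- tab$Df[4]
  pairs_a <- utils::combn(levels(d$A), 2, simplify = FALSE)
  rows <- list()
  for (bl in levels(d$B)) {
    for (pr in pairs_a) {
      x1 <- d$value[d$A == pr[1] & d$B == bl]
      x2 <- d$value[d$A == pr[2] & d$B == bl]
      if (length(x1) == 0L || length(x2) == 0L) next
      se <- sqrt(mse * (1 / length(x1) + 1 / length(x2)))
      tstat <- (mean(x1) - mean(x2)) / se
      rows[[length(rows) + 1L]] <- data.frame(
        level = bl, contrast = paste(pr, collapse = " - "),
        estimate = mean(x1) - mean(x2), t = tstat,
        p_raw = 2 * stats::pt(-abs(tstat), df_res), stringsAsFactors = FALSE)
    }
  }
  ctr <- do.call(rbind, rows)
  m <- nrow(ctr)
  ctr$p_adj <- if (posthoc == "sidak") sidak_adjust(ctr$p_raw, m)
               else ctr$p_raw
  ctr$m <- m
  list(anova = eff, contrasts = ctr, adjustment = posthoc)
}

#' Linear mixed model likelihood-ratio contract
#'
#' Thin wrapper over `lme4` for repeated-measures group effects: fits
#' `value ~ group + (1 | animal)` by maximum likelihood and compares it to
#' the intercept-only null with a likelihood-ratio test. Estimation is fully
#' delegated to `lme4`.
#'
#' @param data `data.frame` with the response, a group column and an animal
#'   identifier column.
#' @param response,group,animal Column names.
#' @return A `test_report` with the chi-squared LRT statistic.
#' @export
mixed_model_lrt <- function(data, response = "value", group = "group",
                            animal = "animal_id") {
  if (!requireNamespace("lme4", quietly = TRUE)) {
    stop("mixed_model_lrt requires the lme4 package", call. = FALSE)
  }
  d <- data.frame(value = data[[response]], group = factor(data[[group]]),
                  animal = factor(data[[animal]]))
  full <- lme4::lmer(value ~ group + (1 | animal), data = d, REML = FALSE)
  null <- lme4::lmer(value ~ 1 + (1 | animal), data = d, REML = FALSE)
  an <- stats::anova(null, full)
  structure(list(test_name = "linear mixed model LRT (group)",
                 statistic = an$Chisq[2], p_value = an$`Pr(>Chisq)`[2],
                 n = table(d$group), normality = NULL, gate = "mixed",
                 variance_equal = NA, adjustment = "none"),
            class = "test_report")
}

#' Simulation-based effect-recovery report
#'
#' Validates the whole pipeline end to end: simulates `n_reps` independent
#' cohorts in which one group's gamma amplitude is attenuated by `gain` in
#' the target band, runs the spectral analysis, and reports per band and
#' condition (tone/ITI) the fraction of replicates in which (i) the group
#' difference has the correct sign and (ii) the gated two-group test is
#' significant at `alpha`. Bands without a simulated effect calibrate the
#' false-detection rate (which should sit near `alpha`).
#'
#' @param n_reps Number of replicate cohorts (>= 1; >= 50 for stable rates).
#' @param n_per_group Animals per group.
#' @param gain Amplitude gain applied to `effect_band` in the second group
#'   (1 = null simulation).
#' @param effect_band Band receiving the gain (default `"low_gamma"`).
#' @param design Session design (scaled-down sessions keep runtime modest).
#' @param config Base [sim_config()]; the default here simulates at the 1 kHz
#'   analysis rate.
#' @param bands Bands to analyze.
#' @param master_seed Integer seed; replicate r uses a seed derived from it.
#' @param alpha Significance level.
#' @return `data.frame` with columns `band`, `condition`,
#'   `sign_recovery_rate`, `detection_rate`, `n_reps`.
#' @export
power_recovery_report <- function(n_reps = 100L, n_per_group = 5L,
                                  gain = 0.6, effect_band = "low_gamma",
                                  design = session_design(baseline_s = 20,
                                                          n_tones = 8),
                                  config = sim_config(sampling_rate_hz = 1000,
                                                      noise_sd = 5),
                                  bands = c("low_gamma", "high_gamma"),
                                  master_seed = 1L, alpha = 0.05) {
  n_reps <- as.integer(n_reps)
  if (n_reps < 1L) stop("n_reps must be >= 1", call. = FALSE)
  if (n_reps < 50L) {
    warning("fewer than 50 replicates: rates will be unstable",
            call. = FALSE)
  }
  if (config$noise_sd == 0 && config$aperiodic_sd == 0) {
    warning("degenerate noiseless configuration", call. = FALSE)
  }
  gg <- list(default = stats::setNames(gain, effect_band))
  specs <- list(control = list(), attenuated = list(group_gain = gg))
  conds <- c("tone", "iti")
  hit_sign <- hit_test <- array(0L, dim = c(length(bands), length(conds)),
                                dimnames = list(bands, conds))
  for (r in seq_len(n_reps)) {
    co <- generate_cohort(n_per_group, specs, design,
                          master_seed = derive_seed(master_seed, r),
                          config = config)
    res <- analyze_cohort(co, bands = bands)
    per_animal <- stats::aggregate(
      value ~ animal_id + group + condition + measure, data = res, FUN = mean)
    for (b in bands) {
      for (cn in conds) {
        sub <- per_animal[per_animal$condition == cn &
                            per_animal$measure == paste0(b, "_power"), ]
        a <- sub$value[sub$group == "control"]
        att <- sub$value[sub$group == "attenuated"]
        if (mean(att) < mean(a)) {
          hit_sign[b, cn] <- hit_sign[b, cn] + 1L
        }
        rep_ <- compare_two_groups(a, att)
        if (rep_$p_value < alpha) hit_test[b, cn] <- hit_test[b, cn] + 1L
      }
    }
  }
  out <- expand.grid(band = bands, condition = conds,
                     stringsAsFactors = FALSE)
  out$sign_recovery_rate <- mapply(function(b, cn) hit_sign[b, cn] / n_reps,
                                   out$band, out$condition)
  out$detection_rate <- mapply(function(b, cn) hit_test[b, cn] / n_reps,
                               out$band, out$condition)
  out$n_reps <- n_reps
  out
}
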