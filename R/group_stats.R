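# Group-level aggregation and inference: posterior ROI averaging over the
# second-order intermodulation pair, mixed-model likelihood-ratio contrasts,
# the expectation x attention interaction analysis, and a sign-flip
# permutation alternative for small samples.

#' The posterior 17-electrode region of interest
#'
#' All occipital (Oz, O1, O2), parieto-occipital (POz, PO3, PO4, PO7, PO8)
#' and parietal (Pz, P1-P8) electrodes.
#'
#' @return a list with `name` and `labels` (17 electrode names).
#' @export
posterior_roi <- function() {
  list(name = "posterior17",
       labels = c("Oz", "O1", "O2",
                  "POz", "PO3", "PO4", "PO7", "PO8",
                  "Pz", paste0("P", 1:8)))
}

#' Aggregate MSPC results over an ROI and an IM pair
#'
#' Restricts a results table to the ROI channels and averages the values of
#' the two intermodulation frequencies within each remaining grouping cell
#' (channel is kept as a factor so models can nest it).
#'
#' @param results data frame with at least `channel`, `freq`, `value`
#'   columns; any other columns (participant, condition factors, `variant`)
#'   are treated as grouping variables.
#' @param roi list with a `labels` element (default [posterior_roi()]).
#' @param im_freqs numeric vector of the (two) IM frequencies to average.
#' @return data frame with the grouping columns and the averaged `value`.
#' @export
roi_aggregate <- function(results, roi = posterior_roi(), im_freqs) {
  missing_ch <- setdiff(roi$labels, unique(results$channel))
  if (length(missing_ch))
    stop("ROI channels absent from results: ",
         paste(missing_ch, collapse = ", "))
  keep <- results$channel %in% roi$labels &
    vapply(results$freq, function(f) any(abs(im_freqs - f) < 1e-9),
           logical(1))
  d <- results[keep, , drop = FALSE]
  by_cols <- setdiff(names(d), c("value", "freq", "input_freqs", "weights",
                                 "K", "null_mean", "degenerate"))
  agg <- stats::aggregate(d$value, by = d[by_cols], FUN = mean)
  names(agg)[ncol(agg)] <- "value"
  agg
}

#' Likelihood-ratio contrast between nested mixed models
#'
#' Fits both models by maximum likelihood on the same rows and reports
#' `chi2 = 2 * (llik_full - llik_reduced)`, with degrees of freedom equal
#' to the number of dropped fixed-effect parameters.
#'
#' @param table data frame of observations.
#' @param full model formula including random effects (lme4 syntax).
#' @param dropped name of the fixed-effect term to drop for the reduced
#'   model.
#' @return list with `chi2`, `df`, `p`, `singular` (logical: either fit had
#'   a singular random-effects estimate).
#' @export
lrt_contrast <- function(table, full, dropped) {
  ctrl <- lme4::lmerControl(optimizer = "bobyqa",
                            optCtrl = list(maxfun = 100000L))
  fit_full <- suppressMessages(
    lme4::lmer(full, data = table, REML = FALSE, control = ctrl))
  reduced <- stats::update(stats::formula(full),
                           paste(". ~ . -", dropped))
  fit_red <- suppressMessages(
    lme4::lmer(reduced, data = table, REML = FALSE, control = ctrl))
  conv <- function(f) {
    msgs <- f@optinfo$conv$lme4$messages
    is.null(msgs) || !any(grepl("failed to converge", msgs))
  }
  if (!conv(fit_full) || !conv(fit_red))
    stop("mixed-model fit failed to converge; contrast not reported")
  df <- length(lme4::fixef(fit_full)) - length(lme4::fixef(fit_red))
  chi2 <- max(0, 2 * (as.numeric(stats::logLik(fit_full)) -
                        as.numeric(stats::logLik(fit_red))))
  list(chi2 = chi2, df = df,
       p = stats::pchisq(chi2, df, lower.tail = FALSE),
       singular = lme4::isSingular(fit_full) || lme4::isSingular(fit_red))
}

#' Median split of a graded factor
#'
#' Levels at or below the median level index become `"low"`, the rest
#' `"high"` (four ordered levels split `{1,2}` vs `{3,4}`).
#'
#' @param x ordered factor, or numeric grade.
#' @return factor with levels `"low"`, `"high"`.
#' @export
median_split <- function(x) {
  idx <- if (is.factor(x)) as.integer(x) else as.numeric(x)
  med <- stats::median(sort(unique(idx)))
  factor(ifelse(idx <= med, "low", "high"), levels = c("low", "high"))
}

#' Expectation x attention interaction analysis
#'
#' Fits the full interaction mixed model
#' `value ~ expectation * attention + (random)` and tests the interaction
#' by likelihood ratio, then runs the two post-hoc contrasts: the
#' expectation effect within the attended condition, and (after a median
#' split of expectation) the attention effect within the expected
#' condition.  Per-condition expectation slopes are also returned.
#'
#' @param table data frame with numeric/graded `expectation` (>= 3 levels),
#'   two-level `attention`, `participant` and `value` columns.
#' @param random random-effects specification as a string; default
#'   `"(1 | participant)"` (use e.g.
#'   `"(1 | participant) + (1 | participant:channel)"` when channels are
#'   present).
#' @return list with `interaction` (LRT), `posthoc_expectation_attended`,
#'   `posthoc_attention_expected`, and `slopes` (per attention level).
#' @export
interaction_analysis <- function(table, random = "(1 | participant)") {
  if (length(unique(table$attention)) < 2)
    stop("`attention` needs two levels")
  if (length(unique(table$expectation)) < 3)
    stop("graded `expectation` needs at least 3 levels")
  exp_num <- as.numeric(table$expectation)
  table$.expectation <- exp_num
  full <- stats::as.formula(paste(
    "value ~ .expectation * attention +", random))
  inter <- lrt_contrast(table, full, ".expectation:attention")

  att_levels <- sort(unique(as.character(table$attention)))
  attended <- table[as.character(table$attention) == att_levels[1], ]
  ph_exp <- lrt_contrast(
    attended, stats::as.formula(paste("value ~ .expectation +", random)),
    ".expectation")

  table$.exp_bin <- median_split(table$.expectation)
  expected <- table[table$.exp_bin == "high", ]
  ph_att <- lrt_contrast(
    expected, stats::as.formula(paste("value ~ attention +", random)),
    "attention")

  slopes <- vapply(att_levels, function(a) {
    d <- table[as.character(table$attention) == a, ]
    stats::coef(stats::lm(value ~ .expectation, data = d))[2]
  }, numeric(1))
  names(slopes) <- att_levels

  list(interaction = inter,
       posthoc_expectation_attended = ph_exp,
       posthoc_attention_expected = ph_att,
       slopes = slopes)
}

#' Sign-flip permutation contrast
#'
#' Participant-level paired contrast robust to the bounded support of
#' coherence values: the per-participant condition difference is computed,
#' and its mean is compared against the distribution obtained by randomly
#' flipping the signs of the participant differences.
#'
#' @param table data frame with `participant`, `condition` (two levels) and
#'   `value`.
#' @param n_flips number of sign-flip draws (default 10000).
#' @param rng_seed integer seed.
#' @return list with `observed` (mean difference, first condition level
#'   minus second), `p` (two-sided), `n_flips`.
#' @export
perm_contrast <- function(table, n_flips = 10000L, rng_seed = 1L) {
  lev <- sort(unique(as.character(table$condition)))
  if (length(lev) != 2) stop("`condition` must have exactly two levels")
  d <- vapply(split(table, table$participant), function(p)
    mean(p$value[p$condition == lev[1]]) -
      mean(p$value[p$condition == lev[2]]), numeric(1))
  obs <- mean(d)
  set.seed(rng_seed)
  null <- vapply(seq_len(n_flips), function(i)
    mean(d * sample(c(-1, 1), length(d), replace = TRUE)), numeric(1))
  list(observed = obs,
       p = (1 + sum(abs(null) >= abs(obs))) / (n_flips + 1),
       n_flips = n_flips)
}

#' Simulate a two-condition contrast table
#'
#' Gaussian generative model for calibration and power studies of
#' [lrt_contrast()]: `value = mu + b_participant + delta * cond + noise`
#' with `b_participant ~ N(0, sd_participant^2)` and
#' `noise ~ N(0, sd_noise^2)` per observation.
#'
#' @param n_participants,n_channels table dimensions (defaults 15 and 17).
#' @param delta injected condition effect (0 = null).
#' @param mu grand mean (default 0.3).
#' @param sd_participant,sd_noise random-intercept and residual standard
#'   deviations (defaults 0.05).
#' @param rng_seed integer seed.
#' @return data frame with `participant`, `channel`, `condition`, `value`.
#' @export
simulate_contrast_table <- function(n_participants = 15L, n_channels = 17L,
                                    delta = 0, mu = 0.3,
                                    sd_participant = 0.05, sd_noise = 0.05,
                                    rng_seed = 1L) {
  set.seed(rng_seed)
  d <- expand.grid(participant = sprintf("P%02d", seq_len(n_participants)),
                   channel = sprintf("ch%02d", seq_len(n_channels)),
                   condition = c("on", "off"), stringsAsFactors = FALSE)
  b <- stats::rnorm(n_participants, 0, sd_participant)
  names(b) <- sprintf("P%02d", seq_len(n_participants))
  d$value <- mu + b[d$participant] + delta * (d$condition == "on") +
    stats::rnorm(nrow(d), 0, sd_noise)
  d
}

#' Simulate a multi-participant HFT study
#'
#' Generates one synthetic "study": per participant and condition, one
#' trial from the nonlinear cascade, analysed to per-channel MSPC values at
#' the two second-order intermodulation components.  In `effect = "g_low"`
#' studies the first condition doubles the stimulus-locked gain (an
#' expectation-like manipulation); in `effect = "g_high"` studies it
#' doubles the response-level gain under latency jitter (an attention-like
#' manipulation).
#'
#' @param n_participants number of simulated participants (default 15).
#' @param effect `"g_low"` or `"g_high"`: which interaction gain the
#'   condition modulates.
#' @param g_on,g_off gains in the high and low condition (defaults 0.6 and
#'   0.3).
#' @param rng_seed integer seed.
#' @param f1,f2 SWIFT and SSVEP frequencies (defaults 1.2 and 15 Hz).
#' @param duration trial length in seconds (default 30).
#' @param epoch_len analysis epoch in seconds (default 5).
#' @param fs sampling rate (default 250 Hz; all analysis frequencies stay
#'   on exact bins).
#' @param noise_level background-noise RMS passed to [cascade_params()].
#' @return data frame with `participant`, `condition`, `channel`,
#'   `variant`, `value` (ROI-style mean over the two IM frequencies).
#' @export
simulate_study <- function(n_participants = 15L,
                           effect = c("g_low", "g_high"),
                           g_on = 0.6, g_off = 0.3, rng_seed = 1L,
                           f1 = 1.2, f2 = 15, duration = 30,
                           epoch_len = 5, fs = 250, noise_level = 1.2) {
  effect <- match.arg(effect)
  n_cycles <- floor(duration * f1)
  sched <- build_exp1_schedule("FHHFFH", "PV", n_cycles = n_cycles,
                               violation_index = n_cycles - 2L,
                               swift_freq = f1, ssvep_freq = f2)
  ims <- enumerate_ims(f1, f2, 2L)
  rows <- list()
  for (p in seq_len(n_participants)) {
    for (cond in c("on", "off")) {
      g <- if (cond == "on") g_on else g_off
      params <- if (effect == "g_low")
        cascade_params(g_low = g, g_high = 0, fs = fs,
                       epoch_len = epoch_len, noise_level = noise_level)
      else
        cascade_params(g_low = 0, g_high = g, fs = fs,
                       epoch_len = epoch_len, noise_level = noise_level)
      seed <- rng_seed * 100000L + p * 10L + (cond == "on")
      trial <- simulate_trial(sched, params, rng_seed = seed)
      res <- mspc_trial(trial$recording, sched, ims, "both", epoch_len)
      agg <- stats::aggregate(res$value,
                              by = list(channel = res$channel,
                                        variant = res$variant), FUN = mean)
      rows[[length(rows) + 1L]] <- data.frame(
        participant = sprintf("P%02d", p), condition = cond,
        channel = agg$channel, variant = agg$variant, value = agg$x)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Condition contrast of one study, per MSPC variant
#'
#' Likelihood-ratio test of the condition fixed effect with participant and
#' trial random intercepts, run separately on the stimulus-referenced and
#' response-referenced values of a [simulate_study()] table.  The trial
#' intercept matters: channels within a trial share the trial's latency
#' jitter realisation, so they are not independent replicates of the
#' condition effect.
#'
#' @param study data frame from [simulate_study()].
#' @return data frame with `variant`, `chi2`, `df`, `p`, `delta` (mean
#'   condition difference, on minus off).
#' @export
study_contrasts <- function(study) {
  study$trial_id <- interaction(study$participant, study$condition)
  do.call(rbind, lapply(split(study, study$variant), function(d) {
    lrt <- lrt_contrast(
      d, value ~ condition + (1 | participant) + (1 | trial_id),
      "condition")
    data.frame(variant = d$variant[1], chi2 = lrt$chi2, df = lrt$df,
               p = lrt$p,
               delta = mean(d$value[d$condition == "on"]) -
                 mean(d$value[d$condition == "off"]))
  }))
}
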