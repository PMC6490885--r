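# Preprocessing: resampling, high-pass, average reference, noisy-sample /
# cycle / channel flagging, channel interpolation and exclusion rules.

#' Standardize a recording
#'
#' Resamples to 500 Hz, applies a zero-phase high-pass at 0.3 Hz and
#' converts to average reference.  The default high-pass is a spectral
#' (frequency-domain) filter that zeroes all components strictly below the
#' cutoff: it is exactly zero-phase and exactly idempotent, which keeps
#' repeated standardization a no-op.  A 4th-order Butterworth applied
#' forward-backward is available for real recordings via
#' `method = "butter"`.  An optional narrow spectral notch around 50 and
#' 100 Hz is provided for line-noise contaminated data.
#'
#' @param recording an [eeg_recording()] with `fs >= 500`.
#' @param hp_cutoff high-pass cutoff in Hz (default 0.3).
#' @param method `"fft"` (default) or `"butter"`.
#' @param notch_50hz if `TRUE`, zero 49-51 Hz and 99-101 Hz bands
#'   (spectral notch).  Default `FALSE`: synthetic data carries no mains
#'   component.
#' @return the standardized recording (`fs == 500`, channel means of each
#'   sample equal to zero).
#' @export
standardize <- function(recording, hp_cutoff = 0.3,
                        method = c("fft", "butter"), notch_50hz = FALSE) {
  stopifnot(inherits(recording, "eeg_recording"))
  method <- match.arg(method)
  fs <- recording$fs
  if (fs < 500)
    stop(sprintf("fs = %g Hz: upsampling to 500 Hz is refused", fs))
  x <- recording$data
  if (fs > 500) {
    g <- gcd_int(round(fs), 500L)
    p <- 500L / g; q <- round(fs) / g
    x <- t(apply(x, 1, function(ch) signal::resample(ch, p, q)))
    recording$events$sample <- pmax(1L,
      as.integer(round((recording$events$sample - 1L) * p / q)) + 1L)
    recording$fs <- 500
    fs <- 500
  }
  n <- ncol(x)
  if (method == "fft") {
    f <- seq(0, n - 1) / n * fs
    f <- pmin(f, fs - f)
    mask <- as.numeric(f >= hp_cutoff)
    if (notch_50hz)
      mask[(f >= 49 & f <= 51) | (f >= 99 & f <= 101)] <- 0
    for (ch in seq_len(nrow(x)))
      x[ch, ] <- Re(stats::fft(stats::fft(x[ch, ]) * mask,
                               inverse = TRUE)) / n
  } else {
    bf <- signal::butter(4, hp_cutoff / (fs / 2), type = "high")
    for (ch in seq_len(nrow(x)))
      x[ch, ] <- signal::filtfilt(bf, x[ch, ])
  }
  x <- sweep(x, 2, colMeans(x))   # average reference
  recording$data <- x
  recording
}

gcd_int <- function(a, b) if (b == 0L) a else gcd_int(b, a %% b)

#' Flag noisy samples, cycles and channels
#'
#' A sample is noisy if (per channel) it exceeds +80 or falls below -80
#' microvolts, differs from the previous sample by more than 30 microvolts,
#' or lies more than 5 standard deviations from that channel's whole-trial
#' mean.  A cycle is noisy if more than 2% of its samples are noisy; a
#' channel is bad if it is noisy in more than 10% of cycles.
#'
#' @param recording an [eeg_recording()].
#' @param cycle_grid integer vector of cycle-onset samples (the last cycle
#'   ends at the final sample), or a two-column matrix/data frame of
#'   `start`, `end` samples.
#' @param amp_thresh,jump_thresh,sd_thresh the three criteria's thresholds
#'   (defaults 80, 30 and 5).
#' @return a `noise_report`: list with `noisy_sample_mask` (channels x
#'   samples logical), `noisy_cycles` (data frame: channel, cycle, frac,
#'   noisy), `channel_noisy_frac`, and `bad_channels` (labels).
#' @export
flag_noise <- function(recording, cycle_grid, amp_thresh = 80,
                       jump_thresh = 30, sd_thresh = 5) {
  stopifnot(inherits(recording, "eeg_recording"))
  x <- recording$data
  n <- ncol(x)
  if (is.null(dim(cycle_grid))) {
    if (!length(cycle_grid)) stop("`cycle_grid` is empty")
    starts <- as.integer(cycle_grid)
    ends <- c(starts[-1] - 1L, n)
  } else {
    cycle_grid <- as.matrix(cycle_grid)
    if (!nrow(cycle_grid)) stop("`cycle_grid` is empty")
    starts <- as.integer(cycle_grid[, 1]); ends <- as.integer(cycle_grid[, 2])
  }
  if (any(starts < 1) || any(ends > n) || any(ends < starts))
    stop("`cycle_grid` does not partition the trial")

  mask <- matrix(FALSE, nrow(x), n)
  for (ch in seq_len(nrow(x))) {
    v <- x[ch, ]
    mask[ch, ] <- (v > amp_thresh | v < -amp_thresh) |
      c(FALSE, abs(diff(v)) > jump_thresh) |
      abs(v - mean(v)) > sd_thresh * stats::sd(v)
  }
  nc <- length(starts)
  frac <- matrix(0, nrow(x), nc)
  for (k in seq_len(nc))
    frac[, k] <- rowMeans(mask[, starts[k]:ends[k], drop = FALSE])
  noisy_cycles <- data.frame(
    channel = rep(recording$channel_labels, nc),
    cycle = rep(seq_len(nc), each = nrow(x)),
    frac = as.vector(frac),
    noisy = as.vector(frac) > 0.02)
  channel_noisy_frac <- rowMeans(frac > 0.02)
  names(channel_noisy_frac) <- recording$channel_labels
  structure(list(noisy_sample_mask = mask, noisy_cycles = noisy_cycles,
                 channel_noisy_frac = channel_noisy_frac,
                 bad_channels =
                   recording$channel_labels[channel_noisy_frac > 0.10]),
            class = "noise_report")
}

#' Replace bad channels by inverse-distance weighted neighbours
#'
#' Each bad channel is replaced by the inverse-distance-weighted mean of
#' its `k` nearest good channels on the unit sphere.
#'
#' @param recording an [eeg_recording()] with channel positions.
#' @param bad character vector of bad channel labels.
#' @param k number of good neighbours to average (default 4).
#' @return the recording with bad channels replaced.
#' @export
interpolate_bad_channels <- function(recording, bad, k = 4L) {
  stopifnot(inherits(recording, "eeg_recording"))
  if (!length(bad)) return(recording)
  if (is.null(recording$channel_positions))
    stop("channel positions are required for interpolation")
  labels <- recording$channel_labels
  if (!all(bad %in% labels))
    stop("unknown channel(s): ", paste(setdiff(bad, labels), collapse = ", "))
  if (length(bad) > length(labels) / 2)
    stop("more than 50% of channels are bad; refusing to interpolate")
  good <- setdiff(labels, bad)
  pos <- recording$channel_positions
  for (b in bad) {
    d <- sqrt(colSums((t(pos[match(good, labels), , drop = FALSE]) -
                         pos[match(b, labels), ])^2))
    nn <- order(d)[seq_len(min(k, length(good)))]
    w <- 1 / pmax(d[nn], 1e-12)
    w <- w / sum(w)
    recording$data[match(b, labels), ] <-
      as.vector(w %*% recording$data[match(good[nn], labels), , drop = FALSE])
  }
  recording
}

#' Apply trial- and participant-level exclusion rules
#'
#' Five rules: a trial is bad if more than 10% of its channels are noisy; a
#' participant is excluded if more than 20% of their trials are bad; an
#' Experiment-1 response is invalid if the space bar was never pressed or
#' was pressed before the target appeared; an Experiment-2 count is invalid
#' if it differs from the true count by more than 3; a participant is
#' excluded if more than 30% of their responses are invalid.
#'
#' @param trials data frame with columns `participant`, `trial`,
#'   `n_channels`, `n_bad_channels`, and either (`pressed`, `press_time`,
#'   `target_time`) for Experiment 1 or (`reported`, `true_count`) for
#'   Experiment 2.
#' @param experiment `"exp1"` or `"exp2"`.
#' @return list with `trials` (input plus logical `bad_trial`,
#'   `invalid_response`) and `participants` (data frame: participant,
#'   frac_bad_trials, frac_invalid, excluded_eeg, excluded_behaviour,
#'   excluded).
#' @export
apply_exclusions <- function(trials, experiment = c("exp1", "exp2")) {
  experiment <- match.arg(experiment)
  stopifnot(all(c("participant", "trial", "n_channels", "n_bad_channels")
                %in% names(trials)))
  trials$bad_trial <- trials$n_bad_channels / trials$n_channels > 0.10
  trials$invalid_response <- if (experiment == "exp1") {
    !trials$pressed | (trials$press_time < trials$target_time)
  } else {
    abs(trials$reported - trials$true_count) > 3
  }
  agg <- do.call(rbind, lapply(split(trials, trials$participant), function(d)
    data.frame(participant = d$participant[1],
               frac_bad_trials = mean(d$bad_trial),
               frac_invalid = mean(d$invalid_response))))
  rownames(agg) <- NULL
  agg$excluded_eeg <- agg$frac_bad_trials > 0.20
  agg$excluded_behaviour <- agg$frac_invalid > 0.30
  agg$excluded <- agg$excluded_eeg | agg$excluded_behaviour
  list(trials = trials, participants = agg)
}
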