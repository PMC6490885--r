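# Synthetic EEG with the statistical structure the coherence analysis
# assumes: tagged fundamentals with harmonics, intermodulation components
# whose phases are locked either to the stimulus or to latency-jittered
# neural responses, 1/f background noise, and injectable artifacts.
#
# Mechanism.  The SWIFT drive s1 and SSVEP drive s2 are cosines locked to
# the stimulus phase references.  A "low-level" multiplicative interaction
# g_low * s1(t - tau) * s2(t - tau) uses a fixed latency tau, so its
# intermodulation phase is constant relative to the stimulus.  The
# "response-level" signals r1, r2 are the drives delayed by tau + delta_e,
# where delta_e is resampled once per analysis-epoch-length block; the
# "high-level" interaction g_high * r1 * r2 therefore jitters with the
# responses.  The measured fundamentals are emitted from the response level,
# so response-referenced coherence sees the jittered phases.  With zero
# jitter the two coherence variants are provably identical (constant delays
# add constant phase offsets, to which the statistic is invariant); with
# jitter, stimulus-referenced coherence survives only for the low-level
# interaction and response-referenced coherence only for the high-level one.

#' Parameters of the synthetic nonlinear cascade
#'
#' @param amp_f1,amp_f2 amplitudes (microvolts) of the SWIFT-envelope and
#'   SSVEP fundamental drives.
#' @param n_harmonics number of SWIFT harmonics (the SWIFT response is
#'   non-sinusoidal in real EEG; default 2).
#' @param harmonic_decay amplitude fraction per harmonic order.
#' @param g_low,g_high interaction gains (microvolts) of the
#'   stimulus-locked and response-level multiplicative interactions.
#' @param tau_low fixed response latency in seconds.
#' @param tau_jitter_sd standard deviation (seconds) of the per-epoch
#'   response-latency jitter.
#' @param noise_alpha exponent of the 1/f^alpha background noise.
#' @param noise_level RMS amplitude (microvolts) of the background noise per
#'   channel.  The default 1.2 gives the fundamental drives an amplitude
#'   SNR of about 5 in a 10-second epoch spectrum at the default gains.
#' @param channel_gains channels x 4 matrix of per-channel gains for the
#'   sources (columns `fund_swift`, `fund_ssvep`, `im_low`, `im_high`);
#'   rownames are used as channel labels.  Default: 4 posterior channels.
#' @param fs sampling rate in Hz (default 500).
#' @param epoch_len analysis-epoch length in seconds; latency jitter is
#'   block-constant over consecutive windows of this length (default 10).
#' @return a `cascade_params` list.
#' @export
cascade_params <- function(amp_f1 = 1, amp_f2 = 1, n_harmonics = 2L,
                           harmonic_decay = 0.5, g_low = 0.5, g_high = 0,
                           tau_low = 0.1, tau_jitter_sd = 0.08,
                           noise_alpha = 1, noise_level = 1.2,
                           channel_gains = NULL, fs = 500, epoch_len = 10) {
  if (is.null(channel_gains)) {
    channel_gains <- matrix(
      c(1.0, 1.0, 1.0, 1.0,
        0.9, 0.8, 0.9, 0.8,
        0.8, 0.9, 0.8, 0.9,
        0.7, 0.7, 0.7, 0.7),
      nrow = 4, byrow = TRUE,
      dimnames = list(c("Oz", "O1", "O2", "POz"),
                      c("fund_swift", "fund_ssvep", "im_low", "im_high")))
  }
  p <- list(amp_f1 = amp_f1, amp_f2 = amp_f2, n_harmonics = n_harmonics,
            harmonic_decay = harmonic_decay, g_low = g_low, g_high = g_high,
            tau_low = tau_low, tau_jitter_sd = tau_jitter_sd,
            noise_alpha = noise_alpha, noise_level = noise_level,
            channel_gains = channel_gains, fs = fs, epoch_len = epoch_len)
  if (any(unlist(p[c("amp_f1", "amp_f2", "g_low", "g_high")]) < 0) ||
      any(channel_gains < 0))
    stop("amplitudes and gains must be non-negative")
  if (tau_jitter_sd < 0) stop("`tau_jitter_sd` must be >= 0")
  if (noise_level < 0) stop("`noise_level` must be >= 0")
  structure(p, class = "cascade_params")
}

#' 1/f^alpha Gaussian noise
#'
#' Spectrally shaped white noise: the Fourier coefficients of a white
#' Gaussian series are scaled by `f^(-alpha/2)` (DC removed) and the series
#' is rescaled to the requested RMS.  Uses the current RNG state.
#'
#' @param n number of samples.
#' @param fs sampling rate in Hz.
#' @param alpha spectral exponent (power falls as `1/f^alpha`).
#' @param rms target root-mean-square amplitude.
#' @return numeric vector of length `n`.
#' @export
one_over_f_noise <- function(n, fs, alpha = 1, rms = 1) {
  if (rms == 0) return(numeric(n))
  x <- stats::rnorm(n)
  X <- stats::fft(x)
  f <- seq(0, n - 1) / n * fs
  f <- pmin(f, fs - f)                     # two-sided frequency magnitude
  scale <- c(0, f[-1]^(-alpha / 2))        # drop DC
  y <- Re(stats::fft(X * scale, inverse = TRUE)) / n
  y / stats::sd(y) * rms
}

# piecewise-constant per-block delay vector for times t
block_delays <- function(t, epoch_len, tau, jitter_sd) {
  block <- floor(t / epoch_len)
  ids <- sort(unique(block))
  delta <- stats::rnorm(length(ids), 0, jitter_sd)
  tau + delta[match(block, ids)]
}

# SWIFT drive with harmonics, evaluated with a (possibly vector) delay
swift_drive <- function(t, delay, freq, amp, n_harmonics, decay, t_peak0) {
  s <- 0
  for (h in seq_len(n_harmonics))
    s <- s + amp * decay^(h - 1) *
      cos(2 * pi * h * freq * (t - delay - t_peak0))
  s
}

#' Simulate one synthetic HFT trial
#'
#' Generates a multichannel recording in which each channel is a gain-
#' weighted sum of four sources -- the response-level SWIFT and SSVEP
#' fundamentals, the stimulus-locked interaction and the latency-jittered
#' response-level interaction -- plus independent 1/f noise.  The ground
#' truth of which interaction dominates each channel is returned alongside.
#'
#' @param schedule a `trial_schedule` (its first SWIFT stream and the SSVEP
#'   frequency drive the cascade; dual-stream schedules add one drive and
#'   one interaction per stream).
#' @param params a [cascade_params()] object.
#' @param rng_seed integer seed.
#' @return a `synthetic_dataset`: list with `recording` ([eeg_recording()]),
#'   `schedule`, and `truth` (per-channel dominant mechanism and injected
#'   artifact positions, empty here).
#' @export
simulate_trial <- function(schedule, params, rng_seed = 1L) {
  stopifnot(inherits(schedule, "trial_schedule"),
            inherits(params, "cascade_params"))
  set.seed(rng_seed)
  fs <- params$fs
  f2 <- schedule$ssvep_freq
  f1s <- swift_freqs(schedule)
  fmax <- max(params$n_harmonics * max(f1s), 2 * f2, f2 + max(f1s))
  if (fs <= 2 * fmax)
    stop(sprintf("fs = %g Hz too low for a maximum frequency of %g Hz",
                 fs, fmax))
  n <- round(schedule$duration * fs)
  t <- (seq_len(n) - 1) / fs

  peak0 <- vapply(seq_along(f1s), function(j)
    schedule$streams[[j]]$onset[1] + schedule$peak_frac / f1s[j], numeric(1))

  d_resp <- block_delays(t, params$epoch_len, params$tau_low,
                         params$tau_jitter_sd)

  # stimulus-locked (constant-delay) copies
  s2_low <- params$amp_f2 * cos(2 * pi * f2 * (t - params$tau_low))
  s1_low <- lapply(seq_along(f1s), function(j)
    swift_drive(t, params$tau_low, f1s[j], params$amp_f1,
                params$n_harmonics, params$harmonic_decay, peak0[j]))
  # response-level (jittered) copies
  r2 <- params$amp_f2 * cos(2 * pi * f2 * (t - d_resp))
  r1 <- lapply(seq_along(f1s), function(j)
    swift_drive(t, d_resp, f1s[j], params$amp_f1,
                params$n_harmonics, params$harmonic_decay, peak0[j]))

  fund_swift <- Reduce(`+`, r1)
  fund_ssvep <- r2
  im_low <- params$g_low *
    Reduce(`+`, lapply(s1_low, function(s) s * s2_low)) /
    (params$amp_f1 * params$amp_f2)
  im_high <- params$g_high *
    Reduce(`+`, lapply(r1, function(s) s * r2)) /
    (params$amp_f1 * params$amp_f2)

  S <- rbind(fund_swift, fund_ssvep, im_low, im_high)
  G <- params$channel_gains
  data <- G %*% S
  if (params$noise_level > 0)
    for (ch in seq_len(nrow(data)))
      data[ch, ] <- data[ch, ] +
        one_over_f_noise(n, fs, params$noise_alpha, params$noise_level)

  labels <- rownames(G)
  if (is.null(labels)) labels <- paste0("ch", seq_len(nrow(G)))
  mech <- rep("none", nrow(G))
  mech[G[, "im_low"] * params$g_low > G[, "im_high"] * params$g_high &
         params$g_low > 0] <- "stim_locked"
  mech[G[, "im_high"] * params$g_high >= G[, "im_low"] * params$g_low &
         params$g_high > 0] <- "response_locked"

  structure(list(
    recording = eeg_recording(data, fs, labels,
                              events = data.frame(sample = 1L,
                                                  label = "trial_start")),
    schedule = schedule,
    truth = list(mechanism = stats::setNames(mech, labels),
                 artifacts = data.frame(channel = integer(0),
                                        sample = integer(0),
                                        kind = character(0)))),
    class = "synthetic_dataset")
}

#' Inject canonical artifacts into a recording
#'
#' The three kinds exercise the three noisy-sample criteria: `spike80` sets
#' one sample to +85 microvolts (absolute-amplitude rule), `jump30` adds a
#' 35-microvolt step between two adjacent samples (sudden-fluctuation
#' rule), and `drift` adds a slow ramp that ends 6 trial-SDs away from the
#' mean (the +/- 5 SD rule).
#'
#' @param recording an [eeg_recording()].
#' @param spec data frame with columns `channel` (index or label), `sample`
#'   and `kind` in `{"spike80", "jump30", "drift"}`.
#' @return the modified recording.
#' @export
inject_artifacts <- function(recording, spec) {
  stopifnot(inherits(recording, "eeg_recording"))
  if (nrow(spec) == 0) return(recording)
  n <- ncol(recording$data)
  for (i in seq_len(nrow(spec))) {
    ch <- spec$channel[i]
    if (is.character(ch)) ch <- match(ch, recording$channel_labels)
    s <- spec$sample[i]
    if (is.na(ch) || ch < 1 || ch > nrow(recording$data) ||
        s < 1 || s > n)
      stop(sprintf("artifact %d: channel/sample out of range", i))
    x <- recording$data[ch, ]
    recording$data[ch, ] <- switch(
      spec$kind[i],
      spike80 = { x[s] <- 85; x },
      jump30 = { x[s:n] <- x[s:n] + 35; x },
      drift = {
        ramp <- seq(0, 6 * stats::sd(x), length.out = n - s + 1)
        x[s:n] <- x[s:n] + ramp
        x
      },
      stop(sprintf("unknown artifact kind '%s'", spec$kind[i])))
  }
  recording
}
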