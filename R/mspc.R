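# Multispectral phase coherence (MSPC): the across-epoch consistency of the
# difference between an intermodulation component's phase and the weighted
# sum of its input-frequency phases,
#
#   Psi = | (1/K) * sum_k exp(i * (sum_r n_r * phi_I,k(f_r) - phi_O,k(f_S))) |
#
# with f_S = sum_r n_r * f_r.  The two variants differ only in where the
# input phases come from: the stimulus modulation itself (stimulus-
# referenced) or the same channel's EEG response at the fundamental
# frequencies (response-referenced).  Values lie in [0, 1]; the statistic
# is invariant to constant phase offsets, so constant (even unequal)
# processing delays leave it unchanged.

#' Specification of one MSPC computation
#'
#' @param input_freqs numeric vector of input frequencies `f_r` in Hz.
#' @param weights integer vector `n_r` (non-zero), same length.
#' @param output_freq output frequency; default `sum(weights * input_freqs)`
#'   and must equal it within `1e-9`.
#' @return an `mspc_spec` list.
#' @export
mspc_spec <- function(input_freqs, weights,
                      output_freq = sum(weights * input_freqs)) {
  if (length(input_freqs) != length(weights))
    stop("`input_freqs` and `weights` must have equal length")
  if (any(weights == 0) || any(weights != round(weights)))
    stop("`weights` must be non-zero integers")
  if (abs(output_freq - sum(weights * input_freqs)) > 1e-9)
    stop("`output_freq` must equal sum(weights * input_freqs)")
  structure(list(input_freqs = input_freqs, weights = as.integer(weights),
                 output_freq = output_freq),
            class = "mspc_spec")
}

#' Multispectral phase coherence of explicit phases
#'
#' @param input_phases `K x R` matrix: per-epoch phases of the `R` input
#'   frequencies (radians).  A vector is treated as `K x 1`.
#' @param output_phases length-`K` vector of output-component phases.
#' @param weights integer vector `n_r` of length `R`.
#' @return coherence value in `[0, 1]`.  `K = 1` degenerately gives 1.
#' @export
mspc <- function(input_phases, output_phases, weights) {
  if (is.null(dim(input_phases))) input_phases <- cbind(input_phases)
  K <- nrow(input_phases)
  if (K == 0) stop("no epochs")
  if (length(output_phases) != K)
    stop("input and output epoch counts differ")
  if (ncol(input_phases) != length(weights))
    stop("phase vector length must match `weights`")
  if (anyNA(input_phases) || anyNA(output_phases))
    stop("phases contain missing values")
  resid <- as.vector(input_phases %*% weights) - output_phases
  Mod(mean(exp(1i * resid)))
}

#' Phase-locking value
#'
#' Coherence of a single per-epoch phase difference, the classical
#' comparator to MSPC: `|mean(exp(i * dphi))|`.
#'
#' @param dphi vector of per-epoch phase differences in radians.
#' @return value in `[0, 1]`.
#' @export
plv <- function(dphi) {
  if (!length(dphi)) stop("no epochs")
  if (anyNA(dphi)) stop("phases contain missing values")
  Mod(mean(exp(1i * dphi)))
}

# per-epoch FFT phases: returns epochs x channels x freqs array
epoch_phases <- function(data, fs, epochs, epoch_len, freqs) {
  ns <- round(epoch_len * fs)
  out <- array(NA_real_, c(nrow(epochs), nrow(data), length(freqs)))
  for (e in seq_len(nrow(epochs))) {
    idx <- epochs$start_sample[e] + seq_len(ns) - 1L
    for (ch in seq_len(nrow(data)))
      out[e, ch, ] <- fft_coeffs(data[ch, idx], fs, freqs)$phase
  }
  out
}

#' Per-channel MSPC of a trial
#'
#' Computes stimulus-referenced and/or response-referenced MSPC for a set
#' of intermodulation components, individually for every channel.  Each
#' epoch's FFT phases are referenced to the epoch's own start; stimulus
#' phases are evaluated at the same start times, which makes the two
#' references comparable.
#'
#' @param recording an [eeg_recording()].
#' @param schedule the trial's `trial_schedule` (phase references and
#'   fundamental frequencies).
#' @param specs an `mspc_spec`, a list of them, or a data frame from
#'   [enumerate_ims()] (weights applied to `(f1, f2)` = first SWIFT
#'   frequency and the SSVEP frequency).
#' @param variant `"stim"`, `"res"` or `"both"`.
#' @param epoch_len epoch length in seconds.
#' @param step epoch step in seconds (default 1).
#' @return data frame with one row per channel x component x variant:
#'   `channel`, `input_freqs`, `weights`, `freq`, `variant`, `value`, `K`,
#'   `null_mean` (the closed-form Rayleigh expectation
#'   `sqrt(pi)/(2*sqrt(K))`), and `degenerate` (`K == 1`).
#' @export
mspc_trial <- function(recording, schedule, specs,
                       variant = c("both", "stim", "res"),
                       epoch_len, step = 1) {
  stopifnot(inherits(recording, "eeg_recording"),
            inherits(schedule, "trial_schedule"))
  variant <- match.arg(variant)
  variants <- if (variant == "both") c("stim", "res") else variant
  if (inherits(specs, "mspc_spec")) specs <- list(specs)
  if (is.data.frame(specs)) {
    f1 <- swift_freqs(schedule)[1]
    f2 <- schedule$ssvep_freq
    specs <- lapply(seq_len(nrow(specs)), function(i)
      mspc_spec(c(f1, f2), c(specs$n1[i], specs$n2[i])))
  }

  all_freqs <- sort(unique(unlist(lapply(specs, function(s)
    c(s$input_freqs, s$output_freq)))))
  epochs <- epoch_for_mspc(ncol(recording$data), recording$fs, schedule,
                           epoch_len, step, check_freqs = all_freqs)
  ph <- epoch_phases(recording$data, recording$fs, epochs, epoch_len,
                     all_freqs)
  K <- nrow(epochs)
  fidx <- function(f) which(abs(all_freqs - f) < 1e-9)[1]

  rows <- list()
  for (s in specs) {
    out_i <- fidx(s$output_freq)
    in_i <- vapply(s$input_freqs, fidx, integer(1))
    stim_in <- NULL
    if ("stim" %in% variants) {
      stim_in <- vapply(s$input_freqs, function(f)
        stimulus_phase(schedule, f, epochs$start_time), numeric(K))
      if (is.null(dim(stim_in))) stim_in <- rbind(stim_in)
    }
    for (ch in seq_len(nrow(recording$data))) {
      out_ph <- ph[, ch, out_i]
      for (v in variants) {
        in_ph <- if (v == "stim") stim_in else
          matrix(ph[, ch, in_i], nrow = K)
        rows[[length(rows) + 1L]] <- data.frame(
          channel = recording$channel_labels[ch],
          input_freqs = paste(s$input_freqs, collapse = ","),
          weights = paste(s$weights, collapse = ","),
          freq = s$output_freq,
          variant = v,
          value = mspc(in_ph, out_ph, s$weights),
          K = K,
          null_mean = sqrt(pi) / (2 * sqrt(K)),
          degenerate = K == 1L)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Stimulus-referenced MSPC of a trial
#'
#' Input phases are taken from the stimulus modulations (contrast cosine
#' and SWIFT cycle phase) at each epoch's start; the output phase is the
#' channel's FFT phase at the component frequency.
#'
#' @inheritParams mspc_trial
#' @return as [mspc_trial()], `variant == "stim"` rows only.
#' @export
mspc_stim <- function(recording, schedule, specs, epoch_len, step = 1) {
  for (s in if (inherits(specs, "mspc_spec")) list(specs) else
         if (is.data.frame(specs)) list() else specs)
    for (f in s$input_freqs)
      stimulus_phase(schedule, f, 0)   # errors early if not tagged
  mspc_trial(recording, schedule, specs, "stim", epoch_len, step)
}

#' Response-referenced MSPC of a trial
#'
#' Input phases are the same channel's FFT phases at the fundamental
#' frequencies, epoch by epoch.
#'
#' @inheritParams mspc_trial
#' @return as [mspc_trial()], `variant == "res"` rows only.
#' @export
mspc_res <- function(recording, schedule, specs, epoch_len, step = 1) {
  mspc_trial(recording, schedule, specs, "res", epoch_len, step)
}

#' Null calibration of the coherence statistic
#'
#' Under independence of input and output phases the statistic follows the
#' resultant length of a K-step uniform random walk, with expectation
#' approximately `sqrt(pi) / (2 * sqrt(K))`.  Given observed phases, the
#' null is built by shuffling the epoch pairing between input-phase vectors
#' and output phases; without them, by drawing uniform phases.
#'
#' @param K epoch count (>= 2).
#' @param n_perm number of permutations / draws (default 1000; fewer than
#'   100 sets `warn_small`).
#' @param rng_seed integer seed.
#' @param input_phases,output_phases,weights optional observed phases as in
#'   [mspc()]; when supplied the null preserves their marginal structure.
#' @return list with `null_mean`, `threshold_95`, `rayleigh` (closed form),
#'   `n_perm`, `warn_small`.
#' @export
null_calibrate <- function(K, n_perm = 1000L, rng_seed = 1L,
                           input_phases = NULL, output_phases = NULL,
                           weights = NULL) {
  if (K < 2) stop("`K` must be >= 2")
  set.seed(rng_seed)
  vals <- if (is.null(input_phases)) {
    vapply(seq_len(n_perm), function(i)
      Mod(mean(exp(1i * stats::runif(K, -pi, pi)))), numeric(1))
  } else {
    if (is.null(dim(input_phases))) input_phases <- cbind(input_phases)
    vapply(seq_len(n_perm), function(i)
      mspc(input_phases, sample(output_phases), weights), numeric(1))
  }
  list(null_mean = mean(vals),
       threshold_95 = stats::quantile(vals, 0.95, names = FALSE),
       rayleigh = sqrt(pi) / (2 * sqrt(K)),
       n_perm = n_perm, warn_small = n_perm < 100L)
}
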