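# Spectral bookkeeping: intermodulation enumeration, epoching for the
# coherence analysis, trial FFT windows, exact-bin Fourier coefficients and
# neighbour-based amplitude SNR.

#' Enumerate intermodulation components
#'
#' All components `n1*f1 + n2*f2` with non-zero integer weights, order
#' `|n1| + |n2|` between 2 and `max_order` and positive frequency.
#' Components colliding in frequency (within `tol`) are deduplicated,
#' keeping the lowest order; collisions are reported in the `"collisions"`
#' attribute rather than silently dropped.
#'
#' @param f1,f2 fundamental frequencies in Hz (`f1 != f2`, both positive).
#' @param max_order maximum order `|n1| + |n2|` (default 2).
#' @param tol frequency tolerance for collision detection.
#' @return data frame with columns `n1`, `n2`, `freq`, `order`, sorted by
#'   frequency.
#' @export
enumerate_ims <- function(f1, f2, max_order = 2L, tol = 1e-9) {
  if (f1 <= 0 || f2 <= 0) stop("fundamentals must be positive")
  if (abs(f1 - f2) < tol) stop("fundamentals must differ")
  if (max_order < 2L) stop("`max_order` must be >= 2")
  w <- seq(-max_order, max_order)
  grid <- expand.grid(n1 = w, n2 = w)
  grid <- grid[grid$n1 != 0 & grid$n2 != 0, ]
  grid$order <- abs(grid$n1) + abs(grid$n2)
  grid <- grid[grid$order <= max_order, ]
  grid$freq <- grid$n1 * f1 + grid$n2 * f2
  grid <- grid[grid$freq > tol, ]
  grid <- grid[order(grid$freq, grid$order, abs(grid$n1)), ]
  key <- round(grid$freq / tol) * tol
  dup <- duplicated(key)
  collisions <- grid[key %in% key[dup], ]
  out <- grid[!dup, c("n1", "n2", "freq", "order")]
  rownames(out) <- NULL
  attr(out, "collisions") <- collisions
  out
}

#' Harmonics of a fundamental up to a frequency limit
#' @param f fundamental in Hz.
#' @param fmax upper limit in Hz (e.g. the Nyquist frequency).
#' @return numeric vector `f, 2f, 3f, ...` up to `fmax`.
#' @export
harmonics_up_to <- function(f, fmax) f * seq_len(max(1L, floor(fmax / f)))

#' Frequencies protected from SNR neighbour means
#'
#' Harmonics of both fundamentals up to `fmax` plus intermodulation
#' components up to `im_order` (default 4): spectral lines that carry
#' stimulus-driven energy and would bias a noise estimate.
#'
#' @param f1,f2 fundamentals in Hz.
#' @param fmax upper frequency limit in Hz.
#' @param im_order maximum IM order to protect.
#' @return sorted numeric vector of protected frequencies.
#' @export
protected_freqs <- function(f1, f2, fmax, im_order = 4L) {
  ims <- enumerate_ims(f1, f2, im_order)
  sort(unique(c(harmonics_up_to(f1, fmax), harmonics_up_to(f2, fmax),
                ims$freq[ims$freq <= fmax])))
}

#' Sliding epochs for the coherence analysis
#'
#' Divides a trial into overlapping epochs of `epoch_len` seconds with a
#' `step`-second step, starting after the first SWIFT cycle (onset effects
#' are strongest there).  Every analysis frequency must complete an integer
#' number of cycles per epoch, so that it falls on an exact FFT bin.
#'
#' @param n_samples trial length in samples.
#' @param fs sampling rate in Hz.
#' @param schedule a `trial_schedule` (supplies the frequencies to check
#'   and the first-cycle duration).
#' @param epoch_len epoch length in seconds (5 for Experiment-1 designs, 10
#'   for Experiment-2).
#' @param step epoch step in seconds (default 1).
#' @param check_freqs extra frequencies that must fall on exact bins, in
#'   addition to the schedule's fundamentals (integer-weight combinations
#'   of exact-bin fundamentals are automatically exact).
#' @return data frame with columns `epoch`, `start_sample`, `start_time`.
#' @export
epoch_for_mspc <- function(n_samples, fs, schedule, epoch_len, step = 1,
                           check_freqs = numeric(0)) {
  stopifnot(inherits(schedule, "trial_schedule"))
  freqs <- c(swift_freqs(schedule), schedule$ssvep_freq, check_freqs)
  cyc <- freqs * epoch_len
  off <- abs(cyc - round(cyc)) > 1e-9
  if (any(off))
    stop(sprintf(
      "non-integer cycles per %g-s epoch for: %s Hz",
      epoch_len, paste(freqs[off], collapse = ", ")))
  t0 <- 1 / min(swift_freqs(schedule))     # drop the first SWIFT cycle
  t_end <- n_samples / fs
  if (t0 + epoch_len > t_end + 1e-9)
    stop("trial too short for one epoch after dropping the first cycle")
  onsets <- seq(t0, t_end - epoch_len + 1e-9, by = step)
  data.frame(epoch = seq_along(onsets),
             start_sample = round(onsets * fs) + 1L,
             start_time = onsets)
}

#' Select and window a trial segment for the full-trial FFT
#'
#' Experiment-1 trials vary in length: those with more than 17 s of data
#' are zero-padded to 20 s (0.05 Hz bins); those with 10-17 s use their
#' first 10 s (0.1 Hz bins); shorter trials are rejected with a reason.
#' Experiment-2 trials use the fixed 3-28 s window (25 s, 0.04 Hz bins,
#' 12500 samples at 500 Hz).
#'
#' @param x numeric vector (one channel) or channels x samples matrix.
#' @param fs sampling rate in Hz (default 500).
#' @param mode `"exp1"` or `"exp2"`.
#' @return list with `ok`; when `ok`, also `data` (possibly zero-padded),
#'   `n_used` (samples of real data), `bin_width` (Hz); otherwise `reason`.
#' @export
trial_fft_window <- function(x, fs = 500, mode = c("exp1", "exp2")) {
  mode <- match.arg(mode)
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  dur <- ncol(x) / fs
  if (mode == "exp2") {
    if (dur < 28)
      return(list(ok = FALSE,
                  reason = sprintf("trial %.1f s < 28 s window end", dur)))
    idx <- (round(3 * fs) + 1L):round(28 * fs)
    return(list(ok = TRUE, data = x[, idx, drop = FALSE],
                n_used = length(idx), bin_width = 1 / 25))
  }
  if (dur < 10)
    return(list(ok = FALSE,
                reason = sprintf("trial %.1f s < 10 s minimum", dur)))
  if (dur > 17) {
    pad <- matrix(0, nrow(x), round(20 * fs))
    keep <- min(ncol(x), ncol(pad))
    pad[, seq_len(keep)] <- x[, seq_len(keep)]
    list(ok = TRUE, data = pad, n_used = keep, bin_width = 1 / 20)
  } else {
    idx <- seq_len(round(10 * fs))
    list(ok = TRUE, data = x[, idx, drop = FALSE],
         n_used = length(idx), bin_width = 1 / 10)
  }
}

#' Fourier coefficients at exact-bin frequencies
#'
#' Rectangular window (every analysis frequency lies on an exact bin, so a
#' taper would only leak tagged energy).  Amplitude is `2|X(f)|/N`, the
#' peak amplitude of the corresponding cosine; phase is `Arg X(f)`, which
#' for an exact-bin cosine equals its phase at the segment start.
#'
#' @param segment numeric vector.
#' @param fs sampling rate in Hz.
#' @param freqs frequencies in Hz; each must sit on an FFT bin of
#'   `length(segment)` within `tol`.
#' @param tol bin tolerance in Hz (default 1e-9).
#' @return data frame with columns `freq`, `amplitude`, `phase`.
#' @export
fft_coeffs <- function(segment, fs, freqs, tol = 1e-9) {
  n <- length(segment)
  bin <- fs / n
  k <- freqs / bin
  off <- abs(k - round(k)) * bin > tol
  if (any(off))
    stop(sprintf("frequencies not on exact %g-Hz bins: %s",
                 bin, paste(freqs[off], collapse = ", ")))
  X <- stats::fft(segment)
  idx <- round(k) + 1L
  data.frame(freq = freqs,
             amplitude = 2 * Mod(X[idx]) / n,
             phase = Arg(X[idx]))
}

#' Full one-sided amplitude spectrum
#'
#' @param segment numeric vector.
#' @param fs sampling rate in Hz.
#' @return data frame with columns `freq`, `amplitude` (`2|X|/N`), up to
#'   the Nyquist frequency.
#' @export
amplitude_spectrum <- function(segment, fs) {
  n <- length(segment)
  X <- stats::fft(segment)
  half <- floor(n / 2)
  data.frame(freq = (0:half) / n * fs,
             amplitude = 2 * Mod(X[seq_len(half + 1)]) / n)
}

#' Amplitude signal-to-noise ratio at a frequency
#'
#' The amplitude at `f` divided by the arithmetic mean amplitude over the
#' `n_side` neighbouring bins on each side, excluding any bin that carries
#' a protected (harmonic or intermodulation) frequency.
#'
#' @param spectrum data frame from [amplitude_spectrum()] (or any with
#'   `freq`, `amplitude` on a regular bin grid).
#' @param f target frequency in Hz (must be a bin).
#' @param n_side neighbours per side: 4 for 10-s windows (+/- 0.4 Hz), 8
#'   for the 25-s window (+/- 0.32 Hz).
#' @param protected numeric vector of protected frequencies.
#' @return list with `snr`, `n_neighbours` used, and `flagged` (`TRUE` when
#'   all neighbours were protected or the neighbour mean was zero).
#' @export
amplitude_snr <- function(spectrum, f, n_side, protected = numeric(0)) {
  bin <- spectrum$freq[2] - spectrum$freq[1]
  k0 <- which.min(abs(spectrum$freq - f))
  if (abs(spectrum$freq[k0] - f) > 1e-6)
    stop(sprintf("%g Hz is not a bin of this spectrum", f))
  nb <- c(k0 - seq_len(n_side), k0 + seq_len(n_side))
  nb <- nb[nb >= 1 & nb <= nrow(spectrum)]
  if (length(protected)) {
    is_prot <- vapply(spectrum$freq[nb], function(fr)
      any(abs(protected - fr) < bin / 2), logical(1))
    nb <- nb[!is_prot]
  }
  if (!length(nb))
    return(list(snr = NA_real_, n_neighbours = 0L, flagged = TRUE))
  m <- mean(spectrum$amplitude[nb])
  if (m == 0)
    return(list(snr = Inf, n_neighbours = length(nb), flagged = TRUE))
  list(snr = spectrum$amplitude[k0] / m, n_neighbours = length(nb),
       flagged = FALSE)
}
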