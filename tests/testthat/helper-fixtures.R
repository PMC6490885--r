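# Shared fixtures, built in code at test time.

# deterministic structured 64x64 test image in [0, 1]: a bright blob on a
# gradient, enough low- and high-frequency content to exercise scrambling
test_image <- function(n = 64) {
  g <- outer(seq(0, 1, length.out = n), seq(0, 1, length.out = n),
             function(a, b) 0.3 * a + 0.2 * b)
  blob <- outer(seq_len(n), seq_len(n), function(i, j)
    exp(-((i - n / 3)^2 + (j - n / 2)^2) / (2 * (n / 8)^2)))
  edges <- outer(seq_len(n), seq_len(n), function(i, j)
    0.15 * ((i + j) %% 8 < 4))
  x <- g + 0.4 * blob + edges
  (x - min(x)) / (max(x) - min(x))
}

# standard Experiment-1 style schedule used across tests
exp1_sched <- function(n_cycles = 36, f1 = 1.2, f2 = 15) {
  build_exp1_schedule("FHHFFH", "PV", n_cycles = n_cycles,
                      violation_index = n_cycles - 2L,
                      swift_freq = f1, ssvep_freq = f2)
}

# per-location wavelet detail-vector norms of an image
detail_norms <- function(img, levels = 6L) {
  w <- wavedec2(img, levels)
  unlist(lapply(w$detail, function(d)
    sqrt(as.vector(d$lh^2 + d$hl^2 + d$hh^2))))
}

# independent naive MSPC: explicit loop over epochs, no vectorisation
mspc_naive <- function(input_phases, output_phases, weights) {
  if (is.null(dim(input_phases))) input_phases <- cbind(input_phases)
  acc <- 0 + 0i
  for (k in seq_len(nrow(input_phases))) {
    s <- 0
    for (r in seq_along(weights))
      s <- s + weights[r] * input_phases[k, r]
    acc <- acc + exp(1i * (s - output_phases[k]))
  }
  Mod(acc / nrow(input_phases))
}

# independent naive noisy-sample flagger: per-sample loop over the three
# criteria, then per-cycle and per-channel recounts
flag_noise_naive <- function(data, starts, ends,
                             amp = 80, jump = 30, nsd = 5) {
  nch <- nrow(data); n <- ncol(data)
  mask <- matrix(FALSE, nch, n)
  for (ch in seq_len(nch)) {
    mu <- mean(data[ch, ]); sdv <- stats::sd(data[ch, ])
    for (s in seq_len(n)) {
      v <- data[ch, s]
      bad <- (v > amp) || (v < -amp) || (abs(v - mu) > nsd * sdv)
      if (s > 1 && abs(v - data[ch, s - 1]) > jump) bad <- TRUE
      mask[ch, s] <- bad
    }
  }
  cyc_noisy <- matrix(FALSE, nch, length(starts))
  for (ch in seq_len(nch))
    for (k in seq_along(starts)) {
      seg <- mask[ch, starts[k]:ends[k]]
      cyc_noisy[ch, k] <- mean(seg) > 0.02
    }
  list(mask = mask, cyc_noisy = cyc_noisy,
       bad_channel = rowMeans(cyc_noisy) > 0.10)
}
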