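test_that("second-order intermodulation frequencies match the designs", {
  im1 <- enumerate_ims(1.2, 15, 2)
  expect_equal(sort(im1$freq), c(13.8, 16.2))
  im2 <- enumerate_ims(1, 12, 2)
  expect_equal(sort(im2$freq), c(11, 13))
  im2b <- enumerate_ims(0.8, 12, 2)
  expect_equal(sort(im2b$freq), c(11.2, 12.8))
  im3 <- enumerate_ims(1.2, 15, 3)
  expect_true(any(abs(im3$freq - 17.4) < 1e-9 & im3$n1 == 2 & im3$n2 == 1))
  expect_error(enumerate_ims(1.2, 1.2, 2), "differ")
  expect_error(enumerate_ims(1.2, 15, 1), "max_order")
})

test_that("enumeration agrees with a brute-force double loop", {
  set.seed(41)
  for (case in 1:25) {
    f1 <- round(runif(1, 0.5, 3), 2)
    f2 <- round(runif(1, 5, 20), 2)
    if (abs(f1 - f2) < 0.01) next
    mo <- sample(2:4, 1)
    got <- enumerate_ims(f1, f2, mo)
    want <- list()
    for (n1 in setdiff(-mo:mo, 0)) for (n2 in setdiff(-mo:mo, 0)) {
      if (abs(n1) + abs(n2) > mo) next
      f <- n1 * f1 + n2 * f2
      if (f > 1e-9) want[[length(want) + 1]] <- f
    }
    expect_equal(sort(got$freq), sort(unique(round(unlist(want), 9))),
                 tolerance = 1e-9)
  }
})

test_that("frequency collisions are reported, not dropped", {
  # f2 = 3 * f1 makes 2f1 + f2 coincide with -f1 + 2f2 ... several collide
  im <- enumerate_ims(5, 15, 4)
  col <- attr(im, "collisions")
  expect_gt(nrow(col), 0)
  expect_false(any(duplicated(round(im$freq, 9))))
  # the retained representative has the lowest order of its collision group
  for (f in unique(round(col$freq, 9))) {
    kept <- im[abs(im$freq - f) < 1e-9, ]
    expect_lte(kept$order, min(col$order[abs(col$freq - f) < 1e-9]))
  }
})

test_that("epoching enforces exact bins and drops the first cycle", {
  sched <- build_exp2_schedule(rng_seed = 1)   # 31.5 s, 0.8/1 Hz, 12 Hz
  ep <- epoch_for_mspc(31.5 * 500, 500, sched, epoch_len = 10, step = 1)
  expect_identical(nrow(ep), 21L)
  expect_equal(ep$start_time[1], 1.25)   # first 0.8 Hz cycle dropped
  expect_equal(diff(ep$start_time), rep(1, 20))
  # a 0.9 Hz stream cannot complete integer cycles in 5 s
  bad <- build_exp1_schedule("FHHFFH", "PV", 27, 25, swift_freq = 0.9)
  expect_error(epoch_for_mspc(30 * 500, 500, bad, epoch_len = 5), "0.9")
  # 5 s x 1.2 Hz = 6 cycles: accepted
  ok <- exp1_sched(36)
  expect_silent(epoch_for_mspc(30 * 500, 500, ok, epoch_len = 5))
})

test_that("trial windows implement the length-dependent FFT rules", {
  fs <- 500
  w18 <- trial_fft_window(rnorm(18 * fs), fs, "exp1")
  expect_true(w18$ok)
  expect_identical(ncol(w18$data), as.integer(20 * fs))   # padded to 20 s
  expect_equal(w18$bin_width, 0.05)
  expect_identical(w18$n_used, as.integer(18 * fs))

  w12 <- trial_fft_window(rnorm(12 * fs), fs, "exp1")
  expect_identical(ncol(w12$data), as.integer(10 * fs))   # first 10 s
  expect_equal(w12$bin_width, 0.1)

  w8 <- trial_fft_window(rnorm(8 * fs), fs, "exp1")
  expect_false(w8$ok)
  expect_match(w8$reason, "minimum")

  w2 <- trial_fft_window(matrix(rnorm(2 * 31.5 * fs), 2), fs, "exp2")
  expect_identical(ncol(w2$data), 12500L)                 # 3-28 s window
  expect_equal(w2$bin_width, 0.04)
})

test_that("exact-bin Fourier coefficients recover amplitude and phase", {
  fs <- 500
  t <- (0:(10 * fs - 1)) / fs
  co <- fft_coeffs(3 * cos(2 * pi * 13.8 * t), fs, 13.8)
  expect_equal(co$amplitude, 3, tolerance = 1e-9)
  expect_equal(co$phase, 0, tolerance = 1e-9)
  si <- fft_coeffs(sin(2 * pi * 1.2 * t), fs, 1.2)
  expect_equal(si$phase, -pi / 2, tolerance = 1e-9)
  # linearity: two tagged cosines recovered independently
  x <- 2 * cos(2 * pi * 1.2 * t + 0.7) + 0.5 * cos(2 * pi * 15 * t - 1.1)
  both <- fft_coeffs(x, fs, c(1.2, 15))
  expect_equal(both$amplitude, c(2, 0.5), tolerance = 1e-9)
  expect_equal(both$phase, c(0.7, -1.1), tolerance = 1e-9)
  expect_error(fft_coeffs(x, fs, 1.25), "exact")
})

test_that("amplitude convention satisfies Parseval for tagged tones", {
  fs <- 500
  t <- (0:(10 * fs - 1)) / fs
  amps <- c(2, 0.5, 1.3)
  freqs <- c(1.2, 13.8, 15)
  x <- amps[1] * cos(2 * pi * freqs[1] * t + 0.4) +
    amps[2] * cos(2 * pi * freqs[2] * t - 1) +
    amps[3] * cos(2 * pi * freqs[3] * t + 2)
  co <- fft_coeffs(x, fs, freqs)
  # mean power of a sum of cosines is sum(A^2)/2
  expect_equal(sum(co$amplitude^2) / 2, mean(x^2), tolerance = 1e-6)
  sp <- amplitude_spectrum(x, fs)
  expect_equal(sum(sp$amplitude^2) / 2, mean(x^2), tolerance = 1e-6)
})

test_that("amplitude SNR excludes protected neighbours", {
  bins <- seq(0, 30, by = 0.04)
  flat <- data.frame(freq = bins, amplitude = rep(2, length(bins)))
  expect_equal(amplitude_snr(flat, 12, 8)$snr, 1)
  # one protected harmonic inside the window: mean over remaining 15 bins
  sp <- flat
  sp$amplitude[abs(sp$freq - 12) < 1e-9] <- 10
  sp$amplitude[abs(sp$freq - 12.2) < 1e-9] <- 50
  res <- amplitude_snr(sp, 12, 8, protected = 12.2)
  expect_identical(res$n_neighbours, 15L)
  expect_equal(res$snr, 5)
  # scale invariance
  sp2 <- sp; sp2$amplitude <- sp2$amplitude * 7
  expect_equal(amplitude_snr(sp2, 12, 8, protected = 12.2)$snr, res$snr)
  # degenerate cases are flagged
  allp <- amplitude_snr(sp, 12, 8, protected = bins)
  expect_true(allp$flagged)
  zero <- data.frame(freq = bins, amplitude = c(rep(0, 300), 1,
                                                rep(0, length(bins) - 301)))
  z <- amplitude_snr(zero, zero$freq[301], 4)
  expect_true(z$flagged)
  expect_identical(z$snr, Inf)
})

test_that("protected set spans harmonics and low-order intermodulations", {
  pr <- protected_freqs(1.2, 15, 125)
  expect_true(all(c(1.2, 2.4, 15, 30, 13.8, 16.2, 17.4, 27.6) %in%
                    round(pr, 9)))
  expect_true(all(pr <= 125))
})
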