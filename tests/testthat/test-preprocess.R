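test_that("standardize resamples, removes drift and re-references", {
  set.seed(31)
  fs <- 1000
  x <- matrix(rnorm(4 * fs * 20), 4, fs * 20) + c(50, -20, 5, 0)
  rec <- eeg_recording(x, fs, c("Oz", "O1", "O2", "POz"),
                       events = data.frame(sample = 1001L, label = "go"))
  out <- standardize(rec)
  expect_identical(out$fs, 500)
  expect_lt(max(abs(colMeans(out$data))), 1e-9)
  expect_lt(max(abs(rowMeans(out$data))), 1e-6)      # offsets removed
  expect_identical(out$events$sample, 501L)           # events remapped
  expect_error(standardize(eeg_recording(x[, 1:100], 250, rec$channel_labels)),
               "refused")
})

test_that("standardization is idempotent", {
  set.seed(32)
  rec <- eeg_recording(matrix(rnorm(3 * 5000), 3, 5000), 500,
                       c("Oz", "O1", "O2"))
  once <- standardize(rec)
  twice <- standardize(once)
  expect_lt(max(abs(twice$data - once$data)), 1e-9)
})

test_that("high-pass response meets the attenuation contract", {
  fs <- 500
  t <- (0:(fs * 40 - 1)) / fs
  # opposite-sign pairs keep the average reference from touching the signal
  rec <- eeg_recording(rbind(10 * sin(2 * pi * 0.05 * t),
                             -10 * sin(2 * pi * 0.05 * t),
                             10 * sin(2 * pi * 15 * t),
                             -10 * sin(2 * pi * 15 * t)),
                       fs, c("a", "b", "c", "d"),
                       channel_positions = diag(4)[, c(1, 2, 3)])
  out <- standardize(rec)
  att_db <- function(ch) 20 * log10(
    sqrt(mean(out$data[ch, ]^2)) / sqrt(mean(rec$data[ch, ]^2)))
  expect_lt(att_db(1), -20)     # 0.05 Hz strongly attenuated
  expect_gt(att_db(3), -0.5)    # 15 Hz essentially untouched
})

test_that("noisy samples, cycles and channels follow the stated thresholds", {
  set.seed(33)
  rec <- eeg_recording(matrix(rnorm(2 * 4170, sd = 2), 2, 4170), 500,
                       c("Oz", "O1"))
  grid <- seq(1, 4170, by = 417)   # ten 1.2 Hz cycles at 500 Hz

  expect_false(any(flag_noise(
    eeg_recording(matrix(0.001 * sin(1:8340 / 50), 2, 4170), 500,
                  c("Oz", "O1")), grid)$noisy_sample_mask))

  one <- flag_noise(inject_artifacts(rec, data.frame(
    channel = 1, sample = 100, kind = "spike80")), grid)
  nc <- one$noisy_cycles
  # a single spike flags ~2/417 samples: under the 2% cycle threshold
  expect_false(any(nc$noisy[nc$channel == "Oz"]))

  many <- rec
  for (k in 1:10)
    many <- inject_artifacts(many, data.frame(channel = 1,
                                              sample = 10 + 4 * k,
                                              kind = "spike80"))
  rep10 <- flag_noise(many, grid)
  nc10 <- rep10$noisy_cycles
  expect_true(nc10$noisy[nc10$channel == "Oz" & nc10$cycle == 1])
  expect_false(any(nc10$noisy[nc10$channel == "Oz" & nc10$cycle > 1]))
  # 1 of 10 cycles noisy: channel not yet bad; over 10% flips it
  expect_identical(rep10$bad_channels, character(0))
  expect_error(flag_noise(rec, integer(0)), "empty")
})

test_that("flag_noise matches an independent per-sample recount", {
  set.seed(34)
  for (case in 1:60) {
    n <- 5 * 100
    rec <- eeg_recording(matrix(rnorm(2 * n, sd = runif(1, 1, 30)), 2, n),
                         500, c("Oz", "O1"))
    n_art <- sample(0:5, 1)
    if (n_art > 0)
      rec <- inject_artifacts(rec, data.frame(
        channel = sample(2, n_art, TRUE),
        sample = sample(10:(n - 10), n_art),
        kind = sample(c("spike80", "jump30", "drift"), n_art, TRUE)))
    starts <- seq(1, n, by = 100)
    ends <- c(starts[-1] - 1, n)
    got <- flag_noise(rec, cbind(starts, ends))
    want <- flag_noise_naive(rec$data, starts, ends)
    expect_identical(got$noisy_sample_mask, want$mask)
    expect_identical(matrix(got$noisy_cycles$noisy, nrow = 2),
                     want$cyc_noisy)
    expect_identical(got$channel_noisy_frac > 0.10,
                     setNames(want$bad_channel, c("Oz", "O1")))
  }
})

test_that("adding artifacts never decreases the noisy-sample count", {
  set.seed(35)
  rec <- eeg_recording(matrix(rnorm(2 * 1000, sd = 3), 2, 1000), 500,
                       c("Oz", "O1"))
  grid <- seq(1, 1000, by = 100)
  base <- sum(flag_noise(rec, grid)$noisy_sample_mask)
  for (k in 1:10) {
    rec <- inject_artifacts(rec, data.frame(
      channel = sample(2, 1), sample = sample(20:980, 1),
      kind = sample(c("spike80", "jump30"), 1)))
    now <- sum(flag_noise(rec, grid)$noisy_sample_mask)
    expect_gte(now, base)
    base <- now
  }
})

test_that("bad channels are replaced by convex neighbour combinations", {
  labels <- c("Oz", "O1", "O2", "POz", "PO3", "PO4")
  set.seed(36)
  sig <- sin(seq(0, 20, length.out = 1000))
  # identical good neighbours: interpolation must reproduce the signal
  same <- eeg_recording(rbind(rnorm(1000), sig, sig, sig, sig, sig),
                        500, labels)
  fixed <- interpolate_bad_channels(same, "Oz")
  expect_equal(fixed$data[1, ], sig, tolerance = 1e-12)
  # generic signals: pointwise convex combination of the k neighbours
  rec <- eeg_recording(matrix(rnorm(6 * 500), 6, 500), 500, labels)
  out <- interpolate_bad_channels(rec, "POz", k = 4)
  others <- rec$data[-4, ]
  expect_true(all(out$data[4, ] <= apply(others, 2, max) + 1e-12))
  expect_true(all(out$data[4, ] >= apply(others, 2, min) - 1e-12))
  expect_identical(interpolate_bad_channels(rec, character(0)), rec)
  expect_error(interpolate_bad_channels(rec, labels[1:4]), "50%")
})

test_that("exclusion rules match the stated thresholds", {
  # trial with 7/64 bad channels (10.9%) excluded; 6/64 (9.4%) kept
  tr <- data.frame(participant = "P01", trial = 1:2, n_channels = 64,
                   n_bad_channels = c(7, 6),
                   reported = c(20, 20), true_count = c(20, 20))
  ex <- apply_exclusions(tr, "exp2")
  expect_identical(ex$trials$bad_trial, c(TRUE, FALSE))
  # count off by 3 valid, by 4 invalid
  tr2 <- data.frame(participant = "P01", trial = 1:2, n_channels = 64,
                    n_bad_channels = 0, reported = c(23, 24),
                    true_count = 20)
  expect_identical(apply_exclusions(tr2, "exp2")$trials$invalid_response,
                   c(FALSE, TRUE))
  # participant with 21% bad trials excluded for EEG quality
  tr3 <- data.frame(participant = "P02", trial = 1:100, n_channels = 10,
                    n_bad_channels = c(rep(2, 21), rep(0, 79)),
                    reported = 20, true_count = 20)
  expect_true(apply_exclusions(tr3, "exp2")$participants$excluded_eeg)
  # press before target, or never, is invalid
  tr4 <- data.frame(participant = "P03", trial = 1:3, n_channels = 10,
                    n_bad_channels = 0,
                    pressed = c(TRUE, TRUE, FALSE),
                    press_time = c(15, 10, NA), target_time = 14)
  expect_identical(apply_exclusions(tr4, "exp1")$trials$invalid_response,
                   c(FALSE, TRUE, TRUE))
  # 2/3 invalid responses > 30%: excluded behaviourally
  expect_true(apply_exclusions(tr4, "exp1")$participants$excluded_behaviour)
})
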